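# ---------------------------------------------------------------------------
# Basis-strategy utilities.
#
# Six simple strategies each score the four joystick directions from a
# restricted feature set.  The path-based strategies (local, evade x2,
# approach, energizer) score every non-reversing depth-10 path from Pac-Man
# and average path utilities within each first-step direction; the global
# strategy counts pellets in the strict half-plane of each direction.
# Unavailable directions carry -Inf.
# ---------------------------------------------------------------------------

#' Basis strategies
#'
#' The six basis strategies in their fixed vectorization order.
#'
#' @format Character vector: `local`, `global`, `evade_blinky`,
#'   `evade_clyde`, `approach`, `energizer`.
#' @export
STRATEGIES <- c("local", "global", "evade_blinky", "evade_clyde",
                "approach", "energizer")

#' Utility parameters of the basis strategies
#'
#' Per-item utility units used by the path-based strategies.  Pellets are
#' worth one unit and energizers two (the units of the local-reward
#' analyses); fruit and ghosts are expressed on the same scale as juice
#' drops divided by two (one pellet = two drops = one unit), and the evade
#' penalty mirrors the ghost reward with a negative sign.  The per-trial
#' normalization applied before fitting makes the fits insensitive to the
#' overall scale of any one strategy, which is why these defaults are safe
#' reimplementation choices.
#'
#' @param pellet,energizer Units per pellet / energizer.
#' @param fruit Either a named vector of units per fruit kind or a single
#'   number applied to any fruit.
#' @param ghost Units awarded by the approach strategy for a ghost on the
#'   path.
#' @param penalty Negative units for a normal-mode ghost on the path (evade
#'   strategies).
#' @param local_depth Path depth in steps for the path-based strategies.
#' @param fruit_unit If `TRUE`, fruit counts with unit weight instead of its
#'   magnitude.
#' @param simple_paths If `TRUE`, enumerate simple (non-revisiting) paths
#'   instead of non-reversing walks.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(pellet = 1, energizer = 2,
                           fruit = c(cherry = 1.5, strawberry = 2.5,
                                     orange = 4, apple = 6, melon = 8.5),
                           ghost = 4, penalty = -4,
                           local_depth = 10L,
                           fruit_unit = FALSE,
                           simple_paths = FALSE) {
  stopifnot(penalty < 0, pellet >= 0, energizer >= 0, ghost >= 0)
  structure(list(pellet = pellet, energizer = energizer, fruit = fruit,
                 ghost = ghost, penalty = penalty,
                 local_depth = as.integer(local_depth),
                 fruit_unit = isTRUE(fruit_unit),
                 simple_paths = isTRUE(simple_paths)),
            class = "utility_params")
}

# flattened path structure for fast per-step membership sums: for each
# direction, the unique tiles of every path as (tile index, path id) pairs
# plus per-path lengths; cached on the maze alongside the path sets
.path_flat <- function(maze, paths) {
  key <- paste0("flat:", paths$start, ":", paths$depth)
  cache <- maze$cache
  if (is.null(cache$paths)) cache$paths <- new.env(parent = emptyenv())
  hit <- cache$paths[[key]]
  if (!is.null(hit)) return(hit)
  out <- lapply(paths$dirs, function(M) {
    uniq <- lapply(seq_len(nrow(M)), function(i) unique(M[i, !is.na(M[i, ])]))
    list(idx = unlist(uniq),
         pid = rep.int(seq_along(uniq), lengths(uniq)),
         npaths = nrow(M))
  })
  cache$paths[[key]] <- out
  out
}

# mean over paths per direction of the sum of `val` over each path's unique
# tiles; named 4-vector with -Inf on unavailable directions
.path_mean_utility <- function(maze, paths, val) {
  flat <- .path_flat(maze, paths)
  u <- stats::setNames(rep(-Inf, 4L), DIRECTIONS)
  for (d in names(flat)) {
    f <- flat[[d]]
    sums <- rep(0, f$npaths)
    if (length(f$idx) > 0L) {
      agg <- rowsum(val[f$idx], f$pid)
      sums[as.integer(rownames(agg))] <- agg[, 1L]
    }
    u[[d]] <- mean(sums)
  }
  u
}

# per-fruit utility units under the configured convention
.fruit_value <- function(params, kind) {
  if (params$fruit_unit) 1
  else if (length(params$fruit) == 1L && is.null(names(params$fruit))) params$fruit
  else params$fruit[[kind]]
}

#' Basis-strategy utility vectors for one game state
#'
#' Each function scores the four directions for a single strategy;
#' [state_utilities()] assembles the full 6 x 4 utility matrix.  The
#' path-based strategies average, over all enumerated paths of a direction,
#' the summed item utilities on each path (an item tile is counted once per
#' path); evade utilities are a single penalty when the respective ghost is
#' in normal mode and sits on the path; the approach utility awards the
#' ghost unit regardless of mode; the global strategy counts the pellets in
#' the strict half-plane of each direction (Pac-Man's own row and column
#' belong to neither side).  Unavailable directions score `-Inf`.
#'
#' @param paths A `path_set` from [enumerate_paths()] at the configured
#'   depth.
#' @param state A `game_state`.
#' @param maze A `maze_graph`.
#' @param which_ghost `"blinky"` or `"clyde"`.
#' @param params A [utility_params()].
#' @return A named 4-vector of utilities over [DIRECTIONS] (for
#'   [state_utilities()], a 6 x 4 matrix with strategies as rows).
#' @export
local_utility <- function(paths, state, maze, params = utility_params()) {
  val <- numeric(maze$n)
  val[state$pellets] <- params$pellet
  val[state$energizers] <- params$energizer
  if (!is.null(state$fruit)) val[state$fruit$pos] <- .fruit_value(params, state$fruit$kind)
  .path_mean_utility(maze, paths, val)
}

#' @rdname local_utility
#' @export
energizer_utility <- function(paths, state, maze, params = utility_params()) {
  val <- numeric(maze$n)
  val[state$energizers] <- params$energizer
  .path_mean_utility(maze, paths, val)
}

#' @rdname local_utility
#' @export
evade_utility <- function(paths, state, maze, which_ghost,
                          params = utility_params()) {
  g <- state$ghosts[[which_ghost]]
  val <- numeric(maze$n)
  if (g$mode == "normal") val[g$pos] <- 1
  flat <- .path_flat(maze, paths)
  u <- stats::setNames(rep(-Inf, 4L), DIRECTIONS)
  for (d in names(flat)) {
    f <- flat[[d]]
    on_path <- rep(FALSE, f$npaths)
    if (g$mode == "normal") on_path[unique(f$pid[f$idx == g$pos])] <- TRUE
    u[[d]] <- mean(ifelse(on_path, params$penalty, 0))
  }
  u
}

#' @rdname local_utility
#' @export
approach_utility <- function(paths, state, maze, params = utility_params()) {
  flat <- .path_flat(maze, paths)
  gpos <- vapply(state$ghosts, function(g) g$pos, integer(1))
  u <- stats::setNames(rep(-Inf, 4L), DIRECTIONS)
  for (d in names(flat)) {
    f <- flat[[d]]
    sums <- rep(0, f$npaths)
    for (gp in gpos) {
      hit <- unique(f$pid[f$idx == gp])
      sums[hit] <- sums[hit] + params$ghost
    }
    u[[d]] <- mean(sums)
  }
  u
}

#' @rdname local_utility
#' @export
global_utility <- function(maze, state) {
  u <- stats::setNames(rep(-Inf, 4L), DIRECTIONS)
  avail <- available_directions(maze, state$pacman)
  p <- tile_pos(maze, state$pacman)
  pe <- tile_pos(maze, state$pellets)
  counts <- c(left = sum(pe$col < p$col), right = sum(pe$col > p$col),
              up = sum(pe$row < p$row), down = sum(pe$row > p$row))
  u[avail] <- counts[avail]
  u
}

#' @rdname local_utility
#' @export
state_utilities <- function(state, maze, params = utility_params()) {
  paths <- enumerate_paths(maze, state$pacman, depth = params$local_depth,
                           simple_only = params$simple_paths)
  rbind(
    local = local_utility(paths, state, maze, params),
    global = global_utility(maze, state),
    evade_blinky = evade_utility(paths, state, maze, "blinky", params),
    evade_clyde = evade_utility(paths, state, maze, "clyde", params),
    approach = approach_utility(paths, state, maze, params),
    energizer = energizer_utility(paths, state, maze, params)
  )
}

#' Shift evade utilities to their within-trial worst case
#'
#' The evade utilities are nonpositive; within each trial (round) they are
#' re-expressed as the difference to the worst value observed in that trial,
#' so that finite outputs are nonnegative.  `-Inf` entries (unavailable
#' directions) are preserved.
#'
#' @param series A steps x 4 matrix of one evade strategy's utilities.
#' @param rounds Integer vector (one entry per step) giving the trial each
#'   step belongs to.
#' @return The shifted matrix.
#' @export
preprocess_evade <- function(series, rounds) {
  stopifnot(nrow(series) == length(rounds))
  for (r in unique(rounds)) {
    sel <- rounds == r
    block <- series[sel, , drop = FALSE]
    fin <- is.finite(block)
    if (!any(fin)) stop("trial ", r, " has no finite evade utilities")
    m <- min(block[fin])
    block[fin] <- block[fin] - m
    series[sel, ] <- block
  }
  series
}

#' Normalize utilities within each strategy and trial
#'
#' Divides each strategy's utilities by the maximal finite value observed in
#' the trial, mapping finite entries into [0, 1].  A strategy whose maximum
#' is not positive in a trial (after the evade shift) is uninformative there
#' and its finite entries are set to 0 rather than divided.  `-Inf` entries
#' are preserved.  The operation is idempotent.
#'
#' @param tensor A steps x 6 x 4 array of raw utilities (evade strategies
#'   already shifted by [preprocess_evade()]).
#' @param rounds Integer vector of trial ids, one per step.
#' @return The normalized array.
#' @export
normalize_utilities <- function(tensor, rounds) {
  stopifnot(dim(tensor)[1] == length(rounds), dim(tensor)[2] == length(STRATEGIES))
  for (r in unique(rounds)) {
    sel <- which(rounds == r)
    for (a in seq_along(STRATEGIES)) {
      block <- tensor[sel, a, , drop = FALSE]
      fin <- is.finite(block)
      if (!any(fin)) next
      mx <- max(block[fin])
      block[fin] <- if (mx > 0) block[fin] / mx else 0
      tensor[sel, a, ] <- block
    }
  }
  tensor
}

#' Compute the full utility tensor of a behavior log
#'
#' Evaluates the six basis-strategy utilities at every recorded step, applies
#' the evade worst-case shift and the per-trial normalization, and returns
#' everything the mixture model needs: raw and normalized steps x 6 x 4
#' arrays, the per-step availability mask, trial (round) ids, and the chosen
#' actions.
#'
#' @param log A `behavior_log`.
#' @param maze The `maze_graph` the log was recorded on.
#' @param params A [utility_params()].
#' @return An object of class `utility_tensor`.
#' @export
compute_utilities <- function(log, maze, params = utility_params()) {
  n <- length(log$records)
  raw <- array(NA_real_, dim = c(n, length(STRATEGIES), 4L),
               dimnames = list(NULL, STRATEGIES, DIRECTIONS))
  for (i in seq_len(n)) {
    raw[i, , ] <- state_utilities(log$records[[i]]$state, maze, params)
  }
  rounds <- log_rounds(log)
  shifted <- raw
  for (a in c("evade_blinky", "evade_clyde")) {
    shifted[, a, ] <- preprocess_evade(matrix(shifted[, a, ], ncol = 4L), rounds)
  }
  norm <- normalize_utilities(shifted, rounds)
  structure(list(
    raw = raw, norm = norm,
    available = matrix(is.finite(raw[, 1L, ]), ncol = 4L,
                       dimnames = list(NULL, DIRECTIONS)),
    rounds = rounds,
    actions = log_actions(log),
    params = params,
    n_steps = n
  ), class = "utility_tensor")
}

#' @export
print.utility_tensor <- function(x, ...) {
  cat(sprintf("<utility_tensor> %d steps x %d strategies x 4 directions, %d round(s)\n",
              x$n_steps, length(STRATEGIES), length(unique(x$rounds))))
  invisible(x)
}

#' Export a utility tensor as a tidy table
#'
#' @param x A `utility_tensor`.
#' @param ... Unused.
#' @return A data frame with one row per (step, strategy, direction):
#'   `time_step`, `strategy`, `direction`, `raw`, `norm`.
#' @export
as.data.frame.utility_tensor <- function(x, ...) {
  grid <- expand.grid(time_step = seq_len(x$n_steps) - 1L,
                      strategy = STRATEGIES, direction = DIRECTIONS,
                      stringsAsFactors = FALSE)
  grid$raw <- as.vector(x$raw)
  grid$norm <- as.vector(x$norm)
  grid
}
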