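# ---------------------------------------------------------------------------
# Analyses downstream of the fitted weights: strategy labels, game contexts,
# dominance statistics, choice curves, global-path optimality, and
# compound-strategy event detection.
# ---------------------------------------------------------------------------

#' Strategy label of a weight vector
#'
#' The dominant strategy, or `"vague"` when the gap between the largest and
#' second-largest normalized weights is strictly less than 0.1 (a gap of
#' exactly 0.1 keeps the argmax label).
#'
#' @param w Strategy weight vector (normalized or not; labels are
#'   scale-free).
#' @return A single label: one of [STRATEGIES] or `"vague"`.
#' @export
label_strategy <- function(w) {
  w <- normalize_weights(w)
  o <- order(w, decreasing = TRUE)
  gap <- w[o[1L]] - w[o[2L]]
  # strict rule with a float guard: a gap of exactly 0.1 keeps the argmax
  if (gap + 1e-9 < 0.1) "vague" else STRATEGIES[o[1L]]
}

#' Per-step strategy labels of a fit
#'
#' @param fit A `strategy_fit`.
#' @return Character vector of labels, one per step.
#' @export
label_steps <- function(fit) {
  apply(fit$weights_step, 1L, label_strategy)
}

#' Game context of a state
#'
#' Contexts are mutually exclusive with precedence scared > early/late >
#' other: `scared` when a scared (or flashing) ghost is within 10 tiles of
#' Pac-Man, `early` when more than 90% of the initial pellets remain,
#' `late` when fewer than 10% remain, `other` otherwise.
#'
#' @param state A `game_state`.
#' @param maze A `maze_graph`.
#' @param initial_pellets Initial pellet count (defaults to the count stored
#'   in the state).
#' @return One of `"early"`, `"late"`, `"scared"`, `"other"`.
#' @export
classify_context <- function(state, maze, initial_pellets = state$initial_pellets) {
  if (is.null(initial_pellets) || initial_pellets == 0L) {
    stop("initial pellet count must be positive")
  }
  for (g in state$ghosts) {
    if (g$mode %in% c("scared", "flash") &&
        maze_distance(maze, state$pacman, g$pos) <= 10) {
      return("scared")
    }
  }
  frac <- length(state$pellets) / initial_pellets
  if (frac > 0.9) "early" else if (frac < 0.1) "late" else "other"
}

#' Dominance statistics of per-step weights
#'
#' Summaries of the ranked per-step weight distributions: how strongly a
#' single strategy dominates at each moment (the take-the-best diagnostic).
#'
#' @param weights_step Steps x 6 matrix of normalized weights.
#' @return A list with `rank_means` (mean weight by rank), `gaps` (per-step
#'   top-two gap), `frac_gap_gt_0.1`, `frac_gap_gt_0.9`, and `ranked` (the
#'   per-step descending-sorted weight matrix).
#' @export
dominance_stats <- function(weights_step) {
  ranked <- t(apply(weights_step, 1L, sort, decreasing = TRUE))
  gaps <- ranked[, 1L] - ranked[, 2L]
  list(rank_means = colMeans(ranked),
       gaps = gaps,
       frac_gap_gt_0.1 = mean(gaps > 0.1),
       frac_gap_gt_0.9 = mean(gaps > 0.9),
       ranked = ranked)
}

# unit local reward (pellet 1, energizer 2) per direction within `radius`
# steps, over the union of tiles on the direction's paths
.local_rewards <- function(maze, state, radius) {
  paths <- enumerate_paths(maze, state$pacman, depth = radius)
  val <- numeric(maze$n)
  val[state$pellets] <- 1
  val[state$energizers] <- 2
  vapply(paths$dirs, function(M) {
    tiles <- unique(as.vector(M))
    sum(val[tiles[!is.na(tiles)]])
  }, numeric(1))
}

#' Local-reward choice curve
#'
#' For every step with at least two available directions, scores each
#' direction by the unit rewards (pellets one unit, energizers two) within
#' `radius` steps along its paths, and records whether the chosen direction
#' carried the maximal reward.  Outcomes are binned by the reward gap
#' between the best and second-best direction and by the number of
#' available directions (the junction type).
#'
#' @param log A `behavior_log`.
#' @param maze A `maze_graph`.
#' @param radius Path depth in steps (default 5).
#' @param gap_breaks Bin edges for the reward gap.
#' @return A data frame with one row per (junction type, gap bin):
#'   `n_dirs`, `gap_bin`, `n`, and `p_max` (probability of choosing a
#'   maximal-reward direction).
#' @export
local_reward_choice_curve <- function(log, maze, radius = 5L,
                                      gap_breaks = c(0, 1, 2, 3, 4, Inf)) {
  rows <- lapply(log$records, function(r) {
    rew <- .local_rewards(maze, r$state, radius)
    if (length(rew) < 2L) return(NULL)
    s <- sort(rew, decreasing = TRUE)
    gap <- s[1L] - s[2L]
    chose_max <- r$action %in% names(rew)[rew >= max(rew)]
    data.frame(n_dirs = length(rew), gap = gap, chose_max = chose_max)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) return(data.frame())
  d$gap_bin <- cut(d$gap, gap_breaks, include.lowest = TRUE, right = FALSE)
  agg <- aggregate(chose_max ~ n_dirs + gap_bin, data = d,
                   FUN = function(x) c(n = length(x), p = mean(x)))
  data.frame(n_dirs = agg$n_dirs, gap_bin = agg$gap_bin,
             n = agg$chose_max[, "n"], p_max = agg$chose_max[, "p"])
}

#' Ghost approach curve
#'
#' The probability that the chosen action strictly decreases the
#' shortest-path distance between Pac-Man and a ghost, binned by the
#' pre-move distance and split by ghost identity and mode.
#'
#' @param log A `behavior_log`.
#' @param maze A `maze_graph`.
#' @param dist_breaks Bin edges for the pre-move distance.
#' @return A data frame with `ghost`, `mode`, `dist_bin`, `n`, `p_toward`.
#' @export
ghost_approach_curve <- function(log, maze,
                                 dist_breaks = c(0, 5, 10, 15, 20, Inf)) {
  rows <- lapply(log$records, function(r) {
    s <- r$state
    if (!r$action %in% available_directions(maze, s$pacman)) return(NULL)
    p2 <- maze$neighbors[[s$pacman, r$action]]
    do.call(rbind, lapply(s$ghosts, function(g) {
      d0 <- maze_distance(maze, s$pacman, g$pos)
      d1 <- maze_distance(maze, p2, g$pos)
      data.frame(ghost = g$name, mode = g$mode, dist = d0, toward = d1 < d0)
    }))
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) return(data.frame())
  d$dist_bin <- cut(d$dist, dist_breaks, include.lowest = TRUE, right = FALSE)
  agg <- aggregate(toward ~ ghost + mode + dist_bin, data = d,
                   FUN = function(x) c(n = length(x), p = mean(x)))
  data.frame(ghost = agg$ghost, mode = agg$mode, dist_bin = agg$dist_bin,
             n = agg$toward[, "n"], p_toward = agg$toward[, "p"])
}

# minimum number of turns over all shortest paths from a to b: Dijkstra on
# the (tile, incoming direction) state graph with lexicographic
# (length, turns) cost folded into a single scalar
.min_turns_shortest <- function(maze, a, b) {
  if (a == b) return(c(length = 0, turns = 0))
  BIG <- 1e6
  dist <- matrix(Inf, nrow = maze$n, ncol = 4L, dimnames = list(NULL, DIRECTIONS))
  frontier <- list()
  for (d in available_directions(maze, a)) {
    nb <- maze$neighbors[[a, d]]
    dist[nb, d] <- BIG
    frontier[[length(frontier) + 1L]] <- c(nb, match(d, DIRECTIONS))
  }
  # Dijkstra with unit BIG cost per step + 1 per turn (BIG dominates turns)
  repeat {
    vals <- vapply(frontier, function(st) dist[st[1L], st[2L]], numeric(1))
    if (length(frontier) == 0L) break
    i <- which.min(vals)
    st <- frontier[[i]]
    frontier[[i]] <- NULL
    v <- dist[st[1L], st[2L]]
    if (!is.finite(v)) break
    pos <- st[1L]; dir <- DIRECTIONS[st[2L]]
    for (d2 in available_directions(maze, pos)) {
      nb <- maze$neighbors[[pos, d2]]
      cost <- v + BIG + (d2 != dir)
      if (cost < dist[nb, match(d2, DIRECTIONS)]) {
        dist[nb, match(d2, DIRECTIONS)] <- cost
        frontier[[length(frontier) + 1L]] <- c(nb, match(d2, DIRECTIONS))
      }
    }
  }
  best <- min(dist[b, ])
  c(length = floor(best / BIG), turns = best %% BIG)
}

#' Path optimality of global-strategy runs
#'
#' For every maximal run of at least `min_run` consecutive steps labeled
#' `global`, compares the trajectory actually taken — from the run's start
#' until the first pellet consumption — with the shortest path between the
#' same endpoints, in length and in turn count (minimum turns over all
#' shortest paths).
#'
#' @param log A `behavior_log`.
#' @param labels Per-step strategy labels (see [label_steps()]).
#' @param maze A `maze_graph`.
#' @param min_run Minimum run length in steps (default 4).
#' @return A data frame with one row per usable run: `start`, `pellet_step`,
#'   `actual_length`, `optimal_length`, `actual_turns`, `optimal_turns`;
#'   runs during which no pellet was reached are counted in the
#'   `n_skipped` attribute.
#' @export
global_path_optimality <- function(log, labels, maze, min_run = 4L) {
  n <- length(log$records)
  rounds <- log_rounds(log)
  runs <- rle(labels == "global")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  out <- NULL
  skipped <- 0L
  for (i in which(keep)) {
    t0 <- starts[i]
    # first pellet consumption from the run start onward, within the round
    t_pellet <- NA_integer_
    for (t in t0:n) {
      if (rounds[t] != rounds[t0]) break
      if ("pellet" %in% log$records[[t]]$events$kind) { t_pellet <- t; break }
    }
    if (is.na(t_pellet)) { skipped <- skipped + 1L; next }
    start_pos <- log$records[[t0]]$state$pacman
    end_pos <- log$records[[t_pellet]]$events$pos[
      log$records[[t_pellet]]$events$kind == "pellet"][1L]
    actions <- log_actions(log)[t0:t_pellet]
    opt <- .min_turns_shortest(maze, start_pos, end_pos)
    out <- rbind(out, data.frame(
      start = t0, pellet_step = t_pellet,
      actual_length = t_pellet - t0 + 1L,
      optimal_length = unname(opt["length"]),
      actual_turns = sum(actions[-1L] != actions[-length(actions)]),
      optimal_turns = unname(opt["turns"])
    ))
  }
  out <- if (is.null(out)) data.frame() else out
  attr(out, "n_skipped") <- skipped
  out
}

#' Compound events around energizer consumptions
#'
#' Classifies every energizer consumption followed by at least 10 more steps
#' in its round: when at least 8 of the 10 subsequent steps are labeled
#' `approach` the event is a `planned_attack`, otherwise an
#' `accidental_consumption`.  Each event also carries the onset of the
#' contiguous pre-consumption `approach` run (for alignment analyses).
#'
#' @param log A `behavior_log`.
#' @param labels Per-step strategy labels.
#' @param maze Unused here; kept for interface symmetry.
#' @return A data frame of events: `kind`, `anchor` (the consuming step),
#'   `onset` (first step of the contiguous approach run ending at the
#'   anchor, `NA` if the anchor itself is not `approach`), `n_approach`
#'   (approach labels among the 10 post-consumption steps).  Events with a
#'   truncated window are counted in the `n_skipped` attribute.
#' @export
detect_energizer_events <- function(log, labels, maze = NULL) {
  n <- length(log$records)
  rounds <- log_rounds(log)
  out <- NULL
  skipped <- 0L
  for (t in seq_len(n)) {
    if (!"energizer" %in% log$records[[t]]$events$kind) next
    win <- (t + 1L):(t + 10L)
    if (t + 10L > n || any(rounds[win] != rounds[t])) { skipped <- skipped + 1L; next }
    n_app <- sum(labels[win] == "approach")
    kind <- if (n_app >= 8L) "planned_attack" else "accidental_consumption"
    onset <- NA_integer_
    if (labels[t] == "approach") {
      onset <- t
      while (onset > 1L && labels[onset - 1L] == "approach" &&
             rounds[onset - 1L] == rounds[t]) onset <- onset - 1L
    }
    out <- rbind(out, data.frame(kind = kind, anchor = t, onset = onset,
                                 n_approach = n_app))
  }
  out <- if (is.null(out)) {
    data.frame(kind = character(0), anchor = integer(0), onset = integer(0),
               n_approach = integer(0))
  } else {
    out
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Compound events around deaths
#'
#' Classifies every death preceded by at least 10 steps in its round, from
#' the labels of the 10 steps ending at the death: all `approach` is a
#' `suicide`; all evade (either ghost) is a `failed_evasion`; anything else
#' is unclassified and not returned.
#'
#' @param log A `behavior_log`.
#' @param labels Per-step strategy labels.
#' @return A data frame of events: `kind`, `anchor` (the death step),
#'   `switch_step` (onset of the contiguous approach/evade run ending at
#'   the death).  Deaths with a truncated window are counted in the
#'   `n_skipped` attribute; unclassified deaths in `n_unclassified`.
#' @export
detect_death_events <- function(log, labels) {
  n <- length(log$records)
  rounds <- log_rounds(log)
  out <- NULL
  skipped <- 0L
  unclassified <- 0L
  for (t in seq_len(n)) {
    if (!"death" %in% log$records[[t]]$events$kind) next
    win <- (t - 9L):t
    if (t < 10L || any(rounds[win] != rounds[t])) { skipped <- skipped + 1L; next }
    lab <- labels[win]
    kind <- if (all(lab == "approach")) {
      "suicide"
    } else if (all(lab %in% c("evade_blinky", "evade_clyde"))) {
      "failed_evasion"
    } else {
      unclassified <- unclassified + 1L
      next
    }
    match_set <- if (kind == "suicide") "approach" else c("evade_blinky", "evade_clyde")
    onset <- t
    while (onset > 1L && labels[onset - 1L] %in% match_set &&
           rounds[onset - 1L] == rounds[t]) onset <- onset - 1L
    out <- rbind(out, data.frame(kind = kind, anchor = t, switch_step = onset))
  }
  out <- if (is.null(out)) {
    data.frame(kind = character(0), anchor = integer(0), switch_step = integer(0))
  } else {
    out
  }
  attr(out, "n_skipped") <- skipped
  attr(out, "n_unclassified") <- unclassified
  out
}

#' Distance covariates of compound events
#'
#' For energizer events (planned attack / accidental consumption): the
#' Pac-Man-energizer, energizer-ghost, and Pac-Man-ghost distances at the
#' event start, defined as the earliest step from which every subsequent
#' step strictly decreases the Pac-Man-energizer distance.  For death
#' events (suicide / failed evasion): the distance from Pac-Man to the
#' closest pellet before the death and from the reset position after it
#' (`pellet_gain = pre - post`, positive when the reset moves Pac-Man
#' closer to pellets), and the mean Pac-Man-ghost distance, both at the
#' strategy-switch step.
#'
#' @param events Event table from [detect_energizer_events()] or
#'   [detect_death_events()].
#' @param log A `behavior_log`.
#' @param maze A `maze_graph`.
#' @return The event table with appended distance columns.
#' @export
event_covariates <- function(events, log, maze) {
  if (nrow(events) == 0L) return(events)
  n <- length(log$records)
  is_energizer <- "n_approach" %in% names(events)
  if (is_energizer) {
    cov <- lapply(seq_len(nrow(events)), function(i) {
      t_anchor <- events$anchor[i]
      e_pos <- log$records[[t_anchor]]$events$pos[
        log$records[[t_anchor]]$events$kind == "energizer"][1L]
      # event start: earliest step from which the Pac-Man-energizer distance
      # strictly decreases at every subsequent step up to the consumption
      dists <- vapply(seq_len(t_anchor), function(t) {
        maze_distance(maze, log$records[[t]]$state$pacman, e_pos)
      }, numeric(1))
      t_start <- t_anchor
      while (t_start > 1L && dists[t_start - 1L] > dists[t_start]) t_start <- t_start - 1L
      s <- log$records[[t_start]]$state
      gd <- vapply(s$ghosts, function(g) maze_distance(maze, s$pacman, g$pos), numeric(1))
      ge <- vapply(s$ghosts, function(g) maze_distance(maze, e_pos, g$pos), numeric(1))
      data.frame(start_step = t_start,
                 d_pac_energizer = dists[t_start],
                 d_energizer_ghost = mean(ge),
                 d_pac_ghost = mean(gd))
    })
  } else {
    cov <- lapply(seq_len(nrow(events)), function(i) {
      t_sw <- events$switch_step[i]
      t_anchor <- events$anchor[i]
      s_sw <- log$records[[t_sw]]$state
      closest_pellet <- function(pos, pellets) {
        if (length(pellets) == 0L) return(NA_real_)
        min(vapply(pellets, function(p) maze_distance(maze, pos, p), numeric(1)))
      }
      pre <- closest_pellet(s_sw$pacman, s_sw$pellets)
      post_state <- if (t_anchor + 1L <= n) log$records[[t_anchor + 1L]]$state else log$final_state
      post <- closest_pellet(post_state$pacman, post_state$pellets)
      gd <- vapply(s_sw$ghosts, function(g) maze_distance(maze, s_sw$pacman, g$pos), numeric(1))
      data.frame(d_pellet_pre = pre, d_pellet_post = post,
                 pellet_gain = pre - post,
                 d_pac_ghost = mean(gd))
    })
  }
  cbind(events, do.call(rbind, cov))
}
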