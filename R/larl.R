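# ---------------------------------------------------------------------------
# Flat baseline: linear approximate reinforcement learning (LARL).
#
# A linear utility over seven hand-crafted game features, updated by a
# temporal-difference rule whose target uses the action actually taken in
# the log (not the greedy action).  Features that do not exist in a game
# context (e.g. distance to a scared ghost when none is scared) are null:
# they contribute 0 to the utility and receive no gradient.
# ---------------------------------------------------------------------------

.LARL_FEATURES <- c("x_local", "x_closest", "x_e", "x_global",
                    "x_gB", "x_gC", "x_gS")

#' LARL feature vector for a candidate direction
#'
#' Evaluates the seven features for the state reached by taking direction
#' `d`: the pellet count within five steps along `d` (`x_local`), the
#' shortest-path distances to the nearest pellet (`x_closest`), nearest
#' energizer (`x_e`), Blinky (`x_gB`), Clyde (`x_gC`) and nearest scared
#' ghost (`x_gS`), and the count of pellets farther than five steps weighted
#' by their inverse distances (`x_global`).  A feature whose referent does
#' not exist is `NA` (null).
#'
#' @param maze A `maze_graph`.
#' @param state A `game_state`.
#' @param d An available direction.
#' @return Named numeric vector of length 7 with `NA` for null features.
#' @export
larl_features <- function(maze, state, d) {
  if (!d %in% available_directions(maze, state$pacman)) {
    stop("direction ", d, " unavailable at tile ", state$pacman)
  }
  p2 <- maze$neighbors[[state$pacman, d]]
  paths5 <- enumerate_paths(maze, state$pacman, depth = 5L)
  tiles_d <- unique(as.vector(paths5$dirs[[d]]))
  tiles_d <- tiles_d[!is.na(tiles_d)]
  x_local <- sum(state$pellets %in% tiles_d)

  dp2 <- .dist_to(maze, p2)
  min_or_na <- function(v) if (length(v) == 0L) NA_real_ else min(v)
  x_closest <- min_or_na(dp2[state$pellets])
  x_e <- min_or_na(dp2[state$energizers])
  far <- dp2[state$pellets]
  far <- far[far > 5]
  x_global <- if (length(state$pellets) == 0L) NA_real_ else sum(1 / far[far > 0])
  x_gB <- dp2[state$ghosts$blinky$pos]
  x_gC <- dp2[state$ghosts$clyde$pos]
  scared <- vapply(state$ghosts, function(g) g$mode %in% c("scared", "flash"), logical(1))
  x_gS <- if (!any(scared)) NA_real_ else {
    min(vapply(state$ghosts[scared], function(g) dp2[g$pos], numeric(1)))
  }
  stats::setNames(c(x_local, x_closest, x_e, x_global, x_gB, x_gC, x_gS),
                  .LARL_FEATURES)
}

#' LARL parameters
#'
#' @param theta Feature weights (length 7).
#' @param alpha Learning rate (> 0).
#' @param gamma Discount factor in [0, 1).
#' @return An object of class `larl_params`.
#' @export
larl_params <- function(theta = numeric(7), alpha = 0.01, gamma = 0.3) {
  stopifnot(length(theta) == 7L, alpha > 0, gamma >= 0, gamma < 1)
  structure(list(theta = stats::setNames(as.numeric(theta), .LARL_FEATURES),
                 alpha = alpha, gamma = gamma),
            class = "larl_params")
}

#' Linear utility of a feature vector
#'
#' @param params A [larl_params()].
#' @param x A feature vector from [larl_features()].
#' @return `sum(theta_i x_i)` over non-null features.
#' @export
larl_q <- function(params, x) {
  sum(params$theta * x, na.rm = TRUE)
}

#' One temporal-difference update
#'
#' Applies the TD rule with the logged next action as the target:
#' `theta_i <- theta_i + alpha (r + gamma Q(s', d') - Q(s, d)) x_i(s, d)`,
#' updating only non-null features.  When the logged actions are greedy this
#' coincides exactly with the standard Q-learning (max-target) update.
#'
#' @param params A [larl_params()].
#' @param x Features of the visited pair `(s, d)`.
#' @param r Reward received on the transition.
#' @param x_next Features of the successor pair `(s', d')`, or `NULL` for a
#'   terminal transition (the continuation value is 0).
#' @return The updated `larl_params`.
#' @export
larl_update <- function(params, x, r, x_next = NULL) {
  q <- larl_q(params, x)
  q_next <- if (is.null(x_next)) 0 else larl_q(params, x_next)
  delta <- r + params$gamma * q_next - q
  upd <- params$alpha * delta * x
  live <- !is.na(x)
  params$theta[live] <- params$theta[live] + upd[live]
  params
}

# per-step LARL feature cache: list over steps, each a named list mapping
# every available direction to its feature vector, plus the reward.
# Features are z-scored over the whole log (nulls excluded): the linear
# utility's prediction ranking is invariant to affine feature rescaling,
# while the TD iteration needs comparably scaled inputs to stay stable.
.larl_prepare <- function(log, maze) {
  n <- length(log$records)
  prep <- lapply(seq_len(n), function(t) {
    s <- log$records[[t]]$state
    dirs <- available_directions(maze, s$pacman)
    feats <- lapply(dirs, function(d) larl_features(maze, s, d))
    names(feats) <- dirs
    list(feats = feats,
         action = log$records[[t]]$action,
         reward = sum(log$records[[t]]$events$drops),
         round = s$round_index)
  })
  all_x <- do.call(rbind, lapply(prep, function(p) do.call(rbind, p$feats)))
  mu <- colMeans(all_x, na.rm = TRUE)
  sd <- apply(all_x, 2L, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  mu[!is.finite(mu)] <- 0
  for (t in seq_len(n)) {
    prep[[t]]$feats <- lapply(prep[[t]]$feats, function(x) (x - mu) / sd)
  }
  attr(prep, "center") <- mu
  attr(prep, "scale") <- sd
  prep
}

# one sweep of TD updates over transitions t -> t+1 (within rounds)
.larl_sweep <- function(params, prep, idx) {
  for (t in idx) {
    cur <- prep[[t]]
    nxt <- if (t + 1L <= length(prep) && prep[[t + 1L]]$round == cur$round) prep[[t + 1L]] else NULL
    if (!cur$action %in% names(cur$feats)) next   # action ran into a wall: skip
    x <- cur$feats[[cur$action]]
    x_next <- if (!is.null(nxt) && nxt$action %in% names(nxt$feats)) {
      nxt$feats[[nxt$action]]
    } else {
      NULL
    }
    params <- larl_update(params, x, cur$reward, x_next)
    if (any(!is.finite(params$theta)) || max(abs(params$theta)) > 1e6) {
      params$theta[] <- 1e6         # diverged: freeze at a sentinel magnitude
      break
    }
  }
  params
}

# argmax-Q prediction accuracy over the given steps
.larl_accuracy <- function(params, prep, idx) {
  ok <- vapply(idx, function(t) {
    q <- vapply(prep[[t]]$feats, function(x) larl_q(params, x), numeric(1))
    .argmax_direction(q) == prep[[t]]$action
  }, logical(1))
  mean(ok)
}

#' Fit the LARL baseline to a behavior log
#'
#' Initializes the feature weights from a seeded random draw, runs TD sweeps
#' over the log's transitions, and selects the learning rate and discount
#' factor by k-fold cross-validated action-prediction accuracy (argmax of
#' the linear utility), with contiguous folds.  The final weights are
#' trained on all transitions with the selected hyperparameters.
#'
#' @param log A `behavior_log`.
#' @param maze The matching `maze_graph`.
#' @param alpha_grid,gamma_grid Hyperparameter grids.
#' @param folds Number of cross-validation folds.
#' @param epochs TD sweeps over the training transitions.
#' @param seed Integer seed for the weight initialization.
#' @return A list with `params` (the fitted `larl_params`), `accuracy`
#'   (cross-validated accuracy of the selected hyperparameters),
#'   `train_accuracy` (all-data accuracy of the final weights), and `grid`
#'   (the cross-validation table).
#' @export
larl_fit <- function(log, maze,
                     alpha_grid = c(0.005, 0.01, 0.025, 0.05),
                     gamma_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                     folds = 3L, epochs = 1L, seed = 1L) {
  prep <- .larl_prepare(log, maze)
  n <- length(prep)
  if (n < folds) stop("fewer transitions (", n, ") than folds (", folds, ")")
  set.seed(seed)
  theta0 <- stats::rnorm(7L, 0, 0.1)
  fold_id <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]

  grid <- expand.grid(alpha = alpha_grid, gamma = gamma_grid)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    accs <- vapply(seq_len(folds), function(f) {
      params <- larl_params(theta0, grid$alpha[i], grid$gamma[i])
      for (e in seq_len(epochs)) {
        params <- .larl_sweep(params, prep, which(fold_id != f))
      }
      .larl_accuracy(params, prep, which(fold_id == f))
    }, numeric(1))
    grid$accuracy[i] <- mean(accs)
  }
  best <- which.max(grid$accuracy)
  params <- larl_params(theta0, grid$alpha[best], grid$gamma[best])
  for (e in seq_len(epochs)) params <- .larl_sweep(params, prep, seq_len(n))
  list(params = params,
       accuracy = grid$accuracy[best],
       train_accuracy = .larl_accuracy(params, prep, seq_len(n)),
       grid = grid)
}
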