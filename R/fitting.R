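# ---------------------------------------------------------------------------
# Softmax utility-mixture model and the two-pass dynamic fitting procedure.
#
# Per time window the model is a multinomial logit over the four directions
# whose linear predictor is the weighted sum of the six normalized strategy
# utilities.  The log-likelihood is concave in the weights for fixed
# utilities; it is maximized under w >= 0 by deterministic multi-start
# L-BFGS-B, and the reported weights are w / sum(w).
# ---------------------------------------------------------------------------

.logsumexp <- function(x) {
  x <- x[is.finite(x)]
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Combine strategy utilities into direction utilities
#'
#' @param U A 6 x 4 utility matrix (one time step, normalized), `-Inf` on
#'   unavailable directions.
#' @param w Strategy weight vector (length 6, or the reduced length after
#'   degenerate merging).
#' @return Named 4-vector `Q` with `Q_d = sum_a w_a U_[a,d]`; `-Inf`
#'   propagates for unavailable directions.
#' @export
combined_utility <- function(U, w) {
  avail <- apply(is.finite(U), 2L, all)
  Q <- stats::setNames(rep(-Inf, ncol(U)), colnames(U))
  Q[avail] <- as.vector(w %*% U[, avail, drop = FALSE])
  Q
}

#' Softmax choice policy over directions
#'
#' @param Q Named 4-vector of direction utilities; `-Inf` marks unavailable
#'   directions and receives probability 0.
#' @return Probability vector summing to 1.
#' @export
softmax_policy <- function(Q) {
  if (!any(is.finite(Q))) stop("softmax undefined: all directions unavailable")
  p <- stats::setNames(numeric(length(Q)), names(Q))
  lse <- .logsumexp(Q)
  p[is.finite(Q)] <- exp(Q[is.finite(Q)] - lse)
  p
}

# internal: log-likelihood and gradient of a window given the steps x A x 4
# utility slab `U`, availability mask, and chosen-direction indices
.window_ll <- function(w, U, avail, chosen) {
  n <- dim(U)[1L]
  ll <- 0
  grad <- numeric(length(w))
  for (t in seq_len(n)) {
    Ut <- U[t, , , drop = TRUE]
    if (is.null(dim(Ut))) Ut <- matrix(Ut, nrow = length(w))
    av <- avail[t, ]
    Q <- as.vector(w %*% Ut[, av, drop = FALSE])
    m <- max(Q)
    e <- exp(Q - m)
    Z <- sum(e)
    pi_t <- e / Z
    j <- match(chosen[t], which(av))
    ll <- ll + Q[j] - m - log(Z)
    grad <- grad + Ut[, av, drop = FALSE][, j] -
      as.vector(Ut[, av, drop = FALSE] %*% pi_t)
  }
  list(ll = ll, grad = grad)
}

#' Log-likelihood of a weight vector on a time window
#'
#' The summed log-probability of the chosen directions under the softmax
#' mixture policy with weights `w`.
#'
#' @param steps Integer vector of step indices (into the tensor) forming the
#'   window.
#' @param tensors A `utility_tensor` from [compute_utilities()].
#' @param w Weight vector over the six strategies.
#' @return The log-likelihood (a scalar).
#' @export
window_log_likelihood <- function(steps, tensors, w) {
  U <- tensors$norm[steps, , , drop = FALSE]
  avail <- tensors$available[steps, , drop = FALSE]
  chosen <- match(tensors$actions[steps], DIRECTIONS)
  if (any(!avail[cbind(seq_along(steps), chosen)])) {
    stop("chosen direction unavailable at some step: log/engine mismatch")
  }
  .window_ll(w, U, avail, chosen)$ll
}

#' Merge strategies that are behaviorally degenerate on a window
#'
#' Two strategies whose per-step utility-argmax action sequences coincide
#' over a window cannot be distinguished by the choices in that window; they
#' are merged into one hybrid column (the members' mean utility) before
#' fitting, and the hybrid's fitted weight is afterwards split equally among
#' the members.
#'
#' @param steps Step indices of the window.
#' @param tensors A `utility_tensor`.
#' @return A list with `groups` (list of integer vectors of strategy
#'   indices, one per merged column) and `n_groups`.
#' @export
merge_degenerate <- function(steps, tensors) {
  sigs <- vapply(seq_along(STRATEGIES), function(a) {
    seqs <- vapply(steps, function(t) {
      u <- tensors$norm[t, a, ]
      .argmax_direction(u)
    }, character(1))
    paste(seqs, collapse = "|")
  }, character(1))
  groups <- split(seq_along(STRATEGIES), factor(sigs, levels = unique(sigs)))
  names(groups) <- NULL
  list(groups = groups, n_groups = length(groups))
}

# deterministic multi-start maximization of the window log-likelihood over
# w >= 0 (reduced dimension m); the upper box bound keeps separable windows
# from diverging.  A tiny ridge penalty acts as a minimum-norm tie-break:
# a strategy whose normalized utility is constant across the available
# directions at every step of the window is likelihood-flat (softmax shift
# invariance), and without the penalty the optimizer could park arbitrary
# weight on it.
.optimize_window <- function(U, avail, chosen, m, control = list()) {
  maxit <- control$maxit %||% 200L
  upper <- control$upper %||% 50
  ridge <- control$ridge %||% 1e-3
  starts <- list(rep(0, m), rep(0.5, m), rep(1, m), rep(2, m), rep(5, m))
  fn <- function(w) -.window_ll(w, U, avail, chosen)$ll + ridge * sum(w^2)
  gr <- function(w) -.window_ll(w, U, avail, chosen)$grad + 2 * ridge * w
  best <- NULL
  for (w0 in starts) {
    fit <- stats::optim(w0, fn, gr, method = "L-BFGS-B",
                        lower = 0, upper = upper,
                        control = list(maxit = maxit, factr = 1e5))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Maximum-likelihood strategy weights for one window
#'
#' Maximizes the window log-likelihood over nonnegative strategy weights
#' (deterministic multi-start quasi-Newton).  Strategies that are
#' behaviorally degenerate on the window are merged before fitting and
#' their hybrid weight split equally afterwards (see [merge_degenerate()]).
#'
#' @param steps Step indices of the window.
#' @param tensors A `utility_tensor`.
#' @param merge Whether to apply degenerate-strategy merging.
#' @param control Optimizer control: `maxit`, `upper` (box bound on raw
#'   weights).
#' @return A list with `w` (raw fitted weights, length 6), `w_norm`
#'   (normalized to sum 1), `loglik`, and `convergence`.
#' @export
fit_window <- function(steps, tensors, merge = TRUE, control = list()) {
  stopifnot(length(steps) >= 1L)
  avail <- tensors$available[steps, , drop = FALSE]
  chosen <- match(tensors$actions[steps], DIRECTIONS)

  if (merge) {
    mg <- merge_degenerate(steps, tensors)
  } else {
    mg <- list(groups = as.list(seq_along(STRATEGIES)),
               n_groups = length(STRATEGIES))
  }
  m <- mg$n_groups
  U <- array(NA_real_, dim = c(length(steps), m, 4L))
  for (g in seq_len(m)) {
    members <- mg$groups[[g]]
    block <- tensors$norm[steps, members, , drop = FALSE]
    U[, g, ] <- apply(block, c(1L, 3L), mean)
  }

  opt <- .optimize_window(U, avail, chosen, m, control)
  if (opt$convergence != 0) {
    warning("window optimizer did not fully converge (code ", opt$convergence,
            "); best iterate returned")
  }
  w <- numeric(length(STRATEGIES))
  for (g in seq_len(m)) {
    members <- mg$groups[[g]]
    w[members] <- opt$par[g] / length(members)
  }
  names(w) <- STRATEGIES
  # report the pure log-likelihood at the optimum (without the ridge term)
  ll <- .window_ll(opt$par, U, avail, chosen)$ll
  list(w = w, w_norm = normalize_weights(w), loglik = ll,
       convergence = opt$convergence)
}

#' Normalize a weight vector to sum 1
#'
#' @param w Nonnegative weight vector.
#' @return `w / sum(w)`; an all-zero vector maps to the uniform vector.
#' @export
normalize_weights <- function(w) {
  s <- sum(w)
  if (s <= 0) rep(1 / length(w), length(w)) else w / s
}

#' Event-bounded fine time windows
#'
#' Splits every round of a log into the fine-grained windows of the first
#' fitting pass: boundaries fall at every change of the chosen direction, at
#' every ghost or energizer consumption (the consuming step starts a new
#' window), and at round boundaries.
#'
#' @param log A `behavior_log`.
#' @return A data frame with columns `round`, `start`, `end`: 1-based,
#'   half-open `[start, end)` step intervals tiling each round.
#' @export
fine_windows <- function(log) {
  n <- length(log$records)
  if (n == 0L) return(data.frame(round = integer(0), start = integer(0), end = integer(0)))
  actions <- log_actions(log)
  rounds <- log_rounds(log)
  consume <- vapply(log$records, function(r) {
    any(r$events$kind %in% c("ghost", "energizer"))
  }, logical(1))
  boundary <- rep(FALSE, n)
  boundary[1L] <- TRUE
  for (t in 2:max(2L, n)) {
    if (t > n) break
    boundary[t] <- rounds[t] != rounds[t - 1L] ||
      actions[t] != actions[t - 1L] || consume[t]
  }
  starts <- which(boundary)
  ends <- c(starts[-1L], n + 1L)
  data.frame(round = rounds[starts], start = starts, end = ends)
}

#' First fitting pass: weights per fine window
#'
#' Applies [fit_window()] to every fine window, producing the weight time
#' series segmented by the change-point step.
#'
#' @param log A `behavior_log`.
#' @param tensors A `utility_tensor`.
#' @param windows Optional window table (defaults to [fine_windows()]).
#' @param control Optimizer control passed to [fit_window()].
#' @return A list with `windows` (the table), `weights` (windows x 6 matrix
#'   of normalized weights), and `loglik` (per-window log-likelihoods).
#' @export
first_pass <- function(log, tensors, windows = fine_windows(log),
                       control = list()) {
  k <- nrow(windows)
  W <- matrix(NA_real_, nrow = k, ncol = length(STRATEGIES),
              dimnames = list(NULL, STRATEGIES))
  ll <- numeric(k)
  for (i in seq_len(k)) {
    steps <- windows$start[i]:(windows$end[i] - 1L)
    f <- fit_window(steps, tensors, control = control)
    W[i, ] <- f$w_norm
    ll[i] <- f$loglik
  }
  list(windows = windows, weights = W, loglik = ll)
}

#' Optimal K-segment partition of a weight series
#'
#' Exact dynamic-programming change-point segmentation of a multivariate
#' series: among all partitions into `K` contiguous segments, returns the
#' one minimizing the within-segment quadratic loss
#' `sum_segments sum_i ||w_i - mean(segment)||^2`.
#'
#' @param series A k x p matrix (rows = fine windows).
#' @param K Number of segments, `1 <= K <= k`.
#' @return A list with `breaks` (the first row index of each segment),
#'   `assignment` (segment id per row), `loss`, and `K`.
#' @export
segment_weights <- function(series, K) {
  series <- as.matrix(series)
  k <- nrow(series)
  stopifnot(K >= 1L, K <= k)
  S <- apply(series, 2L, cumsum)
  S2 <- cumsum(rowSums(series^2))
  seg_cost <- function(i, j) {          # rows i..j inclusive
    s <- S[j, ] - if (i > 1L) S[i - 1L, ] else 0
    q <- S2[j] - if (i > 1L) S2[i - 1L] else 0
    q - sum(s^2) / (j - i + 1L)
  }
  cost <- matrix(Inf, k, k)
  for (i in seq_len(k)) for (j in i:k) cost[i, j] <- seg_cost(i, j)

  D <- matrix(Inf, K, k)                # D[q, j]: best loss of rows 1..j in q segments
  B <- matrix(NA_integer_, K, k)        # start of the last segment
  D[1L, ] <- cost[1L, ]
  B[1L, ] <- 1L
  if (K > 1L) {
    for (q in 2:K) {
      for (j in q:k) {
        cand <- D[q - 1L, (q - 1L):(j - 1L)] + cost[q:j, j]
        i <- which.min(cand)
        D[q, j] <- cand[i]
        B[q, j] <- (q:j)[i]
      }
    }
  }
  breaks <- integer(K)
  j <- k
  for (q in K:1) {
    breaks[q] <- B[q, j]
    j <- breaks[q] - 1L
  }
  assignment <- rep(seq_len(K), times = diff(c(breaks, k + 1L)))
  list(breaks = breaks, assignment = assignment, loss = D[K, k], K = K)
}

#' Second fitting pass over coarse windows
#'
#' Refits the strategy weights by MLE on the coarse windows obtained from a
#' segmentation of the fine windows, and sums the window log-likelihoods.
#'
#' @param tensors A `utility_tensor`.
#' @param windows The fine-window table of the round.
#' @param segmentation Output of [segment_weights()] on the round's
#'   first-pass weight series.
#' @param control Optimizer control.
#' @return A list with the coarse `windows` (step intervals), `weights`
#'   (normalized, one row per coarse window), `raw_weights`, and `loglik`
#'   (the summed log-likelihood).
#' @export
second_pass <- function(tensors, windows, segmentation, control = list()) {
  K <- segmentation$K
  coarse <- data.frame(
    round = windows$round[segmentation$breaks],
    start = windows$start[segmentation$breaks],
    end = windows$end[c(segmentation$breaks[-1L] - 1L, nrow(windows))]
  )
  W <- matrix(NA_real_, K, length(STRATEGIES), dimnames = list(NULL, STRATEGIES))
  Wr <- W
  ll <- 0
  for (i in seq_len(K)) {
    steps <- coarse$start[i]:(coarse$end[i] - 1L)
    f <- fit_window(steps, tensors, control = control)
    W[i, ] <- f$w_norm
    Wr[i, ] <- f$w
    ll <- ll + f$loglik
  }
  list(windows = coarse, weights = W, raw_weights = Wr, loglik = ll)
}

# assemble per-step weight matrix from coarse windows
.step_weights <- function(n, coarse, W) {
  out <- matrix(NA_real_, n, length(STRATEGIES), dimnames = list(NULL, STRATEGIES))
  for (i in seq_len(nrow(coarse))) {
    out[coarse$start[i]:(coarse$end[i] - 1L), ] <- rep(W[i, ], each = coarse$end[i] - coarse$start[i])
  }
  out
}

#' Dynamic compositional strategy fit
#'
#' The full two-pass procedure, applied independently to every round of the
#' log: fine windows are fitted by MLE (first pass), the resulting weight
#' series is segmented by exact change-point detection for each candidate
#' segment count `K`, the coarse windows are refitted (second pass), and the
#' best `K` is selected.  With `criterion = "raw"` the selected `K`
#' maximizes the in-sample log-likelihood `L(K)`; because in-sample
#' likelihood is essentially non-decreasing in `K` this degenerates to the
#' largest candidate, so the default `criterion = "aic"` maximizes
#' `L(K) - 6 K` (an AIC penalty, six weights per segment) and
#' `criterion = "bic"` maximizes `L(K) - 3 K log(n)`, restoring the
#' parsimony the segmentation is meant to provide.  Rounds with fewer than
#' two fine windows fall back to a single-window fit.
#'
#' @param log A `behavior_log`.
#' @param tensors The matching `utility_tensor`.
#' @param k_range Candidate segment counts (default 2 to 20).
#' @param criterion `"aic"`, `"bic"`, or `"raw"` (see above).
#' @param control Optimizer control.
#' @return An object of class `strategy_fit`; see [fit_static()] for the
#'   shared structure.
#' @export
fit_dynamic <- function(log, tensors, k_range = 2:20,
                        criterion = c("aic", "bic", "raw"), control = list()) {
  criterion <- match.arg(criterion)
  n <- length(log$records)
  fw <- fine_windows(log)
  all_coarse <- NULL
  all_W <- NULL
  all_Wr <- NULL
  loglik <- 0
  kstar <- integer(0)
  lk_curves <- list()
  for (r in unique(fw$round)) {
    wr <- fw[fw$round == r, , drop = FALSE]
    round_steps <- wr$start[1L]:(wr$end[nrow(wr)] - 1L)
    n_round <- length(round_steps)
    ks <- k_range[k_range <= nrow(wr)]
    if (nrow(wr) < 2L || length(ks) == 0L) {
      f <- fit_window(round_steps, tensors, control = control)
      coarse <- data.frame(round = r, start = round_steps[1L],
                           end = round_steps[n_round] + 1L)
      best <- list(windows = coarse,
                   weights = matrix(f$w_norm, 1L, dimnames = list(NULL, STRATEGIES)),
                   raw_weights = matrix(f$w, 1L, dimnames = list(NULL, STRATEGIES)),
                   loglik = f$loglik)
      kstar <- c(kstar, 1L)
      lk_curves[[as.character(r)]] <- data.frame(K = 1L, loglik = f$loglik)
    } else {
      fp <- first_pass(log, tensors, windows = wr, control = control)
      fits <- lapply(ks, function(K) {
        seg <- segment_weights(fp$weights, K)
        second_pass(tensors, wr, seg, control = control)
      })
      lk <- vapply(fits, function(f) f$loglik, numeric(1))
      score <- switch(criterion,
        aic = lk - length(STRATEGIES) * ks,
        bic = lk - (length(STRATEGIES) / 2) * ks * log(n_round),
        raw = lk)
      pick <- which.max(score)
      best <- fits[[pick]]
      kstar <- c(kstar, ks[pick])
      lk_curves[[as.character(r)]] <- data.frame(K = ks, loglik = lk, score = score)
    }
    all_coarse <- rbind(all_coarse, best$windows)
    all_W <- rbind(all_W, best$weights)
    all_Wr <- rbind(all_Wr, best$raw_weights)
    loglik <- loglik + best$loglik
  }
  .finish_fit(log, tensors, all_coarse, all_W, all_Wr, loglik,
              model = "dynamic", kstar = kstar, lk = lk_curves)
}

#' Static strategy fit
#'
#' Fits a single set of strategy weights to the entire log (one window over
#' all steps).
#'
#' @param log A `behavior_log`.
#' @param tensors The matching `utility_tensor`.
#' @param control Optimizer control.
#' @return An object of class `strategy_fit`: a list with the coarse
#'   `windows` table, `weights` (normalized, one row per window),
#'   `weights_step` (per-step weights), `loglik`, per-step argmax
#'   predictions `pred`, `accuracy`, `model`, and (for dynamic fits) the
#'   selected `kstar` per round and the `L(K)` curves.
#' @export
fit_static <- function(log, tensors, control = list()) {
  n <- length(log$records)
  f <- fit_window(seq_len(n), tensors, control = control)
  coarse <- data.frame(round = log_rounds(log)[1L], start = 1L, end = n + 1L)
  W <- matrix(f$w_norm, 1L, dimnames = list(NULL, STRATEGIES))
  Wr <- matrix(f$w, 1L, dimnames = list(NULL, STRATEGIES))
  .finish_fit(log, tensors, coarse, W, Wr, f$loglik, model = "static",
              kstar = 1L, lk = NULL)
}

.finish_fit <- function(log, tensors, coarse, W, Wr, loglik, model, kstar, lk) {
  n <- length(log$records)
  Wstep <- .step_weights(n, coarse, W)
  pred <- predict_directions(Wstep, tensors)
  acc <- mean(pred == tensors$actions)
  structure(list(model = model, windows = coarse, weights = W,
                 raw_weights = Wr, weights_step = Wstep, loglik = loglik,
                 pred = pred, accuracy = acc, kstar = kstar, lk = lk,
                 n_steps = n),
            class = "strategy_fit")
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat(sprintf("<strategy_fit> %s model: %d step(s), %d window(s), logLik %.2f, accuracy %.3f\n",
              x$model, x$n_steps, nrow(x$windows), x$loglik, x$accuracy))
  invisible(x)
}

#' Per-step argmax direction predictions
#'
#' @param weights_step Steps x 6 matrix of strategy weights.
#' @param tensors A `utility_tensor`.
#' @return Character vector of predicted directions (argmax of the combined
#'   utility; ties broken by the fixed priority up > left > down > right).
#' @export
predict_directions <- function(weights_step, tensors) {
  n <- nrow(weights_step)
  vapply(seq_len(n), function(t) {
    Q <- combined_utility(tensors$norm[t, , ], weights_step[t, ])
    .argmax_direction(Q)
  }, character(1))
}

#' Prediction accuracy of a fit
#'
#' @param fit A `strategy_fit`.
#' @param tensors The `utility_tensor` the fit was computed on.
#' @param method `"argmax"`: fraction of steps whose argmax-utility
#'   direction equals the chosen one; `"softmax"`: mean model probability
#'   of the chosen direction.
#' @return A fraction in [0, 1].
#' @export
prediction_accuracy <- function(fit, tensors, method = c("argmax", "softmax")) {
  method <- match.arg(method)
  if (fit$n_steps == 0L) stop("empty log")
  if (method == "argmax") {
    return(mean(fit$pred == tensors$actions))
  }
  mean(vapply(seq_len(fit$n_steps), function(t) {
    Q <- combined_utility(tensors$norm[t, , ], fit$weights_step[t, ])
    softmax_policy(Q)[[tensors$actions[t]]]
  }, numeric(1)))
}

#' Chance-level prediction accuracy of a log
#'
#' The expected accuracy of uniform guessing over the available directions.
#'
#' @param tensors A `utility_tensor`.
#' @return Mean of 1 / (number of available directions) over steps.
#' @export
chance_accuracy <- function(tensors) {
  mean(1 / rowSums(tensors$available))
}
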