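# Softmax mixture model, window MLE, and the two-pass dynamic procedure.

test_that("softmax policy has the closed forms and invariances", {
  Q <- stats::setNames(c(0, 0, 0, 0), DIRECTIONS)
  expect_equal(unname(softmax_policy(Q)), rep(0.25, 4L))
  Q2 <- stats::setNames(c(1, 0, 0, -Inf), DIRECTIONS)
  p2 <- softmax_policy(Q2)
  expect_equal(unname(p2), c(exp(1), 1, 1, 0) / (exp(1) + 2))
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  # shift invariance on the finite entries
  Q3 <- Q2
  Q3[1:3] <- Q3[1:3] + 7.5
  expect_equal(softmax_policy(Q3), p2)
  expect_error(softmax_policy(rep(-Inf, 4L)), "unavailable")
})

test_that("combined utility is linear and propagates unavailability", {
  U <- matrix(0, 6, 4, dimnames = list(STRATEGIES, DIRECTIONS))
  expect_equal(unname(combined_utility(U, rep(0, 6))), rep(0, 4L))
  U["local", ] <- c(1, 0, 0, 0.3)
  w1 <- c(1, 0, 0, 0, 0, 0)
  expect_equal(combined_utility(U, w1), U["local", ])
  # worked two-strategy example
  U2 <- matrix(-Inf, 2, 4)
  U2[1, 1:3] <- c(1, 0, 0)
  U2[2, 1:3] <- c(0, 1, 0)
  expect_equal(unname(combined_utility(U2, c(0.5, 0.5))), c(0.5, 0.5, 0, -Inf))
})

test_that("window log-likelihood matches closed forms", {
  n <- 17L
  tens <- synthetic_tensor(n, w = rep(0, 6), seed = 2)
  # zero weights on 4 available directions: uniform policy
  expect_equal(window_log_likelihood(seq_len(n), tens, rep(0, 6)),
               -n * log(4))
  # single-step closed form
  tens1 <- synthetic_tensor(1L, w = rep(0, 6), seed = 3)
  tens1$norm[1, , ] <- 0
  tens1$norm[1, 1, ] <- c(1, 0, 0, 0)
  tens1$actions <- "left"
  expect_equal(window_log_likelihood(1L, tens1, c(1, 0, 0, 0, 0, 0)),
               log(exp(1) / (exp(1) + 3)))
  # invariance to a per-step constant shift
  tens_s <- tens
  tens_s$norm <- tens_s$norm + 0.37
  w <- c(0.2, 0.3, 0.1, 0.1, 0.2, 0.1)
  expect_equal(window_log_likelihood(seq_len(n), tens_s, w),
               window_log_likelihood(seq_len(n), tens, w))
})

test_that("window MLE recovers known weights from model-family data", {
  w_true <- c(0.5, 0.25, 0, 0, 0.25, 0)
  tens <- synthetic_tensor(500L, w = w_true, beta = 10, seed = 4)
  f <- fit_window(seq_len(500L), tens, merge = FALSE)
  expect_lt(max(abs(f$w_norm - w_true)), 0.1)
  # the MLE dominates the truth in-sample
  expect_gte(f$loglik, window_log_likelihood(seq_len(500L), tens, 10 * w_true))
  # normalized-weight contract
  expect_true(all(f$w_norm >= 0))
  expect_equal(sum(f$w_norm), 1)
})

test_that("a window whose choices follow one strategy loads its weight on it", {
  set.seed(5)
  n <- 120L
  tens <- synthetic_tensor(n, w = rep(0, 6), seed = 5)
  # flatten every strategy but local, then act greedily on local
  tens$norm[, 2:6, ] <- 0.5
  tens$actions <- vapply(seq_len(n), function(t) {
    DIRECTIONS[which.max(tens$norm[t, 1L, ])]
  }, character(1))
  f <- fit_window(seq_len(n), tens, merge = FALSE)
  expect_gte(f$w_norm[["local"]], 0.9)
})

test_that("fine windows split on direction changes, consumptions, and rounds", {
  # L,L,R,R,R with an energizer consumed at the fourth step
  log <- stub_log(c("left", "left", "right", "right", "right"),
                  consume_at = 4L)
  fw <- fine_windows(log)
  expect_equal(fw$start, c(1L, 3L, 4L))
  expect_equal(fw$end, c(3L, 4L, 6L))
  # constant direction, no events: a single window
  log1 <- stub_log(rep("up", 7L))
  expect_equal(nrow(fine_windows(log1)), 1L)
  # boundaries are a superset of direction changes; rounds split too
  log2 <- stub_log(c("up", "down", "down", "down"), rounds = c(1L, 1L, 2L, 2L))
  fw2 <- fine_windows(log2)
  expect_equal(fw2$start, c(1L, 2L, 3L))
  expect_equal(fw2$round, c(1L, 1L, 2L))
})

test_that("segmentation equals the exhaustive optimum and is monotone in K", {
  set.seed(6)
  exhaustive <- function(series, K) {
    k <- nrow(series)
    seg_loss <- function(i, j) {
      block <- series[i:j, , drop = FALSE]
      sum(sweep(block, 2L, colMeans(block))^2)
    }
    best <- Inf
    combs <- utils::combn(k - 1L, K - 1L)
    for (c_i in seq_len(ncol(combs))) {
      cuts <- c(0L, combs[, c_i], k)
      loss <- sum(vapply(seq_len(K), function(q) {
        seg_loss(cuts[q] + 1L, cuts[q + 1L])
      }, numeric(1)))
      best <- min(best, loss)
    }
    best
  }
  for (trial in 1:6) {
    series <- matrix(stats::runif(12L * 3L), nrow = 12L)
    losses <- vapply(1:6, function(K) {
      seg <- segment_weights(series, K)
      expect_equal(seg$K, K)
      if (K > 1L) expect_equal(seg$loss, exhaustive(series, K), tolerance = 1e-10)
      seg$loss
    }, numeric(1))
    expect_true(all(diff(losses) <= 1e-10))
  }
  # constant series: zero loss at any K; step series: exact breakpoint
  const <- matrix(1, 8L, 2L)
  expect_equal(segment_weights(const, 3L)$loss, 0)
  step <- rbind(matrix(0, 5L, 2L), matrix(1, 5L, 2L))
  expect_equal(segment_weights(step, 2L)$breaks, c(1L, 6L))
})

test_that("degenerate strategies merge and split their weight equally", {
  n <- 40L
  tens <- synthetic_tensor(n, w = rep(0, 6), seed = 7)
  # make local and energizer columns identical: same argmax sequences; then
  # sample actions at a moderate temperature so the optimum stays interior
  tens$norm[, "energizer", ] <- tens$norm[, "local", ]
  tens$raw <- tens$norm
  set.seed(70)
  w_gen <- c(3, 0, 0, 0, 0, 3)
  tens$actions <- vapply(seq_len(n), function(t) {
    Q <- as.vector(w_gen %*% tens$norm[t, , ])
    p <- exp(Q - max(Q)); p <- p / sum(p)
    DIRECTIONS[sample.int(4L, 1L, prob = p)]
  }, character(1))
  mg <- merge_degenerate(seq_len(n), tens)
  grp <- Filter(function(g) length(g) > 1L, mg$groups)
  expect_true(any(vapply(grp, function(g) {
    all(c(1L, 6L) %in% g)
  }, logical(1))))
  f_merged <- fit_window(seq_len(n), tens, merge = TRUE)
  expect_equal(f_merged$w_norm[["local"]], f_merged$w_norm[["energizer"]])
  # merged and unmerged optimizations reach the same maximum on this fixture
  f_unmerged <- fit_window(seq_len(n), tens, merge = FALSE)
  expect_equal(f_merged$loglik, f_unmerged$loglik, tolerance = 1e-4)
  # distinct argmax sequences map to the identity grouping
  tens2 <- synthetic_tensor(10L, w = rep(0, 6), seed = 8)
  mg2 <- merge_degenerate(seq_len(10L), tens2)
  expect_equal(mg2$n_groups, 6L)
})

test_that("the dynamic fit recovers a mid-series weight switch on synthetic tensors", {
  set.seed(9)
  n1 <- 60L; n2 <- 60L
  w1 <- c(0.85, 0.03, 0.03, 0.03, 0.03, 0.03)
  w2 <- c(0.03, 0.85, 0.03, 0.03, 0.03, 0.03)
  t1 <- synthetic_tensor(n1, w = w1, beta = 10, seed = 9)
  t2 <- synthetic_tensor(n2, w = w2, beta = 10, seed = 10)
  tens <- t1
  tens$norm <- tens$raw <- abind_rows(t1$norm, t2$norm)
  tens$available <- rbind(t1$available, t2$available)
  tens$actions <- c(t1$actions, t2$actions)
  tens$rounds <- rep(1L, n1 + n2)
  tens$n_steps <- n1 + n2
  log <- stub_log(tens$actions)
  fit <- fit_dynamic(log, tens, k_range = 2:8)
  lab <- STRATEGIES[max.col(fit$weights_step, ties.method = "first")]
  truth <- c(rep("local", n1), rep("global", n2))
  expect_gte(mean(lab == truth), 0.9)
  # per-step weights are piecewise constant on the chosen windows
  for (i in seq_len(nrow(fit$windows))) {
    rows <- fit$windows$start[i]:(fit$windows$end[i] - 1L)
    expect_equal(apply(fit$weights_step[rows, , drop = FALSE], 2L, stats::var),
                 stats::setNames(rep(0, 6), STRATEGIES))
  }
})

test_that("static fit yields one window and the likelihood bookkeeping holds", {
  w_true <- c(0.6, 0.2, 0, 0, 0.2, 0)
  tens <- synthetic_tensor(150L, w = w_true, beta = 8, seed = 11)
  log <- stub_log(tens$actions)
  fs <- fit_static(log, tens)
  expect_equal(nrow(fs$windows), 1L)
  expect_s3_class(fs, "strategy_fit")
  # loglik recomputes from the stored raw weights
  expect_equal(fs$loglik,
               window_log_likelihood(1:150, tens, fs$raw_weights[1L, ]),
               tolerance = 1e-8)
  expect_true(all(fs$weights >= 0))
  expect_equal(unname(rowSums(fs$weights)), 1)
  # prediction accuracy equals the argmax agreement and lies in [0,1]
  expect_equal(prediction_accuracy(fs, tens), mean(fs$pred == tens$actions))
  expect_gte(fs$accuracy, 0)
  expect_lte(fs$accuracy, 1)
  soft <- prediction_accuracy(fs, tens, method = "softmax")
  expect_gte(soft, 0)
  expect_lte(soft, 1)
})

test_that("zero weights predict at chance on junctions", {
  tens <- synthetic_tensor(400L, w = rep(0, 6), seed = 12)
  log <- stub_log(tens$actions)
  # actions are uniform over 4 directions; argmax prediction hits ~1/4
  fs <- fit_static(log, tens)
  expect_equal(chance_accuracy(tens), 0.25)
  pred0 <- predict_directions(matrix(0, 400L, 6L), tens)
  expect_lt(abs(mean(pred0 == tens$actions) - 0.25), 3 * sqrt(0.25 * 0.75 / 400))
})
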