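test_that("single-class fit has the closed-form solution", {
  set.seed(1)
  X <- matrix(rbinom(200 * 6, 1, 0.3), 200, 6)
  f <- em_fit(X, 1)
  expect_equal(as.numeric(f$model$theta), colMeans(X), tolerance = 1e-6)
  expect_equal(f$model$pi, 1)
  m <- colMeans(X)
  nj <- colSums(X)
  ll <- sum(nj * log(m) + (200 - nj) * log(1 - m))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$n_params, 6L)
})

test_that("perfectly separated blocks recover the analytic optimum", {
  X <- rbind(matrix(1, 30, 8), matrix(0, 30, 8))
  f <- em_fit(X, 2, n_starts = 5, seed = 2)
  expect_equal(f$model$pi, c(0.5, 0.5), tolerance = 1e-6)
  expect_true(all(abs(f$model$theta[1, ] - 1) < 1e-4))
  expect_true(all(f$model$theta[2, ] < 1e-4))
  expect_true(all(f$posteriors > 0.999 | f$posteriors < 0.001))
  expect_equal(f$entropy, 1, tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(3)
  for (r in 1:5) {
    d <- make_two_class(n = 80, J = 8, p_hi = 0.7, p_lo = 0.3, seed = r)
    f <- em_fit(d$X, 2, n_starts = 3, seed = r)
    expect_true(all(diff(f$loglik_trace) >= -1e-8 * abs(f$loglik)))
  }
})

test_that("fitted log-likelihood matches the brute-force mixture oracle", {
  set.seed(4)
  for (r in 1:5) {
    n <- sample(20:50, 1)
    J <- sample(3:6, 1)
    X <- matrix(rbinom(n * J, 1, runif(1, 0.2, 0.8)), n, J)
    K <- sample(2:3, 1)
    f <- em_fit(X, K, n_starts = 4, seed = r)
    expect_equal(f$loglik,
                 brute_mixture_loglik(X, f$model$pi, f$model$theta),
                 tolerance = 1e-8)
    expect_true(all(abs(rowSums(f$posteriors) - 1) < 1e-9))
    expect_equal(sum(f$model$pi), 1, tolerance = 1e-9)
    expect_true(all(diff(f$model$pi) <= 1e-12))  # canonical order
  }
})

test_that("information criteria follow their definitions", {
  idx <- fit_indices(-100, 10, 100)
  expect_equal(unname(idx["aic"]), 220)
  expect_equal(unname(idx["bic"]), 200 + 10 * log(100))
  expect_equal(unname(idx["caic"]), 200 + 10 * (log(100) + 1))
  expect_equal(unname(idx["caic"] - idx["bic"]), 10)
})

test_that("entropy hits its boundary cases and hand-computed value", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(lca_entropy(onehot), 1)
  expect_equal(lca_entropy(matrix(1 / 4, 5, 4)), 0)
  expect_equal(lca_entropy(matrix(c(0.8, 0.2), 1, 2)),
               1 - 0.5004024 / log(2), tolerance = 1e-6)
  expect_equal(lca_entropy(matrix(1, 10, 1)), 1)
  # separation increases entropy
  lo <- make_two_class(n = 200, J = 8, p_hi = 0.6, p_lo = 0.4, seed = 5)
  hi <- make_two_class(n = 200, J = 8, p_hi = 0.9, p_lo = 0.1, seed = 5)
  e_lo <- em_fit(lo$X, 2, n_starts = 4, seed = 5)$entropy
  e_hi <- em_fit(hi$X, 2, n_starts = 4, seed = 5)$entropy
  expect_gt(e_hi, e_lo)
  expect_true(e_lo >= 0 && e_hi <= 1)
})

test_that("the 2% average-improvement rule picks the documented K", {
  rule <- careclass:::choose_k_from_improvements
  expect_equal(rule(2:6, c(0.05, 0.03, 0.024, 0.015), 0.02), 5L)
  expect_equal(rule(2:3, c(0.01), 0.02), 2L)
  expect_equal(rule(2:4, c(0.021, NA), 0.02), 3L)
  expect_equal(rule(2:4, c(0.5, 0.5), 0.02), 4L)
})

test_that("class selection recovers K = 2 on clearly two-class data", {
  d <- make_two_class(n = 400, J = 12, p_hi = 0.85, p_lo = 0.15, seed = 6)
  sel <- select_num_classes(d$X, k_range = 2:4, n_starts = 4, seed = 6)
  expect_equal(sel$chosen_k, 2L)
  expect_true(sel$trace$chosen[sel$trace$K == 2])
})

test_that("modal assignment is argmax with lowest-index tie-break", {
  expect_equal(modal_assignment(matrix(c(0.9, 0.1), 1)), 1L)
  expect_equal(modal_assignment(matrix(c(0.5, 0.5), 1)), 1L)
  d <- make_two_class(n = 100, J = 10, p_hi = 0.95, p_lo = 0.05, seed = 7)
  f <- em_fit(d$X, 2, n_starts = 4, seed = 7)
  lab <- modal_assignment(f$posteriors)
  # up to label switching, recovery is exact on separated data
  agree <- max(mean(lab == d$labels), mean(lab == 3 - d$labels))
  expect_equal(agree, 1)
})

test_that("bootstrap goodness-of-fit behaves at its extremes", {
  d <- make_two_class(n = 120, J = 6, p_hi = 0.85, p_lo = 0.15, seed = 8)
  f2 <- em_fit(d$X, 2, n_starts = 4, seed = 8)
  expect_error(bootstrap_gof(f2, d$X, n_boot = 0), "n_boot")
  # a 1-class model on strongly 2-class data is overwhelmingly rejected
  f1 <- em_fit(d$X, 1)
  g1 <- bootstrap_gof(f1, d$X, n_boot = 30, seed = 8)
  expect_lt(g1$p_value, 0.05)
  # calibration at reduced scale: for data simulated from the fitted model
  # the p-values spread over (0, 1) instead of piling up near 0
  ps <- numeric(12)
  for (r in seq_len(12)) {
    set.seed(300 + r)
    lab <- sample(1:2, 120, TRUE, f2$model$pi)
    Xs <- matrix(as.numeric(matrix(runif(120 * 6), 120, 6) <
                              f2$model$theta[lab, ]), 120, 6)
    fs <- em_fit(Xs, 2, n_starts = 2, seed = 300 + r)
    ps[r] <- bootstrap_gof(fs, Xs, n_boot = 19, n_starts = 2,
                           seed = 900 + r)$p_value
  }
  expect_lte(mean(ps <= 0.05), 0.25)
  expect_gt(max(ps), 0.5)
  expect_gt(stats::sd(ps), 0)
})

test_that("grouped fit reduces to the plain fit with one group", {
  d <- make_two_class(n = 100, J = 6, seed = 10)
  f <- em_fit(d$X, 2, n_starts = 3, seed = 10)
  g <- grouped_fit(d$X, rep(1, 100), 2, n_starts = 3, seed = 10)
  expect_equal(g$loglik, f$loglik, tolerance = 1e-6)
  expect_equal(as.numeric(g$model$pi), f$model$pi, tolerance = 1e-4)
  expect_equal(g$n_params, f$n_params)
})

test_that("group-specific weights are detected only when present", {
  set.seed(11)
  J <- 8
  theta <- rbind(rep(0.85, J), rep(0.15, J))
  # no group effect: grouped BIC should not beat plain BIC
  lab <- sample(1:2, 400, replace = TRUE, prob = c(0.6, 0.4))
  X <- matrix(as.numeric(matrix(runif(400 * J), 400, J) < theta[lab, ]),
              400, J)
  grp <- rep(1:2, each = 200)
  plain <- em_fit(X, 2, n_starts = 4, seed = 11)
  grouped <- grouped_fit(X, grp, 2, n_starts = 4, seed = 11)
  expect_gte(grouped$bic, plain$bic - 1e-6)
  # opposite mixing proportions across groups: grouped BIC wins
  lab1 <- sample(1:2, 200, replace = TRUE, prob = c(0.9, 0.1))
  lab2 <- sample(1:2, 200, replace = TRUE, prob = c(0.1, 0.9))
  lab <- c(lab1, lab2)
  X2 <- matrix(as.numeric(matrix(runif(400 * J), 400, J) < theta[lab, ]),
               400, J)
  plain2 <- em_fit(X2, 2, n_starts = 4, seed = 12)
  grouped2 <- grouped_fit(X2, grp, 2, n_starts = 4, seed = 12)
  expect_lt(grouped2$bic, plain2$bic)
  expect_error(grouped_fit(X2[1:10, ], rep(1:2, c(9, 1)), 2), "group")
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rbinom(40, 1, 0.5), 10, 4)
  expect_error(em_fit(X, 11), "more classes")
  expect_error(em_fit(X + 0.5, 2), "binary")
})
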