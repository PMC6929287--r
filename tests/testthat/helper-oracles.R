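# Independent oracles used across the suite.

# Mixture log-likelihood summed density-by-density per child, kept free of
# any log-space machinery shared with the implementation.
brute_mixture_loglik <- function(X, pi, theta) {
  n <- nrow(X)
  ll <- 0
  for (i in seq_len(n)) {
    dens <- 0
    for (k in seq_along(pi)) {
      f <- pi[k]
      for (j in seq_len(ncol(X)))
        f <- f * (if (X[i, j] == 1) theta[k, j] else 1 - theta[k, j])
      dens <- dens + f
    }
    ll <- ll + log(dens)
  }
  ll
}

# Exhaustive gap-partition oracle: enumerate every contiguous partition of
# the sorted dates and keep the one where all within-cluster adjacent gaps
# are < gap_days and all between-cluster boundary gaps are >= gap_days.
# The gap rule makes that partition unique.
brute_partition <- function(dates, gap_days = 180L) {
  d <- sort(as.Date(dates))
  n <- length(d)
  if (n == 0L) return(list())
  if (n == 1L) return(list(d))
  gaps <- as.integer(diff(d))
  valid <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    ok <- all(gaps[cuts] >= gap_days) &&
      all(gaps[setdiff(seq_len(n - 1), cuts)] < gap_days)
    if (ok) {
      grp <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% cuts)))
      valid <- split(d, grp)
      break
    }
  }
  valid
}

# Brute-force discriminant classification: evaluate the canonical-space
# score for every group explicitly.
brute_dfa_classify <- function(model, X) {
  sc <- sweep(as.matrix(X), 2, model$grand_mean) %*% model$raw_coefficients
  out <- character(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    best <- Inf; who <- NA
    for (k in seq_len(model$g)) {
      v <- sum((sc[i, ] - model$centroids[k, ])^2) - 2 * log(model$priors[k])
      if (v < best) { best <- v; who <- model$levels[k] }
    }
    out[i] <- who
  }
  out
}

# Small two-class trajectory data with tunable separation.
make_two_class <- function(n = 200, J = 10, p_hi = 0.9, p_lo = 0.1,
                           seed = 1) {
  set.seed(seed)
  lab <- rep(1:2, each = n / 2)
  theta <- rbind(rep(p_hi, J), rep(p_lo, J))
  X <- matrix(as.numeric(matrix(runif(n * J), n, J) < theta[lab, ]), n, J)
  list(X = X, labels = lab, theta = theta)
}
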