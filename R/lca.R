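# Numerically safe bounds for conditional response probabilities.
THETA_EPS <- 1e-6

row_log_sum_exp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# Per-child log joint density log pi_k + sum_j log f(x_ij | theta_kj),
# n x K matrix. X binary, theta K x J.
log_joint <- function(X, pi, theta) {
  lt <- log(theta)
  lt1 <- log1p(-theta)
  S <- X %*% t(lt) + (1 - X) %*% t(lt1)
  sweep(S, 2, log(pi), "+")
}

check_binary <- function(X) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1))) stop("trajectory matrix must be binary")
  storage.mode(X) <- "double"
  X
}

#' Fit a binary latent class model by EM
#'
#' Standard binary LCA with conditional independence: class weights
#' `pi_k` and per-class, per-month visit probabilities `theta_kj`. The
#' E-step computes posteriors in log space; the M-step updates `pi` by
#' posterior means and `theta` by posterior-weighted item means. The best
#' of `n_starts` random starts (by final log-likelihood) is returned; each
#' converged start receives an additional polish phase of up to
#' `polish_iter` EM iterations at a tightened tolerance, standing in for a
#' Newton-type final optimization. Classes are reported in canonical order
#' of descending class weight.
#'
#' @param X Binary n x J matrix (rows = children, columns = months).
#' @param K Number of latent classes.
#' @param n_starts Random starts (default 10).
#' @param max_em_iter Maximum EM iterations per start (default 250).
#' @param polish_iter Additional polish iterations (default 50).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-7).
#' @param seed Integer seed; start s uses `seed + s - 1`.
#' @return An `lca_fit`: list with `model` (K, pi, theta), `loglik`,
#'   `n_params`, `aic`, `bic`, `caic`, `posteriors`, `entropy`,
#'   `loglik_trace` (best start), `n_starts_used`, `converged`,
#'   `best_start_seed`.
#' @export
em_fit <- function(X, K, n_starts = 10L, max_em_iter = 250L,
                   polish_iter = 50L, tol = 1e-7, seed = 1L) {
  X <- check_binary(X)
  n <- nrow(X); J <- ncol(X)
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("more classes than children")

  if (K == 1L) {
    theta <- matrix(pmin(pmax(colMeans(X), THETA_EPS), 1 - THETA_EPS), 1, J)
    ll <- sum(log_joint(X, 1, theta))
    return(finish_fit(list(pi = 1, theta = theta), ll, X,
                      trace = ll, converged = TRUE, n_starts_used = 1L,
                      best_seed = seed, grouped = FALSE, groups = NULL))
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    theta <- matrix(stats::runif(K * J, 0.1, 0.9), K, J)
    pi <- rep(1 / K, K)
    res <- em_run(X, pi, theta, max_em_iter, tol, groups = NULL)
    if (res$converged && polish_iter > 0L) {
      pol <- em_run(X, res$pi, res$theta, polish_iter, 1e-8, groups = NULL)
      pol$trace <- c(res$trace, pol$trace)
      pol$converged <- TRUE
      res <- pol
    }
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$seed <- seed + s - 1L
    }
  }
  finish_fit(best, best$loglik, X, trace = best$trace,
             converged = best$converged, n_starts_used = n_starts,
             best_seed = best$seed, grouped = FALSE, groups = NULL)
}

# Core EM loop; groups = NULL for a single weight vector, otherwise a
# factor giving group-specific class weights (theta shared).
em_run <- function(X, pi, theta, max_iter, tol, groups = NULL) {
  n <- nrow(X)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  grouped <- !is.null(groups)
  for (it in seq_len(max_iter)) {
    if (grouped) {
      lp <- log(pi[groups, , drop = FALSE]) +
        X %*% t(log(theta)) + (1 - X) %*% t(log1p(-theta))
    } else {
      lp <- log_joint(X, pi, theta)
    }
    lse <- row_log_sum_exp(lp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    post <- exp(lp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    nk <- colSums(post)
    if (grouped) {
      cnt <- as.vector(table(groups))
      pi <- rowsum(post, groups)[levels(groups), , drop = FALSE] / cnt
      pi <- pmax(pi, 1e-12)
      pi <- pi / rowSums(pi)
    } else {
      pi <- nk / n
    }
    theta <- crossprod(post, X) / nk
    theta <- pmin(pmax(theta, THETA_EPS), 1 - THETA_EPS)
  }
  list(pi = pi, theta = theta, loglik = ll, trace = trace,
       converged = converged)
}

# Canonical ordering, posteriors, indices, entropy; shared by em_fit and
# grouped_fit.
finish_fit <- function(res, ll, X, trace, converged, n_starts_used,
                       best_seed, grouped, groups) {
  n <- nrow(X); J <- ncol(X)
  pi <- res$pi; theta <- res$theta
  if (grouped) {
    marg <- colMeans(pi[groups, , drop = FALSE])
    ord <- order(-marg, -rowMeans(theta))
    pi <- pi[, ord, drop = FALSE]
    K <- ncol(pi)
    G <- nrow(pi)
    n_params <- G * (K - 1L) + K * J
    lp <- log(pi[groups, , drop = FALSE]) +
      X %*% t(log(theta[ord, , drop = FALSE])) +
      (1 - X) %*% t(log1p(-theta[ord, , drop = FALSE]))
  } else {
    K <- length(pi)
    # ties in class weight broken by descending mean response probability
    ord <- order(-pi, -rowMeans(theta))
    pi <- pi[ord]
    n_params <- (K - 1L) + K * J
    lp <- log_joint(X, pi, theta[ord, , drop = FALSE])
  }
  theta <- theta[ord, , drop = FALSE]
  lse <- row_log_sum_exp(lp)
  post <- exp(lp - lse)
  ll <- sum(lse)  # consistent with the returned parameters
  idx <- fit_indices(ll, n_params, n)
  structure(list(
    model = list(K = K, pi = pi, theta = theta),
    loglik = ll, n_params = n_params,
    aic = idx[["aic"]], bic = idx[["bic"]], caic = idx[["caic"]],
    posteriors = post, entropy = lca_entropy(post),
    loglik_trace = trace, converged = converged,
    n_starts_used = n_starts_used, best_start_seed = best_seed,
    grouped = grouped
  ), class = "lca_fit")
}

#' Information criteria for a fitted model
#'
#' AIC = -2l + 2p; BIC = -2l + p ln n; CAIC = -2l + p (ln n + 1).
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n Sample size.
#' @return Named numeric vector `c(aic, bic, caic)`.
#' @export
fit_indices <- function(loglik, n_params, n) {
  stopifnot(n >= 1)
  c(aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n),
    caic = -2 * loglik + n_params * (log(n) + 1))
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum_i sum_k (-p_ik ln p_ik) / (n ln K)`, with `0 ln 0 := 0`.
#' Values near 1 indicate clearly delineated classes; a single class is
#' defined to have entropy 1.
#'
#' @param posteriors n x K matrix with rows summing to 1.
#' @return Scalar in `[0, 1]`.
#' @export
lca_entropy <- function(posteriors) {
  P <- as.matrix(posteriors)
  K <- ncol(P)
  if (K == 1L) return(1)
  n <- nrow(P)
  h <- -P * log(P)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (n * log(K))
}

# The selection rule itself, factored out so it is testable without fits:
# scan ascending K; chosen K is the largest whose average improvement over
# K-1 meets the threshold before the first failure.
choose_k_from_improvements <- function(k_range, improvements, threshold) {
  stopifnot(length(improvements) == length(k_range) - 1L)
  chosen <- k_range[1]
  for (i in seq_along(improvements)) {
    if (is.na(improvements[i]) || improvements[i] < threshold) break
    chosen <- k_range[i + 1L]
  }
  chosen
}

#' Select the number of latent classes by the 2% average-improvement rule
#'
#' Fits each K in `k_range`; the improvement at K is the mean over AIC,
#' BIC and CAIC of `(index[K-1] - index[K]) / index[K-1]`. Scanning
#' upward, the chosen K is the largest whose improvement meets `threshold`
#' before the first K that fails it. A K that fails to converge is logged
#' and treated as a failure at that K.
#'
#' @param X Binary trajectory matrix.
#' @param k_range Ascending integer vector of class counts (default 2:10).
#' @param threshold Average relative improvement required (default 0.02).
#' @param n_starts,max_em_iter,polish_iter,tol Passed to [em_fit()].
#' @param seed Integer seed; K uses `seed + 100 * K`.
#' @return A `selection_trace`: list with `trace` data frame (K, loglik,
#'   aic, bic, caic, entropy, avg_improvement, chosen), `chosen_k`, and
#'   the list of `fits`.
#' @export
select_num_classes <- function(X, k_range = 2:10, threshold = 0.02,
                               n_starts = 10L, max_em_iter = 250L,
                               polish_iter = 50L, tol = 1e-7, seed = 1L) {
  stopifnot(!is.unsorted(k_range), all(diff(k_range) > 0))
  fits <- lapply(k_range, function(K)
    em_fit(X, K, n_starts = n_starts, max_em_iter = max_em_iter,
           polish_iter = polish_iter, tol = tol, seed = seed + 100L * K))
  names(fits) <- k_range
  idx <- t(vapply(fits, function(f) c(f$aic, f$bic, f$caic), numeric(3)))
  colnames(idx) <- c("aic", "bic", "caic")
  if (any(idx <= 0))
    stop("non-positive fit index: relative improvement undefined")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  imp <- rep(NA_real_, length(k_range) - 1L)
  for (i in seq_along(imp)) {
    if (!conv[i + 1L]) next  # failure to converge counts as a failed step
    imp[i] <- mean((idx[i, ] - idx[i + 1L, ]) / idx[i, ])
  }
  chosen <- choose_k_from_improvements(k_range, imp, threshold)
  trace <- data.frame(
    K = k_range,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    idx,
    entropy = vapply(fits, `[[`, numeric(1), "entropy"),
    avg_improvement = c(NA_real_, imp),
    converged = conv,
    chosen = k_range == chosen
  )
  rownames(trace) <- NULL
  structure(list(trace = trace, chosen_k = chosen, fits = fits,
                 threshold = threshold),
            class = "selection_trace")
}

#' Modal class assignment
#'
#' Argmax of each posterior row; ties go to the lowest class index
#' (classes are in canonical descending-weight order).
#'
#' @param posteriors n x K posterior matrix.
#' @return Integer vector of class indices.
#' @export
modal_assignment <- function(posteriors) {
  max.col(as.matrix(posteriors), ties.method = "first")
}

# Saturated (by observed response pattern) log-likelihood.
saturated_loglik <- function(X) {
  pat <- apply(X, 1, paste, collapse = "")
  tab <- table(pat)
  n <- nrow(X)
  sum(tab * log(tab / n))
}

#' Parametric bootstrap goodness-of-fit test
#'
#' Bootstrap of the likelihood-ratio statistic
#' `G2 = 2 (l_saturated - l_model)`, where the saturated log-likelihood is
#' taken over observed response patterns: `n_boot` datasets are simulated
#' from the fitted model, a K-class model is refit to each, and the
#' p-value is the fraction of simulated `G2` at least as large as the
#' observed one.
#'
#' @param fit An `lca_fit`.
#' @param X The data the model was fitted to.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param n_starts Random starts per refit (default 3; refits start near
#'   the truth so few starts suffice).
#' @param seed Integer seed.
#' @return List with `p_value`, `g2_observed`, `g2_boot`.
#' @export
bootstrap_gof <- function(fit, X, n_boot = 500L, n_starts = 3L, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be at least 1")
  X <- check_binary(X)
  n <- nrow(X); J <- ncol(X)
  K <- fit$model$K
  g2_obs <- 2 * (saturated_loglik(X) - fit$loglik)
  g2_sim <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(seed + b)
    lab <- sample.int(K, n, replace = TRUE, prob = fit$model$pi)
    Xb <- matrix(stats::runif(n * J), n, J) <
      fit$model$theta[lab, , drop = FALSE]
    Xb <- matrix(as.numeric(Xb), n, J)
    fb <- em_fit(Xb, K, n_starts = n_starts, seed = seed + 7919L * b)
    g2_sim[b] <- 2 * (saturated_loglik(Xb) - fb$loglik)
  }
  list(p_value = mean(g2_sim >= g2_obs), g2_observed = g2_obs,
       g2_boot = g2_sim)
}

#' Latent class model with group-specific class weights
#'
#' EM fit in which each group (e.g. intake cohort year or agency) has its
#' own class-weight vector while the conditional visit probabilities are
#' shared. Comparing this fit's BIC with the plain fit's reproduces the
#' check that group structure does not substantively improve the model.
#' With a single group the result coincides with [em_fit()].
#'
#' @param X Binary trajectory matrix.
#' @param groups Per-child group ids (coerced to factor).
#' @param K Number of classes.
#' @inheritParams em_fit
#' @return An `lca_fit` whose `model$pi` is a G x K matrix (group rows).
#' @export
grouped_fit <- function(X, groups, K, n_starts = 10L, max_em_iter = 250L,
                        polish_iter = 50L, tol = 1e-7, seed = 1L) {
  X <- check_binary(X)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(X))
  if (min(table(groups)) < K) stop("every group must have at least K children")
  n <- nrow(X); J <- ncol(X); G <- nlevels(groups)
  if (K > n) stop("more classes than children")

  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    theta <- matrix(stats::runif(K * J, 0.1, 0.9), K, J)
    pi <- matrix(1 / K, G, K, dimnames = list(levels(groups), NULL))
    res <- em_run(X, pi, theta, max_em_iter, tol, groups = groups)
    if (res$converged && polish_iter > 0L) {
      pol <- em_run(X, res$pi, res$theta, polish_iter, 1e-8, groups = groups)
      pol$trace <- c(res$trace, pol$trace)
      pol$converged <- TRUE
      res <- pol
    }
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$seed <- seed + s - 1L
    }
  }
  finish_fit(best, best$loglik, X, trace = best$trace,
             converged = best$converged, n_starts_used = n_starts,
             best_seed = best$seed, grouped = TRUE, groups = groups)
}
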