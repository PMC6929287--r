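# Missingness-pattern bookkeeping: integer code per row, observed-variable
# index list per pattern.
missingness_patterns <- function(X) {
  R <- !is.na(X)
  key <- apply(R * 1L, 1, paste, collapse = "")
  codes <- factor(key)
  obs <- lapply(levels(codes), function(k) {
    which(strsplit(k, "")[[1]] == "1")
  })
  list(codes = codes, obs = obs)
}

#' Multivariate-normal EM estimation with missing data
#'
#' Maximum-likelihood estimation of a mean vector and covariance matrix
#' from an incomplete data matrix under multivariate normality, by EM over
#' missingness patterns. Used by both [little_mcar_test()] and
#' [em_impute()].
#'
#' @param X Numeric matrix with `NA`s (rows with no observed value are
#'   dropped).
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Relative observed-data log-likelihood tolerance (default
#'   1e-6).
#' @param ridge Diagonal ridge added before inversions (default 1e-8).
#' @return List with `mu`, `sigma`, `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`.
#' @export
em_mvnorm <- function(X, max_iter = 200L, tol = 1e-6, ridge = 1e-8) {
  X <- as.matrix(X)
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (any(colSums(!is.na(X)) < 2L))
    stop("every variable must be observed for at least 2 rows")
  pat <- missingness_patterns(X)
  rows_by_pat <- split(seq_len(n), pat$codes)

  mu <- colMeans(X, na.rm = TRUE)
  sigma <- stats::cov(X, use = "pairwise.complete.obs")
  sigma[!is.finite(sigma)] <- 0
  sigma <- sigma * (n - 1) / n
  diag(sigma) <- pmax(diag(sigma), 1e-8)

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    ll <- 0
    for (g in seq_along(rows_by_pat)) {
      rows <- rows_by_pat[[g]]
      o <- pat$obs[[g]]
      m <- setdiff(seq_len(p), o)
      Yo <- X[rows, o, drop = FALSE]
      So <- sigma[o, o, drop = FALSE] + diag(ridge, length(o))
      Soi <- solve(So)
      cent <- sweep(Yo, 2, mu[o])
      # observed-data loglik contribution
      ll <- ll - 0.5 * (length(rows) * (length(o) * log(2 * pi) +
                                          determinant(So)$modulus) +
                          sum((cent %*% Soi) * cent))
      Yfull <- matrix(0, length(rows), p)
      Yfull[, o] <- Yo
      if (length(m)) {
        B <- sigma[m, o, drop = FALSE] %*% Soi
        Em <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          cent %*% t(B)
        Yfull[, m] <- Em
        Cm <- sigma[m, m, drop = FALSE] -
          B %*% sigma[o, m, drop = FALSE]
        T2[m, m] <- T2[m, m] + length(rows) * Cm
      }
      T1 <- T1 + colSums(Yfull)
      T2 <- T2 + crossprod(Yfull)
    }
    mu <- T1 / n
    sigma <- T2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll <- as.numeric(ll)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, loglik = ll, loglik_trace = trace,
       converged = converged, n_iter = it)
}

#' Little's test of missing completely at random
#'
#' Estimates the grand mean and covariance by EM under multivariate
#' normality, then compares each missingness pattern's observed-variable
#' mean with the grand mean:
#' `chi2 = sum_j n_j (ybar_j - mu_j)' Sigma_j^{-1} (ybar_j - mu_j)`,
#' with `df = sum_j p_j - p` (patterns restricted to their observed
#' variables). A significant result indicates the missingness is not MCAR.
#'
#' @param X Numeric matrix (or data frame) with `NA`s.
#' @param max_iter,tol,ridge Passed to [em_mvnorm()].
#' @return List with `chi2`, `df`, `p_value`, `n_patterns`.
#' @export
little_mcar_test <- function(X, max_iter = 200L, tol = 1e-6, ridge = 1e-8) {
  X <- as.matrix(X)
  keep <- rowSums(!is.na(X)) > 0
  X <- X[keep, , drop = FALSE]
  p <- ncol(X)
  pat <- missingness_patterns(X)
  if (nlevels(pat$codes) < 2L)
    stop("single missingness pattern: Little's test is undefined (df = 0)")
  est <- em_mvnorm(X, max_iter = max_iter, tol = tol, ridge = ridge)
  rows_by_pat <- split(seq_len(nrow(X)), pat$codes)
  chi2 <- 0
  df <- -p
  for (g in seq_along(rows_by_pat)) {
    rows <- rows_by_pat[[g]]
    o <- pat$obs[[g]]
    df <- df + length(o)
    ybar <- colMeans(X[rows, o, drop = FALSE])
    d <- ybar - est$mu[o]
    So <- est$sigma[o, o, drop = FALSE] + diag(ridge, length(o))
    chi2 <- chi2 + length(rows) * as.numeric(crossprod(d, solve(So, d)))
  }
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_patterns = nlevels(pat$codes))
}

#' EM imputation of missing values
#'
#' Fits a multivariate normal by EM ([em_mvnorm()]) and replaces each
#' missing cell with its conditional mean given the row's observed
#' variables under the final estimates. Observed cells are never altered.
#'
#' @param X Numeric matrix (or data frame) with `NA`s.
#' @param max_iter,tol,ridge Passed to [em_mvnorm()].
#' @return The completed numeric matrix, with attributes `mu`, `sigma`,
#'   `converged`.
#' @export
em_impute <- function(X, max_iter = 200L, tol = 1e-6, ridge = 1e-8) {
  X <- as.matrix(X)
  if (!anyNA(X)) {
    out <- X
    attr(out, "converged") <- TRUE
    return(out)
  }
  est <- em_mvnorm(X, max_iter = max_iter, tol = tol, ridge = ridge)
  if (!est$converged)
    warning("EM did not converge within max_iter; imputing from last iterate")
  p <- ncol(X)
  pat <- missingness_patterns(X)
  rows_by_pat <- split(seq_len(nrow(X)), pat$codes)
  out <- X
  for (g in seq_along(rows_by_pat)) {
    rows <- rows_by_pat[[g]]
    o <- pat$obs[[g]]
    m <- setdiff(seq_len(p), o)
    if (!length(m)) next
    So <- est$sigma[o, o, drop = FALSE] + diag(ridge, length(o))
    B <- est$sigma[m, o, drop = FALSE] %*% solve(So)
    cent <- sweep(X[rows, o, drop = FALSE], 2, est$mu[o])
    out[rows, m] <- matrix(est$mu[m], length(rows), length(m), byrow = TRUE) +
      cent %*% t(B)
  }
  attr(out, "mu") <- est$mu
  attr(out, "sigma") <- est$sigma
  attr(out, "converged") <- est$converged
  out
}
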