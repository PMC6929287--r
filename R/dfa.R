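#' Canonical discriminant function analysis
#'
#' Eigen-analysis of the within-groups-inverse times between-groups
#' scatter. Raw coefficients are scaled so canonical scores have pooled
#' within-group variance 1 (pooled covariance divisor `n - g`);
#' standardized coefficients multiply the raw ones by the pooled
#' within-group standard deviations; structure coefficients are the pooled
#' within-groups correlations between each predictor and each canonical
#' score. Group centroids are the group means of the canonical scores
#' (centered at the grand mean). Signs are fixed so the
#' largest-magnitude standardized coefficient of each function is
#' positive.
#'
#' @param X Numeric n x p predictor matrix.
#' @param labels Group labels (coerced to factor), g groups.
#' @param priors `"proportional"` (group sizes) or a probability vector in
#'   group-level order.
#' @return A `dfa_model`: eigenvalues, raw/standardized/structure
#'   coefficients (p x s), centroids (g x s), priors, pooled within
#'   covariance, group means and counts, grand mean, n, p, g, s.
#' @export
dfa_fit <- function(X, labels, priors = "proportional") {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X); p <- ncol(X); g <- nlevels(labels)
  if (n <= p + g) stop("need n > p + g observations")
  counts <- table(labels)
  if (min(counts) < 2L) stop("every group needs at least 2 observations")
  grand <- colMeans(X)
  means <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(X[labels == l, , drop = FALSE])))
  rownames(means) <- levels(labels)
  Xc <- X - means[as.integer(labels), , drop = FALSE]
  W <- crossprod(Xc)
  dm <- sweep(means, 2, grand)
  B <- crossprod(dm * sqrt(as.numeric(counts)), dm * sqrt(as.numeric(counts)))
  s <- min(p, g - 1L)
  Sw <- W / (n - g)

  if (rcond(W) < 1e-12) stop("singular within-groups scatter matrix")
  U <- chol(W)
  Vi <- backsolve(U, diag(p))            # U^{-1}
  S <- t(Vi) %*% B %*% Vi                # symmetric, similar to W^{-1} B
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values[seq_len(s)], 0)
  A <- Vi %*% eg$vectors[, seq_len(s), drop = FALSE]  # a' W a = 1
  A <- A * sqrt(n - g)                   # a' Sw a = 1
  std <- A * sqrt(diag(Sw))
  # deterministic sign: largest |standardized coefficient| positive
  for (j in seq_len(s)) {
    i <- which.max(abs(std[, j]))
    if (std[i, j] < 0) {
      A[, j] <- -A[, j]
      std[, j] <- -std[, j]
    }
  }
  struct <- (Sw %*% A) / sqrt(diag(Sw))
  centroids <- dm %*% A
  pri <- if (identical(priors, "proportional")) {
    as.numeric(counts) / n
  } else {
    stopifnot(length(priors) == g, abs(sum(priors) - 1) < 1e-8)
    as.numeric(priors)
  }
  dimnames(A) <- dimnames(std) <- dimnames(struct) <-
    list(colnames(X), paste0("LD", seq_len(s)))
  rownames(centroids) <- levels(labels)
  colnames(centroids) <- paste0("LD", seq_len(s))
  structure(list(
    eigenvalues = lambda, raw_coefficients = A,
    standardized_coefficients = std, structure_coefficients = struct,
    centroids = centroids, priors = pri, pooled_within_cov = Sw,
    group_means = means, group_counts = as.numeric(counts),
    grand_mean = grand, levels = levels(labels),
    n = n, p = p, g = g, s = s
  ), class = "dfa_model")
}

#' Sequential Wilks' lambda tests
#'
#' For m = 0..s-1 functions removed: `Lambda_m = prod_{i>m} 1/(1+lambda_i)`,
#' Bartlett's `chi2 = -(n - 1 - (p+g)/2) ln Lambda_m`, and
#' `df = (p - m)(g - 1 - m)`. Also reports each function's percent of
#' explained variance `lambda_i / sum(lambda) * 100`.
#'
#' @param model A `dfa_model`.
#' @param n Sample size (defaults to the model's).
#' @return Data frame with columns m, wilks_lambda, chi2, df, p_value,
#'   pct_variance.
#' @export
wilks_sequence <- function(model, n = model$n) {
  lambda <- model$eigenvalues
  s <- model$s; p <- model$p; g <- model$g
  pct <- if (sum(lambda) > 0) 100 * lambda / sum(lambda) else rep(0, s)
  out <- lapply(seq_len(s) - 1L, function(m) {
    L <- prod(1 / (1 + lambda[seq_len(s) > m]))
    chi2 <- -(n - 1 - (p + g) / 2) * log(L)
    df <- (p - m) * (g - 1 - m)
    data.frame(m = m, wilks_lambda = L, chi2 = chi2, df = df,
               p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
               pct_variance = pct[m + 1L])
  })
  do.call(rbind, out)
}

# Canonical scores for new data.
dfa_scores <- function(model, X) {
  sweep(as.matrix(X), 2, model$grand_mean) %*% model$raw_coefficients
}

#' Classify cases from a fitted discriminant model
#'
#' Assigns each case to the group with the largest posterior under the
#' equal-covariance Gaussian model with the model's priors — equivalently
#' the smallest squared distance to the group centroid in canonical space
#' minus `2 ln prior`.
#'
#' @param model A `dfa_model`.
#' @param X Predictor matrix.
#' @return Factor of predicted group labels.
#' @export
dfa_classify <- function(model, X) {
  sc <- dfa_scores(model, X)
  d2 <- sapply(seq_len(model$g), function(k) {
    rowSums(sweep(sc, 2, model$centroids[k, ])^2) - 2 * log(model$priors[k])
  })
  d2 <- matrix(d2, ncol = model$g)   # keep matrix shape when nrow(X) == 1
  factor(model$levels[max.col(-d2, ties.method = "first")],
         levels = model$levels)
}

#' Leave-one-out cross-validated classification accuracy
#'
#' Jackknife: refit the discriminant model excluding each case in turn and
#' classify the held-out case; accuracy is the percentage correct.
#'
#' @param X Predictor matrix.
#' @param labels Group labels.
#' @param priors Passed to [dfa_fit()] (a fixed vector is reused as-is;
#'   `"proportional"` recomputes from each training fold).
#' @return List with `accuracy` (percent), `predicted` (factor).
#' @export
dfa_loo <- function(X, labels, priors = "proportional") {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- dfa_fit(X[-i, , drop = FALSE], labels[-i], priors)
    pred[i] <- as.character(dfa_classify(fit, X[i, , drop = FALSE]))
  }
  pred <- factor(pred, levels = levels(labels))
  list(accuracy = 100 * mean(pred == labels), predicted = pred)
}

#' Classification report for a discriminant model
#'
#' @param model A `dfa_model`.
#' @param X,labels Data to classify (typically the training data).
#' @param loo Also run leave-one-out cross-validation (slower).
#' @return List with `table` (actual x predicted), `accuracy` (percent,
#'   resubstitution), `loo_accuracy` (or `NA`), `wilks` (the sequential
#'   test table).
#' @export
dfa_report <- function(model, X, labels, loo = FALSE) {
  labels <- factor(as.character(labels), levels = model$levels)
  pred <- dfa_classify(model, X)
  tab <- table(actual = labels, predicted = pred)
  acc <- 100 * mean(pred == labels)
  loo_acc <- if (loo) dfa_loo(X, labels, model$priors)$accuracy else NA_real_
  list(table = tab, accuracy = acc, loo_accuracy = loo_acc,
       wilks = wilks_sequence(model))
}
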