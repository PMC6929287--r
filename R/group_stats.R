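#' Prevalence-weighted pooled percentage
#'
#' Pools per-pattern percentages (or means) into an overall figure by
#' weighting with pattern sizes: `sum(ns * values) / sum(ns)`. On
#' child-level data this equals the percentage computed directly from the
#' pooled sample.
#'
#' @param values Per-pattern percentages or means.
#' @param ns Per-pattern sizes.
#' @return Scalar pooled value.
#' @export
prevalence_weighted <- function(values, ns) {
  stopifnot(length(values) == length(ns))
  sum(ns * values) / sum(ns)
}

#' Pattern-level service-use and demographic summary table
#'
#' One row per pattern plus a total row: n, per cent of sample, per cent
#' male, age mean and SD, episode-category distribution (0 / 1 / 2+ per
#' cent), duration of involvement mean and SD (years), per cent lasting
#' more than 2 years, visits mean and SD, and per-pattern share of all
#' visits.
#'
#' @param labels Per-child pattern labels.
#' @param sex Per-child sex (`"M"`/`"F"`).
#' @param age Per-child age at index (years).
#' @param summaries Per-child service-use data frame from
#'   [summarize_cohort()] (same order).
#' @return Data frame with one row per pattern and a `"Total"` row.
#' @export
pattern_summary <- function(labels, sex, age, summaries) {
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty pattern")
  n <- length(labels)
  vol <- volume_shares(summaries$total_visits, labels)
  one <- function(idx, name, volume) {
    s <- summaries[idx, ]
    data.frame(
      pattern = name,
      n = length(idx),
      pct = 100 * length(idx) / n,
      pct_male = 100 * mean(sex[idx] == "M"),
      age_mean = mean(age[idx]), age_sd = stats::sd(age[idx]),
      pct_ep0 = 100 * mean(s$episode_category == "0"),
      pct_ep1 = 100 * mean(s$episode_category == "1"),
      pct_ep2plus = 100 * mean(s$episode_category == "2+"),
      duration_mean = mean(s$duration_years),
      duration_sd = stats::sd(s$duration_years),
      pct_over_two_years = 100 * mean(s$over_two_years),
      visits_mean = mean(s$total_visits),
      visits_sd = stats::sd(s$total_visits),
      volume_pct = volume,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(levels(labels), function(l)
    one(which(labels == l), l, vol[[l]]))
  rows <- c(rows, list(one(seq_len(n), "Total", 100)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test with adjusted standardized residuals
#'
#' Pearson chi-square (no continuity correction) with
#' `df = (r - 1)(c - 1)`, plus the adjusted standardized residual per cell
#' `(O - E) / sqrt(E (1 - row/n)(1 - col/n))`; the squared residual is a
#' 1-df chi-square per cell. Warns when any expected count is below 1.
#'
#' @param x Factor (or a contingency table/matrix, in which case `y` is
#'   ignored).
#' @param y Second factor.
#' @return List with `chi2`, `df`, `p_value`, `expected`,
#'   `adjusted_residuals`, `residual_chi2` (squared residuals),
#'   `residual_p` (1-df p-values).
#' @export
contingency_test <- function(x, y = NULL) {
  tab <- if (is.table(x) || is.matrix(x)) as.table(as.matrix(x)) else table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least 2 levels on each margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 1))
    warning("expected cell count below 1")
  res_chi2 <- ct$stdres^2
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected,
       adjusted_residuals = ct$stdres, residual_chi2 = res_chi2,
       residual_p = stats::pchisq(res_chi2, 1, lower.tail = FALSE))
}

# Compact letter display from a logical "not significantly different"
# matrix, by insert-absorb over groups in mean order.
compact_letters <- function(nonsig, order_idx) {
  g <- nrow(nonsig)
  sets <- list()
  for (i in order_idx) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(nonsig[i, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], i)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- i
  }
  letters_out <- character(g)
  for (s in seq_along(sets)) {
    for (i in sets[[s]])
      letters_out[i] <- paste0(letters_out[i], LETTERS[s])
  }
  letters_out
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' Standard one-way ANOVA, followed by pairwise t-tests using the pooled
#' mean-square error with Bonferroni-adjusted p-values, summarized as a
#' compact letter display: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param values Numeric response.
#' @param labels Group labels.
#' @param alpha Family significance level (default 0.05).
#' @return List with `F`, `df1`, `df2`, `p_value`, `group_means`,
#'   `group_ns`, `pairwise` (data frame), `letters` (named by group).
#' @export
oneway_anova_bonferroni <- function(values, labels, alpha = 0.05) {
  labels <- droplevels(as.factor(labels))
  g <- nlevels(labels)
  stopifnot(g >= 2L, all(table(labels) >= 2L))
  fit <- stats::aov(values ~ labels)
  an <- suppressWarnings(stats::anova(fit))
  mse <- an[2, "Mean Sq"]
  if (!is.finite(mse) ||
      mse <= 1e-12 * (stats::var(values) + abs(mean(values)) + 1e-300))
    stop("zero within-group variance")
  df2 <- an[2, "Df"]
  means <- tapply(values, labels, mean)
  ns <- tapply(values, labels, length)
  pairs <- utils::combn(g, 2)
  tstat <- (means[pairs[1, ]] - means[pairs[2, ]]) /
    sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  praw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  padj <- stats::p.adjust(praw, method = "bonferroni")
  pw <- data.frame(
    group1 = levels(labels)[pairs[1, ]], group2 = levels(labels)[pairs[2, ]],
    t = as.numeric(tstat), p_raw = as.numeric(praw),
    p_adjusted = as.numeric(padj)
  )
  nonsig <- matrix(TRUE, g, g)
  for (k in seq_len(ncol(pairs))) {
    ns_k <- padj[k] >= alpha
    nonsig[pairs[1, k], pairs[2, k]] <- ns_k
    nonsig[pairs[2, k], pairs[1, k]] <- ns_k
  }
  letts <- compact_letters(nonsig, order(means))
  names(letts) <- levels(labels)
  list(F = an[1, "F value"], df1 = an[1, "Df"], df2 = df2,
       p_value = an[1, "Pr(>F)"], group_means = means, group_ns = ns,
       pairwise = pw, letters = letts)
}

#' Clinical cut-off flags and comorbidity category
#'
#' Flags each scale at the clinical cut-off (T-score >= 65, the 93rd
#' percentile) and assigns the three-level comorbidity category:
#' `"subclinical"` (neither Externalizing nor Internalizing at or above
#' cut-off), `"either"` (exactly one of the two), `"both"`.
#'
#' @param covariates Complete (imputed) covariate data frame with columns
#'   ext_t, int_t, imp_t, burden_t.
#' @param cutoff Clinical cut-off (default 65).
#' @return Data frame of four logical flags plus `comorbidity` (factor).
#' @export
clinical_cutoffs <- function(covariates, cutoff = 65) {
  ext <- covariates$ext_t >= cutoff
  int <- covariates$int_t >= cutoff
  comorbid <- ifelse(ext & int, "both", ifelse(ext | int, "either",
                                               "subclinical"))
  data.frame(
    ext_ge = ext, int_ge = int,
    imp_ge = covariates$imp_t >= cutoff,
    burden_ge = covariates$burden_t >= cutoff,
    comorbidity = factor(comorbid,
                         levels = c("subclinical", "either", "both"))
  )
}

#' Map latent classes to the five pattern names
#'
#' Names classes from their descriptives: the class with the highest mean
#' visits is Ongoing/Intensive-Episodic and the one with the lowest is
#' Minimal; among the remainder, a class whose modal episode category is
#' "2+" is Brief Episodic; the remaining two are Acute and Intensive in
#' order of mean visits.
#'
#' @param class_index Per-child class index (1..5).
#' @param summaries Per-child service-use summaries (same order).
#' @return Character vector mapping class index to pattern name.
#' @export
assign_pattern_names <- function(class_index, summaries) {
  K <- max(class_index)
  stopifnot(K == 5L)
  mv <- tapply(summaries$total_visits, class_index, mean)
  modal2 <- tapply(summaries$episode_category, class_index,
                   function(x) names(which.max(table(x))) == "2+")
  nm <- character(K)
  ord <- order(mv)
  nm[ord[1]] <- "Minimal"
  nm[ord[K]] <- "Ongoing/Intensive-Episodic"
  mid <- ord[2:(K - 1)]
  briefs <- mid[modal2[mid]]
  if (length(briefs)) {
    b <- briefs[which.min(mv[briefs])]
    nm[b] <- "Brief Episodic"
    mid <- setdiff(mid, b)
  } else {
    # fall back: lowest-visit middle class
    nm[mid[1]] <- "Brief Episodic"
    mid <- mid[-1]
  }
  mid <- mid[order(mv[mid])]
  nm[mid] <- c("Acute", "Intensive")[seq_along(mid)]
  nm
}
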