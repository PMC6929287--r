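# Month-bin boundaries (day offsets from the index date). Month m covers
# [bounds[m], bounds[m + 1]); fixed-width 365.25/12-day bins, not calendar
# months, so the coding is deterministic and timezone-free.
month_bounds <- function(n_months = 48L) {
  round((0:n_months) * 365.25 / 12)
}

#' Names of the five service-use patterns, in default configuration order
#'
#' Order matches the default class weights: Minimal, Acute, Brief Episodic,
#' Intensive, Ongoing/Intensive-Episodic.
#'
#' @return Character vector of length 5.
#' @export
pattern_names <- function() {
  c("Minimal", "Acute", "Brief Episodic", "Intensive",
    "Ongoing/Intensive-Episodic")
}

#' Default synthetic-cohort generator configuration
#'
#' Returns the calibrated default configuration for [sample_cohort()]. The
#' five classes carry the published prevalences (53.2, 20.1, 7.9, 13.0,
#' 5.8 per cent), piecewise-constant 48-month visit-probability profiles
#' anchored at three published points (Ongoing/Intensive-Episodic month 11 =
#' 0.63; Intensive month 21 = 0.22; Brief Episodic month 21 = 0.08), and
#' per-class visit rates solved so that the expected 4-year visit totals
#' equal the published per-pattern means (3.1, 15.6, 28.6, 32.6, 86.7).
#' Class-conditional covariate means and SDs are the published intake
#' T-score descriptives for Externalizing, Internalizing, Child Impairment
#' and Family Burden.
#'
#' The Brief Episodic profile has two activity bumps separated by a
#' 14-month near-zero span, so episode segmentation typically yields two
#' episodes of care for that class; the Ongoing profile sustains a high
#' visit probability for more than 24 months.
#'
#' @param n_children Number of children to simulate.
#' @param seed Default seed stored in the configuration (can be overridden
#'   when sampling).
#' @return An object of class `cohort_config` (a list); see Details for
#'   fields.
#' @export
default_config <- function(n_children = 3000L, seed = 1L) {
  profiles <- rbind(
    Minimal   = c(1, rep(0.40, 2), rep(0.15, 3), rep(0.05, 6), rep(0.005, 36)),
    Acute     = c(1, rep(0.85, 5), rep(0.50, 3), rep(0.20, 3), rep(0.005, 36)),
    `Brief Episodic` = c(1, rep(0.60, 6), rep(0.01, 13), 0.08,
                         rep(0.55, 9), rep(0.30, 6), rep(0.05, 12)),
    Intensive = c(1, rep(0.75, 11), rep(0.50, 6), rep(0.22, 6),
                  rep(0.08, 12), rep(0.03, 12)),
    `Ongoing/Intensive-Episodic` = c(1, rep(0.63, 23), rep(0.45, 12),
                                     rep(0.30, 12))
  )
  stopifnot(ncol(profiles) == 48L)
  target_visits <- c(3.1, 15.6, 28.6, 32.6, 86.7)
  # visits in an active month are 1 + truncated Poisson(rate): solve the rate
  # so expected total visits match the published per-pattern means
  rates <- target_visits / rowSums(profiles) - 1
  stopifnot(all(rates >= 0))

  cfg <- list(
    n_children = as.integer(n_children),
    class_names = pattern_names(),
    class_weights = c(0.532, 0.201, 0.079, 0.130, 0.058),
    monthly_profiles = profiles,
    visits_per_active_month_rate = unname(rates),
    covariate_names = c("ext_t", "int_t", "imp_t", "burden_t"),
    covariate_means = rbind(
      c(65.5, 62.0, 63.4, 70.7),
      c(69.4, 63.8, 66.8, 76.7),
      c(69.6, 63.0, 66.6, 77.0),
      c(70.9, 64.5, 68.6, 79.2),
      c(72.5, 66.2, 71.0, 81.5)
    ),
    covariate_sds = rbind(
      c(13.3, 14.0, 13.8, 19.3),
      c(12.9, 14.4, 13.9, 21.5),
      c(12.0, 14.3, 14.8, 20.6),
      c(13.1, 14.4, 15.2, 21.6),
      c(13.0, 15.3, 15.2, 23.3)
    ),
    covariate_correlation = 0.4,
    sex_male_prob = c(0.615, 0.609, 0.622, 0.678, 0.612),
    age_year_probs = c(8, 10, 9, 11, 12, 12, 12, 13, 14) /
      sum(c(8, 10, 9, 11, 12, 12, 12, 13, 14)),
    missing_rates = c(ext_t = 0.003, int_t = 0.03, imp_t = 0.08,
                      burden_t = 0.124),
    missing_mechanism = "MAR-on-Externalizing",
    mar_slope = 0.06,
    mar_center = 68,
    intake_window = as.Date(c("2004-01-01", "2006-12-31")),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param config A `cohort_config` list.
#' @return The configuration, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  w <- config$class_weights
  if (abs(sum(w) - 1) > 1e-9) stop("class_weights must sum to 1")
  pr <- config$monthly_profiles
  if (any(pr < 0 | pr > 1)) stop("monthly profile entries must lie in [0, 1]")
  if (any(pr[, 1] != 1)) stop("month-1 profile entry must be 1 for every class")
  if (any(config$covariate_sds <= 0)) stop("covariate_sds must be positive")
  if (abs(sum(config$age_year_probs) - 1) > 1e-9)
    stop("age_year_probs must sum to 1")
  if (any(config$missing_rates < 0 | config$missing_rates > 1))
    stop("missing_rates must lie in [0, 1]")
  rho <- config$covariate_correlation
  if (rho < 0 || rho >= 1) stop("covariate_correlation must be in [0, 1)")
  if (config$n_children < 1) stop("n_children must be positive")
  invisible(config)
}

# Exchangeable correlation matrix scaled by per-scale SDs.
class_covariance <- function(sds, rho) {
  p <- length(sds)
  R <- matrix(rho, p, p)
  diag(R) <- 1
  diag(sds) %*% R %*% diag(sds)
}

#' Simulate a synthetic service-use cohort
#'
#' Draws, for each child: a latent service-use class; an index date uniform
#' in the configured intake window; monthly visit activity from the class's
#' 48-month probability profile (month 1 is always active — the index visit
#' defines it); per active month, 1 + a Poisson count truncated at 20 visit
#' dates uniform within the month bin; sex, an integer age-year plus a
#' uniform within-year fraction; and the four intake T-scores from the
#' class-conditional multivariate normal with exchangeable correlation.
#' Identical `(config, seed)` give identical cohorts.
#'
#' @param config A `cohort_config`, e.g. [default_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `simulated_cohort`: a list with data frames
#'   `visits` (child_id, visit_date, contact_mode, program_tag), `children`
#'   (child_id, dob, sex, pdd_flag), `covariates` (child_id, ext_t, int_t,
#'   imp_t, burden_t), `labels` (child_id, class_index, class_name), and
#'   `index_dates` (named Date vector).
#' @export
sample_cohort <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  n <- config$n_children
  if (n <= 0) stop("n_children must be positive")
  set.seed(seed)
  K <- length(config$class_weights)
  J <- ncol(config$monthly_profiles)
  bounds <- month_bounds(J)

  labels <- sample.int(K, n, replace = TRUE, prob = config$class_weights)
  window <- config$intake_window
  span <- as.integer(window[2] - window[1])
  index_dates <- window[1] + sample.int(span + 1L, n, replace = TRUE) - 1L

  # ages: integer year uniform over published distribution + within-year days
  ages_yr <- sample(5:13, n, replace = TRUE, prob = config$age_year_probs)
  extra_days <- sample.int(364L, n, replace = TRUE) # 1..364, keeps floor() exact
  age_days <- floor(ages_yr * 365.25) + extra_days
  dob <- index_dates - age_days

  sex <- ifelse(stats::runif(n) < config$sex_male_prob[labels], "M", "F")

  # covariates: class-conditional MVN with exchangeable correlation
  p <- length(config$covariate_names)
  z <- matrix(stats::rnorm(n * p), n, p)
  covs <- matrix(NA_real_, n, p)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (!length(idx)) next
    L <- chol(class_covariance(config$covariate_sds[k, ],
                               config$covariate_correlation))
    covs[idx, ] <- z[idx, , drop = FALSE] %*% L +
      matrix(config$covariate_means[k, ], length(idx), p, byrow = TRUE)
  }
  colnames(covs) <- config$covariate_names

  # monthly activity: month 1 always active by construction
  active <- matrix(stats::runif(n * J), n, J) <
    config$monthly_profiles[labels, , drop = FALSE]
  active[, 1] <- TRUE

  cell <- which(active, arr.ind = TRUE)
  cell <- cell[order(cell[, 1], cell[, 2]), , drop = FALSE]
  rate <- config$visits_per_active_month_rate[labels[cell[, 1]]]
  extra <- pmin(stats::rpois(nrow(cell), rate), 20L)
  n_vis <- 1L + extra
  child_rep <- rep.int(cell[, 1], n_vis)
  month_rep <- rep.int(cell[, 2], n_vis)
  width <- (bounds[-1] - bounds[-length(bounds)])[month_rep]
  offs <- bounds[month_rep] + floor(stats::runif(length(child_rep)) * width)
  # pin the first visit of month 1 to the index date
  first_of_m1 <- !duplicated(child_rep) & month_rep == 1L
  offs[first_of_m1] <- 0L

  visits <- data.frame(
    child_id = child_rep,
    visit_date = index_dates[child_rep] + offs,
    contact_mode = "face_to_face",
    program_tag = NA_character_,
    stringsAsFactors = FALSE
  )
  visits <- visits[order(visits$child_id, visits$visit_date), ]
  rownames(visits) <- NULL

  children <- data.frame(
    child_id = seq_len(n), dob = dob, sex = sex, pdd_flag = 0L,
    stringsAsFactors = FALSE
  )
  covariates <- data.frame(child_id = seq_len(n), covs,
                           stringsAsFactors = FALSE)
  lab_df <- data.frame(child_id = seq_len(n), class_index = labels,
                       class_name = config$class_names[labels],
                       stringsAsFactors = FALSE)
  names(index_dates) <- seq_len(n)

  structure(list(visits = visits, children = children,
                 covariates = covariates, labels = lab_df,
                 index_dates = index_dates, config = config, seed = seed),
            class = "simulated_cohort")
}

#' Inject missing values into a covariate table
#'
#' Marks intake T-score cells missing at the configured per-scale rates.
#' Under `"MCAR"` every cell of a scale is missing independently at its
#' rate. Under `"MAR-on-Externalizing"` the Externalizing scale is missing
#' at its own (small) rate, while the missingness probability of the other
#' three scales rises with the child's Externalizing score through a
#' logistic link, so that with enough children Little's test detects the
#' departure from MCAR. Demographics are never made missing.
#'
#' @param covariates Complete covariate data frame (as from
#'   [sample_cohort()]).
#' @param config A `cohort_config`; uses `missing_rates`,
#'   `missing_mechanism`, `mar_slope`, `mar_center`.
#' @param seed Integer seed.
#' @return The covariate data frame with `NA`s inserted.
#' @export
inject_missingness <- function(covariates, config = default_config(),
                               seed = config$seed) {
  rates <- config$missing_rates
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  scales <- config$covariate_names
  stopifnot(all(scales %in% names(covariates)))
  set.seed(seed)
  n <- nrow(covariates)
  out <- covariates
  mech <- config$missing_mechanism
  ext <- covariates[[scales[1]]]
  for (j in seq_along(scales)) {
    r <- rates[j]
    if (r == 0) next
    if (identical(mech, "MCAR") || j == 1L) {
      miss <- stats::runif(n) < r
    } else {
      pr <- stats::plogis(stats::qlogis(r) +
                            config$mar_slope * (ext - config$mar_center))
      miss <- stats::runif(n) < pr
    }
    out[[scales[j]]][miss] <- NA_real_
  }
  out
}
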