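# Completed years between two dates, by day count; deterministic and
# consistent with the generator's dob construction.
age_completed_years <- function(dob, date) {
  floor(as.numeric(as.Date(date) - as.Date(dob)) / 365.25)
}

#' Identify a child's index visit
#'
#' The index visit is the earliest face-to-face visit inside the intake
#' window that has no face-to-face visit in the preceding `lookback_days`
#' (a gap of more than `lookback_days` days, or no earlier visit at all).
#'
#' @param visit_dates Date vector of the child's face-to-face visits.
#' @param intake_window Date vector of length 2 (inclusive range).
#' @param lookback_days Clean-lookback requirement in days (default 548,
#'   i.e. 18 months).
#' @return The index date, or `NA` (Date) if no visit qualifies.
#' @export
identify_index_visit <- function(visit_dates, intake_window,
                                 lookback_days = 548L) {
  d <- sort(as.Date(visit_dates))
  if (!length(d)) return(as.Date(NA))
  win <- as.Date(intake_window)
  in_win <- which(d >= win[1] & d <= win[2])
  for (i in in_win) {
    prev <- d[d < d[i]]
    if (!length(prev) || as.numeric(d[i] - max(prev)) > lookback_days)
      return(d[i])
  }
  as.Date(NA)
}

#' Apply the cohort inclusion/exclusion rules
#'
#' Applies, in order: (1) restriction to face-to-face visits (children with
#' none are removed); (2) the index-visit rule — earliest in-window
#' face-to-face visit with a clean 18-month lookback; (3) age at index
#' under 5 removed; (4) age over 13 removed (retain 5 <= age < 14);
#' (5) pervasive-developmental-disorder flag removed; (6) children with a
#' complete prior episode of care ending within `lookback_days` before the
#' index removed. Because rule (2) guarantees no face-to-face visit in that
#' window, rule (6) screens episodes over visits of any contact mode
#' (telephone and indirect contacts included), which is the only reading
#' under which a recent prior episode can coexist with a clean face-to-face
#' lookback. Exact duplicate visit rows are dropped with a logged count.
#' Retained children's face-to-face visit streams are truncated to
#' `[index, index + 48 months)`.
#'
#' @param children Data frame: child_id, dob, sex, pdd_flag.
#' @param visits Data frame: child_id, visit_date, contact_mode.
#' @param intake_window Date vector of length 2.
#' @param lookback_days Lookback for rules (2) and (6); default 548.
#' @param min_visits,gap_days Episode rule constants for rule (6).
#' @param n_months Observation window length for truncation (default 48).
#' @return A `cohort_result`: list with `retained_ids`, `index_dates`
#'   (named Date vector), `attrition` (rule, n_removed), `visits`
#'   (truncated face-to-face stream of retained children), `n_input`,
#'   `n_duplicates_dropped`.
#' @export
apply_filters <- function(children, visits, intake_window,
                          lookback_days = 548L, min_visits = 3L,
                          gap_days = 180L, n_months = 48L) {
  visits$visit_date <- as.Date(visits$visit_date)
  visits$child_id <- as.character(visits$child_id)
  children$child_id <- as.character(children$child_id)
  n_input <- nrow(children)

  dup <- duplicated(visits[c("child_id", "visit_date", "contact_mode")])
  n_dup <- sum(dup)
  visits <- visits[!dup, ]

  ff <- visits[visits$contact_mode == "face_to_face", ]
  ff_dates <- split(ff$visit_date, factor(ff$child_id,
                                          levels = children$child_id))
  all_dates <- split(visits$visit_date, factor(visits$child_id,
                                               levels = children$child_id))

  attrition <- data.frame(rule = character(), n_removed = integer(),
                          stringsAsFactors = FALSE)
  drop_rule <- function(keep_ids, removed, rule) {
    attrition <<- rbind(attrition,
                        data.frame(rule = rule, n_removed = length(removed)))
    setdiff(keep_ids, removed)
  }

  ids <- children$child_id
  # (1) no face-to-face visit at all
  no_ff <- ids[vapply(ff_dates[ids], length, 1L) == 0L]
  ids <- drop_rule(ids, no_ff, "no_face_to_face_visit")

  # (2) index-visit rule
  index <- rep(as.Date(NA), length(ids))
  names(index) <- ids
  for (id in ids)
    index[id] <- identify_index_visit(ff_dates[[id]], intake_window,
                                      lookback_days)
  no_idx <- ids[is.na(index[ids])]
  ids <- drop_rule(ids, no_idx, "no_eligible_index_visit")
  index <- index[ids]

  dob <- children$dob[match(ids, children$child_id)]
  age <- age_completed_years(dob, index)
  # (3) / (4) age eligibility: 5 <= age < 14 at index
  ids <- drop_rule(ids, ids[age < 5], "age_under_5")
  index <- index[ids]
  age <- age_completed_years(children$dob[match(ids, children$child_id)],
                             index)
  ids <- drop_rule(ids, ids[age >= 14], "age_over_13")
  index <- index[ids]

  # (5) pervasive developmental disorder / developmental disability flag
  pdd <- children$pdd_flag[match(ids, children$child_id)]
  ids <- drop_rule(ids, ids[pdd == 1L], "pdd_flag")
  index <- index[ids]

  # (6) complete prior episode (any contact mode) ending within lookback
  has_prior_eoc <- vapply(ids, function(id) {
    pre <- all_dates[[id]][all_dates[[id]] < index[id]]
    if (length(pre) < min_visits) return(FALSE)
    cl <- segment_episodes(pre, min_visits, gap_days)$clusters
    ep <- cl[cl$is_episode, ]
    any(as.numeric(index[id] - ep$last_date) <= lookback_days)
  }, logical(1))
  ids <- drop_rule(ids, ids[has_prior_eoc], "prior_episode_of_care")
  index <- index[ids]

  # truncate retained children's face-to-face streams to the 48-month window
  horizon <- month_bounds(n_months)[n_months + 1L]
  keep <- ff$child_id %in% ids
  out_v <- ff[keep, ]
  idx_of <- index[out_v$child_id]
  off <- as.numeric(out_v$visit_date - idx_of)
  out_v <- out_v[off >= 0 & off < horizon, ]
  rownames(out_v) <- NULL

  structure(list(retained_ids = ids, index_dates = index,
                 attrition = attrition, visits = out_v,
                 n_input = n_input, n_duplicates_dropped = n_dup),
            class = "cohort_result")
}

#' Construct a stratified toy cohort exercising every attrition rule
#'
#' Builds a synthetic cohort of disjoint strata for validating the filter's
#' attrition arithmetic: `n_under` children younger than 5 at index,
#' `n_over` older than 13, `n_pdd` flagged with a pervasive developmental
#' disorder, `n_prior` with a complete prior (telephone-contact) episode of
#' care ending inside the 18-month pre-index window, and `n_clean`
#' eligible children. Every child has one face-to-face visit inside the
#' intake window with a clean face-to-face lookback.
#'
#' @param n_clean,n_under,n_over,n_pdd,n_prior Stratum sizes.
#' @param intake_window Date vector of length 2.
#' @param seed Integer seed.
#' @return List with `children` and `visits` data frames ready for
#'   [apply_filters()].
#' @export
strata_cohort <- function(n_clean = 5632L, n_under = 3099L, n_over = 2711L,
                          n_pdd = 841L, n_prior = 360L,
                          intake_window = as.Date(c("2004-01-01",
                                                    "2006-12-31")),
                          seed = 1L) {
  set.seed(seed)
  n <- n_clean + n_under + n_over + n_pdd + n_prior
  win <- as.Date(intake_window)
  span <- as.integer(win[2] - win[1])
  index <- win[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  stratum <- rep(c("clean", "under", "over", "pdd", "prior"),
                 c(n_clean, n_under, n_over, n_pdd, n_prior))
  age_yr <- integer(n)
  age_yr[stratum == "under"] <- sample(2:4, sum(stratum == "under"), TRUE)
  age_yr[stratum == "over"] <- sample(14:16, sum(stratum == "over"), TRUE)
  elig <- stratum %in% c("clean", "pdd", "prior")
  age_yr[elig] <- sample(5:13, sum(elig), TRUE)
  dob <- index - (floor(age_yr * 365.25) + sample.int(364L, n, TRUE))

  children <- data.frame(
    child_id = sprintf("c%05d", seq_len(n)), dob = dob,
    sex = sample(c("M", "F"), n, TRUE), pdd_flag = as.integer(stratum == "pdd"),
    stringsAsFactors = FALSE
  )
  visits <- data.frame(child_id = children$child_id, visit_date = index,
                       contact_mode = "face_to_face",
                       program_tag = NA_character_, stringsAsFactors = FALSE)
  # prior stratum: a 3-visit telephone episode ending ~300 days pre-index
  pri <- which(stratum == "prior")
  if (length(pri)) {
    ends <- index[pri] - sample(200:500, length(pri), TRUE)
    prior_visits <- data.frame(
      child_id = rep(children$child_id[pri], each = 3L),
      visit_date = as.Date(rep(ends, each = 3L)) - c(20L, 10L, 0L),
      contact_mode = "phone", program_tag = NA_character_,
      stringsAsFactors = FALSE
    )
    visits <- rbind(visits, prior_visits)
  }
  visits <- visits[order(visits$child_id, visits$visit_date), ]
  rownames(visits) <- NULL
  list(children = children, visits = visits)
}
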