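#' Code a visit stream as 48 monthly binary indicators
#'
#' Month 1 starts at the child's index (first) visit; month m covers day
#' offsets `[round((m-1) * 365.25/12), round(m * 365.25/12))` from the index
#' date. Entry m is 1 iff at least one visit falls in bin m.
#'
#' @param visit_dates Date vector of the child's visits.
#' @param index_date The child's index date (its first visit).
#' @param n_months Number of monthly bins (default 48).
#' @return Integer vector of 0/1 of length `n_months`.
#' @export
month_indicators <- function(visit_dates, index_date, n_months = 48L) {
  offs <- as.integer(as.Date(visit_dates) - as.Date(index_date))
  bounds <- month_bounds(n_months)
  if (any(offs < 0))
    stop("visit before the index date: cohort contract violated")
  if (any(offs >= bounds[n_months + 1L]))
    stop("visit beyond the observation window")
  m <- findInterval(offs, bounds)
  out <- integer(n_months)
  out[unique(m)] <- 1L
  out
}

#' Build the n x 48 trajectory matrix for a set of children
#'
#' @param visits Data frame with `child_id` and `visit_date`.
#' @param index_dates Named Date vector (names = child ids) of index dates.
#' @param n_months Number of monthly bins.
#' @return Binary matrix with one row per child (rownames = child ids).
#' @export
trajectory_matrix <- function(visits, index_dates, n_months = 48L) {
  ids <- names(index_dates)
  split_dates <- split(as.Date(visits$visit_date),
                       factor(as.character(visits$child_id), levels = ids))
  X <- t(vapply(ids, function(id)
    month_indicators(split_dates[[id]], index_dates[[id]], n_months),
    integer(n_months)))
  rownames(X) <- ids
  colnames(X) <- sprintf("m%02d", seq_len(n_months))
  X
}

#' Segment a visit stream into episode-of-care clusters
#'
#' Greedy chronological clustering: a new cluster starts whenever the gap
#' from the previous visit is at least `gap_days`. Clusters with at least
#' `min_visits` visits are episodes of care; smaller clusters are retained
#' as non-episode contacts so scattered pre- and post-episode visits remain
#' reportable.
#'
#' @param visit_dates Date vector (sorted defensively).
#' @param min_visits Minimum visits for a cluster to count as an episode
#'   (default 3).
#' @param gap_days Minimum visit-free gap that separates clusters (default
#'   180 days, the 6-month rule).
#' @return An `episode_partition`: list with a `clusters` data frame
#'   (first_date, last_date, n_visits, is_episode) and the rule constants.
#' @export
segment_episodes <- function(visit_dates, min_visits = 3L, gap_days = 180L) {
  d <- sort(as.Date(visit_dates))
  if (!length(d)) {
    cl <- data.frame(first_date = as.Date(character()),
                     last_date = as.Date(character()),
                     n_visits = integer(), is_episode = logical())
  } else {
    gaps <- as.integer(diff(d))
    grp <- cumsum(c(1L, as.integer(gaps >= gap_days)))
    first <- as.Date(as.vector(tapply(as.integer(d), grp, min)),
                     origin = "1970-01-01")
    last <- as.Date(as.vector(tapply(as.integer(d), grp, max)),
                    origin = "1970-01-01")
    nv <- as.integer(tabulate(grp))
    cl <- data.frame(first_date = first, last_date = last, n_visits = nv,
                     is_episode = nv >= min_visits)
    rownames(cl) <- NULL
  }
  structure(list(clusters = cl, min_visits = min_visits,
                 gap_days = gap_days),
            class = "episode_partition")
}

#' Summarize a child's service use
#'
#' Derives the per-child utilization metrics reported by pattern: episode
#' count and category (0 / 1 / 2+), total visits, duration of involvement
#' in years (first to last visit), the over-two-years flag (strictly more
#' than 2 years), visits in non-episode clusters that precede the first
#' episode, the gap between the first and second episode, and per-episode
#' visit counts and durations.
#'
#' @param partition An `episode_partition` from [segment_episodes()].
#' @param visit_dates The same visit dates the partition was derived from.
#' @return A one-row data frame (`per_episode` attached as an attribute).
#' @export
summarize_service_use <- function(partition, visit_dates) {
  d <- sort(as.Date(visit_dates))
  cl <- partition$clusters
  stopifnot(sum(cl$n_visits) == length(d))
  n_ep <- sum(cl$is_episode)
  cat_ep <- if (n_ep == 0L) "0" else if (n_ep == 1L) "1" else "2+"
  dur <- if (length(d)) as.numeric(d[length(d)] - d[1]) / 365.25 else 0
  first_ep <- which(cl$is_episode)[1]
  pre <- if (is.na(first_ep)) NA_integer_ else {
    before <- seq_len(nrow(cl)) < first_ep
    as.integer(sum(cl$n_visits[before & !cl$is_episode]))
  }
  eps <- which(cl$is_episode)
  gap_m <- if (length(eps) >= 2L) {
    as.numeric(cl$first_date[eps[2]] - cl$last_date[eps[1]]) / 365.25 * 12
  } else NA_real_
  per_ep <- data.frame(
    visits = cl$n_visits[eps],
    duration_months = as.numeric(cl$last_date[eps] - cl$first_date[eps]) /
      365.25 * 12
  )
  out <- data.frame(
    n_episodes = n_ep,
    episode_category = cat_ep,
    total_visits = length(d),
    duration_years = dur,
    over_two_years = dur > 2,
    pre_episode_visits = pre,
    inter_episode_gap_months = gap_m,
    stringsAsFactors = FALSE
  )
  attr(out, "per_episode") <- per_ep
  out
}

#' Per-child service-use summaries for a cohort
#'
#' @param visits Data frame with `child_id`, `visit_date`.
#' @param ids Child ids to summarize (defaults to those present).
#' @param min_visits,gap_days Episode rule constants.
#' @return Data frame, one row per child, with a `child_id` column.
#' @export
summarize_cohort <- function(visits, ids = NULL, min_visits = 3L,
                             gap_days = 180L) {
  if (is.null(ids)) ids <- unique(as.character(visits$child_id))
  split_dates <- split(as.Date(visits$visit_date),
                       factor(as.character(visits$child_id), levels = ids))
  rows <- lapply(ids, function(id) {
    d <- split_dates[[id]]
    summarize_service_use(segment_episodes(d, min_visits, gap_days), d)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(child_id = ids, stringsAsFactors = FALSE), out)
}

#' Share of all visits delivered to each class
#'
#' Per-class sum of total visits divided by the grand total, times 100.
#'
#' @param total_visits Per-child visit counts.
#' @param labels Per-child class labels (same length).
#' @return Named numeric vector of percentages summing to 100.
#' @export
volume_shares <- function(total_visits, labels) {
  stopifnot(length(total_visits) == length(labels))
  tot <- tapply(total_visits, labels, sum)
  grand <- sum(tot)
  if (grand == 0) stop("zero grand total of visits")
  stats::setNames(as.vector(100 * tot / grand), dimnames(tot)[[1]])
}
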