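win <- as.Date(c("2004-01-01", "2006-12-31"))

test_that("index identification follows the clean-lookback rule", {
  expect_equal(identify_index_visit(as.Date("2005-03-01"), win),
               as.Date("2005-03-01"))
  # first visit qualifies by absence of earlier data
  expect_equal(identify_index_visit(as.Date(c("2004-01-10", "2005-03-01")),
                                    win),
               as.Date("2004-01-10"))
  # 274-day gap < 548: the in-window visit is disqualified
  expect_true(is.na(identify_index_visit(
    as.Date(c("2003-09-01", "2004-06-01")), win)))
  # empty visit list
  expect_true(is.na(identify_index_visit(as.Date(character()), win)))
  # a later in-window visit can qualify when spaced beyond the lookback
  d <- as.Date(c("2003-12-01", "2004-03-01", "2006-01-01"))
  expect_equal(identify_index_visit(d, win), as.Date("2006-01-01"))
})

test_that("filters retain all eligible children and drop phone-only ones", {
  children <- data.frame(
    child_id = c("a", "b", "c"),
    dob = as.Date(c("1996-06-01", "1996-06-01", "1996-06-01")),
    sex = "M", pdd_flag = 0L, stringsAsFactors = FALSE
  )
  visits <- data.frame(
    child_id = c("a", "b", "c"),
    visit_date = as.Date(c("2005-06-01", "2005-07-01", "2005-08-01")),
    contact_mode = c("face_to_face", "face_to_face", "phone"),
    stringsAsFactors = FALSE
  )
  res <- apply_filters(children, visits, win)
  expect_setequal(res$retained_ids, c("a", "b"))
  expect_equal(res$attrition$n_removed[res$attrition$rule ==
                                         "no_face_to_face_visit"], 1L)
  expect_equal(res$n_input,
               length(res$retained_ids) + sum(res$attrition$n_removed))
})

test_that("duplicate visit rows are de-duplicated with a logged count", {
  children <- data.frame(child_id = "a", dob = as.Date("1996-06-01"),
                         sex = "M", pdd_flag = 0L, stringsAsFactors = FALSE)
  visits <- data.frame(
    child_id = "a",
    visit_date = as.Date(c("2005-06-01", "2005-06-01", "2005-07-01")),
    contact_mode = "face_to_face", stringsAsFactors = FALSE
  )
  res <- apply_filters(children, visits, win)
  expect_equal(res$n_duplicates_dropped, 1L)
  expect_equal(nrow(res$visits), 2L)
})

test_that("retained streams start at the index and have clean lookbacks", {
  ch <- sample_cohort(default_config(300), seed = 10)
  res <- apply_filters(ch$children, ch$visits, win)
  stopifnot(length(res$retained_ids) > 0)
  first <- tapply(as.integer(res$visits$visit_date), res$visits$child_id,
                  min)
  expect_equal(as.vector(first[res$retained_ids]),
               unname(as.integer(res$index_dates[res$retained_ids])))
  # no retained child has a face-to-face visit within 548 days pre-index
  ff <- ch$visits[ch$visits$contact_mode == "face_to_face", ]
  for (id in res$retained_ids[1:20]) {
    d <- as.Date(ff$visit_date[ff$child_id == id])
    gap <- as.numeric(res$index_dates[[id]] - d)
    expect_false(any(gap > 0 & gap <= 548))
  }
  # reruns give identical attrition logs
  res2 <- apply_filters(ch$children, ch$visits, win)
  expect_identical(res$attrition, res2$attrition)
})

test_that("a recent prior episode of non-face-to-face contacts is excluded", {
  children <- data.frame(child_id = c("a", "b"),
                         dob = rep(as.Date("1996-06-01"), 2), sex = "M",
                         pdd_flag = 0L, stringsAsFactors = FALSE)
  base <- as.Date("2005-06-01")
  visits <- rbind(
    data.frame(child_id = "a", visit_date = base,
               contact_mode = "face_to_face", stringsAsFactors = FALSE),
    # complete 3-visit phone episode ending 300 days before a's index
    data.frame(child_id = "a", visit_date = base - c(320, 310, 300),
               contact_mode = "phone", stringsAsFactors = FALSE),
    # b: only 2 prior phone contacts -> not a complete episode
    data.frame(child_id = "b", visit_date = base,
               contact_mode = "face_to_face", stringsAsFactors = FALSE),
    data.frame(child_id = "b", visit_date = base - c(310, 300),
               contact_mode = "phone", stringsAsFactors = FALSE)
  )
  res <- apply_filters(children, visits, win)
  expect_identical(res$retained_ids, "b")
  expect_equal(res$attrition$n_removed[res$attrition$rule ==
                                         "prior_episode_of_care"], 1L)
})

test_that("age eligibility is 5 <= completed years < 14 at index", {
  idx <- as.Date("2005-06-01")
  mk <- function(age_days) {
    children <- data.frame(child_id = "a", dob = idx - age_days, sex = "M",
                           pdd_flag = 0L, stringsAsFactors = FALSE)
    visits <- data.frame(child_id = "a", visit_date = idx,
                         contact_mode = "face_to_face",
                         stringsAsFactors = FALSE)
    length(apply_filters(children, visits, win)$retained_ids)
  }
  expect_equal(mk(floor(4.9 * 365.25)), 0L)   # age 4
  expect_equal(mk(floor(5.1 * 365.25)), 1L)   # age 5
  expect_equal(mk(floor(13.9 * 365.25)), 1L)  # age 13 retained
  expect_equal(mk(floor(14.1 * 365.25)), 0L)  # age 14 removed
})
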