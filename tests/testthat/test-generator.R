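test_that("default configuration carries the published calibration", {
  cfg <- default_config()
  expect_equal(cfg$class_weights, c(0.532, 0.201, 0.079, 0.130, 0.058))
  expect_equal(sum(cfg$class_weights), 1, tolerance = 1e-12)
  expect_true(all(cfg$monthly_profiles >= 0 & cfg$monthly_profiles <= 1))
  expect_true(all(cfg$monthly_profiles[, 1] == 1))
  # published monthly anchors
  expect_equal(unname(cfg$monthly_profiles["Ongoing/Intensive-Episodic", 11]),
               0.63)
  expect_equal(unname(cfg$monthly_profiles["Intensive", 21]), 0.22)
  expect_equal(unname(cfg$monthly_profiles["Brief Episodic", 21]), 0.08)
  # visit rates solved so expected totals match the per-pattern means
  expected <- rowSums(cfg$monthly_profiles) *
    (1 + cfg$visits_per_active_month_rate)
  expect_equal(unname(expected), c(3.1, 15.6, 28.6, 32.6, 86.7),
               tolerance = 1e-9)
  # Ongoing profile sustains high probability for at least 24 months
  expect_true(all(cfg$monthly_profiles["Ongoing/Intensive-Episodic",
                                       1:24] >= 0.45))
})

test_that("identical config and seed give identical cohorts", {
  cfg <- default_config(300)
  a <- sample_cohort(cfg, seed = 5)
  b <- sample_cohort(cfg, seed = 5)
  expect_identical(a$visits, b$visits)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$labels, b$labels)
  c2 <- sample_cohort(cfg, seed = 6)
  expect_false(identical(a$visits, c2$visits))
})

test_that("every child's first visit is its index date, in month 1", {
  ch <- sample_cohort(default_config(400), seed = 2)
  first <- tapply(as.integer(ch$visits$visit_date), ch$visits$child_id, min)
  expect_equal(as.vector(first[as.character(1:400)]),
               unname(as.integer(ch$index_dates)))
  X <- trajectory_matrix(ch$visits, ch$index_dates)
  expect_true(all(X[, 1] == 1))
})

test_that("degenerate mixture produces a single class", {
  cfg <- default_config(100)
  cfg$class_weights <- c(1, 0, 0, 0, 0)
  ch <- sample_cohort(cfg, seed = 3)
  expect_true(all(ch$labels$class_index == 1L))
})

test_that("empirical class prevalences and profiles match the configuration", {
  cfg <- default_config(5000)
  ch <- sample_cohort(cfg, seed = 4)
  prev <- as.numeric(table(factor(ch$labels$class_index, 1:5))) / 5000
  se <- sqrt(cfg$class_weights * (1 - cfg$class_weights) / 5000)
  expect_true(all(abs(prev - cfg$class_weights) <= 3 * se))

  # single-class cohort: per-month visit frequency tracks the profile
  cfg1 <- default_config(5000)
  cfg1$class_weights <- c(0, 0, 0, 1, 0)  # Intensive
  ch1 <- sample_cohort(cfg1, seed = 5)
  X <- trajectory_matrix(ch1$visits, ch1$index_dates)
  pr <- cfg1$monthly_profiles[4, ]
  se_m <- sqrt(pmax(pr * (1 - pr), 1e-12) / 5000)
  expect_true(all(abs(colMeans(X) - pr) <= pmax(3 * se_m, 1e-9)))
})

test_that("class-conditional covariates match the configured moments", {
  cfg <- default_config(5000)
  ch <- sample_cohort(cfg, seed = 6)
  minimal <- ch$labels$class_index == 1L
  m <- mean(ch$covariates$ext_t[minimal])
  se <- 13.3 / sqrt(sum(minimal))
  expect_lt(abs(m - 65.5), 3 * se)
  # exchangeable correlation roughly recovered within class
  cc <- cor(ch$covariates[minimal, c("ext_t", "int_t", "imp_t", "burden_t")])
  expect_true(all(abs(cc[upper.tri(cc)] - 0.4) < 0.06))
})

test_that("missingness injection respects rates and mechanisms", {
  cfg <- default_config(20000)
  ch <- sample_cohort(cfg, seed = 7)

  cfg0 <- cfg
  cfg0$missing_rates[] <- 0
  expect_identical(inject_missingness(ch$covariates, cfg0, seed = 1),
                   ch$covariates)

  cfgm <- cfg
  cfgm$missing_mechanism <- "MCAR"
  cfgm$missing_rates <- c(ext_t = 0.003, int_t = 0.03, imp_t = 0.08,
                          burden_t = 0.124)
  out <- inject_missingness(ch$covariates, cfgm, seed = 8)
  frac <- colMeans(is.na(out[c("ext_t", "int_t", "imp_t", "burden_t")]))
  se <- sqrt(cfgm$missing_rates * (1 - cfgm$missing_rates) / 20000)
  expect_true(all(abs(frac - cfgm$missing_rates) <= 2 * se))
  # child ids and demographics never go missing
  expect_false(anyNA(out$child_id))

  bad <- cfg
  bad$missing_rates[2] <- 1.2
  expect_error(inject_missingness(ch$covariates, bad, seed = 1), "rates")
})

test_that("configuration invariants are enforced", {
  cfg <- default_config()
  cfg$class_weights <- c(0.5, 0.2, 0.1, 0.1, 0.05)
  expect_error(validate_config(cfg), "sum to 1")
  cfg <- default_config()
  cfg$monthly_profiles[2, 1] <- 0.5
  expect_error(validate_config(cfg), "month-1")
  cfg <- default_config()
  cfg$covariate_sds[1, 1] <- 0
  expect_error(validate_config(cfg), "positive")
  cfg <- default_config()
  cfg$n_children <- 0L
  expect_error(sample_cohort(cfg), "positive")
})
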