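test_that("rate_per_1000 reproduces the headline rates", {
  expect_equal(rate_per_1000(79, 15170), 5.21)
  expect_equal(rate_per_1000(43, 17961), 2.39)
  expect_equal(rate_per_1000(0, 1000), 0)
  expect_equal(rate_per_1000(550, 15170, digits = 1), 36.3)
  expect_equal(rate_per_1000(636, 17961, digits = 1), 35.4)
  expect_error(rate_per_1000(1, 0), "admissions")
})

test_that("rate_per_1000 is scale invariant and keeps raw precision", {
  for (k in c(1, 2, 7, 50))
    expect_equal(rate_per_1000(k * 3, k * 700, raw = TRUE),
                 rate_per_1000(3, 700, raw = TRUE))
  expect_equal(rate_per_1000(79, 15170, raw = TRUE), 1000 * 79 / 15170)
})

adm3 <- data.frame(
  admission_id = c("A1", "A2", "A3", "A4"),
  admit_date = as.Date(c("2023-01-05", "2023-01-20", "2023-02-10",
                         "2023-04-02")),
  stringsAsFactors = FALSE)
ev3 <- data.frame(admission_id = c("A1", "A3", "A3"),
                  event_type = c("ihca", "ihca", "death"),
                  event_date = as.Date(c("2023-01-06", "2023-02-11",
                                         "2023-02-12")))

test_that("monthly_series attributes by admission month and conserves totals", {
  m <- monthly_series(adm3, ev3, wz_flags = c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(nrow(m), 4L)  # Jan..Apr
  expect_identical(m$admissions, c(2L, 1L, 0L, 1L))
  expect_identical(m$ihca, c(1L, 1L, 0L, 0L))
  expect_identical(m$deaths, c(0L, 1L, 0L, 0L))
  expect_identical(m$wz_count, c(1L, 1L, 0L, 0L))
  expect_false(m$rate_defined[3])
  expect_true(is.na(m$rate_per_1000[3]))
  expect_identical(sum(m$ihca), 2L)
  expect_identical(sum(m$admissions), nrow(adm3))
})

test_that("a single admission with one event gives a monthly rate of 1000", {
  m <- monthly_series(adm3[1, ], ev3[1, ])
  expect_equal(m$rate_per_1000, 1000)
})

test_that("orphan events are an error listing the orphans", {
  bad <- rbind(ev3, data.frame(admission_id = "ZZ9", event_type = "ihca",
                               event_date = as.Date("2023-01-01")))
  expect_error(monthly_series(adm3, bad), "ZZ9")
})

test_that("control limits use the sample standard deviation", {
  expect_equal(control_limits(c(3, 3, 3)), list(mean = 3, sd = 0))
  cl <- control_limits(c(2, 4))
  expect_equal(cl$mean, 3)
  expect_equal(cl$sd, sqrt(2))
  expect_error(control_limits(3), "at least 2")
  expect_equal(control_limits(c(1, NA, 3))$mean, 2)  # NA months dropped
})

test_that("mean of monthly rates equals pooled rate only for equal denominators", {
  eq <- c(10, 20, 30) / 100 * 1000   # equal denominators of 100
  expect_equal(control_limits(eq)$mean,
               rate_per_1000(60, 300, raw = TRUE))
  uneq_rates <- 1000 * c(1 / 10, 9 / 990)
  expect_false(isTRUE(all.equal(control_limits(uneq_rates)$mean,
                                rate_per_1000(10, 1000, raw = TRUE))))
})

test_that("compare_periods reproduces the before/after contrasts", {
  before <- list(label = "before", admissions = 15170, ihca = 79,
                 deaths = 550)
  after <- list(label = "after", admissions = 17961, ihca = 43,
                deaths = 636)
  ih <- compare_periods(before, after, "ihca", alpha = 0.01)
  expect_equal(round_half_up(ih$rate_a, 2), 5.21)
  expect_equal(round_half_up(ih$rate_b, 2), 2.39)
  expect_lt(ih$test$p_value, 0.01)
  expect_true(ih$significant)
  expect_equal(ih$rate_ratio, (43 / 17961) / (79 / 15170))

  mt <- compare_periods(before, after, "death", alpha = 0.05)
  expect_equal(round_half_up(mt$rate_a, 1), 36.3)
  expect_equal(round_half_up(mt$rate_b, 1), 35.4)
  expect_gt(mt$test$p_value, 0.05)
  expect_false(mt$significant)

  same <- compare_periods(before, before, "ihca")
  expect_equal(same$rate_ratio, 1)
  expect_equal(same$test$p_value, 1)
})

test_that("cohort_summary computes backgrounds and ranked diagnoses", {
  set.seed(31)
  n <- 2000L
  adm <- data.frame(
    admission_id = sprintf("B%04d", 1:n),
    admit_date = as.Date("2023-01-01") + sample(0:364, n, TRUE),
    age = round(rnorm(n, 60, 20), 1),
    sex = sample(c("M", "F"), n, TRUE),
    diagnosis = sample(c("pneumonia", "angina", "other"), n, TRUE,
                       prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE)
  s <- cohort_summary(adm, label = "toy")
  expect_identical(s$admissions, n)
  expect_identical(s$top_diagnoses$diagnosis[1], "pneumonia")
  expect_true(all(diff(s$top_diagnoses$n) <= 0))
  expect_equal(s$top_diagnoses$percent[1],
               round_half_up(100 * s$top_diagnoses$n[1] / n, 1))
  allm <- adm; allm$sex <- "M"
  expect_equal(cohort_summary(allm)$male_fraction, 1)
  expect_error(cohort_summary(adm[0, ]), "empty")
  # the published pneumonia fraction: 922 of 15170 is 6.1%
  expect_equal(round_half_up(100 * 922 / 15170, 1), 6.1)
})
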