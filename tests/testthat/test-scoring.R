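tab <- default_score_table()

test_that("single-parameter lookups hit the documented bands", {
  cases <- list(
    list(120, "sbp", 0L), list(65, "sbp", 3L), list(70, "sbp", 3L),
    list(71, "sbp", 2L), list(100, "sbp", 1L), list(101, "sbp", 0L),
    list(200, "sbp", 2L),
    list(40, "hr", 2L), list(41, "hr", 1L), list(100, "hr", 0L),
    list(130, "hr", 3L), list(129, "hr", 2L),
    list(8, "rr", 2L), list(9, "rr", 0L), list(15, "rr", 1L),
    list(30, "rr", 3L),
    list(35.0, "temp", 2L), list(35.1, "temp", 0L),
    list(38.4, "temp", 0L), list(38.5, "temp", 2L),
    list("alert", "consciousness", 0L),
    list("unresponsive", "consciousness", 3L),
    list(1, "concern", 1L), list(0, "concern", 0L))
  for (cs in cases)
    expect_identical(score_parameter(cs[[1]], cs[[2]], tab), cs[[3]],
                     info = paste(cs[[2]], cs[[1]]))
})

test_that("values are rounded half-up to the granularity before lookup", {
  expect_identical(score_parameter(35.04, "temp", tab), 2L)  # -> 35.0
  expect_identical(score_parameter(35.05, "temp", tab), 0L)  # -> 35.1
  expect_identical(score_parameter(100.4, "sbp", tab), 1L)   # -> 100
  expect_identical(score_parameter(100.5, "sbp", tab), 0L)   # -> 101
})

test_that("out-of-range and invalid values raise informative errors", {
  expect_error(score_parameter(450, "sbp", tab), "\\[0, 400\\]")
  expect_error(score_parameter(19, "temp", tab), "\\[20, 45\\]")
  expect_error(score_parameter("awake", "consciousness", tab),
               "alert, voice, pain, unresponsive")
  expect_error(score_parameter(2, "concern", tab), "0/1")
  expect_error(score_parameter(1, "pulse", tab), "unknown parameter")
})

test_that("compute_mews sums the six parameters", {
  expect_identical(compute_mews(make_obs(rr = 16), tab)$total, 1L)
  expect_identical(compute_mews(make_obs(), tab)$total, 0L)
  worst <- make_obs(sbp = 65, hr = 135, rr = 32, temp = 34.0,
                    consciousness = "unresponsive", concern = 1)
  expect_identical(compute_mews(worst, tab)$total, 15L)
})

test_that("missing-value policy is applied, never silent", {
  o <- make_obs(); o$temp <- NA
  res <- compute_mews(o, tab)
  expect_identical(res$missing_parameters, "temp")
  expect_identical(res$total, 0L)
  strict <- default_score_table(missing_policy = "strict")
  expect_error(compute_mews(o, strict), "strict")
  all_na <- make_obs(sbp = NA, hr = NA, rr = NA, temp = NA,
                     consciousness = NA, concern = NA)
  expect_error(compute_mews(all_na, tab), "all six")
})

test_that("additivity: total equals the sum of per-parameter points", {
  set.seed(11)
  for (i in 1:50) {
    o <- random_obs(tab)
    res <- compute_mews(o, tab)
    by_param <- vapply(names(res$points), function(p)
      score_parameter(o[[p]], p, tab), integer(1))
    expect_identical(res$total, as.integer(sum(by_param)))
    expect_identical(unname(res$points), unname(by_param))
    expect_true(res$total >= 0 && res$total <= tab$max_total)
  }
})

test_that("bands partition every parameter's range (dense grids)", {
  for (p in c("sbp", "hr", "rr")) {
    rng <- switch(p, sbp = c(0, 400), hr = c(0, 350), rr = c(0, 100))
    grid <- seq(rng[1], rng[2], by = 1)
    pts <- score_parameter(grid, p, tab)
    expect_false(any(is.na(pts)))
    expect_true(all(pts %in% 0:3))
  }
  grid <- seq(20, 45, by = 0.1)
  pts <- score_parameter(grid, "temp", tab)
  expect_false(any(is.na(pts)))
  expect_true(all(pts %in% c(0L, 2L)))
})

test_that("monotonicity: worsening one parameter never lowers the total", {
  set.seed(12)
  band_reps <- list(  # one representative value per (param, points)
    sbp = c(`0` = 120, `1` = 90, `2` = 210, `3` = 60),
    hr = c(`0` = 75, `1` = 105, `2` = 120, `3` = 140),
    rr = c(`0` = 12, `1` = 16, `2` = 25, `3` = 35),
    temp = c(`0` = 37, `2` = 39))
  for (i in 1:25) {
    o <- random_obs(tab)
    base <- compute_mews(o, tab)
    for (p in names(band_reps)) {
      cur <- base$points[[p]]
      higher <- band_reps[[p]][as.numeric(names(band_reps[[p]])) > cur]
      for (v in higher) {
        o2 <- o; o2[[p]] <- v
        expect_gte(compute_mews(o2, tab)$total, base$total)
      }
    }
  }
})

test_that("daily_max_mews keeps the highest total, earliest on ties", {
  mk <- function(ts, rr) c(make_obs(rr = rr, timestamp = ts))
  d <- obs_df(mk("2024-01-01T06:00:00", 16),   # total 1
              mk("2024-01-01T10:00:00", 25),   # total 2
              mk("2024-01-01T20:00:00", 12))   # total 0
  res <- daily_max_mews(d, tab)
  expect_identical(res$total, 2L)
  expect_identical(res$timestamp, "2024-01-01T10:00:00")
  # tie -> earliest
  d2 <- obs_df(mk("2024-01-01T14:00:00", 25),
               mk("2024-01-01T05:00:00", 25))
  expect_identical(daily_max_mews(d2, tab)$timestamp, "2024-01-01T05:00:00")
  # singleton
  expect_identical(daily_max_mews(obs_df(mk("2024-01-01T01:00:00", 16)),
                                  tab)$total, 1L)
  expect_error(daily_max_mews(d[0, ], tab), "no observations")
  dm <- d; dm$patient_id <- c("P1", "P2", "P1")
  expect_error(daily_max_mews(dm, tab), "multiple patients")
  dd <- d; dd$timestamp[1] <- "2024-01-02T06:00:00"
  expect_error(daily_max_mews(dd, tab), "multiple calendar days")
})

test_that("daily_max_scores reduces a multi-patient table per day", {
  v <- obs_df(
    c(make_obs(rr = 16, patient_id = "P1", timestamp = "2024-01-01T06:00")),
    c(make_obs(rr = 25, patient_id = "P1", timestamp = "2024-01-01T18:00")),
    c(make_obs(rr = 12, patient_id = "P1", timestamp = "2024-01-02T06:00")),
    c(make_obs(rr = 35, patient_id = "P2", timestamp = "2024-01-01T06:00")))
  dm <- daily_max_scores(v, tab)
  expect_identical(nrow(dm), 3L)
  expect_identical(dm$total[dm$patient_id == "P1" &
                            dm$date == as.Date("2024-01-01")], 2L)
  expect_identical(dm$total[dm$patient_id == "P2"], 3L)
})

test_that("is_warning implements the threshold inclusively", {
  expect_true(is_warning(7, 7))
  expect_false(is_warning(6, 7))
  expect_false(is_warning(0, 7))
  expect_identical(is_warning(c(5, 7, 9), 7), c(FALSE, TRUE, TRUE))
})
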