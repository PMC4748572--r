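test_that("stratify reproduces the audit-table rates", {
  a <- audit_counts()
  scores <- rep(a$score, a$n)
  events <- unlist(mapply(function(n, k) rep(c(1L, 0L), c(k, n - k)),
                          a$n, a$events, SIMPLIFY = FALSE))
  st <- stratify(scores, events, top_bin = 9)
  expect_identical(st$score_label, c("6", "7", "8", "9+"))
  expect_identical(st$n, a$n)
  expect_identical(st$events, a$events)
  # 4/289 is 1.38%, not the printed 1.40% (documented discrepancy)
  expect_equal(round_half_up(st$rate_pct, 2), c(0.18, 1.38, 1.75, 3.57))
  expect_true(all(st$ci_low <= st$rate_pct & st$rate_pct <= st$ci_high))
  # conservation
  expect_identical(sum(st$n), length(scores))
  expect_identical(sum(st$events), sum(events))
})

test_that("stratify handles pooling, zero events, and degenerate input", {
  st <- stratify(c(3, 3, 9, 12, 15), c(0, 0, 0, 0, 0), top_bin = 9)
  expect_identical(st$score_label, c("3", "9+"))
  expect_identical(st$n, c(2L, 3L))
  expect_true(all(st$rate_pct == 0))
  expect_true(all(st$ci_low == 0))
  st1 <- stratify(5, 1, top_bin = 9)
  expect_identical(st1$n, c(1L, 0L))
  expect_equal(st1$rate_pct[1], 100)
  expect_error(stratify(1:3, 1:2), "different lengths")
})

test_that("conservation holds for arbitrary stratifications", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:300, 1)
    scores <- sample(0:15, n, replace = TRUE)
    events <- rbinom(n, 1, 0.1)
    st <- stratify(scores, events, top_bin = sample(2:12, 1))
    expect_identical(sum(st$n), n)
    expect_identical(sum(st$events), sum(events))
  }
})

test_that("chi2_2x2 matches frozen values and flags degenerate tables", {
  t1 <- chi2_2x2(1, 556, 4, 289)
  expect_equal(t1$statistic, 4.68809845, tolerance = 1e-7)
  expect_equal(t1$p_value, 0.03037224, tolerance = 1e-6)
  expect_lt(t1$p_value, 0.05)
  t2 <- chi2_2x2(5, 100, 5, 100)
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_value, 1)
  t3 <- chi2_2x2(79, 15170, 43, 17961)
  expect_lt(t3$p_value, 0.01)
  dg <- chi2_2x2(0, 50, 0, 50)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
  expect_error(chi2_2x2(5, 4, 0, 10))
})

test_that("chi-squared equals the squared two-proportion z statistic", {
  set.seed(22)
  for (i in 1:50) {
    n_a <- sample(5:500, 1); n_b <- sample(5:500, 1)
    e_a <- rbinom(1, n_a, 0.2); e_b <- rbinom(1, n_b, 0.2)
    if ((e_a + e_b) == 0 || (e_a + e_b) == (n_a + n_b)) next
    expect_equal(chi2_2x2(e_a, n_a, e_b, n_b)$statistic,
                 z2_two_prop(e_a, n_a, e_b, n_b), tolerance = 1e-10)
  }
})

test_that("fisher_2x2 matches frozen enumeration values", {
  expect_equal(fisher_2x2(1, 556, 4, 289, "one-sided")$p_value,
               0.04918514, tolerance = 1e-7)
  # the 8-vs-6 stratum comparison that chi-squared calls significant
  expect_equal(fisher_2x2(1, 556, 2, 114, "one-sided")$p_value,
               0.07658186, tolerance = 1e-7)
  dg <- fisher_2x2(0, 50, 0, 50, "two-sided")
  expect_equal(dg$p_value, 1)
  expect_true(dg$degenerate)
})

test_that("fisher_2x2 equals the brute-force oracle on random margins", {
  set.seed(23)
  for (i in 1:80) {
    n_a <- sample(1:100, 1); n_b <- sample(1:100, 1)
    e_a <- sample(0:n_a, 1); e_b <- sample(0:n_b, 1)
    for (side in c("one-sided", "two-sided")) {
      expect_equal(fisher_2x2(e_a, n_a, e_b, n_b, side)$p_value,
                   min(bf_fisher(e_a, n_a, e_b, n_b, side), 1),
                   tolerance = 1e-10,
                   info = paste(e_a, n_a, e_b, n_b, side))
    }
  }
})

test_that("one-sided fisher p is non-increasing in comparison events", {
  set.seed(24)
  for (i in 1:10) {
    n_a <- sample(20:200, 1); n_b <- sample(20:200, 1)
    e_a <- sample(0:5, 1)
    p <- vapply(0:n_b, function(e_b)
      fisher_2x2(e_a, n_a, e_b, n_b, "one-sided")$p_value, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("select_wz reproduces the audit threshold and the fisher contrast", {
  st <- audit_strata()
  dec <- select_wz(st, alpha = 0.05)
  expect_true(dec$found)
  expect_identical(dec$threshold, 7)
  expect_identical(dec$reference_label, "6")
  # all three strata tested against the reference
  t7 <- dec$tests[dec$tests$candidate == 7, ]
  expect_identical(t7$score_label, c("7", "8", "9+"))
  expect_true(all(t7$significant))
  # Fisher's exact does not support threshold 7 (8-vs-6 not significant)
  dec_f <- select_wz(st, alpha = 0.05, test = "fisher")
  expect_false(dec_f$found)
  expect_true(is.na(dec_f$threshold))
})

test_that("select_wz on flat or constructed strata behaves as specified", {
  flat <- strata_from_counts(1:4, rep(1000L, 4), rep(10L, 4))
  expect_false(select_wz(flat, 0.05)$found)
  # rates 0.1%, 0.1%, 5%, 9% at large n -> threshold = third score
  st <- strata_from_counts(4:7, c(5000L, 5000L, 2000L, 1000L),
                           c(5L, 5L, 100L, 90L))
  expect_identical(select_wz(st, 0.05)$threshold, 6)
})

test_that("select_wz threshold is monotone non-increasing in alpha", {
  set.seed(25)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    st <- strata_from_counts(seq_len(k) + 3,
                             sample(200:2000, k),
                             events = rbinom(k, 50, seq(0.05, 0.5,
                                                        length.out = k)))
    prev <- Inf
    for (alpha in c(0.01, 0.05, 0.1, 0.2)) {
      d <- select_wz(st, alpha)
      cur <- if (d$found) d$threshold else Inf
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})
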