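# Shared fixtures and independent oracles.

# The score-stratified audit counts (score 6..8 and pooled 9+).
audit_counts <- function() {
  list(score = 6:9, n = c(556L, 289L, 114L, 56L), events = c(1L, 4L, 2L, 2L))
}

audit_strata <- function() {
  a <- audit_counts()
  strata_from_counts(a$score, a$n, a$events)
}

# Brute-force hypergeometric oracle: enumerate every 2x2 table with the
# observed margins via binomial coefficients (no dhyper/phyper).
bf_fisher <- function(events_a, n_a, events_b, n_b,
                      sidedness = "one-sided") {
  K <- events_a + events_b
  N <- n_a + n_b
  if (K == 0 || K == N) return(1)
  xs <- max(0, K - n_a):min(K, n_b)   # events in group b
  pmf <- choose(K, xs) * choose(N - K, n_b - xs) / choose(N, n_b)
  if (sidedness == "one-sided") sum(pmf[xs >= events_b])
  else sum(pmf[pmf <= pmf[xs == events_b] * (1 + 1e-7)])
}

# Two-proportion z statistic (pooled variance), independent route for
# the chi-squared identity.
z2_two_prop <- function(events_a, n_a, events_b, n_b) {
  p1 <- events_a / n_a; p2 <- events_b / n_b
  pc <- (events_a + events_b) / (n_a + n_b)
  z <- (p1 - p2) / sqrt(pc * (1 - pc) * (1 / n_a + 1 / n_b))
  z^2
}

make_obs <- function(sbp = 120, hr = 75, rr = 12, temp = 36.8,
                     consciousness = "alert", concern = 0,
                     patient_id = "P1", timestamp = "2024-01-01T08:00:00") {
  list(patient_id = patient_id, timestamp = timestamp, sbp = sbp, hr = hr,
       rr = rr, temp = temp, consciousness = consciousness,
       concern = concern)
}

obs_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# random valid observation drawn uniformly over band grids
random_obs <- function(tab) {
  as.list(sample_vitals_for_score(sample(0:tab$max_total, 1), tab))
}

small_params <- function(n = 500, months = 3, ...) {
  cohort_params(n_admissions = n, months = months, period = "test", ...)
}

write_params_file <- function(...) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(...), f)
  f
}
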