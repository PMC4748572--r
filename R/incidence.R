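# Admission-denominated incidence: per-1000 rates, monthly series with
# control limits, cohort background summaries, before/after comparison.

#' Events per 1000 admissions
#'
#' @param events event count (>= 0).
#' @param admissions admission count (>= 1).
#' @param digits report rounding (half-up); the conventional report
#'   shows 2 decimals.
#' @param raw if TRUE, return the unrounded rate.
#' @return numeric rate per 1000 admissions.
#' @export
#' @examples
#' rate_per_1000(79, 15170)  # 5.21
#' rate_per_1000(43, 17961)  # 2.39
rate_per_1000 <- function(events, admissions, digits = 2, raw = FALSE) {
  if (any(admissions == 0))
    stop("admissions must be >= 1 (rate undefined for an empty period)")
  stopifnot(all(admissions >= 1), all(events >= 0))
  r <- 1000 * events / admissions
  if (raw) r else round_half_up(r, digits)
}

#' Monthly admission, warning-zone and event series
#'
#' One point per calendar month in the window. An admission (and its
#' events) is attributed to the month of its admission date. Months
#' with zero admissions appear with `rate_per_1000 = NA` and
#' `rate_defined = FALSE`.
#'
#' @param admissions data frame with `admission_id` and `admit_date`
#'   (Date or ISO-8601 string).
#' @param events data frame with `admission_id`, `event_type`
#'   (`"ihca"`/`"death"`), `event_date`; every event must reference an
#'   admission.
#' @param wz_flags optional logical vector (or 0/1), one per admission
#'   row, marking admissions that reached the warning zone.
#' @param window optional half-open date range `c(start, end)`; defaults
#'   to the months spanned by the admission dates.
#' @return data frame of class `mews_monthly`: `month` (first of
#'   month), `admissions`, `wz_count`, `ihca`, `deaths`,
#'   `rate_per_1000`, `rate_defined`.
#' @export
monthly_series <- function(admissions, events, wz_flags = NULL,
                           window = NULL) {
  stopifnot(is.data.frame(admissions), is.data.frame(events))
  adm_date <- as.Date(admissions$admit_date)
  orphans <- setdiff(events$admission_id, admissions$admission_id)
  if (length(orphans) > 0)
    stop("event(s) with no matching admission: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  if (is.null(wz_flags)) wz_flags <- rep(FALSE, nrow(admissions))
  stopifnot(length(wz_flags) == nrow(admissions))
  wz_flags <- as.logical(wz_flags)

  first_of_month <- function(d) as.Date(format(d, "%Y-%m-01"))
  if (is.null(window)) {
    window <- c(min(first_of_month(adm_date)),
                seq(max(first_of_month(adm_date)), by = "month", length.out = 2)[2])
  }
  window <- as.Date(window)
  months <- seq(first_of_month(window[1]), window[2] - 1, by = "month")
  in_win <- adm_date >= window[1] & adm_date < window[2]
  m_of <- first_of_month(adm_date)

  ihca_ids <- events$admission_id[events$event_type == "ihca"]
  death_ids <- events$admission_id[events$event_type == "death"]
  is_ihca <- admissions$admission_id %in% ihca_ids
  is_death <- admissions$admission_id %in% death_ids

  out <- data.frame(month = months)
  idx <- lapply(months, function(m) which(in_win & m_of == m))
  out$admissions <- vapply(idx, length, integer(1))
  out$wz_count <- vapply(idx, function(i) sum(wz_flags[i]), integer(1))
  out$ihca <- vapply(idx, function(i) sum(is_ihca[i]), integer(1))
  out$deaths <- vapply(idx, function(i) sum(is_death[i]), integer(1))
  out$rate_defined <- out$admissions > 0
  out$rate_per_1000 <- ifelse(out$rate_defined,
                              1000 * out$ihca / pmax(out$admissions, 1),
                              NA_real_)
  class(out) <- c("mews_monthly", "data.frame")
  out
}

#' Mean and SD control limits of a monthly rate series
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' monthly per-1000 rates, as drawn as the centre line and +/- 1 SD
#' bands on a monthly incidence chart. Note the mean of monthly rates
#' equals the pooled-period rate only when monthly denominators are
#' equal.
#'
#' @param monthly_rates numeric vector of monthly rates (NA months
#'   dropped), length >= 2 after dropping.
#' @return list with `mean` and `sd`.
#' @export
#' @examples
#' control_limits(c(2, 4))  # mean 3, sd sqrt(2)
control_limits <- function(monthly_rates) {
  r <- monthly_rates[!is.na(monthly_rates)]
  if (length(r) < 2)
    stop("need at least 2 monthly rates for control limits")
  list(mean = mean(r), sd = stats::sd(r))
}

#' Compare event rates between two periods
#'
#' Per-1000 rates, their ratio, and the uncorrected two-sided
#' chi-squared test of [chi2_2x2()] on the 2x2 outcome-by-period table.
#'
#' @param period_a,period_b lists (or `mews_period` summaries) with at
#'   least `admissions` and the outcome count (`ihca` or `deaths`);
#'   optionally `label`.
#' @param outcome `"ihca"` or `"death"`.
#' @param alpha significance level for the `significant` flag.
#' @return a `mews_comparison`: list with `outcome`, `label_a`,
#'   `label_b`, `rate_a`, `rate_b` (unrounded per-1000), `rate_ratio`,
#'   `test` (a `mews_test`), `significant`, `alpha`.
#' @export
#' @examples
#' before <- list(label = "before", admissions = 15170, ihca = 79)
#' after  <- list(label = "after",  admissions = 17961, ihca = 43)
#' compare_periods(before, after, "ihca", alpha = 0.01)
compare_periods <- function(period_a, period_b,
                            outcome = c("ihca", "death"), alpha = 0.05) {
  outcome <- match.arg(outcome)
  field <- if (outcome == "ihca") "ihca" else "deaths"
  cnt <- function(p) {
    k <- p[[field]] %||% p[["death"]]
    if (is.null(k)) stop("period has no '", field, "' count")
    k
  }
  ea <- cnt(period_a); eb <- cnt(period_b)
  na <- period_a$admissions; nb <- period_b$admissions
  stopifnot(na >= 1, nb >= 1)
  ra <- rate_per_1000(ea, na, raw = TRUE)
  rb <- rate_per_1000(eb, nb, raw = TRUE)
  tst <- chi2_2x2(ea, na, eb, nb)
  structure(list(
    outcome = outcome,
    label_a = period_a$label %||% "A", label_b = period_b$label %||% "B",
    events_a = ea, events_b = eb, admissions_a = na, admissions_b = nb,
    rate_a = ra, rate_b = rb,
    rate_ratio = if (ra > 0) rb / ra else NA_real_,
    test = tst, significant = tst$p_value < alpha, alpha = alpha),
    class = "mews_comparison")
}

#' @export
print.mews_comparison <- function(x, ...) {
  cat(sprintf("%s per 1000 admissions: %s %.2f (%d/%d) vs %s %.2f (%d/%d)\n",
              x$outcome, x$label_a, round_half_up(x$rate_a, 2),
              x$events_a, x$admissions_a,
              x$label_b, round_half_up(x$rate_b, 2),
              x$events_b, x$admissions_b))
  cat(sprintf("rate ratio %.3f; chi-squared p = %.4g (%ssignificant at %.2g)\n",
              x$rate_ratio, x$test$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Cohort background summary for one period
#'
#' Counts, age mean +/- SD, male percentage, and the top diagnoses by
#' frequency, in the style of a patients'-background table.
#'
#' @param admissions data frame with `admission_id`, `age`, `sex`
#'   (`"M"`/`"F"`), `diagnosis`, and optionally `dnr`.
#' @param events data frame with `admission_id`, `event_type`,
#'   `event_date` (may be empty).
#' @param label period label.
#' @param n_diagnoses how many top diagnoses to report.
#' @return a `mews_period`: list with `label`, `admissions`, `ihca`,
#'   `deaths`, `ihca_rate_per_1000`, `mortality_rate_per_1000`,
#'   `age_mean`, `age_sd`, `male_fraction`, `top_diagnoses` (data frame
#'   `diagnosis`, `n`, `percent`).
#' @export
cohort_summary <- function(admissions, events = NULL, label = "period",
                           n_diagnoses = 5) {
  stopifnot(is.data.frame(admissions))
  if (nrow(admissions) == 0L) stop("empty admissions table")
  n <- nrow(admissions)
  if (is.null(events))
    events <- data.frame(admission_id = character(0),
                         event_type = character(0))
  n_ihca <- length(unique(events$admission_id[events$event_type == "ihca"]))
  n_death <- length(unique(events$admission_id[events$event_type == "death"]))
  tab <- sort(table(admissions$diagnosis), decreasing = TRUE)
  tab <- utils::head(tab, n_diagnoses)
  structure(list(
    label = label, admissions = n, ihca = n_ihca, deaths = n_death,
    ihca_rate_per_1000 = rate_per_1000(n_ihca, n, raw = TRUE),
    mortality_rate_per_1000 = rate_per_1000(n_death, n, raw = TRUE),
    age_mean = mean(admissions$age, na.rm = TRUE),
    age_sd = stats::sd(admissions$age, na.rm = TRUE),
    male_fraction = mean(admissions$sex == "M", na.rm = TRUE),
    top_diagnoses = data.frame(diagnosis = names(tab),
                               n = as.integer(tab),
                               percent = round_half_up(100 * as.integer(tab) / n, 1))),
    class = "mews_period")
}

#' @export
print.mews_period <- function(x, ...) {
  cat(sprintf("Period '%s': %d admissions, %d IHCA (%.2f/1000), %d deaths (%.2f/1000)\n",
              x$label, x$admissions, x$ihca,
              round_half_up(x$ihca_rate_per_1000, 2),
              x$deaths, round_half_up(x$mortality_rate_per_1000, 2)))
  cat(sprintf("  age %.1f +/- %.1f, male %.1f%%\n",
              x$age_mean, x$age_sd, 100 * x$male_fraction))
  if (nrow(x$top_diagnoses) > 0) {
    cat("  top diagnoses:\n")
    for (i in seq_len(nrow(x$top_diagnoses)))
      cat(sprintf("    %d. %s %d (%.1f%%)\n", i,
                  x$top_diagnoses$diagnosis[i], x$top_diagnoses$n[i],
                  x$top_diagnoses$percent[i]))
  }
  invisible(x)
}
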