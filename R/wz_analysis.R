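# Warning-zone threshold audit: score-stratified event tables,
# 2x2 tests (uncorrected Pearson chi-squared and exact hypergeometric),
# and the threshold-selection rule.

#' Stratify patients by maximum score and tabulate event rates
#'
#' Builds one stratum per observed score value below `top_bin` plus a
#' pooled top stratum for scores at or above `top_bin`. Rates are
#' percentages with exact Clopper-Pearson 95% confidence bounds.
#'
#' @param scores integer vector, one (maximum) score per patient.
#' @param events logical/0-1 vector, one event flag (e.g. in-hospital
#'   cardiac arrest) per patient.
#' @param top_bin scores at or above this value are pooled (default 9).
#' @param conf_level confidence level for the binomial bounds.
#' @return a data frame of class `mews_strata` with columns
#'   `score_label`, `score` (numeric; `top_bin` for the pooled row),
#'   `n`, `events`, `rate_pct`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' s <- rep(c(6, 7, 8, 9), c(556, 289, 114, 56))
#' e <- unlist(mapply(function(n, k) c(rep(1, k), rep(0, n - k)),
#'                    c(556, 289, 114, 56), c(1, 4, 2, 2)))
#' stratify(s, e)
stratify <- function(scores, events, top_bin = 9, conf_level = 0.95) {
  if (length(scores) != length(events))
    stop("scores and events have different lengths (",
         length(scores), " vs ", length(events), ")")
  stopifnot(top_bin >= 1)
  events <- as.integer(as.logical(events))
  pooled <- scores >= top_bin
  lab <- ifelse(pooled, paste0(top_bin, "+"), as.character(scores))
  val <- ifelse(pooled, top_bin, scores)
  levs <- sort(unique(val[!pooled]))
  levs <- c(levs[levs < top_bin], top_bin)
  n  <- vapply(levs, function(s) sum(val == s), integer(1))
  ev <- vapply(levs, function(s) sum(events[val == s]), integer(1))
  alpha <- 1 - conf_level
  ci_low <- ifelse(n == 0, NA_real_,
                   ifelse(ev == 0, 0, stats::qbeta(alpha / 2, ev, n - ev + 1)))
  ci_high <- ifelse(n == 0, NA_real_,
                    ifelse(ev == n, 1, stats::qbeta(1 - alpha / 2, ev + 1, n - ev)))
  out <- data.frame(
    score_label = ifelse(levs == top_bin, paste0(top_bin, "+"),
                         as.character(levs)),
    score = as.numeric(levs),
    n = n, events = ev,
    rate_pct = ifelse(n == 0, NA_real_, 100 * ev / n),
    ci_low = 100 * ci_low, ci_high = 100 * ci_high)
  class(out) <- c("mews_strata", "data.frame")
  out
}

#' Assemble a stratum table directly from counts
#'
#' Convenience constructor for audits quoted as aggregate counts (one
#' `n`/`events` pair per score stratum) rather than patient-level data.
#'
#' @param score numeric stratum scores (the pooled top stratum is the
#'   largest value).
#' @param n patients per stratum.
#' @param events events per stratum.
#' @param top_bin pooled-top score; defaults to `max(score)`.
#' @inheritParams stratify
#' @return a `mews_strata` data frame (see [stratify()]).
#' @export
#' @examples
#' strata_from_counts(score = 6:9, n = c(556, 289, 114, 56),
#'                    events = c(1, 4, 2, 2))
strata_from_counts <- function(score, n, events, top_bin = max(score),
                               conf_level = 0.95) {
  stopifnot(length(score) == length(n), length(n) == length(events),
            all(events <= n), all(events >= 0), all(n >= 0))
  stratify(rep(score, n),
           unlist(mapply(function(nn, kk) rep(c(1L, 0L), c(kk, nn - kk)),
                         n, events, SIMPLIFY = FALSE)),
           top_bin = top_bin, conf_level = conf_level)
}

#' Uncorrected Pearson chi-squared test on a 2x2 event table
#'
#' Tests equality of event proportions between two groups with the
#' Pearson statistic (no continuity correction) referred to the
#' chi-squared distribution with 1 degree of freedom, two-sided.
#' A table with an empty margin (no events at all, or no non-events)
#' returns statistic 0 and p 1, flagged degenerate.
#'
#' @param events_a,n_a events and group size in the reference group.
#' @param events_b,n_b events and group size in the comparison group.
#' @return a `mews_test`: list with `statistic`, `p_value`, `sidedness`,
#'   `method`, `degenerate`.
#' @export
#' @examples
#' chi2_2x2(1, 556, 4, 289)$p_value  # ~0.030
chi2_2x2 <- function(events_a, n_a, events_b, n_b) {
  .check_2x2(events_a, n_a, events_b, n_b)
  # doubles throughout: the cross-product term overflows 32-bit integers
  a <- as.numeric(events_a); b <- as.numeric(n_a) - a
  c <- as.numeric(events_b); d <- as.numeric(n_b) - c
  N <- as.numeric(n_a) + as.numeric(n_b)
  if ((a + c) == 0 || (b + d) == 0) {
    return(.mews_test(statistic = 0, p_value = 1, sidedness = "two-sided",
                      method = "chi-squared", degenerate = TRUE))
  }
  stat <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  .mews_test(statistic = stat,
             p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             sidedness = "two-sided", method = "chi-squared",
             degenerate = FALSE)
}

#' Fisher's exact test on a 2x2 event table
#'
#' Exact hypergeometric test with both margins fixed. One-sided: the
#' probability that the comparison group's event count is at least the
#' observed count. Two-sided: the sum of probabilities of all tables no
#' more probable than the observed one (the usual small-p-values rule).
#'
#' @inheritParams chi2_2x2
#' @param sidedness `"one-sided"` (comparison group higher) or
#'   `"two-sided"`.
#' @return a `mews_test`; `statistic` is `NA` (no test statistic for the
#'   exact test).
#' @export
#' @examples
#' fisher_2x2(1, 556, 4, 289, "one-sided")$p_value  # ~0.049
fisher_2x2 <- function(events_a, n_a, events_b, n_b,
                       sidedness = c("one-sided", "two-sided")) {
  sidedness <- match.arg(sidedness)
  .check_2x2(events_a, n_a, events_b, n_b)
  K <- events_a + events_b           # total events (fixed margin)
  N <- n_a + n_b
  if (K == 0 || K == N) {
    return(.mews_test(statistic = NA_real_, p_value = 1,
                      sidedness = sidedness, method = "fisher",
                      degenerate = TRUE))
  }
  if (sidedness == "one-sided") {
    p <- stats::phyper(events_b - 1, K, N - K, n_b, lower.tail = FALSE)
  } else {
    support <- max(0, K - n_a):min(K, n_b)
    pmf <- stats::dhyper(support, K, N - K, n_b)
    p_obs <- pmf[support == events_b]
    p <- sum(pmf[pmf <= p_obs * (1 + 1e-7)])
  }
  .mews_test(statistic = NA_real_, p_value = min(p, 1),
             sidedness = sidedness, method = "fisher", degenerate = FALSE)
}

.check_2x2 <- function(events_a, n_a, events_b, n_b) {
  stopifnot(n_a >= 1, n_b >= 1,
            events_a >= 0, events_b >= 0,
            events_a <= n_a, events_b <= n_b)
}

.mews_test <- function(statistic, p_value, sidedness, method, degenerate) {
  structure(list(statistic = statistic, p_value = p_value,
                 sidedness = sidedness, method = method,
                 degenerate = degenerate),
            class = "mews_test")
}

#' @export
print.mews_test <- function(x, ...) {
  cat(x$method, " (", x$sidedness, "): ", sep = "")
  if (!is.na(x$statistic)) cat("statistic =", signif(x$statistic, 4), ", ")
  cat("p =", signif(x$p_value, 4))
  if (x$degenerate) cat("  [degenerate table]")
  cat("\n")
  invisible(x)
}

#' Select the warning-zone threshold from a stratum table
#'
#' Scans candidate thresholds in increasing score order and returns the
#' smallest threshold t such that every stratum with score >= t has a
#' significantly higher event rate (p < alpha and observed rate higher)
#' than the stratum immediately below t. The default test is the
#' uncorrected chi-squared of [chi2_2x2()]; Fisher's exact one-sided
#' test is available for audit.
#'
#' @param strata a `mews_strata` data frame (see [stratify()] /
#'   [strata_from_counts()]).
#' @param alpha significance level in (0, 1).
#' @param test `"chi-squared"` (default) or `"fisher"` (one-sided).
#' @return a `mews_wz_decision`: list with `threshold` (NA if no
#'   candidate satisfies the rule), `found`, `reference_label`, `alpha`,
#'   `test`, and `tests`, a data frame of every stratum-vs-reference
#'   comparison performed (columns `candidate`, `score_label`,
#'   `p_value`, `higher`, `significant`).
#' @export
#' @examples
#' st <- strata_from_counts(6:9, c(556, 289, 114, 56), c(1, 4, 2, 2))
#' select_wz(st, alpha = 0.05)$threshold  # 7
select_wz <- function(strata, alpha = 0.05,
                      test = c("chi-squared", "fisher")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(strata), alpha > 0, alpha < 1)
  strata <- strata[strata$n > 0, , drop = FALSE]  # empty strata carry no test
  if (nrow(strata) < 2)
    stop("need at least 2 non-empty strata")
  strata <- strata[order(strata$score), , drop = FALSE]
  run_test <- function(ref, cmp) {
    if (test == "chi-squared")
      chi2_2x2(strata$events[ref], strata$n[ref],
               strata$events[cmp], strata$n[cmp])
    else
      fisher_2x2(strata$events[ref], strata$n[ref],
                 strata$events[cmp], strata$n[cmp], "one-sided")
  }
  all_tests <- NULL
  chosen <- NA_real_
  ref_label <- NA_character_
  for (ti in 2:nrow(strata)) {
    ref <- ti - 1L
    cmps <- ti:nrow(strata)
    res <- lapply(cmps, function(ci) run_test(ref, ci))
    p <- vapply(res, function(r) r$p_value, numeric(1))
    higher <- strata$rate_pct[cmps] > strata$rate_pct[ref]
    sig <- higher & p < alpha
    all_tests <- rbind(all_tests, data.frame(
      candidate = strata$score[ti],
      score_label = strata$score_label[cmps],
      reference_label = strata$score_label[ref],
      p_value = p, higher = higher, significant = sig))
    if (is.na(chosen) && all(sig)) {
      chosen <- strata$score[ti]
      ref_label <- strata$score_label[ref]
    }
  }
  structure(list(threshold = chosen, found = !is.na(chosen),
                 reference_label = ref_label, alpha = alpha, test = test,
                 tests = all_tests),
            class = "mews_wz_decision")
}

#' @export
print.mews_wz_decision <- function(x, ...) {
  if (x$found)
    cat("Warning-zone threshold:", x$threshold,
        "(vs stratum", x$reference_label, ", ", x$test,
        ", alpha =", x$alpha, ")\n")
  else
    cat("No warning-zone threshold satisfies the rule (", x$test,
        ", alpha =", x$alpha, ")\n")
  invisible(x)
}
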