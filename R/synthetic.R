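# Synthetic inpatient cohort generator: score-conditional vital signs,
# per-admission score trajectories, and event hazards calibrated to a
# published score-stratified arrest-rate audit.

#' Score -> event-probability model calibrated to the audit table
#'
#' Per-admission in-hospital cardiac-arrest probabilities by maximum
#' score stratum, taken directly from the audit counts (1/556 at score
#' <= 6, 4/289 at 7, 2/114 at 8, 2/56 at >= 9; the sub-7 strata share
#' the score-6 reference rate). The baseline distribution of the
#' admission maximum stratum is proportional to the audit patient
#' counts 556/289/114/56 for strata 6/7/8/9+, with the low-score mass
#' (0-5) chosen so that the fraction of admissions reaching the warning
#' zone matches the reported post-introduction census (920 of 17,961
#' admissions, i.e. a monthly mean of 51.1 warning-zone patients at
#' ~998 admissions/month).
#'
#' @param death_prob per-admission in-hospital death probability
#'   (default 636/17,961, the post-introduction mortality).
#' @return a `mews_hazard`: list with `ihca_prob` (named over strata
#'   `0-6`, `7`, `8`, `9+`), `death_prob`, and `stratum_weights` (named
#'   over admission-maximum strata `0-5`, `6`, `7`, `8`, `9+`).
#' @export
#' @examples
#' h <- default_hazard_from_table2()
#' round(h$ihca_prob[["9+"]], 4)  # 0.0357
default_hazard_from_table2 <- function(death_prob = 636 / 17961) {
  wz_fraction <- 920 / 17961               # admissions reaching the WZ
  k <- wz_fraction / (289 + 114 + 56)
  w <- c("0-5" = 1 - (556 + 289 + 114 + 56) * k,
         "6" = 556 * k, "7" = 289 * k, "8" = 114 * k, "9+" = 56 * k)
  new_hazard_model(
    ihca_prob = c("0-6" = 1 / 556, "7" = 4 / 289, "8" = 2 / 114,
                  "9+" = 2 / 56),
    death_prob = death_prob,
    stratum_weights = w)
}

#' Build and validate a hazard model
#'
#' @param ihca_prob named probabilities over hazard strata
#'   `0-6`, `7`, `8`, `9+`.
#' @param death_prob per-admission death probability.
#' @param stratum_weights named distribution of the admission maximum
#'   stratum over `0-5`, `6`, `7`, `8`, `9+` (must sum to 1).
#' @return a `mews_hazard`.
#' @export
new_hazard_model <- function(ihca_prob, death_prob, stratum_weights) {
  stopifnot(setequal(names(ihca_prob), c("0-6", "7", "8", "9+")),
            setequal(names(stratum_weights), c("0-5", "6", "7", "8", "9+")))
  if (any(ihca_prob < 0 | ihca_prob > 1) || death_prob < 0 || death_prob > 1)
    stop("hazard probabilities must be in [0, 1]")
  if (any(stratum_weights < 0) || abs(sum(stratum_weights) - 1) > 1e-8)
    stop("stratum weights must be non-negative and sum to 1")
  structure(list(ihca_prob = ihca_prob[c("0-6", "7", "8", "9+")],
                 death_prob = death_prob,
                 stratum_weights = stratum_weights[c("0-5", "6", "7", "8", "9+")]),
            class = "mews_hazard")
}

.hazard_stratum_of <- function(total) {
  ifelse(total >= 9, "9+", ifelse(total >= 7, as.character(total), "0-6"))
}

.max_stratum_levels <- c("0-5", "6", "7", "8", "9+")

#' Synthetic-cohort generator settings
#'
#' Defaults describe an acute-care hospital of ~330 beds at the scale
#' of the post-introduction study period: 17,961 admissions over 18
#' months (~998/month), geometric length of stay with mean 10 days
#' (consistent with bed count x 30 / monthly admissions), age normal
#' 59.3 +/- 28 truncated at 0, 54.4% male, the published top-5
#' diagnosis frequencies, and a 5% DNR fraction.
#'
#' @param n_admissions admission episodes to generate.
#' @param months window length in calendar months.
#' @param start_date first day of the window.
#' @param monthly_weights positive sampling weights per month.
#' @param los_mean mean length of stay, days (geometric, minimum 1).
#' @param age_mean,age_sd age distribution (normal, truncated at 0).
#' @param male_fraction probability of male sex.
#' @param diagnoses data frame `name`/`prob` (probabilities sum to 1).
#' @param dnr_fraction fraction of admissions with DNR orders.
#' @param persistence per-day probability that an admission remains at
#'   its peak score stratum once reached (geometric excursion length).
#' @param extra_obs_prob probability of each of up to two additional
#'   same-day observations beyond the daily one.
#' @param period period label stamped on the admissions.
#' @return a `mews_cohort_params` list.
#' @export
cohort_params <- function(n_admissions = 17961, months = 18,
                          start_date = "2013-10-01",
                          monthly_weights = NULL,
                          los_mean = 10,
                          age_mean = 59.3, age_sd = 28,
                          male_fraction = 0.544,
                          diagnoses = NULL,
                          dnr_fraction = 0.05,
                          persistence = 0.6,
                          extra_obs_prob = 0.15,
                          period = "synthetic") {
  if (is.null(monthly_weights)) monthly_weights <- rep(1, months)
  if (is.null(diagnoses))
    diagnoses <- data.frame(
      name = c("pneumonia", "angina", "urinary tract infection",
               "congestive heart failure", "acute gastroenteritis", "other"),
      prob = c(0.065, 0.044, 0.024, 0.021, 0.020, 0.826))
  stopifnot(n_admissions >= 1, months >= 1,
            length(monthly_weights) == months, all(monthly_weights > 0),
            los_mean >= 1,
            age_sd > 0,
            male_fraction >= 0, male_fraction <= 1,
            dnr_fraction >= 0, dnr_fraction <= 1,
            persistence >= 0, persistence < 1,
            extra_obs_prob >= 0, extra_obs_prob <= 1)
  if (abs(sum(diagnoses$prob) - 1) > 1e-8 || any(diagnoses$prob < 0))
    stop("diagnosis probabilities must be non-negative and sum to 1")
  structure(list(n_admissions = as.integer(n_admissions),
                 months = as.integer(months),
                 start_date = as.Date(start_date),
                 monthly_weights = monthly_weights,
                 los_mean = los_mean, age_mean = age_mean, age_sd = age_sd,
                 male_fraction = male_fraction, diagnoses = diagnoses,
                 dnr_fraction = dnr_fraction, persistence = persistence,
                 extra_obs_prob = extra_obs_prob, period = period),
            class = "mews_cohort_params")
}

# within-stratum distributions of the daily total (generator policy:
# most ward patients score 0-2; pooled-top totals thin out above 9)
.low_total_weights <- c(`0` = 0.35, `1` = 0.28, `2` = 0.17, `3` = 0.10,
                        `4` = 0.06, `5` = 0.04)
.top_total_weights <- c(`9` = 0.55, `10` = 0.22, `11` = 0.10, `12` = 0.06,
                        `13` = 0.04, `14` = 0.02, `15` = 0.01)

.sample_low_totals <- function(n, max_allowed = 5) {
  w <- .low_total_weights[seq_len(max_allowed + 1)]
  sample(0:max_allowed, n, replace = TRUE, prob = w)
}

#' Draw a vital-sign observation that scores a requested total
#'
#' Inverse of the scoring rubric: draws a per-parameter point
#' decomposition uniformly among all decompositions summing to the
#' target, then draws each vital uniformly (at the parameter's
#' granularity) within a band carrying those points. Rescoring the
#' result reproduces the target exactly. Uses R's global RNG.
#'
#' @param target_total requested MEWS total, 0 to `table$max_total`.
#' @param table a `mews_score_table`.
#' @param n number of observations to draw.
#' @return a data frame with columns `sbp`, `hr`, `rr`, `temp`,
#'   `consciousness`, `concern` (`n` rows).
#' @export
#' @examples
#' set.seed(1)
#' obs <- sample_vitals_for_score(15, default_score_table())
#' compute_mews(as.list(obs), default_score_table())$total  # 15
sample_vitals_for_score <- function(target_total, table, n = 1) {
  stopifnot(inherits(table, "mews_score_table"), n >= 1)
  if (target_total < 0 || target_total > table$max_total)
    stop("target total ", target_total, " infeasible (0..",
         table$max_total, ")")
  sample_vitals_batch(rep(as.integer(target_total), n), table)
}

# decomposition cache ------------------------------------------------

.mewsr_cache <- new.env(parent = emptyenv())

.table_signature <- function(table) {
  paste(vapply(table$bands, function(b)
    paste(b$upper, b$points, collapse = ","), character(1)),
    paste(table$consciousness, collapse = ","),
    paste(table$concern, collapse = ","), collapse = "|")
}

# all per-parameter point vectors (6 columns) summing to each total
.decompositions <- function(table) {
  key <- paste0("decomp:", .table_signature(table))
  if (!is.null(.mewsr_cache[[key]])) return(.mewsr_cache[[key]])
  point_sets <- c(lapply(table$bands, function(b) sort(unique(b$points))),
                  list(consciousness = sort(unique(table$consciousness)),
                       concern = sort(unique(table$concern))))
  grid <- as.matrix(expand.grid(point_sets, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- .mews_param_names
  split_by_total <- split.data.frame(grid, rowSums(grid))
  .mewsr_cache[[key]] <- split_by_total
  split_by_total
}

# candidate value intervals per (continuous parameter, point value)
.bands_for_points <- function(table) {
  key <- paste0("bands:", .table_signature(table))
  if (!is.null(.mewsr_cache[[key]])) return(.mewsr_cache[[key]])
  out <- lapply(names(.vital_params), function(p) {
    spec <- .vital_params[[p]]
    b <- table$bands[[p]]
    g <- spec$granularity
    lo <- c(spec$range[1], b$upper[-nrow(b)] + g)
    hi <- pmin(b$upper, spec$range[2])
    lapply(split(seq_len(nrow(b)), b$points), function(idx) {
      data.frame(lo = lo[idx], hi = hi[idx],
                 nvals = round((hi[idx] - lo[idx]) / g) + 1)
    })
  })
  names(out) <- names(.vital_params)
  .mewsr_cache[[key]] <- out
  out
}

# vectorized inverse scorer: one observation per element of `totals`
sample_vitals_batch <- function(totals, table) {
  n <- length(totals)
  decomp <- .decompositions(table)
  bandinfo <- .bands_for_points(table)
  pts <- matrix(0L, n, 6, dimnames = list(NULL, .mews_param_names))
  for (t in unique(totals)) {
    rows <- which(totals == t)
    D <- decomp[[as.character(t)]]
    if (is.null(D))
      stop("target total ", t, " infeasible for this score table")
    pick <- if (nrow(D) == 1L) rep(1L, length(rows))
            else sample.int(nrow(D), length(rows), replace = TRUE)
    pts[rows, ] <- D[pick, , drop = FALSE]
  }
  out <- data.frame(sbp = numeric(n), hr = numeric(n), rr = numeric(n),
                    temp = numeric(n),
                    consciousness = character(n), concern = integer(n))
  for (p in names(.vital_params)) {
    g <- .vital_params[[p]]$granularity
    val <- numeric(n)
    for (pv in unique(pts[, p])) {
      rows <- which(pts[, p] == pv)
      cand <- bandinfo[[p]][[as.character(pv)]]
      bsel <- if (nrow(cand) == 1L) rep(1L, length(rows))
              else sample.int(nrow(cand), length(rows), replace = TRUE)
      k <- floor(stats::runif(length(rows)) * cand$nvals[bsel])
      val[rows] <- round(cand$lo[bsel] + g * k, 6)
    }
    out[[p]] <- val
  }
  for (pv in unique(pts[, "consciousness"])) {
    rows <- which(pts[, "consciousness"] == pv)
    levs <- names(table$consciousness)[table$consciousness == pv]
    out$consciousness[rows] <- if (length(levs) == 1L) levs
      else levs[sample.int(length(levs), length(rows), replace = TRUE)]
  }
  for (pv in unique(pts[, "concern"])) {
    rows <- which(pts[, "concern"] == pv)
    toks <- which(table$concern == pv) - 1L  # no=0, yes=1
    out$concern[rows] <- if (length(toks) == 1L) toks
      else toks[sample.int(length(toks), length(rows), replace = TRUE)]
  }
  out
}

# cohort core: admissions + daily score paths (RNG already seeded) ----

.gen_core <- function(params, hazard) {
  n <- params$n_admissions
  month_starts <- seq(params$start_date, by = "month",
                      length.out = params$months + 1)
  mdays <- as.integer(diff(month_starts))
  mi <- sample.int(params$months, n, replace = TRUE,
                   prob = params$monthly_weights)
  admit <- month_starts[mi] + floor(stats::runif(n) * mdays[mi])
  los <- 1L + stats::rgeom(n, prob = 1 / params$los_mean)
  age <- stats::qnorm(stats::runif(n, stats::pnorm(0, params$age_mean,
                                                   params$age_sd), 1),
                      params$age_mean, params$age_sd)
  sex <- ifelse(stats::runif(n) < params$male_fraction, "M", "F")
  diagnosis <- sample(params$diagnoses$name, n, replace = TRUE,
                      prob = params$diagnoses$prob)
  dnr <- stats::runif(n) < params$dnr_fraction

  max_stratum <- sample(.max_stratum_levels, n, replace = TRUE,
                        prob = hazard$stratum_weights)
  max_total <- integer(n)
  max_total[max_stratum == "0-5"] <-
    .sample_low_totals(sum(max_stratum == "0-5"))
  max_total[max_stratum == "6"] <- 6L
  max_total[max_stratum == "7"] <- 7L
  max_total[max_stratum == "8"] <- 8L
  i9 <- max_stratum == "9+"
  max_total[i9] <- sample(9:15, sum(i9), replace = TRUE,
                          prob = .top_total_weights)

  onset <- 1L + floor(stats::runif(n) * los)
  dur <- pmin(1L + stats::rgeom(n, prob = 1 - params$persistence),
              los - onset + 1L)

  paths <- vector("list", n)
  peak_days <- vector("list", n)
  for (i in seq_len(n)) {
    tot <- rep(0L, los[i])
    base_max <- min(max_total[i] - 1L, 5L)
    if (base_max >= 0L && los[i] > dur[i])
      tot[] <- .sample_low_totals(los[i], max_allowed = max(base_max, 0L))
    pk <- onset[i]:(onset[i] + dur[i] - 1L)
    tot[pk] <- max_total[i]
    if (max_total[i] == 0L) tot[] <- 0L
    paths[[i]] <- tot
    peak_days[[i]] <- pk
  }
  admissions <- data.frame(
    admission_id = sprintf("A%06d", seq_len(n)),
    admit_date = admit,
    discharge_date = admit + los,
    age = round(age, 1), sex = sex, diagnosis = diagnosis,
    dnr = as.integer(dnr), period = params$period,
    los = los, max_total = max_total, max_stratum = max_stratum,
    stringsAsFactors = FALSE)
  list(admissions = admissions, paths = paths, peak_days = peak_days,
       onset = onset, dur = dur)
}

.daily_frame <- function(core) {
  adm <- core$admissions
  len <- lengths(core$paths)
  data.frame(
    admission_id = rep(adm$admission_id, len),
    date = adm$admit_date[rep(seq_len(nrow(adm)), len)] +
      (unlist(lapply(len, seq_len)) - 1L),
    day = unlist(lapply(len, seq_len)),
    total = unlist(core$paths))
}

#' Generate a synthetic inpatient cohort
#'
#' Produces an admissions table, per-day intended maximum scores,
#' vital-sign observations realizing those scores (via
#' [sample_vitals_for_score()]), and IHCA/death events drawn from the
#' hazard model: each admission's IHCA probability is that of its
#' maximum score stratum, with the event day uniform among the days
#' spent at that stratum; deaths occur at discharge with the model's
#' death probability. No callout intervention is applied (see
#' [simulate_study()] for that).
#'
#' @param params a [cohort_params()] object.
#' @param hazard a hazard model, default [default_hazard_from_table2()].
#' @param seed integer seed; identical inputs give identical output.
#' @param table score table used to realize vitals.
#' @param include_vitals if FALSE, skip the (comparatively expensive)
#'   vital-sign realization and return only scores.
#' @return a `mews_cohort`: list with `admissions`, `daily` (intended
#'   per-day maxima), `vitals` (NULL if not realized), `events`,
#'   `params`, `seed`.
#' @export
generate_cohort <- function(params = cohort_params(),
                            hazard = default_hazard_from_table2(),
                            seed = 1L,
                            table = default_score_table(),
                            include_vitals = TRUE) {
  stopifnot(inherits(params, "mews_cohort_params"),
            inherits(hazard, "mews_hazard"))
  set.seed(seed)
  core <- .gen_core(params, hazard)
  adm <- core$admissions
  n <- nrow(adm)

  p_ihca <- hazard$ihca_prob[.hazard_stratum_of(adm$max_total)]
  has_ihca <- stats::runif(n) < p_ihca
  hazard_days <- ifelse(adm$max_total >= 7, core$dur, adm$los)
  ihca_day <- integer(n)
  for (i in which(has_ihca)) {
    days <- if (adm$max_total[i] >= 7) core$peak_days[[i]] else
      seq_len(adm$los[i])
    ihca_day[i] <- days[1L + floor(stats::runif(1) * length(days))]
  }
  has_death <- stats::runif(n) < hazard$death_prob
  events <- rbind(
    data.frame(admission_id = adm$admission_id[has_ihca],
               event_type = rep("ihca", sum(has_ihca)),
               event_date = adm$admit_date[has_ihca] + ihca_day[has_ihca] - 1L),
    data.frame(admission_id = adm$admission_id[has_death],
               event_type = rep("death", sum(has_death)),
               event_date = adm$discharge_date[has_death]))
  events <- events[order(events$admission_id, events$event_type), ]
  rownames(events) <- NULL

  daily <- .daily_frame(core)
  vitals <- NULL
  if (include_vitals) {
    n_extra <- stats::rbinom(nrow(daily), 2L, params$extra_obs_prob)
    prim <- data.frame(patient_id = daily$admission_id, date = daily$date,
                       total = daily$total)
    extra_rows <- rep(seq_len(nrow(daily)), n_extra)
    extra_tot <- if (length(extra_rows))
      floor(stats::runif(length(extra_rows)) * (daily$total[extra_rows] + 1L))
    else integer(0)
    all_obs <- rbind(prim,
                     data.frame(patient_id = daily$admission_id[extra_rows],
                                date = daily$date[extra_rows],
                                total = as.integer(extra_tot)))
    v <- sample_vitals_batch(all_obs$total, table)
    hh <- floor(stats::runif(nrow(all_obs)) * 24)
    mm <- floor(stats::runif(nrow(all_obs)) * 60)
    vitals <- data.frame(
      patient_id = all_obs$patient_id,
      timestamp = sprintf("%sT%02d:%02d:00", format(all_obs$date), hh, mm),
      v, stringsAsFactors = FALSE)
    vitals <- vitals[order(vitals$patient_id, vitals$timestamp), ]
    rownames(vitals) <- NULL
  }
  structure(list(admissions = adm, daily = daily, vitals = vitals,
                 events = events, params = params, hazard = hazard,
                 seed = seed),
            class = "mews_cohort")
}

#' @export
print.mews_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$admissions), "admissions over",
      x$params$months, "months (seed", x$seed, ")\n")
  cat("  IHCA:", sum(x$events$event_type == "ihca"),
      " deaths:", sum(x$events$event_type == "death"),
      " WZ admissions:", sum(x$admissions$max_total >= 7), "\n")
  invisible(x)
}
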