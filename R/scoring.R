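# Scoring engine: per-parameter band lookup, whole-observation scoring,
# and the daily-maximum reduction.

.parse_ts <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y-%m-%d"))
}

#' Round half-up at a given granularity
#'
#' Unlike [round()], which rounds to even, ties go away from zero. Used
#' before band lookup and for report formatting.
#' @param x numeric vector.
#' @param digits decimal digits to keep.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Score one parameter of a vital-sign observation
#'
#' Continuous vitals are rounded half-up to the parameter's granularity
#' (0.1 degC for temperature, integers otherwise), then mapped to the
#' unique band whose inclusive upper bound contains them.
#' `consciousness` takes an AVPU token, `concern` a logical or 0/1.
#'
#' @param value vector of values (numeric for vitals, character for
#'   consciousness, logical/0-1 for concern).
#' @param parameter one of `"sbp"`, `"hr"`, `"rr"`, `"temp"`,
#'   `"consciousness"`, `"concern"`.
#' @param table a `mews_score_table`.
#' @return integer vector of points; `NA` where `value` is missing
#'   (caller applies the table's missing policy).
#' @export
#' @examples
#' tab <- default_score_table()
#' score_parameter(120, "sbp", tab)            # 0
#' score_parameter(65, "sbp", tab)             # 3
#' score_parameter("unresponsive", "consciousness", tab)  # 3
score_parameter <- function(value, parameter, table) {
  stopifnot(inherits(table, "mews_score_table"))
  if (parameter == "consciousness") {
    pts <- rep(NA_integer_, length(value))
    ok <- !is.na(value)
    bad <- ok & !(value %in% .consciousness_levels)
    if (any(bad))
      stop("unknown consciousness level(s): ",
           paste(unique(value[bad]), collapse = ", "),
           " (allowed: ", paste(.consciousness_levels, collapse = ", "), ")")
    pts[ok] <- table$consciousness[as.character(value[ok])]
    return(pts)
  }
  if (parameter == "concern") {
    v <- as.integer(value)
    if (any(!is.na(v) & !(v %in% c(0L, 1L))))
      stop("concern must be 0/1 or logical")
    pts <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    pts[ok] <- unname(table$concern[c("no", "yes")[v[ok] + 1L]])
    return(pts)
  }
  spec <- .vital_params[[parameter]]
  if (is.null(spec))
    stop("unknown parameter '", parameter, "'")
  v <- as.numeric(value)
  ok <- !is.na(v)
  out_lo <- ok & v < spec$range[1]
  out_hi <- ok & v > spec$range[2]
  if (any(out_lo | out_hi))
    stop(parameter, " value out of physiological range [",
         spec$range[1], ", ", spec$range[2], "]: ",
         paste(utils::head(v[out_lo | out_hi], 3), collapse = ", "))
  b <- table$bands[[parameter]]
  g <- spec$granularity
  # work on the granularity grid so inclusive upper bounds are exact
  vi <- round_half_up(v / g)
  ui <- round(b$upper / g)
  idx <- findInterval(vi, ui, left.open = TRUE) + 1L  # smallest i: vi <= ui[i]
  pts <- rep(NA_integer_, length(v))
  pts[ok] <- b$points[idx[ok]]
  pts
}

.mews_param_names <- c("sbp", "hr", "rr", "temp", "consciousness", "concern")

#' Compute the MEWS for one observation
#'
#' Scores all six parameters with [score_parameter()] and sums them.
#' Missing parameters are handled per the table's missing policy:
#' `"zero"` contributes 0 points and records the parameter in
#' `missing_parameters`; `"strict"` raises an error. An observation with
#' all six parameters missing is an error under either policy.
#'
#' @param observation a list or one-row data frame with fields `sbp`,
#'   `hr`, `rr`, `temp`, `consciousness`, `concern`, and optionally
#'   `patient_id` and `timestamp`.
#' @param table a `mews_score_table`.
#' @return a `mews_result`: list with `points` (named integer vector),
#'   `total`, `missing_parameters`, `patient_id`, `timestamp`.
#' @export
#' @examples
#' tab <- default_score_table()
#' obs <- list(sbp = 120, hr = 75, rr = 16, temp = 36.8,
#'             consciousness = "alert", concern = 0)
#' compute_mews(obs, tab)$total   # 1 (rr 15-20 scores 1)
compute_mews <- function(observation, table) {
  if (is.data.frame(observation)) {
    stopifnot(nrow(observation) == 1L)
    observation <- as.list(observation)
  }
  pts <- integer(0)
  for (p in .mews_param_names) {
    v <- observation[[p]]
    if (is.null(v)) v <- NA
    pts[p] <- score_parameter(v, p, table)
  }
  missing <- names(pts)[is.na(pts)]
  if (length(missing) == length(pts))
    stop("all six parameters are missing; no score computable")
  if (length(missing) > 0 && table$missing_policy == "strict")
    stop("missing parameter(s) under strict policy: ",
         paste(missing, collapse = ", "))
  pts[is.na(pts)] <- 0L
  structure(
    list(points = pts, total = as.integer(sum(pts)),
         missing_parameters = missing,
         patient_id = observation$patient_id %||% NA_character_,
         timestamp = observation$timestamp %||% NA),
    class = "mews_result")
}

#' @export
print.mews_result <- function(x, ...) {
  cat("MEWS", x$total, "(",
      paste(names(x$points), x$points, sep = "=", collapse = " "), ")\n")
  if (length(x$missing_parameters))
    cat("  missing:", paste(x$missing_parameters, collapse = ", "), "\n")
  invisible(x)
}

#' Score a table of vital-sign observations (vectorized)
#'
#' Adds per-parameter point columns (`pts_sbp`, ..., `pts_concern`), the
#' `total`, and `n_missing` to a vitals data frame. Same semantics as
#' [compute_mews()] applied row-wise, but vectorized.
#'
#' @param vitals data frame with columns `sbp`, `hr`, `rr`, `temp`,
#'   `consciousness`, `concern` (plus any identifier columns, preserved).
#' @param table a `mews_score_table`.
#' @return the input with scoring columns appended.
#' @export
score_vitals <- function(vitals, table) {
  stopifnot(is.data.frame(vitals))
  miss_all <- rep(TRUE, nrow(vitals))
  n_missing <- integer(nrow(vitals))
  total <- integer(nrow(vitals))
  for (p in .mews_param_names) {
    v <- if (p %in% names(vitals)) vitals[[p]] else rep(NA, nrow(vitals))
    pts <- score_parameter(v, p, table)
    isna <- is.na(pts)
    if (any(isna) && table$missing_policy == "strict")
      stop("missing ", p, " under strict policy at row(s) ",
           paste(utils::head(which(isna), 5), collapse = ", "))
    miss_all <- miss_all & isna
    n_missing <- n_missing + isna
    pts[isna] <- 0L
    vitals[[paste0("pts_", p)]] <- pts
    total <- total + pts
  }
  if (any(miss_all))
    stop("row(s) with all six parameters missing: ",
         paste(utils::head(which(miss_all), 5), collapse = ", "))
  vitals$total <- total
  vitals$n_missing <- n_missing
  vitals
}

#' Reduce one patient-day's observations to the daily maximum score
#'
#' Among all observations of one patient on one calendar day, the one
#' with the greatest total is kept; ties are broken by earliest
#' timestamp.
#'
#' @param observations data frame of one patient-day's vitals (columns
#'   as in [score_vitals()] plus `patient_id` and `timestamp`).
#' @param table a `mews_score_table`.
#' @return the `mews_result` of the winning observation.
#' @export
daily_max_mews <- function(observations, table) {
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0L)
    stop("no observations supplied")
  if (length(unique(observations$patient_id)) > 1L)
    stop("observations span multiple patients")
  ts <- .parse_ts(observations$timestamp)
  if (length(unique(as.Date(ts))) > 1L)
    stop("observations span multiple calendar days")
  scored <- score_vitals(observations, table)
  ord <- order(-scored$total, ts)
  compute_mews(observations[ord[1L], , drop = FALSE], table)
}

#' Per patient-day maximum scores for a whole vitals table
#'
#' Vectorized daily-maximum reduction: scores every row and keeps, for
#' each (patient, calendar day), the row with the highest total
#' (earliest timestamp on ties).
#'
#' @inheritParams score_vitals
#' @return data frame with one row per patient-day: `patient_id`,
#'   `date`, the winning row's vitals and points, and `total`.
#' @export
daily_max_scores <- function(vitals, table) {
  scored <- score_vitals(vitals, table)
  ts <- .parse_ts(scored$timestamp)
  scored$date <- as.Date(ts)
  ord <- order(scored$patient_id, scored$date, -scored$total, ts)
  scored <- scored[ord, , drop = FALSE]
  keep <- !duplicated(scored[c("patient_id", "date")])
  out <- scored[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Warning-zone test
#'
#' A total is in the warning zone iff it is at or above the threshold
#' (default 7).
#'
#' @param total integer score(s).
#' @param threshold warning-zone threshold (>= 1).
#' @return logical vector.
#' @export
#' @examples
#' is_warning(7, 7)  # TRUE
#' is_warning(6, 7)  # FALSE
is_warning <- function(total, threshold = 7) {
  stopifnot(threshold >= 1, all(total >= 0, na.rm = TRUE))
  total >= threshold
}
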