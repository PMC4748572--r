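# Score-table (banding rubric) construction and validation.
#
# A score table maps each of six parameters to 0-3 points:
# four continuous vitals (systolic blood pressure, heart rate,
# respiratory rate, temperature) banded by inclusive upper bounds,
# the AVPU consciousness scale, and a binary "any concern" flag.

#' Vital-sign parameters and their conventions
#'
#' Continuous parameters are banded; `consciousness` and `concern` use
#' categorical point maps. Granularity is the measurement resolution at
#' which values are rounded (half-up) before band lookup; `range` is the
#' admissible physiological range.
#' @keywords internal
.vital_params <- list(
  sbp  = list(granularity = 1,   range = c(0, 400),  label = "systolic blood pressure (mmHg)"),
  hr   = list(granularity = 1,   range = c(0, 350),  label = "heart rate (bpm)"),
  rr   = list(granularity = 1,   range = c(0, 100),  label = "respiratory rate (breaths/min)"),
  temp = list(granularity = 0.1, range = c(20, 45),  label = "temperature (degC)")
)

.consciousness_levels <- c("alert", "voice", "pain", "unresponsive")

#' Construct the default MEWS score table
#'
#' The default rubric scores six parameters and sums them to a 0--15
#' total. Band-to-column alignment for the continuous vitals follows the
#' Subbe-style MEWS convention:
#' \itemize{
#'   \item SBP (mmHg): <=70 -> 3, 71--80 -> 2, 81--100 -> 1, 101--199 -> 0, >=200 -> 2
#'   \item HR (bpm): <=40 -> 2, 41--50 -> 1, 51--100 -> 0, 101--110 -> 1, 111--129 -> 2, >=130 -> 3
#'   \item RR (breaths/min): <=8 -> 2, 9--14 -> 0, 15--20 -> 1, 21--29 -> 2, >=30 -> 3
#'   \item Temperature (degC): <=35.0 -> 2, 35.1--38.4 -> 0, >=38.5 -> 2
#'   \item Consciousness (AVPU): alert 0, voice 1, pain 2, unresponsive 3
#'   \item Any concern about the patient's condition: no 0, yes 1
#' }
#'
#' @param missing_policy how to score a missing vital: `"zero"` scores it
#'   0 points and records it in `missing_parameters`; `"strict"` raises
#'   an error.
#' @return an object of class `mews_score_table`.
#' @seealso [load_score_table()] to build a table from a configuration
#'   document, [compute_mews()] to apply it.
#' @export
#' @examples
#' tab <- default_score_table()
#' tab$max_total  # 15
default_score_table <- function(missing_policy = c("zero", "strict")) {
  missing_policy <- match.arg(missing_policy)
  bands <- list(
    sbp  = data.frame(upper = c(70, 80, 100, 199, Inf),
                      points = c(3L, 2L, 1L, 0L, 2L)),
    hr   = data.frame(upper = c(40, 50, 100, 110, 129, Inf),
                      points = c(2L, 1L, 0L, 1L, 2L, 3L)),
    rr   = data.frame(upper = c(8, 14, 20, 29, Inf),
                      points = c(2L, 0L, 1L, 2L, 3L)),
    temp = data.frame(upper = c(35.0, 38.4, Inf),
                      points = c(2L, 0L, 2L))
  )
  new_score_table(bands,
                  consciousness = c(alert = 0L, voice = 1L, pain = 2L,
                                    unresponsive = 3L),
                  concern = c(no = 0L, yes = 1L),
                  missing_policy = missing_policy)
}

#' Build and validate a score table from its components
#'
#' @param bands named list (`sbp`, `hr`, `rr`, `temp`) of data frames
#'   with columns `upper` (inclusive upper bound; `Inf` for the open
#'   last band) and `points` (integer 0--3).
#' @param consciousness named integer vector over
#'   `alert`, `voice`, `pain`, `unresponsive`.
#' @param concern named integer vector over `no`, `yes`.
#' @param missing_policy `"zero"` or `"strict"`; see
#'   [default_score_table()].
#' @return a validated `mews_score_table`.
#' @export
new_score_table <- function(bands, consciousness, concern,
                            missing_policy = c("zero", "strict")) {
  missing_policy <- match.arg(missing_policy)
  for (p in names(.vital_params)) {
    if (is.null(bands[[p]]))
      stop("score table is missing bands for parameter '", p, "'")
    b <- bands[[p]]
    if (!all(c("upper", "points") %in% names(b)))
      stop("bands for '", p, "' need columns 'upper' and 'points'")
    if (nrow(b) < 1L)
      stop("bands for '", p, "' are empty")
    if (any(is.na(b$upper)) || any(is.na(b$points)))
      stop("bands for '", p, "' contain missing values")
    n_open <- sum(is.infinite(b$upper))
    if (n_open != 1L)
      stop("parameter '", p, "' must have exactly one open band, found ",
           n_open)
    if (!is.infinite(b$upper[nrow(b)]))
      stop("the open band of '", p, "' must be last")
    if (any(diff(b$upper) <= 0))
      stop("band upper bounds of '", p,
           "' must be strictly increasing (overlapping or unordered bands)")
    if (any(b$points != as.integer(b$points)) ||
        any(b$points < 0) || any(b$points > 3))
      stop("band points of '", p, "' must be integers in 0..3")
    b$points <- as.integer(b$points)
    bands[[p]] <- b
  }
  if (!setequal(names(consciousness), .consciousness_levels))
    stop("consciousness map must cover exactly: ",
         paste(.consciousness_levels, collapse = ", "))
  consciousness <- vapply(consciousness[.consciousness_levels],
                          as.integer, integer(1))
  if (any(consciousness < 0) || any(consciousness > 3))
    stop("consciousness points must be in 0..3")
  if (!setequal(names(concern), c("no", "yes")))
    stop("concern map must have entries 'no' and 'yes'")
  concern <- vapply(concern[c("no", "yes")], as.integer, integer(1))
  if (any(concern < 0) || any(concern > 3))
    stop("concern points must be in 0..3")

  max_total <- sum(vapply(bands, function(b) max(b$points), integer(1))) +
    max(consciousness) + max(concern)
  structure(
    list(bands = bands, consciousness = consciousness, concern = concern,
         missing_policy = missing_policy, max_total = as.integer(max_total)),
    class = "mews_score_table")
}

#' Load a score table from a configuration document
#'
#' The configuration is YAML or JSON (dispatched on file extension), or
#' an already-parsed list. Any subset of the six parameters may be
#' given; unspecified parameters keep their defaults from
#' [default_score_table()]. An empty/NULL configuration returns the
#' default table.
#'
#' Continuous parameters are lists of `{upper, points}` band entries
#' (omit `upper` or set it to `.inf`/`"inf"` for the open band);
#' `consciousness` and `concern` are point maps; `missing_policy` is
#' `"zero"` or `"strict"`.
#'
#' @param config path to a YAML/JSON file, a parsed list, or NULL.
#' @return a validated `mews_score_table`.
#' @export
#' @examples
#' load_score_table(NULL)$max_total                      # 15
#' load_score_table(list(concern = list(no = 0, yes = 2)))$max_total  # 16
load_score_table <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("score-table configuration file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  if (length(config) == 0L) return(default_score_table())
  if (!is.list(config)) stop("score-table configuration must be a list")
  def <- default_score_table()

  bands <- def$bands
  for (p in intersect(names(config), names(.vital_params))) {
    entries <- config[[p]]
    if (is.list(entries) && !is.null(entries$bands)) entries <- entries$bands
    ub <- vapply(entries, function(e) {
      u <- e$upper
      if (is.null(u) || (is.character(u) && grepl("inf", u, ignore.case = TRUE)))
        Inf else as.numeric(u)
    }, numeric(1))
    pts <- vapply(entries, function(e) as.numeric(e$points), numeric(1))
    bands[[p]] <- data.frame(upper = ub, points = pts)
  }
  consciousness <- def$consciousness
  if (!is.null(config$consciousness))
    consciousness <- unlist(config$consciousness)
  concern <- def$concern
  if (!is.null(config$concern)) concern <- unlist(config$concern)
  missing_policy <- config$missing_policy %||% def$missing_policy
  new_score_table(bands, consciousness, concern, missing_policy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mews_score_table <- function(x, ...) {
  cat("MEWS score table (max total ", x$max_total, ", missing policy '",
      x$missing_policy, "')\n", sep = "")
  for (p in names(x$bands)) {
    b <- x$bands[[p]]
    lo <- c(-Inf, b$upper[-nrow(b)])
    cat(sprintf("  %-5s", p),
        paste(sprintf("(%s,%s]=%d", format(lo), format(b$upper), b$points),
              collapse = " "), "\n")
  }
  cat("  consciousness:",
      paste(names(x$consciousness), x$consciousness, sep = "=", collapse = " "),
      "\n  concern:",
      paste(names(x$concern), x$concern, sep = "=", collapse = " "), "\n")
  invisible(x)
}
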