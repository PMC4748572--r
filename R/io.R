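# Readers/writers for the delimited-text interchange formats, with
# validation that names the offending row, and run manifests.
#
# Dialect is fixed: comma-separated, UTF-8, ISO-8601 dates, "." decimal
# separator. An empty field is a missing value.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = "character")
}

.num_field <- function(x, name, rows_offset = 1L) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("unparseable numeric '", name, "' at row(s) ",
         paste(utils::head(bad + rows_offset, 5), collapse = ", "))
  out
}

.date_field <- function(x, name) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("unparseable ISO-8601 date '", name, "' at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  out
}

#' Read a vital-sign observation file
#'
#' Expected columns: `patient_id`, `timestamp` (ISO-8601),
#' `sbp`, `hr`, `rr`, `temp`, `consciousness`
#' (`alert|voice|pain|unresponsive`), `concern` (0|1). Empty fields are
#' missing values (allowed for the six score parameters, not for
#' identifiers). Errors name the first offending data rows (header =
#' row 1).
#'
#' @param path CSV file path.
#' @return validated data frame of observations.
#' @export
read_vitals <- function(path) {
  d <- .read_csv(path)
  need <- c("patient_id", "timestamp", "sbp", "hr", "rr", "temp",
            "consciousness", "concern")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("vitals file lacks column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(d$patient_id)) || any(is.na(d$timestamp)))
    stop("patient_id/timestamp may not be empty")
  ts <- rep(as.POSIXct(NA), nrow(d))
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    idx <- is.na(ts)
    if (!any(idx)) break
    ts[idx] <- as.POSIXct(d$timestamp[idx], tz = "UTC", format = fmt)
  }
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  out <- data.frame(patient_id = d$patient_id, timestamp = d$timestamp,
                    stringsAsFactors = FALSE)
  for (p in names(.vital_params)) {
    v <- .num_field(d[[p]], p)
    rng <- .vital_params[[p]]$range
    bad <- which(!is.na(v) & (v < rng[1] | v > rng[2]))
    if (length(bad))
      stop(p, " out of range [", rng[1], ", ", rng[2], "] at row(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
    out[[p]] <- v
  }
  bad <- which(!is.na(d$consciousness) &
               !(d$consciousness %in% .consciousness_levels))
  if (length(bad))
    stop("unknown consciousness token at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " (allowed: ", paste(.consciousness_levels, collapse = ", "), ")")
  out$consciousness <- d$consciousness
  cc <- .num_field(d$concern, "concern")
  bad <- which(!is.na(cc) & !(cc %in% c(0, 1)))
  if (length(bad))
    stop("concern must be 0 or 1 at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  out$concern <- as.integer(cc)
  out
}

#' Read an admissions file
#'
#' Expected columns: `admission_id`, `admit_date`, `discharge_date`,
#' `age`, `sex` (`M|F`), `diagnosis`, `dnr` (0|1), `period`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_admissions <- function(path) {
  d <- .read_csv(path)
  need <- c("admission_id", "admit_date", "discharge_date", "age", "sex",
            "diagnosis", "dnr", "period")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("admissions file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$admission_id))
    stop("duplicated admission_id: ",
         d$admission_id[anyDuplicated(d$admission_id)])
  bad <- which(!is.na(d$sex) & !(d$sex %in% c("M", "F")))
  if (length(bad))
    stop("sex must be M or F at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  data.frame(admission_id = d$admission_id,
             admit_date = .date_field(d$admit_date, "admit_date"),
             discharge_date = .date_field(d$discharge_date, "discharge_date"),
             age = .num_field(d$age, "age"),
             sex = d$sex, diagnosis = d$diagnosis,
             dnr = as.integer(.num_field(d$dnr, "dnr")),
             period = d$period, stringsAsFactors = FALSE)
}

#' Read an events file
#'
#' Expected columns: `admission_id`, `event_type` (`ihca|death`),
#' `event_date`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_events <- function(path) {
  d <- .read_csv(path)
  need <- c("admission_id", "event_type", "event_date")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("events file lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(d$event_type %in% c("ihca", "death")))
  if (length(bad))
    stop("event_type must be 'ihca' or 'death' at row(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  data.frame(admission_id = d$admission_id, event_type = d$event_type,
             event_date = .date_field(d$event_date, "event_date"),
             stringsAsFactors = FALSE)
}

#' Write a data frame in the canonical dialect
#'
#' @param x data frame.
#' @param path destination.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build a run manifest
#'
#' Records what was run on what: command name, MD5 checksums of input
#' files, the configuration, the seed, package version, and a
#' timestamp. Sufficient to re-run the command.
#'
#' @param command command name.
#' @param inputs character vector of input file paths (existing files
#'   are checksummed).
#' @param config configuration echoed verbatim.
#' @param seed seed used, if any.
#' @return a `mews_manifest` list.
#' @export
run_manifest <- function(command, inputs = character(0), config = list(),
                         seed = NULL) {
  inputs <- inputs[file.exists(inputs)]
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(command = command, inputs = sums, config = config,
                 seed = seed,
                 tool = paste0("mewsr ",
                               as.character(utils::packageVersion("mewsr"))),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "mews_manifest")
}

#' Write a manifest as JSON
#' @param manifest a `mews_manifest`.
#' @param path destination.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}
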