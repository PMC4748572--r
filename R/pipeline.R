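# Umbrella pipeline: score -> stratify -> select threshold -> monthly
# incidence -> before/after comparison, plus the command-line entry
# point.

#' Run the full analysis pipeline
#'
#' Executes, for two study periods, the whole chain: score the vitals
#' with the (configurable) rubric, reduce to per-admission maximum
#' scores, stratify the audit period's patients by score and test the
#' warning-zone threshold, build monthly incidence series, and compare
#' the periods on IHCA and death rates. Inputs are either files
#' (vitals/admissions/events per period) or generator settings.
#'
#' The configuration is a list (or a YAML/JSON file path) with entries:
#' \itemize{
#'   \item `threshold` (default 7), `alpha` (0.05), `top_bin` (9),
#'     `score_table` (path or NULL for the default rubric)
#'   \item `periods`: named list `before`/`after`, each with `vitals`,
#'     `admissions`, `events` file paths; or
#'   \item `generator`: named list `before`/`after`, each a list of
#'     [cohort_params()] arguments plus `intervention` (logical) and
#'     optional `theta`; plus a top-level `seed`.
#' }
#'
#' @param config list or path to a YAML/JSON configuration.
#' @param out_dir if non-NULL, reports are written there
#'   (`strata.csv`, `threshold.json`, `monthly_<period>.csv`,
#'   `comparison_ihca.json`, `comparison_death.json`, `manifest.json`).
#' @param seed seed overriding the configuration's.
#' @return a report bundle: list with `strata`, `decision`, `monthly`
#'   (per period), `periods` (summaries), `comparison_ihca`,
#'   `comparison_death`, `manifest`. Invisibly if `out_dir` given.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  threshold <- config$threshold %||% 7
  alpha <- config$alpha %||% 0.05
  top_bin <- config$top_bin %||% 9
  table <- load_score_table(config$score_table)
  seed <- seed %||% config$seed %||% 1L

  period_names <- names(config$periods %||% config$generator)
  if (is.null(period_names))
    stop("configuration needs a 'periods' or 'generator' section")

  input_files <- character(0)
  per_period <- list()
  for (pn in period_names) {
    if (!is.null(config$periods)) {
      pc <- config$periods[[pn]]
      for (f in c("vitals", "admissions", "events"))
        if (is.null(pc[[f]]))
          stop("period '", pn, "' is missing the '", f, "' input")
      input_files <- c(input_files, unlist(pc[c("vitals", "admissions",
                                                "events")]))
      vit <- read_vitals(pc$vitals)
      admissions <- read_admissions(pc$admissions)
      events <- read_events(pc$events)
      dm <- daily_max_scores(vit, table)
      agg <- stats::aggregate(total ~ patient_id, dm, max)
      max_total <- agg$total[match(admissions$admission_id, agg$patient_id)]
      max_total[is.na(max_total)] <- 0L
    } else {
      gc_args <- config$generator[[pn]]
      interv <- isTRUE(gc_args$intervention)
      theta <- gc_args$theta %||% 0.46
      gc_args$intervention <- NULL; gc_args$theta <- NULL
      gc_args$period <- pn
      params <- do.call(cohort_params, gc_args)
      sim <- simulate_study(params,
                            intervention = intervention_params(theta),
                            intervention_on = interv,
                            seed = seed + match(pn, period_names),
                            threshold = threshold)
      admissions <- sim$admissions
      events <- sim$events
      max_total <- sim$admissions$max_total
    }
    wz <- is_warning(max_total, threshold)
    ihca_flag <- admissions$admission_id %in%
      events$admission_id[events$event_type == "ihca"]
    per_period[[pn]] <- list(
      admissions = admissions, events = events, max_total = max_total,
      wz = wz, ihca_flag = ihca_flag,
      monthly = monthly_series(admissions, events, wz_flags = wz),
      summary = cohort_summary(admissions, events, label = pn))
  }

  audit <- per_period[[1L]]
  strata <- stratify(audit$max_total, audit$ihca_flag, top_bin = top_bin)
  decision <- select_wz(strata, alpha = alpha)

  cmp_args <- lapply(per_period, `[[`, "summary")
  comparison_ihca <- comparison_death <- NULL
  if (length(per_period) >= 2) {
    comparison_ihca <- compare_periods(cmp_args[[1]], cmp_args[[2]],
                                       "ihca", alpha = 0.01)
    comparison_death <- compare_periods(cmp_args[[1]], cmp_args[[2]],
                                        "death", alpha = 0.05)
  }

  manifest <- run_manifest("run", inputs = c(cfg_path, input_files),
                           config = config, seed = seed)
  bundle <- list(strata = strata, decision = decision,
                 monthly = lapply(per_period, `[[`, "monthly"),
                 periods = cmp_args,
                 comparison_ihca = comparison_ihca,
                 comparison_death = comparison_death,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    st <- strata
    st$rate_pct <- round_half_up(st$rate_pct, 2)
    st$ci_low <- round_half_up(st$ci_low, 2)
    st$ci_high <- round_half_up(st$ci_high, 2)
    write_table_csv(st, file.path(out_dir, "strata.csv"))
    jsonlite::write_json(list(threshold = decision$threshold,
                              found = decision$found,
                              alpha = decision$alpha, test = decision$test,
                              tests = decision$tests),
                         file.path(out_dir, "threshold.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    for (pn in names(bundle$monthly)) {
      m <- bundle$monthly[[pn]]
      m$rate_per_1000 <- round_half_up(m$rate_per_1000, 2)
      write_table_csv(m, file.path(out_dir, paste0("monthly_", pn, ".csv")))
    }
    for (oc in c("ihca", "death")) {
      cmpx <- bundle[[paste0("comparison_", oc)]]
      if (is.null(cmpx)) next
      jsonlite::write_json(
        list(outcome = cmpx$outcome,
             rate_a = round_half_up(cmpx$rate_a, 2),
             rate_b = round_half_up(cmpx$rate_b, 2),
             rate_ratio = cmpx$rate_ratio, p_value = cmpx$test$p_value,
             significant = cmpx$significant, alpha = cmpx$alpha),
        file.path(out_dir, paste0("comparison_", oc, ".json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    return(invisible(bundle))
  }
  bundle
}

#' Command-line entry point
#'
#' Dispatches the subcommands `score`, `stratify`, `select-wz`,
#' `incidence`, `compare`, `generate`, `simulate` and `run`. Invoked by
#' the `inst/cli/mews.R` launcher:
#' `Rscript $(Rscript -e 'cat(system.file("cli/mews.R", package="mewsr"))') <subcommand> ...`
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: mews <score|stratify|select-wz|incidence|compare|generate|simulate|run> [options]\n")
    return(invisible(1L))
  }
  sub <- args[[1L]]
  opts <- .parse_cli_opts(args[-1L])
  seed <- as.integer(opts$seed %||% 1L)
  out <- opts$out

  emit <- function(x, name) {
    if (!is.null(out)) {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(x, file.path(out, name))
    } else {
      utils::write.csv(x, stdout(), row.names = FALSE, quote = FALSE, na = "")
    }
  }

  switch(sub,
    "score" = {
      table <- load_score_table(opts$table)
      vit <- read_vitals(opts$vitals)
      threshold <- as.numeric(opts$threshold %||% 7)
      scored <- if (isTRUE(opts[["daily-max"]]))
        daily_max_scores(vit, table) else score_vitals(vit, table)
      scored$wz <- is_warning(scored$total, threshold)
      emit(scored, "scores.csv")
    },
    "stratify" = {
      sc <- utils::read.csv(opts$scores)
      ev <- utils::read.csv(opts$events)
      st <- stratify(sc$max_total,
                     sc[[1]] %in% ev$admission_id[ev$event_type == "ihca"],
                     top_bin = as.numeric(opts[["top-bin"]] %||% 9))
      st$rate_pct <- round_half_up(st$rate_pct, 2)
      emit(st, "strata.csv")
    },
    "select-wz" = {
      st <- utils::read.csv(opts$strata)
      dec <- select_wz(st, alpha = as.numeric(opts$alpha %||% 0.05),
                       test = opts$test %||% "chi-squared")
      print(dec)
    },
    "incidence" = {
      admissions <- read_admissions(opts$admissions)
      events <- read_events(opts$events)
      m <- monthly_series(admissions, events)
      m$rate_per_1000 <- round_half_up(m$rate_per_1000, 2)
      emit(m, "monthly.csv")
    },
    "compare" = {
      a <- read_admissions(opts$admissions)
      ev <- read_events(opts$events)
      labs <- unique(a$period)
      if (length(labs) != 2) stop("need exactly two period labels")
      summaries <- lapply(labs, function(l) {
        sel <- a$period == l
        cohort_summary(a[sel, ],
                       ev[ev$admission_id %in% a$admission_id[sel], ],
                       label = l)
      })
      print(compare_periods(summaries[[1]], summaries[[2]],
                            opts$outcome %||% "ihca",
                            alpha = as.numeric(opts$alpha %||% 0.05)))
    },
    "generate" = {
      gc_args <- if (!is.null(opts$params))
        yaml::read_yaml(opts$params) else list()
      cohort <- generate_cohort(do.call(cohort_params, gc_args), seed = seed)
      if (is.null(out)) stop("generate requires --out DIR")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(cohort$admissions, file.path(out, "admissions.csv"))
      write_table_csv(cohort$vitals, file.path(out, "vitals.csv"))
      write_table_csv(cohort$events, file.path(out, "events.csv"))
      write_manifest(run_manifest("generate", config = gc_args, seed = seed),
                     file.path(out, "manifest.json"))
    },
    "simulate" = {
      gc_args <- if (!is.null(opts$params))
        yaml::read_yaml(opts$params) else list()
      arm <- opts$arm %||% "after"
      sim <- simulate_study(do.call(cohort_params, gc_args),
                            intervention_on = arm == "after", seed = seed)
      if (is.null(out)) stop("simulate requires --out DIR")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(sim$admissions, file.path(out, "admissions.csv"))
      write_table_csv(sim$events, file.path(out, "events.csv"))
      write_table_csv(sim$log, file.path(out, "callout_log.csv"))
      write_manifest(run_manifest("simulate",
                                  config = c(gc_args, list(arm = arm)),
                                  seed = seed),
                     file.path(out, "manifest.json"))
      print(sim)
    },
    "run" = {
      if (is.null(opts$config)) stop("run requires --config FILE")
      run_pipeline(opts$config, out_dir = out, seed = seed)
    },
    stop("unknown subcommand '", sub, "'")
  )
  invisible(0L)
}

# --key value / --flag parser (no dependency on optparse for the core)
.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
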