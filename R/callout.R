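# Callout algorithm: explicit state machine for the warning-zone
# escalation pathway, and a cohort-level study simulator.

#' Callout pathway states
#'
#' `monitoring` and `alerted` accept further daily steps;
#' `icu_transferred`, `terminated_dnr`, `arrested` and `discharged` are
#' absorbing for the purposes of further warning-zone alerts.
#' @export
callout_states <- c("monitoring", "alerted", "icu_transferred",
                    "terminated_dnr", "arrested", "discharged")

.absorbing_states <- c("icu_transferred", "terminated_dnr", "arrested",
                       "discharged")

#' Intervention parameters for the study simulator
#'
#' @param hazard_multiplier theta in (0, 1]: multiplies the IHCA hazard
#'   from the first alert day onward. The magnitude of the treatment
#'   effect is a free simulation parameter, not an observed quantity;
#'   the default 0.46 corresponds to the reported before/after rate
#'   ratio (2.39/5.21).
#' @param deterioration_escalation_prob per-day probability that an
#'   alerted patient continues to deteriorate and is transferred to the
#'   ICU.
#' @return a `mews_intervention` list.
#' @export
intervention_params <- function(hazard_multiplier = 0.46,
                                deterioration_escalation_prob = 0.05) {
  stopifnot(hazard_multiplier > 0, hazard_multiplier <= 1,
            deterioration_escalation_prob >= 0,
            deterioration_escalation_prob <= 1)
  structure(list(hazard_multiplier = hazard_multiplier,
                 deterioration_escalation_prob = deterioration_escalation_prob),
            class = "mews_intervention")
}

#' One daily step of the callout state machine
#'
#' From `monitoring`: a daily total below the threshold keeps
#' monitoring; at or above it, a DNR-flagged patient has the pathway
#' terminated (`terminated_dnr`), otherwise the full alert cascade
#' fires (`alert_raised`, `physician_notified`, `icu_nurses_notified`,
#' `treatment_started`) and the state becomes `alerted`. From
#' `alerted`: continued deterioration escalates to `icu_transferred`
#' with an `icu_transfer` action; otherwise treatment continues with no
#' new actions (one alert cascade per admission).
#'
#' @param state current state (must be non-absorbing).
#' @param daily_total the day's maximum MEWS total (>= 0).
#' @param dnr_flag logical DNR order flag.
#' @param threshold warning-zone threshold.
#' @param deteriorating logical; only consulted in the `alerted` state.
#' @return list with `state` (next state) and `actions` (character
#'   vector, possibly empty).
#' @export
#' @examples
#' step_callout("monitoring", 8, FALSE, 7)$actions
#' step_callout("monitoring", 9, TRUE, 7)$state   # "terminated_dnr"
step_callout <- function(state, daily_total, dnr_flag, threshold = 7,
                         deteriorating = FALSE) {
  if (!state %in% callout_states)
    stop("unknown state '", state, "'")
  if (state %in% .absorbing_states)
    stop("step_callout called on absorbing state '", state, "'")
  stopifnot(daily_total >= 0)
  if (state == "monitoring") {
    if (!is_warning(daily_total, threshold))
      return(list(state = "monitoring", actions = character(0)))
    if (isTRUE(as.logical(dnr_flag)))
      return(list(state = "terminated_dnr", actions = "dnr_termination"))
    return(list(state = "alerted",
                actions = c("alert_raised", "physician_notified",
                            "icu_nurses_notified", "treatment_started")))
  }
  # alerted
  if (isTRUE(deteriorating))
    return(list(state = "icu_transferred", actions = "icu_transfer"))
  list(state = "alerted", actions = character(0))
}

#' Simulate a study period end to end
#'
#' Generates a synthetic cohort (same machinery as
#' [generate_cohort()]), runs the daily callout state machine over each
#' admission's score trajectory, and draws IHCA events day by day: an
#' admission's per-admission stratum probability is converted to a
#' per-day hazard over its days at the maximum stratum, and from the
#' first alert day onward (non-DNR admissions, intervention arm only)
#' the hazard is multiplied by `intervention$hazard_multiplier`.
#'
#' Each admission consumes an independent RNG sub-stream, so the
#' generated cohort and the per-day hazard draws are identical across
#' intervention arms run with the same seed: with a multiplier of 1 the
#' two arms produce byte-identical event logs, and with a multiplier
#' below 1 the intervention arm's events are a coupled subset.
#'
#' Escalation to ICU and DNR termination are recorded in the state
#' trajectory but do not stop the daily hazard draws: the admission's
#' arrest risk is attributed to the admission wherever it is completed,
#' which keeps the null case (multiplier 1) exactly invariant.
#'
#' @param params a [cohort_params()] object.
#' @param hazard a hazard model.
#' @param intervention an [intervention_params()] object.
#' @param intervention_on logical: FALSE simulates the pre-introduction
#'   period (no alerts, no hazard reduction).
#' @param seed integer seed.
#' @param threshold warning-zone threshold.
#' @return a `mews_simulation`: list with `summary` (a `mews_period`
#'   over all admissions), `admissions` (per-admission outcome table
#'   with `max_total`, `wz`, `alert_day`, `final_state`, `ihca`,
#'   `ihca_day`, `death`), `events` (long event table), `log`
#'   (callout-action log: `admission_id`, `day`, `date`, `action`,
#'   `daily_total`), `intervention_on`, `seed`.
#' @export
simulate_study <- function(params = cohort_params(),
                           hazard = default_hazard_from_table2(),
                           intervention = intervention_params(),
                           intervention_on = TRUE,
                           seed = 1L, threshold = 7) {
  stopifnot(inherits(params, "mews_cohort_params"),
            inherits(hazard, "mews_hazard"),
            inherits(intervention, "mews_intervention"))
  set.seed(seed)
  core <- .gen_core(params, hazard)
  adm <- core$admissions
  n <- nrow(adm)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  death_u <- stats::runif(n)

  theta <- intervention$hazard_multiplier
  esc_p <- intervention$deterioration_escalation_prob

  alert_day <- rep(NA_integer_, n)
  final_state <- character(n)
  ihca_day <- rep(NA_integer_, n)
  log_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])               # per-admission sub-stream
    tot <- core$paths[[i]]
    los <- adm$los[i]
    p <- hazard$ihca_prob[[.hazard_stratum_of(adm$max_total[i])]]
    hdays <- if (adm$max_total[i] >= 7) core$peak_days[[i]] else seq_len(los)
    h <- 1 - (1 - p)^(1 / length(hdays))
    u_haz <- stats::runif(length(hdays)) # drawn first: arm-invariant

    state <- "monitoring"
    acts <- list()
    for (d in seq_len(los)) {
      if (intervention_on && state %in% c("monitoring", "alerted")) {
        det <- state == "alerted" && stats::runif(1) < esc_p
        st <- step_callout(state, tot[d], adm$dnr[i] == 1L, threshold,
                           deteriorating = det)
        if (length(st$actions))
          acts[[length(acts) + 1L]] <- data.frame(day = d, action = st$actions)
        if (is.na(alert_day[i]) && "alert_raised" %in% st$actions)
          alert_day[i] <- d
        state <- st$state
      }
      k <- match(d, hdays)
      if (!is.na(k) && state != "arrested") {
        mult <- if (intervention_on && !is.na(alert_day[i]) &&
                    d >= alert_day[i]) theta else 1
        if (u_haz[k] < h * mult) {
          ihca_day[i] <- d
          state <- "arrested"
          acts[[length(acts) + 1L]] <- data.frame(day = d, action = "ihca")
        }
      }
      if (state == "arrested") break
    }
    if (!state %in% .absorbing_states) state <- "discharged"
    final_state[i] <- state
    if (length(acts)) {
      lr <- do.call(rbind, acts)
      lr$admission_id <- adm$admission_id[i]
      lr$daily_total <- tot[lr$day]
      log_rows[[i]] <- lr
    }
  }

  has_ihca <- !is.na(ihca_day)
  has_death <- death_u < hazard$death_prob
  adm_out <- adm
  adm_out$wz <- adm$max_total >= threshold
  adm_out$alert_day <- alert_day
  adm_out$final_state <- final_state
  adm_out$ihca <- has_ihca
  adm_out$ihca_day <- ihca_day
  adm_out$death <- has_death

  events <- rbind(
    data.frame(admission_id = adm$admission_id[has_ihca],
               event_type = rep("ihca", sum(has_ihca)),
               event_date = adm$admit_date[has_ihca] +
                 ihca_day[has_ihca] - 1L),
    data.frame(admission_id = adm$admission_id[has_death],
               event_type = rep("death", sum(has_death)),
               event_date = adm$discharge_date[has_death]))
  events <- events[order(events$admission_id, events$event_type), ]
  rownames(events) <- NULL

  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  if (is.null(log))
    log <- data.frame(day = integer(0), action = character(0),
                      admission_id = character(0), daily_total = integer(0))
  log$date <- adm$admit_date[match(log$admission_id, adm$admission_id)] +
    log$day - 1L
  log <- log[order(log$admission_id, log$day), c("admission_id", "day",
                                                 "date", "action",
                                                 "daily_total")]
  rownames(log) <- NULL

  summary <- cohort_summary(adm, events, label = params$period)
  structure(list(summary = summary, admissions = adm_out, events = events,
                 log = log, intervention_on = intervention_on,
                 intervention = intervention, seed = seed,
                 threshold = threshold),
            class = "mews_simulation")
}

#' @export
print.mews_simulation <- function(x, ...) {
  cat("Simulated study arm (intervention ",
      if (x$intervention_on) "ON" else "OFF", ", seed ", x$seed, ")\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Estimate the intervention hazard ratio from two simulated arms
#'
#' Ratio of IHCA rates among warning-zone-reaching, non-DNR admissions
#' (the treated subgroup) in the intervention arm versus the control
#' arm, with a log-scale Wald 95% confidence interval. Only the treated
#' subgroup identifies the post-alert hazard multiplier: admissions
#' that never reach the warning zone are untouched by the intervention.
#'
#' @param sim_on,sim_off `mews_simulation` objects (intervention on/off).
#' @return list with `estimate`, `ci_low`, `ci_high`, `events`
#'   (2-vector), `n` (2-vector).
#' @export
estimate_rate_ratio <- function(sim_on, sim_off) {
  sub <- function(s) s$admissions[s$admissions$wz & s$admissions$dnr == 0L, ]
  a_on <- sub(sim_on); a_off <- sub(sim_off)
  e <- c(on = sum(a_on$ihca), off = sum(a_off$ihca))
  n <- c(on = nrow(a_on), off = nrow(a_off))
  est <- (e[["on"]] / n[["on"]]) / (e[["off"]] / n[["off"]])
  se <- sqrt(1 / max(e[["on"]], 0.5) - 1 / n[["on"]] +
             1 / max(e[["off"]], 0.5) - 1 / n[["off"]])
  list(estimate = est,
       ci_low = est * exp(-1.96 * se), ci_high = est * exp(1.96 * se),
       events = e, n = n)
}
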