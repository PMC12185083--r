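#' Design configuration of the adaptive platform trial
#'
#' Encodes the trial design: maximum sample size (2500 by default),
#' interim analyses with response-adaptive randomization every 500
#' enrolled, the sqrt(3):1:1:1 starting allocation, posterior decision
#' thresholds, the adaptive-weight exponent, dose and duration dropping,
#' the posterior engine used at interims, and the enrolment model
#' (accrual rate in patients/week; patients contribute to an interim
#' only once their 90-day post-surgery follow-up is complete, while
#' enrolment continues during the follow-up lag).
#'
#' @param max_n enrolment cap.
#' @param interim_every interim cadence in enrolled patients.
#' @param accrual_per_week mean enrolment rate (patients/week).
#' @param thresholds a [decision_thresholds()] list.
#' @param rar_exponent exponent on P(best dose) in [update_weights()].
#' @param drop_durations drop a duration stratum (stop enrolling it and
#'   exclude it from pooled dose contrasts) when its pooled posterior
#'   superiority probability falls below the futility threshold.
#' @param engine `"laplace"` (fast, default for simulation) or
#'   `"mcmc"`.
#' @param randomization_method `"weighted"` or `"blocks"` (blocks apply
#'   only while weights remain at the default ratio).
#' @param ndraws posterior draws per interim fit.
#' @param min_complete minimum number of complete-outcome patients
#'   required before an interim analysis is attempted.
#' @param min_drop_complete minimum number of complete-outcome patients
#'   before futility/inferiority dropping of doses or durations is
#'   permitted (superiority can be declared at any analysis). Dropping
#'   decisions made on a handful of completed patients are dominated by
#'   noise and would routinely discard effective arms, so the design
#'   requires a minimum information fraction first - standard practice
#'   in adaptive platform designs.
#' @param priors model priors ([hfd_priors()]).
#' @return object of class `design_config`.
#' @export
design_config <- function(max_n = 2500, interim_every = 500,
                          accrual_per_week = 20,
                          thresholds = decision_thresholds(),
                          rar_exponent = 0.5,
                          drop_durations = TRUE,
                          engine = c("laplace", "mcmc"),
                          randomization_method = c("weighted", "blocks"),
                          ndraws = 4000, min_complete = 50,
                          min_drop_complete = 300,
                          priors = hfd_priors()) {
  stopifnot(max_n >= interim_every, interim_every > 0,
            accrual_per_week > 0)
  structure(list(max_n = as.integer(max_n),
                 interim_every = as.integer(interim_every),
                 interims = seq(as.integer(interim_every),
                                as.integer(max_n),
                                by = as.integer(interim_every)),
                 accrual_per_week = accrual_per_week,
                 thresholds = thresholds,
                 rar_exponent = rar_exponent,
                 drop_durations = drop_durations,
                 engine = match.arg(engine),
                 randomization_method = match.arg(randomization_method),
                 ndraws = as.integer(ndraws),
                 min_complete = as.integer(min_complete),
                 min_drop_complete = as.integer(min_drop_complete),
                 priors = priors),
            class = "design_config")
}

enroll_batch <- function(n_needed, active_durations, config) {
  # draw patients until n_needed fall in the still-active duration strata
  got <- NULL
  p_active <- sum(config$duration_mix[active_durations])
  while (is.null(got) || nrow(got) < n_needed) {
    draw <- ceiling((n_needed - if (is.null(got)) 0 else nrow(got)) /
                      max(p_active, 0.05)) + 10
    cfg <- config
    cfg$n_patients <- as.integer(draw)
    cfg$seed <- NULL
    b <- generate_cohort(cfg)
    b <- b[b$duration_stratum %in% active_durations, , drop = FALSE]
    got <- if (is.null(got)) b else rbind(got, b)
  }
  got[seq_len(n_needed), , drop = FALSE]
}

#' Simulate one complete adaptive platform trial
#'
#' Runs enrolment, stratified randomization, outcome accrual, interim
#' analyses with the configured posterior engine, response-adaptive
#' weight updates, dose/duration dropping and early stopping, up to the
#' enrolment cap, then a final analysis once every patient has complete
#' 90-day follow-up. Superiority at any analysis stops the platform;
#' dropping every dose stops it for futility. The pooled dose contrast
#' that drives the superiority rule averages the dose's effects over the
#' durations still active at that analysis.
#'
#' @param design a [design_config()].
#' @param scenario an [effect_scenario()].
#' @param config a [cohort_config()] describing the population
#'   (its `n_patients`/`seed` fields are ignored).
#' @param seed integer seed making the replicate fully reproducible.
#' @return object of class `trial_result`: `conclusion`
#'   (`"superiority"`, `"futility"` or `"max_n_reached"`), `winner`,
#'   `n_enrolled`, per-arm sample sizes, `interims` log (one row per
#'   analysis), and the final fit's dose summaries.
#' @export
run_trial <- function(design, scenario, config = cohort_config(),
                      seed = 1L) {
  set.seed(as.integer(seed))
  rate_day <- design$accrual_per_week / 7

  patients <- NULL; assignments <- NULL
  hfd <- integer(0); surgery <- logical(0); enroll_day <- numeric(0)
  weights <- allocation_weights()
  active_doses <- DOSES; active_durations <- DURATIONS
  log_rows <- list(); warm <- NULL
  conclusion <- NA_character_; winner <- NA_character_
  analyses <- c(design$interims)
  n_enrolled <- 0L

  analysis_data <- function(idx) {
    data.frame(hfd90 = hfd[idx], arm = assignments$arm[idx],
               duration_stratum = assignments$duration_stratum[idx],
               surgical_stratum = patients$surgical_stratum[idx],
               stringsAsFactors = FALSE)
  }

  do_fit <- function(idx) {
    fit_hfd_model(analysis_data(idx), engine = design$engine,
                  priors = design$priors, ndraws = design$ndraws,
                  active_doses = active_doses,
                  active_durations = active_durations, start = warm)
  }

  for (target in analyses) {
    if (!is.na(conclusion)) break
    if (length(active_durations) == 0) break
    need <- target - n_enrolled
    batch <- enroll_batch(need, active_durations, config)
    asg <- assign_arms(batch, weights,
                       method = if (identical(
                         as.numeric(weights),
                         as.numeric(allocation_weights())))
                         design$randomization_method else "weighted")
    crs <- generate_courses(batch, asg, scenario, config)
    patients <- if (is.null(patients)) batch else rbind(patients, batch)
    assignments <- if (is.null(assignments)) asg else rbind(assignments, asg)
    hfd <- c(hfd, compute_hfd90(crs))
    surgery <- c(surgery, crs$surgery_performed)
    enroll_day <- c(enroll_day, (n_enrolled + seq_len(need)) / rate_day)
    n_enrolled <- n_enrolled + need

    interim_day <- enroll_day[n_enrolled]
    complete <- which(
      enroll_day + patients$planned_lead_time_days + 90 <= interim_day &
        surgery & !is.na(hfd))
    snap <- list(analysis = length(log_rows) + 1L, n_enrolled = n_enrolled,
                 n_complete = length(complete),
                 weights = allocation_probabilities(weights),
                 active_doses = paste(active_doses, collapse = ","),
                 active_durations = paste(active_durations, collapse = ","),
                 fitted = FALSE)
    if (length(complete) >= design$min_complete &&
        length(active_doses) > 0) {
      fit <- tryCatch(do_fit(complete), error = function(e) NULL)
      if (!is.null(fit)) {
        warm <- fit$mode
        snap$fitted <- TRUE
        dec <- decide(fit, design$thresholds, doses = active_doses)
        snap$decisions <- dec$arms
        if (dec$platform == "superior") {
          sup <- dec$arms[dec$arms$status == "superior", ]
          winner <- sup$dose[which.max(sup$p_superior)]
          conclusion <- "superiority"
        } else {
          allow_drop <- length(complete) >= design$min_drop_complete
          if (design$drop_durations && allow_drop) {
            ds <- fit$summaries[fit$summaries$type == "duration", ]
            ds <- ds[ds$duration %in% active_durations, ]
            dropd <- ds$duration[ds$p_superior <
                                   design$thresholds$futility]
            active_durations <- setdiff(active_durations, dropd)
          }
          arms_for_update <- dec$arms
          if (!allow_drop)
            arms_for_update$status[arms_for_update$status %in%
                                     c("futile", "inferior")] <- "continue"
          upd <- update_weights(weights, arms_for_update,
                                exponent = design$rar_exponent)
          if (is.list(upd) && isTRUE(upd$platform_stop)) {
            conclusion <- "futility"
          } else {
            weights <- upd
            active_doses <- names(weights)[-1][weights[-1] > 0]
          }
          if (length(active_durations) == 0 && is.na(conclusion))
            conclusion <- "futility"
        }
      }
    }
    log_rows[[length(log_rows) + 1L]] <- snap
  }

  final_summaries <- NULL
  if (is.na(conclusion)) {
    idx <- which(surgery & !is.na(hfd))
    fit <- tryCatch(do_fit(idx), error = function(e) NULL)
    if (!is.null(fit)) {
      final_summaries <- fit$summaries[fit$summaries$type == "dose", ]
      dec <- decide(fit, design$thresholds, doses = active_doses)
      log_rows[[length(log_rows) + 1L]] <-
        list(analysis = length(log_rows) + 1L, n_enrolled = n_enrolled,
             n_complete = length(idx),
             weights = allocation_probabilities(weights),
             active_doses = paste(active_doses, collapse = ","),
             active_durations = paste(active_durations, collapse = ","),
             fitted = TRUE, decisions = dec$arms, final = TRUE)
      if (dec$platform == "superior") {
        sup <- dec$arms[dec$arms$status == "superior", ]
        winner <- sup$dose[which.max(sup$p_superior)]
        conclusion <- "superiority"
      } else if (dec$platform == "stopped_futility") {
        conclusion <- "futility"
      } else {
        conclusion <- "max_n_reached"
      }
    } else {
      conclusion <- "max_n_reached"
    }
  }

  arm_n <- table(factor(assignments$arm, levels = ARMS))
  structure(list(conclusion = conclusion, winner = winner,
                 n_enrolled = n_enrolled,
                 arm_n = as.integer(arm_n),
                 arm_labels = names(arm_n),
                 active_doses = active_doses,
                 active_durations = active_durations,
                 interims = log_rows,
                 final_summaries = final_summaries,
                 seed = seed, scenario = scenario$label),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", x$scenario, "| conclusion:", x$conclusion,
      if (!is.na(x$winner)) paste0("(winner ", x$winner, " mg)") else "",
      "\n  enrolled:", x$n_enrolled, "; per arm:",
      paste(x$arm_labels, x$arm_n, collapse = ", "), "\n")
  invisible(x)
}

#' Monte-Carlo operating characteristics of the design
#'
#' Runs `n_replicates` independent simulated trials (per-replicate seeds
#' derived from `seed`) and aggregates the design's frequentist
#' behaviour: power (fraction of replicates declaring the truly best
#' dose superior; under a null scenario the same statistic is the
#' platform type-I error), expected and median final sample size,
#' arm-selection frequencies, and Monte-Carlo standard errors.
#'
#' @param design a [design_config()].
#' @param scenario an [effect_scenario()]; for power, the scenario must
#'   carry `best_dose` (as the presets do).
#' @param n_replicates number of simulated trials (>= 50 recommended for
#'   meaningful MC-SE).
#' @param config population [cohort_config()].
#' @param seed master seed.
#' @return object of class `operating_characteristics`.
#' @export
operating_characteristics <- function(design, scenario,
                                      n_replicates = 200,
                                      config = cohort_config(),
                                      seed = 1L) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  res <- vector("list", n_replicates)
  for (r in seq_len(n_replicates))
    res[[r]] <- run_trial(design, scenario, config, seed = seeds[r])
  concl <- vapply(res, function(x) x$conclusion, character(1))
  winner <- vapply(res, function(x)
    if (is.na(x$winner)) "" else x$winner, character(1))
  any_sup <- concl == "superiority"
  best <- scenario$best_dose %||% NA_character_
  hit <- if (!is.na(best)) any_sup & winner == best else any_sup
  p <- mean(hit)
  mcse <- sqrt(p * (1 - p) / n_replicates)
  nfinal <- vapply(res, function(x) x$n_enrolled, numeric(1))
  sel <- table(factor(winner[any_sup], levels = DOSES))
  structure(list(scenario = scenario$label,
                 n_replicates = n_replicates,
                 power = p, mc_se = mcse,
                 any_superiority = mean(any_sup),
                 type_i_error = if (isTRUE(scenario$is_null)) mean(any_sup)
                                else NA_real_,
                 mean_n = mean(nfinal), median_n = stats::median(nfinal),
                 arm_selection = as.integer(sel) / n_replicates,
                 arm_selection_labels = names(sel),
                 conclusions = table(concl),
                 seed = seed),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("<operating_characteristics>", x$scenario, "|",
      x$n_replicates, "replicates\n")
  cat(sprintf("  power (best-dose superiority): %.3f (MC-SE %.3f)\n",
              x$power, x$mc_se))
  if (!is.na(x$type_i_error))
    cat(sprintf("  type-I error (any superiority): %.3f\n",
                x$type_i_error))
  cat(sprintf("  final n: mean %.0f, median %.0f\n", x$mean_n,
              x$median_n))
  invisible(x)
}

#' Write a trial's interim log to CSV and weights history to JSON
#'
#' @param trial a `trial_result`.
#' @param dir output directory (created if needed).
#' @export
write_trial_log <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trial$interims, function(s)
    data.frame(analysis = s$analysis, n_enrolled = s$n_enrolled,
               n_complete = s$n_complete, fitted = s$fitted,
               active_doses = s$active_doses,
               active_durations = s$active_durations,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "interim_log.csv"), row.names = FALSE)
  wh <- lapply(trial$interims, function(s) as.list(s$weights))
  jsonlite::write_json(wh, file.path(dir, "weights_history.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
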