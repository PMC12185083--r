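#' Configuration for the synthetic patient-cohort generator
#'
#' Bundles every knob of the virtual-patient generator: cohort size, the
#' surgical-stratum and pre-operative duration mixes, the baseline HFD-90
#' outcome parameters, hospital-course event rates, and compliance
#' probabilities. The defaults are calibrated so that a null (no treatment
#' effect) cohort reproduces the trial population's HFD-90 summary: median
#' 88 days with interquartile range 85 to 90, worse outcomes in the spine
#' and colorectal strata, roughly 13.5% 90-day reoperation, 11%
#' readmission, 18.4% nonadherence and 6.7% withdrawal.
#'
#' The baseline outcome model is a three-part mixture per surgical
#' stratum: a point mass at -1 (death within 90 days), a point mass at 0
#' (alive, never discharged), and otherwise `HFD = 90 - T` where the total
#' number of hospitalised days `T` follows a negative-binomial
#' distribution (truncated at 89). Stratum severity enters as a
#' proportional-odds shift of the whole ordinal distribution relative to
#' the general-surgery baseline.
#'
#' @param n_patients number of patients to generate.
#' @param stratum_mix probabilities over the four surgical strata
#'   (spine, general, colorectal, other); must sum to 1.
#' @param duration_mix probabilities over the three planned pre-operative
#'   treatment-duration strata (short, medium, long); must sum to 1.
#' @param baseline_hfd_params list with elements `p_death`, `p_zero`,
#'   `los_mu`, `los_size` (negative-binomial mean/size of total hospital
#'   days) and `stratum_or`, a named vector of proportional-odds shifts
#'   (on the fewer-HFD orientation, >1 = worse) per stratum.
#' @param event_rates list with `reoperation` and `morbidity` (marginal
#'   90-day probabilities) and `readmission`, the probability that a
#'   survivor with at least two hospital days has part of them accrued in
#'   a readmission rather than the index stay (0.22 gives a marginal
#'   readmission rate near 11% under the default baseline).
#' @param nonadherence_prob,withdrawal_prob marginal probabilities of
#'   study-drug nonadherence and of full withdrawal (withdrawal implies
#'   nonadherence, so `withdrawal_prob <= nonadherence_prob`).
#' @param surgery_prob probability that an enrolled patient actually
#'   undergoes the planned operation (non-operated patients are excluded
#'   from the intention-to-treat cohort).
#' @param n_clinics number of synthetic enrolment clinics.
#' @param seed optional integer seed; when supplied, generation is fully
#'   deterministic and does not disturb the caller's RNG stream.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 1000,
                          stratum_mix = c(spine = 0.29, general = 0.38,
                                          colorectal = 0.13, other = 0.20),
                          duration_mix = c(short = 0.61, medium = 0.28,
                                           long = 0.11),
                          baseline_hfd_params = list(
                            p_death = 0.02, p_zero = 0.004,
                            los_mu = 1.75, los_size = 0.95,
                            stratum_or = c(spine = 5, general = 1,
                                           colorectal = 5, other = 1)),
                          event_rates = list(reoperation = 0.135,
                                             readmission = 0.22,
                                             morbidity = 0.22),
                          nonadherence_prob = 0.184,
                          withdrawal_prob = 0.067,
                          surgery_prob = 0.934,
                          n_clinics = 3,
                          seed = NULL) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0)
    stop_config("n_patients", "must be a single non-negative count")
  stratum_mix <- check_prob_vector(stratum_mix, "stratum_mix")
  duration_mix <- check_prob_vector(duration_mix, "duration_mix")
  if (!setequal(names(stratum_mix), STRATA))
    stop_config("stratum_mix", "must be named over spine/general/colorectal/other")
  if (!setequal(names(duration_mix), DURATIONS))
    stop_config("duration_mix", "must be named over short/medium/long")
  b <- baseline_hfd_params
  check_prob(b$p_death, "baseline_hfd_params$p_death")
  check_prob(b$p_zero, "baseline_hfd_params$p_zero")
  if (b$p_death + b$p_zero >= 1)
    stop_config("baseline_hfd_params", "p_death + p_zero must be < 1")
  if (!is.numeric(b$los_mu) || b$los_mu <= 0 ||
      !is.numeric(b$los_size) || b$los_size <= 0)
    stop_config("baseline_hfd_params", "los_mu and los_size must be > 0")
  if (any(b$stratum_or <= 0) || !setequal(names(b$stratum_or), STRATA))
    stop_config("baseline_hfd_params$stratum_or",
                "must be positive and named over the four strata")
  for (f in c("reoperation", "readmission", "morbidity"))
    check_prob(event_rates[[f]], paste0("event_rates$", f))
  check_prob(nonadherence_prob, "nonadherence_prob")
  check_prob(withdrawal_prob, "withdrawal_prob")
  if (withdrawal_prob > nonadherence_prob)
    stop_config("withdrawal_prob",
                "cannot exceed nonadherence_prob (withdrawal implies nonadherence)")
  check_prob(surgery_prob, "surgery_prob")
  structure(list(n_patients = as.integer(n_patients),
                 stratum_mix = stratum_mix[STRATA],
                 duration_mix = duration_mix[DURATIONS],
                 baseline_hfd_params = b, event_rates = event_rates,
                 nonadherence_prob = nonadherence_prob,
                 withdrawal_prob = withdrawal_prob,
                 surgery_prob = surgery_prob,
                 n_clinics = as.integer(n_clinics),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_patients, "patients\n")
  cat("  stratum mix:", paste(names(x$stratum_mix),
                              format(x$stratum_mix), collapse = ", "), "\n")
  cat("  duration mix:", paste(names(x$duration_mix),
                               format(x$duration_mix), collapse = ", "), "\n")
  invisible(x)
}

#' Proportional-odds shift of an ordinal probability vector
#'
#' Applies a constant odds ratio `or` to every cumulative split of an
#' ordinal distribution, counting cumulative probabilities from the worst
#' (first) category: if `F_k` is the baseline probability of being in
#' category `k` or worse, the shifted distribution has cumulative odds
#' `or * F_k / (1 - F_k)`. With categories ordered worst to best,
#' `or > 1` moves mass toward worse outcomes and `or < 1` toward better
#' ones. This is the exact data-generating counterpart of the
#' proportional-odds (cumulative-logit) model, so simulated treatment
#' effects are model-consistent by construction.
#'
#' @param p probability vector over ordered categories (worst first).
#' @param or positive odds ratio on the worst-end cumulative odds.
#' @return shifted probability vector of the same length.
#' @export
po_shift_probs <- function(p, or) {
  stopifnot(is.numeric(p), all(p >= 0), abs(sum(p) - 1) < 1e-8,
            length(or) == 1, or > 0)
  F <- cumsum(p)
  F[length(F)] <- 1
  F2 <- or * F / (1 + (or - 1) * F)
  d <- diff(c(0, F2))
  pmax(d, 0)
}

#' Baseline HFD-90 distribution for one surgical stratum
#'
#' Returns the calibrated null (placebo, no treatment effect) probability
#' vector of the ordinal HFD-90 outcome over categories -1, 0, 1, ..., 90
#' for a given surgical stratum, i.e. the general-surgery baseline mixture
#' shifted by the stratum's proportional-odds severity factor.
#'
#' @param config a [cohort_config()].
#' @param stratum one of `"spine"`, `"general"`, `"colorectal"`, `"other"`.
#' @return named numeric vector of length 92 (names `-1` to `90`).
#' @export
hfd_baseline_probs <- function(config, stratum = "general") {
  stratum <- match.arg(stratum, STRATA)
  b <- config$baseline_hfd_params
  tT <- stats::dnbinom(0:88, mu = b$los_mu, size = b$los_size)
  tT <- c(tT, 1 - sum(tT))                       # T = 89 absorbs the tail
  p_alive <- (1 - b$p_death - b$p_zero) * rev(tT)  # h = 90 - T, h in 1..90
  p <- c(b$p_death, b$p_zero, p_alive)
  names(p) <- as.character(-1:90)
  po_shift_probs(p, b$stratum_or[[stratum]])
}

# ---- effect scenarios -------------------------------------------------

#' Treatment-effect scenarios
#'
#' An effect scenario specifies the proportional-odds ratio (on the
#' fewer-HFD orientation: <1 = beneficial) applied to each of the nine
#' dose-by-duration treatment cells, relative to placebo. `por_by_arm` is
#' a 3x3 matrix with rows `"500","1000","1500"` (mg metformin) and columns
#' `"short","medium","long"`.
#'
#' Presets:
#' * [scenario_null()]: all ratios 1 (no effect anywhere).
#' * [scenario_uniform15()]: the design's maximal effect - a 15%
#'   proportional-odds improvement (ratio 0.85) for one "best" dose in
#'   every duration stratum, other doses null.
#' * [scenario_no_short()]: the same best-dose effect restricted to the
#'   medium and long duration strata (ratio 1 in short).
#'
#' @param por_by_arm 3x3 positive matrix of proportional-odds ratios.
#' @param strata_modifiers optional named per-stratum multipliers applied
#'   on top of the treatment ratio (default none).
#' @param label scenario label used in reports.
#' @return object of class `effect_scenario`.
#' @export
effect_scenario <- function(por_by_arm,
                            strata_modifiers = NULL,
                            label = "custom") {
  m <- as.matrix(por_by_arm)
  if (!all(dim(m) == c(3, 3)) || any(m <= 0))
    stop_config("por_by_arm", "must be a positive 3x3 (dose x duration) matrix")
  dimnames(m) <- list(DOSES, DURATIONS)
  if (!is.null(strata_modifiers)) {
    if (!setequal(names(strata_modifiers), STRATA) || any(strata_modifiers <= 0))
      stop_config("strata_modifiers", "must be positive and named over the strata")
    strata_modifiers <- strata_modifiers[STRATA]
  }
  structure(list(por_by_arm = m, strata_modifiers = strata_modifiers,
                 label = label, is_null = all(m == 1)),
            class = "effect_scenario")
}

#' @rdname effect_scenario
#' @export
scenario_null <- function() {
  effect_scenario(matrix(1, 3, 3), label = "null")
}

#' @rdname effect_scenario
#' @param best_dose dose (mg, as character) carrying the effect.
#' @param por proportional-odds ratio of the maximal effect (fewer-HFD
#'   orientation; 0.85 is the design's "15% improvement").
#' @export
scenario_uniform15 <- function(best_dose = "1000", por = 0.85) {
  m <- matrix(1, 3, 3, dimnames = list(DOSES, DURATIONS))
  m[best_dose, ] <- por
  s <- effect_scenario(m, label = "uniform-15")
  s$best_dose <- best_dose
  s
}

#' @rdname effect_scenario
#' @export
scenario_no_short <- function(best_dose = "1000", por = 0.85) {
  m <- matrix(1, 3, 3, dimnames = list(DOSES, DURATIONS))
  m[best_dose, c("medium", "long")] <- por
  s <- effect_scenario(m, label = "no-short-effect")
  s$best_dose <- best_dose
  s
}

#' Proportional-odds ratio for a given arm under a scenario
#'
#' @param scenario an [effect_scenario()].
#' @param arm `"placebo"` or a dose `"500"/"1000"/"1500"`.
#' @param duration duration stratum.
#' @param stratum optional surgical stratum (applies `strata_modifiers`).
#' @return a single positive ratio (1 for placebo).
#' @export
scenario_por <- function(scenario, arm, duration, stratum = NULL) {
  if (arm == "placebo") return(1)
  if (!arm %in% DOSES) stop("unknown arm: ", arm, call. = FALSE)
  por <- scenario$por_by_arm[arm, duration]
  if (!is.null(scenario$strata_modifiers) && !is.null(stratum))
    por <- por * scenario$strata_modifiers[[stratum]]
  por
}

# ---- patient generation ----------------------------------------------

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` virtual enrollees with the covariate structure the
#' trial's analyses assume: age centred at 68 (sd 6), eligibility by age
#' >= 60 or Charlson comorbidity index > 2, 45% female, the configured
#' surgical-stratum and duration mixes, ordered frailty and
#' operative-stress categories, and a planned enrolment-to-surgery lead
#' time consistent with the duration stratum (short 7-28 days, medium
#' 29-90, long 91-180).
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per patient.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed_if(config$seed, {
    if (n == 0) {
      return(data.frame(patient_id = character(), age = integer(),
                        cci = integer(), sex = character(),
                        surgical_stratum = character(),
                        frailty_category = character(),
                        operative_stress = character(),
                        clinic_id = character(),
                        planned_lead_time_days = integer(),
                        duration_stratum = character(),
                        stringsAsFactors = FALSE))
    }
    age <- pmin(pmax(round(stats::rnorm(n, 68, 6)), 45L), 94L)
    cci <- ifelse(age < 60, 3L + stats::rpois(n, 1.2), stats::rpois(n, 1.5))
    sex <- ifelse(stats::runif(n) < 0.45, "female", "male")
    stratum <- sample(STRATA, n, replace = TRUE, prob = config$stratum_mix)
    frailty <- sample(c("not-frail", "pre-frail", "frail"), n,
                      replace = TRUE, prob = c(0.3, 0.5, 0.2))
    stress <- sample(c("low", "moderate", "high"), n,
                     replace = TRUE, prob = c(0.25, 0.5, 0.25))
    clinic <- sprintf("clinic-%d", sample.int(config$n_clinics, n, replace = TRUE))
    dur <- sample(DURATIONS, n, replace = TRUE, prob = config$duration_mix)
    lead <- integer(n)
    lead[dur == "short"] <- sample(7:28, sum(dur == "short"), replace = TRUE)
    lead[dur == "medium"] <- sample(29:90, sum(dur == "medium"), replace = TRUE)
    lead[dur == "long"] <- sample(91:180, sum(dur == "long"), replace = TRUE)
    data.frame(patient_id = sprintf("P%06d", seq_len(n)),
               age = as.integer(age), cci = as.integer(cci), sex = sex,
               surgical_stratum = stratum,
               frailty_category = factor(frailty,
                 levels = c("not-frail", "pre-frail", "frail"), ordered = TRUE),
               operative_stress = factor(stress,
                 levels = c("low", "moderate", "high"), ordered = TRUE),
               clinic_id = clinic,
               planned_lead_time_days = lead,
               duration_stratum = dur,
               stringsAsFactors = FALSE)
  })
}

# ---- hospital-course generation --------------------------------------

empty_courses <- function() {
  df <- data.frame(patient_id = character(), surgery_performed = logical(),
                   discharge_day = integer(), reoperation_day = integer(),
                   death_day = integer(), morbidity_day = integer(),
                   stringsAsFactors = FALSE)
  df$readmissions <- list()
  df
}

#' Generate hospital courses for an assigned cohort
#'
#' Draws each patient's ordinal HFD-90 outcome from the stratum baseline
#' distribution shifted by the assigned arm's proportional-odds ratio
#' (exact inverse-CDF sampling on the shifted cumulative distribution),
#' then constructs an event-level hospital course realising that outcome:
#' death day for -1, no discharge for 0, and otherwise an index stay plus
#' possibly one readmission interval whose total hospitalised days equal
#' `90 - HFD`. Reoperation and morbidity events are superimposed at the
#' configured marginal rates, never after death. Day 0 is the day of
#' surgery; readmission intervals are half-open `[start, end)` within
#' `[0, 90]`.
#'
#' @param patients data.frame from [generate_cohort()].
#' @param assignments data.frame with columns `patient_id`, `arm`
#'   (placebo/500/1000/1500) and `duration_stratum`; ordering must match
#'   `patients` by `patient_id`.
#' @param scenario an [effect_scenario()].
#' @param config a [cohort_config()].
#' @param seed optional seed (defaults to drawing from the current RNG
#'   stream).
#' @return data.frame of courses, one row per patient, with a
#'   `readmissions` list-column of `[start, end)` two-column matrices.
#' @export
generate_courses <- function(patients, assignments, scenario, config,
                             seed = NULL) {
  stopifnot(inherits(scenario, "effect_scenario"),
            inherits(config, "cohort_config"))
  n <- nrow(patients)
  if (n == 0) return(empty_courses())
  if (!all(assignments$patient_id == patients$patient_id))
    stop("assignments must align with patients by patient_id", call. = FALSE)
  bad <- setdiff(unique(assignments$arm), ARMS)
  if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  with_seed_if(seed, {
    er <- config$event_rates
    surgery <- stats::runif(n) < config$surgery_prob
    hfd <- integer(n)
    # draw the latent ordinal outcome per (stratum, arm, duration) block
    por <- vapply(seq_len(n), function(i)
      scenario_por(scenario, assignments$arm[i],
                   assignments$duration_stratum[i],
                   patients$surgical_stratum[i]), numeric(1))
    key <- paste(patients$surgical_stratum, format(por, digits = 12))
    for (k in unique(key)) {
      idx <- which(key == k)
      p0 <- hfd_baseline_probs(config, patients$surgical_stratum[idx[1]])
      pk <- po_shift_probs(p0, por[idx[1]])
      hfd[idx] <- sample(-1:90, length(idx), replace = TRUE, prob = pk)
    }

    discharge <- rep(NA_integer_, n)
    death <- rep(NA_integer_, n)
    reop <- rep(NA_integer_, n)
    morb <- rep(NA_integer_, n)
    readm <- vector("list", n)

    dead <- surgery & hfd == -1
    death[dead] <- sample(0:90, sum(dead), replace = TRUE)

    alive_disc <- surgery & hfd >= 1
    Tdays <- 90L - hfd
    split_ok <- alive_disc & Tdays >= 2
    do_split <- split_ok & stats::runif(n) < er$readmission
    len <- pmin(Tdays - 1L, 1L + stats::rpois(n, 1.5))
    discharge[alive_disc] <- ifelse(do_split[alive_disc],
                                    Tdays[alive_disc] - len[alive_disc],
                                    Tdays[alive_disc])
    for (i in which(do_split)) {
      s <- discharge[i] + sample.int(90L - len[i] - discharge[i] + 1L, 1L) - 1L
      readm[[i]] <- matrix(c(s, s + len[i]), 1, 2,
                           dimnames = list(NULL, c("start", "end")))
    }

    # reoperation / morbidity, capped at the death day
    cap <- ifelse(dead, death, 89L)
    has_reop <- surgery & stats::runif(n) < er$reoperation
    reop[has_reop] <- floor(stats::runif(sum(has_reop)) * (cap[has_reop] + 1L))
    has_morb <- surgery & stats::runif(n) < er$morbidity
    morb[has_morb] <- floor(stats::runif(sum(has_morb)) * (cap[has_morb] + 1L))

    out <- data.frame(patient_id = patients$patient_id,
                      surgery_performed = surgery,
                      discharge_day = discharge,
                      reoperation_day = reop,
                      death_day = death,
                      morbidity_day = morb,
                      stringsAsFactors = FALSE)
    out$readmissions <- readm
    out
  })
}

#' Generate a single hospital course
#'
#' Convenience wrapper around [generate_courses()] for one patient.
#'
#' @param patient one-row data.frame (as from [generate_cohort()]).
#' @param arm `"placebo"` or a dose in mg (`"500"/"1000"/"1500"`).
#' @param scenario an [effect_scenario()].
#' @param config a [cohort_config()].
#' @param seed optional seed.
#' @return one-row course data.frame.
#' @export
generate_course <- function(patient, arm, scenario, config, seed = NULL) {
  asg <- data.frame(patient_id = patient$patient_id, arm = arm,
                    duration_stratum = patient$duration_stratum,
                    stringsAsFactors = FALSE)
  generate_courses(patient, asg, scenario, config, seed = seed)
}

#' Mark adherence and withdrawal on hospital courses
#'
#' Adds `adherent`, `withdrew` and `withdrawal_day` columns. Withdrawal
#' implies nonadherence; the extra (non-withdrawing) nonadherence
#' probability is chosen so the marginal nonadherence rate equals
#' `nonadherence_prob`. By default compliance is independent of arm.
#'
#' @param courses course data.frame from [generate_courses()].
#' @param config a [cohort_config()].
#' @param seed optional seed.
#' @return `courses` with compliance columns added.
#' @export
apply_compliance <- function(courses, config, seed = NULL) {
  n <- nrow(courses)
  with_seed_if(seed, {
    wd <- stats::runif(n) < config$withdrawal_prob
    p_extra <- if (config$withdrawal_prob >= 1) 0 else
      (config$nonadherence_prob - config$withdrawal_prob) /
      (1 - config$withdrawal_prob)
    nonadh <- wd | (stats::runif(n) < p_extra)
    courses$adherent <- !nonadh
    courses$withdrew <- wd
    courses$withdrawal_day <- ifelse(wd, sample(1:90, n, replace = TRUE),
                                     NA_integer_)
    courses
  })
}

#' Validate a hospital-course record
#'
#' Checks the structural invariants of a course: event days within
#' `[0, 90]`; readmission intervals sorted, non-overlapping, half-open,
#' and not before discharge; no event after the death day; and no
#' downstream events at all when surgery was not performed.
#'
#' @param course a one-row course data.frame or an equivalent list.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_course <- function(course) {
  g <- function(f) {
    v <- course[[f]]
    if (is.list(v)) v <- v[[1]]
    v
  }
  ev <- c(g("discharge_day"), g("reoperation_day"), g("death_day"),
          g("morbidity_day"))
  rd <- g("readmissions")
  if (!isTRUE(g("surgery_performed"))) {
    if (any(!is.na(ev)) || (!is.null(rd) && nrow(rd) > 0))
      stop("course invalid: events recorded without surgery", call. = FALSE)
    return(invisible(TRUE))
  }
  if (any(ev[!is.na(ev)] < 0 | ev[!is.na(ev)] > 90))
    stop("course invalid: event day outside [0, 90]", call. = FALSE)
  if (!is.null(rd) && nrow(rd) > 0) {
    if (any(rd < 0) || any(rd > 90) || any(rd[, 2] <= rd[, 1]))
      stop("course invalid: malformed readmission interval", call. = FALSE)
    if (is.unsorted(rd[, 1]) ||
        (nrow(rd) > 1 && any(rd[-1, 1] < rd[-nrow(rd), 2])))
      stop("course invalid: readmission intervals overlap or unsorted",
           call. = FALSE)
    if (is.na(g("discharge_day")))
      stop("course invalid: readmission without discharge", call. = FALSE)
    if (rd[1, 1] < g("discharge_day"))
      stop("course invalid: readmission before discharge", call. = FALSE)
  }
  dd <- g("death_day")
  if (!is.na(dd)) {
    other <- c(g("reoperation_day"), g("morbidity_day"), g("discharge_day"))
    if (any(other[!is.na(other)] > dd))
      stop("course invalid: event after death", call. = FALSE)
    if (!is.null(rd) && nrow(rd) > 0 && any(rd[, 2] > dd + 1))
      stop("course invalid: readmission after death", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- external interfaces ---------------------------------------------

#' Write a cohort/course table to CSV
#'
#' Flattens the `readmissions` list-column into
#' `readmission_starts`/`readmission_ends` (semicolon-separated) so the
#' table round-trips through plain CSV.
#' @param x data.frame (patients or courses).
#' @param path file path.
#' @export
write_cohort_csv <- function(x, path) {
  if (!is.null(x$readmissions)) {
    x$readmission_starts <- vapply(x$readmissions, function(m)
      if (is.null(m) || nrow(m) == 0) "" else paste(m[, 1], collapse = ";"),
      character(1))
    x$readmission_ends <- vapply(x$readmissions, function(m)
      if (is.null(m) || nrow(m) == 0) "" else paste(m[, 2], collapse = ";"),
      character(1))
    x$readmissions <- NULL
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a course table written by [write_cohort_csv()]
#' @param path file path.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(x$readmission_starts)) {
    x$readmissions <- Map(function(s, e) {
      s <- as.character(s); e <- as.character(e)
      if (is.na(s) || s == "") return(NULL)
      cbind(start = as.integer(strsplit(s, ";")[[1]]),
            end = as.integer(strsplit(e, ";")[[1]]))
    }, x$readmission_starts, x$readmission_ends)
    names(x$readmissions) <- NULL
    x$readmission_starts <- x$readmission_ends <- NULL
  }
  x
}

#' Save / load a cohort configuration as YAML
#' @param config a [cohort_config()].
#' @param path file path.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors must become maps, not bare sequences
  x$stratum_mix <- as.list(x$stratum_mix)
  x$duration_mix <- as.list(x$duration_mix)
  x$baseline_hfd_params$stratum_or <-
    as.list(x$baseline_hfd_params$stratum_or)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("stratum_mix", "duration_mix"))
    x[[f]] <- unlist(x[[f]])
  x$baseline_hfd_params$stratum_or <- unlist(x$baseline_hfd_params$stratum_or)
  do.call(cohort_config, x)
}
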