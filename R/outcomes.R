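#' Compute the 90-day hospital-free-days (HFD-90) endpoint
#'
#' HFD-90 is the ordinal composite primary endpoint: `-1` for patients
#' who die intraoperatively or within 90 postoperative days, `0` for
#' patients alive but hospitalised for the entire 90-day period, and
#' otherwise the number of postoperative days alive and out of hospital.
#'
#' Day-counting convention (fixed so the arithmetic is reproducible):
#' day 0 is the day of surgery; a patient discharged on day `d` is out of
#' hospital from day `d` onward; readmission intervals are half-open
#' `[start, end)`; out-of-hospital days are the days in `[0, 90)` not
#' covered by the index stay or any readmission. A patient discharged on
#' day 2 with no readmission therefore scores 88; adding a readmission
#' `[10, 15)` removes exactly 5 days.
#'
#' @param course a course data.frame (any number of rows) or a single
#'   course as a list; rows with `surgery_performed = FALSE` yield `NA`
#'   (the endpoint is undefined and such patients are excluded upstream).
#' @return integer vector of HFD-90 values in `{-1, 0, ..., 90}`.
#' @export
compute_hfd90 <- function(course) {
  if (!is.data.frame(course)) course <- as.data.frame.course(course)
  n <- nrow(course)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!isTRUE(course$surgery_performed[i])) next
    if (!is.na(course$death_day[i])) {
      out[i] <- -1L
      next
    }
    d <- course$discharge_day[i]
    if (is.na(d)) {
      out[i] <- 0L
      next
    }
    readm <- 0L
    rd <- if (is.null(course$readmissions)) NULL else course$readmissions[[i]]
    if (!is.null(rd) && nrow(rd) > 0) {
      s <- pmax(rd[, 1], d)
      e <- pmin(rd[, 2], 90L)
      readm <- sum(pmax(e - s, 0L))
    }
    out[i] <- as.integer(90L - d - readm)
  }
  out
}

as.data.frame.course <- function(x) {
  df <- data.frame(patient_id = x$patient_id %||% NA_character_,
                   surgery_performed = x$surgery_performed %||% TRUE,
                   discharge_day = x$discharge_day %||% NA_integer_,
                   reoperation_day = x$reoperation_day %||% NA_integer_,
                   death_day = x$death_day %||% NA_integer_,
                   morbidity_day = x$morbidity_day %||% NA_integer_,
                   stringsAsFactors = FALSE)
  df$readmissions <- list(x$readmissions)
  df
}

#' Compute 90-day secondary outcomes from hospital courses
#'
#' Derives the binary-plus-time secondary endpoints from each course:
#' 90-day reoperation, readmission, morbidity and mortality (each with
#' the event day), index length of stay, and the censoring day
#' (administrative at 90, or the withdrawal day for withdrawn patients).
#' Withdrawn patients additionally carry `tte_excluded = TRUE`: the
#' default time-to-event behaviour is to exclude them (their follow-up is
#' incomplete), with censoring at withdrawal available as an option in
#' the analysis functions.
#'
#' @param courses course data.frame (with compliance columns if
#'   available).
#' @return data.frame of secondary outcomes, one row per patient.
#' @export
compute_secondary <- function(courses) {
  n <- nrow(courses)
  wd <- courses$withdrew %||% rep(FALSE, n)
  wday <- courses$withdrawal_day %||% rep(NA_integer_, n)
  readm_day <- vapply(seq_len(n), function(i) {
    rd <- if (is.null(courses$readmissions)) NULL else courses$readmissions[[i]]
    if (is.null(rd) || nrow(rd) == 0) NA_integer_ else as.integer(rd[1, 1])
  }, integer(1))
  death <- courses$death_day
  censor <- ifelse(wd & !is.na(wday), wday, 90L)
  data.frame(
    patient_id = courses$patient_id,
    reoperation_90 = !is.na(courses$reoperation_day),
    reoperation_time = courses$reoperation_day,
    readmission_90 = !is.na(readm_day),
    readmission_time = readm_day,
    morbidity_90 = !is.na(courses$morbidity_day),
    morbidity_time = courses$morbidity_day,
    mortality_90 = !is.na(death),
    mortality_time = death,
    index_los_days = ifelse(is.na(courses$discharge_day),
                            ifelse(is.na(death), 90L, death),
                            courses$discharge_day),
    censor_day = as.integer(censor),
    tte_excluded = wd,
    stringsAsFactors = FALSE)
}

#' Build the intention-to-treat and per-protocol analysis cohorts
#'
#' The ITT cohort contains every randomized patient who underwent a
#' surgical intervention; the per-protocol (PPA) cohort additionally
#' requires adherence to the allocated study drug and no withdrawal, so
#' PPA is always a subset of ITT.
#'
#' @param patients patient data.frame.
#' @param assignments assignment data.frame (`patient_id`, `arm`,
#'   `duration_stratum`).
#' @param courses course data.frame with compliance columns.
#' @return list with elements `itt` and `ppa`, each a merged analysis
#'   data.frame (patients + assignment + course + `hfd90` + secondary
#'   outcomes), plus the full merged table as `all`.
#' @export
build_cohorts <- function(patients, assignments, courses) {
  for (x in list(patients, assignments, courses))
    if (anyDuplicated(x$patient_id))
      stop("duplicated patient_id in input table", call. = FALSE)
  if (!all(patients$patient_id == assignments$patient_id) ||
      !all(patients$patient_id == courses$patient_id))
    stop("inputs must align by patient_id", call. = FALSE)
  tab <- patients
  tab$arm <- assignments$arm
  if (!is.null(assignments$duration_stratum))
    tab$duration_stratum <- assignments$duration_stratum
  keep <- setdiff(names(courses), "patient_id")
  for (f in keep) tab[[f]] <- courses[[f]]
  tab$hfd90 <- compute_hfd90(courses)
  sec <- compute_secondary(courses)
  for (f in setdiff(names(sec), "patient_id")) tab[[f]] <- sec[[f]]
  itt <- tab[tab$surgery_performed, , drop = FALSE]
  adherent <- itt$adherent %||% rep(TRUE, nrow(itt))
  withdrew <- itt$withdrew %||% rep(FALSE, nrow(itt))
  ppa <- itt[adherent & !withdrew, , drop = FALSE]
  list(itt = itt, ppa = ppa, all = tab)
}
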