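#' Prespecified contrast sets
#'
#' Maps each patient's assignment to a comparison group for the four
#' prespecified frequentist contrasts: pooled metformin vs placebo,
#' by dose, by duration, and "low dose & short duration" vs all other
#' treatment combinations (placebo excluded from the latter's reference
#' per the protocol wording "placebo versus low dose and short duration
#' versus all other treatment combinations": the three groups partition
#' the cohort). Every patient maps to exactly one group; the first level
#' is the reference.
#'
#' @param cohort analysis data.frame with `arm` and `duration_stratum`.
#' @param contrast one of `"pooled_metformin_vs_placebo"`, `"by_dose"`,
#'   `"by_duration"`, `"lowdose_short_vs_rest"`.
#' @return factor of group labels (reference level first).
#' @export
contrast_groups <- function(cohort,
                            contrast = c("pooled_metformin_vs_placebo",
                                         "by_dose", "by_duration",
                                         "lowdose_short_vs_rest")) {
  contrast <- match.arg(contrast)
  arm <- as.character(cohort$arm)
  dur <- as.character(cohort$duration_stratum)
  g <- switch(contrast,
    pooled_metformin_vs_placebo =
      factor(ifelse(arm == "placebo", "placebo", "metformin"),
             levels = c("placebo", "metformin")),
    by_dose = factor(arm, levels = ARMS),
    by_duration =
      factor(ifelse(arm == "placebo", "placebo", dur),
             levels = c("placebo", DURATIONS)),
    lowdose_short_vs_rest =
      factor(ifelse(arm == "placebo", "placebo",
                    ifelse(arm == "500" & dur == "short",
                           "lowdose_short", "other_treatment")),
             levels = c("placebo", "lowdose_short", "other_treatment")))
  droplevels(g)
}

wald_estimate <- function(coef, se, measure, benefit_negative = TRUE) {
  # one-sided p in the benefit direction (fewer events / more HFD)
  z <- coef / se
  p1 <- if (benefit_negative) stats::pnorm(z) else stats::pnorm(-z)
  data.frame(measure = measure, estimate = exp(coef),
             ci_low = exp(coef - 1.959963984540054 * se),
             ci_high = exp(coef + 1.959963984540054 * se),
             one_sided_p = p1, stringsAsFactors = FALSE)
}

#' Univariable logistic regression for a binary 90-day endpoint
#'
#' Fits `endpoint ~ group` by maximum-likelihood logistic regression and
#' reports the odds ratio of each non-reference group vs the reference
#' with a Wald 95% CI and a one-sided p-value oriented so that small p
#' means benefit (fewer events) for the treatment group. When a group
#' has zero events or zero non-events the single-covariate fit is
#' replaced by the Haldane-Anscombe 0.5-corrected 2x2 estimate and
#' flagged (`continuity_corrected`).
#'
#' @param cohort analysis data.frame.
#' @param endpoint name of a logical column (e.g. `"reoperation_90"`,
#'   `"readmission_90"`, `"morbidity_90"`).
#' @param contrast contrast-set name passed to [contrast_groups()], or a
#'   ready-made factor.
#' @return data.frame, one row per non-reference group: estimate, CI,
#'   one-sided p, counts, significance at one-sided p < 0.025.
#' @export
fit_binary_endpoint <- function(cohort, endpoint = "reoperation_90",
                                contrast = "pooled_metformin_vs_placebo") {
  y <- cohort[[endpoint]]
  stopifnot(is.logical(y) || all(y %in% c(0, 1, NA)))
  g <- if (is.factor(contrast)) contrast else
    contrast_groups(cohort, contrast)
  ok <- !is.na(y) & !is.na(g)
  y <- as.integer(y[ok]); g <- droplevels(g[ok])
  if (length(unique(y)) < 2)
    stop("endpoint has no events or no non-events overall", call. = FALSE)
  ref <- levels(g)[1]
  out <- list()
  for (lev in levels(g)[-1]) {
    sel <- g %in% c(ref, lev)
    yy <- y[sel]; xx <- as.integer(g[sel] == lev)
    a <- sum(yy == 1 & xx == 1); b <- sum(yy == 0 & xx == 1)
    c_ <- sum(yy == 1 & xx == 0); d <- sum(yy == 0 & xx == 0)
    zero_cell <- any(c(a, b, c_, d) == 0)
    if (zero_cell) {
      co <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
      se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c_ + 0.5) +
                   1 / (d + 0.5))
    } else {
      fit <- stats::glm(yy ~ xx, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12))
      co <- stats::coef(fit)[["xx"]]
      se <- sqrt(stats::vcov(fit)["xx", "xx"])
    }
    r <- wald_estimate(co, se, "OR")
    r$group <- lev; r$reference <- ref
    r$n <- sum(sel); r$events <- a + c_
    r$rate_group <- a / (a + b); r$rate_ref <- c_ / (c_ + d)
    r$continuity_corrected <- zero_cell
    r$significant <- r$one_sided_p < 0.025
    out[[lev]] <- r
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$endpoint <- endpoint
  res
}

#' Cox regression and Kaplan-Meier curves for a time-to-event endpoint
#'
#' Builds event/censoring times from the outcome table (administrative
#' censoring at day 90), fits a univariable Cox proportional-hazards
#' model (Efron tie handling) for each non-reference group, and returns
#' the Kaplan-Meier survivor tables for replotting. Withdrawn patients
#' (`tte_excluded`) are excluded by default since their follow-up is
#' incomplete; `withdrawn = "censor"` censors them at the withdrawal day
#' instead.
#'
#' @param cohort analysis data.frame carrying `<endpoint>` and
#'   `<endpoint_time>` columns plus `censor_day`/`tte_excluded`.
#' @param endpoint `"reoperation_90"`, `"readmission_90"`,
#'   `"morbidity_90"` or `"mortality_90"`.
#' @param contrast contrast-set name or factor.
#' @param withdrawn `"exclude"` (default) or `"censor"`.
#' @return list: `estimate` (HR rows, or zero-event flag), `km`
#'   (data.frame time / n_risk / n_event / survival / group).
#' @export
fit_time_to_event <- function(cohort, endpoint = "reoperation_90",
                              contrast = "pooled_metformin_vs_placebo",
                              withdrawn = c("exclude", "censor")) {
  withdrawn <- match.arg(withdrawn)
  tcol <- sub("_90$", "_time", endpoint)
  excl <- cohort$tte_excluded %||% rep(FALSE, nrow(cohort))
  if (withdrawn == "exclude") cohort <- cohort[!excl, , drop = FALSE]
  ev <- as.integer(cohort[[endpoint]])
  tt <- ifelse(ev == 1, cohort[[tcol]],
               cohort$censor_day %||% rep(90L, nrow(cohort)))
  if (withdrawn == "exclude")
    tt[ev == 0] <- 90L
  g <- if (is.factor(contrast)) contrast else
    contrast_groups(cohort, contrast)
  ok <- !is.na(tt) & !is.na(g)
  tt <- as.numeric(tt[ok]); ev <- ev[ok]; g <- droplevels(g[ok])
  if (any(tt < 0)) stop("negative event times", call. = FALSE)
  sv <- survival::Surv(tt, ev)
  km_fit <- survival::survfit(sv ~ g)
  km <- data.frame(time = km_fit$time, n_risk = km_fit$n.risk,
                   n_event = km_fit$n.event, survival = km_fit$surv,
                   group = rep(sub("^g=", "",
                                   names(km_fit$strata) %||% levels(g)),
                               km_fit$strata %||% length(km_fit$time)),
                   stringsAsFactors = FALSE)
  ref <- levels(g)[1]
  out <- list()
  for (lev in levels(g)[-1]) {
    sel <- g %in% c(ref, lev)
    if (sum(ev[sel]) == 0) {
      out[[lev]] <- data.frame(measure = "HR", estimate = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               one_sided_p = NA_real_, group = lev,
                               reference = ref, n = sum(sel),
                               events = 0L, no_events = TRUE,
                               significant = NA, stringsAsFactors = FALSE)
      next
    }
    x <- as.integer(g[sel] == lev)
    cx <- survival::coxph(survival::Surv(tt[sel], ev[sel]) ~ x,
                          ties = "efron")
    r <- wald_estimate(stats::coef(cx)[["x"]],
                       sqrt(stats::vcov(cx)["x", "x"]), "HR")
    r$group <- lev; r$reference <- ref
    r$n <- sum(sel); r$events <- sum(ev[sel])
    r$no_events <- FALSE
    r$significant <- r$one_sided_p < 0.025
    out[[lev]] <- r
  }
  est <- do.call(rbind, out)
  rownames(est) <- NULL
  est$endpoint <- endpoint
  list(estimate = est, km = km)
}

#' Frequentist sensitivity analysis of HFD-90
#'
#' Recapitulates the primary ordinal analysis with a frequentist
#' proportional-odds fit (`MASS::polr`) under any of the prespecified
#' contrast sets. Following the trial's frequentist convention, the
#' reported OR is oriented so that OR > 1 means higher odds of *more*
#' hospital-free days (the reciprocal of the Bayesian mpOR orientation).
#'
#' @param cohort analysis data.frame with `hfd90`.
#' @param contrast contrast-set name or factor.
#' @param collapse_map collapsing map for the ordinal outcome.
#' @return data.frame of OR rows per non-reference group.
#' @export
fit_hfd_freq <- function(cohort, contrast = "pooled_metformin_vs_placebo",
                         collapse_map = hfd_collapse_map()) {
  g <- if (is.factor(contrast)) contrast else
    contrast_groups(cohort, contrast)
  ycat <- collapse_map[as.character(cohort$hfd90)]
  ok <- !is.na(ycat) & !is.na(g)
  y <- factor(ycat[ok], levels = sort(unique(ycat[ok])), ordered = TRUE)
  g <- droplevels(g[ok])
  fit <- MASS::polr(y ~ g, Hess = TRUE)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit))[seq_along(cf)])
  out <- do.call(rbind, lapply(seq_along(cf), function(i) {
    r <- wald_estimate(cf[i], se[i], "OR", benefit_negative = FALSE)
    r$group <- sub("^g", "", names(cf)[i])
    r
  }))
  out$reference <- levels(g)[1]
  out$significant <- out$one_sided_p < 0.025
  rownames(out) <- NULL
  out
}

#' Exploratory subgroup analyses
#'
#' Re-runs the pooled metformin-vs-placebo comparison of a binary
#' endpoint within each level of a baseline factor (age split at the
#' cohort median, sex, frailty category, surgical stratum, operative
#' stress). No multiplicity adjustment is applied - the analyses are
#' exploratory and flagged as such; empty or single-arm levels are
#' skipped with a warning.
#'
#' @param cohort analysis data.frame.
#' @param factor_name one of `"age_median_split"`, `"sex"`,
#'   `"frailty_category"`, `"surgical_stratum"`, `"operative_stress"`.
#' @param endpoint binary endpoint column name.
#' @return data.frame of per-level estimates with an `exploratory` flag.
#' @export
subgroup_suite <- function(cohort, factor_name = "age_median_split",
                           endpoint = "reoperation_90") {
  f <- if (factor_name == "age_median_split") {
    med <- stats::median(cohort$age)
    factor(ifelse(cohort$age < med, sprintf("<%g", med),
                  sprintf(">=%g", med)),
           levels = c(sprintf("<%g", med), sprintf(">=%g", med)))
  } else {
    factor(cohort[[factor_name]])
  }
  out <- list()
  for (lev in levels(f)) {
    sub <- cohort[f == lev, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("subgroup level '", lev, "' is empty; skipped")
      next
    }
    g <- contrast_groups(sub, "pooled_metformin_vs_placebo")
    if (nlevels(droplevels(g)) < 2 ||
        length(unique(sub[[endpoint]])) < 2) {
      warning("subgroup level '", lev,
              "' lacks both arms or any outcome variation; skipped")
      next
    }
    r <- fit_binary_endpoint(sub, endpoint, "pooled_metformin_vs_placebo")
    r$subgroup <- factor_name; r$level <- lev
    out[[lev]] <- r
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) {
    rownames(res) <- NULL
    res$exploratory <- TRUE
  }
  res
}
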