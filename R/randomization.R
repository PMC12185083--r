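#' Allocation weights across placebo and the three metformin doses
#'
#' The design allocates sqrt(3):1:1:1 to placebo : 500 mg : 1000 mg :
#' 1500 mg, giving placebo probability sqrt(3)/(sqrt(3)+3) ~ 0.36603.
#' The sqrt(3) placebo weight keeps the placebo arm's information share
#' near-optimal for multiple treatment-vs-placebo comparisons.
#'
#' @param placebo,dose500,dose1000,dose1500 nonnegative weights.
#' @return named numeric vector of class `allocation_weights`.
#' @export
allocation_weights <- function(placebo = sqrt(3), dose500 = 1,
                               dose1000 = 1, dose1500 = 1) {
  w <- c(placebo = placebo, `500` = dose500, `1000` = dose1000,
         `1500` = dose1500)
  if (any(!is.finite(w)) || any(w < 0))
    stop("allocation weights must be finite and nonnegative", call. = FALSE)
  structure(w, class = "allocation_weights")
}

#' Normalize allocation weights to arm probabilities
#'
#' @param weights an [allocation_weights()] vector (dropped arms carry
#'   weight 0 and receive probability 0).
#' @return probability vector over (placebo, 500, 1000, 1500) summing to
#'   1 within 1e-12.
#' @export
allocation_probabilities <- function(weights) {
  s <- sum(weights)
  if (s <= 0) stop("design error: all allocation weights are zero",
                   call. = FALSE)
  p <- as.numeric(weights) / s
  names(p) <- names(weights)
  p
}

#' Duration stratum implied by the planned pre-operative lead time
#'
#' Patients are stratified by the window between enrolment and surgery:
#' short 7-28 days, medium 29-90 days, long >90 days. Lead times below 7
#' days are ineligible (insufficient minimum exposure).
#'
#' @param lead_days integer vector of planned lead times in days.
#' @return character vector over `"short"/"medium"/"long"`.
#' @export
duration_stratum <- function(lead_days) {
  if (any(lead_days < 7))
    stop("eligibility error: planned lead time below 7 days", call. = FALSE)
  ifelse(lead_days <= 28, "short", ifelse(lead_days <= 90, "medium", "long"))
}

age_category <- function(age, cci) {
  ifelse(age >= 60, ">=60", "<60 with CCI>2")
}

#' Randomize patients to arms
#'
#' Assigns each patient to placebo or a metformin dose using the current
#' allocation weights, stratified by enrolment clinic, age category and
#' duration stratum. Two mechanisms are available: `"blocks"` uses
#' stratified permuted blocks with the rational approximation 7:4:4:4
#' (block size 19; |7/19 - sqrt(3)/(sqrt(3)+3)| < 0.003), which bounds
#' within-stratum imbalance; `"weighted"` draws each arm independently
#' with the normalized weight probabilities and supports arbitrary
#' (e.g. response-adapted) weights. Blocks automatically fall back to
#' weighted draws when the weights are not the default ratio.
#'
#' @param patients patient data.frame (needs `age`, `cci`, `clinic_id`,
#'   `planned_lead_time_days`).
#' @param weights an [allocation_weights()] vector.
#' @param method `"blocks"` or `"weighted"`.
#' @param seed optional seed.
#' @return assignment data.frame: `patient_id`, `arm`,
#'   `duration_stratum`, `strata_key`, and the weight snapshot columns
#'   `w_placebo`..`w_1500`.
#' @export
assign_arms <- function(patients, weights = allocation_weights(),
                        method = c("blocks", "weighted"), seed = NULL) {
  method <- match.arg(method)
  n <- nrow(patients)
  if (n > 0 && any(patients$age < 60 & patients$cci <= 2))
    stop("eligibility error: patient under 60 with CCI <= 2", call. = FALSE)
  dur <- duration_stratum(patients$planned_lead_time_days)
  key <- paste(patients$clinic_id,
               age_category(patients$age, patients$cci), dur, sep = "|")
  probs <- allocation_probabilities(weights)
  default_ratio <- isTRUE(all.equal(as.numeric(weights) / sum(weights),
                                    c(sqrt(3), 1, 1, 1) / (sqrt(3) + 3)))
  with_seed_if(seed, {
    arm <- character(n)
    if (method == "blocks" && default_ratio) {
      block <- c(rep("placebo", 7), rep("500", 4), rep("1000", 4),
                 rep("1500", 4))
      for (k in unique(key)) {
        idx <- which(key == k)
        seq_arm <- character(0)
        while (length(seq_arm) < length(idx))
          seq_arm <- c(seq_arm, sample(block))
        arm[idx] <- seq_arm[seq_along(idx)]
      }
    } else {
      arm <- sample(ARMS, n, replace = TRUE, prob = probs)
    }
    data.frame(patient_id = patients$patient_id, arm = arm,
               duration_stratum = dur, strata_key = key,
               w_placebo = probs[["placebo"]], w_500 = probs[["500"]],
               w_1000 = probs[["1000"]], w_1500 = probs[["1500"]],
               stringsAsFactors = FALSE)
  })
}

#' Response-adaptive update of the allocation weights
#'
#' Implements the interim weight-update rule: dose arms whose status is
#' futile or inferior are dropped (weight 0, never re-activated);
#' remaining dose weights are proportional to `p_best^exponent`, where
#' `p_best` is each dose's posterior probability of being the best
#' metformin dose (exponent 0.5 by default, a standard damping choice);
#' and the placebo weight is held at sqrt(3) times the mean active-dose
#' weight so the comparator keeps its information share. If no dose arm
#' remains active the function returns a platform-stop signal rather than
#' weights.
#'
#' @param current an [allocation_weights()] vector (dose entries equal to
#'   0 are treated as previously dropped).
#' @param posteriors data.frame with columns `dose`, `p_best` and
#'   `status` (from [decide()]), one row per dose.
#' @param exponent damping exponent on `p_best`.
#' @return updated [allocation_weights()], or a list
#'   `list(platform_stop = TRUE)` when every dose has been dropped.
#' @export
update_weights <- function(current, posteriors, exponent = 0.5) {
  w <- as.numeric(current)
  names(w) <- names(current)
  active <- names(w)[-1][w[-1] > 0]
  drop <- posteriors$dose[posteriors$status %in% c("futile", "inferior")]
  active <- setdiff(active, drop)
  if (length(active) == 0) return(list(platform_stop = TRUE))
  pb <- posteriors$p_best[match(active, posteriors$dose)]
  pb[is.na(pb)] <- 1 / length(active)
  nw <- pb^exponent
  nw <- nw / mean(nw)          # mean active-dose weight = 1
  out <- allocation_weights(0, 0, 0, 0)
  out[active] <- nw
  out["placebo"] <- sqrt(3) * mean(nw)
  out
}
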