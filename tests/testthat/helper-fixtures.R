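# Shared fixtures and independent oracles used across the suite.

# Build a one-row hospital-course table by hand.
make_course <- function(discharge = NA_integer_, readm = NULL,
                        death = NA_integer_, reop = NA_integer_,
                        morb = NA_integer_, surgery = TRUE, id = "X1") {
  df <- data.frame(patient_id = id, surgery_performed = surgery,
                   discharge_day = as.integer(discharge),
                   reoperation_day = as.integer(reop),
                   death_day = as.integer(death),
                   morbidity_day = as.integer(morb),
                   stringsAsFactors = FALSE)
  df$readmissions <- list(readm)
  df
}

# Brute-force day-grid oracle for HFD-90: walk days 0..89 and count the
# days alive and out of hospital, independent of interval arithmetic.
oracle_hfd90 <- function(course) {
  if (!isTRUE(course$surgery_performed[1])) return(NA_integer_)
  if (!is.na(course$death_day[1])) return(-1L)
  d <- course$discharge_day[1]
  if (is.na(d)) return(0L)
  rd <- course$readmissions[[1]]
  out <- 0L
  for (day in 0:89) {
    in_hosp <- day < d
    if (!is.null(rd) && nrow(rd) > 0)
      for (r in seq_len(nrow(rd)))
        if (day >= rd[r, 1] && day < rd[r, 2]) in_hosp <- TRUE
    if (!in_hosp) out <- out + 1L
  }
  out
}

# Random valid course for property tests.
random_course <- function() {
  u <- runif(1)
  if (u < 0.08) return(make_course(death = sample(0:90, 1)))
  if (u < 0.13) return(make_course())            # never discharged
  d <- sample(0:60, 1)
  rd <- NULL
  n_int <- sample(0:3, 1)
  if (n_int > 0) {
    pts <- sort(sample(d:90, 2 * n_int, replace = TRUE))
    s <- pts[seq(1, 2 * n_int, by = 2)]
    e <- pts[seq(2, 2 * n_int, by = 2)]
    keep <- s < e
    if (n_int > 1) keep <- keep & c(TRUE, s[-1] >= e[-n_int])
    if (any(keep)) rd <- cbind(start = s[keep], end = e[keep])
  }
  make_course(discharge = d, readm = rd)
}

# Hand product-limit estimator (Kaplan-Meier oracle).
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Generate a randomized analysis cohort with a given effect scenario.
make_hfd_data <- function(n, scenario, seed, arms = ARMS_ALL,
                          probs = NULL, config = cohort_config()) {
  set.seed(seed)
  cfg <- config
  cfg$n_patients <- as.integer(n)
  cfg$seed <- NULL
  pts <- generate_cohort(cfg)
  arm <- sample(arms, n, replace = TRUE, prob = probs)
  asg <- data.frame(patient_id = pts$patient_id, arm = arm,
                    duration_stratum = pts$duration_stratum,
                    stringsAsFactors = FALSE)
  crs <- generate_courses(pts, asg, scenario, cfg)
  d <- data.frame(hfd90 = compute_hfd90(crs), arm = arm,
                  duration_stratum = pts$duration_stratum,
                  surgical_stratum = pts$surgical_stratum,
                  age = pts$age, sex = pts$sex,
                  stringsAsFactors = FALSE)
  d[crs$surgery_performed, , drop = FALSE]
}

ARMS_ALL <- c("placebo", "500", "1000", "1500")
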