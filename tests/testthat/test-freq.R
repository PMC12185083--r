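make_binary_cohort <- function(events_t, n_t, events_p, n_p) {
  data.frame(
    arm = c(rep("1000", n_t), rep("placebo", n_p)),
    duration_stratum = "short",
    reoperation_90 = c(rep(TRUE, events_t), rep(FALSE, n_t - events_t),
                       rep(TRUE, events_p), rep(FALSE, n_p - events_p)),
    stringsAsFactors = FALSE)
}

test_that("logistic OR equals the 2x2 cross-product ratio", {
  coh <- make_binary_cohort(28, 196, 15, 106)
  r <- fit_binary_endpoint(coh, "reoperation_90",
                           "pooled_metformin_vs_placebo")
  oracle <- (28 * (106 - 15)) / ((196 - 28) * 15)
  expect_equal(r$estimate, oracle, tolerance = 1e-9)
  expect_false(r$continuity_corrected)
  # equal rates with balanced counts: OR exactly 1
  coh2 <- make_binary_cohort(10, 50, 10, 50)
  r2 <- fit_binary_endpoint(coh2, "reoperation_90",
                            "pooled_metformin_vs_placebo")
  expect_equal(r2$estimate, 1, tolerance = 1e-9)
  # exhaustive small tables
  set.seed(701)
  for (i in 1:25) {
    a <- sample(1:9, 1); b <- sample(1:9, 1)
    c_ <- sample(1:9, 1); d <- sample(1:9, 1)
    coh3 <- make_binary_cohort(a, a + b, c_, c_ + d)
    r3 <- fit_binary_endpoint(coh3, "reoperation_90",
                              "pooled_metformin_vs_placebo")
    expect_equal(r3$estimate, (a * d) / (b * c_), tolerance = 1e-9)
  }
})

test_that("zero cells fall back to the continuity-corrected estimate", {
  coh <- make_binary_cohort(0, 60, 5, 60)
  r <- fit_binary_endpoint(coh, "reoperation_90",
                           "pooled_metformin_vs_placebo")
  expect_true(r$continuity_corrected)
  expect_true(is.finite(r$estimate) && is.finite(r$ci_low))
  coh0 <- make_binary_cohort(0, 60, 0, 60)
  expect_error(fit_binary_endpoint(coh0, "reoperation_90"),
               "no events")
})

test_that("the logistic estimator is consistent for a known odds ratio", {
  set.seed(702)
  n <- 60000
  x <- rbinom(n, 1, 0.5)
  p <- plogis(qlogis(0.10) + log(1.45) * x)
  coh <- data.frame(arm = ifelse(x == 1, "1000", "placebo"),
                    duration_stratum = "short",
                    readmission_90 = runif(n) < p,
                    stringsAsFactors = FALSE)
  r <- fit_binary_endpoint(coh, "readmission_90",
                           "pooled_metformin_vs_placebo")
  expect_lt(abs(r$estimate - 1.45), 0.05)
  expect_true(r$ci_low < 1.45 && 1.45 < r$ci_high)
})

test_that("one-sided p < 0.025 agrees with the two-sided CI exclusion", {
  set.seed(703)
  for (i in 1:20) {
    or <- sample(c(0.5, 0.8, 1, 1.3), 1)
    n <- 3000
    x <- rbinom(n, 1, 0.5)
    p <- plogis(qlogis(0.12) + log(or) * x)
    coh <- data.frame(arm = ifelse(x == 1, "1000", "placebo"),
                      duration_stratum = "short",
                      morbidity_90 = runif(n) < p,
                      stringsAsFactors = FALSE)
    r <- fit_binary_endpoint(coh, "morbidity_90",
                             "pooled_metformin_vs_placebo")
    expect_equal(r$one_sided_p < 0.025, r$ci_high < 1)
  }
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # five-patient worked example
  coh <- data.frame(arm = "1000", duration_stratum = "short",
                    reoperation_90 = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                    reoperation_time = c(2, 4, NA, 7, NA),
                    censor_day = c(90, 90, 4, 90, 90),
                    stringsAsFactors = FALSE)
  coh$tte_excluded <- FALSE
  g <- factor(rep("all", 5))
  km <- fit_time_to_event(coh, "reoperation_90", g,
                          withdrawn = "censor")$km
  expect_equal(km$survival[km$time == 2], 0.8)
  expect_equal(km$survival[km$time == 4][1], 0.6)
  expect_equal(km$survival[km$time == 7], 0.3)
  # all event/censor patterns with up to 6 patients, with ties
  times_pool <- c(1, 2, 2, 3, 3, 3)
  for (n in 2:6) {
    tms <- times_pool[1:n]
    for (mask in 1:(2^n - 1)) {
      ev <- as.integer(intToBits(mask)[1:n])
      oracle <- km_oracle(tms, ev)
      sf <- survival::survfit(survival::Surv(tms, ev) ~ 1)
      got <- summary(sf, times = oracle$time)$surv
      expect_equal(got, oracle$survival, tolerance = 1e-12)
    }
  }
})

test_that("Cox model: label symmetry, consistency, zero-event handling", {
  # identical groups give HR = 1
  base <- data.frame(arm = "1000", duration_stratum = "short",
                     reoperation_90 = rep(c(TRUE, FALSE), 25),
                     reoperation_time = rep(c(10, NA), 25),
                     censor_day = 90, tte_excluded = FALSE,
                     stringsAsFactors = FALSE)
  base$reoperation_time[base$reoperation_90] <-
    seq_len(sum(base$reoperation_90)) * 3
  two <- rbind(base, base)
  g <- factor(rep(c("A", "B"), each = nrow(base)), levels = c("A", "B"))
  r <- fit_time_to_event(two, "reoperation_90", g)$estimate
  expect_lt(abs(r$estimate - 1), 1e-6)
  # consistency against an exponential-hazard oracle, HR = 1.37
  set.seed(704)
  n <- 40000
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.004 * 1.37^x)
  ev <- t_ev <= 90
  coh <- data.frame(arm = ifelse(x == 1, "1000", "placebo"),
                    duration_stratum = "short",
                    reoperation_90 = ev,
                    reoperation_time = ifelse(ev, t_ev, NA),
                    censor_day = 90, tte_excluded = FALSE,
                    stringsAsFactors = FALSE)
  r2 <- fit_time_to_event(coh, "reoperation_90",
                          "pooled_metformin_vs_placebo")$estimate
  expect_lt(abs(r2$estimate - 1.37), 0.05)
  # no events anywhere: flagged, not a crash
  coh0 <- coh[1:100, ]
  coh0$reoperation_90 <- FALSE
  coh0$reoperation_time <- NA
  r0 <- fit_time_to_event(coh0, "reoperation_90",
                          "pooled_metformin_vs_placebo")$estimate
  expect_true(r0$no_events)
  expect_true(is.na(r0$estimate))
})

test_that("withdrawn patients are excluded from time-to-event by default", {
  coh <- data.frame(arm = rep(c("1000", "placebo"), each = 20),
                    duration_stratum = "short",
                    reoperation_90 = rep(c(TRUE, FALSE), 20),
                    reoperation_time = rep(c(15, NA), 20),
                    censor_day = 90,
                    tte_excluded = c(rep(TRUE, 5), rep(FALSE, 35)),
                    stringsAsFactors = FALSE)
  out <- fit_time_to_event(coh, "reoperation_90",
                           "pooled_metformin_vs_placebo")
  expect_equal(sum(out$estimate$n), 35)
})

test_that("contrast sets partition the cohort", {
  d <- make_hfd_data(2000, scenario_null(), seed = 705)
  for (ct in c("pooled_metformin_vs_placebo", "by_dose", "by_duration",
               "lowdose_short_vs_rest")) {
    g <- contrast_groups(d, ct)
    expect_equal(length(g), nrow(d))
    expect_false(any(is.na(g)))
  }
  g4 <- contrast_groups(d, "lowdose_short_vs_rest")
  expect_setequal(levels(g4), c("placebo", "lowdose_short",
                                "other_treatment"))
  expect_true(all(g4[d$arm == "500" & d$duration_stratum == "short"] ==
                    "lowdose_short"))
})

test_that("subgroup suite splits at the cohort median age", {
  set.seed(706)
  n <- 4000
  age <- round(rnorm(n, 67, 6))
  x <- rbinom(n, 1, 0.5)
  below <- age < median(age)
  # benefit (higher event odds for placebo) only below the median age
  p <- plogis(qlogis(0.3) + ifelse(below, log(2.5), 0) * x)
  coh <- data.frame(arm = ifelse(x == 1, "1000", "placebo"),
                    duration_stratum = "short", age = age,
                    reoperation_90 = runif(n) < p,
                    stringsAsFactors = FALSE)
  res <- subgroup_suite(coh, "age_median_split", "reoperation_90")
  expect_equal(nrow(res), 2)
  expect_true(all(res$exploratory))
  below_or <- res$estimate[grepl("^<", res$level)]
  above_or <- res$estimate[grepl("^>=", res$level)]
  expect_gt(below_or, above_or)
  # constant factor degenerates to the main analysis
  coh$one <- "all"
  res1 <- subgroup_suite(coh, "one", "reoperation_90")
  expect_equal(nrow(res1), 1)
  main <- fit_binary_endpoint(coh, "reoperation_90",
                              "pooled_metformin_vs_placebo")
  expect_equal(res1$estimate, main$estimate)
})
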