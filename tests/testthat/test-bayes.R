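test_that("posterior centres on the null under a null effect", {
  d <- make_hfd_data(10000, scenario_null(), seed = 601,
                     arms = c("placebo", "1000"))
  fit <- fit_hfd_model(d, engine = "laplace", seed = 602)
  s <- fit$summaries
  mpor <- s$mpOR[s$type == "dose" & s$dose == "1000"]
  expect_lt(abs(mpor - 1), 0.1)
  psup <- s$p_superior[s$type == "dose" & s$dose == "1000"]
  expect_gt(psup, 0.05)
  expect_lt(psup, 0.95)
})

test_that("a known proportional-odds effect is recovered", {
  sc <- scenario_uniform15(best_dose = "1000", por = 0.74)
  d <- make_hfd_data(8000, sc, seed = 603, arms = c("placebo", "1000"))
  fit <- fit_hfd_model(d, engine = "laplace", seed = 604)
  s <- fit$summaries[fit$summaries$type == "dose" &
                       fit$summaries$dose == "1000", ]
  expect_gt(s$cri_high, 0.74 * 0.9)
  expect_lt(s$cri_low, 0.74 * 1.1)
  expect_gt(s$p_superior, 0.99)
})

test_that("two-category data reduce to logistic regression", {
  set.seed(605)
  n <- 8000
  arm <- sample(c("placebo", "1000"), n, replace = TRUE)
  p <- ifelse(arm == "1000", 0.55, 0.45)   # P(best category)
  y <- ifelse(runif(n) < p, 90L, -1L)
  d <- data.frame(hfd90 = y, arm = arm, duration_stratum = "short",
                  surgical_stratum = "general")
  fit <- fit_hfd_model(d, engine = "laplace", seed = 606)
  cell <- fit$summaries[fit$summaries$label == "1000:short", ]
  ref <- glm(I(y == -1) ~ I(arm == "1000"), family = binomial())
  or_ref <- exp(coef(ref)[2])              # odds of the worse category
  expect_lt(abs(log(cell$mpOR) - log(or_ref)), 0.1)
})

test_that("decision rules use strict thresholds and resolve the platform", {
  s <- data.frame(dose = c("500", "1000", "1500"),
                  p_superior = c(0.98, 0.975, 0.4),
                  p_best = c(0.6, 0.3, 0.1), stringsAsFactors = FALSE)
  dec <- decide(s, decision_thresholds())
  expect_equal(dec$arms$status, c("superior", "continue", "continue"))
  expect_equal(dec$platform, "superior")
  s$p_superior <- c(0.05, 0.02, 0.09)
  dec2 <- decide(s, decision_thresholds())
  expect_equal(dec2$arms$status, c("futile", "inferior", "futile"))
  expect_equal(dec2$platform, "stopped_futility")
  s$p_superior <- c(0.5, 0.6, 0.7)
  expect_equal(decide(s, decision_thresholds())$platform, "continue")
})

test_that("cutpoints stay ordered so cumulative probabilities are monotone", {
  d <- make_hfd_data(3000, scenario_uniform15(), seed = 607)
  fit <- fit_hfd_model(d, engine = "laplace", seed = 608)
  K <- length(fit$kept_categories)
  z <- fit$mode[seq_len(K - 1)]
  gamma <- cumsum(c(z[1], exp(z[-1])))
  expect_true(all(diff(gamma) > 0))
  # any draw's implied cumulative curve is increasing across categories
  eta <- fit$draws[1:50, "1000:short"]
  for (e in eta)
    expect_true(all(diff(plogis(gamma + e)) > 0))
})

test_that("Bayesian mpOR and frequentist OR are reciprocal orientations", {
  sc <- effect_scenario(matrix(0.8, 3, 3), label = "uniform-strong")
  d <- make_hfd_data(12000, sc, seed = 609)
  fit <- fit_hfd_model(d, engine = "laplace", seed = 610)
  mpor <- fit$summaries$mpOR[fit$summaries$type == "overall"]
  fr <- fit_hfd_freq(d, "pooled_metformin_vs_placebo")
  expect_lt(abs(mpor * fr$estimate - 1), 0.1)
})

test_that("hierarchical scales control shrinkage of cell effects", {
  m <- matrix(1, 3, 3, dimnames = list(c("500", "1000", "1500"),
                                       c("short", "medium", "long")))
  m["1000", ] <- 0.7                      # one clearly different dose
  d <- make_hfd_data(6000, effect_scenario(m), seed = 611)
  tight <- fit_hfd_model(d, priors = hfd_priors(tau_scale = 0.05),
                         seed = 612)
  loose <- fit_hfd_model(d, priors = hfd_priors(tau_scale = 3),
                         seed = 612)
  spread <- function(f) {
    s <- f$summaries[f$summaries$type == "dose", ]
    diff(range(log(s$mpOR)))
  }
  expect_lt(spread(tight), spread(loose))
})

test_that("duration-restricted effects surface in the sensitivity model", {
  m <- matrix(1, 3, 3, dimnames = list(c("500", "1000", "1500"),
                                       c("short", "medium", "long")))
  m[, "medium"] <- 0.7
  d <- make_hfd_data(9000, effect_scenario(m), seed = 613)
  s <- sensitivity_duration_model(d, engine = "laplace", seed = 614)
  expect_equal(s$duration[which.min(s$mpOR)], "medium")
  expect_gt(s$p_superior[s$duration == "medium"],
            max(s$p_superior[s$duration != "medium"]))
})

test_that("degenerate inputs fail with informative errors", {
  d <- data.frame(hfd90 = rep(88L, 100),
                  arm = rep(c("placebo", "1000"), 50),
                  duration_stratum = "short", surgical_stratum = "general")
  expect_error(fit_hfd_model(d), "single outcome category")
  d2 <- data.frame(hfd90 = rep(c(-1L, 0L, 88L, 90L), 25),
                   arm = rep("placebo", 100),
                   duration_stratum = "short",
                   surgical_stratum = "general")
  expect_error(fit_hfd_model(d2), "two arms")
  d3 <- data.frame(hfd90 = c(rep(-1L, 50), rep(90L, 50)),
                   arm = rep(c("placebo", "1000"), each = 50),
                   duration_stratum = "short", surgical_stratum = "general")
  expect_error(fit_hfd_model(d3), "non-overlapping")
})

test_that("cells without data are flagged as prior-dominated", {
  d <- make_hfd_data(2000, scenario_null(), seed = 615,
                     arms = c("placebo", "1000"))
  d <- d[d$arm == "placebo" | d$duration_stratum == "short", ]
  fit <- fit_hfd_model(d, seed = 616)
  s <- fit$summaries
  expect_true(all(s$prior_dominated[s$type == "cell" &
                                      s$dose == "1000" &
                                      s$duration != "short"]))
  expect_false(any(s$prior_dominated[s$label == "1000:short"]))
})

test_that("MCMC engine agrees with the Laplace approximation", {
  d <- make_hfd_data(2500, scenario_uniform15(), seed = 617)
  fl <- fit_hfd_model(d, engine = "laplace", seed = 618)
  fm <- fit_hfd_model(d, engine = "mcmc", seed = 618, ndraws = 12000)
  expect_lte(fm$diagnostics$rhat, 1.05)
  sl <- fl$summaries[fl$summaries$type == "dose", ]
  sm <- fm$summaries[fm$summaries$type == "dose", ]
  expect_lt(max(abs(log(sl$mpOR) - log(sm$mpOR))), 0.15)
  expect_lt(max(abs(sl$p_superior - sm$p_superior)), 0.2)
  # identical decisions at the trial's threshold
  expect_equal(decide(fl)$platform, decide(fm)$platform)
})

test_that("posterior predictive exceedance curves track the data", {
  d <- make_hfd_data(6000, scenario_null(), seed = 619)
  fit <- fit_hfd_model(d, seed = 620)
  pp <- ppc_exceedance(fit, d)
  expect_true(all(c("observed", "predicted") %in% names(pp)))
  agg <- tapply(abs(pp$observed - pp$predicted), pp$arm, max)
  expect_true(all(agg < 0.08))
})
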