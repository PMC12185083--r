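test_that("configured stratum and duration mixes are reproduced", {
  cfg <- cohort_config(n_patients = 10000, seed = 301)
  pts <- generate_cohort(cfg)
  props <- prop.table(table(pts$surgical_stratum))
  expect_true(all(abs(props[names(cfg$stratum_mix)] -
                        cfg$stratum_mix) < 0.02))
  dprops <- prop.table(table(pts$duration_stratum))
  expect_true(all(abs(dprops[names(cfg$duration_mix)] -
                        cfg$duration_mix) < 0.02))
  expect_true(all(pts$age >= 60 | pts$cci > 2))
  expect_true(all(pts$planned_lead_time_days >= 7))
})

test_that("generation is deterministic under a seed and handles n = 0", {
  cfg <- cohort_config(n_patients = 500, seed = 302)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg0 <- cohort_config(n_patients = 0)
  expect_equal(nrow(generate_cohort(cfg0)), 0)
  # whole-pipeline determinism: identical course tables too
  pts <- generate_cohort(cfg)
  asg <- data.frame(patient_id = pts$patient_id, arm = "placebo",
                    duration_stratum = pts$duration_stratum)
  c1 <- generate_courses(pts, asg, scenario_null(), cfg, seed = 9)
  c2 <- generate_courses(pts, asg, scenario_null(), cfg, seed = 9)
  expect_identical(c1, c2)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(stratum_mix = c(spine = 0.5, general = 0.4,
                                             colorectal = 0.2, other = 0.2)),
               "stratum_mix")
  expect_error(cohort_config(nonadherence_prob = 1.4), "nonadherence_prob")
  expect_error(cohort_config(withdrawal_prob = 0.3,
                             nonadherence_prob = 0.1), "withdrawal_prob")
})

test_that("null placebo cohort reproduces the calibrated HFD-90 summary", {
  cfg <- cohort_config(n_patients = 20000, seed = 303)
  pts <- generate_cohort(cfg)
  asg <- data.frame(patient_id = pts$patient_id, arm = "placebo",
                    duration_stratum = pts$duration_stratum)
  crs <- generate_courses(pts, asg, scenario_null(), cfg, seed = 304)
  h <- compute_hfd90(crs)[crs$surgery_performed]
  expect_equal(median(h), 88)
  q <- quantile(h, c(0.25, 0.75))
  expect_true(abs(q[[1]] - 85) <= 1)
  expect_true(abs(q[[2]] - 90) <= 1)
  # spine/colorectal run worse than general surgery
  med_by <- tapply(h, pts$surgical_stratum[crs$surgery_performed], median)
  expect_true(med_by[["spine"]] < med_by[["general"]])
  expect_true(med_by[["colorectal"]] < med_by[["general"]])
})

test_that("proportional-odds shift: identity, dominance, sampled CDF", {
  cfg <- cohort_config()
  p0 <- hfd_baseline_probs(cfg, "general")
  expect_equal(po_shift_probs(p0, 1), p0)
  # favorable shift stochastically dominates the baseline at every cut
  p_shift <- po_shift_probs(p0, 0.5)
  exceed <- function(p) rev(cumsum(rev(p)))
  expect_true(all(exceed(p_shift) >= exceed(p0) - 1e-12))
  # sampled outcomes match the analytic shifted CDF (brute-force oracle)
  sc <- effect_scenario(matrix(0.5, 3, 3), label = "strong")
  cfg2 <- cohort_config(n_patients = 50000, seed = 305,
                        surgery_prob = 1)
  pts <- generate_cohort(cfg2)
  asg <- data.frame(patient_id = pts$patient_id, arm = "1000",
                    duration_stratum = pts$duration_stratum)
  crs <- generate_courses(pts, asg, sc, cfg2, seed = 306)
  h <- compute_hfd90(crs)
  gen <- pts$surgical_stratum == "general"
  emp_cdf <- cumsum(tabulate(h[gen] + 2L, nbins = 92) / sum(gen))
  ana_cdf <- cumsum(po_shift_probs(p0, 0.5))
  expect_lt(max(abs(emp_cdf - ana_cdf)), 0.015)
})

test_that("a null-effect arm is indistinguishable from placebo", {
  cfg <- cohort_config(n_patients = 20000, seed = 307, surgery_prob = 1)
  pts <- generate_cohort(cfg)
  asg_p <- data.frame(patient_id = pts$patient_id, arm = "placebo",
                      duration_stratum = pts$duration_stratum)
  asg_t <- data.frame(patient_id = pts$patient_id, arm = "500",
                      duration_stratum = pts$duration_stratum)
  h_p <- compute_hfd90(generate_courses(pts, asg_p, scenario_null(), cfg,
                                        seed = 308))
  h_t <- compute_hfd90(generate_courses(pts, asg_t, scenario_null(), cfg,
                                        seed = 309))
  ks <- suppressWarnings(ks.test(h_p, h_t))
  expect_gt(ks$p.value, 0.01)
})

test_that("compliance marking hits configured rates and implications", {
  cfg <- cohort_config(n_patients = 50000, seed = 310)
  pts <- generate_cohort(cfg)
  asg <- data.frame(patient_id = pts$patient_id, arm = "placebo",
                    duration_stratum = pts$duration_stratum)
  crs <- generate_courses(pts, asg, scenario_null(), cfg, seed = 311)
  crs <- apply_compliance(crs, cfg, seed = 312)
  expect_lt(abs(mean(!crs$adherent) - 0.184), 0.01)
  expect_lt(abs(mean(crs$withdrew) - 0.067), 0.01)
  expect_true(all(!crs$adherent[crs$withdrew]))  # withdrawal => nonadherent
  cfg0 <- cohort_config(nonadherence_prob = 0, withdrawal_prob = 0)
  crs0 <- apply_compliance(crs[1:500, ], cfg0, seed = 1)
  expect_true(all(crs0$adherent))
  cfg1 <- cohort_config(nonadherence_prob = 1, withdrawal_prob = 1)
  crs1 <- apply_compliance(crs[1:500, ], cfg1, seed = 1)
  expect_true(all(crs1$withdrew) && all(!crs1$adherent))
})

test_that("generated hospital courses satisfy the structural invariants", {
  for (seed in c(401, 402)) {
    cfg <- cohort_config(n_patients = 400, seed = seed,
                         surgery_prob = if (seed == 401) 0.934 else 1)
    pts <- generate_cohort(cfg)
    arm <- sample(ARMS_ALL, 400, replace = TRUE)
    asg <- data.frame(patient_id = pts$patient_id, arm = arm,
                      duration_stratum = pts$duration_stratum)
    crs <- generate_courses(pts, asg, scenario_uniform15(), cfg,
                            seed = seed + 1)
    for (i in seq_len(nrow(crs)))
      expect_no_error(validate_course(crs[i, ]))
    h <- compute_hfd90(crs)
    expect_true(all(h[crs$surgery_performed] >= -1 &
                      h[crs$surgery_performed] <= 90))
  }
  expect_error(validate_course(make_course(discharge = 5,
                                           readm = cbind(2, 4))),
               "before discharge")
  expect_error(validate_course(make_course(death = 10, discharge = 20)),
               "after death")
})

test_that("unknown arms are rejected and tables round-trip through CSV", {
  cfg <- cohort_config(n_patients = 20, seed = 313)
  pts <- generate_cohort(cfg)
  asg <- data.frame(patient_id = pts$patient_id, arm = "750",
                    duration_stratum = pts$duration_stratum)
  expect_error(generate_courses(pts, asg, scenario_null(), cfg),
               "unknown arm")
  asg$arm <- "500"
  crs <- generate_courses(pts, asg, scenario_null(), cfg, seed = 1)
  tmp <- tempfile(fileext = ".csv")
  write_cohort_csv(crs, tmp)
  back <- read_cohort_csv(tmp)
  expect_equal(compute_hfd90(back), compute_hfd90(crs))
  tmp2 <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, tmp2)
  cfg2 <- read_cohort_config(tmp2)
  expect_equal(cfg2$stratum_mix, cfg$stratum_mix)
})
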