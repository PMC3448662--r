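test_that("per-infusion costs reproduce the hand-computed baselines", {
  # drug + (staff + indirect) x duration + devices [+ non-hospital]
  expect_equal(per_infusion_cost("IS", baseline, "hospital"), 60)
  expect_equal(per_infusion_cost("FCM", baseline, "hospital"), 225)
  expect_equal(per_infusion_cost("IS", baseline, "societal"), 70)
  expect_equal(per_infusion_cost("FCM", baseline, "societal"), 235)
  # zero-overhead limit: only the vial price remains
  p0 <- cost_parameters(staff_rate = 0, indirect_rate = 0, device_cost = 0,
                        nonhospital_cost = 0)
  expect_equal(per_infusion_cost("IS", p0, "hospital"), 23)
})

test_that("patient cost scales each component by the infusion count", {
  pat <- list(annual_dose_mg = 800)
  expect_equal(patient_cost(pat, "FCM", baseline, "hospital")$total, 225)
  expect_equal(patient_cost(pat, "IS", baseline, "hospital")$total, 240)
  expect_equal(patient_cost(pat, "IS", baseline, "societal")$total, 280)
  bd <- patient_cost(pat, "IS", baseline, "societal")
  expect_identical(bd$n_infusions, 4L)
  # breakdown additivity invariant
  expect_equal(bd$total,
               bd$drug + bd$staff + bd$indirect + bd$devices + bd$nonhospital,
               tolerance = 1e-12)
  hosp <- patient_cost(pat, "IS", baseline, "hospital")
  expect_equal(hosp$nonhospital, 0)
})

test_that("societal minus hospital equals the session cost times infusions", {
  set.seed(71)
  for (k in 1:20) {
    dose <- 200 * sample(1:26, 1)
    drug <- sample(c("IS", "FCM"), 1)
    soc <- patient_cost(list(annual_dose_mg = dose), drug, baseline, "societal")
    hosp <- patient_cost(list(annual_dose_mg = dose), drug, baseline, "hospital")
    expect_equal(soc$total - hosp$total,
                 baseline$nonhospital_cost * soc$n_infusions)
  }
})

test_that("cohort mean matches a brute-force per-patient sum", {
  set.seed(29)
  doses <- 200 * sample(1:26, 40, replace = TRUE)
  coh <- toy_cohort(doses)
  for (drug in c("IS", "FCM")) for (persp in c("hospital", "societal")) {
    brute <- mean(vapply(doses, function(d) {
      patient_cost(list(annual_dose_mg = d), drug, baseline, persp)$total
    }, numeric(1)))
    expect_equal(cohort_mean_cost(coh, drug, baseline, persp), brute)
    # linearity: (total infusions x per-infusion cost) / n
    n_inf <- sum(infusions_required(doses, drug))
    expect_equal(cohort_mean_cost(coh, drug, baseline, persp),
                 n_inf * per_infusion_cost(drug, baseline, persp) / length(doses))
  }
})

test_that("mean cost is non-decreasing in every unit cost and in doses", {
  coh <- toy_cohort(c(400, 1000, 2600, 5200))
  for (nm in ironcma:::VARIED_PARAMETERS) {
    lo_v <- cohort_mean_cost(coh, "IS", baseline, "societal")
    hi_p <- baseline
    hi_p[[nm]] <- hi_p[[nm]] + 5
    expect_gte(cohort_mean_cost(coh, "IS", hi_p, "societal"), lo_v)
  }
  bigger <- toy_cohort(c(600, 1000, 2600, 5200))
  expect_gt(cohort_mean_cost(bigger, "IS", baseline, "societal"),
            cohort_mean_cost(coh, "IS", baseline, "societal"))
})

test_that("incremental cost is zero under cost symmetry", {
  # dose 200: one infusion under either strategy; pick an IS vial price that
  # offsets the longer chair time so per-infusion totals coincide
  coh1 <- toy_cohort(200)
  p_eq <- cost_parameters(drug_price_is = 200 + (18 + 6) * (0.75 - 1.25),
                          drug_price_fcm = 200)
  expect_equal(incremental_cost(coh1, p_eq, "hospital"), 0)
  expect_gt(incremental_cost(load_fixture(), baseline, "societal"), 0)
})

test_that("invalid parameters and empty cohorts raise errors", {
  expect_error(cost_parameters(drug_price_is = -1), "non-negative")
  expect_error(cost_parameters(duration_is_h = 0), "positive")
  expect_error(parameter_bounds(drug_price_is = c(30, 40)), "baseline outside")
  expect_error(parameter_bounds(staff_rate = c(24, 12)), "lower bound")
  expect_error(parameter_bounds(badname = c(1, 2)), "unknown")
  expect_error(cohort_mean_cost(data.frame(patient_id = character(0),
                                           indication = character(0),
                                           annual_dose_mg = integer(0)),
                                "IS", baseline, "hospital"), "empty")
})

test_that("the per-patient cost table is consistent with patient_cost", {
  coh <- toy_cohort(c(800, 1400, 5200))
  tab <- cohort_cost_table(coh, baseline)
  expect_identical(nrow(tab), 3L * 2L * 2L)
  row <- tab[tab$patient_id == "T02" & tab$regimen == "FCM" &
               tab$perspective == "societal", ]
  expect_equal(row$total,
               patient_cost(list(annual_dose_mg = 1400), "FCM", baseline,
                            "societal")$total)
  expect_equal(tab$total, tab$drug + tab$staff + tab$indirect + tab$devices +
                 tab$nonhospital)
})
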