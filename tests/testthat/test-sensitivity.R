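fixture <- load_fixture()

test_that("one-way analysis traces the staff-rate line", {
  res <- one_way(fixture, baseline, table_bounds, "staff_rate",
                 n_points = 7, perspective = "societal")
  expect_identical(attr(res, "parameter"), "staff_rate")
  expect_true(all(res$value >= 12 & res$value <= 24))
  expect_true(all(is.finite(res$incremental)))
  # more staff time per IS course: incremental strictly increases
  expect_true(all(diff(res$incremental) > 0))
  # each grid point equals a direct incremental evaluation
  p <- baseline; p$staff_rate <- res$value[3]
  expect_equal(res$incremental[3], incremental_cost(fixture, p, "societal"))
})

test_that("FCM stays favoured at half the baseline staff cost", {
  p <- baseline
  p$staff_rate <- baseline$staff_rate / 2
  expect_gt(incremental_cost(fixture, p, "societal"), 0)
})

test_that("degenerate bounds give a constant one-way line", {
  res <- one_way(fixture, baseline, degenerate_bounds(), "device_cost",
                 n_points = 2, perspective = "societal")
  base_inc <- incremental_cost(fixture, baseline, "societal")
  expect_equal(res$incremental, rep(base_inc, 2))
})

test_that("one-way rejects unknown parameters and tiny grids", {
  expect_error(one_way(fixture, baseline, table_bounds, "duration_is_h"),
               "unknown parameter")
  expect_error(one_way(fixture, baseline, table_bounds, "staff_rate",
                       n_points = 1), "at least 2")
})

test_that("two-way grid classifies cells by sign of the incremental", {
  grid <- two_way_drug_prices(fixture, baseline,
                              is_prices = c(5, 23),
                              fcm_prices = c(80, 200),
                              perspective = "societal")
  expect_identical(dim(grid$incremental), c(2L, 2L))
  expect_identical(grid$favoured,
                   matrix(c("IS", "indifferent", "FCM")[sign(grid$incremental) + 2L],
                          nrow = 2, dimnames = dimnames(grid$incremental)))
  # baseline prices favour FCM; a cheap IS vial against full-price FCM does not
  expect_identical(grid$favoured["23", "200"], "FCM")
  expect_identical(grid$favoured["5", "200"], "IS")
  # exact tie reported as indifferent: 1 infusion each, equal totals
  tie <- two_way_drug_prices(toy_cohort(200),
                             cost_parameters(staff_rate = 0, indirect_rate = 0,
                                             device_cost = 0,
                                             nonhospital_cost = 0),
                             is_prices = 2, fcm_prices = 2,
                             perspective = "hospital")
  expect_identical(tie$favoured[1, 1], "indifferent")
  expect_error(two_way_drug_prices(fixture, baseline, is_prices = numeric(0)),
               "non-empty")
})

bisect_break_even <- function(cohort, params, perspective, parameter,
                              interval = c(-1000, 5000)) {
  stats::uniroot(function(v) {
    p <- params
    p[[parameter]] <- v
    incremental_cost(cohort, p, perspective)
  }, interval = interval, tol = 1e-10)$root
}

test_that("closed-form break-even prices agree with a root-finding oracle", {
  for (persp in c("societal", "hospital")) {
    be_is <- break_even_is_price(fixture, baseline, persp)
    expect_equal(be_is,
                 bisect_break_even(fixture, baseline, persp, "drug_price_is"),
                 tolerance = 1e-6)
    p <- baseline; p$drug_price_is <- be_is
    expect_lt(abs(incremental_cost(fixture, p, persp)), 1e-6)

    be_fcm <- break_even_fcm_price(fixture, baseline, persp)
    expect_equal(be_fcm,
                 bisect_break_even(fixture, baseline, persp, "drug_price_fcm"),
                 tolerance = 1e-6)
    p <- baseline; p$drug_price_fcm <- be_fcm
    expect_lt(abs(incremental_cost(fixture, p, persp)), 1e-6)
  }
})

test_that("break-even prices sit where the published thresholds say", {
  # societal IS threshold just under 10 EUR per 200 mg vial
  expect_equal(break_even_is_price(fixture, baseline, "societal"),
               135 * 235 / 557 - 47, tolerance = 1e-12)
  expect_lte(break_even_is_price(fixture, baseline, "societal"), 10)
  # hospital threshold is higher: fewer components offset the drug gap
  expect_equal(break_even_is_price(fixture, baseline, "hospital"),
               135 * 225 / 557 - 37, tolerance = 1e-12)
  # FCM threshold when IS drops to its lower bound: the 180 EUR region
  p5 <- baseline; p5$drug_price_is <- 5
  expect_equal(break_even_fcm_price(fixture, p5, "societal"),
               557 * 52 / 135 - 35, tolerance = 1e-12)
})

test_that("break-even is a fixed point when the base case is indifferent", {
  p <- baseline
  p$drug_price_is <- break_even_is_price(fixture, baseline, "societal")
  expect_equal(break_even_fcm_price(fixture, p, "societal"),
               baseline$drug_price_fcm)
})

test_that("single-patient break-even matches brute force", {
  coh <- toy_cohort(1000)  # 5 IS infusions vs 1 FCM infusion
  be <- break_even_is_price(coh, baseline, "societal")
  expect_equal(be, bisect_break_even(coh, baseline, "societal",
                                     "drug_price_is"), tolerance = 1e-6)
})
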