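test_that("OD growth rate follows the two-point formula on the control band", {
  tr <- tibble::tibble(time = c(0, 1), od680 = c(0.60, 0.66))
  est <- growth_rate_from_od(tr)
  expect_equal(est$mu, log(0.66 / 0.60), tolerance = 1e-12)
  expect_equal(est$mu, 0.0953, tolerance = 1e-3)
  flat <- tibble::tibble(time = 0:5, od680 = rep(0.62, 6))
  expect_equal(growth_rate_from_od(flat)$mu, 0)
})

test_that("noiseless turbidostat sawtooth round-trips the planted rate exactly", {
  tr <- simulate_turbidostat(0.05, duration = 60, seed = 1)
  expect_true(all(tr$od680 <= 0.66 + 1e-12))
  est <- growth_rate_from_od(tr)
  expect_gt(attr(est, "n_segments"), 10)
  expect_equal(attr(est, "mu_mean"), 0.05, tolerance = 1e-10)
  expect_equal(est$mu_ols, rep(0.05, nrow(est)), tolerance = 1e-10)
  # event-time segmentation agrees with drop detection
  est2 <- growth_rate_from_od(tr,
                              dilution_events = attr(tr, "dilution_events"))
  expect_equal(attr(est2, "mu_mean"), 0.05, tolerance = 1e-10)
})

test_that("OD trace guards: dilution inside an unsegmented window, bad OD", {
  tr <- simulate_turbidostat(0.05, duration = 60, seed = 1)
  expect_error(growth_rate_from_od(tr, segment = FALSE), "dilution")
  expect_error(growth_rate_from_od(tibble::tibble(time = 0:1,
                                                  od680 = c(0.6, 0))),
               "positive")
  expect_error(growth_rate_from_od(tr, window = c(0, 0.005)),
               "two samples")
})

test_that("medium-balance growth rate is the dilution rate", {
  expect_equal(growth_rate_from_balance(40, 400), 0.1)
  expect_equal(growth_rate_from_balance(0, 400), 0)
  expect_error(growth_rate_from_balance(40, 0), "> 0")
  # regression on a noisy depletion series recovers the planted rate
  set.seed(8)
  tt <- seq(0, 24, by = 0.25)
  bal <- tibble::tibble(time = tt, mass = 1000 - 40 * tt + rnorm(length(tt), 0, 2))
  mu_hat <- growth_rate_from_balance(bal, V = 400)
  expect_lt(abs(mu_hat - 0.1), 2 * attr(mu_hat, "se"))
})

test_that("gas-exchange slopes recover planted rates and GP = NP + R", {
  tr <- simulate_gas_trace(np = 1.61 / 3600, r_dark = 0.35 / 3600)
  rec <- gas_exchange_rates(tr)
  expect_equal(rec$np * 3600, 1.61, tolerance = 1e-9)
  expect_equal(rec$r_dark * 3600, 0.35, tolerance = 1e-9)
  expect_equal(rec$gp, rec$np + rec$r_dark)
  expect_equal(rec$gp * 3600, 1.96, tolerance = 1e-9)
  flat <- gas_exchange_rates(simulate_gas_trace(0, 0))
  expect_equal(c(flat$np, flat$r_dark, flat$gp), c(0, 0, 0))
  # noisy recovery within 2 standard errors
  trn <- simulate_gas_trace(np = 1.61 / 3600, r_dark = 0.35 / 3600,
                            n_cycles = 4, noise_sd = 0.02, seed = 4)
  recn <- gas_exchange_rates(trn)
  expect_lt(abs(recn$np - 1.61 / 3600), 2 * recn$np_se + 1e-9)
  expect_error(gas_exchange_rates(dplyr::select(tr, -phase)), "phase")
  # a positive dark slope flags and clamps respiration
  up <- tr
  up$do2[up$phase == "dark"] <- seq_len(sum(up$phase == "dark"))
  expect_warning(rec_up <- gas_exchange_rates(up), "clamped")
  expect_identical(rec_up$r_dark, 0)
  expect_true(rec_up$dark_slope_positive)
})

test_that("photosynthetic ratios reproduce printed values and mark undefined ones", {
  rec <- gas_exchange_record(np = 1.61, r_dark = 0.35, co2_uptake = 0.78)
  ratios <- photosynthesis_ratios(rec)
  expect_equal(ratios$p_r, 5.6, tolerance = 1e-3)
  expect_equal(ratios$pq, 2.1, tolerance = 0.02)
  expect_equal(photosynthesis_ratios(
    gas_exchange_record(np = 0.78, r_dark = 0.2, co2_uptake = 0.78))$pq, 1)
  und <- photosynthesis_ratios(gas_exchange_record(np = 1, r_dark = 0))
  expect_true(is.na(und$p_r))
  expect_true(is.na(und$pq))
})

test_that("nutrient balance flags exactly the deficient elements", {
  medium <- tibble::tibble(
    element = c("Na", "N", "S", "Ca", "Mg", "P", "Fe"),
    conc = c(18, 17.6, 0.3, 0.25, 0.3, 0.18, 0.02))
  quotas <- tibble::tibble(
    element = medium$element,
    quota = c(0.2, 8, 0.15, 0.05, 0.1, 0.4, 0.02))
  bal <- nutrient_balance(0.1, medium, quotas, biomass = 0.35)
  # P consumption (0.1 * 0.35 * 0.4 = 0.014) < refill (0.018): fine; push it
  quotas$quota[quotas$element == "P"] <- 0.6
  bal <- nutrient_balance(0.1, medium, quotas, biomass = 0.35)
  expect_identical(bal$element[bal$deficient], "P")
  # exact steady state has zero margin
  eq <- nutrient_balance(0.1, tibble::tibble(element = "N", conc = 1),
                         tibble::tibble(element = "N", quota = 1 / 0.35),
                         biomass = 0.35)
  expect_equal(eq$margin, 0)
  # doubling a quota decreases the margin monotonically
  m1 <- nutrient_balance(0.1, medium, quotas, 0.35)$margin
  quotas2 <- quotas
  quotas2$quota <- quotas2$quota * 2
  m2 <- nutrient_balance(0.1, medium, quotas2, 0.35)$margin
  expect_true(all(m2 < m1))
  # unmatched elements are reported, not fatal
  b <- nutrient_balance(0.1, medium[1:5, ], quotas, 0.35)
  expect_setequal(attr(b, "unmatched"), c("P", "Fe"))
})
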