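test_that("darkness yields zero growth: maintenance cannot be paid", {
  ss <- steady_state_growth(default_p, 0)
  expect_identical(ss$mu, 0)
  expect_match(ss$status, "infeasible")
})

test_that("solved steady states satisfy mass balance, Q share and flux balance", {
  for (I in c(55, 440)) {
    ss <- steady_state_growth(default_p, I)
    expect_identical(ss$status, "converged")
    expect_gt(ss$mu, 0)
    conc <- ss$concentrations
    expect_equal(sum(conc$conc_aa), default_p$Dc, tolerance = 1e-10)
    expect_equal(conc$mass_fraction[conc$class == "Q"], default_p$phi_Q,
                 tolerance = 1e-10)
    # species residuals below 1e-6 of the largest flux
    vmax <- max(abs(ss$fluxes$value))
    expect_lt(max(abs(ss$residuals[c("ci", "aa", "e")])), 1e-6 * vmax)
    # ribosome allocation is a partition
    expect_equal(sum(ss$allocation$beta), 1, tolerance = 1e-10)
    expect_true(all(ss$allocation$beta >= 0))
  }
})

test_that("fitted parameters reproduce the measured low-light growth rate", {
  ss <- steady_state_growth(default_p, 27.5)
  expect_equal(ss$mu, 0.025, tolerance = 0.2)
})

test_that("light response is photoinhibited with damage and saturating without", {
  I_grid <- c(27.5, 55, 110, 220, 440, 660, 880, 1100)
  lr <- light_response(default_p, I_grid)
  expect_identical(nrow(lr), length(I_grid))
  expect_true(all(lr$status == "converged"))
  i_max <- which.max(lr$mu)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(I_grid))
  expect_lt(lr$mu[lr$I == 1100], max(lr$mu))
  # growth law: R fraction rises and P fraction falls with light when
  # light-limited
  lim <- lr[lr$I <= 440, ]
  expect_true(all(diff(lim$fraction_R) > 0))
  expect_true(all(diff(lim$fraction_P) < 0))
  # without photodamage the response saturates monotonically
  p0 <- default_p
  p0$kd <- 0
  mu0 <- light_response(p0, I_grid)$mu
  expect_true(all(diff(mu0) > -1e-9))
  expect_error(light_response(default_p, c(100, 50)), "non-decreasing")
})

test_that("optimizer dominates the brute-force allocation grid and converges to it", {
  p <- default_p
  p$kdiff <- 2e-5   # diffusion-sufficient instance: optimal phi_T on-grid at 0
  g <- allocation_grid_search(p, 440, step = 0.05)
  opt <- steady_state_growth(p, 440)
  expect_true(all(g$mu <= opt$mu + 1e-6, na.rm = TRUE))
  expect_lt((opt$mu - g$mu[1]) / opt$mu, 0.10)
  expect_error(allocation_grid_search(p, 440, step = 0.03), "divide")
})

test_that("clamping a class at its optimal share is non-binding, elsewhere suboptimal", {
  opt <- steady_state_growth(default_p, 440)
  fr <- setNames(opt$concentrations$mass_fraction,
                 opt$concentrations$class)
  ss_eq <- constrained_growth(default_p, 440, class_id = "R",
                              phi_Z = fr[["R"]])
  expect_equal(ss_eq$mu, opt$mu, tolerance = 1e-2)
  for (spec in list(list("R", 0.3), list("P", 0.05), list("M", 0.25))) {
    ss <- constrained_growth(default_p, 440, class_id = spec[[1]],
                             phi_Z = spec[[2]])
    expect_lte(ss$mu, opt$mu * (1 + 1e-6))
    expect_equal(
      ss$concentrations$mass_fraction[ss$concentrations$class == spec[[1]]],
      spec[[2]], tolerance = 1e-12)
  }
  expect_error(constrained_growth(default_p, 440, class_id = "R",
                                  phi_Z = 0.6), "budget")
})

test_that("steady-state tidier and parameter IO round-trip", {
  ss <- steady_state_growth(default_p, 110)
  td <- tidy(ss)
  expect_identical(nrow(td), 1L)
  expect_equal(td$fraction_T + td$fraction_M + td$fraction_R +
                 td$fraction_P + td$fraction_Q, 1, tolerance = 1e-10)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_parameters(default_p, path)
  expect_equal(unclass(read_model_parameters(path)), unclass(default_p))
  expect_error(model_parameters(phi_Q = 1), "phi_Q")
  expect_error(model_parameters(kd = 2), "kd")
  expect_error(steady_state_growth(default_p, -5), "non-negative")
})
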