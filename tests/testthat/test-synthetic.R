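test_that("generators are reproducible from a seed", {
  expect_identical(simulate_turbidostat(0.06, 24, seed = 3, noise_sd = 0.01),
                   simulate_turbidostat(0.06, 24, seed = 3, noise_sd = 0.01))
  expect_identical(simulate_gas_trace(1e-3, 2e-4, noise_sd = 0.05, seed = 4),
                   simulate_gas_trace(1e-3, 2e-4, noise_sd = 0.05, seed = 4))
  s1 <- simulate_proteomics(n_proteins = 50, seed = 6)
  s2 <- simulate_proteomics(n_proteins = 50, seed = 6)
  expect_identical(s1$matrix$lfq, s2$matrix$lfq)
  expect_identical(s1$truth, s2$truth)
})

test_that("the turbidostat band is respected and a short run warns", {
  tr <- simulate_turbidostat(0.1, duration = 30, seed = 2)
  expect_true(all(tr$od680 >= 0.6 - 1e-12 & tr$od680 <= 0.66 + 1e-12))
  expect_gt(length(attr(tr, "dilution_events")), 0)
  expect_warning(simulate_turbidostat(0.01, duration = 1), "band")
  expect_error(simulate_turbidostat(0, 10), "> 0")
})

test_that("proteomics generator matches the deposited experiment dimensions", {
  sim <- simulate_proteomics(seed = 1)
  expect_identical(nrow(sim$matrix$samples), 30L)   # 6 groups x 5 replicates
  expect_identical(sum(sim$truth$role %in% c("protein", "reference")), 1356L)
  expect_identical(length(unique(sim$matrix$samples$group)), 6L)
  expect_identical(sum(sim$truth$dependent, na.rm = TRUE), 779L)
  # decoys are present in the raw table and flagged
  expect_gt(sum(sim$matrix$proteins$contaminant), 0)
  expect_gt(sum(sim$matrix$proteins$reverse), 0)
  # planting fewer dependent proteins than archetypes is refused
  expect_error(simulate_proteomics(n_proteins = 100,
                                   dependent_fraction = 0.03),
               "archetypes")
})

test_that("a noiseless dataset is classified and clustered perfectly", {
  sim <- simulate_proteomics(n_proteins = 140, dependent_fraction = 0.5,
                             noise_cv = 0, missing_rate = 0, seed = 7)
  filt <- filter_protein_groups(sim$matrix)
  expect_identical(nrow(filt$proteins), 140L)
  calls <- classify_growth_dependence(filt)
  truth <- sim$truth[match(calls$protein_id, sim$truth$protein_id), ]
  expect_identical(calls$dependent, truth$dependent)
  dep <- cyanogrowth:::im_subset(
    filt, which(filt$proteins$protein_id %in%
                  truth$protein_id[truth$dependent]))
  cl <- cluster_profiles(dep, k = 7)
  ari <- mclust::adjustedRandIndex(
    cl$assignments$cluster,
    truth$archetype[match(cl$assignments$protein_id, truth$protein_id)])
  expect_equal(ari, 1)
})

test_that("under a pure null the flag rate matches the 15-test family-wise rate", {
  sim <- simulate_proteomics(n_proteins = 350, dependent_fraction = 0,
                             noise_cv = 0.15, missing_rate = 0, seed = 13)
  calls <- classify_growth_dependence(filter_protein_groups(sim$matrix))
  rate_pipeline <- mean(calls$dependent, na.rm = TRUE)
  # independent oracle: direct simulation of the same 15-pair test battery
  set.seed(14)
  flags <- replicate(350, {
    g <- matrix(rnorm(30), nrow = 5)
    pairs <- utils::combn(6, 2)
    any(apply(pairs, 2, function(jk) {
      pairwise_kw_p(g[, jk[1]], g[, jk[2]])
    }) < 0.05)
  })
  rate_oracle <- mean(flags)
  expect_lt(abs(rate_pipeline - rate_oracle), 0.075)
  expect_gt(rate_pipeline, 0.05)   # well above the single-test level ...
  expect_lt(rate_pipeline, 0.6)    # ... but far from flagging everything
})

test_that("noiseless growth observations reproduce the model curve", {
  obs <- simulate_growth_observations(default_p, light = c(55, 440), sd = 0)
  expect_equal(obs$mu, attr(obs, "mu_true"))
  expect_true(all(obs$sd > 0))
  set.seed(10)
  obs_n <- simulate_growth_observations(default_p, light = c(55, 440),
                                        sd = 0.002, seed = 10)
  expect_false(all(obs_n$mu == attr(obs_n, "mu_true")))
  expect_identical(
    simulate_growth_observations(default_p, c(55, 440), 0.002, seed = 5),
    simulate_growth_observations(default_p, c(55, 440), 0.002, seed = 5))
})
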