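# default archetype library: multiplicative fold-change profiles over the
# condition groups, mirroring the qualitative cluster shapes of
# light-acclimation proteomics (monotone up/down, saturating up/down,
# photoinhibition kinks, and a high-light-only spike)
profile_archetypes <- function(n_groups, fold = 2) {
  x <- seq(0, 1, length.out = n_groups)
  last <- c(rep(1, n_groups - 1), fold)
  list(
    up_linear = fold^x,
    down_linear = fold^(-x),
    up_kink = fold^x * last,
    down_kink = fold^(-x) / last,
    up_saturating = fold^pmin(x / 0.5, 1),
    down_saturating = fold^(-pmin(x / 0.5, 1)),
    spike_high_light = c(rep(1, n_groups - 1), fold^2)
  )
}

#' Simulate a turbidostat OD trace
#'
#' Generates the characteristic sawtooth optical-density trace of
#' turbidostat cultivation: exponential growth at the planted specific
#' growth rate between the control-band bounds, with an instantaneous
#' dilution reset to the lower bound whenever the upper bound is reached.
#'
#' @param mu_true Planted specific growth rate (h^-1, > 0).
#' @param duration Trace duration (h).
#' @param od_bounds Turbidostat control band (default 0.60-0.66).
#' @param dt Sampling interval (h; default 1 min).
#' @param noise_sd Multiplicative log-normal sensor noise (sdlog; 0 = none).
#' @param seed Optional seed for reproducibility.
#' @return A tibble (`time`, `od680`) with the dilution-event times in
#'   attribute `"dilution_events"` and the planted rate in `"mu_true"`.
#' @examples
#' tr <- simulate_turbidostat(0.05, duration = 48)
#' range(tr$od680)
#' @export
simulate_turbidostat <- function(mu_true, duration, od_bounds = c(0.60, 0.66),
                                 dt = 1 / 60, noise_sd = 0, seed = NULL) {
  if (mu_true <= 0) abort("`mu_true` must be > 0")
  if (od_bounds[1] <= 0 || od_bounds[2] <= od_bounds[1]) {
    abort("`od_bounds` must be increasing and positive")
  }
  if (!is.null(seed)) set.seed(seed)
  band_time <- log(od_bounds[2] / od_bounds[1]) / mu_true
  if (duration < band_time) {
    warn("duration is shorter than one crossing of the turbidostat band")
  }
  times <- seq(0, duration, by = dt)
  od <- numeric(length(times))
  events <- numeric(0)
  cur <- od_bounds[1]
  for (i in seq_along(times)) {
    if (i > 1) cur <- cur * exp(mu_true * dt)
    if (cur >= od_bounds[2]) {
      cur <- od_bounds[1]
      events <- c(events, times[i])
    }
    od[i] <- cur
  }
  if (noise_sd > 0) od <- od * rlnorm(length(od), 0, noise_sd)
  out <- tibble(time = times, od680 = od)
  attr(out, "dilution_events") <- events
  attr(out, "mu_true") <- mu_true
  out
}

#' Simulate a dissolved-oxygen trace with light/dark phases
#'
#' Piecewise-linear dissolved-O2 trace over alternating light and dark
#' phases (5 min each by default) with planted slopes and Gaussian sensor
#' noise, emulating the aeration-off gas-exchange measurement.
#'
#' @param np Planted light-phase slope (O2 per second).
#' @param r_dark Planted dark respiration rate (>= 0; the dark-phase slope
#'   is `-r_dark`).
#' @param period_s Phase duration (s; default 300 = 5 min).
#' @param n_cycles Number of light+dark cycles.
#' @param dt_s Sampling interval (s).
#' @param noise_sd Gaussian sensor noise SD (same unit as `do2`).
#' @param o2_0 Initial dissolved O2 level.
#' @param seed Optional seed.
#' @return A tibble (`time`, `do2`, `phase`) with planted rates in
#'   attribute `"planted"`.
#' @export
simulate_gas_trace <- function(np, r_dark, period_s = 300, n_cycles = 3,
                               dt_s = 5, noise_sd = 0, o2_0 = 100,
                               seed = NULL) {
  if (np < 0 || r_dark < 0) abort("planted rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  phase_seq <- rep(c("light", "dark"), n_cycles)
  t0 <- 0
  o2 <- o2_0
  rows <- purrr::map(seq_along(phase_seq), function(i) {
    ph <- phase_seq[i]
    slope <- if (ph == "light") np else -r_dark
    tt <- seq(0, period_s - dt_s, by = dt_s)
    vals <- o2 + slope * tt
    o2 <<- vals[length(vals)] + slope * dt_s
    out <- tibble(time = t0 + tt, do2 = vals, phase = ph)
    t0 <<- t0 + period_s
    out
  })
  out <- dplyr::bind_rows(rows)
  if (noise_sd > 0) out$do2 <- out$do2 + rnorm(nrow(out), 0, noise_sd)
  attr(out, "planted") <- c(np = np, r_dark = r_dark, gp = np + r_dark)
  out
}

#' Simulate a label-free proteomics dataset with planted ground truth
#'
#' Generates a proteins x samples intensity matrix emulating a light-
#' acclimation experiment: per-protein log-normal baselines, multiplicative
#' archetype profiles across condition groups for a planted fraction of
#' growth-dependent proteins (growth-independent proteins are flat),
#' log-normal replicate noise, an intensity-dependent (left-censoring-like)
#' missing-value mechanism on the LFQ layer, and injected contaminant,
#' reverse-decoy and single-peptide entries that the standard filters must
#' remove. Four stable reference proteins (ids matching the default
#' [calibration_spec()]) are planted among the growth-independent proteins,
#' and the iBAQ layer carries planted per-sample scale factors so that
#' normalization and calibration can be tested by round-trip.
#'
#' @param n_proteins Number of genuine proteins (default 1356).
#' @param groups Condition labels (default the six light intensities).
#' @param replicates Replicates per group (default 5).
#' @param dependent_fraction Planted share of growth-dependent proteins
#'   (default 779/1356).
#' @param fold Archetype effect size (maximal fold change; default 2).
#' @param noise_cv Replicate coefficient of variation (default 0.15).
#' @param missing_rate Target overall missing-value rate on the LFQ layer
#'   (default 0.05); missingness probability decreases logistically with
#'   log-intensity.
#' @param n_contaminants,n_reverse,n_low_peptide Numbers of injected decoy
#'   entries.
#' @param seed Optional seed.
#' @return A list with elements `matrix` (an [intensity_matrix()]), `truth`
#'   (tibble `protein_id`, `role`, `dependent`, `archetype`) and
#'   `sample_factors` (planted per-sample iBAQ scale factors).
#' @examples
#' sim <- simulate_proteomics(n_proteins = 60, seed = 1)
#' sim$matrix
#' @export
simulate_proteomics <- function(n_proteins = 1356,
                                groups = c(27.5, 55, 110, 220, 440, 1100),
                                replicates = 5,
                                dependent_fraction = 779 / 1356,
                                fold = 2,
                                noise_cv = 0.15,
                                missing_rate = 0.05,
                                n_contaminants = 20,
                                n_reverse = 10,
                                n_low_peptide = 30,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (replicates < 3) abort("`replicates` must be >= 3")
  if (dependent_fraction < 0 || dependent_fraction > 1) {
    abort("`dependent_fraction` must lie in [0, 1]")
  }
  archetypes <- profile_archetypes(length(groups), fold)
  n_dep <- round(dependent_fraction * n_proteins)
  if (n_dep > 0 && n_dep < length(archetypes)) {
    abort(sprintf(
      "dependent_fraction * n_proteins = %d is below the %d archetypes",
      n_dep, length(archetypes)))
  }
  ref_ids <- c("Q55806", "P72587", "P73505", "Q59978")
  n_ind <- n_proteins - n_dep
  if (n_ind < length(ref_ids)) ref_ids <- character(0)  # all-dependent designs
  ids <- c(sprintf("P%05d", seq_len(n_dep)),
           ref_ids,
           sprintf("I%05d", seq_len(n_ind - length(ref_ids))))
  role <- c(rep("protein", n_dep), rep("reference", length(ref_ids)),
            rep("protein", n_ind - length(ref_ids)))
  dependent <- c(rep(TRUE, n_dep), rep(FALSE, n_ind))
  archetype <- c(
    rep(names(archetypes), length.out = n_dep),
    rep("flat", n_ind)
  )
  if (n_dep == 0) archetype <- rep("flat", n_ind)

  n_real <- length(ids)
  samples <- tibble(
    sample = paste0("s", rep(seq_along(groups), each = replicates), "_",
                    rep(seq_len(replicates), length(groups))),
    group = rep(as.character(groups), each = replicates)
  )
  n_s <- nrow(samples)
  baseline <- rlnorm(n_real, meanlog = log(1e8), sdlog = 1.5)
  baseline[role == "reference"] <- rlnorm(length(ref_ids), log(5e8), 0.1)
  prof <- t(vapply(archetype, function(a) {
    if (a == "flat") rep(1, length(groups)) else archetypes[[a]]
  }, numeric(length(groups))))
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  group_idx <- rep(seq_along(groups), each = replicates)
  mean_mat <- baseline * prof[, group_idx, drop = FALSE]
  noise <- matrix(rlnorm(n_real * n_s, 0, sdlog_noise), n_real, n_s)
  lfq <- mean_mat * noise

  # intensity-dependent missingness: logistic in log-intensity, located at
  # the missing_rate quantile so the overall rate is close to the target
  if (missing_rate > 0) {
    lv <- log(lfq)
    loc <- quantile(lv, missing_rate, names = FALSE)
    p_miss <- plogis((loc - lv) / 0.75)
    p_miss <- p_miss * missing_rate / mean(p_miss)
    drop <- matrix(runif(length(lfq)) < p_miss, n_real, n_s)
    drop[role == "reference", ] <- FALSE     # references stay complete
    lfq[drop] <- NA
  }

  peptides_real <- pmax(2L, 2L + stats::rpois(n_real, 8))
  # injected decoys: contaminants, reverse hits, single-peptide entries
  n_decoy <- n_contaminants + n_reverse + n_low_peptide
  decoy_ids <- c(sprintf("CON__%03d", seq_len(n_contaminants)),
                 sprintf("REV__%03d", seq_len(n_reverse)),
                 sprintf("LOWPEP%03d", seq_len(n_low_peptide)))
  decoy_lfq <- matrix(rlnorm(n_decoy * n_s, log(1e7), 1), n_decoy, n_s)
  proteins <- tibble(
    protein_id = c(ids, decoy_ids),
    peptides = c(peptides_real,
                 pmax(2L, 2L + stats::rpois(n_contaminants + n_reverse, 4)),
                 rep(1L, n_low_peptide)),
    contaminant = c(rep(FALSE, n_real), rep(TRUE, n_contaminants),
                    rep(FALSE, n_reverse + n_low_peptide)),
    reverse = c(rep(FALSE, n_real + n_contaminants), rep(TRUE, n_reverse),
                rep(FALSE, n_low_peptide))
  )
  lfq_all <- rbind(lfq, decoy_lfq)
  # iBAQ: LFQ scaled per protein by theoretically observable peptides and
  # per sample by a planted instrument/loading factor
  theo_pep <- runif(nrow(proteins), 5, 50)
  sample_factors <- rlnorm(n_s, 0, 0.3)
  ibaq <- sweep(lfq_all / theo_pep, 2, sample_factors, "*")
  im <- intensity_matrix(proteins, samples, lfq_all, ibaq)
  truth <- tibble(
    protein_id = proteins$protein_id,
    role = c(role, rep("contaminant", n_contaminants),
             rep("reverse", n_reverse), rep("low_peptide", n_low_peptide)),
    dependent = c(dependent, rep(NA, n_decoy)),
    archetype = c(archetype, rep(NA_character_, n_decoy))
  )
  list(matrix = im, truth = truth,
       sample_factors = setNames(sample_factors, samples$sample))
}

#' Simulate light-growth observations from the allocation model
#'
#' Solves the allocation model at the given light intensities and adds
#' independent Gaussian noise with the supplied standard deviations,
#' producing observations for parameter-recovery studies of [grid_fit()].
#'
#' @param params A [model_parameters()] object (its `tau`, `kd`, `sigma`
#'   are the generating truth).
#' @param light Light intensities (umol photons m^-2 s^-1).
#' @param sd Per-observation noise SDs (h^-1); recycled to `length(light)`.
#'   Zero gives noiseless observations (the reported `sd` column then
#'   defaults to 0.002 h^-1 so the likelihood stays defined).
#' @param cix External inorganic carbon (mM).
#' @param seed Optional seed.
#' @return A [growth_observations()] tibble; the noiseless model curve is
#'   attached as attribute `"mu_true"`.
#' @export
simulate_growth_observations <- function(params, light, sd, cix = 100,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd <- rep_len(sd, length(light))
  lr <- light_response(params, sort(light), cix = cix)
  mu_true <- setNames(lr$mu, lr$I)[as.character(light)]
  if (any(!is.finite(mu_true))) abort("model solve failed at some intensity")
  y <- unname(mu_true) + rnorm(length(light), 0, sd)
  obs <- growth_observations(light, pmax(y, 0),
                             ifelse(sd > 0, sd, 0.002))
  attr(obs, "mu_true") <- unname(mu_true)
  obs
}
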