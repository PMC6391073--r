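#' Candidate grids for photosynthetic-unit parameter fitting
#'
#' The three photosynthetic-unit parameters (turnover rate `tau`, photodamage
#' probability `kd`, absorption cross-section `sigma`) are estimated by
#' exhaustive search over pre-defined candidate sets rather than continuous
#' optimization. The defaults are the published candidate sets: three `tau`
#' values, a `kd` ladder from 5e-7 to 5e-6 (step 1e-7 below 1e-6, step 1e-6
#' above), and `sigma` from 0.1 to 1.0 nm^2 in steps of 0.1.
#'
#' @param tau Candidate turnover rates (s^-1).
#' @param kd Candidate photodamage probabilities.
#' @param sigma Candidate absorption cross-sections (nm^2).
#' @return A list of class `fit_grid`.
#' @export
fit_grid <- function(tau = c(50, 75, 100),
                     kd = c(seq(5e-7, 9e-7, by = 1e-7), seq(1e-6, 5e-6, by = 1e-6)),
                     sigma = seq(0.1, 1.0, by = 0.1)) {
  for (nm in c("tau", "kd", "sigma")) {
    v <- get(nm)
    if (length(v) < 1 || any(v <= 0) || is.unsorted(v, strictly = TRUE)) {
      abort(sprintf("`%s` candidates must be positive, sorted and distinct", nm))
    }
  }
  structure(list(tau = tau, kd = kd, sigma = sigma), class = "fit_grid")
}

#' @export
print.fit_grid <- function(x, ...) {
  cat("<fit_grid>", length(x$tau), "tau x", length(x$kd), "kd x",
      length(x$sigma), "sigma =", length(x$tau) * length(x$kd) * length(x$sigma),
      "candidates\n")
  invisible(x)
}

#' Growth observations for model fitting
#'
#' Light-growth observations: measured specific growth rates with their
#' uncertainties at a set of light intensities.
#'
#' @param light Light intensities (umol photons m^-2 s^-1).
#' @param mu Measured specific growth rates (h^-1).
#' @param sd Standard deviations of the measured growth rates (h^-1, > 0).
#' @return A tibble with columns `light`, `mu`, `sd`.
#' @export
growth_observations <- function(light, mu, sd) {
  if (!(length(light) == length(mu) && length(mu) == length(sd))) {
    abort("`light`, `mu` and `sd` must have equal length")
  }
  if (any(sd <= 0)) abort("all uncertainties `sd` must be > 0")
  if (any(mu < 0)) abort("growth rates must be >= 0")
  tibble(light = light, mu = mu, sd = sd)
}

#' Read or write growth observations as TSV
#'
#' @param path TSV file with columns `light`, `mu`, `sd`.
#' @return A growth-observation tibble.
#' @export
read_growth_observations <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("light", "mu", "sd"), names(d))
  if (length(miss) > 0) {
    abort(paste("missing observation columns:", paste(miss, collapse = ", ")))
  }
  growth_observations(d$light, d$mu, d$sd)
}

#' @param obs A [growth_observations()] tibble.
#' @rdname read_growth_observations
#' @export
write_growth_observations <- function(obs, path) {
  readr::write_tsv(obs, path)
  invisible(path)
}

#' Negative log-likelihood of simulated against measured growth rates
#'
#' Scores a vector of model-simulated growth rates `y_i` against measured
#' growth rates `x_i` with uncertainties `e_i` under independent Gaussian
#' errors:
#' \deqn{l = \sum_i \left[ (y_i - x_i)^2 / e_i^2 + \log(2 \pi e_i^2) \right]}
#' Lower is better. The value decomposes additively over observations; a
#' perfectly matched observation with `e = 1` contributes `log(2*pi)`.
#'
#' @param sim Simulated growth rates (h^-1), same length as `obs` rows.
#' @param obs A [growth_observations()] tibble.
#' @return A list of class `likelihood_result` with elements `l` (the
#'   scalar negative log-likelihood) and `per_point` (a tibble with the
#'   per-observation simulated values, residuals and contributions).
#' @examples
#' obs <- growth_observations(100, 0.05, 1)
#' neg_log_likelihood(0.05, obs)$l  # log(2*pi)
#' @export
neg_log_likelihood <- function(sim, obs) {
  if (length(sim) != nrow(obs)) {
    abort(sprintf("length(sim) == %d but %d observations", length(sim),
                  nrow(obs)))
  }
  if (nrow(obs) < 1) abort("at least one observation is required")
  if (any(obs$sd <= 0)) abort("all uncertainties must be > 0")
  contrib <- (sim - obs$mu)^2 / obs$sd^2 + log(2 * pi * obs$sd^2)
  structure(
    list(
      l = sum(contrib),
      per_point = tibble(light = obs$light, x = obs$mu, e = obs$sd,
                         y = sim, residual = sim - obs$mu,
                         contribution = contrib)
    ),
    class = "likelihood_result"
  )
}

#' Grid-search maximum-likelihood fit of the photosynthetic-unit parameters
#'
#' For every candidate triplet `(tau, kd, sigma)` in the grid, solves the
#' allocation model at every observed light intensity (at the carbon-
#' saturated condition `cix`), scores the simulated growth rates with
#' [neg_log_likelihood()], and returns the best-scoring candidate together
#' with the fully ranked table. The search is deterministic; likelihood ties
#' are broken by smallest `kd`, then smallest `sigma`, then smallest `tau`
#' (preferring the least-damage, least-cost explanation).
#'
#' @param obs A [growth_observations()] tibble spanning at least two light
#'   intensities.
#' @param grid A [fit_grid()].
#' @param base_params A [model_parameters()] object providing all non-fitted
#'   constants.
#' @param cix External inorganic carbon (mM) used during fitting.
#' @param control Solver control passed to [steady_state_growth()].
#' @return An object of class `growth_fit`: list with `best` (one-row
#'   tibble), `table` (ranked candidates), `observations`, and `params_best`
#'   (a [model_parameters()] object at the optimum). Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' \donttest{
#' params <- model_parameters()
#' obs <- simulate_growth_observations(params,
#'   light = c(27.5, 110, 440), sd = rep(0.002, 3))
#' small <- fit_grid(tau = 75, kd = c(5e-7, 1e-6, 2e-6), sigma = c(0.6, 0.7, 0.8))
#' fit <- grid_fit(obs, small, params)
#' glance(fit)
#' }
#' @export
grid_fit <- function(obs, grid = fit_grid(), base_params = model_parameters(),
                     cix = 100, control = list()) {
  stopifnot(inherits(grid, "fit_grid"))
  if (length(unique(obs$light)) < 2) {
    abort("observations must span at least two light intensities")
  }
  cand <- expand.grid(tau = grid$tau, kd = grid$kd, sigma = grid$sigma,
                      KEEP.OUT.ATTRS = FALSE)
  lights <- sort(unique(obs$light))
  warm <- vector("list", length(lights))   # warm starts per intensity
  n_fail <- 0
  score_one <- function(tau, kd, sigma) {
    p <- base_params
    p$tau <- tau; p$kd <- kd; p$sigma <- sigma
    mu_at <- setNames(numeric(length(lights)), lights)
    for (j in seq_along(lights)) {
      st <- tryCatch(
        steady_state_growth(p, lights[j], cix, start = warm[[j]],
                            control = control),
        error = function(e) NULL
      )
      if (is.null(st)) return(NULL)
      mu_at[j] <- st$mu
      if (st$status == "converged") warm[[j]] <<- st$optim$par
    }
    sim <- mu_at[as.character(obs$light)]
    neg_log_likelihood(unname(sim), obs)$l
  }
  ll <- purrr::pmap_dbl(cand, function(tau, kd, sigma) {
    v <- score_one(tau, kd, sigma)
    if (is.null(v)) { n_fail <<- n_fail + 1; NA_real_ } else v
  })
  if (all(is.na(ll))) {
    abort(sprintf("all %d grid candidates failed to solve", nrow(cand)))
  }
  tab <- as_tibble(cand)
  tab$l <- ll
  tab <- dplyr::arrange(tab, is.na(.data$l), .data$l, .data$kd, .data$sigma,
                        .data$tau)
  best <- tab[1, ]
  p_best <- base_params
  p_best$tau <- best$tau; p_best$kd <- best$kd; p_best$sigma <- best$sigma
  structure(
    list(best = best, table = tab, observations = obs,
         params_best = p_best, cix = cix, n_failed = n_fail),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", nrow(x$table), "candidates,", nrow(x$observations),
      "observations\n")
  cat(sprintf("  best: tau = %g s^-1, kd = %g, sigma = %g nm^2, l = %.4f\n",
              x$best$tau, x$best$kd, x$best$sigma, x$best$l))
  invisible(x)
}

#' @rdname grid_fit
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) x$table

#' @rdname grid_fit
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(tau = x$best$tau, kd = x$best$kd, sigma = x$best$sigma,
         l = x$best$l, n_obs = nrow(x$observations),
         n_candidates = nrow(x$table), n_failed = x$n_failed)
}

#' Write a fit report
#'
#' Writes the ranked candidate table as TSV and a JSON summary (best
#' parameters, likelihood, grid size) next to it.
#'
#' @param fit A [grid_fit()] result.
#' @param path Base output path; `.tsv` and `.json` files are written.
#' @return Invisibly, the two paths.
#' @export
write_fit_report <- function(fit, path) {
  tsv <- paste0(path, ".tsv")
  js <- paste0(path, ".json")
  readr::write_tsv(fit$table, tsv)
  jsonlite::write_json(
    list(best = as.list(fit$best), n_obs = nrow(fit$observations),
         n_candidates = nrow(fit$table), grid_table = basename(tsv)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
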