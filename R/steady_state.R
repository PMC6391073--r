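# ---- inner steady-state solve at fixed proteome mass fractions -------------
#
# At fixed mass fractions phi = (phi_T, phi_M, phi_R, phi_P) (with the
# growth-independent share phi_Q implied), the steady-state equations reduce
# to a one-dimensional manifold parametrized by the growth rate mu:
#   * the internal carbon balance is a quadratic in ci with a unique positive
#     root (diffusion, transport, metabolic consumption, dilution),
#   * the amino-acid balance pins the aa pool: aa = vm/mu - Dc,
#   * ribosome self-replication pins the required translational saturation
#     f_req = (mu + delta*phi_P) * n_R / (kcat_R * phi_R), which together with
#     the aa pool determines the energy pool,
#   * the remaining energy balance g(mu) is strictly decreasing in mu, so the
#     steady state is the unique root of g, found by bisection + uniroot.
#
# `alpha` scales the catalytic activity of each class (active fraction); for
# P it scales both energy production and the photodamage flux, since only
# active units cycle through the excited state.
solve_allocation <- function(params, I, cix, phi, alpha = c(1, 1, 1, 1)) {
  p <- params
  u <- psu_unit_rates(p, I)
  phiT <- phi[[1]]; phiM <- phi[[2]]; phiR <- phi[[3]]; phiP <- phi[[4]]
  phiP_a <- alpha[[4]] * phiP
  vt <- alpha[[1]] * p$kcat_T * (phiT * p$Dc / p$n_T) * cix / (p$Km_T + cix)
  km <- alpha[[2]] * p$kcat_M * (phiM * p$Dc / p$n_M)
  kR <- alpha[[3]] * p$kcat_R * phiR / p$n_R
  v2max <- u$eps * (phiP_a * p$Dc / p$n_P)
  dmg <- u$delta * phiP_a              # damaged P mass fraction per second
  fail <- function(d) list(ok = FALSE, deficit = d)

  # energy bill that cannot be avoided even as mu -> 0
  deficit <- p$e_t * vt + p$m + p$e_aa * dmg * p$Dc - v2max
  if (deficit >= 0 || kR <= dmg || km <= 0) {
    return(fail(max(deficit, 0) + 100 * max(dmg - kR, 0) + 1e-2 * (km <= 0)))
  }

  ci_of <- function(mu) {
    a_lin <- p$kdiff / p$v_cell + mu
    A <- p$kdiff * cix + vt
    b <- a_lin * p$Km_M + p$c_aa * km - A
    (-b + sqrt(b^2 + 4 * a_lin * A * p$Km_M)) / (2 * a_lin)
  }
  parts <- function(mu) {
    ci <- ci_of(mu)
    vm <- km * ci / (p$Km_M + ci)
    aa <- vm / mu - p$Dc
    if (!is.finite(aa) || aa <= 0) return(NULL)
    f_req <- (mu + dmg) / kR
    if (f_req >= 1) return(NULL)
    f_aa <- aa / (p$Km_aa + aa)
    f_e <- f_req / f_aa
    if (f_e >= 1) return(NULL)
    e <- p$Km_e * f_e / (1 - f_e)
    vtrans <- (mu + dmg) * p$Dc
    list(ci = ci, vm = vm, aa = aa, e = e, f_aa = f_aa, f_e = f_e,
         vtrans = vtrans,
         g = v2max - p$e_aa * vtrans - p$e_t * vt - p$m - mu * e)
  }
  g_of <- function(mu) {
    pt <- parts(mu)
    if (is.null(pt)) -Inf else pt$g
  }
  mu_up <- min(kR - dmg, km / p$Dc) * (1 - 1e-12)
  mu_lo <- mu_up * 1e-10
  if (g_of(mu_lo) <= 0) return(fail(1e-3))
  lo <- mu_lo; hi <- mu_up
  for (it in seq_len(300)) {
    gh <- g_of(hi)
    if (is.finite(gh) && gh < 0) break
    if (is.finite(gh)) { lo <- hi; hi <- (hi + mu_up) / 2 } else {
      hi <- (lo + hi) / 2
    }
    if ((hi - lo) / mu_up < 1e-13) break
  }
  gh <- g_of(hi)
  mu <- if (is.finite(gh) && gh < 0) {
    uniroot(g_of, c(lo, hi), tol = 1e-15)$root
  } else {
    lo
  }
  pt <- parts(mu)
  if (is.null(pt)) return(fail(1e-4))
  c(list(ok = TRUE, mu = mu, vt = vt, v2 = v2max, dmg = dmg, unit = u),
    pt)
}

.softmax <- function(z) {
  z <- c(z, 0)
  ez <- exp(z - max(z))
  ez / sum(ez)
}

# assemble a full steady_state object from an inner solution
build_steady_state <- function(params, I, cix, phi, alpha, sol, status,
                               optim_info = NULL) {
  p <- params
  classes <- c("T", "M", "R", "P", "Q")
  if (!sol$ok) {
    conc <- c(phi, p$phi_Q) * p$Dc
    out <- list(
      mu = 0, I = I, cix = cix,
      pools = c(ci = NA_real_, aa = NA_real_, e = NA_real_),
      concentrations = tibble(
        class = classes, mass_fraction = c(phi, p$phi_Q),
        conc_aa = conc, n = c(p$n_T, p$n_M, p$n_R, p$n_P, p$n_Q),
        conc_units = conc / c(p$n_T, p$n_M, p$n_R, p$n_P, p$n_Q)
      ),
      fluxes = tibble(flux = character(), value = numeric()),
      allocation = tibble(class = classes, beta = rep(NA_real_, 5)),
      alpha = c(T = alpha[[1]], M = alpha[[2]], R = alpha[[3]],
                P = alpha[[4]], Q = 1),
      residuals = c(ci = NA_real_, aa = NA_real_, e = NA_real_,
                    mass = 0, q_share = 0),
      status = status, params = p, optim = optim_info
    )
    return(structure(out, class = "steady_state"))
  }
  mu <- sol$mu
  phiQ <- p$phi_Q
  conc <- c(phi, phiQ) * p$Dc
  n_z <- c(p$n_T, p$n_M, p$n_R, p$n_P, p$n_Q)
  vi <- sol$dmg * p$Dc                       # aa-equivalents s^-1
  vtrans <- sol$vtrans
  beta <- c(mu * conc[1:3], mu * conc[4] + vi, mu * conc[5]) / vtrans
  vd <- p$kdiff * (cix - sol$ci / p$v_cell)
  v1 <- sol$v2
  fluxes <- tibble(
    flux = c("vd", "vt", "vm", "v1", "v2", "vi", "mv", "vtrans",
             paste0("translation_", classes)),
    value = c(vd, sol$vt, sol$vm, v1, sol$v2, vi, p$m, vtrans,
              beta * vtrans)
  )
  resid <- c(
    ci = vd + sol$vt - p$c_aa * sol$vm - mu * sol$ci,
    aa = sol$vm + vi - vtrans - mu * sol$aa,
    e = sol$v2 - p$e_aa * vtrans - p$e_t * sol$vt - p$m - mu * sol$e,
    mass = sum(conc) - p$Dc,
    q_share = conc[5] / p$Dc - phiQ
  )
  out <- list(
    mu = mu * 3600, I = I, cix = cix,
    pools = c(ci = sol$ci, aa = sol$aa, e = sol$e),
    concentrations = tibble(
      class = classes, mass_fraction = conc / p$Dc, conc_aa = conc,
      n = n_z, conc_units = conc / n_z
    ),
    fluxes = fluxes,
    allocation = tibble(class = classes, beta = beta),
    alpha = c(T = alpha[[1]], M = alpha[[2]], R = alpha[[3]], P = alpha[[4]],
              Q = 1),
    saturation = c(f_aa = sol$f_aa, f_e = sol$f_e),
    residuals = resid,
    status = status, params = p, optim = optim_info
  )
  structure(out, class = "steady_state")
}

#' Steady-state growth at maximal growth rate
#'
#' Solves the coarse-grained proteome-allocation model at one environmental
#' condition: the proteome mass fractions of the four growth-related classes
#' (T, M, R, P) are chosen to maximize the specific growth rate subject to
#' steady-state mass balance of the internal carbon, amino-acid and energy
#' pools and of every protein class (synthesis minus dilution minus
#' photodamage), a fixed total proteome density `Dc`, a fixed
#' growth-independent share `phi_Q`, and a maintenance energy drain.
#' Photodamaged photosynthetic units are degraded back to the amino-acid
#' pool and must be re-translated.
#'
#' The outer allocation search runs a Nelder-Mead optimization on
#' softmax-transformed mass fractions from several fixed starting points
#' (deterministic multi-start); the inner steady state at fixed allocation
#' is exact up to root-finding tolerance (see the vignette for the
#' reduction).
#'
#' @param params A [model_parameters()] object.
#' @param I Light intensity (umol photons m^-2 s^-1), scalar.
#' @param cix External inorganic carbon (mM).
#' @param start Optional warm-start vector (3 softmax coordinates), e.g. the
#'   `optim$par` of a previously solved neighbouring condition.
#' @param control List with `maxit` and `reltol` for the outer Nelder-Mead.
#' @return A `steady_state` object: growth rate `mu` (h^-1), pools,
#'   per-class concentrations and mass fractions, fluxes, ribosome
#'   allocation `beta`, active fractions `alpha`, balance residuals and
#'   solver status. If no allocation sustains positive growth (e.g. in
#'   darkness, where maintenance cannot be paid), a zero-growth state with
#'   an explanatory status is returned. Use [tidy()] for a one-row summary.
#' @examples
#' \donttest{
#' ss <- steady_state_growth(model_parameters(), I = 440)
#' ss$mu
#' tidy(ss)
#' }
#' @export
steady_state_growth <- function(params, I, cix = 100, start = NULL,
                                control = list()) {
  stopifnot(inherits(params, "model_parameters"))
  if (length(I) != 1 || I < 0) abort("`I` must be a non-negative scalar")
  if (cix < 0) abort("`cix` must be >= 0")
  ctrl <- modifyList(list(maxit = 500, reltol = 1e-10), control)
  budget <- 1 - params$phi_Q
  obj <- function(z) {
    s <- solve_allocation(params, I, cix, budget * .softmax(z))
    if (!s$ok) return(1e3 + 1e4 * s$deficit)
    -s$mu * 3600
  }
  starts <- list(c(-3, 0, 0), c(-4, -1, 1), c(-4, -2, -2))
  if (!is.null(start)) starts <- c(list(start), starts[1])
  best <- NULL
  for (z0 in starts) {
    o <- optim(z0, obj, method = "Nelder-Mead",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  phi <- budget * .softmax(best$par)
  sol <- solve_allocation(params, I, cix, phi)
  status <- if (sol$ok) {
    "converged"
  } else {
    "infeasible: maintenance and photodamage costs exceed attainable energy supply"
  }
  build_steady_state(params, I, cix, phi, c(1, 1, 1, 1), sol, status,
                     optim_info = list(par = best$par, value = best$value,
                                       counts = best$counts))
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>", x$status, "\n")
  cat(sprintf("  I = %g umol m^-2 s^-1, cix = %g mM\n", x$I, x$cix))
  cat(sprintf("  mu = %.5f h^-1 (doubling time %.1f h)\n", x$mu,
              if (x$mu > 0) log(2) / x$mu else Inf))
  fr <- setNames(x$concentrations$mass_fraction, x$concentrations$class)
  cat("  mass fractions:",
      paste(sprintf("%s = %.3f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname steady_state_growth
#' @param x A `steady_state` object.
#' @param ... Unused.
#' @method tidy steady_state
#' @export
tidy.steady_state <- function(x, ...) {
  fr <- setNames(x$concentrations$mass_fraction, x$concentrations$class)
  fx <- setNames(x$fluxes$value, x$fluxes$flux)
  tibble(
    I = x$I, cix = x$cix, mu = x$mu,
    fraction_T = fr[["T"]], fraction_M = fr[["M"]], fraction_R = fr[["R"]],
    fraction_P = fr[["P"]], fraction_Q = fr[["Q"]],
    ci = x$pools[["ci"]], aa = x$pools[["aa"]], e = x$pools[["e"]],
    vd = fx["vd"] %||% NA_real_, vt = fx["vt"] %||% NA_real_,
    vm = fx["vm"] %||% NA_real_, v1 = fx["v1"] %||% NA_real_,
    v2 = fx["v2"] %||% NA_real_, vi = fx["vi"] %||% NA_real_,
    mv = fx["mv"] %||% NA_real_,
    status = x$status
  )
}

#' Light-response curve of the allocation model
#'
#' Solves the steady-state growth-rate maximization over a grid of light
#' intensities, warm-starting each point from its predecessor, and returns
#' one row per intensity with the growth rate, the optimal proteome mass
#' fractions and all fluxes.
#'
#' @inheritParams steady_state_growth
#' @param I Non-decreasing vector of light intensities.
#' @return A tibble of class `light_response` (columns as in
#'   [tidy.steady_state()]); the solved `steady_state` objects are attached
#'   as attribute `"states"`.
#' @examples
#' \donttest{
#' lr <- light_response(model_parameters(), I = c(27.5, 110, 440, 1100))
#' lr[, c("I", "mu", "fraction_R", "fraction_P")]
#' }
#' @export
light_response <- function(params, I, cix = 100, control = list()) {
  if (length(I) < 1) abort("`I` must be non-empty")
  if (is.unsorted(I)) abort("`I` must be non-decreasing")
  states <- vector("list", length(I))
  start <- NULL
  for (i in seq_along(I)) {
    st <- tryCatch(
      steady_state_growth(params, I[i], cix, start = start,
                          control = control),
      error = function(e) e
    )
    states[[i]] <- st
    if (inherits(st, "steady_state") && st$status == "converged") {
      start <- st$optim$par
    }
  }
  rows <- purrr::map2(states, I, function(st, ii) {
    if (inherits(st, "steady_state")) {
      tidy(st)
    } else {
      tibble(I = ii, cix = cix, mu = NA_real_,
             status = paste("error:", conditionMessage(st)))
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "states") <- states
  attr(out, "params") <- params
  class(out) <- c("light_response", class(out))
  out
}

#' Write a light-response table as TSV
#'
#' @param lr A [light_response()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_light_response <- function(lr, path) {
  readr::write_tsv(as_tibble(lr), path)
  invisible(path)
}

#' Exhaustive allocation-simplex search
#'
#' Enumerates proteome mass fractions on a regular simplex grid and solves
#' the steady state at each point. This brute-force search is the
#' independent check of the nonlinear allocation optimization in
#' [steady_state_growth()]: on a grid of step `step`, the best enumerated
#' growth rate must never exceed the optimizer's and must approach it as the
#' step shrinks.
#'
#' @inheritParams steady_state_growth
#' @param step Grid step for the mass fractions (fraction of proteome).
#' @return A tibble with one row per feasible grid point (`phi_T`, `phi_M`,
#'   `phi_R`, `phi_P`, `mu`), sorted by decreasing `mu`.
#' @export
allocation_grid_search <- function(params, I, cix = 100, step = 0.05) {
  budget <- 1 - params$phi_Q
  k <- round(budget / step)
  if (abs(k * step - budget) > 1e-9) {
    abort("`step` must divide the growth-related proteome budget 1 - phi_Q")
  }
  pts <- expand.grid(a = 0:k, b = 0:k, c = 0:k)
  pts <- pts[pts$a + pts$b + pts$c <= k, ]
  res <- purrr::pmap(pts, function(a, b, c) {
    phi <- c(a, b, c, k - a - b - c) * step
    s <- solve_allocation(params, I, cix, phi)
    tibble(phi_T = phi[1], phi_M = phi[2], phi_R = phi[3], phi_P = phi[4],
           mu = if (s$ok) s$mu * 3600 else NA_real_)
  })
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out, dplyr::desc(!is.na(.data$mu)), dplyr::desc(.data$mu))
}

#' Growth under a clamped proteome fraction
#'
#' Repeats the growth-rate maximization of [steady_state_growth()] with the
#' mass fraction of one protein class (R, P or M) clamped at `phi_Z` (so its
#' concentration is `phi_Z * Dc / n_Z` units), emulating a cell that cannot
#' re-allocate that class. A free activity variable `alpha_Z` in `[0, 1]`
#' scales the catalytic activity of the clamped class (de/activation by
#' post-translational modification), and the remaining classes are
#' re-optimized. The constrained optimum can never exceed the unconstrained
#' one.
#'
#' @inheritParams steady_state_growth
#' @param class_id One of `"R"`, `"P"`, `"M"`.
#' @param phi_Z Clamped mass fraction, in `(0, 1 - phi_Q)`.
#' @return A `steady_state` object with the clamped fraction and fitted
#'   `alpha` recorded.
#' @examples
#' \donttest{
#' ss <- constrained_growth(model_parameters(), I = 440,
#'                          class_id = "R", phi_Z = 0.1)
#' }
#' @export
constrained_growth <- function(params, I, cix = 100, class_id = c("R", "P", "M"),
                               phi_Z, control = list()) {
  class_id <- match.arg(class_id)
  budget <- 1 - params$phi_Q
  if (!is.numeric(phi_Z) || phi_Z <= 0 || phi_Z >= budget) {
    abort(sprintf(
      "`phi_Z` = %g exceeds the growth-related proteome budget (0, %g)",
      phi_Z, budget))
  }
  ctrl <- modifyList(list(maxit = 600, reltol = 1e-12), control)
  idx <- c(T = 1, M = 2, R = 3, P = 4)[class_id]
  rest <- setdiff(1:4, idx)
  rest_budget <- budget - phi_Z
  make_phi <- function(z) {
    w <- .softmax(z[1:2])
    phi <- numeric(4)
    phi[idx] <- phi_Z
    phi[rest] <- rest_budget * w
    phi
  }
  make_alpha <- function(z) {
    alpha <- c(1, 1, 1, 1)
    alpha[idx] <- plogis(z[3])
    alpha
  }
  obj <- function(z) {
    s <- solve_allocation(params, I, cix, make_phi(z), make_alpha(z))
    if (!s$ok) return(1e3 + 1e4 * s$deficit)
    -s$mu * 3600
  }
  best <- NULL
  for (z0 in list(c(-3, 0, 6), c(-4, 1, 6), c(0, 0, 2))) {
    o <- optim(z0, obj, method = "Nelder-Mead",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  phi <- make_phi(best$par)
  alpha <- make_alpha(best$par)
  sol <- solve_allocation(params, I, cix, phi, alpha)
  status <- if (sol$ok) "converged" else {
    "infeasible: clamped fraction cannot sustain growth at this light"
  }
  st <- build_steady_state(params, I, cix, phi, alpha, sol, status,
                           optim_info = list(par = best$par,
                                             value = best$value,
                                             constrained_class = class_id,
                                             phi_Z = phi_Z))
  st
}
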