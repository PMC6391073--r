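#' Specific growth rate from a turbidostat OD trace
#'
#' In turbidostat operation the culture grows exponentially between dilution
#' events that reset the optical density to the lower bound of the control
#' band. Within each inter-dilution segment the specific growth rate is
#' \eqn{\mu = \ln(OD_{t_2}/OD_{t_1}) / (t_2 - t_1)} from the segment
#' endpoints; an ordinary least-squares slope of `log(od)` against time is
#' reported alongside as a robustness check. Dilution events are detected as
#' relative OD drops larger than `drop_threshold` between consecutive
#' samples unless event times are supplied.
#'
#' @param trace A tibble with columns `time` (h, strictly increasing) and
#'   `od680` (> 0), e.g. from [simulate_turbidostat()].
#' @param window Optional numeric length-2 time interval restricting the
#'   analysis.
#' @param dilution_events Optional vector of dilution time stamps; detected
#'   from the trace when `NULL`.
#' @param drop_threshold Relative OD drop between consecutive samples that
#'   marks a dilution event (default 3%).
#' @param segment If `FALSE`, the trace is treated as a single exponential
#'   segment; an error is raised if a dilution event falls inside the
#'   analysed window.
#' @return A tibble of class `growth_rate_estimate` with one row per
#'   segment (`t_start`, `t_end`, `n`, `mu`, `mu_ols`) and attributes
#'   `mu_mean`, `mu_sd`, `n_segments`.
#' @examples
#' tr <- simulate_turbidostat(0.05, duration = 48)
#' est <- growth_rate_from_od(tr)
#' attr(est, "mu_mean")
#' @export
growth_rate_from_od <- function(trace, window = NULL, dilution_events = NULL,
                                drop_threshold = 0.03, segment = TRUE) {
  need <- c("time", "od680")
  miss <- setdiff(need, names(trace))
  if (length(miss) > 0) {
    abort(paste("trace is missing columns:", paste(miss, collapse = ", ")))
  }
  if (any(trace$od680 <= 0)) abort("optical density must be positive")
  if (is.unsorted(trace$time, strictly = TRUE)) {
    abort("`time` must be strictly increasing")
  }
  if (!is.null(window)) {
    keep <- trace$time >= window[1] & trace$time <= window[2]
    sub <- trace[keep, ]
  } else {
    sub <- trace
  }
  if (nrow(sub) < 2) abort("window must contain at least two samples")
  if (is.null(dilution_events)) {
    drops <- which(sub$od680[-1] / sub$od680[-nrow(sub)] < 1 - drop_threshold)
    event_idx <- drops + 1          # first sample after the reset
  } else {
    event_idx <- vapply(dilution_events, function(t0) {
      w <- which(sub$time >= t0)
      if (length(w) == 0) NA_integer_ else w[1]
    }, integer(1))
    event_idx <- sort(unique(event_idx[!is.na(event_idx)]))
    event_idx <- event_idx[event_idx > 1]
  }
  if (!segment && length(event_idx) > 0) {
    abort("window spans a dilution event; use segment = TRUE or narrow it")
  }
  bounds <- c(1, event_idx, nrow(sub) + 1)
  segs <- purrr::map(seq_len(length(bounds) - 1), function(i) {
    rows <- sub[bounds[i]:(bounds[i + 1] - 1), ]
    if (nrow(rows) < 2) return(NULL)
    dt <- rows$time[nrow(rows)] - rows$time[1]
    if (dt <= 0) return(NULL)
    mu <- log(rows$od680[nrow(rows)] / rows$od680[1]) / dt
    mu_ols <- unname(coef(lm(log(od680) ~ time, data = rows))[2])
    tibble(t_start = rows$time[1], t_end = rows$time[nrow(rows)],
           n = nrow(rows), mu = mu, mu_ols = mu_ols)
  })
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) abort("no segment with at least two samples")
  attr(out, "mu_mean") <- mean(out$mu)
  attr(out, "mu_sd") <- if (nrow(out) > 1) sd(out$mu) else NA_real_
  attr(out, "n_segments") <- nrow(out)
  class(out) <- c("growth_rate_estimate", class(out))
  out
}

#' Doubling time from a specific growth rate
#'
#' @param mu Specific growth rate (h^-1, > 0).
#' @return Doubling time `log(2) / mu` in hours.
#' @examples
#' doubling_time(0.025)  # ~27.7 h
#' doubling_time(0.093)  # ~7.5 h
#' @export
doubling_time <- function(mu) {
  if (any(mu <= 0)) abort("`mu` must be > 0")
  log(2) / mu
}

#' Specific growth rate from medium-balance depletion
#'
#' In a turbidostat the steady-state specific growth rate equals the
#' dilution rate, i.e. the average inflow rate of fresh medium divided by
#' the culture volume: `mu = f / V`.
#'
#' @param f Average medium inflow rate (mL h^-1), or a tibble with columns
#'   `time` (h) and `mass` (g, cumulative depletion of the spare-medium
#'   bottle) from which `f` is estimated as the negative OLS slope
#'   (assuming density 1 g mL^-1).
#' @param V Culture volume (mL, > 0).
#' @return Specific growth rate (h^-1). When `f` is a trace, the estimate's
#'   standard error is attached as attribute `"se"`.
#' @examples
#' growth_rate_from_balance(40, 400)  # 0.1 h^-1
#' @export
growth_rate_from_balance <- function(f, V) {
  if (!is.numeric(V) || V <= 0) abort("culture volume `V` must be > 0")
  if (is.data.frame(f)) {
    miss <- setdiff(c("time", "mass"), names(f))
    if (length(miss) > 0) {
      abort(paste("balance trace missing columns:", paste(miss, collapse = ", ")))
    }
    fit <- lm(mass ~ time, data = f)
    flow <- -unname(coef(fit)[2])
    se <- suppressWarnings(summary(fit))$coefficients[2, 2]
    out <- flow / V
    attr(out, "se") <- se / V
    return(out)
  }
  if (f < 0) abort("inflow rate `f` must be >= 0")
  f / V
}

#' Photosynthesis and respiration rates from a dissolved-oxygen trace
#'
#' With aeration off, the culture is cycled through light and dark phases
#' (typically 5 min each). The net O2 evolution rate (NP) is the slope of
#' dissolved O2 during light phases; the dark respiration rate (R) is the
#' negative of the dark-phase slope; gross photosynthesis is their sum,
#' `GP = NP + R` (photorespiration neglected). Slopes are ordinary
#' least-squares fits over each annotated phase, excluding the first
#' `skip_s` seconds as a mixing transient, and averaged over phase
#' repetitions. The trace's concentration and time units are propagated
#' untouched; normalize inputs to the basis you want rates in (per gDW or
#' per mmol Chl).
#'
#' @param trace A tibble with columns `time` (seconds), `do2` (dissolved
#'   oxygen), `phase` (`"light"`/`"dark"`), e.g. from
#'   [simulate_gas_trace()].
#' @param co2_uptake Optional net CO2 uptake rate measured from the
#'   steady-state efflux deficit, same unit basis as the O2 rates.
#' @param skip_s Seconds discarded at the start of each phase.
#' @return A one-row tibble of class `gas_exchange_record` with columns
#'   `np`, `r_dark`, `gp`, `co2_uptake`, `np_se`, `r_se` and
#'   `dark_slope_positive` (diagnostic flag; a positive dark slope is
#'   clamped to zero respiration).
#' @examples
#' tr <- simulate_gas_trace(np = 1.61 / 3600, r_dark = 0.35 / 3600)
#' gas_exchange_rates(tr)
#' @export
gas_exchange_rates <- function(trace, co2_uptake = NA_real_, skip_s = 30) {
  miss <- setdiff(c("time", "do2", "phase"), names(trace))
  if (length(miss) > 0) {
    abort(paste("gas trace missing columns:", paste(miss, collapse = ", ")))
  }
  if (!all(trace$phase %in% c("light", "dark"))) {
    abort("`phase` must be annotated as \"light\" or \"dark\"")
  }
  runs <- rle(as.character(trace$phase))
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  slope_of <- function(rows) {
    rows <- rows[rows$time >= rows$time[1] + skip_s, ]
    if (nrow(rows) < 2 || length(unique(rows$do2)) == 1) {
      fit <- NULL
    } else {
      fit <- lm(do2 ~ time, data = rows)
    }
    if (is.null(fit)) {
      c(slope = if (nrow(rows) >= 2) 0 else NA_real_, se = NA_real_)
    } else {
      s <- suppressWarnings(summary(fit))$coefficients
      c(slope = unname(s[2, 1]), se = unname(s[2, 2]))
    }
  }
  per_phase <- purrr::map(seq_along(runs$values), function(i) {
    rows <- trace[starts[i]:ends[i], ]
    sl <- slope_of(rows)
    tibble(phase = runs$values[i], slope = sl["slope"], se = sl["se"])
  })
  per_phase <- dplyr::bind_rows(per_phase)
  agg <- function(ph) {
    d <- per_phase[per_phase$phase == ph & !is.na(per_phase$slope), ]
    if (nrow(d) == 0) abort(sprintf("no usable %s phase in trace", ph))
    c(mean(d$slope), if (nrow(d) > 1) sd(d$slope) / sqrt(nrow(d)) else
      mean(d$se, na.rm = TRUE))
  }
  li <- agg("light"); dk <- agg("dark")
  np <- li[1]
  r_dark <- -dk[1]
  positive_dark <- r_dark < 0
  if (positive_dark) {
    warn("dark-phase dO2 slope is positive; respiration clamped at 0")
    r_dark <- 0
  }
  out <- tibble(np = np, r_dark = r_dark, gp = np + r_dark,
                co2_uptake = co2_uptake, np_se = li[2], r_se = dk[2],
                dark_slope_positive = positive_dark)
  class(out) <- c("gas_exchange_record", class(out))
  out
}

#' Build a gas-exchange record from already-estimated rates
#'
#' @param np Net O2 evolution rate.
#' @param r_dark Dark respiration rate (>= 0).
#' @param co2_uptake Net CO2 uptake rate.
#' @return A `gas_exchange_record` tibble with `gp = np + r_dark`.
#' @export
gas_exchange_record <- function(np, r_dark, co2_uptake = NA_real_) {
  if (r_dark < 0) abort("`r_dark` must be >= 0")
  out <- tibble(np = np, r_dark = r_dark, gp = np + r_dark,
                co2_uptake = co2_uptake, np_se = NA_real_, r_se = NA_real_,
                dark_slope_positive = FALSE)
  class(out) <- c("gas_exchange_record", class(out))
  out
}

#' Photosynthesis-to-respiration ratio and photosynthetic quotient
#'
#' `P:R = GP / R` compares gross O2 release to dark O2 consumption; the
#' photosynthetic quotient `PQ = NP / CO2 = (GP - R) / CO2` compares net O2
#' release to net CO2 fixation. Ratios with a non-positive denominator are
#' returned as `NA` (undefined) rather than raising an error.
#'
#' @param rec A [gas_exchange_record()] (or the output of
#'   [gas_exchange_rates()]).
#' @return A one-row tibble with columns `p_r` and `pq`.
#' @examples
#' photosynthesis_ratios(gas_exchange_record(np = 1.61, r_dark = 0.35,
#'                                           co2_uptake = 0.78))
#' @export
photosynthesis_ratios <- function(rec) {
  stopifnot(all(c("np", "r_dark", "gp") %in% names(rec)))
  p_r <- ifelse(rec$r_dark > 0, rec$gp / rec$r_dark, NA_real_)
  pq <- ifelse(!is.na(rec$co2_uptake) & rec$co2_uptake > 0,
               rec$np / rec$co2_uptake, NA_real_)
  tibble(p_r = p_r, pq = pq)
}

#' Volume of a spherical cell
#'
#' @param diameter Cell diameter (um, >= 0).
#' @return Cell volume `pi * d^3 / 6` (um^3).
#' @examples
#' sphere_volume(2.19)  # ~5.49 um^3
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) abort("`diameter` must be >= 0")
  pi * diameter^3 / 6
}

#' Convert cellular contents between per-dry-weight and per-cell bases
#'
#' A content of `x` mg per gDW in a cell of dry weight `w` pg corresponds to
#' `x * w` fg per cell (the mg/g and pg scales compose to femtograms
#' exactly). The two functions are exact inverses.
#'
#' @param per_gdw Content per dry weight (mg gDW^-1).
#' @param per_cell Content per cell (fg cell^-1).
#' @param dry_weight Cellular dry weight (pg cell^-1, > 0).
#' @return The converted content (fg cell^-1, or mg gDW^-1).
#' @examples
#' per_gdw_to_per_cell(84, 5.3)    # glycogen: ~445 fg per cell
#' per_cell_to_per_gdw(445.2, 5.3)
#' @export
per_gdw_to_per_cell <- function(per_gdw, dry_weight) {
  if (any(dry_weight <= 0)) abort("`dry_weight` must be > 0")
  per_gdw * dry_weight
}

#' @rdname per_gdw_to_per_cell
#' @export
per_cell_to_per_gdw <- function(per_cell, dry_weight) {
  if (any(dry_weight <= 0)) abort("`dry_weight` must be > 0")
  per_cell / dry_weight
}

#' Nutrient refill-versus-consumption balance in turbidostat culture
#'
#' For each medium element, compares the refill rate supplied by dilution
#' (`dilution_rate * medium concentration`) with the biomass consumption
#' (`mu * biomass density * elemental quota`). A negative margin flags an
#' element whose refilling cannot keep up with uptake.
#'
#' @param dilution_rate Dilution rate (h^-1); in turbidostat steady state
#'   equal to the specific growth rate.
#' @param medium Tibble with columns `element` and `conc` (mmol L^-1).
#' @param quotas Tibble with columns `element` and `quota`
#'   (mmol gDW^-1).
#' @param biomass Biomass density (gDW L^-1).
#' @param mu Specific growth rate (h^-1); defaults to the dilution rate.
#' @return A tibble with one row per element present in both tables:
#'   `refill`, `consumption`, `margin` (all mmol L^-1 h^-1) and `deficient`;
#'   elements missing from either table are listed in attribute
#'   `"unmatched"`.
#' @export
nutrient_balance <- function(dilution_rate, medium, quotas, biomass,
                             mu = dilution_rate) {
  stopifnot(all(c("element", "conc") %in% names(medium)),
            all(c("element", "quota") %in% names(quotas)))
  if (any(medium$conc < 0) || any(quotas$quota < 0) || biomass <= 0) {
    abort("concentrations, quotas and biomass must be positive")
  }
  joined <- dplyr::inner_join(medium, quotas, by = "element")
  unmatched <- union(setdiff(medium$element, quotas$element),
                     setdiff(quotas$element, medium$element))
  out <- joined |>
    dplyr::mutate(
      refill = dilution_rate * .data$conc,
      consumption = mu * biomass * .data$quota,
      margin = .data$refill - .data$consumption,
      deficient = .data$margin < 0
    ) |>
    dplyr::select("element", "refill", "consumption", "margin", "deficient")
  attr(out, "unmatched") <- unmatched
  out
}
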