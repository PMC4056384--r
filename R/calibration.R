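#' BGO gain-temperature model and reference-spectrum energy rescaling
#'
#' BGO light output falls by about 1.2% per kelvin, which shifts the whole
#' measured energy scale.  The prototype procedure records the photopeak of a
#' 99mTc reference source at thermal equilibrium and rescales subsequent
#' event energies by the ratio nominal/measured peak.
#'
#' @name ybrems-calibration
NULL

#' Temperature gain model
#'
#' @param t0_K reference temperature (K).
#' @param coefficient fractional light-yield change per kelvin; default
#'   -0.012 (BGO).
#' @return object of class `gain_model`.
#' @export
gain_model <- function(t0_K = 293.15, coefficient = -0.012) {
  structure(list(t0 = t0_K, coefficient = coefficient), class = "gain_model")
}

#' Multiplicative gain factor at a temperature
#'
#' Linear model 1 + coefficient * (T - T0); the factor multiplies every
#' measured energy.
#'
#' @param model a [gain_model()].
#' @param t_K temperature (K), vectorized.
#' @return gain factor(s), > 0.
#' @export
#' @examples
#' gain_factor(gain_model(293.15), 298.15)  # 5 K warmer -> 0.94
gain_factor <- function(model, t_K) {
  g <- 1 + model$coefficient * (t_K - model$t0)
  if (any(g <= 0)) stop("temperature outside the supported span: gain <= 0")
  g
}

#' Reference spectrum container
#'
#' @param energy_keV bin centers (keV), strictly increasing.
#' @param counts counts per bin, >= 0.
#' @param nominal_peak_keV nominal photopeak energy; default the 99mTc
#'   140.5 keV line.
#' @return object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(energy_keV, counts, nominal_peak_keV = 140.5) {
  stopifnot(length(energy_keV) == length(counts), all(diff(energy_keV) > 0),
            all(counts >= 0))
  structure(list(energy = energy_keV, counts = counts,
                 nominal_peak = nominal_peak_keV),
            class = "reference_spectrum")
}

#' Simulate a reference photopeak spectrum
#'
#' Gaussian photopeak on a uniform energy grid, optionally Poisson-noised:
#' a stand-in for the per-block 99mTc spectra recorded at thermal
#' equilibrium.
#'
#' @param peak_keV true peak position.
#' @param fwhm_keV peak full width at half maximum.
#' @param total_counts expected counts in the peak.
#' @param grid energy bin centers.
#' @param seed if not `NULL`, Poisson-noise the bins with this seed.
#' @return a [reference_spectrum()].
#' @export
simulate_reference_spectrum <- function(peak_keV = 140.5, fwhm_keV = 15,
                                        total_counts = 1e4,
                                        grid = seq(80, 200, by = 1),
                                        seed = NULL) {
  sigma <- fwhm_keV / 2.354820045
  shape <- exp(-(grid - peak_keV)^2 / (2 * sigma^2))
  mean_counts <- total_counts * shape / sum(shape)
  counts <- if (is.null(seed)) mean_counts else
    .with_seed(seed, rpois(length(grid), mean_counts))
  reference_spectrum(grid, counts, nominal_peak_keV = peak_keV)
}

#' Fit the photopeak centroid of a reference spectrum
#'
#' Gaussian fit (nonlinear least squares) of the windowed peak; falls back
#' to the count-weighted centroid of the window if the fit does not
#' converge.
#'
#' @param spectrum a [reference_spectrum()].
#' @param window `c(lo, hi)` keV; must contain a local maximum.
#' @return fitted peak position (keV).
#' @export
fit_peak <- function(spectrum, window = NULL) {
  stopifnot(inherits(spectrum, "reference_spectrum"))
  e <- spectrum$energy; c0 <- spectrum$counts
  if (is.null(window)) window <- range(e)
  sel <- e >= window[1] & e <= window[2]
  if (sum(sel) < 4) stop("fit window too narrow")
  es <- e[sel]; cs <- c0[sel]
  imax <- which.max(cs)
  if (cs[imax] <= 0) stop("no peak found in the fit window")
  interior <- imax > 1 && imax < length(cs)
  if (!interior) {
    # peak must be a local maximum inside the window
    stop("no local maximum inside the fit window")
  }
  start <- list(a = cs[imax], m = es[imax],
                s = max(diff(window) / 10, diff(es)[1]))
  fit <- tryCatch(
    suppressWarnings(   # zero-residual fits trip nls convergence warnings
      nls(cs ~ a * exp(-(es - m)^2 / (2 * s^2)), start = start,
          control = list(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    m <- coef(fit)[["m"]]
    if (m >= window[1] && m <= window[2]) return(m)
  }
  sum(es * cs) / sum(cs)
}

#' Rescale measured event energies to the nominal reference peak
#'
#' Every event energy is multiplied by `nominal_peak / measured_peak`
#' (linear-through-zero gain correction).
#'
#' @param events_keV measured event energies.
#' @param measured_peak fitted reference peak on the day of acquisition
#'   (keV), > 0.
#' @param nominal_peak nominal reference peak (keV); default 140.5 (99mTc).
#' @return corrected energies (keV).
#' @export
rescale_energies <- function(events_keV, measured_peak,
                             nominal_peak = 140.5) {
  if (measured_peak <= 0) stop("measured peak must be positive")
  events_keV * (nominal_peak / measured_peak)
}

#' Per-block energy rescaling of an event list
#'
#' Applies [rescale_energies()] block by block: each camera block has its
#' own measured reference peak (BGO blocks drift independently with
#' temperature).  Blocks without a measured peak fall back to the single
#' overall factor if one is given, otherwise error.
#'
#' @param events data.frame with columns `block_id` and `energy_keV`.
#' @param measured_peaks named numeric vector of fitted peaks (keV), names
#'   are block ids.
#' @param nominal_peak nominal reference peak (keV).
#' @param fallback_peak optional measured peak for blocks missing from
#'   `measured_peaks`.
#' @return `events` with `energy_keV` corrected.
#' @export
rescale_events <- function(events, measured_peaks, nominal_peak = 140.5,
                           fallback_peak = NULL) {
  stopifnot(all(c("block_id", "energy_keV") %in% names(events)))
  out <- events
  for (b in unique(events$block_id)) {
    pk <- unname(measured_peaks[as.character(b)])
    if (length(pk) == 0 || is.na(pk)) {
      if (is.null(fallback_peak)) {
        stop("no measured peak for block '", b, "' and no fallback")
      }
      pk <- fallback_peak
    }
    sel <- events$block_id == b
    out$energy_keV[sel] <- rescale_energies(events$energy_keV[sel], pk,
                                            nominal_peak)
  }
  out
}
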