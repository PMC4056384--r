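#' Physical-constant tables and evaluators
#'
#' The package bundles narrow-beam photon cross-section tables (photoelectric
#' and incoherent channels; coherent scattering is excluded from the total by
#' the narrow-beam convention) for the materials relevant to bremsstrahlung
#' camera design, on a logarithmic 30 keV to 3 MeV grid, plus the relative
#' yttrium-90 bremsstrahlung yield spectrum in water.  All energies are keV,
#' lengths cm, linear attenuation coefficients 1/cm.
#'
#' @name ybrems-physics
NULL

.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "ybrems", mustWork = FALSE)
  if (!nzchar(p)) stop("bundled data file not found: ", file.path(...))
  p
}

.materials_manifest <- function() {
  if (is.null(.ybrems_cache$manifest)) {
    .ybrems_cache$manifest <- jsonlite::read_json(
      .extdata("attenuation", "materials.json"))
  }
  .ybrems_cache$manifest
}

#' Look up a bundled material
#'
#' @param name material identifier, e.g. `"water"`, `"NaI"`, `"BGO"`, `"GSO"`,
#'   `"CdWO4"`, `"lead"`, `"tungsten"`, `"tin"`, `"perpex"`, `"air"`.  A
#'   `material` object is passed through unchanged.
#' @return An object of class `material` with fields `name`, `density`
#'   (g/cm^3) and `composition` (named element mass fractions).
#' @export
#' @examples
#' material("water")$density
material <- function(name) {
  if (inherits(name, "material")) return(name)
  man <- .materials_manifest()
  if (!name %in% names(man)) {
    stop("unknown material: '", name, "'. Known: ",
         paste(names(man), collapse = ", "))
  }
  m <- man[[name]]
  structure(list(name = name,
                 density = m$density_g_cm3,
                 composition = unlist(m$composition)),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material %s> density %.4g g/cm^3; %s\n", x$name, x$density,
              paste(sprintf("%s=%.4g", names(x$composition), x$composition),
                    collapse = " ")))
  invisible(x)
}

#' Bundled mass attenuation table for a material
#'
#' @param mat material name or object.
#' @return data.frame with columns `energy_keV`, `mu_over_rho_total`,
#'   `mu_over_rho_pe`, `mu_over_rho_incoh` (cm^2/g), ascending energies.
#' @export
attenuation_table <- function(mat) {
  mat <- material(mat)
  key <- paste0("att_", mat$name)
  if (is.null(.ybrems_cache[[key]])) {
    tab <- read.csv(.extdata("attenuation", paste0(mat$name, ".csv")))
    stopifnot(all(diff(tab$energy_keV) > 0), all(tab$mu_over_rho_total > 0))
    .ybrems_cache[[key]] <- tab
  }
  .ybrems_cache[[key]]
}

.channel_column <- function(channel) {
  switch(match.arg(channel, c("total", "photoelectric", "incoherent")),
         total = "mu_over_rho_total",
         photoelectric = "mu_over_rho_pe",
         incoherent = "mu_over_rho_incoh")
}

#' Linear attenuation coefficient
#'
#' Log-log linear interpolation of the bundled mass attenuation table times
#' the material density; exact at table knots.
#'
#' @param mat material name or object.
#' @param energy_keV photon energy (keV), vectorized.
#' @param channel `"total"` (default, photoelectric + incoherent),
#'   `"photoelectric"` or `"incoherent"`.
#' @return mu in 1/cm, same length as `energy_keV`.
#' @export
#' @examples
#' attenuation_coefficient("water", c(100, 200, 500))
attenuation_coefficient <- function(mat, energy_keV,
                                    channel = c("total", "photoelectric",
                                                "incoherent")) {
  mat <- material(mat)
  tab <- attenuation_table(mat)
  if (any(!is.finite(energy_keV)) ||
      any(energy_keV < tab$energy_keV[1] - 1e-9) ||
      any(energy_keV > tab$energy_keV[nrow(tab)] + 1e-9)) {
    stop(sprintf("energy outside bundled table range [%g, %g] keV for %s",
                 tab$energy_keV[1], tab$energy_keV[nrow(tab)], mat$name))
  }
  col <- .channel_column(channel)
  y <- exp(approx(log(tab$energy_keV), log(tab[[col]]),
                  xout = log(pmin(pmax(energy_keV, tab$energy_keV[1]),
                                  tab$energy_keV[nrow(tab)])))$y)
  y * mat$density
}

.water_mu_knots <- function() {
  if (is.null(.ybrems_cache$water_knots)) {
    tab <- attenuation_table("water")
    d <- material("water")$density
    .ybrems_cache$water_knots <- list(E = tab$energy_keV,
                                      mu = tab$mu_over_rho_total * d)
  }
  .ybrems_cache$water_knots
}

#' Invert the water attenuation coefficient
#'
#' The total attenuation coefficient of water is strictly decreasing over the
#' bundled range, so mu <-> E is a bijection.  The inverse is computed
#' exactly on the piecewise log-log representation of the table.
#'
#' @param mu linear attenuation coefficient of water (1/cm), vectorized.
#' @return energy in keV.
#' @export
#' @examples
#' energy_from_mu(attenuation_coefficient("water", 150))
energy_from_mu <- function(mu) {
  k <- .water_mu_knots()
  n <- length(k$E)
  mu_hi <- k$mu[1]; mu_lo <- k$mu[n]      # mu decreasing in E
  if (any(!is.finite(mu)) || any(mu > mu_hi * (1 + 1e-9)) ||
      any(mu < mu_lo * (1 - 1e-9))) {
    stop(sprintf("mu outside attainable water range [%g, %g] 1/cm",
                 mu_lo, mu_hi))
  }
  mu <- pmin(pmax(mu, mu_lo), mu_hi)
  # locate segment on the descending mu knots
  i <- findInterval(-mu, -k$mu, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  b <- (log(k$mu[i + 1]) - log(k$mu[i])) / (log(k$E[i + 1]) - log(k$E[i]))
  exp(log(k$E[i]) + (log(mu) - log(k$mu[i])) / b)
}

#' Yttrium-90 bremsstrahlung yield spectrum
#'
#' Relative number of bremsstrahlung x-rays produced in water per decay and
#' per keV, interpolated from the bundled default table (Kramers thin-target
#' shape folded over an allowed-shape approximation of the beta spectrum,
#' unit integral).  Zero at and above the beta endpoint.
#'
#' @param energy_keV photon energy (keV), vectorized; must be positive.
#' @param table optional replacement table (data.frame with `energy_keV`,
#'   `yield_per_keV`).
#' @return relative yield (1/keV).
#' @export
brems_yield <- function(energy_keV, table = NULL) {
  if (any(energy_keV < 0)) stop("negative energy in brems_yield()")
  if (is.null(table)) {
    if (is.null(.ybrems_cache$brems)) {
      .ybrems_cache$brems <- read.csv(.extdata("brems_yield_y90.csv"))
    }
    table <- .ybrems_cache$brems
  }
  e_max <- max(table$energy_keV)
  y <- approx(table$energy_keV, table$yield_per_keV, xout = energy_keV,
              rule = 2)$y
  y[energy_keV >= e_max] <- 0
  pmax(y, 0)
}

#' Analytic slab absorption probability
#'
#' Probability that a photon at normal incidence interacts anywhere in a slab
#' of the given thickness: 1 - exp(-mu_total * t).  This is the
#' attenuation-based reading of crystal "absorption efficiency"; see
#' [simulate_full_energy_efficiency()] for the full-energy Monte Carlo
#' reading.
#'
#' @param mat material name or object.
#' @param thickness_cm slab thickness (cm), >= 0.
#' @param energy_keV photon energy (keV).
#' @return probability in \[0, 1).
#' @export
absorption_probability <- function(mat, thickness_cm, energy_keV) {
  if (any(thickness_cm < 0)) stop("negative thickness")
  1 - exp(-attenuation_coefficient(mat, energy_keV, "total") * thickness_cm)
}
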