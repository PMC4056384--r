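#' Scintillator slab and full-energy photon-transport Monte Carlo
#'
#' Desk-scale transport of a pencil beam at normal incidence on an
#' infinite-transverse scintillator slab.  Photons undergo photoelectric
#' absorption or Klein-Nishina Compton scattering (free electrons); the
#' scattered photon is tracked until it is absorbed or escapes through a
#' slab face.  Electrons are assumed locally absorbed (no electron
#' transport, no fluorescence escape), so a history deposits the full
#' incident energy exactly when its photon chain ends in absorption.
#'
#' @name ybrems-crystalmc
NULL

.MEC2 <- 510.99895   # electron rest energy, keV

#' Crystal slab description
#'
#' @param mat material name or object (e.g. `"BGO"`, `"GSO"`, `"NaI"`,
#'   `"CdWO4"`).
#' @param thickness_cm slab thickness (cm), > 0.
#' @return object of class `crystal_slab`.
#' @export
crystal_slab <- function(mat, thickness_cm) {
  if (thickness_cm <= 0) stop("slab thickness must be > 0")
  structure(list(material = material(mat), thickness = thickness_cm),
            class = "crystal_slab")
}

#' @export
print.crystal_slab <- function(x, ...) {
  cat(sprintf("<crystal_slab> %s, %.3f cm\n", x$material$name, x$thickness))
  invisible(x)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# vectorized rejection sampling of the Klein-Nishina energy ratio
.kn_sample_eps <- function(E) {
  alpha <- E / .MEC2
  eps_min <- 1 / (1 + 2 * alpha)
  out <- rep(NA_real_, length(E))
  todo <- seq_along(E)
  guard <- 0L
  while (length(todo) > 0) {
    guard <- guard + 1L
    if (guard > 10000L) stop("Klein-Nishina sampler failed to converge")
    em <- eps_min[todo]; al <- alpha[todo]
    eps <- runif(length(todo), em, 1)
    ct <- 1 + 1 / al - 1 / (al * eps)
    g <- eps + 1 / eps - (1 - ct^2)
    acc <- runif(length(todo)) * (1 / em + 1) <= g
    out[todo[acc]] <- eps[acc]
    todo <- todo[!acc]
  }
  out
}

#' Sample the Klein-Nishina differential cross section
#'
#' Rejection sampling of the scattered-to-incident energy ratio from the
#' Klein-Nishina distribution, with the polar scattering angle given by
#' Compton kinematics.
#'
#' @param energy_keV incident photon energy (keV), scalar or vector; > 0.
#' @param n number of samples when `energy_keV` is scalar.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return data.frame with columns `scattered_energy` (keV) and
#'   `polar_angle` (rad).
#' @export
klein_nishina_sample <- function(energy_keV, n = length(energy_keV),
                                 seed = NULL) {
  if (any(energy_keV <= 0)) stop("energy must be positive")
  E <- rep_len(energy_keV, n)
  draw <- function() {
    eps <- .kn_sample_eps(E)
    ct <- 1 + .MEC2 / E - .MEC2 / (E * eps)
    data.frame(scattered_energy = eps * E, polar_angle = acos(pmin(pmax(ct, -1), 1)))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

# Klein-Nishina density in eps (unnormalized), used by tests as quadrature
# oracle: d sigma / d eps proportional to eps + 1/eps - sin^2(theta(eps))
#' @rdname klein_nishina_sample
#' @param eps scattered-to-incident energy ratio.
#' @export
klein_nishina_density <- function(eps, energy_keV) {
  ct <- 1 + .MEC2 / energy_keV - .MEC2 / (energy_keV * eps)
  ifelse(eps >= 1 / (1 + 2 * energy_keV / .MEC2) & eps <= 1,
         eps + 1 / eps - (1 - ct^2), 0)
}

.mu_lookup <- function(mat, channel) {
  tab <- attenuation_table(mat)
  rho <- material(mat)$density
  f <- approxfun(log(tab$energy_keV), log(tab[[.channel_column(channel)]] * rho),
                 rule = 2)
  emin <- tab$energy_keV[1]; emax <- tab$energy_keV[nrow(tab)]
  function(E) exp(f(log(pmin(pmax(E, emin), emax))))
}

#' Full-energy absorption efficiency of a crystal slab (Monte Carlo)
#'
#' @param slab a [crystal_slab()].
#' @param energy_keV incident photon energy (keV); must be inside the
#'   bundled tables.
#' @param n number of histories, >= 1.
#' @param seed integer seed; required for reproducibility.
#' @param compton if `FALSE`, photoelectric-only test mode (transport with
#'   the photoelectric coefficient alone; efficiency then equals
#'   1 - exp(-mu_pe t) up to Monte Carlo error).
#' @param mode `"full_energy"` (fraction of histories depositing the entire
#'   incident energy) or `"attenuation"` (fraction interacting at all).
#' @param e_cut photons falling below this energy are absorbed on the spot
#'   (the bundled tables start at 30 keV; such photons have sub-millimeter
#'   ranges in any scintillator).
#' @return object of class `transport_result` with fields `n_histories`,
#'   `n_full_energy`, `n_partial`, `n_no_interaction`, `efficiency`,
#'   `standard_error`.
#' @export
simulate_full_energy_efficiency <- function(slab, energy_keV, n, seed,
                                            compton = TRUE,
                                            mode = c("full_energy",
                                                     "attenuation"),
                                            e_cut = 30) {
  stopifnot(inherits(slab, "crystal_slab"), n >= 1)
  mode <- match.arg(mode)
  tab <- attenuation_table(slab$material)
  if (energy_keV < tab$energy_keV[1] || energy_keV > tab$energy_keV[nrow(tab)]) {
    stop("incident energy outside the bundled attenuation tables")
  }
  mu_pe <- .mu_lookup(slab$material, "photoelectric")
  mu_in <- .mu_lookup(slab$material, "incoherent")
  t_cm <- slab$thickness

  run <- function() {
    z <- numeric(n); w <- rep(1, n); E <- rep(energy_keV, n)
    n_int <- integer(n)
    absorbed <- logical(n); escaped <- logical(n)
    alive <- rep(TRUE, n)
    guard <- 0L
    while (any(alive)) {
      guard <- guard + 1L
      if (guard > 10000L) stop("transport failed to terminate")
      i <- which(alive)
      mpe <- mu_pe(E[i])
      mtot <- if (compton) mpe + mu_in(E[i]) else mpe
      s <- rexp(length(i)) / mtot
      znew <- z[i] + s * w[i]
      out <- znew < 0 | znew > t_cm
      escaped[i[out]] <- TRUE
      alive[i[out]] <- FALSE
      i <- i[!out]
      if (length(i) == 0) next
      z[i] <- znew[!out]
      n_int[i] <- n_int[i] + 1L
      p_pe <- if (compton) mpe[!out] / mtot[!out] else rep(1, length(i))
      is_pe <- runif(length(i)) <= p_pe
      absorbed[i[is_pe]] <- TRUE
      alive[i[is_pe]] <- FALSE
      i <- i[!is_pe]
      if (length(i) == 0) next
      # Compton scatter: new energy and direction
      eps <- .kn_sample_eps(E[i])
      ct <- 1 + .MEC2 / E[i] - .MEC2 / (E[i] * eps)
      ct <- pmin(pmax(ct, -1), 1)
      st <- sqrt(1 - ct^2)
      phi <- runif(length(i), 0, 2 * pi)
      sw <- sqrt(pmax(1 - w[i]^2, 0))
      w[i] <- w[i] * ct + sw * st * cos(phi)
      E[i] <- eps * E[i]
      low <- E[i] < e_cut
      absorbed[i[low]] <- TRUE
      alive[i[low]] <- FALSE
    }
    list(absorbed = absorbed, escaped = escaped, n_int = n_int)
  }
  res <- .with_seed(seed, run())

  n_full <- sum(res$absorbed)
  n_none <- sum(res$escaped & res$n_int == 0L)
  n_part <- n - n_full - n_none
  k <- if (mode == "full_energy") n_full else n - n_none
  p <- k / n
  structure(list(n_histories = n, n_full_energy = n_full, n_partial = n_part,
                 n_no_interaction = n_none, efficiency = p,
                 standard_error = sqrt(p * (1 - p) / n),
                 mode = mode, seed = seed, energy_keV = energy_keV,
                 material = slab$material$name, thickness_cm = t_cm),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(
    "<transport_result> %s %.3f cm at %g keV: %s efficiency %.4f +/- %.4f (n=%d)\n",
    x$material, x$thickness_cm, x$energy_keV, x$mode, x$efficiency,
    x$standard_error, x$n_histories))
  invisible(x)
}

#' Efficiency versus energy curve
#'
#' @param slab a [crystal_slab()].
#' @param energies energy grid (keV).
#' @param n histories per energy.
#' @param seed base seed; energy k uses `seed + k - 1`.
#' @inheritParams simulate_full_energy_efficiency
#' @return data.frame with columns `energy_keV`, `efficiency`, `stderr`.
#' @export
efficiency_curve <- function(slab, energies, n, seed, compton = TRUE,
                             mode = "full_energy") {
  rows <- lapply(seq_along(energies), function(k) {
    r <- simulate_full_energy_efficiency(slab, energies[k], n, seed + k - 1L,
                                         compton = compton, mode = mode)
    data.frame(energy_keV = energies[k], efficiency = r$efficiency,
               stderr = r$standard_error)
  })
  do.call(rbind, rows)
}
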