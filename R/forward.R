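#' Voxelized phantom container
#'
#' @param activity 3-D numeric array of activity density (Bq/cm^3 per voxel),
#'   all values >= 0.  Axis order is (x, y, z) with z pointing away from the
#'   detector.
#' @param medium 3-D character array congruent with `activity`, one bundled
#'   material name per voxel (`"air"` marks empty space; `lp` is the first
#'   non-air voxel along a line of response).
#' @param voxel_cm scalar voxel edge length (cm).
#' @param origin_cm length-3 position of the low corner of voxel (1,1,1).
#' @return object of class `phantom`.
#' @export
phantom <- function(activity, medium, voxel_cm, origin_cm = c(0, 0, 0)) {
  stopifnot(length(dim(activity)) == 3, identical(dim(activity), dim(medium)),
            voxel_cm > 0, length(origin_cm) == 3)
  if (any(activity < 0)) stop("activity must be nonnegative everywhere")
  structure(list(activity = activity, medium = medium, voxel = voxel_cm,
                 origin = origin_cm, dim = dim(activity)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels of %.3g cm; total activity %.4g Bq\n",
              paste(x$dim, collapse = "x"), x$voxel,
              sum(x$activity) * x$voxel^3))
  invisible(x)
}

#' Total activity of a phantom (Bq)
#' @param ph a phantom.
#' @export
phantom_total_activity <- function(ph) sum(ph$activity) * ph$voxel^3

#' Camera model
#'
#' @param collimator a [parallel_collimator()] or [pinhole_collimator()].
#' @param crystal a [crystal_slab()]; used for the analytic detection
#'   efficiency unless `efficiency = "ideal"`.
#' @param resolution fractional energy resolution `r` at `e_ref`:
#'   FWHM(E) = r * sqrt(E * e_ref).  `r = 0` disables blur.
#' @param e_ref reference energy for the resolution model (keV).
#' @param window acquisition energy window `c(lo, hi)` in keV.
#' @param pixel_pitch_cm,fov_cm detector pixel pitch and field of view
#'   `c(width, height)` in cm; pixel centers sit at
#'   (i + 0.5) * pitch - extent / 2.
#' @param efficiency `"analytic"` (slab interaction probability of the
#'   crystal) or `"ideal"` (unit efficiency).
#' @return object of class `camera_model`.
#' @export
camera_model <- function(collimator = pinhole_collimator(),
                         crystal = crystal_slab("BGO", 3.0),
                         resolution = 0.2, e_ref = 511,
                         window = c(50, 350),
                         pixel_pitch_cm = 0.5, fov_cm = c(45, 25),
                         efficiency = c("analytic", "ideal")) {
  stopifnot(window[1] < window[2], resolution >= 0)
  structure(list(collimator = collimator, crystal = crystal,
                 resolution = resolution, e_ref = e_ref, window = window,
                 pixel_pitch = pixel_pitch_cm, fov = fov_cm,
                 efficiency = match.arg(efficiency)),
            class = "camera_model")
}

#' Detector pixel centers of a camera
#' @param camera a [camera_model()].
#' @return data.frame with columns `x`, `y` (cm).
#' @export
camera_pixels <- function(camera) {
  px <- camera$pixel_pitch
  nx <- max(1L, floor(camera$fov[1] / px))
  ny <- max(1L, floor(camera$fov[2] / px))
  xs <- (seq_len(nx) - 0.5) * px - camera$fov[1] / 2
  ys <- (seq_len(ny) - 0.5) * px - camera$fov[2] / 2
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

.camera_lor <- function(camera, x, y) {
  if (camera$collimator$kind == "parallel") parallel_lor(x, y)
  else pinhole_lor(x, y, camera$collimator$focal_length)
}

#' Default acquisition energy grid
#'
#' @param e_lo,e_hi window limits (keV).
#' @param by bin width (keV).
#' @return list with `edges` and `centers`.
#' @export
energy_grid <- function(e_lo = 50, e_hi = 350, by = 2) {
  edges <- seq(e_lo, e_hi, by = by)
  list(edges = edges, centers = (head(edges, -1) + tail(edges, -1)) / 2)
}

## ---- ray tracing ----------------------------------------------------------

#' Exact voxel path lengths along a line of response (Siddon traversal)
#'
#' @param ph a [phantom()].
#' @param lor a line of response.
#' @return data.frame with one row per traversed voxel: `l_in`, `l_out`
#'   (parameter values, cm), voxel indices `ix`, `iy`, `iz`, and `medium`.
#'   Zero rows if the LOR misses the grid.
#' @export
trace_ray <- function(ph, lor) {
  o <- lor$origin; u <- lor$direction; h <- ph$voxel
  lo <- ph$origin; hi <- ph$origin + ph$dim * h
  l_min <- 0; l_max <- Inf
  for (k in 1:3) {
    if (abs(u[k]) < 1e-12) {
      if (o[k] <= lo[k] || o[k] >= hi[k]) return(.empty_trace())
    } else {
      a1 <- (lo[k] - o[k]) / u[k]; a2 <- (hi[k] - o[k]) / u[k]
      l_min <- max(l_min, min(a1, a2)); l_max <- min(l_max, max(a1, a2))
    }
  }
  if (l_min >= l_max) return(.empty_trace())
  breaks <- c(l_min, l_max)
  for (k in 1:3) {
    if (abs(u[k]) < 1e-12) next
    planes <- lo[k] + (0:ph$dim[k]) * h
    a <- (planes - o[k]) / u[k]
    breaks <- c(breaks, a[a > l_min & a < l_max])
  }
  breaks <- sort(unique(breaks))
  l_in <- head(breaks, -1); l_out <- tail(breaks, -1)
  keep <- (l_out - l_in) > 1e-12
  l_in <- l_in[keep]; l_out <- l_out[keep]
  mid <- (l_in + l_out) / 2
  p <- lor_point(lor, mid)
  idx <- sweep(p, 2, lo) / h
  ii <- pmin(pmax(floor(idx) + 1, 1), matrix(ph$dim, length(mid), 3, byrow = TRUE))
  data.frame(l_in = l_in, l_out = l_out,
             ix = ii[, 1], iy = ii[, 2], iz = ii[, 3],
             medium = ph$medium[cbind(ii[, 1], ii[, 2], ii[, 3])],
             stringsAsFactors = FALSE)
}

.empty_trace <- function() {
  data.frame(l_in = numeric(0), l_out = numeric(0), ix = integer(0),
             iy = integer(0), iz = integer(0), medium = character(0),
             stringsAsFactors = FALSE)
}

#' Depth of the patient surface along a line of response
#'
#' The smallest `l` at which the LOR enters a non-air voxel; `Inf` if the
#' LOR never meets the phantom.
#'
#' @param ph a [phantom()].
#' @param lor a line of response.
#' @return lp in cm (possibly `Inf`).
#' @export
surface_depth <- function(ph, lor) {
  segs <- trace_ray(ph, lor)
  i <- which(segs$medium != "air")
  if (length(i) == 0) Inf else segs$l_in[i[1]]
}

## ---- projector ------------------------------------------------------------

.ray_spectrum <- function(ph, lor, camera, centers, mu_by_mat, mu_water,
                          a_E, path = "water_equivalent",
                          max_sub_cm = 0.2) {
  segs <- trace_ray(ph, lor)
  nE <- length(centers)
  if (nrow(segs) == 0) return(numeric(nE))
  i_surf <- which(segs$medium != "air")
  if (length(i_surf) == 0) return(numeric(nE))
  lp <- segs$l_in[i_surf[1]]

  # subdivide voxel segments so the geometric-efficiency midpoint rule is
  # accurate (attenuation is integrated exactly either way)
  dl0 <- segs$l_out - segs$l_in
  n_sub <- pmax(1L, ceiling(dl0 / max_sub_cm))
  row <- rep(seq_along(dl0), n_sub)
  off <- unlist(lapply(n_sub, function(k) (seq_len(k) - 1) / k))
  l_in <- segs$l_in[row] + off * dl0[row]
  dl <- dl0[row] / n_sub[row]
  medium <- segs$medium[row]
  A <- ph$activity[cbind(segs$ix, segs$iy, segs$iz)][row]
  act <- which(A > 0)
  if (length(act) == 0) return(numeric(nE))

  # geometric efficiency at sub-segment midpoints (0 behind the aperture)
  mids <- lor_point(lor, l_in + dl / 2)
  G <- .geom_eff_safe(camera$collimator, mids)

  # per-sub-segment attenuation coefficient matrix (nseg x nE)
  if (path == "water_equivalent") {
    kappa <- mu_by_mat[medium, , drop = FALSE]
    tau_in <- apply(kappa * dl, 2, function(col) c(0, cumsum(col))[seq_along(dl)])
    tau_in <- matrix(tau_in, nrow = length(dl))
  } else {
    inside <- l_in >= lp - 1e-12
    kappa <- outer(as.numeric(inside), mu_water)
    tau_in <- outer(pmax(l_in - lp, 0), mu_water)
  }

  out <- numeric(nE)
  for (s in act) {
    kd <- kappa[s, ] * dl[s]
    w  <- ifelse(kd > 1e-12, -expm1(-kd) / kappa[s, ], dl[s])
    out <- out + A[s] * G[s] * exp(-tau_in[s, ]) * w
  }
  out * a_E
}

.geom_eff_safe <- function(collimator, pts) {
  if (collimator$kind == "parallel") {
    ok <- pts[, 3] > 0
    g <- numeric(nrow(pts))
    if (any(ok)) g[ok] <- geometric_efficiency(collimator, pts[ok, , drop = FALSE])
    g
  } else {
    ok <- pts[, 3] > collimator$focal_length
    g <- numeric(nrow(pts))
    if (any(ok)) g[ok] <- geometric_efficiency(collimator, pts[ok, , drop = FALSE])
    g
  }
}

#' Energy-resolved forward projection
#'
#' Computes the geometric (unscattered, unblurred) count-rate spectrum
#' c(x, y, E) for every requested detector pixel: the bremsstrahlung yield
#' a(E) times the line integral of activity times geometric efficiency,
#' attenuated by the medium traversed beyond the patient surface.  Exact
#' per-voxel path lengths (Siddon traversal) with an analytic attenuation
#' integral inside each voxel.
#'
#' @param ph a [phantom()].
#' @param camera a [camera_model()].
#' @param energies energy-bin centers (keV); default the camera window on a
#'   2 keV grid.  Must lie inside the bundled attenuation tables.
#' @param pixels data.frame of pixel centers (`x`, `y` in cm); default all
#'   camera pixels.
#' @param path `"water_equivalent"` (default: each voxel attenuates with its
#'   own material, air contributes nothing) or `"geometric"` (water
#'   attenuation over the full geometric depth beyond the surface).
#' @return object of class `energy_spectrum`: list with `pixels`, `energies`
#'   (bin centers), `bin_width`, `values` (pixels x energies count rate per
#'   keV), `unit = "rate"`.
#' @export
project <- function(ph, camera, energies = NULL, pixels = NULL,
                    path = c("water_equivalent", "geometric")) {
  path <- match.arg(path)
  if (is.null(energies)) {
    energies <- energy_grid(camera$window[1], camera$window[2])$centers
  }
  if (is.null(pixels)) pixels <- camera_pixels(camera)
  wt <- attenuation_table("water")
  if (any(energies < wt$energy_keV[1]) ||
      any(energies > wt$energy_keV[nrow(wt)])) {
    stop("energy grid outside the bundled attenuation table range")
  }
  mats <- unique(as.vector(ph$medium))
  mu_by_mat <- matrix(0, length(mats), length(energies),
                      dimnames = list(mats, NULL))
  for (m in setdiff(mats, "air")) {
    mu_by_mat[m, ] <- attenuation_coefficient(m, energies)
  }
  mu_water <- attenuation_coefficient("water", energies)
  a_E <- brems_yield(energies)
  vals <- t(vapply(seq_len(nrow(pixels)), function(i) {
    lor <- .camera_lor(camera, pixels$x[i], pixels$y[i])
    .ray_spectrum(ph, lor, camera, energies, mu_by_mat, mu_water, a_E, path)
  }, numeric(length(energies))))
  structure(list(pixels = pixels, energies = energies,
                 bin_width = if (length(energies) > 1) diff(energies[1:2]) else 1,
                 values = vals, unit = "rate"),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d pixel(s) x %d bins [%g, %g] keV (%s)\n",
              nrow(x$values), length(x$energies), min(x$energies),
              max(x$energies), x$unit))
  invisible(x)
}

#' Normalize a recorded spectrum (remove yield and surface attenuation)
#'
#' Applies C(x, y, E) = c(x, y, E) exp(-mu(E) lp(x, y)) / a(E) pointwise, so
#' that the normalized spectrum of an ideal acquisition equals the Laplace
#' transform (in water mu) of the depth profile along each LOR.
#'
#' @param spec an `energy_spectrum`.
#' @param lp surface depth per pixel (cm), scalar or one value per pixel;
#'   must be finite.
#' @return object of class `normalized_spectrum` (same layout, `values` are
#'   C).
#' @export
normalize_spectrum <- function(spec, lp) {
  stopifnot(inherits(spec, "energy_spectrum"))
  lp <- rep_len(lp, nrow(spec$values))
  if (any(!is.finite(lp))) stop("lp must be finite for every pixel")
  a_E <- brems_yield(spec$energies)
  if (any(a_E <= 0)) {
    stop("bremsstrahlung yield vanishes on part of the energy grid; ",
         "normalization undefined at or above the beta endpoint")
  }
  mu <- attenuation_coefficient("water", spec$energies)
  vals <- spec$values * exp(-outer(lp, mu)) /
    matrix(a_E, nrow(spec$values), length(a_E), byrow = TRUE)
  structure(list(pixels = spec$pixels, energies = spec$energies,
                 bin_width = spec$bin_width, values = vals, lp = lp),
            class = "normalized_spectrum")
}

#' Re-parameterize a normalized spectrum on the water attenuation axis
#'
#' Relabels each energy sample by the water attenuation coefficient,
#' Chat(mu) = C(E(mu)), and reverses the axis so mu ascends.
#'
#' @param nspec a [normalize_spectrum()] result.
#' @return object of class `mu_spectrum`: list with `pixels`, `mu`
#'   (ascending, 1/cm), `values` (pixels x mu).
#' @export
rebin_to_mu <- function(nspec) {
  stopifnot(inherits(nspec, "normalized_spectrum"))
  mu <- attenuation_coefficient("water", nspec$energies)
  ord <- order(mu)
  structure(list(pixels = nspec$pixels, mu = mu[ord],
                 energies = nspec$energies[ord],
                 values = nspec$values[, ord, drop = FALSE]),
            class = "mu_spectrum")
}

#' Apply the detector response to a projected spectrum
#'
#' Scales by the crystal detection efficiency, convolves each pixel spectrum
#' with a Gaussian of FWHM(E) = r sqrt(E e_ref) (total counts conserved by
#' the blur), then zeroes bins outside the acquisition window.
#'
#' @param spec an `energy_spectrum`.
#' @param camera a [camera_model()].
#' @return an `energy_spectrum` with the response applied.
#' @export
apply_detector_response <- function(spec, camera) {
  stopifnot(inherits(spec, "energy_spectrum"))
  E <- spec$energies
  vals <- spec$values
  eff <- if (camera$efficiency == "ideal") rep(1, length(E)) else
    absorption_probability(camera$crystal$material, camera$crystal$thickness, E)
  vals <- vals * matrix(eff, nrow(vals), length(E), byrow = TRUE)
  if (camera$resolution > 0) {
    sigma <- camera$resolution * sqrt(E * camera$e_ref) / 2.354820045
    hw <- spec$bin_width / 2
    K <- vapply(seq_along(E), function(j) {
      p <- pnorm(E + hw, mean = E[j], sd = sigma[j]) -
        pnorm(E - hw, mean = E[j], sd = sigma[j])
      p / sum(p)     # renormalize so the blur conserves counts on the grid
    }, numeric(length(E)))
    vals <- vals %*% t(K)
  }
  inside <- E >= camera$window[1] & E <= camera$window[2]
  vals[, !inside] <- 0
  out <- spec
  out$values <- vals
  out
}
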