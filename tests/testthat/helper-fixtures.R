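# Shared fixtures: all built in code, no stored data.

# water slab starting at z = z_surface with one hot voxel at depth d below
# the surface along the central axis; voxel value is an activity density.
single_voxel_phantom <- function(d, z_surface = 2, h = 0.5, nt = 3, nz = 60,
                                 density = 1) {
  act <- array(0, c(nt, nt, nz))
  med <- array("air", c(nt, nt, nz))
  zc <- (seq_len(nz) - 0.5) * h
  med[, , zc > z_surface] <- "water"
  iz <- which.min(abs(zc - (z_surface + d)))
  ic <- floor(nt / 2) + 1L
  act[ic, ic, iz] <- density
  ph <- phantom(act, med, h, c(-(ic - 0.5) * h, -(ic - 0.5) * h, 0))
  ph$source_z <- zc[iz]          # actual voxel-center depth from detector
  ph$z_surface <- z_surface
  ph
}

ideal_parallel_camera <- function(window = c(50, 350)) {
  camera_model(collimator = parallel_collimator(), resolution = 0,
               window = window, efficiency = "ideal")
}

central_pixel <- data.frame(x = 0, y = 0)

# mu grid used by the reconstruction tests: water mu over the acquisition
# window, ascending
recon_mu_grid <- function(n = 30, e_lo = 50, e_hi = 350) {
  attenuation_coefficient("water", seq(e_hi, e_lo, length.out = n))
}

# point-mass depth profile carrying unit mass at the grid node nearest l0
point_mass_profile <- function(l0, grid = seq(0, 30, by = 0.5)) {
  w <- ybrems:::.trap_weights(grid)
  v <- numeric(length(grid))
  i <- which.min(abs(grid - l0))
  v[i] <- 1 / w[i]
  depth_profile(grid, v)
}

mu_spectrum_from <- function(mu, values) {
  structure(list(pixels = data.frame(x = 0, y = 0), mu = mu,
                 values = matrix(values, nrow = 1)),
            class = "mu_spectrum")
}

# brute-force fine-step ray integrator, independent of the Siddon code path
march_spectrum <- function(ph, lor, energies, G_fun, step = 1e-3,
                           l_max = 40) {
  l <- seq(step / 2, l_max, by = step)
  p <- lor_point(lor, l)
  h <- ph$voxel
  idx <- floor(sweep(p, 2, ph$origin) / h) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= ph$dim[1] &
            idx[, 2] >= 1 & idx[, 2] <= ph$dim[2] &
            idx[, 3] >= 1 & idx[, 3] <= ph$dim[3]
  med <- rep("air", length(l))
  med[inside] <- ph$medium[idx[inside, , drop = FALSE]]
  A <- numeric(length(l))
  A[inside] <- ph$activity[idx[inside, , drop = FALSE]]
  G <- G_fun(p)
  out <- numeric(length(energies))
  for (j in seq_along(energies)) {
    mu_step <- numeric(length(l))
    for (m in setdiff(unique(med), "air")) {
      mu_step[med == m] <- attenuation_coefficient(m, energies[j])
    }
    tau <- cumsum(mu_step * step) - mu_step * step / 2
    out[j] <- brems_yield(energies[j]) * sum(A * G * exp(-tau) * step)
  }
  out
}

march_surface_depth <- function(ph, lor, step = 1e-3, l_max = 40) {
  l <- seq(step / 2, l_max, by = step)
  p <- lor_point(lor, l)
  h <- ph$voxel
  idx <- floor(sweep(p, 2, ph$origin) / h) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= ph$dim[1] &
            idx[, 2] >= 1 & idx[, 2] <= ph$dim[2] &
            idx[, 3] >= 1 & idx[, 3] <= ph$dim[3]
  med <- rep("air", length(l))
  med[inside] <- ph$medium[idx[inside, , drop = FALSE]]
  i <- which(med != "air")
  if (length(i) == 0) Inf else l[i[1]] - step / 2
}
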