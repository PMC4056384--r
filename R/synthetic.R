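#' Synthetic phantoms and acquisitions
#'
#' Deterministic phantom generators and a Poisson acquisition simulator so
#' that the whole pipeline is testable without any external data.
#'
#' @name ybrems-synthetic
NULL

#' Point-source phantom behind a condensed shell
#'
#' A single hot voxel on the central axis at parameter depth
#' `depth_cm + shell_cm` from the detector plane, surrounded by a shell of
#' condensed medium (water by default, perpex to mimic the classic
#' point-source-in-1-cm-perpex test object); the phantom surface facing the
#' collimator therefore sits at `depth_cm`, which is what
#' [surface_depth()] returns along the central LOR.
#'
#' @param depth_cm distance from the detector plane to the phantom surface
#'   (cm), >= 0.
#' @param shell_cm shell thickness between surface and source (cm).
#' @param activity_Bq total source activity.
#' @param medium shell material name (`"water"` or `"perpex"`).
#' @param voxel_cm voxel size.
#' @param half_width_cm transverse half width of the grid.
#' @return a [phantom()]; the source voxel center is at
#'   z = `depth_cm + shell_cm`.
#' @export
point_source_phantom <- function(depth_cm, shell_cm = 1, activity_Bq = 1,
                                 medium = "water", voxel_cm = 0.5,
                                 half_width_cm = 2) {
  if (depth_cm < 0) stop("depth must be >= 0")
  h <- voxel_cm
  z_src <- depth_cm + shell_cm
  z_max <- z_src + shell_cm + h
  nt <- max(3L, 2L * ceiling(half_width_cm / h))
  nz <- ceiling(z_max / h) + 1L
  act <- array(0, c(nt, nt, nz))
  med <- array("air", c(nt, nt, nz))
  zc <- (seq_len(nz) - 0.5) * h
  shell_sel <- zc >= depth_cm - h / 4 & zc <= z_src + shell_cm + h / 4
  med[, , shell_sel] <- medium
  ic <- floor(nt / 2) + 1L              # voxel whose center is nearest x=y=0
  iz <- which.min(abs(zc - z_src))
  act[ic, ic, iz] <- activity_Bq / h^3
  origin <- c(-ic * h + h / 2, -ic * h + h / 2, 0)
  # origin chosen so the source voxel center is exactly on the z axis
  origin[1] <- origin[2] <- -(ic - 0.5) * h
  ph <- phantom(act, med, h, origin)
  ph$source_z <- zc[iz]
  ph
}

#' Primitive-based phantom specification
#'
#' @param dim grid dimensions (3 integers).
#' @param voxel_cm voxel size (cm).
#' @param origin_cm grid low corner.
#' @param primitives list of primitives; each a list with `type`
#'   (`"sphere"`, `"ellipsoid"`, `"box"`), `center` (cm), size (`radius`,
#'   `radii`, or `half_size`), `activity` (Bq/cm^3) and optional `medium`.
#'   Overlaps resolve last-wins.
#' @param background background medium, default `"water"`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim, voxel_cm, origin_cm = c(0, 0, 0),
                         primitives = list(), background = "water") {
  stopifnot(length(dim) == 3, voxel_cm > 0)
  structure(list(dim = as.integer(dim), voxel = voxel_cm,
                 origin = origin_cm, primitives = primitives,
                 background = background),
            class = "phantom_spec")
}

.primitive_inside <- function(prim, x, y, z) {
  ctr <- prim$center
  switch(prim$type,
    sphere = ((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2) <=
      prim$radius^2,
    ellipsoid = ((x - ctr[1])^2 / prim$radii[1]^2 +
                 (y - ctr[2])^2 / prim$radii[2]^2 +
                 (z - ctr[3])^2 / prim$radii[3]^2) <= 1,
    box = abs(x - ctr[1]) <= prim$half_size[1] &
          abs(y - ctr[2]) <= prim$half_size[2] &
          abs(z - ctr[3]) <= prim$half_size[3],
    stop("unknown primitive type: ", prim$type))
}

.primitive_bounds <- function(prim) {
  r <- switch(prim$type, sphere = rep(prim$radius, 3),
              ellipsoid = prim$radii, box = prim$half_size)
  rbind(prim$center - r, prim$center + r)
}

#' Voxelize a primitive-based phantom (e.g. a liver with hot/cold spheres)
#'
#' Fractional voxel occupancy is estimated with `supersample`^3 interior
#' points per voxel, so primitive volumes (and hence total activity) are
#' conserved to better than a couple of percent at millimeter voxels.
#'
#' @param spec a [phantom_spec()].
#' @param supersample sub-sampling points per voxel edge.
#' @return a [phantom()].
#' @export
liver_phantom <- function(spec, supersample = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel
  act <- array(0, spec$dim)
  med <- array(spec$background, spec$dim)
  grid_lo <- spec$origin
  grid_hi <- spec$origin + spec$dim * h
  offs <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * h
  sub <- expand.grid(dx = offs, dy = offs, dz = offs)
  for (prim in spec$primitives) {
    b <- .primitive_bounds(prim)
    if (any(b[1, ] < grid_lo - 1e-9) || any(b[2, ] > grid_hi + 1e-9)) {
      stop("primitive extends outside the phantom grid")
    }
    i1 <- pmax(floor((b[1, ] - grid_lo) / h) + 1, 1)
    i2 <- pmin(ceiling((b[2, ] - grid_lo) / h), spec$dim)
    ix <- i1[1]:i2[1]; iy <- i1[2]:i2[2]; iz <- i1[3]:i2[3]
    cx <- grid_lo[1] + (ix - 0.5) * h
    cy <- grid_lo[2] + (iy - 0.5) * h
    cz <- grid_lo[3] + (iz - 0.5) * h
    vox <- expand.grid(x = cx, y = cy, z = cz)
    frac <- numeric(nrow(vox))
    for (s in seq_len(nrow(sub))) {
      frac <- frac + .primitive_inside(prim, vox$x + sub$dx[s],
                                       vox$y + sub$dy[s], vox$z + sub$dz[s])
    }
    frac <- frac / nrow(sub)
    idx <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
    touched <- frac > 0
    act[idx[touched, , drop = FALSE]] <- prim$activity * frac[touched]
    if (!is.null(prim$medium)) {
      med[idx[frac > 0.5, , drop = FALSE]] <- prim$medium
    }
  }
  phantom(act, med, h, spec$origin)
}

#' Acquisition specification
#'
#' @param phantom a [phantom()].
#' @param camera a [camera_model()].
#' @param live_time_s acquisition live time (s), >= 0.
#' @param seed integer RNG seed for the Poisson draw.
#' @param energies energy-bin centers (keV); default from the camera window.
#' @param pixels pixel subset (data.frame `x`, `y`); default all.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(phantom, camera, live_time_s, seed,
                             energies = NULL, pixels = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(camera, "camera_model"),
            live_time_s >= 0)
  structure(list(phantom = phantom, camera = camera,
                 live_time = live_time_s, seed = as.integer(seed),
                 energies = energies, pixels = pixels),
            class = "acquisition_spec")
}

#' Simulate a Poisson acquisition
#'
#' Projects the phantom, applies the detector response, scales by the live
#' time and bin width, and draws independent Poisson counts per
#' (pixel, bin).  Reproducible for a given seed.
#'
#' @param spec an [acquisition_spec()].
#' @return an `energy_spectrum` with `unit = "counts"`; the noise-free
#'   expectation is attached as attribute `"mean"`.
#' @export
generate_acquisition <- function(spec) {
  stopifnot(inherits(spec, "acquisition_spec"))
  rate <- project(spec$phantom, spec$camera, energies = spec$energies,
                  pixels = spec$pixels)
  rate <- apply_detector_response(rate, spec$camera)
  mean_counts <- rate$values * rate$bin_width * spec$live_time
  counts <- .with_seed(spec$seed,
                       rpois(length(mean_counts), lambda = mean_counts))
  out <- rate
  out$values <- matrix(counts, nrow(mean_counts), ncol(mean_counts))
  out$unit <- "counts"
  attr(out, "mean") <- mean_counts
  out
}
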