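#' Collimator geometry and lines of response
#'
#' Coordinate convention: the detector (crystal) plane is z = 0, the pinhole
#' aperture sits at (0, 0, F), and object space is z > 0 (parallel hole) or
#' z > F (pinhole).  Detector pixel coordinates (x, y) are continuous cm in
#' the detector plane.  The line-of-response parameter `l` is the distance
#' along the ray measured from the crystal (parallel hole) or from the
#' aperture (pinhole); for both kinds the parameterization is unit speed, so
#' `l` is Euclidean arclength.
#'
#' @name ybrems-geometry
NULL

#' Collimator descriptions
#'
#' @param hole_diameter_cm,hole_length_cm,septal_thickness_cm parallel-hole
#'   dimensions (cm).
#' @param focal_length_cm,aperture_diameter_cm pinhole focal length and
#'   aperture diameter (cm).
#' @param front_wall_cm pinhole lead front wall `c(width, height, thickness)`
#'   in cm.
#' @return object of class `collimator`.
#' @export
parallel_collimator <- function(hole_diameter_cm = 0.34,
                                hole_length_cm = 4.2,
                                septal_thickness_cm = 0.14) {
  stopifnot(hole_diameter_cm > 0, hole_length_cm > 0, septal_thickness_cm > 0)
  structure(list(kind = "parallel", hole_diameter = hole_diameter_cm,
                 hole_length = hole_length_cm,
                 septal_thickness = septal_thickness_cm),
            class = "collimator")
}

#' @rdname parallel_collimator
#' @export
pinhole_collimator <- function(focal_length_cm = 15,
                               aperture_diameter_cm = 0.8,
                               front_wall_cm = c(45, 25, 5)) {
  if (focal_length_cm <= 0) stop("pinhole focal length must be > 0")
  stopifnot(aperture_diameter_cm > 0, all(front_wall_cm > 0))
  structure(list(kind = "pinhole", focal_length = focal_length_cm,
                 aperture_diameter = aperture_diameter_cm,
                 front_wall = front_wall_cm),
            class = "collimator")
}

#' @export
print.collimator <- function(x, ...) {
  if (x$kind == "parallel") {
    cat(sprintf("<parallel-hole collimator> d=%.2f cm, l=%.2f cm, septa=%.2f cm\n",
                x$hole_diameter, x$hole_length, x$septal_thickness))
  } else {
    cat(sprintf("<pinhole collimator> F=%.1f cm, aperture=%.2f cm\n",
                x$focal_length, x$aperture_diameter))
  }
  invisible(x)
}

#' Line of response for a detector pixel
#'
#' `parallel_lor()` implements the parallel-hole parameterization
#' x'(l) = x, y'(l) = y, z'(l) = l.  `pinhole_lor()` implements the pinhole
#' parameterization through the aperture at (0, 0, F):
#' x'(l) = -l x / s, y'(l) = -l y / s, z'(l) = F + l F / s with
#' s = sqrt(F^2 + x^2 + y^2).
#'
#' @param x,y pixel coordinates in the detector plane (cm).
#' @param F pinhole focal length (cm), > 0.
#' @return object of class `lor` with fields `kind`, `pixel`, `origin`
#'   (point at l = 0) and `direction` (unit vector).
#' @export
parallel_lor <- function(x, y) {
  structure(list(kind = "parallel", pixel = c(x = x, y = y),
                 origin = c(x, y, 0), direction = c(0, 0, 1)),
            class = "lor")
}

#' @rdname parallel_lor
#' @export
pinhole_lor <- function(x, y, F = 15) {
  if (F <= 0) stop("pinhole focal length must be > 0")
  s <- sqrt(F^2 + x^2 + y^2)
  structure(list(kind = "pinhole", pixel = c(x = x, y = y), F = F,
                 origin = c(0, 0, F),
                 direction = c(-x / s, -y / s, F / s)),
            class = "lor")
}

#' Evaluate a line of response
#'
#' @param lor a [parallel_lor()] or [pinhole_lor()] object.
#' @param l parameter values (cm), vectorized.
#' @return matrix with columns x', y', z' (one row per `l`).
#' @export
lor_point <- function(lor, l) {
  stopifnot(inherits(lor, "lor"))
  cbind(lor$origin[1] + l * lor$direction[1],
        lor$origin[2] + l * lor$direction[2],
        lor$origin[3] + l * lor$direction[3])
}

#' Arclength scale of the LOR parameter
#'
#' Both parameterizations are unit speed (|d point / d l| = 1), so the
#' constant relating `l` to Euclidean arclength is exactly 1 for every
#' pixel; the accessor exists to make that contract explicit.
#'
#' @param lor a line of response.
#' @return the scalar 1.
#' @export
lor_arclength_scale <- function(lor) {
  stopifnot(inherits(lor, "lor"))
  sqrt(sum(lor$direction^2))
}

#' Geometric efficiency of a collimator at a source point
#'
#' Parallel hole: the standard hole-geometry sensitivity
#' (K d^2 / (l_e (d + t)))^2 with K = 0.26 (hexagonal packing) and
#' l_e the hole length; independent of source position.  Pinhole:
#' d^2 sin^3(theta) / (16 h^2) with h the source-aperture distance and theta
#' the incidence angle on the aperture plane.
#'
#' @param collimator a `collimator` object.
#' @param point numeric length-3 source position (x', y', z') in cm, or a
#'   matrix with one point per row.
#' @return geometric efficiency (dimensionless), one value per point.
#' @export
geometric_efficiency <- function(collimator, point) {
  stopifnot(inherits(collimator, "collimator"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (collimator$kind == "parallel") {
    if (any(p[, 3] <= 0)) stop("source point must be in front of the collimator")
    d <- collimator$hole_diameter; t <- collimator$septal_thickness
    g <- (0.26 * d^2 / (collimator$hole_length * (d + t)))^2
    rep(g, nrow(p))
  } else {
    F <- collimator$focal_length
    if (any(p[, 3] <= F)) stop("source point must be beyond the pinhole aperture")
    h2 <- p[, 1]^2 + p[, 2]^2 + (p[, 3] - F)^2
    sin_theta <- (p[, 3] - F) / sqrt(h2)
    collimator$aperture_diameter^2 * sin_theta^3 / (16 * h2)
  }
}

#' Mass of a rectangular lead front wall
#'
#' @param width_cm,height_cm,thickness_cm wall dimensions (cm), > 0.
#' @param density_g_cm3 density (g/cm^3), default lead.
#' @return mass in kg.
#' @export
#' @examples
#' lead_wall_mass(45, 25, 5)   # about 64 kg
lead_wall_mass <- function(width_cm, height_cm, thickness_cm,
                           density_g_cm3 = 11.34) {
  if (any(c(width_cm, height_cm, thickness_cm, density_g_cm3) <= 0)) {
    stop("all wall dimensions and the density must be positive")
  }
  width_cm * height_cm * thickness_cm * density_g_cm3 / 1000
}
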