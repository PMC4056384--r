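#' Readers and writers for the package's plain-text dialects
#'
#' Spectra, depth profiles and phantoms travel as comma-separated UTF-8 CSV
#' (header row, "." decimal); phantom and run configurations as JSON.  Every
#' CLI output is accompanied by a JSON sidecar recording seed, configuration
#' hash and package version.
#'
#' @name ybrems-io
NULL

#' @rdname ybrems-io
#' @param spec an `energy_spectrum`.
#' @param path output file.
#' @export
write_spectrum_csv <- function(spec, path) {
  hw <- spec$bin_width / 2
  n_pix <- nrow(spec$values)
  df <- data.frame(
    pixel_id = rep(seq_len(n_pix), each = length(spec$energies)),
    x_cm = rep(spec$pixels$x, each = length(spec$energies)),
    y_cm = rep(spec$pixels$y, each = length(spec$energies)),
    e_lo_keV = rep(spec$energies - hw, n_pix),
    e_hi_keV = rep(spec$energies + hw, n_pix),
    value = as.vector(t(spec$values)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ybrems-io
#' @param unit `"rate"` or `"counts"`.
#' @export
read_spectrum_csv <- function(path, unit = "counts") {
  df <- read.csv(path)
  ids <- unique(df$pixel_id)
  centers <- sort(unique((df$e_lo_keV + df$e_hi_keV) / 2))
  vals <- matrix(0, length(ids), length(centers))
  px <- data.frame(x = numeric(length(ids)), y = numeric(length(ids)))
  for (k in seq_along(ids)) {
    d <- df[df$pixel_id == ids[k], ]
    d <- d[order(d$e_lo_keV), ]
    vals[k, ] <- d$value
    px$x[k] <- d$x_cm[1]; px$y[k] <- d$y_cm[1]
  }
  structure(list(pixels = px, energies = centers,
                 bin_width = centers[2] - centers[1],
                 values = vals, unit = unit),
            class = "energy_spectrum")
}

#' @rdname ybrems-io
#' @param mspec a `mu_spectrum`.
#' @export
write_mu_spectrum_csv <- function(mspec, path) {
  n_pix <- nrow(mspec$values)
  df <- data.frame(
    pixel_id = rep(seq_len(n_pix), each = length(mspec$mu)),
    mu_per_cm = rep(mspec$mu, n_pix),
    value = as.vector(t(mspec$values)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ybrems-io
#' @export
read_mu_spectrum_csv <- function(path) {
  df <- read.csv(path)
  ids <- unique(df$pixel_id)
  mu <- sort(unique(df$mu_per_cm))
  vals <- matrix(0, length(ids), length(mu))
  for (k in seq_along(ids)) {
    d <- df[df$pixel_id == ids[k], ]
    vals[k, ] <- d$value[order(d$mu_per_cm)]
  }
  structure(list(pixels = data.frame(x = rep(0, length(ids)),
                                     y = rep(0, length(ids))),
                 mu = mu, values = vals),
            class = "mu_spectrum")
}

#' @rdname ybrems-io
#' @param profile a [depth_profile()].
#' @export
write_depth_profile_csv <- function(profile, path) {
  write.csv(data.frame(depth_cm = profile$grid, value = profile$values),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ybrems-io
#' @export
read_depth_profile_csv <- function(path) {
  df <- read.csv(path)
  depth_profile(df$depth_cm, df$value)
}

#' @rdname ybrems-io
#' @param ph a [phantom()].
#' @export
write_phantom_json <- function(ph, path) {
  jsonlite::write_json(
    list(dim = ph$dim, voxel_cm = ph$voxel, origin_cm = ph$origin,
         activity = as.vector(ph$activity), medium = as.vector(ph$medium)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ybrems-io
#' @export
read_phantom_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom(array(j$activity, j$dim), array(j$medium, j$dim),
          j$voxel_cm, j$origin_cm)
}

#' Read a primitive-based phantom spec from JSON
#' @rdname ybrems-io
#' @export
read_phantom_spec_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  prims <- lapply(raw$primitives, function(p) {
    lapply(p, function(v) if (is.list(v)) unlist(v) else v)
  })
  phantom_spec(dim = unlist(raw$dim), voxel_cm = raw$voxel_cm,
               origin_cm = if (is.null(raw$origin_cm)) c(0, 0, 0) else
                 unlist(raw$origin_cm),
               primitives = prims,
               background = if (is.null(raw$background)) "water" else
                 raw$background)
}

# stable 32-bit FNV-1a hash of a deparsed object, for provenance sidecars
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    # XOR only touches the low byte (b < 256); keep h as a double < 2^32
    h <- (h - h %% 256) + bitwXor(h %% 256, b %% 256)
    # modular multiply in 16-bit halves to stay inside double precision
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Write a provenance sidecar next to an output artifact
#'
#' @param path path of the artifact; the sidecar is `<path>.meta.json`.
#' @param config list describing the run configuration.
#' @param seed RNG seed used (or `NA`).
#' @export
write_sidecar <- function(path, config = list(), seed = NA) {
  jsonlite::write_json(
    list(config_hash = .config_hash(config), seed = seed,
         package = "ybrems",
         version = as.character(utils::packageVersion("ybrems")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(paste0(path, ".meta.json"))
}
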