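TS_HEADER <- c("id", "frame", "x [nm]", "y [nm]", "sigma [nm]",
               "intensity [photon]", "offset [photon]", "bkgstd [photon]",
               "uncertainty [nm]")

# Parse a ThunderSTORM-style header name into (base, unit).
parse_header <- function(h) {
  m <- regmatches(h, regexec("^\\s*([^\\[]+?)\\s*(\\[(.*)\\])?\\s*$", h))[[1]]
  list(base = m[2], unit = if (length(m) >= 4 && nzchar(m[4])) m[4] else NA)
}

#' Write a localization table as ThunderSTORM-compatible CSV
#'
#' Columns beyond the standard nine are appended with their plain names,
#' so label or flag columns survive a round trip.
#'
#' @param table Localization table.
#' @param path Output path.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)
  std <- c(id = "id", frame = "frame", x = "x [nm]", y = "y [nm]",
           sigma = "sigma [nm]", intensity = "intensity [photon]",
           offset = "offset [photon]", bkgstd = "bkgstd [photon]",
           uncertainty = "uncertainty [nm]")
  present <- intersect(names(std), names(df))
  extra <- setdiff(names(df), names(std))
  out <- df[, c(present, extra), drop = FALSE]
  names(out) <- c(std[present], extra)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a ThunderSTORM-compatible localization CSV
#'
#' Bracketed unit suffixes in the header are parsed; coordinate and size
#' columns given in micrometres are converted to nanometres. `x`, `y` and
#' `frame` columns are required. Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return A `localization_table` data frame (all lengths in nm).
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- list()
  for (h in names(df)) {
    p <- parse_header(h)
    v <- df[[h]]
    if (!is.na(p$unit)) {
      if (p$unit %in% c("um", "µm")) v <- v * 1000
      else if (p$unit != "nm" && p$unit != "photon")
        warning("unrecognized unit '", p$unit, "' for column '", p$base,
                "'; values taken as-is")
    }
    out[[p$base]] <- v
  }
  out <- as.data.frame(out, check.names = FALSE)
  need <- c("x", "y", "frame")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("localization file is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(out[, need]))
  if (length(bad))
    stop("malformed row(s) (missing x/y/frame) at data row ",
         paste(utils::head(bad, 5), collapse = ", "))
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned samples. The pixel size and optics
#' metadata are written to a JSON sidecar `<path>.meta.json` so
#' [read_stack()] can restore them (plain TIFF carries no pixel-size tag
#' in the dialect used here).
#'
#' @param stack A `frame_stack`.
#' @param path Output path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- 65535
  if (max(stack$frames) > mx) stop("counts exceed the 16-bit range")
  pages <- lapply(seq_len(stack$n_frames), function(f)
    stack$frames[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_nm = stack$optics$pixel_size_nm,
                            psf_sigma_nm = stack$optics$psf_sigma_nm,
                            photons_full_frame = stack$optics$photons_full_frame),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF path.
#' @param pixel_size_nm Pixel size override; required when the file
#'   carries no pixel-size metadata.
#' @param optics Optional [optics_config()] to attach (field size is
#'   replaced by the actual image size).
#' @return A `frame_stack` (counts restored to their integer scale).
#' @export
read_stack <- function(path, pixel_size_nm = NULL, optics = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in TIFF stack")
  meta_path <- paste0(path, ".meta.json")
  md <- if (file.exists(meta_path))
    tryCatch(jsonlite::fromJSON(meta_path), error = function(e) NULL)
  if (is.null(pixel_size_nm)) pixel_size_nm <- md$pixel_size_nm
  if (is.null(pixel_size_nm))
    stop("no pixel-size metadata in file; pass pixel_size_nm explicitly")
  ny <- dims[1, 1]; nx <- dims[2, 1]
  frames <- array(0, dim = c(ny, nx, length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- round(pages[[f]] * 65535)
  if (is.null(optics)) {
    optics <- optics_config(pixel_size_nm = pixel_size_nm,
                            field_px = c(nx, ny))
    if (!is.null(md$psf_sigma_nm)) optics$psf_sigma_nm <- md$psf_sigma_nm
    if (!is.null(md$photons_full_frame))
      optics$photons_full_frame <- md$photons_full_frame
  } else {
    optics$field_px <- c(nx, ny)
    optics$pixel_size_nm <- pixel_size_nm
  }
  structure(list(frames = frames, optics = optics, camera = camera_model(),
                 n_frames = length(pages)),
            class = "frame_stack")
}

#' Write / read a ground-truth sidecar table
#'
#' @param sidecar Data frame from [ground_truth_sidecar()].
#' @param path CSV path.
#' @export
write_sidecar <- function(sidecar, path) {
  utils::write.csv(sidecar, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "emitter_id", "x_nm", "y_nm", "on_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sidecar is missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Deterministic benchmark fixtures
#'
#' Builds the standard simulated bundles used throughout: the 0D point,
#' 1D strand and 2D plane, the four-vesicle cluster, and a two-emitter
#' pair. At scale "ci" the bundles are 200 frames; at scale "paper" 1,000
#' frames. The structure is centred in a field with a 6-pixel margin so
#' fitting windows stay inside the image. Tagging density is 0.5 nm^-2
#' for the small structures and reduced for the large plane and strand so
#' the emitter pool stays tractable while remaining far larger than the
#' number of activations.
#'
#' @param name One of "fig_point", "fig_strand", "fig_plane",
#'   "fig_vesicles", "sweep_pair".
#' @param scale "ci" (200 frames) or "paper" (1,000 frames).
#' @param seed Integer seed.
#' @param p_act Activation probability per emitter per frame; default
#'   picks roughly the optimal activation density for the structure at an
#'   exclusion radius of 440 nm.
#' @param dir If non-NULL, write stack.tif, sidecar.csv and config.yaml
#'   into this directory.
#' @return List `stack`, `sidecar`, `geometry`, `traces`, `nominal_a`,
#'   `config`.
#' @export
make_fixture <- function(name = c("fig_point", "fig_strand", "fig_plane",
                                  "fig_vesicles", "sweep_pair"),
                         scale = c("ci", "paper"), seed = 1, p_act = NULL,
                         dir = NULL) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  n_frames <- if (scale == "ci") 200L else 1000L
  px <- 110
  margin <- 6 * px
  preset <- switch(name,
    fig_point = list(kind = "point", tag = 0.5),
    fig_strand = list(kind = "strand", tag = 0.1),
    fig_plane = list(kind = "plane", tag = 0.01),
    fig_vesicles = list(kind = "vesicles", tag = 0.5),
    sweep_pair = NULL)
  if (name == "sweep_pair") {
    optics <- optics_config(field_px = c(40L, 24L))
    act <- data.frame(frame = 1L, id = 1:2,
                      x = optics$field_px[1] * px / 2 + c(-300, 300),
                      y = optics$field_px[2] * px / 2, on_fraction = 1)
    set.seed(seed)
    stack <- render_frames(act, optics, camera_model(), n_frames = 1L)
    sidecar <- data.frame(frame = 1L, emitter_id = 1:2, x_nm = act$x,
                          y_nm = act$y, on_fraction = 1, photons = 450)
    out <- list(stack = stack, sidecar = sidecar, geometry = NULL,
                traces = NULL, nominal_a = NA_real_,
                config = list(name = name, scale = scale, seed = seed))
  } else {
    geom <- make_structure(preset$kind, origin = c(margin, margin))
    bb <- geometry_bbox(geom)
    field <- c(ceiling((bb["xmax"] + margin) / px),
               ceiling((bb["ymax"] + margin) / px))
    optics <- optics_config(field_px = field)
    if (is.null(p_act)) {
      # default to the optimal (measured) activation density at r = 440 nm
      E <- exclusion_area(as_exclusion_model(geom, 440))
      p_act <- min(1, p_act_for_density(1 / E, preset$tag))
    }
    sim <- simulate_acquisition(geom, n_frames, p_act,
                                tagging_density_per_nm2 = preset$tag,
                                optics = optics, seed = seed)
    out <- list(stack = sim$stack, sidecar = sim$sidecar, geometry = geom,
                traces = sim$traces, nominal_a = sim$nominal_a,
                config = list(name = name, scale = scale, seed = seed,
                              p_act = p_act, tagging = preset$tag,
                              n_frames = n_frames))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_stack(out$stack, file.path(dir, "stack.tif"))
    write_sidecar(out$sidecar, file.path(dir, "sidecar.csv"))
    yaml::write_yaml(out$config, file.path(dir, "config.yaml"))
  }
  out
}

#' Read / write a run configuration
#'
#' Nested key-value YAML; every defaulted value is written back out so a
#' run can be reproduced from its resolved config alone.
#'
#' @param config Named list.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
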