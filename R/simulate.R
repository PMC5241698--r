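#' Optics configuration
#'
#' @param wavelength_nm Emission wavelength (nm). Default 488.
#' @param na Objective numerical aperture. Default 1.4.
#' @param pixel_size_nm Camera pixel size in sample space (nm). Default 110.
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm); default the
#'   Airy-core approximation 0.21 * lambda / NA.
#' @param photons_full_frame Expected photons detected from a fluorophore
#'   active for a whole frame. Default 450.
#' @param field_px Field of view, pixels, `c(nx, ny)`. Default c(32, 32).
#' @return Object of class `optics_config`.
#' @export
optics_config <- function(wavelength_nm = 488, na = 1.4, pixel_size_nm = 110,
                          psf_sigma_nm = 0.21 * wavelength_nm / na,
                          photons_full_frame = 450, field_px = c(32L, 32L)) {
  stopifnot(wavelength_nm > 0, na > 0, pixel_size_nm > 0,
            psf_sigma_nm > 0, photons_full_frame > 0,
            length(field_px) == 2L, all(field_px >= 1))
  structure(list(wavelength_nm = wavelength_nm, na = na,
                 lambda_over_na = wavelength_nm / na,
                 pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 photons_full_frame = photons_full_frame,
                 field_px = as.integer(field_px)),
            class = "optics_config")
}

#' EMCCD camera model
#'
#' The electron-multiplying register is modelled, conditional on n detected
#' photoelectrons, as a Gamma(shape = n, scale = gain) draw; output counts
#' are normalized back by the gain so one photoelectron contributes
#' `counts_per_photoelectron` counts in expectation while keeping the
#' characteristic excess-noise factor of 2. Gain 1 bypasses the EM register.
#'
#' @param em_gain EM gain (>= 1). Default 100.
#' @param readout_noise_rms Gaussian read noise RMS, counts. Default 1.
#' @param baseline_offset Camera baseline, counts. Default 100.
#' @param quantum_efficiency Detection probability per photon. Default 0.9.
#' @param counts_per_photoelectron Gain-normalized counts per photoelectron.
#'   Default 1.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(em_gain = 100, readout_noise_rms = 1,
                         baseline_offset = 100, quantum_efficiency = 0.9,
                         counts_per_photoelectron = 1) {
  stopifnot(em_gain >= 1, readout_noise_rms >= 0, baseline_offset >= 0,
            quantum_efficiency > 0, quantum_efficiency <= 1,
            counts_per_photoelectron > 0)
  structure(list(em_gain = em_gain, readout_noise_rms = readout_noise_rms,
                 baseline_offset = baseline_offset,
                 quantum_efficiency = quantum_efficiency,
                 counts_per_photoelectron = counts_per_photoelectron),
            class = "camera_model")
}

PHOTO_STATES <- c("inactive", "active", "dark", "bleached")

#' Per-frame photoswitching model
#'
#' Four-state Markov chain (inactive, active, dark, bleached) advanced once
#' per camera frame. The default regime is the live-cell "pool" model: a
#' large reservoir of inactive fluorophores of which a small fraction
#' activates each frame, active emitters return to the pool with
#' probability 0.5 per frame, and irreversible bleaching is negligible.
#' The dark (reversible off) state is disabled by default. All
#' probabilities are exposed so other photophysics can be configured.
#'
#' @param p_act Activation probability per emitter per frame.
#' @param p_deact Active -> inactive probability per frame. Default 0.5.
#' @param p_dark Active -> dark probability per frame. Default 0.
#' @param p_dark_recover Dark -> active probability per frame. Default 0.
#' @param p_bleach Active -> bleached probability per frame. Default 0.
#' @return Object of class `photophysics_model` carrying the 4 x 4
#'   transition matrix (rows sum to 1; bleached is absorbing).
#' @export
photophysics_model <- function(p_act, p_deact = 0.5, p_dark = 0,
                               p_dark_recover = 0, p_bleach = 0) {
  probs <- c(p_act, p_deact, p_dark, p_dark_recover, p_bleach)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all transition probabilities must lie in [0, 1]")
  if (p_deact + p_dark + p_bleach > 1)
    stop("active-state exit probabilities sum to more than 1")
  tm <- matrix(0, 4, 4, dimnames = list(PHOTO_STATES, PHOTO_STATES))
  tm["inactive", "active"] <- p_act
  tm["inactive", "inactive"] <- 1 - p_act
  tm["active", "inactive"] <- p_deact
  tm["active", "dark"] <- p_dark
  tm["active", "bleached"] <- p_bleach
  tm["active", "active"] <- 1 - p_deact - p_dark - p_bleach
  tm["dark", "active"] <- p_dark_recover
  tm["dark", "dark"] <- 1 - p_dark_recover
  tm["bleached", "bleached"] <- 1
  structure(list(transition = tm, p_act = p_act, p_deact = p_deact,
                 p_dark = p_dark, p_dark_recover = p_dark_recover,
                 p_bleach = p_bleach),
            class = "photophysics_model")
}

#' Standard test structures
#'
#' Builds the benchmark geometries: an 8 x 8 nm "0D" point, an
#' 8 x 3,520 nm "1D" strand, a 3,520 x 3,520 nm "2D" plane, and the
#' four-vesicle cluster (uniform discs of radius 30 nm at relative
#' positions (0,0), (200,200), (200,400) and (400,600) nm).
#'
#' @param kind One of "point", "strand", "plane", "vesicles".
#' @param origin Position (nm) of the structure's lower corner (for the
#'   vesicles, of the first vesicle centre). Default c(0, 0).
#' @param size_nm Override the structure extent (nm). For "point" a
#'   two-vector (w1, w2); for "strand" c(width, length); for "plane"
#'   c(side, side); ignored for "vesicles".
#' @return A [sample_geometry()].
#' @export
make_structure <- function(kind = c("point", "strand", "plane", "vesicles"),
                           origin = c(0, 0), size_nm = NULL) {
  kind <- match.arg(kind)
  ox <- origin[1]; oy <- origin[2]
  switch(kind,
    point = {
      s <- if (is.null(size_nm)) c(8, 8) else rep_len(size_nm, 2)
      sample_geometry(rect_primitive(ox, oy, s[1], s[2]),
                      dimensionality = 0L, width_nm = s, label = "0D point")
    },
    strand = {
      s <- if (is.null(size_nm)) c(8, 3520) else rep_len(size_nm, 2)
      sample_geometry(rect_primitive(ox, oy, s[1], s[2]),
                      dimensionality = 1L, width_nm = s[1], label = "1D strand")
    },
    plane = {
      s <- if (is.null(size_nm)) c(3520, 3520) else rep_len(size_nm, 2)
      sample_geometry(rect_primitive(ox, oy, s[1], s[2]),
                      dimensionality = 2L, label = "2D plane")
    },
    vesicles = {
      rel <- matrix(c(0, 0, 200, 200, 200, 400, 400, 600),
                    ncol = 2, byrow = TRUE)
      prims <- lapply(seq_len(nrow(rel)), function(i)
        disc_primitive(ox + rel[i, 1], oy + rel[i, 2], 30))
      sample_geometry(prims, dimensionality = 0L, width_nm = c(60, 60),
                      label = "four vesicles")
    })
}

#' Seed ground-truth emitters on a structure
#'
#' The emitter count is Poisson with mean tagging density times tagged
#' area; positions are uniform within the structure.
#'
#' @param geom A [sample_geometry()].
#' @param tagging_density_per_nm2 Fluorophore tagging density (per nm^2).
#'   The benchmark value is 0.5 nm^-2 for small structures; large planes
#'   use a sparser tagging so the emitter pool stays tractable while still
#'   dwarfing the number of activations.
#' @param seed Integer seed.
#' @param max_emitters Refuse to build pools larger than this (default
#'   5e5) with a hint to lower the density.
#' @return Data frame `id`, `x`, `y` (nm).
#' @export
seed_emitters <- function(geom, tagging_density_per_nm2, seed = NULL,
                          max_emitters = 5e5) {
  stopifnot(inherits(geom, "sample_geometry"))
  if (!is.finite(tagging_density_per_nm2) || tagging_density_per_nm2 < 0)
    stop("tagging density must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  area <- geometry_area(geom)
  mean_n <- tagging_density_per_nm2 * area
  if (mean_n > max_emitters)
    stop(sprintf(paste0("expected emitter count %.3g exceeds max_emitters = %g; ",
                        "lower the tagging density or raise the cap"),
                 mean_n, max_emitters))
  n <- stats::rpois(1, mean_n)
  if (n == 0) {
    warning("no emitters seeded (density * area too small)")
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0)))
  }
  pos <- sample_points_in_geometry(geom, n)
  data.frame(id = seq_len(n), x = pos$x, y = pos$y)
}

#' Simulate photoswitching over a frame sequence
#'
#' Advances every emitter's state by the per-frame Markov chain. An emitter
#' that switches on mid-frame contributes a uniform random fraction of the
#' frame on its first active frame (sub-frame switching); full active
#' frames contribute 1.
#'
#' @param emitters Data frame from [seed_emitters()].
#' @param photophysics A [photophysics_model()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return Object of class `emitter_traces`: list with `emitters`,
#'   `active` (data frame frame, id, x, y, on_fraction), `n_frames`.
#' @export
simulate_blinking <- function(emitters, photophysics, n_frames, seed = NULL) {
  stopifnot(inherits(photophysics, "photophysics_model"), n_frames >= 1)
  tm <- photophysics$transition
  if (any(abs(rowSums(tm) - 1) > 1e-12) || any(tm < 0))
    stop("transition matrix is not row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(emitters)
  state <- rep(1L, m)  # all start inactive (in the pool)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    new_state <- state
    u <- stats::runif(m)
    for (s in 1:3) {  # bleached (4) is absorbing
      idx <- which(state == s)
      if (!length(idx)) next
      cum <- cumsum(tm[s, ])
      new_state[idx] <- findInterval(u[idx], cum, left.open = TRUE) + 1L
    }
    act <- which(new_state == 2L)
    if (length(act)) {
      fresh <- state[act] != 2L
      onf <- rep(1, length(act))
      if (any(fresh)) onf[fresh] <- stats::runif(sum(fresh))
      out[[f]] <- data.frame(frame = f, id = emitters$id[act],
                             x = emitters$x[act], y = emitters$y[act],
                             on_fraction = onf)
    }
    state <- new_state
  }
  active <- if (any(!vapply(out, is.null, logical(1))))
    do.call(rbind, out)
  else data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                  y = numeric(0), on_fraction = numeric(0))
  structure(list(emitters = emitters, active = active,
                 n_frames = as.integer(n_frames),
                 photophysics = photophysics),
            class = "emitter_traces")
}

#' Activation probability needed for a target activation density
#'
#' The observable activation density is the mean number of *active*
#' emitters per frame divided by the tagged area (see
#' [measured_activation_density()]). In the pool model an activation
#' stays on for 1/p_deact frames on average, so the stationary active
#' density is tagging * p_act / p_deact; this helper inverts that
#' relation.
#'
#' @param a_per_nm2 Target activation density (active emitters per nm^2
#'   per frame).
#' @param tagging_density_per_nm2 Tagging density (per nm^2).
#' @param p_deact Active -> inactive probability per frame. Default 0.5.
#' @return The per-emitter per-frame activation probability `p_act`.
#' @export
p_act_for_density <- function(a_per_nm2, tagging_density_per_nm2,
                              p_deact = 0.5) {
  stopifnot(a_per_nm2 >= 0, tagging_density_per_nm2 > 0,
            p_deact > 0, p_deact <= 1)
  p <- a_per_nm2 * p_deact / tagging_density_per_nm2
  if (p > 1) stop("target density unreachable at this tagging density")
  p
}

#' Measured activation density
#'
#' Average number of active emitters per frame divided by the tagged area,
#' the estimator used when the nominal activation parameter is unknown.
#'
#' @param traces An [simulate_blinking()] result.
#' @param area_nm2 Tagged area (nm^2).
#' @return Activations per nm^2 per frame.
#' @export
measured_activation_density <- function(traces, area_nm2) {
  stopifnot(inherits(traces, "emitter_traces"), area_nm2 > 0)
  (nrow(traces$active) / traces$n_frames) / area_nm2
}

# Pixel-integrated Gaussian along one axis: probability mass of a Gaussian
# centred at pos (nm) in each pixel [i, i+1) * px, i = 0..n-1.
pixel_gauss <- function(n_px, pos_nm, sigma_nm, px_nm) {
  edges <- (0:n_px) * px_nm
  p <- stats::pnorm(edges, mean = pos_nm, sd = sigma_nm)
  diff(p)
}

# Expected photon image for one frame's active emitters.
expected_frame <- function(active_rows, optics) {
  nx <- optics$field_px[1]; ny <- optics$field_px[2]
  img <- matrix(0, nrow = ny, ncol = nx)
  if (is.null(active_rows) || nrow(active_rows) == 0) return(img)
  for (i in seq_len(nrow(active_rows))) {
    ph <- optics$photons_full_frame * active_rows$on_fraction[i]
    gx <- pixel_gauss(nx, active_rows$x[i], optics$psf_sigma_nm,
                      optics$pixel_size_nm)
    gy <- pixel_gauss(ny, active_rows$y[i], optics$psf_sigma_nm,
                      optics$pixel_size_nm)
    img <- img + ph * (gy %o% gx)
  }
  img
}

#' Render camera frames from emitter traces
#'
#' Per frame: expected photon image as the sum of pixel-integrated Gaussian
#' PSFs weighted by on-fraction times the full-frame photon budget; Poisson
#' shot noise on detected photoelectrons; EM amplification; Gaussian read
#' noise; baseline offset; rounded non-negative integer counts. Emitters
#' outside the field simply contribute their in-field tail (their PSF is
#' clipped at the field edge).
#'
#' @param traces From [simulate_blinking()], or a data frame like its
#'   `active` component.
#' @param optics An [optics_config()].
#' @param camera A [camera_model()].
#' @param seed Integer seed.
#' @param noise If FALSE, return the noise-free expected image in counts
#'   (expected photoelectrons times counts/pe, plus baseline), un-rounded.
#' @param n_frames Frame count; defaults to `traces$n_frames` or the
#'   largest frame index.
#' @return Object of class `frame_stack`: list with `frames` (ny x nx x nf
#'   array of counts), `optics`, `camera`, `n_frames`.
#' @export
render_frames <- function(traces, optics, camera, seed = NULL, noise = TRUE,
                          n_frames = NULL) {
  active <- if (inherits(traces, "emitter_traces")) traces$active else traces
  if (is.null(n_frames))
    n_frames <- if (inherits(traces, "emitter_traces")) traces$n_frames
                else max(1L, suppressWarnings(max(active$frame)))
  stopifnot(inherits(optics, "optics_config"), inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  nx <- optics$field_px[1]; ny <- optics$field_px[2]
  frames <- array(0, dim = c(ny, nx, n_frames))
  by_frame <- if (nrow(active)) split(active, active$frame) else list()
  for (f in seq_len(n_frames)) {
    rows <- by_frame[[as.character(f)]]
    exp_photons <- expected_frame(rows, optics)
    exp_pe <- camera$quantum_efficiency * exp_photons
    if (!noise) {
      frames[, , f] <- exp_pe * camera$counts_per_photoelectron +
        camera$baseline_offset
      next
    }
    npe <- stats::rpois(length(exp_pe), exp_pe)
    if (camera$em_gain > 1) {
      el <- numeric(length(npe))
      nz <- npe > 0
      if (any(nz))
        el[nz] <- stats::rgamma(sum(nz), shape = npe[nz],
                                scale = camera$em_gain)
      sig <- el / camera$em_gain * camera$counts_per_photoelectron
    } else {
      sig <- npe * camera$counts_per_photoelectron
    }
    counts <- sig + camera$baseline_offset
    if (camera$readout_noise_rms > 0)
      counts <- counts + stats::rnorm(length(counts),
                                      sd = camera$readout_noise_rms)
    frames[, , f] <- pmax(0, round(matrix(counts, nrow = ny)))
  }
  structure(list(frames = frames, optics = optics, camera = camera,
                 n_frames = as.integer(n_frames)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px (%.0f nm/px)\n",
              x$n_frames, dim(x$frames)[2], dim(x$frames)[1],
              x$optics$pixel_size_nm))
  invisible(x)
}

#' Ground-truth sidecar table
#'
#' Per-frame active emitter list with the expected photon yield of each
#' activation, carried alongside a simulated stack so that downstream
#' labels can be checked against truth.
#'
#' @param traces From [simulate_blinking()].
#' @param optics An [optics_config()].
#' @return Data frame `frame`, `emitter_id`, `x_nm`, `y_nm`, `on_fraction`,
#'   `photons`.
#' @export
ground_truth_sidecar <- function(traces, optics) {
  a <- traces$active
  data.frame(frame = a$frame, emitter_id = a$id, x_nm = a$x, y_nm = a$y,
             on_fraction = a$on_fraction,
             photons = a$on_fraction * optics$photons_full_frame)
}

#' One-call simulated acquisition
#'
#' Seeds emitters on a structure, runs the photoswitching chain, renders
#' the camera frames and returns the stack together with its ground-truth
#' sidecar.
#'
#' @param geom A [sample_geometry()].
#' @param n_frames Number of frames.
#' @param p_act Activation probability per emitter per frame (with the
#'   tagging density this sets the nominal activation density
#'   a = p_act * tagging density).
#' @param tagging_density_per_nm2 Tagging density; default 0.5 nm^-2.
#' @param optics,camera,photophysics Configuration objects; defaults used
#'   when NULL (photophysics defaults to [photophysics_model()] at the
#'   given `p_act`).
#' @param seed Integer seed (drives seeding, blinking and noise).
#' @param noise Passed to [render_frames()].
#' @param max_emitters Passed to [seed_emitters()].
#' @return List `stack`, `sidecar`, `traces`, `emitters`, `geometry`,
#'   `nominal_a` (per nm^2 per frame).
#' @export
simulate_acquisition <- function(geom, n_frames, p_act,
                                 tagging_density_per_nm2 = 0.5,
                                 optics = NULL, camera = NULL,
                                 photophysics = NULL, seed = 1,
                                 noise = TRUE, max_emitters = 5e5) {
  if (is.null(optics)) optics <- optics_config()
  if (is.null(camera)) camera <- camera_model()
  if (is.null(photophysics)) photophysics <- photophysics_model(p_act)
  set.seed(seed)
  emitters <- seed_emitters(geom, tagging_density_per_nm2,
                            max_emitters = max_emitters)
  traces <- simulate_blinking(emitters, photophysics, n_frames)
  stack <- render_frames(traces, optics, camera, noise = noise)
  list(stack = stack, sidecar = ground_truth_sidecar(traces, optics),
       traces = traces, emitters = emitters, geometry = geom,
       nominal_a = p_act * tagging_density_per_nm2)
}
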