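# Shared fixture builders. Everything is generated in code at test time;
# expensive bundles are cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Ideal camera: no EM noise, no read noise, unit QE, baseline 100 counts.
noise_free_camera <- function(baseline = 100) {
  camera_model(em_gain = 1, readout_noise_rms = 0, baseline_offset = baseline,
               quantum_efficiency = 1)
}

# Render n emitters at given nm positions into a single-frame stack.
emitters_stack <- function(x_nm, y_nm, photons = 450, field = c(21L, 21L),
                           noise = FALSE, camera = noise_free_camera(),
                           on_fraction = 1, seed = NULL) {
  optics <- optics_config(field_px = field, photons_full_frame = photons)
  act <- data.frame(frame = 1L, id = seq_along(x_nm), x = x_nm, y = y_nm,
                    on_fraction = on_fraction)
  render_frames(act, optics, camera, seed = seed, noise = noise, n_frames = 1L)
}

# A stack with one well-separated activation per frame at known positions.
one_per_frame_stack <- function(n_frames = 100, photons = 450, seed = 42,
                                field = c(24L, 24L), camera = camera_model()) {
  set.seed(seed)
  optics <- optics_config(field_px = field, photons_full_frame = photons)
  lim <- c(7, field[1] - 7) * optics$pixel_size_nm
  x <- runif(n_frames, lim[1], lim[2])
  y <- runif(n_frames, lim[1], lim[2])
  act <- data.frame(frame = seq_len(n_frames), id = seq_len(n_frames),
                    x = x, y = y, on_fraction = 1)
  stack <- render_frames(act, optics, camera, noise = TRUE,
                         n_frames = n_frames)
  list(stack = stack, truth = act)
}

# Match localizations to ground-truth positions within a radius; returns
# per-localization distance to the matched truth (NA when unmatched).
match_to_truth <- function(tab, truth, radius = 250) {
  vapply(seq_len(nrow(tab)), function(i) {
    gt <- truth[truth$frame == tab$frame[i], , drop = FALSE]
    if (nrow(gt) == 0) return(NA_real_)
    d <- sqrt((gt$x - tab$x[i])^2 + (gt$y - tab$y[i])^2)
    if (min(d) <= radius) min(d) else NA_real_
  }, numeric(1))
}

# Dense 2D-plane acquisition in the overlap-rich regime (activation
# density twice the optimum for r = 440 nm), localized with the default
# permissive filter. Used by the classifier tests.
dense_plane_bundle <- function() {
  cached("dense_plane", {
    E <- exclusion_area(exclusion_model(2, 440))
    fx <- make_fixture("fig_plane", scale = "ci", seed = 11,
                       p_act = p_act_for_density(2 / E, 0.01))
    tab <- localize_stack(fx$stack)
    lab <- oracle_label(tab, fx$sidecar)
    list(fx = fx, tab = tab, lab = lab)
  })
}
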