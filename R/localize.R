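# Separable Gaussian blur with reflected edges; kernel truncated at 4 sigma.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  hw <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-hw:hw, sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(v, hw) c(rev(v[seq_len(hw) + 1L]), v,
                                   rev(v[length(v) - seq_len(hw)]))
  conv1 <- function(v) {
    vp <- pad_reflect(v, hw)
    stats::filter(vp, k, sides = 2)[(hw + 1):(hw + length(v))]
  }
  tmp <- apply(img, 2, conv1)
  t(apply(tmp, 1, conv1))
}

#' Detect candidate emitters in a frame
#'
#' Band-pass filters the image (difference of Gaussians tuned to the PSF
#' scale), finds local maxima above a robust threshold, and enforces a
#' minimum separation between candidates (ties between equal maxima are
#' broken toward the lowest row, then column index).
#'
#' @param img Matrix of camera counts (rows = y, columns = x).
#' @param psf_sigma_px PSF sigma in pixels.
#' @param k_mad Threshold in robust noise SDs of the filtered image.
#'   Default 4.
#' @param rel_floor Additional threshold as a fraction of the filtered
#'   image maximum (suppresses PSF side-lobes in noise-free images).
#'   Default 0.05.
#' @param min_distance_px Minimum candidate separation (pixels). Default 3.
#' @return Data frame `row`, `col` (1-based pixel indices), `value`.
#' @export
detect_candidates <- function(img, psf_sigma_px = 0.665, k_mad = 4,
                              rel_floor = 0.05, min_distance_px = 3) {
  if (!is.matrix(img) || length(img) == 0) stop("img must be a non-empty matrix")
  det <- gaussian_blur(img, max(0.8, psf_sigma_px * 0.8)) -
    gaussian_blur(img, psf_sigma_px * 3)
  noise_sd <- stats::mad(det)
  thr <- max(k_mad * noise_sd, rel_floor * max(det), 1e-9)
  ny <- nrow(det); nx <- ncol(det)
  if (ny < 3 || nx < 3) stop("image too small for detection")
  ctr <- det[2:(ny - 1), 2:(nx - 1)]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- det[2:(ny - 1) + dr, 2:(nx - 1) + dc]
    # strict on earlier-scanned neighbours, non-strict after: unique winner
    # among equal plateau values is the lowest (row, col)
    is_max <- is_max & if (dr < 0 || (dr == 0 && dc < 0)) ctr > nb else ctr >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     value = ctr[idx])
  cand <- cand[order(-cand$value, cand$row, cand$col), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$row - cand$row[i])^2 + (prev$col - cand$col[i])^2
    keep[i] <- all(d2 >= min_distance_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Residuals and Jacobian of an elliptical pixel-integrated Gaussian over a
# fitting window, parameters p = (N, x, y, sx, sy, b) in pixel units for
# positions/sigmas, counts for N and b.
gauss2d_model <- function(p, xs, ys) {
  p[4:5] <- abs(p[4:5])  # sigma enters through its magnitude
  ex <- stats::pnorm(xs + 1, p[2], p[4]) - stats::pnorm(xs, p[2], p[4])
  ey <- stats::pnorm(ys + 1, p[3], p[5]) - stats::pnorm(ys, p[3], p[5])
  p[6] + p[1] * (ey %o% ex)
}

gauss2d_jac <- function(p, xs, ys) {
  sg <- sign(p[4:5]); sg[sg == 0] <- 1
  p[4:5] <- abs(p[4:5])
  ex <- stats::pnorm(xs + 1, p[2], p[4]) - stats::pnorm(xs, p[2], p[4])
  ey <- stats::pnorm(ys + 1, p[3], p[5]) - stats::pnorm(ys, p[3], p[5])
  dx1 <- stats::dnorm(xs + 1, p[2], p[4]); dx0 <- stats::dnorm(xs, p[2], p[4])
  dy1 <- stats::dnorm(ys + 1, p[3], p[5]); dy0 <- stats::dnorm(ys, p[3], p[5])
  dex_dx <- -(dx1 - dx0)
  dey_dy <- -(dy1 - dy0)
  dex_dsx <- -((xs + 1 - p[2]) * dx1 - (xs - p[2]) * dx0) / p[4]
  dey_dsy <- -((ys + 1 - p[3]) * dy1 - (ys - p[3]) * dy0) / p[5]
  n <- length(xs) * length(ys)
  cbind(as.vector(ey %o% ex),
        p[1] * as.vector(ey %o% dex_dx),
        p[1] * as.vector(dey_dy %o% ex),
        sg[1] * p[1] * as.vector(ey %o% dex_dsx),
        sg[2] * p[1] * as.vector(dey_dsy %o% ex),
        rep(1, n))
}

#' Fit a single emitter in a window
#'
#' Least-squares fit of an elliptical pixel-integrated Gaussian (amplitude,
#' subpixel position, sigma_x, sigma_y, constant offset) in a square window
#' around a detected candidate, by Levenberg-Marquardt with an analytic
#' Jacobian. The localization precision is reported with the standard
#' Thompson-style estimate including the background term.
#'
#' @param img Frame matrix (counts).
#' @param cand_row,cand_col Candidate pixel (1-based).
#' @param optics An [optics_config()].
#' @param camera A [camera_model()] (baseline and counts/pe used to convert
#'   fitted amplitude to photons).
#' @param window Fitting window side (pixels, odd). Default 11.
#' @param max_iter Maximum LM iterations. Default 100.
#' @return One-row data frame (`x`, `y` in nm, `sigma`, `sigma_x`,
#'   `sigma_y` in nm, `intensity` photons, `offset` counts, `bkgstd`
#'   counts, `uncertainty` nm), or NULL if the fit failed.
#' @export
fit_emitter <- function(img, cand_row, cand_col, optics, camera,
                        window = 11, max_iter = 100) {
  hw <- (window - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  if (cand_row - hw < 1 || cand_row + hw > ny ||
      cand_col - hw < 1 || cand_col + hw > nx)
    stop("fitting window extends beyond the image border")
  rows <- (cand_row - hw):(cand_row + hw)
  cols <- (cand_col - hw):(cand_col + hw)
  win <- img[rows, cols]
  # pixel coordinates of window pixel left/lower edges, 0-based image frame
  xs <- cols - 1; ys <- rows - 1
  px <- optics$pixel_size_nm
  s0 <- optics$psf_sigma_nm / px
  b0 <- stats::median(win)
  n0 <- max(sum(win - b0), 1)
  p0 <- c(n0, cand_col - 0.5, cand_row - 0.5, s0, s0, b0)
  res_fn <- function(p) as.vector(win) - as.vector(gauss2d_model(p, xs, ys))
  jac_fn <- function(p) -gauss2d_jac(p, xs, ys)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = p0, fn = res_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-8, ptol = 1e-8))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  p[4:5] <- abs(p[4:5])
  if (!all(is.finite(p)) || p[1] <= 0 || p[4] <= 0 || p[5] <= 0) return(NULL)
  # reject fits that ran away from the window
  if (p[2] < min(xs) || p[2] > max(xs) + 1 ||
      p[3] < min(ys) || p[3] > max(ys) + 1) return(NULL)
  n_photons <- p[1] / camera$counts_per_photoelectron
  sx_nm <- p[4] * px; sy_nm <- p[5] * px
  sigma_nm <- sqrt(sx_nm * sy_nm)
  bkgstd <- stats::sd(res_fn(p))
  # Thompson-Larkin-Webb per-axis precision with background term; the EM
  # register's excess noise doubles the effective variance
  b_var <- (bkgstd / camera$counts_per_photoelectron)^2
  excess <- if (camera$em_gain > 1) 2 else 1
  unc <- sqrt(excess * ((sigma_nm^2 + px^2 / 12) / n_photons +
                8 * pi * sigma_nm^4 * b_var / (px^2 * n_photons^2)))
  data.frame(x = p[2] * px, y = p[3] * px, sigma = sigma_nm,
             sigma_x = sx_nm, sigma_y = sy_nm, intensity = n_photons,
             offset = p[6], bkgstd = bkgstd, uncertainty = unc)
}

#' Width/asymmetry rejection of fitted localizations
#'
#' Keeps a record iff its fitted width lies within `sigma_bounds` times
#' the reference (optical) sigma and the x/y width ratio does not exceed
#' `asymmetry_max`. Merged fits to two overlapping emitters typically show
#' an inflated or strongly elliptical width and are removed here.
#'
#' @param records Localization data frame (needs `sigma`, `sigma_x`,
#'   `sigma_y`).
#' @param sigma_ref_nm Reference PSF sigma (nm).
#' @param sigma_bounds Multiplicative bounds on sigma. Default c(0.7, 1.5).
#' @param asymmetry_max Maximum max(sx,sy)/min(sx,sy). Default 1.5.
#' @return List `kept`, `rejected` (with a `reject_reason` column).
#' @export
reject_fits <- function(records, sigma_ref_nm, sigma_bounds = c(0.7, 1.5),
                        asymmetry_max = 1.5) {
  if (nrow(records) == 0)
    return(list(kept = records, rejected = records))
  lo <- sigma_bounds[1] * sigma_ref_nm
  hi <- sigma_bounds[2] * sigma_ref_nm
  asym <- pmax(records$sigma_x, records$sigma_y) /
    pmin(records$sigma_x, records$sigma_y)
  bad_sigma <- records$sigma < lo | records$sigma > hi
  bad_asym <- asym > asymmetry_max
  keep <- !(bad_sigma | bad_asym)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected))
    rejected$reject_reason <- ifelse(bad_sigma[!keep], "sigma", "asymmetry")
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Localizer configuration
#'
#' Defaults for [localize_stack()]. By default no width filter is applied
#' (only degenerate fits - non-convergent, runaway, or non-positive - are
#' dropped during fitting): the common single-emitter analysis packages
#' apply no width filter in their stock configuration, and it is exactly
#' the accepted fits to overlapping emitters that create the
#' silent-failure regime the downstream classifier exists to catch. Set
#' `sigma_bounds` (e.g. to [reject_fits()]'s strict c(0.7, 1.5)) for a
#' filtered single-emitter table.
#'
#' @param window Fitting window (pixels). Default 11.
#' @param min_distance_px Candidate separation (pixels). Default 3.
#' @param k_mad,rel_floor Detection thresholds, see [detect_candidates()].
#' @param sigma_bounds,asymmetry_max Width filter, see [reject_fits()].
#' @return List of class `localizer_config`.
#' @export
localizer_config <- function(window = 11, min_distance_px = 3, k_mad = 4,
                             rel_floor = 0.05, sigma_bounds = c(0, Inf),
                             asymmetry_max = Inf) {
  structure(list(window = window, min_distance_px = min_distance_px,
                 k_mad = k_mad, rel_floor = rel_floor,
                 sigma_bounds = sigma_bounds, asymmetry_max = asymmetry_max),
            class = "localizer_config")
}

#' Localize an image stack
#'
#' Per frame (frames are processed independently): detect candidates, fit
#' each with a full window (candidates too close to the border are
#' skipped), apply the width filter. Results are concatenated into a
#' localization table.
#'
#' @param stack A `frame_stack` (from [render_frames()] or [read_stack()]).
#' @param config A [localizer_config()].
#' @return Data frame of class `localization_table` with columns `id`,
#'   `frame`, `x`, `y`, `sigma`, `sigma_x`, `sigma_y`, `intensity`,
#'   `offset`, `bkgstd`, `uncertainty`. Pixel size and PSF sigma are
#'   attached as attributes.
#' @export
localize_stack <- function(stack, config = localizer_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  optics <- stack$optics
  hw <- (config$window - 1L) %/% 2L
  psf_px <- optics$psf_sigma_nm / optics$pixel_size_nm
  out <- vector("list", stack$n_frames)
  for (f in seq_len(stack$n_frames)) {
    img <- stack$frames[, , f]
    cand <- detect_candidates(img, psf_sigma_px = psf_px,
                              k_mad = config$k_mad,
                              rel_floor = config$rel_floor,
                              min_distance_px = config$min_distance_px)
    if (nrow(cand) == 0) next
    in_field <- cand$row - hw >= 1 & cand$row + hw <= nrow(img) &
      cand$col - hw >= 1 & cand$col + hw <= ncol(img)
    cand <- cand[in_field, , drop = FALSE]
    if (nrow(cand) == 0) next
    recs <- lapply(seq_len(nrow(cand)), function(i)
      fit_emitter(img, cand$row[i], cand$col[i], optics, stack$camera,
                  window = config$window))
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    recs <- reject_fits(recs, optics$psf_sigma_nm,
                        sigma_bounds = config$sigma_bounds,
                        asymmetry_max = config$asymmetry_max)$kept
    if (nrow(recs)) {
      recs$frame <- f
      out[[f]] <- recs
    }
  }
  keep <- !vapply(out, is.null, logical(1))
  tab <- if (any(keep)) {
    tab <- do.call(rbind, out[keep])
    tab$id <- seq_len(nrow(tab))
    tab[, c("id", "frame", "x", "y", "sigma", "sigma_x", "sigma_y",
            "intensity", "offset", "bkgstd", "uncertainty")]
  } else {
    data.frame(id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), sigma = numeric(0), sigma_x = numeric(0),
               sigma_y = numeric(0), intensity = numeric(0),
               offset = numeric(0), bkgstd = numeric(0),
               uncertainty = numeric(0))
  }
  rownames(tab) <- NULL
  attr(tab, "pixel_size_nm") <- optics$pixel_size_nm
  attr(tab, "psf_sigma_nm") <- optics$psf_sigma_nm
  attr(tab, "n_frames") <- stack$n_frames
  class(tab) <- c("localization_table", "data.frame")
  tab
}

#' Two-emitter separation sweep
#'
#' Renders two equal-brightness emitters at a series of separations,
#' localizes each image (detection + fitting, no width filter so the raw
#' fit behaviour is visible) and records, per separation, how many
#' localizations are returned and the mean inward bias of the fitted
#' positions toward the pair midpoint. Each separation is classified as
#' "merged" (one fit), "biased" (two fits, inward bias at least
#' `bias_tol_nm`) or "accurate" (two fits within tolerance).
#'
#' @param separations_nm Sorted ascending separations (nm).
#' @param optics,camera Configuration objects (defaults if NULL).
#' @param n_repeats Repeats per separation (majority vote on the regime,
#'   mean bias). Default 1, which with `noise = FALSE` is deterministic.
#' @param seed Integer seed (used only when `noise = TRUE`).
#' @param noise Add camera noise? Default FALSE.
#' @param photons Photons per emitter per frame. Default 450.
#' @param bias_tol_nm Accuracy tolerance on the inward bias. Default 25.
#' @return Object of class `separation_sweep`: data frame `separation_nm`,
#'   `n_found`, `bias_nm`, `regime`.
#' @export
separation_sweep <- function(separations_nm, optics = NULL, camera = NULL,
                             n_repeats = 1, seed = NULL, noise = FALSE,
                             photons = 450, bias_tol_nm = 25) {
  if (is.unsorted(separations_nm)) stop("separations must be sorted ascending")
  if (is.null(optics)) optics <- optics_config(field_px = c(40L, 24L))
  if (is.null(camera)) camera <- camera_model()
  optics$photons_full_frame <- photons
  if (!is.null(seed)) set.seed(seed)
  cx <- optics$field_px[1] * optics$pixel_size_nm / 2
  cy <- optics$field_px[2] * optics$pixel_size_nm / 2
  cfg <- localizer_config()
  res <- lapply(separations_nm, function(d) {
    found <- numeric(n_repeats); bias <- rep(NA_real_, n_repeats)
    for (rep_i in seq_len(n_repeats)) {
      act <- data.frame(frame = 1L, id = 1:2,
                        x = c(cx - d / 2, cx + d / 2), y = c(cy, cy),
                        on_fraction = 1)
      stack <- render_frames(act, optics, camera, noise = noise, n_frames = 1L)
      # raw fits: no width filter, so merged single fits are observable
      cfg_raw <- cfg; cfg_raw$sigma_bounds <- c(0, Inf)
      cfg_raw$asymmetry_max <- Inf
      tab <- localize_stack(stack, cfg_raw)
      found[rep_i] <- nrow(tab)
      if (nrow(tab) >= 2) {
        # match each true emitter to its nearest fit; inward bias =
        # reduction of the distance from the midpoint, along x
        fit_off <- abs(tab$x - cx)
        two <- order(abs(tab$y - cy))[1:2]
        bias[rep_i] <- mean(d / 2 - fit_off[two])
      }
    }
    nf <- stats::median(found)
    b <- if (all(is.na(bias))) NA_real_ else mean(bias, na.rm = TRUE)
    regime <- if (nf < 2) "merged"
      else if (!is.na(b) && abs(b) >= bias_tol_nm) "biased"
      else "accurate"
    data.frame(separation_nm = d, n_found = nf, bias_nm = b, regime = regime)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("separation_sweep", "data.frame"),
            bias_tol_nm = bias_tol_nm)
}

#' Estimate the exclusion radius from a separation sweep
#'
#' The sweep partitions the separation axis into merged, biased and
#' accurate regimes. The merge threshold is the largest separation still
#' fitted as a single emitter; the accurate threshold is the smallest
#' separation above which every tested separation is accurate. The
#' recommended exclusion radius is the conservative choice, the accurate
#' threshold.
#'
#' @param sweep A [separation_sweep()] result.
#' @return List `radius_nm` (recommended), `merge_threshold_nm`,
#'   `accurate_threshold_nm`.
#' @export
estimate_exclusion_radius <- function(sweep) {
  stopifnot(inherits(sweep, "separation_sweep"))
  reg <- sweep$regime
  if (!any(reg == "merged") || !any(reg == "accurate"))
    stop("sweep does not bracket both the merged and the accurate regime; widen the separation range")
  merge_thr <- max(sweep$separation_nm[reg == "merged"])
  acc_idx <- which(reg == "accurate")
  # smallest separation from which everything above stays accurate
  runs <- rev(cumprod(rev(reg == "accurate")))
  acc_thr <- min(sweep$separation_nm[runs == 1])
  if (acc_thr <= merge_thr)
    stop("regimes are not ordered (accurate threshold below merge threshold)")
  list(radius_nm = acc_thr, merge_threshold_nm = merge_thr,
       accurate_threshold_nm = acc_thr)
}
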