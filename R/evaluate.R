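#' Render a reconstruction image
#'
#' 2D histogram of localization positions. A localization at (x, y) nm
#' lands in reconstruction pixel (floor(x / p), floor(y / p)) at pixel
#' size p.
#'
#' @param table Localization table (columns `x`, `y` in nm).
#' @param pixel_nm Reconstruction pixel size. Default 10.
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)` nm; default the
#'   tight bounding box of the data.
#' @return Matrix of counts (rows = y), with `pixel_nm` and `bounds`
#'   attributes; image sum equals the table length.
#' @export
render_reconstruction <- function(table, pixel_nm = 10, bounds = NULL) {
  if (nrow(table) == 0) {
    warning("empty localization table; returning a zero image")
    img <- matrix(0, 1, 1)
    attr(img, "pixel_nm") <- pixel_nm
    return(img)
  }
  if (is.null(bounds))
    bounds <- c(min(table$x), max(table$x), min(table$y), max(table$y))
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / pixel_nm + 1e-9))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / pixel_nm + 1e-9))
  ix <- floor((table$x - bounds[1]) / pixel_nm)
  iy <- floor((table$y - bounds[3]) / pixel_nm)
  keep <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  img <- matrix(0, ny, nx)
  counts <- base::table(iy[keep] * nx + ix[keep])
  idx <- as.integer(names(counts))
  img[cbind((idx %/% nx) + 1L, (idx %% nx) + 1L)] <- as.integer(counts)
  attr(img, "pixel_nm") <- pixel_nm
  attr(img, "bounds") <- bounds
  img
}

# FRC curve between two equally-sized images: per-Fourier-ring normalized
# cross-correlation.
frc_curve <- function(img1, img2) {
  stopifnot(all(dim(img1) == dim(img2)))
  n <- dim(img1)
  f1 <- stats::fft(img1); f2 <- stats::fft(img2)
  # ring index from centred frequency coordinates
  fr <- function(k, n) { k <- k - 1; ifelse(k > n / 2, k - n, k) }
  ky <- fr(seq_len(n[1]), n[1]); kx <- fr(seq_len(n[2]), n[2])
  # radial frequency in cycles per pixel, on the common (square) grid
  rr <- sqrt(outer(ky^2, kx^2, "+"))
  ring <- round(rr)
  max_ring <- floor(min(n) / 2) - 1L
  num <- Re(f1 * Conj(f2)); p1 <- Mod(f1)^2; p2 <- Mod(f2)^2
  rings <- 0:max_ring
  frc <- vapply(rings, function(q) {
    sel <- ring == q
    s1 <- sum(p1[sel]); s2 <- sum(p2[sel])
    if (s1 == 0 || s2 == 0) return(NA_real_)
    sum(num[sel]) / sqrt(s1 * s2)
  }, numeric(1))
  n_samples <- vapply(rings, function(q) sum(ring == q), integer(1))
  data.frame(ring = rings, frc = frc, n_samples = n_samples)
}

#' Fourier ring correlation resolution
#'
#' Splits the localization table into two random halves, renders both on a
#' common square grid, correlates them per Fourier ring, repeats over
#' `n_splits` random splits and averages the curves. The resolution is the
#' inverse of the spatial frequency at which the mean curve first crosses
#' the fixed 1/7 threshold; if the curve never crosses, the result is
#' flagged unresolved.
#'
#' @param table Localization table.
#' @param n_splits Number of random half-splits to average. Default 20.
#' @param pixel_nm Rendering pixel. Default 10.
#' @param seed Integer seed for the splits.
#' @param threshold Fixed FRC threshold. Default 1/7.
#' @return Object of class `frc_result`: `resolution_nm` (NA when
#'   unresolved), `unresolved`, `freq_per_nm`, `mean_frc`, `curves`
#'   (matrix ring x split), `n_splits`.
#' @export
frc_resolution <- function(table, n_splits = 20, pixel_nm = 10, seed = NULL,
                           threshold = 1 / 7) {
  n <- nrow(table)
  if (n < 100)
    warning("fewer than 100 localizations: FRC estimates will have high variance")
  if (n < 4) stop("too few localizations for FRC")
  if (!is.null(seed)) set.seed(seed)
  # common square grid so rings are isotropic
  bounds <- c(min(table$x), max(table$x), min(table$y), max(table$y))
  side <- max(bounds[2] - bounds[1], bounds[4] - bounds[3])
  bounds <- c(bounds[1], bounds[1] + side, bounds[3], bounds[3] + side)
  curves <- NULL
  for (s in seq_len(n_splits)) {
    half <- sample.int(n, n %/% 2)
    i1 <- render_reconstruction(table[half, , drop = FALSE], pixel_nm, bounds)
    i2 <- render_reconstruction(table[-half, , drop = FALSE], pixel_nm, bounds)
    cv <- frc_curve(i1, i2)
    curves <- cbind(curves, cv$frc)
  }
  mean_frc <- rowMeans(curves, na.rm = TRUE)
  rings <- seq_along(mean_frc) - 1L
  npix <- ceiling(side / pixel_nm + 1e-9)
  freq <- rings / (npix * pixel_nm)  # cycles per nm
  below <- which(mean_frc < threshold & rings > 0)
  if (!length(below)) {
    res <- NA_real_; unresolved <- TRUE
  } else {
    i <- below[1]
    # linear interpolation between the bracketing rings
    f0 <- freq[i - 1]; f1 <- freq[i]
    c0 <- mean_frc[i - 1]; c1 <- mean_frc[i]
    fc <- if (is.finite(c0) && c0 != c1) f0 + (c0 - threshold) * (f1 - f0) / (c0 - c1) else f1
    res <- 1 / fc; unresolved <- FALSE
  }
  structure(list(resolution_nm = res, unresolved = unresolved,
                 freq_per_nm = freq, mean_frc = mean_frc, curves = curves,
                 n_splits = n_splits, threshold = threshold,
                 pixel_nm = pixel_nm),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  if (x$unresolved) {
    cat("<frc_result> unresolved (curve never crosses threshold)\n")
  } else {
    cat(sprintf("<frc_result> resolution %.1f nm (threshold %.3f, %d splits)\n",
                x$resolution_nm, x$threshold, x$n_splits))
  }
  invisible(x)
}

#' Extrapolate frames needed to reach a target density
#'
#' Given the average number of successful localizations per frame on the
#' structure, the number of frames to reach Q localizations per unit area
#' is Q * area / rate (the density grows linearly with frames).
#'
#' @param locs_per_frame Average successful localizations per frame.
#' @param area_nm2 Area of the structure (nm^2).
#' @param Q_target Target density (per nm^2). Default 1/25.
#' @return Number of frames; `Inf` (with a warning) when the rate is 0.
#' @export
frames_to_quality <- function(locs_per_frame, area_nm2, Q_target = 1 / 25) {
  stopifnot(area_nm2 > 0, Q_target > 0)
  if (locs_per_frame <= 0) {
    warning("localization rate is zero: target density unreachable")
    return(Inf)
  }
  Q_target * area_nm2 / locs_per_frame
}

#' Activation density from localization counts
#'
#' a = (number of localizations / number of frames) / sample area: the
#' plain estimator used when the localizer's per-frame return is trusted.
#'
#' @param table Localization table.
#' @param area_nm2 Estimated sample area (nm^2).
#' @param n_frames Number of frames analysed.
#' @return Activations per nm^2 per frame.
#' @export
activation_density_from_counts <- function(table, area_nm2, n_frames) {
  stopifnot(area_nm2 > 0, n_frames >= 1)
  (nrow(table) / n_frames) / area_nm2
}

#' Brightness-sum proxy for the activated-fluorophore count
#'
#' Sum of the fitted fluorophore brightnesses divided by the median
#' single-fluorophore brightness. Merged fits to several overlapping
#' emitters are still fitted (with roughly the summed brightness), so the
#' proxy counts them with their true multiplicity where a plain count
#' underestimates.
#'
#' @param intensities Fitted brightness per localization.
#' @param median_reference Median single-fluorophore brightness for this
#'   activation level.
#' @return Effective number of activated fluorophores.
#' @export
activation_proxy_from_brightness <- function(intensities, median_reference) {
  if (!is.finite(median_reference) || median_reference <= 0)
    stop("median_reference must be positive")
  if (length(intensities) == 0) return(0)
  sum(intensities) / median_reference
}

# 8-connected component labelling (two-pass union-find on small images).
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (c in seq_len(nx)) for (r in seq_len(ny)) {
    if (!mask[r, c]) next
    nb <- integer(0)
    for (dc in -1:0) for (dr in -1:1) {
      if (dc == 0 && dr >= 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= ny && cc >= 1 && lab[rr, cc] > 0)
        nb <- c(nb, lab[rr, cc])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[r, c] <- nxt
    } else {
      roots <- unique(vapply(nb, find, integer(1)))
      keep_root <- min(roots)
      lab[r, c] <- keep_root
      for (rt in roots) parent[rt] <- keep_root
    }
  }
  if (nxt > 0) {
    for (i in seq_len(nxt)) parent[i] <- find(i)
    relabel <- match(parent, sort(unique(parent)))
    pos <- lab > 0
    lab[pos] <- relabel[lab[pos]]
  }
  lab
}

#' Estimate the sample area from a reconstruction
#'
#' Binarizes the reconstruction (default: any nonzero count), removes
#' 8-connected components smaller than `min_cluster_px` pixels, and
#' returns the remaining pixel count times the pixel area. This is the
#' reproducible replacement for hand-annotating the structure outline.
#'
#' @param img Reconstruction matrix (needs a `pixel_nm` attribute or an
#'   explicit `pixel_nm` argument).
#' @param pixel_nm Reconstruction pixel size (nm).
#' @param threshold Binarization threshold (keep pixels with counts
#'   strictly greater). Default 0.
#' @param min_cluster_px Minimum surviving component size. Default 10.
#' @return Area in nm^2 (0, with a warning, for an empty image).
#' @export
estimate_sample_area <- function(img, pixel_nm = attr(img, "pixel_nm"),
                                 threshold = 0, min_cluster_px = 10) {
  if (is.null(pixel_nm)) stop("pixel_nm must be supplied")
  mask <- img > threshold
  if (!any(mask)) {
    warning("empty reconstruction: area 0")
    return(0)
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster_px)
  sum(lab %in% keep) * pixel_nm^2
}

#' Random frame subsampling
#'
#' Trims the head and tail of the acquisition (high-density start,
#' movement-blurred end), then samples the requested number of the
#' remaining frames uniformly at random without replacement. Sampling
#' frames randomly rather than contiguously prevents repeat localizations
#' of one emitter over consecutive frames from inflating short-sequence
#' FRC values.
#'
#' @param table Localization table (its `frame` column is used), or a
#'   `frame_stack`.
#' @param n_frames Number of frames to keep.
#' @param seed Integer seed.
#' @param trim_head,trim_tail Fraction of frames dropped at either end.
#'   Defaults 0.05 each.
#' @param total_frames Total frame count; default from attributes.
#' @return For a table: the subset of rows whose frame was sampled, with a
#'   `frames_used` attribute. For a stack: a stack restricted to the
#'   sampled frames.
#' @export
subsample_frames <- function(table, n_frames, seed = NULL, trim_head = 0.05,
                             trim_tail = 0.05, total_frames = NULL) {
  is_stack <- inherits(table, "frame_stack")
  if (is.null(total_frames))
    total_frames <- if (is_stack) table$n_frames else
      attr(table, "n_frames") %||% max(table$frame)
  lo <- floor(total_frames * trim_head) + 1L
  hi <- total_frames - floor(total_frames * trim_tail)
  avail <- lo:hi
  if (n_frames > length(avail))
    stop(sprintf("requested %d frames but only %d remain after trimming",
                 n_frames, length(avail)))
  if (!is.null(seed)) set.seed(seed)
  pick <- sort(sample(avail, n_frames))
  if (is_stack) {
    out <- table
    out$frames <- table$frames[, , pick, drop = FALSE]
    out$n_frames <- length(pick)
    attr(out, "frames_used") <- pick
    return(out)
  }
  out <- table[table$frame %in% pick, , drop = FALSE]
  attr(out, "frames_used") <- pick
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
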