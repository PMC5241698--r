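# Bilinear sampling of img (rows = y, cols = x, 0-based nm-free pixel
# coordinates: pixel (r, c) spans [c-1, c] x [r-1, r] with centre at
# (c - 0.5, r - 0.5)). Points outside are reflected at the border.
bilinear_sample <- function(img, xq, yq) {
  ny <- nrow(img); nx <- ncol(img)
  reflect <- function(v, n) {
    # reflect continuous coordinates into [0, n]
    v <- abs(v)
    v <- v %% (2 * n)
    ifelse(v > n, 2 * n - v, v)
  }
  xq <- reflect(xq, nx); yq <- reflect(yq, ny)
  # coordinates of pixel centres are at 0.5 .. n - 0.5
  cx <- pmin(pmax(xq - 0.5, 0), nx - 1)
  cy <- pmin(pmax(yq - 0.5, 0), ny - 1)
  x0 <- pmin(floor(cx), nx - 2); y0 <- pmin(floor(cy), ny - 2)
  fx <- cx - x0; fy <- cy - y0
  i00 <- (x0) * ny + y0 + 1
  v00 <- img[i00];        v01 <- img[i00 + ny]
  v10 <- img[i00 + 1];    v11 <- img[i00 + ny + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v01 +
    (1 - fx) * fy * v10 + fx * fy * v11
}

# Sobel gradient of a matrix at one (row, col) position (1-based, interior).
sobel_at <- function(img, r, c) {
  w <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  c(gx = sum(w * kx), gy = sum(w * ky))
}

#' Extract an aligned patch triple around a localization
#'
#' Cuts a `window` x `window` pixel patch from the localization's frame,
#' resampled (bilinear) so the localization sits at the centre of the
#' middle pixel, rotated so that the image gradient across the centre
#' pixel points vertically, and multiplied by a Gaussian window that
#' down-weights pixels far from the centre. The identical
#' shift-rotation-window transform is applied to the previous and next
#' frames, so the triple records what that region looked like immediately
#' before and after. A missing neighbour frame (first/last frame of the
#' stack) is replaced by a copy of the current patch and flagged.
#'
#' The rotation angle is taken from a Sobel gradient of the shifted
#' current patch after a sigma = 1 px Gaussian smooth; gradients below
#' 1e-12 leave the patch unrotated. Shift and rotation are composed into
#' a single bilinear resampling pass (one interpolation, not two), with
#' reflection padding at the image border.
#'
#' @param stack A `frame_stack`.
#' @param record One row of a localization table (needs `frame`, `x`, `y`
#'   in nm).
#' @param window Patch side in pixels (odd). Default 21.
#' @param gauss_window_sigma_px Gaussian window sigma (px). Default 5.
#' @return Object of class `patch_triple`: list `current`, `previous`,
#'   `next_` (window x window matrices), `has_previous`, `has_next`,
#'   `angle` (radians), `border` (TRUE if the patch touched the border).
#' @export
extract_patch_triple <- function(stack, record, window = 21,
                                 gauss_window_sigma_px = 5) {
  stopifnot(inherits(stack, "frame_stack"), window %% 2 == 1)
  px <- stack$optics$pixel_size_nm
  f <- record$frame
  if (f < 1 || f > stack$n_frames) stop("record frame outside the stack")
  hw <- (window - 1) / 2
  # localization in pixel units (0-based continuous coordinates)
  xc <- record$x / px; yc <- record$y / px
  ny <- dim(stack$frames)[1]; nx <- dim(stack$frames)[2]
  border <- xc < hw + 1 || xc > nx - hw - 1 || yc < hw + 1 || yc > ny - hw - 1
  cur <- stack$frames[, , f]
  off <- seq(-hw, hw)  # patch pixel-centre offsets from the localization
  grid_x <- outer(rep(1, window), off)
  grid_y <- outer(off, rep(1, window))
  # unrotated shifted patch, used only to measure the gradient
  shifted <- matrix(bilinear_sample(cur, xc + grid_x, yc + grid_y),
                    window, window)
  sm <- gaussian_blur(shifted, 1)
  g <- sobel_at(sm, hw + 1, hw + 1)
  angle <- if (sqrt(sum(g^2)) < 1e-12) 0 else atan2(g["gy"], g["gx"])
  # rotate so the gradient points "up" (+y in patch frame)
  rot <- pi / 2 - angle
  cs <- cos(rot); sn <- sin(rot)
  rx <- cs * grid_x - sn * grid_y
  ry <- sn * grid_x + cs * grid_y
  gwin <- exp(-(grid_x^2 + grid_y^2) / (2 * gauss_window_sigma_px^2))
  take <- function(img) {
    matrix(bilinear_sample(img, xc + rx, yc + ry), window, window) * gwin
  }
  current <- take(cur)
  has_prev <- f > 1; has_next <- f < stack$n_frames
  previous <- if (has_prev) take(stack$frames[, , f - 1]) else current
  next_ <- if (has_next) take(stack$frames[, , f + 1]) else current
  structure(list(current = current, previous = previous, next_ = next_,
                 has_previous = has_prev, has_next = has_next,
                 angle = unname(angle), border = border),
            class = "patch_triple")
}

#' Assemble the raw feature vector for one localization
#'
#' Concatenates the three windowed patches (current, previous, next; 441
#' values each) with the numeric outputs of the localization algorithm
#' plus two neighbour-availability flags. The layout is fixed:
#' `[current 441 | previous 441 | next 441 | numerics | has_prev, has_next]`.
#'
#' @param triple A [extract_patch_triple()] result.
#' @param record The matching localization row.
#' @param numeric_cols Which numeric columns of the record to append.
#'   Default sigma, intensity, offset, bkgstd, uncertainty.
#' @return Named numeric vector of length 3 * window^2 + n_extra.
#' @export
assemble_raw_feature <- function(triple, record,
                                 numeric_cols = c("sigma", "intensity",
                                                  "offset", "bkgstd",
                                                  "uncertainty")) {
  stopifnot(inherits(triple, "patch_triple"))
  numerics <- vapply(numeric_cols, function(cl) as.numeric(record[[cl]]),
                     numeric(1))
  c(cur = as.vector(triple$current), prev = as.vector(triple$previous),
    nxt = as.vector(triple$next_), numerics,
    has_prev = as.numeric(triple$has_previous),
    has_next = as.numeric(triple$has_next))
}

#' Log-magnitude transform
#'
#' Replaces each element by the natural log of its magnitude,
#' ln(|v| + eps), so that order-of-magnitude intensity variation does not
#' dominate the feature covariance. The epsilon keeps zeros finite.
#'
#' @param x Numeric vector or matrix (rows = observations).
#' @param eps Stabilizer; default 1e-6 times the median nonzero magnitude
#'   of `x`.
#' @return Transformed object of the same shape.
#' @export
log_magnitude <- function(x, eps = NULL) {
  if (is.null(eps)) {
    nz <- abs(x[x != 0])
    eps <- if (length(nz)) 1e-6 * stats::median(nz) else 1e-12
  }
  log(abs(x) + eps)
}

#' Fit a per-acquisition PCA basis
#'
#' Principal components of the covariance matrix of the supplied
#' (log-transformed) feature vectors. The basis is fitted anew for every
#' acquisition — never reused across data sets — so the reduction adapts
#' to that acquisition's variability. A fingerprint of the basis is
#' attached so train/apply skew can be detected downstream.
#'
#' @param x Matrix of features, rows = observations.
#' @param k Number of components. Default 20.
#' @return Object of class `pca_basis`: `mean`, `rotation` (d x k),
#'   `eigenvalues` (all), `k`, `fingerprint`.
#' @export
fit_pca <- function(x, k = 20) {
  x <- as.matrix(x)
  if (nrow(x) < k + 1)
    stop(sprintf("need at least k + 1 = %d observations for k = %d components; reduce k",
                 k + 1, k))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  eig <- pc$sdev^2
  fp <- sprintf("%.10e|%.10e|%d", sum(pc$center), sum(rot * rot) + sum(rot[1, ]),
                k)
  structure(list(mean = pc$center, rotation = rot, eigenvalues = eig,
                 k = k, fingerprint = fp),
            class = "pca_basis")
}

#' Project features onto a PCA basis
#'
#' @param basis A [fit_pca()] result.
#' @param x Feature matrix (rows = observations) or a single vector.
#' @return Matrix n x k of reduced features.
#' @export
reduce_features <- function(basis, x) {
  stopifnot(inherits(basis, "pca_basis"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(as.matrix(x), 2, basis$mean) %*% basis$rotation
}

#' Build the full feature matrix for a localization table
#'
#' Runs patch extraction, raw assembly, the log-magnitude transform and
#' the per-acquisition PCA for every row of the table.
#'
#' @param stack The raw `frame_stack` the table was fitted from.
#' @param table A localization table.
#' @param window,gauss_window_sigma_px Passed to [extract_patch_triple()].
#' @param k PCA dimensionality. Default 20.
#' @param numeric_cols Passed to [assemble_raw_feature()].
#' @return Object of class `feature_matrix`: `raw` (n x d), `logged`,
#'   `reduced` (n x k), `pca` ([fit_pca()] basis), `fingerprint`.
#' @export
build_feature_matrix <- function(stack, table, window = 21,
                                 gauss_window_sigma_px = 5, k = 20,
                                 numeric_cols = c("sigma", "intensity",
                                                  "offset", "bkgstd",
                                                  "uncertainty")) {
  n <- nrow(table)
  if (n == 0) stop("empty localization table")
  rows <- lapply(seq_len(n), function(i) {
    tr <- extract_patch_triple(stack, table[i, , drop = FALSE], window,
                               gauss_window_sigma_px)
    assemble_raw_feature(tr, table[i, , drop = FALSE], numeric_cols)
  })
  raw <- do.call(rbind, rows)
  logged <- log_magnitude(raw)
  pca <- fit_pca(logged, k = k)
  structure(list(raw = raw, logged = logged,
                 reduced = reduce_features(pca, logged), pca = pca,
                 fingerprint = pca$fingerprint),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  ev <- x$pca$eigenvalues
  cat(sprintf("<feature_matrix> %d localizations, raw dim %d -> %d PCs (%.1f%% variance)\n",
              nrow(x$raw), ncol(x$raw), x$pca$k,
              100 * sum(ev[seq_len(x$pca$k)]) / sum(ev)))
  invisible(x)
}
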