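#' Monte-Carlo void probability for Poisson activations
#'
#' Scatters activations as a homogeneous Poisson process of density `a`
#' on a large plane and measures the fraction with no other activation
#' within radius `r`. Under the acquisition-time model this fraction is
#' exp(-a * pi * r^2): the probability that an activation's exclusion
#' disc stays empty. Neighbour search uses grid binning (cells of side r,
#' 3 x 3 neighbourhood) via a data.table join; the plane is made large
#' enough that edge cells are a negligible fraction and the plane is
#' wrapped toroidally so no activation sees an artificial edge.
#'
#' @param a Activation density (per nm^2).
#' @param r Exclusion radius (nm).
#' @param n_activations Target number of activations (Poisson mean).
#'   Default 1e5.
#' @param seed Integer seed.
#' @return List `fraction_isolated`, `expected` (= exp(-a pi r^2)), `n`,
#'   `se` (binomial standard error).
#' @export
void_probability_mc <- function(a, r, n_activations = 1e5, seed = NULL) {
  stopifnot(a > 0, r > 0)
  if (!is.null(seed)) set.seed(seed)
  side <- sqrt(n_activations / a)
  n <- stats::rpois(1, a * side^2)
  x <- stats::runif(n, 0, side)
  y <- stats::runif(n, 0, side)
  ncell <- max(3L, floor(side / r))
  cell <- side / ncell
  pts <- data.table::data.table(id = seq_len(n), x = x, y = y,
                                cx = pmin(floor(x / cell), ncell - 1),
                                cy = pmin(floor(y / cell), ncell - 1))
  shifts <- data.table::CJ(dx = -1:1, dy = -1:1)
  probe <- pts[, .(id, x, y, cx, cy)]
  probe <- probe[rep(seq_len(.N), each = nrow(shifts))]
  probe[, `:=`(qx = (cx + rep(shifts$dx, length.out = .N)) %% ncell,
               qy = (cy + rep(shifts$dy, length.out = .N)) %% ncell)]
  data.table::setkey(pts, cx, cy)
  hits <- pts[probe, on = c(cx = "qx", cy = "qy"), allow.cartesian = TRUE,
              nomatch = NULL]
  # toroidal distance so edges do not bias the estimate
  dx <- abs(hits$x - hits$i.x); dx <- pmin(dx, side - dx)
  dy <- abs(hits$y - hits$i.y); dy <- pmin(dy, side - dy)
  close_pair <- hits$id != hits$i.id & (dx^2 + dy^2) < r^2
  crowded <- unique(hits$i.id[close_pair])
  frac <- 1 - length(crowded) / n
  expected <- exp(-a * pi * r^2)
  list(fraction_isolated = frac, expected = expected, n = n,
       se = sqrt(expected * (1 - expected) / n))
}

#' Quality report for an analysed acquisition
#'
#' Bundles the headline numbers for one localization table: the achieved
#' reconstruction density on the structure, the extrapolated frames to
#' reach the target density, the activation density by both estimators
#' (plain counts and the brightness-sum proxy) and the reconstruction-based
#' area estimate.
#'
#' @param table Localization table.
#' @param n_frames Frames analysed.
#' @param Q_target Target density (per nm^2). Default 1/25.
#' @param area_nm2 Structure area; if NULL, estimated from a thresholded
#'   10 nm reconstruction with small clusters removed.
#' @param labels Optional `label_set`; when given, the rate and achieved
#'   density count only "good" localizations.
#' @return List of class `quality_report`.
#' @export
quality_report <- function(table, n_frames, Q_target = 1 / 25,
                           area_nm2 = NULL, labels = NULL) {
  stopifnot(n_frames >= 1)
  counted <- table
  if (!is.null(labels)) {
    lab <- if (inherits(labels, "data.frame")) labels$label else labels
    counted <- table[lab == "good", , drop = FALSE]
  }
  if (is.null(area_nm2)) {
    img <- render_reconstruction(table, pixel_nm = 10)
    area_nm2 <- estimate_sample_area(img)
  }
  rate <- nrow(counted) / n_frames
  q_achieved <- if (area_nm2 > 0) nrow(counted) / area_nm2 else NA_real_
  frames_needed <- if (rate > 0 && area_nm2 > 0)
    frames_to_quality(rate, area_nm2, Q_target) else Inf
  a_counts <- if (area_nm2 > 0)
    activation_density_from_counts(table, area_nm2, n_frames) else NA_real_
  med_int <- stats::median(table$intensity)
  a_proxy <- if (area_nm2 > 0 && is.finite(med_int) && med_int > 0)
    activation_proxy_from_brightness(table$intensity, med_int) /
      n_frames / area_nm2 else NA_real_
  structure(list(n_localizations = nrow(table),
                 n_counted = nrow(counted), n_frames = n_frames,
                 area_nm2 = area_nm2, q_achieved = q_achieved,
                 Q_target = Q_target, frames_to_target = frames_needed,
                 locs_per_frame = rate,
                 activation_density_counts = a_counts,
                 activation_density_proxy = a_proxy),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  localizations        %d (%d counted) over %d frames\n",
              x$n_localizations, x$n_counted, x$n_frames))
  cat(sprintf("  area estimate        %.4g nm^2\n", x$area_nm2))
  cat(sprintf("  Q achieved           %.4g nm^-2 (target %.4g)\n",
              x$q_achieved, x$Q_target))
  cat(sprintf("  frames to target     %.4g\n", x$frames_to_target))
  cat(sprintf("  activation density   %.4g (counts) / %.4g (brightness proxy) nm^-2 frame^-1\n",
              x$activation_density_counts, x$activation_density_proxy))
  invisible(x)
}
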