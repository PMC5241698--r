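#' Rectangle primitive
#'
#' Axis-aligned rectangle, specified by its lower corner (smallest x and y)
#' and its side lengths. All lengths are in nanometres.
#'
#' @param x,y Coordinates of the lower corner (nm).
#' @param width,height Side lengths along x and y (nm); must be positive.
#' @return A list describing the primitive, for use in [sample_geometry()].
#' @export
rect_primitive <- function(x, y, width, height) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("rectangle dimensions must be positive and finite")
  structure(list(type = "rect", x = x, y = y, width = width, height = height),
            class = "geometry_primitive")
}

#' Disc primitive
#'
#' @param x,y Centre coordinates (nm).
#' @param radius Disc radius (nm); must be positive.
#' @return A list describing the primitive, for use in [sample_geometry()].
#' @export
disc_primitive <- function(x, y, radius) {
  if (!is.finite(radius) || radius <= 0) stop("disc radius must be positive")
  structure(list(type = "disc", x = x, y = y, radius = radius),
            class = "geometry_primitive")
}

#' Tagged sample geometry
#'
#' The labelled region of a sample, represented as a union of axis-aligned
#' rectangles and discs. Primitives are assumed disjoint (the fixtures built
#' by [make_structure()] satisfy this), so the tagged area is the sum of the
#' primitive areas. The nominal dimensionality records how the structure
#' looks at the scale of the exclusion radius: 0 for a point-like object
#' much smaller than the PSF, 1 for a strand, 2 for an extended patch.
#'
#' @param primitives List of primitives from [rect_primitive()] /
#'   [disc_primitive()].
#' @param dimensionality Integer in \{0, 1, 2\}.
#' @param width_nm For 1D structures the strand width w; for 0D structures
#'   the two extents (w1, w2) (a scalar is taken as w1 = w2). Ignored for 2D.
#' @param label Free-text label.
#' @return An object of class `sample_geometry`.
#' @export
sample_geometry <- function(primitives, dimensionality, width_nm = NULL,
                            label = "") {
  if (inherits(primitives, "geometry_primitive")) primitives <- list(primitives)
  stopifnot(length(primitives) >= 1)
  ok <- vapply(primitives, inherits, logical(1), "geometry_primitive")
  if (!all(ok)) stop("primitives must be built with rect_primitive()/disc_primitive()")
  if (!dimensionality %in% 0:2) stop("dimensionality must be 0, 1 or 2")
  if (dimensionality == 1L) {
    if (is.null(width_nm) || length(width_nm) != 1L || width_nm <= 0)
      stop("a 1D strand must declare a single positive width_nm")
  }
  if (dimensionality == 0L) {
    if (is.null(width_nm)) stop("a 0D structure must declare width_nm (w1, w2)")
    if (length(width_nm) == 1L) width_nm <- rep(width_nm, 2L)
    if (any(width_nm <= 0)) stop("width_nm must be positive")
  }
  structure(list(primitives = primitives,
                 dimensionality = as.integer(dimensionality),
                 width_nm = width_nm, label = label),
            class = "sample_geometry")
}

primitive_area <- function(p) {
  switch(p$type,
         rect = p$width * p$height,
         disc = pi * p$radius^2,
         stop("unknown primitive type"))
}

#' Tagged area of a geometry
#'
#' @param geom A [sample_geometry()].
#' @return Area in nm^2 (primitives assumed disjoint).
#' @export
geometry_area <- function(geom) {
  stopifnot(inherits(geom, "sample_geometry"))
  sum(vapply(geom$primitives, primitive_area, numeric(1)))
}

#' Bounding box of a geometry
#'
#' @param geom A [sample_geometry()].
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)` in nm.
#' @export
geometry_bbox <- function(geom) {
  xs <- ys <- numeric(0)
  for (p in geom$primitives) {
    if (p$type == "rect") {
      xs <- c(xs, p$x, p$x + p$width); ys <- c(ys, p$y, p$y + p$height)
    } else {
      xs <- c(xs, p$x - p$radius, p$x + p$radius)
      ys <- c(ys, p$y - p$radius, p$y + p$radius)
    }
  }
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

#' Point-in-geometry test
#'
#' @param geom A [sample_geometry()].
#' @param x,y Coordinate vectors (nm), recycled to common length.
#' @return Logical vector: does the point fall inside any primitive?
#' @export
point_in_geometry <- function(geom, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  inside <- rep(FALSE, n)
  for (p in geom$primitives) {
    inside <- inside | if (p$type == "rect") {
      x >= p$x & x <= p$x + p$width & y >= p$y & y <= p$y + p$height
    } else {
      (x - p$x)^2 + (y - p$y)^2 <= p$radius^2
    }
  }
  inside
}

#' Uniform random points inside a geometry
#'
#' Draws each point by first choosing a primitive with probability
#' proportional to its area, then sampling uniformly within it, so the
#' union is covered uniformly (primitives assumed disjoint).
#'
#' @param geom A [sample_geometry()].
#' @param n Number of points.
#' @return Data frame with columns `x`, `y` (nm).
#' @export
sample_points_in_geometry <- function(geom, n) {
  areas <- vapply(geom$primitives, primitive_area, numeric(1))
  which_p <- sample.int(length(areas), n, replace = TRUE, prob = areas)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_along(geom$primitives)) {
    idx <- which(which_p == i)
    if (!length(idx)) next
    p <- geom$primitives[[i]]
    if (p$type == "rect") {
      x[idx] <- p$x + stats::runif(length(idx)) * p$width
      y[idx] <- p$y + stats::runif(length(idx)) * p$height
    } else {
      # uniform in disc via sqrt-radius transform
      r <- p$radius * sqrt(stats::runif(length(idx)))
      th <- stats::runif(length(idx), 0, 2 * pi)
      x[idx] <- p$x + r * cos(th)
      y[idx] <- p$y + r * sin(th)
    }
  }
  data.frame(x = x, y = y)
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat(sprintf("<sample_geometry> %dD%s, %d primitive(s), area %.4g nm^2\n",
              x$dimensionality,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$primitives), geometry_area(x)))
  invisible(x)
}

#' Exclusion model
#'
#' The exclusion area E around an active emitter is the intersection of a
#' disc of radius r (the minimum separation the localization algorithm
#' tolerates) with the labelled structure. At the scale of r it follows
#' E = c * r^D with the local dimensionality D: c = pi for D = 2,
#' c = 2w for a strand of width w (D = 1), and c = w1*w2 independent of r
#' for a point-like object (D = 0).
#'
#' @param dimensionality Integer in \{0, 1, 2\}.
#' @param radius_nm Exclusion radius r (nm), positive.
#' @param width_nm Strand width (D = 1) or extents (w1, w2) (D = 0).
#' @return Object of class `exclusion_model` with fields `dimensionality`,
#'   `radius_nm`, `shape_coefficient`.
#' @export
exclusion_model <- function(dimensionality, radius_nm, width_nm = NULL) {
  if (!dimensionality %in% 0:2) stop("dimensionality must be 0, 1 or 2")
  if (!is.finite(radius_nm) || radius_nm <= 0)
    stop("radius_nm must be positive")
  cc <- switch(as.character(dimensionality),
    "2" = pi,
    "1" = {
      if (is.null(width_nm) || length(width_nm) != 1L || width_nm <= 0)
        stop("D = 1 requires a single positive width_nm")
      2 * width_nm
    },
    "0" = {
      if (is.null(width_nm)) stop("D = 0 requires width_nm (w1, w2)")
      if (length(width_nm) == 1L) width_nm <- rep(width_nm, 2L)
      if (any(width_nm <= 0)) stop("width_nm must be positive")
      prod(width_nm[1:2])
    })
  structure(list(dimensionality = as.integer(dimensionality),
                 radius_nm = radius_nm, shape_coefficient = cc,
                 width_nm = width_nm),
            class = "exclusion_model")
}

#' Build an exclusion model from a sample geometry
#'
#' @param geom A [sample_geometry()].
#' @param radius_nm Exclusion radius r (nm).
#' @return An [exclusion_model()] using the geometry's nominal
#'   dimensionality and width.
#' @export
as_exclusion_model <- function(geom, radius_nm) {
  stopifnot(inherits(geom, "sample_geometry"))
  exclusion_model(geom$dimensionality, radius_nm, geom$width_nm)
}

#' Analytic exclusion area
#'
#' Returns E = c * r^D in nm^2. For D = 0 the result is independent of the
#' radius (the whole point-like structure falls inside the exclusion disc).
#'
#' @param model An [exclusion_model()].
#' @return Area in nm^2.
#' @export
exclusion_area <- function(model) {
  stopifnot(inherits(model, "exclusion_model"))
  model$shape_coefficient * model$radius_nm^model$dimensionality
}

#' Numeric disc-structure intersection area
#'
#' Monte-Carlo estimate of the area of the intersection between a disc of
#' radius r centred at a point on the structure and the structure itself.
#' This is the quantity the analytic `exclusion_area()` approximates, and
#' serves as its oracle in scale-separated cases.
#'
#' @param geom A [sample_geometry()].
#' @param x,y Centre of the disc (nm); must lie inside the geometry.
#' @param radius_nm Disc radius (nm).
#' @param n_points Number of Monte-Carlo points (default 1e6 gives ~0.1%
#'   relative error for non-degenerate intersections).
#' @param seed Optional integer seed for reproducibility.
#' @return Estimated intersection area in nm^2.
#' @export
intersection_area_numeric <- function(geom, x, y, radius_nm,
                                      n_points = 1e6, seed = NULL) {
  stopifnot(inherits(geom, "sample_geometry"))
  if (!is.finite(radius_nm) || radius_nm < 0) stop("radius_nm must be >= 0")
  if (!point_in_geometry(geom, x, y))
    stop("the disc centre must lie inside the tagged structure")
  if (radius_nm == 0) return(0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  r <- radius_nm * sqrt(stats::runif(n_points))
  th <- stats::runif(n_points, 0, 2 * pi)
  frac <- mean(point_in_geometry(geom, x + r * cos(th), y + r * sin(th)))
  frac * pi * radius_nm^2
}

#' Frames needed to reach a target localization density
#'
#' In the density-limited regime the number of frames required to
#' accumulate Q successful localizations per unit area, when activations
#' arrive as a Poisson process with per-area per-frame density a and each
#' activation is spoiled by any second activation inside its exclusion
#' area E, is
#' \deqn{T = Q / (a e^{-aE}).}
#'
#' @param Q Target localization density (per nm^2).
#' @param a Activation density (per nm^2 per frame), > 0. Vectorized.
#' @param E Exclusion area (nm^2), >= 0.
#' @return Number of frames (same length as `a`).
#' @export
acquisition_time <- function(Q, a, E) {
  if (any(!is.finite(Q)) || any(Q <= 0)) stop("Q must be positive")
  if (any(!is.finite(a)) || any(a <= 0)) stop("activation density a must be positive")
  if (any(!is.finite(E)) || any(E < 0)) stop("exclusion area E must be >= 0")
  Q / (a * exp(-a * E))
}

#' Optimal activation density and minimum acquisition time
#'
#' Differentiating T(a) = Q / (a exp(-aE)) gives a unique interior minimum
#' at a* = 1/E with T_min = e * Q * E. E = 0 is degenerate (T = Q/a
#' decreases without bound as a grows); it is reported as a flagged special
#' case rather than an infinite optimum.
#'
#' @param Q Target localization density (per nm^2).
#' @param E Exclusion area (nm^2).
#' @return List with `a_star`, `t_min_frames` and logical `degenerate`.
#' @export
optimal_activation <- function(Q, E) {
  if (!is.finite(Q) || Q <= 0) stop("Q must be positive")
  if (!is.finite(E) || E < 0) stop("E must be >= 0")
  if (E == 0) {
    warning("E = 0: T(a) = Q/a has no interior minimum; increase a at will")
    return(list(a_star = NA_real_, t_min_frames = NA_real_, degenerate = TRUE))
  }
  list(a_star = 1 / E, t_min_frames = exp(1) * Q * E, degenerate = FALSE)
}

#' Ratio of minimum acquisition times between two structures
#'
#' At equal target density Q the minimum acquisition times are proportional
#' to the exclusion areas, so the speed penalty of structure A relative to
#' structure B at a common exclusion radius is E_A / E_B.
#'
#' @param geom_a,geom_b [sample_geometry()] objects (or [exclusion_model()]s).
#' @param radius_nm Exclusion radius r (nm); ignored when models are passed.
#' @return The ratio T_min(A) / T_min(B) = E_A / E_B.
#' @export
speed_ratio <- function(geom_a, geom_b, radius_nm = NULL) {
  to_model <- function(g) {
    if (inherits(g, "exclusion_model")) return(g)
    if (is.null(radius_nm)) stop("radius_nm is required with sample geometries")
    as_exclusion_model(g, radius_nm)
  }
  ea <- exclusion_area(to_model(geom_a))
  eb <- exclusion_area(to_model(geom_b))
  if (ea <= 0 || eb <= 0) stop("exclusion areas must be positive for a ratio")
  ea / eb
}

#' Acquisition plan for a structure
#'
#' Convenience wrapper: builds the exclusion model at radius r, computes the
#' exclusion area, the optimal activation density and the minimum number of
#' frames for the target density Q, and tabulates T(a) on a log-spaced grid.
#'
#' @param geom A [sample_geometry()].
#' @param radius_nm Exclusion radius (nm).
#' @param Q Target localization density (per nm^2); default 1/25 nm^-2,
#'   i.e. one localization per 5 x 5 nm region.
#' @param a_grid Optional activation densities for the T(a) curve; default
#'   100 log-spaced points spanning a*/30 .. 30 a*.
#' @return List of class `acquisition_plan` with `exclusion_area_nm2`,
#'   `a_star`, `t_min_frames` and a data frame `curve` (a, frames).
#' @export
plan_acquisition <- function(geom, radius_nm, Q = 1 / 25, a_grid = NULL) {
  model <- as_exclusion_model(geom, radius_nm)
  E <- exclusion_area(model)
  opt <- optimal_activation(Q, E)
  if (is.null(a_grid) && !opt$degenerate)
    a_grid <- exp(seq(log(opt$a_star / 30), log(opt$a_star * 30), length.out = 100))
  curve <- if (is.null(a_grid)) NULL else
    data.frame(a = a_grid, frames = acquisition_time(Q, a_grid, E))
  structure(list(geometry = geom, radius_nm = radius_nm, Q = Q,
                 exclusion_area_nm2 = E, a_star = opt$a_star,
                 t_min_frames = opt$t_min_frames, degenerate = opt$degenerate,
                 curve = curve),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("<acquisition_plan> r = %g nm, Q = %g nm^-2\n", x$radius_nm, x$Q))
  cat(sprintf("  E      = %.4g nm^2 (%.4g um^2)\n",
              x$exclusion_area_nm2, x$exclusion_area_nm2 / 1e6))
  if (x$degenerate) {
    cat("  E = 0: no interior optimum (T = Q/a)\n")
  } else {
    cat(sprintf("  a*     = %.4g nm^-2 per frame (%.4g um^-2)\n",
                x$a_star, x$a_star * 1e6))
    cat(sprintf("  T_min  = %.4g frames\n", x$t_min_frames))
  }
  invisible(x)
}
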