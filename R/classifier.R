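LABEL_LEVELS <- c("good", "background", "too_dense")

#' Time-stratified sample of localizations to label
#'
#' Partitions the table (in frame order) into equal-count time strata and
#' draws the same number from each (plus-minus one), so the labelled subset
#' spans the whole acquisition period without bias.
#'
#' @param table Localization table.
#' @param n Number of indices to draw. Default 300.
#' @param n_strata Number of time strata. Default 30.
#' @param seed Integer seed.
#' @return Integer row indices into `table` (sorted, no duplicates).
#' @export
stratified_sample <- function(table, n = 300, n_strata = 30, seed = NULL) {
  m <- nrow(table)
  if (m == 0) stop("cannot sample from an empty table")
  if (!is.null(seed)) set.seed(seed)
  if (n >= m) {
    if (n > m) warning("requested more samples than localizations; returning all")
    return(seq_len(m))
  }
  n_strata <- min(n_strata, n, m)
  ord <- order(table$frame)
  # equal-count strata over the acquisition, in time order
  stratum <- ceiling(seq_along(ord) / (m / n_strata))
  base <- n %/% n_strata
  per <- rep(base, n_strata)
  extra <- n %% n_strata
  if (extra > 0) per[sample.int(n_strata, extra)] <- base + 1
  picked <- unlist(lapply(seq_len(n_strata), function(s) {
    pool <- ord[stratum == s]
    sample(pool, min(per[s], length(pool)))
  }))
  sort(picked)
}

#' Oracle labels from simulation ground truth
#'
#' Stand-in for the human labeller, usable only on simulated data: each
#' localization is labelled from the ground-truth sidecar. Precedence:
#' "too_dense" if two or more emitters were active within the
#' pair-resolution radius of the localization in its frame; otherwise
#' "good" if exactly one active emitter lies within the match radius and
#' the position error is below `k_uncertainty` times the reported
#' uncertainty; otherwise "background".
#'
#' @param table Localization table.
#' @param sidecar Ground-truth sidecar ([ground_truth_sidecar()]).
#' @param match_radius_nm Radius for matching a localization to an
#'   emitter. Default 250.
#' @param pair_radius_nm Radius within which a second active emitter
#'   spoils the fit. Default 500.
#' @param k_uncertainty Error tolerance in units of the reported
#'   uncertainty. Default 3.
#' @return Data frame of class `label_set`: `index`, `label` (factor
#'   good/background/too_dense), `provenance` = "oracle".
#' @export
oracle_label <- function(table, sidecar, match_radius_nm = 250,
                         pair_radius_nm = 500, k_uncertainty = 3) {
  if (is.null(sidecar) || nrow(sidecar) == 0)
    stop("ground-truth sidecar is missing or empty")
  by_frame <- split(sidecar, sidecar$frame)
  labels <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    gt <- by_frame[[as.character(table$frame[i])]]
    if (is.null(gt) || nrow(gt) == 0) { labels[i] <- "background"; next }
    d <- sqrt((gt$x_nm - table$x[i])^2 + (gt$y_nm - table$y[i])^2)
    if (sum(d <= pair_radius_nm) >= 2) { labels[i] <- "too_dense"; next }
    near <- which(d <= match_radius_nm)
    if (length(near) == 1 &&
        d[near] < k_uncertainty * table$uncertainty[i]) {
      labels[i] <- "good"
    } else {
      labels[i] <- "background"
    }
  }
  structure(data.frame(index = seq_len(nrow(table)),
                       label = factor(labels, levels = LABEL_LEVELS),
                       provenance = "oracle"),
            class = c("label_set", "data.frame"))
}

#' Train the fit-quality random forest
#'
#' 300 bootstrap-trained trees voting by majority, each split drawn from a
#' small random feature subset (ceiling(sqrt(k)) of the 20 components),
#' trained on the labelled subset of the PCA-reduced features. Each
#' tree's bootstrap is drawn class-balanced (the same number of samples
#' per class, equal to the rarest class's count): in the overlap-rich
#' regime the label distribution is heavily skewed toward "too_dense",
#' and an unbalanced bootstrap lets the majority vote drown out the rare
#' good/background classes entirely.
#'
#' @param features_20d Reduced feature matrix (rows = labelled
#'   localizations, in the same order as `labels`).
#' @param labels Factor or character vector of labels (good / background /
#'   too_dense); at least two classes must be present.
#' @param n_trees Number of trees. Default 300.
#' @param seed Integer seed (stored for reproducibility).
#' @param fingerprint PCA basis fingerprint to bind the model to (from
#'   [build_feature_matrix()] / [fit_pca()]).
#' @return Object of class `forest_model`.
#' @export
train_forest <- function(features_20d, labels, n_trees = 300, seed = 1,
                         fingerprint = NULL) {
  y <- factor(as.character(labels),
              levels = intersect(LABEL_LEVELS, unique(as.character(labels))))
  if (nlevels(y) < 2)
    stop("training labels cover a single class; label a more varied subset")
  x <- as.matrix(features_20d)
  stopifnot(nrow(x) == length(y))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = ceiling(sqrt(ncol(x))), nodesize = 1,
    strata = y, sampsize = rep(min(table(y)), nlevels(y)))
  structure(list(forest = rf, n_trees = n_trees, seed = seed,
                 classes = levels(y), fingerprint = fingerprint),
            class = "forest_model")
}

#' Classify all localizations
#'
#' Applies a trained forest to a full reduced feature matrix. If both the
#' model and the features carry a PCA fingerprint they must match: a
#' forest trained in one PCA coordinate system must never be applied to
#' features reduced with a different basis.
#'
#' @param model A [train_forest()] model.
#' @param features A `feature_matrix` (its `reduced` block is used) or a
#'   plain n x k matrix.
#' @param fingerprint Fingerprint of the basis that produced plain-matrix
#'   features; ignored when `features` is a `feature_matrix`.
#' @return `label_set` data frame: `index`, `label`, `provenance` =
#'   "predicted", plus vote-fraction columns `vote_<class>` (rows sum
#'   to 1).
#' @export
classify_all <- function(model, features, fingerprint = NULL) {
  stopifnot(inherits(model, "forest_model"))
  if (inherits(features, "feature_matrix")) {
    fingerprint <- features$fingerprint
    features <- features$reduced
  }
  if (!is.null(model$fingerprint) && !is.null(fingerprint) &&
      !identical(model$fingerprint, fingerprint))
    stop("PCA basis fingerprint mismatch between training and application features")
  votes <- stats::predict(model$forest, as.matrix(features), type = "vote",
                          norm.votes = TRUE)
  lab <- colnames(votes)[max.col(votes, ties.method = "first")]
  out <- data.frame(index = seq_len(nrow(votes)),
                    label = factor(lab, levels = LABEL_LEVELS),
                    provenance = "predicted")
  for (cl in colnames(votes)) out[[paste0("vote_", cl)]] <- votes[, cl]
  structure(out, class = c("label_set", "data.frame"))
}

#' Split a table into good and misfit localizations
#'
#' Misfit = background or too_dense. Used for two-colour reconstructions
#' of accurate versus artefactual localizations.
#'
#' @param table Localization table.
#' @param labels `label_set` (or factor) aligned with the table rows.
#' @return List `good`, `misfit` (both subsets of `table`).
#' @export
split_reconstruction <- function(table, labels) {
  lab <- if (inherits(labels, "data.frame")) labels$label else labels
  stopifnot(length(lab) == nrow(table))
  good <- lab == "good"
  list(good = table[good, , drop = FALSE],
       misfit = table[!good, , drop = FALSE])
}

#' Read / write label files
#'
#' Plain CSV with columns `index`, `label`, `provenance`, the interchange
#' format between this package and any external labelling front end.
#'
#' @param path File path.
#' @param labels A `label_set` data frame.
#' @return `read_labels` returns a `label_set`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("label file is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$label), LABEL_LEVELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  df$label <- factor(df$label, levels = LABEL_LEVELS)
  if (is.null(df$provenance)) df$provenance <- "user"
  structure(df, class = c("label_set", "data.frame"))
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}

#' Balanced accuracy
#'
#' Mean per-class recall over the classes present in the reference
#' labels; the headline metric for classifier-versus-oracle agreement.
#'
#' @param predicted,reference Factors or characters of equal length.
#' @return Scalar in [0, 1].
#' @export
balanced_accuracy <- function(predicted, reference) {
  predicted <- as.character(predicted); reference <- as.character(reference)
  stopifnot(length(predicted) == length(reference))
  classes <- unique(reference)
  mean(vapply(classes, function(cl) {
    idx <- reference == cl
    mean(predicted[idx] == cl)
  }, numeric(1)))
}
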