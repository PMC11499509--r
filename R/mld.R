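#' Multi-label datasets
#'
#' An `mld` couples a numeric feature matrix with a binary label matrix over
#' the same instances. It is the currency of every function in this package:
#' imbalance measures, resamplers, classifiers and the synthetic generator all
#' consume and produce `mld` objects. Construct one from any data frame by
#' naming the columns that hold the binary labels; all remaining numeric
#' columns become features.
#'
#' @param data A data frame (or tibble) holding one row per instance.
#' @param label_cols Character vector of column names holding the binary
#'   labels. Order is preserved.
#' @param provenance Free-text origin tag (a file path, a generator
#'   description, ...). Defaults to `"data.frame"`.
#'
#' @return An object of class `mld`.
#' @export
#' @examples
#' df <- tibble::tibble(x1 = rnorm(4), x2 = rnorm(4),
#'                      a = c(1, 0, 1, 0), b = c(0, 0, 1, 1))
#' m <- mld(df, label_cols = c("a", "b"))
#' m
mld <- function(data, label_cols, provenance = "data.frame") {
  stopifnot(is.data.frame(data), is.character(label_cols))
  missing_cols <- setdiff(label_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("label column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lab_df <- data[label_cols]
  for (cn in label_cols) {
    v <- lab_df[[cn]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad) > 0) {
      stop(sprintf("label column '%s' contains a non-binary value at row %d",
                   cn, bad[1]), call. = FALSE)
    }
  }
  feat_cols <- setdiff(names(data), label_cols)
  feat_df <- data[feat_cols]
  num_ok <- vapply(feat_df, is.numeric, logical(1))
  feat_df <- feat_df[num_ok]
  features <- as.matrix(feat_df)
  if (nrow(data) > 0 && ncol(features) > 0) storage.mode(features) <- "double"
  labels <- as.matrix(lab_df)
  storage.mode(labels) <- "integer"
  new_mld(features, labels,
          label_names = label_cols,
          feature_names = colnames(feat_df) %||% character(0),
          provenance = provenance)
}

#' @keywords internal
new_mld <- function(features, labels, label_names, feature_names,
                    provenance = "constructed", synthetic = NULL) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels)) {
    stop("features and labels must have the same number of rows", call. = FALSE)
  }
  if (anyNA(features)) {
    stop("missing feature values are not supported", call. = FALSE)
  }
  if (length(labels) > 0 && !all(labels %in% c(0L, 1L))) {
    stop("label entries must all be 0 or 1", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (length(features) > 0) storage.mode(features) <- "double"
  if (anyDuplicated(label_names)) {
    stop("label names must be unique", call. = FALSE)
  }
  if (ncol(labels) != length(label_names)) {
    stop("label_names must match the label matrix width", call. = FALSE)
  }
  colnames(labels) <- label_names
  if (ncol(features) > 0) colnames(features) <- feature_names
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(features))
  structure(
    list(features = features, labels = labels,
         label_names = as.character(label_names),
         feature_names = as.character(feature_names),
         provenance = provenance,
         synthetic = synthetic),
    class = "mld"
  )
}

#' @export
print.mld <- function(x, ...) {
  cat(sprintf("<mld> %d instances, %d features, %d labels\n",
              n_instances(x), n_features(x), n_labels(x)))
  cat("  labels:    ", paste(x$label_names, collapse = ", "), "\n")
  if (any(x$synthetic)) {
    cat(sprintf("  synthetic: %d instances\n", sum(x$synthetic)))
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Dimensions of a multi-label dataset
#'
#' @param x An `mld`.
#' @return An integer scalar.
#' @export
n_instances <- function(x) nrow(x$labels)

#' @rdname n_instances
#' @export
n_labels <- function(x) ncol(x$labels)

#' @rdname n_instances
#' @export
n_features <- function(x) ncol(x$features)

#' Extract the feature or label matrix of an `mld`
#'
#' @param x An `mld`.
#' @return A numeric (features) or integer 0/1 (labels) matrix.
#' @export
mld_features <- function(x) x$features

#' @rdname mld_features
#' @export
mld_labels <- function(x) x$labels

#' @method as_tibble mld
#' @export
as_tibble.mld <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$features, .name_repair = "minimal"),
                   tibble::as_tibble(x$labels, .name_repair = "minimal"))
}

#' Per-label positive counts
#'
#' The number of instances carrying each label, the count that drives the
#' per-label imbalance ratio.
#'
#' @param x An `mld`.
#' @return A named integer vector of length `n_labels(x)`.
#' @export
label_counts <- function(x) {
  stopifnot(inherits(x, "mld"))
  cnt <- if (n_instances(x) == 0) rep(0L, n_labels(x)) else colSums(x$labels)
  stats::setNames(as.integer(cnt), x$label_names)
}

#' Descriptive label statistics
#'
#' Label cardinality (mean number of active labels per instance), label
#' density (cardinality divided by the number of labels) and the number of
#' distinct label combinations observed, the standard summary of a
#' multi-label dataset.
#'
#' @param x An `mld` with at least one instance.
#' @return A one-row tibble with columns `n_instances`, `n_labels`,
#'   `cardinality`, `density` and `distinct_combinations`.
#' @export
#' @examples
#' m <- mld(tibble::tibble(x = 1:3, a = c(1, 0, 1), b = c(1, 1, 0)), c("a", "b"))
#' label_stats(m)
label_stats <- function(x) {
  stopifnot(inherits(x, "mld"))
  m <- n_instances(x)
  if (m < 1) stop("label_stats is undefined on an empty dataset", call. = FALSE)
  q <- n_labels(x)
  card <- mean(rowSums(x$labels))
  dens <- if (q > 0) card / q else NA_real_
  dc <- nrow(unique(x$labels))
  tibble::tibble(n_instances = m, n_labels = q,
                 cardinality = card, density = dens,
                 distinct_combinations = as.integer(dc))
}

#' Keep only instances with at least one active label
#'
#' Instances whose label vector is all zero carry no outcome information and
#' are excluded before resampling and modelling; row order is preserved.
#' Idempotent.
#'
#' @param x An `mld`.
#' @return An `mld` containing the active-label instances.
#' @export
filter_active <- function(x) {
  stopifnot(inherits(x, "mld"))
  keep <- rowSums(x$labels) >= 1
  mld_subset(x, which(keep))
}

#' @keywords internal
mld_subset <- function(x, idx) {
  new_mld(x$features[idx, , drop = FALSE],
          x$labels[idx, , drop = FALSE],
          label_names = x$label_names,
          feature_names = x$feature_names,
          provenance = x$provenance,
          synthetic = x$synthetic[idx])
}

#' Concatenate two multi-label datasets
#'
#' Row-binds two datasets over the same label space (labels must match in
#' name and order; feature dimensionality must agree).
#'
#' @param x,y `mld` objects.
#' @return An `mld` with `n_instances(x) + n_instances(y)` instances.
#' @export
bind_mld <- function(x, y) {
  stopifnot(inherits(x, "mld"), inherits(y, "mld"))
  if (!identical(x$label_names, y$label_names)) {
    stop("label spaces differ", call. = FALSE)
  }
  if (n_features(x) != n_features(y)) {
    stop("feature dimensionality differs", call. = FALSE)
  }
  new_mld(rbind(x$features, y$features),
          rbind(x$labels, y$labels),
          label_names = x$label_names,
          feature_names = x$feature_names,
          provenance = x$provenance,
          synthetic = c(x$synthetic, y$synthetic))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
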