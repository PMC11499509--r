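#' SMOTE interpolation between two feature vectors
#'
#' Returns `seed + u * (neighbor - seed)` for a uniform draw `u` on [0, 1),
#' i.e. a point on the closed segment between a minority seed and one of its
#' nearest neighbours — the elementary step of synthetic minority
#' oversampling.
#'
#' @param seed_vector,neighbor_vector Numeric vectors of equal length.
#' @param u Interpolation weight in [0, 1); drawn uniformly by default.
#' @return A numeric vector of the same length.
#' @export
smote_interpolate <- function(seed_vector, neighbor_vector,
                              u = stats::runif(1)) {
  if (length(seed_vector) != length(neighbor_vector)) {
    stop("seed and neighbor vectors differ in dimension", call. = FALSE)
  }
  stopifnot(u >= 0, u < 1)
  seed_vector + u * (neighbor_vector - seed_vector)
}

# Index of each row's nearest neighbour (Euclidean, self excluded, ties
# broken by the lowest index). Chunked so the full distance matrix is never
# materialised.
#' @keywords internal
nearest_neighbor_index <- function(X, chunk = 512L) {
  n <- nrow(X)
  if (n < 2) return(integer(n))
  rs <- rowSums(X^2)
  out <- integer(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    d2 <- -2 * (X[idx, , drop = FALSE] %*% t(X))
    d2 <- d2 + rep(rs, each = length(idx)) + rs[idx]
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

# k nearest neighbours of every row within a (small) pool; returns an
# n x k index matrix into the pool rows.
#' @keywords internal
knn_within <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  res <- apply(D, 1, function(dr) order(dr)[seq_len(k)])
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

#' Tomek links of a binary-class view
#'
#' A Tomek link is a pair of instances of opposite class that are mutual
#' nearest neighbours under Euclidean distance (ties broken by the lowest
#' index). Link members sit on the class boundary or are noise; removing them
#' sharpens the class clusters.
#'
#' @param features An n x d numeric matrix (or data frame).
#' @param binary_target A length-n vector in {0, 1}.
#' @return A tibble with columns `i`, `j` (`i < j`) and `distance`.
#' @export
#' @examples
#' x <- matrix(c(0, 0.9, 2, 3.5), ncol = 1)
#' tomek_links(x, c(0, 1, 0, 0))   # the pair (1, 2)
tomek_links <- function(features, binary_target) {
  X <- as.matrix(features)
  y <- as.integer(binary_target)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  empty <- tibble::tibble(i = integer(0), j = integer(0),
                          distance = numeric(0))
  if (nrow(X) < 2 || length(unique(y)) < 2) return(empty)
  nn <- nearest_neighbor_index(X)
  i <- which(nn > seq_along(nn))           # candidate pairs counted once
  i <- i[nn[nn[i]] == i & y[i] != y[nn[i]]]
  if (length(i) == 0) return(empty)
  j <- nn[i]
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  tibble::tibble(i = i, j = j, distance = d)
}

#' Multi-label SMOTE oversampling of minority labels
#'
#' Oversamples each minority label by SMOTE interpolation within its seed
#' pool. Proceeds in rounds: in every round the imbalance profile is
#' recomputed, labels whose IRLbl exceeds the current MeanIR are taken as
#' minority (rarest first) and each is oversampled until its IRLbl falls to
#' the current MeanIR; rounds stop once MeanIR <= 1.5 and CVIR <= 0.2 (the
#' conventional balance thresholds), when no further progress is possible, or
#' after `max_rounds`. Each synthetic instance copies its seed's full label
#' vector, so oversampling a label never inflates any label in the current
#' majority set; original instances are never modified.
#'
#' The seed pool for label `l` is, under the default strict rule, the set of
#' instances carrying `l` and no other label; under `seed_pool =
#' "no-majority"` only the current majority labels must be absent. Labels
#' whose pool holds fewer than two instances are skipped with a warning, and
#' `k` is clamped to pool size minus one when necessary.
#'
#' @param x An `mld`; every label needs at least one positive instance.
#' @param profile Optional precomputed [imbalance_profile()] of `x`.
#' @param k Number of nearest neighbours considered per seed (default 5).
#' @param seed_pool `"strict"` or `"no-majority"`.
#' @param max_rounds Upper bound on oversampling rounds.
#' @param cap_factor Per-label, per-round cap on synthetic instances as a
#'   multiple of the current pool size (guards tiny pools).
#' @return A list with `data` (the augmented `mld`), `synthetic_added`
#'   (named per-label counts) and `rounds`.
#' @export
ml_smote <- function(x, profile = NULL, k = 5,
                     seed_pool = c("strict", "no-majority"),
                     max_rounds = 10, cap_factor = 5) {
  stopifnot(inherits(x, "mld"), k >= 1)
  seed_pool <- match.arg(seed_pool)
  added <- stats::setNames(rep(0L, n_labels(x)), x$label_names)
  cur <- x
  prof <- profile %||% imbalance_profile(x)
  rounds <- 0L
  repeat {
    if (prof$mean_ir <= 1.5 && prof$cvir <= 0.2) break
    if (rounds >= max_rounds) break
    minority <- prof$minority[order(prof$irlbl[prof$minority],
                                    decreasing = TRUE)]
    if (length(minority) == 0) break
    progressed <- FALSE
    Y <- cur$labels
    for (l in minority) {
      in_pool <- Y[, l] == 1L
      others <- if (seed_pool == "strict") {
        setdiff(seq_len(ncol(Y)), l)
      } else {
        setdiff(prof$majority, l)
      }
      if (length(others) > 0) {
        in_pool <- in_pool & rowSums(Y[, others, drop = FALSE]) == 0L
      }
      pool <- which(in_pool)
      target <- ceiling(max(prof$counts) / prof$mean_ir)
      n_new <- max(0L, as.integer(target) - sum(Y[, l]))
      if (n_new == 0) next
      if (length(pool) < 2) {
        warning(sprintf(
          "label '%s': seed pool has %d instance(s); cannot interpolate, skipped",
          cur$label_names[l], length(pool)), call. = FALSE)
        next
      }
      n_new <- min(n_new, cap_factor * length(pool))
      k_eff <- min(k, length(pool) - 1)
      if (k_eff < k) {
        warning(sprintf("label '%s': k clamped from %d to %d (pool size %d)",
                        cur$label_names[l], k, k_eff, length(pool)),
                call. = FALSE)
      }
      Xp <- cur$features[pool, , drop = FALSE]
      nn <- knn_within(Xp, k_eff)
      seed_ids <- sample.int(length(pool), n_new, replace = TRUE)
      nb_ids <- nn[cbind(seed_ids,
                         sample.int(k_eff, n_new, replace = TRUE))]
      u <- stats::runif(n_new)
      newX <- Xp[seed_ids, , drop = FALSE] +
        u * (Xp[nb_ids, , drop = FALSE] - Xp[seed_ids, , drop = FALSE])
      newY <- cur$labels[pool[seed_ids], , drop = FALSE]
      synth <- new_mld(newX, newY,
                       label_names = cur$label_names,
                       feature_names = cur$feature_names,
                       provenance = cur$provenance,
                       synthetic = rep(TRUE, n_new))
      cur <- bind_mld(cur, synth)
      Y <- cur$labels
      added <- added + colSums(newY)
      progressed <- TRUE
    }
    rounds <- rounds + 1L
    if (!progressed) break
    prof <- imbalance_profile(cur)
  }
  list(data = cur, synthetic_added = added, rounds = rounds)
}

#' Tomek-link cleaning of majority labels
#'
#' For each majority label (most frequent first) the dataset is viewed as a
#' binary problem on that label; Tomek links are recomputed on the instances
#' surviving so far and both members of every link are removed — the
#' post-process cleaning variant — except that an instance is never removed
#' if it is the last remaining positive of any label.
#'
#' @param x An `mld` (typically SMOTE-augmented).
#' @param profile Optional precomputed [imbalance_profile()] of `x`; its
#'   majority set and label order drive the cleaning.
#' @return A list with `data` (the cleaned `mld`) and `removed_by_tomek`
#'   (named counts of instances removed during each majority label's pass).
#' @export
ml_tomek_clean <- function(x, profile = NULL) {
  stopifnot(inherits(x, "mld"))
  prof <- profile %||% imbalance_profile(x)
  removed <- stats::setNames(rep(0L, n_labels(x)), x$label_names)
  surviving <- rep(TRUE, n_instances(x))
  pos_count <- colSums(x$labels)
  majority <- prof$majority[order(prof$irlbl[prof$majority])]
  for (l in majority) {
    idx <- which(surviving)
    y <- x$labels[idx, l]
    if (length(unique(y)) < 2 || length(idx) < 2) next
    links <- tomek_links(x$features[idx, , drop = FALSE], y)
    if (nrow(links) == 0) next
    for (r in seq_len(nrow(links))) {
      for (member in c(idx[links$i[r]], idx[links$j[r]])) {
        if (!surviving[member]) next
        lab_on <- which(x$labels[member, ] == 1L)
        if (any(pos_count[lab_on] <= 1)) next   # never orphan a label
        surviving[member] <- FALSE
        pos_count[lab_on] <- pos_count[lab_on] - 1L
        removed[l] <- removed[l] + 1L
      }
    }
  }
  list(data = mld_subset(x, which(surviving)), removed_by_tomek = removed)
}

#' Hybrid multi-label resampling: SMOTE then Tomek-link cleaning
#'
#' The hybrid resampler first oversamples minority labels with multi-label
#' SMOTE ([ml_smote()]), then cleans the augmented dataset with per-majority-
#' label Tomek links ([ml_tomek_clean()]) computed against a profile of the
#' augmented data, and finally re-measures the imbalance. A dataset already
#' balanced on input (MeanIR <= 1.5 and CVIR <= 0.2) is returned unchanged.
#' With a fixed `seed` the output is reproducible end to end.
#'
#' @param x An `mld` of active-label instances; every label must have at
#'   least one positive instance.
#' @param k SMOTE neighbour count (default 5).
#' @param seed Integer RNG seed (optional but recommended).
#' @param seed_pool Seed-pool rule passed to [ml_smote()].
#' @param max_rounds Passed to [ml_smote()].
#' @return An object of class `ml_tlsmote`: a list with `data` (the
#'   resampled `mld`) and `report` (class `resampling_report`, carrying the
#'   before/after profiles and per-label counts).
#' @export
#' @examples
#' m <- generate_mld(frailty_like_preset(400, seed = 1))
#' res <- ml_tlsmote(m, k = 5, seed = 1)
#' glance(res)
ml_tlsmote <- function(x, k = 5, seed = NULL,
                       seed_pool = c("strict", "no-majority"),
                       max_rounds = 10) {
  stopifnot(inherits(x, "mld"))
  seed_pool <- match.arg(seed_pool)
  cnt <- label_counts(x)
  if (any(cnt == 0)) {
    stop("dataset has label(s) with no positive instance: ",
         paste(names(cnt)[cnt == 0], collapse = ", "),
         "; resampling refused", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  before <- imbalance_profile(x)
  if (before$mean_ir <= 1.5 && before$cvir <= 0.2) {
    report <- new_resampling_report(before, before,
                                    synthetic_added = 0L * cnt,
                                    removed_by_tomek = 0L * cnt,
                                    seed = seed, k = k)
    return(structure(list(data = x, report = report), class = "ml_tlsmote"))
  }
  sm <- ml_smote(x, profile = before, k = k, seed_pool = seed_pool,
                 max_rounds = max_rounds)
  tk <- ml_tomek_clean(sm$data, profile = imbalance_profile(sm$data))
  after <- imbalance_profile(tk$data)
  report <- new_resampling_report(before, after,
                                  synthetic_added = sm$synthetic_added,
                                  removed_by_tomek = tk$removed_by_tomek,
                                  seed = seed, k = k)
  structure(list(data = tk$data, report = report), class = "ml_tlsmote")
}

#' @keywords internal
new_resampling_report <- function(before, after, synthetic_added,
                                  removed_by_tomek, seed, k) {
  structure(
    list(before = before, after = after,
         synthetic_added = synthetic_added,
         removed_by_tomek = removed_by_tomek,
         seed = seed, k = k),
    class = "resampling_report"
  )
}

#' @export
print.ml_tlsmote <- function(x, ...) {
  cat("<ml_tlsmote>\n")
  print(x$report)
  invisible(x)
}

#' @export
print.resampling_report <- function(x, ...) {
  cat(sprintf(
    "resampling report (k = %d%s): +%d synthetic, -%d by Tomek links\n",
    x$k, if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed),
    sum(x$synthetic_added), sum(x$removed_by_tomek)))
  cat(sprintf("  before: n = %d, MeanIR = %.3f, MaxIR = %.3f, CVIR = %.3f\n",
              x$before$n_instances, x$before$mean_ir, x$before$max_ir,
              x$before$cvir))
  cat(sprintf("  after:  n = %d, MeanIR = %.3f, MaxIR = %.3f, CVIR = %.3f\n",
              x$after$n_instances, x$after$mean_ir, x$after$max_ir,
              x$after$cvir))
  invisible(x)
}

#' @method tidy resampling_report
#' @export
tidy.resampling_report <- function(x, ...) {
  tibble::tibble(
    label = names(x$before$irlbl),
    count_before = as.integer(x$before$counts),
    irlbl_before = unname(x$before$irlbl),
    synthetic_added = as.integer(x$synthetic_added),
    removed_by_tomek = as.integer(x$removed_by_tomek),
    count_after = as.integer(x$after$counts),
    irlbl_after = unname(x$after$irlbl)
  )
}

#' @method tidy ml_tlsmote
#' @export
tidy.ml_tlsmote <- function(x, ...) tidy.resampling_report(x$report, ...)

#' @method glance resampling_report
#' @export
glance.resampling_report <- function(x, ...) {
  tibble::tibble(
    n_before = x$before$n_instances, n_after = x$after$n_instances,
    synthetic_added = sum(x$synthetic_added),
    removed_by_tomek = sum(x$removed_by_tomek),
    mean_ir_before = x$before$mean_ir, mean_ir_after = x$after$mean_ir,
    max_ir_before = x$before$max_ir, max_ir_after = x$after$max_ir,
    cvir_before = x$before$cvir, cvir_after = x$after$cvir
  )
}

#' @method glance ml_tlsmote
#' @export
glance.ml_tlsmote <- function(x, ...) glance.resampling_report(x$report, ...)

#' @method autoplot resampling_report
#' @export
autoplot.resampling_report <- function(object, ...) {
  d <- tidy.resampling_report(object)
  long <- tidyr::pivot_longer(
    d[c("label", "irlbl_before", "irlbl_after")],
    cols = -"label", names_to = "stage", names_prefix = "irlbl_",
    values_to = "irlbl")
  long$stage <- factor(long$stage, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$irlbl,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "IRLbl", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot ml_tlsmote
#' @export
autoplot.ml_tlsmote <- function(object, ...) autoplot.resampling_report(object$report, ...)
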