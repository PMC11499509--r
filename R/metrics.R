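#' Rank labels by predicted confidence
#'
#' Converts a row of per-label scores into ranks: rank 1 is the most
#' confident label, and ties are broken by ascending label index so the
#' ranking is always a deterministic permutation of 1..q.
#'
#' @param score_row A finite numeric vector of per-label scores.
#' @return An integer vector of ranks (a permutation of `seq_along(score_row)`).
#' @export
#' @examples
#' rank_labels(c(0.9, 0.1, 0.5))  # 1 3 2
rank_labels <- function(score_row) {
  if (anyNA(score_row)) stop("scores contain NA/NaN", call. = FALSE)
  ord <- order(-score_row, seq_along(score_row))
  rk <- integer(length(score_row))
  rk[ord] <- seq_along(score_row)
  rk
}

#' @keywords internal
rank_matrix <- function(scores) {
  t(apply(scores, 1, rank_labels))
}

#' @keywords internal
check_shapes <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("matrices differ in shape", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Hamming loss
#'
#' Mean fraction of label cells on which truth and prediction disagree
#' (the symmetric difference of the two label sets divided by the number of
#' labels, averaged over instances). 0 is best, 1 worst.
#'
#' @param true,predicted Binary matrices of equal shape (instances x labels).
#' @return A number in [0, 1].
#' @export
hamming_loss <- function(true, predicted) {
  m <- check_shapes(true, predicted)
  mean(m$a != m$b)
}

#' Ranking loss
#'
#' For each instance with at least one relevant and one irrelevant label, the
#' fraction of (relevant, irrelevant) label pairs ranked in the wrong order;
#' averaged over those instances. 0 is best.
#'
#' @param true Binary matrix of true labels.
#' @param scores Numeric score matrix of the same shape (higher = more
#'   relevant).
#' @return A number in [0, 1].
#' @export
ranking_loss <- function(true, scores) {
  m <- check_shapes(true, scores)
  Y <- m$a; R <- rank_matrix(m$b)
  per <- vapply(seq_len(nrow(Y)), function(i) {
    rel <- which(Y[i, ] == 1); irr <- which(Y[i, ] == 0)
    if (length(rel) == 0 || length(irr) == 0) return(NA_real_)
    bad <- sum(outer(R[i, rel], R[i, irr], `>`))
    bad / (length(rel) * length(irr))
  }, numeric(1))
  if (all(is.na(per))) {
    stop("no instance with both a relevant and an irrelevant label",
         call. = FALSE)
  }
  mean(per, na.rm = TRUE)
}

#' Average precision
#'
#' For each instance with at least one relevant label and each relevant label
#' `l`, the fraction of labels ranked at or above `l` that are themselves
#' relevant; averaged over relevant labels, then over instances. 1 is best.
#'
#' @inheritParams ranking_loss
#' @return A number in [0, 1].
#' @export
average_precision <- function(true, scores) {
  m <- check_shapes(true, scores)
  Y <- m$a; R <- rank_matrix(m$b)
  per <- vapply(seq_len(nrow(Y)), function(i) {
    rel <- which(Y[i, ] == 1)
    if (length(rel) == 0) return(NA_real_)
    rr <- R[i, rel]
    mean(vapply(rr, function(r) sum(rr <= r) / r, numeric(1)))
  }, numeric(1))
  if (all(is.na(per))) {
    stop("no instance with a relevant label", call. = FALSE)
  }
  mean(per, na.rm = TRUE)
}

#' Micro-averaged F1 score
#'
#' Pools true positives, false positives and false negatives over every
#' instance/label cell and returns the harmonic mean of the pooled precision
#' and recall, `2 TP / (2 TP + FP + FN)`; 0 by convention when the
#' denominator is zero.
#'
#' @param true,predicted Binary matrices of equal shape.
#' @return A number in [0, 1].
#' @export
micro_f1 <- function(true, predicted) {
  m <- check_shapes(true, predicted)
  tp <- sum(m$a == 1 & m$b == 1)
  fp <- sum(m$a == 0 & m$b == 1)
  fn <- sum(m$a == 1 & m$b == 0)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' Macro-averaged AUROC
#'
#' Per label, the probability that a random positive instance scores above a
#' random negative one (ties counted half, the Mann-Whitney estimator);
#' averaged over labels having both a positive and a negative instance.
#' Labels without both classes are skipped with a warning.
#'
#' @inheritParams ranking_loss
#' @return A number in [0, 1].
#' @export
macro_auroc <- function(true, scores) {
  m <- check_shapes(true, scores)
  Y <- m$a; S <- m$b
  per <- vapply(seq_len(ncol(Y)), function(l) {
    pos <- S[Y[, l] == 1, l]; neg <- S[Y[, l] == 0, l]
    if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
    # Mann-Whitney rank-sum form with mid-ranks for ties
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }, numeric(1))
  if (all(is.na(per))) stop("no label with both classes present", call. = FALSE)
  if (anyNA(per)) {
    warning(sprintf("%d label(s) without both classes skipped in macro AUROC",
                    sum(is.na(per))), call. = FALSE)
  }
  mean(per, na.rm = TRUE)
}

#' All five multi-label metrics at once
#'
#' Convenience wrapper computing macro AUROC, average precision, micro F1,
#' Hamming loss and ranking loss for a score matrix (and binary predictions,
#' by default scores thresholded at 0.5).
#'
#' @param true Binary truth matrix (or the label matrix of an `mld`).
#' @param scores Numeric score matrix.
#' @param predicted Optional binary prediction matrix; defaults to
#'   `scores >= threshold`.
#' @param threshold Threshold used when `predicted` is missing.
#' @return A one-row tibble with columns `auroc`, `ap`, `f1`, `hl`, `rl`.
#' @export
ml_metrics <- function(true, scores, predicted = NULL, threshold = 0.5) {
  if (inherits(true, "mld")) true <- mld_labels(true)
  if (is.null(predicted)) predicted <- (as.matrix(scores) >= threshold) * 1L
  tibble::tibble(
    auroc = macro_auroc(true, scores),
    ap = average_precision(true, scores),
    f1 = micro_f1(true, predicted),
    hl = hamming_loss(true, predicted),
    rl = ranking_loss(true, scores)
  )
}
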