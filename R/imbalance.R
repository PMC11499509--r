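#' Per-label imbalance ratio (IRLbl)
#'
#' The imbalance ratio of a label is the positive count of the most frequent
#' label divided by the positive count of that label. The most frequent label
#' therefore has a ratio of exactly 1 and every other label a ratio above 1.
#'
#' @param x An `mld`.
#' @param label A label name or index, or `NULL` for all labels.
#' @return A named numeric vector (or scalar when `label` is given).
#' @export
#' @examples
#' m <- mld(tibble::tibble(f = 1:4, a = c(1, 1, 1, 0), b = c(1, 0, 0, 0)),
#'          c("a", "b"))
#' irlbl(m)        # a is most frequent: 1; b: 3
irlbl <- function(x, label = NULL) {
  cnt <- label_counts(x)
  if (any(cnt == 0)) {
    bad <- names(cnt)[cnt == 0]
    stop("IRLbl is undefined for label(s) with no positive instance: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- max(cnt) / cnt
  if (is.null(label)) out else unname(out[label])
}

#' Imbalance profile of a multi-label dataset
#'
#' Computes the per-label imbalance ratios together with their mean (MeanIR),
#' maximum (MaxIR) and coefficient of variation (CVIR, the sample standard
#' deviation of the ratios divided by MeanIR). Labels whose ratio exceeds
#' MeanIR form the minority set; all others (including exact ties) form the
#' majority set. A dataset is flagged imbalanced when MeanIR > 1.5 and
#' CVIR > 0.2, the conventional thresholds for multi-label data.
#'
#' @param x An `mld`; every label must have at least one positive instance.
#' @return An object of class `imbalance_profile` with fields `irlbl`,
#'   `counts`, `mean_ir`, `max_ir`, `irlbl_sigma`, `cvir`, `minority`,
#'   `majority` (integer label indices, named) and `is_imbalanced`.
#' @export
imbalance_profile <- function(x) {
  stopifnot(inherits(x, "mld"))
  ir <- irlbl(x)
  q <- length(ir)
  mean_ir <- mean(ir)
  # sample (q-1 denominator) standard deviation of the per-label ratios
  sigma <- if (q > 1) sqrt(sum((ir - mean_ir)^2) / (q - 1)) else 0
  cvir <- sigma / mean_ir
  minority <- which(ir > mean_ir)
  majority <- which(ir <= mean_ir)
  structure(
    list(irlbl = ir, counts = label_counts(x),
         mean_ir = mean_ir, max_ir = max(ir),
         irlbl_sigma = sigma, cvir = cvir,
         minority = minority, majority = majority,
         is_imbalanced = mean_ir > 1.5 && cvir > 0.2,
         n_instances = n_instances(x)),
    class = "imbalance_profile"
  )
}

#' @export
print.imbalance_profile <- function(x, ...) {
  cat("<imbalance_profile>\n")
  print(tidy.imbalance_profile(x), n = length(x$irlbl))
  cat(sprintf("MeanIR %.3f | MaxIR %.3f | CVIR %.3f | %s\n",
              x$mean_ir, x$max_ir, x$cvir,
              if (x$is_imbalanced) "imbalanced" else "balanced"))
  invisible(x)
}

#' @method tidy imbalance_profile
#' @export
tidy.imbalance_profile <- function(x, ...) {
  tibble::tibble(
    label = names(x$irlbl),
    count = as.integer(x$counts),
    irlbl = unname(x$irlbl),
    role = ifelse(seq_along(x$irlbl) %in% x$minority, "minority", "majority")
  )
}

#' @method glance imbalance_profile
#' @export
glance.imbalance_profile <- function(x, ...) {
  tibble::tibble(mean_ir = x$mean_ir, max_ir = x$max_ir,
                 irlbl_sigma = x$irlbl_sigma, cvir = x$cvir,
                 n_minority = length(x$minority),
                 n_majority = length(x$majority),
                 is_imbalanced = x$is_imbalanced)
}

#' @method autoplot imbalance_profile
#' @export
autoplot.imbalance_profile <- function(object, ...) {
  d <- tidy.imbalance_profile(object)
  d$label <- factor(d$label, levels = d$label[order(d$irlbl)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$irlbl,
                                  fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_ir, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "IRLbl",
                  subtitle = sprintf("MeanIR = %.2f, CVIR = %.2f (dashed: MeanIR)",
                                     object$mean_ir, object$cvir)) +
    ggplot2::theme_minimal()
}
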