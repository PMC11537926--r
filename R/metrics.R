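# Segmentation quality metrics and cluster validity indices.

as_binary <- function(m, name) {
  v <- as.vector(m) != 0
  if (anyNA(v)) stop(name, " contains NA", call. = FALSE)
  v
}

check_same_shape <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth have different shapes", call. = FALSE)
}

#' Dice similarity coefficient
#'
#' Overlap between a segmented region E and a reference region R:
#' \eqn{2|E \cap R| / (|E| + |R|)}. Two empty masks agree perfectly and score
#' 1 by convention (a correct no-lesion prediction is not penalized).
#'
#' @param pred,truth binary masks (logical or 0/1 numeric) of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, truth) {
  check_same_shape(pred, truth)
  e <- as_binary(pred, "pred"); r <- as_binary(truth, "truth")
  denom <- sum(e) + sum(r)
  if (denom == 0) return(1)
  2 * sum(e & r) / denom
}

#' Root mean square error between two masks
#'
#' \eqn{\sqrt{(1/N)\sum_i (E_i - R_i)^2}} over all N pixels; for binary masks
#' this is the square root of the mismatch fraction, so it lies in \[0, 1\]
#' and is 0 exactly when Dice is 1.
#'
#' @inheritParams dice
#' @return RMSE (>= 0).
#' @export
rmse <- function(pred, truth) {
  check_same_shape(pred, truth)
  sqrt(mean((as.double(pred) - as.double(truth))^2))
}

#' Confusion counts between binary masks
#'
#' @inheritParams dice
#' @return Named integer vector with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  check_same_shape(pred, truth)
  e <- as_binary(pred, "pred"); r <- as_binary(truth, "truth")
  c(tp = sum(e & r), fp = sum(e & !r), tn = sum(!e & !r), fn = sum(!e & r))
}

#' Precision, sensitivity and specificity
#'
#' tp/(tp+fp), tp/(tp+fn) and tn/(tn+fp). A ratio whose denominator is zero
#' is undefined and reported as `NA` rather than an error.
#'
#' @param counts named vector from [confusion_counts()], or a pair of masks
#'   via `pred`/`truth`.
#' @param pred,truth alternative input: binary masks.
#' @return Named numeric vector `precision`, `sensitivity`, `specificity`.
#' @export
precision_sensitivity_specificity <- function(counts = NULL, pred = NULL,
                                              truth = NULL) {
  if (is.null(counts)) counts <- confusion_counts(pred, truth)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(precision = safe(counts[["tp"]], counts[["tp"]] + counts[["fp"]]),
    sensitivity = safe(counts[["tp"]], counts[["tp"]] + counts[["fn"]]),
    specificity = safe(counts[["tn"]], counts[["tn"]] + counts[["fp"]]))
}

#' Partition coefficient (Vpc)
#'
#' Bezdek's partition coefficient \eqn{V_{pc} = (1/n) \sum_x \sum_y b_{xy}^2};
#' 1 for a crisp partition, 1/f for the maximally fuzzy uniform partition.
#'
#' @param membership f x n column-stochastic membership matrix.
#' @param weights optional per-sample multiplicities (gray-level mode).
#' @return Scalar in \[1/f, 1\].
#' @export
partition_coefficient <- function(membership, weights = NULL) {
  check_membership(membership)
  if (is.null(weights)) return(sum(membership^2) / ncol(membership))
  sum(sweep(membership^2, 2L, weights, "*")) / sum(weights)
}

#' Partition entropy (Vpe)
#'
#' \eqn{V_{pe} = -(1/n) \sum_x \sum_y b_{xy} \ln b_{xy}} with
#' \eqn{0 \ln 0 := 0}; 0 for a crisp partition, \eqn{\ln f} for the uniform
#' one.
#'
#' @inheritParams partition_coefficient
#' @return Scalar >= 0.
#' @export
partition_entropy <- function(membership, weights = NULL) {
  check_membership(membership)
  h <- membership * log(membership)
  h[membership == 0] <- 0
  if (is.null(weights)) return(-sum(h) / ncol(membership))
  -sum(sweep(h, 2L, weights, "*")) / sum(weights)
}

#' Xie-Beni index (Vxb)
#'
#' Compactness-to-separation ratio
#' \eqn{V_{xb} = \sum_x \sum_y b_{xy}^l \|m_y - a_x\|^2 /
#' (n \min_{x \ne g} \|a_x - a_g\|^2)}; smaller is better. Coincident centers
#' make the separation term zero and are rejected.
#'
#' @param x numeric vector or n x h matrix of samples.
#' @param membership f x n membership matrix.
#' @param centers numeric vector or f x h matrix of centers.
#' @param fuzzifier weighting exponent l (default 2).
#' @param weights optional per-sample multiplicities.
#' @return Positive scalar.
#' @export
xie_beni <- function(x, membership, centers, fuzzifier = 2, weights = NULL) {
  xm <- as_sample_matrix(x)
  cm <- as_sample_matrix(centers)
  check_membership(membership, n = nrow(xm), f = nrow(cm))
  if (nrow(cm) < 2) stop("Xie-Beni needs at least 2 centers", call. = FALSE)
  sep <- sq_distances(cm, cm)
  min_sep <- min(sep[upper.tri(sep)])
  if (min_sep <= 0)
    stop("coincident cluster centers: Xie-Beni separation is zero", call. = FALSE)
  bl <- membership^fuzzifier
  if (!is.null(weights)) bl <- sweep(bl, 2L, weights, "*")
  n <- if (is.null(weights)) ncol(membership) else sum(weights)
  sum(bl * sq_distances(xm, cm)) / (n * min_sep)
}

#' Hemorrhage volume errors
#'
#' Absolute error |pred - true| in milliliters and relative error
#' |pred - true| / true, reported as a fraction. The relative error is
#' undefined (NA) for a zero true volume.
#'
#' @param pred_ml,true_ml predicted and reference volumes in mL.
#' @return Named numeric vector `absolute_ml`, `relative`.
#' @export
volume_errors <- function(pred_ml, true_ml) {
  abs_err <- abs(pred_ml - true_ml)
  rel <- ifelse(true_ml > 0, abs_err / true_ml, NA_real_)
  c(absolute_ml = abs_err, relative = rel)
}

#' Per-class Dice of a label map against ground truth
#'
#' Convenience wrapper computing [dice()] for each requested class of two
#' integer label maps.
#'
#' @param pred,truth integer label maps of identical shape.
#' @param classes classes to evaluate (default: all classes in `truth`).
#' @return Named numeric vector of Dice coefficients.
#' @export
dice_per_class <- function(pred, truth, classes = NULL) {
  check_same_shape(pred, truth)
  if (is.null(classes)) classes <- sort(unique(as.vector(truth)))
  out <- vapply(classes, function(k) dice(pred == k, truth == k), 0)
  names(out) <- classes
  out
}
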