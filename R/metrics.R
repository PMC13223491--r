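#' Pixelwise confusion matrix of two binary masks
#'
#' @param pred,truth binary (0/1) matrices of identical shape.
#' @return A `confusion_matrix` list with integer counts `TP`, `TN`, `FP`,
#'   `FN` (positive class = 1, the lesion).
#' @examples
#' confusion(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shape mismatch")
  stopifnot(all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  structure(list(TP = sum(pred == 1 & truth == 1),
                 TN = sum(pred == 0 & truth == 0),
                 FP = sum(pred == 1 & truth == 0),
                 FN = sum(pred == 0 & truth == 1)),
            class = "confusion_matrix")
}

#' Confusion matrix from raw counts
#' @param TP,TN,FP,FN non-negative counts.
#' @return A `confusion_matrix` list.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Segmentation scores from a confusion matrix
#'
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, specificity
#' `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, F-score (harmonic mean of
#' precision and sensitivity), IoU `TP/(TP+FP+FN)` and Dice
#' `2TP/(2TP+FP+FN)`. A zero denominator yields a flagged `NA` rather than
#' an error.
#'
#' @param cm a [confusion()] result.
#' @return List of the seven scores; attribute `"undefined"` names any that
#'   had zero denominators.
#' @examples
#' seg_scores(confusion_counts(TP = 3, FP = 1, FN = 3, TN = 9))$dsc  # 0.6
#' @export
seg_scores <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  prec <- safe_ratio(cm$TP, cm$TP + cm$FP)
  sens <- safe_ratio(cm$TP, cm$TP + cm$FN)
  f <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  out <- list(accuracy = safe_ratio(cm$TP + cm$TN, total),
              precision = prec,
              specificity = safe_ratio(cm$TN, cm$TN + cm$FP),
              sensitivity = sens,
              f_score = f,
              iou = safe_ratio(cm$TP, cm$TP + cm$FP + cm$FN),
              dsc = safe_ratio(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN))
  attr(out, "undefined") <- names(out)[vapply(out, is.na, logical(1))]
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels. Identical images give an infinite
#' PSNR, returned as `Inf` with attribute `"identical" = TRUE`.
#'
#' @param ref,test numeric arrays of identical shape.
#' @param peak peak signal value (1 for unit-range images, 255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, peak = 1) {
  if (!identical(dim(ref), dim(test))) stop("image shape mismatch")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(structure(Inf, identical = TRUE))
  10 * log10(peak^2 / mse)
}

gaussian_window <- function(size = 11, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

# weighted local moments over all valid (fully interior) window placements
local_stat <- function(img, w) {
  k <- nrow(w)
  H <- nrow(img); W <- ncol(img)
  Ho <- H - k + 1; Wo <- W - k + 1
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(k)) for (j in seq_len(k))
    out <- out + w[i, j] * img[i:(i + Ho - 1), j:(j + Wo - 1)]
  out
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window (11 x 11, sigma 1.5) and the
#' standard stabilisers `C1 = (0.01 peak)^2`, `C2 = (0.03 peak)^2`,
#' computed over all fully interior window placements with weighted
#' (population) moments. 1 for identical images; values can be negative
#' for anticorrelated structure.
#'
#' @param ref,test numeric matrices of identical shape, at least the window
#'   size in each dimension.
#' @param peak peak signal value.
#' @param size,sigma Gaussian window size and width.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(ref, test, peak = 1, size = 11, sigma = 1.5) {
  if (!identical(dim(ref), dim(test))) stop("image shape mismatch")
  if (nrow(ref) < size || ncol(ref) < size)
    stop("window larger than image")
  w <- gaussian_window(size, sigma)
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  mu_x <- local_stat(ref, w)
  mu_y <- local_stat(test, w)
  sxx <- local_stat(ref^2, w) - mu_x^2
  syy <- local_stat(test^2, w) - mu_y^2
  sxy <- local_stat(ref * test, w) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
       ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Evaluate predicted masks against ground truth
#'
#' Convenience wrapper: per-image confusion and scores plus the set-level
#' mean of each score.
#'
#' @param preds,truths lists of binary matrices.
#' @return List with `per_image` (list of score lists) and `mean` (named
#'   vector of score means, `NA`s removed).
#' @export
evaluate_masks <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  per <- Map(function(p, t) seg_scores(confusion(p, t)), preds, truths)
  nm <- names(per[[1]])
  means <- vapply(nm, function(k) {
    v <- vapply(per, function(s) s[[k]], numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  list(per_image = per, mean = means)
}
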