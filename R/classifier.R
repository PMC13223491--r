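#' Shape, texture and intensity features of a segmented lesion
#'
#' Computed on the largest connected component of the mask:
#' shape - area fraction, circularity `4 pi A / P^2` (smoothed-contour
#' perimeter), solidity (area over convex-hull area), boundary curvature
#' variance ([boundary_roughness()]); texture - interior intensity
#' variance and a local-contrast statistic (mean absolute deviation from
#' the 3x3 local mean); intensity - interior mean and interior/background
#' contrast ratio.
#'
#' @param image grayscale H x W matrix in `[0, 1]`.
#' @param mask binary H x W matrix; must contain foreground.
#' @return Named numeric vector of 8 features.
#' @export
extract_features <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch")
  if (!any(mask == 1)) stop("no lesion: empty mask")
  lab <- EBImage::bwlabel(mask)
  tab <- table(lab[lab > 0])
  big <- as.integer(names(tab)[which.max(tab)])
  m <- (lab == big) * 1
  A <- sum(m)

  # smoothed contour perimeter; the contour runs through pixel centres, so a
  # half-pixel outward offset (+pi for one closed loop) debiases it
  oc <- EBImage::ocontour(EBImage::Image(m))[[1]]
  np <- nrow(oc)
  if (np >= 7) {
    k <- 1
    sm <- sapply(1:2, function(j) {
      v <- oc[, j]
      stats::filter(c(v[(np - k + 1):np], v, v[1:k]), rep(1 / (2 * k + 1), 2 * k + 1))[
        (k + 1):(k + np)]
    })
  } else sm <- oc
  if (np >= 2) {
    dseg <- sqrt(rowSums((sm - sm[c(2:np, 1), , drop = FALSE])^2))
    P <- sum(dseg) + pi
  } else {
    P <- pi                                  # single-pixel component
  }
  circ <- if (P > 0) min(4 * pi * A / P^2, 1) else NA_real_

  # solidity via convex hull of the boundary (shoelace area)
  pts <- unique(oc)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  hull_area <- if (nh >= 3)
    abs(sum(hp[, 1] * hp[c(2:nh, 1), 2] - hp[c(2:nh, 1), 1] * hp[, 2])) / 2
  else 0
  hull_area <- hull_area + P / 2   # half-pixel rim of the rasterised region
  solidity <- min(A / max(hull_area, 1), 1)

  rough <- boundary_roughness(m)

  inside <- m == 1
  interior_mean <- mean(image[inside])
  interior_var <- if (sum(inside) > 1) var(image[inside]) else 0
  lm3 <- EBImage::imageData(EBImage::filter2(image, matrix(1 / 9, 3, 3)))
  local_contrast <- mean(abs(image - lm3)[inside])

  dil <- EBImage::imageData(EBImage::dilate(m, EBImage::makeBrush(7, "disc")))
  bg <- dil < 0.5
  # a mask covering the frame has no background; fall back to the image mean
  bg_mean <- if (any(bg)) mean(image[bg]) else mean(image)
  contrast_ratio <- interior_mean / max(bg_mean, 1e-6)

  c(area_frac = A / length(mask), circularity = circ, solidity = solidity,
    roughness = rough, interior_var = interior_var,
    local_contrast = local_contrast, interior_mean = interior_mean,
    contrast_ratio = contrast_ratio)
}

#' Fit the maximum-margin lesion classifier (P-SVM)
#'
#' A linear maximum-margin separator (support vector machine) on
#' standardised features; benign is class 0, malignant class 1.
#'
#' @param features numeric matrix (rows = lesions) or list of feature
#'   vectors from [extract_features()].
#' @param labels vector of 0/1 (or `"benign"`/`"malignant"`).
#' @param cost soft-margin cost parameter.
#' @param kernel kernel passed to the underlying SVM (default linear).
#' @return A `psvm` model: the fitted separator plus the standardisation
#'   constants.
#' @export
psvm_fit <- function(features, labels, cost = 1, kernel = "linear") {
  if (is.list(features)) features <- do.call(rbind, features)
  features <- as.matrix(features)
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "malignant")
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) stop("need both classes to fit a separator")
  center <- colMeans(features)
  scale <- apply(features, 2, sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(features, 2, center), 2, scale, `/`)
  fit <- e1071::svm(z, factor(labels, levels = c(0, 1)), kernel = kernel,
                    cost = cost, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 features = colnames(features)), class = "psvm")
}

#' Predict lesion class with a fitted P-SVM
#'
#' @param model a [psvm_fit()] model.
#' @param features feature vector, matrix, or list of vectors.
#' @return Integer vector of decision scores in `{0, 1}` (1 = malignant),
#'   with the signed margin distances as attribute `"margin"`.
#' @export
psvm_predict <- function(model, features) {
  if (!inherits(model, "psvm")) stop("model is not a fitted psvm")
  if (is.list(features)) features <- do.call(rbind, features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  z <- sweep(sweep(as.matrix(features), 2, model$center), 2, model$scale, `/`)
  pr <- stats::predict(model$fit, z, decision.values = TRUE)
  lab <- as.integer(as.character(pr))
  attr(lab, "margin") <- as.numeric(attr(pr, "decision.values"))
  lab
}
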