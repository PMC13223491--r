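#' Specification of a synthetic breast-ultrasound-like phantom
#'
#' The generator emulates the statistical structure of B-mode breast
#' ultrasound with lesion ground truth: a textured tissue background,
#' a hypoechoic (darker) lesion - a smooth-margin ellipse for benign, an
#' irregular spiculated shape for malignant - multiplicative Rayleigh
#' speckle and additive Gaussian sensor noise.
#'
#' @param size image side length in pixels (square images).
#' @param lesion_class `"benign"`, `"malignant"` or `"normal"` (no lesion).
#' @param lesion_area_frac lesion area as a fraction of the image, in
#'   `(0, 0.3]`.
#' @param speckle_scale strength of the multiplicative Rayleigh speckle
#'   field (0 disables it).
#' @param gaussian_sigma standard deviation of additive Gaussian noise.
#' @param contrast background-minus-lesion intensity difference.
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 128,
                         lesion_class = c("benign", "malignant", "normal"),
                         lesion_area_frac = 0.08, speckle_scale = 0.3,
                         gaussian_sigma = 0.02, contrast = 0.3, seed = 1) {
  lesion_class <- match.arg(lesion_class)
  stopifnot(size >= 16, lesion_area_frac > 0, lesion_area_frac <= 0.3,
            speckle_scale >= 0, gaussian_sigma >= 0)
  structure(list(size = as.integer(size), lesion_class = lesion_class,
                 lesion_area_frac = lesion_area_frac,
                 speckle_scale = speckle_scale,
                 gaussian_sigma = gaussian_sigma, contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

smooth_field <- function(n, sigma) {
  f <- matrix(rnorm(n * n), n, n)
  f <- EBImage::imageData(EBImage::gblur(f, sigma = sigma))
  f / max(sd(f), 1e-9)
}

#' Generate one phantom
#'
#' Deterministic in the spec's seed. Benign lesions are ellipses with a
#' low-amplitude smooth boundary perturbation and a well-defined margin;
#' malignant lesions carry high-amplitude mid-harmonic spiculation, a more
#' diffuse margin, and heterogeneous interior texture. The clean image is
#' corrupted by `x * (1 + s * (R/E[R] - 1))` with `R` Rayleigh (the
#' first-order multiplicative speckle model) plus additive Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom` list: `image` (clean, `[0,1]`), `noisy` (observed),
#'   `mask` (binary), `label`, `spec`.
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size
  bg_level <- 0.55
  les_level <- bg_level - spec$contrast

  bg <- bg_level + 0.05 * smooth_field(n, sigma = n / 10)
  mask <- matrix(0, n, n)
  img <- bg

  if (spec$lesion_class != "normal") {
    r0 <- sqrt(spec$lesion_area_frac * n * n / pi)
    margin <- r0 * 1.45 + 2
    if (2 * margin >= n) stop("infeasible lesion area fraction for this size")
    cx <- n / 2 + runif(1, -1, 1) * (n / 2 - margin)
    cy <- n / 2 + runif(1, -1, 1) * (n / 2 - margin)
    asp <- runif(1, 0.65, 0.95)
    phi <- runif(1, 0, pi)
    a <- r0 / sqrt(asp); b <- r0 * sqrt(asp)

    if (spec$lesion_class == "benign") {
      harmonics <- 2:4
      amp <- 0.03
      edge <- 1.2            # pixels, well-defined margin
      hetero <- 0.0
    } else {
      harmonics <- 5:9
      amp <- 0.22
      edge <- 3.0            # diffuse, irregular margin
      hetero <- 0.07
    }
    ak <- rnorm(length(harmonics), sd = 1)
    ak <- ak / sqrt(sum(ak^2))
    ph <- runif(length(harmonics), 0, 2 * pi)

    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), n), n, n)          # row index
    dx <- xs - cx; dy <- ys - cy
    xr <- cos(phi) * dx + sin(phi) * dy
    yr <- -sin(phi) * dx + cos(phi) * dy
    u <- xr / a; v <- yr / b
    re <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    pert <- matrix(0, n, n)
    for (j in seq_along(harmonics))
      pert <- pert + ak[j] * sin(harmonics[j] * th + ph[j])
    rb <- 1 + amp * pert
    mask[re <= rb] <- 1
    interior <- les_level + if (hetero > 0) hetero * smooth_field(n, n / 24) else 0
    alpha <- pmin(pmax((rb - re) * r0 / edge, 0), 1)   # soft margin blend
    img <- bg * (1 - alpha) + interior * alpha
  }

  img <- pmin(pmax(img, 0), 1)
  noisy <- img
  if (spec$speckle_scale > 0) {
    ray <- sqrt(-2 * log(pmax(matrix(runif(n * n), n, n), 1e-12)))
    f <- 1 + spec$speckle_scale * (ray / sqrt(pi / 2) - 1)
    noisy <- noisy * f
  }
  if (spec$gaussian_sigma > 0)
    noisy <- noisy + matrix(rnorm(n * n, sd = spec$gaussian_sigma), n, n)
  noisy <- pmin(pmax(noisy, 0), 1)

  structure(list(image = img, noisy = noisy, mask = mask,
                 label = spec$lesion_class, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s> %dx%d, lesion area %.3f, seed %d\n", x$label,
              nrow(x$image), ncol(x$image), mean(x$mask), x$spec$seed))
  invisible(x)
}

#' Boundary roughness of a lesion mask
#'
#' Curvature-variance statistic: the largest object's contour is expressed
#' as a radius-versus-angle profile about its centroid (72 angular bins,
#' radius normalised by its mean) and the variance of the circular second
#' difference of that profile is returned. Spiculated (malignant-style)
#' boundaries score much higher than smooth elliptical ones.
#'
#' @param mask binary matrix with a non-empty foreground.
#' @param bins number of angular bins for the radius profile.
#' @return Non-negative roughness statistic.
#' @export
boundary_roughness <- function(mask, bins = 72) {
  stopifnot(any(mask == 1))
  lab <- EBImage::bwlabel(mask)
  tab <- table(lab[lab > 0])
  big <- as.integer(names(tab)[which.max(tab)])
  oc <- EBImage::ocontour(EBImage::Image(lab == big))[[1]]
  if (nrow(oc) < 8) return(0)   # too few boundary points for a curvature profile
  ctr <- colMeans(oc)
  d <- sweep(oc, 2, ctr)
  r <- sqrt(rowSums(d^2))
  th <- atan2(d[, 2], d[, 1])
  bin <- floor((th + pi) / (2 * pi) * bins) %% bins + 1
  prof <- vapply(seq_len(bins), function(bb) {
    v <- r[bin == bb]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  # fill empty bins by interpolation around the circle
  if (anyNA(prof)) {
    idx <- which(!is.na(prof))
    prof <- stats::approx(c(idx, idx[1] + bins), c(prof[idx], prof[idx[1]]),
                          xout = seq_len(bins), rule = 2)$y
  }
  prof <- prof / mean(prof)
  curv <- prof[c(2:bins, 1)] - 2 * prof + prof[c(bins, 1:(bins - 1))]
  var(curv)
}

#' Generate a stratified phantom dataset with train/test split
#'
#' @param n total number of phantoms (>= 5).
#' @param class_mix named proportions over
#'   `c("benign", "malignant", "normal")`; default an even benign/malignant
#'   mix.
#' @param split_ratio training fraction in `(0, 1)` (default 0.8).
#' @param seed master seed; each phantom gets a derived per-phantom seed
#'   recorded in the manifest.
#' @param ... further arguments passed to [phantom_spec()] (size, noise
#'   levels, ...).
#' @return List with `train` and `test` (lists of phantoms) and `manifest`
#'   (data frame: id, split, class, seed and spec fields).
#' @export
generate_dataset <- function(n, class_mix = c(benign = 0.5, malignant = 0.5),
                             split_ratio = 0.8, seed = 1, ...) {
  stopifnot(n >= 5, split_ratio > 0, split_ratio < 1,
            abs(sum(class_mix) - 1) < 1e-8)
  classes <- names(class_mix)
  counts <- floor(class_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- class_mix * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  if (any(counts[class_mix > 0] < 2))
    stop("class underrepresented for stratified splitting")
  labels <- rep(classes, counts)
  specs <- lapply(seq_along(labels), function(i) {
    phantom_spec(lesion_class = labels[i],
                 seed = (seed + 7919 * i) %% .Machine$integer.max, ...)
  })
  phantoms <- lapply(specs, phantom_generate)
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    ntr <- round(length(idx) * split_ratio)
    if (ntr < 1 || ntr >= length(idx))
      stop("class underrepresented for stratified splitting")
    train_idx <- c(train_idx, idx[seq_len(ntr)])
  }
  train_idx <- sort(train_idx)
  manifest <- do.call(rbind, lapply(seq_along(phantoms), function(i) {
    s <- specs[[i]]
    data.frame(id = sprintf("phantom_%04d", i),
               split = if (i %in% train_idx) "train" else "test",
               class = s$lesion_class, seed = s$seed, size = s$size,
               lesion_area_frac = s$lesion_area_frac,
               speckle_scale = s$speckle_scale,
               gaussian_sigma = s$gaussian_sigma, contrast = s$contrast,
               stringsAsFactors = FALSE)
  }))
  list(train = phantoms[train_idx],
       test = phantoms[-train_idx],
       manifest = manifest)
}
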