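#' Desk-scale DnCNN network specification
#'
#' The denoising-CNN stack: a first conv+ReLU block, `depth - 2` middle
#' conv+BN+ReLU blocks, and a final conv layer - linear for the `denoise`
#' head (residual noise estimate) or 1-channel sigmoid for the `segment`
#' head. Spatial resolution is preserved throughout (same padding, stride
#' 1).
#'
#' @param depth total number of conv blocks (>= 3).
#' @param width channels in the hidden blocks.
#' @param kernel odd kernel size (default 3).
#' @param residual for the denoise head: predict the noise and subtract it
#'   from the input (residual learning) rather than predicting the clean
#'   image directly.
#' @param head `"denoise"` or `"segment"`.
#' @param in_channels input channels (grayscale default 1).
#' @return A `network_spec` list.
#' @export
network_spec <- function(depth = 5, width = 16, kernel = 3, residual = TRUE,
                         head = c("denoise", "segment"), in_channels = 1) {
  head <- match.arg(head)
  stopifnot(depth >= 3, width >= 1, kernel %% 2 == 1)
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 kernel = as.integer(kernel), residual = residual,
                 head = head, in_channels = as.integer(in_channels)),
            class = "network_spec")
}

#' Training configuration
#'
#' @param learning_rate positive Adam step size.
#' @param epochs positive number of passes over the training set.
#' @param batch_size positive minibatch size.
#' @param seed integer seed controlling initialisation and shuffling.
#' @param mask_threshold sigmoid threshold in (0, 1) for the segment head.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-3, epochs = 60, batch_size = 8,
                         seed = 1, mask_threshold = 0.5) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            mask_threshold > 0, mask_threshold < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 mask_threshold = mask_threshold), class = "train_config")
}

init_layer <- function(k, cin, cout) {
  # He-normal fan-in scaling
  list(W = array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = rep(0, cout))
}

#' Build a DnCNN network
#'
#' Instantiates the layer list for a [network_spec()]. Weights are
#' He-initialised from the current RNG state; [dncnn_train()] re-seeds and
#' re-initialises, so build order does not affect trained results.
#'
#' @param spec a [network_spec()].
#' @return A `dncnn` object with fields `spec`, `layers`, and `n_params`.
#' @export
dncnn_build <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel
  cout_last <- if (spec$head == "segment") 1L else spec$in_channels
  layers <- list()
  layers[[1]] <- c(init_layer(k, spec$in_channels, spec$width),
                   list(bn = FALSE, act = "relu"))
  for (i in seq_len(spec$depth - 2)) {
    layers[[i + 1]] <- c(init_layer(k, spec$width, spec$width),
                         list(bn = TRUE, gamma = rep(1, spec$width),
                              beta = rep(0, spec$width),
                              run_mean = rep(0, spec$width),
                              run_var = rep(1, spec$width), act = "relu"))
  }
  layers[[spec$depth]] <- c(init_layer(k, spec$width, cout_last),
                            list(bn = FALSE, act = "linear"))
  n_params <- sum(vapply(layers, function(l) {
    length(l$W) + length(l$b) + if (isTRUE(l$bn)) 2 * length(l$gamma) else 0
  }, numeric(1)))
  structure(list(spec = spec, layers = layers, n_params = n_params,
                 trained = FALSE, trace = numeric(0)),
            class = "dncnn")
}

#' @export
print.dncnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<dncnn %s head> depth %d, width %d, k=%d, %s params, %s\n",
              s$head, s$depth, s$width, s$kernel,
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

net_forward_train <- function(net, x4) {
  caches <- vector("list", length(net$layers))
  a <- x4
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    cv <- conv_fwd_host(a, l$W, l$b)
    z <- cv$out
    cache <- list(conv = cv)
    if (isTRUE(l$bn)) {
      bn <- bn_fwd_host(z, l$gamma, l$beta)
      cache$bn <- bn
      z <- bn$out
    }
    cache$pre_act <- z
    if (l$act == "relu") z <- pmax(z, 0)
    caches[[i]] <- cache
    a <- z
  }
  list(out = a, caches = caches)
}

net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- caches[[i]]
    dZ <- if (l$act == "relu") dA * (cache$pre_act > 0) else dA
    g <- list()
    if (isTRUE(l$bn)) {
      d <- dim(dZ); n <- prod(d[1:3])
      dzm <- dZ; dim(dzm) <- c(n, dim(dZ)[4])
      g$dgamma <- colSums(dzm * cache$bn$xhat)
      g$dbeta <- colSums(dzm)
      dZ <- bn_bwd_host(dZ, cache$bn, l$gamma)
    }
    cb <- conv_bwd_host(dZ, cache$conv, l$W)
    g$dW <- cb$dW; g$db <- cb$db
    grads[[i]] <- g
    dA <- cb$dX
  }
  grads
}

update_running_stats <- function(net, caches, momentum = 0.1) {
  for (i in seq_along(net$layers)) {
    if (isTRUE(net$layers[[i]]$bn)) {
      bn <- caches[[i]]$bn
      net$layers[[i]]$run_mean <- (1 - momentum) * net$layers[[i]]$run_mean +
        momentum * bn$mu
      net$layers[[i]]$run_var <- (1 - momentum) * net$layers[[i]]$run_var +
        momentum * bn$v
    }
  }
  net
}

loss_and_grad <- function(net, out, xb, yb) {
  n <- length(out)
  if (net$spec$head == "denoise") {
    target <- if (net$spec$residual) xb - yb else yb   # residual: noise itself
    diff <- out - target
    list(loss = mean(diff^2), dOut = 2 * diff / n)
  } else {
    p <- sigmoid(out)
    t <- yb
    eps <- 1e-7
    bce <- -mean(t * log(p + eps) + (1 - t) * log(1 - p + eps))
    sp <- sum(p); st <- sum(t); spt <- sum(p * t)
    dice <- (2 * spt + 1) / (sp + st + 1)
    dbce_dz <- (p - t) / n
    ddice_dp <- (2 * t * (sp + st + 1) - (2 * spt + 1)) / (sp + st + 1)^2
    dz <- dbce_dz - ddice_dp * p * (1 - p)   # minimise bce + (1 - dice)
    list(loss = bce + (1 - dice), dOut = dz)
  }
}

collect_params <- function(net) {
  ps <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    ps[[paste0("W", i)]] <- l$W
    ps[[paste0("b", i)]] <- l$b
    if (isTRUE(l$bn)) {
      ps[[paste0("g", i)]] <- l$gamma
      ps[[paste0("e", i)]] <- l$beta
    }
  }
  ps
}

put_params <- function(net, ps) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$W <- ps[[paste0("W", i)]]
    net$layers[[i]]$b <- ps[[paste0("b", i)]]
    if (isTRUE(net$layers[[i]]$bn)) {
      net$layers[[i]]$gamma <- ps[[paste0("g", i)]]
      net$layers[[i]]$beta <- ps[[paste0("e", i)]]
    }
  }
  net
}

#' Train a DnCNN in host arithmetic
#'
#' Minimises mean-squared error (denoise head, residual learning by
#' default) or Dice + binary cross-entropy (segment head) with Adam.
#' Training is fully determined by `cfg$seed`: the seed is set before
#' weight re-initialisation and governs shuffling throughout, so identical
#' seeds yield identical loss traces.
#'
#' @param net a [dncnn_build()] network.
#' @param x N x H x W x C array (or list of H x W matrices) of inputs:
#'   noisy images for the denoise head, images for the segment head.
#' @param y matching targets: clean images, or binary masks.
#' @param cfg a [train_config()].
#' @return The trained `dncnn` with per-epoch `trace` of training loss.
#' @export
dncnn_train <- function(net, x, y, cfg = train_config()) {
  stopifnot(inherits(net, "dncnn"), inherits(cfg, "train_config"))
  x <- as_batch(x); y <- as_batch(y)
  stopifnot(identical(dim(x)[1:3], dim(y)[1:3]))
  set.seed(cfg$seed)
  net <- dncnn_build(net$spec)         # seeded re-initialisation
  ps <- collect_params(net)
  st <- adam_init(ps)
  N <- dim(x)[1]
  trace <- numeric(cfg$epochs)
  step <- 0
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, N)]
      xb <- x[idx, , , , drop = FALSE]
      yb <- y[idx, , , , drop = FALSE]
      fw <- net_forward_train(net, xb)
      lg <- loss_and_grad(net, fw$out, xb, yb)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      grads <- net_backward(net, fw$caches, lg$dOut)
      net <- update_running_stats(net, fw$caches)
      step <- step + 1
      ps <- collect_params(net)
      for (i in seq_along(net$layers)) {
        for (nm in list(c("W", "dW"), c("b", "db"))) {
          key <- paste0(nm[1], i)
          up <- adam_step(ps[[key]], grads[[i]][[nm[2]]], st[[key]],
                          cfg$learning_rate, step)
          ps[[key]] <- up$p; st[[key]] <- up$st
        }
        if (isTRUE(net$layers[[i]]$bn)) {
          for (nm in list(c("g", "dgamma"), c("e", "dbeta"))) {
            key <- paste0(nm[1], i)
            up <- adam_step(ps[[key]], grads[[i]][[nm[2]]], st[[key]],
                            cfg$learning_rate, step)
            ps[[key]] <- up$p; st[[key]] <- up$st
          }
        }
      }
      net <- put_params(net, ps)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    trace[ep] <- ep_loss / nb
  }
  net$trained <- TRUE
  net$trace <- trace
  net$mask_threshold <- cfg$mask_threshold
  net
}

as_batch <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    x <- array(unlist(lapply(x, aperm_keep)), c(d[1], d[2], length(x)))
    x <- aperm(x, c(3, 1, 2))
  }
  if (length(dim(x)) == 2) {
    dim(x) <- c(1, dim(x), 1)
  } else if (length(dim(x)) == 3) {
    dim(x) <- c(dim(x), 1)
  }
  stopifnot(length(dim(x)) == 4)
  x
}

aperm_keep <- function(m) m

#' Network forward pass for inference
#'
#' Runs a trained network on one image. With an emulated backend every
#' convolution multiply-accumulate routes through the bit-level IEEE
#' datapath (normalisation and activation stay in host floating point,
#' as on the hardware).
#'
#' @param net trained `dncnn`.
#' @param image H x W matrix (grayscale, values in `[0, 1]`).
#' @param backend `"exact"`, `"cutin_fp32"` or `"cutin_fp16"`.
#' @param rounding rounding mode for the emulated backends.
#' @return H x W matrix: raw head output (noise estimate or logits).
#' @export
dncnn_infer <- function(net, image,
                        backend = c("exact", "cutin_fp32", "cutin_fp16"),
                        rounding = "trunc") {
  backend <- match.arg(backend)
  stopifnot(inherits(net, "dncnn"), is.matrix(image))
  a <- image; dim(a) <- c(dim(image), 1L)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (backend == "exact") {
      x4 <- a; dim(x4) <- c(1L, dim(a))
      z <- conv_fwd_host(x4, l$W, l$b)$out
      dim(z) <- dim(z)[2:4]
    } else {
      sp <- conv_spec(net$spec$kernel, dim(a)[3], dim(l$W)[4],
                      backend = backend)
      z <- conv2d(a, l$W, sp, rounding = rounding)
      z <- sweep(z, 3, l$b, `+`)
    }
    if (isTRUE(l$bn))
      z <- bn_infer_host(array(z, c(1, dim(z))), l$gamma, l$beta,
                         l$run_mean, l$run_var)[1, , , , drop = TRUE]
    if (length(dim(z)) == 2) dim(z) <- c(dim(z), 1L)
    if (l$act == "relu") z <- pmax(z, 0)
    a <- z
  }
  out <- a[, , 1]
  dim(out) <- dim(image)
  out
}

#' Denoise an image with a trained denoise-head network
#' @inheritParams dncnn_infer
#' @return H x W matrix, `input - predicted_noise` in residual mode (the
#'   network's direct output otherwise), clipped to `[0, 1]`.
#' @export
dncnn_denoise <- function(net, image, backend = "exact", rounding = "trunc") {
  stopifnot(net$spec$head == "denoise")
  r <- dncnn_infer(net, image, backend, rounding)
  out <- if (net$spec$residual) image - r else r
  pmin(pmax(out, 0), 1)
}

#' Segment an image with a trained segment-head network
#'
#' @inheritParams dncnn_infer
#' @param threshold sigmoid threshold; mask is `sigmoid(logits) >= threshold`.
#'   Defaults to the threshold stored at training time.
#' @return H x W binary (0/1) matrix.
#' @export
dncnn_segment <- function(net, image, threshold = NULL, backend = "exact",
                          rounding = "trunc") {
  stopifnot(net$spec$head == "segment")
  if (is.null(threshold)) threshold <- net$mask_threshold %||% 0.5
  z <- dncnn_infer(net, image, backend, rounding)
  (sigmoid(z) >= threshold) * 1
}

#' Morphological post-processing of a binary mask
#'
#' Closing (dilation then erosion) with a disc structuring element, the
#' standard cleanup that fills pinholes and smooths lesion borders;
#' idempotent for a fixed radius. Radius 0 is the identity.
#'
#' @param mask binary H x W matrix.
#' @param radius disc radius in pixels (non-negative integer).
#' @return Binary H x W matrix.
#' @export
postprocess_mask <- function(mask, radius = 1) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)), radius >= 0)
  if (radius == 0) return(mask)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  out <- EBImage::closing(mask, kern)
  m <- EBImage::imageData(out)
  (m > 0.5) * 1
}
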