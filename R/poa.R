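#' Search-space bounds
#' @param lower,upper numeric vectors with `lower < upper` elementwise.
#' @return A `poa_bounds` list with `lower`, `upper`, `m` (dimension).
#' @export
poa_bounds <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 m = length(lower)), class = "poa_bounds")
}

#' Pelican Optimization Algorithm configuration
#' @param N population size (>= 2).
#' @param T iterations (>= 1).
#' @param seed integer RNG seed.
#' @param R exploitation neighbourhood constant (default 0.2).
#' @return A `poa_config` list.
#' @export
poa_config <- function(N = 20, T = 100, seed = 1, R = 0.2) {
  stopifnot(N >= 2, T >= 1, R > 0)
  structure(list(N = as.integer(N), T = as.integer(T), seed = as.integer(seed),
                 R = R), class = "poa_config")
}

clamp_rows <- function(X, bounds) {
  X <- sweep(X, 2, bounds$lower, pmax)
  sweep(X, 2, bounds$upper, pmin)
}

#' Initialise a pelican population
#'
#' `x[i, j] = l_j + rand[i, j] * (u_j - l_j)` with uniform rand on `[0, 1]`,
#' drawn from the current RNG state (seed it for reproducibility).
#'
#' @param bounds a [poa_bounds()].
#' @param N population size.
#' @return N x m matrix of positions, one pelican per row.
#' @export
poa_initialize <- function(bounds, N) {
  m <- bounds$m
  r <- matrix(runif(N * m), N, m)
  sweep(sweep(r, 2, bounds$upper - bounds$lower, `*`), 2, bounds$lower, `+`)
}

#' One exploration phase ("moving towards prey")
#'
#' A prey position is selected at random from the population once per
#' iteration. Each pelican moves toward the prey when the prey's fitness
#' is better - `x + rand * (prey - I * x)` with `I` randomly 1 or 2 - and
#' away from it otherwise (`x + rand * (x - prey)`). Moves are clamped to
#' the bounds and accepted only if the fitness improves (greedy
#' selection).
#'
#' @param X N x m position matrix.
#' @param fit numeric vector of current fitness values (lower is better).
#' @param fitness objective function over a position vector.
#' @param bounds a [poa_bounds()].
#' @param prey optional explicit prey position (selected from the
#'   population when `NULL`).
#' @param prey_fit fitness of the explicit prey (computed when `NULL`).
#' @return List `X`, `fit` after greedy acceptance.
#' @export
poa_exploration <- function(X, fit, fitness, bounds, prey = NULL,
                            prey_fit = NULL) {
  N <- nrow(X); m <- ncol(X)
  if (is.null(prey)) {
    j <- sample.int(N, 1)
    prey <- X[j, ]
    fprey <- fit[j]
  } else {
    fprey <- if (is.null(prey_fit)) fitness(prey) else prey_fit
  }
  for (i in seq_len(N)) {
    rand <- runif(m)
    if (is.finite(fprey) && fprey < fit[i]) {
      I <- sample(1:2, 1)
      cand <- X[i, ] + rand * (prey - I * X[i, ])
    } else {
      cand <- X[i, ] + rand * (X[i, ] - prey)
    }
    cand <- pmin(pmax(cand, bounds$lower), bounds$upper)
    fc <- fitness(cand)
    if (is.na(fc)) { warning("fitness returned NaN; candidate rejected"); next }
    if (fc < fit[i]) { X[i, ] <- cand; fit[i] <- fc }
  }
  list(X = X, fit = fit)
}

#' One exploitation phase ("winging on the water surface")
#'
#' Local search around each pelican:
#' `x + R * (1 - t/T) * (2 * rand - 1) * x`, radius shrinking linearly to
#' zero as `t` approaches `T`; clamped, greedy acceptance.
#'
#' @inheritParams poa_exploration
#' @param t current iteration (1-based).
#' @param T total iterations.
#' @param R neighbourhood constant.
#' @return List `X`, `fit`.
#' @export
poa_exploitation <- function(X, fit, fitness, bounds, t, T, R = 0.2) {
  N <- nrow(X); m <- ncol(X)
  radius <- R * (1 - t / T)
  for (i in seq_len(N)) {
    cand <- X[i, ] + radius * (2 * runif(m) - 1) * X[i, ]
    cand <- pmin(pmax(cand, bounds$lower), bounds$upper)
    fc <- fitness(cand)
    if (is.na(fc)) { warning("fitness returned NaN; candidate rejected"); next }
    if (fc < fit[i]) { X[i, ] <- cand; fit[i] <- fc }
  }
  list(X = X, fit = fit)
}

#' Run the Pelican Optimization Algorithm
#'
#' Population metaheuristic with the two canonical phases per iteration.
#' Minimises `fitness`; the best-so-far trace is monotone non-increasing by
#' construction (greedy acceptance at every move).
#'
#' @param fitness objective over a length-m position vector (lower better).
#' @param bounds a [poa_bounds()].
#' @param cfg a [poa_config()].
#' @param warm_start optional matrix (or vector) of positions injected into
#'   the initial population (e.g. an incumbent configuration).
#' @return List of class `poa_result`: `best` (list `position`, `fitness`),
#'   `trace` (best-so-far per iteration, index 1 = after initialisation)
#'   and `population`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- poa_optimize(sphere, poa_bounds(rep(-5, 2), rep(5, 2)),
#'                     poa_config(N = 10, T = 20, seed = 1))
#' res$best$fitness
#' @export
poa_optimize <- function(fitness, bounds, cfg = poa_config(),
                         warm_start = NULL) {
  stopifnot(inherits(bounds, "poa_bounds"), inherits(cfg, "poa_config"))
  set.seed(cfg$seed)
  X <- poa_initialize(bounds, cfg$N)
  if (!is.null(warm_start)) {
    ws <- if (is.matrix(warm_start)) warm_start else matrix(warm_start, 1)
    ws <- clamp_rows(ws, bounds)
    k <- min(nrow(ws), cfg$N)
    X[seq_len(k), ] <- ws[seq_len(k), , drop = FALSE]
  }
  fit <- apply(X, 1, fitness)
  if (anyNA(fit)) {
    warning("fitness returned NaN at initialisation; set to +Inf")
    fit[is.na(fit)] <- Inf
  }
  trace <- numeric(cfg$T + 1)
  trace[1] <- min(fit)
  for (t in seq_len(cfg$T)) {
    st <- poa_exploration(X, fit, fitness, bounds)
    st <- poa_exploitation(st$X, st$fit, fitness, bounds, t, cfg$T, cfg$R)
    X <- st$X; fit <- st$fit
    trace[t + 1] <- min(fit)
  }
  b <- which.min(fit)
  structure(list(best = list(position = X[b, ], fitness = fit[b]),
                 trace = trace, population = list(X = X, fit = fit)),
            class = "poa_result")
}

#' Benchmark objectives
#'
#' `poa_sphere` is `sum(x^2)`; `poa_rastrigin` is
#' `10 m + sum(x^2 - 10 cos(2 pi x))`. Both have global minimum 0 at the
#' origin.
#'
#' @param x numeric position vector.
#' @return Objective value.
#' @export
poa_sphere <- function(x) sum(x^2)

#' @rdname poa_sphere
#' @export
poa_rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

#' Decode a position vector into DnCNN hyperparameters
#'
#' Fields: log10 learning rate in `[-4, -1]`, depth in `{3..9}`, width in
#' `{8..32}`, mask threshold in `[0.2, 0.8]`, post-processing disc radius
#' in `{0..3}`. Integer fields round to the nearest valid value.
#'
#' @param position length-5 numeric vector.
#' @return List `learning_rate`, `depth`, `width`, `threshold`, `radius`.
#' @export
decode_hyper <- function(position) {
  stopifnot(length(position) == 5)
  list(learning_rate = 10^min(max(position[1], -4), -1),
       depth = as.integer(min(max(round(position[2]), 3), 9)),
       width = as.integer(min(max(round(position[3]), 8), 32)),
       threshold = min(max(position[4], 0.2), 0.8),
       radius = as.integer(min(max(round(position[5]), 0), 3)))
}

#' Bounds of the DnCNN hyperparameter search space
#' @return A [poa_bounds()] over (log10 lr, depth, width, threshold, radius).
#' @export
hyper_bounds <- function() {
  poa_bounds(c(-4, 3, 8, 0.2, 0), c(-1, 9, 32, 0.8, 3))
}

#' Default hyperparameter position (incumbent configuration)
#' @return Length-5 numeric vector on the [hyper_bounds()] scale.
#' @export
hyper_default <- function() c(log10(5e-3), 5, 16, 0.5, 1)

#' Train final segmenters for candidate hyperparameters and select by
#' validation fitness
#'
#' Short-budget tuning fitness does not always transfer to the full
#' training budget, so the deployed model is chosen by re-training each
#' candidate (typically the POA winner and the incumbent default) at the
#' full budget and comparing the DSC/IoU fitness on a held-out validation
#' subset of the training phantoms. Test data is never touched.
#'
#' @param candidates list of decoded hyperparameter lists (see
#'   [decode_hyper()]).
#' @param images list of training images (e.g. denoised phantoms).
#' @param masks list of matching ground-truth masks.
#' @param val_idx indices of `images` held out for the selection fitness.
#' @param epochs,batch_size,seed full-budget training configuration.
#' @return List with the winning `net`, its `hp`, and `val_fitness` per
#'   candidate.
#' @export
select_segmenter <- function(candidates, images, masks, val_idx,
                             epochs = 150, batch_size = 8, seed = 1) {
  stopifnot(length(images) == length(masks), length(val_idx) >= 1)
  fits <- numeric(length(candidates))
  nets <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    hp <- candidates[[ci]]
    net <- dncnn_build(network_spec(depth = hp$depth, width = hp$width,
                                    head = "segment"))
    net <- dncnn_train(net, images, masks,
                       train_config(learning_rate = hp$learning_rate,
                                    epochs = epochs, batch_size = batch_size,
                                    seed = seed,
                                    mask_threshold = hp$threshold))
    fits[ci] <- mean(vapply(val_idx, function(i) {
      m <- postprocess_mask(dncnn_segment(net, images[[i]],
                                          threshold = hp$threshold),
                            hp$radius)
      sc <- seg_scores(confusion(m, masks[[i]]))
      d <- if (is.na(sc$dsc)) 0 else sc$dsc
      io <- if (is.na(sc$iou)) 0 else sc$iou
      1 - 0.5 * d - 0.5 * io
    }, numeric(1)))
    nets[[ci]] <- net
  }
  best <- which.min(fits)
  list(net = nets[[best]], hp = candidates[[best]], val_fitness = fits)
}

#' Segmentation fitness of a hyperparameter candidate
#'
#' Decodes the candidate, trains a desk-scale segment-head DnCNN on the
#' training phantoms with a short seeded budget, segments the validation
#' phantoms (with morphological post-processing at the decoded radius) and
#' returns `1 - (w_dsc * DSC + w_iou * IoU)` averaged over the validation
#' set; 0 is a perfect segmenter.
#'
#' @param position length-5 candidate vector (see [decode_hyper()]).
#' @param train,val phantom sets as returned by [generate_dataset()]
#'   (lists of [phantom_generate()] objects).
#' @param budget_epochs training epochs per evaluation.
#' @param seed training seed (fixed across candidates for comparability).
#' @param weights DSC/IoU fitness weights, summing to 1.
#' @return Fitness value in `[0, 1]` (lower is better).
#' @export
dncnn_fitness <- function(position, train, val, budget_epochs = 25, seed = 7,
                          weights = c(0.5, 0.5)) {
  hp <- decode_hyper(position)
  # training re-seeds the global RNG; preserve the caller's stream so the
  # surrounding optimizer stays deterministic under one seed
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    rs <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", rs, envir = .GlobalEnv), add = TRUE)
  }
  xs <- lapply(train, function(p) p$noisy)
  ys <- lapply(train, function(p) p$mask)
  net <- dncnn_build(network_spec(depth = hp$depth, width = hp$width,
                                  head = "segment"))
  cfg <- train_config(learning_rate = hp$learning_rate,
                      epochs = budget_epochs, batch_size = 8, seed = seed,
                      mask_threshold = hp$threshold)
  net <- dncnn_train(net, xs, ys, cfg)
  score <- vapply(val, function(p) {
    m <- dncnn_segment(net, p$noisy, threshold = hp$threshold)
    m <- postprocess_mask(m, hp$radius)
    sc <- seg_scores(confusion(m, p$mask))
    d <- if (is.na(sc$dsc)) 0 else sc$dsc
    i <- if (is.na(sc$iou)) 0 else sc$iou
    weights[1] * d + weights[2] * i
  }, numeric(1))
  1 - mean(score)
}
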