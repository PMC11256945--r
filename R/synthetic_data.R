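# Two-view nonlinear simulation with ground-truth signal masks. Signal
# columns in view 1 follow damped/growing trigonometric curves of a latent
# angle, giving the two classes a spiral-arm structure that no linear
# classifier on the raw columns can separate; view 2 is a rectified, noisy
# derivative of view 1 carrying no signal of its own.

#' Simulation setting presets
#'
#' Four sample/feature-size regimes: S1 small n and p (n1=200, n2=150,
#' p=500 per view); S2 large n (n1=3000, n2=2250, p=500); S3 small n, large
#' p (n1=200, n2=150, p=2000); S4 large n and p (n1=3000, n2=2250, p=2000).
#' In every setting the first 10\% of view-1 columns are signals, the noise
#' scale is 0.2, and the latent angle runs over [0, 3pi] with 0.5 U(0,1)
#' jitter.
#'
#' @param name one of "S1", "S2", "S3", "S4".
#' @param n1,n2,p1,p2 override sample/feature sizes (defaults from the
#'   named preset).
#' @export
sim_setting <- function(name = c("S1", "S2", "S3", "S4"),
                        n1 = NULL, n2 = NULL, p1 = NULL, p2 = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    S1 = list(n1 = 200L, n2 = 150L, p1 = 500L, p2 = 500L),
    S2 = list(n1 = 3000L, n2 = 2250L, p1 = 500L, p2 = 500L),
    S3 = list(n1 = 200L, n2 = 150L, p1 = 2000L, p2 = 2000L),
    S4 = list(n1 = 3000L, n2 = 2250L, p1 = 2000L, p2 = 2000L))
  structure(list(name = name,
                 n1 = as.integer(n1 %||% preset$n1),
                 n2 = as.integer(n2 %||% preset$n2),
                 p1 = as.integer(p1 %||% preset$p1),
                 p2 = as.integer(p2 %||% preset$p2),
                 noise_scale = 0.2, signal_fraction = 0.10,
                 theta_max = 3 * pi, theta_jitter = 0.5),
            class = "sim_setting")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one nonlinear two-view dataset
#'
#' View 1: the latent angle theta is an evenly spaced grid on [0, 3pi] plus
#' 0.5 U(0,1) jitter. The first five signal columns are
#' exp(0.15 theta) sin(1.5 theta), the remaining signal columns (up to 10\%
#' of p1) are exp(0.15 theta) cos(1.5 theta), noise columns are masked to
#' zero; 0.2 N(0,1) noise is added everywhere. Class 1 is the first n1
#' points along the grid, class 2 the remaining n2 (our reading of the
#' two-arm structure; configurable by subsetting). View 2 rectifies view 1
#' at zero, scales each column to unit Euclidean norm and adds per-entry
#' U(0,1) noise; it carries no signal features. Rows are jointly shuffled
#' with a seeded permutation.
#'
#' @param setting a \code{\link{sim_setting}} (or a preset name).
#' @param seed integer seed (local to this call).
#' @return \code{multiview_dataset}: \code{views} (list of two matrices with
#'   named columns), \code{labels} (factor "c1"/"c2"), \code{signal_masks}
#'   (logical per feature per view), \code{provenance}, and
#'   \code{intermediates} (theta and the pre-noise view-2 matrix).
#' @export
generate_nonlinear <- function(setting = sim_setting("S1"), seed = 1L) {
  if (is.character(setting)) setting <- sim_setting(setting)
  n1 <- setting$n1; n2 <- setting$n2
  p1 <- setting$p1; p2 <- setting$p2
  n <- n1 + n2
  ns <- floor(setting$signal_fraction * p1)
  with_local_seed(seed, {
    theta_grid <- seq(0, setting$theta_max, length.out = n)
    theta <- theta_grid + setting$theta_jitter * stats::runif(n)
    X1t <- matrix(0, n, p1)
    X1t[, 1:5] <- exp(0.15 * theta) * sin(1.5 * theta)
    if (ns > 5) X1t[, 6:ns] <- exp(0.15 * theta) * cos(1.5 * theta)
    X1t[, (ns + 1):p1] <- stats::rnorm(n * (p1 - ns))
    W <- cbind(matrix(1, n, ns), matrix(0, n, p1 - ns))
    X1 <- X1t * W + setting$noise_scale * matrix(stats::rnorm(n * p1), n, p1)
    # view 2: rectify, unit column norm, per-entry uniform noise
    X2pre <- pmax(X1[, seq_len(p2), drop = FALSE], 0)
    norms <- sqrt(colSums(X2pre^2))
    norms[norms == 0] <- 1
    X2pre <- sweep(X2pre, 2, norms, `/`)
    X2 <- X2pre + matrix(stats::runif(n * p2), n, p2)
    labels <- factor(rep(c("c1", "c2"), c(n1, n2)))
    perm <- sample.int(n)
    colnames(X1) <- paste0("v1_f", seq_len(p1))
    colnames(X2) <- paste0("v2_f", seq_len(p2))
    structure(list(
      views = list(X1[perm, , drop = FALSE], X2[perm, , drop = FALSE]),
      labels = labels[perm],
      signal_masks = list(seq_len(p1) <= ns, rep(FALSE, p2)),
      provenance = list(setting = setting$name, seed = seed,
                        n1 = n1, n2 = n2, p1 = p1, p2 = p2,
                        n_signal = ns, permutation = perm),
      intermediates = list(theta_grid = theta_grid, theta = theta,
                           X2_pre_noise = X2pre[perm, , drop = FALSE])),
      class = "multiview_dataset")
  })
}

#' Linearly separable two-view toy data
#'
#' Two Gaussian class clouds sharing a latent factor across views; intended
#' as a fast sanity fixture (perfectly separable for large \code{gap},
#' uninformative at \code{gap = 0}).
#'
#' @param n_per_class samples per class.
#' @param p features per view.
#' @param gap distance between class means (per view, along a unit vector).
#' @param seed integer seed.
#' @export
generate_linear_toy <- function(n_per_class = 25L, p = 5L, gap = 3,
                                seed = 1L) {
  n <- 2L * n_per_class
  with_local_seed(seed, {
    cls <- rep(c(0, 1), each = n_per_class)
    z <- stats::rnorm(n)
    mk_view <- function() {
      dir <- rep(1 / sqrt(p), p)
      load <- stats::rnorm(p, sd = 0.3)
      outer(cls * gap, dir) + outer(z, load) +
        matrix(stats::rnorm(n * p, sd = 0.5), n, p)
    }
    X1 <- mk_view(); X2 <- mk_view()
    colnames(X1) <- paste0("v1_f", seq_len(p))
    colnames(X2) <- paste0("v2_f", seq_len(p))
    labels <- factor(rep(c("c1", "c2"), each = n_per_class))
    perm <- sample.int(n)
    structure(list(views = list(X1[perm, ], X2[perm, ]),
                   labels = labels[perm],
                   signal_masks = NULL,
                   provenance = list(setting = "linear_toy", seed = seed,
                                     gap = gap),
                   intermediates = NULL),
              class = "multiview_dataset")
  })
}

#' Independent train / validation / test replicates
#'
#' Each replicate draws three independent datasets from the same setting
#' under replicate-specific seeds derived from \code{base_seed}.
#'
#' @param setting a \code{\link{sim_setting}} or preset name.
#' @param n_reps number of Monte-Carlo replicates.
#' @param base_seed integer; replicate r uses seeds
#'   \code{base_seed + 100 r + (1,2,3)}.
#' @export
monte_carlo_replicates <- function(setting = sim_setting("S1"),
                                   n_reps = 20L, base_seed = 1L) {
  if (is.character(setting)) setting <- sim_setting(setting)
  lapply(seq_len(n_reps), function(r) {
    list(train = generate_nonlinear(setting, seed = base_seed + 100L * r + 1L),
         validation = generate_nonlinear(setting, seed = base_seed + 100L * r + 2L),
         test = generate_nonlinear(setting, seed = base_seed + 100L * r + 3L))
  })
}

#' Subset a multiview dataset by sample and/or feature indices
#'
#' @param dataset a \code{multiview_dataset}.
#' @param samples row indices (with repeats allowed, as in bootstrap draws).
#' @param features list of per-view column index vectors, or NULL for all.
#' @export
subset_dataset <- function(dataset, samples = NULL, features = NULL) {
  views <- dataset$views
  labels <- dataset$labels
  masks <- dataset$signal_masks
  if (!is.null(samples)) {
    views <- lapply(views, function(X) X[samples, , drop = FALSE])
    labels <- labels[samples]
  }
  if (!is.null(features)) {
    views <- lapply(seq_along(views), function(d)
      views[[d]][, features[[d]], drop = FALSE])
    if (!is.null(masks)) {
      masks <- lapply(seq_along(masks), function(d) masks[[d]][features[[d]]])
    }
  }
  structure(list(views = views, labels = droplevels(labels),
                 signal_masks = masks, provenance = dataset$provenance,
                 intermediates = NULL),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  dims <- vapply(x$views, function(v) paste(dim(v), collapse = " x "), "")
  cat(sprintf("multiview_dataset (%s): %s; %d classes\n",
              x$provenance$setting %||% "custom",
              paste(dims, collapse = ", "), nlevels(x$labels)))
  invisible(x)
}
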