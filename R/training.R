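# End-to-end fitting. The loss is the negative sum, over views, of the l
# largest eigenvalues of G_d = c1 M_d + c2 sum_{j!=d} N_dj G~_j G~_j' N_dj',
# with the projection matrices G~ re-solved at each evaluation and treated as
# constants during backpropagation. Gradients w.r.t. the top-layer
# representations are derived analytically: eigenvalue adjoints (U U'),
# product rules through M_d and N_dj, a Daleckii-Krein map through the
# inverse matrix square root of the ridged total covariance, and the
# centering chain through the mean of class means.

# Frechet-derivative adjoint of A -> A^{-1/2} at the eigendecomposition of A.
inv_sqrt_backward <- function(eig, barT) {
  s <- eig$values
  V <- eig$vectors
  fs <- s^(-0.5)
  den <- outer(s, s, `-`)
  num <- outer(fs, fs, `-`)
  Km <- num / den
  tie <- abs(den) < 1e-12 * max(abs(s))
  smid <- (outer(s, s, `+`) / 2)[tie]
  Km[tie] <- -0.5 * smid^(-1.5)
  inner <- crossprod(V, sym(barT) %*% V)
  sym(V %*% (Km * inner) %*% t(V))
}

#' Joint association-discrimination loss and its representation gradients
#'
#' Builds all covariances of the supplied top-layer representations, whitens
#' them, solves for the projection matrices, and returns the negative sum of
#' the l leading eigenvalues of each view's combined operator together with
#' the analytic gradient with respect to every representation matrix.
#'
#' @param Hs list of D row-aligned n x o_d representation matrices.
#' @param labels length-n class labels (K >= 2, all present).
#' @param rho separation/association mixing weight in [0,1].
#' @param l number of leading eigenvalues summed (default
#'   \code{min(K-1, o_d)}).
#' @param ridge absolute ridge added to each total covariance before
#'   inversion; NULL for the relative default \code{1e-4 mean(diag(St))}.
#' @param gamma_init optional warm-start projections for the inner solver.
#' @param gamma_seed,gamma_tol,gamma_max_iter inner eigensolver controls.
#' @param grad compute gradients (set FALSE for evaluation only).
#' @param gamma_frozen use \code{gamma_init} exactly as given without
#'   re-solving (the projections are treated as constants during
#'   backpropagation, so freezing them makes the loss differentiable in the
#'   representations alone; used by gradient checks).
#' @return list: \code{value} (the scalar loss), \code{grads} (list of
#'   n x o_d matrices, NULL unless \code{grad}), \code{gamma} (the
#'   \code{gamma_solution} used), \code{eigen_sums} per view.
#' @export
deep_ida_loss <- function(Hs, labels, rho = 0.5, l = NULL, ridge = NULL,
                          gamma_init = NULL, gamma_seed = 1L,
                          gamma_tol = 1e-6, gamma_max_iter = 100L,
                          grad = TRUE, gamma_frozen = FALSE) {
  D <- length(Hs)
  if (D < 2) stop("need at least two views")
  Hs <- lapply(Hs, as.matrix)
  n <- nrow(Hs[[1]])
  labels <- droplevels(as.factor(labels))
  K <- nlevels(labels)
  if (K < 2) stop("need at least two classes in the batch")
  os <- vapply(Hs, ncol, 1L)
  if (any(os >= n)) stop("top-layer width must be smaller than the sample size")

  lev <- levels(labels)
  Z <- vapply(lev, function(g) as.numeric(labels == g), numeric(n))  # n x K
  nk <- colSums(Z)
  if (any(nk == 0)) stop("empty class")
  if (is.null(l)) l <- min(K - 1L, os)

  # forward covariance construction, keeping intermediates
  st <- vector("list", D)
  for (d in seq_len(D)) {
    H <- Hs[[d]]
    mu_k <- crossprod(Z, H) / nk             # K x o
    mu <- colMeans(mu_k)
    delta <- sweep(mu_k, 2, mu)
    Sb <- sym(crossprod(delta * nk, delta) / (n - 1))
    Hc <- sweep(H, 2, mu)
    St <- sym(crossprod(Hc) / (n - 1))
    r <- if (is.null(ridge)) default_ridge(St) else ridge
    eigA <- eigen(St + diag(r, ncol(St)), symmetric = TRUE)
    if (any(eigA$values <= 0)) stop("total covariance not positive definite")
    Tm <- eigA$vectors %*% (t(eigA$vectors) / sqrt(eigA$values))
    st[[d]] <- list(mu_k = mu_k, mu = mu, delta = delta, Sb = Sb, St = St,
                    Hc = Hc, eigA = eigA, Tm = Tm,
                    M = sym(Tm %*% Sb %*% Tm))
  }
  S <- N <- vector("list", D)
  for (d in seq_len(D)) {
    S[[d]] <- N[[d]] <- vector("list", D)
    for (j in seq_len(D)) if (j != d) {
      S[[d]][[j]] <- crossprod(st[[d]]$Hc, st[[j]]$Hc) / (n - 1)
      N[[d]][[j]] <- st[[d]]$Tm %*% S[[d]][[j]] %*% st[[j]]$Tm
    }
  }
  system <- structure(list(M = lapply(st, `[[`, "M"), N = N,
                           c1 = rho / D, c2 = 2 * (1 - rho) / (D * (D - 1)),
                           rho = rho, l = as.integer(l), D = D),
                      class = "whitened_system")
  gamma <- if (gamma_frozen) {
    if (is.null(gamma_init)) stop("gamma_frozen requires gamma_init")
    list(Gammas = gamma_init, l = as.integer(l))
  } else {
    solve_gamma(system, init_seed = gamma_seed, tol = gamma_tol,
                max_iter = gamma_max_iter, init = gamma_init)
  }
  c1 <- system$c1; c2 <- system$c2

  # per-view combined operator at the solved (fixed) projections
  eigG <- vector("list", D)
  eigen_sums <- numeric(D)
  for (d in seq_len(D)) {
    G <- c1 * st[[d]]$M
    if (c2 != 0) for (j in seq_len(D)) if (j != d) {
      NP <- N[[d]][[j]] %*% gamma$Gammas[[j]]
      G <- G + c2 * tcrossprod(NP)
    }
    eigG[[d]] <- eigen(sym(G), symmetric = TRUE)
    eigen_sums[d] <- sum(eigG[[d]]$values[seq_len(l)])
  }
  value <- -sum(eigen_sums)
  if (!grad) {
    return(list(value = value, grads = NULL, gamma = gamma,
                eigen_sums = eigen_sums))
  }

  # ---- backward ----
  barM <- vector("list", D)
  barN <- vector("list", D)
  for (d in seq_len(D)) {
    U <- eigG[[d]]$vectors[, seq_len(l), drop = FALSE]
    barG <- -tcrossprod(U)                   # d(-sum top-l eig)/dG
    barM[[d]] <- c1 * barG
    barN[[d]] <- vector("list", D)
    if (c2 != 0) for (j in seq_len(D)) if (j != d) {
      Pj <- tcrossprod(gamma$Gammas[[j]])
      barN[[d]][[j]] <- 2 * c2 * (barG %*% N[[d]][[j]] %*% Pj)
    }
  }
  barH <- vector("list", D)
  for (d in seq_len(D)) {
    Tm <- st[[d]]$Tm
    barT <- barM[[d]] %*% Tm %*% st[[d]]$Sb + st[[d]]$Sb %*% Tm %*% barM[[d]]
    barSb <- Tm %*% barM[[d]] %*% Tm
    barS_cross_to_Hc <- matrix(0, n, ncol(Hs[[d]]))
    if (c2 != 0) for (j in seq_len(D)) if (j != d) {
      bN <- barN[[d]][[j]]
      barT <- barT + bN %*% st[[j]]$Tm %*% t(S[[d]][[j]])
      # (d,j) ordered pair also contributes to view j's T via S_dj' T_d barN
      barS <- Tm %*% bN %*% st[[j]]$Tm       # adjoint of S_dj
      barS_cross_to_Hc <- barS_cross_to_Hc + st[[j]]$Hc %*% t(barS) / (n - 1)
      st[[j]]$barHc_extra <- (if (is.null(st[[j]]$barHc_extra))
        matrix(0, n, ncol(Hs[[j]])) else st[[j]]$barHc_extra) +
        st[[d]]$Hc %*% barS / (n - 1)
      st[[j]]$barT_extra <- (if (is.null(st[[j]]$barT_extra))
        matrix(0, ncol(Hs[[j]]), ncol(Hs[[j]])) else st[[j]]$barT_extra) +
        t(S[[d]][[j]]) %*% Tm %*% bN
    }
    st[[d]]$barT_own <- barT
    st[[d]]$barSb <- barSb
    st[[d]]$barHc_cross <- barS_cross_to_Hc
  }
  for (d in seq_len(D)) {
    barT <- st[[d]]$barT_own
    if (!is.null(st[[d]]$barT_extra)) barT <- barT + st[[d]]$barT_extra
    barSt <- inv_sqrt_backward(st[[d]]$eigA, barT)
    barHc <- 2 * st[[d]]$Hc %*% barSt / (n - 1)
    barHc <- barHc + st[[d]]$barHc_cross
    if (!is.null(st[[d]]$barHc_extra)) barHc <- barHc + st[[d]]$barHc_extra
    bar_delta <- (2 / (n - 1)) * (st[[d]]$delta * nk) %*% sym(st[[d]]$barSb)
    bar_mu <- -colSums(bar_delta) - colSums(barHc)
    bar_mu_k <- bar_delta + matrix(bar_mu / K, nrow = K,
                                   ncol = ncol(Hs[[d]]), byrow = TRUE)
    barH[[d]] <- barHc + Z %*% (bar_mu_k / nk)
  }
  list(value = value, grads = barH, gamma = gamma, eigen_sums = eigen_sums)
}

# --- Adam optimizer (full-batch first-order updates) ----------------------

adam_init <- function(params) {
  lapply(params$layers, function(lyr)
    list(mW = array(0, dim(lyr$W)), vW = array(0, dim(lyr$W)),
         mb = numeric(length(lyr$b)), vb = numeric(length(lyr$b))))
}

adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (m in seq_along(params$layers)) {
    gW <- grads$layers[[m]]$W + weight_decay * params$layers[[m]]$W
    gb <- grads$layers[[m]]$b
    s <- state[[m]]
    s$mW <- beta1 * s$mW + (1 - beta1) * gW
    s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
    params$layers[[m]]$W <- params$layers[[m]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params$layers[[m]]$b <- params$layers[[m]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[m]] <- s
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param rho mixing weight (0.5 balances class separation and cross-view
#'   association; the recommended default).
#' @param l number of discriminant directions (default min(K-1, widths)).
#' @param epochs full-batch gradient epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the weight gradients
#'   (0 disables).
#' @param l1_input L1 penalty on the first-layer weights, applied as a
#'   proximal soft-threshold after each optimizer step; encourages the
#'   networks to drop uninformative input features (0 disables).
#' @param ridge absolute total-covariance ridge, NULL for the relative default.
#' @param standardize z-score each view's columns with training statistics.
#' @param gamma_tol,gamma_max_iter inner eigensolver controls.
#' @param seed master seed for parameter initialization.
#' @export
train_config <- function(rho = 0.5, l = NULL, epochs = 50L,
                         learning_rate = 1e-3, weight_decay = 0,
                         l1_input = 0, ridge = NULL, standardize = TRUE,
                         gamma_tol = 1e-6, gamma_max_iter = 100L,
                         seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, epochs >= 1)
  list(rho = rho, l = l, epochs = as.integer(epochs),
       learning_rate = learning_rate, weight_decay = weight_decay,
       l1_input = l1_input, ridge = ridge,
       standardize = isTRUE(standardize), gamma_tol = gamma_tol,
       gamma_max_iter = as.integer(gamma_max_iter), seed = as.integer(seed))
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, ctr, scl) {
  sweep(sweep(as.matrix(X), 2, ctr), 2, scl, `/`)
}

#' Fit a joint multiview discriminant model
#'
#' Trains one feed-forward network per view by full-batch Adam on the
#' eigenvalue-sum loss of \code{\link{deep_ida_loss}}. The projection
#' matrices are re-solved at every epoch (warm-started) and re-solved once
#' more on the final representations.
#'
#' @param views list of D n x p_d numeric matrices, row-aligned.
#' @param labels length-n class labels.
#' @param specs list of \code{network_spec}, one per view; NULL for the
#'   default two-hidden-layer architecture (256, 64) with a 20-unit top layer
#'   (capped below the sample size).
#' @param config a \code{\link{train_config}}.
#' @param verbose print the loss once per 10 epochs.
#' @return object of class \code{deep_ida_model} with the fitted networks,
#'   projections, loss trace and preprocessing statistics.
#' @export
train_deep_ida <- function(views, labels, specs = NULL,
                           config = train_config(), verbose = FALSE) {
  D <- length(views)
  if (D < 2) stop("need at least two views")
  views <- lapply(views, as.matrix)
  n <- nrow(views[[1]])
  if (!all(vapply(views, nrow, 1L) == n)) stop("views must be row-aligned")
  labels <- droplevels(as.factor(labels))
  if (anyNA(labels) || any(vapply(views, anyNA, TRUE))) stop("missing values")
  K <- nlevels(labels)
  if (K < 2) stop("need at least two classes")
  if (is.null(specs)) {
    od <- min(20L, n - 1L)
    specs <- lapply(views, function(X)
      network_spec(ncol(X), c(256L, 64L), od))
  }
  for (d in seq_len(D)) {
    if (specs[[d]]$input_dim != ncol(views[[d]])) {
      stop(sprintf("view %d has %d features but spec expects %d",
                   d, ncol(views[[d]]), specs[[d]]$input_dim))
    }
    if (specs[[d]]$output_dim >= n) {
      stop("top-layer width must be smaller than the sample size")
    }
  }
  centers <- scales <- vector("list", D)
  Xs <- vector("list", D)
  for (d in seq_len(D)) {
    if (config$standardize) {
      sf <- standardize_fit(views[[d]])
      centers[[d]] <- sf$center; scales[[d]] <- sf$scale
      Xs[[d]] <- standardize_apply(views[[d]], sf$center, sf$scale)
    } else {
      centers[[d]] <- numeric(ncol(views[[d]]))
      scales[[d]] <- rep(1, ncol(views[[d]]))
      Xs[[d]] <- views[[d]]
    }
  }
  params <- lapply(seq_len(D), function(d)
    init_params(specs[[d]], seed = config$seed + d))
  states <- lapply(params, adam_init)
  trace <- numeric(config$epochs)
  gammas_warm <- NULL
  for (epoch in seq_len(config$epochs)) {
    fwd <- lapply(seq_len(D), function(d)
      nn_forward(params[[d]], Xs[[d]], cache = TRUE))
    Hs <- lapply(fwd, `[[`, "H")
    lo <- deep_ida_loss(Hs, labels, rho = config$rho, l = config$l,
                        ridge = config$ridge, gamma_init = gammas_warm,
                        gamma_seed = config$seed,
                        gamma_tol = config$gamma_tol,
                        gamma_max_iter = config$gamma_max_iter)
    if (!is.finite(lo$value)) {
      stop(sprintf("non-finite loss at epoch %d; lower the learning rate or increase the ridge",
                   epoch))
    }
    trace[epoch] <- lo$value
    gammas_warm <- lo$gamma$Gammas
    for (d in seq_len(D)) {
      bk <- nn_backward(params[[d]], Xs[[d]], fwd[[d]], lo$grads[[d]])
      upd <- adam_step(params[[d]], bk, states[[d]],
                       lr = config$learning_rate, t = epoch,
                       weight_decay = config$weight_decay %||% 0)
      params[[d]] <- upd$params
      states[[d]] <- upd$state
      l1 <- config$l1_input %||% 0
      if (l1 > 0) {
        W1 <- params[[d]]$layers[[1]]$W
        thr <- config$learning_rate * l1
        params[[d]]$layers[[1]]$W <- sign(W1) * pmax(abs(W1) - thr, 0)
      }
    }
    if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
      message(sprintf("epoch %3d  loss %.6f", epoch, lo$value))
    }
  }
  Hs <- lapply(seq_len(D), function(d) nn_forward(params[[d]], Xs[[d]]))
  final <- deep_ida_loss(Hs, labels, rho = config$rho, l = config$l,
                         ridge = config$ridge, gamma_init = gammas_warm,
                         gamma_seed = config$seed,
                         gamma_tol = config$gamma_tol,
                         gamma_max_iter = config$gamma_max_iter, grad = FALSE)
  model <- list(params = params, specs = specs, gamma = final$gamma,
                loss_trace = trace, config = config,
                class_levels = levels(labels),
                standardize = config$standardize,
                centers = centers, scales = scales,
                train_H = Hs, train_labels = labels,
                final_loss = final$value)
  class(model) <- "deep_ida_model"
  model
}

#' Project data through a fitted model
#'
#' @param model a \code{deep_ida_model}.
#' @param views list of matrices with the trained input dimensions.
#' @return list with \code{H} (per-view representations), \code{scores}
#'   (per-view discriminant scores \code{H_d Gamma_d}) and \code{pooled}
#'   (column-concatenated representations across views).
#' @export
project_deep_ida <- function(model, views) {
  D <- length(model$params)
  if (length(views) != D) stop("expected ", D, " views")
  H <- vector("list", D)
  for (d in seq_len(D)) {
    X <- standardize_apply(as.matrix(views[[d]]),
                           model$centers[[d]], model$scales[[d]])
    H[[d]] <- nn_forward(model$params[[d]], X)
  }
  scores <- lapply(seq_len(D), function(d) H[[d]] %*% model$gamma$Gammas[[d]])
  list(H = H, scores = scores, pooled = do.call(cbind, H))
}

#' @export
print.deep_ida_model <- function(x, ...) {
  cat(sprintf("deep_ida_model: %d views, %d classes, rho = %.2f, l = %d\n",
              length(x$params), length(x$class_levels), x$config$rho,
              x$gamma$l))
  cat(sprintf("  final loss %.5f after %d epochs\n",
              x$final_loss, length(x$loss_trace)))
  invisible(x)
}
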