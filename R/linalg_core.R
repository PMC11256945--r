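# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded subroutines do not perturb outer streams.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sym <- function(A) (A + t(A)) / 2

#' Per-view class statistics and covariances of a representation matrix
#'
#' Computes, for one view's top-layer representation \code{H} (samples in
#' rows), the class means, the unweighted mean of class means, the
#' class-size-weighted between-class covariance and the total covariance.
#' All scatters use the \code{1/(n-1)} scaling and are centered at the mean
#' of class means (not the grand sample mean; the two coincide only for
#' balanced classes).
#'
#' @param H numeric matrix, n x o, one row per sample.
#' @param labels factor (or coercible) of length n with K >= 2 levels, every
#'   level present.
#' @return list with \code{class_means} (K x o), \code{view_mean} (length o),
#'   \code{Sb}, \code{St} (o x o), \code{n}, \code{class_counts}.
#' @export
class_statistics <- function(H, labels) {
  H <- as.matrix(H)
  labels <- droplevels(as.factor(labels))
  n <- nrow(H)
  if (n <= 1) stop("degenerate sample size")
  if (length(labels) != n) stop("labels length must match rows of H")
  if (anyNA(H)) stop("H has missing values")
  counts <- table(labels)
  if (any(counts == 0)) stop("empty class")
  K <- length(counts)
  if (K < 2) stop("need at least two classes")
  o <- ncol(H)
  mu_k <- matrix(0, K, o, dimnames = list(names(counts), colnames(H)))
  for (k in seq_len(K)) {
    mu_k[k, ] <- colMeans(H[labels == names(counts)[k], , drop = FALSE])
  }
  mu <- colMeans(mu_k)            # unweighted mean of class means
  d <- sweep(mu_k, 2, mu)
  Sb <- crossprod(d * as.numeric(counts), d) / (n - 1)
  Hc <- sweep(H, 2, mu)
  St <- crossprod(Hc) / (n - 1)
  list(class_means = mu_k, view_mean = mu, Sb = sym(Sb), St = sym(St),
       n = n, class_counts = as.numeric(counts), labels = levels(labels))
}

#' Cross-covariance between two views' representations
#'
#' \code{1/(n-1)}-scaled cross-covariance of two row-aligned representation
#' matrices, each centered at its own mean-of-class-means vector.
#'
#' @param Hd,Hj numeric matrices with the same number of rows.
#' @param mu_d,mu_j centering vectors (typically \code{view_mean} from
#'   \code{\link{class_statistics}}).
#' @export
cross_covariance <- function(Hd, Hj, mu_d, mu_j) {
  Hd <- as.matrix(Hd); Hj <- as.matrix(Hj)
  if (nrow(Hd) != nrow(Hj)) stop("views must have the same number of rows")
  n <- nrow(Hd)
  crossprod(sweep(Hd, 2, mu_d), sweep(Hj, 2, mu_j)) / (n - 1)
}

#' Symmetric inverse square root of a positive-definite matrix
#'
#' Returns symmetric \code{R} with \code{R (S + ridge I) R = I}, via
#' eigendecomposition.
#'
#' @param S symmetric matrix.
#' @param ridge nonnegative scalar added to the diagonal before inversion.
#' @param tol symmetry tolerance relative to the largest entry.
#' @export
inv_sqrt_psd <- function(S, ridge = 0, tol = 1e-8) {
  S <- as.matrix(S)
  scale <- max(abs(S), 1)
  if (max(abs(S - t(S))) > tol * scale) stop("matrix is not symmetric")
  A <- sym(S) + diag(ridge, nrow(S))
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values <= 0)) stop("not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Build covariance structures for all views
#'
#' Convenience wrapper producing the full covariance set (per-view class
#' statistics plus all pairwise cross-covariances) from a list of top-layer
#' representations.
#'
#' @param Hs list of D row-aligned representation matrices.
#' @param labels class labels of length n.
#' @return object of class \code{covariance_set}: per-view stats in
#'   \code{$views}, cross-covariances in \code{$cross[[d]][[j]]}.
#' @export
covariance_set <- function(Hs, labels) {
  D <- length(Hs)
  if (D < 2) stop("need at least two views")
  n <- nrow(Hs[[1]])
  if (!all(vapply(Hs, nrow, 1L) == n)) stop("views must be row-aligned")
  views <- lapply(Hs, class_statistics, labels = labels)
  cross <- vector("list", D)
  for (d in seq_len(D)) {
    cross[[d]] <- vector("list", D)
    for (j in seq_len(D)) {
      if (j != d) {
        cross[[d]][[j]] <- cross_covariance(
          Hs[[d]], Hs[[j]], views[[d]]$view_mean, views[[j]]$view_mean)
      }
    }
  }
  structure(list(views = views, cross = cross, n = n,
                 K = length(views[[1]]$class_counts)),
            class = "covariance_set")
}

default_ridge <- function(St, rel = 1e-4) rel * mean(diag(St))

#' Whitened eigensystem of the joint association-discrimination problem
#'
#' Whitens each view's between-class covariance (\code{M_d = St_d^{-1/2} Sb_d
#' St_d^{-1/2}}) and each pairwise cross-covariance (\code{N_dj = St_d^{-1/2}
#' S_dj St_j^{-1/2}}), and fixes the mixing weights \code{c1 = rho/D},
#' \code{c2 = 2(1-rho)/(D(D-1))}.
#'
#' @param covs a \code{covariance_set}.
#' @param rho mixing weight in [0,1]: 1 = pure class separation, 0 = pure
#'   cross-view association.
#' @param l number of discriminant directions, at most
#'   \code{min(K-1, o_1, ..., o_D)}.
#' @param ridge either a single nonnegative number used for every view or
#'   NULL for the default \code{1e-4 * mean(diag(St_d))} per view.
#' @export
build_system <- function(covs, rho = 0.5, l = NULL, ridge = NULL) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  D <- length(covs$views)
  K <- covs$K
  os <- vapply(covs$views, function(v) ncol(v$St), 1L)
  lmax <- min(K - 1L, os)
  if (is.null(l)) l <- lmax
  if (l > lmax) stop("l exceeds min(K-1, view dimensions)")
  Ts <- vector("list", D)
  M <- vector("list", D)
  for (d in seq_len(D)) {
    St <- covs$views[[d]]$St
    r <- if (is.null(ridge)) default_ridge(St) else ridge
    Ts[[d]] <- inv_sqrt_psd(St, ridge = r)
    M[[d]] <- sym(Ts[[d]] %*% covs$views[[d]]$Sb %*% Ts[[d]])
  }
  N <- vector("list", D)
  for (d in seq_len(D)) {
    N[[d]] <- vector("list", D)
    for (j in seq_len(D)) if (j != d) {
      N[[d]][[j]] <- Ts[[d]] %*% covs$cross[[d]][[j]] %*% Ts[[j]]
    }
  }
  structure(list(M = M, N = N, Tinv_sqrt = Ts,
                 c1 = rho / D, c2 = 2 * (1 - rho) / (D * (D - 1)),
                 rho = rho, l = as.integer(l), D = D),
            class = "whitened_system")
}

# Objective attained by projection matrices Gammas on a whitened system:
# c1 * sum_d tr(G_d' M_d G_d) + c2 * sum_{d<j} tr(G_d' N_dj G_j G_j' N_dj' G_d).
# The association term counts each unordered view pair once, the convention
# under which the alternating eigensolver below is exact blockwise ascent.
eval_objective <- function(system, Gammas) {
  D <- system$D
  val <- 0
  for (d in seq_len(D)) {
    val <- val + system$c1 * sum(diag(crossprod(Gammas[[d]], system$M[[d]] %*% Gammas[[d]])))
  }
  if (system$c2 != 0 && D >= 2) {
    for (d in seq_len(D - 1)) for (j in (d + 1):D) {
      B <- crossprod(Gammas[[d]], system$N[[d]][[j]] %*% Gammas[[j]])
      val <- val + system$c2 * sum(B * B)
    }
  }
  val
}

fix_signs <- function(G) {
  for (c in seq_len(ncol(G))) {
    i <- which.max(abs(G[, c]))
    if (G[i, c] < 0) G[, c] <- -G[, c]
  }
  G
}

random_orthonormal <- function(o, l) {
  Q <- qr.Q(qr(matrix(stats::rnorm(o * max(l, 1)), o)))
  Q[, seq_len(l), drop = FALSE]
}

#' Alternating eigensolver for the per-view projection matrices
#'
#' Iteratively updates each view's projection \code{Gamma_d} to the top-l
#' eigenvectors of \code{G_d = c1 M_d + c2 sum_{j != d} N_dj Gamma_j Gamma_j'
#' N_dj'} holding the other views fixed, until the objective stabilizes.
#' Each sweep is exact blockwise maximization, so the objective is
#' non-decreasing across sweeps.
#'
#' @param system a \code{whitened_system} from \code{\link{build_system}}.
#' @param init_seed seed for the random orthonormal initialization (local to
#'   this call; the caller's RNG stream is untouched). Alternatively pass a
#'   list of starting matrices via \code{init}.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum number of sweeps over the views.
#' @param init optional warm-start list of Gamma matrices.
#' @return object of class \code{gamma_solution}: \code{Gammas} (orthonormal
#'   columns, sign-fixed), \code{eigenvalues} per view (non-increasing),
#'   \code{objective_value}, \code{objective_trace}, \code{iterations_used},
#'   \code{converged}.
#' @export
solve_gamma <- function(system, init_seed = 1L, tol = 1e-6, max_iter = 100L,
                        init = NULL) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  D <- system$D
  l <- system$l
  os <- vapply(system$M, nrow, 1L)
  Gammas <- if (is.null(init)) {
    with_local_seed(init_seed, lapply(os, random_orthonormal, l = l))
  } else init
  vals <- vector("list", D)
  obj_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  all_positive <- TRUE
  for (it in seq_len(max_iter)) {
    for (d in seq_len(D)) {
      G <- system$c1 * system$M[[d]]
      if (system$c2 != 0) {
        for (j in seq_len(D)) if (j != d) {
          NP <- system$N[[d]][[j]] %*% Gammas[[j]]
          G <- G + system$c2 * tcrossprod(NP)
        }
      }
      e <- eigen(sym(G), symmetric = TRUE)
      Gammas[[d]] <- e$vectors[, seq_len(l), drop = FALSE]
      vals[[d]] <- e$values[seq_len(l)]
      if (any(vals[[d]] <= 1e-12)) all_positive <- FALSE
    }
    obj <- eval_objective(system, Gammas)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) <= tol * max(abs(obj_prev), 1e-12)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    # rho = 1 decouples the views: one sweep is exact
    if (system$c2 == 0) { converged <- TRUE; break }
  }
  if (!all_positive) {
    warning("fewer than l strictly positive eigenvalues; padded with next eigenvectors")
  }
  Gammas <- lapply(Gammas, fix_signs)
  structure(list(Gammas = Gammas, eigenvalues = vals,
                 objective_value = eval_objective(system, Gammas),
                 objective_trace = trace, iterations_used = length(trace),
                 converged = converged, l = l),
            class = "gamma_solution")
}
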