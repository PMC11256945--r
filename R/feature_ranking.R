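# Bi-bootstrap permutation importance: bootstrap over sample indices
# (stratified by class, with replacement) and simultaneously over feature
# indices (80% subsets per view), train one model per paired draw, and rank
# every feature by the proportion of permutation evaluations in which
# shuffling it strictly decreased the out-of-bag classification metric.
# The framework is model-agnostic over a small fit/metric trainer contract;
# the default trainer embeds the multiview discriminant model with
# nearest-centroid prediction.

#' Stratified bootstrap sample-index sets
#'
#' Each bootstrap set has the original sample size and is drawn with
#' replacement within class strata, so class counts are preserved exactly.
#' The out-of-bag set contains the indices never drawn.
#'
#' @param labels length-n class labels.
#' @param M number of bootstrap sets.
#' @param seed integer seed (local to this call).
#' @return list of M lists with \code{boot} (length n, with repeats) and
#'   \code{oob} integer vectors.
#' @export
stratified_bootstrap_indices <- function(labels, M, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  counts <- table(labels)
  if (any(counts == 0)) stop("empty class")
  if (any(counts == 1)) {
    warning("a class has a single sample; its out-of-bag set may be empty")
  }
  strata <- split(seq_len(n), labels)
  with_local_seed(seed, {
    lapply(seq_len(M), function(m) {
      boot <- unlist(lapply(strata, function(idx)
        idx[sample.int(length(idx), length(idx), replace = TRUE)]),
        use.names = FALSE)
      list(boot = boot, oob = setdiff(seq_len(n), boot))
    })
  })
}

#' Bootstrap feature-index subsets
#'
#' For each of q draws and each view, samples
#' \code{floor(fraction * p_view)} distinct feature indices uniformly
#' without replacement.
#'
#' @param view_dims integer vector of per-view feature counts.
#' @param fraction fraction of features per subset (default 0.8).
#' @param q number of subsets.
#' @param seed integer seed.
#' @return list of q lists of per-view sorted index vectors.
#' @export
feature_subsets <- function(view_dims, fraction = 0.8, q, seed = 1L) {
  if (any(floor(fraction * view_dims) < 1)) {
    stop("fraction too small: empty feature subset")
  }
  with_local_seed(seed, {
    lapply(seq_len(q), function(m)
      lapply(view_dims, function(p)
        sort(sample.int(p, floor(fraction * p)))))
  })
}

#' Permute one column of a matrix
#'
#' Row-shuffles column \code{k}; every other column is returned untouched.
#'
#' @param X matrix.
#' @param k column index.
#' @param seed seed for the permutation (ignored when \code{perm} given).
#' @param perm optional explicit permutation of the row indices.
#' @export
permute_column <- function(X, k, seed = 1L, perm = NULL) {
  if (k < 1 || k > ncol(X)) stop("column index out of range")
  if (is.null(perm)) perm <- with_local_seed(seed, sample.int(nrow(X)))
  X[, k] <- X[perm, k]
  X
}

#' Ranking configuration
#'
#' @param M number of bootstrap sample-index sets (and model fits).
#' @param q number of feature-index sets; defaults to M and must equal it
#'   (sets are paired 1:1 after a seeded shuffle).
#' @param feature_fraction fraction of each view's features per subset.
#' @param metric out-of-bag metric: "accuracy" (classification rate,
#'   default), "balanced_accuracy" or "weighted_f1".
#' @param top_fraction fraction of features selected per view (default 0.10).
#' @param top_r alternative: select exactly r features per view.
#' @param seed master seed for bootstraps, subsets, pairing and permutations.
#' @export
ranking_config <- function(M = 20L, q = NULL, feature_fraction = 0.8,
                           metric = c("accuracy", "balanced_accuracy",
                                      "weighted_f1"),
                           top_fraction = 0.10, top_r = NULL, seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(q)) q <- M
  if (q != M) stop("q must equal M: sample and feature sets are paired 1:1")
  stopifnot(M >= 1, feature_fraction > 0, feature_fraction <= 1)
  list(M = as.integer(M), q = as.integer(q),
       feature_fraction = feature_fraction, metric = metric,
       top_fraction = top_fraction, top_r = top_r, seed = as.integer(seed))
}

metric_value <- function(metric, y_true, y_pred) {
  switch(metric,
    accuracy = mean(y_pred == y_true),
    balanced_accuracy = {
      lev <- levels(droplevels(as.factor(y_true)))
      mean(vapply(lev, function(g)
        mean(y_pred[y_true == g] == g), numeric(1)))
    },
    weighted_f1 = classification_metrics(y_true, y_pred)$weighted_f1)
}

# forward pass resuming from a given first-layer pre-activation
nn_forward_from_first <- function(params, Z1) {
  spec <- params$spec
  act <- ACTIVATIONS[[spec$activation]]
  nlayers <- length(params$layers)
  linear_head <- function(m) (m == nlayers) && !spec$final_activation
  H <- if (linear_head(1)) Z1 else act$f(Z1)
  if (nlayers >= 2) for (m in 2:nlayers) {
    Z <- sweep(H %*% t(params$layers[[m]]$W), 2, params$layers[[m]]$b, `+`)
    H <- if (linear_head(m)) Z else act$f(Z)
  }
  H
}

#' Default trainer: multiview discriminant model + nearest centroid
#'
#' Builds the fit/metric interface consumed by
#' \code{\link{bibootstrap_rank}}. Permutation evaluations reuse the trained
#' model and update only the permuted feature's contribution to the first
#' network layer, so ranking large views stays affordable.
#'
#' @param config a \code{\link{train_config}} for the per-pair model fits.
#' @param spec_builder function(p, n) returning a \code{network_spec} for a
#'   view with p features given n training samples; NULL for the default
#'   architecture.
#' @param representation representation classified by the centroid rule
#'   ("pooled", "view" or "scores"; see \code{\link{ncc_classify}}).
#' @param view view index for \code{representation = "view"}.
#' @export
deep_ida_trainer <- function(config = train_config(epochs = 20L),
                             spec_builder = NULL,
                             representation = c("pooled", "view", "scores"),
                             view = 1L) {
  representation <- match.arg(representation)
  build_specs <- function(views, n) {
    if (is.null(spec_builder)) {
      od <- min(20L, n - 1L)
      lapply(views, function(X) network_spec(ncol(X), c(256L, 64L), od))
    } else lapply(views, function(X) spec_builder(ncol(X), n))
  }
  pick <- function(proj, gammas = NULL) switch(representation,
    pooled = proj$pooled,
    view = proj$H[[view]],
    scores = do.call(cbind, proj$scores))
  list(
    fit = function(views, labels) {
      model <- train_deep_ida(views, labels,
                              specs = build_specs(views, nrow(views[[1]])),
                              config = config)
      proj <- lapply(seq_along(views), function(d) model$train_H[[d]])
      tr <- list(H = proj, scores = lapply(seq_along(views), function(d)
        proj[[d]] %*% model$gamma$Gammas[[d]]),
        pooled = do.call(cbind, proj))
      model$centroids <- ncc_fit(pick(tr), labels)
      model
    },
    predict = function(model, views) {
      proj <- project_deep_ida(model, views)
      ncc_predict(model$centroids, pick(proj))$class
    },
    make_cache = function(model, views) {
      D <- length(views)
      Xs <- Z1 <- H <- vector("list", D)
      for (d in seq_len(D)) {
        Xs[[d]] <- standardize_apply(as.matrix(views[[d]]),
                                     model$centers[[d]], model$scales[[d]])
        W1 <- model$params[[d]]$layers[[1]]
        Z1[[d]] <- sweep(Xs[[d]] %*% t(W1$W), 2, W1$b, `+`)
        H[[d]] <- nn_forward_from_first(model$params[[d]], Z1[[d]])
      }
      list(Xs = Xs, Z1 = Z1, H = H)
    },
    metric_from_cache = function(model, cache, labels, metric) {
      proj <- list(H = cache$H,
                   scores = lapply(seq_along(cache$H), function(d)
                     cache$H[[d]] %*% model$gamma$Gammas[[d]]),
                   pooled = do.call(cbind, cache$H))
      pred <- ncc_predict(model$centroids, pick(proj))$class
      metric_value(metric, labels, pred)
    },
    permuted_metric = function(model, cache, labels, metric, d, k, perm) {
      xk <- cache$Xs[[d]][, k]
      w1k <- model$params[[d]]$layers[[1]]$W[, k]
      Z1p <- cache$Z1[[d]] + outer(xk[perm] - xk, w1k)
      Hd <- nn_forward_from_first(model$params[[d]], Z1p)
      H <- cache$H
      H[[d]] <- Hd
      proj <- list(H = H,
                   scores = lapply(seq_along(H), function(j)
                     H[[j]] %*% model$gamma$Gammas[[j]]),
                   pooled = do.call(cbind, H))
      pred <- ncc_predict(model$centroids, pick(proj))$class
      metric_value(metric, labels, pred)
    }
  )
}

#' Bi-bootstrap permutation feature ranking
#'
#' Runs the paired sample/feature bootstrap: for each pair, fits a fresh
#' model on the bootstrap subset, computes the baseline out-of-bag metric,
#' permutes every subset feature in the out-of-bag data one at a time
#' (model unchanged) and counts strict metric decreases. Ranks features per
#' view by occurrence proportion \code{n_k / N_k}, ties broken by ascending
#' feature index. Features never drawn (\code{N_k = 0}) are kept with
#' proportion 0 and flagged unevaluated. Pairs whose out-of-bag set is
#' empty are skipped (with a warning) and excluded from both counts.
#'
#' @param dataset a \code{multiview_dataset} (or list with \code{views} and
#'   \code{labels}).
#' @param trainer a trainer contract as built by
#'   \code{\link{deep_ida_trainer}}; any list with \code{fit} and
#'   \code{predict} works (the fast-path entries are optional).
#' @param config a \code{\link{ranking_config}}.
#' @param verbose print one line per pair.
#' @return \code{ranking_result}: per view a data.frame with feature, n_k,
#'   N_k, proportion, rank and the unevaluated flag, plus per-pair baseline
#'   metrics.
#' @export
bibootstrap_rank <- function(dataset, trainer = deep_ida_trainer(),
                             config = ranking_config(), verbose = FALSE) {
  views <- dataset$views
  labels <- droplevels(as.factor(dataset$labels))
  D <- length(views)
  dims <- vapply(views, ncol, 1L)
  M <- config$M
  Bs <- stratified_bootstrap_indices(labels, M, seed = config$seed)
  Vs <- feature_subsets(dims, config$feature_fraction, config$q,
                        seed = config$seed + 1L)
  pairing <- with_local_seed(config$seed + 2L, sample.int(M))
  nk <- lapply(dims, function(p) numeric(p))
  Nk <- lapply(dims, function(p) numeric(p))
  baselines <- rep(NA_real_, M)
  has_fast <- !is.null(trainer$make_cache) &&
    !is.null(trainer$permuted_metric) && !is.null(trainer$metric_from_cache)
  for (m in seq_len(M)) {
    B <- Bs[[m]]
    V <- Vs[[pairing[m]]]
    if (length(B$oob) == 0) {
      warning(sprintf("pair %d skipped: empty out-of-bag set", m))
      next
    }
    train_views <- lapply(seq_len(D), function(d)
      views[[d]][B$boot, V[[d]], drop = FALSE])
    oob_views <- lapply(seq_len(D), function(d)
      views[[d]][B$oob, V[[d]], drop = FALSE])
    y_tr <- labels[B$boot]
    y_oob <- droplevels(labels[B$oob])
    model <- trainer$fit(train_views, y_tr)
    n_oob <- length(B$oob)
    perm_seed <- config$seed + 7919L * m
    if (has_fast) {
      cache <- trainer$make_cache(model, oob_views)
      baseline <- trainer$metric_from_cache(model, cache, y_oob,
                                            config$metric)
      perms <- with_local_seed(perm_seed, {
        lapply(seq_len(D), function(d)
          lapply(seq_along(V[[d]]), function(i) sample.int(n_oob)))
      })
      for (d in seq_len(D)) {
        for (i in seq_along(V[[d]])) {
          val <- trainer$permuted_metric(model, cache, y_oob, config$metric,
                                         d, i, perms[[d]][[i]])
          k <- V[[d]][i]
          Nk[[d]][k] <- Nk[[d]][k] + 1
          if (val < baseline) nk[[d]][k] <- nk[[d]][k] + 1
        }
      }
    } else {
      pred <- trainer$predict(model, oob_views)
      baseline <- metric_value(config$metric, y_oob, pred)
      perms <- with_local_seed(perm_seed, {
        lapply(seq_len(D), function(d)
          lapply(seq_along(V[[d]]), function(i) sample.int(n_oob)))
      })
      for (d in seq_len(D)) {
        for (i in seq_along(V[[d]])) {
          pviews <- oob_views
          pviews[[d]] <- permute_column(pviews[[d]], i,
                                        perm = perms[[d]][[i]])
          val <- metric_value(config$metric, y_oob,
                              trainer$predict(model, pviews))
          k <- V[[d]][i]
          Nk[[d]][k] <- Nk[[d]][k] + 1
          if (val < baseline) nk[[d]][k] <- nk[[d]][k] + 1
        }
      }
    }
    baselines[m] <- baseline
    if (verbose) {
      message(sprintf("pair %2d/%d: oob n = %d, baseline %s = %.3f",
                      m, M, n_oob, config$metric, baseline))
    }
  }
  tables <- lapply(seq_len(D), function(d) {
    prop <- ifelse(Nk[[d]] > 0, nk[[d]] / pmax(Nk[[d]], 1), 0)
    ord <- order(-prop, seq_along(prop))
    rank <- integer(length(prop))
    rank[ord] <- seq_along(prop)
    data.frame(feature = seq_len(dims[d]),
               name = colnames(views[[d]]) %||% paste0("f", seq_len(dims[d])),
               n_k = nk[[d]], N_k = Nk[[d]], proportion = prop, rank = rank,
               unevaluated = Nk[[d]] == 0)
  })
  structure(list(views = tables, baselines = baselines, config = config),
            class = "ranking_result")
}

#' Select the top-ranked features per view
#'
#' @param ranking a \code{ranking_result}.
#' @param top_fraction fraction of each view's features (size
#'   \code{ceiling(fraction * p)}); ignored when \code{top_r} given.
#' @param top_r exact number of features per view.
#' @return list of per-view integer index vectors (rank order).
#' @export
select_top <- function(ranking, top_fraction = 0.10, top_r = NULL) {
  lapply(ranking$views, function(tb) {
    p <- nrow(tb)
    r <- if (!is.null(top_r)) top_r else ceiling(top_fraction * p)
    if (r > p) stop("top_r exceeds the number of features")
    tb$feature[order(tb$rank)][seq_len(r)]
  })
}

#' Feature-selection accuracy against a ground-truth mask
#'
#' @param selected integer vector of selected feature indices (one view).
#' @param truth_mask logical vector marking the true signal features.
#' @return list with \code{tpr} (signals captured), \code{fpr} (noise
#'   features selected) and \code{f1} of the selection.
#' @export
selection_metrics <- function(selected, truth_mask) {
  if (length(truth_mask) == 0 || !any(truth_mask)) stop("empty truth mask")
  signals <- which(truth_mask)
  noise <- which(!truth_mask)
  tp <- length(intersect(selected, signals))
  fp <- length(intersect(selected, noise))
  tpr <- tp / length(signals)
  fpr <- if (length(noise) > 0) fp / length(noise) else 0
  prec <- if (length(selected) > 0) tp / length(selected) else 0
  f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  list(tpr = tpr, fpr = fpr, f1 = f1)
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("ranking_result: %d views, %d pairs (%d evaluated), metric = %s\n",
              length(x$views), x$config$M, sum(!is.na(x$baselines)),
              x$config$metric))
  invisible(x)
}
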