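# Nearest-centroid classification on learned representations, and the
# classification metrics used to evaluate it.

#' Fit a nearest-centroid classifier
#'
#' @param scores n x q matrix of representations or discriminant scores.
#' @param labels length-n class labels, every class present.
#' @return \code{centroid_model} with one per-class mean row.
#' @export
ncc_fit <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts == 0)) stop("empty class")
  lev <- levels(labels)
  centroids <- t(vapply(lev, function(g)
    colMeans(scores[labels == g, , drop = FALSE]), numeric(ncol(scores))))
  rownames(centroids) <- lev
  structure(list(centroids = centroids, levels = lev, dim = ncol(scores)),
            class = "centroid_model")
}

#' Predict with a nearest-centroid classifier
#'
#' Assigns each row to the class with the closest centroid in Euclidean
#' distance. Exact ties go to the class earlier in sorted label order.
#'
#' @param model a \code{centroid_model}.
#' @param scores matrix with the training dimension.
#' @return list: \code{class} (factor of predictions) and
#'   \code{decision_values} (n x K matrix of negative distances, usable as
#'   per-class scores for ROC analysis).
#' @export
ncc_predict <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != model$dim) stop("dimension mismatch")
  C <- model$centroids
  # squared distances via ||x||^2 - 2 x.c + ||c||^2
  d2 <- outer(rowSums(scores^2), rowSums(C^2), `+`) - 2 * tcrossprod(scores, C)
  d2[d2 < 0] <- 0
  dec <- -sqrt(d2)
  colnames(dec) <- model$levels
  idx <- apply(dec, 1, which.max)    # ties -> lowest index = earlier level
  list(class = factor(model$levels[idx], levels = model$levels),
       decision_values = dec)
}

macro_auroc <- function(y_true, decision_values) {
  lev <- colnames(decision_values)
  y_true <- factor(y_true, levels = lev)
  if (length(lev) == 2) {
    r <- pROC::roc(response = y_true == lev[2],
                   predictor = decision_values[, 2],
                   quiet = TRUE, direction = "<")
    return(as.numeric(pROC::auc(r)))
  }
  aucs <- vapply(lev, function(g) {
    pos <- y_true == g
    if (all(pos) || !any(pos)) return(NA_real_)
    r <- pROC::roc(response = pos, predictor = decision_values[, g],
                   quiet = TRUE, direction = "<")
    as.numeric(pROC::auc(r))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Classification performance metrics
#'
#' Accuracy, balanced accuracy (mean per-class recall), one-vs-rest macro
#' AUROC (when decision values are supplied), and precision/recall/F1 in
#' both macro and support-weighted forms. For two classes the second level
#' in sorted order is treated as the positive class for the unweighted
#' precision/recall/F1.
#'
#' @param y_true,y_pred aligned label vectors; every predicted label must be
#'   a known true-label level.
#' @param decision_values optional n x K per-class score matrix (columns
#'   named by class) for the AUROC.
#' @return list of metrics, all in [0, 1] (AUROC NA when not computable).
#' @export
classification_metrics <- function(y_true, y_pred, decision_values = NULL) {
  y_true <- droplevels(as.factor(y_true))
  lev <- levels(y_true)
  if (!all(as.character(y_pred) %in% lev)) stop("y_pred contains unseen label")
  y_pred <- factor(as.character(y_pred), levels = lev)
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  K <- length(lev)
  cm <- table(true = y_true, pred = y_pred)
  support <- rowSums(cm)
  tp <- diag(cm)
  prec_k <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_k <- ifelse(support > 0, tp / support, 0)
  f1_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  w <- support / sum(support)
  auroc <- if (!is.null(decision_values))
    macro_auroc(y_true, decision_values) else NA_real_
  pos <- if (K == 2) 2L else NA_integer_
  list(
    accuracy = mean(y_pred == y_true),
    balanced_accuracy = mean(rec_k),
    auroc = auroc,
    precision = unname(if (K == 2) prec_k[pos] else mean(prec_k)),
    recall = unname(if (K == 2) rec_k[pos] else mean(rec_k)),
    f1 = unname(if (K == 2) f1_k[pos] else mean(f1_k)),
    weighted_precision = sum(w * prec_k),
    weighted_recall = sum(w * rec_k),
    weighted_f1 = sum(w * f1_k),
    confusion = cm
  )
}

#' Nearest-centroid classification through a fitted multiview model
#'
#' Convenience pipeline: project training and test views through the model,
#' fit centroids on the chosen representation and predict the test samples.
#'
#' @param model a \code{deep_ida_model}.
#' @param train_views,train_labels data the centroids are computed on.
#' @param test_views data to classify.
#' @param representation \code{"pooled"} (concatenated network outputs over
#'   views, default), \code{"view"} (a single view's outputs; set
#'   \code{view}), or \code{"scores"} (pooled discriminant scores
#'   \code{H_d Gamma_d}).
#' @param view view index when \code{representation = "view"}.
#' @return list with predictions, decision values and the centroid model.
#' @export
ncc_classify <- function(model, train_views, train_labels, test_views,
                         representation = c("pooled", "view", "scores"),
                         view = 1L) {
  representation <- match.arg(representation)
  tr <- project_deep_ida(model, train_views)
  te <- project_deep_ida(model, test_views)
  pick <- function(p) switch(representation,
    pooled = p$pooled,
    view = p$H[[view]],
    scores = do.call(cbind, p$scores))
  cm <- ncc_fit(pick(tr), train_labels)
  pred <- ncc_predict(cm, pick(te))
  c(pred, list(centroids = cm))
}
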