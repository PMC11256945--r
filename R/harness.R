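# Benchmark harness: Monte-Carlo classification and feature-ranking
# experiments on the built-in nonlinear simulation, at user-chosen scale.

svm_stacked_accuracy <- function(train_views, train_labels,
                                 test_views, test_labels) {
  Xtr <- do.call(cbind, train_views)
  Xte <- do.call(cbind, test_views)
  sf <- standardize_fit(Xtr)
  fit <- e1071::svm(standardize_apply(Xtr, sf$center, sf$scale),
                    as.factor(train_labels), kernel = "linear",
                    scale = FALSE)
  pred <- stats::predict(fit, standardize_apply(Xte, sf$center, sf$scale))
  mean(as.character(pred) == as.character(test_labels))
}

#' Monte-Carlo classification experiment
#'
#' For each replicate, generates independent training and test datasets
#' from the setting, fits the joint multiview model on both views, and
#' reports test accuracy for nearest-centroid classification from (i) the
#' view-1 representations, (ii) the pooled representations of both views,
#' and (iii) a linear-kernel SVM on the stacked raw views.
#'
#' @param setting a \code{\link{sim_setting}} or preset name.
#' @param n_reps number of replicates.
#' @param seed base seed; replicate r derives its data and training seeds
#'   from it.
#' @param config a \code{\link{train_config}} for the model fits.
#' @param specs optional list of per-view \code{network_spec}s.
#' @param methods subset of \code{c("deepida_view1", "deepida_pooled",
#'   "svm_stacked")}.
#' @return list with \code{per_rep} (data.frame of per-replicate
#'   accuracies) and \code{summary} (mean and sd per method).
#' @export
run_classification_experiment <- function(setting = sim_setting("S1"),
                                          n_reps = 5L, seed = 1L,
                                          config = train_config(
                                            epochs = 60L,
                                            learning_rate = 1e-2,
                                            ridge = 1, weight_decay = 1e-2),
                                          specs = NULL,
                                          methods = c("deepida_view1",
                                                      "deepida_pooled",
                                                      "svm_stacked")) {
  if (is.character(setting)) setting <- sim_setting(setting)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    train <- generate_nonlinear(setting, seed = seed + 100L * r + 1L)
    test <- generate_nonlinear(setting, seed = seed + 100L * r + 3L)
    out <- list(rep = r)
    need_model <- any(c("deepida_view1", "deepida_pooled") %in% methods)
    if (need_model) {
      cfg <- config
      cfg$seed <- seed + 17L * r
      specs_r <- specs
      if (is.null(specs_r)) {
        specs_r <- lapply(train$views, function(X)
          network_spec(ncol(X), c(256L, 64L),
                       min(10L, nrow(X) - 1L)))
      }
      model <- train_deep_ida(train$views, train$labels, specs = specs_r,
                              config = cfg)
      if ("deepida_view1" %in% methods) {
        res <- ncc_classify(model, train$views, train$labels, test$views,
                            representation = "view", view = 1L)
        out$deepida_view1 <- mean(res$class == test$labels)
      }
      if ("deepida_pooled" %in% methods) {
        res <- ncc_classify(model, train$views, train$labels, test$views,
                            representation = "pooled")
        out$deepida_pooled <- mean(res$class == test$labels)
      }
    }
    if ("svm_stacked" %in% methods) {
      out$svm_stacked <- svm_stacked_accuracy(train$views, train$labels,
                                              test$views, test$labels)
    }
    rows[[r]] <- as.data.frame(out)
  }
  per_rep <- do.call(rbind, rows)
  cols <- setdiff(names(per_rep), "rep")
  summary <- data.frame(method = cols,
                        mean = vapply(cols, function(c) mean(per_rep[[c]]), 1),
                        sd = vapply(cols, function(c) stats::sd(per_rep[[c]]), 1))
  list(per_rep = per_rep, summary = summary)
}

#' Monte-Carlo feature-ranking experiment
#'
#' For each replicate, generates a dataset from the setting, runs the
#' bi-bootstrap ranking, selects the top fraction per view and scores the
#' view-1 selection against the known signal mask.
#'
#' @param setting a \code{\link{sim_setting}} or preset name.
#' @param n_reps number of replicates.
#' @param seed base seed.
#' @param ranking_cfg a \code{\link{ranking_config}} (its seed is
#'   re-derived per replicate).
#' @param trainer_cfg a \code{\link{train_config}} for the per-pair fits.
#' @param spec_builder optional function(p, n) -> \code{network_spec}.
#' @return list with \code{per_rep} (TPR/FPR/F1 per replicate) and
#'   \code{summary}.
#' @export
run_ranking_experiment <- function(setting = sim_setting("S1"),
                                   n_reps = 5L, seed = 1L,
                                   ranking_cfg = ranking_config(M = 20L),
                                   trainer_cfg = train_config(
                                     epochs = 30L, learning_rate = 1e-2,
                                     standardize = FALSE),
                                   spec_builder = NULL) {
  if (is.character(setting)) setting <- sim_setting(setting)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    data <- generate_nonlinear(setting, seed = seed + 100L * r + 1L)
    cfg <- ranking_cfg
    cfg$seed <- seed + 31L * r
    tcfg <- trainer_cfg
    tcfg$seed <- seed + 53L * r
    sb <- spec_builder
    if (is.null(sb)) {
      sb <- function(p, n) network_spec(p, c(256L, 64L), min(20L, n - 1L))
    }
    ranking <- bibootstrap_rank(
      data, deep_ida_trainer(config = tcfg, spec_builder = sb),
      config = cfg)
    sel <- select_top(ranking, top_fraction = cfg$top_fraction,
                      top_r = cfg$top_r)
    sm <- selection_metrics(sel[[1]], data$signal_masks[[1]])
    rows[[r]] <- data.frame(rep = r, tpr = sm$tpr, fpr = sm$fpr, f1 = sm$f1)
  }
  per_rep <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("tpr", "fpr", "f1"),
    mean = vapply(c("tpr", "fpr", "f1"), function(c) mean(per_rep[[c]]), 1),
    sd = vapply(c("tpr", "fpr", "f1"), function(c) stats::sd(per_rep[[c]]), 1))
  list(per_rep = per_rep, summary = summary)
}

fmt_mean_sd <- function(m, s) sprintf("%.2f(%.2f)", m, ifelse(is.na(s), 0, s))

#' Reproduce the simulation benchmark tables at reduced scale
#'
#' \code{table = 1} runs the feature-selection experiment (TPR/FPR/F1 of the
#' bi-bootstrap selection); \code{table = 2} runs the classification
#' experiment (view-1 model, both-view model, stacked-view SVM). Output is
#' formatted as "mean(sd)" strings.
#'
#' @param table 1 or 2.
#' @param setting preset name.
#' @param n_reps replicates.
#' @param seed base seed.
#' @param ... forwarded to the underlying experiment.
#' @export
reproduce_table <- function(table = 1L, setting = "S1", n_reps = 5L,
                            seed = 1L, ...) {
  if (table == 1) {
    res <- run_ranking_experiment(setting, n_reps = n_reps, seed = seed, ...)
    s <- res$summary
    out <- data.frame(setting = setting,
                      method = "bi-bootstrap ranking",
                      TPR = fmt_mean_sd(s$mean[1], s$sd[1]),
                      FPR = fmt_mean_sd(s$mean[2], s$sd[2]),
                      F1 = fmt_mean_sd(s$mean[3], s$sd[3]))
  } else if (table == 2) {
    res <- run_classification_experiment(setting, n_reps = n_reps,
                                         seed = seed, ...)
    s <- res$summary
    out <- data.frame(setting = setting, method = s$method,
                      accuracy = fmt_mean_sd(s$mean, s$sd))
  } else stop("table must be 1 or 2")
  attr(out, "per_rep") <- res$per_rep
  out
}
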