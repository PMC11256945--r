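# Plain-CSV dataset exchange. Views are samples x features with a header
# row of feature names and a leading sample-ID column; labels are a two-
# column CSV (sample_id, label). A JSON manifest records provenance so any
# run can be replayed.

#' Write a multiview dataset to CSV files
#'
#' Writes one CSV per view (\code{view<d>.csv}), \code{labels.csv},
#' per-view signal masks when present (\code{mask_view<d>.csv}) and a
#' \code{manifest.json} with the provenance (setting, seed, dimensions).
#'
#' @param dataset a \code{multiview_dataset}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_multiview_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(dataset$views[[1]])
  ids <- sprintf("s%04d", seq_len(n))
  for (d in seq_along(dataset$views)) {
    df <- data.frame(sample_id = ids, dataset$views[[d]],
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("view%d.csv", d)),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(sample_id = ids,
                              label = as.character(dataset$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(dataset$signal_masks)) {
    for (d in seq_along(dataset$signal_masks)) {
      utils::write.csv(
        data.frame(feature = seq_along(dataset$signal_masks[[d]]),
                   signal = dataset$signal_masks[[d]]),
        file.path(dir, sprintf("mask_view%d.csv", d)), row.names = FALSE)
    }
  }
  manifest <- list(package = "deepIDA",
                   version = as.character(utils::packageVersion("deepIDA")),
                   n = n, views = length(dataset$views),
                   dims = vapply(dataset$views, ncol, 1L),
                   provenance = dataset$provenance[
                     setdiff(names(dataset$provenance), "permutation")])
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a multiview dataset from CSV files
#'
#' Views must share the same samples in the same order; the sample-ID
#' column is checked across files and a mismatch is reported with the
#' offending file name.
#'
#' @param view_paths character vector of view CSV paths.
#' @param labels_path labels CSV path (columns sample_id, label).
#' @export
read_multiview_csv <- function(view_paths, labels_path) {
  read_one <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    X <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(X) <- "double"
    list(ids = ids, X = X)
  }
  views <- lapply(view_paths, read_one)
  lab <- utils::read.csv(labels_path, check.names = FALSE)
  ids <- as.character(lab[[1]])
  for (d in seq_along(views)) {
    if (!identical(views[[d]]$ids, ids)) {
      stop(sprintf("sample IDs in '%s' do not align with '%s'",
                   view_paths[d], labels_path))
    }
  }
  structure(list(views = lapply(views, `[[`, "X"),
                 labels = factor(as.character(lab[[2]])),
                 signal_masks = NULL,
                 provenance = list(setting = "file",
                                   files = c(view_paths, labels_path)),
                 intermediates = NULL),
            class = "multiview_dataset")
}

#' Stratified train/test split indices
#'
#' @param labels class labels.
#' @param train_fraction fraction per class assigned to training
#'   (default 0.6).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} index vectors.
#' @export
stratified_split <- function(labels, train_fraction = 0.6, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  strata <- split(seq_along(labels), labels)
  with_local_seed(seed, {
    train <- unlist(lapply(strata, function(idx)
      sample(idx, max(1, round(train_fraction * length(idx))))),
      use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(seq_along(labels), train)))
  })
}

#' Write a per-view ranking table to CSV
#'
#' @param ranking a \code{ranking_result}.
#' @param dir output directory.
#' @export
write_ranking_csv <- function(ranking, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ranking$views))
  for (d in seq_along(ranking$views)) {
    paths[d] <- file.path(dir, sprintf("ranking_view%d.csv", d))
    utils::write.csv(ranking$views[[d]], paths[d], row.names = FALSE)
  }
  invisible(paths)
}
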