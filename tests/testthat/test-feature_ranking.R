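test_that("stratified bootstraps preserve class counts exactly", {
  y <- factor(rep(c("a", "b"), each = 5))
  sets <- stratified_bootstrap_indices(y, M = 25, seed = 3)
  for (s in sets) {
    expect_length(s$boot, 10)
    expect_equal(as.vector(table(y[s$boot])), c(5L, 5L))
    expect_true(all(s$oob %in% setdiff(1:10, s$boot)))
  }
  expect_identical(sets, stratified_bootstrap_indices(y, M = 25, seed = 3))
  expect_warning(stratified_bootstrap_indices(factor(c("a", "b", "b")), 2, 1),
                 "single sample")
})

test_that("out-of-bag fraction matches bootstrap theory", {
  y <- factor(rep(c("a", "b"), each = 30))
  sets <- stratified_bootstrap_indices(y, M = 300, seed = 11)
  oob_frac <- mean(vapply(sets, function(s) length(s$oob) / 60, 1))
  expect_lt(abs(oob_frac - (1 - 1 / 30)^30), 0.02)
})

test_that("feature subsets have the contracted size and uniform coverage", {
  subs <- feature_subsets(c(10L, 25L), fraction = 0.8, q = 200, seed = 2)
  expect_true(all(vapply(subs, function(v) length(v[[1]]), 1L) == 8))
  expect_true(all(vapply(subs, function(v) length(v[[2]]), 1L) == 20))
  expect_true(all(vapply(subs, function(v) anyDuplicated(v[[1]]) == 0, TRUE)))
  freq <- rowMeans(vapply(subs, function(v) 1:10 %in% v[[1]], logical(10)))
  expect_true(all(abs(freq - 0.8) < 0.12))
  full <- feature_subsets(c(5L), fraction = 1.0, q = 3, seed = 1)
  expect_true(all(vapply(full, function(v) identical(v[[1]], 1:5), TRUE)))
  expect_identical(subs, feature_subsets(c(10L, 25L), 0.8, 200, seed = 2))
})

test_that("column permutation preserves everything but row order of one column", {
  set.seed(6)
  X <- matrix(rnorm(40), 10)
  Xp <- permute_column(X, 2, seed = 9)
  expect_equal(Xp[, -2], X[, -2])
  expect_equal(sort(Xp[, 2]), sort(X[, 2]))
  expect_equal(sum(Xp[, 2]), sum(X[, 2]))
  Xc <- X; Xc[, 3] <- 7
  expect_equal(permute_column(Xc, 3, seed = 1), Xc)
  expect_equal(permute_column(X[1, , drop = FALSE], 1, seed = 1),
               X[1, , drop = FALSE])
  expect_error(permute_column(X, 5), "out of range")
})

# trainer whose metric drops iff view-1 feature 1 is permuted: view-1
# feature 1 stores an index that decodes to the true label
make_mock_trainer <- function() {
  list(
    fit = function(views, labels) {
      list(key = "parity")
    },
    predict = function(model, views) {
      code <- round(views[[1]][, 1])
      factor(ifelse(code %% 2 == 0, "even", "odd"),
             levels = c("even", "odd"))
    }
  )
}

test_that("a mocked model pins the occurrence proportion on the causal feature", {
  n <- 40
  set.seed(21)
  v1 <- cbind(seq_len(n), matrix(rnorm(n * 4), n))
  v2 <- matrix(rnorm(n * 3), n)
  colnames(v1) <- paste0("v1_f", 1:5)
  colnames(v2) <- paste0("v2_f", 1:3)
  labels <- factor(ifelse(seq_len(n) %% 2 == 0, "even", "odd"))
  ds <- structure(list(views = list(v1, v2), labels = labels),
                  class = "multiview_dataset")
  rk <- bibootstrap_rank(ds, make_mock_trainer(),
                         config = ranking_config(M = 8, feature_fraction = 1.0,
                                                 seed = 5))
  expect_equal(rk$views[[1]]$proportion[1], 1.0)
  expect_true(all(rk$views[[1]]$proportion[-1] == 0))
  expect_true(all(rk$views[[2]]$proportion == 0))
  expect_equal(rk$views[[1]]$rank[1], 1L)
  # counts conservation: every evaluated pair contributes |V_d| to sum(N_k)
  expect_equal(sum(rk$views[[1]]$N_k), 8 * 5)
  expect_equal(sum(rk$views[[2]]$N_k), 8 * 3)
  expect_true(all(rk$baselines == 1))
})

test_that("ranking is reproducible and flags never-drawn features", {
  n <- 30
  set.seed(2)
  ds <- structure(list(
    views = list(matrix(rnorm(n * 6), n), matrix(rnorm(n * 4), n)),
    labels = factor(rep(c("a", "b"), length.out = n))),
    class = "multiview_dataset")
  trainer <- make_mock_trainer()
  trainer$predict <- function(model, views)
    factor(rep(c("a", "b"), length.out = nrow(views[[1]])),
           levels = c("a", "b"))
  cfg <- ranking_config(M = 4, feature_fraction = 0.5, seed = 7)
  rk1 <- bibootstrap_rank(ds, trainer, config = cfg)
  rk2 <- bibootstrap_rank(ds, trainer, config = cfg)
  expect_identical(rk1$views, rk2$views)
  # with 0.5 * 6 = 3 of 6 features per subset some may never be drawn
  expect_true(all(rk1$views[[1]]$unevaluated == (rk1$views[[1]]$N_k == 0)))
  expect_true(all(rk1$views[[1]]$proportion[rk1$views[[1]]$N_k == 0] == 0))
  expect_true(all(rk1$views[[1]]$n_k <= rk1$views[[1]]$N_k))
})

test_that("top selection respects size, fraction and index tie-breaks", {
  tb1 <- data.frame(feature = 1:10, name = letters[1:10], n_k = 0, N_k = 4,
                    proportion = rep(0.5, 10), rank = 1:10,
                    unevaluated = FALSE)
  rk <- structure(list(views = list(tb1)), class = "ranking_result")
  expect_equal(select_top(rk, top_fraction = 1.0)[[1]], 1:10)
  expect_equal(select_top(rk, top_r = 3)[[1]], 1:3)  # equal props -> by index
  expect_error(select_top(rk, top_r = 11), "exceeds")
  tb2 <- tb1
  tb2$proportion <- c(0.1, 0.9, 0.5, 0.5, 0, 0, 0, 0, 0, 0)
  tb2$rank <- c(5L, 1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L, 10L)
  rk2 <- structure(list(views = list(tb2)), class = "ranking_result")
  expect_equal(select_top(rk2, top_r = 3)[[1]], c(2L, 3L, 4L))
  expect_equal(select_top(rk2, top_fraction = 0.1)[[1]], 2L)
})

test_that("ranking orders by proportion with ascending-index tie-break", {
  # via the real pipeline: build a result from known counts
  n <- 20
  ds <- structure(list(
    views = list(cbind(seq_len(n), seq_len(n)),
                 matrix(rnorm(n * 2), n)),
    labels = factor(ifelse(seq_len(n) %% 2 == 0, "even", "odd"))),
    class = "multiview_dataset")
  colnames(ds$views[[1]]) <- c("a", "b")
  rk <- bibootstrap_rank(ds, make_mock_trainer(),
                         config = ranking_config(M = 6, feature_fraction = 1.0,
                                                 seed = 2))
  # both columns encode the index; only column 1 is read by the mock, so
  # column 1 outranks column 2
  expect_lt(rk$views[[1]]$rank[1], rk$views[[1]]$rank[2])
})

test_that("selection metrics reproduce the arithmetic example", {
  mask <- c(rep(TRUE, 50), rep(FALSE, 450))
  exact <- selection_metrics(1:50, mask)
  expect_equal(exact$tpr, 1); expect_equal(exact$fpr, 0); expect_equal(exact$f1, 1)
  all_sel <- selection_metrics(1:500, mask)
  expect_equal(all_sel$tpr, 1); expect_equal(all_sel$fpr, 1)
  mixed <- selection_metrics(c(1:40, 51:60), mask)
  expect_equal(mixed$tpr, 0.80)
  expect_equal(mixed$fpr, 10 / 450, tolerance = 1e-12)
  expect_equal(mixed$f1, 0.80)
  expect_error(selection_metrics(1:3, logical(0)), "empty truth mask")
})

test_that("select_top at 10 percent of 500 features returns 50", {
  tb <- data.frame(feature = 1:500, name = paste0("f", 1:500), n_k = 0,
                   N_k = 1, proportion = runif(500), rank = NA,
                   unevaluated = FALSE)
  tb$rank <- integer(500)
  tb$rank[order(-tb$proportion, tb$feature)] <- 1:500
  rk <- structure(list(views = list(tb)), class = "ranking_result")
  expect_length(select_top(rk, top_fraction = 0.10)[[1]], 50)
})
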