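test_that("analytic loss gradients match finite differences", {
  hx <- make_two_view_H(n = 12, o1 = 3, o2 = 2, seed = 42)
  lo <- deep_ida_loss(hx$Hs, hx$labels, rho = 0.5, ridge = 1e-3,
                      gamma_seed = 5)
  G <- lo$gamma$Gammas
  frozen <- deep_ida_loss(hx$Hs, hx$labels, rho = 0.5, ridge = 1e-3,
                          gamma_init = G, gamma_frozen = TRUE)
  ev <- function(Hs) deep_ida_loss(Hs, hx$labels, rho = 0.5, ridge = 1e-3,
                                   gamma_init = G, gamma_frozen = TRUE,
                                   grad = FALSE)$value
  eps <- 1e-6
  cases <- list(c(1, 1, 1), c(1, 5, 2), c(1, 12, 3), c(2, 3, 1), c(2, 7, 2))
  for (cs in cases) {
    d <- cs[1]; i <- cs[2]; j <- cs[3]
    Hp <- hx$Hs; Hp[[d]][i, j] <- Hp[[d]][i, j] + eps
    Hm <- hx$Hs; Hm[[d]][i, j] <- Hm[[d]][i, j] - eps
    fd <- (ev(Hp) - ev(Hm)) / (2 * eps)
    expect_lt(abs(fd - frozen$grads[[d]][i, j]) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("end-to-end weight gradients match finite differences", {
  toy <- generate_linear_toy(n_per_class = 10, p = 4, gap = 4, seed = 3)
  specs <- lapply(toy$views, function(X) network_spec(ncol(X), c(6L), 3L))
  params <- lapply(1:2, function(d) init_params(specs[[d]], seed = d))
  Xs <- toy$views
  fwd <- lapply(1:2, function(d) nn_forward(params[[d]], Xs[[d]], cache = TRUE))
  lo <- deep_ida_loss(lapply(fwd, `[[`, "H"), toy$labels, ridge = 1e-3,
                      gamma_seed = 2)
  G <- lo$gamma$Gammas
  frozen <- deep_ida_loss(lapply(fwd, `[[`, "H"), toy$labels, ridge = 1e-3,
                          gamma_init = G, gamma_frozen = TRUE)
  bk <- lapply(1:2, function(d)
    nn_backward(params[[d]], Xs[[d]], fwd[[d]], frozen$grads[[d]]))
  ev <- function(params) {
    H <- lapply(1:2, function(d) nn_forward(params[[d]], Xs[[d]]))
    deep_ida_loss(H, toy$labels, ridge = 1e-3, gamma_init = G,
                  gamma_frozen = TRUE, grad = FALSE)$value
  }
  eps <- 1e-6
  for (cs in list(c(1, 1, 3, 2), c(1, 2, 2, 5), c(2, 1, 1, 1), c(2, 2, 3, 6))) {
    d <- cs[1]; m <- cs[2]; i <- cs[3]; j <- cs[4]
    pp <- params; pp[[d]]$layers[[m]]$W[i, j] <- pp[[d]]$layers[[m]]$W[i, j] + eps
    pm <- params; pm[[d]]$layers[[m]]$W[i, j] <- pm[[d]]$layers[[m]]$W[i, j] - eps
    fd <- (ev(pp) - ev(pm)) / (2 * eps)
    expect_lt(abs(fd - bk[[d]]$layers[[m]]$W[i, j]) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("the decoupled loss ignores the other view", {
  hx <- make_two_view_H(n = 14, o1 = 3, o2 = 3, seed = 8)
  lo <- deep_ida_loss(hx$Hs, hx$labels, rho = 1, ridge = 1e-4)
  # equals the negative sum of leading eigenvalues of M_d / D
  covs <- covariance_set(hx$Hs, hx$labels)
  direct <- 0
  for (d in 1:2) {
    Tm <- inv_sqrt_psd(covs$views[[d]]$St, 1e-4)
    M <- Tm %*% covs$views[[d]]$Sb %*% Tm
    direct <- direct - eigen((M + t(M)) / 4, symmetric = TRUE)$values[1]
  }
  expect_equal(lo$value, direct, tolerance = 1e-10)
  # perturbing view 2 leaves view 1's eigenvalue sum unchanged
  Hs2 <- hx$Hs
  Hs2[[2]] <- Hs2[[2]] + matrix(rnorm(length(Hs2[[2]])), nrow(Hs2[[2]]))
  lo2 <- deep_ida_loss(Hs2, hx$labels, rho = 1, ridge = 1e-4)
  expect_equal(lo$eigen_sums[1], lo2$eigen_sums[1], tolerance = 1e-12)
})

test_that("eigenvalue sums equal the trace identity at the solved projections", {
  hx <- make_two_view_H(n = 20, o1 = 3, o2 = 2, seed = 15)
  lo <- deep_ida_loss(hx$Hs, hx$labels, rho = 0.5, ridge = 1e-4)
  covs <- covariance_set(hx$Hs, hx$labels)
  sys <- build_system(covs, rho = 0.5, l = 1, ridge = 1e-4)
  for (d in 1:2) {
    G <- sys$c1 * sys$M[[d]]
    j <- setdiff(1:2, d)
    NP <- sys$N[[d]][[j]] %*% lo$gamma$Gammas[[j]]
    G <- G + sys$c2 * tcrossprod(NP)
    U <- eigen((G + t(G)) / 2, symmetric = TRUE)$vectors[, 1, drop = FALSE]
    expect_equal(lo$eigen_sums[d],
                 sum(diag(crossprod(U, G %*% U))), tolerance = 1e-8)
  }
})

test_that("the loss is invariant to joint sample permutation and per-view scaling", {
  hx <- make_two_view_H(n = 16, o1 = 3, o2 = 2, seed = 30)
  base <- deep_ida_loss(hx$Hs, hx$labels, rho = 0.5, ridge = 1e-6,
                        grad = FALSE)$value
  set.seed(1)
  perm <- sample(16)
  permed <- deep_ida_loss(lapply(hx$Hs, function(H) H[perm, ]),
                          hx$labels[perm], rho = 0.5, ridge = 1e-6,
                          grad = FALSE)$value
  expect_equal(base, permed, tolerance = 1e-8)
  # at rho = 1 whitening removes a positive per-view scale (relative ridge)
  r1 <- deep_ida_loss(hx$Hs, hx$labels, rho = 1, grad = FALSE)$value
  scaled <- hx$Hs
  scaled[[1]] <- 3.7 * scaled[[1]]
  r2 <- deep_ida_loss(scaled, hx$labels, rho = 1, grad = FALSE)$value
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("loss rejects invalid batches", {
  hx <- make_two_view_H(n = 10, o1 = 2, o2 = 2, seed = 2)
  expect_error(deep_ida_loss(hx$Hs, factor(rep("a", 10))), "two classes")
  wide <- list(matrix(rnorm(50), 5), matrix(rnorm(10), 5))
  expect_error(deep_ida_loss(wide, factor(rep(c("a", "b"), length.out = 5))),
               "smaller than the sample size")
})

test_that("training is reproducible and separates the toy fixture", {
  toy <- generate_linear_toy(n_per_class = 15, p = 5, gap = 10, seed = 4)
  specs <- lapply(toy$views, function(X) network_spec(ncol(X), c(8L), 4L))
  cfg <- train_config(epochs = 15, learning_rate = 1e-2, seed = 9)
  m1 <- train_deep_ida(toy$views, toy$labels, specs = specs, config = cfg)
  m2 <- train_deep_ida(toy$views, toy$labels, specs = specs, config = cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_length(m1$loss_trace, 15)
  res <- ncc_classify(m1, toy$views, toy$labels, toy$views)
  expect_equal(mean(res$class == toy$labels), 1.0)
  # loss broadly decreases over training on a separable fixture
  expect_lt(tail(m1$loss_trace, 1), m1$loss_trace[1])
})

test_that("training loss flattens within the epoch budget on spiral data", {
  # small-scale version of the nonlinear simulation; relative change over
  # the last ten epochs should be below 1%
  data <- generate_nonlinear(sim_setting("S1", n1 = 120L, n2 = 90L,
                                         p1 = 120L, p2 = 120L), seed = 5)
  specs <- lapply(data$views, function(X) network_spec(ncol(X), c(64L, 32L), 10L))
  m <- train_deep_ida(data$views, data$labels, specs = specs,
                      config = train_config(epochs = 50,
                                            learning_rate = 1e-2, seed = 3))
  tr <- m$loss_trace
  late <- abs((tr[50] - tr[40]) / tr[40])
  expect_lt(late, 0.01)
})

test_that("projection returns consistent shapes and training representations", {
  toy <- generate_linear_toy(n_per_class = 12, p = 4, gap = 5, seed = 6)
  specs <- lapply(toy$views, function(X) network_spec(ncol(X), c(6L), 3L))
  m <- train_deep_ida(toy$views, toy$labels, specs = specs,
                      config = train_config(epochs = 5, seed = 2))
  pr <- project_deep_ida(m, toy$views)
  expect_equal(pr$H, m$train_H, tolerance = 1e-12)
  expect_true(all(vapply(pr$scores, ncol, 1L) == m$gamma$l))
  expect_equal(ncol(pr$pooled), 6)
  # score covariance equals Gamma' cov(H) Gamma (orthonormal projection)
  C <- stats::cov(pr$H[[1]])
  expect_equal(stats::cov(pr$scores[[1]]),
               crossprod(m$gamma$Gammas[[1]], C %*% m$gamma$Gammas[[1]]),
               tolerance = 1e-10)
  expect_error(project_deep_ida(m, list(toy$views[[1]])), "expected")
})
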