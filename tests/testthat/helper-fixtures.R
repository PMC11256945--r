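# Shared fixtures, all generated in code.

make_two_view_H <- function(n = 12, o1 = 3, o2 = 2, seed = 42,
                            classes = 2) {
  set.seed(seed)
  list(Hs = list(matrix(rnorm(n * o1), n), matrix(rnorm(n * o2), n)),
       labels = factor(rep(seq_len(classes), length.out = n)))
}

# random SPD-derived whitened system for solver tests
make_system <- function(n = 40, o1 = 2, o2 = 2, rho = 0.5, seed = 1,
                        l = 1L) {
  set.seed(seed)
  H1 <- matrix(rnorm(n * o1), n)
  H2 <- matrix(rnorm(n * o2), n)
  y <- factor(rep(c("a", "b"), each = n / 2))
  # give classes some separation so Sb is nontrivial
  H1[y == "a", 1] <- H1[y == "a", 1] + 1.5
  H2[y == "a", 2] <- H2[y == "a", 2] + 1.0
  covs <- covariance_set(list(H1, H2), y)
  build_system(covs, rho = rho, l = l, ridge = 1e-6)
}

# exhaustive maximization of the D=2, l=1 objective over unit vectors
grid_max_objective <- function(system, step = 0.004) {
  th <- seq(0, pi, by = step)
  U <- rbind(cos(th), sin(th))              # 2 x m unit vectors
  q1 <- colSums(U * (system$M[[1]] %*% U))  # gamma' M1 gamma
  q2 <- colSums(U * (system$M[[2]] %*% U))
  B <- t(U) %*% system$N[[1]][[2]] %*% U    # m x m of gamma1' N12 gamma2
  obj <- system$c1 * outer(q1, q2, `+`) + system$c2 * B^2
  max(obj)
}

expect_close <- function(x, y, tol) testthat::expect_lt(abs(x - y), tol)
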