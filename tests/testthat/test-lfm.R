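test_that("factor initialization is deterministic, seeded and scale-bounded", {
  cfg <- lfm_config(n_factors = 4, seed = 9, init_scale = 0.1)
  f1 <- init_factors(5, 7, cfg)
  f2 <- init_factors(5, 7, cfg)
  expect_identical(f1, f2)
  expect_false(identical(f1, init_factors(5, 7, lfm_config(n_factors = 4, seed = 10))))
  expect_true(all(f1$dlf > 0 & f1$dlf < 0.1 / sqrt(4)))
  f0 <- init_factors(3, 3, lfm_config(n_factors = 1, init_scale = 0))
  expect_true(all(f0$dlf == 0) && all(f0$mlf == 0))
})

test_that("cell prediction is the latent inner product", {
  factors <- list(dlf = rbind(c(0.5, 1)), mlf = rbind(c(1, 0.5)))
  expect_equal(predict_cell(factors, 1, 1), 1.0)
  factors$mlf <- rbind(c(0, 0))
  expect_equal(predict_cell(factors, 1, 1), 0)
  set.seed(3)
  f <- list(dlf = matrix(rnorm(10), 2, 5), mlf = matrix(rnorm(15), 3, 5))
  manual <- 0
  for (k in 1:5) manual <- manual + f$dlf[2, k] * f$mlf[3, k]
  expect_equal(predict_cell(f, 2, 3), manual)
})

test_that("training cost matches a literal summation oracle", {
  set.seed(4)
  V <- matrix(runif(12), 4, 3)
  f <- list(dlf = matrix(rnorm(6), 3, 2), mlf = matrix(rnorm(8), 4, 2))
  expect_equal(lfm_cost(V, f, 0.1), oracle_cost(V, f, 0.1))
  # perfect factors, no regularization: zero cost
  fp <- list(dlf = matrix(runif(6), 3, 2), mlf = matrix(runif(8), 4, 2))
  Vp <- fp$mlf %*% t(fp$dlf)
  expect_equal(lfm_cost(Vp, fp, 0), 0)
  # zero factors: each 1-cell contributes 1
  V01 <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  fz <- list(dlf = matrix(0, 3, 2), mlf = matrix(0, 2, 2))
  expect_equal(lfm_cost(V01, fz, 0), 3)
})

test_that("per-cell gradients match direct substitution and finite differences", {
  f <- list(dlf = rbind(c(0.3, 0.3)), mlf = rbind(c(1, 0)))
  V <- matrix(f$dlf %*% t(f$mlf), 1, 1)
  g0 <- cell_gradients(V, f, 1, 1, 0)
  expect_equal(g0$d_dlf, c(0, 0))
  expect_equal(g0$d_mlf, c(0, 0))

  # residual forced to 1 with mlf row (1, 0)
  V1 <- V + 1
  g1 <- cell_gradients(V1, f, 1, 1, 0)
  expect_equal(g1$d_dlf, c(-2, 0))

  # central finite differences of the per-cell loss
  set.seed(8)
  V <- matrix(runif(6), 3, 2)
  f <- list(dlf = matrix(rnorm(4), 2, 2), mlf = matrix(rnorm(6), 3, 2))
  lam <- 0.2; d <- 2L; m <- 3L; h <- 1e-6
  cell_loss <- function(fac) {
    err <- V[m, d] - sum(fac$dlf[d, ] * fac$mlf[m, ])
    err^2 + lam / 2 * (sum(fac$dlf[d, ]^2) + sum(fac$mlf[m, ]^2))
  }
  g <- cell_gradients(V, f, d, m, lam)
  for (k in 1:2) {
    fp <- f; fp$dlf[d, k] <- fp$dlf[d, k] + h
    fm <- f; fm$dlf[d, k] <- fm$dlf[d, k] - h
    expect_equal(g$d_dlf[k], (cell_loss(fp) - cell_loss(fm)) / (2 * h),
                 tolerance = 1e-5)
    fp <- f; fp$mlf[m, k] <- fp$mlf[m, k] + h
    fm <- f; fm$mlf[m, k] <- fm$mlf[m, k] - h
    expect_equal(g$d_mlf[k], (cell_loss(fp) - cell_loss(fm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("full-batch gradient of the cost matches finite differences", {
  for (seed in 1:3) {
    set.seed(seed)
    nm <- sample(3:6, 1); nd <- sample(3:6, 1); nf <- 2
    V <- matrix(runif(nm * nd), nm, nd)
    f <- list(dlf = matrix(rnorm(nd * nf), nd, nf),
              mlf = matrix(rnorm(nm * nf), nm, nf))
    lam <- 0.3
    # analytic full gradient: sum of per-cell residual terms, lambda once per row
    R <- V - f$mlf %*% t(f$dlf)
    G_dlf <- -2 * t(R) %*% f$mlf + lam * f$dlf
    G_mlf <- -2 * R %*% f$dlf + lam * f$mlf
    h <- 1e-6
    for (idx in sample(length(f$dlf), 4)) {
      fp <- f; fp$dlf[idx] <- fp$dlf[idx] + h
      fm <- f; fm$dlf[idx] <- fm$dlf[idx] - h
      fd <- (lfm_cost(V, fp, lam) - lfm_cost(V, fm, lam)) / (2 * h)
      expect_equal(G_dlf[idx], fd, tolerance = 1e-4)
    }
    for (idx in sample(length(f$mlf), 4)) {
      fp <- f; fp$mlf[idx] <- fp$mlf[idx] + h
      fm <- f; fm$mlf[idx] <- fm$mlf[idx] - h
      fd <- (lfm_cost(V, fp, lam) - lfm_cost(V, fm, lam)) / (2 * h)
      expect_equal(G_mlf[idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("SGD fits a noiseless rank-1 matrix and is seed-deterministic", {
  set.seed(21)
  u <- runif(6); v <- runif(6)
  P <- u %*% t(v)
  dimnames(P) <- list(paste0("m", 1:6), paste0("d", 1:6))
  cfg <- lfm_config(n_factors = 1, reg_lambda = 0, learning_rate = 0.05,
                    max_epochs = 500, tol = 0, seed = 2)
  tr <- lfm_train(P, cfg)
  expect_lt(tail(tr$trace$epoch_costs, 1), 1e-3)
  tr2 <- lfm_train(P, cfg)
  expect_identical(tr$factors, tr2$factors)
  expect_false(identical(
    tr$factors,
    lfm_train(P, lfm_config(n_factors = 1, reg_lambda = 0,
                            learning_rate = 0.05, max_epochs = 500,
                            tol = 0, seed = 3))$factors))
})

test_that("strong regularization shrinks factor norms", {
  set.seed(5)
  P <- matrix(runif(30), 6, 5)
  dimnames(P) <- list(paste0("m", 1:6), paste0("d", 1:5))
  base <- lfm_config(n_factors = 3, reg_lambda = 0, learning_rate = 0.001,
                     max_epochs = 100, seed = 4)
  heavy <- base; heavy$reg_lambda <- 100
  n0 <- with(lfm_train(P, base)$factors, sum(dlf^2) + sum(mlf^2))
  n1 <- with(lfm_train(P, heavy)$factors, sum(dlf^2) + sum(mlf^2))
  expect_lt(n1, n0 / 10)
})

test_that("cost is non-increasing across epochs for a small learning rate", {
  set.seed(6)
  P <- matrix(runif(20), 5, 4)
  dimnames(P) <- list(paste0("m", 1:5), paste0("d", 1:4))
  tr <- lfm_train(P, lfm_config(n_factors = 2, reg_lambda = 0.01,
                                learning_rate = 0.005, max_epochs = 80,
                                tol = 0, seed = 7))
  costs <- tr$trace$epoch_costs
  expect_true(all(diff(costs) <= 1e-8))
  expect_lte(tail(costs, 1), costs[1])
})

test_that("divergence at an absurd learning rate is reported as an error", {
  P <- matrix(runif(16), 4, 4)
  dimnames(P) <- list(paste0("m", 1:4), paste0("d", 1:4))
  expect_error(lfm_train(P, lfm_config(n_factors = 2, learning_rate = 50,
                                       max_epochs = 50, seed = 1)),
               "learning_rate")
})

test_that("noiseless low-rank matrices are recovered to tight per-cell error", {
  for (r in c(2, 4)) {
    set.seed(30 + r)
    dlf <- matrix(runif(10 * r), 10, r); mlf <- matrix(runif(14 * r), 14, r)
    P <- mlf %*% t(dlf); P <- P / max(P)
    dimnames(P) <- list(paste0("m", 1:14), paste0("d", 1:10))
    tr <- lfm_train(P, lfm_config(n_factors = r + 2, reg_lambda = 0,
                                  learning_rate = 0.05, max_epochs = 1500,
                                  tol = 1e-10, seed = r))
    R <- tr$factors$mlf %*% t(tr$factors$dlf)
    expect_lt(max(abs(R - P)), 0.05)
  }
})

test_that("final predictions force known cells to 1 and preserve ranking", {
  init <- build_initial_matrix(data.frame(m = "m1", d = "d1"),
                               c("m1", "m2", "m3"), c("d1", "d2"))
  factors <- list(dlf = matrix(c(0.3, 0.6, 0.1, 1.7), 2, 2),
                  mlf = matrix(runif(6), 3, 2))
  P <- finalize_predictions(factors, init)
  expect_equal(P["m1", "d1"], 1)                       # forced despite low score
  raw <- factors$mlf %*% t(factors$dlf)
  expect_equal(P["m2", "d2"], raw[2, 2])               # unknown cell untouched
  Pc <- finalize_predictions(list(dlf = matrix(1.7), mlf = matrix(1)),
                             build_initial_matrix(
                               data.frame(m = character(), d = character()),
                               "m1", "d1"), clip = TRUE)
  expect_equal(Pc["m1", "d1"], 1)                      # clamped from 1.7
  # unclipped predictions never reorder unknown cells
  ord_raw <- order(raw[!(init$values == 1)])
  ord_fin <- order(P[!(init$values == 1)])
  expect_equal(ord_raw, ord_fin)
})

test_that("SVD baseline reconstructs exactly at full rank and obeys Eckart-Young", {
  set.seed(12)
  V <- matrix(runif(40, 0, 0.9), 8, 5)
  dimnames(V) <- list(paste0("m", 1:8), paste0("d", 1:5))
  mdr <- list(values = V, initial = V * 0)
  full <- svd_baseline(mdr, k = 5)
  expect_equal(unclass(full), V, tolerance = 1e-10, ignore_attr = TRUE)

  u <- runif(8); v <- runif(5)
  r1 <- u %*% t(v); dimnames(r1) <- dimnames(V)
  rec1 <- svd_baseline(list(values = r1, initial = r1 * 0), k = 1)
  expect_equal(unclass(rec1), r1, tolerance = 1e-10, ignore_attr = TRUE)

  k <- 2
  rec <- svd_baseline(mdr, k = k)
  sv <- svd(V)$d
  expect_equal(sum((V - rec)^2), sum(sv[(k + 1):length(sv)]^2),
               tolerance = 1e-8)
  expect_error(svd_baseline(mdr, k = 9), "out of range")
})
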