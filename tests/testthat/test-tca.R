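test_that("weight matrix equals the stated block formula and the outer-product form", {
  expect_equal(build_weight_matrix(1, 1), matrix(c(1, -1, -1, 1), 2, 2))

  l22 <- build_weight_matrix(2, 2)
  expect_equal(l22[1:2, 1:2], matrix(0.25, 2, 2))
  expect_equal(l22[3:4, 3:4], matrix(0.25, 2, 2))
  expect_equal(l22[1:2, 3:4], matrix(-0.25, 2, 2))
  expect_equal(rowSums(l22), rep(0, 4))

  u <- c(1/2, 1/2, -1/3, -1/3, -1/3)
  expect_identical(build_weight_matrix(2, 3), outer(u, u))
  expect_error(build_weight_matrix(0, 3), "positive")
})

test_that("weight matrix is exactly rank one and PSD", {
  for (sz in list(c(2, 3), c(5, 1), c(7, 11))) {
    l <- build_weight_matrix(sz[1], sz[2])
    expect_equal(qr(l)$rank, 1L)
    expect_true(all(eigen(l, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
    expect_equal(sum(l), 0)
  }
})

test_that("centering matrix is the mean-removal projector", {
  expect_equal(build_centering_matrix(2), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  h3 <- build_centering_matrix(3)
  expect_equal(diag(h3), rep(2/3, 3))
  expect_equal(h3[1, 2], -1/3)
  for (n in c(2, 5, 9)) {
    h <- build_centering_matrix(n)
    expect_equal(drop(h %*% rep(1, n)), rep(0, n))
    expect_equal(h %*% h, h, tolerance = 1e-12)
    expect_equal(h, t(h))
  }
  expect_error(build_centering_matrix(1), "n >= 2")
})

test_that("kernel construction matches its closed forms", {
  x <- diag(3)  # orthonormal rows
  expect_equal(compute_kernel(x, "linear")$values, diag(3))

  y <- rand_expr(4, 6, seed = 2)  # rows = observations after transpose
  kr <- compute_kernel(t(y), "rbf", gamma = 0.5)
  expect_equal(unname(diag(kr$values)), rep(1, ncol(y)))
  expect_equal(kr$values, t(kr$values))
  d2 <- as.matrix(dist(t(y)))^2
  expect_equal(kr$values, exp(-0.5 * d2), tolerance = 1e-12)

  tiny <- compute_kernel(t(y), "rbf", gamma = 1e-12)$values
  expect_true(all(abs(tiny - 1) < 1e-6))

  expect_error(compute_kernel(t(y), "primal"), "bypasses kernel")
  y[1, 1] <- Inf
  expect_error(compute_kernel(t(y), "linear"), "non-finite")
})

test_that("rbf median-heuristic bandwidth is scale free", {
  x <- t(rand_expr(5, 8, seed = 9))
  g1 <- compute_kernel(x, "rbf", gamma = "median")$gamma
  g2 <- compute_kernel(10 * x, "rbf", gamma = "median")$gamma
  expect_equal(g1, 100 * g2)
  expect_equal(g1, 1 / median(as.matrix(dist(x))[upper.tri(diag(8))]^2))
})

test_that("identical reference and query collapse to zero discrepancy", {
  ref <- rand_counts(30, 12, seed = 11, obs_prefix = "s")
  qry <- ref
  colnames(qry) <- sprintf("c%02d", seq_len(ncol(qry)))
  for (kern in c("primal", "linear", "rbf")) {
    fit <- tca(ref, qry, kernel = kern, d = 4, normalize = FALSE, hvg_n = 0)
    expect_equal(compute_mmd(fit$TC_R, fit$TC_Q), 0, tolerance = 1e-12)
    expect_equal(unname(fit$TC_R), unname(fit$TC_Q), tolerance = 1e-9)
  }
})

test_that("compute_mmd is the squared distance between latent means", {
  expect_equal(compute_mmd(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 2)
  expect_equal(compute_mmd(diag(3), diag(3)), 0)
  expect_error(compute_mmd(matrix(0, 0, 2), diag(2)), "empty")
  expect_error(compute_mmd(matrix(0, 2, 2), matrix(0, 2, 3)), "differ")
})

test_that("minimised discrepancy equals the latent mean gap on random instances", {
  for (seed in 1:20) {
    fit <- fit_random_instance(seed)
    lhs <- sum(diag(literal_terms(fit)$discrepancy))
    rhs <- compute_mmd(fit$TC_R, fit$TC_Q)
    expect_lt(abs(lhs - rhs), 1e-8 * (1 + lhs))
  }
})

test_that("constraint and generalized-eigenvector orthogonality hold after normalisation", {
  for (seed in c(1, 7, 13)) {
    for (kern in c("primal", "linear", "rbf")) {
      fit <- fit_random_instance(seed, kernel = kern)
      lt <- literal_terms(fit)
      expect_lt(max(abs(lt$constraint - diag(fit$config$d))), 1e-6)
      off <- lt$b_inner; diag(off) <- 0
      expect_lt(max(abs(off)) / max(abs(diag(lt$b_inner))), 1e-6)
    }
  }
})

test_that("regularised discrepancy matrix is positive definite for any lambda", {
  x <- t(rand_expr(10, 14, seed = 21))
  k <- compute_kernel(x, "linear")$values
  ku <- drop(k %*% c(rep(1/6, 6), rep(-1/8, 8)))
  for (lambda in c(1e-3, 1, 10)) {
    b <- tcrossprod(ku) + diag(lambda, 14)
    ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
    expect_silent(chol(b))
  }
})

test_that("leading component maximises the Rayleigh quotient over random directions", {
  fit <- fit_random_instance(3, kernel = "linear")
  lt <- literal_terms(fit)
  # recompute the quotient for column 1 and for random unit vectors
  l <- build_weight_matrix(fit$n1, fit$n2)
  h <- build_centering_matrix(fit$n1 + fit$n2)
  s <- fit$K %*% h %*% fit$K
  b <- fit$K %*% l %*% fit$K + fit$config$lambda * diag(fit$n1 + fit$n2)
  quot <- function(a) drop(crossprod(a, s %*% a) / crossprod(a, b %*% a))
  q1 <- quot(fit$A[, 1])
  rand_q <- withr::with_seed(42, replicate(100, {
    v <- rnorm(nrow(fit$A))
    quot(v / sqrt(sum(v^2)))
  }))
  expect_true(all(q1 >= rand_q))
  expect_equal(q1, fit$eta[1], tolerance = 1e-8)
})

test_that("eigenvalues are descending and d above the achievable rank errors", {
  fit <- fit_random_instance(5, kernel = "linear", d = 8)
  expect_true(all(diff(fit$eta) <= 1e-10))
  # 4 genes bound the linear-kernel rank at 4, so d = 6 is unachievable
  ref <- rand_expr(4, 5, seed = 2, obs_prefix = "s")
  qry <- rand_expr(4, 5, seed = 3)
  expect_error(tca(ref, qry, kernel = "linear", d = 6, normalize = FALSE, hvg_n = 0),
               "achievable rank")
  expect_error(tca(ref, qry, d = 2), "at least 3")
  expect_error(tca(ref, qry, d = 4, lambda = 0), "lambda")
})

test_that("permuting query observations permutes latent rows and leaves the spectrum", {
  ref <- rand_expr(20, 10, seed = 31, obs_prefix = "s")
  qry <- rand_expr(20, 12, seed = 32)
  fit <- tca(ref, qry, kernel = "linear", d = 4, normalize = FALSE, hvg_n = 0)
  perm <- withr::with_seed(1, sample(ncol(qry)))
  fit_p <- tca(ref, qry[, perm], kernel = "linear", d = 4, normalize = FALSE, hvg_n = 0)
  expect_lt(max(abs(fit$eta - fit_p$eta)), 1e-8)
  # latent space is defined up to per-component sign: align signs on the
  # (untouched) reference rows, then query rows must permute exactly
  sgn <- sign(colSums(fit$TC_R * fit_p$TC_R))
  tc_q_aligned <- sweep(fit_p$TC_Q, 2, sgn, "*")
  expect_equal(tc_q_aligned[colnames(qry), ], fit$TC_Q, tolerance = 1e-8)
})

test_that("eigenpairs agree with a dense generalized-eigensolver oracle at small n", {
  for (seed in c(2, 4, 6)) {
    n1 <- 6; n2 <- 6
    fit <- fit_random_instance(seed, n1 = n1, n2 = n2, g = 15,
                               kernel = "linear", d = 3)
    l <- build_weight_matrix(n1, n2)
    h <- build_centering_matrix(n1 + n2)
    s <- fit$K %*% h %*% fit$K
    b <- fit$K %*% l %*% fit$K + fit$config$lambda * diag(n1 + n2)
    # independent route: unsymmetric dense solve of B^{-1} S
    eo <- eigen(solve(b, s))
    vals <- Re(eo$values)
    ord <- order(vals, decreasing = TRUE)
    expect_equal(fit$eta, vals[ord][1:3], tolerance = 1e-8)
    for (j in 1:3) {
      v <- Re(eo$vectors[, ord[j]])
      cosang <- abs(sum(v * fit$A[, j])) / sqrt(sum(v^2) * sum(fit$A[, j]^2))
      expect_gt(cosang, 1 - 1e-6)
    }
  }
})

test_that("primal projection and prediction agree", {
  ref <- rand_counts(25, 10, seed = 41, obs_prefix = "s")
  qry <- rand_counts(25, 15, seed = 42)
  fit <- tca(ref, qry, d = 5, normalize = FALSE, hvg_n = 0)
  expect_equal(predict(fit, qry), fit$TC_Q, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), unname(fit$A))
  expect_error(predict(fit, qry[-1, , drop = FALSE]), "lacks fitted genes")
  s <- summary(fit)
  expect_equal(s$objective, s$mmd + s$penalty)
  expect_output(print(fit), "Transfer component analysis")
})
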