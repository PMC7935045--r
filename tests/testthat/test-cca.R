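# Independent oracle: canonical correlations are the singular values of
# Qx' Qy for orthonormal bases of the centered matrices.
qr_svd_cors <- function(X, Y) {
  Qx <- qr.Q(qr(scale(X, scale = FALSE)))
  Qy <- qr.Q(qr(scale(Y, scale = FALSE)))
  svd(crossprod(Qx, Qy))$d
}

test_that("canonical correlations match the orthonormal-basis oracle", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(40 * 3), 40, 3)
    Y <- matrix(rnorm(40 * 2), 40, 2)
    fit <- cca(X, Y)
    expect_lt(max(abs(fit$correlations - qr_svd_cors(X, Y)[1:2])), 1e-8)
  }
  # cross-check one instance against the stats implementation
  set.seed(99)
  X <- matrix(rnorm(60 * 4), 60, 4); Y <- matrix(rnorm(60 * 3), 60, 3)
  expect_lt(max(abs(cca(X, Y)$correlations - cancor(X, Y)$cor)), 1e-8)
})

test_that("identical sides give unit correlations; independent sides give none", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, 3)
  expect_lt(max(abs(cca(X, X)$correlations - 1)), 1e-8)
  set.seed(3)
  A <- matrix(rnorm(10000 * 2), ncol = 2)
  B <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_lt(cca(A, B)$correlations[1], 0.05)
})

test_that("correlations are invariant to invertible affine column transforms", {
  set.seed(4)
  X <- matrix(rnorm(50 * 4), 50, 4); Y <- matrix(rnorm(50 * 3), 50, 3)
  base <- cca(X, Y)$correlations
  Tx <- matrix(rnorm(16), 4); while (abs(det(Tx)) < 0.1) Tx <- matrix(rnorm(16), 4)
  Ty <- matrix(rnorm(9), 3); while (abs(det(Ty)) < 0.1) Ty <- matrix(rnorm(9), 3)
  tr <- cca(sweep(X %*% Tx, 2, rnorm(4), `+`),
            sweep(Y %*% Ty, 2, rnorm(3), `+`))$correlations
  expect_lt(max(abs(base - tr)), 1e-10)
  # successive variates are mutually uncorrelated within each side
  fit <- cca(X, Y)
  cu <- cor(fit$xvariates); cv <- cor(fit$yvariates)
  expect_lt(max(abs(cu[row(cu) != col(cu)])), 1e-8)
  expect_lt(max(abs(cv[row(cv) != col(cv)])), 1e-8)
  # rank deficiency is reduced, not fatal
  expect_message(fit2 <- cca(cbind(X, X[, 1]), Y), "rank deficient")
  expect_lt(max(abs(fit2$correlations - cca(X, Y)$correlations)), 1e-8)
})

test_that("singleton blocks reduce grouped permutation to ordinary row permutation", {
  set.seed(5)
  n <- 5
  X <- matrix(rnorm(n * 2), n, 2); Y <- matrix(rnorm(n), n, 1)
  res <- cca_permutation_test(X, Y, groups = seq_len(n), n_perm = 200,
                              seed = 1)
  expect_equal(res$method, "exact")
  expect_equal(res$n_perm_used, factorial(n))
  # oracle: enumerate every row permutation of X directly
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  obs <- qr_svd_cors(X, Y)[1]
  all_r <- apply(perms, 1, function(p) qr_svd_cors(X[p, ], Y)[1])
  expect_equal(res$p[1], mean(all_r >= obs - 1e-12))
  # a permuted index from the machinery is a true permutation
  idx <- permute_rows_grouped(rep(1:6, each = 2))
  expect_equal(sort(idx), 1:12)
})

test_that("add-one convention bounds sampled permutation p-values", {
  set.seed(6)
  g <- study_groups()
  X <- matrix(rnorm(64 * 3), 64, 3); Y <- matrix(rnorm(64 * 2), 64, 2)
  res <- cca_permutation_test(X, Y, g, n_perm = 19, seed = 2)
  expect_equal(res$method, "sampled")
  expect_true(all(res$p >= 1 / 20))
  expect_true(all(res$p <= 1))
  # the max statistic is at least as conservative for later modes
  rmax <- cca_permutation_test(X, Y, g, n_perm = 99, seed = 3,
                               statistic = "max")
  rper <- cca_permutation_test(X, Y, g, n_perm = 99, seed = 3)
  expect_true(all(rmax$p >= rper$p - 1e-12))
  # blocks of unique sizes cannot be exchanged
  expect_error(cca_permutation_test(X[1:6, ], Y[1:6, ],
                                    rep(c("a", "b", "c"), c(1, 2, 3)),
                                    n_perm = 9),
               "nothing to exchange")
})

test_that("grouped permutation p-values are super-uniform under the null", {
  g <- study_groups()
  alphas <- c(0.05, 0.1, 0.2)
  n_rep <- 300
  set.seed(7)
  ps <- replicate(n_rep, {
    cca_permutation_test(matrix(rnorm(64 * 3), 64),
                         matrix(rnorm(64 * 2), 64),
                         g, n_perm = 99)$p[1]
  })
  for (a in alphas) {
    se <- sqrt(a * (1 - a) / n_rep)
    expect_lte(mean(ps <= a), a + 3 * se)
  }
})

test_that("planted canonical mode is found by the grouped permutation test", {
  cfg <- synth_config(seed = 7)
  inp <- planted_cca_inputs(cfg)
  fit <- suppressMessages(cca(inp$X, inp$Y))
  expect_gt(fit$correlations[1], 0.6)
  res <- suppressMessages(
    cca_permutation_test(inp$X, inp$Y, inp$groups, n_perm = 199, seed = 8))
  expect_lte(res$p[1], 0.01)
})

test_that("grouped cross-validation holds out whole stratified subject blocks", {
  cfg <- synth_config(seed = 7)
  inp <- planted_cca_inputs(cfg)
  cv <- suppressMessages(
    cca_cross_validate(inp$X, inp$Y, inp$groups, n_folds = 12,
                       n_perm = 99, seed = 9))
  expect_equal(nrow(cv$folds), 12)
  # stratified test sets: 4 three-session + 1 two-session subjects = 14 rows
  expect_true(all(vapply(strsplit(cv$folds$test_subjects, ";"),
                         length, 1L) == 5))
  sizes <- table(inp$groups)
  for (ts in strsplit(cv$folds$test_subjects, ";"))
    expect_equal(sort(as.integer(sizes[ts])), c(2L, 3L, 3L, 3L, 3L))
  expect_true(all(cv$folds$p >= 1 / 100))
  expect_error(cca_cross_validate(inp$X[1:6, ], inp$Y[1:6, ],
                                  inp$groups[1:6], n_folds = 2,
                                  train_frac = 0.8),
               "fewer than 3")
})

test_that("post hoc loadings recover defining variables and vanish for noise", {
  set.seed(10)
  X <- matrix(rnorm(10000 * 3), ncol = 3)
  Y <- cbind(X[, 1] + 0.2 * rnorm(10000), rnorm(10000))
  fit <- cca(X, Y)
  lo <- posthoc_loadings(fit, X, Y)
  # a variable identical to the variate has loading 1
  lo_self <- posthoc_loadings(fit, cbind(fit$xvariates[, 1]), Y)
  expect_equal(unname(lo_self$x[1, 1]), 1, tolerance = 1e-10)
  # pure-noise variable has negligible loading at n = 10,000
  expect_lt(abs(lo$y[2, 1]), 0.05)
  expect_gt(abs(lo$y[1, 1]), 0.9)
  # constant variable gives NA with a warning
  expect_warning(lo2 <- posthoc_loadings(fit, cbind(X[, 1], 1), Y),
                 "constant")
  expect_true(is.na(lo2$x[2, 1]))
})

test_that("mode-defining variables outload uncoupled variables across replicates", {
  hits <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    z <- rnorm(200)
    X <- cbind(z + 0.3 * rnorm(200), matrix(rnorm(200 * 2), ncol = 2))
    Y <- cbind(z + 0.3 * rnorm(200), matrix(rnorm(200 * 2), ncol = 2))
    lo <- posthoc_loadings(cca(X, Y), X, Y, modes = 1)
    if (abs(lo$x[1, 1]) > max(abs(lo$x[2:3, 1])) &&
        abs(lo$y[1, 1]) > max(abs(lo$y[2:3, 1]))) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("mode stability sweep enumerates configurations and preserves a strong mode", {
  cfg <- synth_config(seed = 7)
  inp <- planted_cca_inputs(cfg)
  # full study grid (static arm: up to 20 edge PCs) is enumerated
  wide <- matrix(rnorm(64 * 25), 64, 25)
  grid <- mode_stability_sweep(inp$behavior, wide, factor_range = 1:9,
                               pc_range = 1:20, fit = FALSE)$grid
  expect_equal(nrow(grid), 180)
  # a reduced grid: identical configurations agree exactly, and the planted
  # mode is preserved (sign-agnostic) for >= 2 factors
  sw <- suppressMessages(
    mode_stability_sweep(inp$behavior, inp$X, factor_range = c(2, 2, 4, 8),
                         pc_range = c(5, 13)))
  expect_false(any(sw$grid$failed))
  expect_equal(sw$similarity[1, 2], 1.0, tolerance = 1e-12)
  off <- abs(sw$similarity[row(sw$similarity) != col(sw$similarity)])
  expect_gt(min(off), 0.9)
})
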