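test_that("RMSD is zero against itself and handles rigid motion", {
  ens <- gen_ensemble(ensemble_spec(20, 5, sigma = 0.2, seed = 6))
  r <- rmsd_series(ens, ref = 2)
  expect_equal(r[2], 0, tolerance = 1e-9)
  expect_true(all(r >= 0))
  # a rigidly translated + rotated copy superposes back to zero RMSD
  X <- rodnet:::ca_xyz(ens)
  co <- matrix(X[1, ], ncol = 3, byrow = TRUE)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  co2 <- sweep(co %*% R, 2, c(5, -3, 8), "+")
  ens2 <- ens
  ens2$xyz <- rbind(X[1, ], as.numeric(t(co2)))
  ens2$atoms <- rodnet:::node_table(ens)
  ens2$atoms$elety <- "CA"
  ens2$atoms$element <- "C"
  expect_equal(rmsd_series(ens2)[2], 0, tolerance = 1e-6)
})

test_that("RMSF recovers the planted isotropic fluctuation", {
  ens <- gen_ensemble(ensemble_spec(100, 4000, sigma = 0.25,
                                    sidechain_atoms = 1, seed = 3))
  rf <- rmsf_profile(ens)
  expect_equal(mean(rf), 0.25 * sqrt(3), tolerance = 0.03)
})

test_that("summed squared RMSF equals the PCA covariance trace", {
  ens <- gen_ensemble(ensemble_spec(30, 400, sigma = 0.3, seed = 12))
  rf <- rmsf_profile(ens)
  es <- pca_ensemble(ens)
  # identical superposed ensemble up to the n/(n-1) variance factor
  nf <- nrow(ens$xyz)
  expect_equal(sum(rf^2) * nf / (nf - 1), es$trace, tolerance = 1e-8)
})

test_that("PCA conserves the trace and returns an orthonormal basis", {
  ens <- gen_ensemble(ensemble_spec(25, 300, sigma = 0.3, seed = 10))
  es <- pca_ensemble(ens)
  expect_equal(sum(es$values), es$trace, tolerance = 1e-10 * es$trace)
  V <- es$vectors[, 1:10]
  expect_equal(crossprod(V), diag(10), tolerance = 1e-10)
  expect_gte(es$cum_variance, 0.9)
  # projections reproduce the per-mode variances
  pv <- apply(es$projections[, 1:5], 2, stats::var)
  expect_equal(unname(pv), es$values[1:5], tolerance = 1e-8)
})

test_that("a planted rank-1 motion yields a single essential mode", {
  ens <- gen_ensemble(ensemble_spec(40, 2000, sigma = 0.05,
                                    sidechain_atoms = 1,
                                    modes = list(list(sd = 2)), seed = 9))
  es <- pca_ensemble(ens)
  expect_equal(es$n_modes, 1)
  v <- attr(ens, "truth")$modes[[1]]$direction
  expect_gt(abs(sum(es$vectors[, 1] * v)), 0.9)
})

test_that("subspace overlap is 1 on itself and root-half on half-shared bases", {
  ens <- gen_ensemble(ensemble_spec(20, 200, sigma = 0.3, seed = 14))
  es <- pca_ensemble(ens)
  expect_equal(subspace_overlap(es, es), 1, tolerance = 1e-10)
  # synthetic subspaces: b shares exactly one of a's two modes
  n <- 12
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  mk <- function(cols) structure(list(vectors = Q[, cols, drop = FALSE],
                                      n_modes = length(cols)),
                                 class = "essential_subspace")
  expect_equal(subspace_overlap(mk(1:2), mk(c(2, 3))), sqrt(0.5),
               tolerance = 1e-10)
  expect_equal(subspace_overlap(mk(1:2), mk(3:4)), 0, tolerance = 1e-10)
})

test_that("functional mode analysis recovers a planted observable", {
  ens <- gen_ensemble(ensemble_spec(30, 2000, sigma = 0.3, seed = 17))
  es <- pca_ensemble(ens)
  set.seed(1)
  obs <- 1.5 * es$projections[, 1] - 0.7 * es$projections[, 2] +
    rnorm(2000, sd = 0.05)
  fm <- fma(es, obs, n = 6)
  expect_gt(fm$r_train, 0.95)
  expect_gt(fm$r_cv, 0.95)
  expect_equal(sum(fm$mode^2), 1, tolerance = 1e-9)
  # the recovered mode lies in the span of the first two PCs
  proj <- crossprod(es$vectors[, 1:2], fm$mode)
  expect_equal(sum(proj^2), 1, tolerance = 1e-3)
})

test_that("functional mode analysis reports no signal for pure noise", {
  ens <- gen_ensemble(ensemble_spec(30, 2000, sigma = 0.3, seed = 18))
  es <- pca_ensemble(ens)
  set.seed(2)
  noise <- rnorm(2000)
  fm <- fma(es, noise, n = 6)
  se <- 1 / sqrt(2000 - 3)
  expect_lt(abs(fm$r_cv), 3 * se + 0.05)
  expect_error(fma(es, noise[1:10], n = 2), "frame count")
  expect_error(fma(es, noise, n = 10000), "available modes")
})
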