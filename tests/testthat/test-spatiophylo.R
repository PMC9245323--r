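test_that("Matern covariance matches its closed forms and limits", {
  set.seed(171)
  xy <- cbind(stats::runif(12, 0, 100), stats::runif(12, 0, 100))
  rownames(xy) <- paste0("s", 1:12)
  K <- matern_covariance(xy, rho = 30, sigma2 = 2, nu = 0.5)
  d <- as.matrix(stats::dist(xy))
  expect_equal(unname(K), unname(2 * exp(-d / 30)), tolerance = 1e-12)
  expect_equal(unname(diag(K)), rep(2, 12)) # distance 0 gives sigma2
  K15 <- matern_covariance(xy, 30, 1, 1.5)
  expect_true(all(K15[upper.tri(K15)] > 0))
  far <- matern_covariance(rbind(c(0, 0), c(0, 1e6)), 30, 1, 1.5)
  expect_lt(far[1, 2], 1e-10) # decays to zero
  # monotone decay in distance
  dd <- seq(0, 200, by = 10)
  vals <- vapply(dd, function(h)
    matern_covariance(rbind(c(0, 0), c(h, 0)), 50, 1, 1.5)[1, 2], numeric(1))
  expect_true(all(diff(vals) <= 0))
  # duplicate coordinates jitter only the diagonal
  dup <- matern_covariance(rbind(a = c(0, 0), b = c(0, 0)), 30, 1, 1.5)
  expect_equal(dup[1, 1], 1 + 1e-6)
  expect_equal(dup[1, 2], 1)
  expect_error(matern_covariance(xy, 30, 1, 2), "0.5")
})

sim_spatial_data <- function(n, seed, beta_x = 0.3, s2p = 0.4, s2s = 0.4,
                             s2e = 0.2, rho = 600) {
  set.seed(seed)
  tr <- simulate_bd_tree(n, 1)
  coords <- cbind(stats::runif(n, 0, 3000), stats::runif(n, 0, 3000))
  rownames(coords) <- tr$tip.label
  Cstd <- transform_vcv(phylo_vcv(tr), 1, standardize = TRUE)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  u_s <- if (s2s > 0)
    as.numeric(t(chol(matern_covariance(coords, rho, s2s) +
                        1e-8 * diag(n))) %*% stats::rnorm(n))
  else 0
  y <- beta_x * x +
    as.numeric(t(chol(s2p * Cstd)) %*% stats::rnorm(n)) + u_s +
    stats::rnorm(n, 0, sqrt(s2e))
  list(tree = tr, coords = coords,
       data = data.frame(y = y, x = x, z = z, row.names = tr$tip.label))
}

test_that("suppressing the spatial term reduces the fit to lambda-PGLS", {
  s <- sim_spatial_data(120, seed = 172, s2s = 0)
  pg <- fit_pgls(y ~ x + z, s$data, s$tree)
  sp <- fit_spatiophylo(y ~ x + z, s$data, s$tree, s$coords,
                        constrain = "no_spatial")
  expect_lt(max(abs(sp$coefficients$estimate - pg$coefficients$estimate)),
            1e-6)
  expect_equal(sp$logLik, pg$logLik, tolerance = 1e-6)
  expect_equal(unname(sp$varcomp["sigma2_spatial"]), 0)
})

test_that("the full fit recovers a known fixed effect and ranks regimes", {
  s <- sim_spatial_data(150, seed = 173, beta_x = 0.5)
  fit <- fit_spatiophylo(y ~ x + z, s$data, s$tree, s$coords)
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "x"] - 0.5), 0.25)
  expect_true(est$significant[est$term == "x"])
  expect_true(all(fit$varcomp >= 0))
  expect_gt(fit$rho, 0)
  # likelihood at the optimum dominates the boundary cases (built in)
  sp0 <- fit_spatiophylo(y ~ x + z, s$data, s$tree, s$coords,
                         constrain = "no_spatial")
  expect_gte(fit$logLik + 1e-6, sp0$logLik)
  # a phylogeny-heavy regime loads the phylogenetic component hardest
  sphylo <- sim_spatial_data(150, seed = 174, s2p = 0.8, s2s = 0.05,
                             s2e = 0.15)
  f2 <- fit_spatiophylo(y ~ x + z, sphylo$data, sphylo$tree, sphylo$coords)
  expect_gt(f2$varcomp["sigma2_phylo"], f2$varcomp["sigma2_spatial"])
})

test_that("the fit is invariant to a consistent relabeling of species", {
  s <- sim_spatial_data(60, seed = 175)
  f1 <- fit_spatiophylo(y ~ x, s$data, s$tree, s$coords)
  perm <- sample(rownames(s$data))
  f2 <- fit_spatiophylo(y ~ x, s$data[perm, ], s$tree, s$coords[perm, ])
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-8)
})

test_that("prediction surface interpolates and degenerates sensibly", {
  s <- sim_spatial_data(80, seed = 176, s2s = 0.8, s2e = 0.02, s2p = 0.05)
  fit <- fit_spatiophylo(y ~ x, s$data, s$tree, s$coords)
  grid <- rbind(s$coords[1, ], s$coords[1, ] + 5, c(1e6, 1e6))
  pr <- predict_rate_surface(fit, grid)
  expect_equal(nrow(pr), 3)
  # far from data the surface decays to the fixed-effect mean
  expect_lt(abs(pr$mean[3] - mean(fit$.internals$Xbeta)), 1e-6)
  # nearby points differ smoothly
  expect_lt(abs(pr$mean[1] - pr$mean[2]), 0.5)
  # with no spatial variance the surface is flat
  s0 <- sim_spatial_data(60, seed = 177, s2s = 0)
  f0 <- fit_spatiophylo(y ~ x, s0$data, s0$tree, s0$coords,
                        constrain = "no_spatial")
  pr0 <- predict_rate_surface(f0, rbind(c(0, 0), c(500, 500)))
  expect_equal(pr0$mean[1], pr0$mean[2])
})
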