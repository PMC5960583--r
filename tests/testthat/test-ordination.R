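# Hellinger transformation, PCA, RDA with permutation test, and the
# consecutive-wall autocorrelation check.

test_that("Hellinger transform matches the closed form and normalises rows", {
  expect_equal(hellinger(matrix(c(4, 0), 1)), matrix(c(1, 0), 1))
  expect_equal(hellinger(matrix(c(1, 3), 1)),
               matrix(c(0.5, sqrt(3) / 2), 1))
  set.seed(1)
  m <- matrix(rpois(60, 3), 10, 6)
  m[3, ] <- 0  # an empty sample stays empty
  h <- hellinger(m)
  norms <- sqrt(rowSums(h^2))
  expect_equal(norms[-3], rep(1, 9), tolerance = 1e-12)
  expect_equal(norms[3], 0)
  # idempotence fails off the unit sphere (negative check)
  expect_false(isTRUE(all.equal(hellinger(h), h)))
  expect_error(hellinger(matrix(c(-1, 2), 1)), "nonnegative")
})

test_that("Hellinger transform agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(2)
  m <- matrix(rexp(50), 10, 5)
  expect_equal(unname(hellinger(m)),
               unname(as.matrix(vegan::decostand(m, "hellinger"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(3)
  m <- matrix(rnorm(12), 4, 3)
  p <- species_pca(m)
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(sum(p$proportion_explained), 1, tolerance = 1e-8)
  # total variance is preserved
  expect_equal(sum(p$eigenvalues), sum(apply(m, 2, var)), tolerance = 1e-10)
  # sign convention: dominant loading of each axis is positive
  for (k in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)

  expect_true(all(abs(species_pca(m[c(1, 1), ])$eigenvalues) < 1e-14))

  # two uncorrelated unit-variance columns split the variance evenly
  set.seed(4)
  z <- matrix(rnorm(4000), 2000, 2)
  z <- scale(z)
  z[, 2] <- residuals(lm(z[, 2] ~ z[, 1]))
  z <- scale(z)
  pz <- species_pca(z)
  expect_equal(pz$proportion_explained, c(0.5, 0.5), tolerance = 1e-8)
  expect_error(species_pca(m[1, , drop = FALSE]), "2 rows")
})

test_that("boat summaries return group centroids and convex hulls", {
  sc <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(5, 5))
  g <- c("A", "A", "A", "A", "B")
  bs <- boat_summary(sc, g)
  expect_equal(bs$centroids$axis1, c(0.5, 5))
  expect_equal(bs$centroids$axis2, c(0.5, 5))
  expect_equal(nrow(bs$hulls$A), 4L)
  expect_equal(nrow(bs$hulls$B), 1L)
  # random clusters: centroids match independent group means
  set.seed(5)
  sc2 <- matrix(rnorm(40), 20, 2)
  g2 <- rep(c("x", "y"), 10)
  bs2 <- boat_summary(sc2, g2)
  expect_equal(bs2$centroids$axis1,
               as.numeric(tapply(sc2[, 1], g2, mean)))
  expect_error(boat_summary(sc2, g2[-1]), "mapped")
})

test_that("one-factor RDA matches hand computation and brute-force projection", {
  r <- gear_rda(matrix(c(0, 1, 2, 3), 4, 1), c("A", "A", "B", "B"))
  expect_equal(r$constrained_variance, 4 / 3)
  expect_equal(r$residual_variance, 1 / 3)
  expect_equal(r$statistic, 8)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 2L)

  # identical composition across groups (equal group means): nothing explained
  same <- matrix(c(0, 2, 0, 2), 4, 1)
  expect_lt(gear_rda(same, c("A", "A", "B", "B"))$statistic, 1e-20)
  expect_lt(gear_rda(same, c("A", "A", "B", "B"))$constrained_variance,
            1e-20)

  set.seed(6)
  Y <- matrix(rexp(36), 12, 3)
  g <- factor(rep(c("A", "B", "C"), 4))
  got <- gear_rda(Y, g)
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  Yc <- scale(Y, scale = FALSE)
  fit_ss <- sum((H %*% Yc)^2)
  res_ss <- sum((Yc - H %*% Yc)^2)
  expect_equal(got$constrained_variance, fit_ss / 11, tolerance = 1e-10)
  expect_equal(got$residual_variance, res_ss / 11, tolerance = 1e-10)
  # constrained + residual = total PCA variance
  expect_equal(got$constrained_variance + got$residual_variance,
               sum(species_pca(Y)$eigenvalues), tolerance = 1e-8)
  expect_error(gear_rda(Y, rep("A", 12)), "2 factor levels")
})

test_that("RDA agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  Y <- hellinger(matrix(rpois(60, 4), 12, 5))
  g <- factor(rep(c("A", "B"), 6))
  got <- gear_rda(Y, g)
  ref <- vegan::rda(Y ~ g)
  expect_equal(got$constrained_variance, unname(ref$CCA$tot.chi),
               tolerance = 1e-10)
  expect_equal(got$residual_variance, unname(ref$CA$tot.chi),
               tolerance = 1e-10)
})

test_that("permutation test follows the add-one rule and is seed-reproducible", {
  set.seed(8)
  Y <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 3), 10, 4))
  g <- rep(c("A", "B"), each = 10)
  r <- rda_permutation_test(Y, g, n_perm = 999, seed = 42)
  expect_equal(r$p_perm, 1 / 1000)  # minimum attainable p
  r2 <- rda_permutation_test(Y, g, n_perm = 999, seed = 42)
  expect_equal(r2$p_perm, r$p_perm)
  # relabelling the factor levels does not change the p-value
  g2 <- ifelse(g == "A", "Z", "Q")
  r3 <- rda_permutation_test(Y, g2, n_perm = 999, seed = 42)
  expect_equal(r3$p_perm, r$p_perm)
  expect_error(rda_permutation_test(Y, g, n_perm = 50), "99")
  expect_warning(r4 <- rda_permutation_test(matrix(1, 6, 2),
                                            rep(c("A", "B"), 3),
                                            n_perm = 99),
                 "zero total variance")
  expect_equal(r4$p_perm, 1)
})

test_that("consecutive-wall autocorrelation test flags trends and degenerate series", {
  r <- lag1_autocorrelation_test(1:10, rep("N1", 10), n_perm = 199,
                                 seed = 1)
  expect_gt(r$statistic, 0.9)
  expect_lt(r$p_value, 0.05)

  expect_warning(rc <- lag1_autocorrelation_test(rep(2, 8), rep("N1", 8),
                                                 n_perm = 99),
                 "constant")
  expect_true(is.na(rc$statistic))
  expect_equal(rc$p_value, 1)

  expect_error(lag1_autocorrelation_test(1:4, c("N1", "N1", "N2", "N2")),
               "at least 3 walls")
})

test_that("autocorrelation permutation test holds its type-I error on iid data", {
  set.seed(13)
  n_rep <- 200
  rej <- 0
  net <- rep(paste0("N", 1:5), each = 6)
  for (i in seq_len(n_rep)) {
    v <- rnorm(30)
    p <- lag1_autocorrelation_test(v, net, n_perm = 99)$p_value
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})
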