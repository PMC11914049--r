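test_that("robust Aitchison distance is a metric on rclr images", {
  r1 <- c(0.8, 0.1, 0.1); r2 <- c(0.1, 0.1, 0.8)
  m <- rbind(a = r1, b = r2, c = r1)
  d <- robust_aitchison_dist(m)
  dm <- as.matrix(d)
  # identical rows at distance zero
  expect_equal(dm["a", "c"], 0)
  # hand oracle: Euclidean distance of the centred log rows
  z1 <- log(r1) - mean(log(r1)); z2 <- log(r2) - mean(log(r2))
  expect_equal(dm["a", "b"], sqrt(sum((z1 - z2)^2)), tolerance = 1e-12)
  # triangle inequality on random triples
  set.seed(5)
  mat <- t(replicate(12, random_composition(5)))
  dd <- as.matrix(robust_aitchison_dist(mat))
  for (i in 1:20) {
    ijk <- sample(12, 3)
    expect_lte(dd[ijk[1], ijk[2]],
               dd[ijk[1], ijk[3]] + dd[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("nmds embeds exactly embeddable configurations with ~zero stress", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 2), c(2, 0.3))
  rownames(pts) <- paste0("s", 1:6)
  d <- dist(pts)
  ord <- nmds(d, restarts = 20, seed = 7)
  expect_lt(ord$stress, 0.01)
  expect_equal(nrow(ord$points), 6)
  # configuration centred at the origin
  expect_equal(colMeans(as.matrix(ord$points[, -1])), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-6)
  # monotone invariance: a strictly increasing transform of the distances
  # leaves the rank-based solution essentially unchanged
  ord2 <- nmds(sqrt(d), restarts = 20, seed = 7)
  pro <- vegan::procrustes(as.matrix(ord$points[, -1]),
                           as.matrix(ord2$points[, -1]), symmetric = TRUE)
  expect_lt(pro$ss, 0.01)
  expect_s3_class(autoplot(ord), "ggplot")
})

test_that("fitted vectors recover an axis-aligned variable", {
  set.seed(8)
  mat <- t(replicate(20, random_composition(6)))
  ord <- nmds(robust_aitchison_dist(mat), restarts = 10, seed = 2)
  vars <- data.frame(ax1 = ord$points$NMDS1,
                     noise = rnorm(20),
                     flat = rep(1, 20))
  expect_warning(vf <- fit_env_vectors(ord, vars, perms = 199, seed = 3), "flat")
  row1 <- vf[vf$variable == "ax1", ]
  expect_gt(row1$r2, 0.999)
  expect_gt(abs(row1$NMDS1), 0.999)
  expect_lt(row1$p_value, 0.02)
  # unit-norm directions
  expect_equal(sqrt(vf$NMDS1^2 + vf$NMDS2^2), rep(1, nrow(vf)), tolerance = 1e-9)
})

test_that("permanova pseudo-F matches the exhaustive Gower-partition oracle", {
  set.seed(9)
  mat <- t(replicate(6, random_composition(5)))
  rownames(mat) <- paste0("s", 1:6)
  d <- robust_aitchison_dist(mat)
  grp <- factor(c("a", "a", "a", "b", "b", "b"))
  res <- permanova(d, data.frame(substrate = grp), formula = ~substrate,
                   perms = 9999, seed = 1)
  oracle <- permanova_oracle(d, grp)
  expect_equal(res$pseudo_f[1], oracle$pseudo_f, tolerance = 1e-8)
  # SS partition: term + residual = total
  expect_equal(sum(res$sum_of_squares[1:2]), res$sum_of_squares[3],
               tolerance = 1e-8)
  expect_equal(res$sum_of_squares[3], oracle$ss_total, tolerance = 1e-8)
  expect_equal(sum(res$df[1:2]), 5)
  # Monte-Carlo p close to the exact enumeration over all 720 relabelings
  expect_equal(res$p_value[1], oracle$p_exact, tolerance = 0.05)
  # p bounded by the permutation resolution
  expect_gte(res$p_value[1], 1 / (9999 + 1))
})

test_that("permanova separates structured groups and keeps term ordering", {
  set.seed(10)
  n <- 20
  grp <- rep(c("artificial", "natural"), each = n / 2)
  base <- t(replicate(n, random_composition(6)))
  base[grp == "natural", 1] <- base[grp == "natural", 1] * 40
  base <- base / rowSums(base)
  d <- robust_aitchison_dist(base)
  design <- data.frame(substrate = grp, year = rep(2000:2009, 2),
                       depth_m = runif(n, 1, 9))
  res <- permanova(d, design, perms = 9999, seed = 4)
  expect_equal(res$term[1:5],
               c("substrate", "year", "depth_m", "substrate:year",
                 "substrate:depth_m"))
  expect_lte(res$p_value[1], 0.001)
})

test_that("pairwise permanova applies Bonferroni and skips tiny groups", {
  set.seed(11)
  mat <- t(replicate(19, random_composition(5)))
  d <- robust_aitchison_dist(mat)
  grp <- c(rep("g1", 6), rep("g2", 6), rep("g3", 6), "g4")
  expect_warning(pw <- pairwise_permanova(d, grp, perms = 199, seed = 5), "g4")
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 3))
  expect_true(all(pw$p_adjusted >= pw$p_value))
  # identical groups behave as null
  expect_true(all(pw$p_adjusted > 0.05))
})
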