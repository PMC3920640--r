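# Species means, size correction, PCA retention, Wilks MANOVA and the
# simulation-based phylogenetic MANOVA.

make_specimens <- function(means, counts, noise = 0) {
  # means: species x chars (ln scale)
  rows <- lapply(seq_len(nrow(means)), function(i) {
    M <- exp(sweep(matrix(rnorm(counts[i] * ncol(means), 0, noise),
                          nrow = counts[i]), 2, means[i, ], `+`))
    colnames(M) <- colnames(means)
    data.frame(specimen_id = paste0(rownames(means)[i], "_", seq_len(counts[i])),
               species = rownames(means)[i], M)
  })
  do.call(rbind, rows)
}

test_that("species means are log geometric means of specimens", {
  mu <- matrix(log(c(10, 20, 5, 8)), 2, 2,
               dimnames = list(c("sp1", "sp2"), c("a", "b")))
  one <- make_specimens(mu, c(1, 1))
  expect_equal(species_means(one), mu)

  dup <- make_specimens(mu, c(2, 3))       # identical specimens per species
  expect_equal(species_means(dup), mu)

  # geometric means recovered exactly from v and 1/v pairs
  sp <- data.frame(specimen_id = c("x1", "x2"), species = "x",
                   a = c(3, 1 / 3), b = c(7, 7))
  sm <- species_means(sp)
  expect_equal(unname(sm["x", ]), c(0, log(7)))

  sp$a[1] <- -1
  expect_error(species_means(sp), "nonpositive measurement.*x1")
})

test_that("size correction removes allometry exactly and centers residuals", {
  x <- c(0, 1, 2)
  tr <- cbind(svl = x, prop = 2 + 3 * x, y = c(0, 1, 3))
  rownames(tr) <- paste0("s", 1:3)
  res <- size_correct(tr, "svl")
  expect_equal(unname(res[, "prop"]), rep(0, 3), tolerance = 1e-12)
  # hand least squares: slope 3/2, intercept -1/6
  expect_equal(unname(res[, "y"]), c(1 / 6, -1 / 3, 1 / 6), tolerance = 1e-12)
  expect_lt(abs(sum(res[, "y"])), 1e-12)
  expect_lt(abs(sum(res[, "y"] * x)), 1e-12)

  # adding a constant to a trait leaves residuals unchanged
  tr2 <- tr; tr2[, "y"] <- tr2[, "y"] + 5
  expect_equal(size_correct(tr2, "svl")[, "y"], res[, "y"])

  expect_error(size_correct(cbind(svl = c(1, 1, 1), y = 1:3), "svl"),
               "zero variance")
})

test_that("PCA retains axes by the variance-fraction rule", {
  X <- matrix_with_fracs(25, c(0.531, 0.202, 0.106, 0.09, 0.05, 0.021))
  pc <- trait_pca(X, retain = 0.10)
  expect_equal(pc$var_frac[1:3], c(0.531, 0.202, 0.106), tolerance = 1e-9)
  expect_equal(pc$retained, 1:3)
  expect_equal(sum(pc$var_frac), 1)

  # orthonormal loadings and exact reconstruction of centered data
  expect_equal(unname(crossprod(pc$loadings)), diag(ncol(X)), tolerance = 1e-10)
  Xc <- sweep(X, 2, pc$center)
  expect_equal(unname(pc$scores %*% t(pc$loadings)), unname(Xc),
               tolerance = 1e-10)

  # row reordering changes nothing but row order (signs are normalized)
  idx <- sample(nrow(X))
  pc2 <- trait_pca(X[idx, ])
  expect_equal(pc2$scores[rownames(X), ], pc$scores, tolerance = 1e-8)
})

test_that("Wilks lambda matches hand sums of squares and stats::manova", {
  # identical group means: H = 0, lambda = 1 (within-group spread spans 2D)
  Y0 <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0)) + 0
  rownames(Y0) <- paste0("s", 1:4)
  g0 <- setNames(c("a", "a", "b", "b"), rownames(Y0))
  expect_equal(manova_wilks(Y0, g0)$lambda, 1, tolerance = 1e-12)

  # univariate toy: groups {0,1} and {3,4} -> SSE/SST = 1/10
  # (SSE = 0.5 per group, SSB = 9, total 10)
  Y1 <- matrix(c(0, 1, 3, 4), dimnames = list(paste0("s", 1:4), "y"))
  g1 <- setNames(c("a", "a", "b", "b"), rownames(Y1))
  expect_equal(manova_wilks(Y1, g1)$lambda, 1 / 10, tolerance = 1e-12)

  # lambda strictly decreases as one group's mean moves away
  lam <- vapply(seq(0, 3, by = 0.5), function(d) {
    Yd <- Y1; Yd[3:4, ] <- Yd[3:4, ] + d
    manova_wilks(Yd, g1)$lambda
  }, 0)
  expect_true(all(diff(lam) < 0))

  # agreement with stats::manova on random data
  set.seed(9)
  Y <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  g <- setNames(rep(c("a", "b", "c"), length.out = 20), rownames(Y))
  mine <- manova_wilks(Y, g)
  ref <- summary(manova(Y ~ factor(g)), test = "Wilks")$stats
  expect_equal(mine$lambda, ref[1, "Wilks"], tolerance = 1e-10)
  expect_equal(mine$statistic, ref[1, "approx F"], tolerance = 1e-10)
  expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)

  # invariance under a common nonsingular linear transform
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 1.1), 3, 3)
  expect_equal(manova_wilks(Y %*% A, g)$lambda, mine$lambda, tolerance = 1e-8)
})

test_that("phylogenetic MANOVA behaves on star trees and flags bad input", {
  st <- star_tree(18, 1)
  set.seed(13)
  # strong group separation: both classical and phylogenetic p small
  g <- setNames(rep(c("a", "b", "c"), each = 6), st$tip.label)
  X <- matrix(rnorm(18 * 3, 0, 0.3), 18, 3, dimnames = list(st$tip.label, NULL))
  X[g == "b", 1] <- X[g == "b", 1] + 3
  X[g == "c", 2] <- X[g == "c", 2] + 3
  pm <- phylo_manova(X, g, st, nsim = 199, seed = 14)
  expect_lt(pm$p_phylo, 0.05)
  expect_lt(pm$p_value, 1e-6)
  expect_length(pm$null, 199)

  # null data on a star tree: phylogenetic p agrees with the classical
  # parametric p up to Monte-Carlo error, on average over repeats
  diffs <- vapply(1:12, function(i) {
    Xn <- matrix(rnorm(18 * 3), 18, 3, dimnames = list(st$tip.label, NULL))
    pmn <- phylo_manova(Xn, g, st, nsim = 199, seed = 20 + i)
    pmn$p_phylo - pmn$p_value
  }, 0)
  expect_lt(abs(mean(diffs)), 0.15)

  expect_error(phylo_manova(X[1:5, ], g[1:5],
                            prune_to_taxa(st, st$tip.label[6:18]), nsim = 9),
               "missing from tree")
})
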