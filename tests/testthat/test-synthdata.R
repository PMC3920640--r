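# Generators: Yule/slowdown/birth-death trees, posterior jitter, ecotype
# painting, trait and specimen simulation.

test_that("Yule generator has the right crown-age moments and is reproducible", {
  ages <- vapply(1:4000, function(i) node_ages(sim_yule_tree(2, 2))$crown_age, 0)
  expect_equal(mean(ages), 1 / 4, tolerance = 0.05)   # Exp(2 lambda)

  expect_identical(write_trees(sim_yule_tree(15, 1, seed = 9)),
                   write_trees(sim_yule_tree(15, 1, seed = 9)))
  tr <- sim_yule_tree(30, 0.8, seed = 10)
  expect_equal(ape::Ntip(tr), 30)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.binary(tr))
})

test_that("slowdown trees concentrate nodes near the root", {
  g_slow <- vapply(1:60, function(i)
    gamma_stat(sim_slowdown_tree(18, 10, 4.5, seed = 2000 + i))$gamma, 0)
  g_const <- vapply(1:60, function(i)
    gamma_stat(sim_yule_tree(18, 1, seed = 2100 + i))$gamma, 0)
  expect_lt(median(g_slow), -1.5)
  expect_lt(median(g_slow), median(g_const) - 1)
  # decay = 0 is plain Yule at rate lambda0 (same seed, same tree)
  expect_identical(write_trees(sim_slowdown_tree(10, 2, 0, seed = 5)),
                   write_trees(sim_yule_tree(10, 2, seed = 5)))
})

test_that("birth-death trees have n tips and feel the pull of the present", {
  tr <- sim_bd_tree(12, 1, 0.5, seed = 171)
  expect_equal(ape::Ntip(tr), 12)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(write_trees(sim_bd_tree(12, 1, 0.5, seed = 171)),
                   write_trees(tr))
  # mu = 0 delegates to the Yule generator exactly
  expect_identical(write_trees(sim_bd_tree(12, 1, 0, seed = 3)),
                   write_trees(sim_yule_tree(12, 1, seed = 3)))

  g_bd <- vapply(1:150, function(i)
    gamma_stat(sim_bd_tree(25, 1, 0.6, seed = 2200 + i))$gamma, 0)
  g_yu <- vapply(1:150, function(i)
    gamma_stat(sim_yule_tree(25, 1, seed = 2300 + i))$gamma, 0)
  expect_gt(mean(g_bd), mean(g_yu))
  expect_error(sim_bd_tree(5, 1, 1.2), "lambda > mu")
})

test_that("posterior jitter preserves topology and targets the age spread", {
  tr <- sim_yule_tree(14, 1, seed = 181)
  same <- sim_posterior_ensemble(tr, 5, jitter_sd = 0, seed = 182)
  for (t2 in same) expect_equal(t2$edge.length, tr$edge.length)

  ens <- sim_posterior_ensemble(tr, 300, jitter_sd = 0.05, seed = 183)
  for (t2 in ens[1:10]) {
    expect_true(ape::is.ultrametric(t2, tol = 1e-8))
    expect_identical(t2$edge[, 1:2], tr$edge[, 1:2])
    expect_true(all(t2$edge.length > -1e-12))
  }
  crowns <- vapply(ens, function(t2) node_ages(t2)$crown_age, 0)
  cv <- sd(crowns) / mean(crowns)
  expect_equal(cv, 0.05, tolerance = 0.3)
})

test_that("ecotype painting partitions tips into few-clade classes", {
  tr <- sim_yule_tree(18, 1, seed = 191)
  one <- sim_ecotype_regimes(tr, classes = "ground")
  expect_true(all(one$species == "ground"))

  reg <- sim_ecotype_regimes(tr, seed = 192)
  expect_setequal(names(reg$species), tr$tip.label)
  expect_setequal(unique(reg$species), c("ground", "shrub", "treehole"))
  expect_length(reg$edge_regimes, nrow(tr$edge))

  # painted (non-background) classes are unions of at most two clades
  tipsets <- lapply(seq_len(ape::Ntip(tr) + tr$Nnode), function(nd) {
    if (nd <= ape::Ntip(tr)) tr$tip.label[nd]
    else ape::extract.clade(tr, nd)$tip.label
  })
  for (cl in c("shrub", "treehole")) {
    S <- sort(names(reg$species)[reg$species == cl])
    covered <- any(vapply(seq_along(tipsets), function(i) {
      identical(sort(tipsets[[i]]), S)
    }, logical(1)))
    if (!covered) {
      pairs <- combn(seq_along(tipsets), 2)
      covered <- any(apply(pairs, 2, function(pr) {
        identical(sort(unique(c(tipsets[[pr[1]]], tipsets[[pr[2]]]))), S)
      }))
    }
    expect_true(covered)
  }
})

test_that("trait generator: allometry recoverable, ecotypes separable, BM at null", {
  slopes_err <- vapply(1:40, function(i) {
    tr <- sim_yule_tree(30, 1, seed = 2400 + i)
    reg <- sim_ecotype_regimes(tr, seed = 2500 + i)
    X <- sim_species_traits(tr, reg, svl_var = 0.16, opt_sep = 0,
                            alpha_rel = 0, seed = 2600 + i)
    b_hat <- attr(size_correct(X, "snout_vent_length"), "coefficients")[2, ]
    b_true <- rep(c(1.05, 0.95, 1.0, 1.1, 0.9, 1.0, 0.85), length.out = 14)
    median(abs(b_hat - b_true) / b_true)
  }, 0)
  expect_lt(median(slopes_err), 0.1)

  # strong optima separation: MANOVA on true means rejects
  rej <- vapply(1:40, function(i) {
    tr <- sim_yule_tree(18, 1, seed = 2700 + i)
    reg <- sim_ecotype_regimes(tr, seed = 2800 + i)
    X <- sim_species_traits(tr, reg, opt_sep = 0.5, alpha_rel = 5, seed = 2900 + i)
    sc <- trait_pca(cbind(X[, 1, drop = FALSE],
                          size_correct(X, "snout_vent_length")))$scores[, 1:3]
    manova_wilks(sc, reg$species)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("specimen tables round-trip the species means and hit the protocol", {
  tr <- sim_yule_tree(12, 1, seed = 201)
  X <- sim_species_traits(tr, seed = 202)
  tab0 <- sim_specimen_table(X, noise_sd = 0, seed = 203)
  expect_equal(species_means(tab0)[rownames(X), colnames(X)], X,
               tolerance = 1e-12)

  counts <- table(tab0$species)
  expect_true(all(counts >= 3 & counts <= 10))
  expect_true(all(tab0$sex == "M"))

  # median specimen count ~ 8 and noise sd recovered across many species
  big <- matrix(log(20), 250, 3,
                dimnames = list(paste0("sp", 1:250), c("a", "b", "c")))
  tab <- sim_specimen_table(big, noise_sd = 0.1, seed = 204)
  expect_equal(median(table(tab$species)), 8, tolerance = 0.5)
  pooled <- sqrt(mean(tapply(log(tab$a), tab$species, var)))
  expect_equal(pooled, 0.1, tolerance = 0.1)
})

test_that("the bundled fixture is internally consistent and reproducible", {
  sm <- sim_radiation(n_posterior = 4, seed = 211)
  expect_setequal(rownames(sm$traits), sm$tree$tip.label)
  expect_setequal(names(sm$ecotypes), sm$tree$tip.label)
  expect_setequal(unique(sm$specimens$species), sm$tree$tip.label)
  expect_length(sm$posterior, 4)
  sm2 <- sim_radiation(n_posterior = 4, seed = 211)
  expect_identical(write_trees(sm$tree), write_trees(sm2$tree))
  expect_identical(sm$traits, sm2$traits)
  expect_identical(sm$specimens, sm2$specimens)
})
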