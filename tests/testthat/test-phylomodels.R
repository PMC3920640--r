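# Phylogenetic mean/GLS, rate matrix, phylogenetic PCA, BM/OU likelihoods
# and model selection, and trait simulators.

test_that("phylogenetic mean is GLS and reduces to ordinary means", {
  st <- star_tree(6, 2)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(st$tip.label, c("a", "b")))
  expect_equal(phylo_mean(X, tree_vcv(st)), colMeans(X))

  t2 <- read_trees(text = "(A:1,B:1);")[[1]]
  X2 <- matrix(c(1, 3), 2, 1, dimnames = list(c("A", "B"), "a"))
  expect_equal(unname(phylo_mean(X2, tree_vcv(t2))), 2)

  for (i in 1:10) {
    tr <- sim_yule_tree(sample(5:20, 1), 1, seed = 600 + i)
    C <- tree_vcv(tr)
    X <- simulate_bm(tr, diag(2), z0 = 0, seed = 700 + i)
    one <- rep(1, nrow(C))
    a_brute <- drop(solve(t(one) %*% solve(C, one)) %*% t(one) %*% solve(C, X))
    expect_equal(unname(phylo_mean(X, C)), unname(a_brute), tolerance = 1e-10)
  }
})

test_that("GLS residuals satisfy the generalized normal equations", {
  tr <- sim_yule_tree(12, 1, seed = 81)
  C <- tree_vcv(tr)
  X <- simulate_bm(tr, diag(2) + 0.4, z0 = 0, seed = 82)
  y <- X[, 1]; x <- X[, 2]

  # identity covariance reduces to OLS
  I_C <- diag(nrow(C)); dimnames(I_C) <- dimnames(C)
  ols <- size_correct(cbind(size = x, y = y), "size")
  expect_equal(as.numeric(phylo_gls_residuals(y, x, I_C)),
               unname(ols[, "y"]), tolerance = 1e-12)

  # exact affine relationship leaves zero residuals under any C
  expect_equal(max(abs(phylo_gls_residuals(2 + 3 * x, x, C))), 0,
               tolerance = 1e-10)

  r <- phylo_gls_residuals(y, x, C)
  expect_lt(max(abs(crossprod(cbind(1, x), solve(C, r)))), 1e-10)
  expect_error(phylo_gls_residuals(y, rep(1, length(x)), C), "collinear")
})

test_that("evolutionary rate matrix reduces to sample covariance on stars", {
  st <- star_tree(15, 1)
  X <- matrix(rnorm(45), 15, 3, dimnames = list(st$tip.label, letters[1:3]))
  expect_equal(evo_rate_matrix(X, tree_vcv(st)), cov(X), tolerance = 1e-10)
  idx <- sample(15)
  expect_equal(evo_rate_matrix(X[idx, ], tree_vcv(st)), cov(X), tolerance = 1e-10)
})

test_that("phylogenetic PCA matches covariance PCA on stars and phytools on trees", {
  st <- star_tree(12, 1)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(st$tip.label, letters[1:3]))
  pp <- phylo_pca(X, tree_vcv(st))
  pc <- trait_pca(X)
  expect_equal(abs(unname(pp$vectors)), abs(unname(pc$loadings)), tolerance = 1e-8)
  expect_equal(pp$var_frac, pc$var_frac, tolerance = 1e-8)

  expect_equal(sum(pp$eigenvalues), sum(diag(pp$R)), tolerance = 1e-10)

  # retention rule on constructed fractions (0.32, 0.28, 0.13, rest < 0.10)
  Xf <- matrix_with_fracs(30, c(0.32, 0.28, 0.13, 0.09, 0.09, 0.09))
  st2 <- star_tree(30, 1)
  rownames(Xf) <- st2$tip.label
  ppf <- phylo_pca(Xf, tree_vcv(st2), divisor = "n-1")
  expect_equal(ppf$retained, 1:3)

  skip_if_not_installed("phytools")
  tr <- sim_yule_tree(14, 1, seed = 91)
  Xt <- simulate_bm(tr, diag(3) + 0.5, z0 = 0, seed = 92)
  mine <- phylo_pca(Xt, tree_vcv(tr))
  ref <- phytools::phyl.pca(tr, Xt, method = "BM", mode = "cov")
  expect_equal(unname(mine$eigenvalues), unname(diag(ref$Eval)), tolerance = 1e-6)
  expect_equal(abs(unname(mine$scores)), abs(unname(unclass(ref$S))), tolerance = 1e-6)
})

test_that("BM and OU likelihoods equal brute-force Gaussian densities", {
  for (i in 1:8) {
    tr <- sim_yule_tree(sample(5:15, 1), 1, seed = 800 + i)
    C <- tree_vcv(tr)
    y <- simulate_bm(tr, matrix(0.7), z0 = 1, seed = 900 + i)[, 1]
    s2 <- runif(1, 0.3, 2); z0 <- rnorm(1)
    expect_equal(bm_loglik(y, tr, s2, z0),
                 mvn_loglik_brute(y, z0, s2 * C), tolerance = 1e-10)
    a <- runif(1, 0.2, 3)
    T_d <- mean(diag(C))
    V <- (s2 / (2 * a)) * exp(-2 * a * (T_d - C)) * (1 - exp(-2 * a * C))
    expect_equal(ou_loglik(y, tr, s2, a, z0),
                 mvn_loglik_brute(y, z0, V), tolerance = 1e-10)
  }
})

test_that("OU converges to BM as the pull vanishes and to white noise as it grows", {
  tr <- sim_yule_tree(8, 1, seed = 101)
  y <- simulate_bm(tr, matrix(1), z0 = 0, seed = 102)[, 1]
  expect_lt(abs(ou_loglik(y, tr, 1, 1e-9, 0) - bm_loglik(y, tr, 1, 0)), 1e-4)

  # alpha*T >> 1: tips are iid with the stationary variance sigma2/(2 alpha)
  a_big <- 400 / node_ages(tr)$crown_age
  iid <- sum(dnorm(y, 0, sqrt(1 / (2 * a_big)), log = TRUE))
  expect_equal(ou_loglik(y, tr, 1, a_big, 0), iid, tolerance = 1e-6)

  # OU tip covariance is PSD across the pull range
  C <- tree_vcv(tr); T_d <- mean(diag(C))
  for (a in c(0.01, 0.1, 1, 10)) {
    V <- (1 / (2 * a)) * exp(-2 * a * (T_d - C)) * (1 - exp(-2 * a * C))
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("BM/OU model comparison nests correctly and normalizes weights", {
  tr <- sim_yule_tree(20, 1, seed = 111)
  y <- simulate_bm(tr, matrix(1), z0 = 0, seed = 112)[, 1]
  fit <- as.data.frame(fit_evo_models(y, tr))
  expect_equal(sum(fit$weight), 1)
  expect_gte(fit$lnL[fit$model == "OU"], fit$lnL[fit$model == "BM"] - 1e-6)
  expect_equal(fit$k, c(2L, 3L))
})

test_that("Brownian simulation has the covariance the tree implies", {
  # degenerate tree: all branch lengths zero -> everything at the root state
  tr0 <- tree4()
  tr0$edge.length[] <- 0
  X0 <- simulate_bm(tr0, diag(2), z0 = c(3, -1), seed = 121)
  expect_equal(unname(X0), matrix(rep(c(3, -1), each = 4), 4, 2))

  tr <- tree4()
  R <- matrix(c(1, 0.6, 0.6, 2), 2, 2)
  expect_identical(simulate_bm(tr, R, seed = 122), simulate_bm(tr, R, seed = 122))

  sims <- sapply(1:4000, function(i) as.vector(simulate_bm(tr, R, z0 = 0)))
  emp <- cov(t(sims))
  theo <- kronecker(R, tree_vcv(tr))   # column-major: trait blocks
  expect_lt(max(abs(emp - theo)) / max(abs(theo)), 0.12)

  expect_error(simulate_bm(tr, matrix(c(1, 2, 2, 1), 2, 2)), "positive semidefinite")
})

test_that("OU simulation honors regimes and reduces to BM without pull", {
  tr <- sim_yule_tree(10, 1, seed = 131)
  th <- matrix(c(0, 5), 2, 1, dimnames = list(c("bg", "hi"), "y"))
  reg <- rep("bg", nrow(tr$edge))
  expect_identical(simulate_ou(tr, 1, 0.5, th, reg, seed = 132),
                   simulate_ou(tr, 1, 0.5, th, reg, seed = 132))
  expect_error(simulate_ou(tr, 1, 0.5, th, rep("zz", nrow(tr$edge))),
               "without optima")

  # alpha = 0, single regime: tip covariance matches BM moments
  sims_ou <- sapply(1:3000, function(i) simulate_ou(tr, 1, 0, th["bg", , drop = FALSE] + 0,
                                                    reg)[, 1])
  sims_bm <- sapply(1:3000, function(i) simulate_bm(tr, matrix(1), z0 = 0)[, 1])
  expect_lt(max(abs(cov(t(sims_ou)) - cov(t(sims_bm)))) /
              max(abs(tree_vcv(tr))), 0.15)

  # strong pull: tips sit near their regime's optimum
  T_d <- node_ages(tr)$crown_age
  reg_hi <- rep("hi", nrow(tr$edge))
  Xs <- simulate_ou(tr, 1, 20 / T_d, th, reg_hi, z0 = 0, seed = 133)
  stat_sd <- sqrt(1 / (2 * 20 / T_d))
  expect_lt(mean(abs(Xs[, 1] - 5)), 3 * stat_sd)
})
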