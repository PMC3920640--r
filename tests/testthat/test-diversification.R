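# Gamma statistic, pruning null, posterior summaries, model likelihoods
# and AICc ranking.

test_that("gamma matches hand values and the ape implementation", {
  # symmetric case: 2 g2 = T/2 forces gamma = 0  (g2 = 3, g3 = 2)
  tr0 <- read_trees(text = "((A:2,B:2):3,C:5);")[[1]]
  expect_equal(gamma_stat(tr0)$gamma, 0, tolerance = 1e-12)

  g4 <- gamma_stat(tree4())
  expect_equal(g4$gamma, -1 / (9 * sqrt(1 / 24)), tolerance = 1e-12)
  expect_equal(g4$total_time, 9)

  expect_error(gamma_stat(read_trees(text = "(A:1,B:1);")[[1]]), "n < 3")

  for (i in 1:20) {
    tr <- sim_yule_tree(sample(5:60, 1), runif(1, 0.2, 2), seed = 300 + i)
    expect_equal(gamma_stat(tr)$gamma, ape::gammaStat(tr), tolerance = 1e-10)
  }
})

test_that("gamma is invariant to uniform branch-length rescaling", {
  tr <- sim_yule_tree(25, 1, seed = 17)
  g <- gamma_stat(tr)$gamma
  for (c in c(0.1, 10)) {
    trc <- tr
    trc$edge.length <- trc$edge.length * c
    expect_equal(gamma_stat(trc)$gamma, g, tolerance = 1e-10)
  }
})

test_that("the random-pruning null gives a lower-tail +1-corrected p", {
  full <- sim_yule_tree(40, 1, seed = 21)
  sub <- random_prune(full, 15, seed = 22)
  res <- gamma_prune_test(full, sub, reps = 199, seed = 23)
  expect_length(res$null, 199)
  expect_equal(res$p_value, (sum(res$null <= res$gamma) + 1) / 200)
  expect_gt(res$p_value, 0)

  # determinism under seed
  res2 <- gamma_prune_test(full, sub, reps = 199, seed = 23)
  expect_identical(res$null, res2$null)

  # an observed gamma below every null value gives the boundary p = 1/(reps+1)
  res_b <- res
  res_b$gamma <- min(res$null) - 1
  res_b <- gamma_prune_test(full, res_b, m = res_b$n, reps = 199, seed = 23)
  expect_equal(res_b$p_value, 1 / 200)
})

test_that("posterior gamma summaries are percentile-based", {
  tr <- sim_yule_tree(12, 1, seed = 31)
  same <- c(structure(rep(list(tr), 10), class = "multiPhylo"))
  gp <- gamma_posterior(same)
  expect_equal(diff(gp$ci), 0)
  expect_equal(gp$median, gamma_stat(tr)$gamma)

  ens <- sim_posterior_ensemble(tr, 25, jitter_sd = 0.2, seed = 32)
  gp2 <- gamma_posterior(ens)
  expect_equal(gp2$median, median(gp2$values))
  expect_true(gp2$ci[1] <= gp2$median && gp2$median <= gp2$ci[2])
})

test_that("pure-birth likelihood has its textbook form and closed-form MLE", {
  t2 <- read_trees(text = "(A:1,B:1);")[[1]]
  expect_equal(loglik_yule(t2, 1), -2)     # no branching terms, T = 2
  expect_error(loglik_yule(t2, -1), "> 0")

  na <- node_ages(tree4())
  Tt <- sum((2:4) * na$g)
  expect_equal(Tt, 9)
  lam_hat <- (na$n - 2) / Tt
  ll <- vapply(lam_hat * c(0.9, 1, 1.1), function(l) loglik_yule(na, l), 0)
  expect_true(which.max(ll) == 2)
})

test_that("time-varying and birth-death likelihoods reduce exactly to pure birth", {
  for (i in 1:15) {
    tr <- sim_yule_tree(sample(4:40, 1), 1, seed = 400 + i)
    lam <- runif(1, 0.1, 2)
    expect_equal(loglik_expvar(tr, lam, 0), loglik_yule(tr, lam), tolerance = 1e-10)
    expect_equal(loglik_bd(tr, lam, 0), loglik_yule(tr, lam), tolerance = 1e-10)
  }
  expect_error(loglik_bd(tree4(), 1, 1.5), "lambda > mu")
})

test_that("near-zero rate variation stays near the pure-birth likelihood", {
  # a crown-age-20 tree and the conventional starting values
  tr <- sim_yule_tree(15, 1, seed = 41)
  tr$edge.length <- tr$edge.length * 20 / node_ages(tr)$crown_age
  expect_lt(abs(loglik_expvar(tr, 0.05, 1e-5) - loglik_yule(tr, 0.05)), 1e-3)
})

test_that("closed-form rate integrals match numeric quadrature", {
  for (i in 1:10) {
    tr <- sim_yule_tree(sample(5:25, 1), 1, seed = 500 + i)
    na <- node_ages(tr)
    lam0 <- runif(1, 0.2, 1.5); alpha <- runif(1, -1, 1)
    x <- na$ages
    hi <- x; lo <- c(x[-1], 0); k <- 2:na$n
    num <- sum(vapply(seq_along(k), function(j) {
      k[j] * integrate(function(t) lam0 * exp(alpha * t), lo[j], hi[j],
                       rel.tol = 1e-12)$value
    }, 0))
    events <- x[-1]
    ll_events <- sum(log(2:(na$n - 1)) + log(lam0) + alpha * events)
    expect_equal(loglik_expvar(na, lam0, alpha), ll_events - num, tolerance = 1e-8)
  }
})

test_that("birth-death likelihood decreases in extinction at the fitted net rate", {
  tr <- sim_yule_tree(30, 1, seed = 51)
  na <- node_ages(tr)
  r <- (na$n - 2) / sum((2:na$n) * na$g)   # pure-birth MLE as the net rate
  mus <- seq(0, 1.5, by = 0.25)
  ll <- vapply(mus, function(m) loglik_bd(tr, r + m, m), 0)
  expect_true(all(diff(ll) < 0))
})

test_that("model fitting ranks by AICc with weights summing to one", {
  tr <- sim_yule_tree(40, 1, seed = 61)
  fit <- fit_diversification(tr, seed = 62)
  expect_equal(sum(fit$weight), 1)
  expect_true(all(diff(fit$AICc) >= 0))
  expect_equal(fit$delta[1], 0)
  # matches ape::birthdeath on the bd model (independent optimizer)
  bd_row <- fit[fit$model == "bd", ]
  bd_ape <- ape::birthdeath(tr)
  expect_equal(bd_row$lambda - bd_row$mu, unname(bd_ape$para["b-d"]),
               tolerance = 1e-4)
})

test_that("posterior model summaries tally best and second-best fits", {
  tr <- sim_yule_tree(25, 1, seed = 71)
  same <- c(structure(rep(list(tr), 5), class = "multiPhylo"))
  pm <- posterior_models(same, seed = 72)
  expect_equal(sum(pm$best_freq), 1)
  expect_equal(max(pm$best_freq), 1)       # identical trees agree on one model
  expect_equal(sum(pm$second_freq), 1)
  expect_true(all(c("model", "best_freq", "second_freq",
                    "mean_weight", "sd_weight") %in% names(pm)))
  expect_equal(pm$sd_weight, rep(0, 3), tolerance = 1e-12)
})
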