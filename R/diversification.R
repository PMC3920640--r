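# Lineage-accumulation statistics: the gamma constant-rates test (with a
# random-pruning null and posterior summaries) and likelihood-based selection
# among diversification models fitted to branching times.

#' Gamma statistic of branching-time distribution
#'
#' Standardized summary of where divergence times sit between the crown and
#' the present. With internode intervals `g[k]` (k lineages present) and total
#' lineage-time `T = sum(k * g[k])`,
#' `gamma = (mean of partial lineage-time sums - T/2) / (T * sqrt(1/(12(n-2))))`.
#' Under a constant-rate pure-birth process gamma is asymptotically standard
#' normal; significantly negative values (gamma < -1.645, one-sided) indicate
#' internal nodes closer to the root than a Yule process expects, i.e. an
#' early burst of cladogenesis.
#'
#' @param tree An ultrametric `phylo` (n >= 3) or a `node_ages` object.
#' @return Object of class `gamma_test`: `gamma`, `n`, `total_time`, and
#'   (when a null has been attached by [gamma_prune_test()]) `null`,
#'   `p_value`.
#' @seealso [gamma_prune_test()], [gamma_posterior()]
#' @export
gamma_stat <- function(tree) {
  na <- node_ages(tree)
  n <- na$n
  if (n < 3L) stop("gamma undefined for n < 3")
  kg <- (2:n) * na$g              # k * g_k, k = 2..n
  Tt <- sum(kg)
  partial <- cumsum(kg)[seq_len(n - 2L)]  # sums up to i = 2..n-1
  gamma <- (mean(partial) - Tt / 2) / (Tt * sqrt(1 / (12 * (n - 2))))
  structure(list(gamma = gamma, n = n, total_time = Tt,
                 null = NULL, p_value = NULL),
            class = "gamma_test")
}

#' @export
print.gamma_test <- function(x, digits = 4, ...) {
  cat("Constant-rates (gamma) test\n")
  cat("  gamma =", format(x$gamma, digits = digits), " (n =", x$n, "tips)\n")
  if (!is.null(x$p_value)) {
    cat("  random-pruning null:", length(x$null), "replicates, one-sided P =",
        format(x$p_value, digits = digits), "\n")
  } else {
    cat("  one-sided 5% critical value under pure birth: -1.645\n")
  }
  invisible(x)
}

#' Random-pruning significance test for gamma
#'
#' Tests whether the gamma of an exemplar (pruned) tree is lower than expected
#' given the full tree: the null distribution is gamma computed on `reps`
#' replicate trees in which the full tree is randomly pruned to the same
#' number of tips. The p-value is lower-tailed with a +1 correction,
#' `p = (#\{null <= observed\} + 1) / (reps + 1)`.
#'
#' @param full_tree The complete ultrametric `phylo`.
#' @param observed A `gamma_test` from the exemplar tree, or the exemplar
#'   `phylo` itself.
#' @param m Tips to prune to; defaults to the observed tree's tip count.
#' @param reps Number of pruning replicates (1000 by convention).
#' @param seed Optional integer seed.
#' @return The `gamma_test` with `null` and `p_value` filled in.
#' @export
gamma_prune_test <- function(full_tree, observed, m = NULL, reps = 1000,
                             seed = NULL) {
  if (inherits(observed, "phylo")) observed <- gamma_stat(observed)
  if (!inherits(observed, "gamma_test")) stop("'observed' must be a phylo or gamma_test")
  m <- m %||% observed$n
  if (m != observed$n) stop("'m' must equal the observed tree's tip count")
  if (reps < 1L) stop("'reps' must be >= 1")
  null <- with_seed(seed, vapply(seq_len(reps), function(i) {
    gamma_stat(random_prune(full_tree, m))$gamma
  }, numeric(1)))
  observed$null <- null
  observed$p_value <- (sum(null <= observed$gamma) + 1) / (reps + 1)
  observed
}

#' Gamma across a posterior sample of trees
#'
#' Propagates topology/branch-length uncertainty: each posterior tree is
#' (optionally) pruned to `keep` and its gamma computed; the distribution is
#' summarized by its median and an equal-tail 95% percentile interval.
#'
#' @param trees A `multiPhylo` ensemble sharing a tip set.
#' @param keep Optional tip labels to prune each tree to.
#' @param level Interval level (default 0.95).
#' @return Object of class `gamma_posterior`: `values`, `median`, `ci`, `n_trees`.
#' @export
gamma_posterior <- function(trees, keep = NULL, level = 0.95) {
  vals <- vapply(trees, function(tr) {
    if (!is.null(keep)) tr <- prune_to_taxa(tr, keep)
    gamma_stat(tr)$gamma
  }, numeric(1))
  structure(list(values = vals, median = stats::median(vals),
                 ci = percentile_ci(vals, level), level = level,
                 n_trees = length(vals)),
            class = "gamma_posterior")
}

#' @export
print.gamma_posterior <- function(x, digits = 4, ...) {
  cat("Gamma over", x$n_trees, "posterior trees\n")
  cat("  median =", format(x$median, digits = digits), ";",
      sprintf("%.0f%%", 100 * x$level), "interval (",
      format(x$ci[1], digits = digits), ",",
      format(x$ci[2], digits = digits), ")\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Diversification-model likelihoods on branching times.
#
# All three include the combinatorial constant log((n-1)!) so that the
# time-varying and birth-death likelihoods reduce *exactly* to the pure-birth
# likelihood at alpha = 0 and mu = 0 (the constant cancels in AICc deltas).

#' Pure-birth (Yule) log-likelihood of branching times
#'
#' `lnL = log((n-1)!) + (n-2) log(lambda) - lambda * T`, with T the total
#' lineage-time. Maximized in closed form at `lambda = (n-2)/T`.
#'
#' @param ages A `node_ages` object or ultrametric `phylo`.
#' @param lambda Speciation rate (> 0), events per lineage per time unit.
#' @return Log-likelihood (scalar).
#' @export
loglik_yule <- function(ages, lambda) {
  na <- node_ages(ages)
  if (lambda <= 0) stop("'lambda' must be > 0")
  n <- na$n
  Tt <- sum((2:n) * na$g)
  lfactorial(n - 1) + (n - 2) * log(lambda) - lambda * Tt
}

#' Time-varying pure-birth log-likelihood
#'
#' Speciation rate `lambda(t) = lambda0 * exp(alpha * t)` with t the age
#' before present; `alpha > 0` means faster speciation deeper in the past
#' (a slowdown toward the present). Conditioning on the crown event, the
#' density of the branching ages x_i (i = 3..n) is
#' `sum log((i-1) lambda(x_i)) - integral of k(t) lambda(t) dt` over the crown
#' interval, with k(t) the piecewise-constant reconstructed lineage count;
#' the per-interval integrals are closed-form. At `alpha = 0` this equals
#' [loglik_yule()] exactly.
#'
#' @inheritParams loglik_yule
#' @param lambda0 Speciation rate at the present (> 0).
#' @param alpha Exponential rate-change parameter (1/time), unconstrained.
#' @return Log-likelihood (scalar).
#' @export
loglik_expvar <- function(ages, lambda0, alpha) {
  na <- node_ages(ages)
  if (lambda0 <= 0) stop("'lambda0' must be > 0")
  n <- na$n
  x <- na$ages                       # descending, x[1] = crown age
  events <- x[-1L]                   # ages x_i, i = 3..n
  ll_events <- sum(log((2:(n - 1))) + log(lambda0) + alpha * events)
  # integral over intervals: k lineages between ages lo_k and hi_k
  hi <- x                            # x_2 .. x_n
  lo <- c(x[-1L], 0)                 # x_3 .. x_n, 0
  k <- 2:n
  width <- hi - lo
  seg <- lambda0 * exp(alpha * lo) * width * relexpm1(alpha * width)
  if (any(!is.finite(seg))) stop("nonfinite rate integral (|alpha| too large)")
  ll_events - sum(k * seg)
}

#' Constant-rate birth-death log-likelihood (reconstructed process)
#'
#' Standard conditioned birth-death likelihood of branching ages: with net
#' rate `r = lambda - mu` and relative extinction `a = mu/lambda`,
#' `lnL = log((n-1)!) + (n-2) log r + n log(1-a) + r * sum(x_i, i>=3)
#'        - 2 * sum(log(exp(r x_i) - a), i>=2)`.
#' At `mu = 0` this equals [loglik_yule()] exactly.
#'
#' @inheritParams loglik_yule
#' @param lambda Speciation rate (> mu).
#' @param mu Extinction rate (>= 0).
#' @return Log-likelihood (scalar).
#' @export
loglik_bd <- function(ages, lambda, mu) {
  na <- node_ages(ages)
  if (mu < 0) stop("'mu' must be >= 0")
  if (lambda <= mu) stop("need lambda > mu (supercritical reconstructed process)")
  n <- na$n
  x <- na$ages
  r <- lambda - mu
  a <- mu / lambda
  lfactorial(n - 1) + (n - 2) * log(r) + n * log1p(-a) +
    r * sum(x[-1L]) - 2 * sum(log(exp(r * x) - a))
}

# ---------------------------------------------------------------------------
# Model fitting and ranking.

.div_models <- c("yule", "bd", "expvar")

# Maximum-likelihood fit of one model by bounded multi-start optimization on
# transformed parameters (log lambda; alpha free; logit a = mu/lambda).
.fit_one_model <- function(na, model, starts, n_random_starts, seed) {
  n <- na$n
  Tt <- sum((2:n) * na$g)
  lam_hat <- (n - 2) / Tt
  scale_t <- 1 / na$crown_age
  if (model == "yule") {
    f <- function(ll) loglik_yule(na, exp(ll))
    opt <- stats::optimize(function(ll) -f(ll),
                           interval = log(lam_hat) + c(-10, 10), tol = 1e-10)
    # polish: root of the finite-difference score (golden search alone is
    # only sqrt(eps)-accurate in the argument)
    h <- 1e-5
    score <- function(ll) (f(ll + h) - f(ll - h)) / (2 * h)
    ll_hat <- tryCatch(
      stats::uniroot(score, interval = opt$minimum + c(-0.05, 0.05),
                     tol = 1e-13)$root,
      error = function(e) opt$minimum)
    return(list(params = c(lambda = exp(ll_hat)), lnL = f(ll_hat), k = 1L))
  }
  negll <- switch(model,
    expvar = function(p) {
      v <- try(-loglik_expvar(na, exp(p[1]), p[2]), silent = TRUE)
      if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
    },
    bd = function(p) {
      a <- stats::plogis(p[2])
      v <- try(-loglik_bd(na, exp(p[1]), a * exp(p[1])), silent = TRUE)
      if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
    })
  base_start <- switch(model,
    expvar = rbind(c(log(starts$lambda), starts$alpha),
                   c(log(lam_hat), 0)),
    bd = rbind(c(log(starts$lambda), stats::qlogis(0.1)),
               c(log(lam_hat), stats::qlogis(0.05))))
  rand <- with_seed(seed, matrix(c(
    log(lam_hat) + stats::rnorm(n_random_starts, 0, 1),
    switch(model,
           expvar = stats::rnorm(n_random_starts, 0, scale_t * 2),
           bd = stats::qlogis(stats::runif(n_random_starts, 0.01, 0.9)))),
    ncol = 2))
  starts_mat <- rbind(base_start, rand)
  best <- NULL
  for (i in seq_len(nrow(starts_mat))) {
    fit <- try(stats::optim(starts_mat[i, ], negll, method = "Nelder-Mead",
                            control = list(reltol = 1e-12, maxit = 2000)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) return(NULL)
  p <- best$par
  params <- switch(model,
    expvar = c(lambda = exp(p[1]), alpha = p[2]),
    bd = c(lambda = exp(p[1]), mu = stats::plogis(p[2]) * exp(p[1])))
  list(params = params, lnL = -best$value, k = 2L)
}

#' Fit and rank diversification models on a tree's branching times
#'
#' Fits the pure-birth model (`"yule"`), the exponentially time-varying
#' pure-birth model (`"expvar"`) and the constant-rate birth-death model
#' (`"bd"`) by maximum likelihood, then ranks them by small-sample AICc and
#' Akaike weights. Optimization is multi-start on transformed parameters
#' (log speciation rate, free alpha, logit of mu/lambda), starting from
#' `lambda = 0.05`, `alpha = 1e-5` plus random starts. Complete sampling of
#' the clade is assumed throughout.
#'
#' @param tree Ultrametric `phylo` or `node_ages`.
#' @param models Subset of `c("yule", "bd", "expvar")`.
#' @param starts Named list of starting values (`lambda`, `alpha`).
#' @param n_obs AICc sample size: `"internodes"` (n - 2 informative waiting
#'   times, the default) or `"tips"` (n).
#' @param n_random_starts Extra random starts per model.
#' @param seed Optional integer seed (random starts only; fits are otherwise
#'   deterministic).
#' @return Object of class `divfit`: data frame with one row per model
#'   (lambda, alpha, mu, lnL, k, AICc, delta, weight), sorted by AICc.
#' @export
fit_diversification <- function(tree, models = c("yule", "bd", "expvar"),
                                starts = list(lambda = 0.05, alpha = 1e-5),
                                n_obs = c("internodes", "tips"),
                                n_random_starts = 4, seed = NULL) {
  models <- match.arg(models, .div_models, several.ok = TRUE)
  n_obs <- match.arg(n_obs)
  na <- node_ages(tree)
  nobs <- if (n_obs == "internodes") na$n - 2L else na$n
  seeds <- spawn_seeds(seed, length(models))
  rows <- lapply(seq_along(models), function(i) {
    m <- models[i]
    fit <- .fit_one_model(na, m, starts, n_random_starts, seeds[[i]])
    if (is.null(fit)) {
      warning("model '", m, "' failed to converge; excluded from weights")
      return(data.frame(model = m, lambda = NA_real_, alpha = NA_real_,
                        mu = NA_real_, lnL = NA_real_, k = NA_integer_,
                        AICc = NA_real_))
    }
    data.frame(model = m,
               lambda = unname(fit$params["lambda"]),
               alpha = unname(fit$params["alpha"] %|na|% NA_real_),
               mu = unname(fit$params["mu"] %|na|% NA_real_),
               lnL = fit$lnL, k = fit$k,
               AICc = aicc_value(fit$lnL, fit$k, nobs))
  })
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$weight <- aicc_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  structure(tab, class = c("divfit", "data.frame"),
            n = na$n, n_obs = nobs)
}

`%|na|%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.divfit <- function(x, digits = 4, ...) {
  cat("Diversification model comparison (n =", attr(x, "n"),
      "tips, AICc sample size", attr(x, "n_obs"), ")\n")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Model ranking summarized across a posterior tree sample
#'
#' Fits the model set to each posterior tree and tallies, per model, how often
#' it ranks best and second-best by AICc, plus the mean and SD of its Akaike
#' weight across trees.
#'
#' @inheritParams fit_diversification
#' @param trees A `multiPhylo` ensemble.
#' @param keep Optional tip labels to prune each tree to first.
#' @return Object of class `posterior_models`: data frame with columns
#'   `model`, `best_freq`, `second_freq`, `mean_weight`, `sd_weight`, sorted
#'   by `mean_weight`.
#' @export
posterior_models <- function(trees, keep = NULL,
                             models = c("yule", "bd", "expvar"),
                             starts = list(lambda = 0.05, alpha = 1e-5),
                             n_obs = c("internodes", "tips"), seed = NULL) {
  models <- match.arg(models, .div_models, several.ok = TRUE)
  n_obs <- match.arg(n_obs)
  seeds <- spawn_seeds(seed, length(trees))
  best <- second <- character(0)
  wts <- matrix(NA_real_, nrow = length(trees), ncol = length(models),
                dimnames = list(NULL, models))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!is.null(keep)) tr <- prune_to_taxa(tr, keep)
    fit <- fit_diversification(tr, models = models, starts = starts,
                               n_obs = n_obs, seed = seeds[[i]])
    ok <- fit[is.finite(fit$AICc), ]
    if (nrow(ok) == 0L) next
    best <- c(best, ok$model[1L])
    if (nrow(ok) >= 2L) second <- c(second, ok$model[2L])
    wts[i, ok$model] <- ok$weight
  }
  out <- data.frame(
    model = models,
    best_freq = vapply(models, function(m) mean(best == m), numeric(1)),
    second_freq = vapply(models, function(m) mean(second == m), numeric(1)),
    mean_weight = colMeans(wts, na.rm = TRUE),
    sd_weight = apply(wts, 2, stats::sd, na.rm = TRUE))
  out <- out[order(-out$mean_weight), ]
  rownames(out) <- NULL
  structure(out, class = c("posterior_models", "data.frame"),
            n_trees = length(trees))
}

#' @export
print.posterior_models <- function(x, digits = 3, ...) {
  cat("Diversification models across", attr(x, "n_trees"), "posterior trees\n")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}
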