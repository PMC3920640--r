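# Phylogenetically explicit trait machinery: GLS mean and residuals under the
# tree covariance C, the evolutionary rate matrix, phylogenetic PCA, exact
# BM/OU Gaussian likelihoods with AICc model selection, and trait simulation.

# Align a trait matrix (or vector) to the tip order of a covariance matrix.
.align_traits <- function(X, C) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(names(X), "trait"))
  X <- as.matrix(X)
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    miss <- setdiff(rownames(C), rownames(X))
    if (length(miss) > 0L) stop("species missing from traits: ", paste(miss, collapse = ", "))
    X <- X[rownames(C), , drop = FALSE]
  } else if (nrow(X) != nrow(C)) {
    stop("trait rows and covariance dimension differ and labels are absent")
  }
  X
}

.chol_solve <- function(C, B) {
  U <- tryCatch(chol(C), error = function(e) stop("singular phylogenetic covariance matrix"))
  backsolve(U, backsolve(U, B, transpose = TRUE))
}

#' Phylogenetic (GLS) mean of trait columns
#'
#' Generalized least squares estimate of the root state per character,
#' `a = (1' C^-1 1)^-1 1' C^-1 X`, under tree covariance C. On a star tree
#' (C proportional to the identity) this is the ordinary column mean.
#'
#' @param X Species-by-characters matrix (row names matched to `C`), or a
#'   named vector for one character.
#' @param C Phylogenetic covariance matrix from [tree_vcv()].
#' @return Named numeric vector, one entry per character.
#' @export
phylo_mean <- function(X, C) {
  X <- .align_traits(X, C)
  one <- matrix(1, nrow(C), 1)
  CiX <- .chol_solve(C, cbind(one, X))
  a <- drop(crossprod(one, CiX[, -1L, drop = FALSE]) / drop(crossprod(one, CiX[, 1L])))
  stats::setNames(a, colnames(X))
}

#' Phylogenetic GLS regression residuals
#'
#' Residuals of each response column regressed on `x` (with intercept) by
#' generalized least squares under tree covariance C: the phylogenetic
#' size-correction used to build shape variables. With `C = I` this is
#' ordinary least squares.
#'
#' @param Y Response matrix or vector (species rows).
#' @param x Predictor vector (typically log body size), named by species.
#' @param C Phylogenetic covariance matrix.
#' @return Residual matrix with the same shape as `Y`; regression
#'   coefficients in attribute `"coefficients"` (2 x p: intercept, slope).
#' @export
phylo_gls_residuals <- function(Y, x, C) {
  Y <- .align_traits(Y, C)
  x <- .align_traits(x, C)
  Xd <- cbind(`(Intercept)` = 1, slope = drop(x))
  CiX <- .chol_solve(C, Xd)
  XtCiX <- crossprod(Xd, CiX)
  if (!is.finite(rcond <- 1 / kappa(XtCiX)) || rcond < 1e-12) {
    stop("design matrix is (near-)collinear: predictor has no variance?")
  }
  beta <- solve(XtCiX, crossprod(CiX, Y))
  res <- Y - Xd %*% beta
  attr(res, "coefficients") <- beta
  res
}

#' Evolutionary rate matrix of a trait matrix on a tree
#'
#' Among-character covariance of evolutionary change per unit time under
#' Brownian motion: `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` with `a` the
#' phylogenetic mean. On a star tree with unit depths this is the ordinary
#' sample covariance.
#'
#' @inheritParams phylo_mean
#' @param divisor `"n-1"` (GLS cross-product, default) or `"n"` (ML).
#' @return Symmetric positive semidefinite p x p matrix.
#' @export
evo_rate_matrix <- function(X, C, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  X <- .align_traits(X, C)
  a <- phylo_mean(X, C)
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, .chol_solve(C, Xc)) /
    (nrow(X) - if (divisor == "n-1") 1L else 0L)
  R <- (R + t(R)) / 2
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

# Deterministic eigenvector signs: largest-magnitude loading positive.
.fix_signs <- function(V) {
  s <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(V, 2, s, `*`)
}

#' Phylogenetic principal component analysis
#'
#' Eigen-analysis of the evolutionary rate matrix R, with species scores
#' computed about the phylogenetic mean: `scores = (X - 1a) V`. Axes whose
#' eigenvalue fraction is at least `retain` are flagged as retained. On a
#' star tree with equal depths this reduces to ordinary covariance PCA.
#'
#' @inheritParams evo_rate_matrix
#' @param retain Minimum variance fraction for an axis to be retained
#'   (default 0.10).
#' @param scale_loadings `"eigenvector"` (unit-norm columns, default) or
#'   `"correlation"` (eigenvectors scaled by the square roots of their
#'   eigenvalues, comparable to trait-score correlations).
#' @return Object of class `phylo_pca`: `loadings`, `scores`, `eigenvalues`,
#'   `var_frac`, `retained` (axis indices), `mean` (phylogenetic mean), `R`.
#' @export
phylo_pca <- function(X, C, retain = 0.10, divisor = c("n-1", "n"),
                      scale_loadings = c("eigenvector", "correlation")) {
  scale_loadings <- match.arg(scale_loadings)
  X <- .align_traits(X, C)
  if (ncol(X) < 2L) stop("need at least 2 characters")
  R <- evo_rate_matrix(X, C, divisor = divisor)
  eig <- eigen(R, symmetric = TRUE)
  V <- .fix_signs(eig$vectors)
  lam <- pmax(eig$values, 0)
  a <- phylo_mean(X, C)
  scores <- sweep(X, 2, a) %*% V
  axes <- paste0("PC", seq_along(lam))
  dimnames(V) <- list(colnames(X), axes)
  dimnames(scores) <- list(rownames(X), axes)
  loadings <- if (scale_loadings == "correlation") sweep(V, 2, sqrt(lam), `*`) else V
  vf <- lam / sum(lam)
  structure(list(loadings = loadings, vectors = V, scores = scores,
                 eigenvalues = lam, var_frac = vf,
                 retained = which(vf >= retain), mean = a, R = R,
                 scale_loadings = scale_loadings),
            class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, digits = 3, ...) {
  cat("Phylogenetic PCA:", ncol(x$scores), "axes;",
      length(x$retained), "retained (variance fraction >= rule)\n")
  cat("variance fractions:",
      paste(format(x$var_frac[seq_len(min(5, length(x$var_frac)))], digits = digits),
            collapse = ", "),
      if (length(x$var_frac) > 5) "...\n" else "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# BM / OU likelihoods. Both are exact multivariate-normal densities with the
# covariance the process induces on the tips.

# Gaussian log-density via Cholesky of Sigma.
.mvn_loglik <- function(y, mean, Sigma) {
  U <- tryCatch(chol(Sigma), error = function(e) stop("singular trait covariance matrix"))
  r <- backsolve(U, y - mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2))
}

# OU tip covariance shape (sigma2 = 1): for ultrametric depth T and pairwise
# MRCA depths C, Cov_ij = (1/(2a)) exp(-2a(T - C_ij)) (1 - exp(-2a C_ij)).
.ou_shape <- function(C, alpha) {
  T_depth <- mean(diag(C))
  (1 / (2 * alpha)) * exp(-2 * alpha * (T_depth - C)) * (1 - exp(-2 * alpha * C))
}

#' Brownian-motion log-likelihood of one character
#'
#' `y ~ N(z0 * 1, sigma2 * C)` with C the tree covariance: the exact Gaussian
#' log-density of tip values under a random walk with rate `sigma2` started
#' at root state `z0`.
#'
#' @param y Named numeric vector of tip values.
#' @param tree Ultrametric `phylo`.
#' @param sigma2 Brownian rate (> 0), squared trait units per time unit.
#' @param z0 Root state.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(y, tree, sigma2, z0) {
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  C <- tree_vcv(tree)
  y <- drop(.align_traits(y, C))
  .mvn_loglik(y, z0, sigma2 * C)
}

#' Ornstein-Uhlenbeck log-likelihood of one character
#'
#' Single-optimum OU with the root state fixed at the optimum (`z0 = theta`,
#' non-stationary start): mean `z0 * 1` and covariance
#' `(sigma2/(2 alpha)) exp(-alpha d_ij) (1 - exp(-2 alpha t_ij))`, where
#' `t_ij` is the depth of the most recent common ancestor and
#' `d_ij = 2(T - t_ij)` the patristic distance. As `alpha -> 0` this
#' converges to [bm_loglik()]. `stationary = TRUE` instead starts the root at
#' the stationary variance `sigma2/(2 alpha)` (covariance
#' `(sigma2/(2 alpha)) exp(-alpha d_ij)`).
#'
#' @inheritParams bm_loglik
#' @param alpha Pull strength toward the optimum (> 0), 1/time.
#' @param stationary Use the stationary-start variant (default `FALSE`).
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(y, tree, sigma2, alpha, z0, stationary = FALSE) {
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  if (alpha <= 0) stop("'alpha' must be > 0; use bm_loglik for alpha = 0")
  C <- tree_vcv(tree)
  y <- drop(.align_traits(y, C))
  V <- if (stationary) {
    T_depth <- mean(diag(C))
    (1 / (2 * alpha)) * exp(-2 * alpha * (T_depth - C))
  } else {
    .ou_shape(C, alpha)
  }
  .mvn_loglik(y, z0, sigma2 * V)
}

# Profile log-likelihood for a fixed covariance shape V: z0 and sigma2 have
# closed-form ML solutions.
.profile_gauss <- function(y, V) {
  n <- length(y)
  U <- chol(V)
  one <- rep(1, n)
  w <- backsolve(U, cbind(one, y), transpose = TRUE)
  z0 <- sum(w[, 1] * w[, 2]) / sum(w[, 1]^2)
  r <- w[, 2] - z0 * w[, 1]
  s2 <- sum(r^2) / n
  lnL <- -0.5 * (n * log(2 * pi) + n * log(s2) + 2 * sum(log(diag(U))) + n)
  list(z0 = z0, sigma2 = s2, lnL = lnL)
}

#' Fit and compare BM and OU models for one character
#'
#' Maximum-likelihood fits of Brownian motion (k = 2 parameters: rate and
#' root state) and single-optimum Ornstein-Uhlenbeck (k = 3: rate, pull
#' strength, optimum = root state), compared by AICc (sample size = number of
#' species) and Akaike weights. The OU pull strength is profiled over
#' `log(alpha * T)` on a bounded grid refined by golden-section search; since
#' BM is the `alpha -> 0` boundary of OU, the OU log-likelihood is never
#' below the BM one beyond optimizer tolerance.
#'
#' @param y Named numeric vector of tip values (e.g. one PC axis).
#' @param tree Ultrametric `phylo` with `n >= 4` tips.
#' @param stationary Use the stationary-start OU variant.
#' @return Object of class `evofit`: data frame with rows `BM` and `OU`
#'   (sigma2, alpha, z0, lnL, k, AICc, delta, weight).
#' @export
fit_evo_models <- function(y, tree, stationary = FALSE) {
  C <- tree_vcv(tree)
  y <- drop(.align_traits(y, C))
  n <- length(y)
  if (n < 4L) stop("need at least 4 species")
  T_depth <- mean(diag(C))
  bm <- .profile_gauss(y, C)
  ou_prof <- function(log_aT) {
    a <- exp(log_aT) / T_depth
    V <- if (stationary) (1 / (2 * a)) * exp(-2 * a * (T_depth - C)) else .ou_shape(C, a)
    p <- try(.profile_gauss(y, V), silent = TRUE)
    if (inherits(p, "try-error")) return(-1e10)
    p$lnL
  }
  grid <- seq(-6, log(50), length.out = 25)
  vals <- vapply(grid, ou_prof, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ou_prof, interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
  alpha_hat <- exp(opt$maximum) / T_depth
  V_hat <- if (stationary) (1 / (2 * alpha_hat)) * exp(-2 * alpha_hat * (T_depth - C)) else .ou_shape(C, alpha_hat)
  ou <- .profile_gauss(y, V_hat)
  if (ou$lnL < bm$lnL) {           # boundary optimum: OU collapses to BM
    ou <- bm
    alpha_hat <- 0
  }
  tab <- data.frame(
    model = c("BM", "OU"),
    sigma2 = c(bm$sigma2, ou$sigma2),
    alpha = c(NA_real_, alpha_hat),
    z0 = c(bm$z0, ou$z0),
    lnL = c(bm$lnL, ou$lnL),
    k = c(2L, 3L),
    AICc = c(aicc_value(bm$lnL, 2, n), aicc_value(ou$lnL, 3, n)))
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- aicc_weights(tab$AICc)
  structure(tab, class = c("evofit", "data.frame"), n = n)
}

#' @export
print.evofit <- function(x, digits = 4, ...) {
  cat("BM vs OU model comparison (n =", attr(x, "n"), "species)\n")
  print.data.frame(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Simulation.

# Tips-by-edges root-path indicator matrix: tip value = z0 + sum of edge
# increments along its root path. Computed once per tree and reused across
# simulation replicates.
.path_matrix <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  parent_edge <- integer(nn)              # edge index leading into each node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  P <- matrix(0, n, nrow(tree$edge))
  for (tip in seq_len(n)) {
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      P[tip, e] <- 1
      node <- tree$edge[e, 1]
    }
  }
  rownames(P) <- tree$tip.label
  P
}

# nsim BM replicates sharing one precomputed path matrix; returns a list of
# n x p score matrices. Used by the DTT null and the phylogenetic MANOVA.
.simulate_bm_multi <- function(P, edge_len, R, nsim) {
  p <- nrow(R)
  L <- chol(R + diag(1e-12, p))
  sd_edge <- sqrt(edge_len)
  E <- matrix(stats::rnorm(length(edge_len) * p * nsim), nrow = length(edge_len)) * sd_edge
  Y <- P %*% E                            # n x (p * nsim), iid columns
  lapply(seq_len(nsim), function(i) {
    Y[, ((i - 1) * p + 1):(i * p), drop = FALSE] %*% L
  })
}

#' Simulate correlated characters under Brownian motion on a tree
#'
#' Branch-wise Gaussian increments with covariance `R * branch length`,
#' accumulated from the root state to the tips.
#'
#' @param tree Ultrametric `phylo`.
#' @param R p x p evolutionary rate matrix (positive semidefinite).
#' @param z0 Root state vector (recycled to p).
#' @param seed Optional integer seed.
#' @return n x p matrix of tip values, rows named by tip label.
#' @export
simulate_bm <- function(tree, R, z0 = 0, seed = NULL) {
  R <- as.matrix(R)
  if (any(abs(R - t(R)) > 1e-8)) stop("'R' must be symmetric")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("'R' must be positive semidefinite")
  }
  p <- nrow(R)
  z0 <- rep_len(z0, p)
  P <- .path_matrix(tree)
  X <- with_seed(seed, .simulate_bm_multi(P, tree$edge.length, R, 1L)[[1L]])
  X <- sweep(X, 2, z0, `+`)
  colnames(X) <- colnames(R) %||% paste0("V", seq_len(p))
  X
}

#' Simulate characters under an Ornstein-Uhlenbeck process with regimes
#'
#' Exact branch-wise OU transitions: along a branch of length t in regime
#' with optimum theta, the state decays toward theta with factor
#' `exp(-alpha t)` and picks up variance `sigma2/(2 alpha) (1 - exp(-2 alpha t))`
#' independently per character. `alpha = 0` reduces to Brownian motion with
#' rate `sigma2` (optima then have no effect).
#'
#' @param tree Ultrametric `phylo`.
#' @param sigma2 Stochastic rate (> 0), shared across characters.
#' @param alpha Pull strength (>= 0).
#' @param theta Matrix of per-regime optima (regimes x characters, row names
#'   = regime labels), or a named vector for one character.
#' @param regimes Character vector assigning each edge (in `tree$edge` order)
#'   to a regime label.
#' @param z0 Root state vector; defaults to the root edge's regime optimum.
#' @param seed Optional integer seed.
#' @return n x p matrix of tip values, rows named by tip label.
#' @export
simulate_ou <- function(tree, sigma2, alpha, theta, regimes, z0 = NULL,
                        seed = NULL) {
  if (sigma2 <= 0) stop("'sigma2' must be > 0")
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1, dimnames = list(names(theta), "trait"))
  theta <- as.matrix(theta)
  regimes <- as.character(regimes)
  if (length(regimes) != nrow(tree$edge)) {
    stop("'regimes' must assign every edge (length ", nrow(tree$edge), ")")
  }
  bad <- setdiff(unique(regimes), rownames(theta))
  if (length(bad) > 0L) stop("regimes without optima: ", paste(bad, collapse = ", "))
  p <- ncol(theta)
  n <- ape::Ntip(tree)
  root <- n + 1L
  if (is.null(z0)) {
    root_edge <- which(tree$edge[, 1] == root)[1L]
    z0 <- theta[regimes[root_edge], ]
  }
  z0 <- rep_len(z0, p)
  ord <- rev(ape::postorder(tree))           # parents before children
  with_seed(seed, {
    state <- matrix(NA_real_, n + tree$Nnode, p)
    state[root, ] <- z0
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      th <- theta[regimes[e], ]
      if (alpha == 0) {
        mu <- state[par, ]
        v <- sigma2 * t_e
      } else {
        f <- exp(-alpha * t_e)
        mu <- th + (state[par, ] - th) * f
        v <- sigma2 / (2 * alpha) * (1 - f^2)
      }
      state[child, ] <- mu + stats::rnorm(p, 0, sqrt(v))
    }
    X <- state[seq_len(n), , drop = FALSE]
    dimnames(X) <- list(tree$tip.label, colnames(theta))
    X
  })
}
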