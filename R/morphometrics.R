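# Ecomorphology stage: specimen-to-species means, size correction by
# regression residuals, covariance PCA with a variance-fraction retention
# rule, ecotype MANOVA (Wilks) and its simulation-based phylogenetic variant.

#' Species means of log-scale measurements
#'
#' Natural-log transforms each measurement, then averages per species, so the
#' species value is the log geometric mean of its specimens. Working on the
#' log scale makes the downstream size regression an allometric model and the
#' multiplicative measurement noise additive.
#'
#' @param specimens Data frame with a species column and strictly positive
#'   numeric measurement columns.
#' @param species_col Name of the species-id column.
#' @param measure_cols Measurement column names; default all numeric columns
#'   except the species column.
#' @param log Log-transform before averaging (default `TRUE`; `FALSE` gives
#'   raw-scale means).
#' @return Species-by-characters matrix, rows named by species.
#' @export
species_means <- function(specimens, species_col = "species",
                          measure_cols = NULL, log = TRUE) {
  if (!species_col %in% names(specimens)) {
    stop("no column '", species_col, "' in specimens")
  }
  if (is.null(measure_cols)) {
    measure_cols <- setdiff(names(specimens)[vapply(specimens, is.numeric, logical(1))],
                            species_col)
  }
  M <- as.matrix(specimens[, measure_cols, drop = FALSE])
  if (log) {
    bad <- which(!(M > 0), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      id <- if ("specimen_id" %in% names(specimens)) {
        specimens$specimen_id[bad[1L, 1L]]
      } else {
        paste("row", bad[1L, 1L])
      }
      stop("nonpositive measurement in '", measure_cols[bad[1L, 2L]],
           "' for specimen ", id)
    }
    M <- log(M)
  }
  sp <- factor(specimens[[species_col]])
  out <- rowsum(M, sp) / as.vector(table(sp))
  out[order(rownames(out)), , drop = FALSE]
}

#' Size-correct traits by ordinary least-squares residuals
#'
#' Regresses each character (except the size character) on size with an
#' intercept and returns the residuals: shape variables with the allometric
#' component removed. No phylogenetic covariance is used here; see
#' [phylo_gls_residuals()] for the phylogenetic version.
#'
#' @param traits Species-by-characters matrix (log scale).
#' @param size_char Column name of the size measure (snout-vent length).
#' @return Residual matrix (characters except `size_char`); regression
#'   coefficients in attribute `"coefficients"`.
#' @export
size_correct <- function(traits, size_char) {
  traits <- as.matrix(traits)
  if (!size_char %in% colnames(traits)) stop("no column '", size_char, "' in traits")
  if (nrow(traits) < 3L) stop("need at least 3 species")
  x <- traits[, size_char]
  if (stats::sd(x) == 0) stop("size character has zero variance")
  Y <- traits[, setdiff(colnames(traits), size_char), drop = FALSE]
  qx <- qr(cbind(1, x))
  res <- qr.resid(qx, Y)
  attr(res, "coefficients") <- qr.coef(qx, Y)
  res
}

#' Principal component analysis with a variance-fraction retention rule
#'
#' Column-centered, unscaled (covariance) PCA via [stats::prcomp()]; axes
#' whose variance fraction is at least `retain` are flagged as retained.
#' Eigenvector signs are fixed so each axis's largest-magnitude loading is
#' positive.
#'
#' @param X Species-by-variables matrix.
#' @param retain Minimum variance fraction to retain an axis (default 0.10).
#' @param scale. Use correlation-matrix PCA instead (default `FALSE`).
#' @return Object of class `trait_pca`: `loadings`, `scores`, `sdev`,
#'   `var_frac`, `retained`, `center`.
#' @export
trait_pca <- function(X, retain = 0.10, scale. = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 variables")
  if (all(apply(X, 2, stats::sd) == 0)) stop("constant matrix: no variance to analyze")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  s <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, s, `*`)
  pc$x <- sweep(pc$x, 2, s, `*`)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = pc$x, sdev = pc$sdev,
                 var_frac = vf, retained = which(vf >= retain),
                 center = pc$center),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  cat("PCA:", length(x$var_frac), "axes;", length(x$retained), "retained\n")
  cat("variance fractions:",
      paste(format(x$var_frac[seq_len(min(6, length(x$var_frac)))], digits = digits),
            collapse = ", "),
      if (length(x$var_frac) > 6) "...\n" else "\n")
  invisible(x)
}

# Wilks lambda from data and a grouping factor: lambda = det(E)/det(H + E)
# with E/H the within/between-group cross-product matrices. Internal so the
# simulation nulls can recompute the statistic cheaply.
.wilks_lambda <- function(Y, g) {
  Y <- as.matrix(Y)
  gm <- rowsum(Y, g) / as.vector(table(g))
  E <- crossprod(Y - gm[g, , drop = FALSE])
  Tm <- crossprod(sweep(Y, 2, colMeans(Y)))
  dE <- determinant(E, logarithm = TRUE)
  dT <- determinant(Tm, logarithm = TRUE)
  if (!is.finite(dE$modulus) || !is.finite(dT$modulus)) {
    stop("singular within-group cross-product matrix; reduce dimensions")
  }
  exp(as.numeric(dE$modulus - dT$modulus))
}

# Align a grouping map (named vector / factor / data frame) to row names.
.align_groups <- function(groups, labels) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2L]]), as.character(groups[[1L]]))
  }
  if (!is.null(names(groups))) {
    miss <- setdiff(labels, names(groups))
    if (length(miss) > 0L) stop("species without group: ", paste(miss, collapse = ", "))
    groups <- groups[labels]
  } else if (length(groups) != length(labels)) {
    stop("'groups' has no names and wrong length")
  }
  factor(as.character(groups))
}

#' MANOVA with the Wilks statistic
#'
#' Tests whether group (ecotype) means differ in multivariate trait space.
#' Wilks `lambda = det(E) / det(H + E)` from the within-group (E) and
#' between-group (H) cross-product matrices, with significance from Rao's F
#' approximation. Values near 0 mean groups explain most multivariate
#' variation.
#'
#' @param Y Observations-by-variables matrix (e.g. retained PC scores), rows
#'   named by species.
#' @param groups Group membership: named character vector / factor keyed by
#'   species, or a two-column data frame (species, group).
#' @return Object of class `wilks_manova`: `lambda`, `statistic` (F), `df`,
#'   `p_value`, `groups`.
#' @export
manova_wilks <- function(Y, groups) {
  Y <- as.matrix(Y)
  g <- .align_groups(groups, rownames(Y) %||% seq_len(nrow(Y)))
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  n <- nrow(Y); p <- ncol(Y); q <- nlevels(g) - 1L
  if (n < p + nlevels(g)) stop("too few observations for ", p, " variables and ",
                               nlevels(g), " groups")
  lambda <- .wilks_lambda(Y, g)
  # Rao's F approximation
  ve <- n - nlevels(g)
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- ve - (p - q + 1) / 2
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  Fstat <- ((1 - lambda^(1 / s)) / lambda^(1 / s)) * (df2 / df1)
  p_value <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(lambda = lambda, statistic = Fstat, df = c(df1 = df1, df2 = df2),
                 p_value = p_value, groups = g, n = n, p = p),
            class = "wilks_manova")
}

#' @export
print.wilks_manova <- function(x, digits = 4, ...) {
  cat("MANOVA (Wilks):", x$n, "species,", x$p, "variables,",
      nlevels(x$groups), "groups\n")
  cat("  lambda =", format(x$lambda, digits = digits),
      "; F(", format(x$df[1], digits = 3), ",", format(x$df[2], digits = 4),
      ") =", format(x$statistic, digits = digits),
      "; P =", format(x$p_value, digits = digits), "\n")
  if (!is.null(x$p_phylo)) {
    cat("  phylogenetic P =", format(x$p_phylo, digits = digits),
        " (", x$nsim, "BM simulations )\n")
  }
  invisible(x)
}

#' Simulation-based phylogenetic MANOVA
#'
#' Ecotype groups map onto clades, so related species share both group and
#' traits; the standard MANOVA null is then too liberal. This test keeps the
#' group labels fixed and simulates `nsim` multivariate Brownian-motion
#' datasets on the tree (rate matrix estimated from the data), recomputing
#' Wilks lambda for each. The phylogenetic p-value is lower-tailed with a +1
#' correction: `p = (#\{lambda_sim <= lambda_obs\} + 1) / (nsim + 1)`.
#'
#' @param traits Species-by-characters matrix (typically the ln-transformed
#'   measurements, excluding the size character).
#' @param groups As in [manova_wilks()].
#' @param tree Ultrametric `phylo` whose tips cover the species.
#' @param nsim Number of Brownian simulations (1000 by convention).
#' @param seed Optional integer seed.
#' @return A `wilks_manova` with `p_phylo`, `null` (simulated lambdas) and
#'   `nsim` added.
#' @export
phylo_manova <- function(traits, groups, tree, nsim = 1000, seed = NULL) {
  traits <- as.matrix(traits)
  miss <- setdiff(rownames(traits), tree$tip.label)
  if (length(miss) > 0L) stop("species missing from tree: ", paste(miss, collapse = ", "))
  tree <- prune_to_taxa(tree, rownames(traits))
  C <- tree_vcv(tree)
  traits <- traits[rownames(C), , drop = FALSE]
  obs <- manova_wilks(traits, groups)
  R <- evo_rate_matrix(traits, C)
  g <- .align_groups(groups, rownames(traits))
  P <- .path_matrix(tree)
  null <- with_seed(seed, {
    sims <- .simulate_bm_multi(P, tree$edge.length, R, nsim)
    vapply(sims, function(S) .wilks_lambda(S, g), numeric(1))
  })
  obs$null <- null
  obs$nsim <- nsim
  obs$p_phylo <- (sum(null <= obs$lambda) + 1) / (nsim + 1)
  obs
}
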