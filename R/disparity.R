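# Disparity-through-time: average pairwise disparity, subclade relative
# disparity, DTT curves on a tree's node-time grid, Brownian-motion null
# bands, the MDI area statistic, and MDI across posterior tree samples.

#' Morphological disparity of a point cloud
#'
#' Average Euclidean distance between all unordered pairs of points in
#' morphospace; a single point has disparity 0. `squared = TRUE` averages
#' squared distances instead (a common software default).
#'
#' @param points Numeric matrix (points x dimensions) or vector.
#' @param squared Average squared distances instead of distances.
#' @return Non-negative scalar.
#' @export
disparity <- function(points, squared = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  if (nrow(points) == 0L) stop("empty point set")
  if (nrow(points) == 1L) return(0)
  d <- stats::dist(points)
  if (squared) d <- d^2
  mean(d)
}

#' Relative disparity of a subclade
#'
#' Subclade disparity divided by the disparity of the whole set. Values above
#' 1 mean the subclade is more dispersed than the clade overall.
#'
#' @param sub Points of the subclade.
#' @param all Points of the whole clade.
#' @inheritParams disparity
#' @return Non-negative scalar; 0 for a singleton subclade.
#' @export
relative_disparity <- function(sub, all, squared = FALSE) {
  tot <- disparity(all, squared = squared)
  if (tot == 0) stop("total disparity is zero")
  disparity(sub, squared = squared) / tot
}

# ---------------------------------------------------------------------------
# DTT machinery. The time grid and subclade memberships depend only on the
# tree, so they are precomputed once (dtt_prep) and reused across the many
# simulated datasets of a null band.

# For each divergence event (nodes ordered root-first), the tip-index sets of
# the lineages present just after that event. Event m leaves m + 1 lineages.
dtt_prep <- function(tree) {
  n <- ape::Ntip(tree)
  na <- node_ages(tree)
  depth <- ape::node.depth.edgelength(tree)
  T_bar <- mean(depth[seq_len(n)])
  internal <- (n + 1L):(n + tree$Nnode)
  age <- pmax(T_bar - depth[internal], 0)
  # parents sort before children: descending age, preorder index breaks ties
  ord <- internal[order(-age, internal)]
  age_ord <- T_bar - depth[ord]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tipsets <- vector("list", n + tree$Nnode)   # descendant tip indices
  for (nd in c(seq_len(n), rev(ord))) {   # tips, then internals youngest-first
    tipsets[[nd]] <- if (nd <= n) nd else unlist(tipsets[kids[[as.character(nd)]]])
  }
  # active lineage sets after each event
  active <- vector("list", tree$Nnode)
  cur <- kids[[as.character(ord[1L])]]
  active[[1L]] <- cur
  for (m in seq_len(tree$Nnode - 1L)) {
    nd <- ord[m + 1L]
    cur <- c(setdiff(cur, nd), kids[[as.character(nd)]])
    active[[m + 1L]] <- cur
  }
  sets <- lapply(active, function(s) lapply(s, function(nd) tipsets[[nd]]))
  rel_time <- c(0, (T_bar - age_ord[-1L]) / T_bar, 1)
  list(rel_time = rel_time, sets = sets[-1L], n = n,
       tip_labels = tree$tip.label)
}

# Curve values for one dataset given precomputed sets and a pairwise distance
# matrix D (tips in tree order, zero diagonal).
.dtt_values <- function(prep, D, squared = FALSE) {
  n <- prep$n
  if (squared) D <- D^2
  total <- sum(D) / (n * (n - 1))
  if (total == 0) stop("total disparity is zero")
  vals <- vapply(prep$sets, function(lin) {
    rd <- vapply(lin, function(idx) {
      m <- length(idx)
      if (m < 2L) return(0)
      sum(D[idx, idx]) / (m * (m - 1))
    }, numeric(1))
    mean(rd) / total
  }, numeric(1))
  c(1, vals, 0)
}

#' Disparity-through-time curve
#'
#' Mean relative subclade disparity evaluated at each divergence event, on
#' relative time from the root (0) to the present (1). At the root the clade
#' relative to itself has value 1; at each subsequent node the lineages
#' present just after that divergence contribute the relative disparities of
#' their descendant tip sets (singletons contribute 0); a terminal point
#' (1, 0) is appended.
#'
#' @param tree Ultrametric `phylo`.
#' @param scores Species-by-axes matrix of morphospace coordinates (row names
#'   matched to tip labels).
#' @inheritParams disparity
#' @return Object of class `dtt_curve`: `rel_time`, `disparity`.
#' @export
dtt_curve <- function(tree, scores, squared = FALSE) {
  prep <- dtt_prep(tree)
  scores <- .align_traits(scores, diag(prep$n) |>
                            `dimnames<-`(list(prep$tip_labels, prep$tip_labels)))
  D <- as.matrix(stats::dist(scores))
  structure(list(rel_time = prep$rel_time,
                 disparity = .dtt_values(prep, D, squared = squared)),
            class = "dtt_curve")
}

#' @export
print.dtt_curve <- function(x, digits = 3, ...) {
  cat("DTT curve over", length(x$rel_time), "time points\n")
  print(data.frame(rel_time = round(x$rel_time, digits),
                   disparity = round(x$disparity, digits)), row.names = FALSE)
  invisible(x)
}

#' Morphological disparity index (MDI)
#'
#' Signed area between an observed DTT curve and a reference (null median)
#' curve on a shared time grid, by left-step integration:
#' `sum((obs_j - ref_j) * (t_{j+1} - t_j))`. Positive values mean observed
#' subclade disparity exceeds the Brownian expectation, i.e. disparity is
#' partitioned within subclades.
#'
#' @param observed,reference `dtt_curve` objects (or numeric value vectors
#'   on the same grid as `times`).
#' @param times Time grid when raw vectors are given.
#' @return Scalar MDI.
#' @export
mdi <- function(observed, reference, times = NULL) {
  if (inherits(observed, "dtt_curve")) {
    times <- observed$rel_time
    observed <- observed$disparity
  }
  if (inherits(reference, "dtt_curve")) {
    if (is.null(times)) stop("no time grid")
    if (length(reference$rel_time) != length(times) ||
        any(abs(reference$rel_time - times) > 1e-9)) {
      stop("curves are on different time grids")
    }
    reference <- reference$disparity
  }
  if (length(observed) != length(reference) || length(observed) != length(times)) {
    stop("curves are on different time grids")
  }
  sum((observed - reference)[-length(times)] * diff(times))
}

#' DTT null band and MDI under Brownian motion
#'
#' Estimates the evolutionary rate matrix from the scores, simulates `nsim`
#' Brownian datasets on the tree, and computes the DTT curve of each on the
#' tree's node-time grid. Returns per-time median and equal-tail 95% band,
#' and the MDI of the observed curve against the simulation median.
#'
#' @param tree Ultrametric `phylo`.
#' @param scores Species-by-axes morphospace matrix.
#' @param nsim Number of Brownian simulations (10000 for a headline analysis;
#'   smaller values are adequate for per-tree posterior sweeps).
#' @param seed Optional integer seed.
#' @param level Band level (default 0.95).
#' @inheritParams disparity
#' @return Object of class `dtt_null`: `rel_time`, `observed`, `null_median`,
#'   `lo`, `hi`, `mdi`, `nsim`.
#' @export
dtt_null <- function(tree, scores, nsim = 10000, seed = NULL, level = 0.95,
                     squared = FALSE) {
  if (nsim < 2L) stop("'nsim' must be >= 2")
  prep <- dtt_prep(tree)
  C <- tree_vcv(tree)
  scores <- .align_traits(scores, C)
  R <- evo_rate_matrix(scores, C)
  obs <- .dtt_values(prep, as.matrix(stats::dist(scores)), squared = squared)
  P <- .path_matrix(tree)
  sim_curves <- with_seed(seed, {
    sims <- .simulate_bm_multi(P, tree$edge.length, R, nsim)
    vapply(sims, function(S) .dtt_values(prep, as.matrix(stats::dist(S)),
                                         squared = squared),
           numeric(length(prep$rel_time)))
  })
  a <- (1 - level) / 2
  qs <- apply(sim_curves, 1, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  med <- qs[2, ]
  structure(list(rel_time = prep$rel_time, observed = obs, null_median = med,
                 lo = qs[1, ], hi = qs[3, ],
                 mdi = mdi(obs, med, prep$rel_time),
                 nsim = nsim, level = level),
            class = "dtt_null")
}

#' @export
print.dtt_null <- function(x, digits = 4, ...) {
  cat("Disparity-through-time vs", x$nsim, "BM simulations\n")
  cat("  MDI =", format(x$mdi, digits = digits), "\n")
  invisible(x)
}

#' As a data frame: the DTT curve with its null band
#' @param x A `dtt_null` object.
#' @param ... Unused.
#' @export
as.data.frame.dtt_null <- function(x, ...) {
  data.frame(rel_time = x$rel_time, observed = x$observed,
             null_median = x$null_median, lo = x$lo, hi = x$hi)
}

#' MDI distribution across a posterior tree sample
#'
#' For each posterior tree: size-correct the traits phylogenetically with
#' that tree's covariance, run a phylogenetic PCA, take the scores on the
#' requested axes, and compute the MDI against a Brownian null of
#' `nsim_each` simulations. The per-tree MDI values give a posterior
#' distribution summarized by its median and an equal-tail 95% interval.
#'
#' @param trees A `multiPhylo` ensemble.
#' @param traits Species-by-characters matrix of log-scale species means
#'   (including the size character).
#' @param size_char Column name of the size character.
#' @param axes PC-axis indices to use as the morphospace (default `1:3`).
#' @param nsim_each Brownian simulations per tree (1000 by convention).
#' @param seed Optional integer seed.
#' @param level Interval level.
#' @return Object of class `posterior_mdi`: `values`, `median`, `ci`,
#'   `n_trees`, `failures`.
#' @export
posterior_mdi <- function(trees, traits, size_char, axes = 1:3,
                          nsim_each = 1000, seed = NULL, level = 0.95) {
  traits <- as.matrix(traits)
  seeds <- spawn_seeds(seed, length(trees))
  failures <- 0L
  vals <- rep(NA_real_, length(trees))
  for (i in seq_along(trees)) {
    v <- try({
      tr <- prune_to_taxa(trees[[i]], rownames(traits))
      C <- tree_vcv(tr)
      Y <- traits[rownames(C), , drop = FALSE]
      shape <- phylo_gls_residuals(Y[, setdiff(colnames(Y), size_char), drop = FALSE],
                                   Y[, size_char], C)
      pp <- phylo_pca(shape, C)
      sc <- pp$scores[, axes, drop = FALSE]
      dtt_null(tr, sc, nsim = nsim_each, seed = seeds[[i]], level = level)$mdi
    }, silent = TRUE)
    if (inherits(v, "try-error")) failures <- failures + 1L else vals[i] <- v
  }
  ok <- vals[!is.na(vals)]
  if (length(ok) == 0L) stop("MDI failed on every tree")
  structure(list(values = ok, median = stats::median(ok),
                 ci = percentile_ci(ok, level), level = level,
                 n_trees = length(ok), failures = failures),
            class = "posterior_mdi")
}

#' @export
print.posterior_mdi <- function(x, digits = 4, ...) {
  cat("MDI over", x$n_trees, "posterior trees",
      if (x$failures > 0) paste0("(", x$failures, " failed)"), "\n")
  cat("  median =", format(x$median, digits = digits), ";",
      sprintf("%.0f%%", 100 * x$level), "interval (",
      format(x$ci[1], digits = digits), ",",
      format(x$ci[2], digits = digits), ")\n")
  invisible(x)
}
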