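# End-to-end orchestration: reconcile input labels, run the lineage-tempo,
# ecomorphology and disparity stages with independent seed streams, and
# return (optionally write) machine-readable report tables.

#' Reconcile labels across trees, traits and ecotype maps
#'
#' Case- and whitespace-normalized matching of tip labels, trait rows and
#' ecotype keys; reports what fails to match rather than erroring.
#'
#' @param tree A `phylo` (or `multiPhylo`, first tree used).
#' @param traits Species-by-characters matrix.
#' @param ecotypes Named vector or two-column data frame (species, class).
#' @return List: `matched` (canonical labels present everywhere),
#'   `tips_without_traits`, `traits_without_tips`, `species_without_ecotype`.
#' @export
reconcile_labels <- function(tree, traits = NULL, ecotypes = NULL) {
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  norm <- function(x) tolower(gsub("\\s+", "", as.character(x)))
  tips <- tree$tip.label
  trait_sp <- if (is.null(traits)) character(0) else rownames(as.matrix(traits))
  eco_sp <- if (is.null(ecotypes)) {
    character(0)
  } else if (is.data.frame(ecotypes)) {
    as.character(ecotypes[[1L]])
  } else {
    names(ecotypes)
  }
  m_tt <- if (is.null(traits)) tips else tips[norm(tips) %in% norm(trait_sp)]
  list(
    matched = m_tt,
    tips_without_traits = if (is.null(traits)) character(0) else setdiff(tips, tips[norm(tips) %in% norm(trait_sp)]),
    traits_without_tips = if (is.null(traits)) character(0) else trait_sp[!norm(trait_sp) %in% norm(tips)],
    species_without_ecotype = if (is.null(ecotypes)) character(0) else {
      need <- if (is.null(traits)) tips else trait_sp
      need[!norm(need) %in% norm(eco_sp)]
    })
}

#' Run the full radiation-tempo analysis
#'
#' Composes the stages end to end on one input bundle: gamma test (with
#' random-pruning null and posterior summary), diversification-model ranking
#' (single tree and across the posterior), species means, size correction and
#' PCA, ecotype MANOVA with phylogenetic null, phylogenetic PCA,
#' disparity-through-time with a Brownian null band (all retained axes and
#' per axis), BM/OU fits per axis, and the MDI posterior distribution.
#'
#' @param tree Ultrametric `phylo` (the point-estimate tree).
#' @param specimens Specimen data frame (see [species_means()]).
#' @param ecotypes Species-to-ecotype map (named vector or 2-column data
#'   frame).
#' @param posterior Optional `multiPhylo` posterior ensemble.
#' @param full_tree Optional complete tree (e.g. with every sampled
#'   individual) from which `tree` was pruned; when given, the gamma test
#'   gains a random-pruning null (gamma of `full_tree` pruned to
#'   `Ntip(tree)` tips, `nsim$gamma_null` replicates).
#' @param size_char Size-character column name.
#' @param nsim Named list of simulation sizes; defaults
#'   `list(gamma_null = 1000, manova = 1000, dtt = 10000, dtt_tree = 1000)`.
#' @param retain Variance-fraction retention rule for PC axes.
#' @param n_axes Phylogenetic PC axes used for the DTT morphospace.
#' @param posterior_max Cap on posterior trees swept for the heavier
#'   per-tree analyses (`NULL` = all).
#' @param seed Master seed; expanded into independent per-stage streams so
#'   disabling one stage does not shift another's randomness.
#' @param stages Character vector to restrict which stages run
#'   (subset of `c("gamma", "models", "morph", "disparity")`).
#' @return Object of class `radiation_report`: a list of the stage results.
#' @export
run_radiation <- function(tree, specimens, ecotypes, posterior = NULL,
                          full_tree = NULL,
                          size_char = "snout_vent_length",
                          nsim = list(), retain = 0.10, n_axes = 3,
                          posterior_max = NULL, seed = NULL,
                          stages = c("gamma", "models", "morph", "disparity")) {
  nsim_def <- list(gamma_null = 1000, manova = 1000, dtt = 10000, dtt_tree = 1000)
  nsim <- utils::modifyList(nsim_def, nsim)
  seeds <- spawn_seeds(seed, 6L)
  out <- list(seeds = seeds, nsim = nsim, stages = stages)

  traits <- species_means(specimens)
  recon <- reconcile_labels(tree, traits, ecotypes)
  if (length(recon$tips_without_traits) > 0L || length(recon$traits_without_tips) > 0L ||
      length(recon$species_without_ecotype) > 0L) {
    stop("label mismatch between inputs:\n",
         paste(utils::capture.output(utils::str(recon)), collapse = "\n"))
  }
  traits <- traits[tree$tip.label, , drop = FALSE]
  out$traits <- traits

  post <- posterior
  if (!is.null(post) && !is.null(posterior_max) && length(post) > posterior_max) {
    post <- post[seq_len(posterior_max)]
    class(post) <- "multiPhylo"
  }

  if ("gamma" %in% stages) {
    g <- gamma_stat(tree)
    out$gamma <- if (is.null(full_tree)) g else {
      gamma_prune_test(full_tree, g, reps = nsim$gamma_null, seed = seeds[[1L]])
    }
    if (!is.null(post)) out$gamma_posterior <- gamma_posterior(post)
  }
  if ("models" %in% stages) {
    out$divfit <- fit_diversification(tree, seed = seeds[[2L]])
    if (!is.null(post)) {
      out$posterior_models <- posterior_models(post, seed = seeds[[3L]])
    }
  }
  if ("morph" %in% stages) {
    shape <- size_correct(traits, size_char)
    pca_in <- cbind(traits[, size_char, drop = FALSE], shape)
    out$pca <- trait_pca(pca_in, retain = retain)
    sc <- out$pca$scores[, out$pca$retained, drop = FALSE]
    out$manova <- manova_wilks(sc, ecotypes)
    out$phylo_manova <- phylo_manova(traits[, setdiff(colnames(traits), size_char)],
                                     ecotypes, tree, nsim = nsim$manova,
                                     seed = seeds[[4L]])
  }
  if ("disparity" %in% stages) {
    C <- tree_vcv(tree)
    Y <- traits[rownames(C), , drop = FALSE]
    shape_p <- phylo_gls_residuals(Y[, setdiff(colnames(Y), size_char), drop = FALSE],
                                   Y[, size_char], C)
    out$phylo_pca <- phylo_pca(shape_p, C, retain = retain)
    sc <- out$phylo_pca$scores[, seq_len(n_axes), drop = FALSE]
    out$dtt <- dtt_null(tree, sc, nsim = nsim$dtt, seed = seeds[[5L]])
    out$dtt_per_axis <- lapply(seq_len(n_axes), function(j) {
      dtt_null(tree, sc[, j, drop = FALSE], nsim = nsim$dtt, seed = seeds[[5L]])
    })
    out$evofit <- lapply(seq_len(n_axes), function(j) fit_evo_models(sc[, j], tree))
    names(out$evofit) <- names(out$dtt_per_axis) <- colnames(sc)
    if (!is.null(post)) {
      out$posterior_mdi <- posterior_mdi(post, traits, size_char,
                                         axes = seq_len(n_axes),
                                         nsim_each = nsim$dtt_tree,
                                         seed = seeds[[6L]])
    }
  }
  structure(out, class = "radiation_report")
}

#' @export
print.radiation_report <- function(x, digits = 4, ...) {
  cat("== Radiation tempo report ==\n")
  if (!is.null(x$gamma)) print(x$gamma, digits = digits)
  if (!is.null(x$gamma_posterior)) print(x$gamma_posterior, digits = digits)
  if (!is.null(x$divfit)) print(x$divfit, digits = digits)
  if (!is.null(x$posterior_models)) print(x$posterior_models, digits = digits)
  if (!is.null(x$pca)) print(x$pca)
  if (!is.null(x$manova)) print(x$manova, digits = digits)
  if (!is.null(x$phylo_pca)) print(x$phylo_pca)
  if (!is.null(x$dtt)) print(x$dtt, digits = digits)
  if (!is.null(x$posterior_mdi)) print(x$posterior_mdi, digits = digits)
  invisible(x)
}

#' Write a radiation report as CSV/JSON files
#'
#' Emits the report's tables (gamma, model fits, PCA loadings, DTT curve,
#' MDI and MANOVA summaries) as plain CSV plus one JSON summary into a
#' directory.
#'
#' @param report A `radiation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$divfit)) w(as.data.frame(report$divfit), "diversification_models.csv")
  if (!is.null(report$posterior_models)) {
    w(as.data.frame(report$posterior_models), "posterior_models.csv")
  }
  if (!is.null(report$pca)) {
    w(data.frame(trait = rownames(report$pca$loadings), report$pca$loadings,
                 check.names = FALSE), "pca_loadings.csv")
  }
  if (!is.null(report$phylo_pca)) {
    w(data.frame(trait = rownames(report$phylo_pca$loadings),
                 report$phylo_pca$loadings, check.names = FALSE),
      "phylo_pca_loadings.csv")
  }
  if (!is.null(report$dtt)) w(as.data.frame(report$dtt), "dtt_curve.csv")
  if (!is.null(report$evofit)) {
    tab <- do.call(rbind, lapply(names(report$evofit), function(nm) {
      cbind(axis = nm, as.data.frame(report$evofit[[nm]]))
    }))
    w(tab, "evo_model_fits.csv")
  }
  summ <- list()
  if (!is.null(report$gamma)) {
    summ$gamma <- list(value = report$gamma$gamma, n = report$gamma$n,
                       p_prune = report$gamma$p_value)
  }
  if (!is.null(report$gamma_posterior)) {
    summ$gamma_posterior <- list(median = report$gamma_posterior$median,
                                 ci = report$gamma_posterior$ci)
  }
  if (!is.null(report$manova)) {
    summ$manova <- list(wilks_lambda = report$manova$lambda,
                        p = report$manova$p_value)
  }
  if (!is.null(report$phylo_manova)) {
    summ$phylo_manova <- list(wilks_lambda = report$phylo_manova$lambda,
                              p_phylo = report$phylo_manova$p_phylo)
  }
  if (!is.null(report$dtt)) summ$mdi <- report$dtt$mdi
  if (!is.null(report$posterior_mdi)) {
    summ$posterior_mdi <- list(median = report$posterior_mdi$median,
                               ci = report$posterior_mdi$ci)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "summary.json")
    jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
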