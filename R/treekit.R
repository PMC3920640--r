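# Tree input, validation and manipulation. Trees are ape "phylo" objects
# (ensembles are "multiPhylo"); all analyses assume rooted ultrametric
# chronograms with branch lengths in time units.

#' Read ultrametric time trees from Newick or NEXUS text
#'
#' Parses one or more rooted time-calibrated trees and validates each one:
#' branch lengths must be present and non-negative, tip labels unique, internal
#' nodes binary (optionally resolved), and root-to-tip depths equal within a
#' relative tolerance. NEXUS `Translate` tables are resolved to tip labels.
#'
#' @param file Path to a tree file, or `NULL` when `text` is given.
#' @param text Character scalar holding Newick/NEXUS content, as an
#'   alternative to `file`.
#' @param format `"auto"` (detect a `#NEXUS` header), `"newick"`, or `"nexus"`.
#' @param polytomies `"error"` to reject non-binary nodes, `"resolve"` to break
#'   them into zero-length binary splits.
#' @param negative `"error"` to reject negative branch lengths, `"clamp"` to
#'   set them to zero with a warning (negative lengths occur in some maximum
#'   clade credibility trees).
#' @param ultra_tol Relative ultrametricity tolerance: the root-to-tip depth
#'   spread must not exceed `ultra_tol` times the mean depth. Posterior trees
#'   written with finite precision carry rounding jitter, hence a tolerance
#'   rather than exact equality.
#' @return An ape `multiPhylo` list of validated trees (possibly of length 1).
#' @export
read_trees <- function(file = NULL, text = NULL,
                       format = c("auto", "newick", "nexus"),
                       polytomies = c("error", "resolve"),
                       negative = c("error", "clamp"),
                       ultra_tol = 1e-6) {
  format <- match.arg(format)
  polytomies <- match.arg(polytomies)
  negative <- match.arg(negative)
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'file' or 'text'")
  }
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    ape::read.nexus(tf)
  } else {
    ape::read.tree(text = text)
  }
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees), class = "multiPhylo"))
  if (is.null(trees) || length(trees) == 0L) {
    stop("no tree could be parsed from the input (malformed Newick/NEXUS?)")
  }
  out <- lapply(trees, validate_phylo, polytomies = polytomies,
                negative = negative, ultra_tol = ultra_tol)
  class(out) <- "multiPhylo"
  out
}

#' Validate a phylogeny for time-tree analyses
#'
#' @param tree An ape `phylo` object.
#' @inheritParams read_trees
#' @return The (possibly repaired) tree, invisibly usable downstream.
#' @export
validate_phylo <- function(tree, polytomies = c("error", "resolve"),
                           negative = c("error", "clamp"), ultra_tol = 1e-6) {
  polytomies <- match.arg(polytomies)
  negative <- match.arg(negative)
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; time trees require a length on every edge")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(tree$edge.length < 0)) {
    if (negative == "error") {
      stop("negative branch lengths present; use negative = \"clamp\" to zero them")
    }
    warning("clamping ", sum(tree$edge.length < 0), " negative branch length(s) to zero")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (!ape::is.binary(tree)) {
    if (polytomies == "error") {
      stop("tree contains polytomies; use polytomies = \"resolve\" for zero-length splits")
    }
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  .check_ultrametric(tree, ultra_tol)
  tree
}

# Error (naming the worst tip pair) if root-to-tip depths differ beyond
# rel_tol * mean depth.
.check_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  spread <- max(d) - min(d)
  if (spread > rel_tol * mean(d)) {
    stop(sprintf(
      "tree not ultrametric: depth of '%s' (%.8g) vs '%s' (%.8g) differs beyond tolerance",
      tree$tip.label[which.max(d)], max(d),
      tree$tip.label[which.min(d)], min(d)))
  }
  invisible(TRUE)
}

#' Prune a tree to a set of taxa
#'
#' Induced subtree on `keep`: unsampled tips are dropped, degree-2 nodes are
#' suppressed with branch lengths summed. When the retained tips' most recent
#' common ancestor lies below the original root, the collapsed stem path is
#' kept in `root.edge`, so root-to-tip depths of retained tips are unchanged
#' (and [tree_vcv()] still reports shared path lengths from the original
#' root).
#'
#' @param tree An ultrametric `phylo`.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("tips not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  pr <- ape::keep.tip(tree, keep)
  d_full <- ape::node.depth.edgelength(tree)[match(keep[1L], tree$tip.label)]
  d_pr <- ape::node.depth.edgelength(pr)[match(keep[1L], pr$tip.label)]
  stem <- (d_full - d_pr) + (tree$root.edge %||% 0)
  if (stem > 1e-12 * max(d_full, 1)) pr$root.edge <- stem
  pr
}

#' Randomly prune a tree to m tips
#'
#' Keeps a uniformly random `m`-subset of tips (without replacement); used to
#' build the random-pruning null for the gamma statistic.
#'
#' @param tree An ultrametric `phylo`.
#' @param m Number of tips to retain, `2 <= m <= Ntip(tree)`.
#' @param seed Optional integer seed for reproducibility.
#' @return The pruned `phylo`.
#' @export
random_prune <- function(tree, m, seed = NULL) {
  n <- ape::Ntip(tree)
  if (m < 2L || m > n) stop("'m' must be between 2 and the number of tips (", n, ")")
  keep <- with_seed(seed, sample(tree$tip.label, m))
  prune_to_taxa(tree, keep)
}

#' Node ages and internode intervals of an ultrametric tree
#'
#' Ages are measured backward from the present (tips at 0). The oldest age is
#' the crown age. Internode intervals `g[k]` (k = 2..n) are the durations
#' during which exactly k reconstructed lineages existed; the interval with n
#' lineages runs from the youngest divergence to the present. These are the
#' quantities the gamma statistic and the diversification likelihoods consume.
#'
#' Tip depths are symmetrized to their mean before ages are taken, absorbing
#' sub-tolerance rounding jitter.
#'
#' @param tree An ultrametric `phylo` (or an existing `node_ages` object,
#'   returned unchanged).
#' @param ultra_tol Relative ultrametricity tolerance.
#' @return Object of class `node_ages`: list with `ages` (descending,
#'   length n-1), `g` (named, k = 2..n), `n`, `crown_age`.
#' @export
node_ages <- function(tree, ultra_tol = 1e-6) {
  if (inherits(tree, "node_ages")) return(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' or 'node_ages' object")
  n <- ape::Ntip(tree)
  if (n < 2L) stop("need at least 2 tips")
  .check_ultrametric(tree, ultra_tol)
  depth <- ape::node.depth.edgelength(tree)
  T_bar <- mean(depth[seq_len(n)])
  ages <- sort(pmax(T_bar - depth[(n + 1L):(n + tree$Nnode)], 0), decreasing = TRUE)
  g <- c(-diff(ages), ages[length(ages)])
  names(g) <- as.character(2:n)
  structure(list(ages = ages, g = g, n = n, crown_age = ages[1L]),
            class = "node_ages")
}

#' @export
print.node_ages <- function(x, ...) {
  cat("Node ages: n =", x$n, "tips, crown age =", format(x$crown_age), "\n")
  cat("ages:", paste(format(x$ages, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds tip depths. Under Brownian motion this is the covariance
#' structure the tree induces on tip values.
#'
#' @param tree An ultrametric `phylo`. A `root.edge` (e.g. the stem retained
#'   by [prune_to_taxa()]) is shared by every tip pair and is added to the
#'   whole matrix.
#' @return Symmetric positive semidefinite matrix with tip labels as dimnames.
#' @export
tree_vcv <- function(tree) {
  ape::vcv.phylo(tree) + (tree$root.edge %||% 0)
}

#' Lineage-through-time step function
#'
#' @param tree An ultrametric `phylo`.
#' @return Data frame with `age` (time before present, descending from the
#'   crown age to 0) and `lineages` (2 at the crown, n at the present).
#' @export
ltt_steps <- function(tree) {
  na <- node_ages(tree)
  data.frame(age = c(na$ages, 0), lineages = c(2:na$n, na$n))
}

#' Write trees as Newick text
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param file Optional path; when `NULL` the Newick string(s) are returned.
#' @param digits Significant digits for branch lengths.
#' @export
write_trees <- function(trees, file = NULL, digits = 12) {
  txt <- ape::write.tree(trees, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
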