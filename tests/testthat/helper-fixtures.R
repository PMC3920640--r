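# Small fixed trees and brute-force oracles shared across test files.

nwk3 <- "((A:1,B:1):1,C:2);"                 # ages 2, 1
nwk4_equal <- "(((A:1,B:1):1,C:2):1,D:3);"   # g2 = g3 = g4 = 1

tree3 <- function() read_trees(text = nwk3)[[1]]
tree4 <- function() read_trees(text = nwk4_equal)[[1]]

# star tree: n tips, all attached to the root with depth t
star_tree <- function(n, t = 1) {
  read_trees(text = paste0(
    "(", paste(sprintf("t%d:%g", seq_len(n), t), collapse = ","), ");"),
    polytomies = "resolve")[[1]]
}

# data matrix with prescribed sample-covariance eigenvalue fractions: columns
# are exact principal directions, so prcomp/phylo_pca variance fractions are
# exactly `fracs` (up to the trailing zeros).
matrix_with_fracs <- function(n, fracs, seed = 1) {
  p <- length(fracs)
  set.seed(seed)
  Z <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)))
  X <- Z %*% diag(sqrt(fracs * (n - 1)))
  colnames(X) <- paste0("v", seq_len(p))
  rownames(X) <- paste0("t", seq_len(n))
  X
}

# Brute-force DTT oracle: for each internal node (by descending age), slice
# the tree just after that node's age and average the relative disparities of
# the crossing lineages' descendant tip sets.
dtt_oracle <- function(tree, scores) {
  n <- ape::Ntip(tree)
  scores <- scores[tree$tip.label, , drop = FALSE]
  depth <- ape::node.depth.edgelength(tree)
  T_bar <- mean(depth[seq_len(n)])
  node_age <- T_bar - depth
  ages <- sort(node_age[(n + 1):(n + tree$Nnode)], decreasing = TRUE)
  tot <- disparity(scores)
  vals <- vapply(seq_along(ages)[-1], function(m) {
    t_cut <- ages[m] - 1e-9 * max(T_bar, 1)
    crossing <- which(node_age[tree$edge[, 1]] > t_cut &
                        node_age[tree$edge[, 2]] <= t_cut)
    rd <- vapply(crossing, function(e) {
      child <- tree$edge[e, 2]
      tips <- if (child <= n) tree$tip.label[child] else
        ape::extract.clade(tree, child)$tip.label
      if (length(tips) < 2) return(0)
      disparity(scores[tips, , drop = FALSE]) / tot
    }, numeric(1))
    mean(rd)
  }, numeric(1))
  list(rel_time = c(0, (T_bar - ages[-1]) / T_bar, 1),
       disparity = c(1, vals, 0))
}

# Brute-force multivariate-normal log-density via solve()/determinant(),
# an independent route from the package's Cholesky implementation.
mvn_loglik_brute <- function(y, mean, Sigma) {
  r <- y - mean
  -0.5 * (length(y) * log(2 * pi) +
            as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
            drop(crossprod(r, solve(Sigma, r))))
}
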