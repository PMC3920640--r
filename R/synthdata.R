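# Synthetic-data generators: ultrametric trees (constant-rate, slowdown,
# birth-death), posterior-like tree ensembles, clade-structured ecotype
# regimes, species trait values with allometry and ecotype optima, and
# specimen-level measurement tables. Together these emulate the inputs of an
# island-radiation study (a ~12-20 species chronogram with a Bayesian
# posterior sample, three habitat ecotypes mapped onto clades, and 15 linear
# measurements from 3-10 male specimens per species).

# Build a crown-rooted pure-birth tree from forward split times.
# split_times: times of the events creating lineages 3..n (crown at 0);
# present: sampling time > max(split_times). Topology: uniform random pick of
# the splitting lineage at each event.
.build_forward_tree <- function(split_times, present, tip_prefix = "s") {
  n <- length(split_times) + 2L
  n_edges_max <- 2L * n - 2L
  parent <- child <- integer(n_edges_max)
  elen <- numeric(n_edges_max)
  # active lineages: originating node id and start time
  act_node <- c(n + 1L, n + 1L)
  act_start <- c(0, 0)
  next_internal <- n + 2L
  n_edge <- 0L
  for (ev in seq_along(split_times)) {
    i <- sample.int(length(act_node), 1L)
    nd <- next_internal; next_internal <- next_internal + 1L
    n_edge <- n_edge + 1L
    parent[n_edge] <- act_node[i]; child[n_edge] <- nd
    elen[n_edge] <- split_times[ev] - act_start[i]
    act_node[i] <- nd; act_start[i] <- split_times[ev]
    act_node <- c(act_node, nd); act_start <- c(act_start, split_times[ev])
  }
  for (i in seq_along(act_node)) {
    n_edge <- n_edge + 1L
    parent[n_edge] <- act_node[i]; child[n_edge] <- i
    elen[n_edge] <- present - act_start[i]
  }
  tr <- structure(list(
    edge = cbind(parent[seq_len(n_edge)], child[seq_len(n_edge)]),
    edge.length = elen[seq_len(n_edge)],
    tip.label = paste0(tip_prefix, seq_len(n)),
    Nnode = n - 1L), class = "phylo")
  # canonical ape node numbering (downstream tree surgery assumes it)
  ape::read.tree(text = ape::write.tree(tr, digits = 15))
}

#' Simulate a constant-rate pure-birth (Yule) tree
#'
#' Forward birth simulation from the crown: with k lineages the wait to the
#' next split is Exp(k * lambda) and a uniformly chosen lineage splits; after
#' the n-th lineage appears the present is set just before the (n+1)-th split
#' would occur, so every internode interval `g[k]` is an independent
#' Exp(k * lambda) draw — the exact constant-rates null of the gamma test.
#'
#' @param n Number of tips (>= 2).
#' @param lambda Speciation rate (> 0).
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo`.
#' @export
sim_yule_tree <- function(n, lambda = 1, seed = NULL) {
  if (n < 2L) stop("'n' must be >= 2")
  if (lambda <= 0) stop("'lambda' must be > 0")
  with_seed(seed, {
    waits <- stats::rexp(n - 1L, rate = (2:n) * lambda)
    times <- cumsum(waits)
    .build_forward_tree(utils::head(times, -1L), times[n - 1L])
  })
}

#' Simulate a pure-birth tree with an early burst (rate slowdown)
#'
#' Inhomogeneous pure-birth process whose per-lineage speciation rate decays
#' forward in time, `lambda_f(s) = lambda0 * exp(-decay * s)`: divergences
#' concentrate near the root, the signature of an early-burst radiation and
#' of a negative gamma statistic. Simulated by drawing a unit-rate Yule tree
#' in operational time and mapping event times through the inverse integrated
#' rate; for the realized tree height this is exactly the exponentially
#' time-varying speciation model in age form (`lambda(t) = lambda0' e^{a t}`,
#' t = age before present). Realizations whose operational span exceeds the
#' total integrated rate `lambda0/decay` are rejected and redrawn.
#'
#' @param n Number of tips.
#' @param lambda0 Initial speciation rate (> 0).
#' @param decay Exponential decay of the speciation rate forward in time
#'   (>= 0); 0 gives a constant-rate Yule tree.
#' @param seed Optional integer seed.
#' @param max_tries Rejection cap.
#' @return An ultrametric `phylo`.
#' @export
sim_slowdown_tree <- function(n, lambda0 = 1, decay = 0, seed = NULL,
                              max_tries = 1000) {
  if (n < 2L) stop("'n' must be >= 2")
  if (lambda0 <= 0) stop("'lambda0' must be > 0")
  if (decay < 0) stop("'decay' must be >= 0")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      tau <- cumsum(stats::rexp(n - 1L, rate = 2:n))   # unit-rate operational times
      if (decay == 0) {
        s <- tau / lambda0
      } else {
        u <- decay * tau / lambda0
        if (u[n - 1L] >= 1 - 1e-9) next                # rate budget exhausted
        s <- -log1p(-u) / decay
      }
      return(.build_forward_tree(utils::head(s, -1L), s[n - 1L]))
    }
    stop("could not draw a tree within the rate budget; decrease 'decay' or increase 'lambda0'")
  })
}

#' Simulate a reconstructed birth-death tree with n surviving tips
#'
#' Forward birth-death simulation from the crown (per-lineage rates `lambda`
#' and `mu`); runs are rejected and retried if the clade dies out before
#' reaching `n` extant lineages. The present is set just before the event
#' following the first moment `n` lineages coexist, extinct lineages are then
#' pruned, giving the reconstructed (molecular-phylogeny-like) tree. At
#' `mu = 0` this is exactly [sim_yule_tree()].
#'
#' @param n Number of surviving tips.
#' @param lambda Speciation rate (> mu).
#' @param mu Extinction rate (>= 0).
#' @param seed Optional integer seed.
#' @param max_tries Rejection cap.
#' @return An ultrametric `phylo` with `n` tips.
#' @export
sim_bd_tree <- function(n, lambda, mu = 0, seed = NULL, max_tries = 10000) {
  if (n < 2L) stop("'n' must be >= 2")
  if (mu < 0 || lambda <= mu) stop("need lambda > mu >= 0")
  if (mu == 0) return(sim_yule_tree(n, lambda, seed = seed))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      tr <- .sim_bd_once(n, lambda, mu)
      if (!is.null(tr)) return(tr)
    }
    stop("birth-death simulation failed ", max_tries,
         " times; lower 'mu' relative to 'lambda'")
  })
}

# One forward birth-death attempt; NULL if the clade dies out first.
.sim_bd_once <- function(n, lambda, mu, max_events = 200L * n) {
  # lineages: origin node id (0 = crown placeholder), start time, alive flag
  node_ids <- c(-1L, -1L)       # resolved to real ids when building edges
  starts <- c(0, 0)
  alive <- c(TRUE, TRUE)
  events <- list()              # (time, type, lineage index) records
  t <- 0
  repeat {
    k <- sum(alive)
    if (k == 0L) return(NULL)
    t <- t + stats::rexp(1L, rate = k * (lambda + mu))
    if (k == n) break           # present fixed just before this event
    idx_alive <- which(alive)
    i <- idx_alive[sample.int(k, 1L)]
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      events[[length(events) + 1L]] <- list(t = t, type = "b", i = i)
      node_ids <- c(node_ids, -1L); starts <- c(starts, t); alive <- c(alive, TRUE)
      # lineage i continues as itself from t (its edge will be broken at t)
      events[[length(events)]]$new <- length(alive)
    } else {
      events[[length(events) + 1L]] <- list(t = t, type = "d", i = i)
      alive[i] <- FALSE
    }
    if (length(events) > max_events) return(NULL)
  }
  .assemble_bd_tree(events, alive, t)
}

# Turn an event log into a phylo: replay, creating internal nodes at births
# and terminal (extinct) tips at deaths, then prune extinct tips.
.assemble_bd_tree <- function(events, alive_final, present) {
  n_ext <- sum(alive_final)
  n_dead <- sum(vapply(events, function(e) e$type == "d", logical(1)))
  n_tips <- n_ext + n_dead
  parent <- child <- integer(0)
  elen <- numeric(0)
  # active lineage state during replay: current origin node and start time
  origin <- c(n_tips + 1L, n_tips + 1L)
  start <- c(0, 0)
  next_internal <- n_tips + 2L
  next_tip <- 1L
  labels <- character(n_tips)
  extinct <- character(0)
  for (e in events) {
    if (e$type == "b") {
      nd <- next_internal; next_internal <- next_internal + 1L
      parent <- c(parent, origin[e$i]); child <- c(child, nd)
      elen <- c(elen, e$t - start[e$i])
      origin[e$i] <- nd; start[e$i] <- e$t
      origin[e$new] <- nd; start[e$new] <- e$t
    } else {
      lab <- sprintf("x%d", next_tip)
      labels[next_tip] <- lab
      extinct <- c(extinct, lab)
      parent <- c(parent, origin[e$i]); child <- c(child, next_tip)
      elen <- c(elen, e$t - start[e$i])
      next_tip <- next_tip + 1L
    }
  }
  for (i in which(alive_final)) {
    labels[next_tip] <- sprintf("s%d", next_tip)
    parent <- c(parent, origin[i]); child <- c(child, next_tip)
    elen <- c(elen, present - start[i])
    next_tip <- next_tip + 1L
  }
  tr <- structure(list(edge = cbind(parent, child), edge.length = elen,
                       tip.label = labels, Nnode = n_tips - 1L),
                  class = "phylo")
  tr <- ape::read.tree(text = ape::write.tree(tr, digits = 15))
  if (length(extinct) > 0L) tr <- ape::drop.tip(tr, extinct)
  tr$tip.label <- paste0("s", seq_len(ape::Ntip(tr)))
  tr
}

#' Simulate a posterior-like ensemble by jittering node ages
#'
#' Emulates branch-length uncertainty in a Bayesian posterior sample: each
#' replicate multiplies every internal-node age by an independent lognormal
#' factor (median 1, log-sd `jitter_sd`), then clips child ages at their
#' parent's age so each replicate stays a valid ultrametric tree on the same
#' topology. Topological uncertainty is deliberately not emulated.
#'
#' @param tree Base ultrametric `phylo`.
#' @param k Number of replicate trees.
#' @param jitter_sd Log-scale SD of the age multipliers (0 = identical copies).
#' @param seed Optional integer seed.
#' @return A `multiPhylo` of `k` trees.
#' @export
sim_posterior_ensemble <- function(tree, k, jitter_sd = 0.1, seed = NULL) {
  if (k < 1L) stop("'k' must be >= 1")
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0")
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  T_bar <- mean(depth[seq_len(n)])
  age <- c(rep(0, n), pmax(T_bar - depth[(n + 1L):(n + tree$Nnode)], 0))
  # preorder over internal nodes: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  out <- with_seed(seed, lapply(seq_len(k), function(j) {
    f <- stats::rlnorm(tree$Nnode, 0, jitter_sd)
    new_age <- age
    new_age[(n + 1L):(n + tree$Nnode)] <- age[(n + 1L):(n + tree$Nnode)] * f
    for (e in seq_len(nrow(ord))) {       # clip child below parent, top-down
      p <- ord[e, 1L]; ch <- ord[e, 2L]
      if (ch > n && new_age[ch] > new_age[p]) new_age[ch] <- new_age[p]
    }
    tr <- tree
    tr$edge.length <- new_age[tr$edge[, 1L]] - new_age[tr$edge[, 2L]]
    tr
  }))
  class(out) <- "multiPhylo"
  out
}

#' Paint clade-structured ecotype regimes onto a tree
#'
#' Emulates the partitioning of habitat ecotypes into clades, with convergent
#' repeats: each non-background class originates on one or two disjoint
#' internal branches and paints all descendant branches; everything unpainted
#' is the background class. Tips inherit the class of their terminal branch.
#'
#' @param tree Ultrametric `phylo`.
#' @param classes Class labels; the first is the background. Default the
#'   three frog habitat ecotypes `c("ground", "shrub", "treehole")`.
#' @param origins_per_class Clade origins per painted class (1 or 2; 2 gives
#'   convergent repeats when the tree is large enough).
#' @param seed Optional integer seed.
#' @param max_tries Retry cap for finding a painting with every class
#'   non-empty.
#' @return List with `species` (named character vector tip -> class) and
#'   `edge_regimes` (class per edge, in `tree$edge` order).
#' @export
sim_ecotype_regimes <- function(tree, classes = c("ground", "shrub", "treehole"),
                                origins_per_class = 2, seed = NULL,
                                max_tries = 200) {
  n <- ape::Ntip(tree)
  if (length(classes) < 1L || length(classes) > n) stop("bad number of classes")
  n_paint <- length(classes) - 1L
  edge_regimes <- rep(classes[1L], nrow(tree$edge))
  if (n_paint == 0L) {
    return(list(species = stats::setNames(rep(classes[1L], n), tree$tip.label),
                edge_regimes = edge_regimes))
  }
  # candidate origin edges: internal child whose clade is small enough that
  # paintings can stay disjoint and the background non-empty
  tipsets <- .clade_tipsets(tree)
  cand <- which(tree$edge[, 2L] > n)
  sizes <- vapply(cand, function(e) length(tipsets[[tree$edge[e, 2L]]]), integer(1))
  cand <- cand[sizes <= max(2L, floor(n / 3))]
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      paint <- rep(classes[1L], nrow(tree$edge))
      used_tips <- integer(0)
      ok <- TRUE
      for (cl in classes[-1L]) {
        placed <- 0L
        for (o in seq_len(origins_per_class)) {
          free <- cand[vapply(cand, function(e) {
            !any(tipsets[[tree$edge[e, 2L]]] %in% used_tips)
          }, logical(1))]
          if (length(free) == 0L) break
          e0 <- free[sample.int(length(free), 1L)]
          clade_tips <- tipsets[[tree$edge[e0, 2L]]]
          used_tips <- c(used_tips, clade_tips)
          in_clade <- vapply(seq_len(nrow(tree$edge)), function(e) {
            all(tipsets[[tree$edge[e, 2L]]] %in% clade_tips)
          }, logical(1))
          paint[in_clade] <- cl
          placed <- placed + 1L
        }
        if (placed == 0L) { ok <- FALSE; break }
      }
      if (!ok || length(used_tips) >= n) next
      tip_class <- vapply(seq_len(n), function(tp) {
        paint[match(tp, tree$edge[, 2L])]
      }, character(1))
      if (!all(classes %in% tip_class)) next
      return(list(species = stats::setNames(tip_class, tree$tip.label),
                  edge_regimes = paint))
    }
    stop("could not paint all classes non-empty; fewer classes or a larger tree needed")
  })
}

# Descendant tip indices per node.
.clade_tipsets <- function(tree) {
  n <- ape::Ntip(tree)
  tipsets <- vector("list", n + tree$Nnode)
  for (tp in seq_len(n)) tipsets[[tp]] <- tp
  for (e in rev(seq_len(nrow(tree$edge)))) {   # cladewise: reverse = children first
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  tipsets
}

# The 15 linear measurements (mm): body size plus head, limb, digit, tubercle
# and webbing characters.
.measurement_names <- c(
  "snout_vent_length", "head_width", "snout_length", "forearm_length",
  "finger3_length", "finger3_width", "finger3_tip_width", "thigh_length",
  "crus_length", "toe3_length", "toe3_width", "toe3_tip_width",
  "inner_metatarsal_tubercle", "outer_metatarsal_tubercle", "webbing")

# Ecotype contrasts on the shape characters (ln-scale optimum offsets,
# multiplied by opt_sep): climbers (tree-hole, shrub) get wide digit tips and
# more webbing, ground frogs get large metatarsal tubercles -- the
# climbing-versus-digging trade-off axis.
.ecotype_direction <- function() {
  d <- stats::setNames(numeric(14), .measurement_names[-1L])
  d[c("finger3_tip_width", "toe3_tip_width")] <- 1
  d[c("finger3_width", "toe3_width")] <- 0.5
  d["webbing"] <- 0.7
  d[c("inner_metatarsal_tubercle", "outer_metatarsal_tubercle")] <- -1
  d
}

#' Simulate true species trait means on a tree
#'
#' Log snout-vent length evolves by Brownian motion; each of the 14 shape
#' characters is an allometric multiple of log SVL plus an independent
#' Ornstein-Uhlenbeck deviation whose optimum depends on the branch's ecotype
#' regime. Ecotype optima differ along a climbing-versus-digging direction
#' (digit-tip widths and webbing against metatarsal tubercles). With
#' `opt_sep = 0` and `alpha_rel = 0` the characters are pure Brownian motion.
#'
#' @param tree Ultrametric `phylo`.
#' @param regimes Output of [sim_ecotype_regimes()] (edge regimes + species
#'   classes); `NULL` paints everything one background class.
#' @param svl_var Expected tip variance of ln SVL accumulated over the tree
#'   depth (Brownian rate is `svl_var / depth`).
#' @param z0_svl Root ln SVL (default `log(40)` mm).
#' @param allometry Length-14 vector of allometric slopes on ln SVL; default
#'   mild positive/negative allometry around isometry (slope 1).
#' @param opt_sep Ecotype optimum separation (ln units) along the contrast
#'   direction; 0 removes the ecotype effect.
#' @param alpha_rel OU pull strength times tree depth (`alpha = alpha_rel /
#'   depth`); 0 gives Brownian shape deviations.
#' @param resid_sd Stationary SD of the OU shape deviations (ln units).
#' @param seed Optional integer seed.
#' @return Species-by-15 matrix of ln-scale trait means (first column ln SVL
#'   on the original mm scale name).
#' @export
sim_species_traits <- function(tree, regimes = NULL, svl_var = 0.09,
                               z0_svl = log(40), allometry = NULL,
                               opt_sep = 0.35, alpha_rel = 3,
                               resid_sd = 0.12, seed = NULL) {
  n <- ape::Ntip(tree)
  depth <- mean(ape::node.depth.edgelength(tree)[seq_len(n)])
  if (is.null(regimes)) {
    regimes <- list(species = stats::setNames(rep("ground", n), tree$tip.label),
                    edge_regimes = rep("ground", nrow(tree$edge)))
  }
  if (is.null(allometry)) {
    allometry <- stats::setNames(
      rep(c(1.05, 0.95, 1.0, 1.1, 0.9, 1.0, 0.85), length.out = 14),
      .measurement_names[-1L])
  }
  seeds <- spawn_seeds(seed, 2L)
  svl <- simulate_bm(tree, matrix(svl_var / depth, 1, 1,
                                  dimnames = list("svl", "svl")),
                     z0 = z0_svl, seed = seeds[[1L]])[, 1L]
  dir <- .ecotype_direction()
  # background first (root edges lead in cladewise order), then painted classes
  cls <- unique(c(regimes$edge_regimes, regimes$species))
  offs <- stats::setNames(seq_along(cls) - 1, cls)
  theta <- outer(offs, dir) * opt_sep             # classes x 14
  rownames(theta) <- cls
  alpha <- alpha_rel / depth
  sigma2 <- if (alpha > 0) 2 * alpha * resid_sd^2 else resid_sd^2 / depth
  dev <- simulate_ou(tree, sigma2 = sigma2, alpha = alpha, theta = theta,
                     regimes = regimes$edge_regimes, z0 = rep(0, length(dir)),
                     seed = seeds[[2L]])
  shape <- outer(svl - z0_svl, allometry) + dev
  # typical adult measurements (mm) anchoring each character's baseline
  base <- stats::setNames(
    log(c(10, 11, 18, 4, 1.5, 2.2, 19, 18, 7, 1.4, 2.0, 2.5, 1.2, 3.0)),
    .measurement_names[-1L])
  shape <- sweep(shape, 2, base, `+`)
  out <- cbind(svl, shape)
  colnames(out) <- .measurement_names
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a specimen-level measurement table
#'
#' Draws a specimen count per species from a discrete triangular distribution
#' on 3..10 peaked at 8 (so the across-species median is 8), then multiplies
#' each species' back-transformed trait means by lognormal measurement noise.
#' All specimens are male, mirroring a males-only measurement protocol.
#'
#' @param true_means Species-by-characters matrix of ln-scale means (e.g.
#'   from [sim_species_traits()]).
#' @param noise_sd Intraspecific SD on the ln scale.
#' @param n_range Specimen-count range (inclusive).
#' @param seed Optional integer seed.
#' @return Data frame: `specimen_id`, `species`, `sex`, and one positive
#'   (mm-scale) column per character.
#' @export
sim_specimen_table <- function(true_means, noise_sd = 0.08, n_range = c(3L, 10L),
                               seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  true_means <- as.matrix(true_means)
  sp <- rownames(true_means)
  counts_support <- seq(n_range[1L], n_range[2L])
  # triangular weights peaked at 8 (median 8 when the range is 3..10)
  peak <- min(8L, n_range[2L])
  w <- pmax(1, 5 - abs(counts_support - peak) * 1.5)
  w[counts_support == peak] <- 8
  with_seed(seed, {
    counts <- sample(counts_support, length(sp), replace = TRUE, prob = w)
    rows <- lapply(seq_along(sp), function(i) {
      noise <- matrix(stats::rnorm(counts[i] * ncol(true_means), 0, noise_sd),
                      nrow = counts[i])
      M <- exp(sweep(noise, 2, true_means[i, ], `+`))
      colnames(M) <- colnames(true_means)
      data.frame(specimen_id = sprintf("%s_%02d", sp[i], seq_len(counts[i])),
                 species = sp[i], sex = "M", M,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic radiation fixture
#'
#' One call producing every input the analysis pipeline consumes: a species
#' tree, a posterior-like ensemble, ecotype classes, true species trait means
#' and a specimen table. Two scenarios:
#' \describe{
#'   \item{`"radiation"`}{early-burst tree (speciation decaying forward in
#'     time) and ecotype optima pulling shape characters apart (OU): the
#'     regime the analyses are designed to detect — negative gamma,
#'     time-varying-speciation model support, ecotype-structured morphospace
#'     and non-Brownian disparity.}
#'   \item{`"null"`}{constant-rate Yule tree and pure-Brownian characters
#'     with no ecotype effect (labels still assigned, for null calibration).}
#' }
#'
#' @param n_species Number of species (default 18).
#' @param scenario `"radiation"` or `"null"`.
#' @param n_posterior Trees in the jittered ensemble.
#' @param jitter_sd Posterior age-jitter SD.
#' @param lambda0 Initial speciation rate.
#' @param decay Forward-time decay of speciation (radiation scenario).
#' @param opt_sep,alpha_rel Ecotype-optimum separation and OU strength
#'   (radiation scenario).
#' @param noise_sd Intraspecific measurement SD (ln scale).
#' @param seed Optional integer master seed (spawns independent per-stage
#'   streams).
#' @return List with `tree`, `posterior`, `ecotypes` (named vector),
#'   `regimes`, `traits` (true ln-scale species means), `specimens` (data
#'   frame), `scenario`, `params`.
#' @export
sim_radiation <- function(n_species = 18, scenario = c("radiation", "null"),
                          n_posterior = 100, jitter_sd = 0.3,
                          lambda0 = 10, decay = 4.5,
                          opt_sep = 0.5, alpha_rel = 5,
                          noise_sd = 0.08, seed = NULL) {
  scenario <- match.arg(scenario)
  seeds <- spawn_seeds(seed, 5L)
  if (scenario == "radiation") {
    tree <- sim_slowdown_tree(n_species, lambda0 = lambda0, decay = decay,
                              seed = seeds[[1L]])
  } else {
    tree <- sim_yule_tree(n_species, lambda = lambda0, seed = seeds[[1L]])
    opt_sep <- 0
    alpha_rel <- 0
  }
  posterior <- sim_posterior_ensemble(tree, n_posterior, jitter_sd = jitter_sd,
                                      seed = seeds[[2L]])
  regimes <- sim_ecotype_regimes(tree, seed = seeds[[3L]])
  traits <- sim_species_traits(tree, regimes, opt_sep = opt_sep,
                               alpha_rel = alpha_rel, seed = seeds[[4L]])
  specimens <- sim_specimen_table(traits, noise_sd = noise_sd, seed = seeds[[5L]])
  list(tree = tree, posterior = posterior, ecotypes = regimes$species,
       regimes = regimes, traits = traits, specimens = specimens,
       scenario = scenario,
       params = list(n_species = n_species, n_posterior = n_posterior,
                     jitter_sd = jitter_sd, lambda0 = lambda0,
                     decay = if (scenario == "radiation") decay else 0,
                     opt_sep = opt_sep, alpha_rel = alpha_rel,
                     noise_sd = noise_sd, seed = seed))
}
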