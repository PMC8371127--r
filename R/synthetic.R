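# Synthetic data with known ground truth: Yule trees with optional
# long-branch taxa, alignments evolved under the Poisson model with
# gamma-distributed site rates, and single-gain irreversible-loss
# (Dollo) binary trait matrices.
#
# One run is fully determined by (seed, config); each generator derives
# its own sub-stream from the seed with a fixed offset so the three
# outputs are independently reproducible.

SEED_OFFSET_TREE <- 101L
SEED_OFFSET_ALN <- 211L
SEED_OFFSET_TRAITS <- 307L

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' emulate a deep phylogenomic study: tens of taxa, a root-to-tip depth
#' around one substitution per site, strong among-site rate variation
#' (`alpha = 0.5`), and a moderate per-branch trait loss probability.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param birth_rate Yule speciation rate (shapes relative node depths).
#' @param seed integer seed; fully determines all outputs.
#' @param tree_height root-to-tip depth in expected substitutions/site
#'   to which the simulated tree is rescaled.
#' @param long_branch_taxa named numeric vector: leaf label ->
#'   elongation factor (>= 1) applied to its terminal branch.
#' @param alpha gamma shape of among-site rate variation (> 0).
#' @param n_sites number of alignment columns (>= 1).
#' @param loss_prob per-branch probability of irreversible trait loss,
#'   in `[0, 1)`.
#' @param n_traits number of binary traits.
#' @param gain_node `"root"` or a node/tip label at which traits arise.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 16L, birth_rate = 1, seed = 1L,
                       tree_height = 1, long_branch_taxa = NULL,
                       alpha = 0.5, n_sites = 1000L, loss_prob = 0.1,
                       n_traits = 200L, gain_node = "root") {
  if (n_taxa < 3L) stop("n_taxa must be >= 3", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  if (loss_prob < 0 || loss_prob >= 1)
    stop("loss_prob must lie in [0, 1)", call. = FALSE)
  if (!is.null(long_branch_taxa)) {
    if (is.null(names(long_branch_taxa)) || any(long_branch_taxa < 1))
      stop("long_branch_taxa must be a named vector of factors >= 1",
           call. = FALSE)
  }
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 seed = as.integer(seed), tree_height = tree_height,
                 long_branch_taxa = long_branch_taxa, alpha = alpha,
                 n_sites = as.integer(n_sites), loss_prob = loss_prob,
                 n_traits = as.integer(n_traits), gain_node = gain_node),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

#' Simulate a rooted species tree
#'
#' Fixed-n Yule (pure-birth) tree, rescaled so the root-to-tip depth
#' equals `tree_height`, with terminal branches of the listed
#' long-branch taxa multiplied by their elongation factors (emulating
#' fast-evolving lineages that attract each other in distance and
#' likelihood reconstructions).
#'
#' @param config a [sim_config()].
#' @return rooted ultrametric-before-elongation `phylo` tree with leaf
#'   labels `t1..tn`.
#' @export
simulate_tree <- function(config) {
  tr <- with_seed(config$seed + SEED_OFFSET_TREE, {
    ape::rphylo(config$n_taxa, birth = config$birth_rate, death = 0)
  })
  tr$tip.label <- paste0("t", seq_len(config$n_taxa))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth * config$tree_height
  lbt <- config$long_branch_taxa
  if (!is.null(lbt)) {
    unknown <- setdiff(names(lbt), tr$tip.label)
    if (length(unknown))
      stop("unknown long-branch taxa: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(lbt)) {
      tip <- match(nm, tr$tip.label)
      k <- which(tr$edge[, 2L] == tip)
      tr$edge.length[k] <- tr$edge.length[k] * lbt[[nm]]
    }
  }
  tr
}

#' Simulate an alignment with gamma rate heterogeneity
#'
#' Each site draws a relative rate from a mean-one gamma(`alpha`)
#' distribution (returned as ground truth) and evolves down the tree
#' under the 20-state Poisson model: along a branch of length `t` at
#' rate `r` the state is redrawn uniformly with probability
#' `1 - exp(-(20/19) t r)`. Root states are uniform.
#'
#' @param tree `phylo` tree with strictly positive branch lengths.
#' @param config a [sim_config()] (uses `alpha`, `n_sites`, `seed`).
#' @return list with `alignment` (an [aa_alignment()]) and `site_rates`
#'   (true per-site rates).
#' @export
simulate_alignment <- function(tree, config) {
  if (any(tree$edge.length <= 0))
    stop("tree must have strictly positive branch lengths", call. = FALSE)
  S <- config$n_sites
  with_seed(config$seed + SEED_OFFSET_ALN, {
    rates <- rgamma(S, shape = config$alpha, rate = config$alpha)
    n_tip <- length(tree$tip.label)
    tr <- ape::reorder.phylo(tree, "postorder")
    edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
    elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
    states <- matrix(NA_integer_, n_tip + tr$Nnode, S)
    root <- edge[1L, 1L]
    states[root, ] <- sample.int(N_STATES, S, replace = TRUE)
    for (k in seq_len(nrow(edge))) {
      p <- edge[k, 1L]; ch <- edge[k, 2L]
      stay <- runif(S) < exp(-POISSON_BETA * elen[k] * rates)
      x <- states[p, ]
      redraw <- !stay
      if (any(redraw))
        x[redraw] <- sample.int(N_STATES, sum(redraw), replace = TRUE)
      states[ch, ] <- x
    }
    m <- matrix(AA_CODES[states[seq_len(n_tip), ]], n_tip, S)
    rownames(m) <- tr$tip.label
    list(alignment = aa_alignment(m), site_rates = rates)
  })
}

#' Long-branch-attraction benchmark scenario
#'
#' A fixed 12-taxon topology with short internal branches (0.01
#' subs/site) and ordinary terminals (0.1), in which two unrelated
#' leaves (`L1` in one half of the tree, `L2` in the other) have their
#' terminal branches multiplied by `elongation`. Distance and
#' likelihood reconstructions then tend to unite the two long branches
#' into an artifactual `{L1, L2}` clade whose bootstrap support decays
#' as the fastest-evolving sites are removed — the qualitative
#' signature the slow-fast procedure screens for.
#'
#' @param seed integer seed for the alignment simulation.
#' @param elongation factor applied to the two long terminal branches
#'   (default 12).
#' @param n_sites alignment length (default 2000).
#' @param alpha gamma shape of site-rate variation (default 0.5).
#' @return list with `tree` (the true tree, long branches applied),
#'   `alignment`, `site_rates` (true rates) and `false_clade`
#'   (`c("L1", "L2")`).
#' @export
lba_scenario <- function(seed = 1L, elongation = 12, n_sites = 2000L,
                         alpha = 0.5) {
  nwk <- paste0(
    "(((L1:0.1,a1:0.1):0.01,(a2:0.1,a3:0.1):0.01):0.01,",
    "((a4:0.1,a5:0.1):0.01,((L2:0.1,b1:0.1):0.01,",
    "(b2:0.1,b3:0.1):0.01):0.01):0.01);")
  tr <- ape::read.tree(text = nwk)
  for (nm in c("L1", "L2")) {
    k <- which(tr$edge[, 2L] == match(nm, tr$tip.label))
    tr$edge.length[k] <- tr$edge.length[k] * elongation
  }
  cfg <- sim_config(n_taxa = length(tr$tip.label), seed = seed,
                    n_sites = n_sites, alpha = alpha)
  sim <- simulate_alignment(tr, cfg)
  list(tree = tr, alignment = sim$alignment, site_rates = sim$site_rates,
       false_clade = c("L1", "L2"))
}

# node label helper: tips keep their labels, internal nodes get existing
# labels or "node<N>"
node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  lab <- c(tree$tip.label,
           if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
             tree$node.label
           else paste0("node", n_tip + seq_len(tree$Nnode)))
  lab
}

#' Simulate binary traits under a Dollo process
#'
#' Each trait gains exactly once at `gain_node` (present there), and is
#' lost irreversibly and independently with probability `loss_prob` on
#' each branch below it; once lost it stays absent in the whole
#' descendant subtree.
#'
#' @param tree rooted `phylo` tree.
#' @param config a [sim_config()] (uses `n_traits`, `loss_prob`,
#'   `gain_node`, `seed`).
#' @return list with `traits` (a [trait_matrix()], species x trait) and
#'   `true_states` (node x trait presence matrix over all tree nodes,
#'   rows named by node labels).
#' @export
simulate_traits <- function(tree, config) {
  if (!ape::is.rooted(tree))
    stop("simulate_traits requires a rooted tree", call. = FALSE)
  n_tip <- length(tree$tip.label)
  labs <- node_labels(tree)
  root <- n_tip + 1L
  gain <- if (identical(config$gain_node, "root")) root
          else match(config$gain_node, labs)
  if (is.na(gain))
    stop("unknown gain_node: ", config$gain_node, call. = FALSE)
  with_seed(config$seed + SEED_OFFSET_TRAITS, {
    tr <- ape::reorder.phylo(tree, "postorder")
    edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
    Tn <- config$n_traits
    states <- matrix(0L, n_tip + tr$Nnode, Tn)
    in_gain <- rep(FALSE, n_tip + tr$Nnode)
    in_gain[gain] <- TRUE
    states[gain, ] <- 1L
    for (k in seq_len(nrow(edge))) {
      p <- edge[k, 1L]; ch <- edge[k, 2L]
      if (!in_gain[p]) next
      in_gain[ch] <- TRUE
      keep <- states[p, ] == 1L & runif(Tn) >= config$loss_prob
      states[ch, keep] <- 1L
    }
    rownames(states) <- labs
    colnames(states) <- paste0("trait", seq_len(Tn))
    leaf <- states[seq_len(n_tip), , drop = FALSE]
    list(traits = trait_matrix(leaf), true_states = states)
  })
}
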