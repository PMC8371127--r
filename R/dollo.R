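# Dollo parsimony: each trait gains exactly once and can only be lost.
# Under that constraint the minimal-loss ancestral reconstruction places
# the gain at the most recent common ancestor of the possessors and
# marks as present exactly the nodes on paths from that ancestor to
# possessors (the Steiner subtree); losses sit on branches from a
# present node into a wholly-absent descendant subtree.

#' Dollo parsimony ancestral presence reconstruction
#'
#' For every trait with at least one possessor, the gain node is the
#' MRCA of its possessors (the leaf itself for singletons); a node is
#' present iff it lies on a path from the gain node to a possessor;
#' losses are the branches from a present node to an absent child
#' subtree. Traits with no possessor are absent everywhere.
#'
#' @param tree rooted `phylo` tree; every matrix species must be a leaf.
#' @param traits a [trait_matrix()] (species x trait).
#' @return a `dollo_map`: list with `presence` (node x trait 0/1 matrix,
#'   rows named tips-then-internal), `gain_node` (per trait, `NA` when
#'   absent everywhere), `loss_edges` (per trait, integer edge indices
#'   into `tree$edge`), `n_losses`, plus `tree` and node labels.
#' @export
dollo_reconstruct <- function(tree, traits) {
  if (!ape::is.rooted(tree))
    stop("Dollo reconstruction requires a rooted tree", call. = FALSE)
  missing <- setdiff(rownames(traits), tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  labs <- node_labels(tree)
  edge <- tree$edge
  parent_of <- integer(n_node)
  parent_of[edge[, 2L]] <- edge[, 1L]
  root <- n_tip + 1L
  parent_of[root] <- 0L

  Tn <- ncol(traits)
  presence <- matrix(0L, n_node, Tn, dimnames = list(labs, colnames(traits)))
  gain_node <- rep(NA_character_, Tn)
  names(gain_node) <- colnames(traits)
  loss_edges <- vector("list", Tn)
  names(loss_edges) <- colnames(traits)

  for (j in seq_len(Tn)) {
    poss <- rownames(traits)[traits[, j] == 1L]
    loss_edges[[j]] <- integer(0)
    if (!length(poss)) next
    tips <- match(poss, tree$tip.label)
    g <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    gain_node[j] <- labs[g]
    pres <- rep(FALSE, n_node)
    for (tp in tips) {  # walk each possessor up to the gain node
      v <- tp
      while (!pres[v]) {
        pres[v] <- TRUE
        if (v == g) break
        v <- parent_of[v]
      }
    }
    pres[g] <- TRUE
    presence[pres, j] <- 1L
    loss_edges[[j]] <- which(pres[edge[, 1L]] & !pres[edge[, 2L]])
  }
  structure(list(presence = presence,
                 gain_node = gain_node,
                 loss_edges = loss_edges,
                 n_losses = lengths(loss_edges),
                 tree = tree,
                 node_labels = labs,
                 categories = attr(traits, "categories")),
            class = "dollo_map")
}

#' @export
print.dollo_map <- function(x, ...) {
  cat("dollo_map:", ncol(x$presence), "traits on",
      length(x$tree$tip.label), "leaves;",
      sum(!is.na(x$gain_node)), "gained,", sum(x$n_losses), "losses\n")
  invisible(x)
}

#' Per-node repertoire percentages
#'
#' Number and percentage of traits (or gene families) reconstructed as
#' present at each node. With `denominator = "families"` a named map
#' trait -> family is required and a family counts as present when any
#' member trait is present; the denominator is then the number of
#' families.
#'
#' @param map a `dollo_map`.
#' @param denominator `"traits"` or `"families"`.
#' @param families named character vector (trait -> family) when
#'   `denominator = "families"`.
#' @return data frame: `node`, `present_count`, `percentage` (reported
#'   to 0.1).
#' @export
node_percentages <- function(map, denominator = c("traits", "families"),
                             families = NULL) {
  denominator <- match.arg(denominator)
  pres <- map$presence
  if (denominator == "traits") {
    counts <- rowSums(pres)
    total <- ncol(pres)
  } else {
    if (is.null(families))
      stop("families map required for denominator = 'families'",
           call. = FALSE)
    fam <- families[colnames(pres)]
    if (anyNA(fam))
      stop("families map does not cover all traits", call. = FALSE)
    groups <- split(seq_len(ncol(pres)), fam)
    fam_pres <- vapply(groups, function(ix)
      as.integer(rowSums(pres[, ix, drop = FALSE]) > 0), integer(nrow(pres)))
    counts <- rowSums(fam_pres)
    total <- length(groups)
  }
  data.frame(node = rownames(pres),
             present_count = as.integer(counts),
             percentage = round(100 * counts / total, 1),
             row.names = NULL)
}

#' Per-branch gain/loss table
#'
#' Gains are credited to the branch whose child end is the trait's gain
#' node (the root itself for root gains); losses to every branch
#' carrying a loss. With categories attached to the trait matrix, one
#' count column per category is added; category totals sum to the
#' overall totals.
#'
#' @param map a `dollo_map`.
#' @return data frame with one row per node (branch identified by its
#'   child node): `node`, `gains`, `losses`, and optional per-category
#'   columns `gains.<cat>` / `losses.<cat>`.
#' @export
gain_loss_table <- function(map) {
  labs <- map$node_labels
  edge <- map$tree$edge
  n_node <- length(labs)
  gains <- integer(n_node)
  losses <- integer(n_node)
  gained <- !is.na(map$gain_node)
  g_idx <- match(map$gain_node[gained], labs)
  for (v in g_idx) gains[v] <- gains[v] + 1L
  for (j in which(gained)) {
    for (e in map$loss_edges[[j]]) {
      ch <- edge[e, 2L]
      losses[ch] <- losses[ch] + 1L
    }
  }
  out <- data.frame(node = labs, gains = gains, losses = losses,
                    row.names = NULL)
  ct <- map$categories
  if (!is.null(ct)) {
    for (cat in sort(unique(ct))) {
      in_cat <- colnames(map$presence) %in% names(ct)[ct == cat]
      g <- integer(n_node); l <- integer(n_node)
      for (j in which(gained & in_cat)) {
        v <- match(map$gain_node[j], labs)
        g[v] <- g[v] + 1L
        for (e in map$loss_edges[[j]]) l[edge[e, 2L]] <- l[edge[e, 2L]] + 1L
      }
      out[[paste0("gains.", cat)]] <- g
      out[[paste0("losses.", cat)]] <- l
    }
  }
  out
}
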