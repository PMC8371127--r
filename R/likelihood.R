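# Felsenstein pruning under the 20-state Poisson (equal-exchangeability,
# equal-frequency) model. The transition matrix has the closed form
# P_ij(t) = e(t) * delta_ij + (1 - e(t))/20 with e(t) = exp(-(20/19) t),
# so the per-edge update needs only a column sum, never a 20x20 product.

N_STATES <- 20L
POISSON_BETA <- 20 / 19  # rate normalisation: 1 expected substitution per unit t

# integer-encode an alignment: 1..20 residues, NA for missing
encode_alignment <- function(aln) {
  m <- match(unclass(aln), AA_CODES)
  dim(m) <- dim(aln)
  dimnames(m) <- dimnames(aln)
  m
}

# per-site log-likelihood by pruning at a single relative rate.
# codes: integer matrix (taxa x sites); tree leaves must be rownames.
prune_site_loglik <- function(tree, codes, rate) {
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  miss <- setdiff(tree$tip.label, rownames(codes))
  if (length(miss))
    stop("taxa in tree absent from alignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  S <- ncol(codes)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  partial <- vector("list", n_node)
  logscale <- matrix(0, n_node, S)
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) stop("tree has no branch lengths", call. = FALSE)

  tip_partial <- function(i) {
    x <- codes[tree$tip.label[i], ]
    L <- matrix(0, N_STATES, S)
    obs <- !is.na(x)
    if (any(obs)) L[cbind(x[obs], which(obs))] <- 1
    if (any(!obs)) L[, !obs] <- 1
    L
  }

  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1L]; child <- edge[k, 2L]
    if (child <= n_tip) {
      Lc <- tip_partial(child)
      sc <- rep(0, S)
    } else {
      Lc <- partial[[child]]
      sc <- logscale[child, ]
    }
    e <- exp(-POISSON_BETA * elen[k] * rate)
    up <- e * Lc + rep((1 - e) / N_STATES * colSums(Lc), each = N_STATES)
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- up
      logscale[parent, ] <- sc
    } else {
      partial[[parent]] <- partial[[parent]] * up
      logscale[parent, ] <- logscale[parent, ] + sc
      mx <- apply(partial[[parent]], 2L, max)
      mx[mx <= 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2L, mx, "/")
      logscale[parent, ] <- logscale[parent, ] + log(mx)
    }
  }
  root <- edge[nrow(edge), 1L]
  log(colSums(partial[[root]]) / N_STATES) + logscale[root, ]
}

#' Per-site log-likelihoods under the Poisson model
#'
#' Felsenstein pruning on a fixed tree at a single relative rate, with
#' equal amino-acid frequencies and all of `-`, `X`, `?` marginalized as
#' missing. The result is invariant to rerooting of the unrooted tree
#' (pulley principle).
#'
#' @param tree a `phylo` tree with branch lengths; its leaves must be a
#'   subset of the alignment's taxa.
#' @param aln an [aa_alignment()].
#' @param rate relative rate multiplier (default 1).
#' @return numeric vector, one log-likelihood per site.
#' @export
site_loglik <- function(tree, aln, rate = 1) {
  prune_site_loglik(tree, encode_alignment(aln), rate)
}

#' Discrete-gamma category rates
#'
#' Mean rates of `K` equal-probability categories of a mean-one gamma
#' distribution with shape `alpha` (the standard discrete-gamma
#' construction with category means, not medians).
#'
#' @param alpha gamma shape (> 0).
#' @param K number of categories (>= 1).
#' @return numeric vector of K category rates (mean 1).
#' @export
discrete_gamma_rates <- function(alpha, K = 4L) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  b <- qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
  # category mean via the incomplete-gamma identity; means average to 1
  K * diff(pgamma(b, shape = alpha + 1, rate = alpha))
}

# per-category per-site log-likelihood matrix (K x S)
category_site_logliks <- function(tree, codes, alpha, K) {
  rates <- discrete_gamma_rates(alpha, K)
  m <- vapply(rates, function(r) prune_site_loglik(tree, codes, r),
              numeric(ncol(codes)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single-site alignment
  t(m)
}

# total discrete-gamma mixture log-likelihood from a K x S matrix
mixture_loglik <- function(catll) {
  mx <- apply(catll, 2L, max)
  sum(mx + log(colMeans(exp(sweep(catll, 2L, mx, "-")))))
}

# single Poisson edge update: (P(t) %*% L) using the closed form
poisson_edge_update <- function(L, tr_len) {
  e <- exp(-POISSON_BETA * tr_len)
  e * L + rep((1 - e) / N_STATES * colSums(L), each = N_STATES)
}

# Two-pass partials at one rate: downward partial L_v for every node and
# upward ("rest of tree") partial O_k for every edge, each with per-site
# log scales. For edge k = (p, c) the per-site likelihood as a function
# of its length b is then
#   (e(b) * A + (1 - e(b)) * SB) / 20   (times exp(scale)),
# with A = colSums(O_k * L_c), SB = colSums(O_k) * colSums(L_c) / 20.
tree_edge_profiles <- function(tree, codes, rate) {
  S <- ncol(codes)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  edge <- tr$edge
  elen <- tr$edge.length
  L <- vector("list", n_node)
  lsL <- matrix(0, n_node, S)
  msg <- vector("list", nrow(edge))   # P(t_k) L_child per edge
  for (i in seq_len(n_tip)) {
    x <- codes[tr$tip.label[i], ]
    M <- matrix(0, N_STATES, S)
    obs <- !is.na(x)
    if (any(obs)) M[cbind(x[obs], which(obs))] <- 1
    if (any(!obs)) M[, !obs] <- 1
    L[[i]] <- M
  }
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    msg[[k]] <- poisson_edge_update(L[[ch]], elen[k] * rate)
    if (is.null(L[[p]])) {
      L[[p]] <- msg[[k]]
      lsL[p, ] <- lsL[ch, ]
    } else {
      L[[p]] <- L[[p]] * msg[[k]]
      lsL[p, ] <- lsL[p, ] + lsL[ch, ]
      mx <- apply(L[[p]], 2L, max)
      mx[mx <= 0] <- 1
      L[[p]] <- sweep(L[[p]], 2L, mx, "/")
      lsL[p, ] <- lsL[p, ] + log(mx)
    }
  }
  root <- edge[nrow(edge), 1L]
  O <- vector("list", nrow(edge))
  lsO <- matrix(0, nrow(edge), S)
  Up <- vector("list", n_node)
  lsU <- matrix(0, n_node, S)
  Up[[root]] <- matrix(1, N_STATES, S)
  children_of <- split(seq_len(nrow(edge)), edge[, 1L])
  for (k in rev(seq_len(nrow(edge)))) {   # preorder
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    Ok <- Up[[p]]
    ls <- lsU[p, ]
    for (j in children_of[[as.character(p)]]) {
      if (j == k) next
      Ok <- Ok * msg[[j]]
      ls <- ls + lsL[edge[j, 2L], ]
    }
    mx <- apply(Ok, 2L, max)
    mx[mx <= 0] <- 1
    Ok <- sweep(Ok, 2L, mx, "/")
    ls <- ls + log(mx)
    O[[k]] <- Ok
    lsO[k, ] <- ls
    if (ch > n_tip) {
      Up[[ch]] <- poisson_edge_update(Ok, elen[k] * rate)
      lsU[ch, ] <- ls
    }
  }
  A <- matrix(0, nrow(edge), S)
  SB <- matrix(0, nrow(edge), S)
  scale <- matrix(0, nrow(edge), S)
  for (k in seq_len(nrow(edge))) {
    ch <- edge[k, 2L]
    A[k, ] <- colSums(O[[k]] * L[[ch]])
    SB[k, ] <- colSums(O[[k]]) * colSums(L[[ch]]) / N_STATES
    scale[k, ] <- lsO[k, ] + lsL[ch, ]
  }
  list(tree = tr, A = A, SB = SB, scale = scale)
}
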