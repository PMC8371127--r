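# The slow-fast procedure: progressively strip the fastest-evolving
# sites (by posterior-mean rate) in fixed fractional steps, re-infer
# trees with bootstrap on each reduced alignment, and trace bootstrap
# support for named clade hypotheses.

#' Define a clade hypothesis
#'
#' A named bipartition: the set of leaves forming one side of an
#' unrooted split. Must be a proper non-trivial subset (>= 2 leaves,
#' <= n_taxa - 2) of the taxon set it is tested against.
#'
#' @param name short label (e.g. `"C+F"`).
#' @param clade character vector of leaf labels.
#' @return object of class `hypothesis`.
#' @export
hypothesis <- function(name, clade) {
  clade <- unique(as.character(clade))
  if (length(clade) < 2L)
    stop("hypothesis clade must contain at least 2 taxa", call. = FALSE)
  structure(list(name = name, clade = sort(clade)), class = "hypothesis")
}

#' Strip the fastest-evolving sites in cumulative steps
#'
#' Subset k removes the `ceiling(k * step * n_sites)` highest-rate sites
#' (cumulatively), ties broken by removing the lower site index first;
#' subsets are produced while at least `step * n_sites` sites would
#' remain. At `step = 0.05` this yields 19 reduced alignments.
#'
#' @param aln an [aa_alignment()].
#' @param profile a `site_rate_profile` (or numeric vector of per-site
#'   rates) matching the alignment length.
#' @param step fraction of sites removed per step, in (0, 1).
#' @return list of reduced [aa_alignment()]s; each carries the removed
#'   1-based site indices in attribute `"removed_sites"` and the kept
#'   indices in `"kept_sites"`.
#' @export
strip_sites <- function(aln, profile, step = 0.05) {
  rates <- if (inherits(profile, "site_rate_profile")) profile$rates
           else as.numeric(profile)
  if (length(rates) != ncol(aln))
    stop("rate profile length (", length(rates),
         ") does not match alignment sites (", ncol(aln), ")", call. = FALSE)
  if (step <= 0 || step >= 1)
    stop("step must lie strictly between 0 and 1", call. = FALSE)
  S <- ncol(aln)
  # fastest first; among equal rates the lower site index is removed first
  ord <- order(-rates, seq_len(S))
  out <- list()
  k <- 1L
  eps <- 1e-9  # guard the ceiling against binary-fraction step values
  repeat {
    n_remove <- ceiling(k * step * S - eps)
    if (S - n_remove < step * S - eps) break
    removed <- sort(ord[seq_len(n_remove)])
    kept <- setdiff(seq_len(S), removed)
    red <- aln[, kept, drop = FALSE]
    class(red) <- class(aln)
    attr(red, "removed_sites") <- removed
    attr(red, "kept_sites") <- kept
    out[[k]] <- red
    k <- k + 1L
  }
  out
}

#' Maximum-likelihood pairwise distances under the Poisson model
#'
#' `d = -(19/20) log(1 - (20/19) p)` with `p` the mismatch fraction over
#' jointly non-missing sites, capped at `max_dist` when saturated.
#'
#' @param aln an [aa_alignment()].
#' @param max_dist cap for saturated pairs (default 10 subs/site).
#' @return a `dist`-convertible symmetric matrix of distances.
#' @export
ml_distance <- function(aln, max_dist = 10) {
  codes <- encode_alignment(aln)
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      if (!any(ok))
        stop("taxa '", rownames(codes)[i], "' and '", rownames(codes)[j],
             "' share no non-missing sites", call. = FALSE)
      p <- mean(codes[i, ok] != codes[j, ok])
      d[i, j] <- d[j, i] <- poisson_distance(p, max_dist)
    }
  }
  d
}

poisson_distance <- function(p, max_dist = 10) {
  arg <- 1 - POISSON_BETA * p
  ifelse(arg <= 0, max_dist, pmin(-log(arg) / POISSON_BETA, max_dist))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around ape's NJ with negative branch lengths clamped to
#' zero (the usual convention for distance noise).
#'
#' @param d symmetric distance matrix with labels.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Infer a tree with bootstrap replicates
#'
#' Point tree by neighbor-joining on maximum-likelihood Poisson
#' distances; bootstrap trees from site-resampled alignments under the
#' same procedure. Deterministic given `seed`. Stands in for a full ML
#' tree search behind the same interface, so an external engine can be
#' substituted.
#'
#' @param aln an [aa_alignment()] with >= 4 taxa.
#' @param method tree method; only `"nj"` is provided.
#' @param n_bootstrap number of bootstrap replicates (0 for none).
#' @param seed integer seed for the resampling.
#' @param max_dist saturation cap passed to [ml_distance()].
#' @return list with `tree` (`phylo`) and `bootstrap` (list of `phylo`).
#' @export
infer_tree <- function(aln, method = c("nj"), n_bootstrap = 0L, seed = 1L,
                       max_dist = 10) {
  method <- match.arg(method)
  if (nrow(aln) < 4L) stop("need at least 4 taxa", call. = FALSE)
  codes <- encode_alignment(aln)
  n <- nrow(codes); S <- ncol(codes)
  # per-pair per-site mismatch and validity indicators, for fast
  # count-weighted bootstrap distances
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  mism <- matrix(0, nrow(pairs), S)
  valid <- matrix(0, nrow(pairs), S)
  for (k in seq_len(nrow(pairs))) {
    a <- codes[pairs[k, 1L], ]; b <- codes[pairs[k, 2L], ]
    ok <- !is.na(a) & !is.na(b)
    valid[k, ] <- as.numeric(ok)
    mism[k, ok] <- as.numeric(a[ok] != b[ok])
  }
  labs <- rownames(codes)
  dist_from_w <- function(w) {
    nv <- as.numeric(valid %*% w)
    if (any(nv == 0)) {
      bad <- which(nv == 0)[1L]
      stop("taxa '", labs[pairs[bad, 1L]], "' and '", labs[pairs[bad, 2L]],
           "' share no non-missing sites in replicate", call. = FALSE)
    }
    p <- as.numeric(mism %*% w) / nv
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    d[pairs] <- poisson_distance(p, max_dist)
    d + t(d)
  }
  point <- nj_tree(dist_from_w(rep(1, S)))
  boots <- list()
  if (n_bootstrap > 0L) {
    boots <- with_seed(seed, {
      W <- rmultinom(n_bootstrap, S, rep(1 / S, S))
      lapply(seq_len(n_bootstrap), function(b) nj_tree(dist_from_w(W[, b])))
    })
  }
  list(tree = point, bootstrap = boots)
}

#' Bootstrap support of a clade hypothesis
#'
#' Percentage of trees whose unrooted split set contains the bipartition
#' clade | complement. The clade must be a proper non-trivial subset of
#' the shared leaf set; taxa absent from the trees raise an error rather
#' than being silently pruned.
#'
#' @param trees list of `phylo` trees on one leaf set.
#' @param hyp a [hypothesis()].
#' @return support percentage in `[0, 100]`.
#' @export
split_support <- function(trees, hyp) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees supplied", call. = FALSE)
  labs <- sort(trees[[1L]]$tip.label)
  missing <- setdiff(hyp$clade, labs)
  if (length(missing))
    stop("hypothesis taxa absent from trees: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(hyp$clade) < 2L || length(hyp$clade) > length(labs) - 2L)
    stop("hypothesis clade must be a proper non-trivial subset ",
         "(2 .. n_taxa - 2 leaves)", call. = FALSE)
  ref <- labs[1L]
  key <- if (ref %in% hyp$clade) sort(setdiff(labs, hyp$clade)) else hyp$clade
  hits <- vapply(trees, function(tr) {
    if (!setequal(tr$tip.label, labs))
      stop("trees do not share one leaf set", call. = FALSE)
    any(vapply(unrooted_splits(tr), identical, logical(1L), y = key))
  }, logical(1L))
  100 * mean(hits)
}

#' Slow-fast support curve
#'
#' Composes [posterior_mean_rates()] -> [strip_sites()] ->
#' [infer_tree()] -> [split_support()]: per-site rates are estimated
#' once on the full alignment under the supplied tree, the
#' fastest-evolving sites are removed in cumulative `step` fractions,
#' and bootstrap support for each hypothesis is recorded at every step
#' (step 0 is the full alignment).
#'
#' @param aln an [aa_alignment()].
#' @param tree fixed tree used for rate estimation.
#' @param hypotheses list of [hypothesis()] objects.
#' @param step fraction removed per step (default 0.05).
#' @param n_bootstrap bootstrap replicates per step (default 100).
#' @param seed integer seed.
#' @param alpha gamma shape; fitted if `NULL`.
#' @param K rate categories.
#' @return a `support_curve` data frame: `fraction_removed`, `n_sites`,
#'   one support column per hypothesis.
#' @export
support_curve <- function(aln, tree, hypotheses, step = 0.05,
                          n_bootstrap = 100L, seed = 1L, alpha = NULL,
                          K = 4L) {
  if (inherits(hypotheses, "hypothesis")) hypotheses <- list(hypotheses)
  profile <- posterior_mean_rates(tree, aln, alpha = alpha, K = K)
  subsets <- c(list(aln), strip_sites(aln, profile, step))
  fractions <- (seq_along(subsets) - 1L) * step
  sup <- matrix(NA_real_, length(subsets), length(hypotheses))
  colnames(sup) <- vapply(hypotheses, `[[`, character(1L), "name")
  nsites <- integer(length(subsets))
  for (i in seq_along(subsets)) {
    nsites[i] <- ncol(subsets[[i]])
    fit <- infer_tree(subsets[[i]], n_bootstrap = n_bootstrap,
                      seed = seed + i)
    for (h in seq_along(hypotheses))
      sup[i, h] <- split_support(fit$bootstrap, hypotheses[[h]])
  }
  out <- data.frame(fraction_removed = fractions, n_sites = nsites,
                    sup, check.names = FALSE)
  class(out) <- c("support_curve", "data.frame")
  out
}

#' Write a support curve as TSV
#' @param curve a `support_curve`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_support_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
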