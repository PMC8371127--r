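# Comparative statistics on binary presence/absence profiles:
# distances, principal coordinate analysis, Ward clustering and
# heatmap ordering.

#' Pairwise distances between binary species profiles
#'
#' `jaccard`: 1 - shared/union over positions where either species has
#' the trait. `simple_matching`: fraction of disagreeing positions.
#' `pearson_complement`: `1 - phi` where phi is the Pearson (phi)
#' coefficient of the two binary vectors; range `[0, 2]`, deliberately
#' left unclamped so perfectly anti-correlated profiles sit at 2.
#' Constant (all-0/all-1) profiles have no defined phi; their
#' pearson_complement distance is set to 0 against an identical profile
#' and 1 otherwise, with a warning.
#'
#' @param tm a [trait_matrix()] with >= 2 species.
#' @param metric distance metric.
#' @return symmetric `profile_dist` matrix with zero diagonal and the
#'   metric name in attribute `"metric"`.
#' @export
profile_distance <- function(tm, metric = c("pearson_complement", "jaccard",
                                            "simple_matching")) {
  metric <- match.arg(metric)
  m <- unclass(tm)
  if (nrow(m) < 2L) stop("need at least 2 species", call. = FALSE)
  if (metric == "jaccard") {
    d <- as.matrix(dist(m, method = "binary"))
  } else if (metric == "simple_matching") {
    d <- as.matrix(dist(m, method = "manhattan")) / ncol(m)
  } else {
    sds <- apply(m, 1L, function(x) length(unique(x)) > 1L)
    d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
    if (all(sds)) {
      d <- 1 - cor(t(m))
    } else {
      warning("constant all-0/all-1 profile(s): pearson_complement set to ",
              "0 for identical, 1 for differing profiles", call. = FALSE)
      for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
        if (i == j) next
        d[i, j] <- if (sds[i] && sds[j]) 1 - cor(m[i, ], m[j, ])
                   else if (identical(m[i, ], m[j, ])) 0 else 1
      }
    }
    diag(d) <- 0
  }
  d <- (d + t(d)) / 2  # enforce exact symmetry
  structure(d, metric = metric, class = c("profile_dist", class(d)))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and keeps positive
#' eigenvalues up to `n_axes`; coordinates are scaled by the square
#' root of the eigenvalues. Sign convention: the first nonzero loading
#' of each axis is positive. Negative eigenvalues are dropped and their
#' absolute mass reported in attribute `"negative_mass"`.
#'
#' @param d symmetric distance matrix (or `profile_dist`).
#' @param n_axes number of axes to retain (>= 1).
#' @return an `ordination`: list with `coordinates` (species x axes),
#'   `eigenvalues` (positive, non-increasing) and
#'   `proportion_explained`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  if (n_axes < 1L) stop("n_axes must be >= 1", call. = FALSE)
  d <- as.matrix(d)
  n <- nrow(d)
  # cmdscale's own warning about non-positive eigenvalues is redundant:
  # they are filtered below and reported as negative_mass
  sc <- suppressWarnings(cmdscale(as.dist(d), k = n - 1L, eig = TRUE))
  ev <- sc$eig
  pos <- which(ev > max(ev) * 1e-12 & ev > 0)
  if (!length(pos))
    stop("degenerate distances: no positive eigenvalues", call. = FALSE)
  keep <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- sc$points[, keep, drop = FALSE]
  for (a in seq_len(ncol(coords))) {  # deterministic sign convention
    nz <- which(abs(coords[, a]) > 1e-12)
    if (length(nz) && coords[nz[1L], a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = ev[keep],
                 proportion_explained = ev[keep] / sum(ev[pos])),
            negative_mass = sum(abs(ev[ev < 0])),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes (",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Ward hierarchical clustering of profiles
#'
#' `orthologs_euclidean`: clusters traits (columns) on Euclidean
#' distances between their binary presence vectors across species.
#' `species_pearson`: clusters species on `1 - r`, the complement of
#' the interspecific Pearson correlation of their profiles. Ward.D2
#' linkage in both modes; items are taken in ascending label order so
#' ties resolve deterministically.
#'
#' @param tm a [trait_matrix()], or a precomputed distance matrix.
#' @param mode clustering mode (ignored when `tm` is already a
#'   distance).
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the dendrogram), `order` (leaf labels in
#'   dendrogram order) and, when `k` is given, `clusters` (named
#'   membership vector).
#' @export
ward_cluster <- function(tm, mode = c("species_pearson",
                                      "orthologs_euclidean"), k = NULL) {
  mode <- match.arg(mode)
  if (inherits(tm, "trait_matrix")) {
    m <- unclass(tm)
    if (mode == "orthologs_euclidean") {
      m <- t(m)
      d <- dist(m[sort(rownames(m)), , drop = FALSE])
    } else {
      m <- m[sort(rownames(m)), , drop = FALSE]
      cc <- suppressWarnings(cor(t(m)))
      cc[!is.finite(cc)] <- 0
      d <- as.dist(1 - cc)
    }
  } else {
    d <- as.dist(as.matrix(tm))
  }
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  hc <- hclust(d, method = "ward.D2")
  out <- list(hclust = hc, order = hc$labels[hc$order])
  if (!is.null(k)) out$clusters <- cutree(hc, k = k)
  out
}

#' Reorder a trait matrix for heatmap rendering
#'
#' Applies the leaf order of row/column dendrograms (as returned by
#' [ward_cluster()]) to the matrix; values are untouched.
#'
#' @param tm a [trait_matrix()].
#' @param row_order character vector (or `ward_cluster` result) giving
#'   the species order; `NULL` keeps the current order.
#' @param col_order likewise for traits.
#' @return reordered [trait_matrix()].
#' @export
heatmap_order <- function(tm, row_order = NULL, col_order = NULL) {
  get_order <- function(o) if (is.list(o)) o$order else o
  ro <- get_order(row_order); co <- get_order(col_order)
  if (is.null(ro)) ro <- rownames(tm)
  if (is.null(co)) co <- colnames(tm)
  if (!setequal(ro, rownames(tm)))
    stop("row order does not match species labels", call. = FALSE)
  if (!setequal(co, colnames(tm)))
    stop("column order does not match trait labels", call. = FALSE)
  out <- unclass(tm)[ro, co, drop = FALSE]
  trait_matrix(out, categories = attr(tm, "categories"))
}
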