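# Shared fixtures and independent oracles, all built in code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# random alignment with optional missing characters
rand_aln <- function(n_taxa, n_sites, seed = 1, p_missing = 0) {
  set.seed(seed)
  pool <- AA20
  m <- matrix(sample(pool, n_taxa * n_sites, replace = TRUE),
              n_taxa, n_sites)
  if (p_missing > 0) {
    hit <- runif(length(m)) < p_missing
    m[hit] <- sample(c("-", "X", "?"), sum(hit), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(n_taxa))
  suppressWarnings(aa_alignment(m))
}

# character-by-character reference FASTA parser, independent of the
# package reader
ref_fasta_parse <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur <- sub("\\s.*$", "", substring(ln, 2))
      out[[cur]] <- character(0)
    } else {
      out[[cur]] <- c(out[[cur]], toupper(strsplit(ln, "")[[1]]))
    }
  }
  out
}

# exhaustive minimal-loss count under the single-gain (Dollo)
# constraint: enumerate every connected presence assignment over the
# internal nodes that covers the possessor leaves
dollo_brute_force <- function(tree, present_leaves) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- tree$edge
  poss <- match(present_leaves, tree$tip.label)
  if (!length(poss)) return(0L)
  parent <- rep(NA_integer_, n_node)
  parent[edge[, 2]] <- edge[, 1]
  internal <- (n_tip + 1):n_node
  ni <- length(internal)
  best <- Inf
  base <- rep(FALSE, n_node)
  base[poss] <- TRUE
  for (mask in 0:(2^ni - 1)) {
    pres <- base
    if (ni > 0) {
      bits <- bitwAnd(mask, bitwShiftL(1L, seq_len(ni) - 1L)) > 0
      pres[internal[bits]] <- TRUE
    }
    tops <- which(pres & (is.na(parent) | !pres[parent]))
    if (length(tops) != 1L) next   # single gain, connected presence
    losses <- sum(pres[edge[, 1]] & !pres[edge[, 2]])
    if (losses < best) best <- losses
  }
  as.integer(best)
}

# random rooted tree with unique labels (for Dollo property tests)
rand_rooted_tree <- function(n_tip, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tip)
  tr$tip.label <- paste0("sp", seq_len(n_tip))
  tr
}
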