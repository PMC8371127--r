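# Shared domain types and file formats: amino-acid alignments (FASTA,
# relaxed PHYLIP), Newick trees, and binary trait matrices (TSV).

#' Construct an amino-acid alignment
#'
#' An `aa_alignment` is a character matrix with taxa as rows (unique,
#' non-empty rownames) and sites as columns. The alphabet is the 20
#' amino-acid one-letter codes plus `-`, `X` and `?`, which are all
#' treated downstream as a single missing state. Sites are indexed
#' 1-based in every report.
#'
#' @param x character matrix (taxa x sites) or list of equal-length
#'   character vectors named by taxon.
#' @return an object of class `aa_alignment`.
#' @export
aa_alignment <- function(x) {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[which(lens != lens[1L])[1L]]
      stop("ragged alignment: row '", bad, "' differs in length", call. = FALSE)
    }
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.character(x))
    stop("alignment must be a character matrix", call. = FALSE)
  taxa <- rownames(x)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("all taxa must have non-empty names", call. = FALSE)
  if (anyDuplicated(taxa))
    stop("duplicate taxon name: '", taxa[duplicated(taxa)][1L], "'",
         call. = FALSE)
  if (nrow(x) < 2L) stop("alignment needs at least 2 taxa", call. = FALSE)
  if (ncol(x) < 1L) stop("alignment needs at least 1 site", call. = FALSE)
  x[] <- toupper(x)
  alphabet <- c(AA_CODES, MISSING_CODES)
  bad <- !(x %in% alphabet)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop("invalid character '", x[idx], "' (taxon '",
         taxa[(idx - 1L) %% nrow(x) + 1L], "')", call. = FALSE)
  }
  if (ncol(x) > 0L) {
    all_missing <- colSums(matrix(x %in% MISSING_CODES, nrow(x))) == nrow(x)
    if (any(all_missing))
      warning("alignment contains ", sum(all_missing),
              " fully-missing column(s)", call. = FALSE)
  }
  structure(x, class = c("aa_alignment", class(x)))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

#' Number of taxa / sites in an alignment
#' @param aln an `aa_alignment`.
#' @return integer.
#' @export
n_taxa <- function(aln) nrow(aln)

#' @rdname n_taxa
#' @export
n_sites <- function(aln) ncol(aln)

#' Read a protein alignment
#'
#' Reads FASTA (via Biostrings) or sequential relaxed PHYLIP
#' (whitespace-separated name and sequence). Residues are uppercased on
#' read and checked against the amino-acid alphabet; taxon order is
#' preserved from the file.
#'
#' @param path file path.
#' @param dialect `"fasta"` or `"phylip-relaxed"`.
#' @return an [aa_alignment()].
#' @export
read_alignment <- function(path, dialect = c("fasta", "phylip-relaxed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    seqs <- strsplit(as.character(ss), "", fixed = TRUE)
    names(seqs) <- nm
    if (anyDuplicated(nm))
      stop("duplicate taxon name: '", nm[duplicated(nm)][1L], "'",
           call. = FALSE)
    aa_alignment(seqs)
  } else {
    read_phylip_relaxed(path)
  }
}

# phangorn's PHYLIP reader mis-detects sequential vs interleaved layout on
# very short alignments, so the sequential relaxed dialect is parsed here.
read_phylip_relaxed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed PHYLIP header: '", lines[1L], "'", call. = FALSE)
  body <- lines[-1L]
  if (length(body) != hdr[1L])
    stop("PHYLIP: expected ", hdr[1L], " sequences, found ", length(body),
         call. = FALSE)
  seqs <- vector("list", hdr[1L])
  nms <- character(hdr[1L])
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(tok) < 2L)
      stop("PHYLIP: row ", i, " has no sequence", call. = FALSE)
    nms[i] <- tok[1L]
    seqs[[i]] <- strsplit(paste(tok[-1L], collapse = ""), "", fixed = TRUE)[[1L]]
    if (length(seqs[[i]]) != hdr[2L])
      stop("ragged alignment: row '", nms[i], "' has ", length(seqs[[i]]),
           " sites, header says ", hdr[2L], call. = FALSE)
  }
  if (anyDuplicated(nms))
    stop("duplicate taxon name: '", nms[duplicated(nms)][1L], "'",
         call. = FALSE)
  names(seqs) <- nms
  aa_alignment(seqs)
}

#' Write a protein alignment
#'
#' @param aln an [aa_alignment()].
#' @param path output file.
#' @param dialect `"fasta"` or `"phylip-relaxed"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "phylip-relaxed")) {
  dialect <- match.arg(dialect)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  if (dialect == "fasta") {
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- rownames(aln)
    Biostrings::writeXStringSet(ss, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(nrow(aln), ncol(aln)), con)
    writeLines(paste(rownames(aln), seqs), con)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser that add an early balance
#' check with a character offset and keep internal node labels (read as
#' support strings). Round-trips preserve topology, branch lengths and
#' labels.
#'
#' @param path file path (for `read_tree`), or output path.
#' @return `read_tree`: an [ape::phylo] object; `newick` : Newick text.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path), collapse = "")
  check_newick_balance(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path, call. = FALSE)
  tr
}

check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parentheses at character ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " '(' left open at character ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  writeLines(newick(tree), path)
  invisible(path)
}

#' Construct a binary trait matrix
#'
#' Species x trait presence/absence indicators (0/1, no missing cells),
#' optionally with a trait -> functional-category map.
#'
#' @param values numeric/integer matrix of 0/1 with species rownames and
#'   trait colnames.
#' @param categories optional named character vector mapping trait names
#'   to category labels (a subset of traits).
#' @return object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, categories = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("species and trait names required", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate species label", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate trait label", call. = FALSE)
  bad <- !(values %in% c(0, 1))
  if (any(bad)) {
    idx <- which(bad)[1L]
    r <- (idx - 1L) %% nrow(values) + 1L
    c <- (idx - 1L) %/% nrow(values) + 1L
    stop("non-binary cell at species '", rownames(values)[r], "', trait '",
         colnames(values)[c], "': ", values[idx], call. = FALSE)
  }
  storage.mode(values) <- "integer"
  if (!is.null(categories)) {
    if (is.null(names(categories)) || any(!nzchar(categories)))
      stop("categories must be a named vector with non-empty labels",
           call. = FALSE)
    unknown <- setdiff(names(categories), colnames(values))
    if (length(unknown))
      stop("category map names unknown trait(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(values, categories = categories,
            class = c("trait_matrix", class(values)))
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x), "species x", ncol(x), "traits")
  ct <- attr(x, "categories")
  if (!is.null(ct)) cat(" (", length(unique(ct)), "categories )")
  cat("\n")
  invisible(x)
}

#' Read a binary presence/absence trait matrix
#'
#' TSV with a header row of trait labels and a first column of species
#' labels; cells must be 0 or 1. An optional two-column category TSV
#' (trait, category) attaches functional-category labels.
#'
#' @param path trait matrix TSV.
#' @param category_path optional trait-category TSV (no header).
#' @return a [trait_matrix()].
#' @export
read_trait_matrix <- function(path, category_path = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  categories <- NULL
  if (!is.null(category_path)) {
    cd <- tryCatch(
      read.delim(category_path, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) NULL)
    if (!is.null(cd) && nrow(cd) > 0L)
      categories <- setNames(as.character(cd[[2L]]), as.character(cd[[1L]]))
  }
  trait_matrix(m, categories = categories)
}

#' Write a trait matrix as TSV
#' @param tm a [trait_matrix()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(tm, path) {
  df <- data.frame(species = rownames(tm), unclass(tm)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sizes of the attached trait categories
#' @param tm a [trait_matrix()].
#' @return named integer vector (category -> number of traits), or `NULL`.
#' @export
category_sizes <- function(tm) {
  ct <- attr(tm, "categories")
  if (is.null(ct)) return(NULL)
  tab <- table(ct)
  setNames(as.integer(tab), names(tab))
}

#' Canonical unrooted split set of a tree
#'
#' Each non-trivial bipartition is represented by the side that does NOT
#' contain the reference taxon (the alphabetically first leaf label), as
#' a sorted label vector, so complementary duplicates cannot occur.
#'
#' @param tree a `phylo` object (rooted or unrooted).
#' @return list of sorted character vectors, one per internal split.
#' @export
unrooted_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= length(labs) - 2L)
      out[[length(out) + 1L]] <- sort(side)
  }
  out <- unique(out)
  # canonical list order, independent of traversal/rooting
  out[order(vapply(out, paste, character(1L), collapse = "\r"))]
}
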