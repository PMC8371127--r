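test_that("FASTA parsing handles basic records, case and matches a reference parser", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "MKV", ">B", "MKL"), f)
  aln <- read_alignment(f, "fasta")
  expect_s3_class(aln, "aa_alignment")
  expect_equal(n_taxa(aln), 2L)
  expect_equal(n_sites(aln), 3L)
  expect_equal(unname(unclass(aln)["A", ]), c("M", "K", "V"))

  writeLines(c(">a", "mkv"), f)
  expect_error(read_alignment(f, "fasta"), "at least 2 taxa")

  # reference-parser agreement on random files, incl. lowercase and
  # wrapped lines
  for (i in 1:100) {
    set.seed(i)
    nt <- sample(2:5, 1)
    ns <- sample(3:30, 1)
    seqs <- replicate(nt, paste(sample(c(AA20, letters[c(1, 3, 4, 5)],
                                         "-", "?", "X"),
                                       ns, replace = TRUE), collapse = ""))
    nm <- paste0("tx", seq_len(nt))
    txt <- unlist(lapply(seq_len(nt), function(j) {
      body <- seqs[j]
      if (nchar(body) > 10)
        body <- c(substr(body, 1, 10), substr(body, 11, nchar(body)))
      c(paste0(">", nm[j]), body)
    }))
    writeLines(txt, f)
    ref <- ref_fasta_parse(f)
    ok <- all(vapply(ref, function(x)
      all(x %in% c(AA20, "-", "X", "?")), logical(1)))
    if (!ok) {
      expect_error(read_alignment(f, "fasta"), "invalid character")
    } else {
      # random draws can produce fully-missing columns, which warn
      got <- suppressWarnings(read_alignment(f, "fasta"))
      expect_equal(lapply(seq_len(nrow(got)), function(r)
        unname(unclass(got)[r, ])), unname(ref))
    }
  }
})

test_that("relaxed PHYLIP round-trips alignments exactly", {
  f <- withr::local_tempfile(fileext = ".phy")
  aln <- aa_alignment(list(A = c("M", "K", "V"), B = c("M", "K", "L")))
  write_alignment(aln, f, "phylip-relaxed")
  back <- read_alignment(f, "phylip-relaxed")
  expect_equal(unclass(back), unclass(aln))
  # write -> read -> write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".phy")
  write_alignment(back, f2, "phylip-relaxed")
  expect_identical(readLines(f), readLines(f2))

  for (i in 1:20) {
    aln <- rand_aln(sample(2:8, 1), sample(1:40, 1), seed = 1000 + i,
                    p_missing = 0.1)
    write_alignment(aln, f, "phylip-relaxed")
    expect_equal(unclass(read_alignment(f, "phylip-relaxed")), unclass(aln))
  }
})

test_that("alignment errors name the offending label or row", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "MK", ">dup", "ML"), f)
  expect_error(read_alignment(f, "fasta"), "dup")
  p <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 3", "A MKV", "B MK"), p)
  expect_error(read_alignment(p, "phylip-relaxed"), "'B'")
  expect_error(aa_alignment(list(A = c("M"), B = c("M", "K"))), "ragged")
  expect_error(aa_alignment(matrix(c("M", "J", "K", "K"), 2, 2,
                                   dimnames = list(c("A", "B"), NULL))),
               "invalid character 'J'")
  expect_warning(aa_alignment(matrix(c("M", "-", "K", "?"), 2, 2,
                                     byrow = TRUE,
                                     dimnames = list(c("A", "B"), NULL))),
                 "fully-missing")
})

test_that("Newick read/write preserves topology, lengths and labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):1,(C:3,D:4):0);", f)
  tr <- read_tree(f)
  expect_equal(ape::Ntip(tr), 4L)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  int <- tr$edge[, 2] > 4
  expect_true(1 %in% tr$edge.length[int])

  writeLines("((A,B)95,(C,D)87);", f)
  tr2 <- read_tree(f)
  expect_setequal(tr2$node.label[-1], c("95", "87"))

  writeLines("((A:1,B:2):1,(C:3;", f)
  expect_error(read_tree(f), "unbalanced parentheses")

  # split sets survive write -> read on random trees
  for (i in 1:100) {
    set.seed(i)
    tr <- ape::rtree(sample(8:64, 1))
    write_tree(tr, f)
    back <- read_tree(f)
    expect_equal(unrooted_splits(back), unrooted_splits(tr))
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-10)
  }
})

test_that("split sets are invariant to rerooting", {
  set.seed(7)
  tr <- ape::rtree(10)
  s0 <- unrooted_splits(tr)
  for (nd in (ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode)) {
    rr <- ape::root(tr, node = nd, resolve.root = TRUE)
    expect_equal(unrooted_splits(rr), s0)
  }
})

test_that("trait matrix TSV reading preserves values, order and categories", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tg1\tg2", "sp1\t1\t0", "sp2\t1\t1", "sp3\t0\t0"), f)
  tm <- read_trait_matrix(f)
  expect_equal(unname(colSums(tm)), c(2, 1))
  expect_equal(rownames(tm), c("sp1", "sp2", "sp3"))
  expect_equal(colnames(tm), c("g1", "g2"))

  writeLines(c("species\tg1", "sp1\t2"), f)
  expect_error(read_trait_matrix(f), "sp1.*g1|g1.*sp1")

  # category map with the published hyphal category sizes
  cf <- withr::local_tempfile(fileext = ".tsv")
  write_hyphal_category_map(cf)
  sizes <- hyphal_category_sizes()
  mf <- withr::local_tempfile(fileext = ".tsv")
  traits <- sprintf("trait%04d", seq_len(sum(sizes)))
  writeLines(c(paste(c("species", traits), collapse = "\t"),
               paste(c("sp1", rep(1, length(traits))), collapse = "\t"),
               paste(c("sp2", rep(0, length(traits))), collapse = "\t")), mf)
  tm2 <- read_trait_matrix(mf, cf)
  expect_equal(sort(category_sizes(tm2)), sort(sizes))

  # category naming an unknown trait
  writeLines("nosuchtrait\tcatX", cf)
  expect_error(read_trait_matrix(mf, cf), "nosuchtrait")

  # empty category file leaves the matrix valid without categories
  writeLines(character(0), cf)
  tm3 <- read_trait_matrix(mf, cf)
  expect_null(category_sizes(tm3))
})
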