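test_that("site stripping removes the right sites in the right order", {
  aln <- rand_aln(4, 20, seed = 1)
  rates <- seq(0.1, 2, length.out = 20)
  subs <- strip_sites(aln, rates, step = 0.10)
  expect_equal(attr(subs[[1]], "removed_sites"), c(19L, 20L))
  expect_equal(n_sites(subs[[1]]), 18L)
  # cumulative: subset k+1 removes a superset of subset k
  for (k in seq_len(length(subs) - 1))
    expect_true(all(attr(subs[[k]], "removed_sites") %in%
                    attr(subs[[k + 1]], "removed_sites")))
  # tie-break: equal rates drop the lower site index first
  tied <- strip_sites(aln, rep(1, 20), step = 0.10)
  expect_equal(attr(tied[[1]], "removed_sites"), c(1L, 2L))

  big <- rand_aln(4, 1000, seed = 2)
  expect_length(strip_sites(big, runif(1000), step = 0.05), 19L)
  half <- strip_sites(big, runif(1000), step = 0.5)
  expect_length(half, 1L)
  expect_equal(n_sites(half[[1]]), 500L)

  expect_error(strip_sites(aln, rates, step = 1), "between 0 and 1")
  expect_error(strip_sites(aln, rates[-1], step = 0.1), "does not match")
})

test_that("NJ recovers the additive four-taxon worked example exactly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  expect_equal(unrooted_splits(tr), list(c("C", "D")))
  internal <- tr$edge[, 1] > 4 & tr$edge[, 2] > 4
  expect_equal(tr$edge.length[internal], 1, tolerance = 1e-10)
  tip_len <- setNames(tr$edge.length[match(1:4, tr$edge[, 2])],
                      tr$tip.label)
  expect_equal(tip_len[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4),
               tolerance = 1e-10)
})

test_that("identical sequences give a zero-length star-like tree", {
  m <- matrix("M", 5, 30, dimnames = list(paste0("s", 1:5), NULL))
  m[, 1:10] <- "K"
  fit <- infer_tree(aa_alignment(m))
  expect_equal(max(fit$tree$edge.length), 0)
})

test_that("ml distances follow the Poisson correction and error on no overlap", {
  aln <- aa_alignment(matrix(c("M", "M", "K", "M", "M", "M", "M", "K"),
                             2, 4, byrow = FALSE,
                             dimnames = list(c("A", "B"), NULL)))
  d <- ml_distance(aln)
  p <- 0.5
  expect_equal(d["A", "B"], -(19 / 20) * log(1 - (20 / 19) * p),
               tolerance = 1e-12)
  # saturated pair hits the cap
  sat <- aa_alignment(matrix(c("M", "K"), 2, 1,
                             dimnames = list(c("A", "B"), NULL)))
  expect_equal(ml_distance(sat)["A", "B"], 10)
  # disjoint missing patterns
  nm <- suppressWarnings(aa_alignment(
    matrix(c("M", "-", "-", "K"), 2, 2,
           dimnames = list(c("A", "B"), NULL))))
  expect_error(ml_distance(nm), "A.*B|B.*A")
})

test_that("tree inference is deterministic and recovers simulated topologies", {
  cfg <- sim_config(n_taxa = 8, seed = 11, n_sites = 2000, alpha = 1)
  tr <- simulate_tree(cfg)
  aln <- simulate_alignment(tr, cfg)$alignment
  f1 <- infer_tree(aln, n_bootstrap = 10, seed = 5)
  f2 <- infer_tree(aln, n_bootstrap = 10, seed = 5)
  expect_identical(lapply(f1$bootstrap, newick), lapply(f2$bootstrap, newick))
  expect_equal(ape::dist.topo(ape::unroot(tr), f1$tree), 0,
               ignore_attr = TRUE)
  expect_error(infer_tree(rand_aln(3, 10)), "4 taxa")
})

test_that("split support counts bipartitions exactly", {
  with_split <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  without <- ape::read.tree(text = "((A:1,C:1):1,(B:1,(D:1,E:1):1):1);")
  trees <- c(rep(list(with_split), 7), rep(list(without), 3))
  h <- hypothesis("AB", c("A", "B"))
  expect_equal(split_support(trees, h), 70)
  expect_equal(split_support(rep(list(with_split), 5), h), 100)
  # complement labelling gives the same support
  hc <- hypothesis("notAB", c("C", "D", "E"))
  expect_equal(split_support(trees, hc), 70)
  expect_error(hypothesis("single", "A"), "at least 2")
  expect_error(split_support(trees, hypothesis("too_big", LETTERS[1:4])),
               "proper non-trivial")
  expect_error(split_support(trees, hypothesis("alien", c("A", "Z"))), "Z")
})

test_that("support curves have slow-fast bookkeeping and sane supports", {
  cfg <- sim_config(n_taxa = 8, seed = 23, n_sites = 200, alpha = 0.5)
  tr <- simulate_tree(cfg)
  aln <- simulate_alignment(tr, cfg)$alignment
  true_split <- unrooted_splits(tr)[[1]]
  h <- hypothesis("true", true_split)
  cv <- support_curve(aln, tr, list(h), step = 0.05, n_bootstrap = 20,
                      seed = 3, alpha = 0.5)
  expect_equal(nrow(cv), 20L)
  expect_equal(cv$fraction_removed, seq(0, 0.95, by = 0.05))
  expect_true(all(diff(cv$n_sites) < 0))
  expect_true(all(cv$true >= 0 & cv$true <= 100))
  expect_equal(cv$n_sites[1], 200L)
})

test_that("long-branch attraction support collapses once fast sites are removed", {
  # one representative seed of the benchmark scenario; the 10-seed
  # version backs the acceptance criterion
  sc <- lba_scenario(seed = 2)
  fit <- infer_tree(sc$alignment, n_bootstrap = 50, seed = 2)
  prof <- posterior_mean_rates(fit$tree, sc$alignment, K = 4)
  h <- hypothesis("false_clade", sc$false_clade)
  s0 <- split_support(fit$bootstrap, h)
  red <- strip_sites(sc$alignment, prof, 0.05)[[10]]
  fit50 <- infer_tree(red, n_bootstrap = 50, seed = 3)
  s50 <- split_support(fit50$bootstrap, h)
  expect_gt(s0, s50)
})
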