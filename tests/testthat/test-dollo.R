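test_that("Dollo reconstruction matches the worked five-leaf example", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tm <- trait_matrix(matrix(c(1, 1, 0, 1, 0), 5, 1,
                            dimnames = list(c("A", "B", "C", "D", "E"),
                                            "x")))
  map <- dollo_reconstruct(tr, tm)
  pres <- map$presence[, "x"]
  expect_equal(pres[c("A", "B", "D")], c(A = 1L, B = 1L, D = 1L))
  expect_equal(pres[c("C", "E")], c(C = 0L, E = 0L))
  # present: A, B, D plus root, (A,B), (C,(D,E)), (D,E)
  expect_equal(sum(pres), 7L)
  expect_equal(unname(map$gain_node["x"]), "node6")
  expect_equal(unname(map$n_losses[["x"]]), 2L)
})

test_that("ubiquitous and absent traits are handled cleanly", {
  tr <- rand_rooted_tree(6, seed = 1)
  vals <- cbind(all1 = rep(1L, 6), all0 = rep(0L, 6))
  rownames(vals) <- tr$tip.label
  map <- dollo_reconstruct(tr, trait_matrix(vals))
  expect_true(all(map$presence[, "all1"] == 1L))
  expect_equal(unname(map$n_losses[["all1"]]), 0L)
  expect_true(all(map$presence[, "all0"] == 0L))
  expect_true(is.na(map$gain_node["all0"]))
  expect_error(dollo_reconstruct(ape::unroot(tr), trait_matrix(vals)),
               "rooted")
  bad <- vals
  rownames(bad)[1] <- "ghost"
  expect_error(dollo_reconstruct(tr, trait_matrix(bad)), "ghost")
})

test_that("reconstruction attains the exhaustive single-gain minimal loss count", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    tr <- rand_rooted_tree(n, seed = 5000 + i)
    vals <- matrix(rbinom(n, 1, runif(1, 0.2, 0.8)), n, 1,
                   dimnames = list(tr$tip.label, "tr1"))
    map <- dollo_reconstruct(tr, trait_matrix(vals))
    poss <- rownames(vals)[vals[, 1] == 1]
    expect_identical(unname(map$n_losses[["tr1"]]),
                     dollo_brute_force(tr, poss))
    # presence forms a connected subtree below the gain node
    if (length(poss)) {
      pres <- which(map$presence[, 1] == 1L)
      parent <- rep(NA_integer_, n + tr$Nnode)
      parent[tr$edge[, 2]] <- tr$edge[, 1]
      tops <- sum(vapply(pres, function(v)
        is.na(parent[v]) || !(parent[v] %in% pres), logical(1)))
      expect_equal(tops, 1L)
    }
  }
})

test_that("node percentages use the requested denominator", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  vals <- cbind(t1 = c(1, 1, 1, 1), t2 = c(1, 1, 0, 0), t3 = c(0, 1, 0, 0),
                t4 = c(1, 1, 1, 0))
  rownames(vals) <- c("A", "B", "C", "D")
  map <- dollo_reconstruct(tr, trait_matrix(vals))
  np <- node_percentages(map)
  expect_equal(np$percentage[np$node == "A"], 75)
  # root: t1 gains at root, t4 gains at root (possessors A,B,C), t2 at
  # (A,B), t3 at B -> root has t1 + t4 = 50%
  expect_equal(np$percentage[np$node == "node5"], 50)
  fam <- c(t1 = "f1", t2 = "f1", t3 = "f2", t4 = "f2")
  npf <- node_percentages(map, denominator = "families", families = fam)
  expect_equal(npf$percentage[npf$node == "node5"], 100)  # f1 via t1, f2 via t4
  expect_equal(npf$percentage[npf$node == "D"], 50)
  # all-present matrix gives 100 everywhere
  all1 <- trait_matrix(matrix(1L, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                                        c("u", "v"))))
  np1 <- node_percentages(dollo_reconstruct(tr, all1))
  expect_true(all(np1$percentage == 100))
})

test_that("gain/loss tables conserve events and decompose by category", {
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  set.seed(4)
  vals <- matrix(rbinom(5 * 9, 1, 0.5), 5, 9,
                 dimnames = list(c("A", "B", "C", "D", "E"),
                                 paste0("g", 1:9)))
  ct <- setNames(rep(c("c1", "c2", "c3"), each = 3), paste0("g", 1:9))
  tm <- trait_matrix(vals, categories = ct)
  map <- dollo_reconstruct(tr, tm)
  gl <- gain_loss_table(map)
  expect_equal(sum(gl$gains), sum(colSums(vals) > 0))
  expect_equal(sum(gl$losses), sum(map$n_losses))
  # per-category columns equal independent per-category runs
  for (cat in c("c1", "c2", "c3")) {
    sub <- trait_matrix(vals[, ct == cat, drop = FALSE])
    gl_sub <- gain_loss_table(dollo_reconstruct(tr, sub))
    expect_equal(gl[[paste0("gains.", cat)]], gl_sub$gains)
    expect_equal(gl[[paste0("losses.", cat)]], gl_sub$losses)
  }
  expect_equal(gl$gains + 0, rowSums(gl[, paste0("gains.", c("c1", "c2", "c3"))]))

  # a single-possessor trait is one gain at that leaf, no losses
  single <- trait_matrix(matrix(c(0, 0, 1, 0, 0), 5, 1,
                                dimnames = list(c("A", "B", "C", "D", "E"),
                                                "solo")))
  gls <- gain_loss_table(dollo_reconstruct(tr, single))
  expect_equal(gls$gains[gls$node == "C"], 1L)
  expect_equal(sum(gls$gains), 1L)
  expect_equal(sum(gls$losses), 0L)
})

test_that("an all-zero outgroup leaves reconstructions unchanged", {
  for (s in 1:10) {
    tr <- rand_rooted_tree(6, seed = 600 + s)
    set.seed(700 + s)
    vals <- matrix(rbinom(6 * 5, 1, 0.5), 6, 5,
                   dimnames = list(tr$tip.label, paste0("g", 1:5)))
    tm <- trait_matrix(vals)
    map <- dollo_reconstruct(tr, tm)
    # graft an outgroup above the old root
    big <- ape::read.tree(text = paste0("(", sub(";", "", newick(tr)),
                                        ":1,outgroup:1);"))
    vals2 <- rbind(vals, outgroup = 0L)
    map2 <- dollo_reconstruct(big, trait_matrix(vals2))
    expect_identical(unname(map2$n_losses), unname(map$n_losses))
    for (j in colnames(vals)) {
      leaves1 <- rownames(map$presence)[map$presence[, j] == 1L]
      leaves1 <- intersect(leaves1, tr$tip.label)
      leaves2 <- intersect(rownames(map2$presence)[map2$presence[, j] == 1L],
                           big$tip.label)
      expect_setequal(leaves2, leaves1)
    }
  }
})
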