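# Distances, neighbor-joining, and polytomy-aware congruence.

test_that("p-distance and K2P behave on simple pairs", {
  aln <- c(a = "ACGT", b = "ACGA")
  expect_equal(pairwiseDistances(aln, "p_distance")[1, 2], 0.25)
  same <- c(a = "ACGTACGT", b = "ACGTACGT")
  expect_equal(pairwiseDistances(same, "k2p")[1, 2], 0)
  # random pairs against the closed form
  set.seed(4)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    y <- strsplit(x, "")[[1]]
    mut <- sample(300, 30)
    for (m in mut) y[m] <- sample(setdiff(c("A", "C", "G", "T"), y[m]), 1)
    y <- paste(y, collapse = "")
    got <- pairwiseDistances(c(a = x, b = y), "k2p")[1, 2]
    expect_equal(got, oracleK2P(x, y), tolerance = 1e-8)
  }
  # gaps are pairwise-deleted
  gapped <- c(a = "ACG-", b = "ACGA", c = "ACGT")
  d <- pairwiseDistances(gapped, "p_distance")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["b", "c"], 0.25)
})

test_that("saturated K2P errors name the offending pair", {
  sat <- c(tax1 = paste(rep("AC", 50), collapse = ""),
           tax2 = paste(rep("CA", 50), collapse = ""))
  expect_error(pairwiseDistances(sat, "k2p"), "saturated.*tax[12].*tax[12]")
  expect_error(pairwiseDistances(c(a = "ACGT"), "k2p"), "2 taxa")
})

test_that("neighbor-joining is exact on additive matrices", {
  labels <- c("dom", "mus", "cas", "spicilegus", "spretus")
  for (seed in c(3, 11, 27)) {
    tr <- randomLabelledTree(labels, seed)
    dm <- ape::cophenetic.phylo(tr)
    rec <- njTree(dm)
    expect_identical(phangorn::RF.dist(ape::unroot(tr), rec), 0L)
    # branch lengths recovered too: path distances reproduce the input
    expect_equal(ape::cophenetic.phylo(rec)[labels, labels],
                 dm[labels, labels], tolerance = 1e-8)
  }
  expect_error(njTree(matrix(0, 2, 2)), "3 taxa")
})

test_that("three taxa give the unique star with fitted lengths", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(dm)
  # closed form: la = (dab + dac - dbc)/2, etc.
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len["a"]), 1)
  expect_equal(unname(len["b"]), 2)
  expect_equal(unname(len["c"]), 3)
})

test_that("rooting on the outgroup places it basally", {
  labels <- c("dom", "mus", "cas", "spicilegus", "spretus")
  tr <- randomLabelledTree(labels, 5)
  rooted <- njTree(ape::cophenetic.phylo(tr), outgroup = "spretus")
  expect_true(ape::is.rooted(rooted))
  expect_error(njTree(ape::cophenetic.phylo(tr), outgroup = "rat"),
               "outgroup")
})

test_that("a tree is congruent with itself and with polytomy resolutions", {
  sp <- speciesTreePolytomy()
  expect_true(checkCongruence(sp, sp)@congruent)
  for (res in speciesTreeResolutions()) {
    repc <- checkCongruence(res, sp)
    expect_true(repc@congruent)
    expect_identical(repc@rfDistance, 0L)
    expect_length(repc@displacedTaxa, 0)
  }
})

test_that("verdicts over all 15 unrooted topologies match brute force", {
  labels <- c("dom", "mus", "cas", "spicilegus", "spretus")
  sp <- speciesTreePolytomy()
  resolutions <- speciesTreeResolutions()
  # enumerate all 15 unrooted 5-taxon topologies: choose the lone tip, then
  # one of the three pairings of the remaining four into two cherries
  newicks <- character()
  for (lone in 1:5) {
    four <- setdiff(1:5, lone)
    for (mate in 2:4) {
      cherry1 <- c(four[1], four[mate])
      cherry2 <- setdiff(four, cherry1)
      newicks <- c(newicks, sprintf(
        "((%s,%s),%s,(%s,%s));", labels[cherry1[1]], labels[cherry1[2]],
        labels[lone], labels[cherry2[1]], labels[cherry2[2]]))
    }
  }
  all15 <- ape::read.tree(text = paste0(newicks, collapse = "\n"))
  seen <- character()
  for (gt in all15) {
    verdict <- checkCongruence(gt, sp)@congruent
    brute <- any(vapply(resolutions, function(r)
      phangorn::RF.dist(ape::unroot(gt), r) == 0L, logical(1)))
    expect_identical(verdict, brute)
    seen <- c(seen, ape::write.tree(gt))
  }
  expect_gte(length(unique(seen)), 15)
})

test_that("domesticus-displaced topologies are flagged with the culprit", {
  sp <- speciesTreePolytomy()
  displaced <- ape::read.tree(
    text = "(((mus,cas),spicilegus),(dom,spretus));")
  repc <- checkCongruence(displaced, sp, gene = "a27")
  expect_false(repc@congruent)
  expect_true("dom" %in% repc@displacedTaxa)
  expect_gte(repc@rfDistance, 1L)
  expect_error(checkCongruence(displaced,
                               ape::read.tree(text = "((a,b),(c,d));")),
               "leaf set")
})

test_that("congruence is invariant to branch lengths", {
  sp <- speciesTreePolytomy()
  gt <- speciesTreeResolutions()[[1]]
  gt$edge.length <- runif(nrow(gt$edge), 0.01, 2)
  expect_true(checkCongruence(gt, sp)@congruent)
  gt$edge.length <- gt$edge.length * 100
  expect_true(checkCongruence(gt, sp)@congruent)
})

test_that("gene trees from synthetic alignments match their generating topology", {
  b <- abpExampleBundle(seed = 1)
  verdicts <- vapply(names(b$alignments), function(g) {
    gt <- njTree(pairwiseDistances(b$alignments[[g]]), outgroup = "spretus")
    checkCongruence(gt, b$trees$species, gene = g)@congruent
  }, logical(1))
  expect_identical(unname(verdicts[c("Abpa27", "Abpbg26", "Abpbg27")]),
                   c(FALSE, FALSE, TRUE))
})
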