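# Ground-truth generators: reproducibility, planted-truth recovery, and
# format round-trips.

test_that("generators are reproducible under a fixed seed", {
  p1 <- genCongenicPanel(c(30, 50), nMarkers = 50, seed = 8)
  p2 <- genCongenicPanel(c(30, 50), nMarkers = 50, seed = 8)
  expect_identical(p1$markers, p2$markers)
  p3 <- genCongenicPanel(c(30, 50), nMarkers = 50, seed = 9)
  expect_false(identical(p1$markers, p3$markers))
  e1 <- genExpressionTable(seed = 4)
  e2 <- genExpressionTable(seed = 4)
  expect_identical(e1$records, e2$records)
  tr <- speciesTreePolytomy()
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  a1 <- genCodonAlignment(tr, 30, seed = 5)
  a2 <- genCodonAlignment(tr, 30, seed = 5)
  expect_identical(a1$alignment, a2$alignment)
})

test_that("panel generation enforces informativeness and honours IBD", {
  expect_error(genCongenicPanel(c(30, 50), informativeFraction = 0),
               "informative")
  expect_error(genCongenicPanel(c(-5, 50)), "within the region")
  # IBD stretch covering the proximal flank leaves the left end unbounded
  pan <- genCongenicPanel(c(30, 50), nMarkers = 150,
                          informativeFraction = 1,
                          ibd = data.frame(start_mb = 0, end_mb = 30),
                          seed = 3)
  rep <- inferSegment(callOrigins(pan$markers), pan$tracks, NULL, c(0, 80))
  expect_true(rep@unboundedLeft)
  expect_true(any(grepl("unbounded", rep@notes)))
})

test_that("expression categories follow the requested layout", {
  counts <- c(all_three = 10, parotid_only = 7, sublingual_only = 1,
              submandibular_only = 0, other = 8)
  gen <- genExpressionTable(nGenes = 26, categoryCounts = counts, seed = 2)
  expect_identical(
    as.integer(table(gen$truth$categories)[names(counts)[1:3]]),
    c(10L, 7L, 1L))
  # sampled categories land within 3 SE of the multinomial expectation
  probs <- c(all_three = 0.4, parotid_only = 0.3, sublingual_only = 0.1,
             submandibular_only = 0.1, other = 0.1)
  big <- genExpressionTable(nGenes = 600, categoryProbs = probs,
                            nOutside = 0, nSubFloor = 0, seed = 6)
  tab <- table(factor(big$truth$categories, levels = names(probs)))
  for (ct in names(probs)) {
    expv <- 600 * probs[[ct]]
    se <- sqrt(600 * probs[[ct]] * (1 - probs[[ct]]))
    expect_lt(abs(tab[[ct]] - expv), 3 * se + 1e-9)
  }
  # zero genes: empty but well-formed
  none <- genExpressionTable(nGenes = 0, categoryCounts = counts[0],
                             nOutside = 0, nSubFloor = 0, seed = 1)
  expect_identical(length(none$truth$categories), 0L)
})

test_that("sub-floor genes vanish at the intensity filter", {
  gen <- genExpressionTable(nGenes = 10,
                            categoryCounts = c(all_three = 10,
                                               parotid_only = 0,
                                               sublingual_only = 0,
                                               submandibular_only = 0,
                                               other = 0),
                            nOutside = 0, nSubFloor = 5, seed = 9)
  kept <- filterIntensity(gen$records, 10)
  expect_false(any(grepl("^geneN", kept$gene)))
  expect_identical(sort(unique(kept$gene)), sprintf("geneR%02d", 1:10))
})

test_that("generated tables round-trip through the readers bit-exactly", {
  pan <- genCongenicPanel(c(30, 50), nMarkers = 40, seed = 12)
  mf <- tempfile(fileext = ".tsv"); tf <- tempfile(fileext = ".tsv")
  write.table(pan$markers, mf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pan$tracks, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readMarkerTable(mf), pan$markers)
  expect_equal(readAncestryTracks(tf), pan$tracks)
  tr <- speciesTreePolytomy(); tr$edge.length <- rep(0.1, nrow(tr$edge))
  aln <- genCodonAlignment(tr, 25, seed = 3)$alignment
  ff <- tempfile(fileext = ".fasta")
  writeFastaAlignment(aln, ff)
  expect_identical(readFastaAlignment(ff), aln)
})

test_that("codon simulation respects the tree and the omega regime", {
  tr <- speciesTreePolytomy()
  tr$edge.length <- rep(0, nrow(tr$edge))
  frozen <- genCodonAlignment(tr, 40, seed = 2)$alignment
  expect_identical(length(unique(unname(frozen))), 1L)
  # neutral-regime data should not look positively selected overall
  tr$edge.length <- rep(0.15, nrow(tr$edge))
  sim <- genCodonAlignment(tr, 250, kappa = 2,
                           regime = list(model = "M8A", p0 = 0.9, p = 0.5,
                                         q = 1.5), seed = 14)
  f0 <- fitSiteModel(sim$alignment, tr, "M0")
  expect_lt(f0@omegaS, 1.1)   # M0 omega below/near neutrality
  expect_length(sim$selectedSites, 0)
  # selected sites recorded for M8 regimes
  sim8 <- genCodonAlignment(tr, 100, regime = list(model = "M8", p0 = 0.8,
                                                   p = 0.5, q = 1.5,
                                                   omegaS = 6), seed = 15)
  expect_true(all(sim8$omegaTruth[sim8$selectedSites] == 6))
})

test_that("proteome hit lists keep strict hits inside the relaxed list", {
  hits <- genProteomeHits(c("a", "b"), c("c"))
  strict <- hits$gene[hits$stringency == "strict"]
  relaxed <- hits$gene[hits$stringency == "relaxed"]
  expect_true(all(strict %in% relaxed))
  expect_true("c" %in% relaxed && !"c" %in% strict)
})
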