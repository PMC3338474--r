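# Staged candidate filters and the provenance ledger.

.toyExpression <- function() {
  data.frame(
    probe_id = paste0("p", 1:6),
    gene = c("in1", "in1", "straddle", "out", "low", "edge"),
    chrom = "chr7",
    start_mb = c(20, 20, 17.0, 55, 30, 50.88),
    end_mb   = c(20.1, 20.1, 17.5, 55.1, 30.1, 50.95),
    gland = c("parotid", "sublingual", "parotid", "parotid", "parotid",
              "submandibular"),
    sex = "M",
    intensity = c(50, 12, 30, 80, 9.99, 10))
}

test_that("region filter uses interval intersection", {
  rec <- .toyExpression()
  kept <- filterRegion(rec, c(17.3, 50.9))
  expect_setequal(unique(kept$gene), c("in1", "straddle", "low", "edge"))
  # brute-force check on boundary straddlers: intersection iff some point
  # of the gene interval lies inside the query
  for (i in seq_len(nrow(rec))) {
    pts <- seq(rec$start_mb[i], rec$end_mb[i] - 1e-6, length.out = 50)
    brute <- any(pts >= 17.3 & pts < 50.9)
    expect_identical(rec$probe_id[i] %in% kept$probe_id, brute)
  }
  expect_identical(nrow(filterRegion(rec, c(30, 30))), 0L)
  withCoordsGone <- rec
  withCoordsGone$start_mb[2] <- NA
  expect_warning(filterRegion(withCoordsGone, c(17.3, 50.9)), "missing")
})

test_that("intensity floor is inclusive at the boundary", {
  rec <- .toyExpression()
  kept <- filterIntensity(rec, 10)
  expect_true("edge" %in% kept$gene)        # exactly 10 retained
  expect_false("low" %in% kept$gene)        # 9.99 dropped
  expect_error(filterIntensity(rec, -1), "non-negative")
  # distributional sanity on uniform intensities
  set.seed(1)
  u <- data.frame(gene = "g", intensity = runif(20000, 0, 100))
  frac <- nrow(filterIntensity(u, 10)) / nrow(u)
  expect_lt(abs(frac - 0.9), 0.01)
})

test_that("gland profiles and category percentages match brute force", {
  gen <- genExpressionTable(nGenes = 26, region = c(17.3, 50.9),
                            categoryCounts = c(all_three = 10,
                                               parotid_only = 7,
                                               sublingual_only = 1,
                                               submandibular_only = 0,
                                               other = 8),
                            nOutside = 0, nSubFloor = 0, seed = 5)
  kept <- filterIntensity(filterRegion(gen$records, c(17.3, 50.9)), 10)
  prof <- glandProfiles(kept)
  counts <- setNames(prof$counts$n, prof$counts$category)
  expect_identical(counts[["all_three"]], 10L)
  expect_identical(counts[["parotid_only"]], 7L)
  expect_identical(counts[["sublingual_only"]], 1L)
  expect_identical(counts[["submandibular_only"]], 0L)
  pct <- setNames(prof$counts$percent, prof$counts$category)
  expect_identical(pct[["all_three"]], 38L)
  expect_identical(pct[["parotid_only"]], 27L)
  expect_identical(pct[["sublingual_only"]], 4L)
  # brute-force per-gene recomputation on a random table
  set.seed(8)
  rnd <- data.frame(gene = sample(paste0("g", 1:12), 60, replace = TRUE),
                    gland = sample(c("parotid", "sublingual",
                                     "submandibular"), 60, replace = TRUE))
  prof2 <- glandProfiles(rnd)
  for (i in seq_len(nrow(prof2$profiles))) {
    g <- prof2$profiles$gene[i]
    glands <- sort(unique(rnd$gland[rnd$gene == g]))
    expect_identical(prof2$profiles$glands[i], paste(glands, collapse = ","))
  }
})

test_that("localization filter drops intracellular and membrane genes", {
  ann <- data.frame(gene = c("ribo", "rab", "sec", "mys"),
                    class = c("intracellular", "membrane", "secreted",
                              "unknown"))
  kept <- filterLocalization(c("ribo", "rab", "sec", "mys", "absent"), ann)
  expect_setequal(kept, c("sec", "mys", "absent"))
})

test_that("divergence rule drops weakly diverged genes exactly", {
  summ <- data.frame(gene = c("none", "twoCons", "twoRad", "threeCons",
                              "oneCons"),
                     nNonsynNt = c(0L, 2L, 2L, 3L, 1L),
                     nRadical = c(0L, 0L, 1L, 0L, 0L))
  kept <- filterDivergence(summ$gene, summ)
  expect_setequal(kept, c("twoRad", "threeCons"))
  expect_true("missing" %in% filterDivergence("missing", summ))
  # brute force over randomized summaries
  set.seed(3)
  rnd <- data.frame(gene = paste0("g", 1:50),
                    nNonsynNt = sample(0:5, 50, replace = TRUE))
  rnd$nRadical <- vapply(rnd$nNonsynNt, function(n)
    if (n == 0) 0L else sample(0:n, 1), integer(1))
  kept <- filterDivergence(rnd$gene, rnd)
  brute <- rnd$gene[!(rnd$nNonsynNt == 0 |
                        (rnd$nNonsynNt <= 2 & rnd$nRadical == 0))]
  expect_setequal(kept, brute)
})

test_that("proteome cross-reference confines confirmation to the region", {
  b <- abpExampleBundle(seed = 1)
  genes <- unique(filterIntensity(filterRegion(b$expression, b$region),
                                  10)$gene)
  xr <- proteomeCrossref(genes, b$proteome, b$geneCoords, b$region,
                         auxiliary = b$auxiliary)
  expect_setequal(xr$confirmed, c("Abpa27", "Abpbg26", "Abpbg27"))
  expect_setequal(xr$strict, c("Abpa27", "Abpbg26", "Abpbg27"))
  expect_true(all(c("Klk1", "Klk1b5", "Nucb2") %in% xr$outOfRegion))
  empty <- proteomeCrossref(genes, b$proteome[0, ], b$geneCoords, b$region)
  expect_length(empty$confirmed, 0)
})

test_that("ledger replay reconstructs the candidate set; filters commute", {
  b <- abpExampleBundle(seed = 1)
  tri <- triageCandidates(b$expression, b$region, 10,
                          localization = b$localization,
                          divergence = b$divergence, proteome = b$proteome,
                          geneCoords = b$geneCoords,
                          auxiliary = b$auxiliary)
  led <- tri@ledger
  passCols <- grep("^pass_", names(led), value = TRUE)
  replay <- led$gene[apply(as.matrix(led[passCols]), 1, all)]
  expect_setequal(replay, candidates(tri))
  expect_setequal(candidates(tri), c("Abpa27", "Abpbg26", "Abpbg27"))
  # region and intensity commute
  r1 <- filterIntensity(filterRegion(b$expression, b$region), 10)
  r2 <- filterRegion(filterIntensity(b$expression, 10), b$region)
  expect_setequal(unique(r1$probe_id), unique(r2$probe_id))
  # exclusion list removes a gene up front (cross-hybridization handling)
  one <- unique(filterRegion(b$expression, b$region)$gene)[1]
  tri2 <- triageCandidates(b$expression, b$region, 10, exclude = one)
  expect_false(one %in% tri2@ledger$gene)
})
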