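# Origin calling, transferred-segment inference and the IBD-masked
# functional size.

test_that("origin calls follow the haplotype-matching rules", {
  m <- data.frame(
    name = c("donorlike", "recplike", "mixed", "uninf", "unknown"),
    chrom = "chr7", pos_mb = 1:5,
    donor_hap     = c("ACGT", "ACGT", "ACGT", "ACGT", "ACGT"),
    recipient_hap = c("ATGT", "ATGT", "ATGA", "ACGT", "ATGT"),
    congenic_hap  = c("ACGT", "ATGT", "ATGT", "ACGT", "ANGN"))
  calls <- callOrigins(m)
  expect_identical(calls$call[match(c("donorlike", "recplike", "mixed",
                                      "uninf", "unknown"), calls$name)],
                   c("donor", "recipient", "ambiguous", "uninformative",
                     "ambiguous"))
  bad <- m[1, ]; bad$congenic_hap <- "ACG"
  expect_error(callOrigins(bad), "equal length")
})

test_that("a single discordant informative site makes the call ambiguous", {
  m <- data.frame(name = "x", chrom = "c", pos_mb = 1,
                  donor_hap = "AAAA", recipient_hap = "CCCC",
                  congenic_hap = "AAAC")
  expect_identical(callOrigins(m)$call, "ambiguous")
})

test_that("calls recover the planted truth wherever parents differ", {
  for (seed in c(2, 7, 19)) {
    pan <- genCongenicPanel(c(30, 50), nMarkers = 120,
                            informativeFraction = 0.8, seed = seed)
    calls <- callOrigins(pan$markers)
    inside <- calls$pos_mb >= 30 & calls$pos_mb < 50
    informative <- calls$donor_hap != calls$recipient_hap
    expect_true(all(calls$call[informative & inside] == "donor"))
    expect_true(all(calls$call[informative & !inside] == "recipient"))
    expect_true(all(calls$call[!informative] == "uninformative"))
  }
})

test_that("functional size matches a fine grid scan and is additive", {
  tracks <- rbind(
    data.frame(strain = "A", chrom = "c",
               start_mb = c(0, 10, 25), end_mb = c(10, 25, 40),
               subspecies = c("domesticus", "musculus", "domesticus")),
    data.frame(strain = "B", chrom = "c",
               start_mb = c(0, 18, 33), end_mb = c(18, 33, 40),
               subspecies = c("domesticus", "castaneus", "musculus")))
  for (iv in list(c(0, 40), c(5, 30), c(12, 36))) {
    expect_equal(functionalSize(tracks, iv),
                 oracleFunctionalSize(tracks, iv), tolerance = 0.02)
  }
  # additive over disjoint subintervals, invariant to subdivision
  whole <- functionalSize(tracks, c(0, 40))
  expect_equal(functionalSize(tracks, c(0, 21)) +
                 functionalSize(tracks, c(21, 40)), whole)
  finer <- sum(vapply(seq(0, 39, by = 1), function(s)
    functionalSize(tracks, c(s, s + 1)), numeric(1)))
  expect_equal(finer, whole)
  expect_error(functionalSize(tracks, c(30, 10)), "inverted")
})

test_that("identical tracks have zero functional size; unknowns are conservative", {
  same <- rbind(
    data.frame(strain = "A", chrom = "c", start_mb = 0, end_mb = 50,
               subspecies = "musculus"),
    data.frame(strain = "B", chrom = "c", start_mb = 0, end_mb = 50,
               subspecies = "musculus"))
  expect_identical(functionalSize(same, c(0, 50)), 0)
  gappy <- same
  gappy$subspecies[2] <- "unknown"
  expect_identical(functionalSize(gappy, c(0, 50)), 0)
  expect_equal(functionalSize(gappy, c(0, 50), unknownDiffers = TRUE), 50)
})

test_that("the published marker layout yields a ~34 Mb functional segment", {
  ext <- function(f) system.file("extdata", f, package = "congenicScope")
  markers <- readMarkerTable(ext("markers_bcongenic_synthetic.tsv"))
  tracks <- readAncestryTracks(ext("ancestry_tracks_synthetic.tsv"))
  gaps <- readGapTable(ext("assembly_gaps_chr7.tsv"))
  rep <- inferSegment(callOrigins(markers), tracks, gaps, region = c(0, 60))
  expect_equal(rep@functionalSizeMb, 33.6, tolerance = 1e-6)
  expect_identical(round(functionalSizeMb(rep)), 34)
  xo <- rep@crossoverIntervals
  distal <- xo[xo$side == "distal", ]
  expect_equal(nrow(distal), 1L)
  expect_gte(distal$startMb, 38.8)
  expect_lte(distal$endMb, 50.9)
  expect_true(rep@unboundedLeft)
  expect_true(any(grepl("gap", rep@notes)))
  # recipient-called marker bounds the maximal interval distally
  expect_equal(rep@maximalInterval[2], 50.9)
})

test_that("minimal within truth within maximal on synthetic panels", {
  for (seed in 1:10) {
    truth <- sort(runif(2, 5, 75))
    if (diff(truth) < 5) truth[2] <- truth[1] + 5
    pan <- genCongenicPanel(truth, nMarkers = 200,
                            informativeFraction = 0.9, seed = seed)
    rep <- inferSegment(callOrigins(pan$markers), pan$tracks, NULL,
                        region = c(0, 80))
    expect_gte(rep@minimalInterval[1], truth[1])
    expect_lte(rep@minimalInterval[2], truth[2])
    expect_lte(rep@maximalInterval[1], truth[1])
    expect_gte(rep@maximalInterval[2], truth[2] + 1e-9)
  }
})

test_that("adding markers never widens the minimal/maximal sandwich", {
  pan <- genCongenicPanel(c(30, 50), nMarkers = 150,
                          informativeFraction = 1, seed = 4)
  half <- pan$markers[seq(1, 150, by = 2), ]
  repHalf <- inferSegment(callOrigins(half), pan$tracks, NULL, c(0, 80))
  repFull <- inferSegment(callOrigins(pan$markers), pan$tracks, NULL,
                          c(0, 80))
  expect_lte(repFull@minimalInterval[1], repHalf@minimalInterval[1])
  expect_gte(repFull@minimalInterval[2], repHalf@minimalInterval[2])
  expect_gte(repFull@maximalInterval[1], repHalf@maximalInterval[1])
  expect_lte(repFull@maximalInterval[2], repHalf@maximalInterval[2])
})

test_that("no donor calls produce an explicit no-segment result", {
  m <- data.frame(name = c("a", "b"), chrom = "c", pos_mb = c(1, 2),
                  donor_hap = "ACGT", recipient_hap = "ATGT",
                  congenic_hap = "ATGT")
  tracks <- rbind(
    data.frame(strain = "A", chrom = "c", start_mb = 0, end_mb = 10,
               subspecies = "musculus"),
    data.frame(strain = "B", chrom = "c", start_mb = 0, end_mb = 10,
               subspecies = "domesticus"))
  rep <- inferSegment(callOrigins(m), tracks, NULL, region = c(0, 10))
  expect_true(any(grepl("no donor segment", rep@notes)))
  expect_true(all(is.na(rep@minimalInterval)))
  expect_identical(rep@functionalSizeMb, 0)
})
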