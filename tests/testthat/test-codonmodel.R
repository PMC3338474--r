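# Goldman-Yang rate matrices, pruning likelihood, and the M8/M8A machinery.

test_that("rate matrix is a proper reversible generator with unit mean rate", {
  set.seed(6)
  pi <- runif(61); pi <- pi / sum(pi)
  Q <- buildCodonRateMatrix(kappa = 2.5, omega = 0.7, codonFreqs = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance: pi_i q_ij = pi_j q_ji
  flux <- diag(pi) %*% Q
  expect_lt(max(abs(flux - t(flux))), 1e-14)
  # multi-nucleotide exchanges are forbidden
  codons <- congenicScope:::.senseCodons
  nd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  off <- which(Q > 0, arr.ind = TRUE)
  expect_true(all(apply(off, 1, function(ij)
    nd(codons[ij[1]], codons[ij[2]]) == 1)))
  expect_error(buildCodonRateMatrix(-1, 1), "kappa")
  expect_error(buildCodonRateMatrix(2, 1, rep(1, 61)), "sum")
})

test_that("single-sequence likelihood is the sum of log frequencies", {
  aln <- c(one = "ATGAAACCCGGG")
  pi <- rep(1 / 61, 61)
  expect_equal(codonLikelihood(aln, codonFreqs = pi), 4 * log(1 / 61))
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  tr <- ape::read.tree(text = "((a:0.12,b:0.21):0.08,c:0.3,d:0.17);")
  sim <- genCodonAlignment(tr, 3, kappa = 2,
                           regime = list(model = "M8A", p0 = 1, p = 1,
                                         q = 1), seed = 9)
  pi <- congenicScope:::.safeFreqs(codonFreqsF3x4(sim$alignment))
  for (par in list(c(k = 1.5, w = 0.4), c(k = 3, w = 1.8))) {
    got <- codonLikelihood(sim$alignment, tr, kappa = par[["k"]],
                           omega = par[["w"]], codonFreqs = pi)
    want <- oracleCodonLik(sim$alignment, tr, par[["k"]], par[["w"]], pi)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # with a gapped codon treated as missing data
  gapped <- sim$alignment
  substr(gapped["a"], 1, 3) <- "---"
  got <- codonLikelihood(gapped, tr, kappa = 2, omega = 1, codonFreqs = pi)
  want <- oracleCodonLik(gapped, tr, 2, 1, pi)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("F3x4 frequencies come from positional nucleotide counts", {
  aln <- c(a = "ATGATG", b = "ATGATG")
  fr <- codonFreqsF3x4(aln)
  expect_equal(sum(fr), 1)
  expect_true(all(fr >= 0))
  # only A at position 1, T at 2, G at 3 -> all mass on ATG
  expect_equal(unname(fr["ATG"]), 1)
  mixed <- c(a = "ATGCTG")
  fr2 <- codonFreqsF3x4(mixed)
  # positions: 1 in {A,C} each 1/2; 2 = T; 3 = G
  expect_equal(unname(fr2["ATG"]), 0.5)
  expect_equal(unname(fr2["CTG"]), 0.5)
})

test_that("identical sequences collapse branch lengths to zero", {
  tr <- speciesTreePolytomy()
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  s <- paste(rep("ATGGCTAAA", 6), collapse = "")
  aln <- setNames(rep(s, 5), c("dom", "mus", "cas", "spicilegus",
                               "spretus"))
  f0 <- fitSiteModel(aln, tr, "M0")
  pi <- congenicScope:::.safeFreqs(codonFreqsF3x4(aln))
  expect_equal(fitLogLik(f0), codonLikelihood(aln[1], codonFreqs = pi),
               tolerance = 1e-3)
})

test_that("M8 never falls below M8A and the LRT degenerates to p = 1", {
  tr <- ape::read.tree(text = paste0("(((dom:0.08,mus:0.08,cas:0.08):0.10,",
                                     "spicilegus:0.25):0.10,spretus:0.40);"))
  sim <- genCodonAlignment(tr, 150, kappa = 2,
                           regime = list(model = "M8A", p0 = 0.9, p = 0.5,
                                         q = 1.5), seed = 42)
  res <- suppressWarnings(testSelection(sim$alignment, tr, polish = FALSE))
  expect_gte(res@fitM8@logLik, res@fitM8A@logLik - 1e-4)
  expect_gte(res@lrtStat, 0)
  # degenerate data: identical fits, stat 0, p 1 by convention
  s <- paste(rep("ATGGCTAAACCT", 8), collapse = "")
  flat <- setNames(rep(s, 5), tr$tip.label)
  resFlat <- suppressWarnings(testSelection(flat, tr, polish = FALSE))
  expect_lt(resFlat@lrtStat, 1e-3)
  expect_gt(resFlat@pValue, 0.97)
})

test_that("fits are deterministic for identical inputs", {
  tr <- ape::read.tree(text = paste0("(((dom:0.08,mus:0.08,cas:0.08):0.10,",
                                     "spicilegus:0.25):0.10,spretus:0.40);"))
  sim <- genCodonAlignment(tr, 120, kappa = 2,
                           regime = list(model = "M8", p0 = 0.9, p = 0.5,
                                         q = 1.5, omegaS = 6), seed = 13)
  f1 <- fitSiteModel(sim$alignment, tr, "M8", polish = FALSE)
  f2 <- fitSiteModel(sim$alignment, tr, "M8", polish = FALSE)
  expect_identical(f1@logLik, f2@logLik)
  expect_identical(f1@omegaS, f2@omegaS)
})

test_that("selected-class omega is recovered within tolerance (median over reps)", {
  tr <- ape::read.tree(text = paste0("(((dom:0.08,mus:0.08,cas:0.08):0.10,",
                                     "spicilegus:0.25):0.10,spretus:0.40);"))
  errs <- vapply(1:20, function(s) {
    sim <- genCodonAlignment(tr, 300, kappa = 2,
                             regime = list(model = "M8", p0 = 0.9, p = 0.5,
                                           q = 1.5, omegaS = 8),
                             seed = 1000 + s)
    fit <- fitSiteModel(sim$alignment, tr, "M8", polish = FALSE)
    abs(fit@omegaS - 8) / 8
  }, numeric(1))
  expect_lte(median(errs), 0.25)
})

test_that("a lone hyper-variable nonsynonymous column tops the posterior", {
  tr <- ape::read.tree(text = paste0("(((dom:0.05,mus:0.05,cas:0.05):0.05,",
                                     "spicilegus:0.12):0.05,spretus:0.2);"))
  set.seed(77)
  om <- rep(0.02, 60)
  om[25] <- 15
  sim <- genCodonAlignment(tr, 60, kappa = 2, siteOmegas = om, seed = 77)
  fit <- fitSiteModel(sim$alignment, tr, "M8", polish = FALSE)
  beb <- bebSites(fit, referenceTaxon = "dom")
  expect_identical(which.max(beb$posterior), 25L)
  expect_error(bebSites(fit, referenceTaxon = "rat"), "reference taxon")
})

test_that("alignment encoding rejects malformed input", {
  tr <- speciesTreePolytomy()
  bad <- setNames(rep("ATGTAACCC", 5), tr$tip.label)   # internal stop
  expect_error(fitSiteModel(bad, tr, "M0"), "stop codon")
  uneven <- c(a = "ATGAAA", b = "ATG")
  expect_error(fitSiteModel(uneven, tr, "M0"), "equal length")
  wrongTaxa <- c(x = "ATGAAA", y = "ATGAAA")
  expect_error(fitSiteModel(wrongTaxa, tr, "M0"), "match")
})
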