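# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and grid
# scans.

# numeric-integration moments of the one-sided retained length
# min(Exp(rate r) truncated at D): oracle for the closed forms
oracleTruncMoments <- function(r, D) {
  if (D <= 0) return(c(m1 = 0, m2 = 0))
  f1 <- integrate(function(y) y * r * exp(-r * y), 0, D)$value
  f2 <- integrate(function(y) y^2 * r * exp(-r * y), 0, D)$value
  atom <- exp(-r * D)
  c(m1 = f1 + D * atom, m2 = f2 + D^2 * atom)
}

# 0.01 Mb grid scan of the length where two ancestry tracks differ
oracleFunctionalSize <- function(tracks, interval, step = 0.01) {
  strains <- unique(tracks$strain)
  labelAt <- function(strain, x) {
    t1 <- tracks[tracks$strain == strain, ]
    hit <- which(t1$start_mb <= x & x < t1$end_mb)
    if (length(hit)) t1$subspecies[hit[1]] else "unknown"
  }
  xs <- seq(interval[1] + step / 2, interval[2] - step / 2, by = step)
  differs <- vapply(xs, function(x) {
    l1 <- labelAt(strains[1], x); l2 <- labelAt(strains[2], x)
    l1 != "unknown" && l2 != "unknown" && l1 != l2
  }, logical(1))
  sum(differs) * step
}

# independent per-site substitution classification for one codon pair,
# following the stated convention (other sites held at codon1's state)
oracleCodonPairCounts <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  nonsyn <- 0L; syn <- 0L
  for (d in which(s1 != s2)) {
    sw <- s1; sw[d] <- s2[d]
    aa1 <- GC[[c1]]
    aaSw <- GC[[paste(sw, collapse = "")]]
    if (identical(unname(aaSw), unname(aa1))) syn <- syn + 1L
    else nonsyn <- nonsyn + 1L
  }
  aaChange <- as.integer(GC[[c1]] != GC[[c2]])
  c(nonsyn = nonsyn, syn = syn, aaChange = aaChange)
}

# Kimura two-parameter distance from transition/transversion proportions
oracleK2P <- function(x, y) {
  a <- strsplit(toupper(x), "")[[1]]; b <- strsplit(toupper(y), "")[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[use]; b <- b[use]
  isTs <- (a %in% c("A", "G") & b %in% c("A", "G")) |
          (a %in% c("C", "T") & b %in% c("C", "T"))
  P <- sum(a != b & isTs) / length(a)
  Q <- sum(a != b & !isTs) / length(a)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# brute-force codon-alignment likelihood on a small binary tree: sum over
# all internal-node state assignments; P(t) built independently via R's
# eigen on the (reversible) rate matrix
oracleCodonLik <- function(alignment, tree, kappa, omega, pi) {
  codons <- congenicScope:::.senseCodons
  n <- length(codons)
  Q <- buildCodonRateMatrix(kappa, omega, pi, normalize = FALSE) /
    (-sum(pi * diag(buildCodonRateMatrix(kappa, omega, pi,
                                         normalize = FALSE))))
  Pmat <- function(t1) {
    sq <- sqrt(pi)
    B <- diag(sq) %*% Q %*% diag(1 / sq)
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    M <- diag(1 / sq) %*% eg$vectors %*% diag(exp(eg$values * t1)) %*%
      t(eg$vectors) %*% diag(sq)
    pmax(M, 0)
  }
  tree <- ape::unroot(tree)
  po <- reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nint <- po$Nnode
  root <- po$edge[nrow(po$edge), 1]
  Ps <- lapply(seq_len(nrow(po$edge)), function(e) Pmat(po$edge.length[e]))
  seqs <- toupper(alignment[po$tip.label])
  ncod <- nchar(seqs[1]) / 3
  stateAt <- function(taxon, site) {
    cd <- substr(seqs[taxon], 3 * site - 2, 3 * site)
    match(cd, codons)      # NA for gap/ambiguity
  }
  intNodes <- sort(unique(po$edge[po$edge[, 1] > ntip, 1]))
  total <- 0
  for (site in seq_len(ncod)) {
    tipState <- vapply(seq_len(ntip), function(i) stateAt(i, site),
                       integer(1))
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), length(intNodes))))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign1 <- grid[g, ]
      stateOf <- function(node) {
        if (node <= ntip) tipState[node]
        else assign1[match(node, intNodes)]
      }
      term <- unname(pi[stateOf(root)])
      for (e in seq_len(nrow(po$edge))) {
        pa <- stateOf(po$edge[e, 1]); ch <- stateOf(po$edge[e, 2])
        if (is.na(ch)) next            # missing tip: marginalized (sums to 1)
        term <- term * Ps[[e]][pa, ch]
      }
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# the three resolutions of the (dom, mus, cas) polytomy of the species tree
speciesTreeResolutions <- function() {
  lapply(c("(((dom,mus),cas),spicilegus,spretus);",
           "(((dom,cas),mus),spicilegus,spretus);",
           "(((mus,cas),dom),spicilegus,spretus);"),
         function(t1) ape::unroot(ape::read.tree(text = t1)))
}

speciesTreePolytomy <- function() {
  ape::read.tree(text = "(((dom,mus,cas),spicilegus),spretus);")
}

# random binary tree with clean branch lengths on given labels
randomLabelledTree <- function(labels, seed, minBL = 0.05, maxBL = 0.5) {
  set.seed(seed)
  tr <- ape::rtree(length(labels), tip.label = sample(labels))
  tr$edge.length <- runif(nrow(tr$edge), minBL, maxBL)
  tr
}
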