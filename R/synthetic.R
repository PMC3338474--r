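## Synthetic-data generators with known ground truth for every input class:
## congenic marker panels + ancestry tracks, salivary expression tables,
## proteome hit lists, allele pairs with planted substitution counts, and
## codon alignments evolved under neutral (M8A-like) or selected (M8-like)
## regimes. All generators are reproducible under a fixed seed.

.randHap <- function(nSnp) paste(sample(c("A", "C", "G", "T"), nSnp,
                                        replace = TRUE), collapse = "")

.mutateHap <- function(hap, at) {
  chars <- strsplit(hap, "")[[1]]
  for (i in at)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate a congenic marker panel with known introgressed interval
#'
#' Donor and recipient haplotypes differ at \code{informativeFraction} of
#' the markers; the congenic haplotype equals the donor's inside the planted
#' \code{truthInterval} and the recipient's outside. Parental ancestry
#' tracks differ in subspecies everywhere except optional \code{ibd}
#' stretches, where both carry the same label (emulating
#' identity-by-descent).
#'
#' @param truthInterval numeric(2), Mb; the planted introgressed interval.
#' @param nMarkers marker count.
#' @param informativeFraction fraction of markers where parents differ
#'   (> 0).
#' @param region numeric(2), Mb; chromosome span.
#' @param ibd optional data.frame(start_mb, end_mb) of IBD stretches.
#' @param nSnp SNPs per marker haplotype.
#' @param seed RNG seed.
#' @return list: \code{markers} (data.frame for \code{\link{callOrigins}}),
#'   \code{tracks}, \code{gaps} (empty), \code{truth}.
#' @export
genCongenicPanel <- function(truthInterval, nMarkers = 100,
                             informativeFraction = 1, region = c(0, 80),
                             ibd = NULL, nSnp = 6, seed = 1) {
  if (informativeFraction <= 0)
    stop("informativeFraction must be > 0: a panel without informative markers carries no signal")
  if (truthInterval[1] < region[1] || truthInterval[2] > region[2])
    stop("truth interval must lie within the region")
  set.seed(seed)
  pos <- sort(runif(nMarkers, region[1], region[2]))
  informative <- runif(nMarkers) < informativeFraction
  if (!is.null(ibd) && nrow(ibd)) {
    # inside IBD the parents share a haplotype: markers carry no signal
    inIbd <- vapply(pos, function(x)
      any(ibd$start_mb <= x & x < ibd$end_mb), logical(1))
    informative[inIbd] <- FALSE
  }
  if (!any(informative)) informative[which.max(pos)] <- TRUE
  donor <- vapply(seq_len(nMarkers), function(i) .randHap(nSnp), character(1))
  recipient <- vapply(seq_len(nMarkers), function(i) {
    if (informative[i])
      .mutateHap(donor[i], sample(nSnp, sample(1:2, 1)))
    else donor[i]
  }, character(1))
  inside <- pos >= truthInterval[1] & pos < truthInterval[2]
  congenic <- ifelse(inside, donor, recipient)
  markers <- data.frame(name = sprintf("m%03d", seq_len(nMarkers)),
                        chrom = "chrS", pos_mb = pos, donor_hap = donor,
                        recipient_hap = recipient, congenic_hap = congenic)
  subs <- c("domesticus", "musculus", "castaneus")
  mkTrack <- function(strain, label) {
    if (is.null(ibd) || !nrow(ibd)) {
      data.frame(strain = strain, chrom = "chrS", start_mb = region[1],
                 end_mb = region[2], subspecies = label)
    } else {
      cuts <- sort(unique(c(region, ibd$start_mb, ibd$end_mb)))
      cuts <- cuts[cuts >= region[1] & cuts <= region[2]]
      segs <- data.frame(start_mb = cuts[-length(cuts)], end_mb = cuts[-1])
      segs$strain <- strain
      segs$chrom <- "chrS"
      inIbd <- vapply(seq_len(nrow(segs)), function(i)
        any(ibd$start_mb <= segs$start_mb[i] & segs$end_mb[i] <= ibd$end_mb),
        logical(1))
      segs$subspecies <- ifelse(inIbd, "domesticus", label)
      segs[c("strain", "chrom", "start_mb", "end_mb", "subspecies")]
    }
  }
  tracks <- rbind(mkTrack("donor", "musculus"),
                  mkTrack("recipient", "domesticus"))
  list(markers = markers, tracks = tracks,
       gaps = data.frame(chrom = character(), start_mb = numeric(),
                         end_mb = numeric()),
       truth = list(interval = truthInterval, informative = informative,
                    ibd = ibd, region = region, seed = seed))
}

#' Generate a salivary-gland expression table with known gland categories
#'
#' Emulates a probe-level EST/microarray table: per-gene gland patterns
#' drawn from (or fixed to) the category layout, probe intensities with a
#' lognormal body plus a sub-floor noise point mass, both sexes recorded.
#' Category counts can be given exactly (\code{categoryCounts}) or sampled
#' (\code{categoryProbs}).
#'
#' @param nGenes gene count inside the region.
#' @param region numeric(2), Mb; genes are placed inside it.
#' @param categoryCounts named integer vector over \code{all_three},
#'   \code{parotid_only}, \code{sublingual_only}, \code{submandibular_only},
#'   \code{other}; must sum to \code{nGenes}. Overrides
#'   \code{categoryProbs}.
#' @param categoryProbs named probabilities over the same categories
#'   (must sum to 1).
#' @param nOutside genes placed outside the region (retained intensities).
#' @param nSubFloor genes inside the region whose every probe is below the
#'   floor (they should vanish at the intensity filter).
#' @param floor intensity floor the noise mass sits under (default 10).
#' @param meanlog,sdlog lognormal body parameters for retained intensities.
#' @param seed RNG seed.
#' @return list: \code{records} (probe-level data.frame), \code{truth}
#'   (per-gene categories).
#' @export
genExpressionTable <- function(nGenes = 26, region = c(17.3, 50.9),
                               categoryCounts = NULL, categoryProbs = NULL,
                               nOutside = 4, nSubFloor = 3, floor = 10,
                               meanlog = log(60), sdlog = 0.8, seed = 1) {
  cats <- c("all_three", "parotid_only", "sublingual_only",
            "submandibular_only", "other")
  set.seed(seed)
  if (!is.null(categoryCounts)) {
    stopifnot(sum(categoryCounts) == nGenes)
    assign1 <- rep(names(categoryCounts), categoryCounts)
  } else {
    if (is.null(categoryProbs))
      categoryProbs <- c(all_three = 10, parotid_only = 7,
                         sublingual_only = 1, submandibular_only = 0,
                         other = 8) / 26
    stopifnot(abs(sum(categoryProbs) - 1) < 1e-6)
    assign1 <- sample(names(categoryProbs), nGenes, replace = TRUE,
                      prob = categoryProbs[names(categoryProbs)])
  }
  glandsFor <- function(ct) switch(ct,
    all_three = c("parotid", "sublingual", "submandibular"),
    parotid_only = "parotid", sublingual_only = "sublingual",
    submandibular_only = "submandibular",
    other = sample(c("parotid", "sublingual", "submandibular"), 2))
  rows <- list()
  addGene <- function(gene, startMb, glands, retained) {
    for (gl in c("parotid", "sublingual", "submandibular")) {
      for (sx in c("M", "F")) {
        if (gl %in% glands && retained) {
          val <- floor + rlnorm(1, meanlog, sdlog)
        } else {
          if (runif(1) > 0.5) next          # many probes simply absent
          val <- runif(1, 0, floor * 0.99)  # sub-floor noise
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          probe_id = sprintf("%s_%s_%s", gene, gl, sx), gene = gene,
          chrom = "chr7", start_mb = startMb, end_mb = startMb + 0.02,
          gland = gl, sex = sx, intensity = val)
      }
    }
  }
  for (i in seq_len(nGenes)) {
    gene <- sprintf("geneR%02d", i)
    addGene(gene, runif(1, region[1], region[2] - 0.02),
            glandsFor(assign1[i]), TRUE)
  }
  if (nOutside > 0) {
    span <- region[2] - region[1]
    for (i in seq_len(nOutside))
      addGene(sprintf("geneO%02d", i),
              if (i %% 2) region[2] + runif(1, 0.5, span / 4)
              else max(0.1, region[1] - runif(1, 0.5, min(span / 4, region[1]))),
              glandsFor(sample(cats[-4], 1)), TRUE)
  }
  if (nSubFloor > 0) {
    for (i in seq_len(nSubFloor))
      addGene(sprintf("geneN%02d", i),
              runif(1, region[1], region[2] - 0.02), character(), FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows)
             else data.frame(probe_id = character(), gene = character(),
                             chrom = character(), start_mb = numeric(),
                             end_mb = numeric(), gland = character(),
                             sex = character(), intensity = numeric())
  rownames(records) <- NULL
  list(records = records,
       truth = list(categories = setNames(assign1,
                                          sprintf("geneR%02d",
                                                  seq_len(nGenes))),
                    region = region, floor = floor, seed = seed))
}

# ---- coding-sequence generators ------------------------------------------

.randomCds <- function(nCodons, terminalStop = FALSE) {
  codons <- sample(.senseCodons, nCodons, replace = TRUE)
  if (terminalStop) codons[nCodons] <- "TAA"
  paste(codons, collapse = "")
}

# single-site exchanges of a codon, classified; excludes stops
.codonNeighbors <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), s[pos])) {
    s2 <- s; s2[pos] <- nt
    cd2 <- paste(s2, collapse = "")
    if (!cd2 %in% .senseCodons) next
    out[[length(out) + 1L]] <- list(codon = cd2, pos = pos,
                                    nonsyn = .codonAA[[codon]] != .codonAA[[cd2]])
  }
  out
}

#' Generate an allele pair with planted substitution counts
#'
#' Constructs two in-frame coding sequences differing by exactly
#' \code{nSingle} codons carrying one nonsynonymous nucleotide difference,
#' \code{nDouble} codons carrying two (each single-site exchange
#' nonsynonymous under the observed-difference convention, translations
#' differing), and \code{nSyn} synonymous single-site differences -- i.e.
#' \code{nSingle + 2*nDouble} nonsynonymous nucleotide substitutions causing
#' \code{nSingle + nDouble} amino acid changes.
#'
#' @param nCodons total codons (>= nSingle + nDouble + nSyn + 1).
#' @param nSingle codons with one nonsynonymous difference.
#' @param nDouble codons with two nonsynonymous differences.
#' @param nSyn codons with one synonymous difference.
#' @param gene label.
#' @param seed RNG seed.
#' @return list: \code{seq1}, \code{seq2}, \code{gene}, \code{truth}
#'   (planted counts).
#' @export
genAllelePair <- function(nCodons, nSingle, nDouble = 0, nSyn = 0,
                          gene = "gene", seed = 1) {
  stopifnot(nCodons >= nSingle + nDouble + nSyn + 1)
  set.seed(seed)
  c1 <- character(nCodons)
  c2 <- character(nCodons)
  # base: identical codons
  base <- sample(.senseCodons, nCodons, replace = TRUE)
  c1 <- base; c2 <- base
  slots <- sample(nCodons, nSingle + nDouble + nSyn)
  k <- 0L
  for (i in seq_len(nSingle)) {
    k <- k + 1L
    repeat {
      cd <- sample(.senseCodons, 1)
      nb <- Filter(function(x) x$nonsyn, .codonNeighbors(cd))
      if (length(nb)) {
        pick <- nb[[sample(length(nb), 1)]]
        c1[slots[k]] <- cd; c2[slots[k]] <- pick$codon
        break
      }
    }
  }
  for (i in seq_len(nDouble)) {
    k <- k + 1L
    repeat {
      cd <- sample(.senseCodons, 1)
      nb <- Filter(function(x) x$nonsyn, .codonNeighbors(cd))
      ok <- FALSE
      if (length(nb) >= 2) {
        prs <- utils::combn(length(nb), 2)
        prs <- prs[, sample(ncol(prs)), drop = FALSE]
        for (cix in seq_len(ncol(prs))) {
          a <- nb[[prs[1, cix]]]; b <- nb[[prs[2, cix]]]
          if (a$pos == b$pos) next
          s <- strsplit(cd, "")[[1]]
          s[a$pos] <- strsplit(a$codon, "")[[1]][a$pos]
          s[b$pos] <- strsplit(b$codon, "")[[1]][b$pos]
          cd2 <- paste(s, collapse = "")
          if (!cd2 %in% .senseCodons) next
          if (.codonAA[[cd2]] == .codonAA[[cd]]) next
          c1[slots[k]] <- cd; c2[slots[k]] <- cd2
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
  }
  for (i in seq_len(nSyn)) {
    k <- k + 1L
    repeat {
      cd <- sample(.senseCodons, 1)
      nb <- Filter(function(x) !x$nonsyn, .codonNeighbors(cd))
      if (length(nb)) {
        pick <- nb[[sample(length(nb), 1)]]
        c1[slots[k]] <- cd; c2[slots[k]] <- pick$codon
        break
      }
    }
  }
  list(seq1 = paste(c1, collapse = ""), seq2 = paste(c2, collapse = ""),
       gene = gene,
       truth = list(nNonsynNt = as.integer(nSingle + 2L * nDouble),
                    nAaChanges = as.integer(nSingle + nDouble),
                    nSynNt = as.integer(nSyn)))
}

#' Simulate a codon alignment on a tree under a site-omega regime
#'
#' Per-site dN/dS is drawn from the regime -- \code{M8A}: Beta(p, q) with
#' probability p0, else exactly 1; \code{M8}: Beta(p, q) with probability
#' p0, else the selected ratio \code{omegaS} -- and sequences are evolved
#' along the tree by sampling from the transition kernels of the
#' Goldman-Yang generator (matrix exponentials via the reversible
#' eigendecomposition). Rate matrices are scaled by the regime's mean rate
#' so branch lengths read as expected substitutions per codon.
#'
#' @param tree \code{phylo} with branch lengths.
#' @param nCodons alignment length in codons.
#' @param kappa transition/transversion ratio.
#' @param regime list: \code{model} ("M8A" or "M8"), \code{p0}, \code{p},
#'   \code{q}, and for M8 \code{omegaS}.
#' @param codonFreqs length-61 frequencies (default uniform).
#' @param siteOmegas optional explicit per-site omega vector (length
#'   \code{nCodons}); overrides \code{regime}. Sites with omega > 1 are
#'   reported as selected.
#' @param seed RNG seed.
#' @return list: \code{alignment} (named character vector),
#'   \code{omegaTruth} (per-site omega), \code{selectedSites} (indices in
#'   the selected class; empty for M8A).
#' @export
genCodonAlignment <- function(tree, nCodons, kappa = 2,
                              regime = list(model = "M8A", p0 = 0.9,
                                            p = 0.5, q = 1.5),
                              codonFreqs = NULL, siteOmegas = NULL,
                              seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  n <- length(.senseCodons)
  pi <- .safeFreqs(codonFreqs %||% rep(1 / n, n))
  if (!is.null(siteOmegas)) {
    stopifnot(length(siteOmegas) == nCodons, all(siteOmegas >= 0))
    omega <- siteOmegas
    selected <- which(omega > 1)
  } else {
    model <- regime$model %||% "M8A"
    p0 <- regime$p0 %||% 0.9
    inBeta <- runif(nCodons) < p0
    omega <- ifelse(inBeta, rbeta(nCodons, regime$p %||% 0.5,
                                  regime$q %||% 1.5),
                    if (model == "M8") regime$omegaS %||% 5 else 1)
    selected <- if (model == "M8") which(!inBeta) else integer()
  }
  # common scale: mean substitution rate across drawn sites
  rates <- vapply(omega, function(w) .codonRate(kappa, w, pi), numeric(1))
  scale <- mean(rates)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  po <- stats::reorder(tree, "postorder")
  ntip <- length(po$tip.label)
  nNodes <- ntip + po$Nnode
  root <- po$edge[nrow(po$edge), 1]
  sqp <- sqrt(pi)
  seqs <- matrix(NA_integer_, nNodes, nCodons)
  # eigendecompose per site (omegas are continuous draws)
  for (s in seq_len(nCodons)) {
    Q <- buildCodonRateMatrix(kappa, omega[s], pi, normalize = FALSE) / scale
    B <- diag(sqp) %*% Q %*% diag(1 / sqp)
    eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
    W <- diag(1 / sqp) %*% eg$vectors
    Wi <- t(eg$vectors) %*% diag(sqp)
    seqs[root, s] <- sample.int(n, 1, prob = pi)
    # preorder: reverse postorder edges
    for (e in rev(seq_len(nrow(po$edge)))) {
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t1 <- po$edge.length[e]
      prow <- (W[seqs[par, s], , drop = FALSE] *
                 exp(eg$values * t1)) %*% Wi
      prow <- pmax(as.numeric(prow), 0)
      seqs[ch, s] <- sample.int(n, 1, prob = prow)
    }
  }
  aln <- vapply(seq_len(ntip), function(i)
    paste(.senseCodons[seqs[i, ]], collapse = ""), character(1))
  names(aln) <- po$tip.label
  list(alignment = aln, omegaTruth = omega, selectedSites = selected)
}

#' Generate a proteome hit list with a planted confirmed set
#'
#' Strict hits are a subset of the relaxed list, as when the same spectra
#' are re-searched at relaxed identification stringency.
#'
#' @param strictGenes genes identified at strict stringency.
#' @param relaxedOnlyGenes genes appearing only at relaxed stringency.
#' @return data.frame with columns \code{gene}, \code{stringency} (strict
#'   hits are repeated in the relaxed rows, preserving the subset
#'   invariant).
#' @export
genProteomeHits <- function(strictGenes, relaxedOnlyGenes = character()) {
  rbind(data.frame(gene = strictGenes,
                   stringency = rep("strict", length(strictGenes))),
        data.frame(gene = c(strictGenes, relaxedOnlyGenes),
                   stringency = "relaxed"))
}
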