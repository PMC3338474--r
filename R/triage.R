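## Staged filters from expression/proteome evidence to the candidate
## signal-gene set, with per-gene provenance.

#' Keep expression records whose gene overlaps a region
#'
#' Interval-intersection semantics: a record is kept when its gene interval
#' \code{[start_mb, end_mb)} intersects \code{interval}. Records missing
#' coordinates are excluded with a warning.
#'
#' @param records expression data.frame with columns \code{gene},
#'   \code{chrom}, \code{start_mb}, \code{end_mb} (plus any others).
#' @param interval numeric(2), Mb.
#' @return Filtered data.frame.
#' @export
filterRegion <- function(records, interval) {
  if (interval[2] < interval[1]) stop("inverted interval")
  bad <- !is.finite(records$start_mb) | !is.finite(records$end_mb)
  if (any(bad)) {
    warning(sum(bad), " record(s) excluded: missing coordinates")
    records <- records[!bad, , drop = FALSE]
  }
  keep <- records$start_mb < interval[2] & records$end_mb > interval[1]
  records[keep, , drop = FALSE]
}

#' Keep expression records at or above an intensity floor
#'
#' Inclusive: intensity exactly at the floor is retained. The mouse salivary
#' microarray data this emulates ranged 0 to 250--400, with 10 used as the
#' reporting floor.
#'
#' @param records expression data.frame with an \code{intensity} column.
#' @param floor non-negative numeric (default 10).
#' @return Filtered data.frame.
#' @export
filterIntensity <- function(records, floor = 10) {
  if (!is.finite(floor) || floor < 0) stop("floor must be non-negative")
  records[records$intensity >= floor, , drop = FALSE]
}

#' Per-gene gland expression profiles and category counts
#'
#' Collapses probe-level records to genes: a gene is expressed in a gland if
#' any retained probe in either sex supports it. Categories: expressed in
#' all three glands, restricted to one gland (parotid / sublingual /
#' submandibular only), or \code{other}. Percentages are computed against
#' the total gene count and rounded half-up to integers.
#'
#' @param records region- and intensity-filtered expression records with
#'   columns \code{gene} and \code{gland}.
#' @return list with \code{profiles} (data.frame gene, glands, category) and
#'   \code{counts} (data.frame category, n, percent).
#' @export
glandProfiles <- function(records) {
  glandsOf <- function(g) sort(unique(records$gland[records$gene == g]))
  genes <- sort(unique(records$gene))
  cat1 <- function(gl) {
    if (length(gl) == 3L) "all_three"
    else if (identical(gl, "parotid")) "parotid_only"
    else if (identical(gl, "sublingual")) "sublingual_only"
    else if (identical(gl, "submandibular")) "submandibular_only"
    else "other"
  }
  profs <- data.frame(gene = genes,
                      glands = vapply(genes, function(g)
                        paste(glandsOf(g), collapse = ","), character(1)),
                      category = vapply(genes, function(g)
                        cat1(glandsOf(g)), character(1)),
                      row.names = NULL)
  cats <- c("all_three", "parotid_only", "sublingual_only",
            "submandibular_only", "other")
  n <- vapply(cats, function(ct) sum(profs$category == ct), integer(1))
  counts <- data.frame(category = cats, n = as.integer(n),
                       percent = as.integer(floor(100 * n /
                                              max(1L, length(genes)) + 0.5)),
                       row.names = NULL)
  list(profiles = profs, counts = counts)
}

#' Drop genes with intracellular/membrane-bound protein localization
#'
#' A salivary signal must be secreted; genes whose products are strictly
#' intracellular (e.g. ribosomal proteins) or membrane-bound are removed.
#' Genes annotated \code{secreted} or \code{unknown} (or absent from the
#' annotation table) are retained.
#'
#' @param genes character vector.
#' @param annotations data.frame with columns \code{gene} and \code{class}
#'   (\code{secreted}, \code{intracellular}, \code{membrane},
#'   \code{unknown}).
#' @return Retained gene vector.
#' @export
filterLocalization <- function(genes, annotations) {
  cls <- annotations$class[match(genes, annotations$gene)]
  cls[is.na(cls)] <- "unknown"
  genes[!cls %in% c("intracellular", "membrane")]
}

#' Drop weakly diverged genes
#'
#' The rule: eliminate a gene if its allele comparison shows no
#' nonsynonymous substitution, or only one or two that all made
#' conservative amino acid replacements. Genes without a substitution
#' summary are retained (flagged upstream).
#'
#' @param genes character vector.
#' @param summaries data.frame with columns \code{gene}, \code{nNonsynNt},
#'   \code{nRadical} (e.g. built from \code{\link{countSubstitutions}}
#'   results).
#' @return Retained gene vector.
#' @export
filterDivergence <- function(genes, summaries) {
  idx <- match(genes, summaries$gene)
  keep <- vapply(seq_along(genes), function(i) {
    j <- idx[i]
    if (is.na(j)) return(TRUE)             # no data: retained with flag
    nn <- summaries$nNonsynNt[j]
    nr <- summaries$nRadical[j]
    if (nn == 0) return(FALSE)
    !(nn <= 2 && nr == 0)
  }, logical(1))
  genes[keep]
}

#' Cross-reference candidates with saliva proteome identifications
#'
#' Intersects the candidate genes (plus any auxiliary cDNA-confirmed genes,
#' e.g. the Abp paralogs whose salivary cDNAs were amplified directly) with
#' proteome hit lists, restricted to genes located in the region of
#' interest. Hits mapping outside the region are reported separately.
#'
#' @param genes candidate gene symbols.
#' @param hits data.frame with columns \code{gene} and \code{stringency}
#'   (\code{strict} or \code{relaxed}; strict hits are a subset of relaxed).
#' @param geneCoords data.frame \code{gene}, \code{start_mb}, \code{end_mb}.
#' @param region numeric(2), Mb.
#' @param auxiliary extra genes treated as expression-confirmed.
#' @return list: \code{confirmed} (in-region genes with any hit),
#'   \code{strict}/\code{relaxed} per-stringency in-region subsets,
#'   \code{outOfRegion} (hit genes outside the region).
#' @export
proteomeCrossref <- function(genes, hits, geneCoords, region,
                             auxiliary = character()) {
  pool <- union(genes, auxiliary)
  inRegion <- function(g) {
    j <- match(g, geneCoords$gene)
    !is.na(j) & geneCoords$start_mb[j] < region[2] &
      geneCoords$end_mb[j] > region[1]
  }
  hitGenes <- unique(hits$gene)
  confirmed <- intersect(pool, hitGenes)
  inR <- vapply(confirmed, inRegion, logical(1))
  strictGenes <- unique(hits$gene[hits$stringency == "strict"])
  list(confirmed = confirmed[inR],
       strict = intersect(confirmed[inR], strictGenes),
       relaxed = confirmed[inR],
       outOfRegion = hitGenes[!vapply(hitGenes, inRegion, logical(1))])
}

#' Staged candidate-gene triage with provenance
#'
#' Runs the full filter chain -- region, intensity, localization,
#' divergence, proteome confirmation -- and records a per-gene pass/fail
#' ledger; the final candidate set is exactly the genes passing every
#' filter. Genes on \code{exclude} (e.g. probable microarray
#' cross-hybridization artifacts) are dropped at the start.
#'
#' @param expression probe-level expression data.frame (columns \code{gene},
#'   \code{chrom}, \code{start_mb}, \code{end_mb}, \code{gland}, \code{sex},
#'   \code{intensity}).
#' @param region numeric(2), Mb.
#' @param floor intensity floor (default 10).
#' @param localization annotation data.frame (see
#'   \code{\link{filterLocalization}}).
#' @param divergence substitution-summary data.frame (see
#'   \code{\link{filterDivergence}}); NULL skips the filter.
#' @param proteome hit data.frame (see \code{\link{proteomeCrossref}});
#'   NULL skips the filter.
#' @param geneCoords coordinates for proteome region restriction; defaults
#'   to coordinates derived from \code{expression}.
#' @param auxiliary cDNA-confirmed genes added before the proteome step.
#' @param exclude genes removed up front.
#' @return A \code{\linkS4class{CandidateReport}}.
#' @export
triageCandidates <- function(expression, region, floor = 10,
                             localization = NULL, divergence = NULL,
                             proteome = NULL, geneCoords = NULL,
                             auxiliary = character(), exclude = character()) {
  expression <- expression[!expression$gene %in% exclude, , drop = FALSE]
  inReg <- filterRegion(expression, region)
  retained <- filterIntensity(inReg, floor)
  prof <- glandProfiles(retained)
  genes <- sort(unique(retained$gene))
  allGenes <- sort(union(unique(expression$gene), auxiliary))
  if (is.null(geneCoords)) {
    geneCoords <- unique(expression[c("gene", "start_mb", "end_mb")])
    if (length(auxiliary)) {
      extra <- auxiliary[!auxiliary %in% geneCoords$gene]
      if (length(extra))
        geneCoords <- rbind(geneCoords,
                            data.frame(gene = extra, start_mb = mean(region),
                                       end_mb = mean(region)))
    }
  }
  passRegion <- allGenes %in% union(unique(inReg$gene), auxiliary)
  passIntensity <- allGenes %in% union(genes, auxiliary)
  locKeep <- if (is.null(localization)) allGenes
             else filterLocalization(allGenes, localization)
  passLoc <- allGenes %in% locKeep
  divKeep <- if (is.null(divergence)) allGenes
             else filterDivergence(allGenes, divergence)
  passDiv <- allGenes %in% divKeep
  if (!is.null(proteome)) {
    xr <- proteomeCrossref(genes, proteome, geneCoords, region, auxiliary)
    passProt <- allGenes %in% xr$confirmed
  } else {
    xr <- NULL
    passProt <- rep(TRUE, length(allGenes))
  }
  ledger <- data.frame(gene = allGenes, pass_region = passRegion,
                       pass_intensity = passIntensity,
                       pass_localization = passLoc,
                       pass_divergence = passDiv, pass_proteome = passProt,
                       row.names = NULL)
  finals <- ledger$gene[apply(as.matrix(ledger[grep("^pass_", names(ledger))]),
                              1L, all)]
  new("CandidateReport", ledger = ledger, candidates = finals,
      glandCounts = prof$counts,
      params = list(region = region, floor = floor, auxiliary = auxiliary,
                    exclude = exclude, crossref = xr,
                    glandProfiles = prof$profiles))
}
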