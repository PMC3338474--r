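## End-to-end orchestration: segment -> candidates -> divergence -> trees ->
## selection, from one config, with per-stage provenance and failure
## isolation.

.stageSafely <- function(name, expr, report) {
  res <- tryCatch(expr, error = function(e)
    structure(list(error = conditionMessage(e)), class = "stageError"))
  if (inherits(res, "stageError")) {
    report$errors[[name]] <- res$error
    report$stages[[name]] <- NULL
  } else {
    report$stages[[name]] <- res
  }
  report
}

#' Run the full congenic characterization pipeline
#'
#' Stages run in dependency order; a failing stage is recorded under
#' \code{errors} and later stages that do not depend on it still run. The
#' consolidated report mirrors the analysis chain: backcross expectation,
#' transferred-segment inference, candidate triage, per-gene substitution
#' summaries, gene-tree congruence, and site-model selection tests.
#'
#' @param config either a path to a YAML file or a list with (all optional)
#'   entries:
#'   \describe{
#'     \item{backcross}{list(generations, locus_cm, chrom_cm, mb_per_cm,
#'       replicates, seed)}
#'     \item{segment}{list(markers, tracks, gaps, region) -- data.frames or
#'       file paths}
#'     \item{triage}{list(expression, region, floor, localization,
#'       divergence, proteome, auxiliary, exclude)}
#'     \item{seqdiff}{list of list(gene, seq1, seq2) or a gene-keyed
#'       alignment list}
#'     \item{trees}{list(alignments = named list of FASTA paths/vectors,
#'       species_tree = newick string, outgroup, model)}
#'     \item{selection}{list(alignments, trees = named newick strings,
#'       reference_taxon, offset)}
#'     \item{outdir}{output directory for report.json / report.md}
#'     \item{seed}{global seed used where a stage does not set its own}
#'   }
#' @return list with \code{stages} (per-stage results), \code{errors},
#'   \code{headline} (candidate genes and selection verdicts).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  report <- list(stages = list(), errors = list(), headline = list())

  if (!is.null(config$backcross)) {
    bc <- config$backcross
    report <- .stageSafely("backcross", {
      des <- backcrossDesign(bc$generations %||% 16, bc$locus_cm %||% 17,
                             bc$chrom_cm %||% 80, bc$mb_per_cm %||% 2,
                             bc$replicates %||% 20000, bc$seed %||% seed)
      analytic <- expectedFlankingLength(des)
      sim <- simulateBackcross(des)
      list(design = des, analytic = analytic, simulated = sim,
           bounds = sizeBoundsMb(analytic, des@mbPerCM))
    }, report)
  }

  if (!is.null(config$segment)) {
    sg <- config$segment
    report <- .stageSafely("segment", {
      markers <- if (is.character(sg$markers)) readMarkerTable(sg$markers)
                 else sg$markers
      tracks <- if (is.character(sg$tracks)) readAncestryTracks(sg$tracks)
                else sg$tracks
      gaps <- if (is.null(sg$gaps)) NULL
              else if (is.character(sg$gaps)) readGapTable(sg$gaps)
              else sg$gaps
      calls <- callOrigins(markers)
      inferSegment(calls, tracks, gaps, unlist(sg$region))
    }, report)
  }

  if (!is.null(config$triage)) {
    tg <- config$triage
    report <- .stageSafely("triage", {
      expr <- if (is.character(tg$expression))
        readExpressionTable(tg$expression) else tg$expression
      triageCandidates(expr, unlist(tg$region), tg$floor %||% 10,
                       localization = tg$localization,
                       divergence = tg$divergence, proteome = tg$proteome,
                       auxiliary = tg$auxiliary %||% character(),
                       exclude = tg$exclude %||% character())
    }, report)
  }

  if (!is.null(config$seqdiff)) {
    report <- .stageSafely("seqdiff", {
      lapply(config$seqdiff, function(x)
        countSubstitutions(x$seq1, x$seq2, gene = x$gene %||% "gene"))
    }, report)
  }

  if (!is.null(config$trees)) {
    tr <- config$trees
    report <- .stageSafely("trees", {
      spTree <- ape::read.tree(text = tr$species_tree)
      out <- list()
      for (g in names(tr$alignments)) {
        aln <- tr$alignments[[g]]
        if (is.character(aln) && length(aln) == 1L && file.exists(aln))
          aln <- readFastaAlignment(aln)
        dm <- pairwiseDistances(aln, model = tr$model %||% "k2p")
        gt <- njTree(dm, outgroup = tr$outgroup)
        out[[g]] <- list(tree = gt,
                         newick_rooted = ape::write.tree(gt),
                         newick_unrooted = ape::write.tree(ape::unroot(gt)),
                         congruence = checkCongruence(gt, spTree, gene = g))
      }
      out
    }, report)
  }

  if (!is.null(config$selection)) {
    sl <- config$selection
    report <- .stageSafely("selection", {
      out <- list()
      for (g in names(sl$alignments)) {
        aln <- sl$alignments[[g]]
        if (is.character(aln) && length(aln) == 1L && file.exists(aln))
          aln <- readFastaAlignment(aln)
        gt <- ape::read.tree(text = sl$trees[[g]])
        out[[g]] <- testSelection(aln, gt,
                                  referenceTaxon = sl$reference_taxon,
                                  offset = sl$offset %||% 0)
      }
      out
    }, report)
  }

  # headline block
  if (!is.null(report$stages$triage)) {
    cand <- candidates(report$stages$triage)
    report$headline$candidates <- if (length(cand)) sort(cand)
                                  else "no candidate genes survived the filters"
  }
  if (!is.null(report$stages$segment))
    report$headline$functional_size_mb <-
      report$stages$segment@functionalSizeMb
  if (!is.null(report$stages$selection))
    report$headline$selection <- lapply(report$stages$selection, function(x)
      list(p = x@pValue, omega_s = x@omegaSelected,
           percent_codons = x@percentSelected))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.reportAsJson(report),
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(.reportAsMarkdown(report),
               file.path(config$outdir, "report.md"))
  }
  report
}

# JSON-serializable view (S4 objects flattened; no timestamps so re-runs
# with identical config and seed are byte-identical)
.reportAsJson <- function(report) {
  flat <- function(x) {
    if (isVirtualClass(class(x)[1]) || !isS4(x)) {
      if (is.list(x)) return(lapply(x, flat))
      return(x)
    }
    out <- list()
    for (sn in slotNames(class(x))) {
      v <- slot(x, sn)
      if (isS4(v)) v <- flat(v)
      else if (is.list(v)) v <- NULL      # drop heavyweight internals
      else if (inherits(v, "data.frame")) v <- v
      out[[sn]] <- v
    }
    out
  }
  list(headline = report$headline, errors = report$errors,
       stages = lapply(report$stages, function(st)
         if (is.list(st)) lapply(st, flat) else flat(st)))
}

.reportAsMarkdown <- function(report) {
  ln <- c("# Congenic segment characterization report", "")
  if (!is.null(report$headline$functional_size_mb))
    ln <- c(ln, sprintf("* Functional segment size: %.1f Mb (~%d Mb)",
                        report$headline$functional_size_mb,
                        round(report$headline$functional_size_mb)))
  if (!is.null(report$headline$candidates))
    ln <- c(ln, paste("* Candidate signal genes:",
                      paste(report$headline$candidates, collapse = ", ")))
  if (!is.null(report$headline$selection))
    for (g in names(report$headline$selection)) {
      s <- report$headline$selection[[g]]
      ln <- c(ln, sprintf(
        "* %s: p = %.4g, omega_s = %.2f (%.1f%% of codons)",
        g, s$p, s$omega_s, s$percent_codons))
    }
  if (length(report$errors))
    ln <- c(ln, "", "## Stage errors",
            vapply(names(report$errors), function(n)
              paste0("* ", n, ": ", report$errors[[n]]), character(1)))
  ln
}
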