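.titvAsList <- function(titv) {
  list(
    transitions = nTransitions(titv),
    transversions = nTransversions(titv),
    ratio = titvRatio(titv)
  )
}

#' Landscape report over one or more call sets
#'
#' For each input set: candidate de novo count, Ti/Tv summary, GC
#' stratification at the configured threshold, the cumulative SNV
#' density table and (when a catalog is supplied) the overlap rate.
#' Every number is obtained by calling the underlying operations
#' directly; the reporting layer does no arithmetic of its own.
#'
#' @param callsets named list of \linkS4class{TrioCallSet}s (full trio
#'   call sets, i.e. before candidate extraction).
#' @param reference named \code{DNAStringSet}.
#' @param catalog optional known-variant catalog (see
#'   \code{\link{overlapRate}}).
#' @param gcThreshold GC percent split (default 50).
#' @param window context window length in bp (default 100).
#' @param binEdges density cumulative-distribution edges, percent.
#' @param outDir optional directory; when given, writes one annotation
#'   TSV per set and a \code{landscape.json} summary.
#' @return list of per-set summaries (see Details), invisibly identical
#'   to what \code{landscape.json} serialises.
#' @export
runLandscape <- function(callsets, reference, catalog = NULL,
                         gcThreshold = 50, window = 100L,
                         binEdges = c(1, 2, 5, 10, 15, 20, 50),
                         outDir = NULL) {
  if (is(callsets, "TrioCallSet")) callsets <- list(callsets)
  nm <- vapply(callsets, callsetName, character(1))
  names(callsets) <- nm
  out <- lapply(callsets, function(cs) {
    cand <- extractCandidateDnsnvs(cs)
    ann <- annotateCallSet(cand, reference, snvPositions = cs,
      window = window)
    strat <- stratifyByGC(ann, gcThreshold)
    res <- list(
      set = callsetName(cs),
      nRecords = length(cs),
      nCandidates = length(cand),
      titv = .titvAsList(titvSummary(cand)),
      gcHigh = c(n = length(strat$high$callset),
        .titvAsList(strat$high$titv)),
      gcLow = c(n = length(strat$low$callset),
        .titvAsList(strat$low$titv)),
      gcMissing = length(strat$missing),
      densityCumulative = densityCumulative(ann, binEdges),
      annotated = ann
    )
    if (!is.null(catalog) && length(cand) > 0L) {
      res$overlapRatePercent <- overlapRate(cand, catalog)
    }
    res
  })
  if (!is.null(outDir)) {
    .writeLandscape(out, outDir)
  }
  invisible(out)
}

.stripForJson <- function(x) {
  lapply(x, function(res) {
    res$annotated <- NULL
    res$densityCumulative <- as.list(res$densityCumulative)
    res
  })
}

.writeLandscape <- function(out, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  for (res in out) {
    rec <- records(res$annotated)
    cols <- intersect(
      c("chrom", "pos", "ref", "alt", "gcContent", "snvDensity",
        "substClass", "score"),
      names(rec))
    utils::write.table(rec[, cols, drop = FALSE],
      file.path(outDir, paste0(res$set, "_annotation.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(.stripForJson(out),
    file.path(outDir, "landscape.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Filter and compare report over one or more call sets
#'
#' Per set: pre- and post-filter candidate counts and Ti/Tv, the cutoff
#' sweep table and GQ summaries before/after filtering; across sets (2
#' or more): the full \linkS4class{ComparisonReport} on the filtered
#' sets.  Deterministic given its inputs.
#'
#' @param callsets named list of \linkS4class{TrioCallSet}s (full trio
#'   call sets).
#' @param cutoff score threshold (default 0).
#' @param sweepCutoffs ascending cutoffs for the sweep table.
#' @param grouping score grouping, see \code{\link{scoreCallSet}}.
#' @param catalog optional known-variant catalog.
#' @param outDir optional directory for TSV tables and
#'   \code{filter_compare.json}.
#' @return list with per-set summaries (\code{sets}), the filtered call
#'   sets (\code{filtered}) and, when applicable, \code{comparison}.
#' @export
runFilterAndCompare <- function(callsets, cutoff = 0,
                                sweepCutoffs = seq(-3, 3, by = 0.5),
                                grouping = c("product", "quotient"),
                                catalog = NULL, outDir = NULL) {
  grouping <- match.arg(grouping)
  if (is(callsets, "TrioCallSet")) callsets <- list(callsets)
  nm <- vapply(callsets, callsetName, character(1))
  names(callsets) <- nm

  filtered <- list()
  sets <- list()
  for (cs in callsets) {
    cand <- extractCandidateDnsnvs(cs)
    scored <- scoreCallSet(cand, grouping = grouping)
    kept <- applyFilter(scored, cutoff = cutoff)
    filtered[[callsetName(cs)]] <- kept
    sets[[callsetName(cs)]] <- list(
      set = callsetName(cs),
      cutoff = cutoff,
      nCandidates = length(cand),
      nKept = length(kept),
      titvBefore = .titvAsList(titvSummary(cand)),
      titvAfter = .titvAsList(titvSummary(kept)),
      sweep = cutoffSweep(scored, sweepCutoffs),
      gqBefore = gqSummary(cand),
      gqAfter = gqSummary(kept)
    )
  }
  out <- list(sets = sets, filtered = filtered)
  if (length(filtered) >= 2L) {
    out$comparison <- intersectCallSets(filtered, catalog = catalog)
  }
  if (!is.null(outDir)) {
    .writeFilterCompare(out, outDir)
  }
  invisible(out)
}

.comparisonAsList <- function(x) {
  list(
    sets = x@setNames,
    exclusiveCounts = as.list(x@exclusiveCounts),
    pairwiseOverlaps = as.list(x@pairwiseOverlaps),
    commonCount = x@commonCount,
    perChromCounts = as.data.frame(x@perChromCounts),
    overlapRates = as.list(x@overlapRates)
  )
}

.writeFilterCompare <- function(out, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  json <- list(
    sets = lapply(out$sets, function(s) {
      s$sweep <- as.list(s$sweep)
      s$gqBefore <- as.list(s$gqBefore)
      s$gqAfter <- as.list(s$gqAfter)
      s
    })
  )
  for (nm in names(out$sets)) {
    utils::write.table(out$sets[[nm]]$sweep,
      file.path(outDir, paste0(nm, "_sweep.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$comparison)) {
    json$comparison <- .comparisonAsList(out$comparison)
  }
  jsonlite::write_json(json, file.path(outDir, "filter_compare.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
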