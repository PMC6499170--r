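#' Windowed GC content around variant positions
#'
#' Computes the percentage of G and C bases in the \code{window}-base
#' reference window centred on each position.  A window of length w
#' covers \code{[pos - w/2, pos + w/2 - 1]} (1-based, inclusive), so the
#' variant base itself is included.  The percentage is
#' \code{count * 100 / w}.  Windows that overrun a contig end, or that
#' contain any N base, yield \code{NA}: the fixed denominator makes the
#' percentage undefined there and silent rescaling would bias the
#' distribution.
#'
#' @param reference named \code{DNAStringSet}.
#' @param chrom,pos vectors of chromosome labels and 1-based positions.
#' @param window even positive window length in bp (default 100).
#' @return numeric vector of percentages in [0, 100], NA where undefined.
#' @examples
#' ref <- Biostrings::DNAStringSet(c("1" = strrep("AG", 100)))
#' gcContent(ref, "1", 100)
#' @export
gcContent <- function(reference, chrom, pos, window = 100L) {
  .checkWindow(window)
  chrom <- .checkChrom(reference, chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  half <- window %/% 2L
  len <- Biostrings::width(reference)[match(chrom, names(reference))]
  if (any(pos < 1L | pos > len)) {
    i <- which(pos < 1L | pos > len)[1L]
    stop("position out of range: ", chrom[i], ":", pos[i])
  }
  start <- pos - half
  end <- pos + half - 1L
  out <- rep(NA_real_, n)
  ok <- start >= 1L & end <= len
  for (i in which(ok)) {
    win <- Biostrings::subseq(reference[[chrom[i]]], start[i], end[i])
    freq <- Biostrings::letterFrequency(win, c("G", "C", "N"))
    if (freq[["N"]] == 0) {
      out[i] <- (freq[["G"]] + freq[["C"]]) * 100 / window
    }
  }
  out
}

.checkWindow <- function(window) {
  if (length(window) != 1L || window < 2L || window %% 2L != 0L) {
    stop("window must be a single positive even integer")
  }
}

#' Windowed SNV density around variant positions
#'
#' Counts, for each query position, the SNV call positions falling in the
#' \code{window}-base window \code{[pos - w/2, pos + w/2 - 1]} on the same
#' chromosome, expressed as \code{count * 100 / w} percent.  The focal
#' variant counts itself when present in \code{snvPositions}.  The source
#' set should be the full SNV call set of the same sample and pipeline
#' (de novo plus inherited), not only the de novo candidates.
#'
#' @param snvPositions a \linkS4class{TrioCallSet} or a data.frame with
#'   \code{chrom} and \code{pos} columns giving all called SNV positions.
#' @param chrom,pos query chromosome labels and 1-based positions.
#' @param window even positive window length in bp (default 100).
#' @return numeric vector of percentages.
#' @export
snvDensity <- function(snvPositions, chrom, pos, window = 100L) {
  .checkWindow(window)
  if (is(snvPositions, "TrioCallSet")) {
    snvPositions <- records(snvPositions)[, c("chrom", "pos")]
  }
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(.normChrom(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  half <- window %/% 2L
  if (nrow(snvPositions) == 0L) {
    return(rep(0, n))
  }
  sp <- unique(data.frame(
    chrom = .normChrom(snvPositions$chrom),
    pos = as.integer(snvPositions$pos)
  ))
  lev <- union(unique(sp$chrom), unique(chrom))
  subject <- GenomicRanges::GRanges(factor(sp$chrom, lev),
    IRanges::IRanges(sp$pos, width = 1L))
  query <- GenomicRanges::GRanges(
    factor(chrom, lev),
    IRanges::IRanges(start = pmax(1L, pos - half), end = pos + half - 1L)
  )
  GenomicRanges::countOverlaps(query, subject) * 100 / window
}

#' Classify substitutions as transitions or transversions
#'
#' A transition swaps a purine for the other purine (A<->G) or a
#' pyrimidine for the other pyrimidine (C<->T); every other base change
#' is a transversion.  Symmetric in its arguments.
#'
#' @param ref,alt single-base vectors over {A,C,G,T}; elementwise
#'   \code{ref != alt}.
#' @return character vector, "transition" or "transversion".
#' @examples
#' classifySubstitution("A", "G") # transition
#' classifySubstitution("A", "T") # transversion
#' @export
classifySubstitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("ref and alt must be single bases in {A,C,G,T}")
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ (not a substitution)")
  }
  purine <- c("A", "G")
  ti <- (ref %in% purine) == (alt %in% purine)
  ifelse(ti, "transition", "transversion")
}

#' Transition/transversion summary of a call set
#'
#' @param x a \linkS4class{TrioCallSet}, or an integer transition count
#'   (with \code{nTv} the transversion count) to build a summary from
#'   known tallies.
#' @param nTv transversion count when \code{x} is a count.
#' @return A \linkS4class{TiTvSummary}.  The ratio is undefined (NA) when
#'   there are no transversions; textual output rounds it to 2 decimals,
#'   full precision is kept internally.
#' @examples
#' titvRatio(titvSummary(1679L, 891L)) # 1.884...
#' @export
titvSummary <- function(x, nTv = NULL) {
  if (is(x, "TrioCallSet")) {
    rec <- records(x)
    if (nrow(rec) == 0L) {
      return(new("TiTvSummary"))
    }
    cls <- classifySubstitution(rec$ref, rec$alt)
    new("TiTvSummary",
      nTransitions = sum(cls == "transition"),
      nTransversions = sum(cls == "transversion"))
  } else {
    new("TiTvSummary", nTransitions = as.integer(x), nTransversions = as.integer(nTv))
  }
}

#' @describeIn TiTvSummary-accessors transition count.
#' @export
setMethod("nTransitions", "TiTvSummary", function(x) x@nTransitions)

#' Accessors for TiTvSummary
#' @param x a \linkS4class{TiTvSummary}.
#' @name TiTvSummary-accessors
NULL

#' @describeIn TiTvSummary-accessors transversion count.
#' @export
setMethod("nTransversions", "TiTvSummary", function(x) x@nTransversions)

#' @describeIn TiTvSummary-accessors Ti/Tv ratio (NA when no transversions).
#' @export
setMethod("titvRatio", "TiTvSummary", function(x) {
  if (x@nTransversions == 0L) NA_real_ else x@nTransitions / x@nTransversions
})

#' Display a TiTvSummary (ratio to 2 decimals)
#' @param object a TiTvSummary.
#' @return invisible NULL.
#' @export
setMethod("show", "TiTvSummary", function(object) {
  r <- titvRatio(object)
  cat("Ti/Tv: ", if (is.na(r)) "NA" else sprintf("%.2f", r),
    " (", object@nTransitions, "/", object@nTransversions, ")\n", sep = "")
  invisible(NULL)
})

#' Annotate a call set with sequence-context metrics
#'
#' Adds \code{gcContent}, \code{snvDensity} and \code{substClass}
#' columns to the records table.
#'
#' @param callset a \linkS4class{TrioCallSet}.
#' @param reference named \code{DNAStringSet}.
#' @param snvPositions SNV source set for the density metric; defaults to
#'   the callset itself.
#' @param window window length in bp.
#' @return the annotated \linkS4class{TrioCallSet}.
#' @export
annotateCallSet <- function(callset, reference, snvPositions = callset,
                            window = 100L) {
  rec <- records(callset)
  if (nrow(rec)) {
    rec$gcContent <- gcContent(reference, rec$chrom, rec$pos, window)
    rec$snvDensity <- snvDensity(snvPositions, rec$chrom, rec$pos, window)
    rec$substClass <- classifySubstitution(rec$ref, rec$alt)
  } else {
    rec$gcContent <- numeric()
    rec$snvDensity <- numeric()
    rec$substClass <- character()
  }
  .withRecords(callset, rec)
}

#' Stratify an annotated call set by GC content
#'
#' Partitions records into a high stratum (gcContent >= threshold) and a
#' low stratum (< threshold); records with missing GC go to neither and
#' are returned separately.
#'
#' @param callset a \linkS4class{TrioCallSet} annotated with
#'   \code{gcContent} (see \code{\link{annotateCallSet}}).
#' @param threshold GC percent split point (default 50).
#' @return list with elements \code{high} and \code{low}, each a list of
#'   \code{callset} and \code{titv}, plus \code{missing} (a TrioCallSet).
#' @export
stratifyByGC <- function(callset, threshold = 50) {
  rec <- records(callset)
  if (!"gcContent" %in% names(rec)) {
    stop("callset has no gcContent annotation; run annotateCallSet() first")
  }
  gc <- rec$gcContent
  hi <- callset[which(!is.na(gc) & gc >= threshold)]
  lo <- callset[which(!is.na(gc) & gc < threshold)]
  list(
    high = list(callset = hi, titv = titvSummary(hi)),
    low = list(callset = lo, titv = titvSummary(lo)),
    missing = callset[which(is.na(gc))]
  )
}

#' Cumulative distribution of SNV densities
#'
#' For each edge e, the fraction of values strictly below e.
#'
#' @param densities numeric vector of SNV-density percentages, or an
#'   annotated \linkS4class{TrioCallSet}.
#' @param binEdges strictly increasing numeric vector of percent edges.
#' @return data.frame with columns \code{edge} and \code{fraction}
#'   (non-decreasing in \code{edge}).
#' @export
densityCumulative <- function(densities, binEdges) {
  if (is(densities, "TrioCallSet")) {
    rec <- records(densities)
    if (!"snvDensity" %in% names(rec)) {
      stop("callset has no snvDensity annotation; run annotateCallSet() first")
    }
    densities <- rec$snvDensity
  }
  if (is.unsorted(binEdges, strictly = TRUE)) {
    stop("binEdges must be strictly increasing")
  }
  densities <- densities[!is.na(densities)]
  n <- length(densities)
  frac <- vapply(binEdges, function(e) {
    if (n == 0L) NA_real_ else sum(densities < e) / n
  }, numeric(1))
  data.frame(edge = binEdges, fraction = frac)
}
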