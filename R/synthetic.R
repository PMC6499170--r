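#' Build a synthetic trio study configuration
#'
#' Defaults describe a desk-scale whole-exome-like study: two 500 kb
#' autosomes, each half at 40\% GC and half at 60\% GC (mimicking the
#' low/high GC regions over which calling behaviour differs), 2000
#' inherited SNVs, 300 planted de novo SNVs with a transition fraction
#' of 2/3 (Ti/Tv = 2, the genome-wide expectation for true variants),
#' 30x mean depth, 1\% per-read error and a 20\% spurious-candidate
#' fraction.
#'
#' @param nChrom,chromLength,gcSegments,nInherited,nDenovo,tiFraction,meanDepth,seqError,spuriousRate,gqMargin,seed
#'   see \linkS4class{SyntheticTrioConfig}.
#' @return A validated \linkS4class{SyntheticTrioConfig}.
#' @export
syntheticTrioConfig <- function(nChrom = 2L,
                                chromLength = 500000L,
                                gcSegments = data.frame(
                                  length = c(250000L, 250000L),
                                  gc = c(0.4, 0.6)
                                ),
                                nInherited = 2000L,
                                nDenovo = 300L,
                                tiFraction = 2 / 3,
                                meanDepth = 30,
                                seqError = 0.01,
                                spuriousRate = 0.2,
                                gqMargin = 30L,
                                seed = 1234L) {
  new("SyntheticTrioConfig",
    nChrom = as.integer(nChrom), chromLength = as.integer(chromLength),
    gcSegments = gcSegments, nInherited = as.integer(nInherited),
    nDenovo = as.integer(nDenovo), tiFraction = tiFraction,
    meanDepth = meanDepth, seqError = seqError, spuriousRate = spuriousRate,
    gqMargin = as.integer(gqMargin), seed = as.integer(seed))
}

## bases drawn independently: P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2
.sampleSegment <- function(len, gc) {
  sample(c("A", "T", "G", "C"), len, replace = TRUE,
    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Generate a synthetic reference genome
#'
#' Each chromosome is the concatenation of the configured GC segments,
#' with bases drawn independently at the segment's target G+C
#' probability.  Deterministic under the config seed.
#'
#' @param config a \linkS4class{SyntheticTrioConfig}.
#' @param path optional FASTA output path.
#' @return named \code{DNAStringSet} with chromosomes "1", "2", ...
#' @export
generateReference <- function(config, path = NULL) {
  stopifnot(is(config, "SyntheticTrioConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  seg <- config@gcSegments
  chroms <- vapply(seq_len(config@nChrom), function(i) {
    paste(unlist(lapply(seq_len(nrow(seg)), function(k) {
      .sampleSegment(seg$length[k], seg$gc[k])
    })), collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(chroms)
  names(ref) <- as.character(seq_len(config@nChrom))
  if (!is.null(path)) writeReference(ref, path)
  ref
}

## target GC fraction of the segment containing each position
.segmentGC <- function(config, pos) {
  ends <- cumsum(config@gcSegments$length)
  config@gcSegments$gc[findInterval(pos - 1L, c(0L, ends),
    rightmost.closed = TRUE)]
}

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
  C = c("A", "G"), T = c("A", "G"))

#' Generate a synthetic trio call set with ground truth
#'
#' Plants three kinds of variants at distinct positions (all at least
#' half a window from contig ends):
#' \itemize{
#'   \item inherited: a random parent carries the allele (het or hom,
#'     equal odds), the other parent is 0/0, and the child genotype is
#'     drawn by Mendelian transmission;
#'   \item de novo: both parents 0/0, child 0/1;
#'   \item spurious: both parents 0/0, the child is truly 0/0 but the
#'     emitted (called) genotype is 0/1 — a genotype-error false
#'     positive.
#' }
#' Substitutions are transitions with probability \code{tiFraction},
#' otherwise uniform over the two transversions of the reference base.
#' Depths follow the standard sequencing toy model: per-sample depth ~
#' Poisson(meanDepth); alternate reads ~ Binomial(depth, vaf) with vaf =
#' seqError for true genotype 0/0, 0.5 for 0/1 and 1 - seqError for
#' 1/1.  GQ is drawn uniformly on 80..99 and lowered by \code{gqMargin}
#' for the child of spurious records.  The number of spurious records is
#' chosen so they form \code{spuriousRate} of all candidate de novo
#' calls.  Deterministic under the config seed.
#'
#' @param config a \linkS4class{SyntheticTrioConfig}.
#' @param reference the reference from \code{\link{generateReference}}
#'   under the same config.
#' @param dir optional output directory; when given, writes
#'   \code{trio.vcf} (GT/AD/GQ) and \code{truth.tsv} there.
#' @return list with \code{callset} (a \linkS4class{TrioCallSet} of all
#'   emitted records) and \code{truth} (data.frame with key, origin in
#'   {inherited, denovo, spurious}, true genotypes per role, the target
#'   GC of the surrounding segment, and substitution class).
#' @export
generateTrio <- function(config, reference, dir = NULL) {
  stopifnot(is(config, "SyntheticTrioConfig"))
  methods::validObject(config)
  set.seed(config@seed + 1L)

  if (config@spuriousRate >= 1) {
    stop("spuriousRate must be < 1 (it is a fraction of all candidates)")
  }
  nSpur <- if (config@spuriousRate > 0) {
    as.integer(round(config@nDenovo * config@spuriousRate /
      (1 - config@spuriousRate)))
  } else {
    0L
  }
  nTotal <- config@nInherited + config@nDenovo + nSpur
  half <- 50L
  usable <- config@chromLength - 2L * half
  if (nTotal > config@nChrom * usable) {
    stop("more variants requested (", nTotal,
      ") than available positions (", config@nChrom * usable, ")")
  }
  flat <- sample.int(config@nChrom * usable, nTotal)
  chrom <- as.character((flat - 1L) %/% usable + 1L)
  pos <- (flat - 1L) %% usable + half + 1L
  origin <- sample(rep(c("inherited", "denovo", "spurious"),
    c(config@nInherited, config@nDenovo, nSpur)))

  refBase <- refBase(reference, chrom, pos)
  isTi <- stats::runif(nTotal) < config@tiFraction
  altBase <- ifelse(isTi, .TRANSITION[refBase],
    vapply(refBase, function(b) sample(.TRANSVERSIONS[[b]], 1L),
      character(1)))

  ## true genotypes
  fGT <- mGT <- rep("0/0", nTotal)
  sGT <- rep("0/0", nTotal)
  sGT[origin == "denovo"] <- "0/1"
  inh <- which(origin == "inherited")
  if (length(inh)) {
    carrierIsFather <- sample(c(TRUE, FALSE), length(inh), replace = TRUE)
    carrierGT <- sample(c("0/1", "1/1"), length(inh), replace = TRUE)
    fGT[inh[carrierIsFather]] <- carrierGT[carrierIsFather]
    mGT[inh[!carrierIsFather]] <- carrierGT[!carrierIsFather]
    ## one allele from the carrier (certain for hom, fair coin for het),
    ## the other parent always transmits 0
    fromCarrier <- ifelse(carrierGT == "1/1", 1L,
      sample(0:1, length(inh), replace = TRUE))
    sGT[inh] <- ifelse(fromCarrier == 1L, "0/1", "0/0")
  }

  vaf <- function(gt) {
    ifelse(gt == "0/0", config@seqError,
      ifelse(gt == "0/1", 0.5, 1 - config@seqError))
  }
  drawDepths <- function(gt) {
    d <- stats::rpois(nTotal, config@meanDepth)
    altD <- stats::rbinom(nTotal, d, vaf(gt))
    list(refD = as.integer(d - altD), altD = as.integer(altD))
  }
  fD <- drawDepths(fGT)
  mD <- drawDepths(mGT)
  sD <- drawDepths(sGT)

  baseGQ <- function() sample(80:99, nTotal, replace = TRUE)
  fGQ <- baseGQ()
  mGQ <- baseGQ()
  sGQ <- baseGQ() - ifelse(origin == "spurious", config@gqMargin, 0L)

  calledChild <- ifelse(origin == "spurious", "0/1", sGT)

  rec <- data.frame(
    chrom = chrom, pos = pos, ref = refBase, alt = altBase,
    fatherGT = fGT, motherGT = mGT, childGT = calledChild,
    fatherRefDepth = fD$refD, fatherAltDepth = fD$altD,
    motherRefDepth = mD$refD, motherAltDepth = mD$altD,
    childRefDepth = sD$refD, childAltDepth = sD$altD,
    fatherGQ = fGQ, motherGQ = mGQ, childGQ = as.integer(sGQ),
    stringsAsFactors = FALSE
  )
  callset <- TrioCallSet("synthetic", rec)

  truth <- data.frame(
    chrom = chrom, pos = pos, ref = refBase, alt = altBase,
    key = .variantKey(chrom, pos, refBase, altBase),
    origin = origin,
    fatherGT = fGT, motherGT = mGT, childGT = sGT,
    segmentGC = .segmentGC(config, pos),
    substClass = classifySubstitution(refBase, altBase),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(.chromOrder(truth$chrom), truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeCallSetVcf(callset, file.path(dir, "trio.vcf"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  list(callset = callset, truth = truth)
}
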