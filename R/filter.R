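#' Read-coverage score for candidate de novo SNVs
#'
#' Scores each record from its six allele depths.  With parental
#' separations \code{|Fref - Falt|} and \code{|Mref - Malt|} and child
#' separation \code{|Salt - Sref|}, the default \code{"product"} reading
#' is
#' \deqn{score = log10( (|Fref-Falt| + |Mref-Malt|)/2 \times |Salt-Sref| )}
#' and the alternative \code{"quotient"} reading divides instead of
#' multiplying:
#' \deqn{score = log10( (|Fref-Falt| + |Mref-Malt|) / (2 |Salt-Sref|) )}
#' The product rewards large separations in both generations; the
#' quotient rewards clean homozygous-reference parents relative to a
#' balanced (heterozygous-looking) child and is the reading that
#' penalises genotype-error candidates whose child depths are strongly
#' reference-skewed.
#'
#' The score is undefined (NA) exactly when the child separation is zero
#' or the mean parental separation is zero, and when any depth is
#' missing; reason codes distinguish the cases.
#'
#' @param callset a \linkS4class{TrioCallSet}, or a data.frame of
#'   records with the six depth columns.
#' @param grouping "product" (default) or "quotient".
#' @param base logarithm base (default 10).
#' @return the input with \code{score} (numeric, NA when undefined) and
#'   \code{scoreReason} ("ok", "missing_depth", "zero_child_separation"
#'   or "zero_parental_separation") columns added.
#' @examples
#' rec <- exampleRecords("1", 100L, "A", "G",
#'   fatherRefDepth = 20L, fatherAltDepth = 0L,
#'   motherRefDepth = 20L, motherAltDepth = 0L,
#'   childRefDepth = 10L, childAltDepth = 20L
#' )
#' records(scoreCallSet(TrioCallSet("x", rec)))$score # log10(200) = 2.301
#' @export
scoreCallSet <- function(callset, grouping = c("product", "quotient"),
                         base = 10) {
  grouping <- match.arg(grouping)
  isSet <- is(callset, "TrioCallSet")
  rec <- if (isSet) records(callset) else callset
  if (nrow(rec)) {
    sc <- dnsnvScore(
      rec$fatherRefDepth, rec$fatherAltDepth,
      rec$motherRefDepth, rec$motherAltDepth,
      rec$childRefDepth, rec$childAltDepth,
      grouping = grouping, base = base
    )
    rec$score <- sc$score
    rec$scoreReason <- sc$reason
  }
  if (isSet) .withRecords(callset, rec) else rec
}

#' @rdname scoreCallSet
#' @param fRef,fAlt,mRef,mAlt,sRef,sAlt father/mother/child reference and
#'   alternate allele depths (non-negative integers; NA allowed).
#' @return for \code{dnsnvScore}: data.frame with columns \code{score}
#'   and \code{reason}.
#' @export
dnsnvScore <- function(fRef, fAlt, mRef, mAlt, sRef, sAlt,
                       grouping = c("product", "quotient"), base = 10) {
  grouping <- match.arg(grouping)
  n <- max(lengths(list(fRef, fAlt, mRef, mAlt, sRef, sAlt)))
  fRef <- rep_len(fRef, n); fAlt <- rep_len(fAlt, n)
  mRef <- rep_len(mRef, n); mAlt <- rep_len(mAlt, n)
  sRef <- rep_len(sRef, n); sAlt <- rep_len(sAlt, n)
  parentSep <- (abs(fRef - fAlt) + abs(mRef - mAlt)) / 2
  childSep <- abs(sAlt - sRef)
  reason <- rep("ok", n)
  reason[!is.na(parentSep) & parentSep == 0] <- "zero_parental_separation"
  reason[!is.na(childSep) & childSep == 0] <- "zero_child_separation"
  reason[is.na(parentSep) | is.na(childSep)] <- "missing_depth"
  score <- rep(NA_real_, n)
  ok <- reason == "ok"
  score[ok] <- switch(grouping,
    product = log(parentSep[ok] * childSep[ok], base = base),
    quotient = log(parentSep[ok] / childSep[ok], base = base)
  )
  data.frame(score = score, reason = reason, stringsAsFactors = FALSE)
}

#' Filter a call set at a score cutoff
#'
#' Keeps records with score strictly greater than \code{cutoff} (records
#' at exactly the cutoff are removed).  Records with an undefined score
#' (zero separation or missing depths) never pass any finite cutoff;
#' their reason codes are tallied in the skip log of the result.
#'
#' @param callset a \linkS4class{TrioCallSet}; scored on the fly if it
#'   has no \code{score} column.
#' @param cutoff score threshold (default 0, the non-stringent choice).
#' @param grouping,base passed to \code{\link{scoreCallSet}} when scoring
#'   is needed.
#' @return the kept subset, a \linkS4class{TrioCallSet} with score
#'   columns; idempotent at a fixed cutoff, and nested across cutoffs
#'   (larger cutoffs keep subsets).
#' @export
applyFilter <- function(callset, cutoff = 0, grouping = c("product", "quotient"),
                        base = 10) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  scored <- .ensureScores(callset, match.arg(grouping), base)
  rec <- records(scored)
  keep <- !is.na(rec$score) & rec$score > cutoff
  out <- .withRecords(scored, rec[keep, , drop = FALSE])
  dropped <- rec$scoreReason[!keep & rec$scoreReason != "ok"]
  if (length(dropped)) {
    log <- out@skipLog
    tab <- table(dropped)
    for (nm in names(tab)) {
      log[nm] <- tab[[nm]] + if (nm %in% names(log)) log[[nm]] else 0L
    }
    out@skipLog <- .asSkipLog(log)
  }
  out
}

.ensureScores <- function(callset, grouping, base) {
  rec <- records(callset)
  if (nrow(rec) == 0L && !"score" %in% names(rec)) {
    rec$score <- numeric()
    rec$scoreReason <- character()
    return(.withRecords(callset, rec))
  }
  if ("score" %in% names(rec)) callset else scoreCallSet(callset, grouping, base)
}

#' Kept-record counts across a sweep of score cutoffs
#'
#' @param callset a \linkS4class{TrioCallSet}.
#' @param cutoffs numeric vector of cutoffs, sorted non-decreasing
#'   (duplicates allowed); unsorted input is an error.
#' @param grouping,base scoring options, as in \code{\link{scoreCallSet}}.
#' @return data.frame with columns \code{cutoff} and \code{kept};
#'   \code{kept} is non-increasing.
#' @export
cutoffSweep <- function(callset, cutoffs, grouping = c("product", "quotient"),
                        base = 10) {
  if (is.unsorted(cutoffs)) stop("cutoffs must be sorted ascending")
  scored <- .ensureScores(callset, match.arg(grouping), base)
  score <- records(scored)$score
  kept <- vapply(cutoffs, function(cut) sum(!is.na(score) & score > cut),
    integer(1))
  data.frame(cutoff = cutoffs, kept = kept)
}

#' Rank records by score
#'
#' Orders records by descending score; undefined scores come last; ties
#' (including among undefined scores) break by (chromosome, position)
#' for determinism.
#'
#' @inheritParams cutoffSweep
#' @return data.frame of scored records in rank order.
#' @export
rankByScore <- function(callset, grouping = c("product", "quotient"),
                        base = 10) {
  scored <- .ensureScores(callset, match.arg(grouping), base)
  rec <- records(scored)
  if (nrow(rec) == 0L) return(rec)
  ord <- order(-rec$score, .chromOrder(rec$chrom), rec$pos, na.last = TRUE)
  ## order() with na.last puts NA scores last but drops the tie-break for
  ## them; re-sort the NA tail by genomic coordinates
  nNA <- sum(is.na(rec$score))
  if (nNA > 1L) {
    tail_idx <- ord[(length(ord) - nNA + 1L):length(ord)]
    tail_rec <- rec[tail_idx, , drop = FALSE]
    ord[(length(ord) - nNA + 1L):length(ord)] <-
      tail_idx[order(.chromOrder(tail_rec$chrom), tail_rec$pos)]
  }
  out <- rec[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
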