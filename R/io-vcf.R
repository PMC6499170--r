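## INFO keys used when writing annotated call sets
.INFO_HEADER <- function() {
  S4Vectors::DataFrame(
    Number = c("1", "1", "1", "1"),
    Type = c("Float", "Float", "String", "Float"),
    Description = c(
      "GC content percent of the 100-base reference window",
      "SNV density percent of the 100-base window",
      "Substitution class: ti (transition) or tv (transversion)",
      "Read-coverage de novo filter score (log10)"
    ),
    row.names = c("GCC", "SNVD", "TITV_CLASS", "DNSCORE")
  )
}

.DEFAULT_ROLE_MAP <- c(father = "FATHER", mother = "MOTHER", child = "CHILD")

#' Read a trio call set from a multi-sample VCF
#'
#' Keeps only biallelic single-nucleotide substitutions on the autosomes
#' (labels 1-22, with or without "chr" prefix); multi-allelic sites,
#' indels/MNVs, non-autosomal records and duplicate keys are skipped and
#' tallied in the skip log.  Per-role GT, AD-derived depths and GQ are
#' extracted; a record whose AD is absent keeps NA depths (retained but
#' unscorable), and "./." genotypes become NA genotypes.  Annotation
#' INFO keys written by \code{\link{writeCallSetVcf}} (GCC, SNVD,
#' TITV_CLASS, DNSCORE) are read back when present.
#'
#' @param path VCF file (v4.x, FORMAT fields GT, AD, GQ).
#' @param roleMap named character vector mapping the roles
#'   \code{father}, \code{mother}, \code{child} to sample names in the
#'   VCF header.
#' @param name pipeline label for the resulting set (defaults to the
#'   file name).
#' @return A \linkS4class{TrioCallSet}.
#' @export
readTrioVcf <- function(path, roleMap = .DEFAULT_ROLE_MAP,
                        name = tools::file_path_sans_ext(basename(path))) {
  if (!all(TRIO_ROLES %in% names(roleMap))) {
    stop("roleMap must name samples for roles: ",
      paste(TRIO_ROLES, collapse = ", "))
  }
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  hdrSamples <- colnames(v)
  missing <- setdiff(unname(roleMap[TRIO_ROLES]), hdrSamples)
  if (length(missing)) {
    stop("sample(s) not in VCF header: ", paste(missing, collapse = ", "))
  }

  chrom <- .normChrom(as.character(GenomicRanges::seqnames(v)))
  pos <- GenomicRanges::start(v)
  refA <- as.character(VariantAnnotation::ref(v))
  altL <- VariantAnnotation::alt(v)
  nAlt <- S4Vectors::elementNROWS(altL)
  altA <- rep(NA_character_, length(nAlt))
  if (any(nAlt == 1L)) {
    altA[nAlt == 1L] <- vapply(which(nAlt == 1L), function(i) {
      as.character(altL[[i]][[1L]])
    }, character(1))
  }

  multi <- nAlt != 1L
  snv <- !multi & nchar(refA) == 1L & !is.na(altA) & nchar(altA) == 1L &
    toupper(refA) %in% c("A", "C", "G", "T") &
    toupper(altA) %in% c("A", "C", "G", "T") & toupper(refA) != toupper(altA)
  autosome <- chrom %in% AUTOSOMES

  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) {
    stop("VCF has no GT FORMAT field: ", path)
  }
  hasGT <- rowSums(matrix(gt[, roleMap[TRIO_ROLES], drop = FALSE] %in%
    c(".", "./.", ".|."), ncol = 3L)) == 0
  keep <- snv & autosome & hasGT

  skip <- c(
    multiallelic = sum(multi),
    non_snv = sum(!multi & !snv),
    non_autosome = sum(snv & !autosome),
    missing_gt = sum(snv & autosome & !hasGT)
  )

  ad <- VariantAnnotation::geno(v)$AD
  gq <- VariantAnnotation::geno(v)$GQ
  idx <- which(keep)
  pull <- function(role) {
    s <- roleMap[[role]]
    g <- .normGT(gt[idx, s])
    if (!is.null(ad)) {
      refD <- vapply(ad[idx, s], function(x) {
        if (length(x) >= 2L && !is.na(x[1L])) as.integer(x[1L]) else NA_integer_
      }, integer(1))
      altD <- vapply(ad[idx, s], function(x) {
        if (length(x) >= 2L && !is.na(x[2L])) as.integer(x[2L]) else NA_integer_
      }, integer(1))
    } else {
      refD <- altD <- rep(NA_integer_, length(idx))
    }
    q <- if (!is.null(gq)) {
      suppressWarnings(as.integer(gq[idx, s]))
    } else {
      rep(NA_integer_, length(idx))
    }
    list(gt = g, refD = refD, altD = altD, gq = q)
  }
  f <- pull("father")
  m <- pull("mother")
  s <- pull("child")

  rec <- data.frame(
    chrom = chrom[idx], pos = pos[idx],
    ref = toupper(refA[idx]), alt = toupper(altA[idx]),
    fatherGT = f$gt, motherGT = m$gt, childGT = s$gt,
    fatherRefDepth = f$refD, fatherAltDepth = f$altD,
    motherRefDepth = m$refD, motherAltDepth = m$altD,
    childRefDepth = s$refD, childAltDepth = s$altD,
    fatherGQ = f$gq, motherGQ = m$gq, childGQ = s$gq,
    stringsAsFactors = FALSE
  )

  info <- VariantAnnotation::info(v)
  annmap <- c(GCC = "gcContent", SNVD = "snvDensity", DNSCORE = "score")
  for (key in names(annmap)) {
    if (key %in% names(info)) {
      rec[[annmap[[key]]]] <- as.numeric(info[[key]][idx])
    }
  }
  if ("TITV_CLASS" %in% names(info)) {
    cls <- as.character(info$TITV_CLASS[idx])
    rec$substClass <- ifelse(cls == "ti", "transition",
      ifelse(cls == "tv", "transversion", NA_character_))
  }

  key <- .variantKey(rec$chrom, rec$pos, rec$ref, rec$alt)
  if (anyDuplicated(key)) {
    skip["duplicate_key"] <- sum(duplicated(key))
    rec <- rec[!duplicated(key), , drop = FALSE]
  }
  TrioCallSet(name, rec, provenance = path, skipLog = skip[skip > 0L])
}

#' Write a trio call set to VCF
#'
#' Emits a VCF v4.2 with GT, AD (ref,alt) and GQ for samples FATHER,
#' MOTHER, CHILD, and INFO keys GCC / SNVD / TITV_CLASS / DNSCORE for
#' whichever annotation columns are present.  Reading the file back
#' with \code{\link{readTrioVcf}} reproduces the call set.  When
#' \code{cutoff} is given and the set carries scores, the FILTER column
#' marks records not exceeding it as DNSNV_FAIL (PASS otherwise).
#'
#' @param callset a \linkS4class{TrioCallSet}.
#' @param path output file.
#' @param cutoff optional score cutoff used only to fill FILTER.
#' @return \code{path}, invisibly.
#' @export
writeCallSetVcf <- function(callset, path, cutoff = NULL) {
  rec <- records(callset)
  n <- nrow(rec)
  samples <- unname(.DEFAULT_ROLE_MAP[TRIO_ROLES])

  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
      row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "R", "1"),
    Type = c("String", "Integer", "Integer"),
    Description = c("Genotype", "Allelic depths (ref,alt)",
      "Genotype quality"),
    row.names = c("GT", "AD", "GQ")
  )

  ann <- c(gcContent = "GCC", snvDensity = "SNVD", substClass = "TITV_CLASS",
    score = "DNSCORE")
  present <- names(ann)[names(ann) %in% names(rec)]
  infoDf <- S4Vectors::DataFrame(row.names = if (n) seq_len(n) else NULL)
  if (length(present)) {
    VariantAnnotation::info(hdr) <- .INFO_HEADER()[ann[present], , drop = FALSE]
    for (col in present) {
      val <- rec[[col]]
      if (col == "substClass") {
        val <- ifelse(val == "transition", "ti", "tv")
      } else if (col == "score") {
        val <- round(val, 3)
      }
      infoDf[[ann[[col]]]] <- val
    }
  }

  filt <- rep(".", n)
  if (!is.null(cutoff) && "score" %in% names(rec)) {
    filt <- ifelse(!is.na(rec$score) & rec$score > cutoff, "PASS",
      "DNSNV_FAIL")
  }

  gtM <- matrix(NA_character_, n, 3L, dimnames = list(NULL, samples))
  adM <- matrix(list(), n, 3L, dimnames = list(NULL, samples))
  gqM <- matrix(NA_integer_, n, 3L, dimnames = list(NULL, samples))
  for (j in seq_along(TRIO_ROLES)) {
    role <- TRIO_ROLES[j]
    g <- rec[[paste0(role, "GT")]]
    gtM[, j] <- ifelse(is.na(g), "./.", g)
    refD <- rec[[paste0(role, "RefDepth")]]
    altD <- rec[[paste0(role, "AltDepth")]]
    adM[, j] <- lapply(seq_len(n), function(i) {
      c(refD[i], altD[i])
    })
    gqM[, j] <- rec[[paste0(role, "GQ")]]
  }

  gr <- GenomicRanges::GRanges(
    if (n) rec$chrom else character(),
    IRanges::IRanges(start = if (n) rec$pos else integer(), width = 1L)
  )
  v <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
      row.names = samples),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(rec$ref),
      ALT = Biostrings::DNAStringSetList(as.list(rec$alt)),
      QUAL = rep(NA_real_, n),
      FILTER = filt
    ),
    info = infoDf,
    geno = S4Vectors::SimpleList(GT = gtM, AD = adM, GQ = gqM),
    collapsed = TRUE
  )
  VariantAnnotation::writeVcf(v, path)
  if (n == 0L) {
    # writeVcf emits a malformed empty contig line for zero-record sets
    lines <- readLines(path)
    writeLines(lines[lines != "##contig=<ID=>"], path)
  }
  invisible(path)
}
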