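# shared fixture builders; all randomness is locally seeded

# a call set of n records on chromosome 1 at spaced positions
makeCallSet <- function(name, n, start = 1000L, by = 100L, ...) {
  if (n == 0L) {
    return(TrioCallSet(name))
  }
  pos <- seq(start, by = by, length.out = n)
  TrioCallSet(name, exampleRecords("1", pos, "A", "G", ...))
}

# a call set with exact transition / transversion tallies
# (A->G transitions, A->C transversions, distinct positions)
makeTiTvCallSet <- function(nTi, nTv, name = "titv") {
  rec <- rbind(
    if (nTi > 0) {
      exampleRecords("1", seq(1000L, by = 10L, length.out = nTi), "A", "G")
    },
    if (nTv > 0) {
      exampleRecords("2", seq(1000L, by = 10L, length.out = nTv), "A", "C")
    }
  )
  TrioCallSet(name, rec)
}

# random records with assorted genotypes/depths, for property tests
randomRecords <- function(n, seed, chroms = c("1", "2", "3")) {
  set.seed(seed)
  pos <- sample.int(1e6L, n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  gts <- c("0/0", "0/1", "1/1")
  rec <- exampleRecords(sample(chroms, n, replace = TRUE), pos, ref, alt,
    fatherGT = sample(gts, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    motherGT = sample(gts, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    childGT = sample(gts, n, replace = TRUE),
    fatherRefDepth = rpois(n, 25), fatherAltDepth = rpois(n, 2),
    motherRefDepth = rpois(n, 25), motherAltDepth = rpois(n, 2),
    childRefDepth = rpois(n, 15), childAltDepth = rpois(n, 12),
    fatherGQ = sample(30:99, n, replace = TRUE),
    motherGQ = sample(30:99, n, replace = TRUE),
    childGQ = sample(30:99, n, replace = TRUE)
  )
  rec[!duplicated(rec[c("chrom", "pos", "ref", "alt")]), ]
}

# small, fast generator configuration
tinyConfig <- function(seed = 7L, ...) {
  args <- list(
    nChrom = 1L, chromLength = 20000L,
    gcSegments = data.frame(length = c(10000L, 10000L), gc = c(0.4, 0.6)),
    nInherited = 100L, nDenovo = 30L, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(syntheticTrioConfig, args)
}

# write VCF text lines (header + body) to a temp file
writeVcfText <- function(bodyLines, samples = c("FA", "MO", "CH")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, bodyLines), path)
  path
}

vcfLine <- function(chrom, pos, ref, alt, fa = "0/0:20,0:99",
                    mo = "0/0:20,0:99", ch = "0/1:10,10:99") {
  paste(chrom, pos, ".", ref, alt, ".", ".", ".", "GT:AD:GQ", fa, mo, ch,
    sep = "\t")
}

trioRoles <- c(father = "FA", mother = "MO", child = "CH")
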