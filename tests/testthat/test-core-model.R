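test_that("readTrioVcf keeps biallelic autosomal SNVs and logs skips", {
  path <- writeVcfText(c(
    vcfLine("chr1", 100, "A", "G"),
    vcfLine("chr1", 200, "A", "AT"),      # indel: skipped
    vcfLine("chr2", 300, "C", "G,T"),     # multi-allelic: skipped
    vcfLine("chrX", 400, "C", "T"),       # non-autosome: skipped
    vcfLine("chr3", 500, "G", "A")
  ))
  cs <- readTrioVcf(path, trioRoles, name = "toy")
  expect_s4_class(cs, "TrioCallSet")
  expect_equal(length(cs), 2L)
  rec <- records(cs)
  expect_equal(rec$chrom, c("1", "3"))    # chr prefix normalised away
  expect_equal(rec$pos, c(100L, 500L))
  expect_equal(rec$fatherGT, c("0/0", "0/0"))
  expect_equal(rec$childRefDepth, c(10L, 10L))
  expect_equal(rec$childAltDepth, c(10L, 10L))
  expect_equal(rec$motherGQ, c(99L, 99L))
  log <- skipLog(cs)
  expect_equal(unname(log[c("non_snv", "multiallelic", "non_autosome")]),
    c(1L, 1L, 1L))
})

test_that("readTrioVcf handles a single-indel file and autosome restriction", {
  path <- writeVcfText(vcfLine("1", 100, "A", "AT"))
  cs <- readTrioVcf(path, trioRoles)
  expect_equal(length(cs), 0L)
  expect_equal(unname(skipLog(cs)["non_snv"]), 1L)

  path2 <- writeVcfText(c(
    vcfLine("1", 10, "A", "G"), vcfLine("2", 20, "C", "T"),
    vcfLine("X", 30, "G", "A"), vcfLine("X", 40, "T", "C"),
    vcfLine("22", 50, "G", "C")
  ))
  cs2 <- readTrioVcf(path2, trioRoles)
  expect_equal(length(cs2), 3L)
  expect_true(all(records(cs2)$chrom %in% as.character(1:22)))
})

test_that("readTrioVcf reports configuration and data errors usefully", {
  path <- writeVcfText(vcfLine("1", 100, "A", "G"))
  expect_error(readTrioVcf(path, c(father = "FA", mother = "MO",
    child = "NOPE")), "NOPE")
  expect_error(readTrioVcf(path, c(father = "FA", mother = "MO")), "child")
  # missing AD -> depths NA but record retained
  path2 <- writeVcfText(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:GQ\t0/0:99\t0/0:99\t0/1:99")
  cs <- readTrioVcf(path2, trioRoles)
  expect_equal(length(cs), 1L)
  expect_true(is.na(records(cs)$childRefDepth))
  # fully missing GT -> record skipped and logged
  path3 <- writeVcfText(c(
    vcfLine("1", 100, "A", "G", ch = "./.:10,10:99"),
    vcfLine("1", 200, "C", "T")
  ))
  cs3 <- readTrioVcf(path3, trioRoles)
  expect_equal(length(cs3), 1L)
  expect_equal(unname(skipLog(cs3)["missing_gt"]), 1L)
})

test_that("TrioCallSet enforces its invariants", {
  rec <- exampleRecords(c("2", "1"), c(5L, 9L), "A", "G")
  cs <- TrioCallSet("x", rec)
  # sorted numerically by chromosome then position
  expect_equal(records(cs)$chrom, c("1", "2"))
  expect_error(TrioCallSet("x", rbind(rec, rec)), "duplicate")
  expect_error(TrioCallSet("x", exampleRecords("1", 1L, "A", "A")), "ref")
  expect_error(TrioCallSet("x", exampleRecords("X", 1L, "A", "G")),
    "autosome")
  # numeric chromosome order: 10 sorts after 2
  cs2 <- TrioCallSet("x", exampleRecords(c("10", "2"), c(1L, 1L), "A", "G"))
  expect_equal(records(cs2)$chrom, c("2", "10"))
})

test_that("extractCandidateDnsnvs applies the Mendelian-violation pattern", {
  rec <- rbind(
    exampleRecords("1", 100L, "A", "G",
      fatherGT = "0/0", motherGT = "0/0", childGT = "0/1"), # canonical
    exampleRecords("1", 200L, "A", "G",
      fatherGT = "0/1", motherGT = "0/0", childGT = "0/1"), # inherited
    exampleRecords("1", 300L, "A", "G",
      fatherGT = "0/0", motherGT = "0/0", childGT = "1/1"), # hom-alt child
    exampleRecords("1", 400L, "A", "G",
      fatherGT = "0/0", motherGT = "0/0", childGT = "0/0"), # no alt
    exampleRecords("1", 500L, "A", "G",
      fatherGT = "0/0", motherGT = NA_character_, childGT = "0/1") # missing
  )
  out <- extractCandidateDnsnvs(TrioCallSet("x", rec))
  expect_equal(records(out)$pos, c(100L, 300L))
  expect_equal(records(out)$childHomAlt, c(FALSE, TRUE))
  expect_equal(unname(skipLog(out)["missing_genotype"]), 1L)
})

test_that("candidate extraction matches a per-record brute-force scan", {
  for (seed in c(11L, 23L)) {
    cs <- TrioCallSet("r", randomRecords(200, seed))
    out <- extractCandidateDnsnvs(cs)
    rec <- records(cs)
    oracle <- vapply(seq_len(nrow(rec)), function(i) {
      identical(rec$fatherGT[i], "0/0") && identical(rec$motherGT[i], "0/0") &&
        rec$childGT[i] %in% c("0/1", "1/1")
    }, logical(1))
    expect_equal(variantKeys(out), variantKeys(cs)[oracle])
    # subset of input and idempotent
    expect_true(all(variantKeys(out) %in% variantKeys(cs)))
    again <- extractCandidateDnsnvs(out)
    expect_equal(records(again), records(out))
  }
})

test_that("reference FASTA I/O and base lookup behave", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">1", "ACGT"), fa)
  ref <- readReference(fa)
  expect_equal(refBase(ref, "1", 3), "G")
  expect_error(refBase(ref, "1", 5), "out of range")
  expect_error(refBase(ref, "9", 1), "not in reference")

  writeLines(c(">1", "ACGT", ">1", "GGCC"), fa)
  expect_error(readReference(fa), "duplicate")
  writeLines(c(">1", "ACQT"), fa)
  expect_error(readReference(fa), "position 3")

  # round trip: write then read a generated reference
  cfg <- tinyConfig()
  gen <- generateReference(cfg)
  out <- tempfile(fileext = ".fa")
  writeReference(gen, out)
  back <- readReference(out)
  expect_equal(as.character(back), as.character(gen))
})

test_that("VCF write -> read is the identity on modeled fields", {
  # empty set: header-only file
  empty <- TrioCallSet("none")
  p0 <- tempfile(fileext = ".vcf")
  writeCallSetVcf(empty, p0)
  lines <- readLines(p0)
  expect_true(all(grepl("^#", lines)))
  expect_equal(length(readTrioVcf(p0, name = "none")), 0L)

  # one record
  one <- TrioCallSet("one", exampleRecords("5", 42L, "C", "T",
    motherGQ = NA_integer_))
  p1 <- tempfile(fileext = ".vcf")
  writeCallSetVcf(one, p1)
  back1 <- readTrioVcf(p1, name = "one")
  expect_equal(records(back1), records(one))

  # 100 generated records, field-by-field
  cfg <- tinyConfig(nInherited = 70L, nDenovo = 30L, spuriousRate = 0)
  trio <- generateTrio(cfg, generateReference(cfg))
  cs <- trio$callset[seq_len(100L)]
  p2 <- tempfile(fileext = ".vcf")
  writeCallSetVcf(cs, p2)
  back2 <- readTrioVcf(p2, name = "synthetic")
  for (col in names(records(cs))) {
    expect_equal(records(back2)[[col]], records(cs)[[col]], label = col)
  }
})

test_that("annotations survive the VCF round trip via INFO keys", {
  cfg <- tinyConfig()
  ref <- generateReference(cfg)
  trio <- generateTrio(cfg, ref)
  ann <- scoreCallSet(annotateCallSet(
    extractCandidateDnsnvs(trio$callset), ref, snvPositions = trio$callset))
  p <- tempfile(fileext = ".vcf")
  writeCallSetVcf(ann, p, cutoff = 0)
  back <- readTrioVcf(p, name = "x")
  expect_equal(records(back)$gcContent, records(ann)$gcContent)
  expect_equal(records(back)$snvDensity, records(ann)$snvDensity)
  expect_equal(records(back)$substClass, records(ann)$substClass)
  expect_equal(records(back)$score, round(records(ann)$score, 3))
})
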