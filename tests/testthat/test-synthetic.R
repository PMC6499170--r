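test_that("reference segments realise their target GC", {
  cfgAT <- tinyConfig(gcSegments = data.frame(length = 20000L, gc = 0),
    seed = 3L)
  refAT <- generateReference(cfgAT)
  expect_equal(
    sum(Biostrings::letterFrequency(refAT[[1]], c("G", "C"))), 0)

  cfgGC <- tinyConfig(gcSegments = data.frame(length = 20000L, gc = 1),
    seed = 3L)
  refGC <- generateReference(cfgGC)
  expect_equal(
    sum(Biostrings::letterFrequency(refGC[[1]], c("A", "T"))), 0)

  # 10 kb at target 0.6: realised fraction within binomial 99% bounds
  cfg <- tinyConfig(chromLength = 10000L,
    gcSegments = data.frame(length = 10000L, gc = 0.6), seed = 5L)
  ref <- generateReference(cfg)
  frac <- sum(Biostrings::letterFrequency(ref[[1]], c("G", "C"))) / 10000
  expect_lt(abs(frac - 0.6), 2.576 * sqrt(0.6 * 0.4 / 10000))
})

test_that("generation is deterministic under the config seed", {
  cfg <- tinyConfig(seed = 11L)
  r1 <- generateReference(cfg)
  r2 <- generateReference(cfg)
  expect_identical(as.character(r1), as.character(r2))
  t1 <- generateTrio(cfg, r1)
  t2 <- generateTrio(cfg, r2)
  expect_identical(records(t1$callset), records(t2$callset))
  expect_identical(t1$truth, t2$truth)
  # byte-identical written outputs
  d1 <- tempfile(); d2 <- tempfile()
  generateTrio(cfg, r1, dir = d1)
  generateTrio(cfg, r1, dir = d2)
  expect_identical(readLines(file.path(d1, "trio.vcf")),
    readLines(file.path(d2, "trio.vcf")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
    readLines(file.path(d2, "truth.tsv")))
})

test_that("nothing planted means no candidates", {
  cfg <- tinyConfig(nDenovo = 0L, spuriousRate = 0, seed = 23L)
  trio <- generateTrio(cfg, generateReference(cfg))
  expect_equal(length(extractCandidateDnsnvs(trio$callset)), 0L)
})

test_that("inherited variants are Mendelian-consistent", {
  cfg <- tinyConfig(seed = 29L, nInherited = 300L)
  trio <- generateTrio(cfg, generateReference(cfg))
  inh <- trio$truth[trio$truth$origin == "inherited", ]
  expect_gt(nrow(inh), 0)
  childAlleles <- strsplit(inh$childGT, "/")
  parentAlleles <- mapply(function(f, m) {
    unique(c(strsplit(f, "/")[[1]], strsplit(m, "/")[[1]]))
  }, inh$fatherGT, inh$motherGT, SIMPLIFY = FALSE)
  ok <- mapply(function(ch, par) all(ch %in% par),
    childAlleles, parentAlleles)
  expect_true(all(ok))
  # exactly one parent carries each inherited allele
  expect_true(all(xor(inh$fatherGT == "0/0", inh$motherGT == "0/0")))
})

test_that("candidate extraction recovers exactly the planted truth", {
  cfg <- tinyConfig(seed = 31L, spuriousRate = 0.2)
  trio <- generateTrio(cfg, generateReference(cfg))
  cand <- extractCandidateDnsnvs(trio$callset)
  planted <- trio$truth$key[trio$truth$origin %in% c("denovo", "spurious")]
  expect_setequal(variantKeys(cand), planted)
  # no inherited leakage
  expect_length(
    intersect(variantKeys(cand),
      trio$truth$key[trio$truth$origin == "inherited"]), 0)
})

test_that("planted transition fraction is recovered within binomial bounds", {
  cfg <- syntheticTrioConfig(seed = 37L)   # defaults: 300 de novo, ti 2/3
  trio <- generateTrio(cfg, generateReference(cfg))
  den <- trio$truth[trio$truth$origin == "denovo", ]
  expect_equal(nrow(den), 300L)
  obs <- mean(den$substClass == "transition")
  tol <- 2.576 * sqrt((2 / 3) * (1 / 3) / 300)
  expect_lt(abs(obs - 2 / 3), tol)
  # truth labels agree with the classifier applied to the callset
  rec <- records(trio$callset)
  key <- paste(rec$chrom, rec$pos, sep = ":")
  tkey <- paste(trio$truth$chrom, trio$truth$pos, sep = ":")
  expect_equal(classifySubstitution(rec$ref, rec$alt),
    trio$truth$substClass[match(key, tkey)])
})

test_that("segment GC is recovered from the planted variants' windows", {
  cfg <- syntheticTrioConfig(seed = 41L)
  ref <- generateReference(cfg)
  trio <- generateTrio(cfg, ref)
  truth <- trio$truth
  gcObs <- gcContent(ref, truth$chrom, truth$pos)
  for (target in unique(truth$segmentGC)) {
    inSeg <- truth$segmentGC == target & !is.na(gcObs)
    n <- sum(inSeg)
    est <- mean(gcObs[inSeg]) / 100
    # window-level variance p(1-p)/100, averaged over n windows
    se <- sqrt(target * (1 - target) / 100 / n)
    expect_lt(abs(est - target), 4 * se)
  }
})

test_that("the depth filter keeps true de novos and the quotient reading
           separates them from spurious candidates", {
  cfg <- syntheticTrioConfig(seed = 43L)  # depth 30, error 0.01
  trio <- generateTrio(cfg, generateReference(cfg))
  cand <- extractCandidateDnsnvs(trio$callset)
  truthOrigin <- trio$truth$origin[match(variantKeys(cand), trio$truth$key)]

  keptProd <- applyFilter(cand, 0)
  trueKeys <- variantKeys(cand)[truthOrigin == "denovo"]
  retention <- mean(trueKeys %in% variantKeys(keptProd))
  expect_gte(retention, 0.9)

  scored <- records(scoreCallSet(cand, grouping = "quotient"))
  sTrue <- scored$score[truthOrigin == "denovo"]
  sSpur <- scored$score[truthOrigin == "spurious"]
  expect_gt(mean(sTrue, na.rm = TRUE), mean(sSpur, na.rm = TRUE))
  # spurious candidates centre on quotient score 0 (their child depths are
  # as reference-skewed as the parents'), so the score-0 cut removes a
  # large share of them, while the product reading keeps almost all
  spurKeys <- variantKeys(cand)[truthOrigin == "spurious"]
  keptQ <- applyFilter(cand, 0, grouping = "quotient")
  rejQ <- mean(!spurKeys %in% variantKeys(keptQ))
  rejP <- mean(!spurKeys %in% variantKeys(keptProd))
  expect_gt(rejQ, 0.25)
  expect_gt(rejQ, rejP + 0.2)
})

test_that("requesting more variants than positions fails loudly", {
  cfg <- tinyConfig(nInherited = 50000L)
  expect_error(generateTrio(cfg, generateReference(cfg)), "available")
})
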