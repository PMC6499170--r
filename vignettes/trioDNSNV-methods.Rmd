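---
title: "Methods: evaluating and refining trio de novo SNV calls"
author: "trioDNSNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating and refining trio de novo SNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioDNSNV)
```

## The problem

A de novo single-nucleotide variant (DNSNV) is a single-base change
present in a child's germline but absent from both parents.  Germline
DNSNVs occur at roughly 1–3 × 10⁻⁸ per site per generation, so even a
clean exome yields only a few dozen true events while trio calling
pipelines nominate hundreds to thousands of candidates; the excess is
sequencing, alignment and genotyping noise.  `trioDNSNV` implements the
evaluation layer downstream of any trio caller: uniform candidate
extraction, sequence-context characterisation, a read-coverage score
for refinement, and cross-pipeline comparison.  The scope is
deliberately the same as the evaluation it models: biallelic SNVs on
the autosomes only — indels, multi-allelic sites and chromosomes X/Y
are excluded at ingestion (multi-allelic sites are skipped rather than
split, because allele-depth pairs become ambiguous once more than one
alternate allele is in play).

## Candidate extraction

A candidate DNSNV is a record whose called genotypes satisfy the
Mendelian-violation pattern for a novel allele: father 0/0, mother 0/0,
child 0/1 or 1/1.  Trio callers each apply their own internal
definition; re-deriving the pattern uniformly from the emitted GT
fields makes call sets from different pipelines comparable.  Child
1/1 calls are biologically implausible as true de novos (they would
require the same mutation on both haplotypes) but are admitted and
flagged in a `childHomAlt` column so users can exclude them; records
with a missing genotype in any role are excluded and tallied in the
object's skip log.  Positions are 1-based VCF coordinates throughout;
chromosome labels accept both the "chr1" and "1" dialects and are
stored unprefixed, sorted numerically.

## Sequence-context metrics

**Window geometry.** Both context metrics use a 100-base reference
window "centred" on the variant.  An even-length window cannot be
exactly centred; the package fixes `[pos − 50, pos + 49]` (1-based,
inclusive), which contains the variant base itself.  The window length
is a parameter (`window`, even and positive, default 100 bp).

**GC content** is the count of G or C bases in the window × 100 / 100,
i.e. a percentage that is always a whole number at the default window.
Windows that overrun a contig end, or that contain any N, yield a
missing value rather than a rescaled one: the denominator is fixed by
definition, and silently rescaling edge windows would bias the GC
distribution exactly where coverage artefacts already concentrate.
The G+C count is invariant under reverse complementation, which the
test suite asserts per window.

**SNV density** is the number of called SNV positions inside the same
window, again × 100 / 100.  The source set defaults to the *full* SNV
call set of the same sample and pipeline (inherited plus de novo), the
most inclusive reading, and is configurable via `snvPositions`; the
focal variant counts itself when present.  A dense window signals a
locally noisy alignment, so low density is the desirable regime.

**Substitution classes.** A transition swaps purine for purine (A↔G)
or pyrimidine for pyrimidine (C↔T); the eight remaining ordered pairs
are transversions.  Classification uses the purine/pyrimidine rule
directly, which is total and symmetric.  The Ti/Tv ratio of a call set
is the standard quality proxy — true variant sets sit near 2 for
exomes, while random errors would push it toward the 4/8 = 0.5 of the
uniform substitution space.  Ratios are kept at full precision
internally and rounded to 2 decimals for display, percentages to whole
numbers; a set with zero transversions has an undefined (NA) ratio.
GC stratification partitions annotated records at a threshold
(default 50 %), with the boundary value going to the high stratum and
missing-GC records reported separately.

## The read-coverage score

At a true de novo site the parents' reads should be cleanly reference
(large |F~ref~ − F~alt~| and |M~ref~ − M~alt~|) while the child carries
genuine alternate support.  The score condenses the six depths into

$$\mathrm{score} = \log_{10}\!\Big(\frac{|F_{ref}-F_{alt}| + |M_{ref}-M_{alt}|}{2} \times |S_{alt}-S_{ref}|\Big)$$

The grouping of the mean parental separation against the child
separation is a genuine design fork — the defining expression can be
read as a product or as a quotient
$\log_{10}\big((|F_{ref}-F_{alt}|+|M_{ref}-M_{alt}|)/(2\,|S_{alt}-S_{ref}|)\big)$
— and the two behave differently:

* the **product** (the default) increases with both separations, which
  matches the stated intent of rewarding strong coverage signal in both
  generations, and is the reading under which the score is monotone in
  each separation (a tested invariant);
* the **quotient** rewards clean parents *relative to* a depth-balanced
  child.  A heterozygous child has S~alt~ ≈ S~ref~, so true de novos get
  small denominators and high scores, whereas a genotype-error
  candidate whose child is really homozygous reference has a child
  separation as large as a parent's, pinning its score near 0.  Under
  the package's own generative model (below) the quotient is the
  reading that separates true from spurious candidates: the product
  assigns spurious records *higher* scores than true hets, because
  |S~alt~ − S~ref~| is maximal precisely when the child has no real
  alternate support.

Both readings are first-class (`grouping = "product"` / `"quotient"`);
the product is the default and the vignette's retention figures use it.
The base is 10, which places typical exome depths (tens of reads) in a
convenient −3…+3 cutoff range.  The score is undefined exactly when the
child separation or the mean parental separation is zero, or when any
depth is missing; undefined records carry machine-readable reason codes
and never pass any finite cutoff.  Filtering keeps records with score
*strictly* greater than the cutoff (default 0, the non-stringent
choice, so a score of exactly 0 is removed); kept sets are nested
across cutoffs and filtering is idempotent.  Ranking is by descending
score, undefined last, ties broken by genomic coordinate for
determinism.

## Call-set comparison

Records are matched across pipelines on the exact
(chrom, pos, ref, alt) key — position-only matching would count
discordant alleles as agreement.  The report covers every Venn region
for 2–3 sets, pairwise overlaps, the common count, per-autosome counts
(all 22, zeros included) and, when a catalog of known variants is
supplied, the overlap rate 100 × |hits| / |set| per set.  The catalog
is any user-supplied VCF or key list; no allele-frequency notion of
"common" variants is modelled.  GQ summaries report the five-number
summary and mean per role over non-missing values, with missing GQ
counted but never imputed (GQ is an evaluation metric here, not a
filter input).  A packaged fixture,
`inst/extdata/aj_trio_consensus22.vcf`, encodes the 22 consensus de
novo SNVs reported concordantly by GATK, RTG and VarScan on the GIAB
Ashkenazi trio exomes; its genotype fields are synthetic placeholders
(stated in the file header) and its record order follows the published
listing, including one out-of-order chromosome-5 row, which the reader
sorts.

## The synthetic trio generator

Real trio BAMs and external callers are out of scope, so the generator
produces the *downstream products* those would yield, with ground
truth.  The default configuration is one fixed study design, not a
tuning surface:

| parameter | default | rationale |
|---|---|---|
| `nChrom` × `chromLength` | 2 × 500 kb | two autosomes exercise cross-chromosome logic at desk scale |
| `gcSegments` | half 40 %, half 60 % GC | mirrors the low/high GC regimes over which caller behaviour differs |
| `nInherited` | 2000 | realistic dominance of inherited over de novo variation |
| `nDenovo` | 300 | large enough for binomial recovery bounds, small enough for seconds-scale tests |
| `tiFraction` | 2/3 | Ti/Tv = 2, the accepted genome-wide value for true variants |
| `meanDepth` | 30 | standard exome coverage |
| `seqError` | 0.01 | typical per-read error |
| `spuriousRate` | 0.2 | a fifth of candidates are genotype-error false positives |
| `gqMargin` | 30 | spurious child GQ drawn 80–99 minus 30, separating the GQ distributions |

Bases are drawn independently per segment with P(G or C) equal to the
target GC.  Inherited variants give one random parent a het or hom
genotype (equal odds) and transmit to the child by Mendelian sampling;
de novos are parents 0/0, child 0/1; spurious records are truly 0/0 in
the child but *emitted* as 0/1.  Depths follow the standard sequencing
toy model — depth ~ Poisson(`meanDepth`), alternate reads ~
Binomial(depth, vaf) with vaf = `seqError`, 0.5, 1 − `seqError` for
genotypes 0/0, 0/1, 1/1 — so the score's inputs have realistic
magnitudes.  GQ is synthesised directly (the package does not model
genotype likelihoods), with the spurious child lowered by the additive
`gqMargin`.  A single config seed drives everything: the reference uses
`seed`, the trio `seed + 1`, and repeated runs are byte-identical on
disk.

**What the generator does not emulate:** read-level artefacts (mapping
bias, strand bias, GC-dependent coverage), indels, multi-allelic sites,
linkage between neighbouring variants, and caller-specific genotyping
behaviour.  Passing parameter-recovery tests therefore demonstrates
the correctness of the package's arithmetic and contracts under the
stated model — not that any particular cutoff will achieve the same
retention on real data.

## What the model predicts for the filter

Under the defaults, a true de novo child is het at depth ~30, so its
separation |S~alt~ − S~ref~| = |2·Binom(30, ½) − 30| is small but zero
only when the draw is exactly balanced (probability ≈ 0.145 at even
depth, ≈ 0.07 after mixing over Poisson depths).  With parental
separations near 30, the product score exceeds 0 whenever the child
separation is at least 1, so expected retention of true de novos at
cutoff 0 is ≈ 93 %; the suite asserts ≥ 90 % at the study size of 300.
For spurious candidates the quotient score is
log₁₀(parental sum / (2 × child separation)) with numerator and
denominator both concentrated near 2 × depth, i.e. a distribution
centred on 0: roughly half of spurious records fall below any score-0
cut.  The suite therefore asserts the stable directional facts — true
candidates outscore spurious ones on average under the quotient, and
the quotient rejects far more spurious records than the product —
rather than a knife-edge "more than half" count.

## Numerical and degenerate-input choices

* Depths are non-negative integers from the VCF AD pair; a missing AD
  leaves the record present but unscorable (reason `missing_depth`).
* Duplicate (chrom, pos, ref, alt) keys are an error at construction
  and deduplicated (with a skip-log count) at VCF ingestion.
* Empty call sets flow through every operation: Ti/Tv 0/0 with NA
  ratio, 22 zero counts, all-missing GQ summaries; only the
  catalog-overlap rate refuses an empty set, since 0/0 has no sensible
  percentage.
* The density cumulative distribution uses strict "< edge" counting
  and requires strictly increasing edges.
* Cutoff sweeps require non-decreasing cutoffs; duplicate cutoffs are
  allowed and yield equal adjacent counts.
* Report JSON serialises at full precision; rounding (ratios 2 dp,
  percentages integer, VCF DNSCORE 3 dp) is display-only.

## Problem sizes

The test suite runs tiny instances (20 kb single-chromosome configs,
100–600 record call sets) for oracle comparisons and the full default
study (1 Mb, 2 375 variants) for parameter recovery; the whole suite
completes in about a minute, and `scripts/acceptance.R` regenerates the
default study in a few seconds.

## Known limitations

* Depths come from VCF AD fields as emitted by each caller; no pileup
  recomputation or realignment is attempted, so caller-specific AD
  conventions propagate into scores.
* The filter is a point score without a confidence index or p-value;
  extending it would require modelling read mappability and depth
  confidence, which is out of scope.
* GQ handling is purely descriptive.
* The comparison layer reports counts and rates, not rendered Venn or
  bar figures.
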