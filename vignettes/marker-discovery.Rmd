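---
title: "Mining SSR, SNP and CAPS markers from EST unigene assemblies"
author: "estmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SSR, SNP and CAPS markers from EST unigene assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estmarker)
```

## The problem

Expressed sequence tag (EST) collections assembled into unigenes — one
consensus transcript per non-redundant gene — are the cheapest substrate for
molecular-marker discovery in crops without a reference genome. When the
reads come from two contrasting inbred cultivars, the same assembly yields
three marker classes at once:

* **SSRs** (microsatellites): tandem repeats of 2–4 bp units, genotypable by
  fragment size;
* **SNPs/INDELs** between the two cultivars, suitable for high-throughput
  array genotyping if their flanking sequence is clean; and
* **CAPS** markers: the subset of SNPs where one allele creates or destroys
  a restriction site, scorable on an agarose gel.

`estmarker` implements the computational side of this design: repeat
scanning with ORF-aware localization, quality-filtered variant calling from
per-position read evidence of the two genotypes, a marker-selection filter
cascade, restriction-site screening, codon-usage statistics over
full-length ORFs, and the standard summary tables. A synthetic-data
generator with a planted, fully recomputable ground truth makes every stage
testable without the original sequencing data.

## Coordinate conventions

All internal coordinates are 0-based with half-open intervals. The two
1-based, closed-interval file formats (GFF3 and VCF) are converted exactly
once, at read/write time. Keeping a single internal convention is the
cheapest way to avoid off-by-one drift between modules; the format
round-trip tests pin the conversions down.

## SSR mining

`find_ssrs()` reports every *maximal perfect* tandem run of a
non-degenerate unit of length 2, 3 or 4 that has

* at least `min_units = 4` complete units, and
* total length at least `min_total_length = 17` bp.

A run may end mid-unit; the fractional tail counts toward total length but
not toward the unit count (so `(AG)8 A` is a 17 bp locus of 8.5 units).
Runs are broken at `N`. Mismatch-tolerant (interrupted) repeats are
deliberately out of scope: the operative selection criteria in the targeted
study design are the unit lengths, the "at least four repeats" rule and the
observed 17 bp length floor, and a perfect-repeat definition makes the
scanner exactly checkable against a brute-force oracle. Both knobs are
configurable through `ssr_params()`.

Repeat units are normalized with `canonical_motif()`: the lexicographic
minimum over all cyclic rotations of the unit and of its reverse
complement, so `GA`, `TC` and `CT` all report as `AG`. Units that are
powers of a shorter unit (`ACAC`) are rejected to keep the di/tri/tetra
classes disjoint.

Overlapping candidate loci of different unit lengths are resolved by a
deterministic rule — the longer locus wins, ties go to the shorter unit,
then leftmost. Some rule is needed for reproducibility and none is imposed
by the underlying biology; this one favours the stronger repeat signal.

Each locus is classified against the unigene's ORF as `FIVE_UTR`, `ORF`,
`THREE_UTR`, or `OTHER` (boundary-straddling loci and loci on unigenes
without an ORF). For minus-strand ORFs the UTR labels follow coding
orientation.

## Variant calling

The evidence model is a per-position observation table: one row per read
base per unigene position, with genotype label, allele (a base, `-` for a
single-base deletion, `+SEQ` for an insertion), phred base quality and
mapping quality. This is the minimal sufficient statistic the caller needs;
read mapping itself is out of scope.

Calling (`call_snvs()`) proceeds per position:

1. discard observations with mapping quality below 20;
2. per allele, pooled over both genotypes, compute the read count and the
   accumulated (summed) base quality;
3. an allele *qualifies* when count ≥ 2 and accumulated quality ≥ 40;
4. a position is a variant when ≥ 2 alleles qualify. It is an
   INSERTION/DELETION if any qualifying allele is an INDEL token, else a
   SNP.

The numeric thresholds are package defaults (all configurable via
`snv_call_params()`): two independent reads with ordinary qualities
(2 × q20 = 40) are the weakest evidence that cannot be produced by a single
sequencing error, which suits pyrosequencing-style error profiles while
keeping small test datasets sharp. No cap is applied when accumulating
per-allele quality.

The same thresholds are applied *within* each genotype to decide which
alleles that genotype itself supports. This matters for the
within-genotype-variability filters below: a single stray error read in one
genotype must not mark a site as internally variable, so per-genotype
variability requires the same two-read, 40-quality support. A genotype with
zero surviving observations at the position is recorded as unsequenced
there.

## The filter cascade

`apply_filters()` annotates (never removes) each variant with tags; the
marker sets are then cut by tag pattern with `select_candidates()`:

| tag | meaning |
|-----|---------|
| `VKS` | not a SNP (an INDEL) |
| `HVR4` | unigene has more than 4 SNVs per 100 bp |
| `CS60` | another SNV closer than 60 bp |
| `I60` | intron junction closer than 60 bp |
| `CL60` | sequence end closer than 60 bp |
| `NVSM1` | second genotype variable at the site, or unsequenced |
| `NVSM2` | first genotype variable at the site, or unsequenced |
| `CEF` | no enzyme gains/loses a site spanning the SNP (not CAPS-scorable) |

All distances are strict (`<`), centre-to-centre, in unigene coordinates.
The hypervariability rule is applied at whole-unigene level (total count ×
100 / length), which is the natural reading of "sequences with more than 4
SNVs per 100 bases"; a sliding-window variant is available through
`filter_params(hv_window = ...)` for users who prefer a local definition.
Tagging is idempotent and order-independent, and `annotate_cef()` may run
before or after the cascade.

The high-throughput genotyping ("Golden Gate") candidate set keeps variants
whose tag set is empty or exactly `{CEF}` — clean SNPs regardless of CAPS
scorability; the CAPS candidate set keeps variants with no tags at all, and
is by construction a subset of the former.

Multi-allelic SNPs are retained; for spectrum reporting each segregating
allele pair counts once. Discarding them would silently hide information,
and nothing downstream requires biallelism except CAPS evaluation, which
refuses non-biallelic input explicitly.

## CAPS screening

For each biallelic SNP, `caps_evaluate()` builds the two allele sequences
of a window (default 60 bp each side, matching the cascade's 60 bp
flank-cleanliness logic) and asks, per enzyme, whether the set of
recognition-site matches *overlapping the SNP position* differs between
alleles. Only SNP-spanning sites count, so a distant site shared by both
alleles cannot mask detectability; the full-window fragment patterns are
reported anyway so users can judge resolvability on a gel. No uniqueness
requirement is imposed on other sites in the window.

Site matching expands IUPAC codes and covers both strands (palindromic
sites counted once). The built-in panel holds 24 common 4–6 bp cutters and
is user-extensible via a TSV (`read_enzymes()`); a panel is a modelling
input, not a constant of nature, so it is deliberately easy to replace.
For enzymes that cut outside their recognition site the top-strand cut
offset is applied on both strands; cut positions falling outside the window
are ignored, so fragment lengths always sum to the window length.

## Codon usage

`build_codon_table()` counts all 64 codons, including each ORF's single
terminal stop, over ORFs that pass `validate_full_orf()` (starts `ATG`,
ends with a stop, length a multiple of 3, no internal stop — the mechanical
stand-in for manual frameshift screening). `gc3()` reports third-position
G+C over non-stop codons by default (stop codons are constrained in their
third position and would bias the statistic; a switch includes them).
`xcg_xcc_ratio()` is the CpG-suppression measure: codons ending in `CG`
over codons ending in `CC`. `stop_usage()` reports the stop-codon
preference over ORFs.

## The synthetic-data generator

`gen_unigenes()` + `gen_read_observations()` emulate the two-genotype EST
design with a planted truth. Defaults are fixed once to the study
conditions the package targets:

| parameter | default | rationale |
|-----------|---------|-----------|
| `length_mean`/`length_sd` | 626 / 250 bp | observed unigene length scale |
| `orf_fraction` | 0.96 | share of unigenes with one predicted ORF |
| `intron_rate` | 0.35 | introns detected in about a third of unigenes |
| `ts_tv_ratio` | 2.1 | observed ~68:32 transition bias |
| `indel_fraction` | 0.055 | ~1,200 INDELs per ~21,000 variants |
| `within_genotype_het_rate` | 0.55 | ~55% of variants within-genotype variable |
| `snv_rate` | 0.7 / kb | ~21,000 variants over ~31 Mbp |
| `gc_content` | 0.43 | typical dicot transcriptome |
| `coverage_mean` | 10 / genotype | desk-scale depth at which calling is well-posed |
| `base_error_rate` | 0.005 | pyrosequencing-scale miscall rate |
| `base_quality_mean`, `mapq_mean` | 30, 40 | ordinary phred scales |

Generated ORFs always translate cleanly; planted SSRs are exact repeats
overwritten into the requested region, with both flanking bases adjusted so
the planted run is maximal (inside ORFs only trinucleotide motifs are
allowed, placed at codon boundaries, and flank adjustments never create a
stop codon). Planted variants avoid planted repeats; the second genotype
carries the alternative allele; within-genotype-variable sites emit both
alleles as a deterministic near-50/50 split of the drawn depth, which keeps
the zero-noise recovery property exact rather than merely probable.

The truth set records, for every planted variant, the filter tags
*recomputable from planted geometry alone* (edge/intron/cluster distances,
density, within-genotype status, INDEL-ness) under the default
`filter_params()`. `CEF` is excluded from truth: it depends on the enzyme
panel, not on geometry.

What the generator does **not** emulate: homopolymer-specific
pyrosequencing errors, chimeric reads, alignment artefacts around true
INDELs, paralog collapse (the main real-world source of false
within-genotype variability), and expression-level coverage heterogeneity.
Passing recovery tests therefore demonstrate the correctness of the
scanning, calling, tagging and reporting logic — not robustness to
assembly or mapping pathology, which is upstream of this package's scope.

Determinism: each generator function seeds R's RNG from `seed` (the
read-evidence stage from `seed + 1`), so a config reproduces its dataset
byte-for-byte, independent of call order.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen once: scanner-vs-oracle
equivalence on 1,000 random 1 kb sequences; CAPS-vs-digestion-oracle
equivalence on 500 random SNP windows against the full panel; zero-noise
recovery on a 200-unigene dataset at 20× per-genotype coverage (the
recovery property is guaranteed for coverage comfortably above twice the
per-allele read minimum; at 20× the probability of an under-covered site is
negligible). Published summary percentages are reconstructed from their
published input counts, since the original read set and assembly are not
inputs to this package.

## Numerical and degenerate-input choices

* Percent rounding follows the precision of the table being reproduced
  (one decimal for class shares, integers for the spectrum); all table
  writers take a precision argument.
* Empty inputs return empty tables rather than dividing by zero;
  undefined statistics (GC3 of a stop-only table, XCG/XCC with no `NCC`
  codons, stop usage of no ORFs) raise errors rather than returning `NaN`.
* The VCF writer emits `.`— not `PASS` — for untagged records, and joins
  tags in a fixed cascade order, so output is byte-stable. Insertions are
  written as anchored ALT alleles, deletions as the symbolic `<DEL>`; the
  bespoke allele tokens travel in `INFO` so a round-trip is exact.
* GFF3 ORF features: when several are annotated on one unigene the longest
  wins, ties to the leftmost.

## Known limitations

* Perfect repeats only; compound/interrupted SSRs are reported as separate
  loci if each passes thresholds.
* The caller treats the cultivars as inbred lines (no diploid genotype
  likelihoods), as the two-genotype EST design assumes.
* CAPS fragment patterns use the top-strand cut offset for both strands;
  for the panel's orthodox palindromic cutters this is exact, for
  offset-cutters the fragment lengths (not the hit decision) may shift by
  a few bp on reverse-strand sites.
* EST-per-unigene means require an external read-count table, since
  assembly is out of scope.
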