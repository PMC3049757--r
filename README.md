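# estmarker

Molecular-marker discovery from EST unigene assemblies of two inbred
genotypes: microsatellites (SSRs), SNPs/INDELs with a marker-selection
filter cascade, CAPS-detectable SNPs, and codon-usage statistics.

## What it does

Marker development from an expressed-sequence-tag (EST) collection starts
from assembled *unigenes* — one consensus transcript per non-redundant
gene — sequenced in two contrasting cultivars. From a unigene FASTA, an
ORF/intron GFF3, and a per-position read-observation table, the package:

* **SSRs** — finds maximal perfect tandem repeats of 2–4 bp units with
  ≥ 4 complete units and ≥ 17 bp total, normalizes motifs to the
  lexicographic minimum over rotations and reverse complements (`GA`,
  `TC`, `CT` → `AG`), and localizes each locus as 5'UTR / ORF / 3'UTR.
* **SNVs** — at each position, an allele qualifies when it has ≥ 2 reads
  with accumulated phred quality ≥ 40 (after a mapping-quality ≥ 20 cut);
  positions with ≥ 2 qualifying alleles are variants. Each variant is
  annotated with the filter cascade
  `VKS` (INDEL), `HVR4` (> 4 SNVs / 100 bp), `CS60` / `I60` / `CL60`
  (closer than 60 bp to another SNV / an intron / the sequence end),
  `NVSM1` / `NVSM2` (variable or unsequenced within a genotype), and
  `CEF` (no allele-specific restriction site). Variants whose tag set is
  empty or `{CEF}` are clean candidates for multiplexed genotyping; the
  untagged ones are additionally CAPS-scorable.
* **CAPS** — for each biallelic SNP, tests whether any enzyme in a
  24-enzyme (extensible) panel gains or loses a recognition site spanning
  the SNP between the two allele sequences, and reports per-allele
  digestion fragment patterns.
* **Codon usage** — codon-count tables over full-length ORFs, GC3
  (third-position G+C), the CpG-suppression ratio XCG/XCC, and stop-codon
  usage.
* **Reporting** — class/motif/localization tables for SSRs, the
  transition/transversion spectrum, filter attrition and variant-density
  summaries.
* **Synthetic data** — a generator for the whole design (unigene set,
  planted SSRs/SNVs, two-genotype read evidence) with a recomputable
  ground truth, used by the test suite for exact recovery checks.

File formats: FASTA and GFF3 in and out, VCF 4.0 out (and back in), plus a
documented tab-separated read-observation table and YAML configuration.
All coordinates are 0-based half-open internally; GFF3/VCF conversion
happens only at file boundaries.

## Worked example

```r
library(estmarker)

cfg <- simulation_config(
  n_unigenes = 30, coverage_mean = 15, base_error_rate = 0.002,
  ssr_plant_spec = list(
    list(motif = "AG",  units = 10, region = "THREE_UTR"),
    list(motif = "AAG", units = 8,  region = "ORF")),
  seed = 42)
gen <- gen_unigenes(cfg)
obs <- gen_read_observations(gen$unigenes, gen$truth, cfg)

ssrs <- mine_ssrs(gen$unigenes)
ssrs[, c("unigene_id", "start", "end", "motif_canonical", "n_units",
         "location")]
#>   unigene_id start end motif_canonical n_units  location
#> 1    UN00012   198 218              AG      10 THREE_UTR
#> 2    UN00015   106 130             AAG       8       ORF

snvs <- call_snvs(obs, gen$unigenes)
snvs <- apply_filters(snvs, gen$unigenes)
snvs <- annotate_cef(snvs, gen$unigenes)
head(snvs[, c("unigene_id", "pos", "kind", "ref", "alleles", "filters")])
#>   unigene_id pos kind ref alleles        filters
#> 1    UN00005 137  SNP   T     C,T      NVSM1;CEF
#> 2    UN00007 423  SNP   G     C,G      NVSM1;CEF
#> 3    UN00008  39  SNP   T     A,T CL60;NVSM1;CEF
#> 4    UN00008 304  SNP   T     C,T       CS60;CEF
#> 5    UN00008 358  SNP   T     C,T     CS60;NVSM2
#> 6    UN00009 316  SNP   A     A,G       CS60;CEF

sel <- select_candidates(snvs)
c(golden_gate = nrow(sel$golden_gate), caps = nrow(sel$caps))
#> golden_gate        caps
#>           4           2

tab <- build_codon_table(extract_full_orfs(gen$unigenes))
c(orfs = tab$n_orfs, codons = tab$n_codons)
#>   orfs codons
#>     30   3320
round(c(gc3 = gc3(tab), xcg_xcc = xcg_xcc_ratio(tab)), 2)
#>     gc3 xcg_xcc
#>    0.45    0.93
```

Both planted SSRs come back at their exact planted coordinates with their
canonical motifs and region labels. Of 24 called variants, four carry no
tag other than `CEF` (clean genotyping candidates) and two carry no tag at
all (also CAPS-scorable). The filter strings read directly as reasons for
exclusion: e.g. `CL60;NVSM1;CEF` is a SNP too close to the sequence end,
variable (or unsequenced) in the second genotype, and not scorable as a
CAPS. `write_vcf()` exports the table with these tags in the FILTER
column, with `.` marking untagged records.

A thin command-line front end over the same functions ships in
`inst/scripts/estmarker` (subcommands `simulate`, `find-ssrs`,
`call-snvs`, `find-caps`, `codon-usage`, `report`).

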