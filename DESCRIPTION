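Package: estmarker
Title: SSR, SNP and CAPS Marker Discovery from EST Unigene Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining molecular markers from assembled expressed
    sequence tag (EST) unigenes of two inbred genotypes. Detects di-, tri-
    and tetra-nucleotide microsatellites (SSRs) with canonical motif
    normalization and ORF/UTR localization; calls single nucleotide variants
    and short INDELs from per-position read evidence with quality-aware
    allele filtering and annotates them with a marker-selection filter
    cascade (VKS, HVR4, CS60, I60, CL60, NVSM1, NVSM2, CEF); screens
    candidate SNPs for allele-specific restriction sites (CAPS); computes
    codon-usage statistics (GC3, CpG suppression, stop-codon usage) from
    full-length ORFs; and summarizes marker sets as the standard class,
    localization, substitution-spectrum and filter-attrition tables. A
    synthetic-data generator with a planted ground truth supports end-to-end
    validation of every stage. Reads and writes FASTA, GFF3 and VCF 4.0.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
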