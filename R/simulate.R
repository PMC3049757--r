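#' Simulation configuration for the two-genotype EST design
#'
#' Describes a synthetic unigene collection and the read evidence of two
#' inbred genotypes over it. Defaults mirror the sequencing design the
#' package targets: unigene lengths around 626 bp, 96% of unigenes with a
#' single ORF, introns spliced out in about a third of them, a
#' transition-biased variant spectrum (ts:tv odds 2.1, about 68:32), a
#' small INDEL fraction, and a little over half of variant sites additionally
#' variable within one genotype. Coverage, error and quality defaults are
#' desk-scale choices documented in the package vignette.
#'
#' @param n_unigenes Number of unigenes.
#' @param length_mean,length_sd Unigene length distribution (bp).
#' @param gc_content Background GC fraction.
#' @param orf_fraction Fraction of unigenes given an ORF.
#' @param intron_rate Expected intron junctions per unigene (Poisson).
#' @param ssr_plant_spec List of `list(motif, units, region)` entries, each
#'   planting one perfect repeat in one unigene; `region` is `"FIVE_UTR"`,
#'   `"ORF"` or `"THREE_UTR"`. Only trinucleotide motifs may be planted in
#'   ORFs (reading-frame protection).
#' @param snv_rate Planted between-genotype variants per kb.
#' @param ts_tv_ratio Transition:transversion odds for planted SNPs.
#' @param indel_fraction Fraction of planted variants that are INDELs.
#' @param within_genotype_het_rate Fraction of variant sites additionally
#'   made variable inside one (randomly chosen) genotype.
#' @param coverage_mean Mean reads per position per genotype (Poisson).
#' @param base_error_rate Per-base miscall probability.
#' @param base_quality_mean Mean phred base quality.
#' @param mapq_mean Mean phred mapping quality.
#' @param genotypes Ordered pair of genotype labels.
#' @param seed RNG seed; fixes the full output.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_unigenes = 50L,
                              length_mean = 626, length_sd = 250,
                              gc_content = 0.43,
                              orf_fraction = 0.96,
                              intron_rate = 0.35,
                              ssr_plant_spec = list(),
                              snv_rate = 0.7,
                              ts_tv_ratio = 2.1,
                              indel_fraction = 0.055,
                              within_genotype_het_rate = 0.55,
                              coverage_mean = 10,
                              base_error_rate = 0.005,
                              base_quality_mean = 30,
                              mapq_mean = 40,
                              genotypes = c("MU16", "UPV196"),
                              seed = 1L) {
  fracs <- c(gc_content = gc_content, orf_fraction = orf_fraction,
             indel_fraction = indel_fraction,
             within_genotype_het_rate = within_genotype_het_rate,
             base_error_rate = base_error_rate)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop(names(fracs)[bad][1], " must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_unigenes >= 1, length_mean > 0, length_sd >= 0,
            intron_rate >= 0, snv_rate >= 0, ts_tv_ratio > 0,
            coverage_mean >= 0, base_quality_mean >= 0, mapq_mean >= 0,
            length(genotypes) == 2L)
  for (sp in ssr_plant_spec) {
    stopifnot(!is.null(sp$motif), !is.null(sp$units), !is.null(sp$region))
    if (sp$region == "ORF" && nchar(sp$motif) != 3L) {
      stop("only trinucleotide motifs may be planted in ORFs ",
           "(reading-frame protection); got '", sp$motif, "'",
           call. = FALSE)
    }
    if (nchar(sp$motif) == 3L && toupper(sp$motif) %in% STOP_CODONS) {
      stop("motif '", sp$motif, "' is a stop codon and cannot be planted ",
           "in an ORF", call. = FALSE)
    }
  }
  structure(list(n_unigenes = as.integer(n_unigenes),
                 length_mean = length_mean, length_sd = length_sd,
                 gc_content = gc_content, orf_fraction = orf_fraction,
                 intron_rate = intron_rate,
                 ssr_plant_spec = ssr_plant_spec,
                 snv_rate = snv_rate, ts_tv_ratio = ts_tv_ratio,
                 indel_fraction = indel_fraction,
                 within_genotype_het_rate = within_genotype_het_rate,
                 coverage_mean = coverage_mean,
                 base_error_rate = base_error_rate,
                 base_quality_mean = base_quality_mean,
                 mapq_mean = mapq_mean,
                 genotypes = genotypes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

sample_background <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = base_probs(gc))
}

sample_sense_codons <- function(n, gc) {
  codons <- setdiff(all_codons(), STOP_CODONS)
  p <- base_probs(gc)
  w <- vapply(codons, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, 0)
  if (sum(w) == 0) w <- rep(1, length(codons))
  sample(codons, n, replace = TRUE, prob = w)
}

# stop-codon preferences typical of dicot transcriptomes
sample_stop <- function() {
  sample(STOP_CODONS, 1, prob = c(0.414, 0.175, 0.411))
}

# Replace chars[j + 1] (j is 0-based) so that the repeat of period p cannot
# extend across j. forbidden is the base that would continue the repeat.
# Inside an ORF body the replacement must not create a stop codon.
break_flank <- function(chars, j, forbidden, orf) {
  cands <- setdiff(BASES, forbidden)
  for (b in cands) {
    if (!is.null(orf) && j >= orf$start && j < orf$end) {
      cstart <- orf$start + 3L * ((j - orf$start) %/% 3L)
      codon <- chars[(cstart + 1L):(cstart + 3L)]
      codon[j - cstart + 1L] <- b
      if (paste(codon, collapse = "") %in% STOP_CODONS) next
    }
    chars[j + 1L] <- b
    return(chars)
  }
  chars # unreachable for 4-letter alphabet
}

#' Generate a synthetic unigene collection with planted truth
#'
#' Background sequence is i.i.d. with the configured GC content. ORFs start
#' with `ATG`, end with a stop, contain no internal stop and have length a
#' multiple of 3. Requested SSRs are overwritten into the chosen region of a
#' randomly selected eligible unigene (trinucleotide motifs at codon
#' boundaries when inside the ORF), with both flanking bases adjusted so the
#' planted repeat is maximal. Between-genotype variant sites are then drawn
#' along each unigene (avoiding planted repeats) with the configured
#' transition bias, INDEL fraction and within-genotype variability, and
#' their expected filter-cascade tags are derived from the planted geometry
#' (edge and intron distances, variant clustering and density,
#' within-genotype status) under the default [filter_params()].
#'
#' @param config A [simulation_config()].
#' @return `list(unigenes, truth)` where `truth` has elements `ssrs`
#'   (planted loci), `snvs` (planted variants with `expected_filters`), and
#'   the genotype labels.
#' @export
gen_unigenes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_unigenes
  ids <- sprintf("UN%05d", seq_len(n))

  seqs <- vector("list", n)
  orfs <- vector("list", n)
  introns <- vector("list", n)
  for (i in seq_len(n)) {
    L <- max(150L, as.integer(round(stats::rnorm(1, config$length_mean,
                                                 config$length_sd))))
    chars <- sample_background(L, config$gc_content)
    orf <- NULL
    if (stats::runif(1) < config$orf_fraction) {
      utr5 <- as.integer(round(L * stats::runif(1, 0.08, 0.20)))
      orf_len <- 3L * as.integer(L * stats::runif(1, 0.45, 0.65) / 3)
      orf_len <- max(9L, min(orf_len, 3L * ((L - utr5 - 30L) %/% 3L)))
      n_codons <- orf_len %/% 3L
      body <- if (n_codons > 2) {
        sample_sense_codons(n_codons - 2L, config$gc_content)
      } else {
        character(0)
      }
      orf_seq <- paste0("ATG", paste(body, collapse = ""), sample_stop())
      chars[(utr5 + 1L):(utr5 + orf_len)] <-
        strsplit(orf_seq, "")[[1]]
      orf <- list(start = utr5, end = utr5 + orf_len, strand = "+")
    }
    n_intr <- stats::rpois(1, config$intron_rate)
    introns[[i]] <- if (n_intr > 0) {
      sort(sample.int(L + 1L, min(n_intr, L + 1L)) - 1L)
    } else {
      integer(0)
    }
    seqs[[i]] <- chars
    orfs[i] <- list(orf)
  }

  # plant requested SSRs
  planted_ssrs <- list()
  occupied <- lapply(seq_len(n), function(i) {
    data.frame(start = integer(), end = integer())
  })
  for (sp in config$ssr_plant_spec) {
    motif <- toupper(sp$motif)
    p <- nchar(motif)
    rep_str <- strrep(motif, sp$units)
    rlen <- nchar(rep_str)
    placed <- FALSE
    for (i in sample(seq_len(n))) {
      orf <- orfs[[i]]
      L <- length(seqs[[i]])
      bounds <- switch(sp$region,
        FIVE_UTR = if (!is.null(orf)) c(0L, orf$start) else NULL,
        ORF = if (!is.null(orf)) c(orf$start + 3L, orf$end - 3L) else NULL,
        THREE_UTR = if (!is.null(orf)) c(orf$end, L) else NULL,
        OTHER = if (is.null(orf)) c(0L, L) else NULL)
      if (is.null(bounds)) next
      lo <- bounds[1] + 1L            # leave room for the left flank break
      hi <- bounds[2] - rlen - 1L     # and the right one
      if (hi < lo) next
      starts <- lo:hi
      if (sp$region == "ORF") {
        starts <- starts[(starts - orf$start) %% 3L == 0L]
      }
      occ <- occupied[[i]]
      if (nrow(occ)) {
        free <- vapply(starts, function(s0) {
          all(s0 + rlen <= occ$start | s0 >= occ$end)
        }, TRUE)
        starts <- starts[free]
      }
      if (!length(starts)) next
      s0 <- if (length(starts) == 1L) starts else sample(starts, 1)
      chars <- seqs[[i]]
      chars[(s0 + 1L):(s0 + rlen)] <- strsplit(rep_str, "")[[1]]
      chars <- break_flank(chars, s0 - 1L, chars[s0 - 1L + p + 1L], orf)
      chars <- break_flank(chars, s0 + rlen, chars[s0 + rlen - p + 1L], orf)
      seqs[[i]] <- chars
      occupied[[i]] <- rbind(occ, data.frame(start = s0 - 1L,
                                             end = s0 + rlen + 1L))
      planted_ssrs[[length(planted_ssrs) + 1L]] <- data.frame(
        unigene_id = ids[i], start = s0, end = s0 + rlen,
        motif = canonical_motif(motif), motif_planted = motif,
        unit_length = p, n_units = sp$units, total_length = rlen,
        region = sp$region, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place planted SSR (", motif, " x ", sp$units,
           " in ", sp$region, "): no eligible unigene", call. = FALSE)
    }
  }
  truth_ssrs <- if (length(planted_ssrs)) {
    do.call(rbind, planted_ssrs)
  } else {
    data.frame(unigene_id = character(), start = integer(), end = integer(),
               motif = character(), motif_planted = character(),
               unit_length = integer(), n_units = numeric(),
               total_length = integer(), region = character(),
               stringsAsFactors = FALSE)
  }

  # plant between-genotype variants
  p_ts <- config$ts_tv_ratio / (1 + config$ts_tv_ratio)
  snv_rows <- list()
  for (i in seq_len(n)) {
    L <- length(seqs[[i]])
    n_snv <- stats::rpois(1, L * config$snv_rate / 1000)
    if (n_snv == 0) next
    allowed <- setdiff(seq_len(L) - 1L, unlist(lapply(
      seq_len(nrow(occupied[[i]])), function(k) {
        occupied[[i]]$start[k]:(occupied[[i]]$end[k] - 1L)
      })))
    if (!length(allowed)) next
    pos <- sort(sample(allowed, min(n_snv, length(allowed))))
    for (p0 in pos) {
      ref <- seqs[[i]][p0 + 1L]
      is_indel <- stats::runif(1) < config$indel_fraction
      if (is_indel) {
        alt <- if (stats::runif(1) < 0.5) {
          "-"
        } else {
          paste0("+", paste(sample(BASES, sample(1:3, 1), replace = TRUE),
                            collapse = ""))
        }
        kind <- if (alt == "-") "DELETION" else "INSERTION"
      } else {
        alt <- if (stats::runif(1) < p_ts) {
          TRANSITION_PARTNER[[ref]]
        } else {
          sample(setdiff(BASES, c(ref, TRANSITION_PARTNER[[ref]])), 1)
        }
        kind <- "SNP"
      }
      het <- if (stats::runif(1) < config$within_genotype_het_rate) {
        sample(1:2, 1)
      } else {
        0L
      }
      snv_rows[[length(snv_rows) + 1L]] <- data.frame(
        unigene_id = ids[i], pos = p0, kind = kind, ref = ref, alt = alt,
        het_genotype = het, stringsAsFactors = FALSE)
    }
  }
  truth_snvs <- if (length(snv_rows)) {
    do.call(rbind, snv_rows)
  } else {
    data.frame(unigene_id = character(), pos = integer(), kind = character(),
               ref = character(), alt = character(), het_genotype = integer(),
               stringsAsFactors = FALSE)
  }

  unigenes <- stats::setNames(lapply(seq_len(n), function(i) {
    unigene(ids[i], paste(seqs[[i]], collapse = ""), orf = orfs[[i]],
            introns = introns[[i]])
  }), ids)

  truth_snvs <- add_expected_filters(truth_snvs, unigenes)
  list(unigenes = unigenes,
       truth = list(ssrs = truth_ssrs, snvs = truth_snvs,
                    genotypes = config$genotypes))
}

# Expected cascade tags from planted geometry alone (CEF excluded: it
# depends on the enzyme panel, not on geometry).
add_expected_filters <- function(truth_snvs, unigenes,
                                 params = filter_params()) {
  if (!nrow(truth_snvs)) {
    truth_snvs$expected_filters <- character(0)
    return(truth_snvs)
  }
  lens <- unigene_lengths(unigenes)
  tags <- vector("list", nrow(truth_snvs))
  for (i in seq_len(nrow(truth_snvs))) tags[[i]] <- character(0)
  for (uid in unique(truth_snvs$unigene_id)) {
    idx <- which(truth_snvs$unigene_id == uid)
    pos <- truth_snvs$pos[idx]
    L <- lens[[uid]]
    if (length(idx) * 100 / L > params$hv_density) {
      for (i in idx) tags[[i]] <- union(tags[[i]], "HVR4")
    }
    if (length(idx) >= 2) {
      for (k in seq_along(idx)) {
        if (min(abs(pos[-k] - pos[k])) < params$proximity_bp) {
          tags[[idx[k]]] <- union(tags[[idx[k]]], "CS60")
        }
      }
    }
    junc <- unigenes[[uid]]$introns
    for (k in seq_along(idx)) {
      if (length(junc) && min(abs(pos[k] - junc)) < params$intron_bp) {
        tags[[idx[k]]] <- union(tags[[idx[k]]], "I60")
      }
      if (min(pos[k], L - 1L - pos[k]) < params$edge_bp) {
        tags[[idx[k]]] <- union(tags[[idx[k]]], "CL60")
      }
    }
  }
  indel <- truth_snvs$kind != "SNP"
  for (i in which(indel)) tags[[i]] <- union(tags[[i]], "VKS")
  for (i in which(truth_snvs$het_genotype == 2L)) {
    tags[[i]] <- union(tags[[i]], "NVSM1")
  }
  for (i in which(truth_snvs$het_genotype == 1L)) {
    tags[[i]] <- union(tags[[i]], "NVSM2")
  }
  truth_snvs$expected_filters <- join_tags(tags)
  truth_snvs
}

#' Generate per-position read observations for the two genotypes
#'
#' Per position and genotype the read depth is Poisson with the configured
#' mean. The first genotype carries the consensus allele and the second the
#' planted alternative at each between-genotype variant site; at
#' within-genotype-variable sites the affected genotype emits both alleles
#' in a deterministic near-50/50 split. Base miscalls are applied at the
#' configured rate (single-base alleles only) and phred qualities are drawn
#' around their configured means.
#'
#' @param unigenes Named list of unigenes from [gen_unigenes()].
#' @param truth Truth list from [gen_unigenes()].
#' @param config The same [simulation_config()].
#' @return Observation `data.frame` (see [read_observations()]).
#' @export
gen_read_observations <- function(unigenes, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  gts <- config$genotypes
  chunks <- list()
  for (uid in names(unigenes)) {
    u <- unigenes[[uid]]
    L <- nchar(u$seq)
    cons <- strsplit(u$seq, "")[[1]]
    site <- truth$snvs[truth$snvs$unigene_id == uid, , drop = FALSE]
    for (g in 1:2) {
      depth <- stats::rpois(L, config$coverage_mean)
      N <- sum(depth)
      if (N == 0) next
      pos <- rep.int(seq_len(L) - 1L, depth)
      allele <- rep.int(cons, depth)
      if (nrow(site)) {
        for (k in seq_len(nrow(site))) {
          idx <- which(pos == site$pos[k])
          if (!length(idx)) next
          own <- if (g == 1L) site$ref[k] else site$alt[k]
          other <- if (g == 1L) site$alt[k] else site$ref[k]
          if (site$het_genotype[k] == g) {
            allele[idx] <- c(own, other)[(seq_along(idx) - 1L) %% 2L + 1L]
          } else {
            allele[idx] <- own
          }
        }
      }
      if (config$base_error_rate > 0) {
        single <- nchar(allele) == 1L & allele != "-"
        err <- stats::runif(N) < config$base_error_rate & single
        if (any(err)) {
          allele[err] <- vapply(allele[err], function(b) {
            sample(setdiff(BASES, b), 1)
          }, "")
        }
      }
      bq <- pmin(40L, pmax(2L, as.integer(round(
        stats::rnorm(N, config$base_quality_mean, 3)))))
      mq <- pmin(60L, pmax(0L, as.integer(round(
        stats::rnorm(N, config$mapq_mean, 5)))))
      chunks[[length(chunks) + 1L]] <- data.frame(
        unigene_id = uid, pos = pos, genotype = gts[g],
        read_id = sprintf("%s_%s_r%06d", uid, gts[g], seq_len(N)),
        allele = allele, base_qual = bq, map_qual = mq,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(chunks)) {
    return(data.frame(unigene_id = character(), pos = integer(),
                      genotype = character(), read_id = character(),
                      allele = character(), base_qual = integer(),
                      map_qual = integer(), stringsAsFactors = FALSE))
  }
  out <- as.data.frame(data.table::rbindlist(chunks))
  rownames(out) <- NULL
  out
}

# Truth variants expressed in the called-SNV table layout, so they can be
# written with write_vcf() and compared to pipeline output.
truth_snv_table <- function(truth) {
  snvs <- truth$snvs
  n <- nrow(snvs)
  allele_a <- character(n)
  allele_b <- character(n)
  alleles <- character(n)
  for (i in seq_len(n)) {
    both <- sort(c(snvs$ref[i], snvs$alt[i]))
    a <- snvs$ref[i]
    b <- snvs$alt[i]
    if (snvs$het_genotype[i] == 1L) a <- paste(both, collapse = ",")
    if (snvs$het_genotype[i] == 2L) b <- paste(both, collapse = ",")
    allele_a[i] <- a
    allele_b[i] <- b
    alleles[i] <- paste(both, collapse = ",")
  }
  out <- data.frame(unigene_id = snvs$unigene_id, pos = snvs$pos,
                    kind = snvs$kind, ref = snvs$ref, alleles = alleles,
                    allele_a = allele_a, allele_b = allele_b,
                    filters = snvs$expected_filters,
                    stringsAsFactors = FALSE)
  attr(out, "genotypes") <- truth$genotypes
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Generates unigenes and read evidence and writes `unigenes.fasta`,
#' `annotations.gff3`, `observations.tsv`, `truth_ssrs.tsv` and
#' `truth.vcf` (the planted variants with their expected filter tags).
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `list(unigenes, truth, observations, paths)`.
#' @export
simulate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- gen_unigenes(config)
  obs <- gen_read_observations(gen$unigenes, gen$truth, config)
  paths <- list(
    fasta = file.path(dir, "unigenes.fasta"),
    gff = file.path(dir, "annotations.gff3"),
    observations = file.path(dir, "observations.tsv"),
    truth_ssrs = file.path(dir, "truth_ssrs.tsv"),
    truth_vcf = file.path(dir, "truth.vcf"))
  write_fasta(gen$unigenes, paths$fasta)
  write_annotations_gff3(gen$unigenes, paths$gff)
  write_observations(obs, paths$observations)
  utils::write.table(gen$truth$ssrs, paths$truth_ssrs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_vcf(truth_snv_table(gen$truth), gen$unigenes, paths$truth_vcf)
  invisible(list(unigenes = gen$unigenes, truth = gen$truth,
                 observations = obs, paths = paths))
}
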