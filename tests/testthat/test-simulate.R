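test_that("identical config and seed reproduce the dataset byte-for-byte", {
  cfg <- simulation_config(n_unigenes = 6, coverage_mean = 5, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(gc_content = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(
    ssr_plant_spec = list(list(motif = "AG", units = 10, region = "ORF"))),
    "trinucleotide")
  expect_error(simulation_config(
    ssr_plant_spec = list(list(motif = "TAA", units = 8, region = "ORF"))),
    "stop codon")
})

test_that("background composition follows the GC setting at the boundary", {
  cfg <- simulation_config(n_unigenes = 3, gc_content = 1, orf_fraction = 0,
                           snv_rate = 0, seed = 5)
  gen <- gen_unigenes(cfg)
  for (u in gen$unigenes) {
    expect_false(grepl("[AT]", u$seq), info = u$id)
  }
})

test_that("generated ORFs are valid full-length frames", {
  cfg <- simulation_config(n_unigenes = 40, orf_fraction = 1, seed = 8)
  gen <- gen_unigenes(cfg)
  for (u in gen$unigenes) {
    expect_false(is.null(u$orf), info = u$id)
    orf_seq <- substring(u$seq, u$orf$start + 1L, u$orf$end)
    expect_true(validate_full_orf(orf_seq), info = u$id)
  }
})

test_that("planted SSRs land in the requested region as exact repeats", {
  cfg <- simulation_config(
    n_unigenes = 12, orf_fraction = 1, seed = 3,
    ssr_plant_spec = list(
      list(motif = "AG", units = 10, region = "THREE_UTR"),
      list(motif = "AT", units = 9, region = "FIVE_UTR"),
      list(motif = "AAG", units = 8, region = "ORF"),
      list(motif = "AATC", units = 5, region = "THREE_UTR")))
  gen <- gen_unigenes(cfg)
  truth <- gen$truth$ssrs
  expect_equal(nrow(truth), 4L)
  for (i in seq_len(nrow(truth))) {
    u <- gen$unigenes[[truth$unigene_id[i]]]
    planted <- substring(u$seq, truth$start[i] + 1L, truth$end[i])
    expect_equal(planted,
                 strrep(truth$motif_planted[i], truth$n_units[i]))
    if (truth$region[i] == "THREE_UTR") {
      expect_gte(truth$start[i], u$orf$end)
    } else if (truth$region[i] == "FIVE_UTR") {
      expect_lte(truth$end[i], u$orf$start)
    } else if (truth$region[i] == "ORF") {
      expect_gte(truth$start[i], u$orf$start)
      expect_lte(truth$end[i], u$orf$end)
      # frame protection: the ORF still translates cleanly
      orf_seq <- substring(u$seq, u$orf$start + 1L, u$orf$end)
      expect_true(validate_full_orf(orf_seq))
    }
  }
})

test_that("the planted substitution spectrum matches the ts:tv odds", {
  cfg <- simulation_config(n_unigenes = 120, snv_rate = 8,
                           indel_fraction = 0, seed = 17)
  gen <- gen_unigenes(cfg)
  snvs <- gen$truth$snvs
  is_ts <- mapply(function(a, b) {
    classify_substitution(a, b) == "TRANSITION"
  }, snvs$ref, snvs$alt)
  p_hat <- mean(is_ts)
  p <- cfg$ts_tv_ratio / (1 + cfg$ts_tv_ratio)
  tol <- 3 * sqrt(p * (1 - p) / nrow(snvs))
  expect_gt(nrow(snvs), 300)
  expect_lt(abs(p_hat - p), tol)
})

test_that("expected filter tags are consistent with the planted geometry", {
  cfg <- simulation_config(n_unigenes = 60, snv_rate = 4, seed = 23)
  gen <- gen_unigenes(cfg)
  snvs <- gen$truth$snvs
  lens <- vapply(gen$unigenes, function(u) nchar(u$seq), integer(1))
  for (i in seq_len(nrow(snvs))) {
    tags <- strsplit(snvs$expected_filters[i], ";")[[1]]
    L <- lens[[snvs$unigene_id[i]]]
    expect_equal("CL60" %in% tags,
                 min(snvs$pos[i], L - 1 - snvs$pos[i]) < 60,
                 info = paste("row", i))
    expect_equal("VKS" %in% tags, snvs$kind[i] != "SNP")
    junc <- gen$unigenes[[snvs$unigene_id[i]]]$introns
    expect_equal("I60" %in% tags,
                 length(junc) > 0 && min(abs(snvs$pos[i] - junc)) < 60)
    others <- snvs$pos[snvs$unigene_id == snvs$unigene_id[i]]
    others <- others[others != snvs$pos[i]]
    expect_equal("CS60" %in% tags,
                 length(others) > 0 && min(abs(others - snvs$pos[i])) < 60)
  }
})

test_that("disabling within-genotype variability removes all NVSM truth", {
  cfg <- simulation_config(n_unigenes = 40, snv_rate = 3,
                           within_genotype_het_rate = 0, seed = 29)
  gen <- gen_unigenes(cfg)
  expect_gt(nrow(gen$truth$snvs), 10)
  expect_false(any(grepl("NVSM", gen$truth$snvs$expected_filters)))
})

test_that("noise-free evidence shows exactly the planted alleles", {
  cfg <- simulation_config(n_unigenes = 10, snv_rate = 3,
                           base_error_rate = 0, coverage_mean = 20,
                           seed = 31)
  gen <- gen_unigenes(cfg)
  obs <- gen_read_observations(gen$unigenes, gen$truth, cfg)
  for (i in seq_len(nrow(gen$truth$snvs))) {
    s <- gen$truth$snvs[i, ]
    rows <- obs[obs$unigene_id == s$unigene_id & obs$pos == s$pos, ]
    expect_setequal(unique(rows$allele), c(s$ref, s$alt))
    gt1 <- rows$allele[rows$genotype == cfg$genotypes[1]]
    gt2 <- rows$allele[rows$genotype == cfg$genotypes[2]]
    if (s$het_genotype == 0L) {
      expect_equal(unique(gt1), s$ref)
      expect_equal(unique(gt2), s$alt)
    } else if (s$het_genotype == 1L) {
      expect_setequal(unique(gt1), c(s$ref, s$alt))
    } else {
      expect_setequal(unique(gt2), c(s$ref, s$alt))
    }
  }
})
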