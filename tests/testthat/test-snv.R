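two_unigenes <- function() {
  stats::setNames(list(
    unigene("u1", random_dna(1000)),
    unigene("u2", random_dna(500))), c("u1", "u2"))
}

test_that("allele qualification pools genotypes and suppresses singletons", {
  set.seed(1)
  ug <- two_unigenes()
  obs <- bind_obs(
    make_obs("u1", 100L, "MU16", "A", 3),
    make_obs("u1", 100L, "UPV196", "G", 3),
    make_obs("u1", 300L, "MU16", "A", 10),
    make_obs("u1", 300L, "UPV196", "T", 1, base_qual = 20L))
  snvs <- call_snvs(obs, ug)
  expect_equal(nrow(snvs), 1L)           # singleton T fails both thresholds
  expect_equal(snvs$pos, 100L)
  expect_equal(snvs$kind, "SNP")
  expect_equal(snvs$allele_a, "A")
  expect_equal(snvs$allele_b, "G")
  expect_equal(snvs$alleles, "A,G")

  # two reads below the accumulated-quality floor still fail
  obs2 <- bind_obs(
    make_obs("u1", 100L, "MU16", "A", 5),
    make_obs("u1", 100L, "UPV196", "G", 2, base_qual = 15L))
  expect_equal(nrow(call_snvs(obs2, ug)), 0L)
  # ... but qualify once the quality sum reaches the threshold
  obs3 <- bind_obs(
    make_obs("u1", 100L, "MU16", "A", 5),
    make_obs("u1", 100L, "UPV196", "G", 2, base_qual = 20L))
  expect_equal(nrow(call_snvs(obs3, ug)), 1L)
})

test_that("mapping-quality cut and bounds checks apply before counting", {
  set.seed(2)
  ug <- two_unigenes()
  obs <- bind_obs(
    make_obs("u1", 50L, "MU16", "A", 3, map_qual = 10L),
    make_obs("u1", 50L, "UPV196", "G", 3))
  expect_equal(nrow(call_snvs(obs, ug)), 0L)   # A side all discarded
  expect_error(call_snvs(make_obs("u2", 500L, "MU16", "A", 2), ug),
               "beyond length")
  expect_error(call_snvs(make_obs("u9", 5L, "MU16", "A", 2), ug),
               "unknown unigene")
})

test_that("within-genotype variability is recorded per genotype", {
  set.seed(3)
  ug <- two_unigenes()
  obs <- bind_obs(
    make_obs("u1", 200L, "MU16", "A", 5),
    make_obs("u1", 200L, "MU16", "G", 5),
    make_obs("u1", 200L, "UPV196", "A", 5))
  snvs <- call_snvs(obs, ug)
  expect_equal(snvs$allele_a, "A,G")
  expect_equal(snvs$allele_b, "A")
  tagged <- apply_filters(snvs, ug)
  tags <- strsplit(tagged$filters, ";")[[1]]
  expect_true("NVSM2" %in% tags)     # first genotype internally variable
  expect_false("NVSM1" %in% tags)
})

test_that("an unsequenced genotype triggers its NVSM tag", {
  set.seed(4)
  ug <- two_unigenes()
  obs <- bind_obs(
    make_obs("u1", 200L, "MU16", "A", 5),
    make_obs("u1", 200L, "MU16", "G", 5))
  snvs <- call_snvs(obs, ug, genotypes = c("MU16", "UPV196"))
  tagged <- apply_filters(snvs, ug)
  expect_true(grepl("NVSM1", tagged$filters))
})

test_that("INDEL tokens set the variant kind and the VKS tag", {
  set.seed(5)
  ug <- two_unigenes()
  obs <- bind_obs(
    make_obs("u1", 400L, "MU16", "A", 4),
    make_obs("u1", 400L, "UPV196", "+AC", 4),
    make_obs("u1", 700L, "MU16", "C", 4),
    make_obs("u1", 700L, "UPV196", "-", 4))
  snvs <- apply_filters(call_snvs(obs, ug), ug)
  expect_equal(snvs$kind, c("INSERTION", "DELETION"))
  expect_true(all(grepl("VKS", snvs$filters)))
})

test_that("substitution classification matches exhaustive enumeration", {
  purines <- c("A", "G")
  for (a in c("A", "C", "G", "T")) {
    for (b in c("A", "C", "G", "T")) {
      if (a == b) {
        expect_error(classify_substitution(a, b), "distinct")
      } else {
        want <- if ((a %in% purines) == (b %in% purines)) {
          "TRANSITION"
        } else {
          "TRANSVERSION"
        }
        expect_equal(classify_substitution(a, b), want,
                     info = paste(a, b))
        expect_equal(classify_substitution(a, b),
                     classify_substitution(b, a))
      }
    }
  }
})

test_that("distance and density filters follow their definitions", {
  set.seed(6)
  ug <- two_unigenes()
  # single SNP at pos 30 of a 500 bp unigene: only the edge tag
  obs <- bind_obs(
    make_obs("u2", 30L, "MU16", "A", 4),
    make_obs("u2", 30L, "UPV196", "G", 4))
  snvs <- apply_filters(call_snvs(obs, ug), ug)
  expect_equal(snvs$filters, "CL60")

  # SNPs 50 bp apart in the interior: both proximity-tagged
  obs <- bind_obs(
    make_obs("u1", 100L, "MU16", "A", 4),
    make_obs("u1", 100L, "UPV196", "G", 4),
    make_obs("u1", 150L, "MU16", "C", 4),
    make_obs("u1", 150L, "UPV196", "T", 4))
  snvs <- apply_filters(call_snvs(obs, ug), ug)
  expect_equal(snvs$filters, c("CS60", "CS60"))

  # intron junction within 60 bp
  ugi <- stats::setNames(
    list(unigene("u1", random_dna(1000), introns = 460L)), "u1")
  obs <- bind_obs(
    make_obs("u1", 500L, "MU16", "A", 4),
    make_obs("u1", 500L, "UPV196", "G", 4))
  snvs <- apply_filters(call_snvs(obs, ugi), ugi)
  expect_equal(snvs$filters, "I60")

  # 5 variants on a 100 bp unigene: density 5 per 100 bp > 4, all tagged
  ugs <- stats::setNames(list(unigene("u3", random_dna(100))), "u3")
  obs <- do.call(rbind, lapply(c(10L, 30L, 50L, 70L, 90L), function(p) {
    bind_obs(make_obs("u3", p, "MU16", "A", 4),
             make_obs("u3", p, "UPV196", "G", 4))
  }))
  snvs <- apply_filters(call_snvs(obs, ugs), ugs)
  expect_equal(nrow(snvs), 5L)
  expect_true(all(grepl("HVR4", snvs$filters)))
  expect_true(all(grepl("CL60", snvs$filters)))  # geometry of a 100 bp seq
})

test_that("calling and tagging are independent of observation order", {
  set.seed(7)
  cfg <- simulation_config(n_unigenes = 5, coverage_mean = 8, snv_rate = 3,
                           base_error_rate = 0.01, seed = 13)
  gen <- gen_unigenes(cfg)
  obs <- gen_read_observations(gen$unigenes, gen$truth, cfg)
  shuffled <- obs[sample(nrow(obs)), ]
  a <- apply_filters(call_snvs(obs, gen$unigenes), gen$unigenes)
  b <- apply_filters(call_snvs(shuffled, gen$unigenes), gen$unigenes)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("relaxing distance thresholds never untags; selection shrinks", {
  set.seed(8)
  cfg <- simulation_config(n_unigenes = 20, coverage_mean = 10,
                           snv_rate = 2, base_error_rate = 0, seed = 21)
  gen <- gen_unigenes(cfg)
  obs <- gen_read_observations(gen$unigenes, gen$truth, cfg)
  called <- call_snvs(obs, gen$unigenes)
  tag_count <- function(snvs, code) sum(grepl(code, snvs$filters))
  prev_gg <- Inf
  prev <- c(CS60 = -1, CL60 = -1, I60 = -1)
  for (d in c(20, 60, 120)) {
    snvs <- apply_filters(called, gen$unigenes,
                          filter_params(proximity_bp = d, edge_bp = d,
                                        intron_bp = d))
    now <- c(CS60 = tag_count(snvs, "CS60"),
             CL60 = tag_count(snvs, "CL60"),
             I60 = tag_count(snvs, "I60"))
    expect_true(all(now >= prev))
    gg <- nrow(select_candidates(snvs)$golden_gate)
    expect_lte(gg, prev_gg)
    prev <- now
    prev_gg <- gg
  }
})

test_that("candidate selection honors the dot-or-CEF rule", {
  base <- data.frame(
    unigene_id = "u", pos = c(1L, 2L, 3L, 4L), kind = "SNP", ref = "A",
    alleles = "A,G", allele_a = "A", allele_b = "G",
    cov_a = 5L, cov_b = 5L,
    filters = c("", "CEF", "CS60", "CEF;CS60"), stringsAsFactors = FALSE)
  sel <- select_candidates(base)
  expect_equal(sel$golden_gate$pos, c(1L, 2L))
  expect_equal(sel$caps$pos, 1L)
  expect_true(all(sel$caps$pos %in% sel$golden_gate$pos))
})
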