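enzyme_row <- function(name) {
  tab <- default_enzymes()
  tab[tab$name == name, ]
}

test_that("site matching expands IUPAC codes and both strands", {
  expect_equal(find_sites("AAGAATTCAA", enzyme_row("EcoRI")), 2L)
  expect_equal(find_sites("TTGACTCTT", enzyme_row("HinfI")), 2L)
  expect_equal(find_sites("TTTTTTTTT", enzyme_row("EcoRI")), integer())
  # non-palindromic site found via its reverse complement too
  hph <- enzyme_row("HphI")              # GGTGA
  expect_equal(find_sites("AAGGTGAAA", hph), 2L)
  expect_equal(find_sites("AATCACCAA", hph), 2L)   # revcomp occurrence
  # overlapping site occurrences are all reported
  expect_equal(find_sites("GTACGTAC", enzyme_row("RsaI")), c(0L, 4L))
})

test_that("a SNP completing a recognition site yields a gain-of-site hit", {
  # T allele completes GAATTC; C allele does not
  seq <- paste0(strrep("G", 20), "GAATCC", strrep("G", 20))
  u <- unigene("u", seq)
  snv <- list(unigene_id = "u", pos = 24L, kind = "SNP", alleles = "C,T")
  hits <- caps_evaluate(snv, u, window_bp = 15L)
  expect_true("EcoRI" %in% hits$enzyme)
  expect_equal(hits$allele_with_site[hits$enzyme == "EcoRI"], "T")
  # fragment lengths per allele sum to the window length, for every hit
  wlen <- min(nchar(seq), 24 + 15 + 1) - max(0, 24 - 15)
  for (k in seq_len(nrow(hits))) {
    expect_equal(sum(as.integer(strsplit(hits$frags1[k], ",")[[1]])), wlen)
    expect_equal(sum(as.integer(strsplit(hits$frags2[k], ",")[[1]])), wlen)
  }

  # a SNP nowhere near any site: no hits
  u2 <- unigene("u2", strrep("A", 61))
  snv2 <- list(unigene_id = "u2", pos = 30L, kind = "SNP", alleles = "A,T")
  expect_equal(nrow(caps_evaluate(snv2, u2)), 0L)

  expect_error(
    caps_evaluate(list(unigene_id = "u", pos = 5L, kind = "DELETION",
                       alleles = "-,A"), u),
    "SNP-only")
})

test_that("CAPS decisions equal the exhaustive digestion oracle", {
  set.seed(33)
  enzymes <- default_enzymes()
  n_checked <- 0L
  for (i in 1:200) {
    seq <- random_dna(121, gc = stats::runif(1, 0.3, 0.7))
    pos <- 60L
    ref <- substring(seq, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    u <- unigene("u", seq)
    snv <- list(unigene_id = "u", pos = pos, kind = "SNP",
                alleles = paste(sort(c(ref, alt)), collapse = ","))
    hits <- caps_evaluate(snv, u, enzymes, window_bp = 60L)
    al <- sort(c(ref, alt))
    win1 <- paste0(substring(seq, 1, pos), al[1], substring(seq, pos + 2))
    win2 <- paste0(substring(seq, 1, pos), al[2], substring(seq, pos + 2))
    want <- oracle_caps_enzymes(win1, win2, pos, enzymes)
    expect_equal(sort(hits$enzyme), sort(want), info = paste("case", i))
    # fragment patterns agree with independent digestion of each window
    for (k in seq_len(nrow(hits))) {
      enz <- enzymes[enzymes$name == hits$enzyme[k], ]
      expect_equal(as.integer(strsplit(hits$frags1[k], ",")[[1]]),
                   oracle_digest(win1, enz$site, enz$cut_offset))
      expect_equal(as.integer(strsplit(hits$frags2[k], ",")[[1]]),
                   oracle_digest(win2, enz$site, enz$cut_offset))
    }
    n_checked <- n_checked + nrow(hits)
  }
  expect_gt(n_checked, 20L)   # the sweep exercised real hits
})

test_that("hit sets are strand-symmetric", {
  set.seed(44)
  enzymes <- default_enzymes()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:40) {
    seq <- random_dna(101)
    pos <- 50L
    ref <- substring(seq, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    u <- unigene("u", seq)
    hits_fwd <- caps_evaluate(
      list(unigene_id = "u", pos = pos, kind = "SNP",
           alleles = paste(sort(c(ref, alt)), collapse = ",")),
      u, enzymes, window_bp = 50L)
    rcseq <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                   collapse = "")
    rpos <- nchar(seq) - 1L - pos
    urc <- unigene("u", rcseq)
    hits_rev <- caps_evaluate(
      list(unigene_id = "u", pos = rpos, kind = "SNP",
           alleles = paste(sort(comp[c(ref, alt)]), collapse = ",")),
      urc, enzymes, window_bp = 50L)
    expect_equal(sort(hits_fwd$enzyme), sort(hits_rev$enzyme),
                 info = paste("case", i))
  }
})

test_that("CEF tags exactly the SNPs with no allele-specific site", {
  set.seed(55)
  # constructed gain-of-site SNP is never CEF
  seq <- paste0(strrep("T", 30), "GAATCC", strrep("T", 30))
  ug <- stats::setNames(list(unigene("u", seq)), "u")
  snvs <- data.frame(
    unigene_id = "u", pos = 34L, kind = "SNP", ref = "C",
    alleles = "C,T", allele_a = "C", allele_b = "T",
    cov_a = 5L, cov_b = 5L, filters = "", stringsAsFactors = FALSE)
  out <- annotate_cef(snvs, ug)
  expect_false(grepl("CEF", out$filters))

  # a homopolymer context offers no site: CEF
  ug2 <- stats::setNames(list(unigene("v", strrep("A", 100))), "v")
  snvs2 <- data.frame(
    unigene_id = "v", pos = 50L, kind = "SNP", ref = "A",
    alleles = "A,T", allele_a = "A", allele_b = "T",
    cov_a = 5L, cov_b = 5L, filters = "", stringsAsFactors = FALSE)
  expect_true(grepl("CEF", annotate_cef(snvs2, ug2)$filters))

  # an emptied panel makes every SNP CEF; INDELs stay untouched
  snvs3 <- rbind(snvs, snvs2)
  snvs3$unigene_id <- c("u", "v")
  snvs3$kind[2] <- "DELETION"
  snvs3$alleles[2] <- "-,A"
  ug3 <- c(ug, ug2)
  out3 <- annotate_cef(snvs3, ug3, enzymes = default_enzymes()[0, ])
  expect_equal(grepl("CEF", out3$filters), c(TRUE, FALSE))

  # a larger panel can only remove CEF tags, never add
  small <- annotate_cef(snvs3, ug3, enzymes = default_enzymes()[1:3, ])
  full <- annotate_cef(snvs3, ug3, enzymes = default_enzymes())
  expect_lte(sum(grepl("CEF", full$filters)),
             sum(grepl("CEF", small$filters)))
})
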