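# Independent oracles used to validate the scanners against brute force.

# --- SSR oracle: regex-based maximal tandem-run finder -----------------

oracle_degenerate <- function(unit) {
  n <- nchar(unit)
  any(vapply(seq_len(n - 1), function(d) {
    n %% d == 0 && unit == strrep(substring(unit, 1, d), n / d)
  }, TRUE))
}

# All maximal perfect tandem runs passing the thresholds. A zero-width
# lookahead regex enumerates every position where min_units whole units
# begin (overlapping starts included); non-left-maximal starts are pruned
# and each surviving run is measured by character-by-character extension.
oracle_ssrs <- function(seq, params = ssr_params()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cand <- list()
  for (p in params$unit_lengths) {
    pat <- sprintf("(?=([ACGT]{%d})\\1{%d,})", p, params$min_units - 1L)
    h <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (h[1] == -1L) next
    for (i in as.integer(h)) {         # 1-based candidate starts
      if (i > 1L && i - 1L + p <= n && chars[i - 1L] != "N" &&
          chars[i - 1L] == chars[i - 1L + p]) {
        next                           # run extends further left
      }
      t <- 0L
      while (i + p + t <= n && chars[i + t] != "N" &&
             chars[i + p + t] == chars[i + t]) {
        t <- t + 1L
      }
      total <- p + t
      unit <- substring(seq, i, i + p - 1L)
      if (total %/% p >= params$min_units &&
          total >= params$min_total_length &&
          !oracle_degenerate(unit)) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + total,
          motif_found = unit, unit_length = p, total_length = total,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      motif_found = character(), unit_length = integer(),
                      total_length = integer(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  # same deterministic overlap rule: longer locus wins, ties to the
  # shorter unit, then leftmost
  cand <- cand[order(-cand$total_length, cand$unit_length, cand$start), ,
               drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    prior <- which(kept)
    kept[i] <- !any(cand$start[prior] < cand$end[i] &
                      cand$start[i] < cand$end[prior])
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- CAPS oracle: IUPAC regex site finder + full digestion -------------

iupac_regex_map <- c(A = "A", C = "C", G = "G", T = "T",
                     R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                     K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                     H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "")[[1]]), collapse = "")
}

regex_site_positions <- function(seq, site) {   # 0-based, both strands
  find1 <- function(pat) {
    rx <- paste0("(?=", paste(iupac_regex_map[strsplit(pat, "")[[1]]],
                              collapse = ""), ")")
    h <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (h[1] == -1L) integer() else as.integer(h) - 1L
  }
  pos <- find1(site)
  rc <- iupac_revcomp(site)
  if (rc != site) pos <- union(pos, find1(rc))
  sort(pos)
}

oracle_digest <- function(seq, site, cut_offset) {
  cuts <- regex_site_positions(seq, site) + cut_offset
  cuts <- sort(unique(cuts[cuts > 0 & cuts < nchar(seq)]))
  sort(diff(c(0L, cuts, nchar(seq))))
}

# Enzymes whose site set overlapping the SNP differs between the two
# allele windows (the CAPS-detectability decision), by exhaustive digestion.
oracle_caps_enzymes <- function(win1, win2, off, enzymes) {
  hits <- character(0)
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]
    slen <- nchar(site)
    s1 <- regex_site_positions(win1, site)
    s2 <- regex_site_positions(win2, site)
    ov1 <- s1[s1 <= off & off < s1 + slen]
    ov2 <- s2[s2 <= off & off < s2 + slen]
    if (!setequal(ov1, ov2)) hits <- c(hits, enzymes$name[i])
  }
  hits
}

# --- small constructors ------------------------------------------------

# expand per-allele read counts into observation rows
make_obs <- function(unigene_id, pos, genotype, allele, n = 1L,
                     base_qual = 30L, map_qual = 40L) {
  data.frame(unigene_id = unigene_id, pos = pos, genotype = genotype,
             read_id = sprintf("%s_%s_%d_r%d", unigene_id, genotype, pos,
                               seq_len(n)),
             allele = allele, base_qual = base_qual, map_qual = map_qual,
             stringsAsFactors = FALSE)
}

bind_obs <- function(...) do.call(rbind, list(...))
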