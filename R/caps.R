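#' Built-in restriction enzyme panel
#'
#' A panel of common 4-6 bp cutters used to screen SNPs for CAPS
#' detectability. `site` is the IUPAC recognition sequence on the top
#' strand; `cut_offset` is the number of bases between the start of the
#' site and the top-strand cut. The panel is user-extensible: pass any
#' data.frame with the same columns, or load one with [read_enzymes()].
#'
#' @return A `data.frame` with columns `name`, `site`, `cut_offset`.
#' @export
default_enzymes <- function() {
  data.frame(
    name = c("EcoRI", "HindIII", "BamHI", "BglII", "PstI", "SacI", "KpnI",
             "XbaI", "SalI", "EcoRV", "DraI", "AluI", "HaeIII", "RsaI",
             "TaqI", "MseI", "MboI", "MspI", "HhaI", "HinfI", "DdeI",
             "ScrFI", "NlaIII", "HphI"),
    site = c("GAATTC", "AAGCTT", "GGATCC", "AGATCT", "CTGCAG", "GAGCTC",
             "GGTACC", "TCTAGA", "GTCGAC", "GATATC", "TTTAAA", "AGCT",
             "GGCC", "GTAC", "TCGA", "TTAA", "GATC", "CCGG", "GCGC",
             "GANTC", "CTNAG", "CCNGG", "CATG", "GGTGA"),
    cut_offset = c(1L, 1L, 1L, 1L, 5L, 5L, 5L, 1L, 1L, 3L, 3L, 2L, 2L, 2L,
                   1L, 1L, 0L, 1L, 3L, 1L, 1L, 2L, 4L, 13L),
    stringsAsFactors = FALSE)
}

#' Load a restriction-enzyme table from TSV
#'
#' Expects a tab-separated file with header `name site cut_offset`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `name`, `site`, `cut_offset`.
#' @export
read_enzymes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "site", "cut_offset") %in% names(tab))) {
    stop("enzyme table '", path, "': header must contain name, site, ",
         "cut_offset", call. = FALSE)
  }
  tab$site <- toupper(tab$site)
  bad <- nchar(tab$site) < 4 |
    grepl("[^ACGTRYSWKMBDHVN]", tab$site)
  if (any(bad)) {
    stop("enzyme table '", path, "': invalid site for ",
         tab$name[which(bad)[1]], call. = FALSE)
  }
  tab$cut_offset <- as.integer(tab$cut_offset)
  tab[, c("name", "site", "cut_offset")]
}

#' Find restriction-site matches in a sequence
#'
#' Matches the enzyme's IUPAC recognition site on the top strand; for a
#' non-palindromic site the reverse complement is also matched and reported
#' in top-strand coordinates. Palindromic sites are reported once.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param enzyme One row of an enzyme table (list or one-row data.frame
#'   with `site`).
#' @return Sorted integer vector of 0-based site start positions.
#' @export
find_sites <- function(seq, enzyme) {
  site <- toupper(enzyme$site)
  subject <- Biostrings::DNAString(toupper(seq))
  if (nchar(seq) < nchar(site)) return(integer())
  hit_starts <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = FALSE)
    BiocGenerics::start(m) - 1L
  }
  pos <- hit_starts(site)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (rc != site) {
    pos <- union(pos, hit_starts(rc))
  }
  sort(as.integer(pos))
}

snv_biallelic_bases <- function(snv) {
  if (snv$kind != "SNP") {
    stop("CAPS evaluation is SNP-only; got kind ", snv$kind, call. = FALSE)
  }
  alleles <- strsplit(snv$alleles, ",", fixed = TRUE)[[1]]
  if (length(alleles) != 2L || any(nchar(alleles) != 1L)) {
    stop("CAPS evaluation requires a biallelic SNP; got alleles ",
         snv$alleles, call. = FALSE)
  }
  alleles
}

digest_lengths <- function(seq, enzyme) {
  cuts <- find_sites(seq, enzyme) + enzyme$cut_offset
  cuts <- sort(unique(cuts[cuts > 0 & cuts < nchar(seq)]))
  sort(diff(c(0L, cuts, nchar(seq))))
}

#' Evaluate CAPS detectability of one SNP
#'
#' Builds the two allele sequences of a window centered on the SNP (clipped
#' to the unigene) and reports, for each enzyme, whether the sets of
#' recognition sites that overlap the SNP position differ between the
#' alleles — i.e. one allele gains or loses a site spanning the SNP.
#' Distant sites shared by both alleles are ignored for the decision but
#' enter the reported fragment patterns, which come from digesting the full
#' window with all sites of the enzyme.
#'
#' @param snv One SNV record (one-row data.frame or list) with `unigene_id`,
#'   `pos`, `kind`, `alleles`; must be a biallelic SNP.
#' @param unigene The `"unigene"` the SNP lies on.
#' @param enzymes Enzyme table (default [default_enzymes()]).
#' @param window_bp Half-window in bp around the SNP (default 60).
#' @return A `data.frame` of hits: `unigene_id`, `pos`, `enzyme`,
#'   `allele_with_site`, `site_position` (0-based, window coordinates),
#'   `allele1`, `allele2`, `frags1`, `frags2` (sorted fragment lengths,
#'   comma-joined; each set sums to the window length).
#' @export
caps_evaluate <- function(snv, unigene, enzymes = default_enzymes(),
                          window_bp = 60L) {
  alleles <- snv_biallelic_bases(snv)
  len <- nchar(unigene$seq)
  stopifnot(snv$pos >= 0, snv$pos < len)
  wstart <- max(0L, snv$pos - window_bp)
  wend <- min(len, snv$pos + window_bp + 1L)
  off <- snv$pos - wstart                     # SNP offset within window
  win <- substring(unigene$seq, wstart + 1L, wend)
  make_allele_window <- function(a) {
    paste0(substring(win, 1, off), a, substring(win, off + 2L))
  }
  win1 <- make_allele_window(alleles[1])
  win2 <- make_allele_window(alleles[2])

  hits <- list()
  for (i in seq_len(nrow(enzymes))) {
    enz <- enzymes[i, ]
    slen <- nchar(enz$site)
    s1 <- find_sites(win1, enz)
    s2 <- find_sites(win2, enz)
    ov1 <- s1[s1 <= off & off < s1 + slen]
    ov2 <- s2[s2 <= off & off < s2 + slen]
    if (!setequal(ov1, ov2)) {
      gain1 <- setdiff(ov1, ov2)
      gained_by <- if (length(gain1)) 1L else 2L
      site_pos <- if (length(gain1)) gain1[1] else setdiff(ov2, ov1)[1]
      hits[[length(hits) + 1L]] <- data.frame(
        unigene_id = unigene$id, pos = snv$pos,
        enzyme = enz$name,
        allele_with_site = alleles[gained_by],
        site_position = site_pos,
        allele1 = alleles[1], allele2 = alleles[2],
        frags1 = paste(digest_lengths(win1, enz), collapse = ","),
        frags2 = paste(digest_lengths(win2, enz), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(unigene_id = character(), pos = integer(),
                      enzyme = character(), allele_with_site = character(),
                      site_position = integer(), allele1 = character(),
                      allele2 = character(), frags1 = character(),
                      frags2 = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Tag CAPS-incapable SNPs with CEF
#'
#' Adds the `CEF` tag to every biallelic SNP for which no enzyme in the
#' panel gains or loses a site spanning the SNP ([caps_evaluate()] returns
#' no hits). INDELs and multi-allelic variants are never tagged.
#'
#' @param snvs SNV table.
#' @param unigenes Named list of unigenes.
#' @param enzymes Enzyme table.
#' @param window_bp Half-window in bp around each SNP.
#' @return The SNV table with `CEF` added where applicable.
#' @export
annotate_cef <- function(snvs, unigenes, enzymes = default_enzymes(),
                         window_bp = 60L) {
  if (!nrow(snvs)) return(snvs)
  tags <- split_tags(snvs$filters)
  for (i in seq_len(nrow(snvs))) {
    if (snvs$kind[i] != "SNP") next
    alleles <- strsplit(snvs$alleles[i], ",", fixed = TRUE)[[1]]
    if (length(alleles) != 2L || any(nchar(alleles) != 1L)) next
    hits <- caps_evaluate(snvs[i, ], unigenes[[snvs$unigene_id[i]]],
                          enzymes, window_bp)
    if (!nrow(hits)) tags[[i]] <- union(tags[[i]], "CEF")
  }
  snvs$filters <- join_tags(tags)
  snvs
}
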