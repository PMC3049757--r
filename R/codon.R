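STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b3 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                   b1 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

#' Is a sequence a valid full-length ORF?
#'
#' A full-length ORF starts with `ATG`, ends with a stop codon, has length
#' a multiple of 3 (and at least 6), and contains no internal stop — the
#' mechanical equivalent of screening out truncated or frame-shifted
#' coding predictions before codon-usage analysis.
#'
#' @param seq DNA string.
#' @return `TRUE` or `FALSE`.
#' @export
validate_full_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6 || n %% 3 != 0) return(FALSE)
  if (grepl("[^ACGT]", seq)) return(FALSE)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  codons[1] == "ATG" &&
    codons[length(codons)] %in% STOP_CODONS &&
    !any(codons[-length(codons)] %in% STOP_CODONS)
}

#' Build a codon-usage table from full-length ORFs
#'
#' Counts every codon, including each ORF's terminal stop. All 64 codons
#' are present in the result (zero counts allowed).
#'
#' @param orfs Character vector of ORF sequences; each must pass
#'   [validate_full_orf()].
#' @return An object of class `"codon_table"`: list with `counts` (named
#'   integer vector over the 64 codons), `n_codons`, `n_orfs`.
#' @export
build_codon_table <- function(orfs) {
  orfs <- toupper(orfs)
  if (length(orfs)) {
    valid <- vapply(orfs, validate_full_orf, TRUE, USE.NAMES = FALSE)
    if (!all(valid)) {
      i <- which(!valid)[1]
      stop("ORF ", i, " is not a valid full-length ORF: ",
           substring(orfs[i], 1, 30), if (nchar(orfs[i]) > 30) "..." else "",
           call. = FALSE)
    }
  }
  counts <- stats::setNames(integer(64), all_codons())
  for (orf in orfs) {
    n <- nchar(orf)
    codons <- substring(orf, seq(1, n, 3), seq(3, n, 3))
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(counts = counts, n_codons = sum(counts),
                 n_orfs = length(orfs)),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("<codon_table> ", x$n_orfs, " ORFs, ", x$n_codons, " codons\n",
      sep = "")
  invisible(x)
}

as_codon_counts <- function(table) {
  if (inherits(table, "codon_table")) return(table$counts)
  if (is.numeric(table) && !is.null(names(table))) {
    counts <- stats::setNames(integer(64), all_codons())
    counts[names(table)] <- as.integer(table)
    return(counts)
  }
  stop("expected a codon_table or a named count vector", call. = FALSE)
}

#' GC content at the third codon position
#'
#' Fraction of codons whose third base is G or C. Stop codons are excluded
#' by default (set `include_stops = TRUE` to count them).
#'
#' @param table A `"codon_table"` or named codon-count vector.
#' @param include_stops Count stop codons too? Default `FALSE`.
#' @return Fraction in `[0, 1]`.
#' @export
gc3 <- function(table, include_stops = FALSE) {
  counts <- as_codon_counts(table)
  if (!include_stops) counts[STOP_CODONS] <- 0L
  total <- sum(counts)
  if (total == 0) {
    stop("GC3 undefined: no codons counted", call. = FALSE)
  }
  third <- substring(names(counts), 3, 3)
  sum(counts[third %in% c("G", "C")]) / total
}

#' CpG-suppression ratio XCG/XCC
#'
#' Ratio of counts of codons of the form N-C-G to codons of the form
#' N-C-C — the standard measure of CG-dinucleotide suppression at codon
#' positions 2-3. Values below 1 indicate suppression.
#'
#' @param table A `"codon_table"` or named codon-count vector.
#' @return The ratio.
#' @export
xcg_xcc_ratio <- function(table) {
  counts <- as_codon_counts(table)
  tail2 <- substring(names(counts), 2, 3)
  ncg <- sum(counts[tail2 == "CG"])
  ncc <- sum(counts[tail2 == "CC"])
  if (ncc == 0) {
    stop("XCG/XCC undefined: no NCC codons counted", call. = FALSE)
  }
  ncg / ncc
}

#' Stop-codon usage
#'
#' Fraction of ORFs terminating in each of the three stop codons.
#'
#' @param orfs Character vector of full-length ORFs.
#' @return Named numeric vector over `TAA`, `TAG`, `TGA`, summing to 1.
#' @export
stop_usage <- function(orfs) {
  if (!length(orfs)) stop("no ORFs supplied", call. = FALSE)
  orfs <- toupper(orfs)
  last <- substring(orfs, nchar(orfs) - 2, nchar(orfs))
  if (!all(last %in% STOP_CODONS)) {
    stop("ORF without a terminal stop codon", call. = FALSE)
  }
  out <- stats::setNames(numeric(3), c("TAA", "TAG", "TGA"))
  tab <- table(last) / length(orfs)
  out[names(tab)] <- as.numeric(tab)
  out
}

#' Extract ORF sequences from an annotated unigene set
#'
#' Pulls the ORF substring of every unigene with an ORF annotation
#' (reverse-complemented for minus-strand ORFs) and keeps those passing
#' [validate_full_orf()].
#'
#' @param unigenes Named list of unigenes.
#' @return Character vector of full-length ORF sequences, named by unigene.
#' @export
extract_full_orfs <- function(unigenes) {
  out <- character(0)
  for (u in unigenes) {
    if (is.null(u$orf)) next
    s <- substring(u$seq, u$orf$start + 1L, u$orf$end)
    if (u$orf$strand == "-") s <- revcomp(s)
    if (validate_full_orf(s)) out[u$id] <- s
  }
  out
}
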