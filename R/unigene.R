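#' Construct a unigene record
#'
#' A unigene is an assembled consensus transcript sequence, optionally
#' annotated with a single open reading frame (ORF) and with intron junction
#' positions (the unigene coordinate at which a genomic intron was spliced
#' out). All coordinates are 0-based, intervals half-open; conversion to the
#' 1-based closed convention happens only when reading or writing GFF3/VCF.
#'
#' @param id Unigene identifier, unique within a dataset.
#' @param seq DNA sequence; normalized to uppercase. Alphabet `A,C,G,T,N`.
#' @param orf Optional ORF as a list with elements `start`, `end` (0-based
#'   half-open) and `strand` (`"+"` or `"-"`), or `NULL` if none.
#' @param introns Integer vector of intron junction positions in
#'   `[0, nchar(seq)]`.
#' @return An object of class `"unigene"`.
#' @export
unigene <- function(id, seq, orf = NULL, introns = integer()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) {
    stop("unigene '", id, "': empty sequence", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq)) {
    stop("unigene '", id, "': sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  if (!is.null(orf)) {
    orf <- validate_orf_interval(orf, nchar(seq), id)
  }
  introns <- as.integer(introns)
  if (any(introns < 0L | introns > nchar(seq))) {
    stop("unigene '", id, "': intron junction outside [0, length]",
         call. = FALSE)
  }
  structure(list(id = id, seq = seq, orf = orf, introns = sort(introns)),
            class = "unigene")
}

validate_orf_interval <- function(orf, seq_len, id) {
  stopifnot(is.list(orf))
  start <- as.integer(orf$start)
  end <- as.integer(orf$end)
  strand <- if (is.null(orf$strand)) "+" else orf$strand
  if (!strand %in% c("+", "-")) {
    stop("unigene '", id, "': ORF strand must be '+' or '-'", call. = FALSE)
  }
  if (is.na(start) || is.na(end) || start < 0L || start >= end ||
      end > seq_len) {
    stop("unigene '", id, "': invalid ORF interval [", start, ", ", end,
         ") for length ", seq_len, call. = FALSE)
  }
  list(start = start, end = end, strand = strand)
}

#' @export
print.unigene <- function(x, ...) {
  cat("<unigene>", x$id, " (", nchar(x$seq), " bp)\n", sep = "")
  if (!is.null(x$orf)) {
    cat("  ORF: [", x$orf$start, ", ", x$orf$end, ") strand ", x$orf$strand,
        "\n", sep = "")
  }
  if (length(x$introns)) {
    cat("  introns:", paste(x$introns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble a named list of unigenes
#'
#' Joins sequences with optional ORF/intron annotations into the container
#' consumed by the analysis functions. Annotation entries for unknown ids are
#' ignored (annotations may cover a superset of the sequence set).
#'
#' @param seqs Named character vector of sequences, or a list of
#'   `(id, seq)` pairs as returned by [read_fasta()].
#' @param annotations Optional named list as returned by
#'   [read_annotations_gff3()]: per unigene id, a list with `orf`, `introns`.
#' @return Named list of `"unigene"` objects.
#' @export
unigene_set <- function(seqs, annotations = NULL) {
  if (is.list(seqs) && !is.null(seqs[[1]]$id)) {
    ids <- vapply(seqs, `[[`, "", "id")
    seqs <- stats::setNames(vapply(seqs, `[[`, "", "seq"), ids)
  }
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("unigene ids must be present and unique", call. = FALSE)
  }
  out <- lapply(ids, function(id) {
    ann <- annotations[[id]]
    unigene(id, seqs[[id]],
            orf = ann$orf,
            introns = if (is.null(ann$introns)) integer() else ann$introns)
  })
  stats::setNames(out, ids)
}

unigene_lengths <- function(unigenes) {
  vapply(unigenes, function(u) nchar(u$seq), integer(1))
}
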