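#' Read unigene sequences from a FASTA file
#'
#' Sequences are uppercased; `N` is permitted; record order is preserved.
#' Parsing is delegated to [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @return A list of `list(id, seq)` records in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs) | !nzchar(ids)
  if (any(empty)) {
    stop("malformed FASTA '", path, "': empty header or sequence in record ",
         which(empty)[1], " ('", ids[which(empty)[1]], "')", call. = FALSE)
  }
  unname(Map(function(i, s) list(id = i, seq = s), ids, seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences, a list of `(id, seq)`
#'   records, or a unigene set.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_named_seqs(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

as_named_seqs <- function(seqs) {
  if (is.character(seqs)) return(seqs)
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "unigene")) {
    return(vapply(seqs, `[[`, "", "seq"))
  }
  if (is.list(seqs) && length(seqs) && !is.null(seqs[[1]]$id)) {
    return(stats::setNames(vapply(seqs, `[[`, "", "seq"),
                           vapply(seqs, `[[`, "", "id")))
  }
  stop("cannot interpret sequence container", call. = FALSE)
}
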