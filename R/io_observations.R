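#' Read the per-position read-observation table
#'
#' The observation table is the pipeline's evidence model: one row per read
#' base aligned to a unigene position, tab-separated, with header
#' `unigene_id pos genotype read_id allele base_qual map_qual`. `pos` is
#' 0-based. `allele` is a single base `A/C/G/T`, the deletion token `-`
#' (single-base deletion at `pos`), or `+SEQ` (insertion of `SEQ` immediately
#' after `pos`). Qualities are phred-scaled integers.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of typed observations in file order.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obs <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  required <- c("unigene_id", "pos", "genotype", "read_id", "allele",
                "base_qual", "map_qual")
  if (!identical(names(obs), required)) {
    stop("observation table '", path, "': header must be exactly: ",
         paste(required, collapse = " "), call. = FALSE)
  }
  for (col in c("pos", "base_qual", "map_qual")) {
    v <- suppressWarnings(as.integer(obs[[col]]))
    num <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(is.na(v) | is.na(num) | v != num)
    if (length(bad)) {
      stop("observation table '", path, "', line ", bad[1] + 1L,
           ": non-integer ", col, " ('", obs[[col]][bad[1]], "')",
           call. = FALSE)
    }
    if (col != "pos" && any(v < 0L)) {
      stop("observation table '", path, "', line ", which(v < 0L)[1] + 1L,
           ": negative ", col, call. = FALSE)
    }
    if (col == "pos" && any(v < 0L)) {
      stop("observation table '", path, "', line ", which(v < 0L)[1] + 1L,
           ": negative pos", call. = FALSE)
    }
    obs[[col]] <- v
  }
  bad <- which(!grepl("^([ACGT]|-|\\+[ACGT]+)$", obs$allele))
  if (length(bad)) {
    stop("observation table '", path, "', line ", bad[1] + 1L,
         ": invalid allele token '", obs$allele[bad[1]], "'", call. = FALSE)
  }
  obs
}

#' Write a read-observation table
#'
#' @param obs Observation `data.frame` as returned by [read_observations()]
#'   or [gen_read_observations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  required <- c("unigene_id", "pos", "genotype", "read_id", "allele",
                "base_qual", "map_qual")
  stopifnot(all(required %in% names(obs)))
  data.table::fwrite(obs[, required], path, sep = "\t", quote = FALSE)
  invisible(path)
}
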