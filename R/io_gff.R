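#' Read ORF and intron annotations from GFF3
#'
#' Consumes features of type `ORF` (or `CDS`) and `intron` on unigene seqids.
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. When several ORF features are annotated on one
#' unigene only the longest is retained (ties broken by leftmost start). An
#' intron feature contributes one junction position: the 0-based coordinate
#' of its first base. Seqids absent from the sequence set pass through and
#' are joined (or dropped) later.
#'
#' @param path Path to a GFF3 file.
#' @return Named list: per unigene id, `list(orf = list(start, end, strand)
#'   | NULL, introns = integer vector)`.
#' @export
read_annotations_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      stop("malformed GFF3 '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  type <- as.character(gr$type)
  keep <- type %in% c("ORF", "CDS", "intron")
  gr <- gr[keep]
  type <- type[keep]
  if (any(BiocGenerics::width(gr) < 1L)) {
    stop("malformed GFF3 '", path, "': feature with end < start",
         call. = FALSE)
  }
  seqid <- as.character(GenomicRanges::seqnames(gr))
  start1 <- BiocGenerics::start(gr)   # 1-based closed
  end1 <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"

  out <- list()
  for (id in unique(seqid)) {
    sel <- seqid == id
    orf <- NULL
    is_orf <- sel & type %in% c("ORF", "CDS")
    if (any(is_orf)) {
      w <- end1 - start1 + 1L
      w[!is_orf] <- -1L
      best <- which(w == max(w[is_orf]) & is_orf)
      best <- best[order(start1[best])][1]
      orf <- list(start = start1[best] - 1L, end = end1[best],
                  strand = strand[best])
    }
    introns <- sort(start1[sel & type == "intron"] - 1L)
    out[[id]] <- list(orf = orf, introns = as.integer(introns))
  }
  out
}

#' Write ORF and intron annotations to GFF3
#'
#' Inverse of [read_annotations_gff3()]: internal 0-based half-open
#' intervals become 1-based closed GFF3 features of type `ORF` and `intron`
#' (each junction as a single-base feature).
#'
#' @param annotations Named list as returned by [read_annotations_gff3()],
#'   or a unigene set (annotations are extracted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path) {
  if (length(annotations) && inherits(annotations[[1]], "unigene")) {
    annotations <- lapply(annotations, function(u) {
      list(orf = u$orf, introns = u$introns)
    })
  }
  rows <- list()
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    if (!is.null(ann$orf)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = id, type = "ORF",
        start = ann$orf$start + 1L, end = ann$orf$end,
        strand = ann$orf$strand, stringsAsFactors = FALSE)
    }
    for (j in ann$introns) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = id, type = "intron",
        start = j + 1L, end = j + 1L, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand,
    type = tab$type,
    source = "estmarker")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export SSR loci as GFF3 features
#'
#' @param ssrs SSR locus table from [find_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(ssrs, path) {
  if (!nrow(ssrs)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ssrs$unigene_id,
    ranges = IRanges::IRanges(start = ssrs$start + 1L, end = ssrs$end),
    strand = "+",
    type = "microsatellite",
    source = "estmarker",
    motif = ssrs$motif_canonical,
    location = ssrs$location)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
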