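#' @rdname write_vcf
#' @format NULL
#' @export
FILTER_ORDER <- c("VKS", "HVR4", "CS60", "I60", "CL60", "NVSM1", "NVSM2",
                  "CEF")

filter_descriptions <- c(
  VKS   = "Is not an SNP, is an INDEL",
  HVR4  = "The region has more than 4 SNVs per 100 bp",
  CS60  = "SNV is closer than 60 bp to another SNV",
  I60   = "An intron is located closer than 60 bp",
  CL60  = "SNV is closer than 60 bp to the sequence end",
  NVSM1 = "SNV is variable within the second genotype or not sequenced in it",
  NVSM2 = "SNV is variable within the first genotype or not sequenced in it",
  CEF   = "SNV does not alter a restriction target and cannot be detected as a CAPS"
)

# ";"-joined tag string -> character vector (empty string -> character(0))
split_tags <- function(filters) {
  lapply(strsplit(filters, ";", fixed = TRUE), function(x) x[nzchar(x)])
}

# canonical tag string: fixed FILTER_ORDER, "" if untagged
join_tags <- function(tags) {
  vapply(tags, function(t) paste(FILTER_ORDER[FILTER_ORDER %in% t],
                                 collapse = ";"), "")
}

#' Write called variants to VCF 4.0
#'
#' Emits a VCF 4.0 file with one `##FILTER` header line per cascade code
#' (`VKS, HVR4, CS60, I60, CL60, NVSM1, NVSM2, CEF`). POS is 1-based.
#' Untagged records carry `.` in the FILTER column (not `PASS`); tags are
#' semicolon-joined in the fixed cascade order, so output is byte-stable.
#' Per-genotype qualifying alleles are carried in the INFO fields `GA`/`GB`
#' using the observation-table allele dialect (`-` deletion, `+SEQ`
#' insertion); insertions are additionally expressed as anchored ALT
#' alleles and deletions as the symbolic ALT `<DEL>`.
#'
#' @param snvs SNV table from [call_snvs()] (with or without filter tags).
#' @param unigene_lengths Named integer vector of unigene lengths, or a
#'   unigene set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, unigene_lengths, path) {
  if (is.list(unigene_lengths) && length(unigene_lengths) &&
      inherits(unigene_lengths[[1]], "unigene")) {
    unigene_lengths <- unigene_lengths(unigene_lengths)
  }
  unknown <- setdiff(unique(snvs$unigene_id), names(unigene_lengths))
  if (length(unknown)) {
    stop("SNV on unknown unigene: ", unknown[1], call. = FALSE)
  }
  gts <- attr(snvs, "genotypes")
  if (is.null(gts)) gts <- c("A", "B")
  header <- c(
    "##fileformat=VCFv4.0",
    "##source=estmarker",
    sprintf("##FILTER=<ID=%s,Description=\"%s\">",
            FILTER_ORDER, filter_descriptions[FILTER_ORDER]),
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"SNP, INSERTION or DELETION\">",
    "##INFO=<ID=ALS,Number=.,Type=String,Description=\"Qualifying alleles pooled over genotypes\">",
    sprintf("##INFO=<ID=GA,Number=.,Type=String,Description=\"Qualifying alleles in genotype %s\">", gts[1]),
    sprintf("##INFO=<ID=GB,Number=.,Type=String,Description=\"Qualifying alleles in genotype %s\">", gts[2]),
    sprintf("##contig=<ID=%s,length=%d>",
            names(unigene_lengths), as.integer(unigene_lengths)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(0)
  if (nrow(snvs)) {
    o <- order(snvs$unigene_id, snvs$pos)
    snvs <- snvs[o, , drop = FALSE]
    alt <- vapply(seq_len(nrow(snvs)), function(i) {
      alleles <- strsplit(snvs$alleles[i], ",", fixed = TRUE)[[1]]
      ref <- snvs$ref[i]
      alts <- setdiff(alleles, ref)
      if (!length(alts)) return(".")
      vcf_alts <- vapply(sort(alts), function(a) {
        if (a == "-") "<DEL>"
        else if (startsWith(a, "+")) paste0(ref, substring(a, 2))
        else a
      }, "")
      paste(vcf_alts, collapse = ",")
    }, "")
    filt <- join_tags(split_tags(snvs$filters))
    filt[!nzchar(filt)] <- "."
    info <- sprintf("KIND=%s;ALS=%s;GA=%s;GB=%s",
                    snvs$kind, snvs$alleles,
                    ifelse(nzchar(snvs$allele_a), snvs$allele_a, "."),
                    ifelse(nzchar(snvs$allele_b), snvs$allele_b, "."))
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                     snvs$unigene_id, snvs$pos + 1L, snvs$ref, alt, filt,
                     info)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' Recovers position (back to 0-based), kind, per-genotype alleles and the
#' filter tag set for every record.
#'
#' @param path Path to the VCF file.
#' @return An SNV table with the same columns as [call_snvs()] output.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("malformed VCF '", path, "': missing ##fileformat line",
         call. = FALSE)
  }
  gts <- c("A", "B")
  ga_line <- grep("^##INFO=<ID=GA", lines, value = TRUE)
  gb_line <- grep("^##INFO=<ID=GB", lines, value = TRUE)
  if (length(ga_line) && length(gb_line)) {
    gts <- c(sub('.*alleles in genotype ([^"]+)".*', "\\1", ga_line[1]),
             sub('.*alleles in genotype ([^"]+)".*', "\\1", gb_line[1]))
  }
  body <- lines[!startsWith(lines, "#")]
  parse_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else "", "")
  }
  if (!length(body)) {
    out <- empty_snv_table()
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    n <- vapply(f, length, 0L)
    if (any(n < 8L)) {
      stop("malformed VCF '", path, "': record with fewer than 8 columns",
           call. = FALSE)
    }
    chrom <- vapply(f, `[`, "", 1)
    pos1 <- as.integer(vapply(f, `[`, "", 2))
    ref <- vapply(f, `[`, "", 4)
    filt <- vapply(f, `[`, "", 7)
    info <- vapply(f, `[`, "", 8)
    ga <- parse_info(info, "GA")
    gb <- parse_info(info, "GB")
    ga[ga == "."] <- ""
    gb[gb == "."] <- ""
    alleles <- parse_info(info, "ALS")
    out <- data.frame(
      unigene_id = chrom,
      pos = pos1 - 1L,
      kind = parse_info(info, "KIND"),
      ref = ref,
      alleles = alleles,
      allele_a = ga,
      allele_b = gb,
      filters = ifelse(filt == "." | filt == "PASS", "", filt),
      stringsAsFactors = FALSE)
  }
  attr(out, "genotypes") <- gts
  out
}

empty_snv_table <- function() {
  data.frame(unigene_id = character(), pos = integer(), kind = character(),
             ref = character(), alleles = character(),
             allele_a = character(), allele_b = character(),
             filters = character(), stringsAsFactors = FALSE)
}
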