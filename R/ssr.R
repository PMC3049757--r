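#' SSR search parameters
#'
#' Controls the microsatellite scan: which repeat-unit lengths are
#' considered, the minimum number of complete units, and the minimum total
#' locus length in bp (a trailing partial unit counts toward total length
#' but not toward the unit count).
#'
#' @param unit_lengths Subset of `c(2, 3, 4)`.
#' @param min_units Minimum number of complete repeat units (default 4).
#' @param min_total_length Minimum locus length in bp (default 17).
#' @return An object of class `"ssr_params"`.
#' @export
ssr_params <- function(unit_lengths = c(2L, 3L, 4L), min_units = 4L,
                       min_total_length = 17L) {
  unit_lengths <- sort(unique(as.integer(unit_lengths)))
  stopifnot(all(unit_lengths %in% 2:4), min_units >= 2,
            min_total_length >= 2 * min_units)
  structure(list(unit_lengths = unit_lengths,
                 min_units = as.integer(min_units),
                 min_total_length = as.integer(min_total_length)),
            class = "ssr_params")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n), function(i) {
    paste0(substring(unit, i, n), substring(unit, 1, i - 1))
  }, "")
}

#' Canonical form of a repeat unit
#'
#' Repeat units that differ only by cyclic rotation or reverse
#' complementation describe the same microsatellite family (e.g. `GA`,
#' `TC` and `CT` are all `AG` repeats). The canonical representative is the
#' lexicographic minimum over all rotations of the unit and of its reverse
#' complement; the map is idempotent.
#'
#' @param unit Repeat unit over `A,C,G,T`, length 2-4.
#' @return The canonical unit.
#' @export
canonical_motif <- function(unit) {
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit)) {
    stop("ambiguous repeat unit '", unit, "': only A,C,G,T allowed",
         call. = FALSE)
  }
  stopifnot(nchar(unit) >= 2, nchar(unit) <= 4)
  min(c(rotations(unit), rotations(revcomp(unit))))
}

#' Is a repeat unit a power of a shorter unit?
#'
#' `ACAC` is not a genuine tetranucleotide unit: it is two copies of `AC`.
#' Such degenerate units are excluded so that di-, tri- and tetra-repeat
#' classes stay disjoint.
#'
#' @param unit Repeat unit, length 2-4.
#' @return `TRUE` iff `unit` equals a whole-number power of a shorter unit.
#' @export
is_degenerate <- function(unit) {
  n <- nchar(unit)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 &&
        unit == strrep(substring(unit, 1, d), n / d)) {
      return(TRUE)
    }
  }
  FALSE
}

# Maximal perfect tandem runs of period p in a character vector.
# Returns 0-based half-open loci; N breaks runs.
period_runs <- function(chars, p) {
  n <- length(chars)
  if (n <= p) {
    return(data.frame(start = integer(), end = integer()))
  }
  eq <- chars[seq_len(n - p)] == chars[(p + 1):n] &
    chars[seq_len(n - p)] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L,            # 0-based
             end = starts[keep] - 1L + r$lengths[keep] + p)
}

# Longer locus wins; ties broken toward the shorter unit, then leftmost.
resolve_ssr_overlaps <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  o <- order(-cand$total_length, cand$unit_length, cand$start)
  cand <- cand[o, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (cand$start[i] < cand$end[j] && cand$start[j] < cand$end[i]) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  cand <- cand[kept, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Find microsatellites in one unigene
#'
#' Reports every maximal perfect tandem run of a non-degenerate 2-4 bp unit
#' with at least `min_units` complete units and at least `min_total_length`
#' bp in total. Runs may end mid-unit; the fractional tail counts toward the
#' total length. Runs are broken at `N`. Overlapping candidates of different
#' unit length are resolved by keeping the longer locus (ties go to the
#' shorter unit). Each locus is localized relative to the ORF with
#' [localize_ssr()].
#'
#' @param unigene A `"unigene"` object.
#' @param params [ssr_params()].
#' @return A `data.frame` of SSR loci with columns `unigene_id`, `start`,
#'   `end` (0-based half-open), `motif_found`, `motif_canonical`,
#'   `unit_length`, `n_units` (possibly fractional), `total_length`,
#'   `location`.
#' @export
find_ssrs <- function(unigene, params = ssr_params()) {
  stopifnot(inherits(unigene, "unigene"), inherits(params, "ssr_params"))
  chars <- strsplit(unigene$seq, "", fixed = TRUE)[[1]]
  cand <- list()
  for (p in params$unit_lengths) {
    runs <- period_runs(chars, p)
    if (!nrow(runs)) next
    total <- runs$end - runs$start
    full_units <- total %/% p
    keep <- full_units >= params$min_units &
      total >= params$min_total_length
    runs <- runs[keep, , drop = FALSE]
    if (!nrow(runs)) next
    unit <- substring(unigene$seq, runs$start + 1L, runs$start + p)
    genuine <- !vapply(unit, is_degenerate, TRUE)
    runs <- runs[genuine, , drop = FALSE]
    unit <- unit[genuine]
    if (!nrow(runs)) next
    cand[[length(cand) + 1L]] <- data.frame(
      unigene_id = unigene$id,
      start = runs$start, end = runs$end,
      motif_found = unit,
      unit_length = p,
      total_length = runs$end - runs$start,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(cand)) return(empty_ssr_table())
  cand <- do.call(rbind, cand)
  cand <- resolve_ssr_overlaps(cand)
  cand$motif_canonical <- vapply(cand$motif_found, canonical_motif, "",
                                 USE.NAMES = FALSE)
  cand$n_units <- cand$total_length / cand$unit_length
  cand$location <- vapply(seq_len(nrow(cand)), function(i) {
    localize_ssr(list(start = cand$start[i], end = cand$end[i]), unigene)
  }, "")
  rownames(cand) <- NULL
  cand[, ssr_table_columns()]
}

ssr_table_columns <- function() {
  c("unigene_id", "start", "end", "motif_found", "motif_canonical",
    "unit_length", "n_units", "total_length", "location")
}

empty_ssr_table <- function() {
  data.frame(unigene_id = character(), start = integer(), end = integer(),
             motif_found = character(), motif_canonical = character(),
             unit_length = integer(), n_units = numeric(),
             total_length = integer(), location = character(),
             stringsAsFactors = FALSE)
}

#' Find microsatellites in a unigene set
#'
#' @param unigenes Named list of unigenes.
#' @param params [ssr_params()].
#' @return Combined SSR locus table, ordered by unigene then position.
#' @export
mine_ssrs <- function(unigenes, params = ssr_params()) {
  out <- lapply(unigenes, find_ssrs, params = params)
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_ssr_table())
  rownames(out) <- NULL
  out
}

#' Localize an SSR locus relative to the ORF
#'
#' A locus entirely upstream of the ORF is `FIVE_UTR`, entirely inside is
#' `ORF`, entirely downstream is `THREE_UTR`; loci straddling either ORF
#' boundary, and loci on unigenes without an ORF, are `OTHER`. For a
#' minus-strand ORF the UTR labels follow the coding orientation (upstream
#' in unigene coordinates is the 3' UTR).
#'
#' @param locus List or one-row data.frame with `start`, `end` (0-based
#'   half-open).
#' @param unigene The `"unigene"` the locus lies on.
#' @return One of `"FIVE_UTR"`, `"ORF"`, `"THREE_UTR"`, `"OTHER"`.
#' @export
localize_ssr <- function(locus, unigene) {
  orf <- unigene$orf
  if (is.null(orf)) return("OTHER")
  stopifnot(locus$start >= 0, locus$end <= nchar(unigene$seq))
  cls <- if (locus$end <= orf$start) {
    "FIVE_UTR"
  } else if (locus$start >= orf$end) {
    "THREE_UTR"
  } else if (locus$start >= orf$start && locus$end <= orf$end) {
    "ORF"
  } else {
    "OTHER"
  }
  if (orf$strand == "-") {
    cls <- switch(cls, FIVE_UTR = "THREE_UTR", THREE_UTR = "FIVE_UTR", cls)
  }
  cls
}
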