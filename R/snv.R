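#' SNV calling thresholds
#'
#' An allele qualifies at a position when, pooled over both genotypes, it is
#' seen in at least `min_reads_per_allele` reads whose phred base qualities
#' sum to at least `min_allele_quality`. Observations below
#' `min_mapping_quality` are discarded before counting. A position is called
#' a variant when at least two alleles qualify.
#'
#' @param min_allele_quality Minimum accumulated phred base quality per
#'   allele (default 40).
#' @param min_reads_per_allele Minimum supporting reads per allele
#'   (default 2).
#' @param min_mapping_quality Minimum phred mapping quality for an
#'   observation to count (default 20).
#' @return An object of class `"snv_call_params"`.
#' @export
snv_call_params <- function(min_allele_quality = 40,
                            min_reads_per_allele = 2L,
                            min_mapping_quality = 20) {
  stopifnot(min_allele_quality >= 0, min_reads_per_allele >= 0,
            min_mapping_quality >= 0)
  structure(list(min_allele_quality = min_allele_quality,
                 min_reads_per_allele = as.integer(min_reads_per_allele),
                 min_mapping_quality = min_mapping_quality),
            class = "snv_call_params")
}

#' Marker-selection filter thresholds
#'
#' Distances are strict (`<`), center-to-center, in unigene coordinates.
#' `hv_window = NULL` applies the hypervariability rule at the whole-unigene
#' level (total SNVs x 100 / unigene length > `hv_density`); a numeric
#' window size in bp switches to a sliding-window rule instead.
#'
#' @param proximity_bp CS60 distance to another SNV (default 60).
#' @param edge_bp CL60 distance to the sequence end (default 60).
#' @param intron_bp I60 distance to an intron junction (default 60).
#' @param hv_density HVR4 density threshold in SNVs per 100 bp (default 4).
#' @param hv_window `NULL` for unigene-level density, or a window size in bp.
#' @return An object of class `"filter_params"`.
#' @export
filter_params <- function(proximity_bp = 60, edge_bp = 60, intron_bp = 60,
                          hv_density = 4, hv_window = NULL) {
  stopifnot(proximity_bp > 0, edge_bp > 0, intron_bp > 0, hv_density > 0)
  structure(list(proximity_bp = proximity_bp, edge_bp = edge_bp,
                 intron_bp = intron_bp, hv_density = hv_density,
                 hv_window = hv_window),
            class = "filter_params")
}

#' Call SNVs from per-position read evidence
#'
#' Observations failing the mapping-quality cut are discarded. For each
#' position, read count and accumulated base quality are computed per allele
#' pooled across genotypes; an allele qualifies when it meets both
#' thresholds, and a position yields a variant when at least two alleles
#' qualify. The variant is an `INSERTION`/`DELETION` when any qualifying
#' allele is an INDEL token, else a `SNP`. Per genotype, the same thresholds
#' are applied within the genotype to decide which alleles that genotype
#' itself supports (the basis of the NVSM within-genotype-variability
#' filters); a genotype with zero surviving observations at the position is
#' recorded as unsequenced there.
#'
#' @param observations Observation table (see [read_observations()]).
#' @param unigenes Named list of unigenes.
#' @param params [snv_call_params()].
#' @param genotypes Ordered pair of genotype labels (first slot feeds
#'   NVSM2, second NVSM1). Defaults to the sorted labels present.
#' @return SNV table sorted by (unigene, pos): columns `unigene_id`, `pos`,
#'   `kind`, `ref`, `alleles` (pooled qualifying, comma-joined),
#'   `allele_a`/`allele_b` (per-genotype qualifying), `cov_a`/`cov_b`
#'   (post-filter observation counts), `filters` (empty; see
#'   [apply_filters()]). The genotype pair is attached as attribute
#'   `"genotypes"`.
#' @export
call_snvs <- function(observations, unigenes, params = snv_call_params(),
                      genotypes = NULL) {
  stopifnot(inherits(params, "snv_call_params"))
  obs <- data.table::as.data.table(observations)
  lens <- unigene_lengths(unigenes)
  unknown <- setdiff(unique(obs$unigene_id), names(lens))
  if (length(unknown)) {
    stop("observations reference unknown unigene: ", unknown[1],
         call. = FALSE)
  }
  beyond <- obs$pos >= lens[obs$unigene_id]
  if (any(beyond)) {
    i <- which(beyond)[1]
    stop("observation at pos ", obs$pos[i], " beyond length of unigene '",
         obs$unigene_id[i], "'", call. = FALSE)
  }
  if (is.null(genotypes)) {
    genotypes <- sort(unique(obs$genotype))
  }
  if (length(genotypes) != 2L) {
    stop("exactly two genotype labels required, got: ",
         paste(genotypes, collapse = ", "), call. = FALSE)
  }

  obs <- obs[obs$map_qual >= params$min_mapping_quality]
  out <- data.frame(unigene_id = character(), pos = integer(),
                    kind = character(), ref = character(),
                    alleles = character(), allele_a = character(),
                    allele_b = character(), cov_a = integer(),
                    cov_b = integer(), filters = character(),
                    stringsAsFactors = FALSE)
  if (nrow(obs)) {
    unigene_id <- pos <- allele <- base_qual <- genotype <- NULL # NSE guard
    # pooled allele support
    pooled <- obs[, list(n = .N, accq = sum(base_qual)),
                  by = list(unigene_id, pos, allele)]
    pooled$qual <- pooled$n >= params$min_reads_per_allele &
      pooled$accq >= params$min_allele_quality
    nqual <- pooled[, list(n_alleles = sum(qual)), by = list(unigene_id, pos)]
    sites <- nqual[nqual$n_alleles >= 2L]
    if (nrow(sites)) {
      data.table::setkey(sites, unigene_id, pos)
      qal <- pooled[pooled$qual]
      data.table::setkey(qal, unigene_id, pos)
      qal <- qal[sites[, c("unigene_id", "pos")]]
      pooled_str <- qal[, list(alleles = paste(sort(allele), collapse = ",")),
                        by = list(unigene_id, pos)]
      # per-genotype support at called sites
      bygt <- obs[, list(n = .N, accq = sum(base_qual)),
                  by = list(unigene_id, pos, genotype, allele)]
      bygt$qual <- bygt$n >= params$min_reads_per_allele &
        bygt$accq >= params$min_allele_quality
      data.table::setkey(bygt, unigene_id, pos)
      bygt <- bygt[sites[, c("unigene_id", "pos")]]
      gt_str <- function(label) {
        g <- bygt[bygt$genotype == label]
        al <- g[g$qual, list(al = paste(sort(allele), collapse = ",")),
                by = list(unigene_id, pos)]
        cov <- g[, list(cov = sum(n)), by = list(unigene_id, pos)]
        m <- merge(sites[, c("unigene_id", "pos")], cov, all.x = TRUE)
        m <- merge(m, al, all.x = TRUE)
        m$cov[is.na(m$cov)] <- 0L
        m$al[is.na(m$al)] <- ""
        m
      }
      ga <- gt_str(genotypes[1])
      gb <- gt_str(genotypes[2])
      tab <- merge(pooled_str, ga, by = c("unigene_id", "pos"))
      data.table::setnames(tab, c("cov", "al"), c("cov_a", "allele_a"))
      tab <- merge(tab, gb, by = c("unigene_id", "pos"))
      data.table::setnames(tab, c("cov", "al"), c("cov_b", "allele_b"))
      tab <- as.data.frame(tab)
      tab <- tab[order(tab$unigene_id, tab$pos), , drop = FALSE]
      allele_sets <- strsplit(tab$alleles, ",", fixed = TRUE)
      tab$kind <- vapply(allele_sets, function(a) {
        if (any(startsWith(a, "+"))) "INSERTION"
        else if (any(a == "-")) "DELETION"
        else "SNP"
      }, "")
      tab$ref <- substring(
        vapply(unigenes[tab$unigene_id], `[[`, "", "seq"),
        tab$pos + 1L, tab$pos + 1L)
      tab$filters <- ""
      out <- tab[, c("unigene_id", "pos", "kind", "ref", "alleles",
                     "allele_a", "allele_b", "cov_a", "cov_b", "filters")]
      rownames(out) <- NULL
    }
  }
  attr(out, "genotypes") <- genotypes
  out
}

#' Classify a base substitution
#'
#' Purine-purine (`A<->G`) and pyrimidine-pyrimidine (`C<->T`) changes are
#' transitions; all other pairs are transversions. The classification is
#' symmetric in its arguments.
#'
#' @param a,b Two distinct single bases.
#' @return `"TRANSITION"` or `"TRANSVERSION"`.
#' @export
classify_substitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T")) {
    stop("substitution alleles must be single bases, got '", a, "', '", b,
         "'", call. = FALSE)
  }
  if (a == b) stop("substitution requires two distinct bases", call. = FALSE)
  pair <- paste(sort(c(a, b)), collapse = "")
  if (pair %in% c("AG", "CT")) "TRANSITION" else "TRANSVERSION"
}

n_alleles_in <- function(allele_str) {
  lengths(split_tags_comma(allele_str))
}

split_tags_comma <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) v[nzchar(v)])
}

#' Annotate SNVs with the marker-selection filter cascade
#'
#' Adds filter tags to each variant (existing tags, e.g. `CEF` from
#' [annotate_cef()], are preserved; tagging is idempotent and
#' order-independent):
#' \describe{
#'   \item{VKS}{the variant is an INDEL, not a SNP.}
#'   \item{HVR4}{the unigene (or sliding window, see [filter_params()]) has
#'     more than `hv_density` SNVs per 100 bp; tags every SNV of that
#'     unigene.}
#'   \item{CS60}{another SNV lies closer than `proximity_bp` on the same
#'     unigene (both are tagged).}
#'   \item{I60}{an intron junction lies closer than `intron_bp`.}
#'   \item{CL60}{the sequence end lies closer than `edge_bp`.}
#'   \item{NVSM1}{the second genotype supports two or more alleles at the
#'     position, or has no surviving observations there.}
#'   \item{NVSM2}{likewise for the first genotype.}
#' }
#'
#' @param snvs SNV table from [call_snvs()].
#' @param unigenes Named list of unigenes (for lengths and introns).
#' @param params [filter_params()].
#' @return The SNV table with the `filters` column populated.
#' @export
apply_filters <- function(snvs, unigenes, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  if (!nrow(snvs)) return(snvs)
  if (!all(c("cov_a", "cov_b") %in% names(snvs))) {
    stop("SNV table lacks per-genotype coverage columns; ",
         "apply_filters() must run on call_snvs() output", call. = FALSE)
  }
  lens <- unigene_lengths(unigenes)
  tags <- split_tags(snvs$filters)

  add <- function(idx, code) {
    for (i in idx) tags[[i]] <<- union(tags[[i]], code)
  }

  add(which(snvs$kind != "SNP"), "VKS")

  for (uid in unique(snvs$unigene_id)) {
    idx <- which(snvs$unigene_id == uid)
    pos <- snvs$pos[idx]
    len <- lens[[uid]]
    # HVR4: hypervariable unigene (or window)
    if (is.null(params$hv_window)) {
      if (length(idx) * 100 / len > params$hv_density) add(idx, "HVR4")
    } else {
      w <- params$hv_window
      lim <- params$hv_density * w / 100
      for (i in seq_along(idx)) {
        inwin <- pos >= pos[i] & pos < pos[i] + w
        if (sum(inwin) > lim) add(idx[inwin], "HVR4")
      }
    }
    # CS60: proximity to another SNV
    if (length(idx) >= 2) {
      sp <- sort(pos)
      gaps <- diff(sp)
      close_pos <- unique(c(sp[which(gaps < params$proximity_bp)],
                            sp[which(gaps < params$proximity_bp) + 1L]))
      add(idx[pos %in% close_pos], "CS60")
    }
    # I60: proximity to an intron junction
    introns <- unigenes[[uid]]$introns
    if (length(introns)) {
      near <- vapply(pos, function(p) min(abs(p - introns)), 0)
      add(idx[near < params$intron_bp], "I60")
    }
    # CL60: proximity to the sequence end
    add(idx[pmin(pos, len - 1L - pos) < params$edge_bp], "CL60")
  }

  add(which(n_alleles_in(snvs$allele_b) >= 2L | snvs$cov_b == 0L), "NVSM1")
  add(which(n_alleles_in(snvs$allele_a) >= 2L | snvs$cov_a == 0L), "NVSM2")

  snvs$filters <- join_tags(tags)
  snvs
}

#' Split filtered SNVs into genotyping-ready candidate sets
#'
#' The high-throughput (Golden Gate style) set keeps variants whose tag set
#' is empty or `{CEF}` only — clean SNPs regardless of CAPS detectability.
#' The CAPS set keeps variants with no tags at all, i.e. clean SNPs that do
#' alter a restriction target. The CAPS set is a subset of the first.
#'
#' @param snvs SNV table with filters applied (including CEF).
#' @return `list(golden_gate, caps)` of SNV tables.
#' @export
select_candidates <- function(snvs) {
  tags <- split_tags(snvs$filters)
  gg <- vapply(tags, function(t) all(t %in% "CEF"), TRUE)
  caps <- lengths(tags) == 0L
  list(golden_gate = snvs[gg, , drop = FALSE],
       caps = snvs[caps, , drop = FALSE])
}
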