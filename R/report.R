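LOCATION_LEVELS <- c("FIVE_UTR", "ORF", "THREE_UTR", "OTHER")
SUBSTITUTION_PAIRS <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")

#' Class shares from SSR class counts
#'
#' @param counts Named counts per repeat class (e.g. `c(di = 296,
#'   tri = 1387, tetra = 252)` or names `2,3,4`).
#' @param digits Decimal places for percentages.
#' @return A `data.frame` with `class`, `count`, `percent`.
#' @export
ssr_class_summary <- function(counts, digits = 1) {
  total <- sum(counts)
  data.frame(class = names(counts),
             count = as.integer(counts),
             percent = if (total > 0) round(100 * counts / total, digits)
                       else rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize an SSR locus table
#'
#' Produces the standard microsatellite summary: counts and shares per
#' unit-length class, per-class canonical-motif tables (motifs sorted by
#' descending count, then alphabetically), and the localization cross-tab
#' (class x FIVE_UTR/ORF/THREE_UTR/OTHER with row/column totals).
#'
#' @param ssrs SSR locus table from [mine_ssrs()].
#' @param digits Decimal places for percentages.
#' @return List with `classes`, `motifs` (list per class), `localization`
#'   (count matrix with margins), `localization_percent`.
#' @export
summarize_ssrs <- function(ssrs, digits = 1) {
  if (!nrow(ssrs)) {
    return(list(classes = ssr_class_summary(integer(0), digits),
                motifs = list(),
                localization = NULL, localization_percent = NULL))
  }
  cls <- factor(ssrs$unit_length, levels = c(2, 3, 4),
                labels = c("di", "tri", "tetra"))
  classes <- ssr_class_summary(table(cls), digits)
  motifs <- lapply(split(ssrs$motif_canonical, cls), function(m) {
    tab <- sort(table(m), decreasing = TRUE)
    tab <- tab[order(-as.integer(tab), names(tab))]
    data.frame(motif = names(tab), count = as.integer(tab),
               percent = round(100 * as.integer(tab) / sum(tab), digits),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  loc <- factor(ssrs$location, levels = LOCATION_LEVELS)
  xt <- table(loc, cls)
  xt <- stats::addmargins(xt)
  col_tot <- xt["Sum", ]
  pct <- sweep(xt, 2, col_tot, "/") * 100
  list(classes = classes, motifs = motifs,
       localization = xt,
       localization_percent = round(pct, digits))
}

#' Substitution spectrum from per-pair counts
#'
#' @param pair_counts Named counts per substitution pair; names like
#'   `"A/G"` (order within the pair irrelevant).
#' @param digits Decimal places for the transition/transversion shares.
#' @return List with `pairs` (data.frame pair/count/class),
#'   `n_transitions`, `n_transversions`, `transition_pct`,
#'   `transversion_pct`.
#' @export
snv_spectrum <- function(pair_counts, digits = 0) {
  norm <- vapply(names(pair_counts), function(p) {
    b <- sort(strsplit(toupper(p), "[/<>-]+")[[1]])
    paste(b, collapse = "/")
  }, "")
  counts <- stats::setNames(integer(length(SUBSTITUTION_PAIRS)),
                            SUBSTITUTION_PAIRS)
  for (i in seq_along(pair_counts)) {
    counts[norm[i]] <- counts[norm[i]] + as.integer(pair_counts[i])
  }
  cls <- vapply(names(counts), function(p) {
    b <- strsplit(p, "/", fixed = TRUE)[[1]]
    classify_substitution(b[1], b[2])
  }, "")
  n_ts <- sum(counts[cls == "TRANSITION"])
  n_tv <- sum(counts[cls == "TRANSVERSION"])
  total <- n_ts + n_tv
  list(pairs = data.frame(pair = names(counts), count = as.integer(counts),
                          class = cls, stringsAsFactors = FALSE,
                          row.names = NULL),
       n_transitions = n_ts, n_transversions = n_tv,
       transition_pct = if (total) round(100 * n_ts / total, digits) else NA,
       transversion_pct = if (total) round(100 * n_tv / total, digits) else NA)
}

#' Filter attrition table
#'
#' @param filter_counts Named counts of variants carrying each filter tag.
#' @param total Total number of variants.
#' @param digits Decimal places for percentages.
#' @return A `data.frame` with `filter`, `count`, `percent`.
#' @export
attrition_summary <- function(filter_counts, total, digits = 1) {
  data.frame(filter = names(filter_counts),
             count = as.integer(filter_counts),
             percent = round(100 * as.numeric(filter_counts) / total, digits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variant density and unigene coverage
#'
#' @param n_snvs Total variants (SNPs plus INDELs).
#' @param n_variable_unigenes Unigenes containing at least one variant.
#' @param n_unigenes Unigenes screened.
#' @param digits Decimal places.
#' @return List with `mean_per_variable_unigene` and
#'   `variable_unigene_pct`.
#' @export
snv_density <- function(n_snvs, n_variable_unigenes, n_unigenes,
                        digits = 1) {
  list(mean_per_variable_unigene =
         round(n_snvs / n_variable_unigenes, digits),
       variable_unigene_pct =
         round(100 * n_variable_unigenes / n_unigenes, digits))
}

#' Summarize a called, filtered SNV table
#'
#' Builds the substitution spectrum (each segregating allele pair of a SNP
#' counted once, so multi-allelic SNPs contribute one count per pair), the
#' per-filter attrition table, and density/coverage statistics.
#'
#' @param snvs SNV table with filters applied.
#' @param unigene_count Number of unigenes screened.
#' @param est_counts Optional named vector of reads (ESTs) per unigene.
#' @param digits Decimal places for percentages.
#' @return List with `spectrum`, `attrition`, `density`, `n_snps`,
#'   `n_indels`, and `ests_per_unigene_mean` (when `est_counts` given).
#' @export
summarize_snvs <- function(snvs, unigene_count, est_counts = NULL,
                           digits = 1) {
  is_snp <- snvs$kind == "SNP"
  pair_counts <- stats::setNames(integer(length(SUBSTITUTION_PAIRS)),
                                 SUBSTITUTION_PAIRS)
  for (al in strsplit(snvs$alleles[is_snp], ",", fixed = TRUE)) {
    al <- al[nchar(al) == 1L & al %in% c("A", "C", "G", "T")]
    if (length(al) < 2) next
    for (pr in utils::combn(sort(al), 2, simplify = FALSE)) {
      key <- paste(pr, collapse = "/")
      pair_counts[key] <- pair_counts[key] + 1L
    }
  }
  tags <- split_tags(snvs$filters)
  filter_counts <- vapply(FILTER_ORDER, function(code) {
    sum(vapply(tags, function(t) code %in% t, TRUE))
  }, 0L)
  nvar <- length(unique(snvs$unigene_id))
  out <- list(
    spectrum = snv_spectrum(pair_counts, digits = 0),
    attrition = attrition_summary(filter_counts, nrow(snvs), digits),
    density = snv_density(nrow(snvs), nvar, unigene_count, digits),
    n_snps = sum(is_snp),
    n_indels = sum(!is_snp))
  if (!is.null(est_counts)) {
    out$ests_per_unigene_mean <- round(mean(est_counts), digits)
  }
  out
}
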