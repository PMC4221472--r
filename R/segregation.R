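#' Genotype-pattern segregation filter
#'
#' The funnel's first stage. Under a fully penetrant autosomal dominant
#' model, a variant fixed on the founder affected haplotype must be
#' homozygous-alt in every homozygous affected bird, heterozygous in every
#' heterozygous affected bird, and absent (homozygous reference) from the
#' unaffected bird. `segregation_filter()` keeps exactly the variants whose
#' per-sample genotype classes all match the design's expected classes.
#' For the 3 hom-affected / 2 het-affected / 1 unaffected design, exactly 1
#' of the 729 possible non-missing class assignments passes.
#'
#' @param variants Variant tibble from [read_vcf()]; must carry a genotype
#'   column for every design sample.
#' @param design A [cohort_design()].
#' @param missing_policy `"fail"` (default: a MISSING genotype disqualifies
#'   the variant) or `"pass"` (MISSING is compatible with any expectation).
#' @return The retained subset of `variants`, input order preserved.
#' @export
segregation_filter <- function(variants, design,
                               missing_policy = c("fail", "pass")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(design, "cohort_design"))
  absent <- setdiff(design$sample_id, names(variants))
  if (length(absent) > 0L) {
    stop("variant table lacks genotype column(s) for design sample(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(variants) == 0L) return(variants)
  keep <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(design))) {
    keep <- keep & genotype_matches_model(variants[[design$sample_id[i]]],
                                          design$expected_class[i],
                                          missing_policy)
  }
  variants[keep, , drop = FALSE]
}

#' Remove previously catalogued variants
#'
#' Drops every variant whose (chrom, pos, ref, alt) key appears in the
#' known set — the analogue of subtracting database variants seen in
#' unaffected (tailed) birds and therefore not causative. With
#' `by = "position"` matching ignores alleles (the database match criterion
#' is configurable because catalogues differ in how they record alleles).
#'
#' @param variants Variant tibble.
#' @param known A `known_variant_set` from [read_known_variants()] (or any
#'   tibble with chrom/pos/ref/alt).
#' @param by `"key"` (default; exact chrom+pos+ref+alt match) or
#'   `"position"` (chrom+pos only).
#' @return The retained subset of `variants`, input order preserved.
#' @export
exclude_known <- function(variants, known, by = c("key", "position")) {
  by <- match.arg(by)
  cols <- if (by == "key") c("chrom", "pos", "ref", "alt") else c("chrom", "pos")
  if (nrow(variants) == 0L || is.null(known) || nrow(known) == 0L) {
    return(variants)
  }
  dplyr::anti_join(variants, known[, cols, drop = FALSE], by = cols)
}

#' Tally a variant table by kind
#'
#' @param variants Variant tibble.
#' @return Named list with counts `SNP`, `MNV`, `INS`, `DEL`, the combined
#'   `indel` (INS + DEL), and `total`.
#' @examples
#' # 5 SNPs + 3 insertions + 2 deletions -> indel = 5, total = 10
#' @export
count_by_kind <- function(variants) {
  k <- factor(variants$kind, levels = VARIANT_KINDS)
  n <- as.list(table(k))
  n <- lapply(n, as.integer)
  n$indel <- n$INS + n$DEL
  n$total <- nrow(variants)
  n
}
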