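# Genotype classes and variant kinds.

GT_CLASSES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")
VARIANT_KINDS <- c("SNP", "INS", "DEL", "MNV")

#' Classify a variant by ref/alt allele lengths
#'
#' Length-rule classification: equal length 1 -> SNP, equal length > 1 ->
#' MNV, longer alt -> INS, shorter alt -> DEL.
#'
#' @param ref,alt Non-empty allele strings (vectorised).
#' @return Character vector of `"SNP"`, `"MNV"`, `"INS"` or `"DEL"`.
#' @examples
#' classify_variant_kind("A", "G")    # SNP
#' classify_variant_kind("ATT", "A")  # DEL
#' @export
classify_variant_kind <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || anyNA(ref) || anyNA(alt)) {
    stop("ref and alt alleles must be non-empty", call. = FALSE)
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == la & lr == 1L ~ "SNP",
    lr == la            ~ "MNV",
    la > lr             ~ "INS",
    TRUE                ~ "DEL"
  )
}

#' Genotype class from a VCF GT string, relative to one alt allele
#'
#' Multiallelic records are split per alt; classification is relative to the
#' retained alt index: two retained-alt alleles -> HOM_ALT, exactly one ->
#' HET (an allele of another alt counts as non-ref, so "1/2" is HET for
#' either alt), none -> HOM_REF. Any missing allele (".", "./.", half-calls)
#' -> MISSING. Unparseable GT strings -> MISSING (callers may warn).
#'
#' @param gt Character vector of GT fields (e.g. "0/1", "1|1", "./.").
#' @param alt_index Integer allele index of the retained alt (1 for the
#'   first alt).
#' @return Character vector of genotype classes.
#' @export
gt_class_from_gt <- function(gt, alt_index = 1L) {
  vapply(gt, function(g) {
    if (is.na(g) || !nzchar(g)) return("MISSING")
    g <- sub(":.*$", "", g)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L) return("MISSING")
    if (any(alleles == "." | !grepl("^[0-9]+$", alleles))) return("MISSING")
    a <- as.integer(alleles)
    n_alt <- sum(a == alt_index)
    if (n_alt == 2L) "HOM_ALT" else if (n_alt == 1L) "HET" else "HOM_REF"
  }, character(1), USE.NAMES = FALSE)
}

#' Does a genotype class match the class expected under the design?
#'
#' @param gt_class Genotype class (`"HOM_REF"`, `"HET"`, `"HOM_ALT"`,
#'   `"MISSING"`); vectorised.
#' @param expected Expected class from the cohort design.
#' @param missing_policy `"fail"` (a MISSING genotype never matches; the
#'   default, conservative) or `"pass"` (MISSING is compatible with any
#'   expectation).
#' @return Logical vector.
#' @export
genotype_matches_model <- function(gt_class, expected,
                                   missing_policy = c("fail", "pass")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(all(gt_class %in% GT_CLASSES), all(expected %in% GT_CLASSES[1:3]))
  ifelse(gt_class == "MISSING", missing_policy == "pass", gt_class == expected)
}
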