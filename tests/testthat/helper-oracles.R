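# Independent oracles and fixture builders. Each oracle is written from
# the operation's definition, not from the implementation it checks.

default_design <- function() {
  cohort_design(
    c("ARH1", "ARH2", "ARH3", "ARE1", "ARE2", "ATL1"),
    c(rep("AFFECTED", 5), "UNAFFECTED"),
    c("HOM_ALT", "HOM_ALT", "HOM_ALT", "HET", "HET", "HOM_REF"))
}

# variant table from a matrix of genotype classes (rows = variants)
make_variants <- function(classes, design, pos = NULL, chrom = "chr2",
                          ref = "A", alt = "G") {
  if (is.null(dim(classes))) classes <- matrix(classes, nrow = 1)
  n <- nrow(classes)
  if (is.null(pos)) pos <- seq(1000, by = 100, length.out = n)
  out <- tibble::tibble(chrom = chrom, pos = as.double(pos),
                        ref = rep_len(ref, n), alt = rep_len(alt, n),
                        kind = classify_variant_kind(rep_len(ref, n),
                                                     rep_len(alt, n)))
  for (j in seq_len(ncol(classes))) out[[design$sample_id[j]]] <- classes[, j]
  out
}

# every genotype-class assignment for k samples (3^k rows, non-missing)
all_class_assignments <- function(k) {
  g <- expand.grid(rep(list(c("HOM_REF", "HET", "HOM_ALT")), k),
                   stringsAsFactors = FALSE)
  as.matrix(g)
}

# oracle: test each sample's genotype independently, one at a time
oracle_segregates <- function(classes, design, missing_policy = "fail") {
  for (i in seq_len(nrow(design))) {
    g <- classes[i]
    if (g == "MISSING") {
      if (missing_policy == "fail") return(FALSE) else next
    }
    if (g != design$expected_class[i]) return(FALSE)
  }
  TRUE
}

# oracle: exhaustive scan over all maximal runs of markers free of
# AFFECTED_HAP calls, applying the documented boundary convention
oracle_exclusion_map <- function(pos, call_mat, original) {
  if (is.null(dim(call_mat))) call_mat <- matrix(call_mat, ncol = 1)
  n <- length(pos)
  blocking <- apply(call_mat == "AFFECTED_HAP", 1, any)
  supporting <- apply(call_mat == "UNAFFECTED_HAP", 1, all)
  res <- list()
  i <- 1
  while (i <= n) {
    if (blocking[i]) { i <- i + 1; next }
    j <- i
    while (j < n && !blocking[j + 1]) j <- j + 1
    sup <- which(supporting[i:j]) + i - 1
    left <- if (i == 1) original$start else if (length(sup)) pos[min(sup)] else NA
    right <- if (j == n) original$end else if (length(sup)) pos[max(sup)] else NA
    if (!is.na(left) && !is.na(right) && left <= right) {
      res[[length(res) + 1]] <- c(left, right)
    }
    i <- j + 1
  }
  res
}

# oracle: optimal global alignment score by exhaustive recursion over all
# alignments (exponential; use only for very short sequences)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(av), length(bv))
}

# independent implementation cross-check via Biostrings (same scoring)
biostrings_nw_score <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = sm,
                                gapOpening = 0, gapExtension = 2,
                                scoreOnly = TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small scaled-down study spec for fast simulation loops
small_spec <- function(seed, ...) {
  args <- utils::modifyList(list(
    region = genomic_interval("chr2", 1e6, 1.2e6),
    causal_pos = 1.1e6,
    n_linked_private = 40L, n_linked_indels = 6L, n_known_overlap = 5L,
    n_noise = 150L, n_candidates_in_interval = 2L,
    recombinant = c(1.08e6, 1.13e6), n_markers = 7L,
    deletion_pos = 1.15e6, deletion_len = 12L,
    window_width = 120L,
    seed = seed), list(...))
  do.call(cohort_spec, args)
}
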