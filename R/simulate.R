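# Synthetic-study generator.
#
# Emits a complete simulated mapping study — multi-sample VCF, design TSV,
# known-variant VCF, marker haplotype TSV, ortholog-window FASTA, gene
# model GFF3 and a truth record — with the statistical structure the
# analysis assumes: a causal SNP fixed on a founder affected haplotype,
# linked private variants riding the same haplotype, non-segregating noise
# variants, and one unaffected recombinant carrying part of the affected
# haplotype, whose marker calls narrow the critical interval.

#' Specification of a synthetic mapping study
#'
#' Defaults mirror the rumpless-mapping study design: a 740 kb critical
#' region on chromosome 2, three homozygous affected, two heterozygous
#' affected and one unaffected genome, a causal SNP at 86,594,449 on the
#' founder haplotype with 315 linked private variants (24 of them
#' indels, including a 55 bp deletion at 86,830,975), 18 of the linked
#' SNPs also present in the known-variant catalogue, 1776 noise variants
#' (funnel 2092 -> 316 -> 298), and a recombinant unaffected carrier whose
#' breakpoints narrow the interval to 86,476,559--86,601,705 containing
#' exactly 2 surviving SNPs.
#'
#' @param region [genomic_interval()] for the simulated critical region.
#' @param n_hom_affected,n_het_affected,n_unaffected Cohort group sizes.
#' @param causal_pos Position of the planted causal SNP; must lie inside
#'   `region` (and inside the recombinant's breakpoints, if set, for the
#'   narrowed interval to contain it).
#' @param n_linked_private Count of non-causal variants private to the
#'   affected haplotype (these segregate perfectly, like the causal SNP).
#' @param n_linked_indels How many linked variants are indels rather than
#'   SNPs; placed outside the narrowed interval.
#' @param n_known_overlap How many linked SNPs are also written into the
#'   known-variant set (and hence removed by [exclude_known()]).
#' @param n_noise Count of variants whose genotype pattern is drawn
#'   uniformly from the non-segregating class assignments (for the default
#'   3/2/1 design, the 728 of 729 patterns that fail the filter), so
#'   collision with the segregating pattern is impossible by construction.
#' @param n_candidates_in_interval Total surviving variants (causal
#'   included) placed inside the narrowed interval; ignored when
#'   `recombinant` is NULL.
#' @param recombinant Length-2 numeric `(breakpoint_left,
#'   breakpoint_right)` for the unaffected recombinant carrier `RB1`, or
#'   NULL for no recombinant. RB1 carries the affected haplotype at
#'   markers outside the open interval `(left, right)` and the unaffected
#'   haplotype inside it.
#' @param n_markers Number of diagnostic haplotype markers (>= 2 when
#'   `recombinant` is set: the two inner-flank markers at
#'   `breakpoint_left + 1` and `breakpoint_right - 1` are always placed).
#' @param deletion_pos,deletion_len Site and length of a planted private
#'   deletion among the linked indels (NULL to disable); the default
#'   55 bp deletion spans 86,830,975--86,831,030.
#' @param missing_rate Per-genotype probability of masking a cohort call
#'   to missing ("./.").
#' @param ortholog_rates Named per-species substitution rates used to
#'   mutate the query window into orthologous windows.
#' @param window_width Conservation window width in bp.
#' @param seed Integer seed; all outputs are deterministic given the spec.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(region = genomic_interval("chr2", 86110000, 86850000),
                        n_hom_affected = 3L,
                        n_het_affected = 2L,
                        n_unaffected = 1L,
                        causal_pos = 86594449,
                        n_linked_private = 315L,
                        n_linked_indels = 24L,
                        n_known_overlap = 18L,
                        n_noise = 1776L,
                        n_candidates_in_interval = 2L,
                        recombinant = c(86476558, 86601706),
                        n_markers = 9L,
                        deletion_pos = 86830975,
                        deletion_len = 55L,
                        missing_rate = 0,
                        ortholog_rates = c(melGal1 = 0.03, taeGut2 = 0.05,
                                           geoFor1 = 0.08),
                        window_width = 300L,
                        seed = 1L) {
  spec <- list(region = region, n_hom_affected = as.integer(n_hom_affected),
               n_het_affected = as.integer(n_het_affected),
               n_unaffected = as.integer(n_unaffected),
               causal_pos = as.double(causal_pos),
               n_linked_private = as.integer(n_linked_private),
               n_linked_indels = as.integer(n_linked_indels),
               n_known_overlap = as.integer(n_known_overlap),
               n_noise = as.integer(n_noise),
               n_candidates_in_interval = as.integer(n_candidates_in_interval),
               recombinant = if (is.null(recombinant)) NULL else as.double(recombinant),
               n_markers = as.integer(n_markers),
               deletion_pos = if (is.null(deletion_pos)) NULL else as.double(deletion_pos),
               deletion_len = as.integer(deletion_len),
               missing_rate = as.double(missing_rate),
               ortholog_rates = ortholog_rates,
               window_width = as.integer(window_width),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  r <- spec$region
  counts <- c(spec$n_hom_affected, spec$n_het_affected, spec$n_unaffected,
              spec$n_linked_private, spec$n_linked_indels,
              spec$n_known_overlap, spec$n_noise)
  if (any(counts < 0L)) stop("all counts must be >= 0", call. = FALSE)
  if (spec$n_hom_affected + spec$n_het_affected + spec$n_unaffected < 1L) {
    stop("cohort must contain at least one sample", call. = FALSE)
  }
  if (spec$causal_pos < r$start || spec$causal_pos > r$end) {
    stop("causal_pos outside region", call. = FALSE)
  }
  if (spec$missing_rate < 0 || spec$missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(spec$recombinant)) {
    bk <- spec$recombinant
    if (length(bk) != 2L || bk[1] >= bk[2] ||
        bk[1] < r$start || bk[2] > r$end) {
      stop("recombinant breakpoints must be ordered and within region",
           call. = FALSE)
    }
    if (spec$n_markers < 2L) {
      stop("n_markers must be >= 2 when a recombinant is simulated",
           call. = FALSE)
    }
    k_in <- max(0L, spec$n_candidates_in_interval - 1L)
    if (spec$n_linked_private - k_in - spec$n_linked_indels <
        spec$n_known_overlap) {
      stop("n_linked_private too small for the requested indel/known/",
           "in-interval partition", call. = FALSE)
    }
  } else if (spec$n_linked_private - spec$n_linked_indels <
             spec$n_known_overlap) {
    stop("n_linked_private too small for the requested indel/known partition",
         call. = FALSE)
  }
  invisible(spec)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sample_ids_for <- function(spec) {
  c(if (spec$n_hom_affected > 0L) paste0("ARH", seq_len(spec$n_hom_affected)),
    if (spec$n_het_affected > 0L) paste0("ARE", seq_len(spec$n_het_affected)),
    if (spec$n_unaffected > 0L) paste0("ATL", seq_len(spec$n_unaffected)))
}

#' Cohort design implied by a spec
#' @param spec A [cohort_spec()].
#' @return A [cohort_design()].
#' @export
design_for_spec <- function(spec) {
  cohort_design(
    sample_ids_for(spec),
    c(rep("AFFECTED", spec$n_hom_affected + spec$n_het_affected),
      rep("UNAFFECTED", spec$n_unaffected)),
    c(rep("HOM_ALT", spec$n_hom_affected), rep("HET", spec$n_het_affected),
      rep("HOM_REF", spec$n_unaffected)))
}

#' Simulate a complete mapping study
#'
#' Deterministic given the spec (same spec, same seed -> byte-identical
#' files). Sampling order: marker positions and alleles first, then
#' in-interval linked positions, remaining linked positions, noise
#' positions, alleles, noise genotype patterns, missing-genotype masking,
#' and finally the ortholog windows.
#'
#' @param spec A [cohort_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisible list: file `paths` (vcf, design, known, markers,
#'   orthologs, genes, truth) and the `truth` record (causal key, linked
#'   keys, known keys, breakpoints, expected counts, expected interval).
#' @export
simulate_study <- function(spec, outdir) {
  validate_cohort_spec(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  design <- design_for_spec(spec)
  r <- spec$region
  bk <- spec$recombinant
  narrowed <- if (!is.null(bk)) {
    genomic_interval(r$chrom, bk[1] + 1, bk[2] - 1)
  } else {
    r
  }

  study <- with_seed(spec$seed, {
    reserved <- spec$causal_pos

    # gene models (synthetic stand-ins for the IRX cluster) sit outside
    # the narrowed interval; linked variants avoid their spans, matching
    # a study in which no surviving variant is genic for these genes
    genes <- synthetic_gene_models(r, narrowed)
    gene_block <- unlist(lapply(seq_len(nrow(genes)), function(i) {
      seq(genes$gene_start[i], genes$gene_end[i])
    }))

    # markers: with a recombinant, the inner flanks (bk +/- 1) pin the
    # narrowed interval's endpoints and one anchor marker on each side
    # outside the breakpoints (where space exists) delimits the run
    if (!is.null(bk)) {
      flanks <- c(bk[1] + 1, bk[2] - 1)
      anchors <- double()
      if (bk[1] > r$start) anchors <- c(anchors, floor((r$start + bk[1]) / 2))
      if (bk[2] < r$end) anchors <- c(anchors, ceiling((bk[2] + r$end) / 2))
      anchors <- anchors[!(anchors %in% c(reserved, flanks))]
      fixed <- c(flanks, anchors)
      pool <- setdiff_positions(r$start, r$end, c(reserved, fixed))
      extra <- resample(pool, max(0L, spec$n_markers - length(fixed)))
      marker_pos <- sort(c(fixed, extra))
    } else {
      pool <- setdiff_positions(r$start, r$end, reserved)
      marker_pos <- sort(resample(pool, spec$n_markers))
    }
    reserved <- c(reserved, marker_pos)
    bases <- c("A", "C", "G", "T")
    aff_allele <- sample(bases, spec$n_markers, replace = TRUE)
    unaff_allele <- vapply(aff_allele, function(a) {
      sample(setdiff(bases, a), 1L)
    }, character(1), USE.NAMES = FALSE)

    # linked positions
    k_in <- if (!is.null(bk)) max(0L, spec$n_candidates_in_interval - 1L) else 0L
    in_pool <- setdiff_positions(narrowed$start, narrowed$end,
                                 c(reserved, gene_block))
    pos_in <- if (k_in > 0L) resample(in_pool, k_in) else double()
    reserved <- c(reserved, pos_in)

    n_out <- spec$n_linked_private - k_in
    if (!is.null(bk)) {
      out_pool <- c(setdiff_positions(r$start, narrowed$start - 1,
                                      c(reserved, gene_block, spec$deletion_pos)),
                    setdiff_positions(narrowed$end + 1, r$end,
                                      c(reserved, gene_block, spec$deletion_pos)))
    } else {
      out_pool <- setdiff_positions(r$start, r$end,
                                    c(reserved, gene_block, spec$deletion_pos))
    }
    plant_del <- !is.null(spec$deletion_pos) && spec$n_linked_indels > 0L &&
      spec$deletion_pos >= r$start && spec$deletion_pos <= r$end &&
      (is.null(bk) || spec$deletion_pos > bk[2] || spec$deletion_pos < bk[1])
    n_draw_out <- n_out - as.integer(plant_del)
    pos_out <- resample(out_pool, n_draw_out)
    if (plant_del) pos_out <- c(spec$deletion_pos, pos_out)
    reserved <- c(reserved, pos_out)

    # noise positions (anywhere in the region)
    noise_pool <- setdiff_positions(r$start, r$end, reserved)
    pos_noise <- resample(noise_pool, spec$n_noise)

    # alleles: indels and known-overlap SNPs live among the out-of-interval
    # linked variants; the causal variant and in-interval extras are SNPs
    linked <- tibble::tibble(pos = c(pos_in, pos_out),
                             in_interval = c(rep(TRUE, length(pos_in)),
                                             rep(FALSE, length(pos_out))))
    is_indel <- rep(FALSE, nrow(linked))
    out_idx <- which(!linked$in_interval)
    if (spec$n_linked_indels > 0L && length(out_idx) > 0L) {
      if (plant_del) {
        del_row <- which(linked$pos == spec$deletion_pos)
        more <- resample(setdiff(out_idx, del_row),
                       min(spec$n_linked_indels, length(out_idx)) - 1L)
        is_indel[c(del_row, more)] <- TRUE
      } else {
        is_indel[resample(out_idx, min(spec$n_linked_indels, length(out_idx)))] <- TRUE
      }
    }
    known_idx <- if (spec$n_known_overlap > 0L) {
      resample(which(!linked$in_interval & !is_indel), spec$n_known_overlap)
    } else {
      integer()
    }

    alleles <- draw_alleles(linked$pos, is_indel, spec)
    causal <- tibble::tibble(pos = spec$causal_pos, ref = sample(bases, 1L))
    causal$alt <- sample(setdiff(bases, causal$ref), 1L)
    noise_alleles <- draw_alleles(pos_noise, rep(FALSE, length(pos_noise)), spec)

    # genotype patterns
    n_samples <- nrow(design)
    seg_pattern <- design$expected_class
    noise_patterns <- draw_nonsegregating_patterns(spec$n_noise, seg_pattern)

    variants <- dplyr::bind_rows(
      tibble::tibble(chrom = r$chrom, pos = causal$pos, ref = causal$ref,
                     alt = causal$alt, role = "causal"),
      tibble::tibble(chrom = r$chrom, pos = linked$pos, ref = alleles$ref,
                     alt = alleles$alt,
                     role = as.character(
                       ifelse(seq_len(nrow(linked)) %in% known_idx,
                              "linked_known", "linked"))),
      tibble::tibble(chrom = r$chrom, pos = pos_noise,
                     ref = noise_alleles$ref, alt = noise_alleles$alt,
                     role = "noise"))
    variants$kind <- classify_variant_kind(variants$ref, variants$alt)

    class_mat <- matrix("", nrow(variants), n_samples,
                        dimnames = list(NULL, design$sample_id))
    seg_rows <- variants$role != "noise"
    class_mat[seg_rows, ] <- matrix(rep(seg_pattern, sum(seg_rows)),
                                    ncol = n_samples, byrow = TRUE)
    if (spec$n_noise > 0L) class_mat[!seg_rows, ] <- noise_patterns
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(class_mat)) < spec$missing_rate,
                     nrow(class_mat))
      class_mat[mask] <- "MISSING"
    }

    ord <- order(variants$pos)
    variants <- variants[ord, ]
    class_mat <- class_mat[ord, , drop = FALSE]

    # marker genotypes
    geno <- list()
    for (i in seq_len(nrow(design))) {
      geno[[design$sample_id[i]]] <- switch(
        design$expected_class[i],
        HOM_ALT = paste(aff_allele, aff_allele, sep = "/"),
        HET = paste(aff_allele, unaff_allele, sep = "/"),
        HOM_REF = paste(unaff_allele, unaff_allele, sep = "/"))
    }
    if (!is.null(bk)) {
      inside <- marker_pos > bk[1] & marker_pos < bk[2]
      geno[["RB1"]] <- ifelse(inside,
                              paste(unaff_allele, unaff_allele, sep = "/"),
                              paste(aff_allele, unaff_allele, sep = "/"))
    }
    markers <- marker_table(marker_pos, aff_allele, unaff_allele, geno)

    # conservation windows: a random query window around the causal SNP,
    # mutated per species at the spec's substitution rates
    w <- spec$window_width
    query <- paste(sample(bases, w, replace = TRUE), collapse = "")
    orthologs <- c(query = query,
                   vapply(spec$ortholog_rates, function(rate) {
                     mutate_sequence(query, rate)
                   }, character(1)))

    list(variants = variants, class_mat = class_mat, markers = markers,
         genes = genes, orthologs = orthologs)
  })

  variants <- study$variants
  known_keys <- variants[variants$role == "linked_known",
                         c("chrom", "pos", "ref", "alt")]
  linked_keys <- variants[variants$role %in% c("linked", "linked_known"),
                          c("chrom", "pos", "ref", "alt")]
  causal_key <- variants[variants$role == "causal",
                         c("chrom", "pos", "ref", "alt")]

  paths <- list(vcf = file.path(outdir, "cohort.vcf"),
                design = file.path(outdir, "design.tsv"),
                known = file.path(outdir, "known.vcf"),
                markers = file.path(outdir, "markers.tsv"),
                orthologs = file.path(outdir, "orthologs.fa"),
                genes = file.path(outdir, "genes.gff3"),
                truth = file.path(outdir, "truth.json"))

  write_cohort_vcf(variants, study$class_mat, design, paths$vcf)
  write_design(design, paths$design)
  write_sites_vcf(known_keys, paths$known)
  write_marker_table(study$markers, paths$markers)
  seqs <- Biostrings::DNAStringSet(study$orthologs)
  Biostrings::writeXStringSet(seqs, paths$orthologs, width = 80L)
  write_gff3_genes(study$genes, paths$genes)

  truth <- list(
    causal_key = as.list(causal_key),
    linked_keys = linked_keys,
    known_keys = known_keys,
    recombinant_breakpoints = spec$recombinant,
    expected_pattern_matched = 1L + spec$n_linked_private,
    expected_post_exclusion = 1L + spec$n_linked_private - spec$n_known_overlap,
    expected_interval = if (!is.null(bk)) {
      c(start = bk[1] + 1, end = bk[2] - 1)
    } else {
      c(start = r$start, end = r$end)
    },
    expected_candidates_in_interval = if (!is.null(bk)) {
      spec$n_candidates_in_interval
    } else {
      1L + spec$n_linked_private - spec$n_known_overlap
    })
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, spec = spec))
}

# positions start..end excluding `drop`, as a numeric vector
setdiff_positions <- function(start, end, drop) {
  p <- seq(start, end)
  p[!(p %in% drop)]
}

# sample() without its length-1 surprise (sample(5, 2) != sample(c(5), 2))
resample <- function(x, size) {
  if (size > length(x)) stop("position pool exhausted", call. = FALSE)
  x[sample.int(length(x), size)]
}

synthetic_gene_models <- function(region, narrowed) {
  # two divergently transcribed genes downstream of the narrowed interval
  # (stand-ins for the IRX cluster flanking it), scaled to the free space;
  # regions too small to host them get no gene models
  free <- region$end - narrowed$end
  empty <- function() {
    out <- tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), gene_start = double(),
                          gene_end = double(), exons = list())
    class(out) <- c("gene_models", class(out))
    out
  }
  if (free < 40000) return(empty())
  len1 <- min(8000, round(free * 0.2))
  len2 <- min(6000, round(free * 0.15))
  g1_start <- narrowed$end + round(free * 0.2)
  g2_start <- narrowed$end + round(free * 0.6)
  exons1 <- tibble::tibble(
    start = g1_start + round(len1 * c(0, 0.4, 0.75)),
    end = g1_start + round(len1 * c(0.1, 0.5, 1)))
  exons2 <- tibble::tibble(
    start = g2_start + round(len2 * c(0, 0.65)),
    end = g2_start + round(len2 * c(0.2, 1)))
  out <- tibble::tibble(
    gene_id = c("IRX1like", "IRX2like"),
    chrom = region$chrom,
    strand = c("+", "-"),
    gene_start = c(g1_start, g2_start),
    gene_end = c(g1_start + len1, g2_start + len2),
    exons = list(exons1, exons2))
  class(out) <- c("gene_models", class(out))
  out
}

draw_alleles <- function(pos, is_indel, spec) {
  bases <- c("A", "C", "G", "T")
  n <- length(pos)
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- sample(bases, 1L)
    if (!is_indel[i]) {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(bases, anchor), 1L)
    } else if (!is.null(spec$deletion_pos) && pos[i] == spec$deletion_pos) {
      ref[i] <- paste0(anchor, paste(sample(bases, spec$deletion_len,
                                            replace = TRUE), collapse = ""))
      alt[i] <- anchor
    } else {
      len <- sample(1:10, 1L)
      tail_seq <- paste(sample(bases, len, replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5) {           # insertion
        ref[i] <- anchor
        alt[i] <- paste0(anchor, tail_seq)
      } else {                               # deletion
        ref[i] <- paste0(anchor, tail_seq)
        alt[i] <- anchor
      }
    }
  }
  tibble::tibble(ref = ref, alt = alt)
}

# n genotype-class patterns drawn uniformly from the 3^k - 1 assignments
# that differ from the segregating pattern (no rejection: index skipping)
draw_nonsegregating_patterns <- function(n, seg_pattern) {
  classes <- c("HOM_REF", "HET", "HOM_ALT")
  k <- length(seg_pattern)
  seg_digits <- match(seg_pattern, classes) - 1L
  seg_index <- sum(seg_digits * 3^(seq_len(k) - 1L))
  total <- 3^k
  if (n == 0L) {
    return(matrix(character(), 0L, k))
  }
  u <- floor(stats::runif(n) * (total - 1))
  u <- pmin(u, total - 2)  # guard against runif returning exactly 1
  u <- ifelse(u >= seg_index, u + 1, u)
  out <- matrix("", n, k)
  for (j in seq_len(k)) {
    out[, j] <- classes[(u %% 3) + 1L]
    u <- u %/% 3
  }
  out
}

mutate_sequence <- function(seq, rate) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
  paste(v, collapse = "")
}

write_cohort_vcf <- function(variants, class_mat, design, path) {
  gt_of <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rumpmap-simulate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", design$sample_id), collapse = "\t"))
  gts <- matrix(gt_of[class_mat], nrow(class_mat))
  body <- paste(variants$chrom,
                format(variants$pos, scientific = FALSE, trim = TRUE),
                ".", variants$ref, variants$alt, ".", "PASS", ".", "GT",
                apply(gts, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

write_sites_vcf <- function(keys, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=rumpmap-simulate",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO"), collapse = "\t"))
  body <- character(0)
  if (nrow(keys) > 0L) {
    body <- paste(keys$chrom,
                  format(keys$pos, scientific = FALSE, trim = TRUE),
                  ".", keys$ref, keys$alt, ".", "PASS", ".",
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Run the full pipeline on a simulated study and score recovery
#'
#' @param spec A [cohort_spec()].
#' @param outdir Where to write the study (default: fresh temp directory).
#' @param missing_policy Passed to the segregation filter.
#' @param conservation Score the causal window's conservation as part of
#'   the run? Recovery itself depends only on the candidate set and the
#'   narrowed interval, so large recovery sweeps can skip this stage.
#' @return List: `causal_recovered` (planted causal key is in the
#'   pipeline's candidate set), `interval_contains_causal`,
#'   `n_candidates`, plus the pipeline `report` and the `truth` record.
#' @export
recovery_test <- function(spec, outdir = tempfile("study"),
                          missing_policy = "fail", conservation = TRUE) {
  sim <- simulate_study(spec, outdir)
  p <- sim$paths
  report <- run_pipeline(list(
    vcf = p$vcf, design = p$design, known = p$known,
    markers = p$markers,
    excluders = if (is.null(spec$recombinant)) character() else "RB1",
    region = format_region(spec$region),
    gff = p$genes, orthologs = if (conservation) p$orthologs else NULL,
    focal_pos = spec$causal_pos,
    missing_policy = missing_policy))
  ck <- sim$truth$causal_key
  cand <- report$candidates
  causal_recovered <- nrow(cand) > 0L &&
    any(cand$chrom == ck$chrom & cand$pos == ck$pos &
        cand$ref == ck$ref & cand$alt == ck$alt)
  iv_list <- report$intervals
  interval_contains_causal <- any(vapply(iv_list, function(iv) {
    iv$chrom == ck$chrom && iv$start <= ck$pos && ck$pos <= iv$end
  }, logical(1)))
  list(causal_recovered = causal_recovered,
       interval_contains_causal = interval_contains_causal,
       n_candidates = nrow(cand),
       report = report,
       truth = sim$truth)
}
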