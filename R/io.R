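# Readers and writers: design TSV, multi-sample VCF, known-variant sets,
# marker haplotype TSV, GFF3 gene models, FASTA windows.
#
# The in-memory variant container is a tibble with fixed columns
# chrom, pos, ref, alt, kind followed by one column per cohort sample
# holding that sample's genotype class (HOM_REF/HET/HOM_ALT/MISSING).

VARIANT_FIXED_COLS <- c("chrom", "pos", "ref", "alt", "kind")

#' Sample columns of a variant table
#' @param variants A variant tibble as returned by [read_vcf()].
#' @return Character vector of sample ids.
#' @export
variant_samples <- function(variants) {
  setdiff(names(variants), VARIANT_FIXED_COLS)
}

#' Construct a cohort design
#'
#' The design encodes the expected genotype class of every sequenced bird
#' under a fully penetrant autosomal dominant model: affected individuals
#' are expected HOM_ALT (homozygous carriers) or HET (heterozygous
#' carriers); unaffected individuals are expected HOM_REF.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param phenotype `"AFFECTED"` or `"UNAFFECTED"` per sample.
#' @param expected_class `"HOM_ALT"`, `"HET"` or `"HOM_REF"` per sample.
#' @return A tibble of class `cohort_design`.
#' @export
cohort_design <- function(sample_id, phenotype, expected_class) {
  stopifnot(length(sample_id) == length(phenotype),
            length(sample_id) == length(expected_class))
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(phenotype %in% c("AFFECTED", "UNAFFECTED")),
            all(expected_class %in% c("HOM_ALT", "HET", "HOM_REF")))
  bad <- (phenotype == "AFFECTED" & expected_class == "HOM_REF") |
         (phenotype == "UNAFFECTED" & expected_class != "HOM_REF")
  if (any(bad)) {
    stop("phenotype/expected_class inconsistent for: ",
         paste(sample_id[bad], collapse = ", "),
         " (AFFECTED must expect HOM_ALT or HET; UNAFFECTED must expect HOM_REF)",
         call. = FALSE)
  }
  out <- tibble::tibble(sample_id = as.character(sample_id),
                        phenotype = phenotype,
                        expected_class = expected_class)
  class(out) <- c("cohort_design", class(out))
  out
}

#' Read / write a 3-column design TSV (sample_id, phenotype, expected_class)
#' @param path File path.
#' @return [read_design()]: a `cohort_design`; [write_design()]: `path`,
#'   invisibly.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  need <- c("sample_id", "phenotype", "expected_class")
  if (!all(need %in% names(d))) {
    stop("design TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cohort_design(d$sample_id, d$phenotype, d$expected_class)
}

#' @rdname read_design
#' @param design A `cohort_design`.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses VCF 4.x (plain or bgzipped) via vcfR, splits multiallelic records
#' into one row per alt, classifies each sample's genotype relative to the
#' retained alt (see [gt_class_from_gt()]), and sorts rows by (chrom, pos).
#' A sample listed in `design` but absent from the VCF header is a fatal
#' error; a malformed GT becomes MISSING with one warning per file.
#'
#' @param path VCF file path.
#' @param design A `cohort_design`; genotype classes are extracted for
#'   exactly these samples.
#' @return Variant tibble: `chrom`, `pos`, `ref`, `alt`, `kind`, then one
#'   genotype-class column per design sample.
#' @export
read_vcf <- function(path, design) {
  stopifnot(inherits(design, "cohort_design"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- empty_variant_table(design$sample_id)
  if (nrow(v@fix) == 0L) return(empty)
  fix <- v@fix
  gt_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(design$sample_id, gt_samples)
  if (length(missing_samples) > 0L) {
    stop("VCF is missing design sample column(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, gt_samples))
  gt <- gt[, design$sample_id, drop = FALSE]

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.double(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt_field <- as.character(fix[, "ALT"])

  malformed <- FALSE
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    alts <- alts[nzchar(alts) & alts != "."]
    if (length(alts) == 0L) next
    per_alt <- lapply(seq_along(alts), function(k) {
      classes <- gt_class_from_gt(gt[i, ], alt_index = k)
      raw <- gt[i, ]
      bad <- classes == "MISSING" &
        !is.na(raw) & !grepl("^\\.([/|]\\.)?$", sub(":.*$", "", raw)) &
        nzchar(raw)
      if (any(bad)) malformed <<- TRUE
      kind_k <- classify_variant_kind(ref[i], alts[k])
      row <- tibble::tibble(chrom = chrom[i], pos = pos[i],
                            ref = ref[i], alt = alts[k], kind = kind_k)
      for (j in seq_along(design$sample_id)) {
        row[[design$sample_id[j]]] <- classes[j]
      }
      row
    })
    rows[[i]] <- dplyr::bind_rows(per_alt)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  if (malformed) {
    warning("malformed GT field(s) treated as MISSING in ", path,
            call. = FALSE)
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

empty_variant_table <- function(sample_ids) {
  out <- tibble::tibble(chrom = character(), pos = double(),
                        ref = character(), alt = character(),
                        kind = character())
  for (s in sample_ids) out[[s]] <- character()
  out
}

#' Write a variant table (genotype classes) back to a plain-text VCF
#'
#' Genotype classes map to GT fields HOM_REF -> 0/0, HET -> 0/1,
#' HOM_ALT -> 1/1, MISSING -> ./.. Round-trips through [read_vcf()]
#' preserve chrom/pos/ref/alt and all genotype classes.
#'
#' @param variants Variant tibble.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  samples <- variant_samples(variants)
  gt_of <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rumpmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(variants))
  if (nrow(variants) > 0L) {
    gts <- sapply(samples, function(s) gt_of[variants[[s]]])
    if (is.null(dim(gts))) gts <- matrix(gts, nrow = nrow(variants))
    body <- paste(variants$chrom,
                  format(variants$pos, scientific = FALSE, trim = TRUE),
                  ".", variants$ref, variants$alt, ".", ".", ".", "GT",
                  apply(gts, 1L, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a known-variant set from VCF or TSV
#'
#' The set is keyed exactly on (chrom, pos, ref, alt); a TSV must carry
#' those four columns. Multiallelic VCF records contribute one key per alt.
#'
#' @param path Path to a VCF (".vcf", ".vcf.gz") or TSV file.
#' @return Tibble of class `known_variant_set` with the four key columns,
#'   deduplicated.
#' @export
read_known_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    if (nrow(v@fix) == 0L) {
      keys <- tibble::tibble(chrom = character(), pos = double(),
                             ref = character(), alt = character())
    } else {
      fix <- v@fix
      keys <- tibble::tibble(chrom = as.character(fix[, "CHROM"]),
                             pos = as.double(fix[, "POS"]),
                             ref = as.character(fix[, "REF"]),
                             alt = as.character(fix[, "ALT"]))
      keys <- tidyr_separate_alts(keys)
    }
  } else {
    d <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(d))) {
      stop("known-variant TSV must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    keys <- tibble::tibble(chrom = as.character(d$chrom),
                           pos = as.double(d$pos),
                           ref = as.character(d$ref),
                           alt = as.character(d$alt))
  }
  keys <- dplyr::distinct(keys)
  class(keys) <- c("known_variant_set", class(keys))
  keys
}

# split comma-separated alts into one key per alt
tidyr_separate_alts <- function(keys) {
  n_alts <- lengths(strsplit(keys$alt, ",", fixed = TRUE))
  if (all(n_alts == 1L)) return(keys)
  idx <- rep(seq_len(nrow(keys)), n_alts)
  out <- keys[idx, ]
  out$alt <- unlist(strsplit(keys$alt, ",", fixed = TRUE))
  out
}

#' Build / read / write a marker haplotype table
#'
#' Markers are biallelic SNPs whose alleles distinguish the founder
#' affected ("rumpless") haplotype from unaffected haplotypes. The table
#' holds marker positions, the two diagnostic alleles, and each genotyped
#' individual's diploid genotype (e.g. "A/G").
#'
#' @param pos Strictly increasing 1-based marker positions.
#' @param affected_allele,unaffected_allele Diagnostic alleles per marker
#'   (must differ at every marker).
#' @param genotypes Named list (or data frame) of per-individual genotype
#'   strings, one entry per marker.
#' @return Tibble of class `marker_table`: `pos`, `affected_allele`,
#'   `unaffected_allele`, then one genotype column per individual.
#' @export
marker_table <- function(pos, affected_allele, unaffected_allele, genotypes) {
  pos <- as.double(pos)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("marker positions must be strictly increasing", call. = FALSE)
  }
  if (any(affected_allele == unaffected_allele)) {
    stop("affected and unaffected alleles must differ at every marker",
         call. = FALSE)
  }
  out <- tibble::tibble(pos = pos,
                        affected_allele = affected_allele,
                        unaffected_allele = unaffected_allele)
  for (id in names(genotypes)) {
    g <- genotypes[[id]]
    stopifnot(length(g) == length(pos))
    out[[id]] <- as.character(g)
  }
  class(out) <- c("marker_table", class(out))
  out
}

#' @rdname marker_table
#' @param path File path.
#' @export
read_marker_table <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("pos", "affected_allele", "unaffected_allele")
  if (!all(need %in% names(d))) {
    stop("marker TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- setdiff(names(d), need)
  marker_table(d$pos, d$affected_allele, d$unaffected_allele,
               as.list(d[ids]))
}

#' @rdname marker_table
#' @param table A `marker_table`.
#' @export
write_marker_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with an `ID` attribute and `exon` features with
#' `Parent` pointing at the gene. Exons are sorted and must be
#' non-overlapping and contained in the gene span.
#'
#' @param path GFF3 file path.
#' @return Tibble of class `gene_models`: `gene_id`, `chrom`, `strand`,
#'   `gene_start`, `gene_end`, and an `exons` list-column of
#'   start/end tibbles.
#' @export
read_gff3_genes <- function(path) {
  g <- rtracklayer::import(path)
  df <- as.data.frame(g)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  parent <- vapply(exons$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  out <- tibble::tibble(
    gene_id = as.character(genes$ID),
    chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    gene_start = as.double(genes$start),
    gene_end = as.double(genes$end),
    exons = lapply(as.character(genes$ID), function(id) {
      e <- exons[!is.na(parent) & parent == id, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      tibble::tibble(start = as.double(e$start), end = as.double(e$end))
    })
  )
  for (i in seq_len(nrow(out))) {
    e <- out$exons[[i]]
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop("overlapping exons in gene ", out$gene_id[i], call. = FALSE)
    }
    if (nrow(e) > 0L &&
        (min(e$start) < out$gene_start[i] || max(e$end) > out$gene_end[i])) {
      stop("exon outside gene span in gene ", out$gene_id[i], call. = FALSE)
    }
  }
  class(out) <- c("gene_models", class(out))
  out
}

#' Write gene models to GFF3
#' @param genes A `gene_models` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    lines <- c(lines, paste(
      genes$chrom[i], "rumpmap", "gene",
      format(genes$gene_start[i], scientific = FALSE, trim = TRUE),
      format(genes$gene_end[i], scientific = FALSE, trim = TRUE),
      ".", genes$strand[i], ".",
      sprintf("ID=%s;Name=%s", genes$gene_id[i], genes$gene_id[i]),
      sep = "\t"))
    e <- genes$exons[[i]]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, paste(
        genes$chrom[i], "rumpmap", "exon",
        format(e$start[j], scientific = FALSE, trim = TRUE),
        format(e$end[j], scientific = FALSE, trim = TRUE),
        ".", genes$strand[i], ".",
        sprintf("ID=%s.exon%d;Parent=%s", genes$gene_id[i], j, genes$gene_id[i]),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
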