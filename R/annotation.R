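# Gene-context annotation and marker-phenotype concordance.

#' Annotate a position with its gene context
#'
#' `EXONIC` if the position falls within any exon of any gene model;
#' `INTRONIC` if within a gene span but no exon; otherwise `INTERGENIC`
#' with the distance to the nearest gene-span boundary. Candidate causal
#' variants for regulatory mutations are expected INTERGENIC (or intronic),
#' as coding changes would have been caught by the exon scan.
#'
#' @param chrom,pos Position to annotate (single position).
#' @param genes A `gene_models` tibble from [read_gff3_genes()].
#' @return Tibble row: `context`, `nearest_gene_id`, `distance_bp`
#'   (`distance_bp` is 0 inside a gene; `nearest_gene_id` is `NA` when no
#'   gene model shares the chromosome).
#' @export
annotate_gene_context <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(tibble::tibble(context = "INTERGENIC",
                          nearest_gene_id = NA_character_,
                          distance_bp = NA_real_))
  }
  inside <- g$gene_start <= pos & pos <= g$gene_end
  if (any(inside)) {
    hit <- which(inside)[1]
    e <- g$exons[[hit]]
    exonic <- nrow(e) > 0L && any(e$start <= pos & pos <= e$end)
    return(tibble::tibble(
      context = if (exonic) "EXONIC" else "INTRONIC",
      nearest_gene_id = g$gene_id[hit],
      distance_bp = 0))
  }
  d <- pmin(abs(pos - g$gene_start), abs(pos - g$gene_end))
  hit <- which.min(d)
  tibble::tibble(context = "INTERGENIC",
                 nearest_gene_id = g$gene_id[hit],
                 distance_bp = as.double(d[hit]))
}

#' Annotate every variant in a table
#'
#' @param variants Variant tibble.
#' @param genes A `gene_models` tibble.
#' @return `variants` with `context`, `nearest_gene_id`, `distance_bp`
#'   columns appended.
#' @export
annotate_variants <- function(variants, genes) {
  ann <- dplyr::bind_rows(lapply(seq_len(nrow(variants)), function(i) {
    annotate_gene_context(variants$chrom[i], variants$pos[i], genes)
  }))
  if (nrow(variants) == 0L) {
    ann <- tibble::tibble(context = character(),
                          nearest_gene_id = character(),
                          distance_bp = double())
  }
  dplyr::bind_cols(variants, ann)
}

#' Marker-phenotype concordance under the dominant model
#'
#' An individual is concordant when carrier status predicts phenotype:
#' (carrier AND affected) or (non-carrier AND unaffected). This is the
#' genotyping-survey check used to validate a candidate marker across a
#' large cohort; a discordant unaffected carrier is exactly the kind of
#' recombinant individual that powers [exclusion_map()].
#'
#' @param carrier Named logical vector: does the individual carry the
#'   candidate allele?
#' @param phenotype Named character vector (`"AFFECTED"`/`"UNAFFECTED"`)
#'   over the same individuals.
#' @param group Optional named character vector of group labels for a
#'   per-group breakdown.
#' @return List: `n_total`, `n_concordant`, `n_discordant`,
#'   `discordant_ids`, and `per_group` (tibble of group/total/concordant;
#'   empty when `group` is NULL).
#' @export
concordance <- function(carrier, phenotype, group = NULL) {
  ids_c <- names(carrier)
  ids_p <- names(phenotype)
  if (is.null(ids_c) || is.null(ids_p) || !setequal(ids_c, ids_p) ||
      length(carrier) != length(phenotype)) {
    offending <- union(setdiff(ids_c, ids_p), setdiff(ids_p, ids_c))
    stop("carrier/phenotype individual sets differ: ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  phenotype <- phenotype[ids_c]
  stopifnot(all(phenotype %in% c("AFFECTED", "UNAFFECTED")))
  ok <- (carrier & phenotype == "AFFECTED") |
        (!carrier & phenotype == "UNAFFECTED")
  per_group <- tibble::tibble(group = character(), total = integer(),
                              concordant = integer())
  if (!is.null(group)) {
    group <- group[ids_c]
    per_group <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(group = group, ok = ok), .data$group),
      total = dplyr::n(), concordant = sum(.data$ok), .groups = "drop")
  }
  list(n_total = length(ok),
       n_concordant = sum(ok),
       n_discordant = sum(!ok),
       discordant_ids = ids_c[!ok],
       per_group = per_group)
}
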