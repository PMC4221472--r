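# Pipeline orchestration: filter -> exclude known -> narrow interval ->
# intersect -> annotate -> conserve -> concordance, from a single config.

#' Run the full variant-funnel pipeline
#'
#' Executes every stage of the mapping funnel from one configuration and
#' returns a machine-readable report. The report's stage counts chain:
#' each stage's output count is the next stage's input count. The pipeline
#' itself is deterministic — rerunning an identical config on identical
#' inputs yields an identical report (all sampling lives in
#' [simulate_study()]).
#'
#' @param config A named list, or path to a YAML file with the same keys:
#'   \describe{
#'     \item{vcf}{multi-sample VCF of the sequenced cohort (required)}
#'     \item{design}{design TSV path (required)}
#'     \item{known}{known-variant VCF/TSV path (optional)}
#'     \item{markers}{marker haplotype TSV path (required when `excluders`
#'       is non-empty)}
#'     \item{excluders}{ids of unaffected partial-haplotype carriers used
#'       to narrow the interval (optional)}
#'     \item{region}{original critical interval, `"chrom:start-end"`
#'       (required)}
#'     \item{gff}{gene-model GFF3 for candidate annotation (optional)}
#'     \item{orthologs}{FASTA of conservation windows: one record named
#'       `query` plus one per species (optional)}
#'     \item{focal_pos}{position whose window the ortholog FASTA describes;
#'       defaults to the first candidate SNP}
#'     \item{missing_policy}{`"fail"` (default) or `"pass"`}
#'     \item{known_match}{`"key"` (default) or `"position"`}
#'     \item{conservation_threshold}{identity threshold, default 0.70}
#'   }
#' @param outdir Optional output directory; when given, the surviving
#'   candidates are written as `candidates.vcf` and the report as
#'   `report.json`. Outputs are written only after every stage succeeds,
#'   so a failing run leaves no partial files.
#' @return The report: `report_version`, `parameters`, `stages` (tibble of
#'   stage, n_in, n_out), `counts_by_kind`, `intervals`, `candidates`,
#'   `conservation`, `concordance`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(known = NULL, markers = NULL,
                                excluders = character(), gff = NULL,
                                orthologs = NULL, focal_pos = NULL,
                                missing_policy = "fail",
                                known_match = "key",
                                conservation_threshold = 0.70),
                           config)
  for (key in c("vcf", "design", "region")) {
    if (is.null(cfg[[key]])) {
      stop("pipeline config requires '", key, "'", call. = FALSE)
    }
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  region <- if (is.character(cfg$region)) parse_region(cfg$region) else cfg$region

  design <- stage("input", read_design(cfg$design))
  variants <- stage("input", read_vcf(cfg$vcf, design))
  n_input <- nrow(variants)

  pattern <- stage("segregation",
                   segregation_filter(variants, design, cfg$missing_policy))

  surviving <- if (!is.null(cfg$known)) {
    known <- stage("known_exclusion", read_known_variants(cfg$known))
    stage("known_exclusion", exclude_known(pattern, known, cfg$known_match))
  } else {
    pattern
  }

  intervals <- stage("interval", {
    if (length(cfg$excluders) > 0L) {
      if (is.null(cfg$markers)) {
        stop("marker table required for interval narrowing", call. = FALSE)
      }
      exclusion_map(read_marker_table(cfg$markers), region, cfg$excluders)
    } else {
      list(region)
    }
  })

  candidates <- stage("interval_intersection", {
    parts <- lapply(intervals, function(iv) variants_in_interval(surviving, iv))
    out <- dplyr::bind_rows(parts)
    dplyr::distinct(dplyr::arrange(out, .data$chrom, .data$pos))
  })

  if (!is.null(cfg$gff)) {
    genes <- stage("annotation", read_gff3_genes(cfg$gff))
    candidates <- stage("annotation", annotate_variants(candidates, genes))
  }

  conservation <- NULL
  if (!is.null(cfg$orthologs)) {
    conservation <- stage("conservation", {
      seqs <- Biostrings::readDNAStringSet(cfg$orthologs)
      nm <- sub("\\s.*$", "", names(seqs))
      if (!"query" %in% nm) {
        stop("ortholog FASTA must contain a record named 'query'",
             call. = FALSE)
      }
      focal <- cfg$focal_pos
      if (is.null(focal)) {
        snps <- candidates[candidates$kind == "SNP", , drop = FALSE]
        focal <- if (nrow(snps) > 0L) snps$pos[1] else NA_real_
      }
      conservation_score(as.character(seqs[[which(nm == "query")[1]]]),
                         as.list(stats::setNames(as.character(seqs[nm != "query"]),
                                                 nm[nm != "query"])),
                         threshold = cfg$conservation_threshold,
                         query_pos = focal)
    })
  }

  concord <- stage("concordance", {
    if (nrow(candidates) == 0L) NULL else {
      samples <- intersect(design$sample_id, names(candidates))
      lapply(seq_len(nrow(candidates)), function(i) {
        cls <- unlist(candidates[i, samples])
        keep <- cls != "MISSING"
        if (!any(keep)) return(NULL)
        concordance(
          stats::setNames(cls[keep] %in% c("HET", "HOM_ALT"),
                          samples[keep]),
          stats::setNames(design$phenotype[match(samples[keep],
                                                 design$sample_id)],
                          samples[keep]))
      })
    }
  })

  report <- list(
    report_version = 1L,
    parameters = list(region = format_region(region),
                      missing_policy = cfg$missing_policy,
                      known_match = cfg$known_match,
                      known_set_used = !is.null(cfg$known),
                      conservation_threshold = cfg$conservation_threshold,
                      excluders = cfg$excluders),
    stages = tibble::tibble(
      stage = c("input", "segregation", "known_exclusion",
                "interval_intersection"),
      n_in = c(n_input, n_input, nrow(pattern), nrow(surviving)),
      n_out = c(n_input, nrow(pattern), nrow(surviving), nrow(candidates))),
    counts_by_kind = count_by_kind(surviving),
    intervals = intervals,
    candidates = candidates,
    conservation = conservation,
    concordance = concord)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(candidates[, c(VARIANT_FIXED_COLS,
                             intersect(design$sample_id, names(candidates)))],
              file.path(outdir, "candidates.vcf"))
    json_report <- report
    json_report$intervals <- lapply(intervals, function(iv) {
      list(chrom = iv$chrom, start = iv$start, end = iv$end,
           span_bp = interval_span(iv))
    })
    jsonlite::write_json(json_report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
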