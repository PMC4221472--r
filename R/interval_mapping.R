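# Recombinant-haplotype exclusion mapping.
#
# An unaffected individual that nonetheless carries part of the affected
# founder haplotype (a historical recombinant) excludes from the critical
# interval every region where it carries the affected haplotype: the causal
# variant cannot lie where an unaffected bird carries the affected alleles.

HAP_ORIGINS <- c("AFFECTED_HAP", "UNAFFECTED_HAP", "UNINFORMATIVE")

#' Haplotype-origin call at one diagnostic marker
#'
#' For an individual assumed to carry at most one affected haplotype
#' (heterozygous dominant model, no phasing): a genotype containing the
#' affected allele -> `AFFECTED_HAP`; homozygous for the unaffected allele
#' -> `UNAFFECTED_HAP`; alleles matching neither diagnostic allele (or a
#' missing genotype) -> `UNINFORMATIVE`.
#'
#' @param genotype Diploid genotype string, e.g. `"A/G"` (separator `/` or
#'   `|`); vectorised.
#' @param affected_allele,unaffected_allele The marker's diagnostic alleles.
#' @param carrier_state `"HET_CARRIER"` (default), `"HOM_CARRIER"` or
#'   `"NON_CARRIER"`; recorded for interface completeness — the call rule
#'   under the single-carrier assumption is the same for all three.
#' @return `"AFFECTED_HAP"`, `"UNAFFECTED_HAP"` or `"UNINFORMATIVE"`.
#' @export
assign_haplotype <- function(genotype, affected_allele, unaffected_allele,
                             carrier_state = c("HET_CARRIER", "HOM_CARRIER",
                                               "NON_CARRIER")) {
  carrier_state <- match.arg(carrier_state)
  stopifnot(all(affected_allele != unaffected_allele))
  n <- max(length(genotype), length(affected_allele))
  genotype <- rep_len(genotype, n)
  affected_allele <- rep_len(affected_allele, n)
  unaffected_allele <- rep_len(unaffected_allele, n)
  vapply(seq_len(n), function(i) {
    g <- genotype[i]
    if (is.na(g) || !nzchar(g)) return("UNINFORMATIVE")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == "." | alleles == "")) {
      return("UNINFORMATIVE")
    }
    if (any(alleles == affected_allele[i])) return("AFFECTED_HAP")
    if (all(alleles == unaffected_allele[i])) return("UNAFFECTED_HAP")
    "UNINFORMATIVE"
  }, character(1))
}

#' Origin calls for every individual in a marker table
#'
#' @param table A [marker_table()].
#' @param individuals Individuals to call (default: all genotype columns).
#' @return Named list of per-marker origin vectors.
#' @export
marker_origin_calls <- function(table, individuals = NULL) {
  ids <- setdiff(names(table), c("pos", "affected_allele", "unaffected_allele"))
  if (!is.null(individuals)) {
    absent <- setdiff(individuals, ids)
    if (length(absent) > 0L) {
      stop("individual(s) absent from marker table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    ids <- individuals
  }
  stats::setNames(lapply(ids, function(id) {
    assign_haplotype(table[[id]], table$affected_allele,
                     table$unaffected_allele)
  }), ids)
}

#' Narrow a critical interval by recombinant exclusion mapping
#'
#' Given origin calls for one or more unaffected carriers of partial
#' affected haplotypes ("excluders"), the causal variant can only lie where
#' every excluder carries the unaffected haplotype. Markers where any
#' excluder shows `AFFECTED_HAP` block; maximal blocker-free runs of
#' markers become retained intervals.
#'
#' Boundary convention: within a run, the retained interval is closed at
#' the outermost markers where *every* excluder has an informative
#' `UNAFFECTED_HAP` call (conservative inner bound — the stretch between a
#' supporting marker and the adjacent blocking marker is excluded). A run
#' that reaches the edge of the marker ladder extends to the corresponding
#' boundary of `original`, since no marker evidence exists beyond the
#' ladder. `UNINFORMATIVE` calls are transparent: they neither block nor
#' support a run. An interior-bounded run containing no supporting marker
#' is dropped.
#'
#' @param table A [marker_table()]; all markers must lie within `original`.
#' @param original The starting critical interval ([genomic_interval()]).
#' @param excluders Character vector of individual ids (columns of `table`).
#'   With zero excluders the result is `original` unchanged.
#' @return A list of disjoint, sorted `genomic_interval`s.
#' @export
exclusion_map <- function(table, original, excluders) {
  stopifnot(inherits(table, "marker_table"))
  if (any(table$pos < original$start | table$pos > original$end)) {
    stop("marker position(s) outside the original interval", call. = FALSE)
  }
  if (length(excluders) == 0L) return(list(original))
  calls <- marker_origin_calls(table, excluders)
  call_mat <- do.call(cbind, calls)  # markers x excluders
  if (all(call_mat == "UNINFORMATIVE")) {
    warning("no informative markers for any excluder; interval unchanged",
            call. = FALSE)
    return(list(original))
  }
  blocking <- apply(call_mat == "AFFECTED_HAP", 1L, any)
  supporting <- apply(call_mat == "UNAFFECTED_HAP", 1L, all)

  n <- nrow(table)
  # maximal runs of non-blocking markers
  run_id <- cumsum(c(TRUE, diff(blocking) != 0L))
  out <- list()
  for (r in unique(run_id[!blocking])) {
    idx <- which(run_id == r & !blocking)
    open_left <- idx[1] == 1L
    open_right <- idx[length(idx)] == n
    sup <- idx[supporting[idx]]
    left <- if (open_left) original$start
            else if (length(sup) > 0L) table$pos[min(sup)] else NA_real_
    right <- if (open_right) original$end
             else if (length(sup) > 0L) table$pos[max(sup)] else NA_real_
    if (is.na(left) || is.na(right) || left > right) next
    out[[length(out) + 1L]] <- genomic_interval(original$chrom, left, right)
  }
  out[order(vapply(out, function(iv) iv$start, numeric(1)))]
}

#' Restrict a variant table to an interval
#'
#' @param variants Variant tibble.
#' @param interval A [genomic_interval()]; retained variants satisfy
#'   `chrom` equality and `start <= pos <= end`.
#' @param kind_filter Optional kind (`"SNP"`, `"INS"`, `"DEL"`, `"MNV"`)
#'   to additionally require.
#' @return The retained subset, order preserved.
#' @export
variants_in_interval <- function(variants, interval, kind_filter = NULL) {
  keep <- variants$chrom == interval$chrom &
    variants$pos >= interval$start & variants$pos <= interval$end
  if (!is.null(kind_filter)) {
    stopifnot(kind_filter %in% VARIANT_KINDS)
    keep <- keep & variants$kind == kind_filter
  }
  variants[keep, , drop = FALSE]
}
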