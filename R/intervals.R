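#' Genomic intervals
#'
#' A `genomic_interval` is a 1-based closed chromosomal interval. The span
#' convention used throughout the package is `end - start` (NOT
#' `end - start + 1`): the critical interval 86,476,559--86,601,705 has a
#' span of 125,146 bp and the 55 bp deletion occupies 86,830,975--86,831,030.
#' All coordinates are 1-based, as in VCF.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based integer endpoints with `start <= end`.
#' @return A one-row tibble of class `genomic_interval` with columns
#'   `chrom`, `start`, `end`.
#' @examples
#' iv <- genomic_interval("chr2", 86476559, 86601705)
#' interval_span(iv) # 125146
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.double(start)
  end <- as.double(end)
  if (!is.finite(start) || !is.finite(end) || start < 1) {
    stop("interval endpoints must be finite and >= 1", call. = FALSE)
  }
  if (start > end) {
    stop(sprintf("invalid interval %s:%s-%s (start > end)",
                 chrom, format(start, scientific = FALSE),
                 format(end, scientific = FALSE)), call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  class(out) <- c("genomic_interval", class(out))
  out
}

#' @rdname genomic_interval
#' @param interval A `genomic_interval`.
#' @export
interval_span <- function(interval) {
  stopifnot(all(c("chrom", "start", "end") %in% names(interval)))
  if (any(interval$start > interval$end)) {
    stop("start > end in interval", call. = FALSE)
  }
  as.double(interval$end - interval$start)
}

#' Parse a region string of the form "chr2:86110001-86850001"
#'
#' @param region A single `"chrom:start-end"` string; commas in numbers are
#'   tolerated.
#' @return A `genomic_interval`.
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse region '%s' (expected chrom:start-end)", region),
         call. = FALSE)
  }
  num <- function(x) as.double(gsub(",", "", x, fixed = TRUE))
  genomic_interval(m[2], num(m[3]), num(m[4]))
}

#' Format a genomic_interval back to "chrom:start-end"
#' @param interval A `genomic_interval`.
#' @return Character vector.
#' @export
format_region <- function(interval) {
  sprintf("%s:%s-%s", interval$chrom,
          format(interval$start, scientific = FALSE, trim = TRUE),
          format(interval$end, scientific = FALSE, trim = TRUE))
}
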