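# Conservation-window scoring: a fixed-width window around a candidate
# SNP is globally aligned against orthologous windows from related
# species; high identity across species marks the window as constrained
# (the classic signature of a regulatory element).

#' Extract a fixed-width window around a position
#'
#' The window is centred with the focal base at position `floor(width/2)`
#' of the window (rounding toward the sequence start: for the default
#' 300 bp, 149 bp left and 150 bp right of the centre). Windows running
#' off either end of the sequence are clipped with a warning.
#'
#' @param sequence A [Biostrings::DNAString], `DNAStringSet` of length 1,
#'   or plain character sequence.
#' @param center_pos 1-based focal position; must lie within the sequence.
#' @param width Window width in bp (default 300).
#' @return List: `seq` (character window) and `interval`
#'   ([genomic_interval()] in sequence coordinates, chrom `"seq"`).
#' @export
extract_window <- function(sequence, center_pos, width = 300L) {
  s <- as.character(sequence)
  if (length(s) > 1L) s <- s[1]
  n <- nchar(s)
  stopifnot(width >= 1L)
  if (center_pos < 1L || center_pos > n) {
    stop(sprintf("center position %d outside sequence of length %d",
                 as.integer(center_pos), n), call. = FALSE)
  }
  start <- center_pos - (ceiling(width / 2) - 1L)
  end <- center_pos + floor(width / 2)
  if (start < 1L || end > n) {
    warning(sprintf("window [%d, %d] clipped to sequence bounds [1, %d]",
                    as.integer(start), as.integer(end), n), call. = FALSE)
    start <- max(1L, start)
    end <- min(n, end)
  }
  list(seq = substr(s, start, end),
       interval = genomic_interval("seq", start, end))
}

#' Global-alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap penalty of -2 per gapped column. Identity is the number of
#' matching columns divided by the total number of aligned columns
#' (gaps included). Traceback tie-breaking is fixed — diagonal, then up
#' (gap in `b`), then left (gap in `a`) — so results are bit-reproducible.
#'
#' @param a,b Non-empty nucleotide sequences over A/C/G/T/N (case
#'   insensitive). N never matches.
#' @param match,mismatch,gap Alignment scores.
#' @return Identity fraction in `[0, 1]`, with the optimal alignment score
#'   in attribute `"score"` and alignment length in `"columns"`.
#' @export
global_align_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b)) {
    stop("sequences must contain only A/C/G/T/N", call. = FALSE)
  }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)

  # score matrix, (n+1) x (m+1); row i ~ av[1..i-1]
  S <- matrix(0, n + 1L, m + 1L)
  S[1L, ] <- gap * (0:m)
  S[, 1L] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i] & av[i] != "N", match, mismatch)
    prev <- S[i, ]
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + sub[j], prev[j + 1L] + gap, cur[j] + gap)
    }
    S[i + 1L, ] <- cur
  }

  # traceback: prefer diagonal, then up (gap in b), then left (gap in a)
  i <- n; j <- m
  matches <- 0L; columns <- 0L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      sub <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
      if (S[i + 1L, j + 1L] == S[i, j] + sub) {
        matches <- matches + as.integer(av[i] == bv[j] && av[i] != "N")
        i <- i - 1L; j <- j - 1L; columns <- columns + 1L
        next
      }
    }
    if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L; columns <- columns + 1L
      next
    }
    j <- j - 1L; columns <- columns + 1L
  }
  out <- matches / columns
  attr(out, "score") <- S[n + 1L, m + 1L]
  attr(out, "columns") <- columns
  out
}

#' Score cross-species conservation of a query window
#'
#' Aligns the query window against each orthologous window and calls the
#' window conserved when every species reaches the identity threshold.
#' The threshold default of 0.70 is a tunable heuristic, not a calibrated
#' value.
#'
#' @param query_window Character query sequence (e.g. from
#'   [extract_window()]).
#' @param ortholog_windows Named character vector or named list of species
#'   window sequences; must be non-empty.
#' @param threshold Minimum per-species identity fraction (default 0.70).
#' @param query_pos Optional focal position recorded in the result.
#' @return List: `query_pos`, `per_species` (named numeric identities),
#'   `conserved` (all species at/above threshold), `threshold`.
#' @export
conservation_score <- function(query_window, ortholog_windows,
                               threshold = 0.70, query_pos = NA_real_) {
  ortholog_windows <- unlist(ortholog_windows)
  if (length(ortholog_windows) == 0L) {
    stop("at least one ortholog window is required", call. = FALSE)
  }
  if (is.null(names(ortholog_windows)) || any(!nzchar(names(ortholog_windows)))) {
    stop("ortholog windows must be named by species", call. = FALSE)
  }
  per_species <- vapply(ortholog_windows, function(w) {
    as.numeric(global_align_identity(query_window, w))
  }, numeric(1))
  list(query_pos = query_pos,
       per_species = per_species,
       conserved = all(per_species >= threshold),
       threshold = threshold)
}
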