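# Exact-substring matching engine. A probe "hits" a read when its
# sequence (or, for both-orientation sets, its reverse complement)
# occurs at least once as an exact substring; multiple occurrences of
# one probe count once. No mismatches are tolerated at probe level --
# error tolerance comes entirely from probe redundancy.

# logical n_reads x n_patterns hit matrix
.hit_matrix <- function(bases, patterns) {
  n <- length(bases)
  if (length(patterns) == 0L)
    return(matrix(logical(0), nrow = n, ncol = 0L))
  m <- vapply(patterns, function(p) grepl(p, bases, fixed = TRUE),
              logical(n))
  matrix(m, nrow = n, ncol = length(patterns))
}

.read_bases <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("bases" %in% names(reads))
    toupper(reads$bases)
  } else {
    toupper(as.character(reads))
  }
}

#' Count distinct probe matches in reads
#'
#' Returns, for each read, the number of distinct probes of `ps` that
#' occur at least once as an exact substring of the (uppercased) read.
#' For probe sets with `search_both_orientations = TRUE` a probe also
#' counts when only its reverse complement occurs; either way one probe
#' contributes at most 1.
#'
#' @param reads Character vector of read sequences, or a data frame
#'   with a `bases` column.
#' @param ps A [probe_set()].
#' @return Integer vector of distinct-probe match counts, one per read.
#' @export
count_probe_matches <- function(reads, ps) {
  stopifnot(inherits(ps, "probe_set"))
  b <- .read_bases(reads)
  h <- .hit_matrix(b, ps$probes$sequence)
  if (ps$search_both_orientations)
    h <- h | .hit_matrix(b, dna_revcomp(ps$probes$sequence))
  as.integer(rowSums(h))
}

#' Does each read match a probe set?
#'
#' A read matches when [count_probe_matches()] reaches the set's
#' `match_threshold` (n >= 2 by default).
#'
#' @inheritParams count_probe_matches
#' @param threshold Optional override of the probe set's threshold.
#' @return Logical vector, one per read.
#' @export
read_matches <- function(reads, ps, threshold = NULL) {
  thr <- as.integer(threshold %||% ps$match_threshold)
  count_probe_matches(reads, ps) >= thr
}
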