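# Amplicon-level read extraction and barcode-level demultiplexing.
# Both stages are pure functions of read tables and probe sets; file
# handling lives in the pipeline drivers.

#' Extract amplicon-specific full-length reads
#'
#' A read is retained iff it matches both the left and the right
#' end-window probe set (distinct-probe count >= threshold at *both*
#' ends, forward or reverse-complement probe variants). Retained reads
#' are orientation-normalised to the reference strand: reads whose
#' probe hits come predominantly from the reverse-complement variants
#' are reverse-complemented (and their qualities reversed) before
#' output. Input order is preserved.
#'
#' @param reads Read table (`read_id`, `bases`, optional `qual`).
#' @param grep_left,grep_right End-window [probe_set()]s built from the
#'   same amplicon by [make_end_probes()].
#' @param orientation_normalize Reverse-complement reverse-strand reads
#'   before output (default `TRUE`).
#' @return List of class `amplicon_extraction`:
#'   * `reads`: retained reads with an added `orientation` column
#'     (`"forward"`/`"reverse"`, as observed in the input);
#'   * `stats`: list with `total_reads`, `retained`, `rejected`,
#'     `retrieval_rate` (`retained/total_reads`).
#' @export
extract_amplicon_reads <- function(reads, grep_left, grep_right,
                                   orientation_normalize = TRUE) {
  stopifnot(inherits(grep_left, "probe_set"), inherits(grep_right, "probe_set"))
  b <- .read_bases(reads)
  n <- length(b)
  lf <- .hit_matrix(b, grep_left$probes$sequence)
  lr <- .hit_matrix(b, dna_revcomp(grep_left$probes$sequence))
  rf <- .hit_matrix(b, grep_right$probes$sequence)
  rr <- .hit_matrix(b, dna_revcomp(grep_right$probes$sequence))
  count_left <- as.integer(rowSums(lf | lr))
  count_right <- as.integer(rowSums(rf | rr))
  keep <- count_left >= grep_left$match_threshold &
    count_right >= grep_right$match_threshold
  # on the forward strand, left probes occur as-is while right probes
  # (cut from the reverse-complement strand) occur reverse-complemented
  fwd_score <- rowSums(lf) + rowSums(rr)
  rev_score <- rowSums(lr) + rowSums(rf)
  orientation <- ifelse(rev_score > fwd_score, "reverse", "forward")

  out <- if (is.data.frame(reads)) reads[keep, , drop = FALSE]
         else data.frame(read_id = sprintf("read%d", seq_len(n))[keep],
                         bases = b[keep], stringsAsFactors = FALSE)
  out$orientation <- orientation[keep]
  rownames(out) <- NULL
  if (orientation_normalize && nrow(out)) {
    flip <- out$orientation == "reverse"
    if (any(flip)) {
      out$bases[flip] <- dna_revcomp(out$bases[flip])
      if (!is.null(out$qual))
        out$qual[flip] <- .reverse_string(out$qual[flip])
    }
  }
  stats <- list(total_reads = n,
                retained = sum(keep),
                rejected = n - sum(keep),
                retrieval_rate = if (n > 0L) sum(keep) / n else NA_real_)
  structure(list(reads = out, stats = stats), class = "amplicon_extraction")
}

#' @export
print.amplicon_extraction <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<amplicon_extraction> %d/%d reads retained (%.1f%%)\n",
              s$retained, s$total_reads,
              100 * (s$retrieval_rate %||% NA_real_)))
  invisible(x)
}

#' Demultiplex amplicon-extracted reads by barcode probes
#'
#' Each read is assigned to *every* sample whose barcode-primer probe
#' set it matches; multi-assignment is recorded rather than silently
#' dropped, so the duplicate-based false discovery rate can be measured
#' afterwards with [compute_fdr()]. Reads must already be
#' amplicon-extracted and orientation-normalised (the barcode sits at
#' the 5' end of the forward strand).
#'
#' Because step-1 probes overlap heavily, one chance k+1-mer created by
#' sequencing errors anywhere in a multi-kilobase read would satisfy
#' two "distinct" probes at once; the barcode, however, can only sit at
#' the 5' end. The scan is therefore restricted to the first
#' `search_prefix` nt of each read, which removes virtually all
#' chance assignments without costing sensitivity.
#'
#' @param reads Read table (`read_id`, `bases`, ...).
#' @param barcode_probesets Named list of [probe_set()]s, one per
#'   sample; names are the sample ids.
#' @param search_prefix Length of the 5' window scanned for barcode
#'   probes, in nt; `Inf` scans whole reads. The default generously
#'   covers barcode + primer + residual adaptor + error-driven drift.
#' @param strict Drop reads matching more than one sample instead of
#'   keeping them in all bins (off by default).
#' @return Object of class `demux_assignments`: a data frame with
#'   columns `sample_id` and `read_id`, grouped per sample in input
#'   order. Attributes: `total_reads`, `unassigned` (read ids matching
#'   no sample), `per_sample` (named assignment counts).
#' @export
demultiplex <- function(reads, barcode_probesets, search_prefix = 150L,
                        strict = FALSE) {
  stopifnot(length(barcode_probesets) > 0L,
            !is.null(names(barcode_probesets)),
            all(nzchar(names(barcode_probesets))))
  if (anyDuplicated(names(barcode_probesets)))
    stop("duplicate sample_id among barcode probe sets", call. = FALSE)
  b <- .read_bases(reads)
  if (is.finite(search_prefix)) b <- substr(b, 1L, search_prefix)
  ids <- if (is.data.frame(reads)) reads$read_id else sprintf("read%d", seq_along(b))
  hit <- vapply(barcode_probesets, function(ps) read_matches(b, ps),
                logical(length(b)))
  hit <- matrix(hit, nrow = length(b), ncol = length(barcode_probesets),
                dimnames = list(NULL, names(barcode_probesets)))
  if (strict) {
    multi <- rowSums(hit) > 1L
    hit[multi, ] <- FALSE
  }
  parts <- lapply(colnames(hit), function(s) {
    data.frame(sample_id = rep(s, sum(hit[, s])), read_id = ids[hit[, s]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out,
            total_reads = length(b),
            unassigned = ids[rowSums(hit) == 0L],
            per_sample = colSums(hit),
            class = c("demux_assignments", "data.frame"))
}

#' Duplicate-based false discovery rate of a demultiplexing run
#'
#' Mirrors duplicate removal across merged sample bins: every
#' occurrence of a read id beyond its first assignment counts as a
#' duplicate, and the FDR is the proportion of duplicated assignments.
#' This is a misassignment measure, not a multiple-testing quantity.
#'
#' @param assignments A [demultiplex()] result, or any data frame with
#'   a `read_id` column (one row per assignment).
#' @return List with `duplicated_reads`, `total_assigned` and `fdr`
#'   (`0` when nothing is assigned).
#' @export
compute_fdr <- function(assignments) {
  ids <- assignments$read_id
  total <- length(ids)
  dup <- total - length(unique(ids))
  list(duplicated_reads = dup,
       total_assigned = total,
       fdr = if (total > 0L) dup / total else 0)
}

#' Ratio of read counts before and after a binning step
#'
#' May legitimately exceed 1 when two retrieval methods are compared on
#' the same pool.
#'
#' @param reads_before,reads_after Read counts.
#' @return `reads_after / reads_before`.
#' @export
retrieval_rate <- function(reads_before, reads_after) {
  if (reads_before <= 0)
    stop("reads_before must be positive", call. = FALSE)
  reads_after / reads_before
}
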