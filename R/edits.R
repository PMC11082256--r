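# Read-level insertion calling: short dsODN insertions and
# fragmented/full-length plasmid-backbone insertions. Rates are always
# computed over amplicon-extracted read counts (the denominator the
# pipeline feeds in), never raw-pool counts.

#' Insertion rate
#'
#' @param matched,total Read counts; `total` must be positive.
#' @return `matched / total` as a fraction.
#' @export
insertion_rate <- function(matched, total) {
  if (total <= 0) stop("total read count must be positive", call. = FALSE)
  matched / total
}

.new_insertion_summary <- function(kind, total, matched_ids,
                                   per_orientation = NULL,
                                   full_length = NA_integer_,
                                   fragmented = NA_integer_) {
  matched <- length(matched_ids)
  structure(
    list(kind = kind,
         total_reads = total,
         matched_reads = matched,
         rate = if (total > 0L) matched / total else NA_real_,
         per_orientation = per_orientation,
         full_length = full_length,
         fragmented = fragmented,
         matched_read_ids = matched_ids),
    class = "insertion_summary")
}

#' @export
print.insertion_summary <- function(x, ...) {
  cat(sprintf("<insertion_summary> %s: %d/%d reads (rate %s)\n",
              x$kind, x$matched_reads, x$total_reads,
              if (is.na(x$rate)) "undefined" else sprintf("%.4g", x$rate)))
  if (!is.null(x$per_orientation))
    cat("  per orientation: ",
        paste(sprintf("%s=%d", names(x$per_orientation), x$per_orientation),
              collapse = ", "),
        sprintf("; full_length=%d fragmented=%d", x$full_length, x$fragmented),
        "\n", sep = "")
  invisible(x)
}

#' Scan amplicon-specific reads for dsODN insertions
#'
#' A read carries the insert when at least `match_threshold` distinct
#' insert k-mers (either orientation; the probe set holds both) occur
#' in it. The insertion rate is the ratio of matched reads to the total
#' number of amplicon-specific reads scanned. With no reads the rate is
#' reported as missing (`NA`), not 0.
#'
#' @param reads Amplicon-extracted read table.
#' @param dsgrep Insert [probe_set()] from [make_insert_probes()].
#' @return An `insertion_summary` with the matched read ids, so callers
#'   can write the matched reads to a `<ID>-DSgrep` sub-bin.
#' @export
dsodn_scan <- function(reads, dsgrep) {
  stopifnot(inherits(dsgrep, "probe_set"))
  if (nrow(dsgrep$probes) == 0L) stop("empty probe set", call. = FALSE)
  b <- .read_bases(reads)
  ids <- if (is.data.frame(reads)) reads$read_id else as.character(seq_along(b))
  m <- read_matches(b, dsgrep)
  .new_insertion_summary("dsodn", length(b), ids[m])
}

#' Scan amplicon-specific reads for plasmid-backbone insertions
#'
#' Backbone probes are sparse (15-mers every 100 nt by default), cut
#' from both orientations of the backbone. A read is called BB-F when
#' it reaches the threshold on forward-orientation probes, BB-R on
#' reverse-orientation probes; a read meeting both is flagged `both`
#' and counted in each orientation's numerator. Matched reads are
#' classified *full-length* when the span of matched probe origins plus
#' k covers at least `full_length_span` of the backbone, otherwise
#' *fragmented*.
#'
#' With the default 100-nt step a fragment shorter than `step + k` bp
#' can hit at most one probe; `sensitivity = TRUE` lowers the match
#' threshold to 1 and is labelled as such in the summary kind.
#'
#' @param reads Amplicon-extracted read table.
#' @param bb_forward Backbone [probe_set()]; either a single
#'   two-orientation set from [make_backbone_probes()] (then
#'   `bb_reverse` may be omitted) or the forward-only set.
#' @param bb_reverse Reverse-orientation [probe_set()], or `NULL`.
#' @param full_length_span Fraction of the backbone the matched-probe
#'   span must cover to call a full-length insertion.
#' @param sensitivity Use threshold 1 instead of the set's threshold.
#' @return An `insertion_summary` with `per_orientation` counts
#'   (`forward`, `reverse`, `both`), `full_length` and `fragmented`
#'   counts, and per-orientation rates in `rate_forward`/`rate_reverse`.
#' @export
backbone_scan <- function(reads, bb_forward, bb_reverse = NULL,
                          full_length_span = 0.9, sensitivity = FALSE) {
  stopifnot(inherits(bb_forward, "probe_set"))
  if (is.null(bb_reverse)) {
    both <- split_probe_orientations(bb_forward)
    bb_forward <- both$forward
    bb_reverse <- both$reverse
  }
  stopifnot(inherits(bb_reverse, "probe_set"))
  if (nrow(bb_forward$probes) == 0L || nrow(bb_reverse$probes) == 0L)
    stop("empty probe set", call. = FALSE)
  bb_len <- bb_forward$signature_length
  if (is.na(bb_len))
    stop("backbone probe sets must carry signature_length", call. = FALSE)
  thr <- if (sensitivity) 1L else bb_forward$match_threshold

  b <- .read_bases(reads)
  ids <- if (is.data.frame(reads)) reads$read_id else as.character(seq_along(b))
  hf <- .hit_matrix(b, bb_forward$probes$sequence)
  hr <- .hit_matrix(b, bb_reverse$probes$sequence)
  mf <- rowSums(hf) >= thr
  mr <- rowSums(hr) >= thr
  matched <- mf | mr

  span_full <- function(h, ps, i) {
    off <- ps$probes$origin_offset[h[i, ]]
    if (length(off) == 0L) return(FALSE)
    (max(off) - min(off) + ps$k) >= full_length_span * bb_len
  }
  full <- vapply(which(matched), function(i) {
    (mf[i] && span_full(hf, bb_forward, i)) ||
      (mr[i] && span_full(hr, bb_reverse, i))
  }, logical(1))

  out <- .new_insertion_summary(
    if (sensitivity) "backbone(sensitivity:n>=1)" else "backbone",
    length(b), ids[matched],
    per_orientation = c(forward = sum(mf), reverse = sum(mr),
                        both = sum(mf & mr)),
    full_length = sum(full), fragmented = sum(matched) - sum(full))
  out$rate_forward <- if (length(b) > 0L) sum(mf) / length(b) else NA_real_
  out$rate_reverse <- if (length(b) > 0L) sum(mr) / length(b) else NA_real_
  out$matched_forward_ids <- ids[mf]
  out$matched_reverse_ids <- ids[mr]
  out
}

#' Relative rate reduction between two insertion summaries
#'
#' Generic effect-size helper: `1 - treated/baseline` on the rates.
#' Negative values indicate an increase.
#'
#' @param baseline,treated `insertion_summary` objects or bare rates.
#' @return Fraction of the baseline rate removed by the treatment.
#' @export
rate_reduction <- function(baseline, treated) {
  r <- function(x) if (inherits(x, "insertion_summary")) x$rate else as.numeric(x)
  b <- r(baseline); t <- r(treated)
  if (is.na(b) || is.na(t)) stop("rates must be defined", call. = FALSE)
  if (b == 0) stop("baseline rate is zero; reduction undefined", call. = FALSE)
  1 - t / b
}
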