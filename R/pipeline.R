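# Pipeline drivers orchestrating the probe, demux, edits and CIGAR
# stages over files. These are what the command-line wrapper in
# inst/scripts/ampligrep.R calls; all computation stays in the package
# so nothing here needs external tools. Upstream of this pipeline sits
# basecalling and adaptor trimming (e.g. Porechop with
# "--adapter_threshold 85 --extra_end_trim 0"); alignment for the HDR
# stage is external too ("minimap2 -ax map-ont").

#' Run amplicon extraction and barcode demultiplexing over a pool
#'
#' For every reference amplicon: builds end-window probe sets, extracts
#' and orientation-normalises its full-length reads, then demultiplexes
#' them across the samples barcoded on that amplicon. Every input read
#' is accounted for in the stats (retained + rejected == total), and
#' multi-assigned reads are kept in all bins so the duplicate-based FDR
#' can be reported.
#'
#' @param reads Read table or FASTQ path.
#' @param amplicons Named list of [reference_amplicon()]s, or a FASTA
#'   path.
#' @param barcodes Data frame with columns `sample_id`, `barcode`,
#'   `forward_primer`, `amplicon_name`, or a TSV path
#'   ([read_barcode_table()]).
#' @param outdir Optional output directory; per-sample FASTQ files
#'   (`<sample_id>.fastq.gz`) and a `demux_stats.tsv` are written.
#' @param window_start,window_stop,k,step End-window probe parameters
#'   ([make_end_probes()]).
#' @param barcode_k,min_terminal_barcode Barcode probe parameters
#'   ([make_barcode_probes()]).
#' @param match_threshold Distinct-probe threshold for all sets.
#' @param search_prefix 5' window scanned for barcodes
#'   ([demultiplex()]).
#' @param strict Drop multi-sample reads instead of keeping them.
#' @return List of class `grep_run`: `extractions` (per amplicon),
#'   `assignments` (per amplicon [demultiplex()] results), `sample_reads`
#'   (named list of per-sample read tables), `stats` (per-amplicon data
#'   frame), `fdr` ([compute_fdr()] over all bins).
#' @export
run_grep <- function(reads, amplicons, barcodes, outdir = NULL,
                     window_start = 20L, window_stop = 90L,
                     k = 15L, step = 5L,
                     barcode_k = 9L, min_terminal_barcode = 4L,
                     match_threshold = 2L, search_prefix = 150L,
                     strict = FALSE) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.character(amplicons)) amplicons <- read_amplicon_fasta(amplicons)
  if (is.character(barcodes)) barcodes <- read_barcode_table(barcodes)
  stopifnot(all(barcodes$amplicon_name %in% names(amplicons)))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  extractions <- list(); assignments <- list(); sample_reads <- list()
  stats <- list()
  for (an in names(amplicons)) {
    amp <- amplicons[[an]]
    ends <- make_end_probes(amp, window_start, window_stop, k, step,
                            match_threshold = match_threshold)
    ex <- extract_amplicon_reads(reads, ends$grep_left, ends$grep_right)
    extractions[[an]] <- ex
    bc <- barcodes[barcodes$amplicon_name == an, , drop = FALSE]
    if (nrow(bc) == 0L) next
    sets <- lapply(seq_len(nrow(bc)), function(i)
      make_barcode_probes(
        barcode_spec(bc$sample_id[i], bc$barcode[i], bc$forward_primer[i]),
        k = barcode_k, min_terminal_barcode = min_terminal_barcode,
        match_threshold = match_threshold))
    names(sets) <- bc$sample_id
    asn <- demultiplex(ex$reads, sets, search_prefix = search_prefix,
                       strict = strict)
    assignments[[an]] <- asn
    for (s in bc$sample_id) {
      sr <- ex$reads[match(asn$read_id[asn$sample_id == s], ex$reads$read_id), ,
                     drop = FALSE]
      rownames(sr) <- NULL
      sample_reads[[s]] <- sr
      if (!is.null(outdir))
        write_fastq(sr, file.path(outdir, paste0(s, ".fastq.gz")))
    }
    stats[[an]] <- data.frame(
      amplicon_name = an,
      total_reads = ex$stats$total_reads,
      amplicon_extracted = ex$stats$retained,
      demuxed = sum(attr(asn, "per_sample")),
      retrieval_rate = ex$stats$retrieval_rate,
      stringsAsFactors = FALSE)
  }
  all_asn <- do.call(rbind, c(lapply(assignments, as.data.frame),
                              list(make.row.names = FALSE)))
  fdr <- compute_fdr(all_asn %||% data.frame(read_id = character(0)))
  stats <- do.call(rbind, c(stats, list(make.row.names = FALSE)))
  if (!is.null(outdir) && !is.null(stats))
    utils::write.table(stats, file.path(outdir, "demux_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(extractions = extractions, assignments = assignments,
                 sample_reads = sample_reads, stats = stats, fdr = fdr),
            class = "grep_run")
}

#' @export
print.grep_run <- function(x, ...) {
  cat("<grep_run>\n")
  if (!is.null(x$stats)) print(x$stats)
  cat(sprintf("duplicate-based FDR: %d/%d (%.4g)\n",
              x$fdr$duplicated_reads, x$fdr$total_assigned, x$fdr$fdr))
  invisible(x)
}

#' Scan demultiplexed sample bins for insertions
#'
#' Runs [dsodn_scan()] and/or [backbone_scan()] over each sample's
#' amplicon-specific reads and assembles a tidy summary table. Matched
#' reads are written to `<sample_id>-DSgrep.fastq.gz`,
#' `<sample_id>-BBF.fastq.gz` and `<sample_id>-BBR.fastq.gz` sub-bins
#' when `outdir` is given.
#'
#' @param sample_reads Named list of read tables (as from
#'   [run_grep()]`$sample_reads`), or a named character vector of FASTQ
#'   paths.
#' @param dsodn Insert sequence (or `NULL` to skip the dsODN scan).
#' @param backbone Backbone sequence (or `NULL` to skip the backbone
#'   scan).
#' @param outdir Optional output directory for sub-bins and the
#'   `edits_summary.tsv`.
#' @param dsodn_k,dsodn_step,bb_k,bb_step Probe parameters.
#' @param full_length_span,sensitivity Passed to [backbone_scan()].
#' @return Data frame with columns `sample_id`, `class`, `matched`,
#'   `total`, `rate`, `full_length`, `fragmented`.
#' @export
run_edits <- function(sample_reads, dsodn = NULL, backbone = NULL,
                      outdir = NULL, dsodn_k = 13L, dsodn_step = 1L,
                      bb_k = 15L, bb_step = 100L,
                      full_length_span = 0.9, sensitivity = FALSE) {
  if (is.null(dsodn) && is.null(backbone))
    stop("provide at least one of dsodn or backbone", call. = FALSE)
  if (is.character(sample_reads))
    sample_reads <- lapply(sample_reads, read_fastq)
  stopifnot(!is.null(names(sample_reads)))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  ds_probes <- if (!is.null(dsodn))
    make_insert_probes(dsodn, k = dsodn_k, step = dsodn_step)
  bb_probes <- if (!is.null(backbone))
    make_backbone_probes(backbone, k = bb_k, step = bb_step)

  rows <- list()
  for (s in names(sample_reads)) {
    rd <- sample_reads[[s]]
    if (!is.null(ds_probes)) {
      sm <- dsodn_scan(rd, ds_probes)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, class = "dsodn", matched = sm$matched_reads,
        total = sm$total_reads, rate = sm$rate,
        full_length = NA_integer_, fragmented = NA_integer_,
        stringsAsFactors = FALSE)
      if (!is.null(outdir))
        write_fastq(rd[rd$read_id %in% sm$matched_read_ids, , drop = FALSE],
                    file.path(outdir, paste0(s, "-DSgrep.fastq.gz")))
    }
    if (!is.null(bb_probes)) {
      sm <- backbone_scan(rd, bb_probes, full_length_span = full_length_span,
                          sensitivity = sensitivity)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, class = sm$kind, matched = sm$matched_reads,
        total = sm$total_reads, rate = sm$rate,
        full_length = sm$full_length, fragmented = sm$fragmented,
        stringsAsFactors = FALSE)
      if (!is.null(outdir)) {
        write_fastq(rd[rd$read_id %in% sm$matched_forward_ids, , drop = FALSE],
                    file.path(outdir, paste0(s, "-BBF.fastq.gz")))
        write_fastq(rd[rd$read_id %in% sm$matched_reverse_ids, , drop = FALSE],
                    file.path(outdir, paste0(s, "-BBR.fastq.gz")))
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(outdir))
    utils::write.table(out, file.path(outdir, "edits_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Quantify HDR knock-in and large deletions from alignments
#'
#' @param hdr_sam SAM/BAM of amplicon reads aligned to the HDR-allele
#'   reference (path or alignment table).
#' @param wt_sam Optional SAM/BAM against the wild-type reference for
#'   large-deletion frequency.
#' @param threshold_nt Operation-length threshold ([hdr_efficiency()]).
#' @param op_codes Operations thresholded for the HDR calculation.
#' @param deletion_threshold_nt,deletion_op_codes Parameters of the
#'   large-deletion calculation ([large_deletion_frequency()]).
#' @return List with `hdr` (an `hdr_summary`) and, when `wt_sam` is
#'   given, `large_deletion_frequency`.
#' @export
run_hdr <- function(hdr_sam, wt_sam = NULL, threshold_nt = 1000L,
                    op_codes = "S", deletion_threshold_nt = 1000L,
                    deletion_op_codes = c("D", "S")) {
  if (is.character(hdr_sam)) hdr_sam <- read_sam(hdr_sam)
  out <- list(hdr = hdr_efficiency(hdr_sam, threshold_nt, op_codes))
  if (!is.null(wt_sam)) {
    if (is.character(wt_sam)) wt_sam <- read_sam(wt_sam)
    out$large_deletion_frequency <-
      large_deletion_frequency(wt_sam, deletion_threshold_nt,
                               deletion_op_codes)
  }
  out
}
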