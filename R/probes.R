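#' Construct a probe set
#'
#' A probe set is an ordered collection of short k-mer probes cut from a
#' signature sequence, together with the matching policy: how many
#' distinct probes must occur in a read (`match_threshold`) and whether
#' reverse-complement variants are searched on the fly
#' (`search_both_orientations`). All higher-level "grep" logic in the
#' package reduces to probe sets. Probes are exact-match only: error
#' tolerance comes from probe redundancy, not from fuzzy matching.
#'
#' @param kind One of `"grep_left"`, `"grep_right"`, `"barcode"`,
#'   `"insert"`, `"backbone"`.
#' @param k Probe length in nt.
#' @param step Step between probe start positions in nt.
#' @param probes Data frame with columns `sequence`, `origin_offset`
#'   (0-based start in the signature) and `orientation` (`"forward"` or
#'   `"reverse_complement"`).
#' @param match_threshold Minimum number of distinct probes that must
#'   occur in a read for the read to match (n >= 2 by default).
#' @param search_both_orientations If `TRUE`, a probe also matches when
#'   its reverse complement occurs in the read.
#' @param signature_length Length of the signature sequence the probes
#'   were cut from (needed for span-based classification of backbone
#'   hits).
#' @return An object of class `probe_set`.
#' @export
probe_set <- function(kind, k, step, probes,
                      match_threshold = 2L,
                      search_both_orientations = FALSE,
                      signature_length = NA_integer_) {
  kind <- match.arg(kind,
                    c("grep_left", "grep_right", "barcode", "insert", "backbone"))
  stopifnot(is.data.frame(probes),
            all(c("sequence", "origin_offset", "orientation") %in% names(probes)),
            k >= 1L, step >= 1L, match_threshold >= 1L)
  # drop duplicate probe sequences so a palindromic k-mer cannot double-count
  probes <- probes[!duplicated(probes$sequence), , drop = FALSE]
  rownames(probes) <- NULL
  if (nrow(probes) && any(nchar(probes$sequence) != k))
    stop("all probes must have length k = ", k, call. = FALSE)
  structure(
    list(kind = kind, k = as.integer(k), step = as.integer(step),
         probes = probes,
         match_threshold = as.integer(match_threshold),
         search_both_orientations = isTRUE(search_both_orientations),
         signature_length = as.integer(signature_length)),
    class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf(
    "<probe_set> kind=%s  %d probes (k=%d, step=%d)  threshold=%d  both_orientations=%s\n",
    x$kind, nrow(x$probes), x$k, x$step, x$match_threshold,
    x$search_both_orientations))
  invisible(x)
}

# k-mers of `signature` at 0-based starts, skipping windows that contain N
.tile_kmers <- function(signature, starts, k, warn_n = TRUE) {
  seqs <- substring(signature, starts + 1L, starts + k)
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (any(has_n) && warn_n)
    warning(sum(has_n), " probe window(s) contain N and were skipped",
            call. = FALSE)
  data.frame(sequence = seqs[!has_n],
             origin_offset = starts[!has_n],
             stringsAsFactors = FALSE)
}

#' Build end-window probe sets for full-length read retrieval
#'
#' Tiles 15-mers (by default) with a 5-nt step across the window 20-90
#' nt from each end of the reference amplicon, excluding the ~20-nt
#' primer sequence. The left set is cut from the forward strand; the
#' right set is cut identically from the reverse-complemented amplicon,
#' so both sets read 5'->3' into the amplicon from their respective
#' ends. A read counts as full-length when at least `match_threshold`
#' probes of *both* sets occur in it (in either orientation).
#'
#' @param amplicon A [reference_amplicon()].
#' @param window_start,window_stop 0-based half-open window `[start,
#'   stop)` measured from each amplicon end, in nt.
#' @param k Probe length (nt).
#' @param step Step between probe starts (nt).
#' @param match_threshold Distinct-probe threshold for a match.
#' @return List with elements `grep_left` and `grep_right`, each a
#'   [probe_set()] with `search_both_orientations = TRUE`.
#' @export
#' @examples
#' amp <- reference_amplicon("amp", paste(rep("ACGT", 100), collapse = ""))
#' ps <- make_end_probes(amp)
#' nrow(ps$grep_left$probes)  # 12 probes: starts 20, 25, ..., 75
make_end_probes <- function(amplicon, window_start = 20L, window_stop = 90L,
                            k = 15L, step = 5L, match_threshold = 2L) {
  stopifnot(inherits(amplicon, "reference_amplicon"),
            window_stop - window_start >= k)
  if (amplicon$expected_length < 2L * window_stop)
    stop("amplicon too short for end windows (need >= ",
         2L * window_stop, " bp, got ", amplicon$expected_length, " bp)",
         call. = FALSE)
  starts <- seq.int(window_start, window_stop - k, by = step)
  left <- .tile_kmers(amplicon$sequence, starts, k)
  left$orientation <- rep("forward", nrow(left))
  right <- .tile_kmers(dna_revcomp(amplicon$sequence), starts, k)
  right$orientation <- rep("forward", nrow(right))
  list(
    grep_left = probe_set("grep_left", k, step, left,
                          match_threshold = match_threshold,
                          search_both_orientations = TRUE,
                          signature_length = window_stop - window_start),
    grep_right = probe_set("grep_right", k, step, right,
                           match_threshold = match_threshold,
                           search_both_orientations = TRUE,
                           signature_length = window_stop - window_start))
}

#' Build barcode-primer probes for demultiplexing
#'
#' The signature is the concatenation of barcode and forward primer;
#' 9-mers (by default) are tiled with a 1-nt step, keeping only windows
#' that cover at least the last `min_terminal_barcode` bases of the
#' barcode. This anchors every probe on the barcode-primer junction,
#' yielding roughly 5-10 probes regardless of barcode length.
#'
#' @param spec A [barcode_spec()].
#' @param k Probe length (nt).
#' @param step Step between probe starts (nt).
#' @param min_terminal_barcode Number of terminal barcode bases every
#'   probe window must cover.
#' @param match_threshold Distinct-probe threshold for a match.
#' @return A [probe_set()] of kind `"barcode"` (forward orientation
#'   only: demultiplexing happens after orientation normalisation).
#' @export
make_barcode_probes <- function(spec, k = 9L, step = 1L,
                                min_terminal_barcode = 4L,
                                match_threshold = 2L) {
  stopifnot(inherits(spec, "barcode_spec"))
  bl <- nchar(spec$barcode)
  if (bl < min_terminal_barcode)
    stop("barcode shorter than min_terminal_barcode (", min_terminal_barcode,
         " nt)", call. = FALSE)
  signature <- paste0(spec$barcode, spec$forward_primer)
  if (nchar(signature) < k)
    stop("barcode + forward_primer shorter than k = ", k, call. = FALSE)
  # window [s, s+k) must contain barcode positions [bl - min_terminal, bl)
  s_min <- max(0L, bl - k)
  s_max <- min(bl - min_terminal_barcode, nchar(signature) - k)
  if (s_max < s_min)
    stop("no probe window can cover the last ", min_terminal_barcode,
         " nt of the barcode", call. = FALSE)
  starts <- seq.int(s_min, s_max, by = step)
  probes <- .tile_kmers(signature, starts, k)
  probes$orientation <- rep("forward", nrow(probes))
  probe_set("barcode", k, step, probes,
            match_threshold = match_threshold,
            search_both_orientations = FALSE,
            signature_length = nchar(signature))
}

#' Build probes from a short insert (dsODN) in both orientations
#'
#' Tiles k-mers across the insert on the forward strand and on its
#' reverse complement, merges the two and removes duplicates (so a
#' palindromic insert does not double-count). Defaults follow the
#' optimum for a 29-bp dsODN: 13-mers with a 1-nt step.
#'
#' @param insert DNA string of the insert.
#' @param k Probe length (nt).
#' @param step Step between probe starts (nt).
#' @param match_threshold Distinct-probe threshold for a match.
#' @return A [probe_set()] of kind `"insert"` containing both
#'   orientations as explicit probes.
#' @export
make_insert_probes <- function(insert, k = 13L, step = 1L,
                               match_threshold = 2L) {
  insert <- .assert_dna(insert, "insert")
  if (nchar(insert) < k)
    stop("insert shorter than k = ", k, call. = FALSE)
  starts <- seq.int(0L, nchar(insert) - k, by = step)
  fwd <- .tile_kmers(insert, starts, k)
  fwd$orientation <- rep("forward", nrow(fwd))
  rc <- .tile_kmers(dna_revcomp(insert), starts, k)
  rc$orientation <- rep("reverse_complement", nrow(rc))
  probe_set("insert", k, step, rbind(fwd, rc),
            match_threshold = match_threshold,
            search_both_orientations = FALSE,
            signature_length = nchar(insert))
}

#' Build sparse probes from a plasmid backbone in both orientations
#'
#' Tiles 15-mers with a 100-nt step across the backbone and its reverse
#' complement. Each probe keeps its origin offset so that the span of
#' matched probes can classify an insertion as full-length versus
#' fragmented (see [backbone_scan()]). Note the detection floor implied
#' by the sparse step: a fragment shorter than `step + k` bp can hit at
#' most one probe and is invisible at the default threshold of 2.
#'
#' @param backbone DNA string of the plasmid backbone.
#' @param k Probe length (nt).
#' @param step Step between probe starts (nt).
#' @param match_threshold Distinct-probe threshold for a match.
#' @return A [probe_set()] of kind `"backbone"` with both orientations
#'   as explicit probes; split per orientation with
#'   [split_probe_orientations()].
#' @export
make_backbone_probes <- function(backbone, k = 15L, step = 100L,
                                 match_threshold = 2L) {
  backbone <- .assert_dna(backbone, "backbone")
  if (nchar(backbone) < k)
    stop("backbone shorter than k = ", k, call. = FALSE)
  starts <- seq.int(0L, nchar(backbone) - k, by = step)
  fwd <- .tile_kmers(backbone, starts, k)
  fwd$orientation <- rep("forward", nrow(fwd))
  rc <- .tile_kmers(dna_revcomp(backbone), starts, k)
  rc$orientation <- rep("reverse_complement", nrow(rc))
  probe_set("backbone", k, step, rbind(fwd, rc),
            match_threshold = match_threshold,
            search_both_orientations = FALSE,
            signature_length = nchar(backbone))
}

#' Split a two-orientation probe set into forward and reverse sets
#'
#' @param ps A [probe_set()] whose probes carry an `orientation` column.
#' @return List with elements `forward` and `reverse`, each a
#'   [probe_set()] restricted to one orientation.
#' @export
split_probe_orientations <- function(ps) {
  stopifnot(inherits(ps, "probe_set"))
  sub <- function(o) {
    p <- ps$probes[ps$probes$orientation == o, , drop = FALSE]
    probe_set(ps$kind, ps$k, ps$step, p,
              match_threshold = ps$match_threshold,
              search_both_orientations = FALSE,
              signature_length = ps$signature_length)
  }
  list(forward = sub("forward"), reverse = sub("reverse_complement"))
}

#' Cross-match counts between probe sets and candidate sequences
#'
#' Design-validation helper: counts, for every (sequence, probe set)
#' pair, the distinct probes occurring in the sequence. Off-target
#' counts at or above a set's match threshold indicate that the probe
#' signature is not specific — e.g. a barcode-primer junction k-mer
#' that also occurs inside the reference amplicon would make every read
#' of that amplicon demultiplex into the wrong sample. Screen barcode
#' designs against their amplicons with this before a run.
#'
#' @param probesets Named list of [probe_set()]s.
#' @param sequences Named character vector of sequences to screen
#'   (references, templates).
#' @return Integer matrix of distinct-probe counts, sequences in rows,
#'   probe sets in columns.
#' @export
probe_cross_matches <- function(probesets, sequences) {
  stopifnot(length(probesets) > 0L, length(sequences) > 0L)
  m <- vapply(probesets, function(ps) count_probe_matches(sequences, ps),
              integer(length(sequences)))
  matrix(m, nrow = length(sequences),
         dimnames = list(names(sequences), names(probesets)))
}

#' Export a probe set as FASTA (debugging aid)
#'
#' @param ps A [probe_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probes_fasta <- function(ps, path) {
  stopifnot(inherits(ps, "probe_set"))
  x <- Biostrings::DNAStringSet(ps$probes$sequence)
  names(x) <- sprintf("%s_%03d_off%d_%s", ps$kind, seq_len(nrow(ps$probes)),
                      ps$probes$origin_offset, ps$probes$orientation)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
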