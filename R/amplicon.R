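#' Reference amplicon
#'
#' A named reference amplicon sequence with primer-length annotations.
#' The amplicon sequence is expected to be the full PCR product (primers
#' included, barcode excluded); end-window probe sets are built from it
#' with [make_end_probes()].
#'
#' @param name Amplicon identifier, unique within a run.
#' @param sequence DNA string (A/C/G/T/N), any case; stored uppercased.
#' @param forward_primer_len,reverse_primer_len Primer lengths in nt
#'   (annotations only; end windows start past the primer by default).
#' @return An object of class `reference_amplicon` with fields `name`,
#'   `sequence`, `forward_primer_len`, `reverse_primer_len` and
#'   `expected_length` (the sequence length in bp).
#' @export
reference_amplicon <- function(name, sequence,
                               forward_primer_len = 20L,
                               reverse_primer_len = 20L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(sequence), length(sequence) == 1L)
  sequence <- .assert_dna(sequence, sprintf("amplicon '%s'", name))
  structure(
    list(name = name,
         sequence = sequence,
         forward_primer_len = as.integer(forward_primer_len),
         reverse_primer_len = as.integer(reverse_primer_len),
         expected_length = nchar(sequence)),
    class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("<reference_amplicon> %s: %d bp (primers %d/%d nt)\n",
              x$name, x$expected_length,
              x$forward_primer_len, x$reverse_primer_len))
  invisible(x)
}

#' Barcode specification for one sample
#'
#' A sample barcode together with the forward primer it is ligated to.
#' The barcode sits at the 5' end of the forward primer, so the
#' barcode-primer junction is the signature used for demultiplexing
#' (see [make_barcode_probes()]).
#'
#' @param sample_id Sample identifier.
#' @param barcode Barcode sequence, 8-14 nt, no N.
#' @param forward_primer Forward primer sequence, no N.
#' @return An object of class `barcode_spec`.
#' @export
barcode_spec <- function(sample_id, barcode, forward_primer) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  barcode <- .assert_dna(barcode, "barcode", allow_n = FALSE)
  forward_primer <- .assert_dna(forward_primer, "forward_primer", allow_n = FALSE)
  if (nchar(barcode) < 8L || nchar(barcode) > 14L)
    stop("barcode must be 8-14 nt, got ", nchar(barcode), " nt", call. = FALSE)
  structure(
    list(sample_id = sample_id, barcode = barcode,
         forward_primer = forward_primer),
    class = "barcode_spec")
}

#' @export
print.barcode_spec <- function(x, ...) {
  cat(sprintf("<barcode_spec> %s: %s + primer (%d nt)\n",
              x$sample_id, x$barcode, nchar(x$forward_primer)))
  invisible(x)
}

#' Validate pairwise edit distances within a barcode set
#'
#' Barcodes designed to tolerate up to 2 nt of substitution, insertion
#' or deletion error must keep enough pairwise Levenshtein distance.
#' This check never mutates its input: it reports every pair whose
#' distance falls below `min_distance` and warns if any does.
#'
#' @param specs List of [barcode_spec()] objects (at least two).
#' @param min_distance Minimum acceptable pairwise edit distance.
#' @return A data frame with one row per barcode pair: `sample_a`,
#'   `sample_b`, `distance`, `flagged`. Attribute `min_distance` records
#'   the threshold used.
#' @export
validate_barcode_set <- function(specs, min_distance = 5L) {
  stopifnot(length(specs) >= 2L)
  ids <- vapply(specs, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id in barcode set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bcs <- vapply(specs, `[[`, character(1), "barcode")
  d <- utils::adist(bcs)  # generalised Levenshtein, unit costs
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(
    sample_a = ids[pairs[, 1L]],
    sample_b = ids[pairs[, 2L]],
    distance = d[pairs],
    stringsAsFactors = FALSE)
  out$flagged <- out$distance < min_distance
  attr(out, "min_distance") <- as.integer(min_distance)
  if (any(out$flagged))
    warning(sum(out$flagged), " barcode pair(s) below edit distance ",
            min_distance, call. = FALSE)
  out
}

#' Read reference amplicons from a FASTA file
#'
#' @param path FASTA file of reference amplicon sequences.
#' @param forward_primer_len,reverse_primer_len Primer-length
#'   annotations applied to every amplicon.
#' @return Named list of [reference_amplicon()] objects.
#' @export
read_amplicon_fasta <- function(path, forward_primer_len = 20L,
                                reverse_primer_len = 20L) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  amps <- Map(reference_amplicon, nm, as.character(x),
              forward_primer_len = forward_primer_len,
              reverse_primer_len = reverse_primer_len)
  names(amps) <- nm
  amps
}

#' Read a barcode/primer table
#'
#' Expects a TSV with columns `sample_id`, `barcode`, `forward_primer`
#' and `amplicon_name`.
#'
#' @param path Path to the tab-separated table.
#' @return Data frame with the four columns, checked and uppercased.
#' @export
read_barcode_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "barcode", "forward_primer", "amplicon_name")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("barcode table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$barcode <- .assert_dna(tab$barcode, "barcode", allow_n = FALSE)
  tab$forward_primer <- .assert_dna(tab$forward_primer, "forward_primer",
                                    allow_n = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in barcode table", call. = FALSE)
  tab[, need]
}
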