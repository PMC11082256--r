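# CIGAR-based quantification of HDR knock-in efficiency and large
# deletions. Alignment itself is external (e.g. `minimap2 -ax map-ont`);
# SAM is the interface and is consumed through Rsamtools.

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

#' Parse a CIGAR string
#'
#' @param text A CIGAR string per the SAM specification, or `"*"`.
#' @return Data frame with columns `op` (operation code) and `length`
#'   (positive integer), in order; zero rows for `"*"`.
#' @export
#' @examples
#' parse_cigar("50S1400D2413M")
parse_cigar <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  empty <- data.frame(op = character(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (identical(text, "*")) return(empty)
  m <- gregexpr("[0-9]+[MIDNSHP=X]", text)[[1L]]
  if (m[1L] == -1L)
    stop("malformed CIGAR at position 1: '", text, "'", call. = FALSE)
  tokens <- regmatches(text, gregexpr("[0-9]+[MIDNSHP=X]", text))[[1L]]
  # tokens must tile the string with no gaps
  ends <- m + attr(m, "match.length") - 1L
  expected_start <- c(1L, utils::head(ends, -1L) + 1L)
  bad <- which(m != expected_start)
  if (length(bad) || utils::tail(ends, 1L) != nchar(text)) {
    pos <- if (length(bad)) expected_start[bad[1L]] else utils::tail(ends, 1L) + 1L
    stop("malformed CIGAR at position ", pos, ": '", text, "'", call. = FALSE)
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", tokens))
  if (any(len == 0L))
    stop("zero-length CIGAR operation at position ",
         m[which(len == 0L)[1L]], ": '", text, "'", call. = FALSE)
  data.frame(op = sub("^[0-9]+", "", tokens), length = len,
             stringsAsFactors = FALSE)
}

#' Maximum CIGAR operation length over a set of op codes
#'
#' @param x A CIGAR string or a parsed ops data frame from
#'   [parse_cigar()].
#' @param op_codes Character vector of operation codes, e.g. `"S"` or
#'   `c("D", "S")`.
#' @return The maximum length among matching operations; 0 when none.
#' @export
max_op_length <- function(x, op_codes) {
  ops <- if (is.character(x)) parse_cigar(x) else x
  stopifnot(is.data.frame(ops), all(op_codes %in% .CIGAR_OPS))
  hit <- ops$length[ops$op %in% op_codes]
  if (length(hit) == 0L) 0L else max(hit)
}

#' Read alignments from a SAM (or BAM) file
#'
#' @param path SAM or BAM file. SAM input is converted with
#'   [Rsamtools::asBam()] first.
#' @return Data frame with columns `read_id`, `reference_name`, `flag`,
#'   `cigar`, `is_mapped`, `is_primary`.
#' @export
read_sam <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                            indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "flag", "cigar")))[[1L]]
  flag <- res$flag
  data.frame(
    read_id = res$qname,
    reference_name = as.character(res$rname),
    flag = flag,
    cigar = ifelse(is.na(res$cigar), "*", res$cigar),
    is_mapped = bitwAnd(flag, 4L) == 0L,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    stringsAsFactors = FALSE)
}

.primary_mapped <- function(alignments, reference = NULL) {
  stopifnot(is.data.frame(alignments),
            all(c("cigar", "is_mapped", "is_primary") %in% names(alignments)))
  use <- alignments$is_mapped & alignments$is_primary
  if (!is.null(reference))
    use <- use & alignments$reference_name == reference
  alignments[use, , drop = FALSE]
}

#' HDR knock-in efficiency from alignments to the HDR-allele reference
#'
#' Against the expected HDR-edited reference, a wild-type (non
#' knock-in) read cannot align through the cassette and shows a long
#' soft-clip (or deletion, depending on the aligner's representation).
#' Alignments whose maximum operation length over `op_codes` strictly
#' exceeds `threshold_nt` are counted as WT-like; the artificial
#' "deletion" percentage is their share of all primary mapped
#' alignments, and the HDR percentage is its complement to 100.
#'
#' @param alignments Alignment table from [read_sam()] (or any data
#'   frame with `cigar`, `is_mapped`, `is_primary` columns). Only
#'   primary mapped records are used, so each read contributes once.
#' @param threshold_nt Operation-length threshold in nt (strictly
#'   greater-than); 1000 suits a ~1.4-kb cassette.
#' @param op_codes Operations to threshold; `"S"` by default, use
#'   `c("S", "D")` for aligners that gap instead of clipping.
#' @param reference Optional reference name to restrict to.
#' @return Object of class `hdr_summary` with fields
#'   `total_alignments`, `wt_like`, `artificial_deletion_pct`,
#'   `hdr_pct`, `threshold_nt`, `op_codes`. Percentages are `NA` when
#'   no alignment qualifies.
#' @export
hdr_efficiency <- function(alignments, threshold_nt = 1000L,
                           op_codes = "S", reference = NULL) {
  aln <- .primary_mapped(alignments, reference)
  total <- nrow(aln)
  if (total == 0L) {
    return(structure(list(total_alignments = 0L, wt_like = NA_integer_,
                          artificial_deletion_pct = NA_real_,
                          hdr_pct = NA_real_,
                          threshold_nt = as.integer(threshold_nt),
                          op_codes = op_codes),
                     class = "hdr_summary"))
  }
  mx <- vapply(aln$cigar, max_op_length, integer(1), op_codes = op_codes,
               USE.NAMES = FALSE)
  wt_like <- sum(mx > threshold_nt)
  pct <- 100 * wt_like / total
  structure(list(total_alignments = total, wt_like = wt_like,
                 artificial_deletion_pct = pct, hdr_pct = 100 - pct,
                 threshold_nt = as.integer(threshold_nt),
                 op_codes = op_codes),
            class = "hdr_summary")
}

#' @export
print.hdr_summary <- function(x, ...) {
  cat(sprintf(
    "<hdr_summary> %d alignments; WT-like (max %s > %d nt): %s; HDR %.2f%%\n",
    x$total_alignments, paste(x$op_codes, collapse = "/"), x$threshold_nt,
    x$wt_like, x$hdr_pct))
  invisible(x)
}

#' Large-deletion frequency from alignments to the wild-type reference
#'
#' Fraction of primary mapped alignments whose maximum operation length
#' over `op_codes` reaches `threshold_nt` (inclusive).
#'
#' @inheritParams hdr_efficiency
#' @return Fraction in `[0, 1]`, or `NA` when no alignment qualifies.
#' @export
large_deletion_frequency <- function(alignments, threshold_nt,
                                     op_codes = c("D", "S"),
                                     reference = NULL) {
  aln <- .primary_mapped(alignments, reference)
  if (nrow(aln) == 0L) return(NA_real_)
  mx <- vapply(aln$cigar, max_op_length, integer(1), op_codes = op_codes,
               USE.NAMES = FALSE)
  mean(mx >= threshold_nt)
}
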