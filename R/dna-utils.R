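#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors as the working currency of the package.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of reverse complements, uppercased.
#' @export
#' @examples
#' dna_revcomp("ACGTN")
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' @keywords internal
.assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters other than %s", what,
                 if (allow_n) "A/C/G/T/N" else "A/C/G/T"), call. = FALSE)
  }
  invisible(toupper(x))
}

#' @keywords internal
.reverse_string <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
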