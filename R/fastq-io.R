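# FASTQ in/out via Biostrings. Reads are carried through the package as
# plain data frames with columns read_id, bases, qual.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return Data frame with columns `read_id`, `bases`, `qual`. The read
#'   id is the first whitespace-delimited token of the header.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(x) == 0L)
    return(data.frame(read_id = character(0), bases = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    bases = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#'
#' @param reads Data frame with columns `read_id`, `bases` and
#'   optionally `qual` (a constant placeholder quality is emitted when
#'   absent).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("read_id", "bases") %in% names(reads)))
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$bases))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$bases),
    Biostrings::PhredQuality(qual))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
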