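# Fixtures are generated in code; oracles here are deliberately naive
# and independent of the package's matching engine.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# naive all-positions substring scan: does `pattern` occur in `read`?
naive_occurs <- function(read, pattern) {
  k <- nchar(pattern)
  n <- nchar(read)
  if (k > n) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (substr(read, i, i + k - 1L) == pattern) return(TRUE)
  }
  FALSE
}

# distinct-probe count by brute force, honouring both-orientation sets
naive_count_matches <- function(read, ps) {
  read <- toupper(read)
  hits <- 0L
  for (j in seq_len(nrow(ps$probes))) {
    p <- ps$probes$sequence[j]
    found <- naive_occurs(read, p)
    if (!found && ps$search_both_orientations)
      found <- naive_occurs(read, dna_revcomp(p))
    if (found) hits <- hits + 1L
  }
  hits
}

# textbook dynamic-programming Levenshtein distance
naive_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0:m; d[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (a[i] != b[j]))
    }
  }
  d[m + 1L, n + 1L]
}

# brute-force count of valid probe start positions for a tiling
naive_tile_starts <- function(w_start, w_stop, k, step) {
  starts <- integer(0)
  s <- w_start
  while (TRUE) {
    if (s + k > w_stop) break
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# a small reference amplicon whose forward primer is its first 20 nt
test_amplicon <- function(len = 500, name = "amp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reference_amplicon(name, random_dna(len))
}

test_barcode <- function(amp, sample_id = "s1", barcode = "AACGGACTAT") {
  barcode_spec(sample_id, barcode, substr(amp$sequence, 1, 20))
}

# draw a random amplicon whose barcode-primer probe signatures are
# specific: each sample's probes match only its own template, and none
# match the bare reference (an assay-design precondition -- real
# primer/barcode designs are screened the same way)
draw_specific_amplicon <- function(len, name, barcodes, max_tries = 50) {
  for (t in seq_len(max_tries)) {
    amp <- reference_amplicon(name, random_dna(len))
    primer <- substr(amp$sequence, 1, 20)
    ids <- paste0("t", seq_along(barcodes))
    sets <- lapply(seq_along(barcodes), function(i)
      make_barcode_probes(barcode_spec(ids[i], barcodes[i], primer)))
    names(sets) <- ids
    templates <- c(stats::setNames(amp$sequence, "ref"),
                   stats::setNames(paste0(barcodes, amp$sequence), ids))
    cm <- probe_cross_matches(sets, templates)
    off_diag <- cm[ids, ]; diag(off_diag) <- 0L
    ok <- all(diag(cm[ids, ids]) >= 2) && all(off_diag == 0L) &&
      all(cm["ref", ] == 0L)
    if (ok) return(amp)
  }
  stop("could not draw a specific amplicon in ", max_tries, " tries")
}
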