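# Synthetic nanopore-like amplicon reads with exact ground truth.
# The generator emulates the features of pooled long-amplicon ONT runs
# that the analysis modules must survive: per-base substitution /
# insertion / deletion errors, a large population of truncated reads
# and a small population of over-long (concatenated) reads, random
# strand, and spiked edits at known frequencies. Errors are uniform and
# independent per base; homopolymer-biased error clustering of real
# nanopore data is deliberately not modelled.

#' Per-base sequencing error model
#'
#' Defaults total 10% error, split to reflect the indel-heavy profile
#' of ONT reads (accuracy around 90-95%).
#'
#' @param p_sub,p_ins,p_del Per-base probabilities of substitution,
#'   insertion (after the base) and deletion. Their sum must be < 1.
#' @return Object of class `error_model`.
#' @export
error_model <- function(p_sub = 0.04, p_ins = 0.025, p_del = 0.035) {
  stopifnot(p_sub >= 0, p_ins >= 0, p_del >= 0)
  if (p_sub + p_ins + p_del >= 1)
    stop("p_sub + p_ins + p_del must be < 1", call. = FALSE)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del),
            class = "error_model")
}

#' Read-artifact model
#'
#' @param frac_truncated Fraction of reads truncated to a uniform-length
#'   prefix or suffix (aborted sequencing); ~34-40% in raw ONT amplicon
#'   runs.
#' @param frac_overlong Fraction of reads concatenated with a second
#'   independently corrupted copy of the template (~5%).
#' @return Object of class `artifact_model`.
#' @export
artifact_model <- function(frac_truncated = 0.34, frac_overlong = 0.05) {
  stopifnot(frac_truncated >= 0, frac_overlong >= 0)
  if (frac_truncated + frac_overlong > 1)
    stop("frac_truncated + frac_overlong must be <= 1", call. = FALSE)
  structure(list(frac_truncated = frac_truncated,
                 frac_overlong = frac_overlong),
            class = "artifact_model")
}

#' Edit specification for template construction
#'
#' Describes one class of editing outcome spiked into a simulated
#' sample at a known frequency.
#'
#' @param edit_class One of `"wt"`, `"dsodn"`, `"hdr"`,
#'   `"backbone_full"`, `"backbone_fragment"`, `"large_deletion"`.
#' @param frequency Fraction of reads carrying this edit; frequencies
#'   of all non-wt classes in a sample must sum to <= 1 (remainder is
#'   wild type).
#' @param payload DNA string inserted (dsODN, HDR cassette, plasmid
#'   backbone); not used for `wt`/`large_deletion`.
#' @param cut_site 0-based position in the amplicon where the edit is
#'   applied.
#' @param orientation_law `"random"`, `"forward"` or `"reverse"`:
#'   insertion orientation for dsODN/backbone classes.
#' @param interval_len Length of the amplicon interval replaced (`hdr`)
#'   or removed (`large_deletion`), in bp.
#' @param copies Number of tandem payload copies inserted (`dsodn`).
#' @return Object of class `edit_spec`.
#' @export
edit_spec <- function(edit_class, frequency = 1, payload = NULL,
                      cut_site = NULL, orientation_law = "random",
                      interval_len = NULL, copies = 1L) {
  edit_class <- match.arg(edit_class,
                          c("wt", "dsodn", "hdr", "backbone_full",
                            "backbone_fragment", "large_deletion"))
  orientation_law <- match.arg(orientation_law,
                               c("random", "forward", "reverse"))
  stopifnot(frequency >= 0, frequency <= 1)
  if (edit_class != "wt" && is.null(cut_site))
    stop("cut_site required for edit class '", edit_class, "'", call. = FALSE)
  if (edit_class %in% c("dsodn", "hdr", "backbone_full", "backbone_fragment")) {
    if (is.null(payload))
      stop("payload required for edit class '", edit_class, "'", call. = FALSE)
    payload <- .assert_dna(payload, "payload", allow_n = FALSE)
  }
  if (edit_class %in% c("hdr", "large_deletion") && is.null(interval_len))
    stop("interval_len required for edit class '", edit_class, "'",
         call. = FALSE)
  structure(
    list(edit_class = edit_class, frequency = frequency, payload = payload,
         cut_site = if (is.null(cut_site)) NA_integer_ else as.integer(cut_site),
         orientation_law = orientation_law,
         interval_len = if (is.null(interval_len)) NA_integer_
                        else as.integer(interval_len),
         copies = as.integer(copies)),
    class = "edit_spec")
}

.insert_at <- function(seq, pos, what) {
  paste0(substr(seq, 1L, pos), what, substr(seq, pos + 1L, nchar(seq)))
}

#' Build the true (error-free) template for one read
#'
#' The template is the barcode followed by the amplicon carrying the
#' class-specific modification at the cut site: dsODN insertion
#' (oriented per the edit's law, optionally multi-copy), HDR cassette
#' replacement of an interval, insertion of the full backbone or of a
#' uniform random sub-fragment (>= 50 bp), or removal of an interval
#' (large deletion). `wt` leaves the amplicon unchanged.
#'
#' @param amplicon A [reference_amplicon()].
#' @param barcode A [barcode_spec()]; its barcode is prepended.
#' @param edit An [edit_spec()].
#' @return The template DNA string, with attribute `edit_orientation`
#'   recording the realised insertion orientation (`NA` for classes
#'   without one). Random choices (orientation, fragment) draw from the
#'   session RNG.
#' @export
build_template <- function(amplicon, barcode, edit) {
  stopifnot(inherits(amplicon, "reference_amplicon"),
            inherits(barcode, "barcode_spec"),
            inherits(edit, "edit_spec"))
  seq <- amplicon$sequence
  cs <- edit$cut_site
  if (!is.na(cs) && (cs < 0L || cs > nchar(seq)))
    stop("cut_site outside amplicon", call. = FALSE)
  orient <- NA_character_
  if (edit$edit_class %in% c("dsodn", "backbone_full", "backbone_fragment")) {
    orient <- switch(edit$orientation_law,
                     random = sample(c("forward", "reverse"), 1L),
                     edit$orientation_law)
  }
  oriented <- function(p) if (identical(orient, "reverse")) dna_revcomp(p) else p
  mod <- switch(
    edit$edit_class,
    wt = seq,
    dsodn = .insert_at(seq, cs,
                       strrep(oriented(edit$payload), edit$copies)),
    hdr = {
      if (cs + edit$interval_len > nchar(seq))
        stop("hdr interval extends past amplicon end", call. = FALSE)
      paste0(substr(seq, 1L, cs), edit$payload,
             substr(seq, cs + edit$interval_len + 1L, nchar(seq)))
    },
    backbone_full = .insert_at(seq, cs, oriented(edit$payload)),
    backbone_fragment = {
      lp <- nchar(edit$payload)
      if (lp < 50L) stop("backbone payload shorter than 50 bp", call. = FALSE)
      flen <- if (lp == 50L) 50L else sample(50:lp, 1L)
      fs <- if (lp == flen) 0L else sample(0:(lp - flen), 1L)
      .insert_at(seq, cs, oriented(substr(edit$payload, fs + 1L, fs + flen)))
    },
    large_deletion = {
      if (cs + edit$interval_len > nchar(seq))
        stop("deletion interval extends past amplicon end", call. = FALSE)
      paste0(substr(seq, 1L, cs),
             substr(seq, cs + edit$interval_len + 1L, nchar(seq)))
    })
  structure(paste0(barcode$barcode, mod), edit_orientation = orient)
}

.DNA_BASES <- c("A", "C", "G", "T")

# apply per-base substitution / insertion / deletion errors
.apply_errors <- function(template, em) {
  chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n == 0L) return("")
  u <- stats::runif(n)
  t1 <- em$p_sub; t2 <- t1 + em$p_ins; t3 <- t2 + em$p_del
  sub <- u < t1
  ins <- u >= t1 & u < t2
  del <- u >= t2 & u < t3
  if (any(sub)) {
    cur <- match(chars[sub], .DNA_BASES)
    cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)
    # substitute with one of the three other bases
    chars[sub] <- .DNA_BASES[((cur - 1L +
                               sample.int(3L, sum(sub), replace = TRUE)) %% 4L) + 1L]
  }
  counts <- rep.int(1L, n)
  counts[del] <- 0L
  counts[ins] <- 2L  # base kept, random base inserted after it
  out <- rep.int(chars, counts)
  if (any(ins)) {
    out[cumsum(counts)[ins]] <- sample(.DNA_BASES, sum(ins), replace = TRUE)
  }
  paste(out, collapse = "")
}

#' Corrupt one template into a nanopore-like read
#'
#' Applies per-base errors, then (mutually exclusively) truncation to a
#' uniform-length prefix or suffix of at least 100 bp, or concatenation
#' with a second independently corrupted copy of the template, then a
#' strand flip with probability 0.5. Deterministic under a fixed RNG
#' seed.
#'
#' @param template Template DNA string (from [build_template()]).
#' @param em An [error_model()].
#' @param am An [artifact_model()].
#' @param flip Apply the random strand flip (default `TRUE`).
#' @return List with `bases`, `artifact_class` (`"full_length"`,
#'   `"truncated"` or `"overlong"`) and `orientation` (read strand,
#'   `"forward"`/`"reverse"`).
#' @export
corrupt_read <- function(template, em = error_model(),
                         am = artifact_model(), flip = TRUE) {
  stopifnot(inherits(em, "error_model"), inherits(am, "artifact_model"))
  bases <- .apply_errors(template, em)
  artifact <- "full_length"
  u <- stats::runif(1L)
  if (u < am$frac_truncated) {
    n <- nchar(bases)
    if (n > 101L) {
      keep <- sample(100:(n - 1L), 1L)
      bases <- if (stats::runif(1L) < 0.5)
        substr(bases, 1L, keep)
      else
        substr(bases, n - keep + 1L, n)
    }
    artifact <- "truncated"
  } else if (u < am$frac_truncated + am$frac_overlong) {
    bases <- paste0(bases, .apply_errors(template, em))
    artifact <- "overlong"
  }
  orientation <- "forward"
  if (flip && stats::runif(1L) < 0.5) {
    bases <- dna_revcomp(bases)
    orientation <- "reverse"
  }
  list(bases = bases, artifact_class = artifact, orientation = orientation)
}

#' One sample's worth of a simulation design
#'
#' @param amplicon A [reference_amplicon()].
#' @param barcode A [barcode_spec()].
#' @param edits List of [edit_spec()]s whose frequencies sum to <= 1;
#'   the remainder of reads is wild type.
#' @param n_reads Number of reads to emit for this sample.
#' @return Object of class `sim_design_row`.
#' @export
sim_design_row <- function(amplicon, barcode, edits = list(), n_reads) {
  stopifnot(inherits(amplicon, "reference_amplicon"),
            inherits(barcode, "barcode_spec"),
            n_reads >= 0L)
  if (length(edits)) {
    stopifnot(all(vapply(edits, inherits, logical(1), "edit_spec")))
    f <- sum(vapply(edits, `[[`, numeric(1), "frequency"))
    if (f > 1 + 1e-12)
      stop("edit frequencies sum to ", f, " > 1", call. = FALSE)
  }
  structure(list(amplicon = amplicon, barcode = barcode, edits = edits,
                 n_reads = as.integer(n_reads)),
            class = "sim_design_row")
}

#' Simulate a pooled barcoded amplicon run with ground truth
#'
#' Emits `n_reads` reads per design row, drawing each read's edit class
#' from the row's frequencies, building the true template, corrupting
#' it under the error and artifact models, and recording one truth row
#' per read. Fully reproducible under a fixed `seed`.
#'
#' @param design List of [sim_design_row()]s; sample ids must be
#'   unique.
#' @param em An [error_model()].
#' @param am An [artifact_model()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param flip Randomise read strand (default `TRUE`).
#' @param fastq,truth_tsv Optional output paths (FASTQ / tab-separated
#'   truth table).
#' @return List of class `sim_pool` with elements `reads` (data frame
#'   `read_id`, `bases`, `qual`; qualities are a constant placeholder)
#'   and `truth` (data frame `read_id`, `amplicon_name`, `sample_id`,
#'   `edit_class`, `edit_orientation`, `orientation`, `artifact_class`,
#'   `true_template_length`).
#' @export
simulate_pool <- function(design, em = error_model(), am = artifact_model(),
                          seed = NULL, flip = TRUE,
                          fastq = NULL, truth_tsv = NULL) {
  stopifnot(length(design) > 0L,
            all(vapply(design, inherits, logical(1), "sim_design_row")))
  ids <- vapply(design, function(r) r$barcode$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id in design: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  all_reads <- vector("list", length(design))
  all_truth <- vector("list", length(design))
  for (r in seq_along(design)) {
    row <- design[[r]]
    n <- row$n_reads
    freqs <- vapply(row$edits, `[[`, numeric(1), "frequency")
    classes <- c(vapply(row$edits, `[[`, character(1), "edit_class"), "wt")
    draw <- if (n > 0L)
      sample.int(length(classes), n, replace = TRUE,
                 prob = c(freqs, max(0, 1 - sum(freqs))))
    else integer(0)

    bases <- character(n); artifact <- character(n)
    strand <- character(n); eorient <- character(n); tlen <- integer(n)
    wt_spec <- edit_spec("wt")
    wt_template <- build_template(row$amplicon, row$barcode, wt_spec)
    for (i in seq_len(n)) {
      cls_idx <- draw[i]
      template <- if (classes[cls_idx] == "wt") wt_template
                  else build_template(row$amplicon, row$barcode,
                                      row$edits[[cls_idx]])
      rd <- corrupt_read(template, em, am, flip = flip)
      bases[i] <- rd$bases
      artifact[i] <- rd$artifact_class
      strand[i] <- rd$orientation
      eorient[i] <- attr(template, "edit_orientation") %||% NA_character_
      tlen[i] <- nchar(template)
    }
    read_id <- sprintf("%s-%06d", row$barcode$sample_id, seq_len(n))
    all_reads[[r]] <- data.frame(
      read_id = read_id, bases = bases, qual = strrep("I", nchar(bases)),
      stringsAsFactors = FALSE)
    all_truth[[r]] <- data.frame(
      read_id = read_id,
      amplicon_name = row$amplicon$name,
      sample_id = row$barcode$sample_id,
      edit_class = classes[draw],
      edit_orientation = eorient,
      orientation = strand,
      artifact_class = artifact,
      true_template_length = tlen,
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, all_reads)
  truth <- do.call(rbind, all_truth)
  rownames(reads) <- rownames(truth) <- NULL
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  structure(list(reads = reads, truth = truth), class = "sim_pool")
}

#' @export
print.sim_pool <- function(x, ...) {
  cat(sprintf("<sim_pool> %d reads, %d samples, classes: %s\n",
              nrow(x$reads), length(unique(x$truth$sample_id)),
              paste(names(table(x$truth$edit_class)), collapse = ", ")))
  invisible(x)
}

#' Emit idealized alignments for a simulated pool
#'
#' Renders each full-length read of the truth table as one primary SAM
#' record whose CIGAR encodes the true geometry against the chosen
#' reference, so the CIGAR-quantification module can be exercised
#' without an external aligner. Against the HDR-allele reference, HDR
#' reads align end-to-end while wild-type (and other non-HDR) reads
#' carry a soft-clip (`mode = "S"`) or deletion (`mode = "D"`) of
#' exactly the cassette length. Against the wild-type reference,
#' large-deletion reads carry a `D` of the deleted length, HDR reads a
#' cassette-length soft-clip, and insertion-bearing reads an `I` of the
#' inserted length. Truncated and over-long reads are emitted unmapped.
#'
#' @param truth Truth table from [simulate_pool()].
#' @param against `"hdr"` or `"wt"`: which reference the records are
#'   rendered against.
#' @param reference_name Name for the `@SQ` header line.
#' @param reference_length Reference length for the header; defaults to
#'   the longest template plus the cassette length.
#' @param cassette_length HDR cassette length in bp (payload length).
#' @param mode `"S"` (soft-clip) or `"D"` (deletion) representation of
#'   the missing cassette for WT reads against the HDR reference.
#' @param deletion_length,insert_length True event sizes used when
#'   rendering `large_deletion` / insertion classes against `"wt"`.
#' @param path Optional output SAM path.
#' @return Alignment data frame as from [read_sam()] (plus `pos`),
#'   invisibly writing a SAM file when `path` is given.
#' @export
emit_idealized_alignments <- function(truth, against = c("hdr", "wt"),
                                      reference_name = toupper(against),
                                      reference_length = NULL,
                                      cassette_length = 1400L,
                                      mode = c("S", "D"),
                                      deletion_length = NULL,
                                      insert_length = NULL,
                                      path = NULL) {
  against <- match.arg(against)
  mode <- match.arg(mode)
  reference_name <- reference_name[1L]
  len <- truth$true_template_length
  if (is.null(reference_length))
    reference_length <- max(len) + cassette_length
  full <- truth$artifact_class == "full_length"

  cigar <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (!full[i]) { cigar[i] <- "*"; next }
    cls <- truth$edit_class[i]
    L <- len[i]
    cigar[i] <-
      if (against == "hdr") {
        if (cls == "hdr") sprintf("%dM", L)
        else if (mode == "S") sprintf("%dM%dS", max(1L, L - cassette_length),
                                      cassette_length)
        else sprintf("%dM%dD%dM", L %/% 2L, cassette_length, L - L %/% 2L)
      } else {
        if (cls == "wt") sprintf("%dM", L)
        else if (cls == "large_deletion") {
          dl <- deletion_length %||% stop("deletion_length required")
          sprintf("%dM%dD%dM", L %/% 2L, dl, L - L %/% 2L)
        } else if (cls == "hdr") {
          sprintf("%dM%dS", max(1L, L - cassette_length), cassette_length)
        } else {
          il <- insert_length %||% cassette_length
          il <- min(il, L - 2L)
          sprintf("%dM%dI%dM", (L - il) %/% 2L, il, L - il - (L - il) %/% 2L)
        }
      }
  }
  aln <- data.frame(
    read_id = truth$read_id,
    reference_name = ifelse(full, reference_name, "*"),
    flag = ifelse(full, 0L, 4L),
    pos = ifelse(full, 1L, 0L),
    cigar = cigar,
    is_mapped = full,
    is_primary = TRUE,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    header <- c("@HD\tVN:1.6",
                sprintf("@SQ\tSN:%s\tLN:%d", reference_name,
                        as.integer(reference_length)))
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   aln$read_id, aln$flag, aln$reference_name, aln$pos,
                   ifelse(full, 60L, 0L), aln$cigar)
    writeLines(c(header, rec), path)
  }
  invisible(aln)
}
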