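# Probe construction and the exact-substring matching engine.

test_that("end-window probe tiling matches brute-force enumeration", {
  set.seed(101)
  amp <- test_amplicon(4000)
  ps <- make_end_probes(amp)
  expect_equal(nrow(ps$grep_left$probes), 12L)
  expect_equal(nrow(ps$grep_right$probes), 12L)
  expect_equal(ps$grep_left$probes$origin_offset, seq(20L, 75L, by = 5L))
  # first left probe is the amplicon substring [20, 35)
  expect_identical(ps$grep_left$probes$sequence[1L],
                   substr(amp$sequence, 21, 35))
  # right probes are substrings of the reverse-complemented amplicon
  expect_identical(ps$grep_right$probes$sequence[1L],
                   substr(dna_revcomp(amp$sequence), 21, 35))
  expect_true(ps$grep_left$search_both_orientations)
  expect_equal(ps$grep_left$match_threshold, 2L)

  # probe-count law over random (L, k, step, window) combinations
  for (i in 1:50) {
    k <- sample(5:20, 1); step <- sample(1:10, 1)
    w_start <- sample(0:30, 1)
    w_stop <- w_start + k + sample(0:60, 1)
    L <- 2 * w_stop + sample(0:100, 1)
    amp_i <- reference_amplicon("a", random_dna(L))
    ps_i <- make_end_probes(amp_i, w_start, w_stop, k, step)
    expect_equal(nrow(ps_i$grep_left$probes),
                 length(naive_tile_starts(w_start, w_stop, k, step)))
  }
})

test_that("too-short amplicons and N windows are handled", {
  expect_error(make_end_probes(reference_amplicon("short", random_dna(100))),
               "too short")
  set.seed(7)
  s <- random_dna(400)
  substr(s, 25, 25) <- "N"
  expect_warning(ps <- make_end_probes(reference_amplicon("n", s)),
                 "skipped")
  # windows overlapping position 24 (0-based) dropped: starts 10..24 -> here 20
  expect_false(24 %in% unlist(Map(seq,
                                  ps$grep_left$probes$origin_offset,
                                  ps$grep_left$probes$origin_offset + 14)))
})

test_that("barcode probes anchor on the barcode-primer junction", {
  set.seed(11)
  primer <- random_dna(20)
  ps <- make_barcode_probes(barcode_spec("s", random_dna(10), primer))
  expect_equal(nrow(ps$probes), 6L)
  expect_equal(ps$probes$origin_offset, 1:6)
  # every window covers barcode positions [6, 10)
  expect_true(all(ps$probes$origin_offset <= 6 &
                  ps$probes$origin_offset + 9 >= 10))

  # 12-nt barcode: probe count in the expected 5-10 band
  n12 <- nrow(make_barcode_probes(barcode_spec("s", random_dna(12), primer))$probes)
  expect_gte(n12, 5L); expect_lte(n12, 10L)

  # boundary: barcode as short as the coverage requirement
  bc4 <- structure(list(sample_id = "s", barcode = "AAGT",
                        forward_primer = primer), class = "barcode_spec")
  ps4 <- make_barcode_probes(bc4)
  expect_equal(ps4$probes$origin_offset[1L], 0L)  # covers the whole barcode
  bc3 <- structure(list(sample_id = "s", barcode = "AGT",
                        forward_primer = primer), class = "barcode_spec")
  expect_error(make_barcode_probes(bc3), "min_terminal_barcode")
})

test_that("insert probes cover both orientations and deduplicate", {
  set.seed(13)
  ins <- random_dna(29)
  ps <- make_insert_probes(ins)
  expect_equal(nrow(ps$probes), 34L)  # 17 per orientation
  expect_equal(sum(ps$probes$orientation == "forward"), 17L)
  # palindromic insert: forward and RC k-mers coincide after dedup
  pal <- "ACGTACGTACGTACGTACGTACGT"
  expect_identical(pal, dna_revcomp(pal))
  ps_pal <- make_insert_probes(pal, k = 13)
  expect_lt(nrow(ps_pal$probes), 2L * (nchar(pal) - 13L + 1L))
  # k equal to insert length: one window per orientation
  expect_equal(nrow(make_insert_probes(ins, k = 29)$probes), 2L)
  expect_error(make_insert_probes(random_dna(10), k = 13), "shorter than k")
})

test_that("backbone probes are sparse, oriented and offset-annotated", {
  set.seed(17)
  bb <- random_dna(2500)
  ps <- make_backbone_probes(bb)
  split <- split_probe_orientations(ps)
  expect_equal(nrow(split$forward$probes), 25L)
  expect_equal(nrow(split$reverse$probes), 25L)
  expect_equal(split$forward$probes$origin_offset,
               seq(0L, 2400L, by = 100L))
  expect_equal(split$forward$probes$origin_offset[3L], 200L)
  expect_equal(ps$signature_length, 2500L)
  ps15 <- make_backbone_probes(random_dna(15))
  expect_equal(nrow(ps15$probes), 2L)  # one per orientation
})

test_that("count_probe_matches equals the naive scan and counts distinct probes", {
  set.seed(19)
  amp <- test_amplicon(600)
  ps <- make_end_probes(amp)
  # identity and reverse-complement symmetry
  expect_equal(count_probe_matches(amp$sequence, ps$grep_left), 12L)
  expect_equal(count_probe_matches(dna_revcomp(amp$sequence), ps$grep_left), 12L)

  # oracle equivalence over random read/probe-set pairs
  for (i in 1:200) {
    read <- random_dna(sample(50:1000, 1))
    ps_i <- switch(sample(3, 1),
                   make_end_probes(test_amplicon(400))$grep_left,
                   make_insert_probes(random_dna(sample(20:60, 1))),
                   make_barcode_probes(barcode_spec("s", random_dna(10),
                                                    random_dna(20))))
    expect_equal(count_probe_matches(read, ps_i),
                 naive_count_matches(read, ps_i))
  }
})

test_that("match counts are monotone under read extension", {
  set.seed(23)
  amp <- test_amplicon(500)
  ps <- make_end_probes(amp)$grep_left
  read <- random_dna(100)
  prev <- count_probe_matches(read, ps)
  for (i in 1:20) {
    read <- paste0(read, substr(amp$sequence, 1 + 30 * (i - 1), 30 * i))
    cur <- count_probe_matches(read, ps)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("probe redundancy tolerates any single substitution in the window", {
  set.seed(29)
  amp <- test_amplicon(400)
  ps <- make_end_probes(amp)$grep_left  # 12 probes, overlap k - step = 10 nt
  seq <- amp$sequence
  for (pos in 21:90) {  # every position of the left window (1-based)
    mutated <- seq
    orig <- substr(mutated, pos, pos)
    substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"), orig)[1L]
    expect_true(read_matches(mutated, ps),
                label = sprintf("substitution at %d still matches", pos))
  }
})

test_that("read_matches applies the n >= 2 threshold", {
  set.seed(31)
  ps <- make_insert_probes(random_dna(29))
  # a read containing exactly one probe: below threshold
  one <- paste0(random_dna(40), ps$probes$sequence[1L], random_dna(40))
  cnt <- count_probe_matches(one, ps)
  expect_equal(read_matches(one, ps), cnt >= 2L)
  expect_true(read_matches(one, ps, threshold = 1L))
  # two distinct probes: at threshold
  two <- paste0(one, random_dna(10), ps$probes$sequence[10L])
  expect_gte(count_probe_matches(two, ps), 2L)
  expect_true(read_matches(two, ps))
  # empty read never matches
  expect_equal(count_probe_matches("", ps), 0L)
})

test_that("N in a read never matches and reads are uppercased", {
  set.seed(37)
  amp <- test_amplicon(400)
  ps <- make_end_probes(amp)$grep_left
  expect_equal(count_probe_matches(tolower(amp$sequence), ps), 12L)
  blanked <- gsub("[ACGT]", "N", amp$sequence)
  expect_equal(count_probe_matches(blanked, ps), 0L)
})

test_that("barcode-set validation flags close pairs and matches the DP oracle", {
  set.seed(41)
  specs <- list(barcode_spec("a", "AAAAAAAAAA", "ACGT"),
                barcode_spec("b", "TTTTTTTTTT", "ACGT"),
                barcode_spec("c", "AAAAAAAAAA", "ACGT"))
  expect_warning(rep <- validate_barcode_set(specs), "below edit distance")
  expect_equal(rep$distance[rep$sample_a == "a" & rep$sample_b == "c"], 0L)
  expect_true(rep$flagged[rep$sample_a == "a" & rep$sample_b == "c"])
  expect_equal(rep$distance[rep$sample_a == "a" & rep$sample_b == "b"], 10L)
  expect_false(rep$flagged[rep$sample_a == "a" & rep$sample_b == "b"])
  expect_error(validate_barcode_set(list(specs[[1]], specs[[1]])), "duplicate")

  # oracle equivalence on random pairs
  for (i in 1:20) {
    b1 <- random_dna(sample(8:14, 1)); b2 <- random_dna(sample(8:14, 1))
    sp <- list(barcode_spec("x", b1, "ACGT"), barcode_spec("y", b2, "ACGT"))
    rep_i <- suppressWarnings(validate_barcode_set(sp))
    expect_equal(rep_i$distance[1L], naive_levenshtein(b1, b2))
  }
})
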