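# The read simulator: template geometry, error calibration, artifact
# plumbing, determinism.

test_that("templates have the class-specific geometry", {
  set.seed(91)
  amp <- test_amplicon(600)
  bc <- test_barcode(amp)
  base_len <- 600 + nchar(bc$barcode)

  wt <- build_template(amp, bc, edit_spec("wt"))
  expect_identical(as.character(wt), paste0(bc$barcode, amp$sequence))

  dso <- build_template(amp, bc, edit_spec("dsodn", payload = random_dna(29),
                                           cut_site = 300))
  expect_equal(nchar(dso), base_len + 29)

  # 1400-bp cassette replacing a 400-bp interval: net +1000 bp
  hdr <- build_template(amp, bc, edit_spec("hdr", payload = random_dna(1400),
                                           cut_site = 100, interval_len = 400))
  expect_equal(nchar(hdr), base_len + 1000)

  del <- build_template(amp, bc, edit_spec("large_deletion", cut_site = 100,
                                           interval_len = 250))
  expect_equal(nchar(del), base_len - 250)

  bb <- random_dna(500)
  full <- build_template(amp, bc, edit_spec("backbone_full", payload = bb,
                                            cut_site = 300,
                                            orientation_law = "forward"))
  expect_equal(nchar(full), base_len + 500)
  expect_true(grepl(bb, full, fixed = TRUE))
  revt <- build_template(amp, bc, edit_spec("backbone_full", payload = bb,
                                            cut_site = 300,
                                            orientation_law = "reverse"))
  expect_true(grepl(dna_revcomp(bb), revt, fixed = TRUE))
  expect_identical(attr(revt, "edit_orientation"), "reverse")

  frag <- build_template(amp, bc, edit_spec("backbone_fragment", payload = bb,
                                            cut_site = 300,
                                            orientation_law = "forward"))
  flen <- nchar(frag) - base_len
  expect_gte(flen, 50); expect_lte(flen, 500)

  # multi-copy dsODN insertion
  multi <- build_template(amp, bc, edit_spec("dsodn", payload = random_dna(29),
                                             cut_site = 300, copies = 3L,
                                             orientation_law = "forward"))
  expect_equal(nchar(multi), base_len + 87)

  expect_error(edit_spec("dsodn", cut_site = 10), "payload")
  expect_error(edit_spec("hdr", payload = "ACGT", cut_site = 10), "interval_len")
  expect_error(edit_spec("dsodn", payload = "ACGTACGT"), "cut_site")
  expect_error(error_model(0.5, 0.3, 0.3), "< 1")
})

test_that("corruption is the identity at zero error and calibrated otherwise", {
  set.seed(93)
  template <- random_dna(2000)
  clean <- corrupt_read(template, error_model(0, 0, 0), artifact_model(0, 0),
                        flip = FALSE)
  expect_identical(clean$bases, template)
  expect_equal(clean$artifact_class, "full_length")

  # realized per-base substitution rate over ~1e5 bases within 3 SE
  em <- error_model(0.04, 0, 0)
  n_bases <- 0; n_mismatch <- 0
  for (i in 1:50) {
    t_i <- random_dna(2000)
    r_i <- corrupt_read(t_i, em, artifact_model(0, 0), flip = FALSE)$bases
    expect_equal(nchar(r_i), 2000)  # substitutions preserve length
    a <- strsplit(t_i, "")[[1]]; b <- strsplit(r_i, "")[[1]]
    n_bases <- n_bases + 2000
    n_mismatch <- n_mismatch + sum(a != b)
  }
  se3 <- 3 * sqrt(0.04 * 0.96 / n_bases)
  expect_lt(abs(n_mismatch / n_bases - 0.04), se3)

  # insertions lengthen, deletions shorten, by calibrated amounts
  ins_len <- nchar(corrupt_read(template, error_model(0, 0.05, 0),
                                artifact_model(0, 0), flip = FALSE)$bases)
  del_len <- nchar(corrupt_read(template, error_model(0, 0, 0.05),
                                artifact_model(0, 0), flip = FALSE)$bases)
  expect_gt(ins_len, 2000); expect_lt(del_len, 2000)
})

test_that("artifact classes follow the model and truncation keeps >= 100 bp", {
  set.seed(97)
  template <- random_dna(1500)
  am <- artifact_model(0.34, 0.05)
  cls <- character(400); lens <- integer(400)
  for (i in 1:400) {
    r <- corrupt_read(template, error_model(0, 0, 0), am, flip = FALSE)
    cls[i] <- r$artifact_class; lens[i] <- nchar(r$bases)
  }
  frac_t <- mean(cls == "truncated"); frac_o <- mean(cls == "overlong")
  expect_lt(abs(frac_t - 0.34), 3 * sqrt(0.34 * 0.66 / 400))
  expect_lt(abs(frac_o - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_true(all(lens[cls == "truncated"] >= 100))
  expect_true(all(lens[cls == "truncated"] < 1500))
  expect_true(all(lens[cls == "overlong"] == 3000))
  expect_true(all(lens[cls == "full_length"] == 1500))
})

test_that("pools conserve reads, hit requested class frequencies, and are seed-deterministic", {
  set.seed(99)
  amps <- lapply(1:3, function(i) test_amplicon(400 + 50 * i,
                                                name = paste0("amp", i)))
  bcs <- c("AACGGACTAT", "TTGCACGTGA", "CCATGTTGCA", "GGTACAACTG")
  dso <- random_dna(29)
  design <- list()
  for (i in 1:3) for (j in 1:4) {
    design[[length(design) + 1]] <- sim_design_row(
      amps[[i]],
      barcode_spec(sprintf("a%db%d", i, j), bcs[j],
                   substr(amps[[i]]$sequence, 1, 20)),
      list(edit_spec("dsodn", 0.2, payload = dso,
                     cut_site = 200)), 50)
  }
  pool <- simulate_pool(design, seed = 11)
  expect_equal(nrow(pool$reads), 600L)
  expect_equal(nrow(pool$truth), 600L)
  expect_identical(pool$reads$read_id, pool$truth$read_id)
  expect_false(anyDuplicated(pool$reads$read_id) > 0)
  n_ds <- sum(pool$truth$edit_class == "dsodn")
  expect_lt(abs(n_ds - 120), 3 * sqrt(600 * 0.2 * 0.8))

  # identical seed, byte-identical outputs (uncompressed files)
  run <- function() {
    fq <- tempfile(fileext = ".fastq"); tt <- tempfile(fileext = ".tsv")
    p <- simulate_pool(design, seed = 42, fastq = fq, truth_tsv = tt)
    list(pool = p, fq = readLines(fq), tt = readLines(tt))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$pool, r2$pool)
  expect_identical(r1$fq, r2$fq)
  expect_identical(r1$tt, r2$tt)

  # duplicate sample ids are rejected
  expect_error(simulate_pool(list(design[[1]], design[[1]])), "duplicate")
})

test_that("FASTQ round-trips through files", {
  set.seed(103)
  amp <- test_amplicon(300)
  pool <- simulate_pool(list(sim_design_row(amp, test_barcode(amp), list(), 20)),
                        seed = 12)
  fq <- tempfile(fileext = ".fastq.gz")
  write_fastq(pool$reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$read_id, pool$reads$read_id)
  expect_identical(back$bases, pool$reads$bases)
  expect_identical(back$qual, pool$reads$qual)
})
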