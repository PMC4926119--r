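# Synthetic-data generator: determinism, statistical structure, truth.

test_that("make_transcriptome is deterministic and honors its contract", {
  one <- make_transcriptome(1, c(200, 200), gc = 0.5, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_equal(nchar(one$sequence), 200L)
  expect_identical(one, make_transcriptome(1, c(200, 200), gc = 0.5, seed = 7))
  many <- make_transcriptome(100, c(200, 2000), gc = 0.56, seed = 1)
  expect_true(abs(mean(many$gc) - 0.56) <= 0.05)
  expect_true(all(grepl("^[ACGT]+$", many$sequence)))
  expect_error(make_transcriptome(0, c(200, 400)), "integer")
  expect_error(make_transcriptome(5, c(100, 400)), "200")
})

test_that("planted hairpins satisfy the duplex criteria by construction", {
  tr <- make_transcriptome(10, c(400, 800), seed = 21)
  ph <- plant_hairpins(tr, 1, duplex_spec = list(arm_len = c(22, 22),
                                                 loop_len = c(6, 6),
                                                 n_bulges = 0), seed = 22)
  tt <- ph$truth
  expect_equal(nrow(tt), 1L)
  pre <- substr(ph$transcripts$sequence[
    match(tt$transcript_id, ph$transcripts$transcript_id)], tt$start, tt$end)
  f <- fold_rna(pre)
  ds <- duplex_stats(f$structure, 1, nchar(tt$mature_seq))
  expect_gte(ds$paired, 16)
  expect_equal(ds$bulges, 0L)
  expect_equal(ds$asymmetry, 0L)
  expect_lte(f$mfe, -20)
})

test_that("truth tables are deterministic, non-overlapping, and internally consistent", {
  tr <- make_transcriptome(30, c(400, 1200), seed = 31)
  a <- plant_hairpins(tr, 8, seed = 32)
  b <- plant_hairpins(tr, 8, seed = 32)
  expect_identical(a$truth, b$truth)
  expect_identical(a$transcripts, b$transcripts)
  tt <- a$truth
  expect_equal(nrow(tt), 8L)
  # mature and star are substrings of the planted precursor
  for (k in seq_len(nrow(tt))) {
    pre <- substr(a$transcripts$sequence[
      match(tt$transcript_id[k], a$transcripts$transcript_id)],
      tt$start[k], tt$end[k])
    pre <- chartr("T", "U", pre)
    expect_true(grepl(tt$mature_seq[k], pre, fixed = TRUE))
    expect_true(grepl(tt$star_seq[k], pre, fixed = TRUE))
  }
  # loci on a shared transcript do not overlap
  by_tr <- split(tt, tt$transcript_id)
  for (g in by_tr) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # differential flags imply the fold effect
  expect_true(all(tt$fold_effect[tt$de_flag != "none"] >= 2))
  expect_true(all(vapply(tt$abundance, function(a) all(a$tpm >= 0), logical(1))))
})

test_that("library simulation is seed-deterministic at the byte level", {
  tr <- make_transcriptome(15, c(400, 900), seed = 41)
  ph <- plant_hairpins(tr, 3, seed = 42)
  refs <- make_reference_sets(seed = 43)
  spec <- library_spec("S", n_reads = 3000, seed = 44)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  f1 <- simulate_libraries(ph$truth, ph$transcripts, refs, spec, dir = d1)
  f2 <- simulate_libraries(ph$truth, ph$transcripts, refs, spec, dir = d2)
  expect_identical(readLines(f1$path), readLines(f2$path))
})

test_that("noise-free libraries contain only planted miRNA and transcript reads", {
  tr <- make_transcriptome(15, c(400, 900), seed = 41)
  ph <- plant_hairpins(tr, 3, seed = 42)
  refs <- make_reference_sets(seed = 43)
  spec <- library_spec("S", n_reads = 2000,
                       contaminant_fractions = c(rRNA = 0),
                       frac_low_quality = 0, frac_n = 0, frac_short = 0,
                       frac_long = 0, seed = 45)
  fq <- simulate_libraries(ph$truth, ph$transcripts, refs, spec,
                           dir = file.path(tempdir(), "nonoise"))
  reads <- read_fastq_tbl(fq$path)
  cls <- sub("^[^|]+\\|[^|]+\\|([^|]+)\\|.*$", "\\1", reads$name)
  expect_true(all(cls %in% c("miRNA", "unannotated")))
  tt <- trim_adapter(reads, "TGGAATTCTCGGGTGCCAAGG")
  ins <- chartr("T", "U", tt$sequence[cls == "miRNA"])
  expect_true(all(ins %in% ph$truth$mature_seq))
})

test_that("contaminant and differential proportions land near their targets", {
  fx <- fx_pipeline()
  # planted rRNA fraction within +-2% of 0.60 among clean reads
  cls <- fx$truth_class[fx$truth_class$fate == "clean", ]
  rfrac <- mean(cls$planted == "rRNA")
  expect_lt(abs(rfrac - 0.60), 0.02)
  # a 4-fold up_in_R miRNA shows R:S read-count ratio within [2, 8]
  tt <- fx$ph$truth
  up <- tt$mirna_id[tt$de_flag == "up_in_R"]
  counts <- table(sub("^.*\\|([^|]+)$", "\\1", cls$name), cls$library)
  for (m in up) {
    ratio <- mean(counts[m, c("R1", "R2", "R3")]) / counts[m, "S"]
    expect_gt(ratio, 2); expect_lt(ratio, 8)
  }
})

test_that("reference sets carry the expected categories and unique names", {
  refs <- make_reference_sets(seed = 5)
  expect_setequal(unique(refs$category),
                  c("rRNA", "tRNA", "snRNA", "snoRNA", "mature_miRNA"))
  expect_false(any(duplicated(paste(refs$category, refs$name))))
  expect_true(all(nchar(refs$sequence) > 0))
})

test_that("a missing contaminant reference category is a configuration error", {
  tr <- make_transcriptome(10, c(400, 800), seed = 51)
  ph <- plant_hairpins(tr, 2, seed = 52)
  refs <- make_reference_sets(seed = 53)
  refs <- refs[refs$category != "rRNA", ]
  spec <- library_spec("S", n_reads = 500, seed = 54)
  expect_error(simulate_libraries(ph$truth, ph$transcripts, refs, spec,
                                  dir = tempdir()),
               "no reference set")
})

test_that("simulated qPCR recovers planted folds and censors absent targets", {
  tr <- make_transcriptome(15, c(400, 900), seed = 61)
  ph <- plant_hairpins(tr, 4, n_de = 2, fold_effect = 4, seed = 62)
  # noiseless: exact recovery of the 4-fold effect and calibrator identity
  ct0 <- simulate_qpcr(ph$truth, sd_ct = 0, seed = 63)
  up <- ph$truth$mirna_id[ph$truth$de_flag == "up_in_R"][1]
  none <- ph$truth$mirna_id[ph$truth$de_flag == "none"][1]
  rel <- delta_delta_ct(ct0, up, "S")
  expect_equal(rel$relative_expression[rel$group == "R1"], 4)
  expect_equal(rel$relative_expression[rel$group == "S"], 1)
  rel0 <- delta_delta_ct(ct0, none, "S")
  expect_equal(rel0$relative_expression, rep(1, 4), tolerance = 1e-12)
  # noisy, many replicates: fold recovered within 15%
  ctn <- simulate_qpcr(ph$truth, sd_ct = 0.2, seed = 64, n_replicates = 30)
  reln <- delta_delta_ct(ctn, up, "S")
  expect_lt(abs(reln$relative_expression[reln$group == "R1"] - 4) / 4, 0.15)
  # zero abundance is censored at 40 cycles
  tt <- ph$truth[1, ]
  tt$abundance[[1]]$tpm <- 0
  ctz <- simulate_qpcr(tt, sd_ct = 0, seed = 65)
  expect_true(all(ctz$ct[ctz$assay == tt$mirna_id] == 40))
  expect_error(simulate_qpcr(ph$truth, efficiency = 2.5), "efficiency")
})
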