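# Novel miRNA prediction: mapping, windows, duplex statistics, calling.

test_that("map_tags reports exact loci on both strands and honors filters", {
  tr <- tibble::tibble(
    transcript_id = "t1",
    sequence = paste0(strrep("A", 100), "ACGTACGTGGCCTTAACCGGTA", strrep("C", 80)))
  tag <- "ACGTACGTGGCCTTAACCGGTA"
  tags <- tibble::tibble(sequence = tag, t1 = 5L, total = 5L)
  loci <- map_tags(tags, tr)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 101L)
  expect_equal(loci$end, 122L)
  expect_equal(loci$strand, "+")
  # reverse strand
  rc <- revcomp(tag)
  loci_rc <- map_tags(tibble::tibble(sequence = rc, t1 = 5L, total = 5L), tr)
  expect_equal(loci_rc$strand, "-")
  expect_equal(loci_rc$start, 101L)
  # absent tag and under-supported tag
  expect_equal(nrow(map_tags(tibble::tibble(sequence = strrep("GT", 10),
                                            t1 = 5L, total = 5L), tr)), 0L)
  expect_equal(nrow(map_tags(tibble::tibble(sequence = tag, t1 = 1L,
                                            total = 1L), tr)), 0L)
})

test_that("map_tags agrees with naive substring search on planted fragments", {
  set.seed(401)
  tr <- make_transcriptome(8, c(300, 600), seed = 402)
  for (i in 1:10) {
    k <- sample(8, 1)
    L <- sample(18:26, 1)
    p <- sample(nchar(tr$sequence[k]) - L, 1)
    tag <- substr(tr$sequence[k], p, p + L - 1)
    loci <- map_tags(tibble::tibble(sequence = tag, S = 9L, total = 9L), tr)
    naive <- unlist(lapply(seq_len(nrow(tr)), function(j) {
      g <- gregexpr(tag, tr$sequence[j], fixed = TRUE)[[1]]
      if (g[1] == -1) integer(0) else as.integer(g)
    }))
    fwd <- loci[loci$strand == "+", ]
    expect_equal(sort(fwd$start), sort(naive), info = tag)
  }
})

test_that("extract_windows yields three bounded windows and truncates at ends", {
  tr <- tibble::tibble(transcript_id = "t1",
                       sequence = paste(rep("ACGT", 150), collapse = ""))
  loci <- tibble::tibble(sequence = substr(tr$sequence, 301, 322), count = 5,
                         transcript_id = "t1", start = 301L, end = 322L,
                         strand = "+")
  w <- extract_windows(loci, tr, flank = 150)
  expect_equal(nrow(w), 3L)
  expect_true(all(nchar(w$sequence) <= 320))
  expect_true(all(w$win_start >= 1 & w$win_end <= 600))
  # the tag coordinates inside each window point at the tag
  for (k in seq_len(nrow(w))) {
    expect_equal(substr(w$sequence[k], w$tag_start[k], w$tag_end[k]),
                 chartr("T", "U", loci$sequence))
  }
  # locus at the transcript start: windows truncated at 1
  loci2 <- dplyr::mutate(loci, sequence = substr(tr$sequence, 1, 22),
                         start = 1L, end = 22L)
  w2 <- extract_windows(loci2, tr, flank = 150)
  expect_true(all(w2$win_start == 1L))
})

test_that("windows around a planted locus contain the full precursor", {
  fx <- fx_planted()
  tt <- fx$truth[1, ]
  loci <- tibble::tibble(sequence = chartr("U", "T", tt$mature_seq), count = 10,
                         transcript_id = tt$transcript_id,
                         start = tt$start, end = tt$start + nchar(tt$mature_seq) - 1L,
                         strand = "+")
  w <- extract_windows(loci, fx$transcripts)
  pre <- chartr("T", "U", substr(
    fx$transcripts$sequence[match(tt$transcript_id, fx$transcripts$transcript_id)],
    tt$start, tt$end))
  expect_true(any(grepl(pre, w$sequence, fixed = TRUE)))
})

test_that("duplex_stats measures a perfect stem and engineered bulges", {
  # perfect 21-bp stem, 6-nt loop, mature on the 5' arm
  arm <- "GCUAGCUAGGCAUCGAUGCCA"
  hp <- paste0(arm, "AACAAA", revcomp(arm))
  f <- fold_rna(hp)
  ds <- duplex_stats(f$structure, 1, 21)
  expect_equal(ds$paired, 21L)
  expect_equal(ds$bulges, 0L)
  expect_equal(ds$asymmetry, 0L)
  expect_equal(ds$arm, "5p")
  # star arm: pairing partners plus the 2-nt 3' overhang
  expect_equal(ds$star_start, 28L)
  expect_equal(ds$star_end, min(nchar(hp), 48L + 2L))
  # hand-constructed structure with one 2-nt bulge on the mature side
  st <- paste0("((((((..((((((((", "....", "))))))))))))))..")
  ds2 <- duplex_stats(st, 1, 16)
  expect_equal(ds2$paired, 14L)
  expect_equal(ds2$bulges, 1L)
  expect_equal(ds2$asymmetry, 2L)
  # mature spanning the loop is rejected, not an error
  ds3 <- duplex_stats(f$structure, 18, 32)
  expect_true(is.na(ds3$paired))
})

test_that("call_novel applies inclusive criterion boundaries", {
  base <- tibble::tibble(
    window_id = "w", sequence = strrep("ACGU", 20), tag_seq = strrep("ACGU", 5),
    count = 10, transcript_id = "t", win_start = 1L, win_end = 80L,
    strand = "+", tag_start = 1L, tag_end = 20L, structure = strrep(".", 80),
    star_start = 40L, star_end = 60L, arm = "5p")
  pass <- dplyr::mutate(base, mfe = -25, paired = 16L, bulges = 4L,
                        asymmetry = 4L)
  expect_equal(nrow(call_novel(pass)), 1L)
  expect_equal(nrow(call_novel(dplyr::mutate(pass, mfe = -19.5))), 0L)
  expect_equal(nrow(call_novel(dplyr::mutate(pass, paired = 15L))), 0L)
  expect_equal(nrow(call_novel(dplyr::mutate(pass, bulges = 5L))), 0L)
  expect_equal(nrow(call_novel(dplyr::mutate(pass, asymmetry = 5L))), 0L)
  expect_equal(nrow(call_novel(dplyr::mutate(pass, mfe = -20))), 1L)
})

test_that("call_novel decisions are invariant to candidate ordering", {
  fx <- fx_planted()
  tags <- collapse_unique(list(S = rep(chartr("U", "T", fx$truth$mature_seq),
                                       times = 5)))
  loci <- map_tags(tags, fx$transcripts, min_count = 5)
  cands <- evaluate_candidates(extract_windows(loci, fx$transcripts))
  a <- call_novel(cands)
  set.seed(403)
  b <- call_novel(cands[sample(nrow(cands)), ])
  expect_equal(a, b)
})

test_that("noiseless simulation recovers every planted hairpin", {
  fx <- fx_planted()
  tags <- collapse_unique(list(S = rep(chartr("U", "T", fx$truth$mature_seq),
                                       times = 10)))
  calls <- predict_novel(tags, fx$transcripts)
  expect_true(all(fx$truth$mature_seq %in% calls$mature_seq))
  expect_true(all(calls$mfe <= -20))
  expect_true(all(calls$paired >= 16))
  # names are assigned in descending supporting-read order
  expect_equal(calls$name, sprintf("novel-bsy-miR-%d", seq_len(nrow(calls))))
  expect_true(all(diff(calls$count) <= 0))
})
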