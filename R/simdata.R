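# Synthetic data generator. Emulates the study design the analysis
# modules assume: one sensitive pool and three resistant pools of a grass
# weed, sRNA libraries dominated by rRNA fragments (~60%), planted
# hairpin-derived miRNA reads, and >= 2-fold differential miRNAs between
# resistant and sensitive pools. Every generator is driven by an explicit
# integer seed and returns ground truth for recovery tests.

DEFAULT_LIBRARIES <- c("S", "R1", "R2", "R3")

# Illumina TruSeq small RNA 3' adapter
DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

DEFAULT_CONTAMINANTS <- c(rRNA = 0.60, tRNA = 0.03, snRNA = 5e-4, snoRNA = 1e-4)

#' Generate a synthetic reference transcriptome
#'
#' Random transcripts over A/C/G/T at a requested GC content, standing in
#' for a de novo assembly (unigene set) of the study organism.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_range length interval in bp, minimum 200.
#' @param gc target GC fraction; realized mean GC is within +-5%.
#' @param seed integer seed.
#' @return A tibble with `transcript_id`, `sequence`, `length`, `gc`.
#' @export
make_transcriptome <- function(n_transcripts, length_range = c(200, 2000),
                               gc = 0.56, seed = 1) {
  n_transcripts <- check_scalar_count(n_transcripts, "n_transcripts")
  if (length(length_range) != 2 || any(length_range < 200) ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be an increasing interval with lengths >= 200 bp.")
  }
  stopifnot(gc > 0, gc < 1)
  set.seed(seed)
  lens <- sample_int_range(n_transcripts, length_range[1], length_range[2])
  seqs <- random_seq(n_transcripts, lens, gc = gc)
  tibble(transcript_id = sprintf("comp%d", seq_len(n_transcripts) + 10000L),
         sequence = seqs, length = lens, gc = gc_fraction(seqs))
}

#' Plant hairpin (pre-miRNA) loci into a transcriptome
#'
#' Constructs stem-loop precursors by design — an arm of `arm_len` nt, a
#' short non-pairing loop, and the arm's reverse complement — and writes
#' them into randomly chosen transcripts at non-overlapping loci. Each
#' precursor therefore satisfies the hairpin calling criteria (>= 16
#' duplex pairs, <= 4 bulges, <= 4 nt asymmetry, MFE well below the
#' -20 kcal/mol gate) when folded. Expected TPM abundances are drawn per
#' library; `n_de` miRNAs receive a >= 2-fold resistant-vs-sensitive effect
#' (alternating up/down in the resistant pools).
#'
#' @param transcripts tibble from [make_transcriptome()].
#' @param n_mirnas number of hairpins to plant.
#' @param duplex_spec list with `arm_len` (range, nt), `loop_len` (range,
#'   nt, within 4-15), `n_bulges` (bulges to engineer into the stem; 0
#'   keeps a perfect stem).
#' @param seed integer seed.
#' @param libraries library names; first is the sensitive pool.
#' @param n_de number of differential miRNAs to plant.
#' @param fold_effect resistant/sensitive abundance ratio (>= 2) for
#'   differential miRNAs.
#' @param tpm_range base (sensitive-pool) expected TPM interval.
#' @param adapter sequencing adapter the libraries will carry; mature
#'   sequences resembling its prefix are rejected so planted reads trim
#'   back to themselves.
#' @return A list with `transcripts` (edited tibble) and `truth`, a tibble
#'   with one row per planted miRNA: `mirna_id`, `transcript_id`, `start`,
#'   `end` (precursor locus, 1-based inclusive), `mature_seq`, `star_seq`
#'   (RNA), `de_flag` (`none`/`up_in_R`/`down_in_R`), `fold_effect`, and a
#'   nested `abundance` tibble (`library`, `tpm`).
#' @export
plant_hairpins <- function(transcripts, n_mirnas,
                           duplex_spec = list(arm_len = c(20, 24),
                                              loop_len = c(5, 9),
                                              n_bulges = 0),
                           seed = 1,
                           libraries = DEFAULT_LIBRARIES,
                           n_de = min(3, n_mirnas),
                           fold_effect = 4,
                           tpm_range = c(500, 5000),
                           adapter = DEFAULT_ADAPTER) {
  n_mirnas <- check_scalar_count(n_mirnas, "n_mirnas")
  if (n_de > 0 && fold_effect < 2) {
    abort("planted differential miRNAs must have `fold_effect` >= 2.")
  }
  set.seed(seed)
  arm_rng <- duplex_spec$arm_len %||% c(20, 24)
  loop_rng <- duplex_spec$loop_len %||% c(5, 9)
  n_bulges <- duplex_spec$n_bulges %||% 0
  seqs <- transcripts$sequence
  used <- vector("list", nrow(transcripts))
  rows <- vector("list", n_mirnas)
  planted <- 0L
  attempts <- 0L
  while (planted < n_mirnas && attempts < n_mirnas * 50L) {
    attempts <- attempts + 1L
    arm_len <- sample_int_range(1, arm_rng[1], arm_rng[2])
    loop_len <- sample_int_range(1, loop_rng[1], loop_rng[2])
    mature <- random_seq(1, arm_len, gc = 0.55)
    jpos <- adapter_match_pos(paste0(mature, adapter), adapter)
    if (is.na(jpos) || jpos != arm_len + 1L) next  # would not trim cleanly
    arm3 <- revcomp(mature)
    if (n_bulges > 0) {
      # engineer small bulges into the 3' arm (extra unpaired bases)
      at <- sort(sample(2:(nchar(arm3) - 1), n_bulges))
      for (b in rev(at)) {
        arm3 <- paste0(substr(arm3, 1, b), "A", substr(arm3, b + 1, nchar(arm3)))
      }
    }
    loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE, prob = c(.6, .4)),
                  collapse = "")
    precursor <- paste0(mature, loop, arm3)
    plen <- nchar(precursor)
    ok <- which(transcripts$length >= plen + 60)
    if (!length(ok)) {
      if (planted == 0L && attempts >= n_mirnas * 50L) break
      warn("transcript set too short for a precursor; skipping attempt")
      next
    }
    tr <- sample(ok, 1)
    start <- sample_int_range(1, 30, transcripts$length[tr] - plen - 30 + 1)
    end <- start + plen - 1
    overlaps <- any(vapply(used[[tr]], function(iv) start <= iv[2] && end >= iv[1],
                           logical(1)))
    if (overlaps) next
    used[[tr]] <- c(used[[tr]], list(c(start, end)))
    seqs[tr] <- paste0(substr(seqs[tr], 1, start - 1), precursor,
                       substr(seqs[tr], end + 1, nchar(seqs[tr])))
    planted <- planted + 1L
    rows[[planted]] <- tibble(
      mirna_id = sprintf("mir_%02d", planted),
      transcript_id = transcripts$transcript_id[tr],
      start = start, end = end,
      mature_seq = as_rna(mature), star_seq = as_rna(arm3))
  }
  if (planted == 0L) abort("no transcript long enough to host a precursor.")
  if (planted < n_mirnas) {
    warn(sprintf("planted %d of %d requested hairpins.", planted, n_mirnas))
  }
  truth <- list_rbind(rows[seq_len(planted)])
  # differential structure: first n_de miRNAs, alternating up/down in R
  de_flag <- rep("none", planted)
  eff <- rep(1, planted)
  if (n_de > 0) {
    idx <- seq_len(min(n_de, planted))
    de_flag[idx] <- ifelse(seq_along(idx) %% 2 == 1, "up_in_R", "down_in_R")
    eff[idx] <- fold_effect
  }
  base_tpm <- runif(planted, tpm_range[1], tpm_range[2])
  truth$de_flag <- de_flag
  truth$fold_effect <- eff
  truth$abundance <- pmap(list(base_tpm, de_flag, eff), function(b, f, e) {
    tpm <- rep(b, length(libraries))
    r <- libraries != libraries[1]
    if (f == "up_in_R") tpm[r] <- b * e
    if (f == "down_in_R") tpm[r] <- b / e
    tibble(library = libraries, tpm = tpm)
  })
  out_tr <- transcripts
  out_tr$sequence <- seqs
  out_tr$gc <- gc_fraction(seqs)
  list(transcripts = out_tr, truth = truth)
}

#' Generate synthetic non-coding RNA reference sets
#'
#' Random Rfam-like reference sequences per contaminant category plus a
#' miRBase-like mature miRNA set. Contaminant reads in simulated libraries
#' are drawn as substrings of these sequences, so classification against
#' them recovers the planted category exactly.
#'
#' @param seed integer seed.
#' @return A tibble with `category`, `name`, `sequence`.
#' @export
make_reference_sets <- function(seed = 1) {
  set.seed(seed)
  spec <- list(
    rRNA = list(n = 4, len = c(1500, 3000)),
    tRNA = list(n = 10, len = c(70, 90)),
    snRNA = list(n = 6, len = c(100, 200)),
    snoRNA = list(n = 6, len = c(70, 150)),
    mature_miRNA = list(n = 25, len = c(20, 22))
  )
  fams <- c(156, 159, 160, 164, 166, 167, 168, 169, 171, 172,
            319, 390, 393, 394, 396, 397, 398, 399, 408, 444,
            528, 827, 2118, 5048, 9662)
  out <- imap(spec, function(sp, cat) {
    lens <- sample_int_range(sp$n, sp$len[1], sp$len[2])
    nm <- if (cat == "mature_miRNA") {
      sprintf("osa-miR%d%s-5p", fams[seq_len(sp$n)],
              sample(letters[1:3], sp$n, replace = TRUE))
    } else sprintf("%s_%02d", cat, seq_len(sp$n))
    tibble(category = cat, name = nm, sequence = random_seq(sp$n, lens, 0.5))
  })
  list_rbind(out)
}

#' Library specification for the read simulator
#'
#' @param name library name.
#' @param n_reads total reads to simulate.
#' @param adapter 3' adapter appended to every insert.
#' @param contaminant_fractions named fractions (of clean-destined reads)
#'   per non-coding RNA category; must sum to <= 1.
#' @param frac_low_quality,frac_n,frac_short,frac_long fractions of reads
#'   planted to fail each cleaning filter (mean quality < 20, contains N,
#'   insert < 18 nt, no adapter so the raw read stays > 30 nt).
#' @param read_length raw read length before trimming.
#' @param seed integer seed for this library.
#' @return A one-row tibble.
#' @export
library_spec <- function(name, n_reads = 1e5, adapter = DEFAULT_ADAPTER,
                         contaminant_fractions = DEFAULT_CONTAMINANTS,
                         frac_low_quality = 0.01, frac_n = 0.001,
                         frac_short = 0.05, frac_long = 0.02,
                         read_length = 50, seed = 1) {
  n_reads <- check_scalar_count(n_reads, "n_reads")
  if (any(contaminant_fractions < 0) || sum(contaminant_fractions) > 1) {
    abort("contaminant fractions must be in [0,1] and sum to <= 1.")
  }
  if (!nzchar(adapter)) abort("`adapter` must be non-empty.")
  tibble(name = name, n_reads = n_reads, adapter = adapter,
         contaminants = list(contaminant_fractions),
         frac_low_quality = frac_low_quality, frac_n = frac_n,
         frac_short = frac_short, frac_long = frac_long,
         read_length = as.integer(read_length), seed = as.integer(seed))
}

#' Default four-library study design
#'
#' One sensitive pool and three resistant pools, ~1e5 reads each. Desk
#' scale: proportions, not totals, carry the signal.
#'
#' @param n_reads reads per library.
#' @param seed integer seed; per-library seeds are derived from it.
#' @param ... passed to [library_spec()].
#' @return A tibble of library specs.
#' @export
default_library_specs <- function(n_reads = 1e5, seed = 1, ...) {
  list_rbind(map(seq_along(DEFAULT_LIBRARIES), function(i) {
    library_spec(DEFAULT_LIBRARIES[i], n_reads = n_reads,
                 seed = seed * 100L + i, ...)
  }))
}

qual_string <- function(lens, mean_q) {
  q <- pmin(40, pmax(2, round(rnorm(sum(lens), rep(mean_q, lens), 2))))
  big <- intToUtf8(q + 33L)
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

# Fragments destined to survive cleaning must trim back to themselves:
# resample any fragment with a spurious adapter-like match inside the
# fragment or across the fragment/adapter junction.
clean_fragment <- function(sequences, n, adapter, min_len = 18, max_len = 30) {
  out <- random_fragment(sequences, n, min_len, max_len)
  for (iter in 1:25) {
    pos <- adapter_match_pos(paste0(out, adapter), adapter)
    bad <- which(is.na(pos) | pos != nchar(out) + 1L)
    if (!length(bad)) break
    out[bad] <- random_fragment(sequences, length(bad), min_len, max_len)
  }
  out
}

# raw-length fragments standing for reads whose adapter was never reached:
# any adapter-like match in the first max_len + 1 positions would change
# their cleaning fate, so those are resampled.
long_fragment <- function(sequences, n, adapter, read_length, max_len = 30) {
  out <- random_fragment(sequences, n, read_length, read_length)
  for (iter in 1:25) {
    pos <- adapter_match_pos(out, adapter)
    bad <- which(!is.na(pos) & pos <= max_len + 1L)
    if (!length(bad)) break
    out[bad] <- random_fragment(sequences, length(bad), read_length, read_length)
  }
  out
}

random_fragment <- function(sequences, n, min_len = 18, max_len = 30) {
  if (n == 0) return(character(0))
  src <- sample(seq_along(sequences), n, replace = TRUE,
                prob = nchar(sequences))
  lens <- sample_int_range(n, min_len, max_len)
  lens <- pmin(lens, nchar(sequences)[src])
  starts <- floor(runif(n, 1, nchar(sequences)[src] - lens + 2))
  substr(rep(sequences[src], 1), starts, starts + lens - 1)
}

#' Simulate small RNA sequencing libraries
#'
#' Composes reads per library from the planted miRNA truth (multinomial
#' counts around expected TPM abundances), contaminant fragments drawn as
#' random 18-30 nt substrings of the category reference sets, and
#' unannotated transcript fragments; appends the 3' adapter, pads to the
#' raw read length, and writes Sanger Phred+33 FASTQ. A controlled share
#' of reads is planted to fail each cleaning filter. Read names encode the
#' planted class (`lib|serial|class|source`) so recovery tests can compare
#' against ground truth. Identical seeds give byte-identical FASTQ.
#'
#' @param truth truth tibble from [plant_hairpins()].
#' @param transcripts (edited) transcript tibble from [plant_hairpins()].
#' @param refsets reference tibble from [make_reference_sets()].
#' @param specs tibble of library specs ([default_library_specs()]).
#' @param dir output directory for FASTQ files.
#' @return A tibble with `library`, `path`, `n_reads`.
#' @export
simulate_libraries <- function(truth, transcripts, refsets,
                               specs = default_library_specs(),
                               dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cats <- unique(refsets$category)
  out <- vector("list", nrow(specs))
  for (r in seq_len(nrow(specs))) {
    sp <- specs[r, ]
    set.seed(sp$seed)
    fr <- sp$contaminants[[1]]
    missing_cat <- setdiff(names(fr)[fr > 0], cats)
    if (length(missing_cat)) {
      abort(sprintf("no reference set for contaminant category: %s",
                    paste(missing_cat, collapse = ", ")))
    }
    n <- sp$n_reads
    n_lowq <- rbinom(1, n, sp$frac_low_quality)
    n_nread <- rbinom(1, n - n_lowq, sp$frac_n)
    n_short <- rbinom(1, n - n_lowq - n_nread, sp$frac_short)
    n_long <- rbinom(1, n - n_lowq - n_nread - n_short, sp$frac_long)
    n_clean <- n - n_lowq - n_nread - n_short - n_long
    # clean-destined composition
    tpm <- map_dbl(truth$abundance, function(a) a$tpm[a$library == sp$name])
    p_mirna <- tpm / 1e6
    p_contam <- fr[fr > 0]
    p_unann <- max(0, 1 - sum(p_mirna) - sum(p_contam))
    probs <- c(p_mirna, p_contam, unannotated = p_unann)
    classes <- c(truth$mirna_id, names(p_contam), "unannotated")
    counts <- as.vector(rmultinom(1, n_clean, probs))
    inserts <- character(0); class_lab <- character(0); src_lab <- character(0)
    for (k in seq_along(classes)) {
      ck <- counts[k]
      if (ck == 0) next
      cl <- classes[k]
      if (cl %in% truth$mirna_id) {
        ins <- rep(as_dna(truth$mature_seq[truth$mirna_id == cl]), ck)
        lab <- "miRNA"; src <- cl
      } else if (cl == "unannotated") {
        ins <- clean_fragment(transcripts$sequence, ck, sp$adapter)
        lab <- "unannotated"; src <- "transcriptome"
      } else {
        refs <- refsets$sequence[refsets$category == cl]
        ins <- clean_fragment(as_dna(refs), ck, sp$adapter)
        lab <- cl; src <- cl
      }
      inserts <- c(inserts, ins)
      class_lab <- c(class_lab, rep(lab, ck))
      src_lab <- c(src_lab, rep(src, ck))
    }
    mean_q <- rep(36, length(inserts))
    # planted filter failures
    if (n_nread > 0) {
      ins <- clean_fragment(transcripts$sequence, n_nread, sp$adapter)
      pos <- sample(18, n_nread, replace = TRUE)
      substr(ins, pos, pos) <- "N"
      inserts <- c(inserts, ins)
      class_lab <- c(class_lab, rep("n_read", n_nread))
      src_lab <- c(src_lab, rep("planted", n_nread))
      mean_q <- c(mean_q, rep(36, n_nread))
    }
    if (n_short > 0) {
      ins <- random_fragment(transcripts$sequence, n_short, 14, 17)
      inserts <- c(inserts, ins)
      class_lab <- c(class_lab, rep("too_short", n_short))
      src_lab <- c(src_lab, rep("planted", n_short))
      mean_q <- c(mean_q, rep(36, n_short))
    }
    if (n_lowq > 0) {
      ins <- clean_fragment(transcripts$sequence, n_lowq, sp$adapter)
      inserts <- c(inserts, ins)
      class_lab <- c(class_lab, rep("low_quality", n_lowq))
      src_lab <- c(src_lab, rep("planted", n_lowq))
      mean_q <- c(mean_q, rep(12, n_lowq))
    }
    # assemble raw reads: insert + adapter, padded/truncated to read_length
    raw <- paste0(inserts, sp$adapter)
    pad_n <- pmax(0, sp$read_length - nchar(raw))
    big <- paste(sample(DNA_BASES, sum(pad_n), replace = TRUE), collapse = "")
    ends <- cumsum(pad_n)
    pad <- substring(big, ends - pad_n + 1L, ends)
    raw <- substr(paste0(raw, pad), 1, sp$read_length)
    if (n_long > 0) {
      # adapter never sequenced: raw read is all transcript
      long_raw <- long_fragment(transcripts$sequence, n_long, sp$adapter,
                                sp$read_length)
      raw <- c(raw, long_raw)
      class_lab <- c(class_lab, rep("too_long", n_long))
      src_lab <- c(src_lab, rep("planted", n_long))
      mean_q <- c(mean_q, rep(36, n_long))
    }
    qual <- qual_string(nchar(raw), mean_q)
    ord <- sample(length(raw))  # shuffle so filtering order-stability is real
    reads <- tibble(
      name = sprintf("%s|%06d|%s|%s", sp$name, seq_along(raw),
                     class_lab[ord], src_lab[ord]),
      sequence = raw[ord], quality = qual[ord])
    path <- file.path(dir, paste0(sp$name, ".fastq"))
    write_fastq_tbl(reads, path)
    out[[r]] <- tibble(library = sp$name, path = path, n_reads = nrow(reads))
  }
  list_rbind(out)
}

#' Simulate a qPCR Ct table
#'
#' Generates per-replicate Ct values for each planted miRNA assay across
#' sample groups, with three reference-gene assays (CAP, GAPDH, UBQ) whose
#' Cts are constant across groups up to noise. Target Ct follows
#' `baseline - log_e(abundance)` with `e` the amplification efficiency
#' (fold per cycle), plus Gaussian noise; non-positive abundances are
#' censored at 40 cycles. Group abundances come from the truth table's
#' per-library TPM (first library = calibrator group).
#'
#' @param truth truth tibble from [plant_hairpins()].
#' @param efficiency amplification efficiency in (1, 2].
#' @param sd_ct Gaussian noise SD in cycles.
#' @param seed integer seed.
#' @param n_replicates biological replicates per group (default 3).
#' @param baseline baseline cycles for 1 TPM of target.
#' @return A tibble (`group`, `replicate`, `assay`, `ct`) containing target
#'   and reference-gene wells.
#' @export
simulate_qpcr <- function(truth, efficiency = 2, sd_ct = 0.2, seed = 1,
                          n_replicates = 3, baseline = 35) {
  if (efficiency <= 1 || efficiency > 2) abort("`efficiency` must be in (1, 2].")
  set.seed(seed)
  groups <- truth$abundance[[1]]$library
  refs <- c(CAP = 16, GAPDH = 17.5, UBQ = 19)
  rows <- list()
  for (g in groups) {
    for (rep_i in seq_len(n_replicates)) {
      for (m in seq_len(nrow(truth))) {
        ab <- truth$abundance[[m]]
        a <- ab$tpm[ab$library == g]
        ct <- if (a <= 0) 40 else {
          min(40, baseline - log(a, base = efficiency) + rnorm(1, 0, sd_ct))
        }
        rows[[length(rows) + 1]] <- tibble(group = g, replicate = rep_i,
                                           assay = truth$mirna_id[m], ct = ct)
      }
      for (rg in names(refs)) {
        rows[[length(rows) + 1]] <- tibble(group = g, replicate = rep_i,
                                           assay = rg,
                                           ct = refs[[rg]] + rnorm(1, 0, sd_ct))
      }
    }
  }
  list_rbind(rows)
}
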