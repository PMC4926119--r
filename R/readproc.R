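# Read cleaning: adapter removal, quality/N/length filters with the fixed
# precedence low_quality -> n_reads -> too_short -> too_long -> clean, and
# collapsing of clean reads to unique tags with per-library counts.

# Leftmost adapter match per read: at least `min_match` nt of the adapter
# prefix aligned with at most `max_mismatch` mismatches. Returns NA where
# no match. N bases count as mismatches.
adapter_match_pos <- function(sequences, adapter, min_match = 8,
                              max_mismatch = 1) {
  if (!nzchar(adapter)) abort("`adapter` must be non-empty.")
  k <- min(min_match, nchar(adapter))
  probe <- substr(as_dna(adapter), 1, k)
  subj <- Biostrings::DNAStringSet(as_dna(sequences))
  hits <- Biostrings::vmatchPattern(probe, subj, max.mismatch = max_mismatch,
                                    fixed = TRUE)
  n_hit <- S4Vectors::elementNROWS(hits)
  flat <- IRanges::start(unlist(hits))
  out <- rep(NA_integer_, length(n_hit))
  has <- n_hit > 0
  # matches are reported left to right: the first per read is the leftmost
  out[has] <- flat[c(0L, cumsum(n_hit))[which(has)] + 1L]
  out
}

#' Trim the 3' adapter from small RNA reads
#'
#' Finds the leftmost position where at least 8 nt of the adapter prefix
#' match with at most one mismatch, and returns the read prefix before it.
#' Reads without an adapter match are kept whole if they are already at
#' most `max_len` nt (the adapter may have fallen off the read end);
#' longer matchless reads carry no recoverable insert and are dropped
#' (`NA`), to be counted as too long downstream.
#'
#' @param reads tibble with `sequence` (and optionally `quality`) columns,
#'   or a character vector of sequences.
#' @param adapter 3' adapter sequence (DNA, non-empty).
#' @param max_len longest retainable insert (default 30 nt).
#' @return A tibble with `sequence`, `quality` (if supplied), both trimmed
#'   (`NA` where no insert is recoverable), `adapter_found`, `raw_length`.
#' @export
trim_adapter <- function(reads, adapter, max_len = 30) {
  if (is.character(reads)) reads <- tibble(sequence = reads)
  pos <- adapter_match_pos(reads$sequence, adapter)
  raw_len <- nchar(reads$sequence)
  found <- !is.na(pos)
  ins_end <- ifelse(found, pos - 1L, raw_len)
  keep <- found | raw_len <= max_len
  out <- tibble(
    sequence = ifelse(keep, substr(reads$sequence, 1, ins_end), NA_character_),
    adapter_found = found,
    raw_length = raw_len)
  if (!is.null(reads[["quality"]])) {
    out$quality <- ifelse(keep, substr(reads[["quality"]], 1, ins_end),
                          NA_character_)
    out <- relocate(out, "quality", .after = "sequence")
  }
  if (!is.null(reads[["name"]])) {
    out <- bind_cols(tibble(name = reads[["name"]]), out)
  }
  out
}

#' Clean a small RNA library and account for every read
#'
#' Trims adapters, then assigns each read to exactly one outcome in the
#' fixed order low quality (mean base quality of the insert below
#' `min_quality`) -> contains N -> shorter than `min_len` -> longer than
#' `max_len` -> clean. The returned statistics satisfy the accounting
#' identity `clean = total - low_quality - n_reads - too_short - too_long`
#' exactly. Reads lacking an adapter match that are still longer than
#' `max_len` are binned as too long.
#'
#' @param reads FASTQ path or tibble with `name`, `sequence`, `quality`.
#' @param adapter 3' adapter sequence.
#' @param min_quality minimum mean Phred quality of the trimmed insert.
#' @param min_len,max_len retained insert length bounds (nt).
#' @param library library name recorded in the stats row.
#' @return A list with `tags` (tibble of clean reads: `name`, `sequence`),
#'   `stats` (one-row tibble: `library`, `total_reads`, `low_quality`,
#'   `n_reads`, `too_short`, `too_long`, `clean_reads`) and `fates`
#'   (per-read outcome, for auditing).
#' @export
clean_library <- function(reads, adapter = DEFAULT_ADAPTER, min_quality = 20,
                          min_len = 18, max_len = 30, library = "library") {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq_tbl(reads)
  stopifnot(all(c("sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    stats <- tibble(library = library, total_reads = 0L, low_quality = 0L,
                    n_reads = 0L, too_short = 0L, too_long = 0L,
                    clean_reads = 0L)
    return(list(tags = tibble(name = character(), sequence = character()),
                stats = stats,
                fates = tibble(name = character(), fate = character())))
  }
  tr <- trim_adapter(reads, adapter, max_len = max_len)
  len <- ifelse(is.na(tr$sequence), tr$raw_length, nchar(tr$sequence))
  mq <- rep(NA_real_, n)
  has_ins <- !is.na(tr$sequence) & nchar(tr$sequence) > 0
  mq[has_ins] <- mean_phred(tr$quality[has_ins])
  has_n <- !is.na(tr$sequence) & grepl("N", tr$sequence, fixed = TRUE)
  fate <- rep("clean", n)
  fate[len > max_len] <- "too_long"
  fate[len < min_len] <- "too_short"
  fate[has_n] <- "n_read"
  fate[!is.na(mq) & mq < min_quality] <- "low_quality"
  stats <- tibble(
    library = library,
    total_reads = n,
    low_quality = sum(fate == "low_quality"),
    n_reads = sum(fate == "n_read"),
    too_short = sum(fate == "too_short"),
    too_long = sum(fate == "too_long"),
    clean_reads = sum(fate == "clean"))
  keep <- fate == "clean"
  nm <- if (!is.null(reads[["name"]])) reads[["name"]] else sprintf("read_%d", seq_len(n))
  list(tags = tibble(name = nm[keep], sequence = tr$sequence[keep]),
       stats = stats,
       fates = tibble(name = nm, fate = fate))
}

#' Collapse clean reads to unique tags with per-library counts
#'
#' @param tags long tibble with `library` and `sequence` columns (clean
#'   reads; one row per read), or a named list of character vectors.
#' @return A tibble with `sequence`, one count column per library, and
#'   `total`. Per-library column sums equal that library's clean read
#'   count.
#' @export
collapse_unique <- function(tags) {
  if (is.list(tags) && !is.data.frame(tags)) {
    tags <- list_rbind(imap(tags, function(s, nm) {
      tibble(library = nm, sequence = s)
    }))
  }
  libs <- unique(tags$library)
  wide <- tags |>
    count(.data$library, .data$sequence, name = "count") |>
    pivot_wider(names_from = "library", values_from = "count",
                values_fill = 0L)
  wide <- wide[, c("sequence", libs)]
  wide$total <- rowSums(wide[, libs, drop = FALSE])
  arrange(wide, desc(.data$total), .data$sequence)
}

#' Write unique tags as FASTA with count headers
#'
#' Headers follow the `tag_<i>_x<count>` convention.
#'
#' @param tags tibble from [collapse_unique()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  write_fasta_tbl(tibble(
    name = sprintf("tag_%d_x%d", seq_len(nrow(tags)), tags$total),
    sequence = tags$sequence), path)
}

#' Read or write cleaning statistics as TSV
#'
#' @param stats tibble of per-library cleaning statistics.
#' @param path TSV path.
#' @return `path` invisibly for write; a tibble for read.
#' @export
write_clean_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}
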