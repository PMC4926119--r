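# Sequence utilities shared across modules. Sequences are plain uppercase
# character vectors; RNA/DNA alphabet differences only matter at pairing
# time, so T and U are interconverted freely.

DNA_BASES <- c("A", "C", "G", "T")

as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of DNA/RNA strings
#'
#' @param x character vector of sequences (A/C/G/T or A/C/G/U).
#' @return Character vector of reverse complements, in the same alphabet
#'   (input containing U returns RNA, otherwise DNA).
#' @export
revcomp <- function(x) {
  is_rna <- grepl("U", toupper(x), fixed = TRUE)
  comp <- chartr("ACGTUacgtu", "TGCAATGCAA", x)
  out <- vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
                character(1))
  ifelse(is_rna, as_rna(out), toupper(out))
}

# vectorized per-sequence GC fraction
gc_fraction <- function(x) {
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / nchar(x)
}

# uniform integers in [lo, hi]; safe when lo == hi (unlike sample(seq(...)))
sample_int_range <- function(n, lo, hi) {
  lo + floor(runif(n, 0, hi - lo + 1))
}

random_seq <- function(n, length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length[[min(i, base::length(length))]],
                 replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# integer base codes for folding: A=0, C=1, G=2, U=3; anything else -1
encode_rna <- function(seq) {
  ch <- strsplit(as_rna(seq), "")[[1]]
  codes <- match(ch, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) {
    abort(sprintf("invalid character(s) in sequence: %s",
                  paste(unique(ch[is.na(codes)]), collapse = ", ")))
  }
  codes
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_fasta_tbl <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(name = sub("\\s.*", "", names(ss)), sequence = toupper(as.character(ss)))
}

#' Write sequences from a tibble to FASTA
#'
#' @param x tibble with `name` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path) {
  ss <- Biostrings::BStringSet(setNames(x$sequence, x$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Sanger Phred+33 qualities are kept as strings; `read_fastq_tbl()` is the
#' entry point for the cleaning module.
#'
#' @param path FASTQ file.
#' @return A tibble with columns `name`, `sequence`, `quality`.
#' @export
read_fastq_tbl <- function(path) {
  # the mcols carried by FASTQ import are not part of this contract
  ss <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(name = sub("\\s.*", "", names(ss)),
         sequence = as.character(ss),
         quality = as.character(Biostrings::quality(ss)))
}

#' Write reads from a tibble to FASTQ (Phred+33)
#'
#' @param x tibble with `name`, `sequence`, `quality` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq_tbl <- function(x, path) {
  sq <- Biostrings::DNAStringSet(setNames(as_dna(x$sequence), x$name))
  qs <- Biostrings::PhredQuality(x$quality)
  out <- Biostrings::QualityScaledDNAStringSet(sq, qs)
  Biostrings::writeQualityScaledXStringSet(out, path)
  invisible(path)
}

# mean Phred score per read from quality strings (Phred+33); empty
# strings yield NA
mean_phred <- function(quality) {
  lens <- nchar(quality)
  out <- rep(NA_real_, length(quality))
  ok <- lens > 0
  if (!any(ok)) return(out)
  q <- utf8ToInt(paste(quality[ok], collapse = "")) - 33L
  grp <- rep(seq_len(sum(ok)), lens[ok])
  out[ok] <- as.vector(rowsum(q, grp)) / lens[ok]
  out
}
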