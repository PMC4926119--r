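# Novel miRNA prediction: map unannotated tags to the transcriptome,
# extract candidate precursor windows, fold them, and apply the four
# MIREAP-style calling criteria (stem-loop, MFE <= -20 kcal/mol,
# >= 16 miRNA/miRNA* pairs with <= 4 bulges, duplex asymmetry <= 4 nt).

#' Map tags to exact loci on a transcriptome
#'
#' Exact-match loci on both strands, 1-based inclusive coordinates on the
#' transcript. Tags mapping to more than `max_loci` loci are discarded as
#' repeats; tags supported by fewer than `min_count` reads are skipped
#' (precursor evaluation needs read support and desk-scale runtime).
#'
#' @param tags tibble from [collapse_unique()] (unannotated-category tags).
#' @param transcripts tibble with `transcript_id`, `sequence`.
#' @param min_count minimum total read support per tag.
#' @param max_loci repeat-filter threshold (default 20).
#' @return A tibble with `sequence`, `count`, `transcript_id`, `start`,
#'   `end`, `strand`.
#' @export
map_tags <- function(tags, transcripts, min_count = 5, max_loci = 20) {
  tags <- tags[tags$total >= min_count, ]
  if (nrow(tags) == 0) {
    return(tibble(sequence = character(), count = numeric(),
                  transcript_id = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  subj <- Biostrings::DNAStringSet(setNames(as_dna(transcripts$sequence),
                                            transcripts$transcript_id))
  out <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    tg <- as_dna(tags$sequence[i])
    loci <- list()
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") tg else revcomp(tg)
      hits <- Biostrings::vmatchPattern(probe, subj)
      ns <- lengths(hits)
      for (k in which(ns > 0)) {
        st <- IRanges::start(hits[[k]])
        loci[[length(loci) + 1]] <- tibble(
          sequence = tags$sequence[i], count = tags$total[i],
          transcript_id = transcripts$transcript_id[k],
          start = st, end = st + nchar(tg) - 1L, strand = strand)
      }
    }
    loci <- if (length(loci)) list_rbind(loci) else NULL
    if (!is.null(loci) && nrow(loci) <= max_loci) out[[i]] <- loci
  }
  found <- !vapply(out, is.null, logical(1))
  if (!any(found)) {
    return(tibble(sequence = character(), count = numeric(),
                  transcript_id = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  list_rbind(out[found])
}

#' Extract candidate precursor windows around mapped loci
#'
#' Three windows per locus — the tag with both flanks, with the 5' flank
#' only, and with the 3' flank only — truncated at transcript ends and
#' capped at `max_window` nt. Windows shorter than the tag plus 20 nt are
#' skipped. For minus-strand loci the window sequence is the reverse
#' complement of the transcript region.
#'
#' @param loci tibble from [map_tags()].
#' @param transcripts tibble with `transcript_id`, `sequence`.
#' @param flank flank length each side (default 150 nt).
#' @param max_window window length cap (default 320 nt).
#' @return A tibble with `window_id`, `sequence` (RNA, window orientation),
#'   `tag_seq`, `count`, `transcript_id`, `win_start`, `win_end`, `strand`,
#'   `tag_start` and `tag_end` (1-based positions of the tag within the
#'   window).
#' @export
extract_windows <- function(loci, transcripts, flank = 150, max_window = 320) {
  seqs <- setNames(transcripts$sequence, transcripts$transcript_id)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    tr_seq <- seqs[[loci$transcript_id[i]]]
    tlen <- nchar(tr_seq)
    s <- loci$start[i]; e <- loci$end[i]
    tag_len <- e - s + 1L
    for (kind in c("both", "five", "three")) {
      f5 <- if (kind %in% c("both", "five")) flank else 0L
      f3 <- if (kind %in% c("both", "three")) flank else 0L
      ws <- max(1L, s - f5); we <- min(tlen, e + f3)
      # cap total window length, trimming the flanks evenly
      over <- (we - ws + 1L) - max_window
      while (over > 0) {
        if (s - ws >= we - e) ws <- ws + 1L else we <- we - 1L
        over <- over - 1L
      }
      if (we - ws + 1L < tag_len + 20L) next
      win <- substr(tr_seq, ws, we)
      if (loci$strand[i] == "-") {
        win <- revcomp(win)
        t_start <- we - e + 1L
      } else {
        t_start <- s - ws + 1L
      }
      rows[[length(rows) + 1]] <- tibble(
        window_id = sprintf("%s:%d-%d:%s:%s", loci$transcript_id[i], ws, we,
                            loci$strand[i], kind),
        sequence = as_rna(win),
        tag_seq = loci$sequence[i], count = loci$count[i],
        transcript_id = loci$transcript_id[i],
        win_start = ws, win_end = we, strand = loci$strand[i],
        tag_start = t_start, tag_end = t_start + tag_len - 1L)
    }
  }
  if (!length(rows)) {
    return(tibble(window_id = character(), sequence = character(),
                  tag_seq = character(), count = numeric(),
                  transcript_id = character(), win_start = integer(),
                  win_end = integer(), strand = character(),
                  tag_start = integer(), tag_end = integer()))
  }
  list_rbind(rows)
}

#' miRNA/miRNA* duplex statistics from a folded precursor
#'
#' Given a dot-bracket structure and the mature arm coordinates, locates
#' the star arm as the positions pairing with the mature arm extended by a
#' 2-nt 3' overhang (Dicer-product geometry), and computes the number of
#' common base pairs, the number of bulges (maximal unpaired runs interior
#' to the duplex, on either side), and the duplex asymmetry (absolute
#' difference of interior unpaired counts between the two sides). A mature
#' arm that spans the hairpin loop (pairs with itself) yields `NA`
#' statistics — the candidate is rejected, not an error.
#'
#' @param structure dot-bracket string of the folded window.
#' @param mature_start,mature_end 1-based mature arm coordinates within the
#'   window.
#' @return A one-row tibble: `paired`, `bulges`, `asymmetry`, `star_start`,
#'   `star_end`, `arm` (`"5p"`/`"3p"`).
#' @export
duplex_stats <- function(structure, mature_start, mature_end) {
  empty <- tibble(paired = NA_integer_, bulges = NA_integer_,
                  asymmetry = NA_integer_, star_start = NA_integer_,
                  star_end = NA_integer_, arm = NA_character_)
  pr <- structure_pairs(structure)
  if (nrow(pr) == 0) return(empty)
  m_idx <- mature_start:mature_end
  in_mature_i <- pr[, "i"] %in% m_idx
  in_mature_j <- pr[, "j"] %in% m_idx
  # a pair internal to the mature arm means it spans the hairpin loop
  if (any(in_mature_i & in_mature_j)) return(empty)
  partners <- c(pr[in_mature_i, "j"], pr[in_mature_j, "i"])
  paired_pos <- c(pr[in_mature_i, "i"], pr[in_mature_j, "j"])
  if (length(partners) == 0) return(empty)
  arm <- if (all(partners > mature_end)) "5p"
         else if (all(partners < mature_start)) "3p"
         else return(empty)
  n <- nchar(structure)
  star_start <- max(1L, min(partners))
  star_end <- min(n, max(partners) + 2L)
  # interior unpaired runs on the mature side
  m_paired <- sort(paired_pos)
  m_span <- seq(min(m_paired), max(m_paired))
  m_unp <- setdiff(m_span, m_paired)
  s_paired <- sort(partners)
  s_span <- seq(min(s_paired), max(s_paired))
  s_unp <- setdiff(s_span, s_paired)
  n_runs <- function(v) if (!length(v)) 0L else sum(diff(c(-10L, v)) > 1L)
  tibble(paired = length(paired_pos),
         bulges = n_runs(m_unp) + n_runs(s_unp),
         asymmetry = abs(length(m_unp) - length(s_unp)),
         star_start = star_start, star_end = star_end, arm = arm)
}

#' Fold candidate windows and evaluate duplex criteria
#'
#' Runs [fold_rna()] on each window and [duplex_stats()] at the tag (mature
#' arm) position, producing the candidate table that [call_novel()]
#' filters.
#'
#' @param windows tibble from [extract_windows()].
#' @return `windows` with `structure`, `mfe`, `paired`, `bulges`,
#'   `asymmetry`, `star_start`, `star_end`, `arm` columns added.
#' @export
evaluate_candidates <- function(windows) {
  if (nrow(windows) == 0) {
    return(bind_cols(windows,
                     tibble(structure = character(), mfe = numeric())[0, ],
                     duplex_stats(".", 1, 1)[0, ]))
  }
  folds <- map(windows$sequence, fold_rna)
  stats <- map2(folds, seq_len(nrow(windows)), function(f, i) {
    duplex_stats(f$structure, windows$tag_start[i], windows$tag_end[i])
  })
  bind_cols(windows,
            tibble(structure = map_chr(folds, "structure"),
                   mfe = map_dbl(folds, "mfe")),
            list_rbind(stats))
}

#' Call novel miRNAs from evaluated precursor candidates
#'
#' Retains candidates passing all four criteria (inclusive boundaries:
#' MFE <= `mfe_max`, paired >= `min_paired`, bulges <= `max_bulges`,
#' asymmetry <= `max_asym`), keeps the best-MFE window per distinct mature
#' sequence, and assigns names `novel-<prefix>-miR-<k>` in descending
#' supporting-read order. Decisions do not depend on candidate order.
#'
#' @param candidates tibble from [evaluate_candidates()].
#' @param mfe_max maximal precursor free energy (kcal/mol).
#' @param min_paired minimum miRNA/miRNA* common base pairs.
#' @param max_bulges maximum bulges in the duplex.
#' @param max_asym maximum duplex asymmetry (nt).
#' @param prefix species prefix for assigned names.
#' @return A tibble with `name`, `mature_seq`, `star_seq`, `transcript_id`,
#'   `win_start`, `win_end`, `strand`, `mfe`, `paired`, `bulges`,
#'   `asymmetry`, `count`, `structure`, `precursor_seq`.
#' @export
call_novel <- function(candidates, mfe_max = -20, min_paired = 16,
                       max_bulges = 4, max_asym = 4, prefix = "bsy") {
  ok <- candidates |>
    filter(!is.na(.data$paired),
           .data$mfe <= mfe_max,
           .data$paired >= min_paired,
           .data$bulges <= max_bulges,
           .data$asymmetry <= max_asym)
  if (nrow(ok) == 0) {
    return(tibble(name = character(), mature_seq = character(),
                  star_seq = character(), transcript_id = character(),
                  win_start = integer(), win_end = integer(),
                  strand = character(), mfe = numeric(), paired = integer(),
                  bulges = integer(), asymmetry = integer(),
                  count = numeric(), structure = character(),
                  precursor_seq = character()))
  }
  best <- ok |>
    mutate(star_seq = substr(.data$sequence, .data$star_start, .data$star_end)) |>
    group_by(mature_seq = as_rna(.data$tag_seq)) |>
    arrange(.data$mfe, .data$window_id) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(desc(.data$count), .data$mature_seq)
  tibble(name = sprintf("novel-%s-miR-%d", prefix, seq_len(nrow(best))),
         mature_seq = best$mature_seq,
         star_seq = best$star_seq,
         transcript_id = best$transcript_id,
         win_start = best$win_start, win_end = best$win_end,
         strand = best$strand, mfe = best$mfe, paired = best$paired,
         bulges = best$bulges, asymmetry = best$asymmetry,
         count = best$count, structure = best$structure,
         precursor_seq = best$sequence)
}

#' End-to-end novel miRNA prediction
#'
#' Convenience wrapper: [map_tags()] -> [extract_windows()] ->
#' [evaluate_candidates()] -> [call_novel()].
#'
#' @param tags unannotated-category unique tags ([collapse_unique()]).
#' @param transcripts transcriptome tibble.
#' @param ... passed to [call_novel()].
#' @param min_count,flank see the stage functions.
#' @return The [call_novel()] table.
#' @export
predict_novel <- function(tags, transcripts, min_count = 5, flank = 150, ...) {
  loci <- map_tags(tags, transcripts, min_count = min_count)
  wins <- extract_windows(loci, transcripts, flank = flank)
  cands <- evaluate_candidates(wins)
  call_novel(cands, ...)
}
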