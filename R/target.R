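# Plant miRNA target prediction with position-specific mismatch rules on a
# gap-free miRNA:mRNA duplex. Positions are counted from the miRNA 5' end;
# a G:U wobble scores 0.5 penalty in the 5'-region weighted sum but does
# not count as a mismatch for the count-based rules.

#' Align a miRNA against a candidate target site
#'
#' The site is the transcript window 5'->3'; the duplex is antiparallel,
#' so miRNA position 1 pairs with the last site base. Each position is
#' scored match (Watson-Crick), wobble (G:U), or mismatch; penalties are
#' 0, 0.5 and 1.
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA).
#' @param site transcript window 5'->3', same length as `mirna`.
#' @return A one-row tibble: `mirna`, `site`, `states` (list of per-position
#'   states over miRNA positions 1..L), `mismatches`, `wobbles`,
#'   `mm_1_9`, `mm_10_11`, `penalty_1_12`, `penalty_total`.
#' @export
align_site <- function(mirna, site) {
  m <- strsplit(as_rna(mirna), "")[[1]]
  s <- strsplit(as_rna(site), "")[[1]]
  if (length(m) != length(s)) {
    abort("`mirna` and `site` must have equal length (gap-free duplex).")
  }
  t_aligned <- rev(s)  # miRNA position i pairs site base L - i + 1
  states <- pair_states(m, t_aligned)
  summarize_alignment(mirna = as_rna(mirna), site = as_rna(site),
                      states = states)
}

pair_states <- function(m, t) {
  wc <- (m == "A" & t == "U") | (m == "U" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  wb <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, "match", ifelse(wb, "wobble", "mismatch"))
}

summarize_alignment <- function(mirna, site, states) {
  L <- length(states)
  mm <- states == "mismatch"
  wob <- states == "wobble"
  pen <- ifelse(mm, 1, ifelse(wob, 0.5, 0))
  r12 <- seq_len(min(12L, L))
  tibble(mirna = mirna, site = site, states = list(states),
         mismatches = sum(mm), wobbles = sum(wob),
         mm_1_9 = sum(mm[seq_len(min(9L, L))]),
         mm_10_11 = sum(mm[intersect(10:11, seq_len(L))]),
         penalty_1_12 = sum(pen[r12]),
         penalty_total = sum(pen))
}

#' Apply the five position-specific target rules
#'
#' Accepts an alignment iff: (1) at most `max_mismatch` mismatches in
#' total; (2) no run of 3 or more consecutive mismatches; (3) at most 1
#' mismatch at positions 1-9; (4) no mismatch at positions 10-11; (5)
#' weighted penalty over positions 1-12 (mismatch 1, wobble 0.5) at most
#' `max_penalty_5p`. Wobbles do not count as mismatches for rules 1-4.
#'
#' @param aln one-row tibble from [align_site()] (or several rows).
#' @param max_mismatch,max_adjacent,max_mm_1_9,max_penalty_5p rule
#'   thresholds.
#' @return `aln` with `accept` (logical) and `first_violated` (rule label
#'   or `NA`) columns added.
#' @export
apply_rules <- function(aln, max_mismatch = 4, max_adjacent = 2,
                        max_mm_1_9 = 1, max_penalty_5p = 2.5) {
  run3 <- vapply(aln$states, function(st) {
    mm <- st == "mismatch"
    L <- length(mm)
    L >= 3 && any(mm[1:(L - 2)] & mm[2:(L - 1)] & mm[3:L])
  }, logical(1))
  viol <- cbind(
    total_mismatches = aln$mismatches > max_mismatch,
    adjacent_mismatches = run3,
    mismatches_1_9 = aln$mm_1_9 > max_mm_1_9,
    mismatches_10_11 = aln$mm_10_11 > 0,
    penalty_1_12 = aln$penalty_1_12 > max_penalty_5p)
  first <- apply(viol, 1, function(v) {
    w <- which(v)
    if (length(w)) colnames(viol)[w[1]] else NA_character_
  })
  aln$accept <- !apply(viol, 1, any)
  aln$first_violated <- first
  aln
}

#' Predict miRNA target sites on a transcriptome
#'
#' Scans every gap-free window on the sense strand of each transcript
#' (mRNA) for each miRNA, applies the five position rules, and reports the
#' best accepted site per (miRNA, transcript): minimum 5'-region penalty,
#' ties to the smallest coordinate.
#'
#' @param mirnas tibble with `name`, `sequence` columns (or a named
#'   character vector).
#' @param transcripts tibble with `transcript_id`, `sequence`.
#' @param ... rule thresholds passed to [apply_rules()].
#' @return A tibble with `mirna`, `transcript_id`, `start`, `end` (1-based
#'   site coordinates), `site`, `mismatches`, `wobbles`, `penalty_1_12`,
#'   `penalty_total`.
#' @export
predict_targets <- function(mirnas, transcripts, ...) {
  if (is.character(mirnas)) {
    mirnas <- tibble(name = names(mirnas) %||%
                       sprintf("mirna_%d", seq_along(mirnas)),
                     sequence = unname(mirnas))
  }
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    m <- strsplit(as_rna(mirnas$sequence[i]), "")[[1]]
    L <- length(m)
    for (k in seq_len(nrow(transcripts))) {
      tr <- strsplit(as_rna(transcripts$sequence[k]), "")[[1]]
      n_off <- length(tr) - L + 1L
      if (n_off < 1) next
      # state matrix: rows miRNA positions, cols window offsets
      mm <- matrix(FALSE, L, n_off); wob <- matrix(FALSE, L, n_off)
      for (p in seq_len(L)) {
        tv <- tr[(L - p) + seq_len(n_off)]  # base pairing miRNA position p
        st <- pair_states(rep(m[p], n_off), tv)
        mm[p, ] <- st == "mismatch"
        wob[p, ] <- st == "wobble"
      }
      pen <- mm + 0.5 * wob
      r12 <- seq_len(min(12L, L))
      tot_mm <- colSums(mm)
      mm19 <- colSums(mm[seq_len(min(9L, L)), , drop = FALSE])
      r1011 <- intersect(10:11, seq_len(L))
      mm1011 <- if (length(r1011)) {
        colSums(mm[r1011, , drop = FALSE])
      } else rep(0, n_off)
      pen12 <- colSums(pen[r12, , drop = FALSE])
      run3 <- if (L >= 3) {
        colSums(mm[1:(L - 2), , drop = FALSE] & mm[2:(L - 1), , drop = FALSE] &
                  mm[3:L, , drop = FALSE]) > 0
      } else rep(FALSE, n_off)
      dots <- list(...)
      accept <- tot_mm <= (dots$max_mismatch %||% 4) &
        !run3 &
        mm19 <= (dots$max_mm_1_9 %||% 1) &
        mm1011 == 0 &
        pen12 <= (dots$max_penalty_5p %||% 2.5)
      if (!any(accept)) next
      offs <- which(accept)
      best <- offs[order(pen12[offs], offs)][1]
      out[[length(out) + 1]] <- tibble(
        mirna = mirnas$name[i],
        transcript_id = transcripts$transcript_id[k],
        start = best, end = best + L - 1L,
        site = paste(tr[best:(best + L - 1L)], collapse = ""),
        mismatches = tot_mm[best], wobbles = sum(wob[, best]),
        penalty_1_12 = pen12[best],
        penalty_total = sum(pen[, best]))
    }
  }
  if (!length(out)) {
    return(tibble(mirna = character(), transcript_id = character(),
                  start = integer(), end = integer(), site = character(),
                  mismatches = numeric(), wobbles = numeric(),
                  penalty_1_12 = numeric(), penalty_total = numeric()))
  }
  list_rbind(out)
}
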