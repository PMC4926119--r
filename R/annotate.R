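# Annotation of unique tags against non-coding RNA reference sets by
# exhaustive mismatch-limited (Hamming) matching, category assignment with
# a configurable precedence, and conserved miRNA identification.

CATEGORY_PRECEDENCE <- c("rRNA", "tRNA", "snRNA", "snoRNA", "mature_miRNA")

#' Best mismatch-limited hit of tags against a reference set
#'
#' Ungapped alignment of each full-length tag against every equal-length
#' subsequence of every reference (an exhaustive Hamming scan, exact and
#' strictly stronger than a heuristic local aligner at these lengths).
#' Ties are broken by fewest mismatches, then first reference in file
#' order, then leftmost position. Tags longer than a reference by at most
#' `len_tol` nt slide the reference along the tag instead (isomiR ends).
#'
#' @param tags character vector of tag sequences (18-30 nt).
#' @param refset tibble with `name`, `sequence` (one reference set).
#' @param max_mismatch most mismatches allowed for a hit.
#' @param both_strands also scan the reverse complement of each reference.
#' @param len_tol tag/reference length difference tolerated (nt).
#' @return A tibble with one row per tag: `sequence`, `ref_name`,
#'   `mismatches`, `position`, `strand` (`NA`s where no hit).
#' @export
match_reference <- function(tags, refset, max_mismatch = 2,
                            both_strands = FALSE, len_tol = 0) {
  if (nrow(refset) == 0) abort("empty reference set.")
  tags_dna <- as_dna(tags)
  refs_dna <- as_dna(refset$sequence)
  fwd <- .hamming_scan_cpp(tags_dna, refs_dna, max_mismatch, len_tol)
  res <- tibble(sequence = tags,
                ref_name = refset$name[fwd$ref_index],
                mismatches = fwd$mismatches,
                position = fwd$position,
                strand = ifelse(is.na(fwd$ref_index), NA_character_, "+"))
  if (both_strands) {
    rev <- .hamming_scan_cpp(tags_dna, revcomp(refs_dna), max_mismatch, len_tol)
    better <- !is.na(rev$mismatches) &
      (is.na(res$mismatches) | rev$mismatches < res$mismatches)
    res$ref_name[better] <- refset$name[rev$ref_index[better]]
    res$mismatches[better] <- rev$mismatches[better]
    res$position[better] <- rev$position[better]
    res$strand[better] <- "-"
  }
  res
}

#' Classify unique tags into RNA categories
#'
#' Assigns each tag to exactly one category: the first set in `precedence`
#' it matches (default rRNA > tRNA > snRNA > snoRNA > mature miRNA), or
#' `unannotated`. Non-coding RNA sets are scanned on both strands with
#' `ncrna_mismatch` mismatches; the mature miRNA set sense-only with
#' `mirna_mismatch` mismatches and `mirna_len_tol` nt length tolerance.
#' Category counts are weighted by per-library tag read counts (set
#' `weight = "tags"` to count unique tags once instead).
#'
#' @param tags tibble from [collapse_unique()] (`sequence` + per-library
#'   count columns + `total`).
#' @param refsets tibble with `category`, `name`, `sequence`.
#' @param precedence total order over categories to try.
#' @param ncrna_mismatch,mirna_mismatch,mirna_len_tol matching tolerances.
#' @param weight `"reads"` (default) or `"tags"`.
#' @return A list with `assignments` (tags plus `category`, `ref_name`,
#'   `mismatches`) and `category_table` (long tibble: `library`,
#'   `category`, `count`, `percent`; includes a `total` row per library).
#' @export
classify_tags <- function(tags, refsets, precedence = CATEGORY_PRECEDENCE,
                          ncrna_mismatch = 0, mirna_mismatch = 2,
                          mirna_len_tol = 2, weight = c("reads", "tags")) {
  weight <- match.arg(weight)
  libs <- setdiff(names(tags), c("sequence", "total"))
  category <- rep("unannotated", nrow(tags))
  ref_name <- rep(NA_character_, nrow(tags))
  mism <- rep(NA_integer_, nrow(tags))
  todo <- rep(TRUE, nrow(tags))
  for (cat in precedence) {
    rs <- refsets[refsets$category == cat, ]
    if (nrow(rs) == 0 || !any(todo)) next
    is_mirna <- cat == "mature_miRNA"
    hit <- match_reference(tags$sequence[todo], rs,
                           max_mismatch = if (is_mirna) mirna_mismatch
                                          else ncrna_mismatch,
                           both_strands = !is_mirna,
                           len_tol = if (is_mirna) mirna_len_tol else 0)
    got <- !is.na(hit$ref_name)
    idx <- which(todo)[got]
    category[idx] <- if (is_mirna) "miRNA" else cat
    ref_name[idx] <- hit$ref_name[got]
    mism[idx] <- hit$mismatches[got]
    todo[idx] <- FALSE
  }
  assignments <- tags
  assignments$category <- category
  assignments$ref_name <- ref_name
  assignments$mismatches <- mism
  w <- if (weight == "reads") tags[, libs, drop = FALSE] else {
    as.data.frame(matrix(1L, nrow(tags), length(libs),
                         dimnames = list(NULL, libs)))
  }
  long <- bind_cols(tibble(category = category), w) |>
    pivot_longer(cols = -"category", names_to = "library",
                 values_to = "count") |>
    group_by(.data$library, .data$category) |>
    summarise(count = sum(.data$count), .groups = "drop")
  list(assignments = assignments,
       category_table = category_table(long))
}

#' Build a category table with percentages
#'
#' Completes a long (library, category, count) tibble to the canonical
#' category order, adds per-library totals, and derives percentages as
#' `round(100 * count / total, 2)`. Category counts sum exactly to each
#' library's total.
#'
#' @param counts long tibble with `library`, `category`, `count` (no
#'   `total` rows).
#' @return A long tibble with `library`, `category` (total, miRNA, rRNA,
#'   snRNA, snoRNA, tRNA, unannotated), `count`, `percent`.
#' @export
category_table <- function(counts) {
  cats <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unannotated")
  libs <- unique(counts$library)
  full <- tidyr::expand_grid(library = libs, category = cats) |>
    left_join(counts, by = c("library", "category")) |>
    mutate(count = dplyr::coalesce(.data$count, 0))
  totals <- full |>
    group_by(.data$library) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(category = "total")
  out <- bind_rows(totals, full) |>
    group_by(.data$library) |>
    mutate(percent = round(100 * .data$count /
                             .data$count[.data$category == "total"], 2)) |>
    ungroup() |>
    mutate(category = factor(.data$category, levels = c("total", cats))) |>
    arrange(match(.data$library, libs), .data$category) |>
    mutate(category = as.character(.data$category))
  out
}

mir_family <- function(ref_name) {
  fam <- stringr::str_extract(ref_name, "miR[0-9]+")
  ifelse(is.na(fam), ref_name, fam)
}

#' Identify conserved miRNAs among miRNA-category tags
#'
#' Groups mature-reference hits (at most `max_mismatch` mismatches) into
#' miRNA families and assigns each family a species-prefixed name
#' (`bsy-<family>` by default). One record per distinct family; member
#' tags are nested.
#'
#' @param tags tibble of miRNA-category tags ([collapse_unique()] columns).
#' @param mature_ref tibble with `name`, `sequence` (mature miRNA set).
#' @param max_mismatch mismatches tolerated (default 2).
#' @param len_tol length tolerance in nt (default 2).
#' @param prefix species prefix for assigned names.
#' @return A tibble with `family`, `assigned_name`, `n_tags`,
#'   `total_reads`, and nested `members` (tag sequence, `ref_name`,
#'   `mismatches`, per-library counts).
#' @export
identify_conserved <- function(tags, mature_ref, max_mismatch = 2,
                               len_tol = 2, prefix = "bsy") {
  hits <- match_reference(tags$sequence, mature_ref,
                          max_mismatch = max_mismatch, both_strands = FALSE,
                          len_tol = len_tol)
  keep <- !is.na(hits$ref_name)
  if (!any(keep)) {
    return(tibble(family = character(), assigned_name = character(),
                  n_tags = integer(), total_reads = numeric(),
                  members = list()))
  }
  members <- bind_cols(tags[keep, ],
                       hits[keep, c("ref_name", "mismatches")]) |>
    mutate(family = mir_family(.data$ref_name))
  members |>
    group_by(.data$family) |>
    summarise(n_tags = n(),
              total_reads = sum(.data$total),
              members = list(dplyr::pick(dplyr::everything())),
              .groups = "drop") |>
    mutate(assigned_name = paste0(prefix, "-", .data$family)) |>
    relocate("assigned_name", .after = "family") |>
    arrange(desc(.data$total_reads))
}
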