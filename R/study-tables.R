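# Published per-library accounting for the four B. syzigachne pools
# (AFCJ-S sensitive; JCWL-R, JCJT-R, JYJD-R resistant), shipped as
# plain-text data, and the arithmetic the pipeline must reproduce over
# them: the cleaning accounting identity, category-count conservation
# with 2-decimal percentages, and the PBO susceptibility fractions.

#' Published sequencing accounting for the four study libraries
#'
#' @param which one of `"cleaning"` (per-library read-cleaning summary),
#'   `"categories"` (RNA-category distribution of clean reads), or
#'   `"pbo"` (100-plant outcome counts of the PBO + herbicide
#'   susceptibility assay in the three resistant populations).
#' @return A tibble.
#' @export
study_counts <- function(which = c("cleaning", "categories", "pbo")) {
  which <- match.arg(which)
  file <- switch(which,
                 cleaning = "library_cleaning_counts.tsv",
                 categories = "rna_category_counts.tsv",
                 pbo = "pbo_response_counts.tsv")
  readr::read_tsv(system.file("extdata", file, package = "mirweed"),
                  show_col_types = FALSE)
}

#' Recompute clean-read counts from filter accounting
#'
#' Applies the accounting identity `clean = total - low_quality - n_reads
#' - too_short - too_long` to a cleaning summary, for checking a reported
#' summary against itself.
#'
#' @param stats tibble with the [clean_library()] stats columns.
#' @return `stats` with `clean_expected` and `consistent` columns added.
#' @export
check_clean_accounting <- function(stats) {
  stats |>
    mutate(clean_expected = .data$total_reads - .data$low_quality -
             .data$n_reads - .data$too_short - .data$too_long,
           consistent = .data$clean_expected == .data$clean_reads)
}

#' Re-derive category percentages from counts
#'
#' Recomputes each category's percentage of the per-library total
#' (2 decimals) and checks that category counts sum to the total.
#'
#' @param categories long tibble with `library`, `category`, `count`
#'   (including `total` rows).
#' @return A list with `table` (counts with recomputed `percent`) and
#'   `conserved` (per-library logical: categories sum to total).
#' @export
check_category_table <- function(categories) {
  cats <- filter(categories, .data$category != "total")
  tab <- category_table(cats[, c("library", "category", "count")])
  conserved <- categories |>
    group_by(.data$library) |>
    summarise(conserved = sum(.data$count[.data$category != "total"]) ==
                .data$count[.data$category == "total"][1],
              .groups = "drop")
  list(table = tab, conserved = conserved)
}

#' Limited-growth (NTSR-indicating) fractions from outcome counts
#'
#' Fraction of plants per population showing limited growth after the
#' P450-inhibitor (PBO) + herbicide treatment — the arithmetic behind the
#' "at least 74-82% of plants carry NTSR" statement.
#'
#' @param counts tibble with `population`, `died`, `normal_growth`,
#'   `limited_growth` (plants per outcome).
#' @return `counts` with `n_plants` and `limited_pct` columns added.
#' @export
limited_growth_fraction <- function(counts = study_counts("pbo")) {
  counts |>
    mutate(n_plants = .data$died + .data$normal_growth + .data$limited_growth,
           limited_pct = 100 * .data$limited_growth / .data$n_plants)
}
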