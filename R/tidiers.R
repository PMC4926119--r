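# broom-style methods for the fitted result objects.

#' Tidy a differential-expression result
#'
#' @param x a `mirna_de` object.
#' @param ... ignored.
#' @return A tibble with one row per (miRNA, comparison).
#' @export
tidy.mirna_de <- function(x, ...) {
  as_tibble(unclass(x)) |>
    select("mirna", "comparison", estimate = "log2_fold_change",
           statistic = "t", "df", p.value = "p_value", "call", "excluded")
}

#' One-row summary of a differential-expression result
#'
#' @param x a `mirna_de` object.
#' @param ... ignored.
#' @return A tibble with counts of comparisons, exclusions and calls.
#' @export
glance.mirna_de <- function(x, ...) {
  tibble(n_comparisons = nrow(x),
         n_excluded = sum(x$excluded),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"),
         n_tested = sum(!is.na(x$p_value)))
}

#' Tidy a relative-expression (qPCR) result
#'
#' @param x a `rel_expr` object.
#' @param ... ignored.
#' @return A tibble with one row per group.
#' @export
tidy.rel_expr <- function(x, ...) {
  as_tibble(unclass(x)) |>
    select("group", "target", estimate = "relative_expression",
           "n_replicates")
}

#' One-row summary of a relative-expression result
#'
#' @param x a `rel_expr` object.
#' @param ... ignored.
#' @return A tibble.
#' @export
glance.rel_expr <- function(x, ...) {
  tibble(target = x$target[1], n_groups = nrow(x),
         max_fold = max(pmax(x$relative_expression,
                             1 / x$relative_expression)))
}
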