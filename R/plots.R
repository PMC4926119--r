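# ggplot2 displays for the main result types.

#' Plot the RNA-category composition of libraries
#'
#' Stacked per-library bars of category shares of clean reads.
#'
#' @param categories long category table ([category_table()] or
#'   [study_counts()]`("categories")`).
#' @return A ggplot object.
#' @export
plot_categories <- function(categories) {
  df <- filter(categories, .data$category != "total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$library, y = .data$count,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of clean reads", fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot a folded precursor's pairing profile
#'
#' Dot-bracket state along the precursor with the mature arm highlighted.
#'
#' @param call one row of a [call_novel()] table.
#' @return A ggplot object.
#' @export
plot_hairpin <- function(call) {
  st <- strsplit(call$structure[1], "")[[1]]
  n <- length(st)
  mat <- regexpr(as_dna(call$mature_seq[1]), as_dna(call$precursor_seq[1]),
                 fixed = TRUE)
  df <- tibble(position = seq_len(n),
               paired = st != ".",
               mature = seq_len(n) >= mat &
                 seq_len(n) < mat + nchar(call$mature_seq[1]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = as.integer(.data$paired),
                                   fill = .data$mature)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("unpaired", "paired")) +
    ggplot2::labs(title = call$name[1],
                  subtitle = sprintf("MFE %.1f kcal/mol", call$mfe[1]),
                  x = "precursor position", y = NULL, fill = "mature arm") +
    ggplot2::theme_minimal()
}

#' Volcano-style display of differential miRNA calls
#'
#' log2 fold change against -log10 p where p values exist; otherwise a
#' fold-change dot plot colored by call.
#'
#' @param object a `mirna_de` result ([call_differential()]).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.mirna_de <- function(object, ...) {
  df <- filter(as_tibble(object), !.data$excluded)
  if (all(is.na(df$p_value))) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                     y = .data$mirna,
                                     color = .data$call)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
      ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2) +
      ggplot2::labs(x = "log2 fold change (R/S)", y = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                     y = -log10(.data$p_value),
                                     color = .data$call)) +
      ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2) +
      ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
      ggplot2::labs(x = "log2 fold change (R/S)", y = "-log10 p") +
      ggplot2::theme_minimal()
  }
}

#' Relative-expression bars for a qPCR result
#'
#' @param object a `rel_expr` result ([delta_delta_ct()]).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.rel_expr <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$relative_expression)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(title = df$target[1], x = NULL,
                  y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
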