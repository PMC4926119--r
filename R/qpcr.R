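# Relative quantification from qPCR Ct tables by the 2^-ddCt method with
# multi-reference normalization (arithmetic mean of reference-gene Cts,
# equivalent to the geometric mean of reference quantities) and Welch
# group comparisons against the calibrator.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = target Ct minus the combined reference Ct (the
#' arithmetic mean over reference-gene assays in that (group, replicate));
#' ddCt = mean dCt of the group minus mean dCt of the calibrator group;
#' relative expression = 2^-ddCt. Invariant to adding a constant to every
#' Ct. The calibrator group's relative expression is 1 by construction.
#'
#' @param ct tibble with `group`, `replicate`, `assay`, `ct`.
#' @param target target assay name.
#' @param calibrator_group calibrator (control) group name.
#' @param reference_assays reference-gene assay names.
#' @return An object of class `rel_expr`: tibble with `group`, `target`,
#'   `relative_expression`, `n_replicates`, nested per-replicate
#'   `replicates` (`replicate`, `dct`, `rel`), where `rel` is the
#'   per-replicate 2^-ddCt against the calibrator mean dCt.
#' @export
delta_delta_ct <- function(ct, target, calibrator_group,
                           reference_assays = c("CAP", "GAPDH", "UBQ")) {
  stopifnot(all(c("group", "replicate", "assay", "ct") %in% names(ct)))
  if (!calibrator_group %in% ct$group) {
    abort(sprintf("calibrator group '%s' not present.", calibrator_group))
  }
  refs <- ct |>
    filter(.data$assay %in% reference_assays) |>
    group_by(.data$group, .data$replicate) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  tg <- filter(ct, .data$assay == target)
  if (nrow(tg) == 0) abort(sprintf("no wells for target '%s'.", target))
  d <- left_join(tg, refs, by = c("group", "replicate"))
  if (anyNA(d$ref_ct)) {
    bad <- d[is.na(d$ref_ct), c("group", "replicate")]
    abort(sprintf("missing reference wells for (%s, replicate %s).",
                  bad$group[1], bad$replicate[1]))
  }
  d$dct <- d$ct - d$ref_ct
  cal_mean <- mean(d$dct[d$group == calibrator_group])
  out <- d |>
    group_by(.data$group) |>
    summarise(relative_expression = 2^-(mean(.data$dct) - cal_mean),
              n_replicates = n(),
              replicates = {
                rr <- .data$replicate; dd <- .data$dct
                list(tibble(replicate = rr, dct = dd,
                            rel = 2^-(dd - cal_mean)))
              },
              .groups = "drop") |>
    mutate(target = target) |>
    relocate("target", .after = "group")
  class(out) <- c("rel_expr", class(out))
  out
}

#' Compare groups to the calibrator with significance calls
#'
#' Welch's t-test ([welch_t()]) on per-replicate 2^-ddCt values of each
#' group against the calibrator group; a group is flagged significant
#' (up- or down-regulated) when p < `alpha` and the relative expression
#' changes at least `fold`-fold in either direction. Groups with fewer
#' than 2 replicates get no p value and are flagged untested.
#'
#' @param rel `rel_expr` object from [delta_delta_ct()].
#' @param calibrator_group calibrator group name.
#' @param alpha p threshold (default 0.05).
#' @param fold fold-change threshold (default 2).
#' @return A tibble: `group`, `target`, `relative_expression`, `p_value`,
#'   `significant`, `direction` (`up`/`down`/`none`), `label` (value with
#'   an asterisk when significant, Table-style).
#' @export
compare_groups <- function(rel, calibrator_group, alpha = 0.05, fold = 2) {
  cal <- rel$replicates[[which(rel$group == calibrator_group)]]
  out <- rel |>
    mutate(p_value = map_dbl(.data$replicates, function(rr) {
      if (nrow(rr) < 2 || nrow(cal) < 2) return(NA_real_)
      welch_t(rr$rel, cal$rel)$p
    })) |>
    mutate(
      change = pmax(.data$relative_expression, 1 / .data$relative_expression),
      significant = !is.na(.data$p_value) & .data$p_value < alpha &
        .data$change >= fold,
      direction = dplyr::case_when(
        .data$significant & .data$relative_expression >= fold ~ "up",
        .data$significant & .data$relative_expression <= 1 / fold ~ "down",
        .default = "none"),
      label = sprintf("%.2f%s", .data$relative_expression,
                      ifelse(.data$significant, "*", ""))) |>
    select("group", "target", "relative_expression", "p_value",
           "significant", "direction", "label")
  out
}

#' Full qPCR analysis shaped like a validation table
#'
#' Runs [delta_delta_ct()] and [compare_groups()] for every target assay
#' in a Ct table and returns a groups-by-assays table of labelled relative
#' expressions (calibrator column all 1).
#'
#' @param ct Ct tibble (`group`, `replicate`, `assay`, `ct`).
#' @param calibrator_group calibrator group.
#' @param reference_assays reference-gene assay names.
#' @param ... passed to [compare_groups()].
#' @return A list with `results` (long tibble over targets/groups) and
#'   `table` (wide: rows targets, columns groups, labelled values).
#' @export
qpcr_table <- function(ct, calibrator_group,
                       reference_assays = c("CAP", "GAPDH", "UBQ"), ...) {
  targets <- setdiff(unique(ct$assay), reference_assays)
  results <- list_rbind(map(targets, function(tg) {
    rel <- delta_delta_ct(ct, tg, calibrator_group, reference_assays)
    compare_groups(rel, calibrator_group, ...)
  }))
  wide <- results |>
    select("target", "group", "label") |>
    pivot_wider(names_from = "group", values_from = "label")
  list(results = results, table = wide)
}
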