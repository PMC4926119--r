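# Differential miRNA expression: TPM normalization (count / clean reads *
# 1e6), zero revision to 0.01 at comparison time, exclusion of pairs where
# both values are below 1 TPM, log2 fold change, and Welch's t-test when
# replicate values are available.

#' TPM-normalize a miRNA count matrix
#'
#' TPM = count / library clean-read total * 1e6. Zeros are kept as 0 here;
#' the revision to 0.01 happens at comparison time
#' ([call_differential()], [log2_fold_change()] inputs).
#'
#' @param counts tibble with `mirna` and one count column per library.
#' @param clean_totals named numeric vector of clean-read totals per
#'   library (all > 0).
#' @return A long tibble: `mirna`, `library`, `count`, `tpm`, `revised`
#'   (whether the 0.01 revision would apply, i.e. `tpm == 0`).
#' @export
tpm_normalize <- function(counts, clean_totals) {
  libs <- setdiff(names(counts), "mirna")
  missing <- setdiff(libs, names(clean_totals))
  if (length(missing)) {
    abort(sprintf("no clean-read total for library: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(clean_totals[libs] <= 0)) abort("clean-read totals must be > 0.")
  counts |>
    pivot_longer(-"mirna", names_to = "library", values_to = "count") |>
    mutate(tpm = .data$count / unname(clean_totals[.data$library]) * 1e6,
           revised = .data$tpm == 0)
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (length/1000) / (mapped_total/1e6)`.
#'
#' @param count read count (>= 0).
#' @param feature_length feature length in bp (> 0).
#' @param mapped_total total mapped reads (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, feature_length, mapped_total) {
  if (any(feature_length <= 0) || any(mapped_total <= 0)) {
    abort("`feature_length` and `mapped_total` must be positive.")
  }
  count / (feature_length / 1000) / (mapped_total / 1e6)
}

#' Log2 fold change between two expression values
#'
#' `log2(x / y)`; antisymmetric under argument swap. Inputs must be
#' positive — apply the 0.01 zero revision first.
#'
#' @param tpm_1,tpm_2 positive expression values (sample 1 over sample 2).
#' @return log2 ratio.
#' @export
log2_fold_change <- function(tpm_1, tpm_2) {
  if (any(tpm_1 <= 0) || any(tpm_2 <= 0)) {
    abort("inputs must be positive; revise zeros to 0.01 before comparing.")
  }
  log2(tpm_1 / tpm_2)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. When both groups have zero variance
#' and equal means the statistic is 0 with p = 1 (and p = 0 for unequal
#' constant groups).
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return A one-row tibble: `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t() needs at least 2 values per group.")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(tibble(t = sign(mean(x) - mean(y)) * Inf,
                  df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Call differential miRNAs between resistant and sensitive libraries
#'
#' For each miRNA and each resistant-vs-sensitive comparison: the pair is
#' excluded when both compared TPM values are below `min_tpm`; zeros are
#' revised to 0.01; the log2 fold change is computed; and, when replicate
#' vectors are available for both sides, Welch's t-test supplies a p
#' value. A call of up or down requires |log2FC| >= log2(`fold`) and,
#' when a p value exists, p < `alpha`. Without replicates calls are made
#' on fold change alone (with a warning). An optional Benjamini-Hochberg
#' correction is off by default, matching the raw-p convention.
#'
#' @param tpm long tibble from [tpm_normalize()], or, for replicated
#'   designs, a tibble with `mirna`, `library`, `replicate`, `tpm`.
#' @param r_libs,s_lib resistant library names and the single sensitive
#'   library per comparison.
#' @param alpha p-value threshold (default 0.05).
#' @param fold fold-change threshold (default 2, i.e. |log2FC| >= 1).
#' @param min_tpm low-expression exclusion bound (default 1 TPM).
#' @param adjust apply Benjamini-Hochberg to p values (default FALSE).
#' @return An object of class `mirna_de`: a tibble with `mirna`,
#'   `comparison`, `tpm_r`, `tpm_s`, `excluded`, `log2_fold_change`, `t`,
#'   `df`, `p_value`, `call` (`up`/`down`/`none`).
#' @export
call_differential <- function(tpm, r_libs, s_lib, alpha = 0.05, fold = 2,
                              min_tpm = 1, adjust = FALSE) {
  stopifnot(length(s_lib) == 1, length(r_libs) >= 1)
  has_rep <- "replicate" %in% names(tpm)
  lfc_min <- log2(fold)
  rows <- list()
  for (r in r_libs) {
    for (m in unique(tpm$mirna)) {
      xr <- tpm$tpm[tpm$mirna == m & tpm$library == r]
      xs <- tpm$tpm[tpm$mirna == m & tpm$library == s_lib]
      mr <- mean(xr); ms <- mean(xs)
      excluded <- mr < min_tpm && ms < min_tpm
      mr_r <- ifelse(mr == 0, 0.01, mr)
      ms_r <- ifelse(ms == 0, 0.01, ms)
      lfc <- if (excluded) NA_real_ else log2_fold_change(mr_r, ms_r)
      tt <- if (!excluded && has_rep && length(xr) >= 2 && length(xs) >= 2) {
        welch_t(pmax(xr, 0.01), pmax(xs, 0.01))
      } else tibble(t = NA_real_, df = NA_real_, p = NA_real_)
      rows[[length(rows) + 1]] <- tibble(
        mirna = m, comparison = paste0(r, "_vs_", s_lib),
        tpm_r = mr, tpm_s = ms, excluded = excluded,
        log2_fold_change = lfc, t = tt$t, df = tt$df, p_value = tt$p)
    }
  }
  out <- list_rbind(rows)
  if (has_rep && any(is.na(out$p_value) & !out$excluded)) {
    warn("some comparisons lack replicate structure; calls use fold change only.")
  }
  if (!has_rep && nrow(out)) {
    warn("no replicate structure supplied; p values omitted, calls by fold change only.")
  }
  if (adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  pass_p <- is.na(out$p_value) | out$p_value < alpha
  out$call <- dplyr::case_when(
    out$excluded ~ "none",
    !is.na(out$log2_fold_change) & out$log2_fold_change >= lfc_min & pass_p ~ "up",
    !is.na(out$log2_fold_change) & out$log2_fold_change <= -lfc_min & pass_p ~ "down",
    .default = "none")
  class(out) <- c("mirna_de", class(out))
  out
}
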