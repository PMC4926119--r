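# TPM normalization, fold changes, Welch's t, and differential calls.

test_that("tpm_normalize applies the count/total*1e6 identity", {
  counts <- tibble::tibble(mirna = c("a", "b"), L1 = c(50L, 0L), L2 = c(10L, 5L))
  tpm <- tpm_normalize(counts, c(L1 = 1e6, L2 = 1e5))
  expect_equal(tpm$tpm[tpm$mirna == "a" & tpm$library == "L1"], 50)
  expect_equal(tpm$tpm[tpm$mirna == "b" & tpm$library == "L2"], 50)
  expect_equal(tpm$tpm[tpm$mirna == "b" & tpm$library == "L1"], 0)
  expect_true(tpm$revised[tpm$mirna == "b" & tpm$library == "L1"])
  expect_error(tpm_normalize(counts, c(L1 = 1e6)), "L2")
  expect_error(tpm_normalize(counts, c(L1 = 1e6, L2 = 0)), "> 0")
})

test_that("tpm column sums equal 1e6 times the counted fraction", {
  set.seed(601)
  counts <- tibble::tibble(mirna = paste0("m", 1:50))
  counts$L1 <- rpois(50, 400)
  counts$L2 <- rpois(50, 900)
  totals <- c(L1 = 5e5, L2 = 8e5)
  tpm <- tpm_normalize(counts, totals)
  for (l in names(totals)) {
    expect_equal(sum(tpm$tpm[tpm$library == l]),
                 1e6 * sum(counts[[l]]) / totals[[l]])
  }
})

test_that("rpkm matches its closed form", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 1500, 1e6), 0)
  set.seed(602)
  for (i in 1:20) {
    n <- rpois(1, 500); len <- sample(200:3000, 1); tot <- sample(1e5:1e7, 1)
    expect_equal(rpkm(n, len, tot), n / (len / 1000) / (tot / 1e6))
  }
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 100, 0), "positive")
})

test_that("log2 fold change is antisymmetric and matches closed forms", {
  expect_equal(log2_fold_change(2, 1), 1)
  expect_equal(log2_fold_change(1, 1), 0)
  expect_equal(log2_fold_change(0.01, 1), log2(0.01))
  expect_equal(log2_fold_change(0.01, 1), -6.6438562, tolerance = 1e-6)
  set.seed(603)
  a <- runif(20, 0.01, 100); b <- runif(20, 0.01, 100)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_error(log2_fold_change(0, 1), "positive")
})

test_that("welch_t matches the textbook closed form and handles edges", {
  id <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  got <- welch_t(c(1, 2, 3), c(2, 3, 4))
  want <- oracle_welch(c(1, 2, 3), c(2, 3, 4))
  expect_equal(got$t, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p)
  set.seed(604)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 2)
    got <- welch_t(x, y); want <- oracle_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # degenerate zero-variance groups
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welch_t(c(2, 2), c(1, 1))$p, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("welch p values are consistent with a permutation test", {
  set.seed(605)
  x <- rnorm(6); y <- rnorm(6, mean = 1.2)
  p_welch <- welch_t(x, y)$p
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    idx <- sample(12, 6)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_welch - p_perm), 4 * se + 0.02)
})

test_that("the Welch implementation holds its type-I error under the null", {
  set.seed(606)
  p <- replicate(1000, welch_t(rnorm(3), rnorm(3))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("identical expression yields no differential calls", {
  counts <- tibble::tibble(mirna = paste0("m", 1:5),
                           S = c(100L, 50L, 10L, 5L, 0L))
  counts$R1 <- counts$S
  tpm <- tpm_normalize(counts, c(S = 1e5, R1 = 1e5))
  de <- suppressWarnings(call_differential(tpm, r_libs = "R1", s_lib = "S"))
  expect_true(all(de$call == "none"))
})

test_that("low-expression rows are excluded and zeros revised to 0.01", {
  counts <- tibble::tibble(mirna = c("low", "zero"),
                           S = c(5L, 0L), R1 = c(8L, 120L))
  tpm <- tpm_normalize(counts, c(S = 1e7, R1 = 1e7))  # low: 0.5 and 0.8 TPM
  de <- suppressWarnings(call_differential(tpm, r_libs = "R1", s_lib = "S"))
  expect_true(de$excluded[de$mirna == "low"])
  expect_equal(de$call[de$mirna == "low"], "none")
  z <- de[de$mirna == "zero", ]
  expect_false(z$excluded)  # R side is 12 TPM: not a both-below-1 case
  expect_equal(z$log2_fold_change, log2(12 / 0.01))
})

test_that("replicated 4-fold effects are called with fold change in range", {
  set.seed(607)
  rows <- list()
  for (l in c("S", "R1")) for (r in 1:3) {
    mu <- c(target = if (l == "S") 100 else 400, stable = 250)
    for (m in names(mu)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        mirna = m, library = l, replicate = r,
        tpm = max(0.01, rnorm(1, mu[[m]], mu[[m]] * 0.05)))
    }
  }
  tpm <- dplyr::bind_rows(rows)
  de <- call_differential(tpm, r_libs = "R1", s_lib = "S")
  tg <- de[de$mirna == "target", ]
  expect_equal(tg$call, "up")
  expect_gt(tg$log2_fold_change, 1.5)
  expect_lt(tg$log2_fold_change, 2.5)
  expect_lt(tg$p_value, 0.05)
  expect_equal(de$call[de$mirna == "stable"], "none")
})

test_that("calls are invariant under row relabeling", {
  set.seed(608)
  counts <- tibble::tibble(mirna = paste0("m", 1:20),
                           S = rpois(20, 300), R1 = rpois(20, 300))
  counts$R1[3] <- counts$S[3] * 5L
  tpm <- tpm_normalize(counts, c(S = 1e5, R1 = 1e5))
  de1 <- suppressWarnings(call_differential(tpm, "R1", "S"))
  relab <- tpm
  relab$mirna <- chartr("m", "x", relab$mirna)
  de2 <- suppressWarnings(call_differential(relab, "R1", "S"))
  expect_equal(de1$call, de2$call[match(chartr("m", "x", de1$mirna), de2$mirna)])
})

test_that("unreplicated designs warn and fall back to fold-change calls", {
  counts <- tibble::tibble(mirna = "m", S = 100L, R1 = 500L)
  tpm <- tpm_normalize(counts, c(S = 1e5, R1 = 1e5))
  expect_warning(de <- call_differential(tpm, "R1", "S"), "fold change only")
  expect_equal(de$call, "up")
  expect_true(is.na(de$p_value))
})

test_that("tidy and glance summarize a de result", {
  counts <- tibble::tibble(mirna = c("a", "b"), S = c(100L, 200L),
                           R1 = c(500L, 210L))
  tpm <- tpm_normalize(counts, c(S = 1e5, R1 = 1e5))
  de <- suppressWarnings(call_differential(tpm, "R1", "S"))
  td <- tidy(de)
  expect_setequal(names(td), c("mirna", "comparison", "estimate", "statistic",
                               "df", "p.value", "call", "excluded"))
  gl <- glance(de)
  expect_equal(gl$n_comparisons, 2L)
  expect_equal(gl$n_up, 1L)
})
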