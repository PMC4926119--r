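# RNA secondary structure prediction under a simplified nearest-neighbor
# energy model: stacking free energies for the 21 distinct WC/G:U stacks
# (shipped as a versioned CSV, expanded to the full 6x6 table by the
# antiparallel symmetry stack(p,q) = stack(flip(q), flip(p))) plus affine
# length penalties for hairpin, bulge, internal and multibranch loops.
# Minimum hairpin loop is 3 nt; only A:U, G:C and G:U pairs are allowed.

PAIR_LEVELS <- c("AU", "UA", "GC", "CG", "GU", "UG")

flip_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))

#' Energy parameters for RNA folding
#'
#' Loads the package's nearest-neighbor-lite energy table: stacking free
#' energies (kcal/mol, 37 degrees C nominal) for all ordered combinations of
#' the six allowed pairs, and affine loop penalties. The stack table is
#' stored as 21 canonical entries and expanded by the antiparallel symmetry
#' relation; loop penalties are `hairpin(L) = a + b*(L-3)`,
#' `bulge(L) = a + b*(L-1)`, `internal(L) = a + b*(L-2)` with `L` the total
#' number of unpaired loop bases, and a multibranch loop costs
#' `close + branch * n_branches + unpaired * n_unpaired`.
#'
#' @return A list with `stack` (6x6 numeric matrix, rows/cols AU, UA, GC,
#'   CG, GU, UG) and `loops` (named numeric vector of loop coefficients).
#' @export
rna_energy_params <- function() {
  cached <- .mirweed_env$energy_params
  if (!is.null(cached)) return(cached)
  st <- readr::read_csv(system.file("extdata", "stack_energies.csv",
                                    package = "mirweed"),
                        show_col_types = FALSE)
  lp <- readr::read_csv(system.file("extdata", "loop_penalties.csv",
                                    package = "mirweed"),
                        show_col_types = FALSE)
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))
  for (k in seq_len(nrow(st))) {
    p <- st$pair5[k]; q <- st$pair3[k]; dg <- st$dg[k]
    m[p, q] <- dg
    m[flip_pair(q), flip_pair(p)] <- dg
  }
  stopifnot(!anyNA(m))
  out <- list(stack = m, loops = setNames(lp$value, lp$term))
  .mirweed_env$energy_params <- out
  out
}

.mirweed_env <- new.env(parent = emptyenv())

#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Computes the pseudoknot-free minimum-free-energy secondary structure of a
#' single sequence by Zuker-style dynamic programming under the package's
#' simplified nearest-neighbor energy model ([rna_energy_params()]).
#' Deterministic; on exact energy ties the structure with fewer pairs is
#' preferred, so a sequence with no stabilizing (negative-energy) structure
#' folds to the open chain with MFE 0.
#'
#' @param sequence single RNA/DNA string (T read as U), length <= 400.
#' @return A one-row tibble (the fold result) with columns `sequence`
#'   (as RNA), `structure` (dot-bracket), `mfe` (kcal/mol), `n_pairs`.
#' @examples
#' fold_rna("GGGGGGAAAACCCCCC")
#' @export
fold_rna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) > 400) {
    abort("fold_rna() accepts sequences of at most 400 nt.")
  }
  codes <- encode_rna(sequence)
  par <- rna_energy_params()
  res <- .fold_mfe_cpp(codes, par$stack, par$loops)
  tibble(sequence = as_rna(sequence),
         structure = res$structure,
         mfe = res$mfe,
         n_pairs = sum(strsplit(res$structure, "")[[1]] == "("))
}

#' Reference MFE by an independently coded dynamic program
#'
#' A plain-R re-derivation of the minimum free energy under the same energy
#' model as [fold_rna()], written against the recursion in a different
#' form and kept free of the compiled code path. Used to validate the
#' folding engine; returns the MFE only (no structure). Slow: intended for
#' sequences up to ~60 nt.
#'
#' @param sequence single RNA/DNA string.
#' @return MFE in kcal/mol (0 for the open chain).
#' @export
fold_mfe_reference <- function(sequence) {
  s <- encode_rna(sequence) + 1L  # 1..4 = A,C,G,U
  n <- length(s)
  par <- rna_energy_params()
  lp <- par$loops
  pair_id <- matrix(0L, 4, 4)
  pair_id[1, 4] <- 1L; pair_id[4, 1] <- 2L; pair_id[3, 2] <- 3L
  pair_id[2, 3] <- 4L; pair_id[3, 4] <- 5L; pair_id[4, 3] <- 6L
  INF <- 1e9
  if (n < 5) return(0)
  pid <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) pid[i, j] <- pair_id[s[i], s[j]]
  V <- matrix(INF, n, n); WM <- matrix(INF, n, n)
  maxloop <- 30
  for (len in 2:n) {
    for (i in seq_len(n - len + 1)) {
      j <- i + len - 1
      p <- pid[i, j]
      if (p > 0L && j - i - 1 >= 3) {
        cand <- lp["hairpin_a"] + lp["hairpin_b"] * (j - i - 1 - 3)
        if (pid[i + 1, j - 1] > 0L && V[i + 1, j - 1] < INF / 2) {
          cand <- c(cand, V[i + 1, j - 1] + par$stack[p, pid[i + 1, j - 1]])
        }
        for (k in (i + 1):(j - 1)) {
          l1 <- k - i - 1
          if (l1 > maxloop) break
          ls <- (k + 1):(j - 1)
          ls <- ls[ls > k & ls < j]
          if (length(ls)) {
            l2 <- j - ls - 1
            keep <- (l1 + l2) >= 1 & (l1 + l2) <= maxloop &
              pid[k, ls] > 0L & V[k, ls] < INF / 2
            if (any(keep)) {
              pen <- ifelse(l1 == 0 | l2 == 0,
                            lp["bulge_a"] + lp["bulge_b"] * (l1 + l2 - 1),
                            lp["internal_a"] + lp["internal_b"] * (l1 + l2 - 2))
              cand <- c(cand, min(V[k, ls][keep] + pen[keep]))
            }
          }
        }
        if (j - i >= 3) {
          ks <- (i + 1):(j - 2)
          w <- WM[i + 1, ks] + WM[cbind(ks + 1, j - 1)]
          w <- w[w < INF / 2]
          if (length(w)) cand <- c(cand, lp["multi_close"] + min(w))
        }
        V[i, j] <- min(cand)
      }
      w <- INF
      if (p > 0L && V[i, j] < INF / 2) w <- V[i, j] + lp["multi_branch"]
      if (WM[i + 1, j] < INF / 2) w <- min(w, WM[i + 1, j] + lp["multi_unpaired"])
      if (WM[i, j - 1] < INF / 2) w <- min(w, WM[i, j - 1] + lp["multi_unpaired"])
      if (len > 2) {
        ks <- (i + 1):(j - 1)
        ww <- WM[i, ks] + WM[cbind(ks + 1, j)]
        ww <- ww[ww < INF / 2]
        if (length(ww)) w <- min(w, min(ww))
      }
      WM[i, j] <- w
    }
  }
  W <- numeric(n + 1)
  for (j in 1:n) {
    best <- W[j]
    is <- which(pid[1:j, j] > 0L)
    if (length(is)) {
      v <- V[cbind(is, j)]
      ok <- v < INF / 2
      if (any(ok)) best <- min(best, min(W[is[ok]] + v[ok]))
    }
    W[j + 1] <- best
  }
  min(W[n + 1], 0)
}

#' Base pairs of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return Integer matrix with columns `i`, `j` (1-based, i < j).
#' @export
structure_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  pairs <- list()
  for (k in seq_along(ch)) {
    if (ch[k] == "(") open <- c(open, k)
    else if (ch[k] == ")") {
      if (!length(open)) abort("unbalanced dot-bracket string")
      pairs[[length(pairs) + 1]] <- c(open[length(open)], k)
      open <- open[-length(open)]
    }
  }
  if (length(open)) abort("unbalanced dot-bracket string")
  if (length(pairs)) out <- do.call(rbind, pairs)
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}
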