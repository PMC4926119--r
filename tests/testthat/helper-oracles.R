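# Independent oracles used across the suite. Each is deliberately naive
# (enumeration, closed form, direct scanning) and shares no code with the
# implementation paths it checks.

ALLOWED_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracle_can_pair <- function(a, b) paste0(a, b) %in% ALLOWED_PAIRS

# --- structure enumeration -------------------------------------------------

# all pseudoknot-free pair sets over s[i..j] with hairpin loops >= 3,
# returned as lists of rbind(i, j) matrices (or NULL for the empty set)
oracle_enumerate <- function(ch, i, j) {
  if (j - i < 4) return(list(NULL))
  out <- oracle_enumerate(ch, i + 1, j)  # i unpaired
  for (k in (i + 4):j) {
    if (!oracle_can_pair(ch[i], ch[k])) next
    left <- oracle_enumerate(ch, i + 1, k - 1)
    right <- oracle_enumerate(ch, k + 1, j)
    for (L in left) for (R in right) {
      out[[length(out) + 1]] <- cbind(c(i, k), L, R)
    }
  }
  out
}

# energy of one complete structure by loop decomposition, independent of
# the dynamic programs: hairpin / stack / bulge / internal / multibranch
oracle_energy <- function(ch, pairs, par = mirweed::rna_energy_params()) {
  if (is.null(pairs) || ncol(pairs) == 0) return(0)
  lp <- par$loops
  ii <- pairs[1, ]; jj <- pairs[2, ]
  ord <- order(ii)
  ii <- ii[ord]; jj <- jj[ord]
  e <- 0
  for (p in seq_along(ii)) {
    i <- ii[p]; j <- jj[p]
    # children: pairs directly nested under (i, j)
    inside <- which(ii > i & jj < j)
    if (length(inside)) {
      nested_in_other <- vapply(inside, function(q) {
        any(ii[inside] < ii[q] & jj[inside] > jj[q])
      }, logical(1))
      inside <- inside[!nested_in_other]
    }
    if (length(inside) == 0) {
      e <- e + lp[["hairpin_a"]] + lp[["hairpin_b"]] * (j - i - 1 - 3)
    } else if (length(inside) == 1) {
      k <- ii[inside]; l <- jj[inside]
      l1 <- k - i - 1; l2 <- j - l - 1
      if (l1 == 0 && l2 == 0) {
        e <- e + par$stack[paste0(ch[i], ch[j]), paste0(ch[k], ch[l])]
      } else if (l1 == 0 || l2 == 0) {
        e <- e + lp[["bulge_a"]] + lp[["bulge_b"]] * (l1 + l2 - 1)
      } else {
        e <- e + lp[["internal_a"]] + lp[["internal_b"]] * (l1 + l2 - 2)
      }
    } else {
      covered <- unlist(lapply(inside, function(q) ii[q]:jj[q]))
      unpaired <- (j - i - 1) - length(covered)
      e <- e + lp[["multi_close"]] + lp[["multi_branch"]] * length(inside) +
        lp[["multi_unpaired"]] * unpaired
    }
  }
  e
}

# exhaustive-enumeration MFE (and optimal structure count); lengths <= ~20
oracle_enum_mfe <- function(seq) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  structs <- oracle_enumerate(ch, 1L, length(ch))
  energies <- vapply(structs, function(p) oracle_energy(ch, p), numeric(1))
  min(0, min(energies))
}

# --- mismatch-limited matching --------------------------------------------

# naive best Hamming hit of one tag over reference windows, sense only
oracle_hamming_best <- function(tag, refs, max_mm) {
  best <- list(mm = max_mm + 1L, ref = NA_integer_, pos = NA_integer_)
  tch <- strsplit(tag, "")[[1]]
  L <- length(tch)
  for (r in seq_along(refs)) {
    rch <- strsplit(refs[r], "")[[1]]
    if (length(rch) < L) next
    for (p in seq_len(length(rch) - L + 1)) {
      mm <- sum(tch != rch[p:(p + L - 1)])
      if (mm < best$mm) best <- list(mm = mm, ref = r, pos = p)
    }
  }
  if (is.na(best$ref)) return(NULL)
  best
}

# --- adapter trimming ------------------------------------------------------

# naive leftmost adapter-prefix scan (>= 8 nt of adapter, <= 1 mismatch)
oracle_trim_pos <- function(read, adapter) {
  k <- min(8L, nchar(adapter))
  probe <- strsplit(substr(adapter, 1, k), "")[[1]]
  rch <- strsplit(read, "")[[1]]
  if (length(rch) < k) return(NA_integer_)
  for (p in seq_len(length(rch) - k + 1)) {
    if (sum(rch[p:(p + k - 1)] != probe) <= 1) return(p)
  }
  NA_integer_
}

# --- Welch's t -------------------------------------------------------------

# textbook closed form: statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# --- target rules ----------------------------------------------------------

# direct evaluation of the five position rules from a state vector
oracle_rules_ok <- function(states) {
  mm <- states == "mismatch"
  pen <- ifelse(mm, 1, ifelse(states == "wobble", 0.5, 0))
  L <- length(states)
  runs <- rle(mm)
  sum(mm) <= 4 &&
    !any(runs$values & runs$lengths >= 3) &&
    sum(mm[1:min(9, L)]) <= 1 &&
    sum(mm[intersect(10:11, 1:L)]) == 0 &&
    sum(pen[1:min(12, L)]) <= 2.5
}

# states for a miRNA / site-window pair (site 5'->3', antiparallel duplex)
oracle_site_states <- function(mirna, site) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  s <- rev(strsplit(chartr("T", "U", toupper(site)), "")[[1]])
  mapply(function(a, b) {
    if (paste0(a, b) %in% c("AU", "UA", "GC", "CG")) "match"
    else if (paste0(a, b) %in% c("GU", "UG")) "wobble"
    else "mismatch"
  }, m, s, USE.NAMES = FALSE)
}
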