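# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# All maximal pure runs of `target` with at least `min_len` residues.
oracle_pure_runs <- function(seq, target, min_len) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == target) {
      j <- i
      while (j < n && chars[j + 1L] == target) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, data.frame(start = i, end = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

oracle_is_primitive <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L) {
      ok <- TRUE
      for (i in seq_len(u - p)) {
        if (substr(unit, i, i) != substr(unit, i + p, i + p)) { ok <- FALSE; break }
      }
      if (ok) return(FALSE)
    }
  }
  TRUE
}

# O(n^2 * u) tandem-array scanner: every (start, unit length) pair, primitive
# units only, >= 2 copies, maximal (no full copy before or after), phase
# anchored at the right edge of the periodicity.
oracle_tandem <- function(seq, min_unit = 2L, max_unit = 12L) {
  n <- nchar(seq)
  sub <- function(i, j) substr(seq, i, j)
  rows <- list()
  for (u in seq.int(min_unit, max_unit)) {
    if (2L * u > n) break
    for (i in seq_len(n - 2L * u + 1L)) {
      unit <- sub(i, i + u - 1L)
      if (!oracle_is_primitive(unit)) next
      k <- 1L
      while (i + (k + 1L) * u - 1L <= n &&
             sub(i + k * u, i + (k + 1L) * u - 1L) == unit) k <- k + 1L
      if (k < 2L) next
      if (i - u >= 1L && sub(i - u, i - 1L) == unit) next   # not maximal left
      after <- i + k * u
      if (after <= n && sub(after, after) == sub(after - u, after - u)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, start = i, copies = k, unit_len_aa = u,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(unit = character(0), start = integer(0),
                      copies = integer(0), unit_len_aa = integer(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$unit_len_aa), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Per-position window score, written independently of the vectorised scanner.
oracle_window_score <- function(window, pattern, w_high = 1.0, w_low = 0.25) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  wc <- strsplit(window, "", fixed = TRUE)[[1L]]
  num <- 0; den <- 0
  for (i in seq_along(pc)) {
    w <- if (pc[i] == ".") 0 else if (pc[i] %in% LETTERS) w_high else w_low
    den <- den + w
    if (w > 0 && toupper(wc[i]) == toupper(pc[i])) num <- num + w
  }
  num / den
}

# Two-sided Fisher exact p by explicit hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than the
# observed one. The (1 + 1e-7) relative slack matches the usual convention
# for comparing floating-point table probabilities.
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
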