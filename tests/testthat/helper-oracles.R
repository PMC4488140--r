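# Independent oracles used by the test suite. These deliberately use
# different algorithms / data structures from the package code paths
# they check.

# --- brute-force SSR scanner -------------------------------------------
# Maximal same-period chains found via run-length encoding of the
# shifted-equality vector, filtered by primitive leading unit and
# minimum repeat units; N never participates.
oracle_scan <- function(seq, min_units = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                           `5` = 4L, `6` = 4L)) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  out <- list()
  for (p in 2:6) {
    if (n < 2 * p) next
    eqv <- v[seq_len(n - p)] == v[seq_len(n - p) + p] &
      v[seq_len(n - p)] != "N" & v[seq_len(n - p) + p] != "N"
    r <- rle(eqv)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      chain <- r$lengths[k]          # matched offsets
      start <- pos[k]                # 1-based start of the run
      run_len <- chain + p           # total bases with period p
      units <- run_len %/% p
      if (units < min_units[[as.character(p)]]) next
      motif <- paste(v[start:(start + p - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      # primitivity via divisor check
      prim <- TRUE
      for (d in seq_len(p - 1L)) {
        if (p %% d != 0) next
        if (paste(rep(substr(motif, 1, d), p / d), collapse = "") == motif) {
          prim <- FALSE
          break
        }
      }
      if (!prim) next
      out[[length(out) + 1L]] <- data.frame(
        start = start - 1L, end = start - 1L + units * p,
        period = p, motif = motif, repeat_units = units,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), motif = character(),
                      repeat_units = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start, df$period), , drop = FALSE]
}

# --- classic Nussinov count (4-case recurrence) ------------------------
oracle_nussinov <- function(seq, min_loop = 3L) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  pairable <- function(a, b)
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  E <- matrix(0L, n, n)
  for (len in 2:n) for (i in seq_len(n - len + 1L)) {
    j <- i + len - 1L
    best <- max(E[i + 1L, j] * (i + 1L <= j),
                E[i, j - 1L] * (i <= j - 1L))
    if (j - i > min_loop && pairable(v[i], v[j]))
      best <- max(best, (if (j - 1L >= i + 1L) E[i + 1L, j - 1L] else 0L) + 1L)
    if (len > 2) for (k in i:(j - 1L))
      best <- max(best, E[i, k] + E[k + 1L, j])
    E[i, j] <- best
  }
  E[1, n]
}

# --- brute Hamming scan ------------------------------------------------
oracle_hamming <- function(pattern, text) {
  k <- nchar(pattern)
  n <- nchar(text)
  if (n < k) return(integer())
  vapply(1:(n - k + 1L), function(s) {
    a <- strsplit(substr(text, s, s + k - 1L), "")[[1]]
    b <- strsplit(pattern, "")[[1]]
    sum(a != b | a == "N" | b == "N")
  }, integer(1))
}

# --- exhaustive per-offset binding-site oracle -------------------------
# For every candidate (start, end) window, a plain recursive alignment
# enumerates achievable (mismatch, gap) pairs; qualifying ends are those
# whose minimum-cost alignment fits the budgets and matches the 3'
# anchor exactly.
oracle_site_ends <- function(pattern, text, MM = 3L, GG = 2L, anchor = 2L) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p)
  n <- length(t)
  # enumerate via explicit recursion with memo-free search (windows tiny)
  window_pairs <- function(tw) {
    res <- list()
    rec <- function(pi, ti, mm, g) {
      if (mm > MM + 2L * GG || g > GG) return()
      if (pi > m && ti > length(tw)) {
        res[[length(res) + 1L]] <<- c(mm, g)
        return()
      }
      anchored <- pi > m - anchor
      if (pi <= m && ti <= length(tw)) {
        if (p[pi] == tw[ti] && tw[ti] != "N") rec(pi + 1L, ti + 1L, mm, g)
        else if (!anchored) rec(pi + 1L, ti + 1L, mm + 1L, g)
      }
      if (!anchored) {
        if (pi <= m) rec(pi + 1L, ti, mm, g + 1L)       # primer base gapped
        if (ti <= length(tw)) rec(pi, ti + 1L, mm, g + 1L)  # inserted base
      }
    }
    rec(1L, 1L, 0L, 0L)
    res
  }
  ends <- list()
  for (jend in seq_len(n)) {
    best <- NULL
    for (L in max(1L, m - GG):(m + GG)) {
      s <- jend - L + 1L
      if (s < 1) next
      prs <- window_pairs(t[s:jend])
      for (pr in prs) {
        cost <- pr[1] + 2L * pr[2]
        if (is.null(best) || cost < best$cost)
          best <- list(mm = pr[1], g = pr[2], cost = cost)
        else if (cost == best$cost && pr[2] < best$g)
          best <- list(mm = pr[1], g = pr[2], cost = cost)
      }
    }
    if (!is.null(best) && best$mm <= MM && best$g <= GG)
      ends[[length(ends) + 1L]] <- data.frame(end = jend, cost = best$cost)
  }
  if (length(ends) == 0)
    return(data.frame(end = integer(), cost = integer()))
  do.call(rbind, ends)
}

# --- hand-written codon table for translation spot checks --------------
oracle_translate <- function(dna) {
  tab <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
           ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
           TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
           ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
           TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
           AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
           TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
           AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  codons <- substring(dna, seq(1, nchar(dna) - 2, 3),
                      seq(3, nchar(dna), 3))
  paste(tab[codons], collapse = "")
}

# random DNA string
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# compare two locus tables on the scanner's defining columns
expect_same_loci <- function(found, expected) {
  cols <- c("start", "end", "period", "motif", "repeat_units")
  f <- found[, cols]
  e <- expected[, cols]
  rownames(f) <- rownames(e) <- NULL
  expect_equal(f, e)
}
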