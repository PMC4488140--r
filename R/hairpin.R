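# Watson-Crick pairs plus the G:U (here G:T) wobble, DNA alphabet
can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Maximum base-pairing fold of a sequence
#'
#' Base-pair maximization (Watson--Crick plus G:U wobble, minimum loop
#' of `min_loop` unpaired bases) computed by dynamic programming over
#' subsequences, with a traceback returning one optimal set of nested
#' pairs. This is a secondary-structure stand-in chosen for determinism:
#' it maximizes the number of pairs, it does not model thermodynamics.
#'
#' @param seq DNA string (the pre-miRNA candidate window).
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return list: `n_pairs`, `pairs` (two-column matrix of 1-based
#'   partner positions), `paired_fraction`.
#' @export
fold_maxpair <- function(seq, min_loop = 3L) {
  v <- s2c(as.character(seq)[1])
  n <- length(v)
  if (n < min_loop + 2L)
    return(list(n_pairs = 0L, pairs = matrix(integer(), 0, 2),
                paired_fraction = 0))
  E <- matrix(0L, n, n)
  # E[i,j]: max pairs in v[i..j]; either j unpaired, or j pairs with k
  for (len in (min_loop + 2L):n) {
    i <- seq_len(n - len + 1L)
    j <- i + len - 1L
    for (a in seq_along(i)) {
      ii <- i[a]; jj <- j[a]
      best <- E[ii, jj - 1L]
      ks <- ii:(jj - min_loop - 1L)
      ks <- ks[can_pair(v[ks], v[jj])]
      if (length(ks)) {
        left <- ifelse(ks > ii, E[cbind(pmax(ii, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == ii] <- 0L
        inner <- E[cbind(ks + 1L, rep(jj - 1L, length(ks)))]
        best <- max(best, max(left + 1L + inner))
      }
      E[ii, jj] <- best
    }
  }
  pairs <- matrix(integer(), 0, 2)
  # iterative traceback over subproblem stack
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ii <- ij[1]; jj <- ij[2]
    if (jj - ii < min_loop + 1L) next
    if (E[ii, jj] == E[ii, jj - 1L]) {
      stack[[length(stack) + 1L]] <- c(ii, jj - 1L)
      next
    }
    ks <- ii:(jj - min_loop - 1L)
    ks <- ks[can_pair(v[ks], v[jj])]
    for (k in ks) {
      left <- if (k > ii) E[ii, k - 1L] else 0L
      inner <- if (jj - 1L >= k + 1L) E[k + 1L, jj - 1L] else 0L
      if (left + 1L + inner == E[ii, jj]) {
        pairs <- rbind(pairs, c(k, jj))
        if (k > ii) stack[[length(stack) + 1L]] <- c(ii, k - 1L)
        if (jj - 1L >= k + 1L) stack[[length(stack) + 1L]] <- c(k + 1L, jj - 1L)
        break
      }
    }
  }
  list(n_pairs = E[1, n], pairs = pairs,
       paired_fraction = 2 * E[1, n] / n)
}

#' Validate a candidate pre-miRNA hairpin window
#'
#' Folds the window by base-pair maximization ([fold_maxpair()]) and
#' calls the window a valid fold-back precursor iff (a) the overall
#' paired fraction is at least `min_paired_frac`, (b) at least
#' `min_mature_paired_frac` of the mature-site bases are paired, and (c)
#' those mature-site bases pair to one side only (the mature site sits
#' in a single stem arm). The fraction thresholds are tunable
#' stand-in choices, not thermodynamic quantities.
#'
#' @param window DNA string, 60--200 nt, centered on the mature-miRNA
#'   hit.
#' @param mature_offset 0-based offset of the mature site within the
#'   window.
#' @param mature_length mature-miRNA length in nt.
#' @param min_paired_frac minimum overall paired fraction.
#' @param min_mature_paired_frac minimum fraction of mature-site bases
#'   paired.
#' @param min_loop minimum hairpin loop size.
#' @return list: `valid`, `paired_fraction`, `mature_paired_fraction`,
#'   `single_arm`, `n_pairs`.
#' @export
validate_hairpin <- function(window, mature_offset, mature_length,
                             min_paired_frac = 0.55,
                             min_mature_paired_frac = 0.6,
                             min_loop = 3L) {
  window <- as.character(window)[1]
  n <- nchar(window)
  if (n < 60) stop("window too short (< 60 nt)")
  if (n > 200) stop("window too long (> 200 nt)")
  stopifnot(mature_offset >= 0,
            mature_offset + mature_length <= n)
  fold <- fold_maxpair(window, min_loop)
  mat_pos <- (mature_offset + 1L):(mature_offset + mature_length)
  partners <- rep(NA_integer_, n)
  if (nrow(fold$pairs)) {
    partners[fold$pairs[, 1]] <- fold$pairs[, 2]
    partners[fold$pairs[, 2]] <- fold$pairs[, 1]
  }
  mat_partners <- partners[mat_pos]
  mature_paired <- mean(!is.na(mat_partners))
  outside <- mat_partners[!is.na(mat_partners)]
  outside <- outside[!(outside %in% mat_pos)]
  single_arm <- length(outside) == 0 ||
    all(outside > max(mat_pos)) || all(outside < min(mat_pos))
  list(
    valid = fold$paired_fraction >= min_paired_frac &&
      mature_paired >= min_mature_paired_frac && single_arm,
    paired_fraction = fold$paired_fraction,
    mature_paired_fraction = mature_paired,
    single_arm = single_arm,
    n_pairs = fold$n_pairs
  )
}
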