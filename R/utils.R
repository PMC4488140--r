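#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over \code{A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @examples
#' revcomp_dna("ATGC")
#' @export
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; survey tables here use the
#' conventional round-half-away-from-zero (so 6.5 -> 7, 28.5 -> 29).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Integer percentage of a count over a total
#'
#' Computes `100 * count / total` rounded half away from zero to an
#' integer, the convention used throughout the summary tables.
#'
#' @param count numeric vector of counts.
#' @param total totals (recycled).
#' @return integer percentages.
#' @examples
#' pct_int(62690, 87396)  # 72
#' @export
pct_int <- function(count, total) {
  out <- rep(NA_real_, length(count))
  ok <- !is.na(total) & total > 0
  out[ok] <- round_half_away(100 * count[ok] / rep_len(total, length(count))[ok])
  out
}

#' Combine per-dataset integer percentages into an overall value
#'
#' The overall column of a multi-dataset survey table is the unweighted
#' arithmetic mean of the per-dataset integer percentages, rounded half
#' away from zero (not a pooled-count percentage).
#'
#' @param pcts numeric vector of per-dataset integer percentages.
#' @return single overall percentage.
#' @examples
#' combine_percent(c(72, 73, 44, 67))  # 64
#' @export
combine_percent <- function(pcts) {
  stopifnot(length(pcts) >= 1, !anyNA(pcts))
  round_half_away(mean(pcts))
}

#' SSR density as kbp per SSR
#'
#' @param total_bp total examined sequence length in bp.
#' @param n_ssrs number of SSRs found.
#' @return rounded integer kbp per SSR, or `NA` when `n_ssrs` is zero.
#' @examples
#' kbp_per_ssr(473e6, 87396)  # 5
#' @export
kbp_per_ssr <- function(total_bp, n_ssrs) {
  if (n_ssrs == 0) return(NA_real_)
  round_half_away((total_bp / 1000) / n_ssrs)
}

# coerce a sequence set (DNAStringSet or character) to a named
# character vector; base as.character() would drop character names
as_seqs <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

# split a DNA string into a single-character vector
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

c2s <- function(x) paste0(x, collapse = "")

# GC content (%) of a DNA string, N excluded from the denominator
gc_percent <- function(x) {
  v <- s2c(x)
  v <- v[v != "N"]
  if (length(v) == 0) return(NA_real_)
  100 * sum(v %in% c("G", "C")) / length(v)
}

# empty locus table with the canonical column set
empty_loci <- function() {
  data.frame(
    locus_id = character(), seq_id = character(),
    start = integer(), end = integer(),
    period = integer(), motif = character(),
    canonical_motif = character(), repeat_units = integer(),
    tract_length = integer(), is_compound = logical(),
    n_members = integer(), members = character(),
    stringsAsFactors = FALSE
  )
}
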