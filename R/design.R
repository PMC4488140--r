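#' Extract flanking sequence around an SSR locus
#'
#' Returns up to `flank_length` bp on each side of the repeat tract,
#' truncated at the sequence boundaries (truncation is flagged, not an
#' error). The concatenation left + tract + right always equals the
#' source subsequence.
#'
#' @param locus one locus row (from the locus table).
#' @param record source sequence (character string or
#'   [Biostrings::DNAStringSet] element).
#' @param flank_length flank length per side in bp.
#' @return list of class `flanked_locus`: `locus`, `left_flank`,
#'   `right_flank`, `tract`, `left_truncated`, `right_truncated`,
#'   `left_start` (0-based genomic start of the left flank).
#' @export
extract_flanks <- function(locus, record, flank_length = 200L) {
  seq <- as.character(record)[1]
  n <- nchar(seq)
  stopifnot(locus$start >= 0, locus$end <= n)
  left_start <- max(0L, locus$start - flank_length)
  right_end <- min(n, locus$end + flank_length)
  out <- list(
    locus = locus,
    left_flank = substr(seq, left_start + 1L, locus$start),
    right_flank = substr(seq, locus$end + 1L, right_end),
    tract = substr(seq, locus$start + 1L, locus$end),
    left_truncated = left_start > locus$start - flank_length ||
      locus$start < flank_length,
    right_truncated = right_end < locus$end + flank_length,
    left_start = left_start
  )
  class(out) <- "flanked_locus"
  out
}

#' Primer melting temperature (Wallace rule)
#'
#' Tm = 2(A+T) + 4(G+C) degrees C. Exact and deterministic; adequate for
#' the short (18--24 bp) primers designed here.
#'
#' @param primer character vector of primer sequences (length >= 8, no
#'   `N`).
#' @return numeric vector of melting temperatures in degrees C.
#' @examples
#' primer_tm("ACGTACGTACGTACGTACGT")  # 60
#' @export
primer_tm <- function(primer) {
  vapply(primer, function(p) {
    if (nchar(p) < 8) stop("primer shorter than 8 bp")
    if (grepl("N", p, fixed = TRUE)) stop("primer contains N")
    v <- s2c(p)
    2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Tm/GC for every window of lengths in len_range along a flank.
# Returns data.frame: start (0-based within flank), len, tm, gc.
candidate_windows <- function(flank, len_range) {
  n <- nchar(flank)
  if (n < len_range[1]) return(NULL)
  v <- s2c(flank)
  cum_at <- cumsum(v %in% c("A", "T"))
  cum_gc <- cumsum(v %in% c("G", "C"))
  cum_n <- cumsum(v == "N")
  out <- list()
  for (len in seq(len_range[1], min(len_range[2], n))) {
    starts <- 0:(n - len)
    at <- cum_at[starts + len] - c(0, cum_at)[starts + 1L]
    gc <- cum_gc[starts + len] - c(0, cum_gc)[starts + 1L]
    nn <- cum_n[starts + len] - c(0, cum_n)[starts + 1L]
    keep <- nn == 0
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[keep], len = len,
      tm = 2 * at[keep] + 4 * gc[keep],
      gc = 100 * gc[keep] / len
    )
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Design one primer pair for a flanked SSR locus
#'
#' Exhaustively scores every candidate window of the configured length
#' range in each flank. A compliant pair satisfies the Tm, GC and
#' product-size constraints; among compliant pairs the one minimizing
#' `|Tm_f - Tm_target| + |Tm_r - Tm_target|` (Tm_target = midpoint of
#' the Tm range) is returned, with ties broken by smaller product, then
#' leftmost forward window, then leftmost reverse window -- fully
#' deterministic. The repeat tract always lies strictly inside the
#' product. Failures are data, not errors: status
#' `failed(insufficient_flank)` when a flank is shorter than the minimum
#' primer length, `failed(no_compliant_pair)` when no window combination
#' complies.
#'
#' The expected product runs from the forward primer's 5' end to the
#' reverse primer's 5' end, inclusive.
#'
#' @param flanked a `flanked_locus` from [extract_flanks()].
#' @param config an [ssr_config()].
#' @return one-row data.frame: `status`, `reason`, `forward`, `reverse`
#'   (reverse given 5'->3' on the opposite strand), `tm_forward`,
#'   `tm_reverse`, `gc_forward`, `gc_reverse`, `expected_product`,
#'   `f_start`, `r_end` (0-based genomic coordinates of the product
#'   boundaries).
#' @export
design_primer_pair <- function(flanked, config = ssr_config()) {
  fail <- function(reason) data.frame(
    status = "failed", reason = reason,
    forward = NA_character_, reverse = NA_character_,
    tm_forward = NA_real_, tm_reverse = NA_real_,
    gc_forward = NA_real_, gc_reverse = NA_real_,
    expected_product = NA_integer_, f_start = NA_integer_,
    r_end = NA_integer_, stringsAsFactors = FALSE
  )
  lr <- config$primer_length_range
  if (nchar(flanked$left_flank) < lr[1] || nchar(flanked$right_flank) < lr[1])
    return(fail("insufficient_flank"))
  ok_win <- function(w) {
    w[w$tm >= config$primer_tm_range[1] & w$tm <= config$primer_tm_range[2] &
      w$gc >= config$primer_gc_range[1] & w$gc <= config$primer_gc_range[2],
      , drop = FALSE]
  }
  fw <- candidate_windows(flanked$left_flank, lr)
  rw <- candidate_windows(flanked$right_flank, lr)
  if (!is.null(fw)) fw <- ok_win(fw)
  if (!is.null(rw)) rw <- ok_win(rw)
  if (is.null(fw) || is.null(rw) || nrow(fw) == 0 || nrow(rw) == 0)
    return(fail("no_compliant_pair"))

  left_len <- nchar(flanked$left_flank)
  tract_len <- nchar(flanked$tract)
  # genomic coordinates (0-based) of window boundaries
  f_start <- flanked$left_start + fw$start
  r_end <- flanked$left_start + left_len + tract_len + rw$start + rw$len
  # all pairs: product size r_end - f_start, constraint + score
  prod <- outer(r_end, f_start, `-`)          # [reverse, forward]
  tm_target <- mean(config$primer_tm_range)
  score <- outer(abs(rw$tm - tm_target), abs(fw$tm - tm_target), `+`)
  ok <- prod >= config$product_size_range[1] &
    prod <= config$product_size_range[2]
  if (!any(ok)) return(fail("no_compliant_pair"))
  idx <- which(ok)
  ri <- ((idx - 1L) %% nrow(rw)) + 1L
  fi <- ((idx - 1L) %/% nrow(rw)) + 1L
  ord <- order(score[idx], prod[idx], f_start[fi], rw$start[ri])
  best <- ord[1]
  fi <- fi[best]; ri <- ri[best]
  fwd_seq <- substr(flanked$left_flank, fw$start[fi] + 1L,
                    fw$start[fi] + fw$len[fi])
  rev_win <- substr(flanked$right_flank, rw$start[ri] + 1L,
                    rw$start[ri] + rw$len[ri])
  f_start_best <- flanked$left_start + fw$start[fi]
  r_end_best <- flanked$left_start + left_len + tract_len +
    rw$start[ri] + rw$len[ri]
  data.frame(
    status = "designed", reason = NA_character_,
    forward = fwd_seq, reverse = revcomp_dna(rev_win),
    tm_forward = fw$tm[fi], tm_reverse = rw$tm[ri],
    gc_forward = fw$gc[fi], gc_reverse = rw$gc[ri],
    expected_product = r_end_best - f_start_best,
    f_start = f_start_best,
    r_end = r_end_best,
    stringsAsFactors = FALSE
  )
}

#' Design primers for every locus in a table
#'
#' Extracts flanks and designs a primer pair per locus, producing a
#' marker table (one row per locus, designed or failed).
#'
#' @param loci locus table.
#' @param seqs source sequence set ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param config an [ssr_config()].
#' @return marker data.frame: locus columns plus the primer columns of
#'   [design_primer_pair()], with `marker_id` equal to `locus_id`.
#' @export
design_markers <- function(loci, seqs, config = ssr_config()) {
  sv <- as_seqs(seqs)
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, , drop = FALSE]
    fl <- extract_flanks(locus, sv[[locus$seq_id]], config$flank_length)
    pp <- design_primer_pair(fl, config)
    cbind(marker_id = locus$locus_id, locus, pp, row.names = NULL)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$length_class <- length_class(out$tract_length)
  out$composition <- ifelse(out$is_compound, NA_character_,
                            composition_class(out$motif))
  out
}

#' Remove redundant primer pairs
#'
#' Two pairs are redundant iff their (forward, reverse) primer sequences
#' are identical after orientation normalization (a pair is also matched
#' against its forward/reverse swap). The first occurrence in input
#' order is kept. Idempotent.
#'
#' @param markers marker table with `forward` / `reverse` columns; rows
#'   with failed design pass through unchanged (they carry no primers).
#' @return list with `markers` (non-redundant table) and `report`
#'   (data.frame: input_pairs, kept, removed, retention_pct).
#' @examples
#' \dontrun{
#' dd <- deduplicate_primers(designed)
#' dd$report$retention_pct
#' }
#' @export
deduplicate_primers <- function(markers) {
  designed <- !is.na(markers$forward)
  key <- rep(NA_character_, nrow(markers))
  key[designed] <- paste(
    pmin(markers$forward[designed], markers$reverse[designed]),
    pmax(markers$forward[designed], markers$reverse[designed])
  )
  dup <- designed & duplicated(key) & !is.na(key)
  kept <- markers[!dup, , drop = FALSE]
  n_in <- sum(designed)
  n_kept <- n_in - sum(dup)
  list(
    markers = kept,
    report = data.frame(
      input_pairs = n_in, kept = n_kept, removed = sum(dup),
      retention_pct = pct_int(n_kept, n_in)
    )
  )
}

#' Export designed primers as FASTA
#'
#' @param markers marker table with designed primers.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_primer_fasta <- function(markers, path) {
  ok <- markers[!is.na(markers$forward), , drop = FALSE]
  seqs <- as.vector(rbind(ok$forward, ok$reverse))
  names(seqs) <- as.vector(rbind(paste0(ok$marker_id, "_F"),
                                 paste0(ok$marker_id, "_R")))
  write_fasta(seqs, path)
}
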