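#' Canonical motif of an SSR repeat unit
#'
#' The family representative of a motif is the lexicographically smallest
#' string among all cyclic rotations of the motif and all cyclic
#' rotations of its reverse complement, so e.g. `TC`, `CT`, `GA` and
#' `AG` all canonicalize to `AG`. Deterministic and idempotent.
#'
#' @param motif character vector of primitive repeat units (length 2--6,
#'   over `A,C,G,T`).
#' @return character vector of canonical motifs.
#' @examples
#' canonical_motif(c("TC", "AT", "GGC"))
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    if (grepl("[^ACGT]", m)) stop("motif must be over ACGT: ", m)
    if (!is_primitive(m)) stop("motif is not primitive: ", m)
    min(c(rotations(m), rotations(revcomp_dna(m))))
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  n <- nchar(m)
  v <- s2c(m)
  vapply(seq_len(n), function(i) c2s(v[((seq_len(n) + i - 2) %% n) + 1]),
         character(1))
}

# TRUE when the motif is not a repetition of any shorter unit
is_primitive <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1)) {
    if (n %% d != 0) next
    unit <- substr(m, 1, d)
    if (c2s(rep(unit, n / d)) == m) return(FALSE)
  }
  TRUE
}

#' Detect perfect SSRs in one sequence
#'
#' MISA-style scan for perfect di- to hexanucleotide repeats. Each
#' maximal repeat run is reported exactly once at its smallest period
#' (primitive motif), with the leftmost phase and the number of complete
#' repeat units; tracts never span `N`. Mononucleotide runs are not
#' searched. The minimum repeat units per period come from the
#' configuration (defaults 6/5/5/4/4 for periods 2--6).
#'
#' @param record a single DNA sequence: character string, or a
#'   length-one [Biostrings::DNAStringSet] / element thereof.
#' @param config an [ssr_config()].
#' @param seq_id sequence id used in the locus table (defaults to the
#'   record name or `"seq"`).
#' @return data.frame of simple loci sorted by start: `locus_id, seq_id,
#'   start, end` (0-based half-open), `period, motif, canonical_motif,
#'   repeat_units, tract_length, is_compound, n_members, members`.
#' @examples
#' find_perfect_ssrs("CCCATATATATATATCCC", ssr_config(), "demo")
#' @export
find_perfect_ssrs <- function(record, config = ssr_config(), seq_id = NULL) {
  if (inherits(record, "DNAStringSet") || inherits(record, "DNAString")) {
    if (is.null(seq_id) && !is.null(names(record))) seq_id <- names(record)[1]
    record <- as.character(record)[1]
  }
  if (is.null(seq_id)) seq_id <- if (!is.null(names(record))) names(record) else "seq"
  seq <- unname(record)
  rows <- list()
  for (p in 2:6) {
    min_units <- config$min_repeat_units[[as.character(p)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, min_units - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (k in seq_along(starts)) {
      motif <- substr(seq, starts[k], starts[k] + p - 1L)
      if (!is_primitive(motif)) next  # reported at its smallest period
      units <- lens[k] %/% p
      tract <- units * p
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id,
        start = starts[k] - 1L,
        end = starts[k] - 1L + tract,
        period = p,
        motif = motif,
        repeat_units = units,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty_loci())
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$period), , drop = FALSE]
  data.frame(
    locus_id = sprintf("%s_ssr%04d", seq_id, seq_len(nrow(df))),
    seq_id = df$seq_id,
    start = df$start, end = df$end,
    period = df$period, motif = df$motif,
    canonical_motif = canonical_motif(df$motif),
    repeat_units = df$repeat_units,
    tract_length = df$end - df$start,
    is_compound = FALSE,
    n_members = NA_integer_,
    members = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Scan a whole sequence set for perfect SSRs
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @inheritParams find_perfect_ssrs
#' @return combined locus table over all sequences.
#' @export
scan_ssrs <- function(seqs, config = ssr_config()) {
  sv <- as_seqs(seqs)
  ids <- names(sv)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sv))
  out <- lapply(seq_along(sv), function(i)
    find_perfect_ssrs(sv[[i]], config, seq_id = ids[i]))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Merge zero-gap adjacent SSRs into compound loci
#'
#' Maximal runs of two or more loci on the same sequence whose
#' consecutive gaps are exactly 0 bp (no interrupting nucleotides) become
#' one compound locus retaining its members; all other loci pass through
#' unchanged. Abutting same-motif runs cannot occur (the scanner reports
#' maximal runs), so compounds always join different motifs.
#'
#' @param loci simple-locus table from [find_perfect_ssrs()] /
#'   [scan_ssrs()].
#' @return locus table where compound rows have `is_compound = TRUE`,
#'   `members` encoded as `"MOTIF:units;MOTIF:units"`, and `NA` period /
#'   repeat_units.
#' @export
merge_compound <- function(loci) {
  if (nrow(loci) <= 1) return(loci)
  loci <- loci[order(loci$seq_id, loci$start), , drop = FALSE]
  same_seq <- loci$seq_id[-1] == loci$seq_id[-nrow(loci)]
  if (any(same_seq & loci$start[-1] < loci$end[-nrow(loci)]))
    stop("overlapping input loci: scanner invariant violated")
  gap0 <- same_seq & (loci$start[-1] == loci$end[-nrow(loci)])
  grp <- cumsum(c(TRUE, !gap0))
  out <- lapply(split(seq_len(nrow(loci)), grp), function(idx) {
    block <- loci[idx, , drop = FALSE]
    if (nrow(block) == 1) return(block)
    data.frame(
      locus_id = block$locus_id[1],
      seq_id = block$seq_id[1],
      start = block$start[1], end = block$end[nrow(block)],
      period = NA_integer_,
      motif = paste0("(", block$motif, ")", block$repeat_units,
                     collapse = ""),
      canonical_motif = NA_character_,
      repeat_units = NA_integer_,
      tract_length = block$end[nrow(block)] - block$start[1],
      is_compound = TRUE,
      n_members = nrow(block),
      members = paste(block$motif, block$repeat_units, sep = ":",
                      collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Per-dataset SSR density summary
#'
#' Survey-table statistics for one dataset: sequences examined, total
#' size, SSR counts, sequences with (multiple) SSRs, SSRs in compound
#' formation, and densities. Compound loci count once in `total_ssrs`;
#' their members are additionally tallied in
#' `compound_member_count` and in `total_ssrs_counting_members`.
#' `kbp_per_ssr` is rounded to the nearest integer; `ssr_per_mbp` is
#' unrounded. With zero loci the density fields are `NA`, not infinite.
#'
#' @param loci locus table (after [merge_compound()] if compound
#'   statistics are wanted).
#' @param seqs the scanned sequence set.
#' @param dataset_tag dataset label for the report.
#' @return one-row data.frame of summary fields.
#' @export
summarize_density <- function(loci, seqs, dataset_tag = "other") {
  sv <- as_seqs(seqs)
  total_bp <- sum(nchar(sv))
  per_seq <- table(factor(loci$seq_id, levels = unique(loci$seq_id)))
  n_members <- ifelse(loci$is_compound, loci$n_members, 1L)
  data.frame(
    dataset_tag = dataset_tag,
    sequences_examined = length(sv),
    total_bp = total_bp,
    total_ssrs = nrow(loci),
    total_ssrs_counting_members = sum(n_members),
    sequences_with_ssr = length(unique(loci$seq_id)),
    sequences_with_multiple_ssr = sum(per_seq > 1),
    compound_loci = sum(loci$is_compound),
    compound_member_count = sum(loci$n_members[loci$is_compound]),
    kbp_per_ssr = kbp_per_ssr(total_bp, nrow(loci)),
    ssr_per_mbp = if (nrow(loci) == 0) NA_real_ else
      nrow(loci) / (total_bp / 1e6),
    stringsAsFactors = FALSE
  )
}
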