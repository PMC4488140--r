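#' Read a multi-FASTA DNA sequence set
#'
#' Sequences are uppercased on ingest; any character outside
#' \code{A,C,G,T,N} (including other IUPAC ambiguity codes) is coerced to
#' `N` with a warning giving the number of replaced characters. Record
#' ids are the first whitespace-delimited token of the header and must be
#' unique.
#'
#' @param path FASTA file path.
#' @param dataset_tag one of `"AA"`, `"BB"`, `"EST"`, `"GSS"`, `"other"`.
#' @return a [Biostrings::DNAStringSet] named by record id, with the
#'   dataset tag in `metadata(x)$dataset_tag`.
#' @export
read_fasta <- function(path, dataset_tag = c("other", "AA", "BB", "EST", "GSS")) {
  dataset_tag <- match.arg(dataset_tag)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seqs), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1)))
  if (n_bad > 0) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_bad, " non-ACGTN character(s) coerced to N in ", path)
  }
  if (any(nchar(seqs) < 1)) stop("zero-length sequence in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$dataset_tag <- dataset_tag
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' End-clean EST sequences
#'
#' Simplified EST end cleanup: terminal `N` runs of any length are
#' removed, together with 3' poly-A and 5' poly-T tails of at least
#' `min_tail` bp (the orientation a poly-A mRNA tail takes on either
#' strand). Trimming is iterated to a fixed point, so the operation is
#' idempotent. Records shorter than `min_keep` bp after trimming are
#' dropped and reported, not errored.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector) of
#'   EST sequences.
#' @param min_tail minimum terminal homopolymer run length to trim (bp).
#' @param min_keep minimum retained length (bp); shorter records are
#'   dropped.
#' @return list with `seqs` (trimmed `DNAStringSet`) and `report`
#'   (data.frame: id, input_length, trimmed_length, dropped).
#' @export
trim_est <- function(seqs, min_tail = 8L, min_keep = 100L) {
  sv <- as_seqs(seqs)
  if (is.null(names(sv))) names(sv) <- paste0("est", seq_along(sv))
  trim1 <- function(s) {
    repeat {
      old <- s
      s <- sub("^N+", "", s)
      s <- sub("N+$", "", s)
      s <- sub(sprintf("^T{%d,}", min_tail), "", s)
      s <- sub(sprintf("A{%d,}$", min_tail), "", s)
      if (identical(s, old)) return(s)
    }
  }
  trimmed <- vapply(sv, trim1, character(1))
  keep <- nchar(trimmed) >= min_keep
  report <- data.frame(
    id = names(sv),
    input_length = nchar(sv),
    trimmed_length = nchar(trimmed),
    dropped = !keep,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- Biostrings::DNAStringSet(trimmed[keep])
  list(seqs = out, report = report)
}

#' Write SSR loci as GFF3
#'
#' One `microsatellite` feature per locus. Internal coordinates are
#' 0-based half-open; GFF3 output is 1-based inclusive. Attributes carry
#' the locus id, motif, canonical motif, period, repeat count, length
#' class, composition and compound structure.
#'
#' @param loci locus table from [find_perfect_ssrs()] /
#'   [merge_compound()].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_ssr_gff3()] for the inverse.
#' @export
write_ssr_gff3 <- function(loci, path) {
  if (nrow(loci) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$seq_id,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = "+"
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "ssrmine",
    type = "microsatellite",
    ID = loci$locus_id,
    motif = loci$motif,
    canonical_motif = ifelse(is.na(loci$canonical_motif), ".",
                             loci$canonical_motif),
    period = ifelse(is.na(loci$period), ".", as.character(loci$period)),
    repeat_units = ifelse(is.na(loci$repeat_units), ".",
                          as.character(loci$repeat_units)),
    length_class = length_class(loci$tract_length),
    composition = ifelse(loci$is_compound, ".",
                         composition_class(loci$motif)),
    is_compound = as.character(loci$is_compound),
    members = ifelse(is.na(loci$members), ".", loci$members)
  )
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read SSR loci back from GFF3
#'
#' @param path GFF3 file written by [write_ssr_gff3()].
#' @return a locus table in the same form [find_perfect_ssrs()] returns.
#' @export
read_ssr_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_loci())
  mc <- S4Vectors::mcols(gr)
  dot_na <- function(x) ifelse(x == ".", NA_character_, x)
  data.frame(
    locus_id = as.character(mc$ID),
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    period = as.integer(suppressWarnings(as.integer(dot_na(mc$period)))),
    motif = as.character(mc$motif),
    canonical_motif = dot_na(as.character(mc$canonical_motif)),
    repeat_units = as.integer(
      suppressWarnings(as.integer(dot_na(mc$repeat_units)))),
    tract_length = GenomicRanges::width(gr),
    is_compound = as.logical(mc$is_compound),
    n_members = ifelse(is.na(dot_na(mc$members)), NA_integer_,
                       lengths(strsplit(dot_na(mc$members), ";", fixed = TRUE))),
    members = dot_na(as.character(mc$members)),
    stringsAsFactors = FALSE
  )
}

marker_table_columns <- c(
  "marker_id", "seq_id", "start", "end", "motif", "canonical_motif",
  "period", "repeat_units", "tract_length", "length_class", "composition",
  "is_compound", "forward", "reverse", "tm_forward", "tm_reverse",
  "gc_forward", "gc_reverse", "expected_product", "status", "reason",
  "map_status", "chromosome", "transferability_count", "polymorphism",
  "te_associated", "te_family", "mirna_associated", "function_category"
)

#' Write / read the flat marker table
#'
#' Tab-delimited, one row per marker, with locus coordinates (1-based
#' inclusive in the file), primer sequences and properties, and the
#' evaluation flags produced by the mapping, transferability and
#' association stages. Markers whose primer design or mapping failed keep
#' their row with the corresponding status values.
#'
#' @param markers marker data.frame (missing evaluation columns are
#'   filled with `NA`).
#' @param path output TSV path.
#' @return `write_marker_table` returns `path` invisibly;
#'   `read_marker_table` returns the marker data.frame.
#' @export
write_marker_table <- function(markers, path) {
  out <- markers
  for (col in marker_table_columns)
    if (is.null(out[[col]])) out[[col]] <- NA
  out <- out[, marker_table_columns]
  out$start <- out$start + 1L  # serialized 1-based inclusive
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(identical(names(df), marker_table_columns))
  df$start <- df$start - 1L
  df
}
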