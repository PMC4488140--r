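#' Six-frame translation
#'
#' Translates a DNA string in frames +1..+3 and -1..-3 (reverse-strand
#' frames are forward translations of the reverse complement) under the
#' standard genetic code. Stops appear as `*`; codons containing `N` or
#' other ambiguity translate to `X` when unresolvable.
#'
#' @param dna DNA string (length >= 3).
#' @return named character vector of 6 peptides (`"+1"`, `"+2"`, `"+3"`,
#'   `"-1"`, `"-2"`, `"-3"`).
#' @examples
#' translate_six_frames("ATGGCC")[["+1"]]  # "MA"
#' @export
translate_six_frames <- function(dna) {
  dna <- as.character(dna)[1]
  stopifnot(nchar(dna) >= 3)
  one <- function(s, off) {
    s <- substr(s, off, nchar(s))
    s <- substr(s, 1, (nchar(s) %/% 3) * 3)
    if (nchar(s) < 3) return("")
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(s), if.fuzzy.codon = "solve")))
  }
  rc <- revcomp_dna(dna)
  c(`+1` = one(dna, 1), `+2` = one(dna, 2), `+3` = one(dna, 3),
    `-1` = one(rc, 1), `-2` = one(rc, 2), `-3` = one(rc, 3))
}

# Karlin-Altschul E-value with standard ungapped BLOSUM62 parameters
karlin_altschul_evalue <- function(score, m, n,
                                   lambda = 0.3176, K = 0.134) {
  K * m * n * exp(-lambda * score)
}

#' Transposable-element association of a flanked SSR locus
#'
#' Translated (six-frame) local-alignment search of the flanks + tract
#' region against a protein library of TE families: Smith--Waterman with
#' BLOSUM62, gap open 11 / extend 1 (via
#' [Biostrings::pairwiseAlignment]). The single best-scoring alignment
#' (ties: first library entry) is reported as a hit iff its identity over
#' the aligned region is at least `min_identity` percent and its
#' Karlin--Altschul E-value (ungapped-parameter approximation over the
#' searched space) is at most `max_evalue`. The TE family is parsed from
#' the library entry's header `Class/Family` token (e.g. `LTR/Copia`).
#'
#' @param flanked a `flanked_locus` from [extract_flanks()], or a DNA
#'   character string to search as-is.
#' @param te_proteins protein library as [Biostrings::AAStringSet] (or
#'   named character vector).
#' @param min_identity minimum percent identity.
#' @param max_evalue maximum E-value.
#' @return one-row data.frame (`te_id`, `te_family`, `frame`,
#'   `identity`, `alignment_length`, `score`, `e_value`) or a zero-row
#'   data.frame when there is no qualifying hit.
#' @export
te_association <- function(flanked, te_proteins, min_identity = 65,
                           max_evalue = 1e-10) {
  no_hit <- data.frame(te_id = character(), te_family = character(),
                       frame = character(), identity = numeric(),
                       alignment_length = integer(), score = numeric(),
                       e_value = numeric(), stringsAsFactors = FALSE)
  if (length(te_proteins) == 0) return(no_hit)
  region <- if (inherits(flanked, "flanked_locus"))
    paste0(flanked$left_flank, flanked$tract, flanked$right_flank) else
      as.character(flanked)[1]
  lib <- as.character(te_proteins)
  if (is.null(names(lib))) names(lib) <- paste0("te", seq_along(lib))
  peptides <- translate_six_frames(region)
  peptides <- peptides[nchar(peptides) > 0]
  m_space <- sum(nchar(peptides))
  n_space <- sum(nchar(lib))
  best <- NULL
  for (frame in names(peptides)) {
    pep <- Biostrings::AAString(peptides[[frame]])
    for (k in seq_along(lib)) {
      aln <- Biostrings::pairwiseAlignment(
        pep, Biostrings::AAString(lib[[k]]), type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, scoreOnly = FALSE)
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, frame = frame, k = k, aln = aln)
      }
    }
  }
  aln <- best$aln
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  identity <- Biostrings::pid(aln, type = "PID1")
  ev <- karlin_altschul_evalue(best$score, m_space, n_space)
  if (identity < min_identity || ev > max_evalue) return(no_hit)
  hdr <- names(lib)[best$k]
  data.frame(
    te_id = sub("[#\\s].*$", "", hdr, perl = TRUE),
    te_family = te_family_from_header(hdr),
    frame = best$frame, identity = identity,
    alignment_length = alen, score = best$score, e_value = ev,
    stringsAsFactors = FALSE
  )
}

# "Class/Family" token from a FASTA header, split on whitespace or '#'
te_family_from_header <- function(hdr) {
  tokens <- unlist(strsplit(hdr, "[#\\s]+", perl = TRUE))
  fam <- grep("/", tokens, fixed = FALSE, value = TRUE)
  if (length(fam)) fam[1] else NA_character_
}

# positions (0-based) and mismatch counts of an ungapped full-length
# scan of `pattern` along `text`; N never matches
hamming_scan <- function(pattern, text) {
  k <- nchar(pattern)
  n <- nchar(text)
  if (n < k) return(data.frame(offset = integer(), mismatches = integer()))
  pv <- s2c(pattern)
  tv <- s2c(text)
  mm <- integer(n - k + 1L)
  for (i in seq_len(k)) {
    seg <- tv[i:(n - k + i)]
    mm <- mm + as.integer(seg != pv[i] | seg == "N" | pv[i] == "N")
  }
  data.frame(offset = 0:(n - k), mismatches = mm)
}

#' miRNA association of a flanked SSR locus
#'
#' Ungapped full-length scan of each mature miRNA (and its reverse
#' complement) along the flanks + tract region; matches with at most
#' `max_mm` mismatches are reported with their exact offset. Mature
#' sequences are DNA-ized (`U` -> `T`) on ingest.
#'
#' @param flanked a `flanked_locus` or a DNA character string.
#' @param mature_mirnas mature miRNA set ([Biostrings::DNAStringSet],
#'   [Biostrings::RNAStringSet] or named character vector), typically
#'   18--26 nt.
#' @param max_mm maximum number of mismatches (default 4).
#' @return data.frame: `mirna_id`, `strand`, `offset` (0-based within
#'   the scanned region), `mismatches`.
#' @export
mirna_association <- function(flanked, mature_mirnas, max_mm = 4L) {
  region <- if (inherits(flanked, "flanked_locus"))
    paste0(flanked$left_flank, flanked$tract, flanked$right_flank) else
      as.character(flanked)[1]
  mat <- toupper(as.character(mature_mirnas))
  mat <- gsub("U", "T", mat, fixed = TRUE)
  if (is.null(names(mat))) names(mat) <- paste0("mirna", seq_along(mat))
  out <- list()
  for (id in names(mat)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") mat[[id]] else revcomp_dna(mat[[id]])
      hits <- hamming_scan(pat, region)
      hits <- hits[hits$mismatches <= max_mm, , drop = FALSE]
      if (nrow(hits))
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = id, strand = strand, offset = hits$offset,
          mismatches = hits$mismatches, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(mirna_id = character(), strand = character(),
                      offset = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Categorize a functional-annotation string
#'
#' Case-insensitive keyword mapping of externally supplied annotation
#' descriptions into five categories (plus `non_functional` for absent
#' annotation). Keyword lists are configurable; matching is checked in
#' the order hypothetical/uncharacterized, stress-related, transcription
#' factor, housekeeping, with unmatched strings falling into `other`.
#'
#' @param description character vector of annotation strings; `NA` or
#'   empty means no annotation.
#' @param keywords named list of regular expressions per category.
#' @return character vector of categories.
#' @examples
#' categorize_annotation(c("hypothetical protein", "heat shock protein 70", NA))
#' @export
categorize_annotation <- function(description,
    keywords = list(
      hypothetical_uncharacterized =
        "hypothetical|putative|uncharacterized|unknown",
      stress_related =
        "heat shock|pathogenesis|drought|osmotic|dehydrin|stress|cold[ -]induced",
      transcription_factor =
        "transcription factor|zinc finger|\\bMYB\\b|\\bWRKY\\b|\\bbZIP\\b|homeobox",
      housekeeping =
        "ribosomal|actin|tubulin|histone|ubiquitin|elongation factor|ATP synthase|cytochrome|polymerase|kinase|ATPase"
    )) {
  vapply(description, function(d) {
    if (is.na(d) || !nzchar(trimws(d))) return("non_functional")
    for (cat in names(keywords))
      if (grepl(keywords[[cat]], d, ignore.case = TRUE, perl = TRUE))
        return(cat)
    "other"
  }, character(1), USE.NAMES = FALSE)
}
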