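#' Generate a random background genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc` (split evenly within the AT and
#' GC pairs). With `repeat_free = TRUE`, windows containing accidental
#' qualifying SSRs are redrawn until the scanner finds none, so planted
#' elements are the only repeats present.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; identical seeds give identical sequences.
#' @param repeat_free redraw accidental SSRs away.
#' @param id sequence id.
#' @param config scanner configuration used for the repeat-free check.
#' @return a length-one named [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(length, gc = 0.39, seed = 1L,
                            repeat_free = FALSE, id = "chr1",
                            config = ssr_config()) {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  v <- sample(names(probs), length, replace = TRUE, prob = probs)
  seq <- c2s(v)
  if (repeat_free) {
    for (iter in 1:50) {
      loci <- find_perfect_ssrs(seq, config, seq_id = id)
      if (nrow(loci) == 0) break
      vv <- s2c(seq)
      for (r in seq_len(nrow(loci))) {
        idx <- (loci$start[r] + 1L):loci$end[r]
        vv[idx] <- sample(names(probs), length(idx), replace = TRUE,
                          prob = probs)
      }
      seq <- c2s(vv)
    }
    if (nrow(find_perfect_ssrs(seq, config, seq_id = id)) > 0)
      stop("could not generate a repeat-free background")
  }
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- id
  out
}

#' Build planting payloads
#'
#' `ssr_payload` is a perfect repeat tract; `te_payload` reverse
#' translates a protein fragment with fixed codons (one codon per amino
#' acid, deterministic) so a translated search recovers it at 100%
#' identity; `hairpin_payload` builds a fold-back precursor
#' `arm + loop + reverse-complement(arm)` with the mature sequence in
#' the 5' arm.
#'
#' @param motif,units SSR motif and repeat count.
#' @return character payload sequence. For `hairpin_payload`, attributes
#'   `mature_offset` and `mature_length` locate the mature site.
#' @export
ssr_payload <- function(motif, units) c2s(rep(motif, units))

#' @rdname ssr_payload
#' @param protein amino-acid string (no stops).
#' @export
te_payload <- function(protein) {
  codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
             Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
             L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
             S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  aa <- s2c(protein)
  stopifnot(all(aa %in% names(codon)))
  c2s(codon[aa])
}

#' @rdname ssr_payload
#' @param mature mature miRNA sequence (DNA alphabet).
#' @param arm5_pad,loop random-free padding before the mature site in
#'   the 5' arm and the loop sequence.
#' @export
hairpin_payload <- function(mature, arm5_pad = "GCGAG", loop = "TTCG") {
  mature <- gsub("U", "T", toupper(mature), fixed = TRUE)
  arm <- paste0(arm5_pad, mature, "CTCGC")
  out <- paste0(arm, loop, revcomp_dna(arm))
  attr(out, "mature_offset") <- nchar(arm5_pad)
  attr(out, "mature_length") <- nchar(mature)
  out
}

#' Plant elements into a background genome
#'
#' Payloads overwrite the background at the stated positions (0-based);
#' planted intervals must not overlap. For SSR payloads the single base
#' on each side of the tract is adjusted, if necessary, so the planted
#' repeat cannot extend into the background by chance (coordinates in
#' the truth table stay exact).
#'
#' @param genome length-one [Biostrings::DNAStringSet] (or character).
#' @param specs data.frame with columns `kind`
#'   (`ssr`/`te_fragment`/`mirna_hairpin`), `position` (0-based),
#'   `payload` (sequence string) and optional `motif`, `units`,
#'   `mature_offset`, `mature_length`, `label`.
#' @return list: `genome` (planted `DNAStringSet`), `truth` (data.frame
#'   with kind, 0-based half-open coordinates and parameters).
#' @export
plant_elements <- function(genome, specs) {
  seq <- as.character(genome)[1]
  id <- if (!is.null(names(genome))) names(genome)[1] else "chr1"
  n <- nchar(seq)
  specs <- specs[order(specs$position), , drop = FALSE]
  starts <- specs$position
  ends <- starts + nchar(specs$payload)
  if (any(ends > n) || any(starts < 0)) stop("planted element out of bounds")
  if (nrow(specs) > 1 && any(starts[-1] < ends[-nrow(specs)]))
    stop("planted elements overlap")
  v <- s2c(seq)
  for (r in seq_len(nrow(specs))) {
    idx <- (starts[r] + 1L):ends[r]
    v[idx] <- s2c(specs$payload[r])
    if (specs$kind[r] == "ssr") {
      p <- nchar(specs$motif[r])
      # break same-period chain extension at both tract boundaries
      if (starts[r] >= 1 && v[starts[r]] == v[starts[r] + p])
        v[starts[r]] <- setdiff(c("A", "C", "G", "T"),
                                c(v[starts[r] + p]))[1]
      if (ends[r] < n && v[ends[r] + 1L] == v[ends[r] + 1L - p])
        v[ends[r] + 1L] <- setdiff(c("A", "C", "G", "T"),
                                   c(v[ends[r] + 1L - p]))[1]
    }
  }
  out <- Biostrings::DNAStringSet(c2s(v))
  names(out) <- id
  truth <- data.frame(
    label = if (!is.null(specs$label)) specs$label else
      sprintf("%s_%03d", specs$kind, seq_len(nrow(specs))),
    kind = specs$kind, seq_id = id,
    start = starts, end = ends,
    motif = if (!is.null(specs$motif)) specs$motif else NA_character_,
    units = if (!is.null(specs$units)) specs$units else NA_integer_,
    mature_offset = if (!is.null(specs$mature_offset))
      specs$mature_offset else NA_integer_,
    mature_length = if (!is.null(specs$mature_length))
      specs$mature_length else NA_integer_,
    stringsAsFactors = FALSE
  )
  list(genome = out, truth = truth)
}

#' Diverge a genome by random substitutions and indels
#'
#' Per-base substitution with probability `sub_rate` (uniform over the
#' three alternatives) and per-base indel initiation with probability
#' `indel_rate`; indel lengths are geometric with mean 2, insertions and
#' deletions equally likely. Seeded and reproducible.
#'
#' @param genome sequence set ([Biostrings::DNAStringSet] or character).
#' @param sub_rate,indel_rate per-base rates in \[0, 0.5\].
#' @param seed integer seed.
#' @return diverged [Biostrings::DNAStringSet] with the same names.
#' @export
diverge_genome <- function(genome, sub_rate, indel_rate = 0, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  set.seed(seed)
  sv <- as_seqs(genome)
  bases <- c("A", "C", "G", "T")
  out <- vapply(sv, function(seq) {
    v <- s2c(seq)
    n <- length(v)
    if (sub_rate > 0) {
      hit <- which(runif(n) < sub_rate)
      if (length(hit)) {
        repl <- vapply(v[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1))
        v[hit] <- repl
      }
    }
    if (indel_rate > 0) {
      sites <- which(runif(n) < indel_rate)
      if (length(sites)) {
        # process right-to-left so earlier coordinates stay valid
        for (s in rev(sites)) {
          len <- rgeom(1, 0.5) + 1L
          if (runif(1) < 0.5) {  # deletion
            del <- s:min(n, s + len - 1L)
            v <- v[-del]
          } else {               # insertion
            ins <- sample(bases, len, replace = TRUE)
            v <- append(v, ins, after = s)
          }
          n <- length(v)
        }
      }
    }
    c2s(v)
  }, character(1))
  res <- Biostrings::DNAStringSet(unname(out))
  names(res) <- names(sv)
  res
}

#' Simulate a diploid genotype table from known allele frequencies
#'
#' Each accession draws two alleles i.i.d. from the marker's frequency
#' vector.
#'
#' @param freqs named list of per-marker frequency vectors (names =
#'   allele sizes in bp; each vector sums to 1).
#' @param n_accessions number of accessions.
#' @param seed integer seed.
#' @return genotype table in the long format of
#'   [read_genotype_table()].
#' @export
generate_genotypes <- function(freqs, n_accessions, seed = 1L) {
  stopifnot(all(abs(vapply(freqs, sum, numeric(1)) - 1) < 1e-9))
  set.seed(seed)
  if (is.null(names(freqs))) names(freqs) <- paste0("M", seq_along(freqs))
  rows <- list()
  for (m in names(freqs)) {
    sizes <- names(freqs[[m]])
    for (a in seq_len(n_accessions)) {
      pick <- sample(sizes, 2L, replace = TRUE, prob = freqs[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, accession = sprintf("acc%03d", a),
        alleles = paste(sort(unique(pick)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a complete planted-truth fixture
#'
#' Builds a repeat-free background genome of `length` bp at the given
#' GC content, then plants `n_ssrs` perfect SSRs spanning all periods
#' and both length classes, `n_te` transposon-protein fragments and
#' `n_hairpins` pre-miRNA hairpins, at evenly spaced non-overlapping
#' positions. Each TE fragment and hairpin is planted inside the flank
#' reach of a dedicated companion SSR, so the association screens can be
#' tested against planted truth. The truth table records every planted
#' element exactly; the generation seed is recorded too.
#'
#' @param length genome length in bp.
#' @param gc background GC fraction.
#' @param n_ssrs,n_te,n_hairpins element counts.
#' @param seed integer seed governing all randomness.
#' @param te_proteins optional [Biostrings::AAStringSet] to draw TE
#'   fragments from; defaults to [example_te_library()].
#' @param mature_mirnas optional mature-miRNA set; defaults to
#'   [example_mirnas()].
#' @param config scanner configuration.
#' @return list: `genome`, `truth`, `te_proteins`, `mature_mirnas`,
#'   `seed`.
#' @export
simulate_fixture <- function(length = 1e6, gc = 0.39, n_ssrs = 200L,
                             n_te = 10L, n_hairpins = 10L, seed = 1L,
                             te_proteins = example_te_library(),
                             mature_mirnas = example_mirnas(),
                             config = ssr_config()) {
  genome <- generate_genome(length, gc, seed = seed, repeat_free = TRUE,
                            config = config)
  set.seed(seed + 1L)
  motifs <- c("AT", "AG", "AC", "CG",
              "AAT", "AAG", "AGG", "ACT", "CCG",
              "AAAT", "ACAT", "AGAT",
              "AAAAT", "AATAT", "AAAAG",
              "ACATAT", "AAGAGG")
  n_slots <- n_ssrs + n_te + n_hairpins
  margin <- 500L
  slot_pos <- floor(seq(margin, length - margin,
                        length.out = n_slots + 1L))[seq_len(n_slots)]
  te_lib <- as.character(te_proteins)
  mat_lib <- stats::setNames(as.character(mature_mirnas),
                             names(mature_mirnas))
  ssr_spec <- function(k, position, label) {
    motif <- motifs[((k - 1L) %% length(motifs)) + 1L]
    p <- nchar(motif)
    min_u <- config$min_repeat_units[[as.character(p)]]
    # alternate short (Class II) and long (Class I) tracts
    units <- min_u + (if (k %% 2L == 0L) 0L else
      max(0L, ceiling(20 / p) - min_u + sample(0:4, 1L)))
    data.frame(
      label = label, kind = "ssr", position = position,
      payload = ssr_payload(motif, units),
      motif = motif, units = units,
      mature_offset = NA_integer_, mature_length = NA_integer_,
      stringsAsFactors = FALSE)
  }
  specs <- list()
  for (k in seq_len(n_ssrs))
    specs[[length(specs) + 1L]] <-
      ssr_spec(k, slot_pos[k], sprintf("ssr_%03d", k))
  for (k in seq_len(n_te)) {
    pos <- slot_pos[n_ssrs + k]
    prot <- te_lib[[((k - 1L) %% length(te_lib)) + 1L]]
    frag <- substr(prot, 1, min(80L, nchar(prot)))
    # companion SSR whose right flank covers the TE fragment
    comp <- ssr_spec(k, pos, sprintf("te_ssr_%03d", k))
    te_start <- pos + nchar(comp$payload) + 40L
    specs[[length(specs) + 1L]] <- comp
    specs[[length(specs) + 1L]] <- data.frame(
      label = sprintf("te_%03d", k), kind = "te_fragment",
      position = te_start, payload = te_payload(frag),
      motif = NA_character_, units = NA_integer_,
      mature_offset = NA_integer_, mature_length = NA_integer_,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_hairpins)) {
    pos <- slot_pos[n_ssrs + n_te + k]
    mat <- mat_lib[[((k - 1L) %% length(mat_lib)) + 1L]]
    hp <- hairpin_payload(mat)
    comp <- ssr_spec(k + 3L, pos, sprintf("mir_ssr_%03d", k))
    hp_start <- pos + nchar(comp$payload) + 30L
    specs[[length(specs) + 1L]] <- comp
    specs[[length(specs) + 1L]] <- data.frame(
      label = sprintf("mir_%03d", k), kind = "mirna_hairpin",
      position = hp_start, payload = as.character(hp),
      motif = NA_character_, units = NA_integer_,
      mature_offset = attr(hp, "mature_offset"),
      mature_length = attr(hp, "mature_length"),
      stringsAsFactors = FALSE)
  }
  specs <- do.call(rbind, c(specs, list(make.row.names = FALSE)))
  planted <- plant_elements(genome, specs)
  c(planted, list(te_proteins = te_proteins, mature_mirnas = mat_lib,
                  seed = seed))
}

#' Small built-in transposon-protein and miRNA example sets
#'
#' Synthetic stand-ins for a TE protein library and a mature-miRNA set,
#' used by [simulate_fixture()] and the examples. The sequences are
#' constructed (not taken from any database); headers follow the
#' `Class/Family` token convention.
#'
#' @return `example_te_library()`: an [Biostrings::AAStringSet];
#'   `example_mirnas()`: a named character vector of mature sequences.
#' @export
example_te_library <- function() {
  seqs <- c(
    "synTE01#LTR/Copia" = paste0(
      "MGKTEALVRQWHEKLGHPSFDLLRKMASKDLVRGLPKLKFEKDHLCSACQ",
      "LGKQVKVSFKSKNEPSVSRPLELLHMDLFGPTRVESLGGKRYGLVIVDDY",
      "SRYTWVFFLRSKSEAFDKFKVFAKLAQ"),
    "synTE02#LTR/Gypsy" = paste0(
      "MPSGKELVDLLNQGVIRPSKSPFSSPVLLVKKKDGSWRFCVDYRALNKAT",
      "VPDKFPIPVIDELLDELHGAKYFTKLDLRSGYHQIRVAEGDEWKTAFKTR",
      "EGLYEWLVMPFGLTNAPSTFQSLMNDIF"),
    "synTE03#DNA/hAT" = paste0(
      "MSSRRNTSVWDYFTKLDDGRAKCNHCGKELSYHNSTSSMLNHLKRRHPNE",
      "VEEARKRQSTLDSFVKRGGSEADVLNAIAHWIAQDNRPFSVVEDEGFKHM",
      "MKTAMPHYKVPSRNTIS"),
    "synTE04#LINE/L1" = paste0(
      "MGDQERIASLEQKIDSLTSTVQDLTTRVGELERRSPSSPSAHVASTSRSP",
      "RKIVIRGLPLDVDSEEIKSDLRGQGFEVQSVRRLKNKEGNSFSDVLVLKT",
      "DSDVFFNTLKGKSALEG")
  )
  out <- Biostrings::AAStringSet(unname(seqs))
  names(out) <- names(seqs)
  out
}

#' @rdname example_te_library
#' @export
example_mirnas <- function() {
  c(synmiR01 = "TGAAGCTGCCAGCATGATCTA",
    synmiR02 = "TTCCACAGCTTTCTTGAACTG",
    synmiR03 = "TCGGACCAGGCTTCATTCCCC",
    synmiR04 = "AGAATCTTGATGATGCTGCAT",
    synmiR05 = "TGACAGAAGAGAGTGAGCAC")
}
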