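test_that("six-frame translation follows the standard code", {
  tf <- translate_six_frames("ATGGCC")
  expect_equal(tf[["+1"]], "MA")
  expect_equal(translate_six_frames("TAA")[["+1"]], "*")
  # spot-check all forward frames against a hand-written codon table
  set.seed(101)
  for (i in 1:5) {
    dna <- rand_dna(60)
    tf <- translate_six_frames(dna)
    expect_equal(tf[["+1"]], oracle_translate(dna))
    expect_equal(tf[["+2"]], oracle_translate(substr(dna, 2, 58)))
    expect_equal(tf[["-1"]], oracle_translate(revcomp_dna(dna)))
  }
})

test_that("a perfect in-frame TE copy is flagged at 100% identity", {
  set.seed(5)
  lib <- example_te_library()
  prot60 <- substr(as.character(lib)[[1]], 1, 60)
  flank <- paste0(rand_dna(60), te_payload(prot60), rand_dna(60))
  hit <- te_association(flank, lib)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 100)
  expect_equal(hit$te_family, "LTR/Copia")
  expect_lt(hit$e_value, 1e-10)
})

test_that("alignments below 65% identity are not TE hits", {
  lib <- example_te_library()
  prot60 <- substr(as.character(lib)[[1]], 1, 60)
  # corrupt every second residue: ~50% identity, uniformly interspersed
  aa <- strsplit(prot60, "")[[1]]
  swap <- c(A = "V", R = "E", N = "G", D = "K", C = "S", Q = "L", E = "R",
            G = "N", H = "T", I = "P", L = "Q", K = "D", M = "W", F = "Y",
            P = "I", S = "C", T = "H", W = "M", Y = "F", V = "A")
  aa[seq(2, 60, 2)] <- swap[aa[seq(2, 60, 2)]]
  set.seed(6)
  flank <- paste0(rand_dna(60), te_payload(paste(aa, collapse = "")),
                  rand_dna(60))
  hit <- te_association(flank, lib)
  expect_equal(nrow(hit), 0L)
})

test_that("an empty TE library yields no hit", {
  expect_equal(nrow(te_association(rand_dna(300),
                                   Biostrings::AAStringSet())), 0L)
})

test_that("tighter TE thresholds never add hits", {
  set.seed(7)
  lib <- example_te_library()
  prot <- substr(as.character(lib)[[2]], 1, 50)
  flanks <- c(
    paste0(rand_dna(50), te_payload(prot), rand_dna(50)),
    rand_dna(250),
    paste0(rand_dna(120), te_payload(substr(prot, 1, 20)), rand_dna(120))
  )
  n_hits <- function(min_id, max_ev) sum(vapply(flanks, function(fl)
    nrow(te_association(fl, lib, min_id, max_ev)), numeric(1)))
  base <- n_hits(65, 1e-10)
  expect_lte(n_hits(80, 1e-10), base)
  expect_lte(n_hits(65, 1e-30), base)
  expect_gte(n_hits(50, 1e-5), base)
})

test_that("miRNA matching honors the 0-4 mismatch budget exactly", {
  mat <- c(mirX = "TGAAGCTGCCAGCATGATCTA")  # 21 nt
  embed <- function(x) paste0(rand_dna(80), x, rand_dna(80))
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- seq(2, by = 4, length.out = k)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  set.seed(8)
  h0 <- mirna_association(embed(mat[[1]]), mat)
  expect_true(any(h0$mismatches == 0 & h0$strand == "+"))
  expect_equal(h0$offset[h0$strand == "+" & h0$mismatches == 0], 80L)
  h4 <- mirna_association(embed(mutate(mat[[1]], 4)), mat)
  expect_true(any(h4$mismatches == 4))
  h5 <- mirna_association(embed(mutate(mat[[1]], 5)), mat)
  expect_equal(nrow(h5), 0L)
  # reverse-complement embedding is found on the minus strand
  hrc <- mirna_association(embed(revcomp_dna(mat[[1]])), mat)
  expect_true(any(hrc$strand == "-" & hrc$mismatches == 0))
})

test_that("miRNA scan equals the brute-force Hamming oracle", {
  set.seed(9)
  for (i in 1:5) {
    mat <- c(m = rand_dna(21))
    region <- paste0(rand_dna(150), mat[[1]], rand_dna(150))
    hits <- mirna_association(region, mat, max_mm = 4)
    plus <- hits[hits$strand == "+", ]
    mm <- oracle_hamming(mat[[1]], region)
    expect_equal(plus$offset, which(mm <= 4) - 1L)
    expect_equal(plus$mismatches, mm[mm <= 4])
  }
})

test_that("hairpin pairing equals the independent Nussinov oracle", {
  set.seed(10)
  for (i in 1:6) {
    hp <- hairpin_payload(rand_dna(21))
    w <- paste0(rand_dna(10), hp, rand_dna(10))
    expect_equal(fold_maxpair(w)$n_pairs, oracle_nussinov(w))
  }
})

test_that("planted hairpins validate; shuffles and poly-A do not fold as well", {
  set.seed(11)
  mat <- "TTCCACAGCTTTCTTGAACTG"
  hp <- hairpin_payload(mat)
  v <- validate_hairpin(hp, attr(hp, "mature_offset"),
                        attr(hp, "mature_length"))
  expect_true(v$valid)
  expect_equal(v$n_pairs, oracle_nussinov(as.character(hp)))
  # column shuffle destroys the stem: paired fraction drops
  shuffled <- paste(sample(strsplit(as.character(hp), "")[[1]]),
                    collapse = "")
  vs <- fold_maxpair(shuffled)
  expect_lt(vs$paired_fraction, v$paired_fraction)
  # no pairing at all in homopolymer windows
  expect_false(validate_hairpin(strrep("A", 80), 30, 21)$valid)
  expect_error(validate_hairpin(strrep("A", 40), 10, 21), "short")
})

test_that("annotation strings map to the five functional categories", {
  expect_equal(categorize_annotation("hypothetical protein"),
               "hypothetical_uncharacterized")
  expect_equal(categorize_annotation("heat shock protein 70"),
               "stress_related")
  expect_equal(categorize_annotation("WRKY transcription factor 40"),
               "transcription_factor")
  expect_equal(categorize_annotation("60S ribosomal protein L7"),
               "housekeeping")
  expect_equal(categorize_annotation("photosystem II reaction center"),
               "other")
  expect_equal(categorize_annotation(c(NA, "")),
               rep("non_functional", 2))
})
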