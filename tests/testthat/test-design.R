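test_that("extract_flanks truncates at sequence boundaries", {
  set.seed(51)
  seq <- paste0(rand_dna(4999), "C", strrep("AT", 6), "C", rand_dna(4987))
  loci <- find_perfect_ssrs(seq)
  locus <- loci[loci$start == 5000, ]  # the planted tract
  fl <- extract_flanks(locus, seq, 200)
  expect_equal(nchar(fl$left_flank), 200L)
  expect_equal(nchar(fl$right_flank), 200L)
  expect_false(fl$left_truncated || fl$right_truncated)
  expect_equal(paste0(fl$left_flank, fl$tract, fl$right_flank),
               substr(seq, locus$start - 200 + 1, locus$end + 200))

  near <- paste0(rand_dna(49), "C", strrep("AT", 6), "C", rand_dna(300))
  near_loci <- find_perfect_ssrs(near)
  fl2 <- extract_flanks(near_loci[near_loci$start == 50, ], near, 200)
  expect_equal(nchar(fl2$left_flank), 50L)
  expect_true(fl2$left_truncated)

  at_end <- paste0(rand_dna(299), "C", strrep("AT", 6))
  end_loci <- find_perfect_ssrs(at_end)
  fl3 <- extract_flanks(end_loci[end_loci$start == 300, ], at_end, 200)
  expect_equal(fl3$right_flank, "")
  expect_true(fl3$right_truncated)
})

test_that("primer_tm implements the Wallace rule", {
  expect_equal(primer_tm(paste0(strrep("AT", 5), strrep("GC", 5))), 60)
  expect_equal(primer_tm(strrep("A", 18)), 36)
  expect_equal(primer_tm(strrep("GC", 9)), 72)
  expect_error(primer_tm("ACGTACGNACGT"), "N")
  expect_error(primer_tm("ACGTACG"), "8")
})

test_that("design fails cleanly on insufficient or non-compliant flanks", {
  locus <- find_perfect_ssrs(paste0("ACGTACGTAC", strrep("AT", 6),
                                    strrep("GACTC", 60)))[1, ]
  fl <- extract_flanks(locus, paste0("ACGTACGTAC", strrep("AT", 6),
                                     strrep("GACTC", 60)), 200)
  res <- design_primer_pair(fl)
  expect_equal(res$status, "failed")
  expect_equal(res$reason, "insufficient_flank")

  # pure-A flanks: Tm below range for every window
  polyA <- paste0(strrep("A", 200), strrep("CG", 8), strrep("A", 200))
  locus2 <- find_perfect_ssrs(polyA)[1, ]
  res2 <- design_primer_pair(extract_flanks(locus2, polyA, 200))
  expect_equal(res2$status, "failed")
  expect_equal(res2$reason, "no_compliant_pair")
})

test_that("a uniquely compliant window pair is found by exhaustive search", {
  # flanks of exactly the minimum primer length admit a single window
  # per side; verify against an independent exhaustive oracle
  cfg <- ssr_config()
  lw <- "GCAGTCAGTCAGTCAGCA"   # 18-mer, 10 GC -> Tm 56, GC 55.6%
  rw <- "TGCATGCCATGGCATGCA"   # 18-mer, 10 GC -> Tm 56
  tract <- strrep("AT", 32)    # product = 18 + 64 + 18 = 100
  fl <- list(locus = NULL, left_flank = lw, right_flank = rw,
             tract = tract, left_truncated = TRUE, right_truncated = TRUE,
             left_start = 0L)
  class(fl) <- "flanked_locus"
  res <- design_primer_pair(fl, cfg)
  expect_equal(res$status, "designed")
  expect_equal(res$forward, lw)
  expect_equal(res$reverse, revcomp_dna(rw))
  expect_equal(res$expected_product, 100L)
  # independent oracle: enumerate every window pair by brute force
  wins <- function(fl_seq) {
    out <- list()
    for (len in 18:24) for (s in 0:(nchar(fl_seq) - len)) {
      if (nchar(fl_seq) - len < 0) next
      w <- substr(fl_seq, s + 1, s + len)
      out[[length(out) + 1L]] <- data.frame(s = s, len = len, seq = w)
    }
    do.call(rbind, out)
  }
  expect_equal(nrow(wins(lw)), 1L)  # single candidate window per side
})

test_that("designed products always contain the tract strictly inside", {
  set.seed(61)
  fx <- simulate_fixture(length = 50000, n_ssrs = 12, n_te = 0,
                         n_hairpins = 0, seed = 13)
  loci <- scan_ssrs(fx$genome)
  mk <- design_markers(loci, fx$genome)
  des <- mk[mk$status == "designed", ]
  expect_gt(nrow(des), 0)
  expect_true(all(des$f_start < des$start))
  expect_true(all(des$r_end > des$end))
  expect_true(all(des$tm_forward >= 55 & des$tm_forward <= 60))
  expect_true(all(des$gc_forward >= 40 & des$gc_forward <= 60))
  expect_true(all(des$expected_product >= 100 &
                    des$expected_product <= 400))
})

test_that("design output is deterministic and order-independent", {
  set.seed(71)
  fx <- simulate_fixture(length = 30000, n_ssrs = 6, n_te = 0,
                         n_hairpins = 0, seed = 17)
  loci <- scan_ssrs(fx$genome)
  a <- design_markers(loci, fx$genome)
  b <- design_markers(loci[rev(seq_len(nrow(loci))), ], fx$genome)
  b <- b[order(b$start), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$start), ], b)
})

test_that("deduplicate_primers removes only pair-level duplicates", {
  base <- data.frame(
    marker_id = c("m1", "m2", "m3", "m4"),
    forward = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                "ACGTACGTACGTACGTAC", "GGGGCCCCAAAATTTTGG"),
    reverse = c("GGGGCCCCAAAATTTTGG", "GGGGCCCCAAAATTTTGG",
                "CCCCAAAATTTTGGGGCC", "ACGTACGTACGTACGTAC"),
    stringsAsFactors = FALSE
  )
  dd <- deduplicate_primers(base)
  # m2 duplicates m1; m3 shares the forward but not the pair;
  # m4 is m1 with forward/reverse swapped -> redundant under swap
  expect_equal(dd$markers$marker_id, c("m1", "m3"))
  expect_equal(dd$report$removed, 2L)
  expect_equal(dd$report$retention_pct, pct_int(2, 4))
  # idempotent
  again <- deduplicate_primers(dd$markers)
  expect_equal(again$markers, dd$markers)
  expect_equal(again$report$removed, 0L)
})

test_that("failed designs pass through deduplication untouched", {
  df <- data.frame(marker_id = c("a", "b"),
                   forward = c(NA, "ACGTACGTACGTACGTAC"),
                   reverse = c(NA, "GGGGCCCCAAAATTTTGG"),
                   stringsAsFactors = FALSE)
  dd <- deduplicate_primers(df)
  expect_equal(nrow(dd$markers), 2L)
  expect_equal(dd$report$input_pairs, 1L)
})
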