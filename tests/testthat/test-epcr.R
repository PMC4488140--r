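make_subject <- function(insert, pad = 150, seed = 1) {
  set.seed(seed)
  paste0(rand_dna(pad), insert, rand_dna(pad))
}

test_that("exact and budget-boundary binding sites behave as specified", {
  primer <- "ACGTTGCAACGGTCAATGCA"
  # exact reverse-complement site: one minus-strand site, zero cost
  s <- make_subject(revcomp_dna(primer))
  hit <- find_binding_sites(primer, s, 3, 2, 2)
  exact <- hit[hit$cost == 0, ]
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$strand, "-")
  expect_equal(exact$start, 150L)
  expect_equal(exact$end, 170L)

  # 3 substitutions, intact 3' anchor: accepted at the budget boundary
  rot <- c(A = "C", C = "G", G = "T", T = "A")  # always a real change
  mutate_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- rot[[substr(s, p, p)]]
    s
  }
  mm3 <- mutate_at(primer, c(2, 6, 11))
  h3 <- find_binding_sites(primer, make_subject(mm3, seed = 2), 3, 2, 2,
                           strands = "+")
  h3 <- h3[h3$start >= 140 & h3$start <= 160, ]
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$mismatches, 3L)
  expect_equal(h3$gaps, 0L)

  # 4 substitutions: rejected
  mm4 <- mutate_at(primer, c(2, 6, 11, 15))
  h4 <- find_binding_sites(primer, make_subject(mm4, seed = 3), 3, 2, 2,
                           strands = "+")
  expect_equal(nrow(h4[h4$start >= 140 & h4$start <= 160, ]), 0L)
})

test_that("the 3' anchor must match exactly", {
  primer <- "ACGTTGCAACGGTCAATGCA"
  bad <- primer
  substr(bad, 20, 20) <- "T"  # mutate terminal base of the site
  h <- find_binding_sites(primer, make_subject(bad, seed = 4), 3, 2, 2,
                          strands = "+")
  expect_equal(nrow(h[h$mismatches > 0 & h$start >= 140 & h$start <= 160 &
                        h$end >= 168, ]), 0L)
})

test_that("gap budgets admit up to two gaps and no more", {
  primer <- "ACGTTGCAACGGTCAATGCA"
  del1 <- paste0(substr(primer, 1, 9), substr(primer, 11, 20))
  h1 <- find_binding_sites(primer, make_subject(del1, seed = 5), 3, 2, 2,
                           strands = "+")
  h1 <- h1[h1$gaps > 0, ]
  expect_equal(h1$gaps, 1L)
  expect_equal(h1$cost, 2L)

  del2 <- paste0(substr(primer, 1, 5), substr(primer, 7, 13),
                 substr(primer, 15, 20))
  h2 <- find_binding_sites(primer, make_subject(del2, seed = 6), 3, 2, 2,
                           strands = "+")
  expect_true(any(h2$gaps == 2))

  # reported sites always respect the budgets, whatever the variant
  set.seed(7)
  for (rep in 1:5) {
    corrupt <- paste0(substr(primer, 1, 4), rand_dna(3),
                      substr(primer, 9, 12), rand_dna(2),
                      substr(primer, 16, 20))
    h <- find_binding_sites(primer, make_subject(corrupt, seed = rep),
                            3, 2, 2)
    expect_true(all(h$mismatches <= 3 & h$gaps <= 2))
  }
  # a heavily corrupted variant (8 spread substitutions) is never a site
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  wreck <- primer
  for (p in c(2, 4, 6, 8, 10, 12, 14, 16))
    substr(wreck, p, p) <- rot[[substr(wreck, p, p)]]
  hw <- find_binding_sites(primer, make_subject(wreck, seed = 8), 3, 2, 2,
                           strands = "+")
  expect_equal(nrow(hw[hw$start >= 140 & hw$start <= 160, ]), 0L)
})

test_that("site finding agrees with the exhaustive alignment oracle", {
  set.seed(81)
  for (rep in 1:6) {
    primer <- rand_dna(sample(14:18, 1))
    text <- rand_dna(160)
    # implant a variant to make non-trivial hits likely
    var <- primer
    nmut <- sample(0:3, 1)
    if (nmut > 0)
      for (pos in sample(seq_len(nchar(primer) - 2), nmut))
        substr(var, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(var, pos, pos)), 1)
    text <- paste0(substr(text, 1, 60), var, substr(text, 61, 160))
    impl <- find_binding_sites(primer, text, 3, 2, 2, strands = "+")
    orc <- oracle_site_ends(primer, text, 3L, 2L, 2L)
    # every implementation site must be a qualifying oracle end with the
    # same minimal cost, and every oracle end must overlap a reported
    # (collapsed) site of cost <= its own
    for (k in seq_len(nrow(impl)))
      expect_equal(impl$cost[k], orc$cost[orc$end == impl$end[k]])
    for (k in seq_len(nrow(orc))) {
      covering <- impl[abs(impl$end - orc$end[k]) <= nchar(primer), ]
      expect_true(nrow(covering) > 0)
      expect_lte(min(covering$cost), orc$cost[k])
    }
  }
})

test_that("raising budgets never loses sites", {
  set.seed(91)
  for (rep in 1:5) {
    primer <- rand_dna(16)
    text <- paste0(rand_dna(100), primer, rand_dna(100))
    n_prev <- -1L
    for (budget in list(c(0, 0), c(1, 0), c(2, 1), c(3, 2))) {
      h <- find_binding_sites(primer, text, budget[1], budget[2], 2)
      expect_gte(nrow(h), n_prev)
      n_prev <- nrow(h)
    }
  }
})

test_that("every designed marker amplifies its own source exactly", {
  set.seed(31)
  fx <- simulate_fixture(length = 40000, n_ssrs = 8, n_te = 0,
                         n_hairpins = 0, seed = 23)
  loci <- scan_ssrs(fx$genome)
  mk <- design_markers(loci, fx$genome)
  mk <- mk[mk$status == "designed", ]
  expect_gt(nrow(mk), 0)
  for (i in seq_len(nrow(mk))) {
    hits <- epcr(mk[i, ], fx$genome, max_mismatches = 0, max_gaps = 0)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$product_size, mk$expected_product[i])
    expect_equal(hits$mismatches + hits$gaps, 0L)
  }
})

test_that("divergently oriented primers never amplify", {
  set.seed(41)
  fwd <- "GCAGTCAGTCAGTCAGCA"
  rev <- "TGCATGCCATGGCATGCA"
  # place them back-to-back (divergent): revcomp(fwd) then rev
  subject <- paste0(rand_dna(100), revcomp_dna(fwd), rand_dna(30), rev,
                    rand_dna(100))
  pair <- data.frame(forward = fwd, reverse = revcomp_dna(rev))
  hits <- epcr(pair, c(s = subject), max_mismatches = 0, max_gaps = 0)
  expect_equal(nrow(hits), 0L)
})

test_that("a tandem-duplicated target yields two amplicons", {
  set.seed(51)
  fwd <- "GCAGTCAGTCAGTCAGCA"
  rvw <- "TGCATGCCATGGCATGCA"  # plus-strand window; reverse primer is its RC
  unit <- paste0(fwd, rand_dna(80), rvw)
  subject <- paste0(rand_dna(120), unit, unit, rand_dna(120))
  pair <- data.frame(forward = fwd, reverse = revcomp_dna(rvw))
  hits <- epcr(pair, c(s = subject), max_mismatches = 0, max_gaps = 0,
               max_product = 150)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$product_size, rep(nchar(unit), 2))
})

test_that("ePCR product sizes are strand-symmetric", {
  set.seed(61)
  fx <- simulate_fixture(length = 20000, n_ssrs = 4, n_te = 0,
                         n_hairpins = 0, seed = 29)
  loci <- scan_ssrs(fx$genome)
  mk <- design_markers(loci, fx$genome)
  mk <- mk[mk$status == "designed", ][1:2, ]
  g_fwd <- fx$genome
  g_rev <- Biostrings::reverseComplement(fx$genome)
  names(g_rev) <- names(g_fwd)
  for (i in seq_len(nrow(mk))) {
    a <- epcr(mk[i, ], g_fwd)
    b <- epcr(mk[i, ], g_rev)
    expect_equal(sort(a$product_size), sort(b$product_size))
  }
})

test_that("polymorphism classification uses the >= 10 bp rule", {
  expect_equal(classify_polymorphism(200, 212), "polymorphic")
  expect_equal(classify_polymorphism(200, 205), "monomorphic")
  expect_equal(classify_polymorphism(200, 210), "polymorphic")  # boundary
  expect_equal(classify_polymorphism(200, 191), "monomorphic")
  expect_equal(classify_polymorphism(200, 190), "polymorphic")
  expect_equal(classify_polymorphism(200, c(202, 195)), "monomorphic")
  expect_equal(classify_polymorphism(200, c(202, 260)), "polymorphic")
  expect_error(classify_polymorphism(200, integer()), "empty")
})

test_that("physical mapping separates unique, multi and absent markers", {
  set.seed(71)
  fwd <- "GCAGTCAGTCAGTCAGCA"
  rvw <- "TGCATGCCATGGCATGCA"
  tract <- strrep("AT", 32)
  unit <- paste0(fwd, tract, rvw)
  genome <- c(chr1 = paste0(rand_dna(200), unit, rand_dna(200)),
              chr2 = paste0(rand_dna(150), unit, rand_dna(100), unit,
                            rand_dna(150)))
  mk <- data.frame(
    marker_id = c("u1", "m1", "n1", "c1"),
    is_compound = c(FALSE, FALSE, FALSE, TRUE),
    forward = c(fwd, fwd, "AACCGGTTAACCGGTTAA", fwd),
    reverse = c(revcomp_dna(rvw), revcomp_dna(rvw),
                "TTGGCCAATTGGCCAATT", revcomp_dna(rvw)),
    stringsAsFactors = FALSE
  )
  g1 <- c(chr1 = genome[["chr1"]])
  res1 <- physical_map(mk[c(1, 3, 4), ], g1)
  expect_equal(res1$map_status, c("unique", "none", "excluded_compound"))
  expect_equal(res1$chromosome[1], "chr1")
  res2 <- physical_map(mk[2, ], c(chr2 = genome[["chr2"]]))
  expect_equal(res2$map_status, "multi")
})

test_that("transferability cells distinguish hit classes", {
  set.seed(81)
  fwd <- "GCAGTCAGTCAGTCAGCA"
  rvw <- "TGCATGCCATGGCATGCA"
  expected <- 18 + 64 + 18
  mk <- data.frame(marker_id = "m1", forward = fwd,
                   reverse = revcomp_dna(rvw),
                   expected_product = expected, stringsAsFactors = FALSE)
  mono <- c(g = paste0(rand_dna(100), fwd, strrep("AT", 32), rvw,
                       rand_dna(100)))
  poly <- c(g = paste0(rand_dna(100), fwd, strrep("AT", 32), "TACGATCGGATCGAT",
                       rvw, rand_dna(100)))
  none <- c(g = rand_dna(300))
  tm <- transferability_matrix(mk, list(mono = mono, poly = poly,
                                        none = none))
  expect_equal(unname(unlist(tm$matrix["m1", ])),
               c("monomorphic", "polymorphic", "no_hit"))
  expect_equal(tm$per_genome$pct_transferable, c(100, 100, 0))
  # identical target genome: 100% transferable, monomorphic
  expect_equal(tm$matrix["m1", "mono"], "monomorphic")
})
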