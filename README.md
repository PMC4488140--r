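# ssrmine

Microsatellite mining, marker design and in silico evaluation for plant
genomes.

Simple sequence repeats (SSRs, microsatellites) — tandem repetitions of
2–6 bp DNA motifs — are the workhorse codominant markers of plant
breeding programs. Turning a genome assembly into a usable SSR marker
panel takes a chain of steps that are usually scattered across separate
tools and one-off scripts: mine perfect repeats, classify them by
attribute, design flanking primers, throw away redundant primer pairs,
check by electronic PCR that each marker amplifies a single locus,
estimate cross-taxon transferability and amplicon-size polymorphism,
flag loci sitting in transposable elements or pre-miRNA hairpins, and
score the surviving markers' information content from genotype data.
`ssrmine` implements that whole chain as one coherent, deterministic R
package, aimed at researchers building marker panels for crops with few
existing resources (the defaults emulate a banana-scale survey: four
sequence sets, GC ≈ 0.39 genomic background).

## The method at a glance

* **Repeat mining** — perfect di- to hexanucleotide repeats with at
  least 6/5/5/4/4 repeat units respectively (MISA-style search
  criteria). A maximal run is reported once at its smallest period with
  its primitive motif; tracts never span `N`. Adjacent repeats with
  zero intervening bases merge into *compound* SSRs. Motifs are grouped
  into canonical families (the lexicographic minimum over cyclic
  rotations and the reverse complement, so AG/GA/CT/TC are one family:
  there are 4 dinucleotide, 10 trinucleotide, 33 tetranucleotide, 102
  pentanucleotide and 350 hexanucleotide families).
* **Classification** — tract-length Class I (≥ 20 bp) vs Class II
  (< 20 bp); motif composition AT-rich / GC-rich / balanced; per-dataset
  survey tables with integer percentages whose "overall" column is the
  unweighted mean of per-dataset percentages.
* **Primer design** — exhaustive window search over 200 bp flanks:
  length 18–24 bp, Wallace-rule Tm = 2(A+T) + 4(G+C) in 55–60 °C, GC
  40–60 %, product 100–400 bp, fully deterministic tie-breaking.
  Redundant pairs (identical primer sequences up to forward/reverse
  swap) are removed, keeping first occurrences.
* **Electronic PCR** — semi-global alignment of each primer against
  both strands under budgets of ≤ 3 mismatches and ≤ 2 gaps per primer
  with a 2 bp exact 3′ anchor; a site is judged on its minimum-cost
  alignment (cost = mismatches + 2·gaps). Convergent site pairs within
  5 kb become amplicons; markers are classed unique / multi / absent on
  the reference, and a marker is *polymorphic* in a target genome when
  its amplicon size differs from the expected product by ≥ 10 bp.
* **Association screens** — six-frame translated Smith–Waterman
  (BLOSUM62, gap 11/1) against a TE protein library with hits at
  ≥ 65 % identity and E ≤ 1e-10 (Karlin–Altschul ungapped
  approximation); ungapped mature-miRNA scan allowing 0–4 mismatches,
  with candidate precursors validated by a base-pair-maximization
  fold-back check (Nussinov dynamic programming, Watson–Crick + G:U).
* **Marker potential** — pooled allele frequencies and PIC
  (polymorphism information content, Botstein definition):
  `PIC = 1 − Σ pᵢ² − Σᵢ<ⱼ 2 pᵢ² pⱼ²`, plus the five pre-selection
  criteria (single reference hit, transferable, polymorphic in silico,
  not TE-associated, functional markers ranked first).
* **Synthetic fixtures** — seeded simulators that generate repeat-free
  background genomes, plant SSRs / TE fragments / pre-miRNA hairpins
  with exact truth tables, diverge genomes by substitutions and indels,
  and draw diploid genotype tables from known allele frequencies — so
  every stage is testable without downloading anything.

## Worked example

```r
library(ssrmine)

fx   <- simulate_fixture(length = 50000, gc = 0.39, n_ssrs = 12,
                         n_te = 2, n_hairpins = 2, seed = 7)
loci <- merge_compound(scan_ssrs(fx$genome))
head(loci[, c("locus_id", "start", "end", "motif", "repeat_units")], 4)
#>       locus_id start  end motif repeat_units
#> 1 chr1_ssr0001   500  526    AT           13
#> 2 chr1_ssr0002  3562 3574    AG            6
#> 3 chr1_ssr0003  6625 6647    AC           11
#> 4 chr1_ssr0004  9687 9699    CG            6

markers <- design_markers(loci, fx$genome)
dd      <- deduplicate_primers(markers)
dd$report
#> designed: 16 of 16 | non-redundant: 16 (100%)

m1 <- dd$markers[dd$markers$status == "designed", ][1, ]
m1[, c("forward", "reverse", "tm_forward", "expected_product")]
#> F: GAATCGTGAGACAGACCATT  R: TTCAACACCGCTCACTTCG  Tm: 58/58  product: 134 bp

epcr(m1, fx$genome, max_mismatches = 0, max_gaps = 0)
#>   seq_id start end product_size orientation mismatches gaps
#> 1   chr1   414 548          134          FR          0    0
```

The marker's own genome yields exactly one zero-mismatch amplicon whose
size equals the designed product — the self-consistency every designed
marker must satisfy. Genotype scoring works the same way:

```r
gt <- generate_genotypes(list(M1 = c(`200` = .5, `210` = .5),
                              M2 = c(`150` = .25, `156` = .25,
                                     `162` = .25, `168` = .25)),
                         n_accessions = 8, seed = 7)
summarize_genotypes(gt)$per_marker
#>   marker_id n_alleles      pic polymorphic amplified
#> 1        M1         2 0.345679        TRUE      TRUE
#> 2        M2         4 0.678163        TRUE      TRUE
```

A two-allele locus caps at PIC = 0.375 (here 0.346 from the sampled
frequencies); more, evenly frequent alleles push PIC toward 1.

A thin command-line surface over the same functions lives at
`inst/cli/ssrmine.R` with subcommands `scan`, `classify`, `design`,
`epcr`, `associate`, `stats`, `simulate` and `run-all`.

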