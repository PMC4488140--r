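---
title: "From genome to SSR marker panel: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genome to SSR marker panel: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ssrmine` turns DNA sequence sets into evaluated microsatellite (SSR)
marker panels. This vignette explains the procedure stage by stage: the
model behind each step, the tunable parameters and their defaults, the
numerical conventions, what the synthetic-data generator does and does
not emulate, and the design choices made where more than one reasonable
convention exists.

## 1. Repeat mining

A perfect SSR is a maximal tandem run of a primitive 2–6 bp motif (a
motif is primitive when it is not itself a repetition of a shorter
unit). The scanner reports a run once, at its smallest period, with the
leftmost phase and the number of *complete* repeat units; partial
trailing units are not counted in the tract. Minimum repeat units
default to 6 (di-), 5 (tri-), 5 (tetra-), 4 (penta-) and 4
(hexanucleotide) — the classical genome-survey search criteria — and
are configurable per period via `ssr_config(min_repeat_units = ...)`.
Consequences of these rules worth knowing:

* Mononucleotide runs are never reported (a homopolymer's 2-mer unit is
  non-primitive), matching the deliberate exclusion of poly-A/T noise.
* `N` breaks a tract: repeats never span ambiguous bases.
* Two abutting runs of the *same* motif cannot occur (maximality); runs
  of different motifs separated by exactly 0 bp are merged by
  `merge_compound()` into one *compound* locus that keeps its members.
  Compound loci count once in locus totals; their members additionally
  feed the motif-frequency tables and a separate compound tally. Both
  tallies are emitted because either convention is defensible for the
  survey-table "total SSRs" row.

Internally the scan is a per-period backreference regular expression
(`([ACGT]{p})\1{k-1,}`), which the test suite holds equal to an
independent run-length-encoding oracle on hundreds of random sequences.
Coordinates are 0-based half-open internally and 1-based inclusive in
every serialized file (GFF3 convention).

Motif families are canonicalized to the lexicographic minimum over all
cyclic rotations of the motif and of its reverse complement; this
yields the familiar family counts 4 / 10 / 33 / 102 / 350 for periods
2–6, which the tests recompute by exhaustive enumeration.

## 2. Classification and survey tables

Two attribute axes apply per locus: tract length (Class I ≥ 20 bp,
Class II < 20 bp — the 20 bp tract itself is assigned to Class I, the
common convention when the boundary is otherwise unspecified) and motif
base composition (AT-rich when more than half the motif bases are A/T,
GC-rich below half, balanced at exactly half; composition of a perfect
tract equals composition of its motif).

Survey tables print integer percentages, rounded **half away from
zero** (`round_half_away()`), each over its own dataset's total. The
"overall" column of a multi-dataset table is the *unweighted arithmetic
mean of the per-dataset integer percentages*, again rounded half away
from zero — not a pooled-count percentage. Pooling would weight a large
genomic set overwhelmingly over a small EST set; the unweighted mean
treats the four sequence sources as four replicates of the survey, and
is the only convention under which a table's per-dataset and overall
columns stay mutually consistent when datasets differ in size by orders
of magnitude. Densities (kbp per SSR, rounded to integer) combine the
same way. With zero loci, densities are reported absent (`NA`), never
infinite.

## 3. EST end cleanup

`trim_est()` iterates three trims to a fixed point: terminal `N` runs
(any length), 3′ poly-A tails and 5′ poly-T tails of at least
`min_tail` bp (default 8 — long enough that an 8+ homopolymer at a read
end is far more likely a technical tail than biology). Records shorter
than `min_keep` bp (default 100) after trimming are dropped and counted
in the trim report, not errored. Quality-score-aware and
low-complexity-window cleanup are out of scope; those require raw
chromatogram/quality inputs this pipeline does not take. The fixed
point guarantees idempotence, which the tests exercise directly.

## 4. Primer design

Primer design is a deterministic exhaustive search rather than a
heuristic optimizer, so results are exactly reproducible across
machines and repeated runs:

| parameter | default | unit |
|---|---|---|
| flank length per side | 200 | bp |
| primer length | 18–24 | bp |
| melting temperature (Wallace) | 55–60 | °C |
| GC content | 40–60 | % |
| product size | 100–400 | bp |

Tm uses the Wallace rule, 2(A+T) + 4(G+C): for 18–24-mers it is a
monotone, integer-valued, exactly testable proxy that keeps the whole
pipeline free of floating-point thermodynamic tables. Every window of
the allowed lengths in each flank is scored; compliant windows are
paired; the pair minimizing `|Tm_f − Tm*| + |Tm_r − Tm*|` (Tm* = 57.5,
the Tm-range midpoint) wins, with ties broken by smaller product, then
leftmost forward, then leftmost reverse window. The expected product
runs from the forward primer's 5′ end to the reverse primer's 5′ end
inclusive, and the repeat tract always lies strictly inside it. Design
failures are data, not errors: `failed(insufficient_flank)` when a
flank is shorter than the minimum primer length, otherwise
`failed(no_compliant_pair)`.

Redundancy filtering treats two pairs as identical when their
(forward, reverse) sequences match after orientation normalization
(i.e. also testing the forward/reverse swap); the first occurrence in
input order is kept. Sequence-level identity was chosen over
amplicon-coordinate identity because it is the criterion that transfers
across datasets — the two-stage filter (within each dataset, then
across the pooled sets) only makes sense for a coordinate-free
criterion.

## 5. Electronic PCR

`find_binding_sites()` aligns a primer semi-globally against both
strands under per-primer budgets: at most 3 mismatches **and** at most
2 gaps (both configurable), with the 2 3′-terminal primer bases
required to match exactly and contiguously — an addition motivated by
PCR chemistry (3′-end mismatches abort extension) and likewise
configurable. Budgets are interpreted per primer, the convention of
electronic-PCR tools, rather than per pair.

Candidate alignments are scored by cost = mismatches + 2·gaps, and a
site qualifies only when its *minimum-cost* alignment fits the budgets.
This matters: under a naive "exists an alignment within budgets" rule,
any site with 4 substitutions would sneak in by rewriting one
substitution as a deletion-plus-insertion (3 mismatches + 2 gaps),
making the mismatch budget vacuous. Judging the optimum keeps the
boundary sharp: 3 substitutions qualify, 4 never do. Overlapping
candidate alignments collapse to the minimum-cost one, ties leftmost.
The implementation is a layered boolean dynamic program vectorized
along the subject; the suite checks it cell-for-cell against an
exhaustive recursive aligner on small inputs.

Amplicons are convergent forward/reverse site combinations on one
sequence within 5 kb (the product cap that bounds the pair search),
sized 5′-to-5′, in both pair orientations. Physical mapping calls a
marker `unique` / `multi` / `none` by its genome-wide amplicon count;
compound-SSR markers are excluded from mapping onward, and only
`unique` markers enter the transferability study. A marker is
*polymorphic* in a target genome when some amplicon's size differs from
the **expected** product by at least 10 bp (the threshold is
configurable; comparison is against the marker's expected size, not
pairwise among targets, because the expected size is the panel's
reference point). Note that with 18-mer primers the full 3 mm + 2 gap
sensitivity is permissive — spurious cost-7 sites occur at a low but
non-negligible rate per Mb, which is precisely why the unique-hit
filter and the 3′ anchor exist; raising `epcr_anchor` tightens the
screen.

## 6. TE and miRNA association

Flanks (200 bp per side, the same reach used for primer design — also
used for the miRNA screen, keeping the two screens comparable) plus the
tract are translated in six frames and searched against a TE protein
library by local alignment (Smith–Waterman, BLOSUM62, gap open 11 /
extend 1, via `Biostrings::pairwiseAlignment`). The single best-scoring
alignment is reported as a TE hit iff identity over the aligned region
is ≥ 65 % and its E-value ≤ 1e-10; E-values use the Karlin–Altschul
formula with standard ungapped BLOSUM62 parameters (λ = 0.3176,
K = 0.134) over the searched space (all six frame lengths × library
length). Full BLAST heuristics (seeding, HSP chaining) are deliberately
not reproduced: the thresholds define association, and a deterministic
exhaustive search honors them exactly. TE families are parsed from the
library FASTA headers' `Class/Family` token (e.g. `LTR/Copia`).

Mature miRNAs (typically 21 nt) are matched ungapped, full length, on
both strands, with 0–4 mismatches — at these lengths a gapped search
adds nothing but instability. Candidate precursors are then validated
by a fold-back check: base-pair maximization (Nussinov dynamic
programming over Watson–Crick plus G:U pairs, minimum loop 3) on a
60–200 nt window centered on the hit. A window passes when (a) the
overall paired fraction is ≥ 0.55, (b) ≥ 60 % of mature-site bases are
paired, and (c) those bases pair to one side only (the mature sequence
sits in a single stem arm). The pairing model and both thresholds are
package choices standing in for thermodynamic folding — maximizing
pairs is not minimizing free energy, and random sequence folds
surprisingly well under pure pair-maximization, so the discriminating
conditions are (b) and (c), not (a) alone. All three are configurable;
the pairing count itself is held equal to an independent cubic-time
oracle in the tests.

Functional annotation is not computed ab initio; externally supplied
description strings are mapped by case-insensitive keyword lists into
hypothetical/uncharacterized, stress-related, transcription factor,
housekeeping, other, and non-functional for absent annotation. The
keyword lists are arguments, and the first-match order (hypothetical →
stress → TF → housekeeping) resolves multi-keyword strings.

## 7. Marker potential statistics

Allele sizes pool across accessions into frequencies. PIC uses the
Botstein definition

\[ \mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2 , \]

with the simpler expected heterozygosity \(1 - \sum p_i^2\) available
by switch; Botstein PIC never exceeds heterozygosity, a bound the suite
verifies over 10⁴ random frequency vectors. The cohort's mean alleles
per polymorphic locus is **truncated**, not rounded, to two decimals —
the convention under which a cohort of 243 loci and 1047 alleles prints
4.30. Genotype cells are treated as codominant allele-size calls.

The five pre-selection criteria apply in order — unique reference hit,
transferable, polymorphic in silico, not TE-associated — with the fifth
(functional annotation) acting as a rank key placing functional markers
first, not as a filter; an attrition report counts removals per step.

## 8. The synthetic-data generator

`generate_genome()` draws i.i.d. bases at a target GC (default 0.39, a
banana-like genomic background) and can redraw windows until the
scanner finds nothing (`repeat_free = TRUE`), so planted elements are
the only repeats present. `plant_elements()` overwrites the background
at exact positions and records the truth; for SSR payloads the single
boundary base on each side is adjusted when needed so a planted tract
cannot extend by chance, keeping truth coordinates exact.
`simulate_fixture()` combines these — by default a 1 Mb genome with 200
SSRs spanning all periods and both length classes, 10 TE protein
fragments and 10 pre-miRNA hairpins, each of the latter two planted
within flank reach of a dedicated companion SSR so the association
screens can be scored against truth. `diverge_genome()` applies
per-base substitutions and geometric-length (mean 2) indels;
`generate_genotypes()` samples diploid accessions from given allele
frequencies. One seed governs everything; identical seeds give
byte-identical fixtures.

What the generator deliberately does **not** emulate: positional
rate heterogeneity, transposition dynamics, repeat-length mutation
models, linkage between markers, or genotyping error. Passing the
planted-truth suites therefore demonstrates algorithmic correctness —
exact recovery, exact self-amplification, correct threshold behavior —
not field performance on real genomes, where interrupted repeats,
assembly gaps and paralogy will lower design and unique-mapping rates.

The bundled TE protein and mature-miRNA example sets
(`example_te_library()`, `example_mirnas()`) are synthetic constructs
(headers carry a `syn` prefix); they exist so fixtures and examples run
self-contained and are not curated biological references.

## 9. Problem sizes and numerical conventions in the tests

The test suite runs the scanner-oracle comparison on 200 random
sequences up to 2 kb, the end-to-end planted-truth check on a 1 Mb
fixture with 220 planted SSRs, transferability monotonicity on a 12 kb
fixture (6 markers, 5 replicate divergence seeds per rate at 0 / 5 /
30 % substitutions), and the fold oracle on 50 windows up to ~160 nt —
sizes chosen to exercise every code path at full fidelity while keeping
a complete run in a few minutes on one core. `scripts/acceptance.R`
re-runs the pipeline end to end on seeded fixtures (60 kb pipeline
fixture, 12 kb transferability fixture, a 243-locus genotype cohort)
and emits its quantities as JSON.

Known limitations worth restating: perfect repeats only (no
interrupted/imperfect SSR model); Wallace-rule Tm rather than
nearest-neighbor thermodynamics; pair-maximization rather than MFE
folding; exhaustive rather than heuristic translated search (fine for
flank-scale queries, not a BLAST replacement at database scale); and
in-silico polymorphism is a size-difference proxy that cannot see
sequence-level variation preserving amplicon length.
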