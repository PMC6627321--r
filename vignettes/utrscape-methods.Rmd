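---
title: "Methods: comparative 5'UTR feature analysis with utrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative 5'UTR feature analysis with utrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrscape)
```

# The analysis

`utrscape` analyses the spliced 5' untranslated regions (5'UTRs) of an
ortholog family — for example the vertebrate orthologs of a human
ATP-binding-cassette transporter gene — for features that regulate
translation initiation. Most vertebrate 5'UTRs of such genes carry a single
intron ("Intron 1"); the spliced transcript therefore splits into a
*before-Intron-1* and an *after-Intron-1* section, and many of the package's
statistics are reported per section. Coordinates are 1-based and inclusive,
position 1 is the transcription start site, and intron sequence is absent:
the intron exists only as the offset that separates the two sections.
Records with no 5'UTR intron are handled throughout as a single section
labelled `whole`, never as an error.

The stages, each usable on its own and chained by `run_utr_pipeline()`:

1. **Section lengths** (`summarize_lengths()`, `pairwise_mw()`): group-wise
   medians and ranges of whole/before/after/intron/protein lengths, with
   two-sided Mann–Whitney tests for every group pair and Bonferroni
   correction (factor = number of pairs actually tested, capped at 1).
2. **Conservation** (`profile_columns()`, `call_hotspots()`): per alignment
   column, *identity* = 100 × modal-base count / non-gap count and
   *occupancy* = 100 × non-gap count / rows. A *hot spot* is a column
   strictly exceeding both thresholds (defaults 80 and 84). The strict
   inequality matters: with 59 aligned transcripts, `min_occupancy_count(59,
   84)` is 50, i.e. at least 50 of 59 rows must carry a base. Hot-spot
   columns form maximal runs and are projected through the gap structure
   onto each transcript's own coordinates.
3. **Upstream codons and uORFs** (`census_by_section()`, `find_orfs()`,
   `call_uorfs()`): overlapping any-frame census of the eight upstream
   start/stop codons (ATG, GTG, CTG, TTG, ACG; TAG, TAA, TGA), each codon
   assigned to the section containing its first base; ORF calling from
   every ATG to the first in-frame stop, *stop codon included* in the length
   (so a 111-nt uORF codes 36 aa: 111/3 − 1). uORF–mORF geometry uses
   `gap_to_morf = morf_start − stop_end − 1`; negative values flag uORFs
   overlapping the main ORF. Start-codon (Kozak) contexts are 21-nt windows
   (9 + ATG + 9, clipped at sequence ends) classified strong (purine at −3
   AND G at +4), weak (neither), adequate (exactly one), or undetermined
   (clipped away).
4. **Composition** (`gc_percent()`, `section_gc()`,
   `segment_repetition_regions()`): GC = Count(G+C)/Count(A+T+G+C) × 100
   with N excluded from both counts; per-section GC with two dominance
   flags (after-section leading by > 8 points, before-section by > 14);
   sliding-window GC series; and base-repetition-rich subregion
   segmentation (below).
5. **Secondary structure** (`read_dotbracket()`, `enumerate_hairpins()`,
   `assign_sections()`): hairpin loops — base pairs enclosing only unpaired
   bases — are enumerated from supplied Vienna dot-bracket structures and
   assigned to sections by the midpoint of the closing pair; a midpoint
   exactly on the boundary counts as before-Intron-1, and loops whose
   closing pair straddles the boundary are flagged `spans_boundary`.
   Thermodynamic folding is deliberately out of scope: structures (and any
   free energies) are inputs produced by dedicated folders. The package's
   own `maxpair_fold()` is a Nussinov-style base-pair maximiser used as a
   deterministic combinatorial structure generator for testing, not a
   thermodynamic prediction.
6. **Variants** (`hotspot_overlap()`): distinct variant positions are
   intersected with the merged hot-spot projections by closed-interval
   containment; the percentage is rounded to the nearest integer, half away
   from zero (39 of 161 → 24%).

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `identity_min` | 80 % | strict lower bound on column identity |
| `occupancy_min` | 84 % | strict lower bound on column occupancy |
| `start_codons` | `ATG` | uORF start set; alternates (GTG/CTG/TTG/ACG) are census-only by default |
| `min_len_nt` | 0 | minimum stop-inclusive uORF length |
| composition `window`/`step` | 30 / 1 nt | segmentation scan geometry |
| `fraction_min` | 0.8 | minimum subset fraction per window and per segment |
| `min_len` | 20 nt | minimum segment length |
| `merge_gap` | 5 nt | maximum gap bridged between qualifying windows |

Identity uses non-gap counts as its denominator and occupancy handles gaps
separately; the two scores are independent criteria. Gap-containing
conventions (counting gaps in the identity denominator) would conflate the
two. Modal-base ties use the tied maximal count for identity; the reported
modal base is alphabetically first, for display only. All-gap columns score
0/0 and can never be hot spots. The alphabet is A, C, G, T, N: N never
matches any codon, is excluded from GC numerator and denominator, and
counts against subset fractions in segmentation.

# Segmentation: from visual pattern to algorithm

Base-repetition-rich subregions (G/C-, T/C-, G/A-, G/C/A-rich) are a
qualitative, visually recognisable feature of these 5'UTRs. The package
re-specifies them quantitatively: a sliding window marks stretches whose
subset fraction reaches `fraction_min`; qualifying windows closer than
`merge_gap` merge; each merged span is then refined to its maximum-scoring
subsegment, scoring every position `in-subset − fraction_min` (a
Kadane-style scan). A non-negative best score guarantees the reported
segment's fraction is at least `fraction_min`; candidates shorter than
`min_len` are dropped, and overlapping candidates of different labels
resolve by higher fraction, then smaller subset, then 5'-most start.

Boundary accuracy is information-limited: a background run of in-subset
bases abutting a block is indistinguishable from the block itself, so for
a moderately enriched block on uniform background an individual boundary
can land more than a few nt off even for a likelihood-optimal estimator.
The tests therefore assert the *median* boundary error over a batch of
seeded plants, not every single boundary. The module reports segments and does not assert their 5'→3'
order, which is an empirical observation about particular families, not an
invariant.

# The synthetic family generator

`generate_family()` emits an annotated ortholog family, its alignment and a
ground-truth table, so every stage is testable without downloads or an
external aligner. It emulates the statistical structure the analysis
assumes, with defaults chosen as a realistic vertebrate-like study
condition:

* four groups (primates-like, rodents-like, other-placental-like,
  reptiles/birds-like) of 5 species each; **after-section lengths constant
  within groups** (99/90/84/69 nt), before-section lengths uniform in
  group-specific ranges (240–340 down to 60–160 nt);
* a **15-nt conserved block** at the start of the after-Intron-1 section
  carrying the family's single upstream ATG out of frame with the main ORF,
  substituted at `block_sub_rate = 0.02` versus `sub_rate = 0.35` in the
  background;
* a **planted uORF** from that uATG whose stop is placed at a
  group-specific relation to the main ORF: overlapping by 22 nt in the
  primates-like group, gaps of 5/8 nt in the rodent/placental-like groups,
  17 nt in the birds-like group — mirroring the banded pattern seen across
  vertebrates;
* per-section **GC targets** (58.7% before, 67.4% after, the human-like
  contrast). Substitutions redraw the base from the section's stationary
  composition, so expected GC stays exactly on target (a draw can silently
  restore the original base; the effective change rate is
  `rate × (1 − p(base))`);
* alignment rows generated directly from the consensus: leading gaps for
  shorter before-sections, before-section deletions at `indel_rate = 0.02`,
  trailing gaps for shorter after-sections. The alignment covers the 5'UTR
  only, so ungapping a row reproduces the record's 5'UTR exactly.

Codon-critical positions (the planted uATG, its stop, the main-ORF ATG) are
never mutated or deleted. Stray upstream ATGs are rewritten (a base set to
C, which can create neither an ATG nor a stop) and premature in-frame stops
inside the planted uORF are likewise cleared, so the planted coordinates
are exactly what an ORF caller must return. `plant_composition_block()`
places its off-subset bases in the block's middle third for the same
reason: sharp, identifiable edges.

What the generator does **not** emulate: tree-structured evolution (species
are i.i.d. around one consensus within groups), insertion events, alignment
error from real aligners, CpG or codon-usage structure, and multiple
competing uORFs. Passing recovery tests on this generator shows the
algorithms are correct under the stated statistical conditions, not that
real Ensembl families will be as clean; with real data the alignment
quality is inherited from whichever aligner produced the input.

All randomness flows through one seed (`spec$seed`, default 0); the global
RNG state is saved and restored, and the same spec yields byte-identical
output.

# Numerical and design choices

* `min_occupancy_count(n, t)` is `floor(n·t/100) + 1`: the smallest count
  strictly exceeding the percentage threshold.
* Percentage rounding in variant overlap is half-away-from-zero to match
  integer-percent reporting conventions.
* Mann–Whitney p-values are exact when `min(n, m) ≤ 8` and there are no
  ties, otherwise a normal approximation with continuity and tie
  correction; a comparison with zero rank variance (all values tied)
  carries no evidence and reports p = 1.
* `maxpair_fold()` pairs AU/UA, GC/CG and GU/UG wobble with hairpin loops of
  at least 3 nt; its traceback is deterministic (pairing is preferred at
  ties, with the smallest admissible partner).
* Open-ended ORFs (no in-frame stop before the sequence end) are flagged
  and excluded from uORF summary tables by default (`keep_open = FALSE`).
* Ties in the longest hot-spot run go to the 5'-most run; an empty hot-spot
  set reports length 0.
* Tables of published coordinates can be fed straight into
  `uorf_geometry()`; exact human intron-1 offsets within spliced
  transcripts are rarely published, so section boundaries are always inputs
  here, not constants.

# Problem sizes used in the test-suite

The suites compare every algorithm against an independent brute-force
oracle at sizes where exhaustive computation is cheap: 1000 random
sequences ≤ 60 nt for the ORF caller, random dot-bracket structures ≤ 40 nt
for the hairpin enumerator, sequences ≤ 12 nt for the exhaustive
nested-pairing check of `maxpair_fold()`, 200 seeded family simulations
(20 species each) for conserved-block recovery, and 20 seeded plants for
segmentation recovery. These sizes keep the default suite comfortably
within a few minutes on one CPU while giving the Monte-Carlo assertions
tight operating characteristics.

# Known limitations

* Conservation is scored on whichever single alignment is supplied;
  comparing alternative aligners, phylogeny-aware conservation scores
  (phastCons/phyloP-style) and consensus logos are out of scope.
* Thermodynamic folding, partition functions and free energies are not
  computed; structure analysis is limited to supplied dot-bracket input.
* Variant positions must already be in transcript coordinates;
  genome-to-transcript liftover is upstream of this package.
* Motif catalogue matching and de-novo motif discovery are external
  analyses; segmentation captures only base-subset repetition structure.
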