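---
title: "Methods: structural LTR detection, insertion dating and siRNA attribution"
author: "retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural LTR detection, insertion dating and siRNA attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscape)
```

# Scope

`retroscape` re-implements, at desk scale and with full ground truth, the
bespoke computations of a TE-centric genome analysis of a large,
repeat-rich plant genome: structural detection of full-length LTR
retrotransposons, Wicker-code bookkeeping with the classical >= 80 bp /
>= 80 % identity filter, molecular-clock dating of insertions from
LTR-pair divergence, attribution of small RNA reads to TEs, and
gene--TE/promoter context analysis. Consensus-library construction,
protein-domain phylogenies, gene prediction and expression quantification
are deliberately out of scope: those steps belong to established
pipelines, while the operations here are the ones a study typically wires
together by hand.

Because the real assembly and read libraries of such a study are far too
large for routine testing, the package ships a first-class synthetic-data
generator. Every quantitative claim the test suite makes is made against
genomes in which the truth -- element coordinates, ages, TSDs, read
origins -- is known by construction.

# The synthetic genome generator

`simulation_config()` + `simulate_genome()` build a single-chromosome
genome of i.i.d. background sequence (GC fraction `background_gc`,
default 0.35, typical of plant genomes) hosting three feature kinds, all
placed without overlap by drawing inter-feature gaps from a uniform
multinomial split of the free space:

* **Full-length LTR retrotransposons**: `TSD -- 5'LTR -- internal --
  3'LTR -- TSD`. The ancestral LTR starts `TG` and ends `CA`; a
  lineage-diagnostic signature is embedded at a random position of the
  internal region. The two LTR copies are then mutated *independently*
  under Jukes--Cantor: after `T` years at rate `r` substitutions per site
  per year, each site changes with probability
  `p1 = (3/4)(1 - exp(-(4/3) r T))`, so the expected corrected divergence
  of the pair is `2 r T` -- the additivity that makes LTR dating exactly
  invertible. No indels are introduced, keeping the divergence estimator
  free of alignment noise by construction (an explicit simplification).
* **Degenerate fragments**: a single LTR plus a truncated internal
  region of an independently drawn element; they carry TE sequence but no
  LTR pair, so a structural detector must not report them.
* **Genes**: background-composition loci with a strand and a start-codon
  coordinate, used by the proximity and promoter stages.

Two generator choices deserve explanation:

* **Terminal dinucleotides are conserved during mutation.** The `TG...CA`
  termini are required for integration and are effectively invariant in
  elements recognisable as full-length; mutating them at the neutral rate
  would make a detector that (correctly) requires them miss ~15 % of old
  elements, which is a statement about terminal decay, not about
  detection. Conserving 4 of ~1500 LTR sites biases the planted
  divergence by < 0.3 %, far below the 3-standard-error bands used in the
  calibration checks.
* **TSD mismatch mix.** TSDs are planted identically on both flanks and
  then 0, 1 or 2 mismatches are injected on one side with probabilities
  0.794 / 0.190 / 0.015 -- the observed mix of intact, one-mismatch and
  two-mismatch TSDs among dateable elements. The cap of 2 matches the
  downstream validator's acceptance rule.

The read simulator draws lengths from `sirna_profile` (default peaked at
23--24 nt, the heterochromatic siRNA signature, with 24 nt carrying the
RdDM pathway), origins uniformly over TE base pairs for a fraction
`frac_te_reads` (default 0.7) and uniformly over gene/background base
pairs otherwise, and strands uniformly. All stages derive deterministic
sub-seeds from `config$seed`, so identical configurations reproduce
byte-identical outputs.

What the generator does **not** emulate: nested insertions, solo-LTR
formation, sequencing error, adapter remnants, expression-weighted read
production, methylation. Passing tests therefore demonstrate algorithmic
correctness against the stated model, not performance on real libraries.

# Structural detection of full-length elements

The reference tool for this task has unpublished internals, so
`detect_full_length_ltrs()` defines its own transparent search built on
the same structural requirements (long direct repeat, `TG...CA`,
near-intact TSD):

1. **Seed scan.** Every exact 15-mer (`seed_word`) is hashed with a
   rolling 2-bit code; positions sharing a hash within a plausible
   separation window form seed pairs. Sequences are split at `N` runs
   longer than 11 nt before scanning, and k-mers containing ambiguous
   bases never seed.
2. **Diagonal clustering.** Because the simulator (and, to first order,
   real LTR pairs) diverge by substitutions, all seed pairs of one LTR
   pair share a diagonal (equal separation `d`); runs on a diagonal with
   gaps <= 500 bp merge into one candidate.
3. **Ungapped X-drop extension** (match +1, mismatch -2, drop 15) pushes
   both boundaries outward; extension halts quickly once it crosses into
   the flanks, which are unrelated sequence.
4. **Termini snapping.** When `require_tg_ca` is set, boundaries are
   snapped (within +/- 12 bp) to offsets where *both* copies carry `TG`
   at the start and `CA` at the end. Among feasible boundary pairs the
   one minimising TSD mismatches, then boundary movement, wins. Using the
   TSD as the arbiter is what makes the flanking windows -- and hence the
   downstream mismatch tally -- line up exactly.
5. **Filters and overlap resolution.** Candidates must satisfy the LTR
   length (100--3000 bp), element span (1--15 kb) and pair identity
   (>= 0.80) constraints; overlapping candidates are resolved by highest
   identity, then longest span, then leftmost position.
6. **Validation** (`validate_structure()`) re-checks termini and finds
   the best-matching TSD of length 4--6 bp in the flanking windows,
   rejecting above 2 mismatches -- the same "almost intact TSD at both
   ends" rule used when selecting elements for dating. Rejections carry a
   reason (`"termini"`, `"tsd_mismatches>2"`).
7. **Lineage labelling** (`classify_lineage()`) scans the internal region
   for the catalogued signature with the best local alignment at >= 0.7
   identity over >= 50 % of the signature; elements without one stay
   `RLX`/unknown. The shipped signatures are synthetic stand-ins (real
   diagnostic domains are not redistributable); 60 bp long on purpose,
   below the minimum LTR length, so signature repeats shared by
   neighbouring elements can never themselves become accepted candidates.

The scan is forward-strand only, matching the generator; reverse-strand
detection is an extension point, not a current claim. Known limitation:
when a planted TSD carries 1--2 mismatches, an in-register alternative
boundary occasionally presents a cleaner TSD and wins the snap, slightly
deflating the mismatch tally (a few elements in 200) and moving a
boundary by a couple of base pairs -- visible in truth comparisons,
negligible for dating.

# Insertion dating

The age of a full-length element is estimated as `T = d / (2 r)`: both
LTR copies are identical at insertion, so their divergence `d`
accumulates at twice the per-site rate. The rate is calibrated from
cross-species synonymous divergence: with `dKs = 0.37 - 0.23 = 0.14`
between two related species separated `T_spec = 36` My,

```{r calibration}
cal <- calibrate_rate_from_ks(0.37, 0.23, t_spec_my = 36,
                              noncoding_multiplier = 2.0)
cal
```

The doubling for non-coding sequence happens **before** any rounding:
`2 x 1.9444e-9 = 3.8889e-9` displays as `3.89e-09`, whereas doubling the
rounded `1.94e-9` would print `3.88e-09`. All fields are stored at full
precision; 3-significant-figure formatting is display-only.

`align_ltr_pair()` computes a global affine-gap alignment (match +2,
mismatch -2, gap open -6, gap extend -1 -- fixed defaults recorded in the
output for reproducibility); gap columns are excluded from the p-distance
denominator. `divergence()` offers two models: `raw` (`d = p`) and the
default `jc` (`d = -(3/4) log(1 - 4p/3)`), which exactly inverts the
generator's substitution process in expectation and saturates at
`p >= 0.75`. The source study writes "Ks" for LTR divergence without
naming a correction; since LTRs are non-coding and "Ks" is used loosely
there, both models are provided and every output row records which one
produced it. `raw` underestimates `jc` for every `p > 0` (a tested
invariant), so model choice shifts ages systematically -- worth knowing
when comparing age histograms across studies.

`bin_ages()` bins ages into half-open `[k w, (k+1) w)` intervals (default
`w = 0.5` My) per superfamily or lineage, the conventional resolution for
insertion-time histograms.

# Small RNA attribution

The pipeline mirrors the usual annotate-by-intersection recipe:
`collapse_reads()` (U -> T, lexicographic order, multiplicities),
`exclude_mirnas()` (exact-sequence blacklist), `map_best_hit()`,
`intersect_te()`, then `size_distribution()` and
`production_by_superfamily()`.

Mapping replaces a heuristic aligner with exact both-strand matching
(`PDict`/`matchPDict` per length group): for 20--25 nt reads every
genuine hit is a full-length exact match, which makes "best hit"
deterministic and testable. The heuristic aligner's vocabulary survives
as configuration (`min_score`, default 10); mismatched alignment is
refused rather than half-implemented. A read with one best locus is
`unique`; with several, `ambiguous`, recorded at the leftmost locus
(chromosome lexicographic, then coordinate, `+` before `-`) and excluded
from quantification; with none, `unmapped`.

A locus is TE-derived iff it overlaps a TE by >= `min_overlap_bp`
(default 1), assigned to the TE with the largest overlap (leftmost on
ties). Because "size distribution of unique accessions" and "percent of
total reads" are both in circulation, `size_distribution()` implements
both weightings and labels its output; read-count weighting is the
default for per-superfamily production tables, where percentages are
taken over the three-letter Wicker codes (completeness suffix dropped).

# Genomic context

* `gene_te_proximity()` counts a gene for threshold `t` iff the minimum
  distance from its annotated span (not the TSS -- the anchor is
  configurable by supplying different intervals) to any TE is <= `t`;
  overlap counts as distance zero, and the fraction is monotone in `t`.
* `extract_promoters()` returns the `length_bp` (default 2000) bases
  upstream of the start codon, reverse-complemented for minus-strand
  genes and truncated at contig edges ("when possible"), with the actual
  width reported.
* `scan_motifs()` counts IUPAC patterns on both strands, overlapping
  occurrences included; palindromic patterns are counted once per strand
  by default (switchable), and the double-count rule is explicit because
  it changes enhancer-box totals. The shipped catalog carries the
  familiar element names (CAAT-box, G-Box, ARE, ABRE, ...) with
  synthetic placeholder patterns -- the proprietary reference matrices
  are not redistributable, so counts from the default catalog are for
  exercising the machinery, not for biological comparison.
* `dotplot_matrix()` reports exact word matches (default 10-mers) on both
  strands for side-by-side locus comparison, the word-matrix equivalent
  of the usual dot-plot tools.

# Numerical and testing choices

* Coordinates are 1-based inclusive everywhere, the native convention of
  both GFF3 and the IRanges/GRanges stack; conversion layers would be the
  only place an off-by-one could hide, so there are none.
* Wicker-code quirks follow the printed convention: Helitrons code as
  `HX`, LARD/TRIM as `RXX-LARD`/`RXX-TRIM` without a completeness
  suffix.
* Filter thresholds mean "at least" (>= 80 bp, >= 80.0 %), reconciling
  the two phrasings in circulation (">79 bp & >79 % id" for integer
  lengths). Genome coverage merges overlapping TE spans per chromosome
  before summing -- per-base occupancy is the only self-consistent
  "percent of genome".
* Interval engines (intersection, proximity, dot-plot) are tested against
  hand-written all-pairs brute-force oracles on randomized fixtures; the
  stochastic claims (mutation calibration, profile recovery) are tested
  within 3 binomial standard errors at the stated problem sizes.
* Problem sizes in the test suite -- 200 planted elements of 1500 bp LTRs
  for age recovery, a 1e5-site LTR pair for the closed-form
  Jukes--Cantor check, 1e4 reads for profile recovery, 1 Mb x 5 seeds of
  pure background for the false-positive invariant -- were chosen so each
  statistical band is tight enough to be informative while a full run
  stays a desk-scale computation.
* Genome-scale figures from real assemblies (overall TE content, total
  filtered copy numbers, the 11 % / 8.2 % proximity fractions, the
  per-superfamily siRNA shares) depend on data this package does not
  ship; the procedures that produce them are covered by the property
  tests above, and `scripts/acceptance.R` recomputes the package's own
  quantities from scratch on simulated inputs.
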