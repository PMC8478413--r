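---
title: "Designing Cas12a CRISPR arrays with AT-rich synthetic separators"
author: "cas12array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Cas12a CRISPR arrays with AT-rich synthetic separators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12array)
```

## The problem this package addresses

Cas12a can process its own CRISPR array: a single transcript of
alternating direct repeats and spacers is cleaved at the 5' end of every
repeat, releasing individual guide RNAs (gRNAs). This makes Cas12a
attractive for multiplexed editing and CRISPR activation (CRISPRa), but
array performance is unpredictable: a high-GC spacer can strongly impair
the activity of the *downstream* gRNA, in extreme cases through a single
A/T-to-G/C change near the spacer's 3' end. The mechanism is secondary
structure: GC-rich 3' spacer ends base-pair with the following repeat and
spacer, occluding the Cas12a cleavage site.

Natural Cas12a arrays contain, in each pre-processing repeat, an AT-rich
~16-18-nt fragment (the *CRISPR separator*) that is excised during
maturation and insulates adjacent gRNAs. Synthetic constructs have
historically omitted it entirely — and re-inserting the full-length
separator is counterproductive, because Cas12a cannot fully excise it and
the long 3' tail impairs the gRNA. The effective compromise is a short,
1-4-nt AT-rich *synSeparator* (e.g. `AAAT`, the 3'-terminal fragment of the
*Lachnospiraceae bacterium* separator; `TTTT` for *Acidaminococcus* sp.)
placed upstream of every repeat.

`cas12array` implements this design space end to end: GC-window statistics
that identify risky spacers, structure-interference scoring in array
context, annotated array construction under per-site separator policies,
prediction of post-processing fragment species, planning of the
oligo-duplex ligation assembly, and quantification of processing
efficiency from electropherogram peak tables.

## Spacer GC statistics

`sliding_gc()` computes GC content in a sliding window of `base_width`
(default 5) nt. Near the 3' end the window shrinks one nucleotide at a
time to `min_width` (default 2), each shrunk window anchored at the 3'
terminus: resolution is increased exactly where it matters, next to the
cleavage site. A 20-nt spacer therefore yields `(20 - 5 + 1) + 3 = 19`
windows.

`window_predictive_power()` quantifies which part of a spacer matters. It
divides each spacer of a library into all contiguous 3-nt windows
(eighteen for 20-nt spacers), regresses a response (e.g. percent
GFP-positive cells in an activation assay) on window GC across the
library, and reports each window's R². Degenerate regressions
(zero-variance response or predictor) are defined as R² = 0 rather than
an error. The R² of whole-spacer GC is reported alongside: the
characteristic result is that the *last* 3-nt window is more predictive
than whole-spacer GC.

`group_profiles()` reproduces the grouped-profile view: spacers are
split into response tiers and per-window mean GC ± standard error
(sample SD / sqrt(n)) is reported per tier. The tiers are *tertiles by
count* in response rank order, ties broken by stable input order; the
alternative (tertiles by response value) is not used because equal-sized
groups keep the standard errors comparable across tiers.

```{r windowscan}
lib <- generate_benchmark_library(seed = 1)
tgc <- vapply(lib$entries, function(s) s$terminal_gc_k3, 0)
set.seed(2); resp <- 1 - tgc + rnorm(51, 0, 0.05)
scan <- window_predictive_power(lib$entries, resp)
tail(scan, 3)
attr(scan, "whole_sequence_r2")
```

## The benchmark spacer library

`generate_benchmark_library()` regenerates the 51-spacer GC benchmark:
five random 20-nt dummy spacers per 10%-GC decile from 10% to 90%, plus
six pilot spacers spanning 30-80% GC. The source recipe states only the
pilot range, so the generator places one pilot per decile from 30% to 80%;
this choice is recorded in the library's `recipe` field. GC targets are
realized as exact base counts — `round(gc_target * length)` G/C residues,
rounding half up — so the decile histogram of a generated library is exact
by construction and testable, while sequences vary freely with the seed.
Because these are *random* spacers (the original benchmark adapted
scrambled guide sequences), analyses that depend on the exact published
spacer sequences (e.g. the published fluorescence R² values of 0.45/0.52
or the structure-GC R² of 0.66) are reproducible only in shape and sign,
not in value; the package's checks assert exactly that and no more.

## Natural separator profiling

Natural Cas12a spacers vary from 25 to 36 nt. `anchor_3prime()` stacks
them on their 3' ends (5'-truncating longer sequences to 25 nt,
gap-padding shorter ones) so that positions are comparable relative to the
cleavage site; `column_gc_profile()` then applies the same
sliding/shrinking window machinery to per-column GC, with gaps excluded
from both numerator and denominator and all-gap columns reported as
missing. For separator collections, which are aligned externally (e.g.
with T-Coffee or MAFFT — this package consumes alignments, it never
computes them), `iupac_consensus()` reports per-column minimal IUPAC
codes. The inclusion threshold is `min_freq = 0.25` so that a 50/50
two-state column yields a two-fold code — the setting under which the
conserved 5' separator motif reads `GTYTA`. If no base reaches the
threshold the observed bases are covered instead, so the consensus never
silently drops a column.

## Structure-interference scoring

`context_score()` folds the direct concatenation — no linker, matching how
the transcript is actually joined — of an upstream spacer with its
downstream gRNA (repeat + spacer) and reports
`score = max(0, -ensemble_free_energy)`, so larger scores mean more stable
predicted structure. Two backends:

* `"vienna"`: RNAfold (ViennaRNA) partition-function folding at 37 °C,
  default parameters; the ensemble free energy is parsed from `-p0`
  output. Used when quantitative energies are wanted.
* `"oracle"`: an internal exact dynamic program maximizing weighted nested
  base pairs (GC = 3, AU = 2, GU = 1, hairpin loops ≥ 3), rescaled at
  −0.8 pseudo-kcal/mol per weight unit. It is deliberately simple — no
  stacking, no loop entropies, no pseudoknots — but exact for its own
  objective, fully self-contained, and doubles as an independent oracle
  in the test suite.

A missing RNAfold is an explicit error instructing backend selection;
backends are never substituted silently, because scores from the two
backends are on different scales.

`risk_report()` combines the two predictive features into a flag:
`HIGH` when the GC fraction of the last three nucleotides is ≥ 2/3 (i.e.
at least two of the last three bases are G/C — the region most predictive
of downstream-gRNA failure), otherwise `ELEVATED` when the context score
exceeds the collection's 75th percentile, otherwise `LOW`. Both cutoffs
are package choices (the underlying data support a qualitative, not a
calibrated, threshold) and both are exposed as arguments.

## Array construction and fragment prediction

`build_array()` assembles `leader + [separator + repeat + spacer]*n +
(separator + trailing repeat) + flank` under a per-site
`separator_policy()` — one entry per cleavage site, each `none`, `full`,
`syn`, or a literal sequence — and annotates every feature with 0-based
half-open intervals that tile the sequence exactly. The trailing repeat
defaults to on (a two-gRNA assay array then has three cleavage sites).
Designs export to FASTA and to a minimal GenBank flat file that
round-trips through `read_genbank()`.

`predicted_fragments()` models complete processing: cuts at the 5'
boundary of every repeat, with any separator upstream of a cut retained on
the *upstream* fragment — which is why a synSeparator slightly lengthens
the gRNA it follows. For the two-gRNA assay geometry (57-nt leader, 20-nt
repeat, 21/22-nt spacers, 138-nt flank) this yields fragments
57/41/42/158 nt without separators and 61/45/46/158 nt under the
AAAT-everywhere policy:

```{r fragments}
profile <- get_species_profile("LbCas12a")
sp <- list(generate_spacer(21, 0.70, 11, "dummy70"),
           generate_spacer(22, 0.45, 12, "gfp"))
set.seed(13); leader <- paste(sample(c("A","C","G","T"), 57, TRUE), collapse = "")
set.seed(14); flank <- paste(sample(c("A","C","G","T"), 138, TRUE), collapse = "")
d <- build_array(sp, profile, separator_policy("AAAT", 3),
                 leader = leader, three_prime_flank = flank)
predicted_fragments(d)
```

Intra-repeat cut offsets are deliberately not modeled: the quantification
arithmetic only needs which side of the repeat boundary each separator
lands on.

`polya_scan()` screens designs for the twelve common human
polyadenylation-signal hexamers — AT-rich insertions could in principle
create one and truncate the transcript — reporting every overlapping
occurrence.

## Assembly planning

`plan_oligos()` divides the double-stranded array into oligo duplexes of
≤ 60 nt per strand joined by 4-nt 5' overhangs, partitioned into ligation
pots of ≤ 8 duplexes (12 duplexes split as 6 + 6). Because pot products
are themselves ligated in a second round, overhang uniqueness is enforced
*globally*, not per pot — the stricter reading, and the safe one.
Beyond uniqueness, palindromic overhangs and reverse-complement pairs are
excluded by default since either permits misligation in a one-pot
reaction; both exclusions are toggleable.

The search is deterministic backtracking over junction positions: target
fragment sizes of about `max_oligo - 2*overhang` nt leave each junction
placement slack, candidates are explored outward from the ideal
equal-spacing position (positive offsets before negative), and a node
budget per duplex count makes the search fall through to one more duplex
rather than thrash when a region is overhang-poor. Infeasible inputs
(e.g. homopolymers, where every candidate overhang is identical) raise an
infeasibility error naming the first violated constraint; the planner
never emits an invalid plan, and every plan it does emit is re-checked by
`verify_plan()`, an independent verifier that works only from the oligos
themselves. Plan ends are blunt: the array joins its vector by In-Fusion
(20-bp homology added by `add_infusion_flanks()`), not by ligation.

The stagger convention: at a junction at top-strand position *j*, the top
strand is cut at *j* and the bottom strand at *j + 4*, so the 4-nt region
between is a 5' extension on the downstream duplex's top oligo and on the
upstream duplex's bottom oligo:

```
top     5'-ACGTACGTACGT    OHOH ACGTACGT-3'
                           ||||
bottom  3'-TGCATGCATGCA HOHO    TGCATGCA-5'
```

## Processing quantification

`theoretical_max_fraction()` computes the mass fraction of single gRNAs
at complete processing under mass-length proportionality (Bioanalyzer
areas report mass): `(41 + 42)/(57 + 41 + 42 + 158) = 0.28` for the assay
array above, rising to 29% with the AAAT synSeparator. `match_peaks()`
assigns observed peaks to expected fragments greedily, one-to-one, in
order of increasing distance, within a ±10% sizing tolerance
(instrument-typical; configurable). An expected fragment left unmatched
while a peak within its tolerance was claimed by another fragment is an
*ambiguous assignment* error — unless the two fragments are declared a
co-migrating group (the 41/42-nt doublet sized as one peak), in which case
the peak covers the group. A declared marker length (25 nt by default) is
always excluded. `normalize_replicates()` rescales tables to the sample
with the lowest total non-marker area, and `percent_of_max()` reports
`100 * observed fraction / theoretical maximum`.

`simulate_electropherogram()` generates synthetic peak tables at a given
processing completeness: fragment peaks carry `completeness x length`
mass, the intact transcript the remainder, with 1% Gaussian sizing and
area noise and a marker peak. It emulates a clean endpoint mixture of
fully-processed and intact molecules — real digests also contain partial
intermediates, baseline drift, and sizing bias that it does not model —
so round-trip recovery of completeness (±2 points) validates the
quantification arithmetic, not the instrument model.

## Problem sizes and numerical choices

The test-suite and validation workloads use the sizes the methods are
designed for: the 51-spacer library, 200 spacers for the GC-structure
sign check, 500 random sequences (50-3000 bp) for assembly round-trips,
and a 30-gRNA array (~1.4 kb) as the assembly capability floor. Exact
reproduction of published R² values would require the original spacer
sequences and fluorescence source data, which are distributed as
supplementary files; `scripts/validate_natural_sets.R` recomputes the
natural-collection statistics (spacer count, mean GC, separator count and
consensus) from such files when the user supplies them.

Other conventions: coordinates are 0-based half-open on the top strand;
DNA is the canonical storage alphabet with RNA views generated for
folding; GC ambiguity codes S/W are resolved (1/0) and other codes
rejected unless explicitly permitted; `round(gc_target * length)` rounds
half up so GC counts are platform-stable; and every seeded function
restores the caller's RNG state.

## Known limitations

* The packaged registry's full-length separator sequences are synthetic
  placeholders (marked as such in their provenance fields): the curated
  per-species separators live in supplementary species records. Replace
  them via a custom registry file before relying on `policy = "full"`
  designs.
* The fallback structure backend scores base-pairing potential, not
  thermodynamics; use it for ranking and sign, not for energies.
* No pseudoknot prediction: the repeat's natural pseudoknot is outside
  both backends' structure space.
* Assembly planning optimizes constraint satisfaction and balance, not
  melting temperature or synthesis cost.
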