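---
title: "Methods: out-of-frame stop codons and indel-driven loop variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: out-of-frame stop codons and indel-driven loop variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscindel)
```

## The model

Coding DNA read in its annotated frame is littered with *out-of-frame
stop codons* (OSCs): TAA/TAG/TGA triplets whose start offset is not a
multiple of 3. They are silent during normal translation but become
active stops the moment an insertion or deletion (indel) shifts the
reading frame. Consecutive codons such as CTG AAA hide a TGA in the +1
frame at their junction. This package implements the computational side
of a gain-of-function experimental design built on that fact:

1. An ornithine-carbamoyltransferase-like ORF carries an engineered +1
   single-base insertion downstream of a glutamine codon followed by
   A-A, so the very next in-frame codon is an ochre TAA and the protein
   is truncated (selection "off", arginine auxotrophy in the wet
   system).
2. A revertant indel whose net length change `d` satisfies
   `(+1 + d) mod 3 = 0` restores the frame. It produces a functional
   protein **only if** translation from codon 1 then reaches the
   construct's natural stop codon exactly, with no earlier stop.
3. Latent OSCs upstream of the engineered insertion veto a subset of
   frame-restoring indels: an OSC in frame `+1` whose window starts
   downstream of the event is displaced by `d ≡ 2 (mod 3)` into frame 0
   and terminates translation prematurely. Removing those OSCs by
   synonymous recoding (the `-OSC` construct) widens the set of
   permitted revertants — the computational core of the `+OSC`/`-OSC`
   contrast, and the mechanism behind `reconstruct_in_host()` and
   `fraction_forbidden()`.

Classification in `classify_outcome()` is exactly this contract:

* `functional_restored` — net frame shift 0 **and** first stop is the
  natural stop;
* `premature_stop` — some stop read before the natural stop position;
* `frame_disrupted` — everything else, including read-through past the
  natural stop (reported with an absent stop index).

`loop_delta_aa` is the signed codon-count change of the loop,
`(frameshift_offset + d)/3` for functional revertants; this assumes the
engineered insertion and the revertant event both fall inside the loop
region, which is the designed use of the system.

## Coordinates, codon table, ambiguity

Internal coordinates are 0-based half-open; everything at an I/O
boundary (TSV, CLI, error messages) is 1-based inclusive, matching how
codons are conventionally numbered. There is one conversion boundary, in
the CLI writers.

Translation uses NCBI table 11 (bacterial/plastid) with no start-codon
special-casing: the machinery here is frame arithmetic over an already
annotated ORF, not gene calling. Input is strictly A/C/G/T by default;
`strict = FALSE` admits IUPAC ambiguity codes, and the scanner then
skips windows containing them.

## OSC scanning conventions

`scan_oscs()` reports every stop triplet fully inside the sequence whose
offset mod 3 is in the requested frame set, forward strand only,
default frames +1 and +2. No wrapping, no partial windows, and no
exclusion near the natural stop — OSCs overlapping the terminator region
count like any other, so a reported total for a real gene is
reproducible under exactly one stated convention. Output is ordered by
offset then frame. Which frames (or strand) produced any published
per-gene OSC total is a choice the original analyses leave implicit;
forward +1/+2 is this package's documented one.

## Indel normalization

Events inside repeat runs admit several placements that yield the same
mutant (the classic ambiguous di-adenine deletion). Before
deduplication and spectrum tallying, `left_align_indel()` shifts events
to the leftmost equivalent placement, mirroring variant-call
left-alignment practice. Whether the original mutant tables were left-
or right-aligned is not stated anywhere authoritative; left is this
package's documented and tested choice, and normalization provably
never changes the mutant sequence, hence never the outcome class.
Spectrum denominators are per-strain totals of sequenced mutants.

## Alignment profiling choices

* **Conservation** is the strict rule "more than 50% of *sequences*
  share the residue", computed by default over all rows, so a gap counts
  against conservation (`gaps_in_denominator = FALSE` switches to
  non-gap rows; whether the original rule excluded gapped rows is
  unstated, so both are available and the default is flagged).
* **Information content** is `log2(20) − H` bits with `H` the Shannon
  entropy of the non-gap residue frequencies. The WebLogo small-sample
  correction `e_n = 19/(2 ln 2 · n)` is implemented but **off** by
  default: at n = 100 it shifts bits by ~0.14 and published figures do
  not state whether it was applied.
* **Loop lengths** count non-gap residues between two anchor columns,
  *inclusive of both anchors*: anchors at reference residues 36 and 47
  give a 12-residue reference loop, which fixes the inclusivity
  convention.
* **OSC overlay** marks an OSC as "on a conserved codon" when *any* of
  its one or two overlapped codons maps to a conserved column
  (any-overlap rule) — boundary-spanning triplets have no published
  overlap convention, so this one is stated and tested.
* Consensus ties break to the lexicographically smallest residue and are
  flagged in the output.

## Junction OSC likelihoods

For an ordered amino-acid pair the junction windows are exactly the two
out-of-frame triplets fully contained in the 6-nt codon pair: offsets +1
(`c1[2] c1[3] c2[1]`) and +2 (`c1[3] c2[1] c2[2]`). Windows extending
into neighboring codons are excluded because the analysis concerns
isolated position pairs; this choice changes the numbers and is stated
prominently. A junction with stops in both frames counts once (the
probability of the union); `frame_breakdown` exposes the per-frame
parts. Default codon usage is uniform within each amino acid — the
instrument for "independent of codon bias" statements — and organism
usage tables are accepted. Lysine–lysine junctions have probability 0
(no T anywhere); leucine–lysine has 5/6 under uniform usage (only CTC
among leucine's six codons avoids a junction stop). Whether published
position labels are reference-protein or alignment coordinates is
ambiguous; both are accepted and the caller chooses the columns.

## Fluctuation statistics

The Lea–Coulson method of the median solves `r̃/m − ln m = 1.24` for the
expected mutations per culture `m`, with `r̃` the interpolated median of
per-culture mutant counts, by bracketed bisection on `[1e-6, 1e6]` to
`|f| < 1e-9`; the cited method names no formulas, so the constant, the
bracket and the tolerance are this package's documented choices from the
classical formulation. The rate is reported as `mu = m / N_t` per cell
per culture growth, with no ln 2 per-generation refinement. A
leave-one-culture-out jackknife CI is available as a labeled extra.
`r̃ = 0` is an estimation error ("rate below detection"), not a number.
SPM frequency curves normalize cumulative revertants to the *initial*
CFU plated only; viability series are carried alongside but never
rescale the curve.

## The synthetic world

The generators state a world once and the tests measure it:

* **ORFs**: `gen_coding_sequence()` defaults to GC 0.435 (a
  B. subtilis-like genome average), single terminal stop, no internal
  stops, optional homopolymer cap. Codons are drawn with an
  exponentially tilted distribution solved to hit the GC target in
  expectation, then rejection-checked to ±0.05.
* **Construct pairs**: `remove_oscs_synonymously()` recodes a codon
  region by dynamic programming over junctions (every out-of-frame
  window spans a junction, so this is exhaustive), minimizing changed
  codons, then changed nucleotides, then alphabetically. Irreducible
  junctions (e.g. Met–Lys, whose ATG AAA always reads TGA off-frame) are
  reported as explicit infeasibility.
* **Revertant pools**: `gen_mutant_pool()` draws events by weight; with
  `selectable_only = TRUE` the spectrum entries are classified once and
  sampling is restricted to the functional ones with renormalized
  weights — mathematically identical to per-draw rejection sampling,
  since outcomes are deterministic given the construct.
* **Fluctuation cultures**: the default `"asynchronous"` model draws
  each mutation's population size uniformly over divisions and gives its
  clone `floor(n_final/N)` cells, reproducing the clone-size law
  `P(size ≥ s) = 1/s` that the 1.24 calibration assumes; the estimator
  recovers planted `m` essentially unbiasedly on it. A synchronized
  discrete-generation variant (`model = "discrete"`) was the initially
  planned default, but its power-of-two clone quantization measurably
  biases the median estimate ~15% low, so it is retained only for
  comparison against generation-by-generation brute-force simulators.
* **Alignments**: `gen_alignment()` plants per-column consensus identity
  and per-taxon loop-length distributions realized as gaps inside the
  loop span (anchors always occupied). The default acceptance design
  uses two taxa of 100 sequences with loop lengths in the 11–21 range
  tracked by taxon, emulating the shape of real cross-phylum loop
  variation.
* The SPM generator plants a fold change of 3.5 between two strains at a
  design scale (daily means 700 vs 200 over 14 days) chosen so sampling
  error (~2%) sits well inside the 10% recovery band.

What the generators do **not** emulate: real phylogenetic correlation
between rows, substitution processes, indel phylogenetics,
plating-efficiency or phenotypic-lag effects, and real mutational
sequence context. A green recovery test therefore establishes that the
pipeline's statistics are correct on data matching its model
assumptions — not that the model captures every property of the wet
system.

## The shipped toy fixture

`toy_construct_pair()` builds a 13-codon ORF with a frame +2 TGA at the
codon 3|4 junction, a frame +1 TGA at the CTG AAA codon 5|6 junction,
and the +1T-after-Gln-7 off switch; the synonymous recoding (AAT→AAC,
CTG→CTC) is found by the DP and removes both OSCs while preserving the
protein. The 11 revertant events in `inst/extdata/toy_events.tsv` are
all functional in the −OSC construct; exactly the 4 events upstream of
the frame +1 OSC are vetoed in the +OSC construct, reproducing the
4/11 ≈ 36.4% "forbidden" arithmetic. These events are a constructed
demonstration of the mechanism, not a re-derivation of any published
mutant list (which lives in figure graphics and is not recoverable from
text).

## Numerical and degenerate-input choices

* Root finding: monotone `f(m) = r̃/m − ln m − 1.24`, bracket widened
  automatically if ever needed, bisection-polished to `|f| < 1e-9`.
* Fold change with a zero denominator is `NA` with a warning, never
  `Inf`.
* All-gap alignment columns have gap fraction 1, no consensus, `NA`
  bits; all-gap column pairs are an error in the observed-likelihood
  method.
* Empty event lists are an argument error for `fraction_forbidden()`
  (a 0/0 fraction has no meaning) but an empty pool is valid output for
  `gen_mutant_pool(n = 0)`.
* TSV numerics default to full 17-significant-digit round-trip-exact
  serialization; a documented `digits` argument trades precision for
  readability.

## Known limitations

* Site correspondence between constructs is identity of coordinates,
  valid only for synonymous pairs of equal length; arbitrary homolog
  mapping is out of scope.
* Multi-event mutants are not modeled (revertants in the motivating
  design are single-event).
* `classify_outcome()` assumes edits upstream of the natural stop; an
  event downstream of it would misplace the expected stop position.
* The CLI is a thin, deterministic wrapper; it does not parallelize and
  holds inputs in memory, which is appropriate for gene-scale data.
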