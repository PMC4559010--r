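---
title: "Methods: simulating and assembling optical genome maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and assembling optical genome maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmapr)
```

## The measurement being modelled

Nanochannel optical mapping images mega-sized DNA molecules on which a
nicking endonuclease (here Nt.BspQ1, recognition motif `GCTCTTC`) has
deposited fluorescent labels. Each molecule is reduced to an ordered list
of label positions plus a total length; a consensus genome map is an
ordered label pattern assembled from many molecules covering the same
locus. `opmapr` implements the full in-silico counterpart: digestion of
sequences into label maps, simulation of labelled molecules under an
explicit error model, consensus assembly, and error-aware alignment of
label maps, together with the descriptive statistics (N50, label
densities, depth titration) used to judge such an experiment.

## In-silico digestion and enzyme choice

`find_motif_sites()` scans both strands — a nickase cuts one strand, but
the label is visible regardless of which strand carries the site — and
pools the 0-based positions of occurrences; windows containing `N` never
match. Two sites closer than the optical resolution (500 bp by default)
cannot be told apart on an image, so `apply_resolution()` collapses
maximal chains of sub-resolution sites to the midpoint of each chain's
extremes. Comparison against the resolution is strict (`gap < 500`
merges, `gap == 500` does not), the merge is idempotent, and output gaps
are always at least the resolution. Nick density (motif occurrences per
100 kb) therefore always bounds label density from above.

`enzyme_report()` ranks candidate enzymes by the distance of their label
density from the platform optimum of ~10 per 100 kb. Only the Nt.BspQ1
motif ships with the package; other enzymes' motifs must be supplied by
the caller. Empirically the genome-wide average label density observed on
the instrument fluctuates about ±15% around the pilot in-silico estimate,
which `fluctuation_band()` encodes; for a pilot estimate of 11.0 per
100 kb the lower edge is 9.35.

## The synthetic-data generator

`simulate_genome()` draws i.i.d. background bases at a requested GC
content (0.4 by default, a typical teleost value) and plants motif copies
at Poisson spacings. Planting is tuned so that the *post-resolution*
density hits the target: for a Poisson site process of rate λ the
post-merge label rate is λ·exp(−λ·res), and the planted rate is the root
of that relation minus the expected background motif rate at the given
base composition. The default target of 11 labels per 100 kb corresponds
to the enzyme-selection estimate for the genome the package emulates.

Molecule lengths follow a log-normal law truncated at the instrument
minimum of 100 kb. The law has two free parameters and the package pins
them with two observable targets: molecule N50 (176 kb by default) and
the median retained length (150 kb, matching the observation that about
half of all molecules fall between 100 and 150 kb). Both calibrations
use closed-form truncated log-normal expressions solved by root finding,
so a simulated set of a few thousand molecules reproduces the target N50
within a few percent.

`corrupt_molecule()` applies the error model in a fixed order:

1. each true label is dropped with probability `fn_prob` (0.15);
2. false labels arrive as a Poisson count at `fp_rate` per 100 kb (1.5),
   uniformly placed;
3. every inter-label gap (including the two terminal flanks) receives
   Gaussian noise with sd `s0·sqrt(gap)` (`s0 = 5` bp^0.5), and positions
   are re-accumulated, so molecule length is noisy too;
4. a per-molecule stretch factor `Normal(1.008, 0.01)` scales positions
   and length — the 0.8% mean encodes the observation that the effective
   pixel scale is about 504 bp against a 500-bp nominal pixel;
5. positions are quantized to the pixel grid (`bpp = 500`);
6. labels closer than the resolution fuse (truth correspondence is
   recorded before the merge).

The composition order is a modelling choice: the physical error sources
are label chemistry (FN), imaging artefacts (FP), local sizing noise,
global stretch, then camera discretization and resolution. The
square-root sizing law is the standard treatment for length measurements
that accumulate independent local errors. Chimeric molecules and
unlabeled-molecule dropout are not modelled. One RNG stream seeded once
drives every stage, so a seed reproduces a dataset byte for byte.

What passing tests on these simulations do *not* show: real molecule
populations carry chimeras, knots, stretch heterogeneity along a single
molecule, and locus-dependent label efficiency, none of which the
generator emulates. Results on simulation bound what the algorithms can
do under the stated error model, not instrument performance.

## Alignment scoring

Label-map alignment is a local dynamic programme over label pairs.
Matching two consecutive pairs scores `-(Δref − Δquery)² / (2·(s0²·Δref +
sd0²))` plus a match bonus; skipping a reference label costs
`−log(fn_prob)`; skipping a query label costs the log-odds that an
observed label is spurious, `−log(fp_rate / ref_label_density)` with a
nominal genuine-label density of 10 per 100 kb. The additive variance
floor `sd0 = 250` bp absorbs pixel quantization and resolution-merge
shifts, which do not scale with gap length. `max_skip` (4) bounds
consecutive skips and is part of the scoring model — the brute-force
oracle (`brute_force_align()`), which enumerates every monotone pairing in
both orientations, applies the same bound and must agree with the DP
exactly.

The mapping length ratio divides the aligned query span by the query's
total length. The span runs between the terminal matched labels, extended
on each side by half the flanking gap to the nearest unmatched label;
when every label on a side is matched the span extends to the molecule
end. Under this rule self-alignment scores exactly 1, and the thorough
threshold of 0.95 (inclusive) reflects that the flanks before the first
and after the last nicking site carry no label information. The
denominator is the full sequence length, not the inter-label span, as the
ratio is meant to expose partial (e.g. end-of-map) alignments.

Two estimators read instrument parameters back off alignments.
`estimate_fp_rate()` projects unmatched in-span query labels into
reference coordinates and classifies them against the reference label
set with a noise-scaled tolerance, then divides by two detection
efficiencies computed from the data (the chance a spurious label escapes
the classification window, and the chance it escapes resolution fusion
with an observed label). The estimator carries a mild upward bias of
order 10% at the default rates, from true labels orphaned by chain
trimming; spurious labels absorbed into matches by the DP bias it the
other way. `estimate_bpp()` regresses matched query gaps on reference
gaps through the origin; the pooled slope times the nominal pixel size is
the effective bp-per-pixel scale, so the default 0.8% stretch reads out
as ≈504.

## Consensus assembly

The assembler follows cluster → layout → density-peak consensus, with
three design choices that proved necessary at realistic error rates:

**Overlap graph with statistical gating.** Pairwise overlap distances
come from the same DP scoring, normalized as `1 − S/(match_bonus ·
min(n_A, n_B))` and gated on a minimum matched chain of 8 sites. A single
agreeing gap separates genuine overlap from coincidence only weakly
(sizing sd is hundreds of bp against an exponential gap distribution), so
chain length carries the evidence; 8 sites keeps the per-pair
coincidence rate near 10⁻³ while any ≥100-kb true overlap qualifies at
the default densities. Remaining coincidental edges are removed by
per-molecule placement disambiguation: a molecule's edges are grouped
into mutually consistent placements (neighbour pairs whose transforms
compose within `confirm_offset_tol`), and a rival group is rejected when
it implies overlaps with the main group that the detection model says
should have been seen but were not, or directly contradicts it.

**Corroborated, globally synchronized layout.** Single linkage over the
gated graph defines clusters; the default linkage is single rather than
average because molecules tile a region while sharing only partial
intervals — average-linkage distances between region-scale groups
saturate near 1 and no cut height separates tiling from disjoint loci.
Within a cluster the layout grows best-first from the longest molecule;
once three molecules are placed, each further placement needs a second,
independent placed neighbour agreeing on the position within 5 kb, and a
support veto rejects placements that land on placed coverage while
holding far fewer overlap edges than the detection model expects.
Coincidental placements fail both tests, so chimeric joins stall rather
than grow; stalled growth closes the layout and reseeds. Because
progressive growth accumulates drift and leaves seams where growth fronts
meet, all offsets are then re-estimated jointly: a weighted least-squares
translation synchronization over the pairwise edge constraints (solved
per connected component with outlier trimming) distributes residual error
smoothly. Scaffolding runs on the longest `max_scaffold_molecules`
(1500) molecules; the rest are recruited against provisional consensus
maps, which keeps the all-pairs stage quadratic in a bounded number.
Layouts that re-cover ground already assembled (their consensus aligns
onto a larger map) are dissolved into the recruitment pool, and maps
whose mean molecule depth falls below 20% of the deepest map are dropped
as reject-pool residue.

**Kernel-density peak calling with refinement.** Pooled anchored label
positions are smoothed with a Gaussian kernel (bandwidth 500 bp, the
optical resolution scale); local maxima become consensus labels when
supported by at least 25% of the molecules covering that position. A
molecule supports a peak if it holds a label within two bandwidths — the
width clouds actually reach once accumulated sizing error over a
molecule's span (sd `s0·sqrt(distance)`, i.e. ~2 kb at 150 kb) is in
play — while the reported position is the median of the labels within
one bandwidth of the maximum, which stays exact for noise-free input.
Peaks closer than the resolution merge, keeping the better-supported
one. Map extent is trimmed to two-molecule coverage — an end carried by a
single molecule is that molecule's private opinion, not consensus — and
the truth-based evaluator (`evaluate_assembly()`) accordingly counts a
true site as consensus-covered only when at least two placed molecules
span it. A single refinement round then re-places every molecule directly
against its map's consensus and re-calls the consensus: this collapses
progressive-layout chain noise to single-alignment error. Molecules that
fail re-placement keep their progressive placement rather than being
dropped.

These choices — the gates, the corroboration, the synchronization, the
refinement round — were each added because the plain
cluster/anchor/peak-call pipeline measurably failed on simulated data at
the default error rates: coincidental 8-site chains fuse unrelated loci
under single linkage at a rate of roughly one per thousand molecule
pairs, and un-synchronized progressive layouts leave kilobase-scale
seams that blur the label clouds past what peak calling can resolve.

## Problem sizes and numerical choices

The package's own verification uses genomes of 1–10 Mb at 40–100X
molecule coverage — roughly a hundredth of a full vertebrate experiment —
chosen so that a complete digest → simulate → assemble → align → evaluate
cycle runs in minutes while still exercising every failure mode the
algorithms guard against (coincidental overlaps, seams, end effects).
Depth titration uses length-matched subsamples at 20–80X over three
subsampling seeds; contiguity (map N50) rises and fragmentation (map
count) falls monotonically in coverage over this range, the scaled-down
analogue of the full experiment's titration behaviour.

Ties in the DP break deterministically (first-found in scan order,
forward orientation preferred); cluster ordering, seed choice (longest
molecule, then lexicographic id) and map numbering are all deterministic,
so identical inputs and parameters reproduce identical CMAP bytes.
Degenerate inputs are defined throughout: empty datasets assemble to
empty map sets, molecules with fewer than two labels are set aside with
maximal distance, zero-length sequences and unsorted label lists are
rejected at construction.

## Known limitations

Evaluation against simulation truth (`evaluate_assembly()`) projects
true labels through each molecule's recorded stretch; without that
correction the global 0.8% frame stretch masquerades as kilobase-scale
error. Consensus positions at map ends rest on one-sided coverage and
carry errors up to ~1–2 kb where interior positions stay within a few
hundred bp. Very rare pattern coincidences that mimic a genuine locus
over 8+ sites can still embed single foreign molecules in a map (the
support veto stops their followers); at the simulated scales this
affects of order one molecule per thousand. The assembler does not
attempt haplotype-aware splitting, chimeric-molecule detection, or
vendor-equivalent output.
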