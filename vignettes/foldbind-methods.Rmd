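---
title: "Structure-mediated variant effects on RNA-protein binding: models and design"
author: "foldbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-mediated variant effects on RNA-protein binding: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbind)
```

## The problem

Many RNA-binding proteins (and microRNAs) bind single-stranded RNA only:
every base under the protein's footprint must be unpaired. RNA secondary
structure therefore competes with binding, and a single-nucleotide variant
that re-weights the ensemble of secondary structures can change a
protein's affinity for a transcript *without touching the binding motif*
-- from tens of bases away. `foldbind` quantifies this mechanism: it folds
windows of transcript sequence over the full Boltzmann ensemble, converts
footprint accessibility into an effective dissociation constant, and
compares the two alleles of a variant. The case study shaping the
defaults is HuR (ELAVL1), a 7-nt-footprint AU-rich-element binder, with
binding sites of the kind produced by PAR-CLIP experiments and per-k-mer
affinities of the kind produced by RNAcompete assays.

## The ensemble model

A secondary structure is a pseudoknot-free set of canonical pairs
(GC, AU, GU wobble) with hairpin loops of at least `min_hairpin_loop = 3`
unpaired bases. The built-in energy model assigns one energy per pair
(defaults GC $-3$, AU $-2$, GU $-1$ kcal/mol) and optionally a bonus per
stacked pair (default 0), at $T = 310.15$ K, so
$kT = 0.0019872 \times 310.15 = 0.61633$ kcal/mol. The partition function

$$Z = \sum_{S} e^{-E(S)/kT}, \qquad G = -kT \ln Z,$$

is computed by the standard $O(N^3)$ recursion (implemented in C++ with
extended-precision accumulation so that 401-nt windows need no rescaling).
The open chain has weight 1, so $Z \ge 1$ and $G \le 0$. Hard constraints
("these bases must stay unpaired") model a bound protein: they simply
remove pairings from the recursion.

This model is deliberately minimal rather than a full nearest-neighbour
parameterisation: it keeps the entire package self-contained and --
crucially -- checkable against an *exhaustive enumeration oracle*
(`enumerate_structures()`, sequences up to 25 nt), which the test suite
uses to verify the dynamic programme, the opening probabilities and the
effective dissociation constant to $10^{-9}$ relative accuracy. Absolute
energy scales are therefore not comparable to measured Turner-model
values; all shape-level and sign-level statements (symmetry of distal
effects, footprint-size ordering, direction of planted effects) are the
quantities the package is designed to reproduce. Without loop-length
penalties the model also pairs more promiscuously than real RNA -- an
isolated pair at 100 nt distance costs nothing -- which lowers absolute
accessibilities; ratios between alleles, the package's primary readout,
are far less affected.

## Accessibility and binding observables

For a footprint $[i, i+k)$:

* **Opening probability** $p_\mathrm{open} = Z_\mathrm{constrained}/Z$,
  the ensemble probability that the whole footprint is unpaired.
* **Opening free energy** $\Delta G_\mathrm{open} = -kT\ln p_\mathrm{open} \ge 0$.
* **ddG between alleles** $\Delta\Delta G = \Delta G_\mathrm{open}^{mut} -
  \Delta G_\mathrm{open}^{wt}$ for a fixed footprint. The protein's
  intrinsic binding energy is identical for both alleles when the variant
  lies outside the footprint, so it cancels, and four configurations
  (each allele, bound and unbound) reduce to two constrained folds per
  allele. With this sign convention a *positive* value means the mutant
  site is harder to open, i.e. binding became harder. (The opposite
  verbal convention also circulates; `foldbind` implements the formula
  above literally and states the direction in every doc string.)
* **Effective dissociation constant**. In the dilute, single-occupancy
  limit every footprint placement contributes in parallel, discounted by
  its accessibility:
  $$\frac{1}{K_\mathrm{eff}} \;=\; \sum_i \frac{p_\mathrm{open}(i)}{K_D(w_i)},$$
  where $w_i$ is the k-mer at placement $i$ and $K_D$ comes from a
  complete $4^k$ affinity table (`Inf` = non-binder contributes exactly
  zero). `ensemble` mode sums every placement in the window; `single_site`
  mode keeps only a designated footprint, which isolates the effect of a
  variant on one site. The statistical-mechanics ground truth -- explicit
  enumeration of (structure, bound state) pairs and the bound fraction as
  protein concentration goes to zero -- is implemented in the test suite
  as an independent oracle.
* **Affinity ratio** $K_\mathrm{eff}^{alt}/K_\mathrm{eff}^{ref}$; values
  above 1 mean the alternate allele makes binding harder. In
  `single_site` mode with a sequence-independent table,
  $-kT\ln(\text{ratio})$ and $-\Delta\Delta G$ coincide exactly, a
  consistency the tests assert.

## The random-sequence scan

`run_random_scan()` reproduces the generic-distance experiment: for
uniform-random sequences of odd length (101/201/401 by convention), the
central base is substituted and $\Delta\Delta G$ evaluated for every
footprint start and each of the six unordered nucleotide pairs, each
evaluated once in lexicographic direction (the reverse is the exact
negation, so it adds no information). Means and population standard
deviations are taken across the sequence ensemble; seeds are mandatory
arguments and the scan is deterministic given the seed.
`smooth_profile()` applies a centred running mean (default window 10,
shrinking symmetrically at the edges; even windows are widened to the
next odd size so the average stays centred), averaging the six pairs
first -- the display used to compare footprint sizes.

Expected behaviour under the built-in model, asserted by the acceptance
tests at desk scale (30 sequences x 101 nt): the mean far-field
$\Delta\Delta G$ (footprint starts $\ge 20$ nt from the substitution) is
zero within two standard errors while its spread stays strictly positive
at 30 nt, and the smoothed spread for a 10-nt footprint dominates that of
a 7-nt footprint near the substitution. Absolute spreads on the order of
1 kcal/mol at 30-50 nt require a full nearest-neighbour parameter set and
are not expected from the built-in model.

## The SNP pipeline

`snp_binding_effects()` runs the genome-style analysis on transcript-space
inputs (FASTA transcripts; SNPs as minimal VCF 4.x with `CHROM` =
transcript ID, or 4-column TSV; sites as BED; the affinity table as TSV):

1. **Matching**: a SNP and a site pair up when they share a transcript and
   the SNP is within 40 nt (inclusive) of the site middle
   ($\lfloor(start_0+end_0)/2\rfloor$); a SNP near several sites goes to
   the nearest, ties to the smaller start.
2. **Motif selection**: the k-mer window inside the site with the smallest
   table $K_D$, ties leftmost; the motif center is $start + \lfloor k/2\rfloor$.
3. **Window extraction**: an odd-length window (default $L = 201$)
   centred on the motif; windows overrunning a transcript end are
   *skipped and counted*, never truncated, so all folds see equal-length
   windows.
4. **Effects**: after verifying the reference allele against the
   transcript (mismatches are skipped and counted), both alleles are
   folded and the affinity ratio, signed distance (SNP minus motif
   center; upstream negative), fold change $\max(r, 1/r)$ and stratum
   (`<2`, `2-3` including 2, `>=3` including 3) are recorded.
5. **Statistics**: `asymmetry_test()` counts ratios strictly above and
   below 1 (exact ties excluded but reported) and computes an *exact*
   one-sided binomial p-value for an excess of ratios $> 1$ -- the
   direction meaning alternate alleles impede binding. The exact tail sum
   is used at every $n$: it is cheap at any size, and at the published
   count scale ($n > 10^5$) the normal approximation visibly differs in
   the third significant figure. One-sidedness is fixed (not
   majority-driven): only a fixed-direction test has a uniform null
   distribution, which the calibration suite verifies.
   `distance_distribution()` reports per-stratum population standard
   deviations with seeded bootstrap standard errors (1000 resamples), and
   `cumulative_ratio_curves()` builds the reciprocated cumulative curves.

All coordinates in the R API are 1-based inclusive (the R/Bioconductor
idiom); BED and VCF conventions are converted at the I/O boundary.
Identical inputs produce byte-identical output TSVs.

## Synthetic data: what it emulates, and what it does not

The generators stand in for variant catalogues, CLIP binding sites and
in-vitro affinity tables:

* `gen_random_sequences()` -- i.i.d. uniform bases, seeded.
* `gen_affinity_table()` -- complete $4^k$ table with
  $K_D(w) = K_0\,e^{\beta\,\mathrm{GC}(w)}$ times lognormal jitter;
  $\beta > 0$ makes AU-rich k-mers bind tighter (HuR-like). Defaults
  $K_0 = 5$ nM, $\beta = 6$, jitter sd 0.25 give low-nM AU-rich binders
  and micromolar GC-rich ones, the dynamic range typical of
  RNAcompete-derived tables.
* `gen_planted_switch()` -- a transcript with a designed, fully
  interpretable structural toggle: a decoy (C$_7$), an arm (G$_7$) and
  the target motif (C$_7$) form two mutually exclusive pure-GC helices;
  the SNP at the decoy center (20 nt upstream of the motif center)
  simultaneously breaks one GC pair of the decoy helix and the decoy's
  copy of the motif, releasing the arm to sequester the real motif.
  Flanks are random over {A, U} only, so no flank base can pair a motif
  base: the planted direction is guaranteed by the alphabet partition,
  not by tuning. (Earlier, fully uniform flanks were found to wash out
  the toggle in a fraction of a percent of seeds through chance
  complementarity, which the loop-penalty-free model exaggerates; the
  partitioned design removes that failure mode by construction.)
  Fixtures are read out against `planted_switch_table()`, a two-tier
  table (10 nM motif, 1 uM background).
* `gen_cohort()` -- mixes planted switches (direction drawn with
  probability `asymmetry` toward ratio $> 1$) with neutral cases (uniform
  random transcripts and SNPs near a site), one site per transcript, and
  round-trips through FASTA/VCF/BED/TSV.

What the synthetic cohorts do **not** emulate: linkage between variants,
realistic transcript base composition and length distributions, CLIP
noise (site boundaries, crosslink bias), or the ascertainment bias of
binding-site discovery. Passing the planted-recovery and calibration
suites therefore demonstrates that the machinery measures what it is
pointed at -- not that real-transcriptome effect sizes are reproduced,
which requires real variant/CLIP/affinity inputs.

## Numerical and statistical choices

* Extended-precision (long double) accumulation in the C++ recursion;
  no Boltzmann rescaling needed up to 401-nt windows.
* Affinity tables are stored radix-sorted so k-mers are indexed
  arithmetically (base-4 rank), not by name lookup.
* `Inf` table entries contribute an exact zero (IEEE `x/Inf`).
* Exact binomial tail via `pbinom` at every cohort size.
* Bootstrap SEs and all generators run under explicit seeds; generators
  save and restore the caller's RNG state.
* Degenerate inputs: empty footprint intervals have $p_\mathrm{open}=1$;
  sites shorter than the footprint, windows crossing transcript ends and
  reference-allele mismatches are skipped with per-category counters
  exposed in the run report; ratios exactly 1 are excluded from the
  binomial counts and reported.

**Problem sizes in the validation suites** (the package's own choice of
desk-scale conditions): oracle equivalence on 200 random 8-16-nt
sequences; ddG algebra on 1000 random triples; scans with 30 sequences of
101 nt; planted-switch recovery over 50 seeded fixtures read out in
single-site mode at $L = 61$; null calibration on 200 cohorts of 600
planted records each ($L = 61$, single-site, `asymmetry = 0.5`). The
calibration check compares the p-value sample against uniformity by a KS
test; note the exact binomial p-value is discrete and conservative, so
perfect uniformity is unattainable in principle and the check operates at
the cohort sizes where discreteness is negligible.

## Known limitations

* The built-in energy model omits loop penalties, dangling ends and
  measured stacking parameters; absolute $\Delta\Delta G$ and $K_D$
  scales are not comparable to experiment. An external Turner-parameter
  engine can be wrapped behind the same partition-function interface,
  and all observables are defined model-independently.
* Single occupancy only: no multi-protein loading or cooperativity.
* Transcript-space only: genomic-to-transcript mapping (and canonical
  isoform choice beyond an ID allowlist) happens upstream.
* Single-nucleotide substitutions only; indels and modified bases are out
  of scope.
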