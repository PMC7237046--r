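# foldbind

Quantify how single-nucleotide variants alter the binding of
single-stranded-RNA-binding proteins through changes in RNA secondary
structure.

Proteins such as HuR (ELAVL1) bind RNA only where their footprint
(7 nt for HuR) is unpaired, so the ensemble of secondary structures a
transcript folds into competes with binding. A variant that re-weights
this ensemble changes the protein's affinity even when it lies tens of
bases away from the binding motif. `foldbind` implements the full chain
from sequence to statistics:

* **Constrained ensemble folding** — an O(N³) partition-function
  recursion over pseudoknot-free structures (canonical GC/AU/GU pairs,
  hairpin loops ≥ 3 nt) under a self-contained nearest-neighbour energy
  model, with hard constraints forcing chosen bases unpaired; plus an
  exhaustive enumeration oracle (≤ 25 nt) used as ground truth by the
  test suite.
* **Binding observables** — footprint opening probability
  p<sub>open</sub> = Z<sub>constrained</sub>/Z and opening free energy
  ΔG<sub>open</sub> = −kT·ln p<sub>open</sub>; the allele difference
  ΔΔG = ΔG<sub>open</sub><sup>mut</sup> − ΔG<sub>open</sub><sup>wt</sup>;
  and the structure-aware effective dissociation constant in the dilute
  single-occupancy limit,
  1/K<sub>eff</sub> = Σ<sub>i</sub> p<sub>open</sub>(i)/K<sub>D</sub>(w<sub>i</sub>),
  built from a complete k-mer affinity table (RNAcompete-style). The
  affinity ratio K<sub>eff</sub><sup>alt</sup>/K<sub>eff</sub><sup>ref</sup>
  is > 1 when the alternate allele makes binding harder.
* **Random-sequence scan** — ΔΔG of a central substitution versus
  footprint position, averaged over seeded random-sequence ensembles,
  with running-mean smoothing, for comparing footprint sizes.
* **SNP pipeline** — match SNPs to binding sites (≤ 40 nt from the site
  middle), select the highest-affinity motif per site, fold equal-length
  windows centred on the motif for both alleles, and summarise: signed
  distances, fold-change strata, cumulative reciprocated-ratio curves,
  and an exact one-sided binomial test for an excess of ratios above 1.
* **Synthetic data** — seeded generators for random transcripts,
  AU-preference affinity tables, planted structure switches (a distal
  SNP toggling a designed helix over the motif) and whole cohorts with
  controllable direction asymmetry, written/read as FASTA/VCF/BED/TSV.

## Worked example

A planted structure switch: the SNP sits 17 nt upstream of the motif and
toggles whether a designed helix sequesters it.

```r
library(foldbind)

sw  <- gen_planted_switch(seed = 7, direction = "harder", L = 101)
sw
#> Planted structure switch (harder): 101 nt, motif CCCCCCC at 48, SNP C>A at 31 (seed 7)

tab <- planted_switch_table()          # 10 nM motif, 1 uM background
alt <- paste0(substr(sw$transcript, 1, sw$snp$pos - 1), sw$snp$alt,
              substr(sw$transcript, sw$snp$pos + 1, 101))
effective_kd(sw$transcript, tab)       # reference allele
#> [1] 25.97199
effective_kd(alt, tab)                 # alternate allele
#> [1] 2149.015
affinity_ratio(sw$transcript, alt, tab)
#> [1] 82.74356
```

The alternate allele raises the effective K<sub>D</sub> 83-fold — binding
became harder — although the substitution never touches the motif.

The same machinery at cohort scale, through the pipeline object:

```r
co  <- gen_cohort(40, frac_planted = 0.8, asymmetry = 0.9, seed = 11, L = 101)
fit <- snp_binding_effects(co$transcripts, co$snps, co$sites, co$table, L = 101)
summary(fit)
#> SNP binding effects (window 101 nt, ensemble mode)
#>   records: 40; ratio min 0.008743, max 80.63
#>   fold-change strata: <2=4, 2-3=0, >=3=36
#> Binomial asymmetry of affinity-ratio directions
#>   ratios > 1: 33, < 1: 7
#>   one-sided exact binomial p = 2.114e-05
#>   mean ratio: >1 41.61, <1 0.2735, all 34.37
```

With 90% of planted effects pointed toward "harder", the binomial test
rejects a 50/50 split (p ≈ 2·10⁻⁵); the strata count how many SNPs change
affinity less than 2-fold, 2–3-fold, or ≥ 3-fold. `plot(fit, "ratios")`,
`plot(fit, "distance")` and `plot(fit, "cumulative")` draw the
corresponding displays, and `write_snp_effects(fit, dir)` writes
deterministic TSVs plus a run report with all skip counters.

A thin command-line interface wraps the same functions:

```sh
exec/foldbind simulate cohort --seed 3 --n-sites 50 --length 201 --out-dir sim/
exec/foldbind snp-effects --fasta sim/transcripts.fa --snps sim/snps.vcf \
    --sites sim/sites.bed --affinity sim/affinity.tsv --length 201 \
    --mode ensemble --out-dir out/
exec/foldbind scan-random --n 100 --length 201 --footprint 7 --seed 5 --out profile.tsv
```

## Documentation

The methods vignette (`vignettes/foldbind-methods.Rmd`) describes the
energy model and its deliberate simplifications, the statistical
mechanics behind the effective K<sub>D</sub>, the design of the planted
switch and what the synthetic cohorts do and do not emulate, and all
numerical/statistical conventions (coordinates, tie-breaks, exact
binomial, bootstrap).
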