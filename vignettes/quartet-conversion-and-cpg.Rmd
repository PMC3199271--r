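---
title: "Detecting paralog gene conversion and CpG-driven diversity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting paralog gene conversion and CpG-driven diversity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraconv)
```

## The scientific setting

Tandemly duplicated genes such as the cytochrome P450 pair
*CYP1A1*/*CYP1A2* pose a recurring analytical problem: the two copies do
not evolve independently.  Inter-paralog gene conversion can homogenize
parts of the copies long after duplication, and relaxation of purifying
selection on one copy can change its polymorphism spectrum dramatically —
especially in CpG-rich genes, where methylated CpG dinucleotides
deaminate at roughly an order of magnitude above the background mutation
rate, predominantly producing TpG (on the C strand) or CpA (on the G
strand).  `paraconv` implements the three analyses that separate these
forces, plus generators for data with known ground truth.

## The quartet conversion scan

### Model

Take one paralog pair from each of two species: α1, α2, β1, β2.  If the
duplication preceded speciation and the copies then diverged
independently, the true unrooted gene tree pairs orthologs:
`((α1,β1),(α2,β2))` ("type-N").  If gene conversion homogenized the copies
within a lineage after speciation, the within-species paralogs pair:
`((α1,α2),(β1,β2))` ("type-C"); conversion in only one lineage already
yields the type-C unrooted topology.  Because conversion is regional, the
alignment is cut into windows — 150 bp advanced in 9-bp (3-codon) steps,
with exons shorter than 150 bp kept whole — and both topologies are fit
per window.

Within a window the substitution model is HKY85: empirical base
frequencies from the window's four sequences, a transition/transversion
rate ratio κ shared across branches, and five free branch lengths (four
terminal, one internal).  The likelihood is computed by Felsenstein's
pruning algorithm on collapsed site patterns, using the closed-form HKY
transition probabilities.  Columns containing a gap or `N` in any of the
four sequences are excluded; a window retaining fewer than 30 columns is
flagged `low_information`.  The reported statistic is
`delta = lnL_C − lnL_N`.  A chi-square(1) tail on `2·|delta|` is included
as a descriptive index only — the two topologies are fixed, not nested
hypotheses, so this is not a calibrated p-value, and the scan's own
calibration comes from simulation (below).

### Numerical choices

Each window fit maximizes the log-likelihood over the five branch lengths
(bounded `[0, 5]`) and log-κ (κ in `[0.01, 100]`) with bounded
quasi-Newton (L-BFGS-B), using an analytic gradient for the branch
lengths (the HKY transition matrix differentiates in closed form) and a
central difference for κ.  The optimizer runs from two starting points
(all branch lengths 0.05, then 0.5) and keeps the better optimum; on test
problems the optima agree with an independent phylogenetic likelihood
implementation (phangorn, constrained to HKY) to 1e-4 log-units.  A
gradient-based joint optimizer was chosen over one-dimensional coordinate
schemes because the scan's calibration experiments fit thousands of
windows; the two approaches were verified to reach the same optima.
Empirical base frequencies are floored at 1e-6 and renormalized so that
windows missing a base entirely remain well-conditioned.  Site
likelihoods are floored at 1e-300 to keep the objective finite at extreme
parameter values.

### What the scan can and cannot see

The scan integrates signal over a full window, so conversion tracts much
shorter than 150 bp are invisible by construction.  Sensitivity also
falls as the converted region re-diverges: a tract converted early in a
terminal branch (low `conversion_time` in the simulator) accumulates new
paralog differences that erode the type-C signal.  The package's
calibration scenario uses a late conversion event (`conversion_time =
0.85` of the terminal branch), which reproduces the near-identity of
paralogs actually observed inside detected conversion tracts in the
*CYP1A* system (amino-acid p-distance around 0.05 in the converted exon,
versus 0.2–0.65 outside); under that scenario the planted full-window
tract is recovered in ≥ 90% of replicates, while quartets simulated
without conversion essentially never produce `delta > 3`.

## Population-genetic statistics

`diversity_stats()` reports the standard per-locus battery.  π is the
mean pairwise difference proportion (pairwise deletion of gap/`N` sites;
each pair over its own compared length).  S counts columns with two or
more distinct non-gap states — a site at which only a gap segregates is
not a segregating site, and deletion alleles are excluded from π and S
(they re-enter through the null-allele table).  Tajima's D follows the
published constants, with n ≥ 4 required and D undefined (reported
missing, never zero) at S = 0.

The synonymous/nonsynonymous partition is Nei–Gojobori (1986): fractional
site counting per codon (each position contributes the fraction of its
three possible changes that are synonymous; changes to stops count as
nonsynonymous), and pathway averaging for codons differing at more than
one position, excluding pathways that pass through a stop codon unless
every pathway is blocked.  Within-species π_A/π_S is reported without
multiple-hit correction — at within-species divergences (p « 0.05) the
correction is negligible — while between-species dN/dS applies the
Jukes–Cantor correction `d = −(3/4)·ln(1 − 4p/3)`, which is undefined at
p ≥ 3/4 and raises an explicit error there.  Per-codon site counts and
codon-pair difference counts are memoized (61 sense codons; observed
codon pairs), which makes the 45-pair-by-500-codon computations used in
calibration fast without changing any value.

The HKA test uses the one-species-polymorphism form: with `M_i = θ_i L_i`
and divergence-time parameter T (units of 2N generations), `E[S_i] = M_i
a(n_i)` and `E[D_i] = M_i (T + 1)`, with variances `E[S_i] + M_i² a2(n_i)`
and `E[D_i] + M_i²`.  The estimates solve the per-locus equations `S_i +
D_i = M_i (a_i + T + 1)` together with `ΣD_i = (T+1) ΣM_i` (the root in T
is bracketed and solved to 1e-10), and the goodness-of-fit statistic is
referred to chi-square with L−1 degrees of freedom.  When building HKA
inputs from data the package uses the mean pairwise difference between
each sampled haplotype and the outgroup for D (deterministic for a given
data set); the size calibration below simulates D as a single
haplotype–outgroup comparison, which is the quantity whose variance the
HKA moments describe.  Empirical size at α = 0.05 over 500 neutral
two-locus simulations falls within [0.03, 0.08].

Null-allele annotation classifies every segregating substitution against
the reference reading frame (premature stops before the reference stop
codon are `nonsense`), groups contiguous deletion runs into events
(length not divisible by 3 → `frameshift`; otherwise an in-frame
deletion, which is not a null allele), and tabulates derived/reference
chromosome counts per species.  Reported frequencies are rounded to whole
percent, π to 5 decimals, D to 3, ratios to 2 — matching the precision
conventions of the tables this mirrors.

## CpG analysis

CpG dinucleotides are counted with an overlap-permitting scan (the common
dinucleotide definition; a non-overlapping variant is exposed as a flag),
and the CpG site fraction is `2·count/length` since each dinucleotide
occupies two sites.  SNP polarization uses a single outgroup sequence as
the ancestral state — no probabilistic reconstruction — and a site whose
ancestral base matches neither observed allele is flagged and excluded
from category counts.  The diversity–CpG association uses Spearman rank
correlation (mid-ranks, two-sided t approximation, adequate for the
20–30 regions per class this targets), and the genic/intergenic density
contrast uses the Wilcoxon rank-sum test (exact null up to combined n =
20 without ties, normal approximation with tie correction beyond).

## The simulators

`simulate_quartet()` evolves a root sequence along the five-branch
duplication-then-speciation history under HKY with per-branch transition
sampling; a conversion event overwrites the tract of α2 with α1's current
state at a chosen fraction of the terminal branch, after which both
continue evolving.  Defaults (`t_dup = 0.3`, `t_spec = 0.12` expected
substitutions/site, κ = 2) reproduce the divergence scales of the
motivating system: ortholog p-distances around 0.15–0.2 and paralog
p-distances above 0.3 outside converted regions.  With `both_species =
TRUE` the event homogenizes both lineages' paralog pairs at the same
relative time.  The distinction matters for signal strength: with
one-lineage conversion the unconverted species' copy-2 tip sits on a long,
nearly saturated branch and per-window `delta` stays small, whereas
both-lineage homogenization — which is what near-identical paralog pairs
in *both* species inside converted exons imply for the motivating system —
yields per-window `delta` on the order of tens of log-units, matching the
magnitude reported for real converted windows.

`simulate_population_sample()` draws a Kingman coalescent genealogy
(constant size, no recombination — the locus is a single CDS) and places
mutations as a Poisson process with per-site rate θ/2, multiplied by
`cpg_multiplier` (default 10, the accepted order of magnitude for
methylated-CpG hypermutability) at sites currently inside a CpG of the
carrying lineage.  Context is re-evaluated after every mutation, so a CpG
created along a lineage becomes hypermutable — the mechanism by which a
CpG-rich gene decays once constraint is lost.  CpG mutations take the
deamination target (C→T or G→A) with probability `cpg_bias` (default
30/32, the observed fraction of CpG changes that are deaminations);
otherwise targets are uniform over the three alternatives.  Selection is
modeled as mutation rejection: each nonsynonymous or nonsense mutation is
discarded with probability `constraint` (c = 0 is a pseudogene, c = 1
full constraint).  This generates the π_A/π_S gradient the analysis tests
— ratio ≈ 1 at c = 0, « 1 under constraint — without simulating fixation
dynamics, which the desk-scale calibrations do not need.  An optional
outgroup lineage joins the genealogy at a chosen split time (in 2N
units), providing the ancestral sequence for polarization and the
divergence counts for HKA.  Diploid genotypes are formed by random
pairing without replacement, so Hardy–Weinberg proportions hold by
construction.  All simulators are deterministic given a seed, and restore
the caller's RNG state.

### What the simulations do and do not establish

The generators emulate the statistical structure the analyses assume —
quartet histories with regional conversion, coalescent samples with
context-dependent hypermutability, constraint, and null alleles.  They do
not emulate demography (the motivating species show genome-wide negative
Tajima's D consistent with expansion; the simulator is constant-size),
recombination within the locus, insertion polymorphism, or
sequencing/phasing error.  Passing calibrations therefore demonstrate
correctness of the statistics and detectability under the stated model,
not robustness to those unmodeled features.

## Calibration problem sizes

The packaged calibrations use: 100 replicates for conversion-scan tract
recovery (213-bp exon, full-window tract) and for the no-conversion
false-positive rate; 500 replicates for neutral Tajima's D (n = 20, θ =
0.005/site, 1.5-kb CDS) and for HKA size (two 1.5-kb loci, n = 12, θL =
7, T = 12); and 200 replicates per constraint level for the π_A/π_S
gradient (n = 10, θ = 0.01/site, 501-bp CDS).  These sizes give
simulation standard errors comfortably inside the acceptance bands while
keeping the full suite at desk scale.

## Known limitations

- The scan reports window start positions; with 9-bp steps the argmax
  window localizes a tract only to window resolution, and tract edges are
  recovered no finer than the step.
- The chi-square index on `2·|delta|` overstates significance for the
  non-nested topology comparison; use the simulation-calibrated
  `delta > 3` rule or the tract-run summary instead.
- NG86 site counting treats all mutations as equally likely within a
  codon position; under strong CpG bias the synonymous/nonsynonymous site
  normalization is approximate (this is a property of the method, kept
  for comparability with the standard implementations).
- HKA inputs built from data use mean divergence to the outgroup, which
  has slightly smaller variance than the single-pair quantity the model
  moments assume; with the sample sizes here the effect on the test is
  small relative to its chi-square approximation error.
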