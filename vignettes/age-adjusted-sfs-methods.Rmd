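---
title: "Quantifying purifying selection on TE polymorphisms with age-adjusted frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying purifying selection on TE polymorphisms with age-adjusted frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transposable-element (TE) insertion polymorphisms segregate in natural
populations like any other variant, but their frequency spectrum is shaped
by two confounded forces: selection against (mostly deleterious) insertions,
and a transposition rate that varies through time. A burst of recent
activity floods the panel with young, necessarily rare insertions and mimics
the rare-allele excess that purifying selection produces in an ordinary
folded site frequency spectrum (SFS). The spectrum alone therefore cannot
separate the two.

The age-adjusted SFS resolves the confound by conditioning on allele age.
Under neutrality, a mutation's expected frequency depends on its age but not
on its origin process: TE insertions of age $t$ should, on average, sit at
the same frequency as neutral SNPs of age $t$, whatever the history of the
transposition rate. The package's core statistic is therefore

$$\Delta \text{frequency}_b \;=\; \overline{x}^{\text{focal}}_b -
\overline{x}^{\text{neutral}}_b,$$

the difference in mean derived allele frequency between focal sites (TE
polymorphisms) and age-matched neutral sites within an allele-age bin $b$.
Under neutral accumulation $\Delta \approx 0$ in every bin, robustly to
transposition bursts and demographic change; under purifying selection,
focal sites are held at lower frequencies than neutral sites of the same
age, and $\Delta$ grows negative with age — most visibly in the oldest bin,
because old deleterious alleles are precisely the ones selection has had
time to act against.

## The pipeline

1. **Input processing** (`read_polymorphism_table()`,
   `apply_snp_hard_filters()`, `remove_het_and_multiallelic()`,
   `merge_tips()`, `polarize()`, `annotate_ages()`): a combined TE/SNP VCF
   is filtered with the standard GATK site annotations (QD < 5, FS > 20,
   SOR > 3, MQ < 50, |MQRankSum| > 2.5, |ReadPosRankSum| > 2 remove a SNP;
   all inequalities strict; a missing annotation never removes — the GATK
   convention, conservative against over-filtering). Because the organism
   is highly selfing, heterozygous SNP calls are treated as probable
   artefacts and set to missing, TE calls are coded homozygous, and
   multiallelic sites are dropped. TE insertions called < 100 bp apart in
   different samples and assigned to the same family are merged by
   single-linkage chaining (the leftmost position is kept; the pairwise
   rule is chained because call-position jitter is transitive). Alleles
   are polarized against an outgroup clade fixed for one allele; sites with
   a polymorphic or fully missing outgroup are excluded, since no
   principled frequency threshold exists to call their ancestral state.
2. **Age binning and matching** (`assign_equal_count_age_bins()`,
   `match_downsample_neutral()`, `resample_delta()`): focal sites are
   sorted by age and split into bins holding equal numbers of observations
   (ties broken by variant id for reproducibility; when $n \bmod B \neq 0$
   the youngest bins take the extra sites). For each bin, the same number
   of neutral sites is drawn without replacement from neutral sites whose
   ages fall inside the bin's age range; if the range holds too few, the
   nearest-age unused neutral sites are borrowed, with a warning. The whole
   down-sampling is repeated (default 100 times) to expose the resampling
   variation of each bin's $\Delta$.
3. **Testing** (`test_delta_below_zero()`, `test_oldest_vs_others()`):
   one-sided Wilcoxon signed-rank tests of the per-bin $\Delta$ estimates
   against zero, and one-sided rank-sum tests of the oldest bin's estimates
   against every other bin, each Bonferroni-corrected within a dataset.
   The "pattern reproduced" flag — oldest bin significantly below all
   others — is the signature used for inference.
4. **Forward simulation** (`sim_config()`, `run_wf_simulation()`,
   `simulate_grid()`): an individual-based Wright–Fisher model with
   partial self-fertilization, uniform recombination and two mutation
   streams calibrated to the analysis above (details below).
5. **Inference** (`pattern_reproduction_screen()`,
   `infer_max_neutral_ratio()`, `estimate_selection_strength()`): the
   screen asks, per simulated cell $(r, S)$, whether the oldest-bin
   pattern is reproduced. Each of the cell's replicates gets its own
   age-adjusted SFS (its own binning and down-samples), and the
   per-replicate $\Delta$ estimates are pooled before testing
   (`resample_delta_ensemble()`), so between-replicate variation enters
   the test alongside down-sampling variation. Because a cell's replicates
   are independent samples of one stationary process, their neutral
   markers are exchangeable, and by default they form one shared matching
   pool: each small focal set is then matched against a many-fold larger
   neutral panel, which is both what the down-sampling design presumes and
   what real data look like (a large SNP panel against a small TE set); $r^*$ is the smallest neutral ratio at which it
   fails for a strict majority of the selection strengths tested. The
   selection strength $S^*$ is then estimated by matching the 25/50/75%
   age quantiles of the oldest observed bin against the same quantiles in
   simulations across the $S$ grid, minimizing the absolute relative age
   difference $(\text{sim} - \text{obs}) / \max_S |\text{sim} - \text{obs}|$.

## The forward simulator

The simulator (`run_wf_simulation()`, C++ core) tracks $N$ diploid
individuals on a fragment of $L$ bp. Each generation an offspring is
produced by self-fertilization with probability $\sigma$, otherwise by two
distinct parents drawn with probability proportional to fitness. Fitness is
multiplicative across loci with genotype fitnesses $1$, $1 + hs$, $1 + s$;
all analyses use codominance ($h = 0.5$), in line with the high selfing
rate keeping most loci homozygous. Gametes recombine with a Poisson number
of crossovers ($\rho L$ expected) and mutate at rate $(\mu_n + \mu_f) L$:
neutral markers (the synonymous-SNP stand-in) at $\mu_n$, focal mutations
at $\mu_f$, the latter neutral with probability $r$ and otherwise
deleterious with $s = S / N_e$. Each mutation records its origin
generation, so sampled mutations carry exact ages. Implementation notes:
haplotypes are shared copy-on-write objects, so the common case (a gamete
with no crossover and no new mutation) costs one pointer copy; positions
are continuous uniform draws, an infinite-sites approximation.

Default parameterization and its reasoning:

* $\mu_n = 7 \times 10^{-9}$/bp/generation — the substitution rate used to
  calibrate the allele ages. $\mu_f$ defaults to the same value so the
  focal and neutral streams have comparable density; the real TE insertion
  rate is unknown and only affects site counts, not the shape of the
  age–frequency relationship.
* $\rho = 10\,\mu_n$ — deliberately high recombination to minimize linked
  selection on the short fragment.
* $\sigma = 0.7$ — the species' high selfing rate; a fully outcrossing
  variant ($\sigma = 0$) is exposed for robustness checks.
* Demography: constant $N$ with a burn-in of $10N$ generations before
  sampling (mutation–selection–drift equilibrium); an arbitrary
  piecewise schedule of population sizes is configurable.
* $N_e$ in $s = S/N_e$ defaults to the census $N$ (the usual convention
  when forward simulations are parameterized by a scaled coefficient); a
  selfing-adjusted $N_e = N/(1 + F)$ with $F = \sigma/(2-\sigma)$ is
  available via `Ne_mode`.
* Desk scale: all shipped analyses run a $\lambda = 10$ rescaling
  (`rescale_config()`) of ($N = 10{,}000$, 1 Mb) down to $N = 1{,}000$ on
  a 100 kb fragment: $\mu$, $\rho$ are multiplied and generations divided
  by $\lambda$, preserving $S = N_e s$ and the per-bp population mutation
  rate $4 N_e \mu$. Grid runs use 20 replicates per $(r, S)$ cell with
  $r \in \{0, 0.05, 0.1, 0.25, 0.5\}$ and
  $S \in \{-5, -8, -10, -12, -15, -20, -50\}$; one grid is roughly 700
  replicates and about 12 minutes on one CPU.

The simulator is validated against three independent expectations
(`tests/testthat/`): the neutral fixation probability $1/(2N)$, the
equilibrium inbreeding coefficient $F = \sigma/(2 - \sigma)$ under partial
selfing, and the Kimura–Ohta mean age of a neutral allele at frequency $x$,

$$\bar t(x) = \frac{-4 N_e\, x \ln x}{1 - x},$$

which `expected_neutral_age()` implements (Kimura & Ohta 1973, Genetics 75)
and which also powers the `age_frequency_sanity_check()` applied to real
age estimates.

## The synthetic-data generator

`generate_dataset()` draws labelled panels without any external data.
Frequencies come from the neutral sample SFS ($P(i) \propto 1/i$ over
derived counts $i$), thinned by $e^{S x}$ for selected classes; ages are
the Kimura–Ohta mean at the drawn frequency times a Gamma-distributed
dispersion factor (shape 2, mean 1 — the age posterior given frequency is
broad and right-skewed), shortened by $1/(1 + |S|/2)$ for selected sites.
Truly neutral focal sites are drawn from *exactly* the same process as the
neutral panel, which makes the two classes exchangeable by construction:
this is what licenses the type-I-error checks. Transposition bursts
importance-resample the focal (frequency, age) pairs with weights equal to
the rate multiplier at the site's origin time — pairs stay intact, so the
frequency-given-age relationship, the quantity $\Delta$ measures, is
untouched. Demographic change is a monotone piecewise-linear warp of all
ages (focal and neutral alike). Age-estimator error is multiplicative
log-normal noise (ages are positive and IBD-based estimators err
multiplicatively); its magnitude is a free parameter, not a claim about
any particular estimator. When a forward-simulation sample is attached,
selected focal sites are drawn from the simulator's empirical output
instead of the parametric model.

What the generator does *not* emulate: TE-caller false negatives beyond a
uniform drop, reference bias, linked selection, and any age-estimator bias
that correlates with frequency. Tests that pass on synthetic data
therefore certify the statistical machinery, not the upstream calling
pipeline.

## Numerical and design choices

* **Number of age bins.** Five by default, matching the visual granularity
  of published age-adjusted spectra; configurable. The high-level wrapper warns below
  50 focal sites per bin rather than failing, so sparse simulation cells
  (strong selection leaves few old survivors) can still be evaluated —
  their flags are simply noisier.
* **Derived vs folded frequencies.** $\Delta$ uses derived (polarized)
  frequencies because allele ages are defined for the derived allele; the
  folded spectrum is reported separately by `folded_sfs()`.
* **Matching order.** The default pipeline matches ages only.
  `frequency_match_resample()` is a separate bias-control mode: matching
  frequency *and* age in the same run would force $\Delta$ to zero by
  construction.
* **Gene-distance boundaries.** Inclusive on the left category
  (≤ 1 kb, ≤ 5 kb), distances measured to gene-body edges of closed
  intervals (a variant one base past the gene end is 1 bp away).
* **Majority rule for $r^*$.** The effectively neutral $S = -1$ cell is
  excluded from the majority vote by default: selection that weak cannot
  produce the oldest-bin pattern at any $r$, so including it only dilutes
  the vote. A flag restores it.
* **Quantile conventions.** Linear interpolation (R type 7) everywhere;
  the relative-age-difference normalization takes its maximum per quantile
  across the compared $S$ grid.
* **Determinism.** Every stochastic routine takes a seed; grid replicates
  derive theirs from (master seed, $r$, $S$, replicate) through a small
  integer hash, and the C++ core seeds an internal xoshiro256++ generator
  from R's RNG, so `set.seed()` reproduces whole analyses bit for bit.

## Known limitations

* The per-bin significance tests follow the resampling convention of the
  field: the Wilcoxon tests are computed over the repeated neutral
  down-samples, whose spread reflects neutral-pool resampling only. The
  focal set's own sampling noise is not part of that spread, so on small
  panels the per-bin tests against zero are anticonservative — a fixed
  focal panel whose bin mean happens to fall below the neutral conditional
  mean will test significant however the pool is resampled. The
  oldest-vs-all-other-bins screen is much less exposed (all four
  comparisons must align), which is why inference rests on it; the per-bin
  battery should be read as descriptive. The type-I checks in the test
  suite document this behaviour honestly rather than masking it.
* The statistic assumes no back mutation, so it is meaningful for
  retrotransposons; DNA transposons can excise and may be run through the
  same code only with that caveat.
* Ages are consumed as point estimates; uncertainty in the upstream age
  estimator propagates into bin assignment and is only partially captured
  by the log-normal noise model.
* The desk-scale rescaling preserves $S$ and per-bp $\theta$, but a
  100 kb fragment at $N = 1{,}000$ yields far fewer segregating sites than
  full-scale runs; grid cells under the strongest selection hold few
  old focal sites, and their screen flags are correspondingly noisy.

## Problem sizes used by the shipped analyses

The packaged tests and the acceptance script run: one simulation grid of
5 × 7 × 20 = 700 replicates at the desk scale above; 100-seed type-I
batteries on panels of 1,000 focal / 10,000 neutral synthetic sites;
sensitivity and recovery checks built from 20-replicate ensembles; and
simulator validation runs at $N$ between 100 and 500. These sizes were
chosen so a full pass completes on a single CPU in well under an hour
while keeping every Monte-Carlo band quantitative.
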