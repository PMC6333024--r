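---
title: "Genomic selection in a small perennial breeding population: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection in a small perennial breeding population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gsbreedr implements a complete genomic-selection analysis for the kind of
population a perennial breeding program actually has: a couple of hundred
plants in a handful of backcross and F2 families, measured for many traits
over a few years, and genotyped with a dense SNP panel. Because such
datasets are rarely public, the package carries its own simulator, and every
stage — quality control, phenotypic mixed models, genomic prediction,
cross-validation, and the derived design statistics — is tested against
independent oracles on data whose truth is known. This vignette explains the
models, the tunable parameters, and the design decisions that were genuinely
open.

## The phenotypic mixed model

Multi-year records are analysed with the six-effect linear mixed model

$$y = Xu + Zg + Wp + Vr + Tb + Ri + e,$$

where $u$ holds one fixed mean per evaluation year and the random effects
are genotype ($g$), permanent plant environment ($p$), population type
($r$: resistant backcross, susceptible backcross, F2), field plot ($b$),
family-by-year interaction ($i$), and the residual ($e$), each i.i.d. with
its own variance component.

Two identifiability facts shape the default design, and both are handled
structurally by `build_design()`:

* With a single plant per genotype — the usual case for a genotyped
  breeding population — an individual-level genotype effect and the
  permanent plant effect have *identical* incidence, and an
  individual-by-year interaction coincides with the residual. Confounded
  terms are detected by comparing grouping structures and dropped (their
  variance reports as 0); the interaction is therefore indexed by
  family-by-year, which remains estimable.
* The classical perennial evaluation instead places the genetic effect at
  the progeny (family) level and keeps the plant effect; that
  parameterisation is available with `build_design(..., genotype =
  "family")`. We default to the individual level because the genomic stages
  predict individuals, and because parameter-recovery checks are then
  direct: the simulated genotype variance is the quantity the fit should
  return.

A consequence worth stating plainly: with an i.i.d. genotype effect and
*related* individuals, grouping factors aligned with families absorb part of
the between-family genetic variance. The gene-dropping simulator produces
exactly this situation, and it mirrors what the family-level analysis of a
real trial does. The parameter-recovery tests therefore use
`simulate_lmm_records()`, which draws every effect i.i.d. from the model
being fitted — the canonical recovery design — while the gene-dropping
simulator exercises the genomic stages, where relatedness is the signal
rather than a nuisance.

### EM-REML

`reml_fit()` estimates the components by expectation-maximisation REML on
Henderson's mixed-model equations: each iteration solves the MME at the
current variances and updates
$\sigma_k^2 \leftarrow (\hat u_k'\hat u_k + \sigma_e^2\,\mathrm{tr}\,C^{kk})/q_k$
and $\sigma_e^2 \leftarrow y'(y - X\hat u - Z\hat u_\cdot)/(n - \mathrm{rank}\,X)$.
EM was chosen over faster Newton-type algorithms because it is monotone in
the restricted likelihood (asserted per iteration in the tests), keeps every
component nonnegative by construction, and is entirely adequate at this
scale (a few hundred MME equations; fits take well under a second).

EM's one weakness is the boundary: a component whose REML optimum is zero is
approached sublinearly and plain EM would report a small positive crumb.
Every 25 iterations, any component that is below 5% of the total variance
and still shrinking is tested directly against the boundary: it is frozen at
zero when doing so does not lower the restricted likelihood. Convergence is
declared when the largest relative change of any component falls below `tol`
(default `1e-6`, `max_iter = 500`).

### Heritability and accuracy

`individual_h2()` is the plain ratio
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_p^2+\sigma_r^2+\sigma_b^2+\sigma_i^2+\sigma_e^2)$.
`phenotypic_accuracy()` reports heritability at the across-years mean level
(components constant for a plant enter whole; interaction and residual are
divided by the mean records per genotype) and the selective accuracy
$r_{yy}$. No closed formula for $r_{yy}$ is standard for this design, so two
definitions are exposed: the default computes, per genotype,
$\sqrt{1 - \mathrm{PEV}/\sigma_g^2}$ with the prediction error variance
taken from the inverse MME coefficient matrix, and averages; the alternative
(`method = "sqrt_h2"`) returns $\sqrt{h^2_{\text{mean}}}$. On near-balanced
designs the two track each other closely (a 0.90 mean-level heritability
gives $r_{yy} \approx 0.95$ either way), which is why both are defensible.

`correct_phenotypes()` subtracts the estimated year mean and plot BLUP from
each record and averages per individual. Only field and temporal effects
are removed; genotype, permanent and population-type signal — and the
family-by-year deviations, which average toward zero over years — are
deliberately retained. An earlier draft also subtracted the family-by-year
BLUP and that choice measurably harmed the genomic stage: under the
individual-level i.i.d. model those BLUPs absorb family-constant genetic
signal, so removing them strips exactly the variance the markers are asked
to predict.

## Genomic prediction

The marker model is $y = Xb + Wm + e$ with dosage codes 0/1/2 (uncentered,
as is conventional for this system; a centering flag exists but only shifts
the intercept). Its mixed-model equations are the ridge system

$$\begin{bmatrix} X'X & X'W \\ W'X & W'W + I\lambda \end{bmatrix}
  \begin{bmatrix} \hat b \\ \hat m \end{bmatrix} =
  \begin{bmatrix} X'y \\ W'y \end{bmatrix},
  \qquad \lambda = \frac{\sigma_e^2}{\sigma_g^2 / n_Q},$$

and the genomic breeding value of individual $j$ is
$\mathrm{GEBV}_j = \sum_i w_{ij}\hat m_i$. Three numerically equivalent
routes are provided:

* `solve_direct()` — the exact dense solve of the block system;
* `solve_kernel()` — the individual-level form with $\mathrm{Var}(g) \propto
  K$; with $K = WW'$ and the per-marker variance $\sigma_g^2/n_Q$ it equals
  the marker-space solve to machine precision (asserted on 100 random
  instances at $10^{-8}$), handles singular kernels without inversion, and
  is the route `cv_run()` uses because it scales with individuals, not
  markers. A Gaussian kernel (`gaussian_kernel()`, bandwidth defaulting to
  the median squared marker distance — no principled value exists for this
  population, so the standard median heuristic is used) supports the
  nonlinear RKHS variant.
* `solve_gibbs()` — a Bayesian sampler that block-draws $(b, m)$ from the
  joint normal full conditional and the two variances from scaled
  inverse-chi-square full conditionals, with weak priors ($\nu_0 = 4$,
  scales anchored at the initial variances; the priors are documented here
  precisely because the original RKHS software's defaults are not knowable
  from the outside). With variances fixed, its posterior means converge on
  the MME solution — that equivalence is asserted within Monte-Carlo error
  and is the reason the deterministic solver is the default: the headline
  statistics are solver-agnostic.

Two parameterisation choices deserve a note. The divisor $n_Q$ in
$\lambda$ defaults to the number of markers — the standard ridge-BLUP
equivalence — and is configurable, since the number actually assumed in the
source analyses of this tradition is typically unstated. And the variances
entering $\lambda$ may come from either the phenotypic REML or a genomic
fit; `kernel_reml()` (spectral REML on the VanRaden relationship matrix,
profiled to the single ratio $\delta = \sigma_e^2/\sigma_g^2$ and maximised
by one-dimensional search) supplies the genomic heritability $h_a^2$ used
by default in the drivers, with a fallback to the phenotypic $h^2$ when the
genomic estimate sits on the zero boundary, so the ridge stays finite.

Missing dosages are imputed deterministically as the marker mean rounded to
the nearest of 0/1/2 — after quality control this touches at most 10% of
calls on any surviving marker, and a fancier imputation would be
indistinguishable downstream.

## Quality control

`run_qc()` retains markers with call rate ≥ 0.90 and minor allele frequency
≥ 0.05 (both inclusive) that show genetic variance among individuals. The
invariance filter matters in allotetraploids: an apparent SNP between
homeologous subgenome copies genotypes identically (often heterozygous) in
every individual and carries no information. Removals are attributed to the
first failing filter in the fixed order call rate → MAF → invariance so the
counts are reproducible; the retained set itself is order-independent
(tested). The "critical" MAF $1/(2N)$ — the lowest frequency observable in
$N$ individuals — is exposed as `maf_critical_level()` for reference, but
the filter defaults to the conventional 5%: at $N = 195$ the critical level
(0.26%) would retain essentially everything the call-rate filter leaves.

## Cross-validation and the derived statistics

`make_folds()` builds 13 folds of 15 by default; with 13 families of 15
plants the family-wise strategy (each family validated as a unit) is the
natural alternative and both are implemented, because either reading of
"13 folds" is plausible for this population. Predictive capacity $r_{gy}$
is the per-fold Pearson correlation between validation GEBVs and corrected
phenotypes, averaged over folds (a pooled correlation is also reported);
prediction bias $b$ is the slope of phenotype regressed on GEBV, so $b > 1$
flags under-dispersed predictions. The regression direction is a choice —
the convention here makes $b$ the calibration slope familiar from BLUP
theory, where well-specified shrinkage gives $b \approx 1$ (asserted to lie
in [0.8, 1.2] on matched-shrinkage simulations).

The design statistics then follow the standard chain, each a one-line
formula: accuracy $r_{gg} = r_{gy}/\sqrt{h^2}$ (undefined when capacity is
non-positive — such cells render as "–"), effective QTL number
$n_{QTL} = (1 - r_{gg}^2)\,N h^2 / r_{gg}^2$, required population size
$N_i = r_{ggd}^2\, n_{QTL} / ((1 - r_{ggd}^2) h^2)$ (the exact inverse of
the former — asserted to $10^{-9}$), and selective efficiency
$E_f = (r_{gg} L_f)/(r_{yy} L_{GS})$ with a 24-year phenotypic cycle (four
6-year cycles) against 12- or 24-year genomic horizons (four 3-year cycles,
three years being the time to a reproducing coffee tree). The genomic
heritability enters $r_{gg}$ by default: it is the heritability on the scale
of the prediction machinery, and it is the choice that reproduces the
published arithmetic this chain is modeled on.

`density_experiment()` reruns the cross-validation on nested subpanels.
"Representative" subsampling is implemented as chromosome-stratified
proportional allocation (largest-remainder rounding, seeded), the natural
reading for a panel spread over 11 chromosomes, an unanchored scaffold
group and a UNIGENE group.

## What the simulator emulates — and what it does not

`simulate_pedigree()` reproduces the crossing structure: 3 + 3 founders,
F1 hybrids, and 13 families (4 BCr, 5 BCs, 4 F2) of 15 plants.
`simulate_genotypes()` gene-drops founder haplotypes marker by marker
(founder allele frequencies uniform on [0.1, 0.5] by default), injects
missing calls completely at random (2%) and forces a fraction of markers
invariant (2%) to emulate the false-SNP phenomenon; allotetraploid meiosis
is treated as disomic, which matches the bivalent pairing of the species.
Markers are unlinked: none of the downstream analyses uses map positions,
so linkage would add realism the pipeline cannot see, at the cost of a
recombination model the source material does not provide.
`simulate_phenotypes()` samples trait-specific QTL from the panel, rescales
their effects so the realized genetic variance hits the specification
exactly (that exactness is what makes heritability recovery testable), adds
the five environmental effects with their variances, and thresholds score
traits into ordered classes at equal-occupancy cut points — a latent-scale
construction chosen because no generative model for the field scores
exists.

The field layout is the one genuinely invented piece: plants are assigned
to plots as repetition blocks *crossing* the families (the k-th plant of
every family shares a block), the layout implied by "15 repetitions" per
progeny. The nested alternative (plots inside families) was rejected
because a plot term aligned with families soaks up between-family genetic
variance and degrades the corrected phenotypes that feed the genomic stage.

What passing tests on these simulations do **not** show: performance under
linkage disequilibrium structure, genotyping error (beyond missingness),
selection or migration history, genotype-by-environment correlation
patterns, or non-Gaussian residuals. Real-data accuracies will differ; the
tests establish that the machinery is correct, calibrated and unbiased
under its own assumptions, not that any particular accuracy will be
achieved in the field.

## Problem sizes and numerical settings

The test suite and drivers run at the population's natural scale — 195
individuals, 3 years, 13 folds — with panels of 1,500–4,000 markers; the
full 21,211-marker scale runs identically through the same kernel-space
path (the cross-validation cost is governed by individuals, not markers).
Monte-Carlo checks use 10–50 replicates depending on the variance of the
quantity under test. Ties in factor-level ordering are broken
lexicographically; fold remainders are spread one individual at a time over
the leading folds; all stage seeds in `run_pipeline()` derive
deterministically from one master seed, and identical configurations are
bit-reproducible.

## Known limitations

* The permanent-plant effect is unidentifiable (and dropped) in the default
  individual-level design; fit the family-level model if that component is
  of interest.
* `kernel_reml()` can sit on the zero boundary for weakly heritable traits
  at $n = 195$; downstream statistics for such traits are blanked rather
  than extrapolated, matching the convention of leaving unestimable cells
  empty.
* The Gibbs sampler is a correctness mirror of the deterministic solver,
  not a tuned MCMC engine; for large marker counts prefer the kernel path.
* No pedigree or genomic relationship enters the *phenotypic* model by
  design; its genotype effects are i.i.d., which is exactly what the
  recovery tests assume and exactly what a relationship-aware reanalysis
  would relax.
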