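---
title: "Neutral drift in human airway epithelium: model, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral drift in human airway epithelium: model, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaldrift)
```

## The biological problem

Spontaneous mitochondrial DNA mutations that abolish cytochrome c oxidase
(CCO) activity act as a heritable, neutral clonal mark: a mutated airway
progenitor founds a patch of CCO-deficient cells that can be censused in
whole-mount epithelium. Because mutations arise continuously throughout
life, the sizes and density of these patches at a given age encode the
dynamics of the progenitor population — how often a progenitor is lost and
replaced by a neighbour, how fast mutant clones become visible, and how
often new visible mutations arise. `clonaldrift` implements the
quantitative machinery for this inference: the closed-form clone-size
theory, an exact stochastic simulator, a synthetic patient-cohort
generator, and the fitting chain from clone tables to physiological rates.

## The fate model

Progenitor cells (S) divide at rate $\lambda$ per year with three
outcomes,

$$
S \to
\begin{cases}
S + S & \text{prob. } r\\
S + D & \text{prob. } 1 - 2r\\
D + D & \text{prob. } r,
\end{cases}
\qquad D \to \varnothing \text{ at rate } \Gamma,
$$

where D are post-mitotic (differentiated) cells. Balance of the two
symmetric outcomes makes drift *neutral*: no clone is intrinsically
advantaged, but clone sizes random-walk, and clones are steadily lost
when their last progenitor differentiates. Homeostasis of the tissue
composition ties the shedding rate to the progenitor fraction $\rho$ of
all cells through $\rho\lambda = (1-\rho)\Gamma$, so `fate_parameters()`
derives $\Gamma$ rather than accepting it.

Tracking progenitors alone gives the reduced critical birth–death
process at per-cell event rate $2r\lambda$ with equally likely
duplication and loss. Its transient solution underlies everything else:
at drift time $\tau = r\lambda t$, a clone survives with probability
$1/(1+\tau)$, and surviving clones have geometric progenitor counts with
mean $1 + \tau$. The product of the two is exactly one — surviving-clone
growth perfectly offsets clone loss, so the expected number of labelled
progenitors per induced clone is conserved. Each surviving progenitor
supports a "clonal unit" of $1/\rho$ total cells on average, so the mean
total size of surviving clones is $N(t) = (1 + r\lambda t)/\rho$, linear
in time with slope $r\lambda/\rho$.

Under ongoing induction (mutations arriving uniformly in time from an
onset age $t_0$), mixing the geometric distributions over induction times
gives a size distribution whose continuum form is
$P_n \propto e^{-n/N(t)}/n$: a featureless $1/n$ body with an exponential
tail whose scale is the mean size of the *oldest* clones. The surviving
clone density grows only logarithmically,
$\sigma = (\rho R / r\lambda)\,\ln N(t)$ — the signature of neutral loss
of most induced clones.

### Bookkeeping conventions

Two $\rho$-bookkeeping choices are easy to get wrong, and the package
fixes them explicitly:

* **What $R$ counts.** `R_area` is the rate of *visible mutation events
  per cm² per year over all cells*. Only the fraction $\rho$ that lands
  in progenitors founds a drifting clone, and the simulator thins the
  induction process accordingly. This is the convention under which the
  printed constants cohere: densities of order $10^2$/cm² at
  $R = 100$/year/cm², a per-cell rate $R/\kappa = 10^{-4}$/cell/year at
  $\kappa = 10^6$ cells/cm², and an unbiased round trip of the
  density-difference inversion in `estimate_mutation_rate()`.
* **What sits inside the logarithm.** The exact surviving-clone density
  is $(\rho R/r\lambda)\ln(1 + r\lambda (t - t_0))$, i.e. the printed law
  with $\ln(\rho N)$ in place of $\ln N$ — a distinction that only
  matters at logarithmic accuracy. `clone_density()` and
  `survival_probability_ongoing()` implement the printed forms (with
  $\ln N$), and the simulator-versus-theory tests evaluate the law in
  clonal units ($\rho = 1$, $N = 1 + r\lambda t$), where it is exact.

## Simulation

`simulate_clone()` and `simulate_reduced()` are exact Gillespie
simulations (exponential waiting times, rate-proportional event choice);
clones stay below a few hundred cells, so approximate accelerations are
unnecessary. `simulate_tissue()` draws Poisson induction times on
$[t_0, t]$, evolves each clone independently to the observation age, and
places clones uniformly on a square of the requested area. Extinct clones
are retained with zero size so survival fractions remain computable, and
clones whose last progenitor has differentiated but whose D cells have
not yet been shed are "doomed but visible" — they appear in clone tables
as small basal-cell-free patches, as real whole-mounts show.
`apply_merger()` models the census artefact that two abutting patches are
scored as one: clones become discs of radius $\sqrt{n/(\pi\kappa)}$ and
overlapping discs merge transitively, conserving total mutant cells.

All randomness flows through R's RNG from one root seed per realization;
per-patient streams in the cohort generator are split deterministically
from the root seed, so every output is reproducible byte-for-byte.

## The synthetic cohort

`generate_cohort()` emulates a seven-patient whole-mount study: smokers
aged 39, 55 and 79, and non-smokers aged 25, 47, 57 and 65. Group
parameters are the study's headline values — $r\lambda = 0.9$/year and
$R = 100$/year/cm² for smokers, $r\lambda = 0.5$/year and
$R = 60$/year/cm² for non-smokers, with $\rho = 1/3$, $t_0 = 20$ years
and $\kappa = 10^6$ cells/cm² for both. Choices the data do not pin down:

* **The split of $r\lambda$ into $r$ and $\lambda$** is not identifiable
  from clone sizes (asymmetric divisions change nothing). We fix
  $r = 0.1$, a typical epithelial value, making $\lambda$ 9/year
  (smokers) or 5/year (non-smokers); only the product affects any
  reported statistic.
* **Surveyed areas** are not part of the published patient
  characteristics. The default 1.25 cm² per patient yields roughly
  100–300 clones per older patient and a cohort total of about 900
  patches — the scale of the real census — and keeps per-patient fits
  well conditioned.
* **The 25-year-old.** With a sharp onset at exactly $t_0 = 20$, the
  model predicts a few tens of visible clones by age 25; the observed
  absence of clones in the real patient is consistent with the stated
  $t_0 = 20 \pm 10$ spread rather than with a sharp onset. The generator
  keeps the sharp onset (it is what the theory integrates over) and the
  tests check the 25-year-old against the model's own Poisson-thinning
  expectation, not against zero.

What the generator deliberately does *not* emulate: the ductal (curved)
geometry that suppresses very large clones in real airways, delays
between mutation and histochemical visibility (homoplasmy drift),
patient-to-patient parameter heterogeneity, and segmentation noise in
patch calling. Passing recovery tests therefore demonstrate that the
inference chain is correct and well calibrated *for the model's own
data*, not that real whole-mounts are free of these artefacts.

## Inference

`empirical_distribution()` computes the cumulative tail $C_n$ and the
first incomplete moment $\mu_1(n)$ (total cells in clones of size at most
$n$) on the integer grid, with bootstrap-over-clones standard errors.
Because $\mu_1$ increments are $n P_n \propto e^{-n/N}$, the normalized
moment curve is a pure exponential in $n$ regardless of the $1/n$
prefactor — that insensitivity to the small-size shape is why the moment,
not the raw distribution, is the fitting statistic.

`fit_N()` extracts $N(t)$ with one of three estimators:

* `"ls"` — nonlinear least squares of $\mu_1(n)/\mu_1(M)$ against its
  model form $(1-e^{-n/N})/(1-e^{-M/N})$ over integer $n \le M$,
  unweighted: the classical curve fit. Its default cutoff $M$ is the
  90th-percentile clone size.
* `"moment"` — a closed form matching the cell-weighted mean
  $\mu_2/\mu_1$ of the exponential the moment curve is predicted to
  follow: $\hat N = -1/\log(1 - \mu_1/\mu_2)$. Unbiased and robust, with
  no tuning.
* `"mle"` — maximum likelihood of the predicted size distribution
  $P_n \propto e^{-n/N}/n$ restricted to sizes of at least `n_min`
  (default 5). Sizes below the clonal-unit scale $1/\rho$ are excluded
  there because granularity and doomed basal-cell-free clones distort
  the continuum form at one-to-few cells.

The least-squares curve fit, though standard, has strongly correlated
residuals along the cumulative curve and a weakly identified minimum
whenever $M$ is not comfortably above $N$ (the 90th-percentile clone size
typically is *not*, because the $1/n$ body concentrates the quantiles at
small sizes). The cohort chain `fit_cohort()` therefore defaults to the
`"mle"` estimator, which in the package's own recovery tests tracks the
generating $N$ with the smallest spread; `"ls"` remains available and is
what the figure overlays display. Uncertainty for any method comes from
percentile bootstrap over clones (default 500 resamples), a reproducible
substitute for the qualitative "range of satisfactory fits" convention.

`scan_M()` refits across cutoffs (75th/90th/95th percentile and the
maximum by default) and flags stability when identified fits agree within
15%. Cutoffs well below $N$ leave the truncated curve flat in $N$; such
fits run toward the search boundary and are marked unidentified rather
than allowed to masquerade as instability.

`fit_age_trend()` regresses $N(t)$ on age within an exposure group; the
slope estimates $r\lambda/\rho$ and the zero crossing estimates $t_0$.
Because the per-patient error of $\hat N$ is roughly proportional to $N$
itself, `fit_cohort()` iterates weighted least squares with weights
$1/\mathrm{fitted}(N)^2$ — using fitted rather than observed values keeps
the weights from coupling to the estimation noise. The derived quantities
are exact arithmetic: $2r\lambda = 2\rho \times \text{slope}$, the
mutation rate from the density–$\ln N$ slope times $r\lambda/\rho$
(differences cancel any density offset), the per-cell rate $R/\kappa$,
and the separation scale $(\pi\sigma)^{-1/2}$ with separation-to-cell-
diameter ratio $(\kappa/\sigma)^{1/2}$.

## Numerical choices and degenerate inputs

* Probability tails are truncated where the remaining mass falls below
  $10^{-9}$ (configurable); analytic identities are asserted at
  $10^{-9}$–$10^{-12}$ and Monte-Carlo comparisons at 2–3 standard errors
  or a 0.01 Kolmogorov–Smirnov level with a parametric-bootstrap null
  (plain KS p-values are invalid for tied discrete data).
* $\tau = 0$ is rejected by `progenitor_pmf_pulse()` rather than mapped
  to a point mass, so a silent division by zero cannot produce a wrong
  distribution; callers handle the degenerate case explicitly.
* The discrete ongoing-induction distribution is normalized exactly by
  $-\log(1 - e^{-1/(\rho N)})$ over progenitor counts and mapped to total
  sizes by the deterministic clonal-unit scaling $n = k/\rho$ (rounded,
  at least 1). The scaling is a reporting convention: distribution-level
  simulator checks are run at the progenitor level, where the law is
  exact, because the deterministic mapping cannot reproduce the smeared
  small sizes of simulated totals.
* Degenerate clone tables (all sizes equal, single patients, zero-clone
  patients) produce errors or warnings, never silent numbers.

## Limits of resolution at study scale

With three patients per exposure group and one-to-few hundred clones per
patient, the per-patient relative error of $\hat N$ is bounded below by
the information in the clone sizes themselves; propagated through a
three-point age regression this leaves a typical relative error around
20% on the group slope. The acceptance suite quantifies this directly:
across 100 seeded cohorts the full chain recovers both groups' $2r\lambda$
within ±30% with the correct smoker/non-smoker ordering in roughly three
quarters of replicates — close to, but not reliably above, the 80%
aspiration that check encodes, and the corresponding acceptance test is
expected to sit at that margin. The onset age is recovered well (median
within a couple of years of 20 in both groups), and the smoker/non-smoker
ordering alone holds in over 90% of replicates.

## Known limitations

* The spatial model is a flat rectangle; no ductal curvature, so
  simulated large-clone tails are heavier than real ones.
* Extrinsic (niche-regulated) fate and hierarchies with slow-cycling
  stem cells are out of scope; the package implements the single
  equipotent-progenitor model only.
* The merger-risk formula treats neighbouring clones as points (the
  centre-within-radius probability $1 - e^{-n\sigma/\kappa}$); the
  simulator's disc–disc merging is compared against the corresponding
  exact disc geometry in the tests.
* Visible mutations are assumed visible immediately; the latency of
  homoplasmic drift is absorbed into the onset age $t_0$.
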