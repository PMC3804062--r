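# clonaldrift

Neutral-drift analysis of clonally marked human airway epithelium.

Spontaneous mitochondrial mutations that silence cytochrome c oxidase
(CCO) mark single airway progenitor cells and all of their descendants,
so a whole-mount census of CCO-deficient patches is a lifelong,
continuously induced lineage trace. `clonaldrift` is for quantitative
biologists who want to turn such clone tables — one row per patch, with
patient age, smoking status, surveyed area and clone size — into
estimates of progenitor dynamics:

* the **progenitor loss/replacement rate** `2rλ` (how often a progenitor
  is stochastically lost and replaced by a duplicating neighbour),
* the **onset age** `t0` at which mutant clones first become visible,
* the **visible mutation rate** `R` (per cm² per year) and its per-cell
  equivalent `R/κ`.

## The model

Progenitors divide at rate λ with symmetric outcomes S+S and D+D each at
probability `r` and asymmetric outcome S+D otherwise; differentiated
cells are shed at rate Γ fixed by homeostasis, ρλ = (1−ρ)Γ, where ρ is
the progenitor fraction of all cells. Tracking progenitors alone gives a
critical birth–death process at rate 2rλ. Its classical consequences,
all implemented in closed form:

* pulse-labelled clones survive with probability 1/(1+rλt), and
  survivors have geometric progenitor counts with mean 1+rλt, so the
  mean total clone size grows linearly, `N(t) = (1 + rλt)/ρ`;
* under continuous induction from age `t0`, clone sizes follow
  `P_n ∝ exp(−n/N(t))/n` and the clone density grows only
  logarithmically, `σ = (ρR/rλ) ln N(t)`;
* the first incomplete moment `μ1(n)` (cells in clones of size ≤ n)
  saturates as `1 − exp(−n/N)`, which is what the fits exploit.

The package couples this theory to an exact Gillespie simulator
(`simulate_clone`, `simulate_reduced`, `simulate_tissue`,
`apply_merger`), a seven-patient synthetic cohort generator
(`generate_cohort`, with smokers aged 39/55/79 and non-smokers
25/47/57/65), clone-table I/O (`write_clone_table`,
`read_clone_table`), and the fitting chain
(`empirical_distribution` → `fit_N` → `scan_M` → `fit_age_trend` →
derived rates, bundled as `fit_cohort`).

## Worked example

Generate a synthetic cohort at the reference parameters (smokers
rλ = 0.9/year, R = 100/year/cm²; non-smokers rλ = 0.5/year,
R = 60/year/cm²; ρ = 1/3, t0 = 20 years) and run the full chain:

```r
library(clonaldrift)
cohort <- generate_cohort(cohort_config(seed = 7))
fit <- fit_cohort(cohort, n_boot = 200)
print(fit)
```

```
Cohort fit (rho = 0.3333333 )

Per patient:
 patient_id age smoker area n_clones density  N_hat lower upper   M stable
         P1  39      1 1.25      172     138  38.67  26.7  53.6 151  FALSE
         P2  55      1 1.25      167     134  95.66  59.4 131.5 291  FALSE
         P3  79      1 1.25      205     164 145.54 110.8 201.9 396  FALSE
         P4  25      0 1.25       90      72   8.34   3.6  14.3  27  FALSE
         P5  47      0 1.25      150     120  41.13  27.3  58.2 132  FALSE
         P6  57      0 1.25      180     144  70.10  49.8  97.4 309  FALSE
         P7  65      0 1.25      182     146  78.72  59.2 106.4 221  FALSE

smoker (3 patients):
  slope r*lambda/rho   : 2.94 +/- 0.62 cells/year
  onset age t0         : 25.4 +/- 7.8 years
  loss/replacement 2rl : 1.96 /year
  mutation rate R      : 47.1 /year/cm^2 (difference form)
  per-cell rate        : 4.7e-05 /cell/year
  separation           : 83 cell diameters (a = 0.047 cm)

nonsmoker (4 patients):
  slope r*lambda/rho   : 1.74 +/- 0.23 cells/year
  onset age t0         : 20.2 +/- 2.0 years
  loss/replacement 2rl : 1.16 /year
  mutation rate R      : 57.5 /year/cm^2 (difference form)
  per-cell rate        : 5.7e-05 /cell/year
  separation           : 91 cell diameters (a = 0.051 cm)
```

Reading the output: each patient's `N_hat` is the fitted mean size of
the oldest surviving clones, with its bootstrap range and the cutoff `M`
used. Within each exposure group, `N(t)` is regressed on age: the slope
estimates rλ/ρ, its zero crossing estimates the onset age, and
`2rλ = 2ρ·slope` is the loss/replacement rate. Here the chain recovers
1.96/year for smokers and 1.16/year for non-smokers against generating
values of 1.8 and 1.0 — single-cohort estimates carry a relative error
of order 20%, and the mutation-rate inversion (from density differences
against ln N) is noisier still; recovery statistics over many seeds are
what the test suite checks. `run_pipeline()` wraps generation, fitting,
JSON results and figure output in one call, and
`inst/scripts/clonaldrift` exposes the same steps as a command-line
tool.

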