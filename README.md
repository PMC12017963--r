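# coreniche

Tools for finding the **core taxa** of a spatiotemporal plankton survey,
assigning them **trophic modes** (autotroph / heterotroph / mixotroph), and
locating the **multi-stressor niche optimum** of core mixoplankton — protists
that combine photosynthesis and phagotrophy in one cell and whose relative
success under combined temperature, oxygen and nutrient pressure is hard to
read off single-factor regressions.

The package targets amplicon (ASV) surveys shaped like a coastal monitoring
program: a set of stations sampled monthly, a sample × taxon count table, a
taxonomy with trophic annotations, and a table of water-quality variables per
sample. Because real surveys carry no ground truth, a synthetic-data
generator is a first-class component: it plants a known core membership,
known trophic labels and a known environmental optimum, so every stage of
the pipeline can be validated by parameter recovery.

## What it computes

**Core selection.** Taxa are ranked by occupancy across temporal and spatial
scales (mean of the scaled ranks of overall occupancy and of the monthly
fraction of stations occupied). For the ranked list the package computes the
Bray–Curtis **contribution curve**

&nbsp;&nbsp;&nbsp;&nbsp;C(k) = Σ<sub>i&lt;j</sub> BC<sub>k</sub>(i,j) / Σ<sub>i&lt;j</sub> BC(i,j),
&nbsp;&nbsp;BC<sub>k</sub>(i,j) = 2 Σ<sub>t≤k</sub> min(x<sub>it</sub>, x<sub>jt</sub>) / (N<sub>i</sub> + N<sub>j</sub>),

the fraction of total pairwise Bray–Curtis similarity explained by the top-k
taxa (full-community sample totals N stay in the denominator so C is a true,
nondecreasing fraction). The core is the prefix ending at the **last rank
whose relative gain (C(k)−C(k−1))/C(k−1) still reaches 1%**.

**Neutral baseline.** The Sloan neutral community model predicts occupancy
from mean relative abundance p as 1 − I<sub>d/N<sub>T</sub></sub>(N<sub>T</sub>m p, N<sub>T</sub>m(1−p));
the migration parameter m is fitted by least squares and taxa are classified
against a 95% Wilson band (above / within / below neutral expectation).

**Trophic structure.** Database trophic annotations are merged with manual
overrides (manual wins; the most specific lineage rank wins among
overrides), and per-sample reads are pooled into the three modes, with the
competitiveness ratios Auto:Mixo and Hete:Mixo.

**Diversity and drivers.** Shannon/richness with Kruskal–Wallis + pairwise
Wilcoxon seasonal tests; Bray–Curtis PCoA (Lingoes-corrected) with
PERMANOVA; ordinary kriging of station Shannon fields (semivariogram fitted
by weighted least squares over spherical/exponential/gaussian models,
leave-one-out Pearson r as cross-validation); variance partitioning of
Hellinger-transformed composition into Nutrient / Physicochemistry /
Geography adjusted-R² fractions; partial Mantel tests controlling for
geographic distance; and a 1000-tree random forest whose %IncMSE importances
get permutation p-values from response-permuted refits.

**Niche model.** The mixotroph proportion is log₁₀-transformed (zeros
floored at 10⁻⁴), |z| > 3 outliers removed, predictors screened by VIF, and
four nested Gaussian GAMMs with a random station intercept are fitted with
`mgcv::gamm()`: main-effect smooths of temperature, DO and NO₃-N (M1), plus
tensor interactions T×DO (M2), +T×NO₃ (M3), +DO×NO₃ (M4). The lowest-AIC
model predicts over a 50³ grid spanning the central [2nd, 98th] percentile
box, and the grid argmax is the reported optimum (T\*, DO\*, N\*).

## Worked example

Simulate the default survey design (24 stations × 12 months, 5000 taxa,
900 planted core taxa with occupancy 0.9 vs 0.1, planted mixotroph optimum
at 18 °C, 3.5 mg/L DO, 0.64 mg/L NO₃-N) and run the chain:

```r
library(coreniche)
library(dplyr)

cfg <- sim_config(seed = 10017)
env <- generate_environment(cfg)
sim <- generate_community(cfg, env)

occ   <- compute_occupancy(sim$community)
curve <- contribution_curve(sim$community, occ$taxon_id)
core  <- select_core(curve, gain = 0.01)

length(core)                                        # 815
core_fraction(length(core), 5000)                   # 16.3
mean(core %in% sim$ground_truth$core_members)       # 1  (precision)

fit_neutral(occ, Nt = 20000, n_samples = 288)
#> Sloan neutral community model fit
#>   m = 0.1486, Nt = 20000, d = 1
#>   R^2 = 0.4275 over 5000 taxa

modes   <- annotate_trophic(sim$taxonomy)
profile <- trophic_profile(sim$community, modes, core)

dat <- profile$samples |>
  select(sample_id, station, mixotroph_prop) |>
  inner_join(env |> select(sample_id, temperature, DO, NO3_N),
             by = "sample_id")

fit <- dat |>
  clean_response("mixotroph_prop") |>
  fit_ladder() |>
  locate_optimum(resolution = 50)
fit
#> GAMM ladder (Gaussian, ML smoothing selection)
#> # A tibble: 4 × 4
#>   spec  converged   aic   edf
#> 1 M1    TRUE      -564.  14.9
#> 2 M2    TRUE      -570.  20.4
#> 3 M3    TRUE      -667.  28.0
#> 4 M4    TRUE      -666.  30.0
#> selected: M3
#> optimum: T* = 18.38 degC, DO* = 3.39 mg/L, N* = 0.631 mg/L
```

The selected core (815 taxa, 16.3% of the community) contains only planted
core members, and the ladder recovers the planted optimum to within a grid
step or two on every axis. The low neutral R² is expected: the planted
occupancy structure is deliberately non-neutral. `run_pipeline(run_config(...))`
wires the same stages (plus kriging, VPA, Spearman and random-forest
screens) behind one configuration object — YAML configs load with
`read_run_config()` — and writes every artifact (occupancy and curve TSVs,
core membership, annotation, ordination, kriged grids, importance tables,
ladder AICs, optimum JSON, run manifest) to an output directory. Results
have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` builders.

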