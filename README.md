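# gapmech

In silico clinical trials for surgical fracture care: how strongly do
anthropometric parameters (body weight, height, BMI, tibia length)
determine the micromechanics of a tibial fracture gap, and how often do
two randomly recruited trial cohorts differ in anthropometric makeup
enough to bias a fracture-healing trial?

`gapmech` implements the whole virtual-trial chain as an R package with
numbered analysis drivers:

1. **Avatar population** — men aged 20–60 in 5-year age groups, height
   and BMI drawn per group from truncated normal laws (height
   1.60–1.95 m, BMI 18–35), weight = BMI·height², tibia length from a
   stature formula.
2. **Gait loads** — five stance-phase landmarks S1–S5 as six-component
   internal loads at the fracture level, stored relative to a 755 N
   reference body weight and rescaled per avatar by
   λ = weight·g / 755 N.
3. **Surrogate mechanics** — nail and tissue annulus as parallel springs
   across a 3 mm gap; loads map linearly to interfragmentary motion and
   then to per-cell strain tensors over polar meshes of the fracture gap
   and callus annuli.
4. **Strain invariants & statistics** — per cell: hydrostatic strain
   tr(ε)/3, octahedral shear strain
   (2/3)·√[(ε₁−ε₂)²+(ε₂−ε₃)²+(ε₃−ε₁)²] = 2·√(2·J₂/3), maximum principal
   strain, and J₂ = ½·Σ devᵢⱼ²; per avatar/landmark/region: mean,
   median, IQR, MAD, P90, P95; then a 160-row Pearson correlation
   battery (4 parameters × 5 landmarks × 2 regions × 4 invariants).
5. **Cohort resampling** — Algorithm A searches a 300-avatar population
   for two disjoint cohorts of 30 with `p < 0.05` (pooled two-sample t)
   **and** |Cohen's d| ≥ 0.9; Algorithm B tabulates the mean number of
   cohort-pair draws until such a pair occurs over a 10⁶-subject
   metadata population, for trial sizes 10–60 and d thresholds 0.5–0.9.
   The two statistics are linked exactly by t = d·√(n₁n₂/(n₁+n₂)).

The methods vignette (`vignettes/in-silico-fracture-trials.Rmd`)
documents the models, assumptions, defaults and limitations.

## Worked example

```r
library(gapmech)

## 300-avatar population, full mechanics run at the 5 landmarks
res <- run_pipeline(n_avatars = 300)
res$manifest$simulation_records
#> [1] 1500

## anthropometry vs gap mechanics at the axial-force peak S4
subset(res$correlations, landmark == "S4" & region == "gap" &
         quantity %in% c("hydrostatic", "oct_shear"))[, 1:6]
#>        parameter    quantity      r         p
#>           weight hydrostatic -1.000  0.00e+00
#>           height hydrostatic -0.569  3.70e-27
#>              bmi hydrostatic -0.855  4.24e-87
#>     tibia_length hydrostatic -0.517  6.09e-22
#>           weight   oct_shear  0.966 5.62e-177
#>           height   oct_shear  0.739  5.70e-53
#>              bmi   oct_shear  0.705  2.37e-46
#>     tibia_length   oct_shear  0.718  8.90e-49
```

Heavier avatars load the gap harder: hydrostatic strain (compressive,
negative) becomes more negative with body weight (r = −1.00 at S4, where
the axial force peaks) and the distortional invariants rise with it
(r = 0.97). The length-type parameters act through the cross-section
geometry and correlate moderately (|r| ≈ 0.5–0.75), strongest where the
bending moments peak (S5).

```r
## Algorithm A: find two trial cohorts differing relevantly in BMI
algorithm_a(res$avatars, parameter = "bmi", d_min = 0.9,
            max_iter = 1e5, seed = 7)
#> Cohort pair on 'bmi' after 192 iteration(s): d = 0.912, t = 3.532, p = 0.000815
#>   cohort means 27.877 vs 25.034 (n = 30 each)

## Algorithm B: mean draws until two cohorts differ, by size and threshold
meta <- generate_population(n = 1e5, seed = 2)
algorithm_b(meta$bmi, trial_sizes = c(30, 50), d_grid = c(0.5, 0.7),
            repeats = 100, parameter = "bmi", seed = 3)
#>   parameter trial_size d_threshold mean_iterations sd_iterations repeats censored_runs
#>         bmi         30         0.5           18.30         18.79     100             0
#>         bmi         30         0.7          116.90        120.95     100             0
#>         bmi         50         0.5           61.74         57.59     100             0
#>         bmi         50         0.7         1360.96       1404.71     100             0
```

Anthropometrically different cohort pairs are easy to stumble into at
small trial sizes (≈18 draws at n = 30, d ≥ 0.5) and become rapidly
rarer as cohorts grow — mean draw counts rise roughly exponentially with
trial size once the effect-size condition binds.

## Analysis workflow

The numbered drivers under `analysis/` rerun the full experiment and
write their tables under `results/`:

```sh
Rscript analysis/01_population.R      # avatars.csv, population_summary.csv
Rscript analysis/02_gap_mechanics.R   # results/pipeline/: loads, summaries, manifest
Rscript analysis/03_correlations.R    # correlations.csv, regressions_s4.csv
Rscript analysis/04_algorithm_a.R     # algoa_result.json, cohort correlations
Rscript analysis/05_algorithm_b.R     # algob_iterations.csv (10^6 population)
```

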