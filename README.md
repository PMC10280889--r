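# emfreq — rank-frequency analysis of emergency admission diagnoses

Is the diagnosis mix of a hospital's emergency admissions random, or a
stable, predictable pattern you can plan against? `emfreq` is an R package
for answering that question from multi-year admission records, and for
turning the answer into a duty-roster competence list: the minimal set of
high-volume diagnoses ("the vital few") an on-call team must master.

It is aimed at emergency physicians, hospital planners and
epidemiologists with access to an electronic patient record extract
(one row per admission: patient id, ICD-10 main discharge diagnosis,
calendar year).

## What it computes

Given admission records, the package:

1. **Preprocesses ICD-10 codes** — normalizes and lexically validates
   them, truncates to the 3-character category (`I21.0 → I21`), groups by
   capital-letter chapter (A and B merged into one infectious-disease
   group), excludes the non-emergency Z chapter, and optionally splits
   categories into surgical vs medical duty-roster arms via an editable
   YAML mapping.
2. **Builds the ranked profile** — counts per (category, year), rates per
   100,000 catchment inhabitants, categories ranked by across-year mean
   rate, each with a 95% *prediction interval* for one future year's
   value: mean ± t₀.₉₇₅,ₙ₋₁ · s · √(1 + 1/n), clipped at 0.
3. **Fits two competing laws** to frequency vs rank x:
   - exponential decay f(x) = b₀e^(−b₁x), nonlinear least squares
     (start b₀ = 1000, b₁ = 0.1);
   - Pareto power law f(x|α,k,C) = Cαk^α/x^(α+1) with closed-form MLE
     α̂ = n/Σlog(xᵢ/k̂), k̂ = min(xᵢ), overlaid on the rank axis via the
     rank-size mapping x_r = k(n/r)^(1/α);

   and reports which law fits better (residual sum of squares, or AIC).
4. **Extracts the vital few** — cumulative coverage curve, the minimal
   top-rank set covering 80% (or any threshold) of admissions, the top-10
   share, and whether the community-diagnosis rule of thumb (top ten ≥
   80%) holds.
5. **Runs it all reproducibly** — `run_pipeline()` writes per-scope
   frequency tables, ranked profiles, fit/comparison JSON, the vital-few
   competence list, and a manifest with exact record accounting
   (input = malformed + Z-excluded + retained); identical config + seed
   gives byte-identical outputs.

A deterministic synthetic admission-stream generator with a known
ground-truth law (`generate_admissions()`) stands in for registry data, so
the whole pipeline is testable end to end.

## Worked example

Simulate a six-year cohort at the default study conditions (100 diagnosis
categories, exponential law b₀ = 1000, b₁ = 0.1, 315,000 inhabitants,
2.7% Z-chapter contamination, Poisson annual noise), then analyze it:

```r
library(emfreq)

sim <- simulation_config(exponential_law(1000, 0.1, n_categories = 100),
                         years = 2015:2020, population = 315000,
                         z_fraction = 0.027, noise = "poisson", seed = 2026)
adm <- generate_admissions(sim)   # 58,833 records
pre <- preprocess_records(adm)
pre$counts
#>      input  malformed z_excluded   retained
#>      58833          0       1588      57245

tab  <- tabulate_admissions(pre$records, population = 315000, years = sim$years)
prof <- rank_by_mean(tab)
head(prof, 5)
#>   category chapter_group rank mean_per_100k pi_lower pi_upper mean_count
#> 1      A00           A/B    1         287.1    269.8    304.3      904.3
#> 2      B00           A/B    2         257.0    237.6    276.4      809.5
#> 3      C00             C    3         235.3    199.0    271.5      741.2
#> 4      D00             D    4         215.1    197.7    232.6      677.7
#> 5      E00             E    5         194.0    174.6    213.3      611.0
```

The rank-1 category runs at 287 admissions per 100k inhabitants per year
(904 admissions/year), and next year's value is expected between 270 and
304 per 100k. Fit and compare the two laws:

```r
ef <- fit_exponential(prof)
ef
#> Exponential decay fit: b0 = 317.363, b1 = 0.0994553 (SSE 119.466, converged, scale per100k)
pf <- pareto_mle(prof$mean_per_100k)
compare_models(prof, ef, pf)
#> Model comparison (sse): exponential 119.466 vs pareto 6.64652e+06 -> exponential preferred
```

The fitted decay rate b₁ = 0.0995 recovers the generating 0.1 (b₀ is on
the per-100k scale: 317.4 × 3.15 ≈ 1000 admissions). Finally, the
competence list and the year-to-year stability:

```r
vital_few_set(cumulative_curve(prof))
#> Vital few at 80% coverage: 17 categories (achieved 81.7%)
#> Top-10 share: 63.1% (< 80%)
rank_stability(tab)$mean
#> [1] 0.959
```

Seventeen diagnosis categories cover 80% of this cohort's admissions —
that is the minimal competence list — and the rank order is highly stable
across years (mean pairwise Spearman ρ = 0.96). Running the same analysis
per chapter group or per roster arm is one argument
(`scope = "chapter:I"`, `scope = "roster:surgical"`), or use
`run_pipeline()` to produce every scope's CSV/JSON in one call. A thin CLI
(`inst/scripts/emfreq-cli.R`) wraps `simulate` and `run-all` for shell
use.

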