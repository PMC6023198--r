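# fetclust

Voxelwise time-activity-curve (TAC) clustering for dynamic
¹⁸F-FET PET in gliomas.

Dynamic amino-acid PET acquires a 50-minute, 10-frame image series
after tracer injection. The shape of the uptake curve — steadily
accumulating versus rapid wash-in/wash-out — tracks tumor biology:
IDH1-mutant gliomas (better prognosis) accumulate slowly, aggressive
tumors wash out. `fetclust` analyses this at the **voxel** level
rather than for the whole tumor:

1. **Segmentation** — a patient's late (40–50 min) static image is
   compared voxelwise against a normal-brain template as a Z-score map
   `Z = (static − μ)/σ`; the tumor mask is `Z > 2.5`, connected
   components ≥ 250 voxels, dilated twice (6-connected cross).
2. **Clustering** — every tumor voxel's TAC is z-normalized
   (`T ↦ (T − mean T)/sd T`) and clustered by k-means under dynamic
   time warping, `γ(i,j) = d(qᵢ,cⱼ) + min(γ(i−1,j−1), γ(i−1,j),
   γ(i,j−1))`, with DTW-barycenter-averaging centroid updates. The
   number of centroids is chosen by the elbow of the SSE-versus-k
   curve; on this kind of data the elbow sits at **k = 3**: centroid
   #1 slowly increasing, #2 rapid rise then slow decline, #3 rapid
   rise then rapid washout. Voxels are finally assigned to the frozen
   centroids by Euclidean distance.
3. **Features** — per patient: % of tumor voxels per centroid,
   SUVmax/SUVmean, TBRmax/TBRmean (tumor over contralateral reference),
   time-to-peak (start time of the maximal frame, minutes) and the
   late-phase OLS slope (20–50 min, SUV/hour).
4. **Cohort statistics** — Mann-Whitney and chi-square group
   comparisons, Kaplan-Meier curves with log-rank tests, and an
   X-tile-style exhaustive survival cutpoint scan.

A synthetic-data module (`simulatePhantom()`, `simulateCohort()`,
`simulateArchetypeTACs()`) generates 4D phantoms and cohorts with the
statistical structure the pipeline assumes, so everything is testable
without image downloads. A 37-patient glioma cohort table ships as a
fixture (`fetCohort()`).

## Worked example

```r
library(fetclust)

co <- fetCohort()                      # packaged 37-patient cohort
idh1Summary(co)[, c("variable", "median_all", "q25_all", "q75_all", "p")]
#>      variable median_all q25_all q75_all          p
#> 1     tbr_max       3.10    2.40    3.90 0.03528279
#> 2    tbr_mean       2.10    1.90    2.50 0.01620018
#> 3     ttp_min      25.00   15.00   45.00 0.02683062
#> 4 slope_suv_h      -0.08   -0.66    0.34 0.02054076
```

Every conventional parameter separates IDH1-mutant from wild-type
tumors (all p < 0.05, two-sided Mann-Whitney). Splitting the cohort at
more than 90 % of tumor voxels in centroid #1:

```r
s <- centroid1Stratification(co, threshold = 90)
s$table
#>      mutant wild
#> high     10    3
#> low       7   17
round(c(s$pctMutantHigh, s$pctMutantLow, s$chi2, s$p), 4)
#> [1] 76.9231 29.1667  7.7436  0.0054
```

77 % of the high-centroid-#1 group is IDH1-mutant versus 29 % below
the cutoff (Pearson χ² = 7.74, p = 0.005).

The full image pipeline on a simulated phantom whose lesion mixes the
three kinetic archetypes 60/25/15:

```r
tmpl <- buildTemplate(simulateNormalStatics(n = 41, dim = c(32, 32, 32), seed = 11))
ph   <- simulatePhantom(phantomSpec(weights = c(0.6, 0.25, 0.15), seed = 201))
res  <- runPipeline(list(phantom1 = list(image = ph$image)), tmpl,
                    config = pipelineConfig(seed = 17))
round(res$features[, c("pct_c1", "pct_c2", "pct_c3", "tbr_max",
                       "tbr_mean", "ttp_min", "slope_suv_h")], 2)
#>   pct_c1 pct_c2 pct_c3 tbr_max tbr_mean ttp_min slope_suv_h
#> 1  61.26   25.2  13.54    3.13     1.55      40        0.06
```

The generating mixture (60/25/15) is recovered within ~1–2 points,
and the tumor-level kinetics (late TTP, mildly positive slope) reflect
the accumulating majority class.

Command-line wrappers over the same functions live in
`inst/cli/fetclust.R` (`segment`, `train`, `elbow`, `features`,
`stats`, `simulate-phantom`, `simulate-cohort`).

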