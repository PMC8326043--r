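# dietbiome

Diet-quality scoring and gut-microbiome association analysis in R.

`dietbiome` is for epidemiologists and microbiome researchers who want to
relate habitual diet, measured with a food propensity questionnaire (FPQ),
to gut metagenome structure. It provides, as one tested pipeline:

* **Healthy food choices (HFC) scoring** — ordinal FPQ categories 1–6 are
  converted to times-per-month frequencies (0.5, 1.5, 4.3, 8.6, 21.5, and
  an item tier of 30/45/60 for "once a day or more"), red/processed-meat
  items are inverse scored (category `c -> 7 - c`), and the HFC score is
  the sum of 11 component scores. A combined fiber sources score sums the
  fiber-rich items only. The 18-item default configuration ships as a
  versioned TSV.
* **Diversity** — Shannon alpha diversity `H = -Σ p_i ln p_i` (nats) and
  Bray-Curtis dissimilarity `Σ|x-y| / Σ(x+y)` on compositional abundance
  tables.
* **Distance-matrix inference** — PCoA (with Lingoes/Cailliez corrections),
  PERMANOVA with covariate-before-diet sequential partitioning of
  `trace(-½ J D² J)`, Clarke's ANOSIM on extreme HFC deciles, and dbRDA
  with constrained-variance decomposition and biplot scores. All
  permutation tests are seeded, use the add-one estimator
  `(1 + #{F* ≥ F})/(1 + n_perm)` with 999 permutations by default, and have
  an exhaustive-enumeration mode at small n.
* **Association scans** — MaAsLin-style per-taxon regressions on
  core-filtered (detection ≥ 0.1% in ≥ 1% of samples), arcsine-sqrt
  transformed abundances with Benjamini-Hochberg q-values per scan, effects
  reported per 1 SD of the diet variable (β/SD); KO-group scans on
  log10-transformed abundances with sign-split significant tables.
* **A calibrated synthetic cohort generator** — FPQ responses from a
  latent-factor cut-point model (HFC mean 250, SD 103 times/month, sex
  differences in the published directions), log-normal genus and KO panels
  with planted effects on exactly the scales the scans fit, so parameter
  recovery is testable end to end.

## Worked example

```r
library(dietbiome)

co     <- simulate_cohort(cohort_spec(n_participants = 500), seed = 1)
scores <- co$scores
head(scores[, c("participant_id", "vegetables", "red_processed_meat",
                "hfc_score", "fiber_score")], 3)
#>   participant_id vegetables red_processed_meat hfc_score fiber_score
#> 1         S00001       38.7               43.0     236.5       178.1
#> 2         S00002       31.6               14.4     103.6        76.1
#> 3         S00003       14.4               62.2     242.1       153.1
```

Each row is one participant; component scores and the HFC/fiber scores are
monthly consumption frequencies (times/month). Alpha diversity and its
covariate-adjusted association with the HFC score:

```r
X <- simulate_abundances(co, seed = 1)
H <- shannon_index(X)
C <- co$covariates[c("age", "sex", "bmi", "smoking", "medication")]
rownames(C) <- co$covariates$sample_id
fit_linear_association(H, scores$hfc_score, C, feature_id = "hfc_score")
#>   feature_id beta_per_sd     se      p   n
#> 1  hfc_score      0.0441 0.0173 0.0109 500
```

Shannon diversity rises by 0.044 nats per 1 SD of the HFC score (p = 0.011)
— the generator's planted alpha effect, recovered. Beta diversity, with
covariates entered before the diet term:

```r
D  <- bray_curtis_matrix(X)
dd <- cbind(sample_id = co$covariates$sample_id, C, hfc = scores$hfc_score)
permanova(D, dd, c("age", "sex", "bmi", "smoking", "medication", "hfc"),
          n_perm = 999, seed = 1)
#> PERMANOVA (terms SS, 999 permutations, seed 1)
#>        term  df       SS       R2      F     p
#>         age   1  0.19987 0.003137  1.688 0.036
#>         sex   1  0.52427 0.008228  4.428 0.001
#>         bmi   1  0.25192 0.003954  2.128 0.006
#>     smoking   1  0.22484 0.003529  1.899 0.023
#>  medication   1  0.16980 0.002665  1.434 0.097
#>         hfc   1  3.97730 0.062420 33.600 0.001
#>    Residual 493 58.36600 0.916100     NA    NA
#>       Total 499 63.71400 1.000000     NA    NA
```

The diet term explains 6.2% of the Bray-Curtis sum of squares after the
covariates (p at the 1e-3 permutation floor). The per-taxon scan flags the
two planted genera at their planted effect sizes (+0.10 and −0.07 per SD):

```r
scan <- per_taxon_scan(X, setNames(scores$hfc_score, rownames(X)), C)
head(scan, 3)
#>    feature_id beta_per_sd      se         p         q   n significant
#> 3        g003     0.09745 0.00232 2.53e-165 2.30e-163 500        TRUE
#> 5        g005    -0.06616 0.00172 1.52e-150 6.91e-149 500        TRUE
#> 80       g080     0.00372 0.00116  1.40e-03  4.25e-02 500        TRUE
```

`run_all(config)` executes the whole graph (scoring → diversity → per-diet
alpha and PERMANOVA tables → dbRDA on significant components →
extreme-decile ANOSIM → per-taxon scans → KO scan) from four input TSVs and
writes tidy, config-hash-stamped TSV outputs plus a JSON run log;
`inst/cli/dietbiome.R` exposes `simulate`, `score`, `diversity`, `pcoa`,
`permanova`, `anosim`, `dbrda`, `associations` and `run-all` subcommands
for shell use.

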