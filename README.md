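# stromasig

Anchor-gene stromal signatures and survival stratification for tumor
transcriptomics.

## What it does

Pancreatic ductal adenocarcinoma (PDAC) carries a massive stromal
compartment whose fibroblast activation state predicts outcome. One way to
extract such a program from bulk expression cohorts is an **anchor-gene
screen**: correlate every gene with a single anchor (here the stemness
factor *SALL4*) within each cohort, keep genes passing per-cohort cutoffs,
and intersect across cohorts. `stromasig` implements that derivation and
everything downstream of it:

- **Correlation screen** — per-gene Pearson *r* against the anchor,
  p-values from *t* = *r*·√((n−2)/(1−r²)), Benjamini–Hochberg q-values,
  strict cutoffs (*q* < 0.05, *r* > 0.4/0.4/0.3 per cohort), cross-cohort
  intersection (`correlate_to_anchor`, `select_correlated`,
  `intersect_signatures`, `derive_anchor_signature`).
- **Signature scoring** — mean of row-z-scored expression per sample
  (`signature_score`), MCP-counter-style marker means
  (`marker_population_score`), hypergeometric over-representation
  (`ora_hypergeometric`).
- **Survival** — native Kaplan–Meier with Greenwood log(−log) bands and
  Brookmeyer–Crowley median CIs (`km_estimate`), native log-rank test
  (`logrank_test`), maximally selected log-rank cutpoints à la
  Hothorn–Lausen with a permutation p (`maxstat_cutpoint`), upper-tertile
  dichotomization (`categorize_by_quantile`), and Cox models with the
  univariate → multivariable p < 0.05 entry rule via `survival::coxph`
  with Efron ties (`cox_fit`).
- **Differential expression** — Welch or empirical-Bayes moderated t with
  a moment-matched variance prior, strict |log₂FC| > 1, q < 0.05 filters,
  and the three-way intersection producing the invasiveness signature
  (`dge`, `filter_dge`, `derive_invasive_signature`).
- **Subtypes** — nearest-centroid transfer from one-vs-all DE signatures
  (`build_centroids`, `assign_by_centroid`) and correlation-distance
  hierarchical clustering with deterministic branch labels
  (`consensus_cluster`).
- **Synthetic cohorts** — a latent-factor generator with planted gene
  modules, proportional-hazards survival and full ground truth
  (`cohort_spec`, `generate_cohort`, `generate_multicohort`,
  `generate_panin_study`), used by the validation suite.
- **Pipeline** — `run_pipeline()` drives simulate → screen → intersect →
  score → stratify → KM/log-rank → Cox from one YAML/JSON config with a
  checksummed output manifest.

The published 24-gene SALL4 stromal signature and its 7-gene invasiveness
subset ship as `sall4_signature()` / `invasive_signature()` and as a GMT
under `inst/extdata/`.

## Worked example

```r
library(stromasig)

specs <- lapply(1:3, function(i)
  cohort_spec(n_samples = 150, n_genes = 1500, module_genes = 24,
              anchor_loading = 1.2, module_loading = 1.2, beta = 0.5,
              seed = 7000 + i))
mc  <- generate_multicohort(specs)                     # shared 24-gene module
out <- derive_anchor_signature(lapply(mc$cohorts, `[[`, "expr"),
                               anchor = "SALL4",
                               r_min = c(0.4, 0.4, 0.3), q_max = 0.05)
out$signature
#> gene_set 'anchor_signature' (24 genes)
#>  MODG001, MODG002, MODG003, MODG004, MODG005, ...

sc  <- signature_score(mc$cohorts[[1]]$expr, out$signature)
cut <- maxstat_cutpoint(sc, mc$cohorts[[1]]$surv, n_perm = 200, seed = 7)
cut
#> maximally selected log-rank cutpoint
#>   cutpoint: -0.1048  (85 high / 65 low)
#>   max |z|: 3.797  over 121 candidates
#>   permutation p: 0.00498

km_estimate(mc$cohorts[[1]]$surv[cut$groups == "high", ])
#> Kaplan-Meier curve: 85 subjects, 69 events
#> median survival: 13.81135 (95% CI 9.928977-18.65636)

sv <- mc$cohorts[[1]]$surv
sv$signature_high <- as.integer(cut$groups == "high")
cox_fit(sv, "signature_high")$table
#>             term hazard_ratio    ci_lo    ci_hi            p
#> 1 signature_high     2.165899 1.440017 3.257682 0.0002064973
```

The screen recovers all 24 planted module genes; the maximally selected
cutpoint splits the cohort into 85 high / 65 low samples whose median
survival differs by ten months (13.8 vs 23.9), and the high-signature group
carries a hazard ratio of 2.2 (95% CI 1.44–3.26) — the planted β = 0.5
latent-factor effect seen through the derived signature.

The same flow runs from a single config file:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "stromasig"),
             outdir = "demo_out")
```

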