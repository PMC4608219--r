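# btwas — two-cohort whole-blood transcriptome-wide association analysis of BMI

`btwas` is an R package for transcriptome-wide association analysis of a
quantitative phenotype — body mass index — in whole-blood microarray data
from paired population-based cohorts. It is written for statistical
geneticists and epidemiologists who need the complete analysis chain as
tested, reusable functions rather than a one-off script: sample and
transcript quality control, quantile normalization, per-transcript
covariate-adjusted regression, cross-cohort meta-analysis, gene-level
direction classification, pathway over-representation with a permutation
robustness check, and a pathway-overlap network.

Because real cohort expression data are access controlled, the package
includes a synthetic-data generator that emulates the statistical
structure of such a study (two cohorts of ~990 samples, realistic
covariates, planted signed effects, a reticulocyte-like confounding
factor, detection p-values). Every stage is testable against known ground
truth, and a full run is reproducible from one seed.

## The statistics at the core

Per cohort and transcript, ordinary least squares:

    y_ij = a_j + b_j * BMI_i + g_j' C_i + e_ij

with covariates C = (age, sex, RBC, WBC, hematocrit, platelets, RIN,
plate, storage time). Cohorts are combined by the sample-size-weighted
z-score method:

    z_meta = sum_c sqrt(n_c) z_c / sqrt(sum_c n_c),   z_c = sign(b_c) * qnorm(1 - p_c/2)

with Benjamini–Hochberg control across the detection-filtered transcripts
(significant at q < 0.01). Genes are represented by their minimum-p probe
and classified positive / negative / inconsistent from the signs of their
significant probes. Over-representation of a gene list against a GMT
collection uses the right-tailed Fisher's exact test with BH correction
per direction stratum, the enrichment ratio x/K, and an empirical
permutation FDR from matched-size random gene lists. The pathway-overlap
graph connects sets sharing transcripts whose Jaccard coefficient reaches
the 90th percentile of all pairwise coefficients.

See `vignettes/blood-twas-methods.Rmd` for the full model description,
parameter defaults and known limitations.

## Worked example

```r
library(btwas)

cfg <- pipeline_config(
  sim = simulation_config(n_samples_per_cohort = c(300L, 300L),
                          n_probes = 1000L, n_genes = 800L,
                          frac_positive = 0.04, frac_negative = 0.06),
  n_sets = 20L, set_size_range = c(10L, 30L), n_enriched = 4L,
  perm_B = 500L, seed = 42L)

out <- file.path(tempdir(), "demo")
run_pipeline(cfg, out)

meta  <- read_tsv(file.path(out, "meta_probes.tsv"))
cat(sprintf("%d of %d detected transcripts significant at q < 0.01\n",
            sum(meta$significant), nrow(meta)))
#> 142 of 650 detected transcripts significant at q < 0.01

read_tsv(file.path(out, "direction_summary.tsv"))
#>          class count percent
#> 1     positive    73    59.3
#> 2     negative    50    40.7
#> 3 inconsistent     0     0.0
```

Of the 1000 simulated probes, 650 pass the both-cohort detection filter
(the rest are simulated as low-expressed); 142 of them reach q < 0.01,
collapsing to 123 genes whose direction split reflects the planted 4%/6%
positive/negative fractions plus the positively-associated reticulocyte
block. The enrichment table ranks the four planted gene sets first, with
the permutation FDR at its add-one floor (1/501 with `perm_B = 500`):

```r
head(read_tsv(file.path(out, "enrichment.tsv")), 5)
#>               set set_size n_all ratio  fdr_all perm_fdr
#> 1 SET_004_planted       29    27 0.931 7.70e-16   0.0020
#> 2 SET_001_planted       20    17 0.850 1.55e-08   0.0020
#> 3 SET_003_planted       12    11 0.917 2.55e-06   0.0020
#> 4 SET_002_planted       17    12 0.706 8.79e-05   0.0020
#> 5         SET_017       17     7 0.412 2.24e-01   0.0619

read_tsv(file.path(out, "concordance.tsv"))
#>          model_pair r2_beta r2_se r2_neglog10p n_probes
#> 1 base_vs_augmented   99.82 99.56        99.77      650
```

The concordance row is the sensitivity analysis: re-running association
and meta-analysis with five relative leukocyte differential counts added
to the model changes effect sizes, standard errors and −log10 p-values by
almost nothing (R² > 99%), as expected when the added covariates are
independent of the phenotype's effect on expression.

The run directory also contains the per-cohort association tables, QC and
detection-rate reports, the gene-level results, the overlap graph
(GraphML + edge/node TSVs), the simulation truth tables, and a
`manifest.json` recording seed and thresholds; rerunning with the same
seed reproduces every artifact byte for byte (the timestamped `run.log`
aside).

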