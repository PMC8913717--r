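# allotrace

Longitudinal TCR-beta repertoire analysis for transplant cohorts: from
MiXCR-style clonotype exports to donor-reactive clone tracking, diversity
and turnover metrics, virus-specificity annotation, and the cohort-level
statistics, with a ground-truth synthetic-cohort generator for validation.

## The problem

After kidney transplantation, recipients under a lymphodepleting induction
antibody (ATLG) or a non-depleting one (basiliximab) rebuild their T-cell
compartment. Bulk TCR-beta CDR3 sequencing of sorted CD4/CD8 cells at
pre-transplant and months 1, 3 and 12, plus a pre-transplant mixed
lymphocyte reaction (MLR) against donor cells, lets one ask: does the
repertoire narrow after depletion, does it turn over faster, and do the
*donor-reactive* clones — those expanded at least five-fold in the MLR —
grow after transplantation? `allotrace` implements that downstream analysis
as a tested pipeline for anyone with clonotype tables and a sample
manifest; the original study data are controlled-access, so a synthetic
cohort generator with planted ground truth stands in for them everywhere
the package needs data.

## The quantities at its core

With clone frequencies `f_i` (i = 1..S) in one repertoire:

- **Clonality** `= 1 − H/log S`, `H = −Σ f_i log f_i` (one minus Pielou's
  evenness): 0 = perfectly even, 1 = monoclonal.
- **R20** `= k/S`, with `k` the smallest number of clones, in decreasing
  frequency order, whose cumulative frequency reaches 0.2: small values
  mean immunodominance.
- **JSD(p, q)** `= ½ KL(p‖m) + ½ KL(q‖m)`, `m = (p+q)/2`, base 2 — clone
  turnover on the union of each repertoire's top 1,000 clones, and VJ
  usage shifts.
- **Donor-reactive set**: clonotypes (CDR3nt + V + J) with
  stimulated/unstimulated read fold `≥ 5` at a common downsampled depth;
  tracked as % of bulk clonotypes and cumulative frequency.
- All repertoire metrics are means over repeated downsampling without
  replacement to the lowest read count in each phenotype group.
- Inference: paired/unpaired t-tests and mixed factorial (split-plot)
  ANOVA with Mauchly test and Greenhouse–Geisser correction, α = 0.05, no
  multiplicity adjustment.

## Worked example

```r
library(allotrace)

# a synthetic two-arm cohort: 2+2 patients, 4 timepoints, CD4/CD8,
# preTx MLR pairs, planted donor-reactive and virus-specific clones
spec <- cohort_spec(n_per_group = c(ATLG = 2L, basiliximab = 2L),
                    clonotype_count_range = list(CD4 = c(300L, 1500L),
                                                 CD8 = c(300L, 1500L)),
                    seed = 1L)
cohort <- generate_cohort(spec, out_dir = "demo_cohort")

cfg <- run_config(manifest = cohort$manifest, n_replicates = 100L, seed = 2L,
                  specificity_path = system.file("extdata", "vdjdb_synthetic.tsv",
                                                 package = "allotrace"),
                  out_dir = "demo_results")
res <- run_pipeline(cfg, repertoires = cohort$repertoires)

res$dr_tracking[phenotype == "CD4" & timepoint %in% c("preTx", "M1"),
                .(patient_id, timepoint, cum_freq = round(cum_freq, 2))]
#>    patient_id timepoint cum_freq
#>        <char>    <char>    <num>
#> 1:        P01     preTx     0.27
#> 2:        P01        M1     0.57
#> 3:        P02     preTx     0.28
#> 4:        P02        M1     0.45
#> 5:        P03     preTx     0.91
#> 6:        P03        M1     1.76
#> 7:        P04     preTx     0.43
#> 8:        P04        M1     0.80

res$stats[test == "donor_reactive_pre_vs_post" & phenotype == "CD4" &
          measure == "cum_freq", formatted]
#> [1] "t(3) = -2.86, p = 0.065"
```

Reading the output: each patient's donor-reactive clones carried ~0.3–0.9%
of the CD4 repertoire before transplantation and roughly doubled by month
1 (the generator plants a 1.9× post-transplant multiplier; at this reduced
300–1,500-clonotype scale the planted mass sits below the full-scale ~1%).
The paired t-test is computed pre minus post, so an increase appears as a
negative t; with only 4 patients it is underpowered — the full 5+5 default
cohort detects the rise decisively.
`demo_results/` holds one long-format TSV per figure-ready table
(clonotype counts, clonality, R20, turnover JSD, donor-reactive tracking,
virus specificity, the statistics battery) plus per-sample VJ matrices and
a provenance record; runs with the same config and seed are byte-identical.

Real data enter the same way: a manifest TSV (`patient_id, group,
timepoint, phenotype, condition, path`) pointing at clonotype TSVs
(MiXCR export headers by default; AIRR readable via the column map), and
optionally a VDJdb-style TSV for CMV/EBV annotation — the bundled table is
synthetic and only for tests/examples.

Command line:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","allotrace.R",package="allotrace"))') \
    synth --out cohort/ --seed 1 --n-per-group 5
Rscript ... run --config run.json
```

## Layout

- `R/` — ingestion and data model, ambiguity correction and downsampling
  (Rcpp engine in `src/`), donor-reactive calling/tracking, diversity and
  overlap metrics, specificity annotation, statistics, synthetic cohorts,
  pipeline orchestration.
- `vignettes/allotrace-methods.Rmd` — the model, every tunable parameter
  with its default and rationale, what the generator does and does not
  emulate, numerical conventions, limitations.
- `inst/extdata/vdjdb_synthetic.tsv` — synthetic specificity fixture.
- `inst/cli/allotrace.R` — command-line entry point.
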