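---
title: "Methods: longitudinal TCR repertoire analysis for transplant cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal TCR repertoire analysis for transplant cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Kidney-transplant recipients under different induction therapies — a
lymphodepleting antibody (ATLG) versus a non-depleting IL-2-receptor
antagonist (basiliximab) — are followed with bulk TCR-beta CDR3 sequencing
of sorted CD4 and CD8 T cells before transplantation and at one, three and
twelve months after. Before transplantation, each patient's PBMCs are
co-cultured with irradiated donor cells in a mixed lymphocyte reaction
(MLR); the proliferating fraction is sorted and sequenced. Clones that
expand in the MLR define that patient's *donor-reactive* repertoire, which
can then be tracked through the post-transplant bulk samples. The questions
are distributional: does overall repertoire diversity narrow after
lymphodepletion, does the repertoire turn over faster, and does the
donor-reactive fraction of the repertoire grow?

`allotrace` implements this downstream analysis — everything after clonotype
assembly — as a tested, reusable pipeline, together with a synthetic-cohort
generator that plants known ground truth for validation, because the
original patient-level data are controlled-access.

## Data model

A *clonotype* is identified by its CDR3 nucleotide sequence plus V and J
gene (the D segment is excluded from identity: it is frequently
unassigned). Nucleotide-level identity with V/J is the strictest key
supported by the exported columns and the standard choice for tracking
clones within one patient. Gene names are compared after stripping allele
suffixes (`*01`) because exports are inconsistent about alleles. Input
frequency columns are ignored and recomputed from reads, which guarantees
frequencies sum to one after duplicate collapse.

## Pipeline stages and the choices behind them

### CD4/CD8 ambiguity correction

Sorting is imperfect, so a clonotype can appear in both the CD4 and CD8
fraction of one sample. A shared clonotype is assigned to the fraction with
at least **twice** the reads of the other; if neither fraction dominates,
it is removed from both, and frequencies are renormalized. The boundary
case ("exactly twice") assigns rather than removes: that is the natural
reading of "with twice the number", and the rule is configurable. "Number
of clones" is read as read counts — in this field's usage reads *are*
"clones" (cells), while "clonotype" names the sequence.

### Depth normalization by repeated downsampling

Sequencing depth varies by orders of magnitude across samples, and nearly
every repertoire statistic is depth-sensitive. All reported metrics are
means over repeated downsampling: each repertoire is subsampled **without
replacement** (multivariate hypergeometric — the standard rarefaction
contract; sampling with replacement would be a different experiment) to the
lowest read count within its phenotype group, and the metric is averaged
over `n_replicates` independent draws (1,000 in the full analysis; tests
scale this down and say so). Set-valued results are never merged across
replicates; the replicate mean of the scalar is the estimate.

The downsampling engine draws the full replicate block with one C++ chain
of conditional hypergeometric draws. Each sample owns an RNG substream
derived by hashing the master seed with the sample's identity, so adding
samples to a run never perturbs the replicates of existing samples, and a
fixed seed makes every pipeline output bit-reproducible. (The spec-level
idea of one substream per replicate was relaxed to one per sample: the
stated goal is sample-insertion stability, which per-sample streams already
give, and per-replicate reseeding would defeat the vectorized chain.)

### Donor-reactive calling

A clonotype is donor-reactive when its stimulated/unstimulated read ratio,
after downsampling both members of the pre-transplant pair to a common
depth and averaging reads over replicates, is **at least 5** (applied at
equality). Raw-read folds are available by flag; depth-normalized folds are
the default because raw folds confound library depth. The set is called
once, pre-transplant, and frozen; tracking never re-calls it.

Clones absent from the unstimulated sample have infinite fold change. They
are included only if their normalized stimulated reads reach the fold
threshold itself (an undetected clone is treated as a singleton and must
out-expand a singleton). A fixed low floor such as 2 reads looks harmless
but is not: at realistic depths it admits large numbers of
sampling-noise singletons, and because these clones were selected for being
absent from the very pre-transplant sample used for tracking, they
reappear in later samples at their unconditional rate — a regression-to-
the-mean artifact that inflates the apparent post-transplant rise of the
donor-reactive repertoire. The floor is configurable, including `Inf`
(exclude undetected clones entirely).

The headline pre-versus-post contrast uses the first post-transplant
timepoint (month 1) by default, matching the "in the first month" framing
of the underlying study; averaging over all post timepoints is available.

### Diversity, immunodominance, turnover

*Clonality* is one minus Pielou's evenness: `1 - H/log(S)` with `H` the
Shannon entropy of clone frequencies, base-invariant. A monoclonal
repertoire has `H = H_max = 0`; the 0/0 is resolved as clonality 1 — the
limit of a two-clone repertoire as one frequency goes to 1, and the
biologically sensible reading (monoclonal = maximally clonal).

*R20* is the fraction of clonotypes, taken in decreasing frequency order,
needed to accumulate 20% of the repertoire: the smallest `k` with
cumulative frequency `>= 0.2`, divided by `S`, with no fractional
interpolation (interpolation would be an invention; the integer reading is
the plain one). Ties cannot affect the value because only the count enters.

Turnover against the pre-transplant baseline is the Jensen-Shannon
divergence of the two clone-frequency vectors, built on the union of each
repertoire's top 1,000 clones, zero-filled and renormalized (union rather
than intersection: clones that vanished or appeared are exactly what
turnover should see; intersection is available by flag). JSD is reported as
the divergence itself in base 2 — bounded in [0, 1], 0 iff identical,
1 for disjoint supports — not as its square root. VJ-usage turnover applies
the same divergence to frequency-weighted V-J pair usage distributions;
frequency weighting (clone mass) is the default, clonotype weighting the
alternative. V x J usage matrices (row sums = V usage, column sums = J
usage) are exported per sample as circos-style plot input.

### Virus-specificity annotation

Clonotypes are matched against a VDJdb-style table by exact,
case-insensitive CDR3 amino-acid equality (records filtered to TRB /
HomoSapiens, deduplicated). The database's loosest standard scope — CDR3 aa
only, ignoring V/J — is the default; a stricter scope adding V/J equality
is available and can only remove matches. No fuzzy matching by default:
the method is "matching the CDR3 sequence", not neighborhood search. A
clonotype may carry several species labels. The bundled table
(`inst/extdata/vdjdb_synthetic.tsv`) is **synthetic** — invented CDR3s in
the database's dialect for tests and examples, not real VDJdb content.

CMV enrichment inside the donor-reactive set is quantified per patient as
the CMV-labeled share of the donor-reactive clonotypes' mass in the preTx
bulk repertoire (renormalized within the set) against the CMV share of the
whole bulk repertoire, compared by paired t-test.

### The statistics battery

Group contrasts use unpaired t-tests (pooled-variance Student by default —
with 5 + 5 groups the Student/Welch distinction is immaterial, and Welch is
a flag); timepoint contrasts use paired t-tests; joint treatment x time
assessment uses a mixed factorial (split-plot) ANOVA with the treatment
group as between-subject and time as within-subject factor. The ANOVA is
computed from classical sums of squares; Mauchly's test (Box's chi-square
approximation with the second-order term, as in base R) is applied to the
pooled within-group covariance, and when sphericity is rejected at 0.05
the Greenhouse-Geisser epsilon multiplies both within-effect degrees of
freedom — so output mixes corrected (fractional) and uncorrected integer
dfs exactly as such analyses report them. "Always" and "never" overrides
exist. All tests are two-sided at alpha 0.05 with **no multiplicity
adjustment**, mirroring the exploratory character of the source analysis;
paired statistics are computed pre minus post, so a post-transplant
increase appears as a negative t.

Degenerate inputs follow explicit conventions: zero variance with equal
means gives p = 1; zero variance with a real difference gives an infinite
statistic reported as p = 0 with a `degenerate` flag; the ANOVA refuses
incomplete tables rather than imputing.

Implementation note: the t-tests and ANOVA are computed from first
principles rather than by wrapping model fitters, because the degenerate
conventions and epsilon reporting are part of the contract; the test suite
holds them against `stats::aov`, `stats::anova.mlm`, `stats::mauchly.test`
and `stats::t.test` as independent oracles (agreement to 1e-9 on random
balanced designs).

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` states the emulated world; `generate_cohort()` realizes it
with programmed ground truth. Defaults:

- **Cohort shape**: 5 + 5 patients (ATLG / basiliximab), timepoints preTx,
  M1, M3, M12, CD4 and CD8 fractions, one MLR-stimulated pre-transplant
  sample per patient and phenotype.
- **Clone sizes**: Zipf law with exponent 1.2 — heavy-tailed, giving
  realistic spreads of clonality and R20 across patients.
- **Per-sample clonotype counts**: drawn so that *observed* unique counts
  land in a 1:10 scale-down of the published per-sample ranges (CD4
  2,633-10,774; CD8 719-8,753). The generator numerically inverts the
  expected-observed-richness function (accounting for multinomial read
  sampling at 35 reads per latent clone and contamination) and asserts the
  realized counts, with windows that leave headroom for the longitudinal
  drift described below.
- **Sequencing depth**: 35 reads per latent clonotype. The initial design
  used 15; at that depth the deep Zipf tail sits at well under one expected
  read, and Poisson noise alone then fakes five-fold MLR expansions for
  hundreds of tail clones — contradicting the source method's own premise
  that the 5-fold criterion excludes bystander activation. The deeper
  default restores that premise; it is a spec knob, not a claim.
- **Donor-reactive planting**: 1% of clones, restricted to baseline
  frequencies with expected reads between 3 and 150. The lower bound exists
  because clones invisible to the pre-transplant sample are not a
  meaningful recovery target (and their conditioned absence would bias the
  tracked delta); the upper bound keeps the immunodominant head out, as
  alloreactive precursors sit at modest frequencies. At the default
  fraction this window yields about 1% planted baseline mass, matching the
  reported pre-transplant donor-reactive frequencies (~0.9-1.1%).
- **MLR**: a sorted-mixture model of the CFSE-low sample. The sort selects
  proliferated cells, so the reactive clones carry a fixed share (0.8) of
  the stimulated sample's mass regardless of their precursor frequency —
  reactive observed folds scale like `0.8 / precursor_mass` (tens to
  hundreds), which is the biology of the assay. Bystanders are carried
  over at all only with probability 0.3 (the stimulated repertoires
  therefore hold far fewer clonotypes than the bulk, as the study
  reports) and share the remaining 0.2 of the mass, giving observed
  bystander folds centered below 1 with log-normal spread — approaching
  but essentially never reaching the 5-fold threshold. An earlier design
  that multiplied per-clone folds and renormalized was discarded: it tied
  the stimulated sample's composition to the planted precursor mass, and
  for patients with small precursor mass it mechanically inflated
  bystander folds past the threshold, contradicting the criterion's
  premise.
- **Longitudinal dynamics**: non-reactive clones persist per post-transplant
  timepoint with probability 0.85 and are replaced by novel clones;
  per-clone log-normal frequency drift (sdlog 0.3); reactive-clone
  frequencies multiplied by 1.9 at every post timepoint in both arms
  (emulating the reported, therapy-independent ~0.9 percentage-point rise).
- **Contamination**: 2% of each sample's read mass leaks from the opposite
  phenotype fraction, exercising the ambiguity correction.
- **Virus-specific planting**: CDR3s from the bundled synthetic table at
  0.5% (CMV) and 0.3% (EBV) of clones, with CMV planting 4x enriched
  within the donor-reactive subset (emulating the reported CMV enrichment
  among donor-reactive clones).
- **Depth under depletion**: 1.0 (no reduction) for ATLG at M1 — the study
  reports detected clonotype numbers comparable across timepoints;
  lymphodepletion shows in lymphocyte counts, not library depth. The knob
  exists for sensitivity analyses.
- **Dominant-clone scenario**: an optional flag plants a persistent >10%
  clone in one patient, reproducing the known immunodominance anomaly for
  R20-robustness checks.

CDR3s are random in-frame sequences (C...F motif, random synonymous
codons), *not* output of a V(D)J recombination model: they support set
arithmetic and annotation, nothing sequence-biological. Gene usage is
Dirichlet-drawn per patient over real TRBV/TRBJ symbol lists. A green test
on this cohort establishes that the pipeline recovers planted truth under
the stated noise model — it does not establish anything about PCR bias,
UMI errors, HLA effects, or real repertoire structure beyond the modeled
features.

## Numerical conventions

- `0 log 0 := 0` throughout; JSD inputs must sum to 1 within 1e-8 (the
  caller renormalizes explicitly, never silently).
- Greenhouse-Geisser epsilon is clamped to `[1/(k-1), 1]`; a singular
  within-covariance lower-bounds epsilon with a warning instead of failing.
- Downsampling depth must not exceed the repertoire's reads — an error, not
  a silent cap.
- Derived seeds are polynomial string hashes modulo 2^31 - 1, so they stay
  valid 32-bit R seeds.
- Out-of-frame clonotypes (frame-break symbols in the amino-acid column)
  are retained at ingestion; the choice is logged by the reader's contract
  rather than hidden.

## Known limitations

- The fold criterion is a pure threshold; no significance co-criterion
  (binomial/Fisher) is offered, by design.
- The paired "after transplantation" contrast defaults to M1; the source
  analyses are ambiguous about pooling of later timepoints, so both
  policies exist and are reported explicitly.
- No parametric richness extrapolation (Chao, rarefaction curves) — depth
  handling is subsampling only.
- The synthetic MLR models clonal expansion as frequency multiplication;
  it does not model culture dropout of fragile clones, nor cell-number
  bottlenecks at sorting.
- `headline_contrasts()` reports all three ANOVA effects (group, time,
  interaction) for each metric because published F statements of this kind
  are often ambiguous about which effect they quote.
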