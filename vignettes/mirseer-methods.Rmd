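---
title: "Inferring microRNA activity from mRNA profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microRNA activity from mRNA profiles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseer)
```

## The problem and the model

MicroRNAs repress their direct mRNA targets, so the expression levels of a
microRNA and of its target genes tend to be inversely correlated. When no
microRNA assay is available but mRNA arrays are, this regularity can be
turned around: if the predicted targets of a microRNA sit systematically
*high* in a sample's expression ranking, the microRNA itself is plausibly
*down*-regulated in that sample. `mirseer` operationalizes this as a
rank-based activity score and carries it through a complete inference
chain: probe-level quality control, per-sample scoring, permutation
association with patient recurrence, cross-dataset candidate selection,
meta-analysis, and a qPCR validation toolkit.

### Activity score

Within each sample the genes are ranked by expression (rank 1 = highest;
ties get the average rank) and each rank $r$ receives a weight. Two
schemes are provided:

* **linear** (default): $w(r) = N - r + 1$, i.e. the weight of a gene is
  its ascending-expression rank;
* **exponential**: $w(r) = N e^{-\beta r / N}$ with decay rate
  $\beta > 0$ (default 1), which concentrates weight on the top of the
  ranking.

For microRNA $m$ with target set $T_m$ the activity score in sample $s$ is

$$ A_{m,s} \;=\; \overline{w}_{T_m}(s) \; - \; \overline{w}_{\bar T_m}(s), $$

the difference between the mean weight of its targets and of all other
measured genes. The linear scheme makes $A_{m,s}$ an affine function of
the Wilcoxon rank-sum statistic of targets versus non-targets, which is
what the test suite exploits as an independent oracle. The exact weight
function used by the original web implementation of this idea is not
recoverable; the linear scheme is the default for transparency and the
exponential one is offered for sensitivity analysis. Planted-signal
recovery must (and does) succeed under both.

**Sign convention.** A positive score means targets are up-ranked, which
under the inverse-correlation assumption reads as microRNA
*down*-regulation. A positive recurrent-minus-non-recurrent effect size
therefore reports a microRNA inferred to be down-regulated in the
recurrence group.

**Non-target universe.** The comparison set is *all* measured genes not
targeted by the microRNA, not only genes targeted by some other microRNA.

### Quality control

Array platforms differ in probe design, so two screens are applied per
dataset before scoring:

1. **IQR filter**: the inter-quartile range of every probe across samples
   is computed once (type-7 linear-interpolation quartiles, the common
   spreadsheet/stat-package convention), and probes with IQR *strictly
   lower* than the median probe IQR are discarded. Probes exactly at the
   median are retained; with all-distinct IQRs this keeps
   $\lceil n/2 \rceil$ probes. The median is computed on all probes,
   including unannotated ones.
2. **Probe collapse**: when several probes interrogate one gene, the probe
   with the largest IQR is kept; exact IQR ties are broken by the
   lexicographically smallest probe id, so the pipeline is deterministic
   and invariant to row order.

Probes must be at least 80% finite (and have at least 4 finite values);
remaining missing entries of retained probes are median-imputed per probe
before ranking. Each (accession, stage) pair is treated as an independent
stage-specific dataset.

### Association and selection

Per dataset and microRNA, the effect size is the difference in mean score
between recurrent and non-recurrent patients, with standard error
$\sqrt{s_1^2/n_1 + s_0^2/n_0}$. Significance comes from a two-sided
permutation test on the absolute mean difference: group labels are
permuted (1000 draws by default) and the Monte-Carlo p-value uses add-one
smoothing, $p = (1 + \#\{|T^\ast| \ge |T_{obs}|\})/(1 + B)$, which keeps
the p-value valid and strictly positive. An exhaustive mode enumerates all
label assignments for small cohorts (guarded at 20 samples) and returns
the exact exceedance fraction. Two-sidedness is our choice — the source
analysis does not state sidedness — and is the conservative reading.

Each (microRNA, dataset) pair derives its own RNG seed from the global
seed by hashing the identifiers, so results are reproducible and
independent of evaluation order.

A microRNA is a stage-level candidate when $p \le 0.1$ in *every* dataset
of the stage **and** the effect sign agrees across them; cross-stage
candidates are the intersection of the stage lists. The 0.1 screen is
deliberately liberal (a type-II-error guard at the screening step), and
the sign-consistency requirement is our explicit tightening of a rule the
source analysis applied implicitly through direction-consistent findings.

### Meta-analysis

Candidates are pooled over all stage-specific datasets by inverse-variance
weighting: fixed effects with $w_i = 1/se_i^2$ and a 1.96 normal CI
multiplier; Cochran's $Q$ with $k-1$ df for heterogeneity; and the
DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)$
for the random-effects model. When $Q \le k-1$, $\hat\tau^2 = 0$ and the
two models coincide exactly — the near-homogeneous regime in which the
method's source reported identical fixed- and random-effects results.
Evidence across datasets is combined with Fisher's method,
$\chi^2 = -2\sum\ln p_i$ on $2k$ df, with a genome-wide cutoff of
$5\times10^{-5}$ (about $0.05/711$ for a 711-microRNA database). REML
estimation of $\tau^2$ and publication-bias diagnostics are deliberately
out of scope; DL was the era-standard estimator.

One numerical consequence worth stating: with $B$ permutations, each
per-dataset p-value is floored at $1/(B+1)$, so the Fisher combination of
six datasets at $B = 1000$ cannot go below $\approx 1.1\times10^{-12}$
and, more importantly, published combined p-values far below what six
permutation p-values can produce imply a denser permutation null or a
parametric p-value upstream. The package exposes `n_perm` rather than
guessing; ranking and the $5\times10^{-5}$ decision are unaffected because
ties at the floor are broken by pooled effect magnitude.

### Validation-cohort statistics

qPCR relative expression uses the standard
$\log_{10}(2^{-\Delta Ct})$ transform with
$\Delta Ct = Ct_{miR} - Ct_{ref}$ (U6b reference; triplicate wells are
averaged to one Ct before the difference). The crude group comparison is a
two-sided pooled-variance t-test (Welch by flag; the source says only
"independent t-test", and the pooled form reproduces its printed p-values
from the published summary table), also computable from (n, mean, sd)
summaries alone. The adjusted comparison is the group term of an ANCOVA
`value ~ group + age + sex + stage` with stage categorical; constant or
collinear covariates are dropped with a warning rather than silently
absorbed. Markers are dichotomized at the sample median with ties (and the
median element itself) going to "low". Early recurrence is analyzed by
truncating follow-up at a 12-month horizon (events beyond it become
censored at the horizon), Kaplan–Meier curves per marker group, and the
two-group log-rank test; with no events the log-rank statistic is
undefined and the function returns $p = 1$ with a warning. The
product-limit estimator and log-rank test are delegated to the `survival`
package; the suite pins them against hand-tabulated risk sets and the
empirical survival function.

## The synthetic study

The generator produces every input the pipeline consumes, with known
ground truth, at the scale of the motivating six-dataset colorectal-cancer
study. Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| genes / microRNAs | 2,000 / 200 | large enough for stable rank scores, minutes-scale runs |
| targets per microRNA | 20–60, uniform | mid-range of predicted-target-set sizes after restriction to measured genes |
| datasets | 3 stage II + 3 stage III | the six stage-specific datasets the design mirrors |
| per-group samples | 12–53, uniform | dataset totals 24–106, matching the 23–106 span of the emulated cohorts |
| intensity model | gene baseline $\mathcal N(8, 2)$ + residual $\mathcal N(0, 1)$ | normalized log-intensity-like scale |
| planted shift $\delta$ | 3 (= 3 × noise SD) | a strong, unambiguous signal for recovery testing; $\delta = 0$ gives the null generator |
| probes per gene | 1–3, probe noise SD 0.25 | redundant-probe structure the QC step must resolve |
| missing / unannotated rate | 2% / 2% | light corruption; missingness capped so probes stay ≥ 85% finite |

The planted signal adds $+\delta$ to the planted microRNA's target genes
in recurrent samples only — exactly the inverse-correlation footprint the
scorer is designed to detect, with "targets up in recurrence" reading as
microRNA down-regulation. The qPCR generator draws log-scale relative
expression per group (defaults: 27 vs 41 patients, means 1.57 vs 1.25,
common SD 0.5, matching the emulated validation cohort), back-converts to
Ct pairs through the exact inverse of the $\Delta Ct$ transform, and draws
exponential recurrence times with a group hazard ratio (default 3) under
36-month administrative censoring.

What the generator does **not** emulate: platform-specific normalization
artifacts, batch effects, correlated gene modules, realistic probe
sequences, or target-prediction error. Passing the recovery tests
therefore demonstrates that the inference chain is correct and calibrated
under its own assumptions — not that the method is robust to the full mess
of real array data.

## Reproducibility and problem sizes

Everything stochastic flows from explicit seeds: the simulation config
carries one, and the association step derives per-(microRNA, dataset)
seeds from the global one. `run_full_analysis()` validates all inputs
before computing, writes every intermediate table plus a manifest (config
snapshot, input MD5 digests, seed, candidate lists, package version), and
two runs from the same config are byte-identical.

The test suite exercises the full chain at the default scale (six
datasets, 2,000 genes, 200 microRNAs, 1000 permutations — about a minute),
calibration on 300 null microRNAs in a 20-vs-20 dataset, permutation
oracle equivalence on 100 exhaustive instances, and the closed-form
oracles for the meta-analysis and validation statistics. The interface of
the package is its exported functions: `simulate_study()` +
`run_full_analysis()` reproduce the whole analysis from a YAML config, and
the per-module functions expose each stage individually.

## Known limitations

* Identifier matching between the target database and probe annotations is
  exact and case-sensitive; an alias map can be supplied, but no fuzzy
  symbol reconciliation is attempted.
* The permutation p floor $1/(B+1)$ bounds how small Fisher-combined
  p-values can get (see above).
* The activity score treats target sets as unweighted; prediction scores,
  seed-match quality and context features are not used.
* No FDR machinery at the screening stage (by design: a liberal fixed
  screen followed by cross-dataset consistency and a Bonferroni-style
  genome-wide cutoff at the meta stage), and no Cox regression in the
  validation module (KM/log-rank only).
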