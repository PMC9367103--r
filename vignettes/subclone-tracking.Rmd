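---
title: "Tracking tumor subclones across sequential treatment from read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking tumor subclones across sequential treatment from read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetracer)
```

## The problem

Neoadjuvant chemotherapy reshapes the clonal composition of a tumor. Biopsies
taken before treatment, between two sequential drug regimens, and at surgery
give three snapshots of that process, but comparing them naively is
misleading for two reasons. First, the observed variant allele fraction (VAF)
of a somatic mutation confounds its true cellular prevalence with the tumor
cell fraction of the biopsy and the local copy number. Second, conventional
somatic calling applies hard thresholds (a minimum VAF, a minimum number of
supporting reads), so a subclone that shrinks under therapy "disappears" from
the call set long before it is actually eradicated — and a subclone that
expands appears to arise *de novo* even when it was present all along.

`clonetracer` addresses both problems on count-level data: it corrects VAFs
for purity and copy number, emulates threshold calling so the detection
process itself can be studied, rescans sub-threshold samples for trace reads,
clusters mutations into subclones jointly across timepoints, and summarises
burden, copy-number and clinical-response dynamics at the cohort level.
Because trial sequencing data of this kind are typically controlled-access,
the package ships a synthetic cohort generator with a known clonal ground
truth; every stage can be validated end to end against that truth.

## The rVAF model

For a mutation with multiplicity $n_{mut}$ (mutated alleles per tumor cell)
at a locus with total tumor copy number $n_{tot}$, in a sample with tumor
cell fraction $\rho$, a fully clonal mutation is expected at

$$ VAF_{exp} = \frac{n_{mut}\,\rho}{2(1-\rho) + n_{tot}\,\rho}, $$

the ratio of mutated alleles to all alleles in the normal/tumor admixture
(normal cells contribute two copies). The *relative VAF* is

$$ rVAF = VAF_{obs} / VAF_{exp}, $$

which estimates the cancer cell fraction of the mutation: truncal mutations
sit near 1, subclonal ones below. Sampling noise can push rVAF above 1; the
raw value is kept (`rvaf()`), and a [0, 1]-clamped copy
(`cellular_prevalence()`) is used wherever a prevalence is needed.
Multiplicity is not observable from counts alone; `estimate_multiplicity()`
picks the $m \in \{1..n_{tot}\}$ whose expected VAF is nearest the observed
one (ties toward the smaller $m$) — the simplest estimator consistent with
the definition. In the pipeline one multiplicity is shared across a
mutation's samples with the same local copy number, taken from its most
informative sample (highest purity × depth): multiplicity is a property of
the mutated locus, and letting it flip between samples would inject spurious
prevalence jumps.

## Detection, traces and trajectories

`call_variants()` reproduces a conventional calling gate on count tables:
called iff depth > 0, $VAF_{obs} \ge$ `min_vaf` (default 0.05) and
`alt_reads` $\ge$ `min_alt` (default 3; this stands in for the
two-caller-intersect confirmation used by alignment-level pipelines, which
cannot be re-run on counts). `trace_scan()` then inspects samples where a
variant was *not* called: one or more supporting reads is a trace — direct
evidence the carrying subclone is present below the detection limit. Trace
reads are counted as-is and never capped.

`classify_trajectories()` combines the two per sample pair: called in both
samples → `persistent`; called only later → `emerging`, with the earlier
sample rescanned (`pre_existing_trace` vs `no_trace`); called only earlier →
`disappearing`, with the later sample rescanned (`residual_trace` vs
`no_trace`). Mutations never called in either sample stay out of the
trajectory table by default. Pairs are only formed between samples with
tumor cell fraction at or above `min_cellularity` (default 0.20) — below
that, absence of evidence is mostly absence of tumor. When the intermediate
sample fails the gate but the first and last do not, the pipeline compares
them directly (`pre -> post_b` fallback), and flags the pair.

## Clonal clustering

`clone_mixture()` clusters mutations by their cellular prevalence vectors
jointly across timepoints with a finite binomial mixture: cluster $k$ has a
prevalence $\theta_{kt}$ per timepoint, and a mutation contributes binomial
likelihoods with its clamped rVAF converted back to successes over an
effective depth. EM runs for each $K = 1..k_{max}$ with 10 random restarts
(best log-likelihood kept), and $K$ is chosen by BIC with ties toward the
smaller $K$. This is a deliberate desk-scale stand-in for Dirichlet-process
samplers (PyClone and kin), adequate for three-point prevalence vectors; it
is not a reproduction of them.

Two display rules are applied after fitting. *Singleton merge*: a
one-mutation cluster is compared to every non-singleton cluster by the
standardized distance between its prevalence vector and the cluster mean
(scale: the binomial standard error of the cluster mean at the mutation's
depth); it merges into the nearest cluster when every per-timepoint z-score
lies within [−1, +1], otherwise it is kept and flagged. Cluster means are
*not* recomputed after a merge — the merged mutation adopts the target's
trajectory, keeping the displayed means those of the well-supported members.
*Pruning*: clusters with fewer than 3 mutations are dropped from display
output but retained in a removed-list, so the analysis stays complete.
`build_fishplot_table()` emits a long-format table with a parent guess per
cluster by containment (a parent's prevalence is ≥ the child's at every
timepoint; the tightest container wins; exact ties are marked ambiguous).
The heuristic cannot distinguish a newly appearing subclone that carries all
truncal mutations from one that lost some.

### Effective depth and a known failure mode

On the prevalence scale the sampling noise of rVAF is the VAF noise divided
by $VAF_{exp}$. The pipeline therefore hands the mixture an effective depth
of `depth` × $VAF_{exp}$, which makes the binomial successes equal the
actual alt reads and carries approximately the right variance at
intermediate prevalences. At prevalence ≈ 1, however, a binomial kernel has
vanishing variance while clamped rVAFs keep scattering below 1, so BIC can
split a truncal cluster into two or three adjacent clusters, and inferred
cluster counts tend to over-estimate the true clone count in low-purity
samples. A beta-binomial kernel would absorb this; with the binomial
stand-in the over-splitting is visible in the simulation scorecard and
should be kept in mind when reading per-patient cluster counts. Cluster
*prevalences* remain accurate (the recovery benchmark in the test suite
requires mean absolute error ≤ 0.05 at depth 150 with 30 mutations per
cluster).

## Copy-number and cohort dynamics

`call_gain_loss()` calls each segment against a baseline total copy number
of 2 (no whole-genome-duplication adjustment by default, because a reliable
WGD call is an input we do not infer; the baseline is overridable per
sample). `cohort_fraction_delta()` computes, per bin, the fraction of
patients carrying a gain (or loss) after treatment minus the same fraction
before — the cohort-level CNA shift — over the inner join of patients
present at both timepoints. `gene_cn_trajectory()` extracts per-patient
total copy number at a gene locus across the three timepoints, resolving
multi-segment overlaps by the length-weighted majority segment (deterministic
and order-independent); missing samples stay missing. Paired changes are
tested with the two-sided Wilcoxon signed-rank test (`paired_cn_test()`),
exact up to 25 pairs when ties permit, normal approximation otherwise;
all-zero differences are reported as a degenerate p = 1 rather than an
error.

Burden (`compute_tmb()`) is mutations per megabase over a configurable
target size (default 50 Mb, a typical whole-exome capture), restricted by
default to amino-acid-changing effects (missense, nonsense, frameshift,
splice); both modes are exposed because burden definitions vary between
pipelines. `substitution_spectrum()` collapses SNVs onto the six
pyrimidine-reference classes.

## Clinical response and association scans

`classify_recist()` applies single-lesion RECIST 1.x thresholds (CR at
disappearance, PR at ≥ 30% shrinkage of the largest diameter, PD at ≥ 20%
growth, SD otherwise). `classify_uicc_pd()` implements the UICC progression
rule — ≥ 25% increase (inclusive) of the product of the largest and
perpendicular diameters — and `assess_response()` lets a UICC-PD flag
override the final category before dichotomizing into responders (CR/PR)
versus non-responders (SD/PD). `compare_tmb_by_group()` runs the paired
signed-rank comparison of burden within each response group.
`mutation_response_association()` scans genes mutated in at least
`min_mutated` patients (default 3) with the two-sided Fisher exact test and
Benjamini–Hochberg correction across tested genes; BH is the standard
default where no specific correction is prescribed. A Cochran–Armitage-style
trend test across the ordered categories is available as
`response_trend_test()` (via `prop.trend.test`).

## The synthetic cohort generator

`simulate_cohort()` draws, per patient:

* a clonal tree with one truncal clone (prevalence 1 at every timepoint) and
  2–6 subclones attached at random to earlier clones. Prevalences are
  *inclusive* (a clone's prevalence counts its descendants), so siblings'
  prevalences sum to at most the parent's; a mutation's cancer cell fraction
  equals its clone's inclusive prevalence (infinite sites, one clone per
  mutation);
* treatment dynamics: at each transition every subclone's prevalence is
  multiplied by $e^{\epsilon}$, $\epsilon \sim N(0, \texttt{expansion\_sd})$
  (default 0.5), and subclones below 0.1 prevalence go extinct with
  probability 0.3; violations of the nesting constraint are repaired by
  proportionally rescaling children. These parameter values are artifact
  choices — there is no accepted generative model of chemotherapy-driven
  prevalence change — picked so that small subclones frequently cross the
  5%-VAF detection boundary while truncal clones persist, which is the regime
  the detection and trajectory machinery must handle;
* copy number: diploid everywhere, with optional directed events (bin,
  timepoint, gain/loss, probability) that persist from their timepoint
  onward, as clonal copy-number events do; losses never drop below one copy
  in mutation-bearing bins;
* purities: per-timepoint means 0.65/0.45/0.35 with ±0.15 uniform jitter
  (declining cellularity under effective treatment, spanning roughly
  0.2–0.9), and read counts: depth Poisson with mean 150 (exome-like
  coverage), alt reads binomial at $CCF \times VAF_{exp}$, plus an optional
  per-read error rate (default 0) for stressing trace specificity.

What the generator does **not** emulate: trinucleotide-context mutation
spectra, germline contamination, mapping artefacts, regional coverage bias,
subclonal copy number, or sample swaps. Passing tests on this generator
therefore demonstrate that the statistical machinery is correct under its
stated model, not that real exome pipelines are free of artefacts upstream
of the count tables.

## Numerical choices

* EM: success counts may be fractional (prevalence × depth); cluster
  probabilities are clamped to $[10^{-6}, 1-10^{-6}]$; convergence at a
  relative log-likelihood change below $10^{-8}$, 500 iterations cap;
  restarts are seeded once per fit for reproducibility; BIC uses
  $K\,T + (K-1)$ free parameters.
* Degenerate inputs: all-zero depth matrices, empty baselines, zero-tumor
  purity and negative counts raise errors; zero-denominator rates
  (trace fractions with no emerging mutations) are reported `NA`, never 0.
* Determinism: every stochastic stage takes a seed; `run_pipeline()` derives
  per-patient clustering seeds from the run seed, and the manifest hash
  covers the full configuration, so identical configs give identical
  reports.
* Test and acceptance problem sizes (10–19 patients, $10^4$ replicate draws,
  10 clustering seeds) were chosen as the smallest cohorts at which the
  Monte-Carlo assertions have comfortable margins; they run on a laptop in
  about a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(simulate = sim_config(n_patients = 4, seed = 42),
                  seed = 42, k_max = 8)
report <- run_pipeline(cfg)
report
plot(report$clusters[["P001"]]$display)
report$trace_summary
```

## Limitations

* The clustering is a binomial-mixture stand-in, not a Dirichlet-process
  sampler: no posterior uncertainty, and the truncal-splitting failure mode
  described above.
* The rVAF correction trusts the supplied purity and segments; it cannot
  rescue a mis-called copy-number profile.
* Trace reads are accepted as given — base and mapping qualities are
  upstream of the count-table contract, so sequencing-error traces must be
  controlled by the caller or modelled via the generator's error rate.
* Response classification is single-lesion; multi-focal summarisation is the
  caller's responsibility.
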