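---
title: "Profiling intrinsic disorder across proteome groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling intrinsic disorder across proteome groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idproteome)
```

## The problem

Intrinsically disordered proteins (IDPs) and regions (IDPRs) lack a fixed
three-dimensional structure, globally or locally, and tissues differ in how
much of their proteome is disordered. A recurring comparative design in the
field — applied, for example, to the human ocular lens at different donor
ages and to the zonular fibers that suspend it — asks whether distinct
proteome groups differ systematically in their disorder content, and
whether donor age tracks with that content. `idproteome` implements that
comparison as a reusable, fully testable pipeline. It does not reimplement
any trained disorder predictor: per-residue disorder scores are inputs,
supplied as plain tabular tracks (one score in $[0,1]$ per residue per
predictor, the dialect of batch predictor platforms), and a self-contained
baseline predictor is included only so the pipeline can run end to end
without external services.

## Amino-acid composition profiling

For a query proteome and a background set, the enrichment of residue $x$ is
the fractional difference

$$ \mathrm{FD}_x = \frac{C_x - C_{\mathrm{bg}}}{C_{\mathrm{bg}}}, $$

where $C_x$ is the relative frequency of $x$ in the pooled query sequences
and $C_{\mathrm{bg}}$ its frequency in the background. Positive values mean
enrichment, negative depletion, and the statistic is bounded below by $-1$.
Residues are reported on the fixed order-to-disorder ranking axis: the ten
order-promoting residues C, W, I, Y, F, L, H, V, N, M, then the ten
disorder-promoting residues R, T, D, G, A, K, Q, S, E, P.

Uncertainty comes from a bootstrap over *proteins*: whole sequences are
resampled with replacement independently within the query and background
(keeping each group's size), because proteins — not residues — are the
independent sampling units of a proteome. The default is 10,000 iterations
(`iterations`), reducible for exploratory runs. Significance uses a
two-sided sign-crossing test: with $k$ the smaller of the counts of
non-positive and non-negative resampled fractional differences over $n$
finite iterations, $p = \min\{1, 2(k+1)/(n+1)\}$. The add-one correction
keeps $p$ away from exactly zero at finite $n$. A residue absent from the
background has an undefined ratio; it is flagged `undefined` (with an
`Inf`/`NaN` sentinel) rather than silently dropped, and a `strict` policy
can turn it into an error. No background composition is hard-coded:
curated reference backgrounds are not redistributable here, so the
background is always supplied, either as a FASTA set or as a frequency
table.

## Per-protein disorder summaries

For each protein and predictor track of length $L$:

* **ADS** (average disorder score): the arithmetic mean of the per-residue
  scores.
* **PPDR** (percentage of predicted disordered residues): the fraction of
  residues with score *strictly above* 0.5. The strict inequality follows
  the usual "above 0.5" reading; an inclusive variant is available for
  sensitivity checks (`ppdr(..., inclusive = TRUE)`).
* **MDP** (mean disorder profile): the residue-wise mean across that
  protein's predictor tracks, itself a track, summarised like any other.
  When all tracks have equal length, `ads(MDP)` equals the mean of the
  per-predictor ADS values exactly — an algebraic identity the test suite
  asserts at $10^{-12}$.

The cutoff grid classifies each protein on both axes: by ADS, highly
ordered below 0.15, moderately disordered in $[0.15, 0.5)$, highly
disordered at 0.5 or more; by PPDR, the same three levels at 10% and 30%.
Lower bins are half-open and the top bin is closed below ("30% or more",
"0.5 or more"). Two combination modes exist because the two natural
readings of "highly disordered" differ: `strict_and` takes the less
disordered of the two axes (so the top class requires both), `lenient_or`
the more disordered. The default is `lenient_or`, which is the reading
under which published per-class counts in this design are internally
consistent; every report states the mode used, and the mode never affects
the per-axis classes or the ANOVA inputs.

## CH-CDF classification

Two whole-protein binary classifiers are combined:

* **ΔCH** — the signed distance of the protein from a line in
  charge-hydropathy space: $\Delta CH = \langle R \rangle - (a \langle H
  \rangle + b)$, with $\langle R \rangle$ the mean absolute net charge
  (K, R positive; D, E negative; histidine neutral; no pH model) and
  $\langle H \rangle$ the mean scaled hydropathy (Kyte–Doolittle values
  min–max rescaled to $[0,1]$, averaged over full sliding windows of width
  5, then over the protein). Positive ΔCH is the disordered side.
* **ΔCDF** — the mean signed distance of the protein's cumulative score
  distribution above a boundary curve: at each boundary $x$, the fraction
  of residues with score $\le x$, minus the boundary $y$. Positive ΔCDF
  (curve above boundary, most residues at low scores) is the ordered side.

The quadrants follow the standard sign table: Q1 ordered by both
(ΔCH < 0, ΔCDF > 0), Q2 disordered by CDF only (molten-globule-like),
Q3 disordered by both, Q4 disordered by CH only. Exact zeros are a
measure-zero case; they are resolved by treating ΔCH ≥ 0 as the disordered
side and ΔCDF ≥ 0 as the ordered side, and every tie is logged.

The CH line ($a = 2.785$, $b = -1.151$) and the bundled 7-point CDF
boundary (`inst/extdata/ch_cdf_boundary.yaml`) are literature-standard
defaults, supplied as configuration precisely because they are
conventions, not results: the package's tests depend only on sign and
geometry properties (rescaling invariance, monotone CDF curves, the
closed form $\Delta CDF = \mathrm{mean}(1 - y_{\mathrm{boundary}})$ for
all-zero tracks), never on the constants.

The bundled `baseline` predictor maps the same windowed
hydropathy/charge geometry through a logistic squashing (steepness 3) to
a per-residue score in $(0,1)$. It is a transparent physics-style
heuristic for running the pipeline self-contained — it is *not* a
substitute for trained predictors and is labelled accordingly in every
output.

## Group statistics

Per predictor and metric (ADS, PPDR), groups are compared with classical
one-way ANOVA ($F = MS_{\mathrm{between}}/MS_{\mathrm{within}}$), followed
by Tukey HSD simultaneous intervals using the Tukey–Kramer adjustment —
the groups in this design have very different sizes, and Tukey–Kramer is
the standard equal-variance procedure for that case. Count tables
(cutoff-grid classes, CH-CDF quadrants) are compared with the plain
Pearson chi-squared test of independence, no continuity correction, with
$\mathrm{DoF} = (r-1)(c-1)$. No multiple-testing correction is applied
across the predictor-metric table, matching the design being reproduced;
raw p-values are always written to the output tables, and any "<0.01"-style
bucketing is display-only.

The expression-weighted pool score summarises a sample pool (e.g. pooled
zonule donors) as
$$ s = \frac{\sum_i a_i \cdot \mathrm{ADS}^{\mathrm{MDP}}_i}{\sum_i a_i}, $$
with $a_i \ge 0$ the protein's abundance. It is invariant to abundance
rescaling and bounded by the pool's ADS range; a positive-abundance
protein without an MDP ADS is an error, not a silent drop.

## The synthetic-data generator

`synthetic_spec()` describes a complete synthetic study; the corpus is a
pure function of the spec and its seed. The defaults emulate the study
conditions the pipeline targets:

* three proteome groups of 926, 261 and 279 proteins (younger lens, older
  lens, zonules), sequence lengths uniform on 60–400 residues, residues
  i.i.d. from a uniform 1/20 baseline composition optionally reweighted by
  per-residue multiplicative biases. The uniform baseline is a deliberate
  neutral choice — any frequency table may be substituted;
* six pseudo-predictors whose per-group target mean ADS values follow the
  published per-predictor group means (e.g. 0.42/0.39/0.47 for the
  VSL2B-like predictor), with protein-level means drawn from a Beta
  distribution re-parameterized by (mean, concentration) — chosen because
  it respects the $[0,1]$ support — at a between-protein SD of 0.15, plus
  residue-level noise (SD 0.1) made autocorrelated by a moving average
  over 5 residues and clipped to $[0,1]$. Clipping introduces a small
  mean bias, acceptable at the tolerances the recovery tests state;
* four expression pools A–D with mean donor ages 39, 51.5, 60 and 38.5
  years (the prose values of the source design; its summary table prints
  38.5/50.5 for the first two, and ages are plain configuration inputs
  here) and log-normal abundances. A pool may carry a `target_score`; the
  generator then rescales the above-target side of the abundance vector by
  the unique positive factor making the weighted mean ADS hit the target
  exactly, so pools with known normalized disorder scores (defaults
  0.323/0.310/0.353/0.310) can be constructed for validation.

What the generator deliberately does **not** emulate: real sequence
families (crystallins, fibrillins), domain architecture, residue-level
coupling between composition and disorder scores, or shared proteins
across groups. Passing recovery tests therefore demonstrates the
*statistical machinery* — calibration, power, sign recovery — not
biological realism of the inputs.

## Numerical choices and scale of the checks

Degenerate inputs fail loudly: empty groups, all-zero abundances,
track/sequence length mismatches (an error, never a truncation) and
non-contiguous residue indices are errors naming the offending protein.
Residue indices are 1-based in files. FASTA ambiguity codes B, Z, X, U, O
follow a configurable policy (`drop_ambiguous` by default, `strict`,
`map_to_nearest` with B→N, Z→Q, U→C, O→K and X dropped); any other letter
is always an error.

The test suite validates calibration at deliberately moderate problem
sizes chosen to make the checks sharp but quick: ANOVA type-I rate over
500 null replicates of three 200-protein groups (expected in the 3–8%
band at $\alpha = 0.05$); power over 100 replicates at the published group
sizes and VSL2B means; composition-bias recovery on a corpus of about
$1.2 \times 10^5$ residues with 2,000 bootstrap iterations; pool-score
construction to within $5 \times 10^{-3}$ (in practice exact to floating
point). Monte-Carlo self-consistency of bootstrap p-values across seeds is
asserted at ±0.02 with 10,000 iterations.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(
  group_sizes = c(younger_lens = 120L, older_lens = 100L, zonules = 110L),
  length_range = c(60L, 200L), seed = 7L)
cfg <- synthesize_corpus(spec, "corpus")
cfg$iterations <- 1000L
run <- run_pipeline(cfg)
run$results$pool_scores
run$results$chisq
```

The run writes, under `corpus/results/`: the composition profile table,
the per-protein disorder summary, the per-predictor group summary with
ANOVA, the Tukey table, classification and quadrant count tables with
their chi-squared tests, the pool scores, and a `manifest.json` recording
the seed, parameters and a hash of the configuration. Reruns with an
identical configuration and seed are byte-identical in every TSV.

## Known limitations

* The composition bootstrap treats the background as a random sample too;
  for a fixed reference background, supply it as a frequency table and
  interpret the SD as query-only variability is *not* currently offered —
  both sets are resampled.
* ΔCDF is a geometric recomputation from whichever track the
  configuration selects (default MDP); it is not a reimplementation of
  any published CDF predictor, and quadrant counts from real studies are
  treated as worked-example inputs, not recomputation targets.
* The pipeline assumes one track per (protein, predictor); alternative
  splice forms must carry distinct ids.
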