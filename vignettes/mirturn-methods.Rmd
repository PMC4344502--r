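---
title: "mirturn: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirturn: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirturn)
```

`mirturn` estimates miRNA and isomiR turnover from small-RNA time courses
collected after transcriptional shutoff. This vignette is the package's
own account of the science: the decay model and its assumptions, every
threshold that matters, what the synthetic-data generator does and does
not emulate, the numerical choices inside the fitters, and the places
where the design was genuinely open.

## The measurement model

After transcription is blocked at `t = 0`, no new precursor is made, so
the abundance of a mature species only decays. Sequencing depth is
arbitrary per library, so raw counts are normalized to the **total
mature-mapped reads** of each sample. This "total constant" normalization
rests on an empirical observation that the summed miRNA signal is nearly
stable over at least 12–24 h of shutoff (most miRNAs are long-lived); the
package checks the analogous property on profiling matrices with
`total_mirna_abundance()` after spike-in normalization. The assumption
degrades gracefully: if the aggregate decays by a fraction ε, every
remaining fraction is inflated by the same per-sample factor ≈ 1/(1−ε),
which shifts fitted plateaus slightly upward but barely moves half-lives
(the end-to-end noiseless test quantifies this: a planted 1 h fast phase
is recovered as 1.019 h under default conditions).

The **remaining fraction** of an entity is

$$R(t) = \frac{\overline{f}(t)}{\overline{f}(0)},$$

the replicate-mean frequency at time `t` over the 0 h mean, so `R(0) = 1`
by construction. Frequencies are reads over total mature-mapped reads;
loop- and otherwise-assigned reads are excluded from the denominator.

## Quantification

Reads (adapter-free, ≥ 15 nt) are assigned to hairpins by **exact
substring matching** — the zero-mismatch regime under which positional
composition statements about the 3′ end are meaningful (a mismatch-tolerant
mapper would conflate templated last bases with non-templated additions).
A read is assigned to a mature arm when at least 75% of its bases fall
within the annotated mature interval extended by 2 nt on each side
(`mature_window`, `mature_overlap` in `threshold_config()`); reads fully
inside the region between the arms are `loop` (Dicer processing
byproducts), anything else `other`. The window/overlap rule is this
package's operationalization of "maps to the mature region" — the wider
literature delegates it to quantifier tools with their own internal
conventions; both knobs are exposed.

A read matching several hairpins is counted **once per distinct mature
sequence group** (identical mature sequences from paralogous precursors
form one group) and flagged `multimapped`; per-sample totals count every
read exactly once, which keeps the per-sample isoform frequencies summing
to 1. An optional second pass (`nta = TRUE`) matches leftover reads
exactly except for ≤ 2 terminal 3′ bases and records the suffix as a
non-templated addition. It is off by default: NTA isoforms are typically
too few for stable statistics, and the main analyses deliberately exclude
them.

**Detection.** Only entities whose mean 0 h frequency is at least
`5 × 10⁻⁶` of mature-mapped reads ("reliably quantifiable") enter the
statistics; everything else is retained in outputs but left unclassified.
At a typical depth of 2×10⁶ that threshold corresponds to ~10 reads per
untreated library — below it, replicate ratios are dominated by shot
noise.

**Star annotation** is empirical, not taken from an annotation database:
for each two-arm hairpin the arm with the larger mean 0 h frequency is
`non_star`, the other `star`; single-arm hairpins are `non_star`. An
exact tie (possible on synthetic or heavily rounded data) is broken
5p → non-star and flagged `ambiguous`.

## Turnover classes

Per entity, two-sided equal-variance t-tests compare per-replicate
frequencies: 0 h vs 4 h, 0 h vs 12 h, and 0 h vs the pooled 4 + 12 h
group. Pooling (6 vs 3 values at full design) rather than averaging per
timepoint is a deliberate reading of the "0 versus 4 and 12 h"
comparison; the pooled p-value is emitted separately (`p_0v412`) so the
choice is visible. The class rules:

* `fast_lt50`: `R(12) < 0.50` and any nominal `p < 0.05`;
* `fast_lt25`: additionally `R(12) < 0.25` (a subset of `fast_lt50` by
  construction);
* `slow`: `R(12) ≥ 0.75` and **no** significant comparison;
* `intermediate`: everything else;
* `unclassified`: undetected, no computable baseline, or < 2 replicates
  in a compared group.

No multiple-testing correction is applied to the class rules — the
gate is deliberately a *nominal* p-value, because the 12 h
remaining-fraction cutoff is the primary filter and the test only guards
against noise-driven drops. A Benjamini–Hochberg column (`p_min_bh`) is
emitted for information. Tests run on frequencies, not log-frequencies:
the classification compares group means on the scale on which the
remaining-fraction cutoffs are defined. With zero variance in both groups
the t-statistic is undefined; the package returns `p = 1` for equal means
and `p = 0` otherwise, which is the correct limit for the rule's purpose.

## Decay models

**Single exponential.** `log2 R` is regressed on `t` through the origin;
`h = −1/slope`, with `slope ≥ 0` reported as `h = ∞`. Timepoints with
non-positive mean `R` are excluded (log undefined); with fewer than two
usable points the fit is undefined rather than extrapolated.

**Two-pool mixture.** Fast-turnover species often show *two-step*
kinetics: a fast phase (half-life ≈ 1 h) losing the bulk of the
population, then a plateau. The mechanistic reading is two co-existing
pools — an AGO-associated but not fully loaded pool that is degraded
quickly, and a fully loaded, protected pool. The model is

$$R(t) = F_{fast}\,2^{-t/h_{fast}} + F_{slow}\,2^{-t/h_{slow}},
\qquad F_{fast}+F_{slow}=1,$$

fitted by minimizing the replicate-count-weighted sum of squares of the
mean ratios, with `h_fast ∈ [0.05, 50]` h and `h_slow ∈ [h_fast, ∞]`.
Fitting mean ratios with replicate-count weights (rather than a full
per-replicate error model) mirrors how such curves are summarized
(mean ± SD per timepoint) and keeps the objective well-defined when a
replicate drops out.

Numerics: for fixed half-lives the optimal `F_fast` is a clipped linear
least-squares solution, so the search is a coarse log-grid over
`(h_fast, h_slow)` (30 × 13 nodes, `h_slow = ∞` included as an explicit
plateau candidate) followed by bounded L-BFGS-B refinement of the three
best nodes, in both the plateau and finite-`h_slow` parameterizations.
The single-exponential solution is always injected as a candidate
(`F_fast ∈ {0, 1}`), which guarantees the nesting property
`SSE_two ≤ SSE_single` that the model-comparison below relies on. If a
refined solution comes out with `h_slow < h_fast` the pools are swapped,
so `h_fast` is always the faster pool. Degenerate flat data (`R ≡ 1`)
yields `F_fast = 0` with infinite half-lives, not an error. SSE values
are floored at 1e−12 before logs so that perfect fits do not produce
−∞ AIC.

**Model choice and kinetic shapes.** The fits are compared by AIC
(`n log(SSE/n) + 2k`, `k = 1` vs `3`). Shapes, in rule order:

1. `ultrafast` — `R(1) ≤ 0.10`: effectively gone within the first hour,
   the signature of loop fragments and of mis-annotated non-miRNA small
   RNAs. Requires a 1 h timepoint; otherwise unreachable.
2. `two_step` — two-phase fit preferred by ≥ 2 AIC units, fitted
   `h_fast ≤ 2` h, **and both** `F_slow ≥ 0.10` and `F_fast ≥ 0.10`. The
   symmetric lower bound on `F_fast` is deliberate: without it, entities
   that are actually flat can be labelled two-step whenever replicate
   noise rewards the two extra parameters, which contradicts the intent
   that a two-step call describes a genuine biphasic loss. The 0.10
   cutoff on `R(1)`, the 2-AIC margin, the 2 h bound and the 0.10 pool
   floors are all configurable in `threshold_config()`.
3. `continuous` — fast-class entities adequately described by a single
   exponential (no AIC preference for two phases) or with `h ≥ 4` h:
   canonical first-order decay.
4. `stable` — slow-class entities.
5. `unclassified` — everything else.

## Sequence features

Feature analysis runs at the **isoform** level, because isoforms of one
miRNA can have sharply different turnover, and pooling them would blur
exactly the positional signals of interest. The fast set is
`fast_lt25 ∪ fast_lt50`, the slow set is `slow`; intermediate and
unclassified isoforms are excluded.

For a position (1-based from the 5′ end, or `last` = final base) and a
nucleotide, the 2×2 table (nucleotide yes/no × fast/slow) is tested two
ways:

* **Fisher's exact test**, two-sided, computed by exact hypergeometric
  enumeration: the p-value is the sum of the probabilities of all tables
  (margins fixed) whose probability does not exceed the observed one,
  with a 1e−7 relative tolerance for floating-point ties. Zero-margin
  tables return 1.
* **Permutation test**: `M` draws (default 10,000) of `|fast|` isoforms
  without replacement from the pooled fast+slow set; `p` is the fraction
  of draws with a nucleotide count as or more extreme than observed,
  *one-sided in the observed direction* (the direction — enriched or
  depleted — is part of the result). No pseudocount is added, matching
  the exceedance-count definition exactly; a zero count therefore reports
  `p = 0`, and the 1/M resolution floor is emitted alongside
  (`p_perm_floor`). Sequences shorter than a position drop out of that
  position's tally (and of its permutation pool), so per-position set
  sizes can differ.

The **A-rich central window** statistic summarizes positions 13–16: per
set, the fraction of isoforms (of length ≥ 16) with at least `min_a = 3`
A's in the window, tested like any other feature, plus per-position A
frequencies for the same window. "A-rich" has no canonical numeric
definition; both the thresholded indicator (with `min_a` configurable)
and the per-position view are emitted so neither choice hides the other.
`length_distribution()` reports per-set length histograms and modes — on
canonical data both sets peak at 22 nt.

## Profiling matrices

Bead-array (or similar) intensity matrices carry no internal read total,
so two normalizations are provided:

* `spikein_normalize()`: each sample is scaled by
  `reference / geometric mean of its spike-in intensities`, the reference
  being the geometric mean of those summaries across samples. Spike-ins
  are added at a fixed amount per unit of total RNA, so the result is
  abundance per total RNA. The per-sample summary is a geometric mean of
  the three probes because spike-in error is multiplicative and a single
  outlying probe should not dominate — the exact formula of the original
  bead-array protocol is not public, so this robust summary stands in
  for it.
* `total_constant_normalize()`: each sample is scaled so its summed
  mature-probe intensity equals the across-sample mean of those sums.

Both reference levels are data-derived, so rescaling one input sample
changes every output by one common global factor and nothing else
("scale-equivariant up to a global factor"); any fixed target constant
would give the same matrix up to that factor. Within-sample probe ratios
are preserved exactly, and both operations are idempotent.

## The synthetic-data generator

`sim_config()` defaults *are* the study conditions the pipeline targets,
and they are not tuned per analysis:

| parameter | default | what it encodes |
|---|---|---|
| `timepoints_h` | 0, 1, 4, 12 | shutoff time course, hours |
| `n_replicates` | 3 | biological triplicate |
| `depth` | 2×10⁶ | mature-mapped reads per sample |
| `frac_fast` | 0.08 | ~8% of species fast, the observed minority |
| `frac_fast_star_bias` | 0.8 | fast species are mostly star strands |
| `h_fast` | 1 h | fast-pool half-life |
| `stable_fraction_range` | [0.05, 0.4] | plateau `F_slow` of two-step species |
| `h_slow` | ∞ | plateau (finite values supported) |
| `nb_dispersion` | 0.05 | replicate noise; see below |
| `dominant_isoform_frac` | 0.9 | one dominant isoform per species |
| `loop_halflife_h` | 0.3 | ultrafast Dicer-byproduct loop reads |
| `abundance_sdlog` | 1.0 | log-normal abundance across species |

Counts are drawn negative-binomially (`var = μ + d·μ²`) around
depth-scaled expected abundances; `d = 0.05` puts the replicate
coefficient of variation for well-expressed species in the 0.2–0.4 band
reported for real triplicates. `nb_dispersion = 0` is a deterministic
mode emitting the exact expected values — real-valued, not integer — so
that oracle tests can compare pipeline output against the generating
decay law at 1e−6 rather than at sampling noise. The abundance law
across species is log-normal (`sdlog = 1`), a standard choice for
expression data; nothing downstream depends on it beyond giving a
realistic dynamic range. Star strands are at least 4-fold less abundant
than their partner strand (ratio `4·exp(Exp(1.2))`, median ≈ 9:1), which
is what makes empirical star annotation recoverable. Minor isoforms are
5′/3′ trims of 1–3 nt with geometrically decaying weights (no generative
law for isomiR spectra is established; this one reproduces the
one-dominant-isoform regime). Planted composition biases for fast
species — elevated G/C and depleted U at the first base, elevated C and
depleted G at the last base, A-depleted positions 13–16 — are the
signals the feature stage is tested against.

What the generator does **not** emulate: sequencing errors, adapters and
quality scores (inputs are modelled post-trimming; FASTA suffices),
genomic multimapping outside the hairpin set, cross-hairpin isoform
collisions beyond identical matures, residual transcription under
imperfect shutoff, and cell-division dilution. Passing tests on
synthetic data therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to upstream artifacts
of real libraries.

## Problem sizes used in the checks

The packaged checks run at deliberately chosen scales: the two-phase
recovery benchmark embeds exactly 200 two-step species in a
1250-hairpin, mostly stable reference (200 species alone would decay in
aggregate and violate the total-constant normalization the method itself
uses — embedding reproduces the fast-minority regime); classifier
fidelity runs on the 200-hairpin default design; oracle comparisons for
the quantifier use a few thousand reads, where an exhaustive
position-scan is still exact and fast. Fisher enumeration is verified
against an independent log-choose oracle over every 2×2 table with total
≤ 40, and the Monte-Carlo permutation p against full subset enumeration
on pools of ≤ 12.

## Known limitations

* Half-lives far beyond the last timepoint (here 12 h) are extrapolation;
  `h = ∞` and very large finite values are reported but should be read as
  "no measurable decay", which is why endpoint ratios (`R12`) are emitted
  alongside fitted half-lives.
* The t-test gate with `n = 3` replicates has limited power for shallow
  drops; entities with `0.5 ≤ R(12) < 0.75` and noisy replicates land in
  `intermediate` by design rather than being forced into either class.
* The two-pool fit cannot distinguish a finite-but-long `h_slow` from ∞
  inside a 12 h window; `h_slow` should be interpreted qualitatively.
* Exact-substring assignment does not tolerate SNPs/editing within the
  read body; such reads fall out of pass 1 and (unless they fit the 3′
  NTA pattern) are tallied as unassigned.
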