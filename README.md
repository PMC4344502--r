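# mirturn

Genome-wide miRNA turnover analysis from transcriptional shutoff time
courses.

## The problem

Steady-state miRNA levels balance biogenesis against decay. When
transcription is blocked (actinomycin D or DRB), each mature miRNA — and
each of its sequence isoforms (isomiRs) — decays at its own rate, so a
small-RNA sequencing time course after shutoff measures turnover directly.
`mirturn` is for analysts who have such a time course (or a bead-array
profiling matrix with spike-ins) and want, per miRNA and per isoform:

* **remaining fractions** `R(t)` relative to the untreated 0 h level,
* **turnover classes** (fast `< 50%` / `< 25%` remaining at 12 h with a
  nominal t-test `p < 0.05`; slow `>= 75%` remaining with no significant
  change),
* **decay-model fits** — a single exponential and a two-pool mixture

  `R(t) = F_fast · 2^(−t/h_fast) + F_slow · 2^(−t/h_slow)`,

  which captures the characteristic two-step kinetics of star strands: a
  fast phase with ~1 h half-life (the AGO-associated but not fully loaded
  pool) followed by a stable plateau (the loaded pool),
* **kinetic shapes** (ultrafast / continuous / two-step / stable),
* **positional sequence features** distinguishing fast from slow isoforms
  (first base, last base, A-rich window at positions 13–16, lengths),
  tested with Fisher's exact test (exact hypergeometric enumeration) and a
  permutation null that redraws the fast set from the pooled isoforms.

Everything runs end to end on synthetic data from a truth-labelled
generator, so the whole pipeline is testable without downloads: hairpin
references with planted composition bias, negative-binomial replicate
noise around two-pool decay expectations, ultrafast loop reads, constant
spike-ins, and star-strand abundance skew.

## Worked example

Simulate the default study design (0/1/4/12 h, triplicate, ~8% fast
species biased to star strands) and run every stage:

```r
library(mirturn)
cfg <- sim_config(n_hairpins = 100, depth = 5e5, seed = 42)
res <- run_pipeline(pipeline_config(sim = cfg, perm_iterations = 1000),
                    "out/")
res$summary
```

which prints (this exact run):

```
detectable mature: 200  isoforms: 397
   fast_lt25    fast_lt50 intermediate         slow
          11            6           32          151
  continuous       stable     two_step unclassified
           3          145           19           33
fast sensitivity: 1  specificity: 0.995
```

All 200 simulated mature species pass the detection threshold (mean 0-h
frequency ≥ 5×10⁻⁶ of mature-mapped reads); 17 are called fast (11 of them
below 25% remaining), and the calls recover the planted truth with
sensitivity 1.00 and specificity 0.995. Most fast species are fitted as
two-step. The feature stage compares the 30 fast against the 306 slow
isoforms; at the first base it reports

```
  nucleotide freq_fast freq_slow fisher_p perm_p direction
           A     0.267     0.288   1.0000  0.489  depleted
           C     0.167     0.232   0.4993  0.298  depleted
           G     0.367     0.170   0.0136  0.013  enriched
           T     0.200     0.310   0.2963  0.138  depleted
```

i.e. the planted first-base G enrichment (and U depletion) of fast
isoforms is recovered with both tests agreeing. `out/` contains the TSVs
for every stage (frequencies, strand roles, turnover calls, feature
statistics) plus `summary.json` and a run log.

Individual stages are plain functions — `generate_reference()`,
`simulate_timecourse()`, `quantify_reads()`, `compute_frequencies()`,
`annotate_star()`, `turnover_calls()`, `fit_two_phase()`,
`position_enrichment_test()`, `spikein_normalize()`, … — see the methods
vignette (`vignettes/mirturn-methods.Rmd`) for the model and every
threshold.

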