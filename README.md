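# foldcensus

Generative protein language models (PLMs) can emit sequences that look like
proteins, but a batch of generated sequences is only useful if you can say
*how much of natural structure-space it covers*, *how novel its sequences
are*, and *how those answers move with the sampling hyperparameters*.
`foldcensus` is an R package for exactly that audit. It provides:

- **Decoding engines** — autoregressive (left-to-right next-token) and
  left-to-right Gibbs decoding for masked models, plus an
  abundance-weighted random background sampler — over a pluggable
  token-probability model interface, with the standard transform chain
  (repetition penalty → temperature → top-k → nucleus/top-p →
  renormalize).
- **Sequence filters** — truncation, rare/ambiguous-letter validity
  (B, J, O, U, X, Z), single-residue composition caps, exact
  deduplication — with per-stage accounting.
- **Consensus fold annotation** from structure-search hit tables
  (Foldseek-style TSV): a query is assigned the SCOP fold accounting for
  the most hits with TM-score > 0.5 and max(query coverage, target
  coverage) > 0.8, with a deterministic tie rule.
- **Sequence-escape statistics** from homology hit tables (BLAST-m8 /
  MMseqs2): a sequence "escapes" when it returns no hit at E ≤ 0.01.
- **Biophysical metrics** — Shrake–Rupley solvent accessible surface
  area, per-residue burial fraction, DSSP coil fraction.
- **Scan summaries** reproducing the per-cell report shape of a
  (temperature × top-k) hyperparameter grid.
- **Synthetic-data generators with planted ground truth** — toy Markov
  token models with exactly enumerable output distributions, hit tables
  with planted assignable/escape fractions and fold compositions, and toy
  coordinate sets — so every stage is testable without GPU inference or
  external databases.

## The statistics at the core

For a batch of generated sequences, after filtering:

- **structural hit rate** = assigned / valid, where a sequence is
  *assigned* if any fold receives a plurality of its threshold-passing
  structure hits (TM > 0.5, max(q-cov, t-cov) > 0.8, strict);
- **fold coverage** = distinct assigned folds / 1579 reference SCOP fold
  labels;
- **escape rate** = |{queries with no homology hit at E ≤ 0.01}| /
  |queries| (reported among assigned sequences by default);
- **burial fraction** = 1 − SASA(structure) / Σᵢ ref_area(aaᵢ), the
  fractional burial of amino-acid surface area relative to the maximally
  exposed reference state;
- **fold enrichment** = log₂((g_f+1)/(G+K)) − log₂((n_f+1)/(N+K)) for
  generated vs natural per-fold counts over a K-fold universe.

## Worked example

Generate a planted synthetic batch, run the full annotation/escape
pipeline, and summarize it:

```r
library(foldcensus)

spec <- planted_batch_spec(n_sequences = 5000, invalid_fraction = 0.001,
                           assigned_fraction = 0.327, n_distinct_folds = 50,
                           escape_fraction_among_assigned = 0.58, seed = 42)
syn <- make_synthetic_hit_tables(spec)

flt <- apply_filter_pipeline(syn$records, filter_config(), dedup = FALSE)
ann <- annotate_folds(syn$structure_hits, syn$fold_map,
                      query_ids = flt$records$id)
esc <- escape_rate(ann$query_id[!is.na(ann$fold)], syn$homology_hits)

summarize_run(flt$report, ann, esc,
              params = list(top_k = 950, temperature = 1.0))
#>  top_k temperature valid_fraction n_folds structural_hit_rate
#>    950       1.000          0.999      50               0.327
#>  sequence_escape_rate
#>                 0.580
```

The row reads: 99.9% of the 5,000 sequences pass the validity filter; the
valid ones hit 50 distinct folds; 32.7% are structurally assignable; and
58.0% of the assignable ones have no homology hit at E ≤ 0.01 — the
planted truth, recovered exactly by the pipeline.

Decoding engines attach to any conditional-distribution provider:

```r
model <- make_toy_markov_model(3, "two_mode")
params <- sampling_params(temperature = 1, top_k = 3,
                          repetition_penalty = 1.2, max_tokens = 4)
recs <- generate_autoregressive(model, params, n = 100000, seed = 5)
truth <- enumerate_sequence_distribution(model, params, max_len = 4)
```

`enumerate_sequence_distribution()` is the exact enumeration oracle; the
total-variation distance between `truth` and the empirical distribution of
`recs$sequence` is ≈ 0.006 at 100,000 draws.

A thin command-line wrapper over the same functions is installed as
`inst/scripts/foldcensus` (subcommands `generate`, `filter`, `assign`,
`escape`, `biophys`, `report`, `simulate`).

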