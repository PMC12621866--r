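---
title: "Methods: auditing generative protein language model output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing generative protein language model output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldcensus)
```

`foldcensus` characterizes what a generative protein language model (PLM)
actually produces: how many of its sequences are valid proteins, how many
fold into recognizable structural families, how many are genuinely novel
with respect to known sequence-space, and how all of this shifts with the
sampling hyperparameters. This vignette explains the models and procedures
the package implements, the parameters that matter, the numerical choices
behind them, and what the synthetic test substrate does and does not
establish about real data.

## Decoding model

All generation flows through one seam, the *token model*: a deterministic
provider of conditional distributions over a vocabulary of amino-acid
tokens plus a distinguished STOP symbol. Real PLMs attach through this
contract via user-written adapters; the package itself never runs neural
inference. Two decoding engines consume the contract:

* **Autoregressive** (`generate_autoregressive()`): sequences grow token
  by token, left to right. The vocabulary may contain multi-residue
  "subword" tokens, as subword-tokenized PLMs use. Generation stops at
  STOP or after `max_tokens` steps; the concatenated residue string is
  then truncated to `max_residues`. A multi-residue token is never split
  mid-step — truncation acts on the finished residue string.
* **Left-to-right Gibbs** (`generate_gibbs_lr()`): for masked
  (bidirectional) models. A fixed-length template of `max_residues`
  masked positions is filled one position at a time, left to right, each
  draw conditioned on the filled prefix with the remainder masked. We use
  a *single pass* with no revisiting: the incremental left-to-right
  description of the procedure implies one sweep, and a single sweep
  keeps the exact output distribution enumerable for testing. STOP is
  sampleable at any position and cuts the sequence before it. This engine
  requires single-residue tokens (one template position holds one
  residue), which matches amino-acid-alphabet masked models.
* **Background control** (`generate_background()`): position-independent
  draws from natural amino-acid abundances at fixed length. This control
  preserves first-order composition statistics and nothing else; by
  construction it needs no filtering or truncation.

At every sampling step the model's distribution passes through the
standard transform chain, in this order: **repetition penalty** (on
log-probabilities) → **temperature** → **top-k** → **top-p** →
renormalize. The order is not dictated by the statistics themselves — it
is the convention of the mainstream generation stacks, and we match it so
that adapters for real models reproduce what those stacks would sample.
The repetition penalty is the CTRL-style sign-dependent rule (positive
logits divided by the penalty, negative multiplied); applied to
log-probabilities (all ≤ 0) it acts as `p ↦ p^penalty` before
renormalization. At the neutral settings (T = 1, k = |V|, p = 1,
penalty = 1) the chain is the exact identity, which the tests assert to
1e-9.

No priming token is prepended before autoregressive decoding: the model's
conditional at the empty context is its start distribution. An adapter
for a model that expects a begin-of-sequence symbol should fold that
symbol into its own context handling.

Default decoding parameters are the conventional autoregressive settings
for subword PLMs — T = 1, top-k = 950, top-p = 1.0, repetition penalty
1.2, 40-token cap, 100-residue truncation — and, for Gibbs decoding,
T = 1, full token distribution, no penalty, 100 positions
(`gibbs_params()`). The hyperparameter grid explored by `run_scan()` is
T ∈ {0.8, 1.0, 1.2, 1.5, 2.0, 5.0} × top-k ∈ {600, 950, 1500, 2400,
4000} when driven at scale; the packaged tests exercise reduced grids.

**Reproducibility.** Each sequence draws from its own RNG substream,
seeded as `(seed + i · 48271) mod (2³¹ − 1)`. The modulus is prime, so
substreams never collide for any batch size, and sequence *i* is
identical whether the batch is generated whole, split, or in parallel.

**The enumeration oracle.** `enumerate_sequence_distribution()` computes
the exact probability of every output sequence by exhaustive path
enumeration under the same transform chain, with a 10⁶-path budget. It is
the independent reference for the samplers: on a 3-token toy Markov
model, 100,000 seeded autoregressive draws sit within total-variation
0.02 of the enumerated distribution (observed ≈ 0.006).

## Filters

The filter pipeline runs truncate → validity → (optional composition) →
(optional dedup), with per-stage in/out/removed accounting and
`valid_fraction` = valid / batch input. Truncation precedes validity, so
a forbidden letter beyond the truncation point does not invalidate a
sequence — filtering is described downstream of generation, and the
truncated string is what downstream analysis sees. Validity rejects empty
sequences and the rare/ambiguous codes B, J, O, U, X, Z. The composition
rule (any single amino acid strictly exceeding 20% of residues) and the
minimum-length and resolution rules are validation-set filters, off by
default for generated batches; the 20% comparison is strict because the
rule is stated as "> 20%". Deduplication is exact string match, first
occurrence kept. The pipeline is idempotent, and stage counts are
conserved (in = out + removed) at every stage.

## Consensus fold assignment

Structure-search hits arrive as Foldseek-style TSV rows (query, target,
TM-score, query coverage, target coverage; configurable column map). A
hit *passes* when TM-score > 0.5 and max(query coverage, target coverage)
> 0.8 — both inequalities strict, following the "greater than" statement
of the rule. Passing hits vote, one vote per hit row, for the SCOP fold
of their target under the fold map; the plurality fold wins.

Plurality ties are not specified by the rule, so the package makes them
deterministic: the tied fold containing the single highest TM-score hit
wins; if still tied, the lexicographically smallest fold id; either way
the annotation is flagged `tie_broken`. Queries with no passing hits (or
no hit rows at all) are annotated `NA`, not treated as errors. Votes are
counted per hit row rather than per unique target domain — the simplest
reading; on the synthetic tables the two coincide because planted targets
are unique per hit.

The derived statistics are the **structural hit rate** (assigned /
total), the **fold inventory** (distinct assigned folds, with coverage
against the 1579-label SCOP fold universe), the **topology distribution**
over SCOP classes (fold-id prefix: a = all-α, b = all-β, c = α/β,
d = α+β), and the add-one-smoothed **per-fold log₂ enrichment** between
two batches, which is exactly antisymmetric under swapping the batches.

A separate rule, `reciprocal_filter()`, serves sequence–structure
database construction: pairs must pass in *both* search directions with
TM > 0.5 and *both* coverages > 0.8. The consensus rule and the
reciprocal rule are deliberately distinct configurations
(`coverage_rule = "max_of_two"` vs `"both"`) because they are stated
differently.

## Sequence escape

Homology hits arrive in the 12-column BLAST-m8 dialect. A query *escapes*
when it has no hit with E ≤ 0.01. The cutoff is interpreted inclusively —
"maximum E-value 0.01" reads most naturally as E ≤ 0.01 — but the
boundary behaviour is a flag (`inclusive`) and is echoed in the result,
since search tools differ. Because tabular search output omits queries
with no hits, the query universe must be supplied independently of the
hit file; queries absent from the file are escapes. Escape is reported
overall, per assigned fold, and (in scan summaries) among structurally
assigned sequences by default — that denominator matches the convention
of per-cell grid reports, and is switchable via `escape_denominator`.

## Biophysical metrics

**SASA.** `shrake_rupley_sasa()` implements the classic test-point
algorithm: each atom's sphere of radius `vdW + probe` carries a
deterministic golden-spiral lattice of `n_sphere_points` points
(default 960; probe 1.4 Å), and a point is accessible when outside every
neighbour's expanded sphere. Two numerical choices matter:

* The lattice is oriented in the molecule's *principal-axis frame* with
  deterministic sign conventions, so the discretized area is exactly
  invariant under rigid motions of the structure (tested to 1e-6
  relative), not merely invariant up to lattice discretization error
  (~0.2% at 960 points) as with a lab-frame lattice. For pathological
  perfectly symmetric coordinate clouds the frame is ambiguous and
  invariance degrades to discretization error; real and fixture
  structures are nowhere near this regime.
* Convergence: doubling the point count changes a 50-atom cluster's
  total by well under 1%.

Van der Waals radii are a single element-wise (Bondi) set, substitutable
per atom table; hydrogens are dropped on input.

**Burial fraction** = 1 − SASA(structure) / Σᵢ ref(aaᵢ), where ref is the
per-residue maximally-exposed reference area. We ship theoretical maximum
ASA values (Tien et al. 2013) as the default reference — the
isolated-residue interpretation of "relative to the linear polypeptide
chain", matching the cited style of per-residue reference tables — and
the table is a plain argument, so any alternative set drops in. Values
above the reference (slightly negative burial) are reported with a
warning, never clamped, because clamping would hide unit errors.

**Coil fraction** is the complement of the DSSP helix/strand codes
{H, G, I, E, B} over a per-residue code string; turns, bends,
poly-proline, C and unassigned positions all count as coil. DSSP dialects
disagree on "coil", so the structured code set is an argument with that
default. Secondary structure itself is always consumed, never assigned —
DSSP is external.

## Synthetic substrate and what it shows

The generators in `make_synthetic_hit_tables()` plant ground truth with
*exact* realized counts: assigned queries, fold memberships
(largest-remainder apportionment over the planted folds), and escape sets
are fixed by deterministic rounding, never sampled. Counts-based
statistics — hit rate, fold inventory, escape rate — are therefore
recovered exactly by the pipeline, and the packaged checks exercise them
at the full scale of a reference run (a 100,000-sequence batch with
99,982 valid, 32,694 assignable across 668 folds, 18,962 escaping; a
148,500-sequence masked-model batch reduced to 144,043 by
deduplication and filtering; a 74,250-sequence background control;
110,700 = 36,900 × 3 inverse-folding designs). Only the
sampler-distribution comparisons are stochastic, and they are seeded.

What passing these tests shows: the arithmetic, thresholds, vote and tie
rules, and bookkeeping are implemented exactly, at realistic scale. What
it does not show: anything about real PLM output distributions, real
TM-score or E-value statistics, or structure prediction quality — the
synthetic hit tables only exercise the thresholds, with passing scores
drawn comfortably inside the pass region and decoys comfortably outside.
Toy coordinate fixtures (isolated residues, ideal helices at 2.3 Å
radius / 1.5 Å rise / 100° per residue, 120 Å-spaced extended chains,
packed clusters) validate the SASA code against closed forms and
inequalities, not against experimental structures.

Problem sizes in the packaged tests are chosen to keep the default suite
fast while leaving no rule unexercised: toy vocabularies of 2–8 tokens
with 10⁵ draws for distribution checks, 1,000 random tables for the
consensus-vote oracle comparison, 20 random planted specs for recovery,
planted batches of 10²–10⁵ sequences, and ≤ 50-atom SASA fixtures.

## Known limitations

* No neural inference, alignment, TM-score, E-value or DSSP computation:
  all scores are consumed from tool output, by design.
* The Gibbs engine is a single left-to-right sweep; iterated or
  arbitrary-order Gibbs schedules are out of scope.
* The masked conditional of the toy Markov models depends only on the
  filled left neighbour; it exercises the masked *contract*, not
  bidirectional dependence.
* `fold_enrichment()` uses add-one smoothing; for very small universes
  the pseudocount visibly shrinks extreme ratios (the 8× worked example
  yields ≈ 2.99 rather than 3).
* PDB input follows the crystallographic conventions (first model,
  altloc blank/'A', heavy atoms); mmCIF is unsupported.
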