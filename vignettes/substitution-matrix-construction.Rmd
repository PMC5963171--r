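---
title: "Building and benchmarking BLOSUM-family substitution matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking BLOSUM-family substitution matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blosumkit)
```

## The model

BLOSUM-family substitution matrices are log-odds scores estimated from
ungapped alignment blocks. Given blocks of fixed width $w$, every unordered
pair of rows contributes one aligned residue pair per column. To stop
families of near-duplicate sequences from dominating the counts, rows whose
percent identity meets a clustering threshold $L$ are merged and each row
is down-weighted by $1/(\text{its cluster's size})$; only *between*-cluster
pairs are counted, each with weight $w_u w_v$.

With $f_{ij}$ the accumulated weighted count for unordered pair $(i,j)$ and
$T = \sum_{i \le j} f_{ij}$:

$$
q_{ij} = \frac{f_{ij}}{T}, \qquad
p_i = q_{ii} + \sum_{j \ne i} \frac{q_{ij}}{2}, \qquad
e_{ij} = \begin{cases} p_i^2 & i = j \\ 2 p_i p_j & i \ne j \end{cases}
$$

$$
s_{ij} = \log_2 \frac{q_{ij}}{e_{ij}}, \qquad
H = \sum_{i \le j} q_{ij}\, s_{ij} \;\; (\text{bits}).
$$

$H$ is the relative entropy of the target frequencies against chance: the
average information per aligned pair. Scores are published rounded to
$1/n$-bit units, `score = round(n * s)`, with ties rounded half away from
zero. Matrices from different pipelines are comparable only at matched
$H$ — hence "analog" selection: sweep $L$ and pick the member whose entropy
is closest to the reference's.

## The three clustering variants

The central subtlety is *how* the percentage threshold is compared against
an integer identity count $k$ out of $w$ columns:

* `legacy_blosum` and `rblosum` use the integer rule of the original code:
  a pair meets the threshold iff $k \ge \lfloor Lw/100 \rfloor$. Truncation
  means pairs slightly *below* $L\%$ can still be merged — at $w=7$,
  $L=62$, a pair with $k=4$ (57.1%) clusters because
  $\lfloor 4.34 \rfloor = 4$.
* `corblosum` compares the exact fraction, $100k \ge Lw$, evaluated in
  integer arithmetic so no new floating-point rounding is introduced.

The two rules differ exactly on cells with
$\lfloor Lw/100 \rfloor \le k < Lw/100$, and coincide whenever $Lw$ is
divisible by 100. All variants merge by single-linkage transitive closure
(two rows share a cluster iff connected by a chain of above-threshold
pairs). The merge-pass details of the originally distributed legacy binary
are not recoverable from its published description, so `legacy_blosum`
here is the integer rule plus transitive closure — identical to `rblosum`
by construction — and is kept as a separate enum value purely as a seam
where a faithful port of the legacy pass could be slotted in. The threshold
comparison is non-strict (`>=`); that choice is documented on
`threshold_met()`.

Identity uses the full block width $w$ as denominator (blocks are ungapped
and fixed-width); positions carrying ambiguity letters (B/Z/X) never count
as identities, and such residues are excluded from pair counting — the
published tables are over exactly 20 residues.

## Numerical choices

* **Zero cells.** A pair of observed residues with a zero count gets
  $q_{ij}=0$, $s_{ij}=-\infty$, and contributes nothing to $H$ (the
  $0 \log 0 := 0$ convention). Integer scores cannot be produced from such
  a model: `finalize_model()` raises an error naming the pair. Zeros are
  pathological at realistic block volumes; for deliberate small-data work
  an explicit `pseudocount = TRUE` adds 1 to every pair cell and is
  recorded in the model's provenance. Nothing is ever smoothed silently.
* **Bit units.** `auto_scale()` maps entropy to the denominator $n$ by a
  piecewise rule ($n=2$ for $H \ge 0.6$; 3 for $[0.3, 0.6)$; 4 for
  $[0.2, 0.3)$; 5 for $[0.145, 0.2)$; 6 below), calibrated so that every
  published entropy/bit-unit pairing across BLOCKS releases is reproduced.
  The published pairs only pin the 5/6 boundary inside $(0.1198, 0.1477)$;
  0.145 is a documented choice and an explicit `scale` override exists.
* **Rounding.** Half-away-from-zero, not banker's rounding, matching the
  classic matrix programs; the rounding error per cell is bounded by 0.5.
* **Analog ties** break toward the lower threshold (fixed, documented).
* **Entropy** is always computed from unrounded log-odds; rounding loses
  information.

## Alignment and evaluation

`smith_waterman()` (an Rcpp kernel) computes local alignment with affine
gaps where a gap of length $\ell$ costs $G_o + \ell G_e$
(*open-plus-extend*; tools quoting "12/1" in an open-includes-first-step
convention correspond to `gap_open = 11, gap_extend = 1` here — gap
conventions are the single most common source of cross-tool score
discrepancies, hence the prominence).

Benchmarks follow the SCOP convention: two domains are homologs iff they
share a superfamily; different folds are non-homologs; same fold but
different superfamily is ambiguous and excluded from both sides of the
ledger. A ranked hit list is summarised by its coverage-versus-errors-
per-query (CVE) staircase: sweeping a threshold down the list, coverage is
the (query-weighted) fraction of true homolog pairs recovered and EPQ is
the weighted count of false positives divided by the number of queries.
The operating point is coverage at 0.01 EPQ. Errors count false-positive
*hits* (weighted by their query), the EPQ denominator is the query count,
and ranking ties break stably by query then target id so curves are
reproducible — each of these is a convention the literature leaves open.

Score normalization: `normalize_hits()` offers `raw`, `linear`
(`rank_stat = raw - a·ln(mn)`) and `quadratic`
(`... - b·(ln mn)^2`) modes, with coefficients fitted by least squares
over presumed-unrelated pairs (hits labelled non-homolog when labels are
present). These regression forms are stand-ins chosen for transparency:
the published pairwise-comparison evaluation tooling does not state its
normalization formulas, and no extreme-value E-value machinery is
implemented because the comparisons here are rank-based.

The Bayesian bootstrap compares two matrices on the same queries: each
replicate draws one standard-exponential weight per query, normalized to
mean one (a flat-Dirichlet draw scaled by the query count), *shared*
between the two hit lists (paired design), and records the difference in
weighted coverage at 0.01 EPQ. Identical seeds give bit-identical
replicates.

## What the generators emulate — and what they do not

`generate_blocks()` plants groups of related rows in each block: members
are copies of a group root, resampled per site with probability
$1-\text{identity}$ to a uniformly chosen *different* residue, so
row-to-root identity is exactly Bernoulli(identity) and testable with
binomial standard errors. With exactly two planted groups and a matrix
`pair_model`, column pairs are drawn jointly from a target $q^*$, which
closes the estimation loop: all-singleton counting recovers
$\hat q \to q^*$ and $\hat H \to H(q^*)$.

`generate_benchmark()` plants a fold/superfamily/member hierarchy with one
uniform-random ancestor per superfamily and per-site substitution at a
fixed rate. Ancestors are independent even within a fold, so the same-fold
"ambiguous" label carries no planted signal — exactly the pairs the CVE
machinery excludes.

Neither generator models position-specific conservation, realistic residue
composition, tree-structured evolution, or indels (blocks are ungapped by
construction). Passing tests therefore demonstrate correctness of the
counting, clustering, scoring and evaluation machinery under a known
substitution process — not that any particular matrix is superior on real
proteins.

## Canonical synthetic study conditions

The small-scale study used by `synthetic_study_inputs()` and the
acceptance script fixes: 200 blocks of depth 8 and width 60 with two
planted groups of 4 at 70% row-to-root identity, and a 60-sequence
benchmark (6 folds × 2 superfamilies × 5 members, lengths 60–100,
mutation rate 0.3). The group identity is chosen so that within-group
*pairwise* identity sits near 50% — below the 45–70 clustering range —
so related pairs are actually counted and the entropy sweep spans a
realistic range (roughly 0.07–0.30 bits across thresholds); the benchmark
mutation rate puts pairwise member identity in the same regime, matching
the substitution process the blocks encode. At these sizes a full
three-variant study (reference build, two 26-threshold sweeps, fold
split, 12-cell gap tuning per matrix, test evaluation, and bootstrap)
runs in well under a minute; the same pipeline scales to full BLOCKS
releases, whose reproduction is exercised by an integration test that
requires the release flat files on disk.

```{r study, eval = FALSE}
inp <- synthetic_study_inputs(seed = 1)
cfg <- study_config(inp$blocks, inp$benchmark, seed = 1)
report <- run_study(cfg, verbose = TRUE)
report
```

## Known limitations

* `legacy_blosum` is not a byte-faithful port of the original merge loop;
  it is the integer threshold with transitive closure (see above).
* Linear/quadratic normalizations are regression stand-ins, not the
  published evaluation tool's formulas.
* The bit-unit rule's 5/6 boundary is only interval-constrained by the
  published pairings.
* No indel model in the generators; benchmark superfamily members share
  their ancestor's length.
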