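---
title: "Quantifying gene-gene dynamics influence with Boolean network models"
author: "gdinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-gene dynamics influence with Boolean network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdinet)
```

## The problem

Molecular interaction maps record which genes regulate which, but not how
far a perturbation travels.  A gene can change the long-run behaviour of
another gene it never touches directly — through signalling cascades,
feedback loops, and the multistability of the regulatory dynamics — and,
conversely, a physical interaction may have no dynamical consequence at
all.  `gdinet` quantifies this *dynamics influence* for every ordered
gene pair of a signed directed gene-gene molecular interaction (GMI)
network and assembles the positive influences into a gene-gene dynamics
influence (GDI) network that can be analysed structurally and compared
with knockout-expression experiments.

## The model

**Boolean dynamics.** Each gene $v_i$ carries a binary state; all states
update synchronously.  Genes with regulators update through a *nested
canalyzing function* (NCF): regulators are tested in a fixed cascade
order, the first regulator $v_{i_m}$ whose state equals its canalyzing
value $I_m$ sets the output to its canalyzed value $O_m$, and if no
regulator canalyzes the output falls back to a default fixed at
$1 - O_{k}$ (the complement of the last canalyzed value).  NCFs are a
standard model class for transcriptional logic; here they are drawn at
random, each $I_m$ and $O_m$ an independent fair coin flip
(`mode = "unconstrained"`).  Because the input networks carry activation
and inhibition signs, a `"sign_respecting"` mode is also provided in
which $O_m = I_m$ for activating and $O_m = 1 - I_m$ for inhibiting
regulators; the unconstrained mode is the default because it is the
plain randomization procedure the influence measure is defined over.
Genes with no regulators hold their state, which keeps initial-condition
diversity intact (a common Boolean-network convention; the model
equation itself requires at least one regulator).

**Attractors.**  Deterministic dynamics on a finite state space must
revisit a state, so every trajectory ends in a fixed point or a limit
cycle.  `findAttractor()` returns the transient length $\tau$, the
period $p$, and the ordered cycle states.

**Knockouts.**  A knockout freezes the target gene to 0 for the first
$T$ update steps (`knockout(gene, T)`), after which its native rule is
restored; `duration = Inf` gives a permanent knockout.  Two readings of
"the first $T$ steps" are possible at the boundary: we force the states
produced at steps $1..T$ and leave the user-supplied initial state
untouched, because the initial state belongs to the shared initial-state
set, not to the mutant dynamics.  For finite $T$, cycle detection begins
only after the rule is restored, so the reported cycle is an attractor
of the unmutated rule set; during the mutation window all states are
transient by construction.

**The influence measure.**  For an ordered pair $(v_i, v_j)$ and an
initial state $\mathbf{v}(0)$, the wild-type and $v_i$-knockout
trajectories are run to their attractors and the state sequence of
$v_j$ is read off both cycles.  With periods $p$ and $p'$, both
sequences are unrolled to the least common multiple $c$, and for each
cyclic offset $m \in [0, g-1]$ ($g = \gcd(p, p')$) the fraction of
mismatching positions is counted; the distance is the minimum over
offsets.  The influence $\mu(v_i, v_j)$ is the mean of this distance
over an initial-state set $S$ — exhaustive ($2^N$ states) for small
networks, a seeded uniform sample of distinct states otherwise.  The GDI
network has an edge $(v_i, v_j)$ iff $\mu(v_i, v_j) > 0$.

Restricting offsets to $[0, g-1]$ is the definition of the measure; when one node's subsequence has internal period larger than
$g$ this does not scan every cyclic alignment, so a diagnostic
`fullAlignment = TRUE` mode scans all $c$ offsets.  The default mode is
the definition.

## Exact arithmetic

Each distance is a ratio of whole numbers and the edge rule is a strict
inequality on their average, so `gdinet` keeps $\mu$ as an exact reduced
fraction throughout (`Rational` objects in R; 64-bit integers with
128-bit intermediates in the compiled loop).  A $\mu$ of $1/1024$ is an
edge; no floating-point epsilon is involved, and arithmetic that would
leave the exact range raises an error rather than rounding silently.
`influenceMatrix()` computes wild-type attractors once per initial state
and mutant attractors once per (initial state, source); this caching is
bit-for-bit equivalent to the per-pair `dynamicsInfluence()` route and
is tested against an independent brute-force oracle.

## Parameters that matter

* **`duration` (T, steps)** — how long the knockout lasts.  Default 20,
  the setting used for the large-network degree analyses; the
  structure-correlation analyses sweep 1–10 or 2–20.  Longer knockouts
  push the perturbation deeper into the state space before the rule is
  restored.
* **`states` (S)** — exhaustive for $N \le 14$ by default; otherwise
  2000 sampled states for $N \le 100$ and 4000 above, matched to
  typical small/medium/large regulatory-network scales.  Always
  overridable, always seeded.
* **`maxSteps`** — attractor-search cap (10^4 for $N \le 64$, 10^5
  above).  A revisit is guaranteed mathematically; the cap only bounds
  time and memory, and hitting it is an explicit error, never a silent
  truncation.
* **`maxLen` (edges)** — cap for simple-path and feedback-loop
  enumeration, which is exponential in general: default $N$ for
  networks of at most 15 nodes, 8 above.  Recorded in the feature-table
  output.
* **`nSwaps`** — degree-preserving shuffle length, default $10|A|$, the
  standard mixing heuristic for double-edge-swap randomization.

## Structural analyses

`pairwiseFeatureTable()` tabulates, per ordered pair with a finite
shortest path: $\mu$, the shortest-path length $l$, the number of simple
directed paths $n$ up to `maxLen` edges, and the number of simple
directed cycles through both genes $f$ (each cycle counted once,
regardless of rotation; "different paths" is read as node-simple paths,
consistent with the no-revisit definition of a feedback loop).
Unreachable pairs are excluded rather than given an arbitrary large
$l$.  `correlate()` computes Pearson (default) or Spearman coefficients
and refuses zero-variance input with a classed condition.
`groupDegreeComparison()` compares mean in/out-degrees between gene
groups (e.g. drug-target classes) with two-sided Wilcoxon rank-sum
tests — degree data are non-normal counts, so a rank test is the
robust default.

Two null models are provided: `baRandomNetwork()` grows a directed
preferential-attachment network (m isolated seeds, each new node
attaching m degree-proportional edges, orientation uniform at random,
giving exactly $m(N-m)$ edges), and `shuffleNetwork()` randomizes an
existing network by double-edge swaps that exactly preserve every
node's in- and out-degree, with signs travelling with their source.

## The validation pipeline and its synthetic data

The knockout-validation pipeline binarizes a gene × sample expression
matrix (bit 1 iff a value exceeds the gene's cross-sample mean, or a
per-gene two-cluster k-means split with the higher-centroid cluster
coded 1), derives the experimentally affected set $EXP_O(g)$ — genes
whose majority-consensus bit differs between knockout and wild-type
samples, ties excluded with a warning, the knocked-out gene itself not
reported — and computes the precision ratio
$|EXP_O(g) \cap GDI_O(g)| / |EXP_O(g)|$ against the GDI
out-neighbourhood.  How replicate profiles should be aggregated into one
Boolean profile per condition is an open design point; majority vote is
our choice, and the gene-mean threshold is the default binarization
because it is the simplest operational rule, with the k-means split as
the alternative.

`synthesizeKnockoutDataset()` generates test data with a planted truth:
per-gene baselines drawn once from a unit-variance normal around a
global mean of 8 (log-intensity scale), knockout samples shifting the
planted affected genes down by `effectSize` (default 2, a strong
two-unit repression) and the knocked-out gene itself set low, plus
i.i.d. Gaussian measurement noise (`noiseSd`, default 0.25).  Default
replicate numbers are 9 wild-type and 3 knockout samples, the
per-condition scale of the compendium the pipeline is shaped after.
The generator emulates the two-condition replicate structure and shift
pattern the pipeline assumes; it does **not** emulate correlated
regulatory programs, batch effects, or intensity-dependent variance of
real microarray compendia, so passing tests demonstrate pipeline
correctness (planted-truth recovery, noise monotonicity), not
real-data performance.  Real compendium integration is a file-format
contract (`readExpression()`) only.

## Numerical and degenerate-input policies

* Self-loops in input edge lists are dropped with a message; duplicate
  identical edges collapse; duplicated pairs with conflicting signs are
  a hard error (data quality surfaced early, never silently picked).
* Node order is the sorted unique label order of the input file; state
  vectors are index-aligned with it.
* States are compared by exact content (packed byte keys in the
  compiled core), never by probabilistic hashing.
* Constant genes binarize to all-0 with one collapsed warning (no
  threshold exists); empty experimental sets make the precision ratio
  an explicit error, not 0.
* Every random draw (rules, sampled states, generators, synthetic data)
  takes an explicit seed; one pipeline seed is expanded into
  per-component sub-seeds so stages can be re-run independently.

## Test problem sizes

The test suite works at desk scale, chosen so the full suite runs in
minutes: oracle-equivalence sweeps use 200 random networks of 4–6 nodes
with exhaustive initial states and knockout durations 1 and 5, checked
exactly against brute-force trajectory and formula oracles;
reachability uses 100 networks of 5–7 nodes; the structure-correlation
replication uses 20 thirty-node preferential-attachment/shuffled
networks with 500 sampled initial states at the default T = 20; the
demonstration pipeline run uses a 10-node network with all 1024 initial
states at T = 10.  These sizes are the package's own test-design
choices; the methods themselves scale to the hundreds-of-nodes regime
via sampled initial-state sets.

## Known limitations

* Synchronous deterministic updating only — no asynchronous or
  probabilistic schemes, no multi-valued logic, no knock-ins or
  multi-gene mutations.
* $\mu$ computed from sampled initial states is an estimate of the
  exhaustive value; the exactness guarantee is about the arithmetic on
  the sampled set, not about sampling error.
* Path and cycle counts are capped at `maxLen` edges; on dense graphs
  counts at the cap can dominate correlations involving $n$.  In our
  30-node random-network replication the negative $\mu$–$l$ relation is
  highly reproducible, while the positive $\mu$–$n$ relation is weak
  (a majority of replicates, with the exceptions indistinguishable
  from zero correlation) — sparse preferential-attachment graphs at
  this cap dilute the short-multipath signal that denser real
  signalling networks carry.
* The GDI network depends on the random rule draw; analyses should be
  read per rule set (and seed), which is why every output carries its
  provenance.
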