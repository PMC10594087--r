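---
title: "Methods: longitudinal symptom networks with pairnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal symptom networks with pairnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairnet)
```

## The problem

Clinical symptom scales — here the running example is a 12-item negative
symptom instrument scored 0–6 per item, with the "lack of normal distress"
control item excluded — are increasingly analysed as *networks*: items are
nodes, and edges are partial correlations (the association between two
items after conditioning on all others).  When the same subjects are rated
at baseline and again at follow-up, three questions follow naturally:

1. **Structure**: which items are conditionally connected, and how central
   is each item (strength, closeness, betweenness)?
2. **Stability over time**: did the *topology* of the network change
   between waves, and did its *overall connectivity* (global strength)
   change?  Because the same people contribute both waves, any test must
   respect within-subject dependence.
3. **Domains**: do the items aggregate into symptom domains (anhedonia,
   asociality, avolition, blunted affect, alogia), and how reproducible is
   that aggregation across stochastic community-detection runs?

`pairnet` implements this pipeline end-to-end and ships a synthetic-data
generator with a *planted* network so every stage can be validated against
ground truth.

## Model and estimator

### Nonparanormal transformation

Ordinal 0–6 scores are far from Gaussian, so each item is marginally
Gaussianized before correlation: with mid-rank empirical CDF values
$u_i = \mathrm{rank}_i / n$ (average ranks for ties), Winsorized to
$[\delta_n, 1-\delta_n]$ with
$\delta_n = \{4 n^{1/4} \sqrt{\pi \log n}\}^{-1}$, the transformed value is
$\Phi^{-1}(u_i)$, rescaled to unit column standard deviation.  This is the
standard truncated-ecdf nonparanormal estimator; the rescaling keeps
column SDs near 1 even for heavily tied, right-skewed items (without it,
an item with 40% of its mass at 0 lands near SD 0.81).

Two consequences of the truncation are worth knowing: the most extreme
ranks (those with $u$ outside the truncation band) collapse to a common
value, so the transform is monotone *nondecreasing*, not strictly
increasing, at the boundary; and Spearman correlation between raw and
transformed columns can fall microscopically below 1 when a rare extreme
category collapses into its neighbour.  Tests assert exactly this
behaviour rather than idealized strictness.

### Penalized network estimation

From the Pearson correlation matrix $S$ of the transformed items, the
precision matrix $\Theta$ is estimated by the graphical lasso
$$
\hat\Theta = \arg\max_{\Theta \succ 0} \;\log\det\Theta -
\mathrm{tr}(S\Theta) - \lambda \sum_{i \ne j} |\Theta_{ij}|,
$$
with the diagonal unpenalized (so $\lambda \ge \max_{i\ne j}|S_{ij}|$
yields an exactly empty network by the KKT conditions).  Edge weights are
partial correlations $e_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$.
The solver is block coordinate descent (Friedman-style column sweeps) in
C++, converged when the largest parameter change between sweeps falls
below `tol` (default `1e-6`, max 500 sweeps); the unpenalized limit is
computed directly as $S^{-1}$.

$\lambda$ runs over a 100-point log-spaced grid from
$\lambda_{\max} = \max_{i\ne j}|S_{ij}|$ down to $0.01\,\lambda_{\max}$,
warm-started, and the model minimizing the extended BIC
$$
\mathrm{EBIC}_\gamma = -2\,\ell(\hat\Theta) + E\log n + 4\gamma E\log p
$$
is selected, with $\gamma = 0.5$ — the "tuning parameter 0.5" idiom of
this literature.  The description "adaptive LASSO" in this family of
analyses is ambiguous; an adaptive-weights variant (penalty weights
$1/|\hat\theta_{ij}|$ from the least-penalized plain fit) is available via
`estimator_settings(penalty = "adaptive")`, but EBIC-glasso is the
default and the validated configuration.

### Centrality

Strength is $\sum_j |e_{ij}|$ (absolute values: estimated networks carry
negative edges, and absolute strength is the conventional index; the
signed sum is reported as `expected_influence`).  Shortest-path indices
use edge lengths $1/|e_{ij}|$: closeness is the inverse total distance to
all other nodes (0 for nodes with unreachable partners, reported via a
message), and betweenness gives fractional credit $\sigma_{st}(v)/\sigma_{st}$
under tied shortest paths.  Global strength is
$g = \sum_{i<j} |e_{ij}|$, so $g = \tfrac12\sum_i \mathrm{strength}_i$
(the handshake identity used as a test invariant).  Distances and
betweenness are delegated to igraph; tests validate them against an
exhaustive simple-path-enumeration oracle on all networks with $p \le 5$.

## Stability and comparison

### Bootstraps

Edge accuracy: $B$ nonparametric resamples of subjects, full pipeline
re-run per resample, percentile intervals per edge (BCa offers little at
these sizes and the percentile interval is the reference behaviour).
Centrality stability: case-dropping bootstrap over drop proportions
$q = 0.1, \dots, 0.9$, retaining subsamples of size $\ge p + 5$, with the
correlation-stability coefficient CS = the largest $q$ at which the
correlation with full-sample centralities stays $\ge 0.7$ in $\ge 95\%$ of
draws.  Draws whose re-estimated network has constant centrality (e.g. an
empty network in a small subsample) yield undefined correlations; they are
kept in the raw draw table as NA and excluded from the qualifying
fractions.

### Dependent-samples network comparison test

The observed statistics are $M = \max_{i<j} |e^{(1)}_{ij} - e^{(2)}_{ij}|$
(network structure) and $S = |g_1 - g_2|$ (global strength).  The null
distribution respects pairing: independently per subject, with probability
1/2, that subject's baseline and follow-up rows are swapped; both networks
are re-estimated from scratch (transform, correlation, EBIC-glasso) in
every one of the $B$ replicates.  P-values use the add-one estimator
$(1 + \#\{\text{replicate} \ge \text{observed}\})/(B+1)$, so they are
never 0 and never below $1/(B+1)$.  Per-edge differences are tested
against the same replicates and Holm-adjusted; following the usual
workflow the edge table is reported when a global test reaches
$\alpha = 0.05$ (policy configurable).  Under an exchangeable null
(both waves generated from one planted network) the type-I error of the
$S$ test at $\alpha = 0.05$ is verified by 200-replication simulation to
lie in $[0.02, 0.09]$, and the sampled permutation distribution matches a
full $2^{10}$ enumeration for 10 subjects (binned total variation
$\le 0.05$).

## Signed spinglass communities

Community structure minimizes the signed Potts Hamiltonian
$$
H(\sigma) = -\sum_{i<j}\left[(w^+_{ij} - \gamma^+ p^+_{ij}) -
(w^-_{ij} - \gamma^- p^-_{ij})\right]\delta(\sigma_i, \sigma_j),
$$
where $w^\pm$ are the positive/negative parts of the edge weights and
$p^\pm_{ij} = s^\pm_i s^\pm_j / 2m^\pm$ are signed configuration-model
expectations; $\gamma^\pm = 1$ by default.  Minimization is simulated
annealing over single-node relabel proposals with Metropolis acceptance
(start temperature 1.0, stop 0.01, cooling 0.99, 50 sweeps per
temperature), followed by a zero-temperature quench, so every returned
partition is a *local* optimum.

**Why the final state, not the best-seen state, is returned.**  The whole
point of repeating the detection (10,000 runs in the reference workflow)
is to tally the *frequency of different structures* as a stability
measure.  A best-seen tracker with this schedule solves $p = 12$
landscapes essentially every run, so the tally degenerates to one
structure and the measure carries no information; the reference
implementation (igraph's spinglass) returns annealed final states, which
is what makes the tally meaningful.  The quench keeps returned partitions
interpretable (local optima) without restoring the degeneracy.

Partitions are canonicalized (communities labelled by first appearance
over the node order) so label permutations collapse, and tallies report
the fraction of runs per canonical structure together with the exact
Hamiltonian of each.

**A calibration caveat on the 4-vs-5 domain phenomenon.**  With a planted
avolition–asociality cross-coupling of 0.15 (against 0.02 elsewhere and
0.3 within domains), the merged 4-domain partition is *strictly*
energetically dominant: 0.15 is roughly 2.4 times its configuration-null
expectation ($\approx 0.06$), giving the merged basin an energy advantage
of $\approx 0.35$.  The split 5-domain structure is a local optimum, but
across 10,000 annealed runs it is never the freeze-out state (igraph's
own spinglass reaches it in well under 1% of runs on the same network).
Genuine bistability of the kind reported in real data — a roughly 2:1
split between the merged and split structures — requires cross-coupling
*near the null expectation*, i.e. a truly marginal separation.  The
acceptance test encoding the 0.15 world is therefore expected to flag
exactly this: its merged-frequency assertion passes, its split-frequency
assertion fails, and the package deliberately does not re-tune the world
to manufacture a pass.

## The synthetic generator

The generator is a latent-Gaussian threshold model — the standard ordinal
model, and the one under which the nonparanormal analysis is correctly
specified:

- A planted partial-correlation matrix $P$: `within_weight` (default 0.3)
  inside each of the 5 domains, `between_weight` (default 0.02)
  elsewhere, with optional per-block-pair overrides.  The implied
  precision is $I - P$ (configs whose precision is not positive definite
  are rejected), and its standardized inverse is the latent correlation
  matrix.
- The follow-up network is the baseline network scaled element-wise by
  `strength_scale_followup` (default 0.9, mirroring the reported modest
  decline in overall connectivity).
- Cross-wave dependence: with $A, B$ the symmetric square roots of the two
  latent correlation matrices and $\rho$ = `subject_dependence` (default
  0.5), $X_b = Z_1 A$ and $X_f = (\rho Z_1 + \sqrt{1-\rho^2} Z_2)B + \mu$,
  giving each wave its own planted network and each subject latent
  correlation $\approx \rho$ across waves — the simplest mechanism that
  makes the paired permutation scheme meaningful.
- Discretization: per-item cut-points on the latent scale; the defaults
  $(-0.25, 0.5, 1.1, 1.7, 2.3, 2.9)$ give a right-skewed score
  distribution (roughly 40/29/17/8/3/1.2/0.2% across 0–6), matching a
  mild-to-moderate severity profile.  The per-item mean shift at
  follow-up defaults to $-0.2$ latent SD, so all item means decline.
- Defaults mirror the scale of a typical longitudinal negative-symptom
  cohort: $n = 612$ paired subjects, 12 items, 5 domains, 7 categories.

What the generator does *not* emulate: real marginal distributions per
item (no item-level calibration target exists in the public record),
attrition between waves beyond an optional missingness rate, secondary
symptom covariates, and any measurement error structure beyond the
threshold model.  A green recovery test therefore establishes that the
estimator recovers *latent-Gaussian block worlds*, not that it would
recover any particular clinical dataset.

## Numerical choices

- glasso convergence `1e-6` (max parameter change between sweeps), inner
  lasso tolerance one order tighter; estimates are validated to `1e-4`
  per entry against an independent proximal-gradient (FISTA) maximizer.
- Partial correlations below `1e-10` in magnitude are snapped to exactly 0.
- Shortest-path ties are resolved fractionally; path-length comparisons
  tolerate `1e-12`.
- P-values use add-one estimators; Holm adjustment enforces monotonicity
  by cumulative maximum and caps at 1.
- Every pipeline stage derives its own seed from the master seed via a
  deterministic hash (`derive_seed`), so stages re-run independently and
  two `run-all` executions from one master seed are byte-identical in
  their result files.  The annealer uses its own `std::mt19937` streams,
  keyed per run, for platform-stable tallies.
- Display thresholding (`|e| >= 0.05`, boundary inclusive) applies to the
  exported diagram/layout files only; no analysis statistic is ever
  computed from a thresholded network.

## Known limitations

- The estimator assumes a monotone latent-Gaussian item model; polychoric
  input correlations are not the default (and genuinely non-Gaussian
  dependence structures are out of scope).
- The NCT permutes whole wave assignments within subjects; it does not
  model attrition or time-varying covariates.
- Spinglass frequencies are kinetic quantities: they depend on the
  annealing schedule as well as the energy landscape, and are not claimed
  to reproduce any published frequency values.
- Bootstrap defaults (B = 1000 edge / 250 per drop proportion) are
  desk-scale choices; the reference analyses do not report their counts.
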