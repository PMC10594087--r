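# pairnet

Longitudinal symptom-network analysis for paired ordinal panels.

`pairnet` is for researchers who rate the same subjects on an ordinal
symptom scale (items scored 0–6, e.g. a negative symptom instrument) at
two time points and want to know whether the *network* of symptoms — the
conditional dependence structure among items — stayed put, weakened, or
reorganised into different domains.  It implements the standard
psychometric network pipeline as tested, reusable code:

- **Preprocessing** — panel ingestion with validation and listwise
  deletion, item exclusion (e.g. dropping a control item), and the
  nonparanormal transformation: ranks through the Winsorized empirical
  CDF composed with `qnorm`, making ordinal items usable in a Gaussian
  graphical model.
- **Estimation** — graphical LASSO over a 100-point λ path with extended
  BIC model selection (γ = 0.5):
  `EBIC = -2·loglik + E·log n + 4γ·E·log p`.  Edge weights are partial
  correlations `e_ij = -Θ_ij / √(Θ_ii Θ_jj)`.
- **Centrality** — strength `Σ_j |e_ij|`, closeness (inverse total
  shortest-path distance at edge lengths `1/|e_ij|`), fractional
  betweenness, and global strength `g = Σ_{i<j} |e_ij|`.
- **Stability** — nonparametric edge-weight bootstrap with percentile
  intervals, and the case-dropping bootstrap with correlation-stability
  (CS) coefficients.
- **Comparison** — the dependent-samples permutation network-comparison
  test: per-subject wave swaps, structure statistic
  `M = max |e⁽¹⁾ - e⁽²⁾|`, global-strength statistic `S = |g₁ - g₂|`,
  add-one permutation p-values, and Holm-corrected per-edge tests.
- **Communities** — signed spinglass detection (Potts Hamiltonian with a
  signed configuration-model null, simulated annealing in C++), repeated
  across thousands of seeds with canonical partition-frequency tallying.
- **Synthetic data** — a latent-Gaussian threshold generator with a
  planted block network (5 symptom domains, scaled follow-up network,
  within-subject cross-wave dependence), so every stage has ground truth.

## Worked example

```r
library(pairnet)

cfg  <- generator_config(n_subjects = 612, seed = 2026)
made <- make_paired_panel(cfg)       # paired panel + planted ground truth
made$panel
#> <paired_panel> 612 subjects x 12 items (baseline + followup)

net_b <- fit_panel_network(made$panel$baseline)   # npn -> cor -> EBIC-glasso
net_f <- fit_panel_network(made$panel$followup)
net_b
#> <pc_network> 12 nodes, 9 edges, global strength 1.430
net_f
#> <pc_network> 12 nodes, 12 edges, global strength 1.586

head(centrality_table(net_b)[, 1:4], 4)
#>    item   strength closeness betweenness
#> 1 bnss1 0.44665838         0           0
#> 2 bnss2 0.41923598         0           0
#> 3 bnss3 0.37756876         0           0
#> 4 bnss5 0.07428369         0           0

nct <- nct_dependent(made$panel, B = 500, seed = 7)
nct
#> <nct_result> dependent-samples NCT, B = 500
#>   global strength: 1.430 vs 1.586; S = 0.156 (p = 0.5749)
#>   network structure: M = 0.144 (p = 0.0419)
#>   edge tests: 0 of 66 edges significant (Holm, alpha = 0.05)

tal <- community_tally(net_b, n_runs = 500, seed = 11)
tal
#> <community_tally> 500 runs, 4 distinct structures
#>    86.4%  5 communities (H = -1.0898)
#>     5.0%  4 communities (H = -1.0816)
#>     4.6%  4 communities (H = -1.0811)
#>     4.0%  4 communities (H = -1.0817)
domain_merge_frequency(tal, paste0("bnss", 5:6), paste0("bnss", 7:8))
#> [1] 0.04
```

Reading the output: the two estimated networks keep the planted 5-domain
topology; anhedonia items (`bnss1`–`bnss3`) carry the highest strength.
The global-strength test finds no significant connectivity change on this
draw (`S = 0.156, p = 0.57`), the structure statistic sits at the 0.05
boundary, and across 500 stochastic spinglass runs the 5-domain solution
dominates (86%), with the asociality and avolition items merging into a
single domain in 4% of runs — the frequency tally that quantifies how
reproducible the domain structure is.

Closeness is 0 here because the estimated network is disconnected at this
sample size (between-domain partial correlations of 0.02 are shrunk to
zero), which the package reports explicitly.

## End-to-end pipeline and CLI

```r
cfg <- pipeline_config(generator = generator_config(n_subjects = 612),
                       outdir = "out", seed = 1)
run_pipeline(cfg)   # panels, networks (CSV/TSV/GraphML), centrality,
                    # bootstraps, NCT, community tallies, layout, manifest
```

or from the shell:

```sh
Rscript inst/cli/pairnet.R run-all --seed 1 --outdir out
Rscript inst/cli/pairnet.R generate --seed 7 --outdir data
```

Subcommands: `generate`, `estimate`, `centrality`, `stability`,
`compare`, `communities`, `run-all`; `--config FILE` takes a JSON mirror
of `pipeline_config()`.

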