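# crnlayers

Cellular translation does not run in isolation: the ribosome and its helper
factors are themselves products of polymer biosynthesis, which in turn is fed
by metabolism. `crnlayers` builds and analyses the three-layer bipartite
chemical reaction network that couples these processes in *Escherichia coli*
— a translation layer (T), a polymer biosynthesis layer (B) generated
automatically from gene–protein–reaction (GPR) rules, and a genome-scale
metabolic layer (M) — and asks systems-level questions about it: are the
layers' degree distributions heavy-tailed, is the compound mass distribution
multimodal (even discontinuous), which modules hold the integrated network
together, and do the layers occupy separable neighbourhoods of the graph?

The package is aimed at systems biologists and network scientists who work
with reaction networks in tabular form (TSV reaction tables, BiGG-style JSON
models) and want a tested, scriptable pipeline rather than one-off notebook
code.

## The model

The network is strictly bipartite: one node class holds chemical compounds
(metabolites, amino acids, proteins, RNAs, complexes, ions, energy carriers
and a generic "peptide" placeholder for incomplete chains), the other holds
reactions. The degree *k* of a compound is the number of **distinct**
reactions involving it in any role — reactant, product, catalyst or
transporter. Analyses provided:

- **Tail fits.** Maximum-likelihood power-law and exponential fits of each
  layer's degree distribution, in continuous
  (γ̂ = 1 + n / Σ ln(kᵢ/k_min)) and discrete (Hurwitz-zeta likelihood)
  domains, with the lower cutoff k_min selected by minimising the
  Kolmogorov–Smirnov distance between the empirical and fitted tails, and a
  one-sided normal (Vuong) log-likelihood-ratio test deciding between a
  heterogeneous (power-law) and homogeneous (exponential) network.
- **Mass modes.** A log₁₀-binned histogram of compound masses with a
  detector for modes (prominent local maxima) and troughs (minimal-count
  runs between modes); empty trough bins flag a *discontinuous* mass
  distribution.
- **Contraction and centrality.** Reactions and module-private compounds
  collapse into module nodes; directed betweenness centrality
  BC(n) = Σ_{s≠n≠t} σ_st(n)/σ_st ranks the bridges that hold the
  translation–metabolism network together.
- **Embeddings.** Biased second-order random walks (node2vec scheme) with a
  PPMI/SVD co-occurrence factorisation yield node vectors; a separation
  score (mean inter-label / mean intra-label distance) quantifies how
  cleanly the layers separate.
- **Synthetic generator.** A seeded configuration-model generator emits
  three-layer networks with known ground truth — planted per-layer degree
  exponents, exact cross-layer bridge counts, a trimodal lognormal mass
  mixture with enforced gaps, and a GPR table — so the whole pipeline is
  testable without any download.

## Worked example

```r
library(crnlayers)

cfg <- synth_config(seed = 42)       # study-scale defaults
gen <- generate_network(cfg)
gen$net
#> <mlnet> multilayer bipartite reaction network
#>   compounds: 8342  reactions: 4973  compound-reaction links: 13533
#>   reactions per layer: B=1455  M=2085  T=1433

rep <- tail_report(degree_sequence(gen$net, "M"), domain = "discrete")
rep
#> <llr_comparison> R = 1229.765, p = 2.07e-09, preferred = power_law (k_min = 1, n = 2712)
rep$power_law
#> <tail_fit> power_law (discrete): gamma = 2.3104, k_min = 1, n_tail = 2712, KS = 0.0053, logLik = -3261.81

rec <- mass_degree_table(gen$net)
detect_modes_troughs(log_mass_histogram(rec, 0.25))
#> <mass_mode_summary> 3 mode(s), 2 trough(s), discontinuous = TRUE
#>   mode centres (Da): 197, 35000, 1970000
```

The metabolic layer's degree distribution is read as heavy-tailed: the
log-likelihood ratio R > 0 favours the power law and p ≪ 0.05 makes the
call significant, with the fitted exponent γ̂ = 2.31 recovering the planted
2.29. The compound mass histogram concentrates in three modes (here near
2×10², 4×10⁴ and 2×10⁶ Da) separated by troughs containing empty bins —
a discontinuous, trimodal mass distribution.

`run_pipeline()` chains all stages (build → counts → tail fits → mass modes
→ contraction/centrality → embeddings) into a single reproducible report;
`tidy()`/`glance()` methods return tibbles, and `plot_ccdf()`,
`plot_mass_histogram()`, `plot_embedding()` draw the standard figures.
Networks round-trip through TSV and export to GraphML/GEXF for Gephi.

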