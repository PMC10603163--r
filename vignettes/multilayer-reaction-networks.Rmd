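---
title: "Methods: multilayer bipartite reaction networks of cellular translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilayer bipartite reaction networks of cellular translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnlayers)
```

## The model

`crnlayers` represents the biochemistry that enables cellular translation as
a single bipartite graph spanning three reaction layers. Compound nodes are
chemical objects — metabolites, amino acids, ions, energy molecules,
proteins, RNAs, hetero-complexes and one generic *peptide placeholder* that
stands for any incomplete polypeptide still threaded through the ribosome.
Reaction nodes are logical chemical relationships. Every edge joins a
compound to a reaction, never two compounds or two reactions; the role of
the compound fixes edge direction, with reactants, catalysts and
transporters treated as inputs (the reaction cannot fire without them) and
products as outputs. Reversible reactions are stored once with a flag and
expanded to both orientations only inside directed analyses, so a
reversible reaction never inflates a compound's degree.

The three layers are:

* **T — translation**: curator-annotated reactions covering initiation,
  elongation, termination, translation-machinery biosynthesis (ribosome
  assembly), tRNA charging and the starvation response. Loaded from the
  package's reaction-table TSV schema by `load_translation_reactions()`.
* **M — metabolism**: a genome-scale metabolic model, read either from the
  same TSV schema or from a BiGG-style JSON subset
  (`load_metabolic_model()`); module labels come from the model's
  subsystem field, and reversibility from the flux bounds.
* **B — polymer biosynthesis**: generated, not curated.
  `build_biosynthesis_layer()` parses each metabolic reaction's
  gene–protein–reaction (GPR) rule (`and` = complex subunits, `or` =
  isozymes), expands it to its minimal protein sets, and emits one
  non-stoichiometric synthesis reaction per protein (twenty amino acids
  plus the peptide placeholder → protein) and one formation reaction per
  distinct hetero-complex (members → complex). The catalysing protein or
  complex is attached to the metabolic reaction *in place*; the metabolic
  reaction stays in layer M, and only the synthesis/formation reactions
  populate layer B.

Three modelling assumptions are worth making explicit. First, synthesis
reactions are non-stoichiometric: protein sequence composition is out of
scope, so every synthesis reaction consumes the full amino-acid alphabet.
Second, synthesis and formation reactions are deduplicated across the many
metabolic reactions that share an enzyme — duplicates would inflate
biosynthesis-layer degrees artifactually. A `dedup = FALSE` switch emits
per-reaction copies for sensitivity analyses. Third, complex masses are the
sum of the masses of their *distinct* components, each counted once
regardless of copy number, because assembly stoichiometry is generally not
known; nested complexes resolve recursively to unique leaves
(`assign_masses()`).

GPR expansion applies absorption after the disjunctive-normal-form step, so
the enzyme alternatives returned are exactly the minimal satisfying protein
sets of the boolean rule; `a or (a and b)` yields `{a}` alone. This keeps
the expansion stable under logically equivalent rewrites of the same rule,
which the test suite verifies against a truth-table oracle.

## Degree-tail statistics

The degree of a compound is the number of distinct reactions involving it
in any role. Tail analysis follows the maximum-likelihood framework of
Clauset-style power-law fitting:

* Continuous power law: closed form
  $\hat\gamma = 1 + n / \sum_i \ln(k_i / k_{\min})$. The numerical path is
  required to agree with this closed form to 1e-12.
* Discrete power law: $\hat\gamma$ maximises
  $-\gamma \sum_i \ln k_i - n \ln \zeta(\gamma, k_{\min})$ by 1-D
  optimisation over the bracket (1.01, 6.0), which comfortably covers the
  exponent range observed in reaction networks. The Hurwitz zeta is
  computed by direct summation of 1000 terms plus an Euler–Maclaurin tail
  correction, giving well below 1e-10 relative error over that bracket.
* Exponential alternatives: shifted-exponential closed form in the
  continuous domain, geometric-form MLE in the discrete domain.
* `select_kmin()` scans candidate cutoffs over the observed unique degrees
  and picks the cutoff minimising the Kolmogorov–Smirnov distance between
  empirical and fitted tail, ties going to the smallest cutoff. The cutoff
  is selected under the power-law family and reused for the exponential
  comparison — the standard practice, chosen here because the power law is
  the hypothesis under test and both models must see the identical tail.
* `compare_distributions()` computes the pairwise log-likelihood ratio
  $R = \sum_i d_i$ and a one-sided normal (Vuong) p-value
  $p = 1 - \Phi(|R|/(\sigma\sqrt n))$; the significance threshold defaults
  to 0.05. Below threshold the sign of $R$ names the winner; otherwise the
  comparison is *undecided* — the honest outcome for a layer whose tail
  cannot be told apart from exponential decay.

A fit requires at least 10 tail points (`min_tail`); smaller tails error
out rather than returning absurd exponents on tiny layers. Degree-zero
compounds are excluded from fitting and reported via an attribute. The
CCDF is computed on the raw unique-degree support; any binning is
presentation-only.

## Mass modes and troughs

`mass_degree_table()` joins each compound's mass and degree (unknown-mass
compounds, notably the peptide placeholder, are excluded and counted).
`log_mass_histogram()` bins on the log₁₀ axis with right-open bins anchored
at the smallest observed mass — anchoring at the data rather than at
integer decades makes mode detection exactly scale-equivariant: multiplying
all masses by ten shifts every bin edge by one decade and changes nothing
else.

`detect_modes_troughs()` formalises what is usually assessed by eye. A
*mode* is a local maximum (plateau-aware) whose height is at least
`prominence_fraction` of the global maximum and which is separated from
every higher retained mode by at least one bin below half its own height.
*Troughs* are the minimal-count runs between consecutive retained modes; a
trough containing at least one empty bin marks the distribution as
discontinuous — a mass range in which no molecule is reported at all. The
defaults, `bin_width_log10 = 0.25` and `prominence_fraction = 0.05`, keep
modes spanning several decades (small metabolites near 10² Da, polypeptides
near 10⁴–10⁵ Da, ribonucleoprotein assemblies near 10⁶ Da) well separated
while per-amino-acid mass jitter cannot split the metabolite mode; both are
exposed as arguments. Mode count is non-increasing in the prominence
threshold, which the property tests check. No kernel density estimation or
formal multimodality test (e.g. a dip test) is attempted: the detector is a
transparent, parameter-sparse reading of the histogram.

## Contraction and betweenness

`contract_by_module()` collapses all reactions sharing a module label into
one module node and absorbs every compound whose reactions all lie in a
single module; compounds spanning two or more modules survive as explicit
bridge nodes, so the contracted network is again bipartite (modules vs
bridging compounds) with direction inherited from the underlying roles. By
default the contraction covers the translation and metabolism layers — the
question being which modules and shared compounds hold those two domains
together — with the biosynthesis layer includable via the `layers`
argument.

Betweenness centrality uses the ordered-pair sum
$BC(n) = \sum_{s\ne n\ne t} \sigma_{st}(n)/\sigma_{st}$ with all shortest
paths of a pair counted fractionally, unit edge lengths, unreachable pairs
contributing zero, and unnormalised values by default. Directed mode (the
default, with reversible reactions expanded to both orientations) counts
$(s,t)$ and $(t,s)$ separately, as the formula's unordered-constraint-free
sum implies: an undirected star with four leaves scores 12 at the hub. The
`directed = FALSE` convention counts each unordered pair once (6 on the
same star). The fast path is igraph's Brandes implementation; the test
suite pins it against a brute-force all-pairs BFS path-counting oracle to
1e-9 on dozens of seeded random graphs.

## Embeddings and separation

`generate_walks()` implements second-order biased walks: from node $v$
reached from $t$, the unnormalised weight of stepping to $x$ is $1/p$ for
returning to $t$, 1 for an $x$ adjacent to $t$, and $1/q$ otherwise.
The bipartite graph is walked as-is on its undirected view — walks
alternate compound and reaction nodes, and no projection is applied. The
reference parameterisation is `p = q = 1`, `walk_length = 80`,
`walks_per_node = 10`, `window = 10`, `dimension = 128` (the standard
node2vec defaults); the pipeline runs a scaled-down setting
(`walk_length = 20`, `walks_per_node = 2`, `window = 5`, `dimension = 64`)
that keeps multi-thousand-node networks tractable in pure R while leaving
the separation analysis unchanged in character.

`embed_nodes()` trains vectors from walk co-occurrences: symmetric
within-window pair counts → positive pointwise mutual information →
seeded randomized truncated SVD (Halko-style range finding with subspace
iteration on the sparse PPMI matrix), with node vectors
$U \sqrt{\Sigma}$ and per-component sign fixing for bit-reproducibility.
This factorisation route was chosen over stochastic-gradient skip-gram
training because it is deterministic given a seed, has no learning-rate
tuning, and satisfies the contract that matters here: nodes with
overlapping walk contexts receive higher cosine similarity than nodes with
disjoint contexts. `reduce_2d()` is a plain principal-component projection
used for plotting only; no quantitative claim depends on 2D geometry, so a
t-SNE-style nonlinear layout was deliberately not added.

`separation_score()` is the mean inter-label pairwise distance divided by
the mean intra-label pairwise distance, computed on the full-dimensional
vectors; it is invariant under rotation and translation, exceeds 1 when
labels cluster, and sits near 1 for randomly assigned labels. On networks
beyond 4000 nodes the pairwise computation runs on a deterministic evenly
strided subsample to bound memory.

## The synthetic generator

`generate_network()` exists so that every stage is testable with known
ground truth. Its defaults are fixed study conditions, not tuning knobs:

* per-layer reaction counts 1433 (T), 1455 (B), 2085 (M);
* per-layer compound degree families: discrete power laws with exponents
  3.526 (T), 3.470 (B) and 2.290 (M), realised by inverting the
  zeta-distribution CDF;
* directed cross-layer bridge counts 25 (T→M) and 27 (M→T), with
  same-order counts for the biosynthesis pairs (15/15 T↔B, 30/30 B↔M) —
  cross-layer coupling through a few dozen shared compounds is the regime
  of interest;
* a trimodal lognormal mass mixture with medians 240 Da, 4×10⁴ Da and
  2×10⁶ Da (log₁₀ standard deviations 0.35/0.35/0.25, weights
  0.55/0.33/0.12, reflecting metabolite-dominated composition) and two
  enforced empty log-mass gaps (3.3–3.7 and 5.3–5.7) maintained by
  rejection sampling;
* per-layer compound counts (2800/2800/2600) set so each layer's reactions
  can always draw at least two participants from the planted degree
  sequence and the total node count is of the same order as the curated
  network (>13,000 nodes here).

Realisation uses a bipartite configuration model: compound stubs drawn
from the degree sequence are matched to reactions, every reaction is
seeded with one reactant and one product (same-compound collisions are
swapped away; an irreducible remainder is dropped), and remaining stubs
receive random roles with reactant/product/catalyst/transporter weights
0.4/0.4/0.15/0.05. Exact degree control was preferred over
preferential-attachment realism because the generator's job is to exercise
the fitters against a known exponent. Bridge compounds attach only to
irreversible reactions so the planted directed connectivity counts are
exact by construction. The GPR table (70% coverage of metabolic reactions;
30% AND-complex, 20% OR-isozyme, remainder monomer over a 300-protein
pool) is emitted as ground truth for the biosynthesis builder but its
proteins are *not* injected into the emitted network — cross-layer
connectivity stays exactly as planted.

What the generator does not emulate: stoichiometric coefficients and flux
feasibility, the actual module structure of real subsystems (labels are
assigned at random), correlations between a compound's mass and its degree,
and the single extreme ribosome-mass peak of the real translation
machinery. Passing tests on synthetic data therefore demonstrate that the
statistical machinery recovers known structure — planted exponents within
±0.15 at n = 10,000, planted modes/troughs, planted bridges — not that any
particular biological claim holds; conclusions about real networks require
the curated tables.

## Problem sizes, determinism, degenerate inputs

The test suite runs the generator at reduced sizes (tens of reactions and a
few hundred compounds per layer) and the full pipeline at those sizes in
well under two minutes; the acceptance script runs the study-scale default
configuration end to end in about one minute. Every stochastic stage —
degree sampling, network realisation, walks, the randomized SVD — takes an
explicit seed and is bit-reproducible; the pipeline derives per-stage seeds
from one master seed.

Degenerate inputs are handled explicitly rather than silently: an all-zero
degree sequence, an empty mass table, a tail smaller than `min_tail`, a
zero-variance tail for the exponential fit, cyclic complex composition,
unbalanced GPR parentheses, unlabeled reactions at contraction, and
single-label separation scoring all raise informative errors; isolated
nodes yield length-1 walks; nodes absent from a walk corpus receive zero
vectors with a warning.

## Known limitations

* The continuous-domain fits applied to inherently discrete degree data
  can drift for small tails (visible on layers with only a dozen tail
  points); the discrete fits are the primary read-out and the continuous
  ones are reported for comparability with closed-form expectations.
* The mode detector reports bin-centre mode locations; centres are only as
  precise as the bin width (0.25 decades by default).
* The PPMI/SVD embedding captures neighbourhood overlap but, unlike
  negative-sampling skip-gram, does not downweight very-high-frequency hub
  nodes beyond what PMI itself does; hubs can compress the separation
  score toward 1 on densely bridged graphs.
* Pure-R walk generation is adequate up to a few tens of thousands of
  walk-steps per second; far larger networks would warrant a compiled
  walker.
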