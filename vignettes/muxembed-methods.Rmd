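---
title: "Methods: random-walk similarity and contrastive embedding of multiplex networks"
author: "muxembed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-walk similarity and contrastive embedding of multiplex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`muxembed` learns vector representations of nodes from *multiplex* networks
(several layers of edges over one node set — e.g. physical protein
interactions, co-complex membership and co-expression over the same genes)
and from *multiplex-heterogeneous* networks (two multiplexes over different
node types, such as genes and diseases, joined by bipartite edges). The
embedding pipeline has two stages:

1. a **graph similarity**: per-node Random Walk with Restart on the
   multiplex (RWR-M) or multiplex-heterogeneous (RWR-MH) structure, giving
   each node a probability distribution over all nodes;
2. a **learner**: a noise-contrastive estimation (NCE) scheme that trains
   one d-vector per node so that dot-product similarity in the embedding
   space approximates the walk similarity (a VERSE-style objective).

The package also implements the matching evaluation protocols
(connectivity-preserving edge splitting, link prediction, network
reconstruction, bipartite link prediction), classical link-prediction
heuristics, and seeded stochastic-block-model (SBM) generators used by the
test-suite fixtures.

# The walk similarity

## States and the supra-transition matrix

A multiplex network with $n$ nodes and $L$ layers is flattened into
$nL$ node–layer states $(i, \alpha)$. From $(i,\alpha)$ the walker

* moves within layer $\alpha$ to a neighbour of $i$, chosen proportionally
  to edge weight, with total probability $1-\delta$;
* jumps to a counterpart state $(i,\beta)$, $\beta \neq \alpha$, chosen
  uniformly, with total probability $\delta$.

Column-normalising layer adjacencies and assembling these moves yields the
column-stochastic supra-transition matrix $M$ ([`supraTransition()`]).
Degenerate cases are resolved so that stochasticity is preserved rather than
deleting nodes: a node isolated in one layer sends its within-layer mass to
the inter-layer jump; with a single layer the $\delta$ mass stays in the
layer; a node isolated everywhere (no moves at all) becomes a flagged
*dangling* state whose mass the solver returns to the restart vector.

For a multiplex-heterogeneous network the state space is the union of both
sides' node–layer states. A state whose node has bipartite neighbours spends
probability $\lambda$ on a bipartite jump (neighbour chosen by weight,
arrival layer uniform over the other side's layers — the bipartite graph is
conceptually replicated across layers) and scales its intra-multiplex moves
by $1-\lambda$; nodes without bipartite partners walk purely within their
own multiplex. At $\lambda = 0$, or with no bipartite edges at all, the
matrix is block-diagonal and each block is exactly the corresponding
single-multiplex construction — a limit the tests assert.

## Restart iteration

With restart probability $r$ the walk distribution follows

$$p_{t+1} = (1-r)\,M\,p_t + r\,p_0,$$

iterated from the restart vector $p_0$ until the L1 change falls below
`tol` (default `1e-8`, iteration cap 1000; the map is a contraction with
factor $1-r$, so roughly $\log(\mathrm{tol})/\log(1-r) \approx 16$
iterations at $r = 0.7$). For a seed node $v$, $p_0$ places mass $\tau_\alpha$
on each of $v$'s layer states; $\tau$ defaults to uniform $1/L$. In the
heterogeneous case the walk restarts on both sides in general ($\eta$ splits
the restart mass between the sides), but the similarity matrix is built from
single-seed runs, where the whole restart mass belongs to the seed's own
side — $\eta$ therefore only matters for user-supplied multi-side seed sets.

Running one walk per node and summing the stationary distribution over each
node's layer states gives the similarity matrix: column $v$ is a probability
distribution over all nodes ([`rwrSimilarity()`]). Per-node aggregation is a
plain sum over layers; under the uniform $\tau$ used throughout this is
identical to a $\tau$-weighted sum. All seeds are iterated jointly as one
matrix recurrence, which is why the solver accepts a matrix of restart
vectors.

Defaults follow the established parameterisation of restart walks on
multiplex-heterogeneous graphs: $r = 0.7$, $\delta = 0.5$,
$\tau = (1/L, \dots, 1/L)$, $\lambda = 0.5$, $\eta = 0.5$.

## A note on the identical-layer reduction

It is tempting to expect RWR-M on $L$ identical layers to reproduce the
monoplex walk on one copy. That is exact only when inter-layer jumps are
disabled ($\delta = 0$). For $\delta > 0$, summing the states of identical
layers yields a *lazy* monoplex walk — with probability $\delta$ the
aggregated walker stays put. Substituting into the fixed-point equation
gives

$$q = \tfrac{(1-r)(1-\delta)}{1-(1-r)\delta}\,\hat A q
      + \tfrac{r}{1-(1-r)\delta}\,p_0,$$

i.e. the monoplex RWR at the effective restart
$r' = r / (1 - (1-r)\delta)$ (at $r=0.7$, $\delta=0.5$: $r' \approx 0.824$).
The test suite asserts both identities ($\delta = 0$ exactly; $\delta = 0.5$
against the $r'$-walk) to $10^{-6}$.

## Truncation

The tail of a restart distribution decays fast, so before training each
similarity column is truncated to its `nMax` largest entries and
renormalised ([`truncateSimilarity()`]). Ties are broken by ascending node
index, for determinism. The seed is excluded from its own support: sampling
a node as its own positive context carries no gradient information. `nMax`
defaults to 300 for networks above 5000 nodes and to
$\lceil 0.15\,n \rceil$ below.

# The contrastive learner

The target is to make the embedding-space similarity — the softmax of dot
products of the rows of the $n \times d$ matrix $W$ — match the walk
similarity, i.e. to minimise the summed Kullback–Leibler divergence from
the walk distributions to the embedding softmax ([`klDivergence()`]
monitors exactly this quantity). The softmax normalisation over all nodes is
avoided with NCE: a binary classifier distinguishes positive context
samples, drawn from the truncated walk distribution, from noise samples,
drawn uniformly over non-anchor nodes.

Each of `totalSteps` steps draws an anchor $u$ uniformly, one positive $v$
from $u$'s truncated distribution, and `s` uniform negatives. For a sample
with label $y \in \{0, 1\}$ the logit is $g = w_u \cdot w_v - b$ with
$b = \log(n_{\max})$ for positives and $b = \log(n_{\max}/s)$ for negatives
— the standard NCE partition-function correction for a noise support of
size $n_{\max}$ — and both rows move by $\mathrm{lr}\cdot(y - \sigma(g))$
along each other ([`nceUpdate()`]).

Hyper-parameter defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `d` | 128 | the standard dimension for comparable embedding studies |
| `s` | 3 (10 above 5000 nodes) | small noise ratios are known to work; more noise helps at scale |
| `nMax` | $\lceil 0.15 n\rceil$ (300 above 5000 nodes) | retains almost all mass of the fast-decaying walk distribution |
| `lr` | 0.0025 | constant; raising it tenfold visibly degraded embedding quality on the test fixtures |
| `totalSteps` | $1000\,n$ | the deterministic probe loss ([`nceProbeLoss()`]) plateaus between $500n$ and $1500n$ on desk-scale fixtures; $100n$ leaves the embedding indistinguishable from its initialisation |

The learning rate does not decay; a decay schedule can be emulated by
chaining `trainEmbeddings()` calls with the `init` argument.

Serial training is bit-reproducible for a fixed seed. The "parallel" mode
models concurrent workers *semantically* rather than by threading: steps are
processed in synchronous groups of `workers`, every update in a group is
computed from the group-start snapshot of $W$, and the increments are
summed. The contract is not bit-equality with serial mode but equal
downstream quality (the tests require link-prediction AUC within 0.02 of
the serial reference).

# Evaluation protocols

**Edge splitting.** Link-prediction evaluation removes 30% of each layer's
edges while keeping every connected component spanned. Per component a
uniform random spanning tree is drawn by Broder's random-walk procedure
(walk until all vertices are visited; first-entry edges form the tree); test
edges are sampled from the non-tree edges. If a layer is (nearly) a tree the
protocol takes what is removable and warns about the shortfall.

**Negatives.** The classifiers need absent pairs. Negatives are sampled
uniformly from unordered pairs absent from *every* layer (union-graph
non-edges), 1:1 with positives in both train and test sets. On very dense
toy networks the train negatives are capped at the available count with a
warning; test negatives are never compromised.

**Link prediction.** Edge features are built from the two endpoint
embeddings with one of five operators (Hadamard, Average, Weighted-L1,
Weighted-L2, Cosine). The component formulas are implemented exactly as
printed in the source tables — Hadamard carries a factor $1/2$ and Average
is the component sum — with `verbatim = FALSE` switching to the
conventional variants; the choice is irrelevant to scale-invariant
classifiers but kept explicit for fidelity. The cosine operator uses
full-vector norms (a per-component norm would collapse every component to
$\pm 1$); its components sum to the classical cosine similarity, which the
tests assert. The classifier is a ridge-penalised logistic regression
(penalty `lambda = 0.01`, exposed), scored by ROC-AUC on the held-out
edges.

**Heuristics.** Jaccard, common-neighbours, Adamic–Adar and preferential
attachment are computed per layer and averaged arithmetically across layers.
Adamic–Adar uses the natural logarithm and skips degree-1 common neighbours
(whose contribution $1/\log 1$ is undefined).

**Network reconstruction.** Per layer, a fraction of all node pairs is
sampled, labelled by adjacency, and a 100-tree random forest is fitted on
the operator features; `precision@K` is reported with $K$ = number of true
edges in the subset. The protocol deliberately has no held-out pairs. The
subset is scored with the forest's *out-of-bag* predictions: resubstitution
scores of a probability forest memorise continuous features and would
return precision $\approx 1$ for any embedding, informative or not, while
out-of-bag scores measure what the features actually encode. The evaluation
remains optimistic by construction (train and evaluation pairs coincide).

**Bipartite link prediction.** For heterogeneous networks, 30% of the
bipartite edges are removed (multiplex layers untouched, no connectivity
constraint), the *training* network is embedded, and a random forest on the
remaining bipartite edges plus matched bipartite non-pairs is scored by
ROC-AUC on the removed edges plus matched non-pairs.

# Synthetic fixtures and what they can show

`generateMultiplexSBM()` draws $L$ stochastic-block-model layers over a
shared node universe; per layer each node keeps its base community with
probability `layerCorr` (default 1: all layers share one planted
partition). `generateMHSBM()` adds community-aligned bipartite edges
(probability `pBipIn` between matched blocks, `pBipOut` otherwise). The
default single-layer densities (`pIn = 0.1`, `pOut = 0.01`, two equal
blocks of 150 over 3 layers) define the standard multiplex fixture used
throughout the tests.

These fixtures emulate the one property the evaluation tasks need —
predictable, community-driven edge formation shared across layers — and
deliberately *not* other properties of real molecular or social networks:
heavy-tailed degrees, local clustering beyond blocks, weighted edges,
layer-specific densities. Passing tests therefore demonstrate that the
pipeline recovers planted mesoscale structure, not that it reproduces
performance numbers on any real network.

One consequence of the SBM deserves emphasis, because it bounds what *any*
method can score on such fixtures. Conditional on block membership, SBM
edges are i.i.d.; a removed within-block edge is statistically exchangeable
with a within-block non-edge, so no scorer can separate them. The
link-prediction AUC of the best possible classifier is then determined by
the block composition of the test positives and sampled negatives. For the
standard fixture (two equal blocks, `pIn = 0.1`, `pOut = 0.01`) about 44%
of union non-edges lie within a block and the ceiling works out to roughly
0.73 — which is where both a block-membership oracle and the full pipeline
land. Fixtures intended to demonstrate *high* scores must therefore plant
an identifiable signal:

* the trainer quality property uses the same 300-node, 3-layer, 2-block
  geometry with `pIn = 0.35`, `pOut = 0.002` (ceiling ≈ 0.87);
* the heterogeneous fixture uses two 150-node, 2-layer SBMs with **five**
  aligned blocks of 30 (`pIn = 0.2`, `pOut = 0.01`) and bipartite densities
  `pBipIn = 0.2`, `pBipOut = 0.002` (ceiling ≈ 0.9): with two equal blocks
  no bipartite density pushes the ceiling past ~0.78.

Problem sizes used by the test suite and the acceptance script: multiplex
pipelines embed 300 nodes (3 layers, supra dimension 900); the
heterogeneous pipeline embeds 150+150 nodes over 2+2 layers; solver
correctness is checked on twenty random fixtures of at most 50 supra states
against a dense direct solve of the linear fixed-point system.

# Numerical and degenerate-input conventions

* Supra-transition columns are renormalised after assembly, so stochasticity
  holds to $10^{-12}$; all-zero (dangling) columns are flagged, never
  repaired silently.
* Similarity columns sum to 1 within $10^{-6}$ after aggregation.
* Truncation ties break by ascending node index; `nMax >= n` keeps all
  positive entries.
* $0 \log 0 = 0$ throughout the KL computation.
* Fully isolated nodes: restart-only walk columns, empty truncated support,
  skipped by the trainer (an all-isolated network is an error).
* Empty bipartite sets are allowed with a warning; the heterogeneous walk
  then degenerates to two independent multiplex walks, which the tests
  assert.

# Known limitations

* Directed or temporal layers are out of scope; layers must be undirected
  with non-negative weights and no self-loops.
* The heterogeneous structure supports exactly two multiplexes and one
  bipartite set; generalising to $k$ multiplexes with pairwise bipartites
  would require extending the supra-matrix assembly.
* The per-seed walk is solved by dense-vector iteration over all seeds
  jointly; memory grows as (states × seeds), which is comfortable at desk
  scale but would need batching beyond ~$10^4$ nodes.
* Training is single-threaded; the grouped "parallel" mode reproduces the
  semantics, not the wall-clock benefit, of concurrent workers.
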