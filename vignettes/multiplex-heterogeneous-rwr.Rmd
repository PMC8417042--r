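---
title: "Ranking lncRNA-disease associations by a restart walk on a multiplex-heterogeneous network"
author: "mhrwr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking lncRNA-disease associations by a restart walk on a multiplex-heterogeneous network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhrwr)
```

## The problem

Experimentally confirmed lncRNA-disease associations are sparse: a typical
curated extract has a few hundred associations over a hundred-odd lncRNAs
and diseases. Guilt-by-association methods exploit the observation that
similar lncRNAs tend to be implicated in similar diseases. `mhrwr` encodes
that idea as a random walk with restart (RWR) on a *multiplex and
heterogeneous* network: several similarity layers per node class, coupled
through the known bipartite associations, so that evidence from every
similarity source diffuses jointly rather than being averaged into a single
matrix beforehand.

## Similarity layers

Four layers are built from two inputs, the binary association matrix
$LD \in \{0,1\}^{n \times m}$ and a disease-ontology DAG with a
disease-to-term mapping.

**Disease semantic similarity.** Each term of the ontology receives, for a
given disease term $d$, a semantic contribution $D_d(k)$: 1 for $d$ itself,
and for every ancestor $k$ the maximum over its children $k'$ (within the
ancestor closure) of $\Delta \cdot D_d(k')$, with decay
$\Delta \in (0, 1)$ (parameter `decay`, default 0.5). Two diseases are
similar in proportion to the contributions of their shared ancestors
relative to their total semantic values:
$$\mathrm{DSS}(d_i, d_j) =
  \frac{\sum_{k \in T_i \cap T_j} \left(D_{d_i}(k) + D_{d_j}(k)\right)}
       {\sum_{k \in T_i} D_{d_i}(k) + \sum_{k \in T_j} D_{d_j}(k)}.$$
Diseases without an ontology mapping get 0 off-diagonal and 1 on the
diagonal; the GIP layer (below) still covers them, which is the reason for
running several layers in the first place.

**Gaussian interaction profile (GIP) kernels, both sides.** With
$IP(l_i)$ the $i$-th row of $LD$ (and $IP(d_j)$ the $j$-th column),
$$K(i, j) = \exp\!\left(-\gamma \, \lVert IP_i - IP_j \rVert^2\right),
  \qquad
  \gamma = \frac{\gamma'}{\tfrac{1}{n}\sum_i \lVert IP_i \rVert^2},$$
with $\gamma' = 1$ by default (`gammaPrime`). Dividing by the mean squared
profile norm makes $\gamma$ dimensionless, so the kernel is insensitive to
the overall association density.

**lncRNA functional similarity.** For disease sets $D_i$, $D_j$ of two
lncRNAs, each disease is matched to its best semantic counterpart in the
other set, $SS(d, D) = \max_{d' \in D} \mathrm{DSS}(d, d')$, and
$$\mathrm{NFS}(l_i, l_j) =
  \frac{\sum_{a \in D_i} SS(a, D_j) + \sum_{b \in D_j} SS(b, D_i)}
       {|D_i| + |D_j|}.$$
An empty disease set carries no evidence: $SS(\cdot, \emptyset) = 0$ and
$\mathrm{NFS} = 0$ when either set is empty. This case arises routinely
during cross-validation, when masking an association can empty a profile,
so the convention is part of the model rather than an edge case.

## The walk

Each node class forms a multiplex: $L$ lncRNA layers over the same $n$
nodes and $K$ disease layers over the same $m$ nodes. Every layer is first
self-loop-stripped and row-normalized, then stacked into a supra-adjacency
matrix whose diagonal blocks carry $(1-\delta)$ times the normalized layer
and whose off-diagonal blocks are $\frac{\delta}{L-1} I$: a particle moves
within its layer with probability $1-\delta$ and teleports to another copy
of its current node with probability $\delta$. Pre-normalizing the layers
makes $\delta$ the *exact* inter-layer jump probability instead of one
modulated by raw similarity row sums; with normalized layers the
alternative reading (normalizing the assembled supra-matrix) coincides, so
nothing is lost. A node isolated within one layer keeps its $(1-\delta)$
mass on its own copy, which keeps every row stochastic; the restart makes
the chain well-behaved regardless.

The two multiplexes are coupled by the bipartite matrix $B = LD$,
replicated across all layer pairs. From a lncRNA copy with at least one
association, the walk stays in the lncRNA multiplex with probability
$1-\lambda$ and crosses with probability $\lambda$, picking an associated
disease proportionally to its association row and one of that disease's
$K$ copies uniformly (the $1/K$ split is what makes the cross rows sum to
$\lambda$ exactly; without it the matrix is not stochastic). A lncRNA with
no associations keeps its full supra-adjacency row. Disease copies mirror
this with the columns of $B$ and a $1/L$ split. The $(1-\lambda)$ factor
scales the whole supra-row, i.e. the inter-layer $\delta$-jump and the
within-layer move are reduced together; this composes the two jump types
multiplicatively, which is the natural reading when both are probabilities.

The restart vector splits its mass $\eta$ : $(1-\eta)$ between the disease
and lncRNA sides. The query disease gets the disease mass, uniformly over
its $K$ copies; the seed lncRNAs (those associated with the query) share
the lncRNA mass uniformly, then uniformly over their $L$ copies. A seed
assignment of "probability 1 per seed" cannot be a distribution when there
are several seeds, so uniform normalization is used; if there is no seed
lncRNA the whole mass is renormalized onto the disease side. The iteration
$$P_{t+1} = (1-\gamma) H^{\top} P_t + \gamma P_{RS}, \qquad P_0 = P_{RS}$$
is an L1 contraction with factor $1-\gamma$, so the fixed point is unique
and the initial vector is irrelevant to it; $P_0 = P_{RS}$ is simply the
cheapest start. Convergence is declared when
$\lVert P_{t+1} - P_t \rVert_1 < \texttt{tol}$ (default $10^{-10}$; the L1
norm is natural for probability vectors and all norms are equivalent at
this tolerance). With $\gamma = 0.9$ the residual shrinks tenfold per
iteration, so about a dozen iterations suffice — a property the test suite
asserts. Entity scores are the sums of their copies' stationary
probabilities (the mean would differ by the constant $1/L$ and give
identical rankings); the seeds are removed and the remaining candidates
ranked.

## Parameters

| parameter | meaning | range | default |
|---|---|---|---|
| `gamma` | restart probability | (0, 1) | 0.9 |
| `lambda` | bipartite jump probability | [0, 1) | 0.9 |
| `eta` | disease-side restart weight | (0, 1) | 0.9 |
| `delta` | inter-layer jump probability | [0, 1) | 0.5 |
| `decay` | semantic contribution decay | (0, 1) | 0.5 |
| `gammaPrime` | GIP reference bandwidth | > 0 | 1 |
| `tol` | L1 convergence threshold | > 0 | 1e-10 |

$\gamma = \lambda = \eta = 0.9$ is the setting reported to perform best
for this family of walks, and $\eta$, $\lambda$, $\gamma$ only matter
within broad ranges. No established value exists for $\delta$; 0.5 treats
within-layer and cross-layer evidence symmetrically and is exposed in the
configuration. `lambda = 0` and `delta = 0` are accepted (though outside
the defaults' open intervals) because the decoupled limits are scientific
checks in their own right: $\delta = 0$ confines the walk to its starting
layer, and $L = K = 1$ collapses the construction to the classic
two-network heterogeneous RWR, which the tests verify bit-for-bit.

## Cross-validation

`loocv()` withholds each known association $(l, d)$ in turn, re-ranks the
lncRNAs for $d$, and records the held-out lncRNA's score against the
candidate scores (lncRNAs with no remaining association to $d$). Global
mode pools all positives against the union of candidate scores; local mode
averages the per-fold AUC, with the reported curve built from a top-$k$
sweep over the per-fold candidate lists. Ties always earn half credit, so
the global AUC equals the normalized Mann-Whitney statistic — each is
cross-checked against exhaustive pair enumeration in the tests.

By default the two GIP kernels and the functional layer are recomputed
from the masked matrix in every fold (`recomputeSimilarity = TRUE`):
without the refit, the held-out edge leaks into the kernels and inflates
the estimate. The semantic layer depends only on the ontology and is never
refit. The cheaper no-refit protocol remains available (`--no-refit`)
since either may be wanted when comparing against published figures whose
protocol is unspecified.

## The synthetic benchmark

`syntheticSpec()`/`benchmarkRecovery()` generate a planted co-cluster
world: lncRNAs and diseases are partitioned into matching blocks, pairs
inside a block associate with probability `withinDensity` and outside with
`crossDensity`; an ontology is grown by giving each new term one or two
random earlier parents, and diseases map to uniform random terms. The
default benchmark (30 x 30, 3 co-clusters, within 0.6, cross 0.02) mirrors
the sparsity scale of curated association extracts while being small
enough for LOOCV with per-fold refitting to run in seconds; the test suite
averages it over 10 generator seeds. All generators are pure functions of
the seed (Mersenne-Twister, caller's RNG state restored), so fixtures are
reproducible without shipping data files.

What the benchmark does and does not show: recovering planted co-clusters
well above chance (mean global LOOCV AUC near 0.88 under the defaults,
against about 0.5 for the density-matched structureless control —
recomputed, not assumed, by both the test suite and
`scripts/acceptance.R`) demonstrates that the diffusion machinery ranks
held-out edges by shared structure. It does not emulate the skewed degree
distribution, the ontology depth, or the annotation biases of real
curated databases, so performance on real data must be measured on real
data; the random disease-to-term mapping also makes the semantic layer
pure noise here, which is deliberate — the benchmark then also exercises
the walk's robustness to an uninformative layer.

## Numerical choices and degenerate inputs

* All-zero interaction profiles across the board make the GIP bandwidth
  undefined; this is an error, and the generator guarantees nonempty
  profiles by construction. A single empty profile is fine (its kernel row
  is still defined).
* Score ties in rankings are kept in `order()`'s stable order; ties in
  evaluation earn half credit, making the AUC estimator-consistent with
  the U statistic.
* Equality of floating-point row sums to 1 is enforced to 1e-12 in the
  class validity checks; the power iteration conserves total mass to 1e-9.
* Unknown identifiers are exact-string mismatches and raise errors rather
  than being fuzzily matched; the CLI reports diseases without ontology
  mappings up front.

## Known limitations

* Dense base-R matrices throughout: adequate far beyond the few-hundred
  node scale this method targets, but not for genome-scale multiplexes.
* Only multiplex replication is supported — every layer must cover the
  identical node set; truly heterogeneous multilayer topologies are out of
  scope.
* No accelerated solvers; the power iteration with a dense-solve test
  oracle is deliberately simple, and at $\gamma = 0.9$ converges in a
  dozen steps anyway.
* LOOCV with per-fold refitting is quadratic in the association count; the
  `--no-refit` flag is the pragmatic escape hatch for large inputs.
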