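---
title: "Mixed-curvature embeddings of pathway graphs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-curvature embeddings of pathway graphs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpathway)
```

## The problem

Biological pathway graphs — nodes are genes, proteins, or metabolites;
edges are cellular relationships — are small by graph-learning standards
(tens to a few hundred nodes) but structurally heterogeneous: some are
tree-like signaling cascades, some contain feedback cycles, some are
densely interconnected complexes. A node embedding is useful downstream
(e.g., for predicting unobserved protein–protein interactions) to the
extent that embedded distances reflect graph distances. Euclidean space
cannot represent some of these structures at low distortion at any
dimension; constant-curvature alternatives can: hyperbolic space
accommodates the exponential volume growth of trees, spherical space the
bounded closed geometry of cycles.

`mcpathway` embeds a pathway graph into a Cartesian **product of model
spaces** — a *signature* such as `H34_1.0 x S33_1.0 x E33` listing each
component's type, manifold dimension, and curvature scale — and selects,
per graph, the signature of minimum distortion under a fixed total
dimension budget. A **product GCN** then consumes the embedding for edge
prediction, running message passing in the tangent spaces of each
component.

## Model spaces and the product metric

Each component is a sphere, a hyperboloid, or a Euclidean space. With
curvature scale $C$ (radius $\sqrt C$), points satisfy
$\langle x,x\rangle = C$ (sphere) or
$\langle x,x\rangle_L = -C,\ x_0>0$ (hyperboloid, Minkowski inner
product), with one extra ambient dimension each. Distances are

$$d_S = \sqrt C\,\arccos(\langle x,y\rangle/C),\qquad
  d_H = \sqrt C\,\operatorname{arcosh}(-\langle x,y\rangle_L/C),\qquad
  d_E = \lVert x-y\rVert,$$

and the product distance decomposes as
$d_\mathcal{P}^2 = \sum_i d_{M_i}^2$. Exponential and logarithmic maps
(closed forms in `exp_map()`/`log_map()`) move between each manifold and
its tangent spaces; `project_to_tangent()` converts ambient gradients to
Riemannian ones (with the Minkowski metric correction on the
hyperboloid).

A note on the spherical log map: the closed form implemented is the
standard one mutually inverse with the cosine/sine exponential map; the
suite verifies $\log_x(\exp_x(v)) = v$ to $10^{-6}$ relative error across
all space types and curvature scales rather than trusting any printed
formula.

## The distortion objective

Training minimizes, over node pairs at graph distance $d_G$ (unweighted
shortest paths) and embedded distance $d_\mathcal{P}$,

$$\mathcal{L}(f) \;=\; \sum_{u<v}
  \left(\frac{d_\mathcal{P}(f(u),f(v))^2}{d_G(u,v)^2} - 1\right)^{\!2},$$

the relative squared-distance deviation (an absolute-value reading is
available via `loss_form = "abs"`). Embeddings are *evaluated* by the
average relative distortion
$\mathcal{D} = \tfrac1P\sum_{u\neq v} |d_\mathcal{P}-d_G|/d_G$ over the
$P = |V|^2-|V|$ ordered pairs ($\mathcal{D}=0$ iff isometric; a $|V|^2$
denominator variant is provided, differing by the factor $(|V|-1)/|V|$).

**Optimization.** Riemannian gradient descent: the ambient gradient of
$\mathcal{L}$ is projected onto the tangent space at each point (metric
correction first on hyperboloids), the point retracted along the geodesic
with the exponential map, then renormalized exactly onto its constraint
surface so constraint drift cannot accumulate. Three numerical choices
matter and are defaults for a reason:

* **Trust region** (`max_step = 1`): the loss is quartic in distances;
  uncapped early steps diverge. Each point moves at most a unit geodesic
  length per step.
* **Initialization scale**: coordinates are drawn with spread
  $1/\sqrt{d}$ per dimension (spheres: uniform), then Euclidean and
  hyperbolic tangent coordinates are rescaled once so the mean embedded
  distance matches the mean graph distance. Without this, a
  100-dimensional initialization starts ~14x too spread out and the
  quartic loss is unstable.
* **Clamping**: $\arccos$ arguments to $[-1,1]$, $\operatorname{arcosh}$
  arguments to $[1,\infty)$; tangent vectors below $10^{-12}$ norm are
  treated as zero (the closed forms divide by the norm); geodesic angles
  are capped at 250 to keep $\cosh$ finite.

Default schedule: full-batch pairs (pathway graphs are small; pairs are
sampled only above `batch_pairs`), 1000 epochs, learning rates swept over
$\{0.01, 0.1\}$.

## The signature sweep

`signature_grid()` enumerates signatures with 0–3 components per space
type (at least one overall) whose dimensions sum exactly to the
100-dimension budget, partitioned as evenly as possible (1 component:
100; 2: 50+50; 3: 34+33+33; ...), crossed with the learning-rate grid.
`sweep_and_select()` trains each configuration and returns the signature
of minimum distortion; when two *different* signatures come within a
relative $10^{-4}$ of the minimum the graph has no unique best space and
is flagged as a tie (such graphs are excluded from downstream
comparisons, since no canonical representative space exists).

**Curvature scales in the sweep.** The default grid fixes $C = 1$.
Spherical distances are bounded by $\pi\sqrt C$, so on a graph of
diameter larger than $\pi$ a unit sphere *cannot* match graph distances
and the sweep should include larger spherical curvature scales; the
natural scale for an $n$-cycle is the circle of circumference $n$, i.e.
$C \approx (n/2\pi)^2$. The geometry-recovery experiments therefore
sweep $C \in \{1, 4, 9, 16\}$ for spherical components on the 20-cycle
(whose natural scale is $C \approx 10$). Hyperbolic and Euclidean
components face no such bound.

Because every Euclidean-only signature is a member of the grid, the best
mixed-curvature distortion can never exceed the best Euclidean
distortion over the same grid — the practical question, answered
per-graph by the sweep, is how large the improvement is.

## Baselines and the scaling optimization

Two standard Euclidean baselines are provided: `node2vec_embed()`
(biased second-order random walks, skip-gram with negative sampling —
implemented in-package, walks of length 80, 10 per node, window 10) and
`laplacian_embed()` (eigenvectors of the combinatorial Laplacian
$L = D - A$, ascending eigenvalues, dimension $|V|$, constant eigenvector
kept, signs canonicalized). Neither optimizes distortion, and both are
scale-arbitrary, so raw distortion would be meaningless; `optimal_scaling()`
finds the constant minimizing
$\sum_{i<j}(c\,d(x_i,x_j)/d_G - 1)^2$ in closed form
($c^* = \sum r_{ij}/\sum r_{ij}^2$ with $r_{ij}$ the distance ratios) and
`scaled_distortion()` re-evaluates distortion after rescaling. The third
baseline, `euclidean_distortion_embed()`, is the Euclidean special case
of the product embedding itself.

## The product GCN

One GCN stack per signature component. At each layer, points are pulled
to the tangent space at the **component origin** via the log map, the
canonical propagation $\hat A H W + b$ runs there
($\hat A = D^{-1/2}(A+I)D^{-1/2}$), and the result is pushed back with
the exp map. Curved components use identity activation on tangent
features; Euclidean components use ReLU (hidden layers only). Stack
depth defaults to 2 per component.

Edge scores use a Fermi–Dirac decoder on each component's geodesic
distance, $p_i = 1/(e^{(d_i^2-r_i)/t_i}+1)$ with trainable threshold
$r_i$ and temperature $t_i$, averaged across components — monotone
decreasing in every component distance.

**Embedding slicing.** A flat $n\times 100$ feature matrix feeding a
$k$-component GCN is split into $k$ contiguous slices of
$\lfloor 100/k\rfloor$ dimensions (trailing remainder dropped; a
7-component signature yields 7 slices of 14 with 2 dimensions unused)
and each slice is lifted onto its component via exp at the origin.
Flattening a pretrained product embedding uses tangent coordinates (log
at the origin), so a 100-manifold-dimension embedding flattens to
exactly 100 numbers and the Euclidean case is the identity.

**Training.** Binary cross-entropy on positive edges versus uniformly
sampled non-adjacent pairs (one negative per positive, resampled each
epoch; evaluation negatives fixed per seed). Optimization is Riemannian
Adam: layer weights and decoder parameters are Euclidean and get
standard Adam moments; the input node points (fine-tuned by default, as
they arrive as pretrained initializations) are manifold-valued and get a
tangent-vector first moment with a per-point scalar second moment (the
EMA of the squared Riemannian gradient norm), so the update is a scalar
multiple of a tangent vector, retracted with the exp map, with the first
moment re-projected after each retraction. The scalar second moment is a
deliberate choice: elementwise ambient moments produce non-tangent
updates whose tangent projection is amplified quadratically in the
point's coordinate magnitude far from the hyperboloid origin.

With an all-Euclidean signature every map above is the identity and the
model reduces *exactly* to a plain GCN with a distance decoder; the test
suite verifies this equivalence against an independently written plain
implementation to $10^{-5}$.

## Edge-prediction benchmark

`run_benchmark()` compares four models on one graph: Euclidean GCNs
initialized with node2vec, Laplacian, and distortion-trained Euclidean
embeddings, and the product GCN matched to the sweep's best signature.
95% of edges train, 5% validate; each method sweeps learning rates and
the product GCN additionally sweeps the curvature of its non-Euclidean
components over three values (tripling its configuration count); the
configuration with the highest mean of validation AUROC and AP is
selected. External candidate edges — high-confidence interactions from
an external database, standing in for pre-mapped STRING pairs with
integer scores 0–1000 — are filtered at score ≥ 500, restricted to
pathway nodes, and scored as an out-of-distribution test set against
fresh negatives that never influence selection. Pretrained embeddings
come from the full pathway graph, as in the two-task design where the
distortion task precedes the edge split.

AUROC uses the tie-corrected rank-sum formulation; AP is the area under
the precision–recall step curve over distinct thresholds.

## What the synthetic generators emulate — and what they do not

Generators produce graphs at curated-pathway scale (10–300 nodes) with
controlled geometry: balanced trees (hyperbolic-favored), cycles
(spherical-favored), 2-D grids (Euclidean-competitive), trees of cycles
(mixed), Erdős–Rényi and planted-partition graphs. `make_fixture()`
withholds a fraction of edges as planted "missing interactions" (entering
the candidate table at scores ≥ 800) among distractor non-edges with
scores uniform over 0–1000, so the score filter is exercised on both
sides of its threshold.

These fixtures validate the geometric machinery, not biological realism:
they do not reproduce pathway degree distributions, annotation noise,
database-specific curation biases, or the identifier-mapping ambiguities
of real interaction databases. Passing tests show the method recovers
known geometry and planted structure at pathway scale — not that any
particular biological pathway favors any particular signature.

## Problem sizes and experiment design

The packaged experiments use a depth-4 binary tree (31 nodes), a
20-cycle, a 4×5 grid, and a 60-node two-block planted partition
(within-block edge probability 0.3, between 0.02); embeddings use the
full 100-dimension budget with 1200 training epochs for the geometry
comparisons and 400 for GCN pretraining; the GCN trains 120 epochs over
a 6-configuration grid. Distortion comparisons take the best over the
learning-rate grid per signature, majority over 5 seeds; these are the
scales at which the packaged results and acceptance quantities are
computed.

## Degenerate inputs and edge cases

* Disconnected graphs: shortest-path distances are undefined across
  components, so embedding requires a connected graph;
  `largest_component_subgraph()` restricts with a note. Isolated nodes
  contribute no distance constraints and are dropped on read.
* Antipodal spherical pairs have no log map and raise an error; exactly
  coincident points return zero vectors and zero distances.
* Complete graphs admit no negative samples and raise an error.
* Validation splits keep a minimum of one edge; single-edge graphs are
  rejected.

## Known limitations

* Curvature magnitudes are fixed per configuration and swept, not
  learned.
* The spherical sweep needs user-supplied curvature scales on
  large-diameter graphs (see above); no automatic scale selection is
  attempted.
* Tangent-space message passing at a single basepoint (the origin) is
  the established convention but linearizes the geometry around that
  point; per-node basepoints and attention layers are out of scope.
* node2vec here is a compact reimplementation adequate for
  pathway-scale graphs; it makes no claim of performance parity with
  optimized C implementations on large corpora.
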