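# mcpathway

Mixed-curvature product-manifold embeddings for biological pathway
graphs, with a product-space graph convolutional network for predicting
missing protein–protein interaction edges.

## Why

Pathway graphs (nodes: genes/proteins/metabolites; edges: cellular
relationships) are small but geometrically diverse — signaling cascades
are tree-like, feedback loops are cyclic, complexes are densely
interconnected. Euclidean embeddings cannot represent all of these at
low distortion; constant-curvature spaces can, but which one depends on
the graph. `mcpathway` embeds each graph into a Cartesian product of
spherical, hyperbolic (hyperboloid model), and Euclidean components —
a *signature* such as `H34_1.0 x S33_1.0 x E33` — and selects the
signature of minimum distortion under a fixed total dimension budget
(default 100).

The embedding `f` minimizes the relative squared-distance loss over node
pairs,

$$\mathcal{L}(f)=\sum_{u<v}\Bigl(\tfrac{d_\mathcal{P}(f(u),f(v))^2}{d_G(u,v)^2}-1\Bigr)^2,$$

by Riemannian stochastic gradient descent (tangent projection +
exponential-map retraction), where $d_G$ is the shortest-path distance
and $d_\mathcal{P}^2$ decomposes as the sum of squared component
distances. Embedding quality is the average distortion
$\mathcal{D}=\frac1P\sum_{u\ne v}|d_\mathcal{P}-d_G|/d_G$.

Downstream, a **product GCN** — one tangent-space GCN stack per
signature component, log/exp maps at the component origins, a
Fermi–Dirac decoder $1/(e^{(d^2-r)/t}+1)$ on component distances with
scores averaged across components, trained with Riemannian Adam — is
benchmarked against Euclidean GCNs initialized with node2vec,
graph-Laplacian, and distortion-trained Euclidean embeddings, on
held-out pathway edges (in-distribution) and on external candidate
interactions filtered at confidence score ≥ 500/1000
(out-of-distribution).

## Worked example

Sweep a depth-4 balanced binary tree (31 nodes) over all one- and
two-component signatures at a 20-dimension budget:

```r
library(mcpathway)

g <- generate_synthetic("balanced_tree", branching = 2, depth = 4)
grid <- signature_grid(total_dim = 20, max_components_per_type = 1,
                       lr_choices = c(0.01, 0.1), epochs = 600, seed = 1)
sw <- sweep_and_select(g, grid)
head(sw$results[order(sw$results$distortion), ], 3)
#>         signature learning_rate final_loss distortion   tie
#>       H10_1 x E10          0.01       14.9     0.0715 FALSE
#>             H20_1          0.10       38.1     0.0740 FALSE
#>  H7_1 x S7_1 x E6          0.01       16.7     0.0764 FALSE
sw$best
#> <mc_embed_result> H10_1 x E10  loss 14.93  distortion 0.07148
```

The two lowest-distortion signatures contain hyperbolic components, as
expected for a tree; the best Euclidean-only configuration in the same
sweep reaches distortion 0.097. A scale-optimized spectral baseline is
far worse on this graph:

```r
lap <- laplacian_embed(g)
scaled_distortion(lap, graph_distances(g))
#> $c_star     1.578
#> $distortion 0.561
```

Edge prediction end to end, with a synthetic candidate table standing in
for an external interaction database:

```r
fx <- make_fixture(fixture_spec("planted_partition",
        params = list(n = 60, blocks = 2, p_in = 0.3, p_out = 0.02),
        planted_holdout = 0.1, n_distractors = 60, seed = 1))
bm <- run_benchmark(largest_component_subgraph(fx$graph),
                    candidates = fx$candidates, seed = 1)
bm$report
```

which reports validation and test AUROC/AP for the three Euclidean
baselines and the signature-matched product GCN.

A thin CLI wraps the same functions (`inst/cli/mcpathway`): subcommands
`embed`, `sweep`, `baseline`, `scale-distortion`, `train-gcn`,
`predict-edges`, `make-fixtures`.

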