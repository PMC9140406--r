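# pathlink

Link prediction in bipartite networks from path-induced local structures.

Many interaction datasets in systems biology and beyond are bipartite:
drug–target interactions, protein–ligand binding, club or board membership,
user–item ratings. Observed edge lists are incomplete, and the task is to
score unobserved node pairs for the probability that a link exists.
`pathlink` does this from purely structural evidence: for a candidate pair
(u, v) it enumerates all simple connecting paths of a fixed odd length
between u and v, induces the subgraph on the nodes of those paths (with the
direct u–v edge removed), labels each node of that *local structure* by its
partition type and hop distance to the targets, and scores the labelled
subgraph with a small graph neural network. No node attributes are needed.

## The model

For a pair (u, v) at depth *k*, the local structure G_k(u, v) is the
subgraph induced on all nodes lying on at least one simple u–v path with
2k + 1 edges (the shortest indirect route between partitions has 3 edges).
Each node gets a one-hot feature: partition type (U = 0, V = 1) spliced
with hop distance to the nearer target, capped at *k*, giving dimension
k + 3. Node states h_i are updated by L graph-convolution layers

    h_i^(l+1) = ReLU( h_i^(l) + Σ_{j ∈ N(i)} W^(l) h_j^(l) )

mean-pooled into a fixed-size representation H_ls = mean(h_1, …, h_{n+m}),
and mapped to a score r = sigmoid(w · H_ls) ∈ (0, 1). Training minimises
the mean squared error between scores and 0/1 link indicators with SGD
(lr 1e-2, momentum 0.9, weight decay 1e-5, 80 epochs, batch size 5).
Evaluation follows the standard protocol: withhold 20% of edges as test
positives, sample matched non-edge negatives, report MAE and RMSE. All
structures are extracted from the training graph only, so no test edge
ever leaks into the evidence.

## Worked example

```r
library(pathlink)

# a planted two-block affiliation-style network: 40x40 nodes,
# within-block edge probability 0.25, cross-block 0.02
net <- generate_block_bipartite(block_model_spec())
net
#> Bipartite network: |U| = 40, |V| = 40, 225 edges

res <- run_experiment(net, k = 1, seed = 1, keep_fit = TRUE)
summary(res$fit)
#> Local-structure link prediction model
#>   depth k = 1, 2 layers, hidden dim 32, 80 epochs (seed 312928385)
#>   training pairs: 360 (180 positive); 0 hit the path cap
#>   training MSE 0.2174, MAE 0.4417; score range [0.215, 0.715]
res
#> Link prediction evaluation (k = 1, seed 1)
#>   90 test pairs: RMSE = 0.4844, MAE = 0.4575
head(res$per_pair, 3)
#>   u  v truth     score
#> 1 1 19     1 0.4698332
#> 2 1 33     1 0.5211953
#> 3 1 38     1 0.5211953
```

The RMSE sits below the 0.5 floor of an uninformed constant-0.5 predictor:
the model has learned to push scores of pairs embedded in many connecting
paths (mostly true links) up and of path-free pairs down. Pairs whose local
structure is empty — no indirect connection at all — are scored by a common
low constant, which is all the evidence admits. `depth_sweep()` and
`sparsity_sweep()` repeat the experiment across structure depths and edge
retention rates; `pathlink()` / `predict()` expose the fitted model directly.

Real edge lists in KONECT-style TSV are read with
`read_edge_list("out.file", format = "konect")` and evaluated identically.
A command-line interface wraps the same functions:

```sh
Rscript inst/cli/pathlink.R evaluate --simulate block --seed 7 --out results/
Rscript inst/cli/pathlink.R sweep depth --input mynet.tsv --ks 1,2,3 --seeds 1,2,3 --out results/
```

## Vignette

`vignettes/local-structure-link-prediction.Rmd` documents the method, its
assumptions, the parameter choices, what the synthetic generator does and
does not emulate, and known limitations.
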