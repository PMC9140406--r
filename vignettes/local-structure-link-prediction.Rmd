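---
title: "Link prediction from path-induced local structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link prediction from path-induced local structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A bipartite network records interactions between two node classes — drugs
and targets, members and clubs, users and items. Given the observed edge
list alone, we want a score in (0, 1) for any candidate pair (u, v)
estimating whether a link exists. `pathlink` scores a pair from its *local
structure*: the subgraph induced on every node that lies on at least one
simple connecting path between u and v. The intuition is that a genuine
link is usually embedded in a dense web of short indirect routes
(co-membership, shared neighbours of neighbours), while a non-link is not.

The pipeline has four stages, each exposed as a documented function:

1. **Extraction** (`extract_local_structure`). All simple u–v paths of a
   fixed odd length are enumerated by depth-first search; the direct u–v
   edge is never traversed. The nodes of those paths induce the structure;
   the target edge is removed from it and its existence kept aside as the
   training label, so the structure itself is label-free. Pairs without
   any connecting path yield the two-node, zero-edge structure — negatives
   in sparse networks must still receive a score, so this degenerate case
   is an ordinary input, not an error.
2. **Labeling** (`assign_type_labels`, `assign_hop_labels`,
   `encode_features`). Real node attributes are typically unavailable, so
   nodes are labelled structurally: partition type (U = 0, V = 1) and hop
   distance, within the structure, to the nearer of the two targets
   (targets get 0). Both labels are one-hot encoded and spliced, giving a
   fixed dimension k + 3.
3. **Encoding** (`gcn_layer`, `encode_structure`). Node states are
   projected into a hidden space and updated by L rounds of
   `h_i <- relu(h_i + sum_j W h_j)` over the structure's adjacency. The
   self term is unweighted, which requires all layers to share one hidden
   dimension; a separate linear input projection maps the one-hot features
   into that space. Mean pooling over all nodes gives a fixed-size
   representation regardless of structure size, and makes the score
   exactly invariant to node relabelling.
4. **Scoring and training** (`predict_link`, `pathlink_train`,
   `pathlink`). A single readout vector and a sigmoid map the
   representation to a score; training minimises mean squared error
   against 0/1 link indicators with SGD (momentum 0.9, weight decay 1e-5,
   learning rate 1e-2, 80 epochs, batches of 5 structures, gradients
   averaged within a batch). The sigmoid is chosen so scores are directly
   comparable to the 0/1 labels under MSE and under the MAE/RMSE
   evaluation metrics; with all weights zero every score is exactly 0.5,
   which the tests use as a calibration point.

## The depth parameter

The one modelling parameter a user must choose is the depth `k`. In a
bipartite graph a U-to-V path has odd length, and the shortest *indirect*
route has 3 edges; a literal 1-edge "path" between the targets would be the
removed target edge itself and carries no information. `k` therefore
indexes odd connecting-path lengths: depth k uses paths of exactly 2k + 1
edges, so k = 1 captures the 3-edge routes, k = 2 the 5-edge routes, and
so on. For users who want the literal reading — paths of exactly k edges —
`literal_hops = TRUE` provides it (k must then be odd). Hop labels on a
(2k+1)-edge path never exceed k, which fixes the feature dimension.

Path counts grow exponentially in dense graphs, so enumeration stops at a
configurable cap (`path_cap`, default 10,000 paths per pair) and flags the
truncation; the desk-scale networks this package targets (tens to hundreds
of nodes per side, hundreds of edges) rarely hit it below k = 3. The
enumeration is exact below the cap, and is pruned with exact BFS distances
to the far target so its cost is proportional to the number of qualifying
paths, not to the number of dead-end prefixes.

## Evaluation protocol

`run_experiment` implements the standard split protocol: 20% of edges
(rounding half away from zero) become test positives, an equal number of
non-edge pairs are sampled uniformly as test negatives, and the remaining
80% of edges plus an equally sized negative sample form the training set.
Negatives are drawn once per split, not resampled per epoch, and are
pairwise distinct across train and test. Two choices deserve emphasis:

* **Leak-freedom.** Every structure — training and test — is extracted
  from the *training* graph, i.e. the observed network with test edges
  removed. Extracting test structures from the full graph would let the
  withheld edges serve as evidence for themselves through 3-edge paths.
  The price is a thinner evidence graph: roughly a quarter of the
  candidate pairs at k = 1 have no connecting path at all after the 20%
  removal, and their structures are information-free.
* **Regression metrics.** MAE and RMSE compare sigmoid scores directly to
  the 0/1 indicators without thresholding. An uninformed constant-0.5
  predictor scores RMSE exactly 0.5 on a balanced test set, which is the
  natural floor to beat; RMSE ≥ MAE always (power-mean inequality).

`depth_sweep` and `sparsity_sweep` wrap this experiment across structure
depths and across edge-retention fractions (`subsample_links` keeps the
node sets, so isolated nodes remain part of the network).

## The synthetic generator

`generate_block_bipartite` draws a two-sided stochastic block model: U and
V nodes carry block labels, matched-block pairs are edges with probability
`p_in`, all others with `p_out`. The defaults — 40×40 nodes, two blocks
per side, p_in = 0.25, p_out = 0.02, about 216 edges, mean degree ≈ 5 —
emulate the small dense affiliation-style networks (club and board
memberships, corporate interlocks) this method is aimed at. A matched-block
pair is embedded in many 3-edge connecting paths; a cross-block pair in
few or none, so the local structure carries a genuine, learnable link
signal. This is the minimal generator with that property, and it is what
all trend and recovery tests run on.

What the generator does *not* emulate: degree heterogeneity (real
affiliation data are heavy-tailed), triadic or community closure beyond the
two planted blocks, and any dependence between an edge and the rest of the
graph given the blocks. The last point matters for interpreting results:
in a block model, conditional on the block labels, the presence of a
specific edge is independent of every other edge, so the local structure
can reveal *block membership* but nothing more. Test error on this
generator is therefore bounded away from zero no matter the model
capacity: empty structures are a mixture of unlucky within-block pairs and
cross-block pairs, and within-block positives and negatives are
structurally indistinguishable. Passing the recovery tests shows the
pipeline extracts and uses the available structural signal, not that it
would reach any particular error on real data. A related consequence,
visible in the depth sweep, is that on this generator *deeper* structures
(k = 3) score better than k = 1: longer paths nearly always reveal the
block, whereas at k = 1 many pairs have no path and hence no evidence. On
real dense affiliation data, where short paths are abundant and long paths
mix communities, shallow structures are typically the best choice.

## Numerical and design choices

* **Rounding.** Split and subsample sizes round half away from zero;
  the remainder stays in training.
* **Initialisation.** Glorot-uniform per matrix, drawn from the run seed;
  `init = "zero"` gives the exact constant-0.5 model for calibration.
* **Optimiser convention.** Velocity `v <- momentum*v + g + wd*theta`,
  update `theta <- theta - lr*v` (the convention of the major deep
  learning frameworks), so weight decay participates in momentum.
* **Batching.** Structures vary in size, so batches accumulate per-graph
  gradients and average them; no padding is involved.
* **Seeding.** A single seed fans out to sub-seeds for the split, the
  negative draw, initialisation and shuffling, so any stage can be
  reproduced in isolation; every CLI run logs its resolved configuration
  and is byte-reproducible from it.
* **Degenerate inputs.** Complete bipartite graphs have no negatives to
  sample (an error naming the available count); pairs with no path yield
  the two-node structure; isolated nodes survive subsampling; a node
  unreachable from both targets would receive the sentinel hop k + 1,
  which folds into the cap during encoding.
* **Problem sizes.** The shipped tests and the acceptance script run on
  the default 40×40 generator with 3 replicate splits per condition and
  depths k ∈ {1, 3}; one split-train-evaluate cycle takes a few seconds
  on one core.

## Known limitations

* Exact path enumeration is exponential in the worst case; the cap makes
  cost predictable but truncates the node set in very dense graphs at
  k ≥ 3 (the structure then under-reports, never over-reports, evidence).
* One weight matrix per layer is shared across all neighbours. A
  type-dependent variant (one matrix per neighbour partition) is a
  natural extension and deliberately not implemented.
* Scores are calibrated only in-distribution: training negatives are
  uniform non-edges, so heavily non-uniform test negatives (e.g.
  degree-matched) would shift calibration.
* Weighted, temporal and multigraph edges are out of scope; edges are
  binary and static.
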