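#' Planted-block bipartite network specification
#'
#' Describes a two-sided stochastic block model: every U x V pair whose block
#' assignments match is an edge with probability `p_in`, every other pair
#' with probability `p_out`. With `p_in > p_out` matched-block pairs are
#' embedded in many short connecting paths, giving the local structure a
#' genuine, learnable link signal. Defaults emulate a small dense
#' affiliation-style network: 40 x 40 nodes in two matched blocks with
#' `p_in = 0.25`, `p_out = 0.02` (expected 216 edges, mean degree about 5.4).
#'
#' @param n_u,n_v Partition sizes.
#' @param blocks_u,blocks_v Integer block assignment per node; both sides
#'   must use the same set of block ids.
#' @param p_in Edge probability for matched-block pairs.
#' @param p_out Edge probability otherwise; `0 <= p_out <= p_in <= 1`.
#' @param seed Integer seed used by [generate_block_bipartite()].
#' @return An object of class `block_model_spec`.
#' @export
block_model_spec <- function(n_u = 40L, n_v = 40L,
                             blocks_u = rep(1:2, each = ceiling(n_u / 2))[seq_len(n_u)],
                             blocks_v = rep(1:2, each = ceiling(n_v / 2))[seq_len(n_v)],
                             p_in = 0.25, p_out = 0.02, seed = 1L) {
  stopifnot(n_u >= 1, n_v >= 1)
  if (length(blocks_u) != n_u || length(blocks_v) != n_v)
    stop("block assignments must cover all nodes")
  if (!is.numeric(p_in) || !is.numeric(p_out) ||
      p_out < 0 || p_in > 1 || p_out > p_in)
    stop("need 0 <= p_out <= p_in <= 1")
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 blocks_u = as.integer(blocks_u),
                 blocks_v = as.integer(blocks_v),
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "block_model_spec")
}

#' Generate a planted-block bipartite network
#'
#' Draws each U x V pair independently as an edge with probability `p_in`
#' when the pair's blocks match and `p_out` otherwise. Deterministic for a
#' fixed spec (the spec carries the seed).
#'
#' @param spec A [block_model_spec()].
#' @return A [bipartite_network] with `n_u`/`n_v` nodes (isolated nodes
#'   retained).
#' @examples
#' net <- generate_block_bipartite(block_model_spec(seed = 7))
#' net
#' @export
generate_block_bipartite <- function(spec = block_model_spec()) {
  stopifnot(inherits(spec, "block_model_spec"))
  probs <- ifelse(outer(spec$blocks_u, spec$blocks_v, `==`),
                  spec$p_in, spec$p_out)
  draw <- withr::with_seed(spec$seed,
                           matrix(stats::runif(length(probs)),
                                  spec$n_u, spec$n_v) < probs)
  idx <- which(draw, arr.ind = TRUE)
  bipartite_network(idx, n_u = spec$n_u, n_v = spec$n_v)
}

#' Worked-example fixture: the 4-node path network
#'
#' Returns the bipartite path u1 - v1 - u2 - v2 together with hand-computed
#' expectations for the pair (u1, v2) at depth k = 1: its single connecting
#' 3-edge path, the local structure (all 4 nodes, 3 induced edges, label 0),
#' hop labels and the one-hot feature matrix. Used across the package tests
#' as a fully traceable example.
#'
#' @return List with `network`, `pair`, `k`, and expected `path`,
#'   `u_nodes`, `v_nodes`, `n_edges`, `label`, `hop_labels`, `type_labels`,
#'   `features`.
#' @export
toy_fixture <- function() {
  net <- bipartite_network(cbind(c(1L, 2L, 2L), c(1L, 1L, 2L)))
  # canonical node order: u1, u2, v1, v2
  list(network = net,
       pair = c(u = 1L, v = 2L),
       k = 1L,
       path = c(1L, 3L, 2L, 4L),      # combined indexing: u1, v1, u2, v2
       u_nodes = c(1L, 2L), v_nodes = c(1L, 2L),
       n_edges = 3L, label = 0L,
       type_labels = c(0L, 0L, 1L, 1L),
       hop_labels = c(0L, 1L, 1L, 0L),
       features = rbind(c(1, 0, 1, 0),    # u1: type 0, hop 0
                        c(1, 0, 0, 1),    # u2: type 0, hop 1
                        c(0, 1, 0, 1),    # v1: type 1, hop 1
                        c(0, 1, 1, 0)))   # v2: type 1, hop 0
}
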