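# Shared helpers: random bipartite graphs and the igraph path oracle.

# Erdos-Renyi bipartite graph with at least `min_edges` edges
random_bipartite <- function(n_u, n_v, p, min_edges = 1L) {
  repeat {
    em <- matrix(stats::runif(n_u * n_v) < p, n_u, n_v)
    if (sum(em) >= min_edges) break
  }
  bipartite_network(which(em, arr.ind = TRUE), n_u = n_u, n_v = n_v)
}

# igraph object in combined indexing (U: 1..n_u, V: n_u+1..n_u+n_v)
as_igraph <- function(net) {
  g <- igraph::graph_from_edgelist(
    cbind(net$edges[, 1L], net$n_u + net$edges[, 2L]), directed = FALSE)
  extra <- net$n_u + net$n_v - igraph::vcount(g)
  if (extra > 0) g <- igraph::add_vertices(g, extra)
  g
}

drop_direct_edge <- function(g, a, b) {
  eid <- igraph::get_edge_ids(g, c(a, b))
  if (eid > 0) igraph::delete_edges(g, eid) else g
}

# independent oracle: all simple u-v paths with exactly `len` edges, with the
# direct u-v edge deleted first; returns sorted signature strings
oracle_paths <- function(net, u, v, len) {
  g <- drop_direct_edge(as_igraph(net), u, net$n_u + v)
  ap <- igraph::all_simple_paths(g, from = u, to = net$n_u + v, cutoff = len)
  ap <- Filter(function(p) length(p) == len + 1L, ap)
  sort(vapply(ap, function(p) paste(as.integer(p), collapse = "-"), ""))
}

# node set the oracle implies for a local structure (combined indexing)
oracle_structure_nodes <- function(net, u, v, len) {
  g <- drop_direct_edge(as_igraph(net), u, net$n_u + v)
  ap <- igraph::all_simple_paths(g, from = u, to = net$n_u + v, cutoff = len)
  ap <- Filter(function(p) length(p) == len + 1L, ap)
  sort(unique(c(u, net$n_u + v, unlist(lapply(ap, as.integer)))))
}

combined_nodes <- function(ls, n_u) sort(c(ls$u_nodes, n_u + ls$v_nodes))

# pure-R forward pass used as the hand-rolled oracle for the C++ kernels
r_forward_score <- function(X, A, params) {
  H <- X %*% params$P
  for (W in params$W) H <- pmax(H + A %*% H %*% W, 0)
  g <- colMeans(H)
  1 / (1 + exp(-sum(g * params$w)))
}
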