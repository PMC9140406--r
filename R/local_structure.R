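#' Enumerate connecting simple paths between a candidate pair
#'
#' Finds every simple path with exactly `length` edges from U-node `u` to
#' V-node `v` by depth-first search. The direct edge between `u` and `v`, if
#' present, is never traversed, so positive and negative candidate pairs are
#' treated identically. In a bipartite graph a U-to-V path must have an odd
#' number of edges, so even `length` is rejected.
#'
#' @param net A [bipartite_network].
#' @param u,v Target pair: U-partition index and V-partition index.
#' @param length Exact number of edges in each path (odd positive integer).
#' @param path_cap Maximum number of paths to enumerate before giving up
#'   (the enumeration is exact below the cap). Default 10000.
#' @param warn_cap Emit a warning when the cap truncates the enumeration.
#' @return List of integer vectors in combined indexing (U node i is `i`,
#'   V node j is `n_u + j`); each starts at `u` and ends at `v`. Attribute
#'   `capped` records whether the cap was hit.
#' @examples
#' net <- bipartite_network(cbind(c(1, 2, 2), c(1, 1, 2)))
#' enumerate_connecting_paths(net, u = 1, v = 2, length = 3)
#' @export
enumerate_connecting_paths <- function(net, u, v, length, path_cap = 10000L,
                                       warn_cap = TRUE) {
  stopifnot(inherits(net, "bipartite_network"))
  .check_pair(net, u, v)
  if (length %% 2 == 0)
    stop("no U-to-V path of even length exists in a bipartite graph")
  if (length < 1) stop("`length` must be a positive odd integer")
  res <- .cpp_connecting_paths(.adjacency(net), as.integer(u),
                               net$n_u + as.integer(v),
                               as.integer(length), as.integer(path_cap))
  if (res$capped && warn_cap)
    warning(sprintf("path cap %d reached for pair (%d, %d); enumeration truncated",
                    path_cap, u, v), call. = FALSE)
  structure(res$paths, capped = res$capped)
}

.check_pair <- function(net, u, v) {
  if (!is.numeric(u) || length(u) != 1L || u < 1 || u > net$n_u)
    stop("`u` is not a U-partition node of the network")
  if (!is.numeric(v) || length(v) != 1L || v < 1 || v > net$n_v)
    stop("`v` is not a V-partition node of the network")
}

#' Extract the local structure around a candidate pair
#'
#' The local structure of a pair (u, v) at depth `k` is the subgraph of the
#' network induced on all nodes lying on at least one connecting simple path
#' between u and v, with the direct u-v edge removed. Whether that edge
#' existed is carried separately as the structure's label, so the structure
#' itself contains no trace of it. Pairs with no connecting path yield the
#' two-node, zero-edge structure.
#'
#' By default depth `k` maps to connecting paths of `2k + 1` edges: the
#' shortest indirect route between opposite partitions has 3 edges, so k = 1
#' captures it, k = 2 adds 5-edge paths, and so on. `literal_hops = TRUE`
#' instead uses paths of exactly `k` edges (`k` must then be odd).
#'
#' @param net A [bipartite_network].
#' @param u,v Target pair (U index, V index).
#' @param k Depth parameter, a positive integer.
#' @param literal_hops If `TRUE`, connecting paths have `k` edges instead of
#'   `2k + 1`.
#' @param path_cap,warn_cap Passed to [enumerate_connecting_paths()].
#' @return An object of class `local_structure`: `target_u`, `target_v`,
#'   `u_nodes`, `v_nodes` (sorted network indices, targets always included),
#'   `edges` (induced edges in network indexing, target edge absent), `k`,
#'   `path_length`, `label` (1 if the u-v edge exists in `net`, else 0),
#'   `n_paths` and `capped`.
#' @export
extract_local_structure <- function(net, u, v, k, literal_hops = FALSE,
                                    path_cap = 10000L, warn_cap = TRUE) {
  stopifnot(inherits(net, "bipartite_network"))
  .check_pair(net, u, v)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != as.integer(k))
    stop("`k` must be a positive integer")
  L <- if (literal_hops) as.integer(k) else 2L * as.integer(k) + 1L
  paths <- enumerate_connecting_paths(net, u, v, L, path_cap = path_cap,
                                      warn_cap = warn_cap)
  .structure_from_paths(net, u, v, k, L, paths)
}

.structure_from_paths <- function(net, u, v, k, L, paths) {
  u <- as.integer(u); v <- as.integer(v)
  combined <- sort(unique(c(u, net$n_u + v, unlist(paths))))
  u_nodes <- combined[combined <= net$n_u]
  v_nodes <- combined[combined > net$n_u] - net$n_u
  in_u <- net$edges[, 1L] %in% u_nodes
  in_v <- net$edges[, 2L] %in% v_nodes
  edges <- net$edges[in_u & in_v, , drop = FALSE]
  label <- as.integer(.has_edge(net, u, v))
  is_target <- edges[, 1L] == u & edges[, 2L] == v
  edges <- edges[!is_target, , drop = FALSE]
  structure(list(target_u = u, target_v = v,
                 u_nodes = u_nodes, v_nodes = v_nodes,
                 edges = edges, k = as.integer(k), path_length = L,
                 label = label, n_paths = length(paths),
                 capped = isTRUE(attr(paths, "capped"))),
            class = "local_structure")
}

#' @export
print.local_structure <- function(x, ...) {
  cat(sprintf(
    "Local structure of pair (u%d, v%d), k = %d (paths of %d edges)\n",
    x$target_u, x$target_v, x$k, x$path_length))
  cat(sprintf("  %d U-nodes, %d V-nodes, %d edges, %d connecting paths%s, label = %d\n",
              length(x$u_nodes), length(x$v_nodes), nrow(x$edges),
              x$n_paths, if (x$capped) " (capped)" else "", x$label))
  invisible(x)
}

# canonical node order of a structure: U nodes then V nodes, each ascending,
# in combined indexing relative to the parent network is not needed --
# structures are self-contained once extracted.
.structure_nodes <- function(ls) {
  list(u = ls$u_nodes, v = ls$v_nodes)
}

# adjacency matrix of the structure in canonical node order
.structure_adjacency <- function(ls) {
  n <- length(ls$u_nodes) + length(ls$v_nodes)
  A <- matrix(0, n, n)
  if (nrow(ls$edges) > 0L) {
    i <- match(ls$edges[, 1L], ls$u_nodes)
    j <- length(ls$u_nodes) + match(ls$edges[, 2L], ls$v_nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Serialize a local structure to JSON
#'
#' Writes the targets, depth, node sets, edges and label as a compact JSON
#' record for caching or inspection; [local_structure_from_json()] inverts it.
#'
#' @param ls A `local_structure`.
#' @return A JSON string.
#' @export
local_structure_json <- function(ls) {
  stopifnot(inherits(ls, "local_structure"))
  rec <- list(target_u = ls$target_u, target_v = ls$target_v,
              k = ls$k, path_length = ls$path_length,
              u_nodes = ls$u_nodes, v_nodes = ls$v_nodes,
              edges_u = ls$edges[, 1L], edges_v = ls$edges[, 2L],
              label = ls$label, n_paths = ls$n_paths, capped = ls$capped)
  as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}

#' @rdname local_structure_json
#' @param json A JSON string produced by `local_structure_json()`.
#' @export
local_structure_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  edges <- cbind(u = as.integer(unlist(rec$edges_u)),
                 v = as.integer(unlist(rec$edges_v)))
  structure(list(target_u = as.integer(rec$target_u),
                 target_v = as.integer(rec$target_v),
                 u_nodes = as.integer(rec$u_nodes),
                 v_nodes = as.integer(rec$v_nodes),
                 edges = edges, k = as.integer(rec$k),
                 path_length = as.integer(rec$path_length),
                 label = as.integer(rec$label),
                 n_paths = as.integer(rec$n_paths),
                 capped = isTRUE(rec$capped)),
            class = "local_structure")
}
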