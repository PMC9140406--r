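#' Node type labels of a local structure
#'
#' U-partition nodes are labelled 0, V-partition nodes 1, in the structure's
#' canonical node order (U nodes ascending, then V nodes ascending).
#'
#' @param ls A `local_structure`.
#' @return Integer vector of 0/1 type labels, one per node.
#' @export
assign_type_labels <- function(ls) {
  stopifnot(inherits(ls, "local_structure"))
  c(rep(0L, length(ls$u_nodes)), rep(1L, length(ls$v_nodes)))
}

# BFS hop distances from a start node over the structure adjacency list;
# unreachable nodes get NA
.bfs_hops <- function(adj, start) {
  n <- length(adj)
  d <- rep(NA_integer_, n)
  d[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- d[frontier[1L]] + 1L
    frontier <- nxt
  }
  d
}

#' Hop labels of a local structure
#'
#' Each node is labelled with its shortest-path hop distance, within the
#' structure (target edge absent), to the nearer of the two target nodes.
#' The targets themselves are labelled 0; a node unreachable from both
#' targets (impossible for structures built by [extract_local_structure()],
#' but tolerated) receives the sentinel `k + 1`.
#'
#' @param ls A `local_structure`.
#' @return Integer vector of hop labels in canonical node order.
#' @export
assign_hop_labels <- function(ls) {
  stopifnot(inherits(ls, "local_structure"))
  nu <- length(ls$u_nodes)
  n <- nu + length(ls$v_nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(ls$edges) > 0L) {
    i <- match(ls$edges[, 1L], ls$u_nodes)
    j <- nu + match(ls$edges[, 2L], ls$v_nodes)
    for (r in seq_along(i)) {
      adj[[i[r]]] <- c(adj[[i[r]]], j[r])
      adj[[j[r]]] <- c(adj[[j[r]]], i[r])
    }
  }
  tu <- match(ls$target_u, ls$u_nodes)
  tv <- nu + match(ls$target_v, ls$v_nodes)
  d <- pmin(.bfs_hops(adj, tu), .bfs_hops(adj, tv), na.rm = TRUE)
  d[is.na(d)] <- ls$k + 1L
  as.integer(d)
}

#' One-hot node feature encoding
#'
#' Splices a 2-slot one-hot encoding of the node type with a `(k + 1)`-slot
#' one-hot encoding of the hop label capped at `k`, giving feature vectors of
#' fixed dimension `k + 3` regardless of the structure they come from.
#'
#' @param type_labels Integer vector of 0/1 type labels.
#' @param hop_labels Integer vector of non-negative hop labels (the sentinel
#'   `k + 1` folds into the cap).
#' @param k Depth parameter, a positive integer.
#' @return Numeric matrix with one row per node and `k + 3` columns; every
#'   row has exactly two entries equal to 1.
#' @examples
#' encode_features(c(0L, 1L), c(0L, 1L), k = 1)
#' @export
encode_features <- function(type_labels, hop_labels, k) {
  if (length(type_labels) != length(hop_labels))
    stop("type and hop label vectors differ in length")
  if (any(type_labels < 0) || any(hop_labels < 0))
    stop("labels must be non-negative")
  if (!all(type_labels %in% c(0L, 1L)))
    stop("type labels must be 0 or 1")
  k <- as.integer(k)
  if (k < 1) stop("`k` must be a positive integer")
  n <- length(type_labels)
  X <- matrix(0, n, 2L + k + 1L)
  X[cbind(seq_len(n), type_labels + 1L)] <- 1
  X[cbind(seq_len(n), 2L + pmin(hop_labels, k) + 1L)] <- 1
  X
}

#' Feature matrix of a local structure
#'
#' Convenience wrapper: type labels, hop labels, one-hot encoding.
#'
#' @param ls A `local_structure`.
#' @return Numeric matrix, one row per node in canonical order, `k + 3`
#'   columns.
#' @export
node_features <- function(ls) {
  encode_features(assign_type_labels(ls), assign_hop_labels(ls), ls$k)
}
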