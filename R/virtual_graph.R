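#' Augment a sparse PLV graph with local and global virtual nodes
#'
#' The functional-connectivity graph over `n` real electrode nodes is fused
#' with the montage's spatial structure by adding one local virtual node per
#' electrode group and a single global virtual node. Each real node connects
#' to exactly its group's local virtual node, and each local virtual node
#' connects to the global one; there are no real-global or local-local edges.
#' With the default 64-channel montage and 8 groups the augmented adjacency
#' is 73 x 73.
#'
#' Node order is fixed and reproducible: real channels first (montage order),
#' then local virtual nodes by group id, then the global virtual node.
#'
#' @param sparse a `vnfc_sparse_plv` (or symmetric non-negative matrix with
#'   zero diagonal) over the real channels.
#' @param groups a `vnfc_groups` assignment covering those channels.
#' @param w_virtual weight given to every virtual edge (default 1, comparable
#'   to the PLV scale).
#' @return A `vnfc_graph`: list with `adjacency` (m x m), `roles`
#'   (`"real"`/`"local_virtual"`/`"global_virtual"` per node), `group_of`
#'   (per real channel), `n`, `g` (nonempty groups), `m = n + g + 1`.
#' @export
build_augmented_graph <- function(sparse, groups, w_virtual = 1.0) {
  A0 <- unclass(sparse)
  n <- nrow(A0)
  if (length(groups) != n) {
    rlang::abort(sprintf("group scheme covers %d channels but PLV has %d",
                         length(groups), n))
  }
  if (w_virtual <= 0) rlang::abort("w_virtual must be positive")
  gids <- sort(unique(unclass(groups)))   # empty groups simply absent
  g <- length(gids)
  m <- n + g + 1L
  A <- matrix(0, m, m)
  A[1:n, 1:n] <- A0
  local_idx <- stats::setNames(n + seq_len(g), gids)
  for (i in seq_len(n)) {
    li <- local_idx[[as.character(groups[i])]]
    A[i, li] <- A[li, i] <- w_virtual
  }
  glob <- m
  for (li in local_idx) A[li, glob] <- A[glob, li] <- w_virtual
  labs_ <- c(rownames(A0) %||% paste0("ch", seq_len(n)),
             paste0("VL", gids), "VG")
  dimnames(A) <- list(labs_, labs_)
  structure(list(adjacency = A,
                 roles = c(rep("real", n), rep("local_virtual", g), "global_virtual"),
                 group_of = as.integer(groups), group_ids = gids,
                 n = n, g = g, m = m),
            class = "vnfc_graph")
}

#' @export
print.vnfc_graph <- function(x, ...) {
  cat(sprintf("<vnfc_graph: %d nodes (%d real + %d local virtual + 1 global)>\n",
              x$m, x$n, x$g))
  invisible(x)
}

#' All-ones node-feature matrix
#'
#' The classifier looks only at connection patterns, so node features carry
#' no signal of their own: every node gets the constant feature vector 1.
#'
#' @param m number of nodes.
#' @param feature_dim feature dimension N (default 32, the width that matches
#'   the first graph-convolution layer).
#' @return An `m x feature_dim` matrix of ones.
#' @export
make_node_features <- function(m, feature_dim = 32) {
  if (m < 1 || feature_dim < 1) rlang::abort("m and feature_dim must be >= 1")
  matrix(1, m, feature_dim)
}

#' Augmented graph restricted to a channel layout
#'
#' Used by the ablation protocols: the sparse PLV block is sliced to the kept
#' channels, the group assignment is restricted, and any group left with no
#' channels is dropped (its local virtual node disappears), so the augmented
#' graph stays connected.
#'
#' @param sparse sparse PLV over the full channel set.
#' @param groups full `vnfc_groups` assignment.
#' @param layout a `vnfc_layout` of kept channels.
#' @param w_virtual virtual edge weight.
#' @return A `vnfc_graph` over the kept channels.
#' @export
subgraph_for_layout <- function(sparse, groups, layout, w_virtual = 1.0) {
  stopifnot(inherits(layout, "vnfc_layout"))
  if (length(layout$kept) == 0) rlang::abort("empty layout")
  kept <- layout$kept
  sub <- unclass(sparse)[kept, kept, drop = FALSE]
  sub_groups <- structure(unclass(groups)[kept],
                          g = attr(groups, "g"), class = "vnfc_groups")
  build_augmented_graph(sub, sub_groups, w_virtual)
}
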