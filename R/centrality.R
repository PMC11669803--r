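#' Expected influence and bridge expected influence
#'
#' For a directed cross-lagged network, a node's out expected influence
#' (out-EI) is the sum of the absolute values of all edges coming from the
#' node, and its in expected influence (in-EI) the sum of absolute values of
#' all edges pointing to it. Bridge variants restrict the sums to edges
#' connecting the node to nodes of *other* constructs. Autoregressive
#' (diagonal) effects are always removed. A signed (non-absolute) mode is
#' available for sensitivity but absolute sums are the default, matching the
#' usual EI definition.
#'
#' @param net a `clpn` object or a bare 24 x 24 weight matrix.
#' @param node node label (or index).
#' @param signed if `TRUE`, sum raw weights instead of absolute values.
#' @return a single centrality value.
#' @name expected_influence
NULL

clpn_weight_matrix <- function(net) {
  W <- if (inherits(net, "clpn")) net$W else as.matrix(net)
  info <- clpn_node_info()
  if (!all(dim(W) == nrow(info)))
    fail("expected a %d x %d weight matrix", nrow(info), nrow(info))
  if (is.null(dimnames(W))) dimnames(W) <- list(info$node, info$node)
  W
}

node_index <- function(node, info) {
  j <- if (is.character(node)) match(node, info$node) else as.integer(node)
  if (is.na(j) || j < 1 || j > nrow(info))
    fail("unknown node: %s", as.character(node))
  j
}

#' @rdname expected_influence
#' @export
in_ei <- function(net, node, signed = FALSE) {
  W <- clpn_weight_matrix(net)
  info <- clpn_node_info()
  j <- node_index(node, info)
  v <- W[-j, j]
  if (signed) sum(v) else sum(abs(v))
}

#' @rdname expected_influence
#' @export
out_ei <- function(net, node, signed = FALSE) {
  W <- clpn_weight_matrix(net)
  info <- clpn_node_info()
  i <- node_index(node, info)
  v <- W[i, -i]
  if (signed) sum(v) else sum(abs(v))
}

#' @rdname expected_influence
#' @param direction `"in"` (edges from other constructs into the node) or
#'   `"out"` (edges from the node into other constructs).
#' @export
bridge_ei <- function(net, node, direction = c("in", "out"), signed = FALSE) {
  direction <- match.arg(direction)
  W <- clpn_weight_matrix(net)
  info <- clpn_node_info()
  k <- node_index(node, info)
  if (is.na(info$construct[k]) || !nzchar(info$construct[k]))
    fail("node '%s' has no construct label", info$node[k])
  other <- which(info$construct != info$construct[k])
  other <- setdiff(other, k)  # diagonal never included
  v <- if (direction == "in") W[other, k] else W[k, other]
  if (signed) sum(v) else sum(abs(v))
}

#' Centrality table for all nodes
#'
#' Computes in-EI, out-EI, bridge in-EI and bridge out-EI for every node on
#' the weight matrix with the diagonal (autoregressive effects) zeroed.
#'
#' @inheritParams expected_influence
#' @return data.frame of class `clpn_centrality`: `node`, `construct`,
#'   `in_ei`, `out_ei`, `bridge_in_ei`, `bridge_out_ei`; attribute
#'   `autoregressive_removed = TRUE`.
#' @export
#' @examples
#' W <- matrix(0, 24, 24); W[1, 4] <- 0.5  # PI -> PHQ1
#' centrality_table(W)[1, ]
centrality_table <- function(net, signed = FALSE) {
  W <- clpn_weight_matrix(net)
  info <- clpn_node_info()
  V <- if (signed) W else abs(W)
  diag(V) <- 0
  cross <- outer(info$construct, info$construct, "!=")  # between-construct mask
  out <- info
  out$in_ei <- unname(colSums(V))
  out$out_ei <- unname(rowSums(V))
  out$bridge_in_ei <- unname(colSums(V * cross))
  out$bridge_out_ei <- unname(rowSums(V * cross))
  rownames(out) <- NULL
  structure(out, autoregressive_removed = TRUE,
            class = c("clpn_centrality", "data.frame"))
}

centrality_indices <- function() {
  c("in_ei", "out_ei", "bridge_in_ei", "bridge_out_ei")
}
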