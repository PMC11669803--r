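#' Correlation between two networks' edge-weight matrices
#'
#' Pearson correlation (with the standard correlation-test p-value) over the
#' vectorized off-diagonal cells of the two weight matrices. The diagonal
#' (autoregressive effects) is excluded by default, consistent with their
#' removal from all between-network comparisons; set
#' `include_diagonal = TRUE` to keep it. Symmetric in its arguments.
#'
#' @param net_a,net_b `clpn` objects or bare weight matrices over the same
#'   node set and ordering.
#' @param include_diagonal include autoregressive cells (default `FALSE`).
#' @return list with `r` and `p`.
#' @export
matrix_correlation <- function(net_a, net_b, include_diagonal = FALSE) {
  A <- clpn_weight_matrix(net_a); B <- clpn_weight_matrix(net_b)
  if (!identical(colnames(A), colnames(B))) {
    diffs <- union(setdiff(colnames(A), colnames(B)),
                   setdiff(colnames(B), colnames(A)))
    fail("matrix_correlation: node sets differ: %s",
         paste(diffs, collapse = ", "))
  }
  keep <- if (include_diagonal) rep(TRUE, length(A)) else row(A) != col(A)
  ct <- cor.test(A[keep], B[keep])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Proportion of one network's edges replicated in another
#'
#' An edge of the reference network (a nonzero off-diagonal entry) counts as
#' replicated when the corresponding entry of the other network is nonzero
#' *with the same sign*; `same_sign = FALSE` relaxes this to mere
#' nonzero-ness. The measure is intentionally asymmetric: it is a property
#' of the reference network's edge set. Edges are taken from the estimated
#' (post-LASSO) matrices; `threshold` can impose the display cut for
#' sensitivity analysis.
#'
#' @param reference,other `clpn` objects or weight matrices, same node set.
#' @param same_sign require matching sign (default `TRUE`).
#' @param threshold minimum absolute weight for an entry to count as an edge
#'   (default 0, i.e. any nonzero entry).
#' @return list with `proportion`, `replicated`, `total`, and `flags`
#'   (names any undefined quantity).
#' @export
edge_replication_proportion <- function(reference, other, same_sign = TRUE,
                                        threshold = 0) {
  R <- clpn_weight_matrix(reference); O <- clpn_weight_matrix(other)
  if (!identical(colnames(R), colnames(O)))
    fail("edge_replication_proportion: node sets differ")
  off <- row(R) != col(R)
  is_edge <- function(M) M != 0 & abs(M) >= threshold
  ref_edges <- which(off & is_edge(R))
  total <- length(ref_edges)
  flags <- character(0)
  if (total == 0) {
    flags <- c(flags, "no_reference_edges")
    return(list(proportion = NA_real_, replicated = 0L, total = 0L,
                flags = flags))
  }
  hit <- is_edge(O)[ref_edges] &
    (!same_sign | sign(O[ref_edges]) == sign(R[ref_edges]))
  list(proportion = sum(hit) / total, replicated = sum(hit), total = total,
       flags = flags)
}

#' Correlation of a centrality index between two networks
#'
#' Pearson correlation across the 24 nodes of the named index (computed with
#' autoregressive effects removed) between two centrality tables.
#'
#' @param table_a,table_b `clpn_centrality` tables over the same nodes.
#' @param index one of `"in_ei"`, `"out_ei"`, `"bridge_in_ei"`,
#'   `"bridge_out_ei"`.
#' @return list with `r`, `p`, and `flags` (non-empty when a vector is
#'   constant and the correlation undefined).
#' @export
centrality_correlation <- function(table_a, table_b, index) {
  if (!index %in% centrality_indices())
    fail("centrality_correlation: unknown index '%s'", index)
  if (!identical(table_a$node, table_b$node))
    fail("centrality_correlation: node sets differ")
  a <- table_a[[index]]; b <- table_b[[index]]
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, flags = "constant_vector"))
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, flags = character(0))
}

#' Full between-network comparison report
#'
#' Bundles the edge-matrix correlation, the reference-based edge replication
#' proportion, and the four centrality-index correlations.
#'
#' @param net_a reference network (e.g. the baseline-positive group).
#' @param net_b comparison network.
#' @param include_diagonal passed to [matrix_correlation()].
#' @param same_sign,threshold passed to [edge_replication_proportion()].
#' @return list of class `clpn_comparison`.
#' @export
compare_networks <- function(net_a, net_b, include_diagonal = FALSE,
                             same_sign = TRUE, threshold = 0) {
  mc <- matrix_correlation(net_a, net_b, include_diagonal)
  rep_ab <- edge_replication_proportion(net_a, net_b, same_sign, threshold)
  ca <- centrality_table(net_a); cb <- centrality_table(net_b)
  cent <- lapply(setNames(nm = centrality_indices()),
                 function(i) centrality_correlation(ca, cb, i))
  structure(list(matrix_correlation = mc, replication = rep_ab,
                 centrality_correlations = cent),
            class = "clpn_comparison")
}

#' @export
print.clpn_comparison <- function(x, ...) {
  cat(sprintf("<clpn_comparison> edge-matrix r = %.3f (p = %.3g); replication %.1f%% (%d/%d)\n",
              x$matrix_correlation$r, x$matrix_correlation$p,
              100 * x$replication$proportion, x$replication$replicated,
              x$replication$total))
  for (i in names(x$centrality_correlations)) {
    cc <- x$centrality_correlations[[i]]
    cat(sprintf("  %-14s r = %.3f (p = %.3g)\n", i, cc$r, cc$p))
  }
  invisible(x)
}
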