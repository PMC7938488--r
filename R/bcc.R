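#' Build the bipartite enhancer-promoter graph from an IEP set
#'
#' Every IEP set corresponds to a bipartite graph: enhancers on one side,
#' target genes on the other, one edge per interacting pair. Only nodes
#' with at least one edge exist in the graph.
#'
#' @param ieps IEP data.frame.
#' @return An object of class `bcc_graph`: adjacency lists for both sides.
#' @export
bipartite_graph <- function(ieps) {
  .check_ieps(ieps)
  enh <- lapply(split(ieps$gene_id, ieps$enh_id), unique)
  prom <- lapply(split(ieps$enh_id, ieps$gene_id), unique)
  structure(list(enh = enh, prom = prom), class = "bcc_graph")
}

#' @export
print.bcc_graph <- function(x, ...) {
  cat(sprintf("bipartite IEP graph: %d enhancers, %d promoters, %d edges\n",
              length(x$enh), length(x$prom),
              sum(lengths(x$enh))))
  invisible(x)
}

# Adjacency (node -> partner set) for the requested side, and its reverse.
.side_adj <- function(graph, side = c("enhancer", "promoter")) {
  side <- match.arg(side)
  if (side == "enhancer") list(adj = graph$enh, rev = graph$prom)
  else list(adj = graph$prom, rev = graph$enh)
}

.get_neighbors <- function(adj, u) {
  nu <- adj[[u]]
  if (is.null(nu)) stop(sprintf("node '%s' not present on this side", u))
  nu
}

#' Pairwise bipartite clustering coefficient
#'
#' For two same-side nodes u and v, BCC(u, v) is the Jaccard similarity of
#' their neighbor sets: |n(u) n n(v)| / |n(u) u n(v)|. It is 1 exactly when
#' the two nodes interact with identical partner sets and 0 when the sets
#' are disjoint.
#'
#' @param graph A [bipartite_graph()].
#' @param u,v Node ids on the same side.
#' @param side `"enhancer"` or `"promoter"`.
#' @return BCC(u, v) in \[0, 1\].
#' @export
pairwise_bcc <- function(graph, u, v, side = "enhancer") {
  adj <- .side_adj(graph, side)$adj
  nu <- .get_neighbors(adj, u)
  nv <- .get_neighbors(adj, v)
  length(intersect(nu, nv)) / length(union(nu, nv))
}

#' Per-node bipartite clustering coefficient
#'
#' BCC(u) averages BCC(u, v) over the set n(n(u)) of same-side nodes
#' sharing at least one partner with u. This set contains u itself, so the
#' denominator |n(n(u))| - 1 counts the *other* sharing nodes. When u
#' shares no partner with any other node (|n(n(u))| = 1), the value is
#' undefined and `NA` is returned; undefined nodes are excluded from
#' averages rather than scored 0.
#'
#' @inheritParams pairwise_bcc
#' @return BCC(u) in \[0, 1\], or `NA_real_` when undefined.
#' @export
node_bcc <- function(graph, u, side = "enhancer") {
  sides <- .side_adj(graph, side)
  nu <- .get_neighbors(sides$adj, u)
  sharing <- unique(unlist(sides$rev[nu], use.names = FALSE))  # = n(n(u))
  others <- setdiff(sharing, u)
  if (length(others) == 0) return(NA_real_)
  total <- 0
  for (v in others) {
    nv <- sides$adj[[v]]
    total <- total + length(intersect(nu, nv)) / length(union(nu, nv))
  }
  total / length(others)
}

#' Summarize BCC over one side of the graph
#'
#' Computes per-node BCCs and their mean over eligible nodes. With
#' `restrict = "all"` every node with a defined BCC contributes; with
#' `restrict = "multiple"` only nodes interacting with more than one
#' partner do. Also reports the two headline percentages used to summarize
#' IEP sets: the share of all side-nodes that have multiple partners and
#' BCC > 0, and the share of those whose BCC is at or above
#' `high_threshold`.
#'
#' @inheritParams pairwise_bcc
#' @param restrict `"all"` or `"multiple"`.
#' @param high_threshold Threshold for the "high-BCC" percentage
#'   (default 0.9, applied inclusively).
#' @return An object of class `bcc_summary` with fields `side`, `restrict`,
#'   `mean_bcc`, `per_node`, `n_eligible`, `pct_multi_sharing`,
#'   `pct_ge_threshold`.
#' @export
average_bcc <- function(graph, side = "enhancer",
                        restrict = c("all", "multiple"),
                        high_threshold = 0.9) {
  restrict <- match.arg(restrict)
  sides <- .side_adj(graph, side)
  nodes <- names(sides$adj)
  per_node <- vapply(nodes, function(u) node_bcc(graph, u, side), numeric(1))
  names(per_node) <- nodes
  degree <- lengths(sides$adj)
  eligible <- !is.na(per_node)
  if (restrict == "multiple") eligible <- eligible & degree >= 2
  mean_bcc <- if (any(eligible)) mean(per_node[eligible]) else NA_real_
  multi_sharing <- !is.na(per_node) & degree >= 2 & per_node > 0
  pct_multi <- if (length(nodes) > 0) 100 * sum(multi_sharing) / length(nodes) else NA_real_
  pct_hi <- if (any(multi_sharing)) {
    100 * sum(per_node[multi_sharing] >= high_threshold) / sum(multi_sharing)
  } else {
    NA_real_
  }
  structure(list(side = side, restrict = restrict, mean_bcc = mean_bcc,
                 per_node = per_node, n_eligible = sum(eligible),
                 pct_multi_sharing = pct_multi, pct_ge_threshold = pct_hi,
                 high_threshold = high_threshold),
            class = "bcc_summary")
}

#' @export
print.bcc_summary <- function(x, ...) {
  cat(sprintf("BCC summary (%s side, restrict = %s)\n", x$side, x$restrict))
  cat(sprintf("  mean BCC over %d eligible node(s): %s\n", x$n_eligible,
              format(x$mean_bcc, digits = 4)))
  cat(sprintf("  %% nodes with multiple partners and BCC > 0: %s\n",
              format(x$pct_multi_sharing, digits = 4)))
  cat(sprintf("  %% of those with BCC >= %.2f: %s\n", x$high_threshold,
              format(x$pct_ge_threshold, digits = 4)))
  invisible(x)
}

#' Pool of per-node BCC values entering the significance test
#'
#' The binomial comparison against degree-preserving random IEPs uses the
#' BCCs of nodes that interact with multiple partners and have a defined
#' BCC; this helper extracts exactly that pool.
#'
#' @inheritParams pairwise_bcc
#' @return Named numeric vector of BCC values.
#' @export
bcc_pool <- function(graph, side = "enhancer") {
  s <- average_bcc(graph, side, restrict = "multiple")
  degree <- lengths(.side_adj(graph, side)$adj)
  keep <- !is.na(s$per_node) & degree >= 2
  s$per_node[keep]
}
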