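#' Build the shared-target enhancer graph
#'
#' Nodes are enhancers; an edge joins two enhancers that interact with at
#' least one common target gene. Enhancers sharing no target are retained
#' as isolated nodes (they never enter clusters).
#'
#' @param graph A [bipartite_graph()].
#' @return An undirected `igraph` graph with enhancer ids as vertex names.
#' @export
build_enhancer_graph <- function(graph) {
  stopifnot(inherits(graph, "bcc_graph"))
  nodes <- names(graph$enh)
  edges <- unique(do.call(rbind, lapply(graph$prom, function(enh_set) {
    if (length(enh_set) < 2) return(NULL)
    t(utils::combn(sort(enh_set), 2))
  })))
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
  igraph::graph_from_data_frame(
    d = as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

#' Enumerate maximal cliques of the enhancer graph
#'
#' All maximal cliques with at least two members, found by Bron-Kerbosch
#' enumeration. Each clique is an enhancer cluster; clusters may share
#' enhancers. Output order is deterministic (lexicographic on sorted
#' member ids).
#'
#' @param graph An undirected `igraph` graph (see [build_enhancer_graph()]).
#' @return List of character vectors of sorted member ids.
#' @export
maximal_cliques <- function(graph) {
  cl <- igraph::max_cliques(graph, min = 2)
  members <- lapply(cl, function(x) sort(igraph::V(graph)$name[as.integer(x)]))
  key <- vapply(members, paste, character(1), collapse = "\r")
  members[order(key)]
}

#' Split a cluster's targets into fully and partially shared genes
#'
#' A target of a cluster is fully shared when every member enhancer
#' interacts with it, and partially shared when only a proper non-empty
#' subset does. The two sets partition the union of the members' targets.
#'
#' @param members Character vector of at least two enhancer ids.
#' @param graph The source [bipartite_graph()].
#' @return List with sorted character vectors `fully_shared` and
#'   `partially_shared`.
#' @export
classify_targets <- function(members, graph) {
  stopifnot(inherits(graph, "bcc_graph"), length(members) >= 2)
  target_sets <- graph$enh[members]
  if (any(vapply(target_sets, is.null, logical(1)))) {
    stop("cluster member absent from bipartite graph")
  }
  all_targets <- sort(unique(unlist(target_sets, use.names = FALSE)))
  fully <- all_targets[vapply(all_targets, function(g) {
    all(vapply(target_sets, function(s) g %in% s, logical(1)))
  }, logical(1))]
  list(fully_shared = fully,
       partially_shared = setdiff(all_targets, fully))
}

#' Find enhancer clusters in an IEP set
#'
#' End-to-end clustering: bipartite graph, shared-target enhancer graph,
#' maximal cliques, and per-cluster target classification and genomic span.
#'
#' @param ieps IEP data.frame.
#' @param enhancers Enhancer intervals covering every enhancer in `ieps`.
#' @return Object of class `enhancer_clusters`: a list of cluster records,
#'   each with `cluster_id`, `members`, `chrom`, `span_start`, `span_end`,
#'   `fully_shared`, `partially_shared`; the bipartite graph is attached as
#'   the `graph` attribute.
#' @export
find_enhancer_clusters <- function(ieps, enhancers) {
  .check_intervals(enhancers, "enhancers")
  graph <- bipartite_graph(ieps)
  cliques <- maximal_cliques(build_enhancer_graph(graph))
  clusters <- lapply(seq_along(cliques), function(i) {
    members <- cliques[[i]]
    idx <- match(members, enhancers$id)
    if (any(is.na(idx))) {
      stop("cluster member missing from enhancer table: ",
           paste(members[is.na(idx)], collapse = ", "))
    }
    targets <- classify_targets(members, graph)
    list(cluster_id = sprintf("cluster%04d", i),
         members = members,
         chrom = enhancers$chrom[idx[1]],
         span_start = min(enhancers$start[idx]),
         span_end = max(enhancers$end[idx]),
         fully_shared = targets$fully_shared,
         partially_shared = targets$partially_shared)
  })
  structure(clusters, class = "enhancer_clusters", graph = graph)
}

#' @export
print.enhancer_clusters <- function(x, ...) {
  cat(sprintf("%d enhancer cluster(s); sizes: %s\n", length(x),
              paste(utils::head(vapply(x, function(cl) length(cl$members),
                                       integer(1)), 10), collapse = " ")))
  invisible(x)
}

#' Flatten enhancer clusters to a data.frame
#'
#' @param clusters An [find_enhancer_clusters()] result.
#' @return data.frame with one row per cluster (member and gene lists
#'   comma-separated).
#' @export
clusters_to_df <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      span_start = integer(0), span_end = integer(0),
                      n_members = integer(0), members = character(0),
                      fully_shared = character(0),
                      partially_shared = character(0)))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, chrom = cl$chrom,
               span_start = cl$span_start, span_end = cl$span_end,
               n_members = length(cl$members),
               members = paste(cl$members, collapse = ","),
               fully_shared = paste(cl$fully_shared, collapse = ","),
               partially_shared = paste(cl$partially_shared, collapse = ","))
  }))
}

# Gaps between coordinate-sorted adjacent intervals and whether each
# adjacent pair is "consecutive" (no other interval from `universe` lying
# strictly inside the gap between the pair).
.adjacent_gaps <- function(iv, universe) {
  ord <- order(iv$start, iv$end)
  iv <- iv[ord, , drop = FALSE]
  n <- nrow(iv)
  if (n < 2) {
    return(list(gaps = numeric(0), consecutive = logical(0), order = ord))
  }
  gaps <- numeric(n - 1)
  consecutive <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    gaps[i] <- max(0, iv$start[i + 1] - iv$end[i])
    between <- universe$chrom == iv$chrom[i] &
      !(universe$id %in% iv$id) &
      universe$start >= iv$end[i] & universe$end <= iv$start[i + 1]
    consecutive[i] <- !any(between)
  }
  list(gaps = gaps, consecutive = consecutive, order = ord)
}

# Percentage of members with at least one consecutive flanking pair.
.pct_members_consecutive <- function(n, consecutive) {
  if (n < 2) return(NA_real_)
  member_ok <- logical(n)
  for (i in seq_len(n - 1)) {
    if (consecutive[i]) member_ok[c(i, i + 1)] <- TRUE
  }
  100 * mean(member_ok)
}

#' Distance and consecutiveness statistics for one enhancer cluster
#'
#' Gaps (end-to-start, 0 when overlapping) are measured between
#' coordinate-adjacent cluster members and, separately, between the
#' cluster's coordinate-adjacent target genes. An adjacent pair is
#' "consecutive" when no other active feature of the same kind lies
#' strictly between the two intervals; a member (target) counts as
#' consecutive when at least one of its flanking in-cluster pairs is.
#'
#' @param cluster One cluster record from [find_enhancer_clusters()].
#' @param all_enhancers All active enhancers in the sample (the universe
#'   deciding consecutiveness of members).
#' @param all_genes Intervals for all active genes (e.g. promoter windows
#'   with `gene_id` as `id`); the universe for target consecutiveness.
#' @param bin_edges Histogram bin edges in bp for the member-gap
#'   distribution; the default upper edge reflects clusters spanning up to
#'   two megabases.
#' @return List of class `cluster_stats`: gap vectors, histogram counts,
#'   `pct_within_10kb`, `pct_over_50kb`, member/target consecutiveness
#'   percentages (per member and per adjacent pair) and
#'   `pct_partially_shared`.
#' @export
cluster_stats <- function(cluster, all_enhancers, all_genes,
                          bin_edges = c(0, 5e3, 1e4, 2e4, 5e4, 1e5, 5e5,
                                        1e6, 2e6, Inf)) {
  members <- all_enhancers[match(cluster$members, all_enhancers$id), ,
                           drop = FALSE]
  if (any(is.na(members$start))) stop("cluster member missing from enhancer table")
  targets <- c(cluster$fully_shared, cluster$partially_shared)
  tgt <- all_genes[match(targets, all_genes$id), , drop = FALSE]
  if (any(is.na(tgt$start))) stop("cluster target missing from gene table")
  enh <- .adjacent_gaps(members, all_enhancers)
  gen <- .adjacent_gaps(tgt, all_genes)
  hist_counts <- if (length(enh$gaps) > 0) {
    as.integer(table(cut(enh$gaps, bin_edges, right = TRUE,
                         include.lowest = TRUE)))
  } else {
    integer(length(bin_edges) - 1)
  }
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  structure(list(
    cluster_id = cluster$cluster_id,
    consecutive_enh_gaps = enh$gaps,
    target_gaps = gen$gaps,
    gap_hist = stats::setNames(hist_counts,
                               paste(utils::head(bin_edges, -1),
                                     bin_edges[-1], sep = "-")),
    pct_within_10kb = pct(enh$gaps <= 1e4),
    pct_over_50kb = pct(enh$gaps > 5e4),
    pct_members_consecutive = .pct_members_consecutive(nrow(members),
                                                       enh$consecutive),
    pct_pairs_consecutive = pct(enh$consecutive),
    pct_targets_consecutive = .pct_members_consecutive(nrow(tgt),
                                                       gen$consecutive),
    pct_target_pairs_consecutive = pct(gen$consecutive),
    pct_partially_shared = if (length(targets) == 0) NA_real_ else
      100 * length(cluster$partially_shared) / length(targets)
  ), class = "cluster_stats")
}

#' Fraction of clusters from one sample found in another
#'
#' Directional: the percentage of `clusters_a` that are also identified in
#' `clusters_b`. Under the default `"exact"` rule two clusters match when
#' their member coordinate sets are identical; under `"span_overlap"` they
#' match when their genomic spans reciprocally overlap by at least
#' `min_overlap` of each span (useful when enhancer coordinate sets differ
#' between samples).
#'
#' @param clusters_a,clusters_b [find_enhancer_clusters()] results; member
#'   coordinates are taken via `enhancers_a`/`enhancers_b`.
#' @param enhancers_a,enhancers_b Enhancer tables for the two samples.
#' @param match_rule `"exact"` or `"span_overlap"`.
#' @param min_overlap Reciprocal overlap fraction for `"span_overlap"`.
#' @return Percentage in \[0, 100\] (100 * matched / |clusters_a|); 0 when
#'   `clusters_a` is empty.
#' @export
cross_sample_sharing <- function(clusters_a, clusters_b, enhancers_a,
                                 enhancers_b,
                                 match_rule = c("exact", "span_overlap"),
                                 min_overlap = 0.5) {
  match_rule <- match.arg(match_rule)
  if (length(clusters_a) == 0) return(0)
  if (match_rule == "exact") {
    coord_key <- function(cl, enh) {
      idx <- match(cl$members, enh$id)
      paste(sort(sprintf("%s:%d-%d", enh$chrom[idx], enh$start[idx],
                         enh$end[idx])), collapse = ";")
    }
    keys_b <- vapply(clusters_b, coord_key, character(1), enh = enhancers_b)
    matched <- vapply(clusters_a, function(cl) {
      coord_key(cl, enhancers_a) %in% keys_b
    }, logical(1))
  } else {
    matched <- vapply(clusters_a, function(a) {
      any(vapply(clusters_b, function(b) {
        if (a$chrom != b$chrom) return(FALSE)
        ov <- min(a$span_end, b$span_end) - max(a$span_start, b$span_start)
        ov >= min_overlap * (a$span_end - a$span_start) &&
          ov >= min_overlap * (b$span_end - b$span_start)
      }, logical(1)))
    }, logical(1))
  }
  100 * sum(matched) / length(clusters_a)
}

#' Percent identity between two enhancer sequences
#'
#' Global (Needleman-Wunsch) alignment of two nucleotide sequences followed
#' by 100 * matches / alignment columns (gap columns count toward the
#' denominator).
#'
#' @param seq_a,seq_b Non-empty A/C/G/T/N strings.
#' @param match,mismatch Substitution scores (defaults +1 / -1).
#' @param gap Per-base gap penalty (default -2).
#' @return Percent identity in \[0, 100\].
#' @export
sequence_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -2) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = -gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}
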