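# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately work from raw edge lists / adjacency matrices,
# sharing no code with the package implementations they check.

# Canonical IEP table from an (enh, gene) edge list; coordinates spaced so
# features never overlap and every enhancer-promoter gap clears 2.5 kb.
ieps_from_edges <- function(edges, chrom = "chr1") {
  edges <- unique(edges)
  enh_ids <- sort(unique(edges$enh))
  gene_ids <- sort(unique(edges$gene))
  e_start <- stats::setNames(seq_along(enh_ids) * 10000L, enh_ids)
  tss <- stats::setNames(5000000L + seq_along(gene_ids) * 10000L, gene_ids)
  data.frame(iep_id = paste(edges$enh, edges$gene, sep = "::"),
             chrom = chrom,
             enh_start = unname(e_start[edges$enh]),
             enh_end = unname(e_start[edges$enh]) + 500L,
             enh_id = edges$enh, gene_id = edges$gene,
             tss = unname(tss[edges$gene]), strand = "+",
             support = NA_real_, source = "test")
}

# The three-enhancer / three-promoter worked example: e1-{p1,p2,p3},
# e2-{p1,p2}, e3-{p1}.
toy_ieps <- function() {
  ieps_from_edges(data.frame(enh = c("e1", "e1", "e1", "e2", "e2", "e3"),
                             gene = c("p1", "p2", "p3", "p1", "p2", "p1")))
}

# Seeded random bipartite edge list (never empty).
random_edges <- function(n_e, n_p, p_edge, seed) {
  withr::with_seed(seed, {
    grid <- expand.grid(enh = paste0("e", seq_len(n_e)),
                        gene = paste0("g", seq_len(n_p)),
                        stringsAsFactors = FALSE)
    out <- grid[stats::runif(nrow(grid)) < p_edge, , drop = FALSE]
    if (nrow(out) == 0) out <- grid[1, , drop = FALSE]
    out
  })
}

# Brute-force per-node BCC straight from the two defining formulas,
# computed on the raw edge list.
oracle_bcc <- function(edges, side = "enhancer") {
  if (side == "enhancer") {
    A <- edges$enh; B <- edges$gene
  } else {
    A <- edges$gene; B <- edges$enh
  }
  nodes <- sort(unique(A))
  nbr <- function(u) unique(B[A == u])
  per <- vapply(nodes, function(u) {
    nu <- nbr(u)
    others <- Filter(function(v) {
      v != u && length(intersect(nbr(v), nu)) > 0
    }, nodes)
    if (length(others) == 0) return(NA_real_)
    mean(vapply(others, function(v) {
      nv <- nbr(v)
      length(intersect(nu, nv)) / length(union(nu, nv))
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(per, nodes)
}

# Exhaustive maximal-clique enumeration over all vertex subsets of a
# symmetric 0/1 adjacency matrix (rownames = vertex ids), via a subset DP:
# S is a clique iff S minus its lowest vertex is one and that vertex is
# adjacent to the rest.
oracle_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 16, identical(adj, t(adj)))
  bits <- bitwShiftL(1L, 0:(n - 1))
  adjmask <- vapply(seq_len(n), function(v) {
    sum(bits[adj[v, ] == 1])
  }, numeric(1))
  nsub <- bitwShiftL(1L, n)
  is_clique <- logical(nsub)
  is_clique[1] <- TRUE
  for (s in seq_len(nsub - 1L)) {
    rest <- bitwAnd(s, s - 1L)   # clears the lowest set bit
    v <- match(s - rest, bits)
    is_clique[s + 1L] <- is_clique[rest + 1L] &&
      bitwAnd(rest, adjmask[v]) == rest
  }
  out <- list()
  ids <- rownames(adj)
  for (s in seq_len(nsub - 1L)) {
    if (!is_clique[s + 1L]) next
    members <- which(bitwAnd(s, bits) != 0L)
    if (length(members) < 2) next
    grows <- FALSE
    for (v in seq_len(n)) {
      if (bitwAnd(s, bits[v]) == 0L && is_clique[bitwOr(s, bits[v]) + 1L]) {
        grows <- TRUE
        break
      }
    }
    if (!grows) out[[length(out) + 1L]] <- sort(ids[members])
  }
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# Sorted set-of-sets representation for clique comparison.
clique_key <- function(cliques) {
  sort(vapply(cliques, function(x) paste(sort(x), collapse = ","),
              character(1)))
}

# Canonical (enh, gene) key set of an IEP table.
iep_key <- function(ieps) sort(paste(ieps$enh_id, ieps$gene_id))
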