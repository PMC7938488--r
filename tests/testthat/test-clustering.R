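test_that("shared-target graph connects exactly the sharing enhancer pairs", {
  g <- bipartite_graph(toy_ieps())
  eg <- build_enhancer_graph(g)
  expect_setequal(igraph::V(eg)$name, c("e1", "e2", "e3"))
  expect_equal(igraph::gsize(eg), 3)  # all three pairs share p1

  disjoint <- bipartite_graph(ieps_from_edges(do.call(rbind, lapply(1:2,
    function(k) expand.grid(enh = paste0("c", k, "e", 1:2),
                            gene = paste0("c", k, "g", 1:2),
                            stringsAsFactors = FALSE)))))
  eg2 <- build_enhancer_graph(disjoint)
  comps <- igraph::components(eg2)
  expect_equal(comps$no, 2)
  expect_equal(igraph::gsize(eg2), 2)
})

test_that("maximal cliques cover paths, triangles and shared nodes", {
  g <- bipartite_graph(toy_ieps())
  expect_equal(maximal_cliques(build_enhancer_graph(g)),
               list(c("e1", "e2", "e3")))
  # path a-b-c: two overlapping clusters sharing b
  path <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")), directed = FALSE)
  expect_equal(clique_key(maximal_cliques(path)), c("a,b", "b,c"))
})

test_that("clique enumeration matches exhaustive subset enumeration", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      n <- sample(5:12, 1)
      adj <- matrix(0L, n, n, dimnames = list(paste0("v", 1:n),
                                              paste0("v", 1:n)))
      p <- stats::runif(1, 0.2, 0.6)
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
        }
      }
      ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(clique_key(maximal_cliques(ig)),
                   clique_key(oracle_maximal_cliques(adj)))
    })
  }
})

test_that("targets partition into fully and partially shared", {
  g <- bipartite_graph(toy_ieps())
  cls <- classify_targets(c("e1", "e2", "e3"), g)
  expect_equal(cls$fully_shared, "p1")
  expect_equal(cls$partially_shared, c("p2", "p3"))

  biclique <- bipartite_graph(ieps_from_edges(
    expand.grid(enh = c("a", "b"), gene = c("x", "y"),
                stringsAsFactors = FALSE)))
  cls2 <- classify_targets(c("a", "b"), biclique)
  expect_setequal(cls2$fully_shared, c("x", "y"))
  expect_equal(length(cls2$partially_shared), 0)

  # partition property on random graphs
  for (seed in 20:24) {
    edges <- random_edges(6, 6, 0.5, seed = seed)
    bg <- bipartite_graph(ieps_from_edges(edges))
    for (cl in maximal_cliques(build_enhancer_graph(bg))) {
      cls3 <- classify_targets(cl, bg)
      all_targets <- unique(unlist(bg$enh[cl]))
      expect_setequal(c(cls3$fully_shared, cls3$partially_shared),
                      all_targets)
      expect_equal(length(intersect(cls3$fully_shared,
                                    cls3$partially_shared)), 0)
    }
  }
})

test_that("cluster gaps and consecutiveness follow the intervening rule", {
  mk_cluster <- function(members) {
    list(cluster_id = "c1", members = members, chrom = "chr1",
         span_start = 0L, span_end = 1L,
         fully_shared = "g1", partially_shared = character(0))
  }
  genes <- data.frame(chrom = "chr1", start = 900000L, end = 901101L,
                      id = "g1")
  two <- data.frame(chrom = "chr1", start = c(0L, 150L),
                    end = c(100L, 250L), id = c("m1", "m2"))
  st <- cluster_stats(mk_cluster(c("m1", "m2")), two, genes)
  expect_equal(st$consecutive_enh_gaps, 50)
  expect_equal(st$pct_members_consecutive, 100)

  withIn <- rbind(two, data.frame(chrom = "chr1", start = 110L, end = 140L,
                                  id = "other"))
  st2 <- cluster_stats(mk_cluster(c("m1", "m2")), withIn, genes)
  expect_equal(st2$pct_members_consecutive, 0)
  expect_equal(st2$pct_pairs_consecutive, 0)

  three <- data.frame(chrom = "chr1",
                      start = c(0L, 5100L, 65200L),
                      end = c(100L, 5200L, 65300L),
                      id = c("m1", "m2", "m3"))
  st3 <- cluster_stats(mk_cluster(c("m1", "m2", "m3")), three, genes)
  expect_equal(st3$consecutive_enh_gaps, c(5000, 60000))
  expect_equal(st3$pct_within_10kb, 50)
  expect_equal(st3$pct_over_50kb, 50)
})

test_that("partially shared targets vanish when enhancer BCC is 1", {
  tr <- generate_synthetic(synthetic_config(seed = 21))
  g <- bipartite_graph(tr$clean_ieps)
  expect_equal(average_bcc(g, "enhancer")$mean_bcc, 1)
  cl <- find_enhancer_clusters(tr$clean_ieps, tr$enhancers)
  expect_true(all(vapply(cl, function(x) length(x$partially_shared) == 0,
                         logical(1))))
  gene_iv <- data.frame(chrom = tr$promoters$chrom,
                        start = tr$promoters$start,
                        end = tr$promoters$end, id = tr$promoters$gene_id)
  st <- cluster_stats(cl[[1]], tr$enhancers, gene_iv)
  expect_equal(st$pct_partially_shared, 0)
})

test_that("cross-sample sharing counts coordinate-identical clusters", {
  tr <- generate_synthetic(synthetic_config(n_clusters = 4, seed = 2))
  cl <- find_enhancer_clusters(tr$clean_ieps, tr$enhancers)
  expect_equal(cross_sample_sharing(cl, cl, tr$enhancers, tr$enhancers), 100)
  other <- tr$enhancers
  other$chrom <- "chr7"
  expect_equal(cross_sample_sharing(cl, cl, tr$enhancers, other), 0)
  expect_equal(cross_sample_sharing(cl, cl[1], tr$enhancers, tr$enhancers),
               25)
  # reciprocal span overlap tolerates boundary jitter
  jitter <- tr$enhancers
  jitter$start <- jitter$start - 5L
  jitter$end <- jitter$end + 5L
  cl_j <- find_enhancer_clusters(tr$clean_ieps, jitter)
  expect_equal(cross_sample_sharing(cl, cl_j, tr$enhancers, jitter,
                                    match_rule = "span_overlap"), 100)
  expect_equal(cross_sample_sharing(cl, cl_j, tr$enhancers, jitter), 0)
})

test_that("percent identity scores global alignments", {
  expect_equal(sequence_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(sequence_identity("AAAA", "TTTT"), 0)
  expect_equal(sequence_identity("ACGT", "ACGA"), 75)
  expect_error(sequence_identity("", "ACGT"), "empty")
})
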