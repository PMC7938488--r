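# Small universe shared by the randomization tests.
.null_fixture <- function() {
  enhancers <- data.frame(chrom = "chr1",
                          start = seq(10000L, by = 10000L, length.out = 6),
                          end = seq(10500L, by = 10000L, length.out = 6),
                          id = paste0("e", 1:6))
  genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                      tss = seq(2000000L, by = 10000L, length.out = 8),
                      strand = "+", gene_name = NA)
  promoters <- derive_promoters(genes)
  ieps <- overlap_ieps(enhancers, promoters, data.frame(
    pair_id = paste0("p", 1:4), chrom = "chr1",
    a1_start = enhancers$start[c(1, 1, 1, 2)],
    a1_end = enhancers$end[c(1, 1, 1, 2)],
    a2_start = promoters$start[c(1, 2, 3, 1)],
    a2_end = promoters$end[c(1, 2, 3, 1)],
    support = NA_real_, source = "looplist"))
  list(enhancers = enhancers, promoters = promoters, ieps = ieps)
}

test_that("randomization preserves degrees exactly for every seed and side", {
  fx <- .null_fixture()
  for (seed in c(1, 7, 104)) {
    r_e <- randomize_ieps(fx$ieps, fx$enhancers, fx$promoters,
                          side = "enhancer", seed = seed)
    expect_equal(table(r_e$enh_id), table(fx$ieps$enh_id))
    r_p <- randomize_ieps(fx$ieps, fx$enhancers, fx$promoters,
                          side = "promoter", seed = seed)
    expect_equal(table(r_p$gene_id), table(fx$ieps$gene_id))
  }
})

test_that("randomization is deterministic given the seed", {
  fx <- .null_fixture()
  a <- randomize_ieps(fx$ieps, fx$enhancers, fx$promoters, seed = 42)
  b <- randomize_ieps(fx$ieps, fx$enhancers, fx$promoters, seed = 42)
  expect_identical(a, b)
})

test_that("randomized partners respect chromosome and distance constraints", {
  fx <- .null_fixture()
  # add a second-chromosome promoter that must never be drawn
  far <- data.frame(gene_id = "far", chrom = "chr9", start = 0L, end = 1101L,
                    tss = 1000L, strand = "+")
  proms <- rbind(fx$promoters, far)
  for (seed in 1:10) {
    r <- randomize_ieps(fx$ieps, fx$enhancers, proms, seed = seed)
    expect_false("far" %in% r$gene_id)
    idx <- match(r$gene_id, proms$gene_id)
    gaps <- interval_gap(r$enh_start, r$enh_end,
                         proms$start[idx], proms$end[idx])
    expect_true(all(gaps >= 2500))
  }
})

test_that("a universe exactly matching the degree is forced by pigeonhole", {
  fx <- .null_fixture()
  three <- fx$promoters[1:3, ]
  r <- randomize_ieps(fx$ieps[fx$ieps$enh_id == "e1", ], fx$enhancers,
                      three, seed = 5)
  expect_setequal(r$gene_id, three$gene_id)
  expect_error(
    randomize_ieps(fx$ieps[fx$ieps$enh_id == "e1", ], fx$enhancers,
                   three[1:2, ], seed = 5),
    "universe too small.*e1")
})

test_that("binomial tail handles the boundary cases of the formula", {
  expect_identical(binomial_pvalue(17, 0, 0.3), 1)
  expect_identical(binomial_pvalue(10, 0, 0), 1)
  expect_identical(binomial_pvalue(10, 3, 0), 0)
  expect_identical(binomial_pvalue(10, 3, 1), 1)
  expect_equal(binomial_pvalue(2, 2, 0.5), 0.25, tolerance = 1e-15)
  expect_error(binomial_pvalue(5, 6, 0.5), "0 <= k <= n")
  expect_error(binomial_pvalue(5, 2, 1.2), "0 <= p <= 1")
})

test_that("binomial tail matches the cumulative-distribution oracle", {
  for (n in c(5, 20, 50, 100, 200)) {
    for (p in c(0.01, 0.1, 0.3, 0.5, 0.9)) {
      for (k in unique(pmin(n, c(1, 2, n %/% 4, n %/% 2, n - 1, n)))) {
        mine <- binomial_pvalue(n, k, p)
        ref <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
        expect_equal(mine, ref, tolerance = 1e-12,
                     label = sprintf("p-value(n=%d,k=%d,p=%g)", n, k, p))
      }
    }
  }
  expect_equal(binomial_pvalue(50, 30, 0.1),
               stats::pbinom(29, 50, 0.1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("binomial tail is monotone in p and in k", {
  ps <- seq(0.05, 0.95, by = 0.1)
  vals_p <- vapply(ps, function(p) binomial_pvalue(40, 12, p), numeric(1))
  expect_true(all(diff(vals_p) > 0))
  ks <- 1:40
  vals_k <- vapply(ks, function(k) binomial_pvalue(40, k, 0.4), numeric(1))
  expect_true(all(diff(vals_k) < 0))
})

test_that("null comparison wires the pools into the binomial test", {
  strong <- compare_to_null(rep(1, 20), rep(0.2, 100))
  expect_identical(strong$p, 0)
  expect_identical(strong$p_value, 0)
  expect_equal(strong$k, 20)

  pool <- withr::with_seed(8, stats::runif(400))
  same <- compare_to_null(pool, pool)
  expect_gt(same$p_value, 0.2)  # no enrichment when pools coincide

  expect_identical(compare_to_null(rep(0.5, 10), rep(0.1, 50))$p_value, 1)
  expect_error(compare_to_null(numeric(0), rep(0.5, 5)), "empty")
})

test_that("rank comparison behaves as a two-sided Mann-Whitney test", {
  expect_equal(rank_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  sep <- rank_compare(c(1, 2, 3), c(101, 102, 103))
  expect_equal(sep$U, 0)
  expect_lt(sep$p_value, 0.1)
  expect_error(rank_compare(numeric(0), 1:3), "non-empty")
  # p-values under the null are roughly uniform
  ps <- vapply(1:200, function(s) {
    withr::with_seed(s, rank_compare(stats::rnorm(20), stats::rnorm(20))$p_value)
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})
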