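# Shared mini-geometry: two anchors 500 kb apart.
.pair <- function(a1 = c(1000L, 6000L), a2 = c(500000L, 505000L),
                  support = NA_real_) {
  data.frame(pair_id = "pr0", chrom = "chr1",
             a1_start = a1[1], a1_end = a1[2],
             a2_start = a2[1], a2_end = a2[2],
             support = support, source = "looplist")
}

.prom <- function(gene_id, start, end) {
  data.frame(gene_id = gene_id, chrom = "chr1", start = start, end = end,
             tss = start + 1000L, strand = "+")
}

test_that("anchor overlap IEPs form the cross-anchor cartesian product", {
  enh1 <- data.frame(chrom = "chr1", start = 2000L, end = 2500L, id = "e1")
  prom1 <- .prom("g1", 501000L, 502101L)
  expect_equal(nrow(overlap_ieps(enh1, prom1, .pair())), 1)

  enh2 <- rbind(enh1,
                data.frame(chrom = "chr1", start = 4000L, end = 4500L, id = "e2"))
  prom2 <- rbind(prom1, .prom("g2", 503000L, 504101L))
  ieps <- overlap_ieps(enh2, prom2, .pair())
  expect_equal(nrow(ieps), 4)
  expect_setequal(paste(ieps$enh_id, ieps$gene_id),
                  c("e1 g1", "e1 g2", "e2 g1", "e2 g2"))
})

test_that("a feature spanning both anchors yields one cross-anchor IEP", {
  wide_enh <- data.frame(chrom = "chr1", start = 500L, end = 506000L,
                         id = "wide")
  prom <- .prom("g1", 501000L, 502101L)  # overlaps anchor2 only
  ieps <- overlap_ieps(wide_enh, prom, .pair())
  expect_equal(nrow(ieps), 1)
  expect_equal(ieps$enh_id, "wide")
})

test_that("overlap IEPs are invariant to anchor order within a pair", {
  enh <- data.frame(chrom = "chr1", start = c(2000L, 501500L),
                    end = c(2500L, 502000L), id = c("eL", "eR"))
  prom <- rbind(.prom("gL", 3000L, 4101L), .prom("gR", 503000L, 504101L))
  flipped <- .pair()
  flipped[, c("a1_start", "a1_end", "a2_start", "a2_end")] <-
    flipped[, c("a2_start", "a2_end", "a1_start", "a1_end")]
  expect_equal(iep_key(overlap_ieps(enh, prom, .pair())),
               iep_key(overlap_ieps(enh, prom, flipped)))
})

test_that("cutoff IEPs apply the threshold inclusively with max support", {
  enh <- data.frame(chrom = "chr1", start = 1000L, end = 2000L, id = "e1")
  prom <- .prom("g1", 499000L, 500101L)
  contacts <- function(count) {
    structure(data.frame(chrom = "chr1", bin_i = 0, bin_j = 495000,
                         normalized_count = count),
              resolution = 5000)
  }
  at35 <- cutoff_ieps(enh, prom, contacts(35), cutoff = 30)
  expect_equal(nrow(at35), 1)
  expect_equal(at35$support, 35)
  expect_equal(at35$source, "matrix")
  expect_equal(nrow(cutoff_ieps(enh, prom, contacts(30), cutoff = 30)), 1)
  expect_equal(nrow(cutoff_ieps(enh, prom, contacts(29.9), cutoff = 30)), 0)
})

test_that("cutoff IEP sets shrink monotonically with the cutoff", {
  withr::with_seed(77, {
    enh <- data.frame(chrom = "chr1",
                      start = seq(0L, by = 20000L, length.out = 15),
                      end = seq(800L, by = 20000L, length.out = 15),
                      id = paste0("e", 1:15))
    genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                        tss = seq(1000000L, by = 30000L, length.out = 10),
                        strand = "+", gene_name = NA)
    prom <- derive_promoters(genes)
    bins_e <- unique(floor(enh$start / 5000) * 5000)
    bins_p <- unique(floor(prom$start / 5000) * 5000)
    contacts <- structure(
      expand.grid(bin_i = bins_e, bin_j = bins_p), resolution = 5000)
    contacts$chrom <- "chr1"
    contacts$normalized_count <- stats::runif(nrow(contacts), 0, 450)
    keys <- lapply(c(30, 50, 100, 400), function(x) {
      iep_key(cutoff_ieps(enh, prom, contacts, cutoff = x))
    })
    for (i in 2:4) expect_true(all(keys[[i]] %in% keys[[i - 1]]))
  })
})

test_that("the distance filter keeps gaps >= 2.5 kb inclusively", {
  enh <- data.frame(chrom = "chr1", start = 0L, end = 500L, id = "e1")
  mk_iep <- function(p_start, p_end) {
    list(ieps = data.frame(iep_id = "i", chrom = "chr1", enh_start = 0L,
                           enh_end = 500L, enh_id = "e1", gene_id = "g1",
                           tss = p_start + 1000L, strand = "+",
                           support = NA_real_, source = "test"),
         prom = .prom("g1", p_start, p_end))
  }
  at <- mk_iep(3000L, 4101L)     # gap exactly 2500
  expect_equal(nrow(distance_filter(at$ieps, at$prom)), 1)
  near <- mk_iep(2999L, 4100L)   # gap 2499
  expect_equal(nrow(distance_filter(near$ieps, near$prom)), 0)
  over <- mk_iep(400L, 1501L)    # overlapping, gap 0
  expect_equal(nrow(distance_filter(over$ieps, over$prom)), 0)
  # idempotent and subset
  once <- distance_filter(at$ieps, at$prom)
  expect_equal(distance_filter(once, at$prom), once)
  expect_error(distance_filter(at$ieps, .prom("other", 1L, 2L)),
               "unknown gene_id")
})

test_that("subset counts tabulate per source with a grand total", {
  empty <- subset_counts(toy_ieps()[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total"), 0L)

  ieps <- toy_ieps()[1:3, ]
  ieps$source <- c("looplist", "looplist", "link")
  counts <- subset_counts(ieps)
  expect_equal(counts$n_ieps[counts$source == "looplist"], 2L)
  expect_equal(counts$n_ieps[counts$source == "link"], 1L)
  expect_equal(attr(subset_counts(toy_ieps()), "total"), 6L)
})
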