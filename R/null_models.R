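#' Degree-preserving random IEP sets
#'
#' Randomizes the partner assignments of an IEP set while preserving the
#' degree of every node on one side: with `side = "enhancer"`, each
#' enhancer is re-paired with partners drawn uniformly without replacement
#' from the same-chromosome promoter universe, so it keeps exactly its
#' original number of interactions (and dually for `side = "promoter"`).
#' Candidate partners violating the minimum enhancer-promoter distance are
#' excluded when `respect_min_distance` is on, matching the filter applied
#' to the observed IEPs. Deterministic given `seed`.
#'
#' @param ieps Observed IEP data.frame.
#' @param enhancers Enhancer universe (`chrom`, `start`, `end`, `id`);
#'   candidate partners for promoter-side randomization.
#' @param promoters Promoter-window universe from [derive_promoters()];
#'   candidate partners for enhancer-side randomization.
#' @param side Which side's degrees are preserved.
#' @param seed Integer seed; the RNG state outside the call is untouched.
#' @param respect_min_distance Exclude partners closer than `min_distance`.
#' @param min_distance Minimum gap in bp (default 2500).
#' @return IEP data.frame with `source = "random"`.
#' @export
randomize_ieps <- function(ieps, enhancers, promoters,
                           side = c("enhancer", "promoter"), seed,
                           respect_min_distance = TRUE, min_distance = 2500) {
  side <- match.arg(side)
  .check_ieps(ieps)
  .check_intervals(enhancers, "enhancers")
  if (nrow(ieps) == 0) return(.empty_ieps())
  withr::with_seed(as.integer(seed), {
    if (side == "enhancer") {
      .randomize_one_side(ieps, fixed_ids = ieps$enh_id,
                          fixed_tab = enhancers, partner_tab = promoters,
                          partner_is_promoter = TRUE,
                          respect_min_distance, min_distance)
    } else {
      .randomize_one_side(ieps, fixed_ids = ieps$gene_id,
                          fixed_tab = promoters, partner_tab = enhancers,
                          partner_is_promoter = FALSE,
                          respect_min_distance, min_distance)
    }
  })
}

.randomize_one_side <- function(ieps, fixed_ids, fixed_tab, partner_tab,
                                partner_is_promoter, respect_min_distance,
                                min_distance) {
  fixed_key <- if (partner_is_promoter) fixed_tab$id else fixed_tab$gene_id
  degrees <- table(fixed_ids)
  out <- vector("list", length(degrees))
  for (i in seq_along(degrees)) {
    node <- names(degrees)[i]
    d <- as.integer(degrees[[i]])
    frow <- fixed_tab[match(node, fixed_key), , drop = FALSE]
    if (is.na(frow$chrom[1])) stop("node absent from its universe: ", node)
    cand <- partner_tab[partner_tab$chrom == frow$chrom, , drop = FALSE]
    if (respect_min_distance) {
      gap <- interval_gap(frow$start, frow$end, cand$start, cand$end)
      cand <- cand[gap >= min_distance, , drop = FALSE]
    }
    if (nrow(cand) < d) {
      stop(sprintf("randomization universe too small for node '%s' (degree %d, %d candidates)",
                   node, d, nrow(cand)))
    }
    pick <- cand[sample.int(nrow(cand), d), , drop = FALSE]
    out[[i]] <- if (partner_is_promoter) {
      .make_ieps(frow[rep(1, d), , drop = FALSE], pick,
                 support = rep(NA_real_, d), source = "random",
                 evidence_id = NA_character_)
    } else {
      .make_ieps(pick, frow[rep(1, d), , drop = FALSE],
                 support = rep(NA_real_, d), source = "random",
                 evidence_id = NA_character_)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$enh_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Upper-tail binomial p-value
#'
#' Probability of observing at least `k` successes in `n` trials at success
#' probability `p`: 1 minus the sum over i = 0..k-1 of C(n, i) p^i
#' (1-p)^(n-i). Evaluated as the complementary (upper-tail) sum in log
#' space, which stays accurate for the large n and tiny tail probabilities
#' encountered with genome-scale IEP sets.
#'
#' @param n Number of trials (non-negative integer).
#' @param k Observed success count, 0 <= k <= n; `k = 0` gives 1.
#' @param p Success probability in \[0, 1\].
#' @return The p-value; values underflowing double precision are 0.
#' @export
binomial_pvalue <- function(n, k, p) {
  if (length(n) != 1 || length(k) != 1 || length(p) != 1) {
    stop("n, k and p must be scalars")
  }
  if (is.na(n) || is.na(k) || is.na(p) || n < 0 || k < 0 || k > n ||
      p < 0 || p > 1) {
    stop("require 0 <= k <= n and 0 <= p <= 1")
  }
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- seq.int(k, n)
  logterms <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(logterms)
  val <- exp(m + log(sum(exp(logterms - m))))
  min(1, val)
}

#' Compare observed per-node BCCs with a randomized null pool
#'
#' The observed pool (nodes with multiple partners and defined BCC, see
#' [bcc_pool()]) is compared with the pooled per-node BCCs from
#' degree-preserving random IEP replicates: the null frequency of BCC
#' strictly above `threshold` becomes the binomial probability parameter
#' `p`, and the observed count `k` out of `n` nodes above the threshold is
#' tested with [binomial_pvalue()].
#'
#' @param original_bccs Numeric vector of observed per-node BCCs (already
#'   restricted to multi-partner nodes).
#' @param null_bccs Numeric vector pooling per-node BCCs across all random
#'   replicates (may be empty: `p` is then 0).
#' @param threshold High-BCC threshold, strictly exceeded (default 0.9).
#' @return Object of class `binomial_comparison` with fields `p`, `n`, `k`,
#'   `p_value`, `threshold`.
#' @export
compare_to_null <- function(original_bccs, null_bccs, threshold = 0.9) {
  original_bccs <- original_bccs[!is.na(original_bccs)]
  null_bccs <- null_bccs[!is.na(null_bccs)]
  if (length(original_bccs) == 0) stop("empty original BCC pool")
  p <- if (length(null_bccs) == 0) 0 else mean(null_bccs > threshold)
  n <- length(original_bccs)
  k <- sum(original_bccs > threshold)
  structure(list(p = p, n = n, k = k,
                 p_value = binomial_pvalue(n, k, p), threshold = threshold),
            class = "binomial_comparison")
}

#' @export
print.binomial_comparison <- function(x, ...) {
  cat(sprintf(
    "binomial test: %d of %d observed nodes with BCC > %.2f (null frequency %.4f)\n",
    x$k, x$n, x$threshold, x$p))
  cat(sprintf("  p-value = %g\n", x$p_value))
  invisible(x)
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' Compares two samples (e.g. within-cluster enhancer distances or
#' sequence-similarity scores vs their random counterparts) with the
#' standard two-sided Mann-Whitney U test, normal approximation with tie
#' correction.
#'
#' @param xs,ys Non-empty numeric samples.
#' @return List with `U` (statistic for `xs`) and `p_value`.
#' @export
rank_compare <- function(xs, ys) {
  if (length(xs) == 0 || length(ys) == 0) stop("both samples must be non-empty")
  w <- suppressWarnings(
    stats::wilcox.test(xs, ys, alternative = "two.sided", exact = FALSE,
                       correct = TRUE))
  list(U = unname(w$statistic), p_value = w$p.value)
}
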