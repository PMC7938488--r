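#' Overlap of enhancer clusters with super-enhancers
#'
#' A cluster overlaps a super-enhancer (SE) when its genomic span -- the
#' region from the first to the last member enhancer -- shares at least one
#' bp with the SE. Both directional percentages are reported, plus, for
#' every overlapping (cluster, SE) pair, the fraction of the cluster span
#' lying within the SE.
#'
#' @param clusters An [find_enhancer_clusters()] result.
#' @param super_enhancers SE intervals (`chrom`, `start`, `end`, `id`).
#' @return Object of class `overlap_report` with fields
#'   `pct_clusters_hitting_se`, `pct_se_hitting_clusters`,
#'   `span_within_se_fractions` (named `cluster_id|se_id`).
#' @export
se_overlap <- function(clusters, super_enhancers) {
  .check_intervals(super_enhancers, "super-enhancers")
  spans <- .cluster_spans(clusters)
  hits <- .overlap_pairs(spans, super_enhancers)
  fractions <- numeric(0)
  if (nrow(hits) > 0) {
    ov <- pmin(spans$end[hits$q], super_enhancers$end[hits$s]) -
      pmax(spans$start[hits$q], super_enhancers$start[hits$s])
    fractions <- ov / (spans$end[hits$q] - spans$start[hits$q])
    names(fractions) <- paste(spans$id[hits$q],
                              super_enhancers$id[hits$s], sep = "|")
  }
  pct_of <- function(n_hit, n_tot) if (n_tot == 0) NA_real_ else 100 * n_hit / n_tot
  structure(list(
    pct_clusters_hitting_se = pct_of(length(unique(hits$q)), nrow(spans)),
    pct_se_hitting_clusters = pct_of(length(unique(hits$s)),
                                     nrow(super_enhancers)),
    span_within_se_fractions = fractions
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("clusters overlapping an SE: %s%%\n",
              format(x$pct_clusters_hitting_se, digits = 4)))
  cat(sprintf("SEs overlapping a cluster: %s%%\n",
              format(x$pct_se_hitting_clusters, digits = 4)))
  if (length(x$span_within_se_fractions) > 0) {
    cat(sprintf("mean span fraction within SE: %s\n",
                format(mean(x$span_within_se_fractions), digits = 4)))
  }
  invisible(x)
}

.cluster_spans <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0)))
  }
  data.frame(chrom = vapply(clusters, `[[`, character(1), "chrom"),
             start = vapply(clusters, `[[`, numeric(1), "span_start"),
             end = vapply(clusters, `[[`, numeric(1), "span_end"),
             id = vapply(clusters, `[[`, character(1), "cluster_id"))
}

#' Containment of cluster members within a single TAD
#'
#' For each cluster, the TAD fully containing the most member enhancers is
#' chosen (ties broken by leftmost TAD start) and the percentage of members
#' it contains is reported. A member straddling a TAD boundary is not
#' contained. With `include_gaps = TRUE`, the gaps between consecutive TADs
#' on a chromosome are treated as implicit domains.
#'
#' @param clusters An [find_enhancer_clusters()] result.
#' @param tads TAD intervals (`chrom`, `start`, `end`, `id`).
#' @param enhancers Enhancer table giving member coordinates.
#' @param include_gaps Treat inter-TAD gaps as domains (default `FALSE`).
#' @return List with `per_cluster` (named percentage vector) and
#'   `average`.
#' @export
tad_containment <- function(clusters, tads, enhancers, include_gaps = FALSE) {
  .check_intervals(tads, "TADs")
  if (include_gaps) tads <- rbind(tads, .tad_gaps(tads))
  per_cluster <- vapply(clusters, function(cl) {
    idx <- match(cl$members, enhancers$id)
    if (any(is.na(idx))) stop("cluster member missing from enhancer table")
    m_start <- enhancers$start[idx]; m_end <- enhancers$end[idx]
    cand <- tads[tads$chrom == cl$chrom, , drop = FALSE]
    if (nrow(cand) == 0) return(0)
    cand <- cand[order(cand$start, cand$end), , drop = FALSE]
    contained <- vapply(seq_len(nrow(cand)), function(t) {
      sum(m_start >= cand$start[t] & m_end <= cand$end[t])
    }, numeric(1))
    100 * max(contained) / length(idx)
  }, numeric(1))
  names(per_cluster) <- vapply(clusters, `[[`, character(1), "cluster_id")
  list(per_cluster = per_cluster,
       average = if (length(per_cluster) > 0) mean(per_cluster) else NA_real_)
}

# Implicit domains between consecutive TADs on each chromosome.
.tad_gaps <- function(tads) {
  out <- lapply(split(tads, tads$chrom), function(tt) {
    tt <- tt[order(tt$start, tt$end), , drop = FALSE]
    if (nrow(tt) < 2) return(NULL)
    gs <- tt$end[-nrow(tt)]; ge <- tt$start[-1]
    keep <- ge > gs
    if (!any(keep)) return(NULL)
    data.frame(chrom = tt$chrom[1], start = gs[keep], end = ge[keep],
               id = paste0(tt$chrom[1], "_gap", which(keep)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0))
  }
  rownames(out) <- NULL
  out
}
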