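# Assemble the canonical IEP data.frame from matched enhancer/promoter rows.
.make_ieps <- function(enh_rows, prom_rows, support, source, evidence_id) {
  if (length(support) == 0) return(.empty_ieps())
  data.frame(iep_id = paste(enh_rows$id, prom_rows$gene_id, sep = "::"),
             chrom = enh_rows$chrom,
             enh_start = enh_rows$start, enh_end = enh_rows$end,
             enh_id = enh_rows$id, gene_id = prom_rows$gene_id,
             tss = prom_rows$tss, strand = prom_rows$strand,
             support = support, source = source,
             evidence_id = evidence_id, stringsAsFactors = FALSE)
}

# Collapse duplicate (enh_id, gene_id) rows keeping the maximum support
# (records at adjacent bins are not independent, so supports are not summed;
# NA support loses to any numeric support).
.dedupe_ieps <- function(ieps) {
  if (nrow(ieps) == 0) return(ieps)
  key <- paste(ieps$enh_id, ieps$gene_id)
  ord <- order(key, -xtfrm(ifelse(is.na(ieps$support), -Inf, ieps$support)))
  ieps <- ieps[ord, , drop = FALSE]
  out <- ieps[!duplicated(paste(ieps$enh_id, ieps$gene_id)), , drop = FALSE]
  out <- out[order(out$enh_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build IEPs by overlapping features with interaction anchors
#'
#' For every interaction pair, each enhancer overlapping one anchor is
#' combined with each promoter overlapping the *other* anchor (both
#' orientations are considered). Pairs are only formed across anchors, so a
#' single wide feature overlapping both anchors never creates
#' self-evidence. Duplicates arising from several records are collapsed,
#' keeping the maximum support.
#'
#' @param enhancers Active enhancer intervals (`chrom`, `start`, `end`, `id`).
#' @param promoters Active promoter windows from [derive_promoters()].
#' @param pairs Interaction pairs from [read_looplist()] or
#'   [read_link_table()].
#' @return IEP data.frame with columns `iep_id`, `chrom`, `enh_start`,
#'   `enh_end`, `enh_id`, `gene_id`, `tss`, `strand`, `support`, `source`,
#'   `evidence_id`.
#' @export
overlap_ieps <- function(enhancers, promoters, pairs) {
  .check_intervals(enhancers, "enhancers")
  if (nrow(pairs) == 0 || nrow(enhancers) == 0 || nrow(promoters) == 0) {
    return(.empty_ieps())
  }
  a1 <- data.frame(chrom = pairs$chrom, start = pairs$a1_start,
                   end = pairs$a1_end)
  a2 <- data.frame(chrom = pairs$chrom, start = pairs$a2_start,
                   end = pairs$a2_end)
  prom_iv <- data.frame(chrom = promoters$chrom, start = promoters$start,
                        end = promoters$end)
  e1 <- .overlap_pairs(enhancers, a1)  # enhancer x anchor1 (s = pair row)
  e2 <- .overlap_pairs(enhancers, a2)
  p1 <- .overlap_pairs(prom_iv, a1)
  p2 <- .overlap_pairs(prom_iv, a2)
  combine <- function(eh, ph) {
    m <- merge(eh, ph, by = "s", suffixes = c("_e", "_p"))
    if (nrow(m) == 0) return(.empty_ieps())
    .make_ieps(enhancers[m$q_e, , drop = FALSE],
               promoters[m$q_p, , drop = FALSE],
               support = pairs$support[m$s],
               source = pairs$source[m$s],
               evidence_id = pairs$pair_id[m$s])
  }
  out <- rbind(combine(e1, p2), combine(e2, p1))
  .dedupe_ieps(out)
}

#' Build IEPs from normalized contact records at a read-count cutoff
#'
#' An enhancer-promoter pair becomes an IEP when some pair of bins they
#' overlap is supported by at least `cutoff` normalized reads (inclusive).
#' The support recorded is the maximum qualifying count. Output is monotone
#' non-increasing in `cutoff`.
#'
#' @param enhancers,promoters As in [overlap_ieps()].
#' @param contacts Contact records from [read_contact_records()].
#' @param cutoff Normalized read-count threshold (e.g. 30, 50, 100; 400 for
#'   very deeply sequenced samples).
#' @param resolution Bin size in bp; defaults to the `resolution` attribute
#'   of `contacts`, else 5000.
#' @return IEP data.frame (see [overlap_ieps()]), `source = "matrix"`.
#' @export
cutoff_ieps <- function(enhancers, promoters, contacts, cutoff,
                        resolution = NULL) {
  if (is.null(resolution)) {
    resolution <- attr(contacts, "resolution")
    if (is.null(resolution)) resolution <- 5000
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  qual <- contacts[contacts$normalized_count >= cutoff, , drop = FALSE]
  if (nrow(qual) == 0) return(.empty_ieps())
  pairs <- data.frame(pair_id = paste0("contact", seq_len(nrow(qual)) - 1L),
                      chrom = qual$chrom,
                      a1_start = as.integer(qual$bin_i),
                      a1_end = as.integer(qual$bin_i + resolution),
                      a2_start = as.integer(qual$bin_j),
                      a2_end = as.integer(qual$bin_j + resolution),
                      support = qual$normalized_count, source = "matrix")
  overlap_ieps(enhancers, promoters, pairs)
}

#' Remove IEPs whose enhancer and promoter are closer than a minimum distance
#'
#' Distance is the gap between the enhancer interval and the promoter
#' window (0 when they overlap); IEPs with gap `>= min_distance` are kept,
#' so overlapping or near-adjacent features are filtered out. Idempotent.
#'
#' @param ieps IEP data.frame.
#' @param promoters Promoter windows; looked up by `gene_id` (an IEP
#'   referencing an unknown gene is an error). When `NULL`, windows are
#'   reconstructed from the IEP's `tss`/`strand` columns at the default
#'   1000/100 extents.
#' @param min_distance Minimum enhancer-promoter gap in bp (default 2500).
#' @return Filtered IEP data.frame.
#' @export
distance_filter <- function(ieps, promoters = NULL, min_distance = 2500) {
  if (nrow(ieps) == 0) return(ieps)
  if (is.null(promoters)) {
    promoters <- derive_promoters(
      data.frame(gene_id = ieps$gene_id, chrom = ieps$chrom,
                 tss = ieps$tss, strand = ieps$strand))
    promoters <- promoters[!duplicated(promoters$gene_id), , drop = FALSE]
  }
  idx <- match(ieps$gene_id, promoters$gene_id)
  if (any(is.na(idx))) {
    stop("IEP references unknown gene_id: ",
         paste(unique(ieps$gene_id[is.na(idx)]), collapse = ", "))
  }
  gap <- interval_gap(ieps$enh_start, ieps$enh_end,
                      promoters$start[idx], promoters$end[idx])
  out <- ieps[gap >= min_distance, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate IEP counts per source (and optional sample label)
#'
#' @param ieps IEP data.frame; a `label` column, when present, is used as a
#'   second grouping variable.
#' @return data.frame of counts with a `total` attribute.
#' @export
subset_counts <- function(ieps) {
  if (nrow(ieps) == 0) {
    out <- data.frame(source = character(0), n_ieps = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  groups <- if ("label" %in% names(ieps)) {
    list(source = ieps$source, label = ieps$label)
  } else {
    list(source = ieps$source)
  }
  out <- stats::aggregate(list(n_ieps = rep(1L, nrow(ieps))), groups, sum)
  out <- out[do.call(order, out[setdiff(names(out), "n_ieps")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- nrow(ieps)
  out
}
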