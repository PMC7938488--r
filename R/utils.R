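#' Normalize chromosome naming style
#'
#' Interaction files from different sources disagree on the `chr` prefix
#' (e.g. GSE63525 loop lists use `1`, GENCODE uses `chr1`). All readers pass
#' chromosome names through this helper so a single style is used internally.
#'
#' @param x Character vector of chromosome names.
#' @param style Either `"chr"` (default; prefix added when absent) or
#'   `"plain"` (prefix stripped).
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("1", "chrX"))          # "chr1" "chrX"
#' normalize_chrom(c("1", "chrX"), "plain") # "1" "X"
normalize_chrom <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  if (style == "chr") paste0("chr", bare) else bare
}

#' Gap between two genomic intervals
#'
#' Distance in bp between the closest ends of two 0-based half-open
#' intervals; 0 when they overlap or touch. Vectorized.
#'
#' @param start1,end1,start2,end2 Integer-like coordinate vectors.
#' @return Numeric vector of gaps (bp).
#' @export
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start1, start2) - pmin(end1, end2))
}

# Validate a data.frame of 0-based half-open intervals with columns
# chrom/start/end/id. Used by every operation consuming feature sets.
.check_intervals <- function(df, what = "intervals") {
  need <- c("chrom", "start", "end", "id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing column(s) %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(df) > 0) {
    if (any(df$end <= df$start)) stop(sprintf("%s: end <= start", what))
    if (any(df$start < 0)) stop(sprintf("%s: negative start", what))
    if (anyDuplicated(df$id)) stop(sprintf("%s: duplicated ids", what))
  }
  invisible(df)
}

# All pairwise overlaps (>= 1 bp) between two interval data.frames.
# Returns data.frame(q, s) of row indices. Coordinates are 0-based
# half-open, converted to 1-based closed for IRanges.
.overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(q = integer(0), s = integer(0)))
  }
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start + 1L, query$end))
  s <- GenomicRanges::GRanges(subject$chrom,
                              IRanges::IRanges(subject$start + 1L, subject$end))
  suppressWarnings(h <- GenomicRanges::findOverlaps(q, s))
  data.frame(q = S4Vectors::queryHits(h), s = S4Vectors::subjectHits(h))
}

# TRUE for query rows overlapping >= 1 subject interval.
.overlaps_any <- function(query, subject) {
  hits <- .overlap_pairs(query, subject)
  seq_len(nrow(query)) %in% hits$q
}

# Empty IEP data.frame with the canonical column set.
.empty_ieps <- function() {
  data.frame(iep_id = character(0), chrom = character(0),
             enh_start = integer(0), enh_end = integer(0),
             enh_id = character(0), gene_id = character(0),
             tss = integer(0), strand = character(0),
             support = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

.check_ieps <- function(ieps) {
  need <- c("iep_id", "chrom", "enh_start", "enh_end", "enh_id",
            "gene_id", "tss", "strand", "support", "source")
  miss <- setdiff(need, names(ieps))
  if (length(miss) > 0) {
    stop("IEP table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(paste(ieps$enh_id, ieps$gene_id))) {
    stop("IEP table contains duplicate (enh_id, gene_id) pairs")
  }
  invisible(ieps)
}
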