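#' Describe activity evidence for enhancers or promoters
#'
#' Activity filtering is cell-specific: enhancers are called active when
#' they overlap H3K27ac ChIP-seq peaks (or, for samples without H3K27ac
#' data, the interaction anchors themselves); promoters are called active
#' when their gene is expressed at or above a threshold. `kind = "none"`
#' encodes the no-filter case (segmentation enhancers that are already
#' cell-specific, or samples without RNA-seq where every promoter counts as
#' active).
#'
#' @param kind One of `"h3k27ac_peaks"`, `"anchors"`, `"expression_table"`,
#'   `"none"`.
#' @param data For peak/anchor evidence, an interval data.frame
#'   (`chrom`, `start`, `end`, `id`); for expression evidence, a data.frame
#'   with columns `gene_id` and `expression`.
#' @param expression_threshold Minimum expression (RPKM) for an active
#'   promoter; default 0.30, applied inclusively.
#' @return An object of class `activity_evidence`.
#' @export
activity_evidence <- function(kind = c("h3k27ac_peaks", "anchors",
                                       "expression_table", "none"),
                              data = NULL, expression_threshold = 0.30) {
  kind <- match.arg(kind)
  if (expression_threshold < 0) stop("expression_threshold must be >= 0")
  if (kind %in% c("h3k27ac_peaks", "anchors")) {
    if (is.null(data)) stop("interval data required for ", kind, " evidence")
    .check_intervals(data, "evidence intervals")
  }
  if (kind == "expression_table") {
    if (is.null(data) || !all(c("gene_id", "expression") %in% names(data))) {
      stop("expression evidence needs a data.frame with gene_id and expression")
    }
  }
  structure(list(kind = kind, data = data,
                 expression_threshold = expression_threshold),
            class = "activity_evidence")
}

#' Derive promoter windows from gene TSSs
#'
#' A promoter is the window from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS, orientation following the strand and the TSS base
#' itself included (1101 bp total at the defaults). Windows are clipped at
#' position 0; one promoter is produced per gene.
#'
#' @param genes Gene data.frame from [read_gencode_genes()].
#' @param upstream,downstream Window extent in bp (defaults 1000 and 100).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `tss`, `strand`; coordinates 0-based half-open.
#' @export
derive_promoters <- function(genes, upstream = 1000, downstream = 100) {
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      tss = integer(0), strand = character(0)))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("genes with invalid strand")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream + 1L, genes$tss + upstream + 1L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(pmax(0, start)), end = as.integer(end),
             tss = genes$tss, strand = genes$strand)
}

#' Filter enhancers for cell-specific activity
#'
#' Keeps enhancers overlapping (by at least 1 bp, half-open arithmetic) at
#' least one evidence interval. With `kind = "none"` the input is returned
#' unchanged.
#'
#' @param enhancers Interval data.frame (`chrom`, `start`, `end`, `id`).
#' @param evidence An [activity_evidence()] object of kind
#'   `"h3k27ac_peaks"`, `"anchors"` or `"none"`.
#' @return Subset of `enhancers`.
#' @export
filter_active_enhancers <- function(enhancers, evidence) {
  stopifnot(inherits(evidence, "activity_evidence"))
  .check_intervals(enhancers, "enhancers")
  if (evidence$kind == "expression_table") {
    stop("expression evidence applies to promoters, not enhancers")
  }
  if (evidence$kind == "none") return(enhancers)
  keep <- .overlaps_any(enhancers, evidence$data)
  out <- enhancers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter promoters for cell-specific activity
#'
#' Keeps promoters whose gene is expressed at or above the evidence
#' threshold (inclusive). Genes absent from the expression table are
#' treated as unexpressed and reported via a message. With `kind = "none"`
#' every promoter is kept (the rule for samples without RNA-seq data).
#'
#' @param promoters Promoter data.frame from [derive_promoters()].
#' @param evidence An [activity_evidence()] object of kind
#'   `"expression_table"` or `"none"`.
#' @return Subset of `promoters`.
#' @export
filter_active_promoters <- function(promoters, evidence) {
  stopifnot(inherits(evidence, "activity_evidence"))
  if (!evidence$kind %in% c("expression_table", "none")) {
    stop("promoter activity needs expression_table or none evidence")
  }
  if (evidence$kind == "none") return(promoters)
  tab <- evidence$data
  expr <- tab$expression[match(promoters$gene_id, tab$gene_id)]
  n_missing <- sum(is.na(expr))
  if (n_missing > 0) {
    message(sprintf("%d promoter gene(s) absent from expression table; treated as 0",
                    n_missing))
    expr[is.na(expr)] <- 0
  }
  out <- promoters[expr >= evidence$expression_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
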