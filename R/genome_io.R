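#' Read a BED3+ file of genomic intervals
#'
#' Reads enhancers, H3K27ac peaks, TADs or super-enhancers from BED-like
#' text. BED's native 0-based half-open coordinates are preserved, which is
#' the canonical convention of every interval in this package. Header,
#' `track` and `browser` lines are tolerated.
#'
#' @param path Path to a tab-separated BED3+ file.
#' @param id_prefix Prefix used to assign ids `prefix0, prefix1, ...` when
#'   the 4th (name) column is absent.
#' @param chrom_style Chromosome naming style, see [normalize_chrom()].
#' @return data.frame with columns `chrom`, `start`, `end`, `id`.
#' @export
read_bed_intervals <- function(path, id_prefix = "iv", chrom_style = "chr") {
  lines <- readLines(path)
  is_data <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(is_data)
  if (length(idx) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0)))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- length(idx)
  chrom <- character(n); start <- integer(n); end <- integer(n); id <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop(sprintf("malformed BED line %d: fewer than 3 columns", idx[i]))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("malformed BED line %d: non-integer coordinates", idx[i]))
    }
    if (e <= s) {
      stop(sprintf("malformed BED line %d: end <= start", idx[i]))
    }
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    id[i] <- if (length(f) >= 4 && nzchar(f[4])) f[4] else paste0(id_prefix, i - 1L)
  }
  out <- data.frame(chrom = normalize_chrom(chrom, chrom_style),
                    start = start, end = end, id = id)
  .check_intervals(out, basename(path))
  out
}

#' Read gene records from a GENCODE-style GTF
#'
#' Extracts one record per `gene` feature row. GTF coordinates are 1-based
#' inclusive; the transcriptional start site (TSS) is converted to a 0-based
#' position: `start - 1` for `+` strand genes and `end - 1` for `-` strand
#' genes. Rows with unknown strand are skipped with a warning; a missing
#' `gene_id` attribute is an error.
#'
#' @param path Path to a GTF file.
#' @param chrom_style Chromosome naming style, see [normalize_chrom()].
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `gene_name`.
#' @export
read_gencode_genes <- function(path, chrom_style = "chr") {
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "gene")
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0),
                      gene_name = character(0)))
  }
  gene_id <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (is.null(gene_id) || any(is.na(gene_id) | !nzchar(gene_id))) {
    stop("GTF gene row(s) without a gene_id attribute")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sprintf("skipped %d gene row(s) with unknown strand", sum(bad)))
  }
  gr <- gr[!bad]; gene_id <- gene_id[!bad]; strand <- strand[!bad]
  tss <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L,
                BiocGenerics::end(gr) - 1L)
  gene_name <- S4Vectors::mcols(gr)$gene_name
  if (is.null(gene_name)) gene_name <- rep(NA_character_, length(gr))
  data.frame(gene_id = gene_id,
             chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr)),
                                     chrom_style),
             tss = as.integer(tss), strand = strand,
             gene_name = as.character(gene_name))
}

# Canonical empty pair table (one row per two-anchor interaction record).
.empty_pairs <- function() {
  data.frame(pair_id = character(0), chrom = character(0),
             a1_start = integer(0), a1_end = integer(0),
             a2_start = integer(0), a2_end = integer(0),
             support = numeric(0), source = character(0))
}

# Order anchors within each pair so a1_start <= a2_start.
.order_anchors <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  flip <- pairs$a1_start > pairs$a2_start
  if (any(flip)) {
    tmp_s <- pairs$a1_start[flip]; tmp_e <- pairs$a1_end[flip]
    pairs$a1_start[flip] <- pairs$a2_start[flip]
    pairs$a1_end[flip] <- pairs$a2_end[flip]
    pairs$a2_start[flip] <- tmp_s
    pairs$a2_end[flip] <- tmp_e
  }
  pairs
}

#' Read a Hi-C loop list
#'
#' Reads the GSE63525 loop-list dialect: a tab-separated table with a header
#' and columns `chr1, x1, x2, chr2, y1, y2` (additional columns ignored).
#' Inter-chromosomal rows are skipped with a warning; loop lists carry no
#' quantitative support, stored as `NA` (never 0, so cutoff filters are not
#' wrongly triggered).
#'
#' @param path Path to the loop-list file.
#' @param chrom_style Chromosome naming style, see [normalize_chrom()].
#' @return data.frame of interaction pairs with columns `pair_id`, `chrom`,
#'   `a1_start`, `a1_end`, `a2_start`, `a2_end`, `support`, `source`.
#' @export
read_looplist <- function(path, chrom_style = "chr") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chr1", "x1", "x2", "chr2", "y1", "y2")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("loop list missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0) return(.empty_pairs())
  intra <- normalize_chrom(tab$chr1, chrom_style) ==
    normalize_chrom(tab$chr2, chrom_style)
  if (any(!intra)) {
    warning(sprintf("skipped %d inter-chromosomal loop row(s)", sum(!intra)))
  }
  tab <- tab[intra, , drop = FALSE]
  if (nrow(tab) == 0) return(.empty_pairs())
  out <- data.frame(pair_id = paste0("loop", seq_len(nrow(tab)) - 1L),
                    chrom = normalize_chrom(tab$chr1, chrom_style),
                    a1_start = as.integer(tab$x1), a1_end = as.integer(tab$x2),
                    a2_start = as.integer(tab$y1), a2_end = as.integer(tab$y2),
                    support = NA_real_, source = "looplist")
  .order_anchors(out)
}

#' Read sparse Hi-C contact records
#'
#' Reads a per-chromosome three-column sparse matrix (`bin_i`, `bin_j`,
#' count) at a fixed resolution. When a normalization vector is supplied
#' (one factor per bin, GSE63525 convention), raw counts are divided by the
#' product of the two bins' factors; entries with `NaN`/`NA` factors are
#' dropped. Records are stored upper-triangle (`bin_i <= bin_j`); symmetric
#' duplicates are collapsed keeping the maximum count.
#'
#' @param path Path to the sparse contact text file.
#' @param chrom Chromosome the file describes (sparse dumps are per-chrom).
#' @param resolution Bin size in bp (default 5000).
#' @param norm_vector_path Optional path to a one-column normalization
#'   vector; entry `i` corresponds to the bin starting at `(i-1)*resolution`.
#' @return data.frame with columns `chrom`, `bin_i`, `bin_j`,
#'   `normalized_count` and a `resolution` attribute.
#' @export
read_contact_records <- function(path, chrom = "chr1", resolution = 5000,
                                 norm_vector_path = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("bin_i", "bin_j", "count"),
                           colClasses = c("numeric", "numeric", "numeric"))
  out <- data.frame(chrom = character(0), bin_i = numeric(0),
                    bin_j = numeric(0), normalized_count = numeric(0))
  if (nrow(tab) > 0) {
    if (any(tab$bin_i %% resolution != 0 | tab$bin_j %% resolution != 0)) {
      stop("contact bin not a multiple of the resolution")
    }
    if (any(tab$count < 0)) stop("negative contact count")
    cnt <- tab$count
    if (!is.null(norm_vector_path)) {
      norm <- scan(norm_vector_path, what = numeric(), quiet = TRUE)
      fi <- norm[tab$bin_i / resolution + 1L]
      fj <- norm[tab$bin_j / resolution + 1L]
      cnt <- tab$count / (fi * fj)
    }
    keep <- is.finite(cnt)
    bi <- pmin(tab$bin_i, tab$bin_j)[keep]
    bj <- pmax(tab$bin_i, tab$bin_j)[keep]
    cnt <- cnt[keep]
    if (length(cnt) > 0) {
      key <- paste(bi, bj)
      agg <- tapply(cnt, key, max)
      first <- !duplicated(key)
      out <- data.frame(chrom = chrom, bin_i = bi[first], bin_j = bj[first],
                        normalized_count = as.numeric(agg[key[first]]))
      out <- out[order(out$bin_i, out$bin_j), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "resolution") <- resolution
  out
}

#' Read a generic two-anchor link table
#'
#' Unifies ChIA-PET, promoter-capture Hi-C and similar tables into the
#' interaction-pair form. A schema maps the table's column names onto the
#' two anchors and an optional support column.
#'
#' @param path Path to a tab-separated table with a header.
#' @param schema Named list with entries `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2` and optionally `support`, giving the column
#'   names in the file.
#' @param chrom_style Chromosome naming style, see [normalize_chrom()].
#' @return data.frame of interaction pairs (see [read_looplist()]), with
#'   `source = "link"`.
#' @export
read_link_table <- function(path, schema, chrom_style = "chr") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  miss <- setdiff(need, names(schema))
  if (length(miss) > 0) {
    stop("link schema missing entries: ", paste(miss, collapse = ", "))
  }
  cols <- unlist(schema[c(need, if (!is.null(schema$support)) "support")])
  absent <- setdiff(cols, names(tab))
  if (length(absent) > 0) {
    stop(sprintf("link table lacks column(s) %s; available: %s",
                 paste(absent, collapse = ", "),
                 paste(names(tab), collapse = ", ")))
  }
  if (nrow(tab) == 0) return(.empty_pairs())
  coord_cols <- unlist(schema[c("start1", "end1", "start2", "end2")])
  for (cc in coord_cols) {
    if (any(is.na(suppressWarnings(as.numeric(tab[[cc]]))))) {
      stop(sprintf("link table column '%s' has missing/non-numeric coordinates", cc))
    }
  }
  intra <- normalize_chrom(tab[[schema$chrom1]], chrom_style) ==
    normalize_chrom(tab[[schema$chrom2]], chrom_style)
  if (any(!intra)) {
    warning(sprintf("skipped %d inter-chromosomal link row(s)", sum(!intra)))
  }
  tab <- tab[intra, , drop = FALSE]
  if (nrow(tab) == 0) return(.empty_pairs())
  support <- if (!is.null(schema$support)) {
    as.numeric(tab[[schema$support]])
  } else {
    rep(NA_real_, nrow(tab))
  }
  out <- data.frame(pair_id = paste0("link", seq_len(nrow(tab)) - 1L),
                    chrom = normalize_chrom(tab[[schema$chrom1]], chrom_style),
                    a1_start = as.integer(tab[[schema$start1]]),
                    a1_end = as.integer(tab[[schema$end1]]),
                    a2_start = as.integer(tab[[schema$start2]]),
                    a2_end = as.integer(tab[[schema$end2]]),
                    support = support, source = "link")
  .order_anchors(out)
}

.IEP_VERSION_LINE <- "#bcc-iep v1"

#' Write / read the package's IEP TSV
#'
#' The IEP table is serialized as a version-stamped TSV with columns
#' `iep_id, chrom, enh_start, enh_end, enh_id, gene_id, tss, strand,
#' support, source`. `read_ieps(write_ieps(x, p), p)` is the identity on
#' these columns.
#'
#' @param ieps IEP data.frame (see [overlap_ieps()]).
#' @param path Output (input) file path.
#' @return `write_ieps` returns `path` invisibly; `read_ieps` returns the
#'   IEP data.frame.
#' @export
write_ieps <- function(ieps, path) {
  .check_ieps(ieps)
  cols <- c("iep_id", "chrom", "enh_start", "enh_end", "enh_id",
            "gene_id", "tss", "strand", "support", "source")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.IEP_VERSION_LINE, con)
  utils::write.table(ieps[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ieps
#' @export
read_ieps <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, .IEP_VERSION_LINE)) {
    stop(sprintf("not an IEP TSV (expected version line '%s', found '%s')",
                 .IEP_VERSION_LINE, first))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE,
                           colClasses = c(iep_id = "character",
                                          chrom = "character",
                                          enh_start = "integer",
                                          enh_end = "integer",
                                          enh_id = "character",
                                          gene_id = "character",
                                          tss = "integer",
                                          strand = "character",
                                          support = "numeric",
                                          source = "character"))
  if (nrow(tab) == 0) return(.empty_ieps())
  .check_ieps(tab)
  tab
}
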