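#' Configuration for the synthetic IEP generator
#'
#' Describes a miniature chromosome carrying planted enhancer-cluster /
#' gene-set bicliques: groups of nearby enhancers that all interact with
#' the same small set of genes, TADs covering whole clusters, singleton
#' enhancers with no planted interactions, and tunable false-positive /
#' false-negative edge noise. Defaults emulate the observed regime:
#' clusters of 2-5 enhancers targeting 1-4 genes, most intra-cluster gaps
#' within tens of kb with a rare tail out to 2 Mb, and all planted
#' enhancer-promoter gaps at least 2.5 kb so the distance filter is
#' vacuous on clean data.
#'
#' @param n_clusters Number of planted clusters (default 30).
#' @param members_per_cluster Range (or single value) of enhancers per
#'   cluster.
#' @param genes_per_cluster Range (or single value) of target genes per
#'   cluster.
#' @param intra_cluster_gap Log-uniform range (bp) for gaps between
#'   consecutive cluster enhancers.
#' @param gap_tail_prob Probability a gap is drawn from the long tail.
#' @param gap_tail_range Log-uniform range (bp) of the long tail.
#' @param enhancer_length Uniform range (bp) of enhancer lengths.
#' @param n_singleton_enhancers Enhancers with no planted interaction,
#'   placed inside TADs (they become false-positive partners under
#'   `noise_add_rate`).
#' @param chrom,chrom_length Chromosome name and length (bp).
#' @param tad_policy `"cover_clusters"` (one TAD per cluster containing all
#'   its features) or `"random"`.
#' @param noise_add_rate Probability of adding each possible non-planted
#'   IEP (within a TAD under `"cover_clusters"`, genome-wide otherwise).
#' @param noise_drop_rate Probability of deleting each planted IEP.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 30,
                             members_per_cluster = c(2, 5),
                             genes_per_cluster = c(1, 4),
                             intra_cluster_gap = c(1e3, 2e4),
                             gap_tail_prob = 0.05,
                             gap_tail_range = c(5e4, 2e6),
                             enhancer_length = c(200, 1000),
                             n_singleton_enhancers = 30,
                             chrom = "chr1", chrom_length = 250e6,
                             tad_policy = c("cover_clusters", "random"),
                             noise_add_rate = 0, noise_drop_rate = 0,
                             seed = 1) {
  tad_policy <- match.arg(tad_policy)
  rng <- function(x) if (length(x) == 1) c(x, x) else as.numeric(x[1:2])
  cfg <- list(n_clusters = as.integer(n_clusters),
              members_per_cluster = rng(members_per_cluster),
              genes_per_cluster = rng(genes_per_cluster),
              intra_cluster_gap = rng(intra_cluster_gap),
              gap_tail_prob = gap_tail_prob,
              gap_tail_range = rng(gap_tail_range),
              enhancer_length = rng(enhancer_length),
              n_singleton_enhancers = as.integer(n_singleton_enhancers),
              chrom = chrom, chrom_length = chrom_length,
              tad_policy = tad_policy,
              noise_add_rate = noise_add_rate,
              noise_drop_rate = noise_drop_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_clusters >= 1,
            cfg$noise_add_rate >= 0, cfg$noise_add_rate <= 1,
            cfg$noise_drop_rate >= 0, cfg$noise_drop_rate <= 1,
            all(cfg$members_per_cluster >= 2),
            all(cfg$genes_per_cluster >= 1),
            all(cfg$intra_cluster_gap >= 1000),
            all(cfg$enhancer_length >= 50))
  structure(cfg, class = "synthetic_config")
}

.runif_int <- function(lo, hi) if (lo == hi) as.integer(lo) else
  sample.int(hi - lo + 1L, 1L) + as.integer(lo) - 1L

.log_unif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))

#' Generate a synthetic IEP dataset with planted biclique structure
#'
#' Lays out features left to right without overlap, plants one complete
#' enhancer-gene biclique per cluster, then derives the noisy IEP list by
#' dropping planted edges and adding spurious ones at the configured rates.
#' All planted enhancer-to-promoter-window gaps are at least 2.5 kb.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_truth`: `enhancers` (with `role` and
#'   `cluster` columns), `genes`, `promoters`, `tads`, `planted_clusters`
#'   (member-id and gene-id sets), `clean_ieps`, `noisy_ieps`, `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_synthetic_impl(config))
}

.generate_synthetic_impl <- function(cfg) {
  enh <- list(); genes <- list(); tads <- list(); clusters <- list()
  strand_flip <- 0L
  cursor <- 10000
  singles_per_cluster <- tabulate(
    rep_len(seq_len(cfg$n_clusters), cfg$n_singleton_enhancers),
    nbins = cfg$n_clusters)
  for (k in seq_len(cfg$n_clusters)) {
    m <- .runif_int(cfg$members_per_cluster[1], cfg$members_per_cluster[2])
    g <- .runif_int(cfg$genes_per_cluster[1], cfg$genes_per_cluster[2])
    cluster_start <- cursor
    member_ids <- character(m)
    last_end <- cursor
    for (j in seq_len(m)) {
      len <- .runif_int(cfg$enhancer_length[1], cfg$enhancer_length[2])
      member_ids[j] <- sprintf("C%02dE%02d", k, j)
      enh[[length(enh) + 1L]] <- data.frame(
        chrom = cfg$chrom, start = cursor, end = cursor + len,
        id = member_ids[j], role = "member", cluster = k)
      last_end <- cursor + len
      gap <- if (stats::runif(1) < cfg$gap_tail_prob) {
        .log_unif(cfg$gap_tail_range[1], cfg$gap_tail_range[2])
      } else {
        .log_unif(cfg$intra_cluster_gap[1], cfg$intra_cluster_gap[2])
      }
      cursor <- last_end + round(gap)
    }
    # first promoter window starts exactly min_distance past the last member
    tss_base <- last_end + 3500
    gene_ids <- character(g)
    for (j in seq_len(g)) {
      strand <- if (strand_flip %% 2L == 0L) "+" else "-"
      strand_flip <- strand_flip + 1L
      gene_ids[j] <- sprintf("C%02dG%02d", k, j)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gene_ids[j], chrom = cfg$chrom,
        tss = tss_base + (j - 1L) * 5000L, strand = strand,
        gene_name = gene_ids[j], cluster = k)
    }
    last_tss <- tss_base + (g - 1L) * 5000L
    cursor <- last_tss + 1001 + 5000  # past the widest promoter window
    for (s in seq_len(singles_per_cluster[k])) {
      len <- .runif_int(cfg$enhancer_length[1], cfg$enhancer_length[2])
      enh[[length(enh) + 1L]] <- data.frame(
        chrom = cfg$chrom, start = cursor, end = cursor + len,
        id = sprintf("C%02dS%02d", k, s), role = "singleton", cluster = k)
      cursor <- cursor + len + 5000
    }
    tads[[k]] <- data.frame(chrom = cfg$chrom,
                            start = cluster_start - 1000,
                            end = cursor + 1000,
                            id = sprintf("tad%02d", k))
    clusters[[k]] <- list(members = member_ids, genes = gene_ids)
    cursor <- cursor + 50000
  }
  if (cursor > cfg$chrom_length) {
    stop(sprintf("infeasible layout: features extend to %.0f bp on a %.0f bp chromosome",
                 cursor, cfg$chrom_length))
  }
  enhancers <- do.call(rbind, enh)
  genes <- do.call(rbind, genes)
  tads <- do.call(rbind, tads)
  if (cfg$tad_policy == "random") {
    width <- round(vapply(seq_len(cfg$n_clusters), function(i)
      .log_unif(2e5, 2e6), numeric(1)))
    start <- round(stats::runif(cfg$n_clusters, 0, cfg$chrom_length - width))
    tads <- data.frame(chrom = cfg$chrom, start = start,
                       end = start + width,
                       id = sprintf("tad%02d", seq_len(cfg$n_clusters)))
  }
  promoters <- derive_promoters(genes)
  clean <- .planted_ieps(clusters, enhancers, genes)
  noisy <- .apply_edge_noise(clean, clusters, enhancers, genes, cfg)
  structure(list(enhancers = enhancers, genes = genes,
                 promoters = promoters, tads = tads,
                 planted_clusters = clusters,
                 clean_ieps = clean, noisy_ieps = noisy, config = cfg),
            class = "synthetic_truth")
}

.planted_ieps <- function(clusters, enhancers, genes) {
  rows <- lapply(clusters, function(cl) {
    expand.grid(enh_id = cl$members, gene_id = cl$genes,
                stringsAsFactors = FALSE)
  })
  combos <- do.call(rbind, rows)
  e <- enhancers[match(combos$enh_id, enhancers$id), , drop = FALSE]
  g <- genes[match(combos$gene_id, genes$gene_id), , drop = FALSE]
  out <- .make_ieps(e, g, support = rep(NA_real_, nrow(combos)),
                    source = "synthetic", evidence_id = NA_character_)
  out <- out[order(out$enh_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.apply_edge_noise <- function(clean, clusters, enhancers, genes, cfg) {
  keep <- stats::runif(nrow(clean)) >= cfg$noise_drop_rate
  noisy <- clean[keep, , drop = FALSE]
  # candidate spurious pairs: within-TAD under cover_clusters (each TAD
  # holds one cluster plus its singletons), genome-wide otherwise
  cand <- if (cfg$tad_policy == "cover_clusters") {
    do.call(rbind, lapply(seq_along(clusters), function(k) {
      singles <- enhancers$id[enhancers$role == "singleton" &
                                enhancers$cluster == k]
      if (length(singles) == 0) return(NULL)
      expand.grid(enh_id = singles, gene_id = clusters[[k]]$genes,
                  stringsAsFactors = FALSE)
    }))
  } else {
    all_pairs <- expand.grid(enh_id = enhancers$id,
                             gene_id = genes$gene_id,
                             stringsAsFactors = FALSE)
    planted_key <- paste(clean$enh_id, clean$gene_id)
    all_pairs[!(paste(all_pairs$enh_id, all_pairs$gene_id) %in% planted_key), ,
              drop = FALSE]
  }
  if (!is.null(cand) && nrow(cand) > 0 && cfg$noise_add_rate > 0) {
    add <- cand[stats::runif(nrow(cand)) < cfg$noise_add_rate, , drop = FALSE]
    if (nrow(add) > 0) {
      e <- enhancers[match(add$enh_id, enhancers$id), , drop = FALSE]
      g <- genes[match(add$gene_id, genes$gene_id), , drop = FALSE]
      noisy <- rbind(noisy,
                     .make_ieps(e, g, support = rep(NA_real_, nrow(add)),
                                source = "synthetic",
                                evidence_id = NA_character_))
    }
  }
  noisy <- noisy[order(noisy$enh_id, noisy$gene_id), , drop = FALSE]
  rownames(noisy) <- NULL
  noisy
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits the file dialects the readers consume: enhancer BED, a minimal
#' GENCODE-style GTF of gene rows, the IEP TSV (noisy list), a two-anchor
#' link table with 1-kb anchors centered on each IEP's enhancer midpoint
#' and TSS, TAD BED, a super-enhancer BED built from the spans of a subset
#' of planted clusters, and the truth as JSON. Re-reading the link table
#' and rebuilding IEPs through the overlap/distance pipeline reproduces the
#' noisy IEP list exactly.
#'
#' @param truth A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @param se_fraction Fraction of planted clusters whose spans become
#'   super-enhancer records (first `ceiling(fraction * n)` clusters).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixture <- function(truth, dir, se_fraction = 0.3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  paths <- c(enhancers = file.path(dir, "enhancers.bed"),
             genes = file.path(dir, "genes.gtf"),
             ieps = file.path(dir, "ieps.tsv"),
             links = file.path(dir, "links.tsv"),
             tads = file.path(dir, "tads.bed"),
             super_enhancers = file.path(dir, "super_enhancers.bed"),
             truth = file.path(dir, "truth.json"))
  enh <- truth$enhancers
  utils::write.table(enh[, c("chrom", "start", "end", "id")],
                     paths[["enhancers"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- truth$genes
  gtf_start <- ifelse(g$strand == "+", g$tss + 1L, pmax(1L, g$tss - 999L))
  gtf_end <- ifelse(g$strand == "+", g$tss + 1000L, g$tss + 1L)
  writeLines(sprintf(
    "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    g$chrom, gtf_start, gtf_end, g$strand, g$gene_id, g$gene_name),
    paths[["genes"]])
  write_ieps(truth$noisy_ieps, paths[["ieps"]])
  ni <- truth$noisy_ieps
  mid <- floor((ni$enh_start + ni$enh_end) / 2)
  links <- data.frame(chrom1 = ni$chrom, start1 = mid - 500L,
                      end1 = mid + 500L, chrom2 = ni$chrom,
                      start2 = ni$tss - 500L, end2 = ni$tss + 500L,
                      support = 1)
  utils::write.table(links, paths[["links"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(truth$tads[, c("chrom", "start", "end", "id")],
                     paths[["tads"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n_se <- ceiling(se_fraction * length(truth$planted_clusters))
  se <- do.call(rbind, lapply(utils::head(truth$planted_clusters, n_se),
                              function(cl) {
    idx <- match(cl$members, enh$id)
    data.frame(chrom = enh$chrom[idx[1]], start = min(enh$start[idx]),
               end = max(enh$end[idx]))
  }))
  if (is.null(se)) se <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0))
  se$id <- sprintf("SE%02d", seq_len(nrow(se)))
  utils::write.table(se, paths[["super_enhancers"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(planted_clusters = truth$planted_clusters,
         n_clean_ieps = nrow(truth$clean_ieps),
         n_noisy_ieps = nrow(truth$noisy_ieps),
         config = unclass(truth$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
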