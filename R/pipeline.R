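#' Validate a pipeline configuration
#'
#' Checks the configuration before any work: required fields, existence of
#' every referenced input path, and mode-specific requirements (a cutoff in
#' matrix mode, an anchor schema in link mode).
#'
#' @param config Named list; see [run_pipeline()] for the recognized
#'   fields.
#' @return The config, invisibly, with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  need <- c("out_dir", "enhancers", "gtf", "interactions", "mode")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    stop("pipeline config missing field(s): ", paste(miss, collapse = ", "))
  }
  if (!config$mode %in% c("looplist", "matrix", "link")) {
    stop("mode must be looplist, matrix or link")
  }
  if (config$mode == "matrix" && is.null(config$cutoff)) {
    stop("matrix mode requires a cutoff")
  }
  if (config$mode == "link" && is.null(config$link_schema)) {
    stop("link mode requires a link_schema")
  }
  paths <- c(config$enhancers, config$gtf, config$interactions,
             config$norm_vector, config[["expression"]],
             config$super_enhancers, config$tads,
             config$enhancer_evidence$path)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    stop("pipeline input path(s) not found: ", paste(absent, collapse = ", "))
  }
  defaults <- list(min_distance = 2500, chrom_style = "chr",
                   resolution = 5000, contact_chrom = "chr1",
                   expression_threshold = 0.30,
                   randomization = list(n_replicates = 5, seed_base = 1,
                                        side = "enhancer", threshold = 0.9),
                   skip = character(0))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  invisible(config)
}

#' Run the full IEP characterization pipeline
#'
#' Orchestrates feature definition, IEP construction, the distance filter,
#' BCC summaries on both sides, degree-preserving randomization with the
#' binomial test, enhancer clustering with per-cluster statistics, and
#' super-enhancer/TAD overlap, writing one plain TSV/JSON artifact per
#' stage plus a manifest so each stage can be audited independently. A
#' stage failure halts the run naming the stage; artifacts of completed
#' stages are preserved. Reruns with identical config produce identical
#' outputs.
#'
#' @param config Named list with fields: `out_dir`; input paths
#'   `enhancers` (BED), `gtf`, `interactions`, and optionally
#'   `norm_vector`, `expression` (TSV with `gene_id` and `expression`),
#'   `super_enhancers`, `tads` (BEDs), `enhancer_evidence`
#'   (`list(kind=, path=)`); `mode` one of `"looplist"`, `"matrix"`,
#'   `"link"` with `cutoff`/`resolution`/`contact_chrom` (matrix) or
#'   `link_schema` (link); `min_distance`; `randomization`
#'   (`n_replicates`, `seed_base`, `side`, `threshold`); `skip`, a vector
#'   of stage names among `"randomization"`, `"clustering"`, `"overlap"`.
#' @return Manifest list, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out <- function(f) file.path(cfg$out_dir, f)

  features <- stage("features", {
    enhancers <- read_bed_intervals(cfg$enhancers, id_prefix = "E",
                                    chrom_style = cfg$chrom_style)
    genes <- read_gencode_genes(cfg$gtf, chrom_style = cfg$chrom_style)
    promoters <- derive_promoters(genes)
    enh_ev <- if (is.null(cfg$enhancer_evidence)) {
      activity_evidence("none")
    } else {
      activity_evidence(cfg$enhancer_evidence$kind,
                        read_bed_intervals(cfg$enhancer_evidence$path,
                                           id_prefix = "ev",
                                           chrom_style = cfg$chrom_style))
    }
    prom_ev <- if (is.null(cfg[["expression"]])) {
      activity_evidence("none")
    } else {
      activity_evidence("expression_table",
                        utils::read.delim(cfg[["expression"]]),
                        expression_threshold = cfg$expression_threshold)
    }
    list(enhancers = filter_active_enhancers(enhancers, enh_ev),
         promoters = filter_active_promoters(promoters, prom_ev))
  })

  ieps <- stage("iep_construction", {
    x <- switch(cfg$mode,
      looplist = overlap_ieps(features$enhancers, features$promoters,
                              read_looplist(cfg$interactions,
                                            chrom_style = cfg$chrom_style)),
      link = overlap_ieps(features$enhancers, features$promoters,
                          read_link_table(cfg$interactions, cfg$link_schema,
                                          chrom_style = cfg$chrom_style)),
      matrix = cutoff_ieps(features$enhancers, features$promoters,
                           read_contact_records(cfg$interactions,
                                                chrom = cfg$contact_chrom,
                                                resolution = cfg$resolution,
                                                norm_vector_path = cfg$norm_vector),
                           cutoff = cfg$cutoff,
                           resolution = cfg$resolution))
    x <- distance_filter(x, features$promoters,
                         min_distance = cfg$min_distance)
    write_ieps(x, out("ieps.tsv"))
    x
  })

  graph <- bipartite_graph(ieps)
  bcc <- stage("bcc", {
    summaries <- list()
    for (side in c("enhancer", "promoter")) {
      for (restrict in c("all", "multiple")) {
        s <- average_bcc(graph, side, restrict)
        summaries[[paste(side, restrict, sep = "_")]] <-
          list(side = s$side, restrict = s$restrict, mean_bcc = s$mean_bcc,
               n_eligible = s$n_eligible,
               pct_multi_sharing = s$pct_multi_sharing,
               pct_ge_threshold = s$pct_ge_threshold,
               per_node = as.list(s$per_node))
      }
    }
    jsonlite::write_json(summaries, out("bcc_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    summaries
  })

  seeds <- NULL
  if (!"randomization" %in% cfg$skip && nrow(ieps) > 0) {
    stage("randomization", {
      rnd <- cfg$randomization
      seeds <- rnd$seed_base + seq_len(rnd$n_replicates) - 1L
      null_pool <- unlist(lapply(seeds, function(s) {
        bcc_pool(bipartite_graph(
          randomize_ieps(ieps, features$enhancers, features$promoters,
                         side = rnd$side, seed = s,
                         min_distance = cfg$min_distance)), rnd$side)
      }))
      observed <- bcc_pool(graph, rnd$side)
      res <- if (length(observed) > 0) {
        cmp <- compare_to_null(observed, null_pool, threshold = rnd$threshold)
        list(side = rnd$side, seeds = seeds, threshold = rnd$threshold,
             null_mean_bcc = if (length(null_pool) > 0) mean(null_pool) else NA,
             observed_mean_bcc = mean(observed),
             p = cmp$p, n = cmp$n, k = cmp$k, p_value = cmp$p_value)
      } else {
        list(side = rnd$side, seeds = seeds, threshold = rnd$threshold,
             note = "no multi-partner nodes in observed IEPs")
      }
      jsonlite::write_json(res, out("null_test.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    })
  }

  clusters <- NULL
  if (!"clustering" %in% cfg$skip) {
    clusters <- stage("clustering", {
      cl <- find_enhancer_clusters(ieps, features$enhancers)
      utils::write.table(clusters_to_df(cl), out("clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gene_iv <- data.frame(chrom = features$promoters$chrom,
                            start = features$promoters$start,
                            end = features$promoters$end,
                            id = features$promoters$gene_id)
      if (length(cl) > 0) {
        st <- lapply(cl, cluster_stats, features$enhancers, gene_iv)
        agg <- function(f) mean(vapply(st, `[[`, numeric(1), f), na.rm = TRUE)
        jsonlite::write_json(
          list(n_clusters = length(cl),
               mean_pct_within_10kb = agg("pct_within_10kb"),
               mean_pct_over_50kb = agg("pct_over_50kb"),
               mean_pct_members_consecutive = agg("pct_members_consecutive"),
               mean_pct_targets_consecutive = agg("pct_targets_consecutive"),
               mean_pct_partially_shared = agg("pct_partially_shared")),
          out("cluster_stats.json"), auto_unbox = TRUE, digits = NA,
          na = "null")
      }
      cl
    })
  }

  if (!"overlap" %in% cfg$skip && !is.null(clusters) && length(clusters) > 0) {
    stage("overlap", {
      rep <- list()
      if (!is.null(cfg$super_enhancers)) {
        se <- se_overlap(clusters,
                         read_bed_intervals(cfg$super_enhancers, "SE",
                                            chrom_style = cfg$chrom_style))
        rep$pct_clusters_hitting_se <- se$pct_clusters_hitting_se
        rep$pct_se_hitting_clusters <- se$pct_se_hitting_clusters
        rep$mean_span_within_se <- if (length(se$span_within_se_fractions))
          mean(se$span_within_se_fractions) else NA
      }
      if (!is.null(cfg$tads)) {
        tc <- tad_containment(clusters,
                              read_bed_intervals(cfg$tads, "TAD",
                                                 chrom_style = cfg$chrom_style),
                              features$enhancers)
        rep$mean_pct_members_in_single_tad <- tc$average
      }
      if (length(rep) > 0) {
        jsonlite::write_json(rep, out("overlap.json"), auto_unbox = TRUE,
                             digits = NA, na = "null")
      }
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("iepbcc")),
    mode = cfg$mode, min_distance = cfg$min_distance,
    cutoff = cfg$cutoff, randomization_seeds = seeds,
    inputs = as.list(tools::md5sum(c(enhancers = cfg$enhancers,
                                     gtf = cfg$gtf,
                                     interactions = cfg$interactions))),
    n_active_enhancers = nrow(features$enhancers),
    n_active_promoters = nrow(features$promoters),
    n_ieps = nrow(ieps),
    n_clusters = if (is.null(clusters)) NA else length(clusters),
    enhancer_mean_bcc = bcc$enhancer_all$mean_bcc,
    promoter_mean_bcc = bcc$promoter_all$mean_bcc)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest)
}
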