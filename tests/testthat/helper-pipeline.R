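# Standard schema for the link tables emitted by emit_fixture().
fixture_link_schema <- function() {
  list(chrom1 = "chrom1", start1 = "start1", end1 = "end1",
       chrom2 = "chrom2", start2 = "start2", end2 = "end2",
       support = "support")
}

# Rewrite an emitted link table in the loop-list dialect (header
# chr1,x1,x2,chr2,y1,y2).
write_looplist_from_links <- function(links_path, out_path) {
  tab <- utils::read.delim(links_path)
  loop <- data.frame(chr1 = tab$chrom1, x1 = tab$start1, x2 = tab$end1,
                     chr2 = tab$chrom2, y1 = tab$start2, y2 = tab$end2)
  utils::write.table(loop, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out_path
}

# Rewrite an emitted link table as a sparse 5-kb contact file: one contact
# per link joining the bins of the two anchor midpoints, all at the given
# count. Returns the contact path.
write_contacts_from_links <- function(links_path, out_path, count = 50,
                                      resolution = 5000) {
  tab <- utils::read.delim(links_path)
  mid1 <- floor((tab$start1 + tab$end1) / 2)
  mid2 <- floor((tab$start2 + tab$end2) / 2)
  con <- data.frame(bin_i = floor(mid1 / resolution) * resolution,
                    bin_j = floor(mid2 / resolution) * resolution,
                    count = count)
  utils::write.table(con, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  out_path
}

# Emit a synthetic fixture and assemble a ready-to-run pipeline config.
fixture_pipeline_config <- function(truth, mode = "link",
                                    out_dir = tempfile(), ...) {
  dir <- tempfile("fixture")
  paths <- emit_fixture(truth, dir)
  cfg <- list(out_dir = out_dir,
              enhancers = paths[["enhancers"]], gtf = paths[["genes"]],
              interactions = paths[["links"]], mode = mode,
              link_schema = fixture_link_schema(),
              super_enhancers = paths[["super_enhancers"]],
              tads = paths[["tads"]],
              randomization = list(n_replicates = 2, seed_base = 1,
                                   side = "enhancer", threshold = 0.9))
  if (mode == "looplist") {
    cfg$interactions <- write_looplist_from_links(paths[["links"]],
                                                  file.path(dir, "loops.txt"))
  }
  if (mode == "matrix") {
    cfg$interactions <- write_contacts_from_links(paths[["links"]],
                                                  file.path(dir, "contacts.txt"))
    cfg$cutoff <- 30
  }
  utils::modifyList(cfg, list(...))
}
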