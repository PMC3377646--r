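# Single-call orchestration: parse -> catalog -> scan -> regulon
# (-> discover), writing one reproducible report bundle.

#' Default pipeline configuration
#'
#' All defaults are the conventional parameters of CelR-style operator
#' mining: mismatch budget 1, operon gap rule <100 bp, 300 bp upstream
#' windows, motif widths 6-20.
#'
#' @param consensi named list of [degenerate_consensus()] to scan
#'   (default: the CelR consensus only).
#' @param max_mismatch scan budget (default 1).
#' @param gap_threshold operon gap rule in bp (default 100).
#' @param upstream_window assignment/discovery window in bp (default 300).
#' @param width_range motif-discovery width range (default `c(6, 20)`).
#' @param seed RNG seed for discovery (default 1).
#' @param discover run de novo motif discovery on the upstream regions of
#'   predicted cellulases (default FALSE; needs >= 2 such regions).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(consensi = builtin_sites()["CelR"],
                            max_mismatch = 1, gap_threshold = 100,
                            upstream_window = 300,
                            width_range = c(6, 20), seed = 1,
                            discover = FALSE) {
  structure(list(consensi = consensi, max_mismatch = max_mismatch,
                 gap_threshold = gap_threshold,
                 upstream_window = upstream_window,
                 width_range = width_range, seed = seed,
                 discover = discover),
            class = "pipeline_config")
}

#' Run the full genome-mining pipeline
#'
#' Stages, in order: operon partitioning, cellulase cataloguing, operator
#' scanning for every configured consensus, site-to-operon regulon
#' assignment, cellobiose-operon detection, and (optionally) de novo
#' motif discovery on cellulase upstream regions. Every stage's output is
#' written to `out_dir` (catalog TSV, sites BED, regulon TSV, operons
#' GFF3, summary JSON, log) when given, and always returned.
#'
#' @param g genome object from [read_annotated_genome()] or
#'   [generate_synthetic_genome()].
#' @param domains domain table from [read_domain_table()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result`: `operons`, `calls`, `hits`
#'   (per consensus), `regulon` (per consensus), `cellobiose`, `summary`
#'   (per-genome site counts by mismatch class and cellulase counts by
#'   activity), `discovery` (when run), `paths`.
#' @export
run_pipeline <- function(g, domains, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(
    sprintf("celluminer pipeline: genome=%s", g$genome_id),
    sprintf("parameters: max_mismatch=%d gap_threshold=%d upstream_window=%d width_range=%d:%d seed=%d",
            config$max_mismatch, config$gap_threshold,
            config$upstream_window, config$width_range[1],
            config$width_range[2], config$seed),
    sprintf("consensi: %s", paste(names(config$consensi), collapse = ", ")))

  ops <- build_operons(g, config$gap_threshold)
  log_lines <- c(log_lines, sprintf("operons: %d", nrow(ops$operons)))

  calls <- call_cellulases(g, domains)
  aux <- inventory_auxiliary(g, domains)
  summary_sys <- system_type(calls, g$genome_id, aux)
  log_lines <- c(log_lines, sprintf("cellulase calls: %d (%d pseudo)",
                                    nrow(calls), sum(calls$is_pseudo)))

  hits <- list(); regulon <- list(); site_counts <- list()
  for (cid in names(config$consensi)) {
    h <- scan_genome(g, config$consensi[[cid]], config$max_mismatch)
    hits[[cid]] <- h
    regulon[[cid]] <- assign_hits(h, ops, g, config$upstream_window)
    site_counts[[cid]] <- as.list(table(factor(
      h$mismatches, levels = 0:config$max_mismatch)))
    log_lines <- c(log_lines, sprintf("scan %s: %d hit(s)", cid, nrow(h)))
  }

  cellobiose <- detect_cellobiose_operon(g, domains)
  log_lines <- c(log_lines,
                 sprintf("cellobiose operon candidates: %d",
                         length(cellobiose)))

  discovery <- NULL
  if (isTRUE(config$discover)) {
    targets <- unique(calls$locus_tag[!calls$is_pseudo])
    if (length(targets) >= 2) {
      us <- compile_upstream_set(g, targets, config$upstream_window,
                                 config$gap_threshold)
      if (length(us) >= 2) {
        discovery <- discover_motif(us, config$width_range,
                                    seed = config$seed)
        log_lines <- c(log_lines,
                       sprintf("discovery: width %d, argmax %s",
                               discovery$pwm$width, discovery$consensus))
      }
    }
  }

  summary <- list(
    genome_id = g$genome_id,
    n_genes = nrow(g$genes),
    n_operons = nrow(ops$operons),
    site_counts_by_mismatch = site_counts,
    cellulase_counts = as.list(summary_sys$counts),
    total_cellulases = summary_sys$total_cellulases,
    system_type = summary_sys$system_type,
    auxiliary = as.list(aux),
    n_cellobiose_clusters = length(cellobiose))

  res <- list(operons = ops, calls = calls, hits = hits, regulon = regulon,
              cellobiose = cellobiose, summary = summary,
              system = summary_sys, discovery = discovery)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(catalog = file.path(out_dir, "catalog.tsv"),
                  operons = file.path(out_dir, "operons.gff3"),
                  summary = file.path(out_dir, "summary.json"),
                  log = file.path(out_dir, "pipeline.log"))
    write.table(calls, paths$catalog, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_operons_gff3(ops, paths$operons)
    for (cid in names(hits)) {
      p <- file.path(out_dir, sprintf("sites_%s.bed", cid))
      write_sites(hits[[cid]], p)
      paths[[paste0("sites_", cid)]] <- p
      p2 <- file.path(out_dir, sprintf("regulon_%s.tsv", cid))
      write.table(regulon[[cid]], p2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths[[paste0("regulon_", cid)]] <- p2
    }
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA, null = "null")
    writeLines(log_lines, paths$log)
    res$paths <- paths
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d operons, %d cellulase calls, %s\n",
              x$summary$genome_id, x$summary$n_operons,
              nrow(x$calls), x$summary$system_type))
  for (cid in names(x$hits))
    cat(sprintf("  %s: %d site(s)\n", cid, nrow(x$hits[[cid]])))
  invisible(x)
}
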