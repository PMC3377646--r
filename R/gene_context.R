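# Operon partitioning, upstream-region extraction, site-to-gene assignment,
# and detection of cellobiose ABC-transporter gene clusters.

#' Partition genes into operons by the intergenic-gap rule
#'
#' Runs of adjacent genes on the same contig and strand whose every
#' intergenic gap (`next$start - prev$end`) is strictly less than
#' `gap_threshold` form one operon; every gene belongs to exactly one
#' operon, singletons included. Co-transcription requires a shared strand,
#' so a strand switch always breaks an operon regardless of gap. The
#' default 100 bp threshold is the conventional operational rule for
#' bacterial operon calling from annotation alone.
#'
#' @param g genome object.
#' @param gap_threshold intergenic distance bound in bp (strict, default 100).
#' @return an `operon_set`: list with `operons` (data frame: `operon_id`,
#'   `contig_id`, `strand`, `n_genes`, `leader`, `start`, `end`) and
#'   `genes` (data frame: `locus_tag`, `operon_id`, `tx_order` giving the
#'   position in transcription order, 1 = leader).
#' @export
build_operons <- function(g, gap_threshold = 100) {
  genes <- g$genes
  n <- nrow(genes)
  op_index <- integer(n)
  if (n > 0) {
    op_index[1] <- 1L
    for (i in seq_len(n)[-1]) {
      same_run <- genes$contig_id[i] == genes$contig_id[i - 1] &&
        genes$strand[i] == genes$strand[i - 1] &&
        (genes$start[i] - genes$end[i - 1]) < gap_threshold
      op_index[i] <- if (same_run) op_index[i - 1] else op_index[i - 1] + 1L
    }
  }
  ops <- list(); gene_rows <- list()
  for (k in unique(op_index)) {
    idx <- which(op_index == k)
    strand <- genes$strand[idx[1]]
    tx_idx <- if (strand == "+") idx else rev(idx)   # transcription order
    oid <- sprintf("%s_op%04d", g$genome_id, k)
    ops[[length(ops) + 1]] <- data.frame(
      operon_id = oid, contig_id = genes$contig_id[idx[1]], strand = strand,
      n_genes = length(idx), leader = genes$locus_tag[tx_idx[1]],
      start = min(genes$start[idx]), end = max(genes$end[idx]),
      stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows) + 1]] <- data.frame(
      locus_tag = genes$locus_tag[tx_idx], operon_id = oid,
      tx_order = seq_along(tx_idx), stringsAsFactors = FALSE)
  }
  structure(list(
    operons = if (length(ops)) do.call(rbind, ops) else
      data.frame(operon_id = character(0), contig_id = character(0),
                 strand = character(0), n_genes = integer(0),
                 leader = character(0), start = integer(0), end = integer(0)),
    genes = if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(locus_tag = character(0), operon_id = character(0),
                 tx_order = integer(0)),
    gap_threshold = gap_threshold),
    class = "operon_set")
}

#' @export
print.operon_set <- function(x, ...) {
  cat(sprintf("<operon_set> %d operons over %d genes (gap < %d bp)\n",
              nrow(x$operons), nrow(x$genes), x$gap_threshold))
  invisible(x)
}

#' Upstream region of an operon leader
#'
#' The `window` bp 5' of the leader gene's translational start on its
#' coding strand, truncated at the contig edge. Overlap with the previous
#' gene is deliberately permitted (operator sites frequently sit inside or
#' just past a neighbour's 3' end).
#'
#' @param op one row of the `operons` table from [build_operons()], or an
#'   operon_id string together with `ops`.
#' @param g genome object.
#' @param window upstream window in bp (default 300).
#' @param ops operon_set, required when `op` is given as an id string.
#' @return list(contig_id, start, end, strand) in 0-based half-open
#'   coordinates; `end - start` may be < window at a contig edge.
#' @export
upstream_region <- function(op, g, window = 300, ops = NULL) {
  if (is.character(op)) {
    stopifnot(!is.null(ops))
    op <- ops$operons[ops$operons$operon_id == op, ]
  }
  stopifnot(nrow(op) == 1)
  leader <- g$genes[g$genes$locus_tag == op$leader, ]
  clen <- nchar(g$contigs[[leader$contig_id]])
  if (leader$strand == "+") {
    start <- max(0L, leader$start - as.integer(window)); end <- leader$start
  } else {
    start <- leader$end; end <- min(clen, leader$end + as.integer(window))
  }
  list(contig_id = leader$contig_id, start = start, end = end,
       strand = leader$strand)
}

#' Assign motif hits to operons and genes
#'
#' Each hit is labelled `upstream` of every operon whose leader's upstream
#' window overlaps any part of the site (a site between divergent genes can
#' therefore be assigned to two operons); hits with no upstream assignment
#' that overlap a CDS are `intragenic`; the rest are `unassigned`. Internal
#' operon genes inherit regulation through their operon, so targets of
#' upstream rows are operon ids.
#'
#' @param hits data frame from [scan_genome()].
#' @param ops operon_set from [build_operons()].
#' @param g genome object.
#' @param window upstream assignment window in bp (default 300).
#' @return data frame (`regulon_report`) with the hit columns plus
#'   `relation` (`upstream`/`intragenic`/`unassigned`), `target` (operon_id
#'   or locus_tag), and `offset` — for upstream rows the distance in bp
#'   from the target's translational start to the nearest site base
#'   (clamped into `[1, window]`); for intragenic rows the site start's
#'   distance into the CDS in transcription direction.
#' @export
assign_hits <- function(hits, ops, g, window = 300) {
  out <- list()
  optab <- ops$operons
  genes <- g$genes
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    a <- h$start
    b <- h$start + nchar(h$matched_seq)   # half-open site [a, b)
    assigned <- FALSE
    for (j in seq_len(nrow(optab))) {
      op <- optab[j, ]
      if (op$contig_id != h$contig_id) next
      reg <- upstream_region(op, g, window)
      if (a < reg$end && b > reg$start) {
        leader <- genes[genes$locus_tag == op$leader, ]
        off <- if (leader$strand == "+") leader$start - b + 1L
               else a - leader$end + 1L
        off <- min(max(off, 1L), as.integer(window))
        out[[length(out) + 1]] <- cbind(
          h, data.frame(relation = "upstream", target = op$operon_id,
                        offset = off, stringsAsFactors = FALSE))
        assigned <- TRUE
      }
    }
    if (!assigned) {
      ov <- genes$contig_id == h$contig_id & genes$start < b & genes$end > a
      if (any(ov)) {
        for (j in which(ov)) {
          gn <- genes[j, ]
          off <- if (gn$strand == "+") a - gn$start else gn$end - b
          out[[length(out) + 1]] <- cbind(
            h, data.frame(relation = "intragenic", target = gn$locus_tag,
                          offset = off, stringsAsFactors = FALSE))
        }
      } else {
        out[[length(out) + 1]] <- cbind(
          h, data.frame(relation = "unassigned", target = NA_character_,
                        offset = NA_integer_, stringsAsFactors = FALSE))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(hits[0, ], data.frame(relation = character(0), target = character(0),
                                offset = integer(0)))
  rownames(res) <- NULL
  class(res) <- c("regulon_report", "data.frame")
  res
}

#' Default domain-label -> role map for cellobiose-operon detection
#'
#' Maps Pfam-style domain labels (and fallback product-string patterns) to
#' the functional roles of a cellobiose-uptake operon: substrate-binding
#' protein, membrane permeases, ATPase, LacI-family regulator,
#' beta-glucosidase, aldose 1-epimerase, and cellobiose phosphorylase.
#' Shipped as data so users can edit or replace it (e.g. via a YAML file
#' read with [yaml::read_yaml()]).
#'
#' @return list with `domain_labels` and `product_patterns`, each mapping
#'   role -> character vector.
#' @export
default_role_map <- function() {
  list(
    domain_labels = list(
      sbp = c("Peripla_BP_4", "Peripla_BP_1", "SBP_bac_1", "SBP_bac_8"),
      permease = c("BPD_transp_1", "BPD_transp_2"),
      atpase = c("ABC_tran"),
      regulator = c("HTH_LacI", "LacI"),
      beta_glucosidase = c("Glyco_hydro_1", "Glyco_hydro_3"),
      epimerase = c("Aldose_epim"),
      cellobiose_phosphorylase = c("Glyco_hydro_94", "Glyco_transf_36")
    ),
    product_patterns = list(
      sbp = "substrate[ -]binding|sugar[ -]binding",
      permease = "permease|membrane protein",
      atpase = "ATP[ -]binding|ATPase",
      regulator = "LacI",
      beta_glucosidase = "beta-glucosidase",
      epimerase = "aldose 1-epimerase",
      cellobiose_phosphorylase = "cellobiose phosphorylase"
    ))
}

# Roles of one gene from its domain labels, falling back to product text.
gene_roles <- function(labels, product, role_map) {
  roles <- names(role_map$domain_labels)[
    vapply(role_map$domain_labels, function(ls) any(labels %in% ls), logical(1))]
  if (!length(roles) && nzchar(product)) {
    roles <- names(role_map$product_patterns)[
      vapply(role_map$product_patterns,
             function(p) grepl(p, product, ignore.case = TRUE), logical(1))]
  }
  roles
}

#' Detect candidate cellobiose ABC-transporter operons
#'
#' Scans windows of up to `max_genes` consecutive genes on one contig for
#' the core of a cellobiose-uptake cluster — at least one sugar-ABC
#' substrate-binding protein and two permease components — and annotates
#' which optional members (ATPase, GH1/GH3 beta-glucosidase, LacI
#' regulator, aldose 1-epimerase, GH94 cellobiose phosphorylase) are
#' present. Only maximal windows (not contained in a larger reported
#' window) are returned.
#'
#' @param g genome object.
#' @param domains domain table from [read_domain_table()].
#' @param role_map role map as from [default_role_map()].
#' @param max_genes window bound in genes (default 8).
#' @return list of clusters; each has `contig_id`, `locus_tags`, `roles`
#'   (named list role -> locus_tags), `optional_present`,
#'   `optional_absent`.
#' @export
detect_cellobiose_operon <- function(g, domains, role_map = default_role_map(),
                                     max_genes = 8) {
  genes <- g$genes
  labels_by_tag <- split(domains$domain_label, domains$locus_tag)
  roles_by_gene <- lapply(seq_len(nrow(genes)), function(i) {
    gene_roles(labels_by_tag[[genes$locus_tag[i]]] %||% character(0),
               genes$product[i], role_map)
  })
  optional_roles <- c("atpase", "beta_glucosidase", "regulator",
                      "epimerase", "cellobiose_phosphorylase")
  clusters <- list()
  for (cid in unique(genes$contig_id)) {
    idx <- which(genes$contig_id == cid)
    n <- length(idx)
    # minimal windows containing the core (>=1 SBP, >=2 permeases), then
    # extended over adjacent role-bearing genes up to the gene bound --
    # one cluster per transporter core rather than every shifted window
    has_sbp <- vapply(roles_by_gene[idx], function(r) "sbp" %in% r, logical(1))
    has_perm <- vapply(roles_by_gene[idx], function(r) "permease" %in% r,
                       logical(1))
    windows <- list()
    for (i in which(has_sbp)) {
      best <- NULL
      for (lo in max(1, i - max_genes + 1):i) {
        for (hi in i:min(n, lo + max_genes - 1)) {
          if (sum(has_perm[lo:hi]) >= 2) {
            if (is.null(best) || (hi - lo) < (best[2] - best[1]))
              best <- c(lo, hi)
            break
          }
        }
      }
      if (is.null(best)) next
      lo <- best[1]; hi <- best[2]
      repeat {
        grew <- FALSE
        if (lo > 1 && (hi - lo + 2) <= max_genes &&
            length(roles_by_gene[[idx[lo - 1]]])) {
          lo <- lo - 1; grew <- TRUE
        }
        if (hi < n && (hi - lo + 2) <= max_genes &&
            length(roles_by_gene[[idx[hi + 1]]])) {
          hi <- hi + 1; grew <- TRUE
        }
        if (!grew) break
      }
      windows[[length(windows) + 1]] <- idx[lo:hi]
    }
    if (length(windows)) {
      # identical cores found from different SBPs collapse to one window
      windows <- unique(windows)
      keep <- vapply(seq_along(windows), function(k) {
        !any(vapply(seq_along(windows), function(m) {
          m != k && all(windows[[k]] %in% windows[[m]]) &&
            (length(windows[[m]]) > length(windows[[k]]) || m < k)
        }, logical(1)))
      }, logical(1))
      for (w in windows[keep]) {
        rl <- roles_by_gene[w]
        role_members <- lapply(
          setNames(nm = c("sbp", "permease", optional_roles)),
          function(role) genes$locus_tag[w][vapply(rl, function(r)
            role %in% r, logical(1))])
        present <- optional_roles[vapply(role_members[optional_roles],
                                         length, integer(1)) > 0]
        clusters[[length(clusters) + 1]] <- list(
          contig_id = cid,
          locus_tags = genes$locus_tag[w],
          roles = role_members[vapply(role_members, length, integer(1)) > 0],
          optional_present = present,
          optional_absent = setdiff(optional_roles, present))
      }
    }
  }
  clusters
}

#' Write an operon set as GFF3
#'
#' @param ops operon_set from [build_operons()].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_operons_gff3 <- function(ops, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ops$operons))) {
    op <- ops$operons[i, ]
    members <- ops$genes$locus_tag[ops$genes$operon_id == op$operon_id]
    lines <- c(lines, paste(op$contig_id, "celluminer", "operon",
                            op$start + 1L, op$end, ".", op$strand, ".",
                            sprintf("ID=%s;genes=%s", op$operon_id,
                                    paste(members, collapse = ",")),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
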