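# Seeded synthetic-genome generator with complete ground truth.
#
# Generates a high-GC genome with gene models on both strands, operon
# structure straddling the 100 bp gap rule, operator sites planted at
# controlled mismatch counts and upstream offsets, proteins carrying the
# cellulase domain architectures the classifier must recognize, and a
# cellobiose ABC-transporter gene cluster. With background scrubbing on,
# every chance occurrence of a planted consensus within its scan budget is
# mutated away, so planted site counts are exact by construction.

.cache <- new.env(parent = emptyenv())

codons_for <- function() {
  if (is.null(.cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .cache$codons <- split(names(gc), unname(gc))
  }
  .cache$codons
}

# Reverse-translate an amino-acid string, preferring GC-rich codons so
# coding regions stay close to a high-GC genome composition.
reverse_translate <- function(aa) {
  tab <- codons_for()
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  cod <- vapply(chars, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot reverse-translate symbol: ", a)
    gc_w <- vapply(opts, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")) + 0.5, numeric(1))
    sample(opts, 1, prob = gc_w^2)
  }, character(1))
  paste(c(cod, sample(c("TAA", "TGA", "TAG"), 1, prob = c(1, 4, 4))),
        collapse = "")
}

# Amino-acid sampling weighted toward residues with GC-rich codons
# (Ala/Gly/Pro/Arg-heavy), mirroring the proteome bias of high-GC
# actinobacteria and keeping reverse-translated coding regions near the
# genome's target GC.
random_protein <- function(n) {
  if (is.null(.cache$aa_weights)) {
    tab <- codons_for()
    aas <- setdiff(names(tab), "*")
    exp_gc <- vapply(aas, function(a) {
      opts <- tab[[a]]
      gcn <- vapply(opts, function(cd)
        sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))
      w <- (gcn + 0.5)^2
      sum((gcn / 3) * w) / sum(w)
    }, numeric(1))
    .cache$aa_weights <- setNames(exp_gc^2, aas)
  }
  w <- .cache$aa_weights
  paste(sample(names(w), n, replace = TRUE, prob = w), collapse = "")
}

#' Generate a window at an exact mismatch count from a consensus
#'
#' Draws a window matching the consensus at every position, then mutates
#' `k` uniformly chosen positions to bases outside their allowed sets.
#' Positions allowing all four bases cannot mismatch and are never chosen.
#'
#' @param c a [degenerate_consensus()].
#' @param k exact mismatch count, `0 <= k <= width`.
#' @return DNA string `w` with `count_mismatches(w, c) == k`.
#' @export
mutate_to_mismatch <- function(c, k) {
  stopifnot(inherits(c, "degenerate_consensus"), k >= 0, k <= c$width)
  bases <- vapply(c$positions, function(p) sample(p, 1)[1], character(1))
  mutable <- which(vapply(c$positions, length, integer(1)) < 4)
  if (k > length(mutable))
    stop("cannot place ", k, " mismatches: only ", length(mutable),
         " positions have disallowed bases")
  for (i in sample(mutable, k)) {
    bases[i] <- sample(setdiff(DNA_BASES, c$positions[[i]]), 1)
  }
  paste(bases, collapse = "")
}

# Built-in protein architectures: domain rows (label, length) in N->C
# order plus the expected classification, used for ground truth.
ARCHITECTURES <- list(
  ThemeB_GH9 = list(
    domains = data.frame(label = c("GH9", "CBM3", "fn3", "CBM2"),
                         len = c(400, 100, 90, 90)),
    gh_family = "GH9", activity = "processive_endocellulase", arch = "untyped"),
  GH9_plain = list(
    domains = data.frame(label = "GH9", len = 420),
    gh_family = "GH9", activity = "endocellulase", arch = "untyped"),
  GH48_typeI = list(
    domains = data.frame(label = c("CBM2", "GH48"), len = c(90, 600)),
    gh_family = "GH48", activity = "exocellulase_reducing", arch = "I"),
  GH48_typeII = list(
    domains = data.frame(label = c("GH48", "CBM3"), len = c(600, 90)),
    gh_family = "GH48", activity = "exocellulase_reducing", arch = "II"),
  GH6_exo_typeI = list(
    domains = data.frame(label = c("CBM2", "GH6"), len = c(90, 300)),
    gh_family = "GH6", activity = "exocellulase_nonreducing", arch = "I",
    anchor = "exo"),
  GH6_endo_typeI = list(
    domains = data.frame(label = c("GH6", "CBM2"), len = c(300, 90)),
    gh_family = "GH6", activity = "endocellulase", arch = "I",
    anchor = "endo"),
  GH6_exo_typeII = list(
    domains = data.frame(label = c("GH6", "CBM2"), len = c(300, 90)),
    gh_family = "GH6", activity = "exocellulase_nonreducing", arch = "II",
    anchor = "exo"),
  GH5_plain = list(
    domains = data.frame(label = "GH5", len = 350),
    gh_family = "GH5", activity = "endocellulase", arch = "untyped"),
  GH12_plain = list(
    domains = data.frame(label = "GH12", len = 220),
    gh_family = "GH12", activity = "endocellulase", arch = "untyped"),
  GH1_aux = list(
    domains = data.frame(label = "GH1", len = 440),
    gh_family = "GH1", activity = NA_character_, arch = NA_character_),
  GH94_aux = list(
    domains = data.frame(label = "GH94", len = 700),
    gh_family = "GH94", activity = NA_character_, arch = NA_character_)
)

# Cellobiose-operon templates: per-gene role labels and products.
CELLOBIOSE_TEMPLATES <- list(
  tfusca_like = data.frame(
    label = c("HTH_LacI", "Peripla_BP_4", "BPD_transp_1", "BPD_transp_1",
              "Glyco_hydro_1"),
    product = c("LacI family transcriptional regulator",
                "ABC transporter substrate-binding protein",
                "ABC transporter permease", "ABC transporter permease",
                "beta-glucosidase"),
    len = c(340, 430, 300, 290, 460), stringsAsFactors = FALSE),
  cflavigena_like = data.frame(
    label = c("HTH_LacI", "Peripla_BP_4", "BPD_transp_1", "BPD_transp_1"),
    product = c("LacI family transcriptional regulator",
                "ABC transporter substrate-binding protein",
                "ABC transporter permease", "ABC transporter permease"),
    len = c(340, 430, 300, 290), stringsAsFactors = FALSE)
)

#' Specification for a synthetic genome
#'
#' Defaults describe the conditions the generator emulates: a high-GC
#' (70%) actinobacterial chromosome, operons obeying the <100 bp gap rule
#' with gap sampling that straddles the boundary, CelR sites planted at
#' 0-1 mismatches within 300 bp upstream windows, the major cellulase
#' domain architectures, and a cellobiose ABC-transporter cluster.
#'
#' @param seed RNG seed; fully determines the output.
#' @param genome_id identifier.
#' @param gc_content background GC fraction (default 0.70).
#' @param n_operons number of operons to lay out (default 12).
#' @param operon_sizes candidate operon sizes, sampled uniformly.
#' @param planted_sites data frame with columns `consensus_id`,
#'   `mismatches`, `where` (`"upstream"` or `"intergenic"`). Default:
#'   4 perfect + 2 single-mismatch CelR sites, five upstream of distinct
#'   operons and one intergenic.
#' @param consensi named list of [degenerate_consensus()] referenced by
#'   `planted_sites` (default: the built-in operator sites).
#' @param planted_proteins character vector of architecture names; each
#'   is attached to a distinct gene. Default plants one of each major
#'   cellulase architecture plus auxiliary enzymes.
#' @param cellobiose_operon `"tfusca_like"`, `"cflavigena_like"`, or
#'   `NA` for none.
#' @param scan_budget mismatch budget the scrub must protect (default 1).
#' @param background_scrub mutate away all chance hits within
#'   `scan_budget` (default TRUE).
#' @param anchor_noise substitution rate applied to GH6 anchor sequences
#'   when building planted GH6 proteins (default 0.05).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, genome_id = "syn",
                           gc_content = 0.70,
                           n_operons = 12,
                           operon_sizes = 1:4,
                           planted_sites = data.frame(
                             consensus_id = "CelR",
                             mismatches = c(0, 0, 0, 1, 1, 0),
                             where = c(rep("upstream", 5), "intergenic"),
                             stringsAsFactors = FALSE),
                           consensi = builtin_sites(),
                           planted_proteins = c(
                             "ThemeB_GH9", "GH9_plain", "GH48_typeI",
                             "GH6_exo_typeI", "GH6_endo_typeI",
                             "GH5_plain", "GH1_aux", "GH94_aux"),
                           cellobiose_operon = "tfusca_like",
                           scan_budget = 1,
                           background_scrub = TRUE,
                           anchor_noise = 0.05) {
  structure(list(seed = seed, genome_id = genome_id,
                 gc_content = gc_content, n_operons = n_operons,
                 operon_sizes = operon_sizes,
                 planted_sites = planted_sites, consensi = consensi,
                 planted_proteins = planted_proteins,
                 cellobiose_operon = cellobiose_operon,
                 scan_budget = scan_budget,
                 background_scrub = background_scrub,
                 anchor_noise = anchor_noise),
            class = "synthetic_spec")
}

perturb_protein <- function(aa, rate) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  i <- which(runif(length(chars)) < rate)
  if (length(i))
    chars[i] <- sample(setdiff(names(codons_for()), "*"), length(i),
                       replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with ground truth
#'
#' See [synthetic_spec()] for the knobs. When `out_dir` is given, the
#' genome is also written as GenBank, GFF3 + FASTA, a domain TSV, and a
#' ground-truth JSON mirror of all planted entities.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional output directory.
#' @return list: `genome` (a [new_genome()] object), `domains` (domain
#'   table), `truth` (ground truth: `operons` as list of locus_tag
#'   vectors in transcription order, `sites`, `proteins`, `cellobiose`,
#'   `system_type`), and `paths` when files were written.
#' @export
generate_synthetic_genome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, generate_impl(spec, out_dir))
}

# Build the amino-acid sequence and domain rows for one planted
# architecture. GH6 architectures splice a perturbed anchor catalytic
# core into the GH6 span so nearest-anchor classification is testable.
plan_protein <- function(name, anchors, anchor_noise) {
  arch <- ARCHITECTURES[[name]]
  if (is.null(arch)) stop("unknown architecture: ", name)
  doms <- arch$domains
  core <- NULL
  if (!is.null(arch$anchor)) {
    if (is.null(anchors)) stop("GH6 architectures require the anchor set")
    pool <- anchors$seqs[anchors$labels == arch$anchor]
    core <- perturb_protein(pool[[sample.int(length(pool), 1)]], anchor_noise)
    doms$len[doms$label == "GH6"] <- nchar(core)
  }
  total_len <- sum(doms$len) + 20 * (nrow(doms) + 1)
  aa <- random_protein(total_len)
  off <- 20; rows <- list()
  for (d in seq_len(nrow(doms))) {
    if (!is.null(core) && doms$label[d] == "GH6")
      substr(aa, off + 1, off + doms$len[d]) <- core
    rows[[d]] <- data.frame(domain_label = doms$label[d],
                            aa_start = off + 1, aa_end = off + doms$len[d],
                            score = round(runif(1, 50, 300), 1))
    off <- off + doms$len[d] + 20
  }
  list(name = name, arch = arch, protein = aa,
       domains = do.call(rbind, rows), locus_tag = NA_character_)
}

generate_impl <- function(spec, out_dir) {
  gc <- spec$gc_content
  contig_id <- paste0(spec$genome_id, "_c1")
  n_upstream_sites <- sum(spec$planted_sites$where == "upstream")
  n_ops <- max(spec$n_operons, n_upstream_sites + 2)

  anchors <- if (any(vapply(spec$planted_proteins, function(n)
    !is.null(ARCHITECTURES[[n]]$anchor), logical(1))))
    gh6_anchors() else NULL
  protein_plan <- lapply(spec$planted_proteins, plan_protein,
                         anchors = anchors,
                         anchor_noise = spec$anchor_noise)
  protein_next <- 1L

  # --- operon / gene layout -------------------------------------------------
  # Operons are laid out left to right. Operons targeted by an upstream
  # site (and the cellobiose cluster) are forced to '+' strand with a
  # >= 320 bp clear gap before the leader, so the planted site region is
  # intergenic by construction. A pre-gap below 100 bp forces a strand
  # switch so the intended operon boundary survives the gap rule.
  op_plan <- data.frame(kind = c(rep("targeted", n_upstream_sites),
                                 rep("plain", n_ops - n_upstream_sites)))
  if (!is.na(spec$cellobiose_operon))
    op_plan <- rbind(op_plan, data.frame(kind = "cellobiose"))

  genes <- list(); truth_ops <- list(); gene_seqs <- list()
  domain_rows <- list()
  cursor <- 400L; gene_no <- 0L; prev_strand <- NULL
  cellobiose_genes <- character(0)

  emit_gene <- function(strand, protein_idx = NA, template_row = NULL) {
    gene_no <<- gene_no + 1L
    tag <- sprintf("%s_%04d", spec$genome_id, gene_no)
    if (!is.null(template_row)) {
      aa <- random_protein(template_row$len)
      dna <- reverse_translate(aa)
      product <- template_row$product
      pseq <- aa
      domain_rows[[length(domain_rows) + 1]] <<- data.frame(
        locus_tag = tag, domain_label = template_row$label,
        aa_start = 10, aa_end = template_row$len - 10,
        score = round(runif(1, 80, 300), 1))
      cellobiose_genes <<- c(cellobiose_genes, tag)
    } else if (!is.na(protein_idx)) {
      pp <- protein_plan[[protein_idx]]
      dna <- reverse_translate(pp$protein)
      product <- paste("planted", pp$name)
      pseq <- pp$protein
      domain_rows[[length(domain_rows) + 1]] <<-
        cbind(data.frame(locus_tag = tag), pp$domains)
      protein_plan[[protein_idx]]$locus_tag <<- tag
    } else {
      len <- 3L * sample(120:450, 1)
      dna <- random_dna(len, gc)
      product <- "hypothetical protein"
      pseq <- NA_character_
    }
    glen <- nchar(dna)
    genes[[length(genes) + 1]] <<- data.frame(
      locus_tag = tag, contig_id = contig_id,
      start = cursor, end = cursor + glen, strand = strand,
      product = product, is_pseudo = FALSE, protein_seq = pseq,
      stringsAsFactors = FALSE)
    gene_seqs[[tag]] <<- if (strand == "-") revcomp(dna) else dna
    cursor <<- cursor + glen
    tag
  }

  for (k in seq_len(nrow(op_plan))) {
    kind <- op_plan$kind[k]
    if (kind %in% c("targeted", "cellobiose")) {
      # targeted leaders get a wide clear gap so a planted site can never
      # fall inside the upstream window of the preceding (possibly
      # divergent) operon
      pre_gap <- if (kind == "targeted") sample(620:750, 1)
        else sample(320:450, 1)
      strand <- "+"
    } else {
      pre_gap <- if (runif(1) < 0.6) sample(100:400, 1) else sample(10:95, 1)
      if (runif(1) < 0.15) pre_gap <- 100L
      strand <- if (pre_gap < 100 && !is.null(prev_strand))
        setdiff(c("+", "-"), prev_strand) else sample(c("+", "-"), 1)
    }
    cursor <- cursor + as.integer(pre_gap)

    op_tags <- character(0)
    if (kind == "cellobiose") {
      template <- CELLOBIOSE_TEMPLATES[[spec$cellobiose_operon]]
      for (j in seq_len(nrow(template))) {
        if (j > 1) cursor <- cursor + sample(0:95, 1)
        op_tags <- c(op_tags, emit_gene(strand, template_row = template[j, ]))
      }
    } else {
      n_genes_op <- sample(spec$operon_sizes, 1)
      for (j in seq_len(n_genes_op)) {
        if (j > 1) cursor <- cursor + sample(c(0:95, 99L), 1)
        pidx <- NA
        if (protein_next <= length(protein_plan) && runif(1) < 0.5) {
          pidx <- protein_next; protein_next <- protein_next + 1L
        }
        op_tags <- c(op_tags, emit_gene(strand, protein_idx = pidx))
      }
    }
    truth_ops[[k]] <- if (strand == "+") op_tags else rev(op_tags)
    prev_strand <- strand
  }
  # guarantee every planted protein got a gene: append singleton operons
  while (protein_next <= length(protein_plan)) {
    cursor <- cursor + sample(150:350, 1)
    tag <- emit_gene("+", protein_idx = protein_next)
    protein_next <- protein_next + 1L
    truth_ops[[length(truth_ops) + 1]] <- tag
    prev_strand <- "+"
  }
  contig_len <- cursor + 720L
  genes_df <- do.call(rbind, genes)

  # --- assemble sequence ----------------------------------------------------
  seq_chars <- strsplit(random_dna(contig_len, gc), "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(genes_df))) {
    g <- genes_df[i, ]
    seq_chars[(g$start + 1):g$end] <-
      strsplit(gene_seqs[[g$locus_tag]], "", fixed = TRUE)[[1]]
  }

  # --- plant sites ----------------------------------------------------------
  # Targeted operons are all '+' strand, so upstream offsets count back
  # from the leader's start; intergenic sites go in the gene-free tail,
  # beyond any leader's 300 bp window.
  sites_truth <- list()
  up_counter <- 0
  for (i in seq_len(nrow(spec$planted_sites))) {
    ps <- spec$planted_sites[i, ]
    cns <- spec$consensi[[ps$consensus_id]]
    if (is.null(cns)) stop("unknown consensus_id: ", ps$consensus_id)
    w <- cns$width
    window_seq <- mutate_to_mismatch(cns, ps$mismatches)
    if (ps$where == "upstream") {
      up_counter <- up_counter + 1
      if (up_counter > n_upstream_sites)
        stop("more upstream sites than targeted operons")
      op_tags <- truth_ops[[up_counter]]
      leader <- genes_df[genes_df$locus_tag == op_tags[1], ]
      offset <- sample(seq(w + 5, 280), 1)
      start0 <- leader$start - offset
      target <- op_tags[1]
    } else {
      start0 <- cursor + 360L + sample.int(300 - w, 1)
      target <- NA_character_
    }
    seq_chars[(start0 + 1):(start0 + w)] <-
      strsplit(window_seq, "", fixed = TRUE)[[1]]
    sites_truth[[i]] <- data.frame(
      consensus_id = ps$consensus_id, contig_id = contig_id,
      start = start0, strand = if (is_palindrome(cns)) "." else "+",
      mismatches = ps$mismatches,
      target_leader = target, stringsAsFactors = FALSE)
  }
  sites_df <- if (length(sites_truth)) do.call(rbind, sites_truth) else NULL

  # --- background scrub -----------------------------------------------------
  protected <- if (!is.null(sites_df))
    unlist(lapply(seq_len(nrow(sites_df)), function(i) {
      w <- spec$consensi[[sites_df$consensus_id[i]]]$width
      (sites_df$start[i] + 1):(sites_df$start[i] + w)
    })) else integer(0)
  touched_coding <- FALSE
  if (spec$background_scrub) {
    scrub_ids <- unique(spec$planted_sites$consensus_id)
    for (iter in seq_len(500)) {
      seq_str <- paste(seq_chars, collapse = "")
      fixed_one <- FALSE
      for (cid in scrub_ids) {
        cns <- spec$consensi[[cid]]
        hits <- scan_genome(setNames(seq_str, contig_id), cns,
                            spec$scan_budget)
        planted_starts <- if (is.null(sites_df)) integer(0) else
          sites_df$start[sites_df$consensus_id == cid]
        chance <- hits[!(hits$start %in% planted_starts), , drop = FALSE]
        if (nrow(chance) == 0) next
        h <- chance[1, ]
        w <- cns$width
        cols <- (h$start + 1):(h$start + w)
        free <- setdiff(cols, protected)
        if (!length(free))
          stop("infeasible background scrub: chance hit at ", h$start,
               " lies entirely within planted sites")
        col <- if (length(free) == 1) free else sample(free, 1)
        pos <- col - h$start
        allowed_fwd <- if (h$strand == "-")
          complement_set(cns$positions[[w + 1 - pos]])
        else cns$positions[[pos]]
        choices <- setdiff(DNA_BASES, union(allowed_fwd, seq_chars[col]))
        if (!length(choices)) choices <- setdiff(DNA_BASES, allowed_fwd)
        seq_chars[col] <- if (length(choices) == 1) choices
          else sample(choices, 1)
        in_gene <- genes_df$start < col & genes_df$end >= col &
          !is.na(genes_df$protein_seq)
        touched_coding <- touched_coding || any(in_gene)
        fixed_one <- TRUE
        break
      }
      if (!fixed_one) break
      if (iter == 500) stop("background scrub did not converge")
    }
  }
  contig_seq <- paste(seq_chars, collapse = "")

  genome <- new_genome(spec$genome_id, setNames(contig_seq, contig_id),
                       genes_df)
  # scrub mutations may have landed inside annotated coding sequence;
  # re-derive translations so annotation and sequence stay consistent.
  if (touched_coding) {
    for (i in which(!is.na(genome$genes$protein_seq))) {
      genome$genes$protein_seq[i] <-
        translate_gene(genome, genome$genes$locus_tag[i])
    }
  }

  domains <- if (length(domain_rows)) do.call(rbind, domain_rows) else
    data.frame(locus_tag = character(0), domain_label = character(0),
               aa_start = integer(0), aa_end = integer(0),
               score = numeric(0))
  rownames(domains) <- NULL

  # --- ground truth ---------------------------------------------------------
  placed <- Filter(function(p) !is.na(p$locus_tag), protein_plan)
  proteins_df <- if (length(placed)) do.call(rbind, lapply(placed, function(p)
    data.frame(locus_tag = p$locus_tag, architecture = p$name,
               gh_family = p$arch$gh_family,
               activity = p$arch$activity,
               architecture_type = p$arch$arch,
               stringsAsFactors = FALSE))) else NULL
  typed <- if (!is.null(proteins_df))
    proteins_df$architecture_type[proteins_df$architecture_type %in%
                                    c("I", "II")] else character(0)
  expected_system <- if (!length(typed)) "undetermined"
    else if (all(typed == "I")) "Thermobifida_type_I"
    else if (all(typed == "II")) "Cellulomonas_type_II" else "mixed"

  truth <- list(
    operons = truth_ops,
    sites = sites_df,
    proteins = proteins_df,
    cellobiose = if (length(cellobiose_genes)) list(
      locus_tags = cellobiose_genes,
      template = spec$cellobiose_operon,
      beta_glucosidase_absent =
        spec$cellobiose_operon == "cflavigena_like") else NULL,
    system_type = expected_system)

  out <- list(genome = genome, domains = domains, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genbank = file.path(out_dir, paste0(spec$genome_id, ".gbk")),
      gff3 = file.path(out_dir, paste0(spec$genome_id, ".gff3")),
      fasta = file.path(out_dir, paste0(spec$genome_id, ".fna")),
      domains = file.path(out_dir, paste0(spec$genome_id, "_domains.tsv")),
      truth = file.path(out_dir, paste0(spec$genome_id, "_truth.json")))
    write_genbank(genome, paths$genbank)
    write_gff3(genome, paths$gff3, paths$fasta)
    write.table(domains, paths$domains, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, null = "null")
    out$paths <- paths
  }
  out
}
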