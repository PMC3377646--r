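# GH-family assignment, activity and domain-architecture classification,
# auxiliary enzyme inventory, and per-genome system summaries.
#
# Family membership alone fixes activity for GH48 (reducing-end
# exocellulase) and for GH5/GH8/GH12/GH51 (endocellulase). GH9 splits into
# processive vs non-processive endocellulase by the Theme-B domain
# architecture, and GH6 splits into exo vs endo clades by nearest-anchor
# similarity against a labelled reference set.

#' Default domain-label -> family map
#'
#' Maps Pfam-style domain labels (and bare family names) to CAZy GH
#' families and carbohydrate-binding module (CBM) labels. Covers the
#' families relevant to cellulose utilization: GH1, GH3, GH5, GH6, GH8,
#' GH9, GH12, GH16, GH48, GH51, GH94 plus CBM2, CBM3, CBM32, CBM33, fn3.
#'
#' @return named character vector label -> family.
#' @export
default_family_map <- function() {
  c(Glyco_hydro_1 = "GH1", Glyco_hydro_3 = "GH3", Cellulase = "GH5",
    Glyco_hydro_5 = "GH5", Glyco_hydro_6 = "GH6", Glyco_hydro_8 = "GH8",
    Glyco_hydro_9 = "GH9", Glyco_hydro_12 = "GH12", Glyco_hydro_16 = "GH16",
    Glyco_hydro_48 = "GH48", Glyco_hydro_51 = "GH51",
    Glyco_hydro_94 = "GH94", Glyco_transf_36 = "GH94",
    GH1 = "GH1", GH3 = "GH3", GH5 = "GH5", GH6 = "GH6", GH8 = "GH8",
    GH9 = "GH9", GH12 = "GH12", GH16 = "GH16", GH48 = "GH48",
    GH51 = "GH51", GH94 = "GH94",
    CBM_2 = "CBM2", CBM2 = "CBM2", CBM_3 = "CBM3", CBM3 = "CBM3",
    CBM_32 = "CBM32", CBM32 = "CBM32", CBM_33 = "CBM33", CBM33 = "CBM33",
    AA10 = "CBM33", fn3 = "fn3", FN3 = "fn3")
}

CATALYTIC_FAMILIES <- c("GH1", "GH3", "GH5", "GH6", "GH8", "GH9", "GH12",
                        "GH16", "GH48", "GH51", "GH94")
CELLULASE_FAMILIES <- c("GH5", "GH6", "GH8", "GH9", "GH12", "GH48", "GH51")
CBM_FAMILIES <- c("CBM2", "CBM3", "CBM32", "CBM33")

# Normalize a vector of domain labels to family names (NA when unmapped).
map_labels <- function(labels, family_map = default_family_map()) {
  unname(family_map[labels])
}

#' Assign GH families to one protein's domains
#'
#' @param domains domain-table rows for a single protein (ordered or not).
#' @param family_map label -> family map as [default_family_map()].
#' @return data frame with one row per catalytic (GH-family) domain in
#'   N-to-C order: `gh_family`, `aa_start`, `aa_end`. Unmapped labels that
#'   look catalytic (contain "Glyco_hydro") are reported with a message and
#'   ignored; CBMs are not catalytic and never appear.
#' @export
assign_gh_families <- function(domains, family_map = default_family_map()) {
  if (nrow(domains) == 0)
    return(data.frame(gh_family = character(0), aa_start = integer(0),
                      aa_end = integer(0)))
  domains <- domains[order(domains$aa_start), , drop = FALSE]
  fam <- map_labels(domains$domain_label, family_map)
  unmapped_cat <- is.na(fam) & grepl("Glyco_hydro", domains$domain_label)
  if (any(unmapped_cat))
    message("ignoring unmapped catalytic-looking label(s): ",
            paste(unique(domains$domain_label[unmapped_cat]), collapse = ", "))
  keep <- !is.na(fam) & fam %in% CATALYTIC_FAMILIES
  data.frame(gh_family = fam[keep],
             aa_start = domains$aa_start[keep],
             aa_end = domains$aa_end[keep],
             stringsAsFactors = FALSE)
}

# TRUE iff `pattern` (list of acceptable-label vectors) occurs as a
# subsequence of `layout`.
is_subsequence <- function(layout, pattern) {
  i <- 1
  for (x in layout) {
    if (i <= length(pattern) && x %in% pattern[[i]]) i <- i + 1
  }
  i > length(pattern)
}

#' Classify a GH9 enzyme by domain architecture
#'
#' Actinobacterial processive endocellulases carry the Theme-B
#' architecture: a GH9 catalytic domain followed by CBM3, a fibronectin
#' type 3 (fn3) domain, and a CBM2 or a second CBM3. A GH9 protein whose
#' N-to-C domain layout contains that subsequence is called processive;
#' any other GH9 layout is a non-processive endocellulase.
#'
#' @param layout character vector of domain family names in N-to-C order
#'   (e.g. `c("GH9", "CBM3", "fn3", "CBM2")`).
#' @return `"processive_endocellulase"` or `"endocellulase"`.
#' @export
classify_gh9 <- function(layout) {
  stopifnot("GH9" %in% layout)
  theme_b <- list("GH9", "CBM3", "fn3", c("CBM2", "CBM3"))
  if (is_subsequence(layout, theme_b)) "processive_endocellulase"
  else "endocellulase"
}

#' Load the packaged GH6 anchor set
#'
#' Labelled catalytic-domain sequences anchoring the two GH6 clades:
#' the exocellulase subfamily (Tfu_0620/Cel6B-like) and the endocellulase
#' subfamily (Tfu_1074/Cel6A-like). The shipped file contains synthetic
#' stand-in sequences (two divergent sequence families generated to mimic
#' the clade structure; see the file header) and is meant to be replaced
#' with real catalytic-domain sequences for production use.
#'
#' @param path FASTA of anchors; headers must end in `|exo` or `|endo`.
#'   Defaults to the packaged synthetic set.
#' @return named list with `seqs` (character vector) and `labels`
#'   (`"exo"`/`"endo"` per anchor).
#' @export
gh6_anchors <- function(path = system.file("extdata",
                                           "gh6_anchors_synthetic.fasta",
                                           package = "celluminer")) {
  if (!nzchar(path) || !file.exists(path)) stop("anchor FASTA not found")
  aa <- Biostrings::readAAStringSet(path)
  labels <- sub(".*\\|", "", names(aa))
  if (!all(labels %in% c("exo", "endo")))
    stop("anchor headers must end in |exo or |endo")
  if (length(unique(labels)) < 2)
    stop("anchor set must contain both exo and endo anchors")
  list(seqs = setNames(as.character(aa), names(aa)), labels = labels)
}

#' Classify a GH6 catalytic domain as exo- or endocellulase
#'
#' Deterministic nearest-anchor classification: the query (restricted to
#' its GH6 domain span if `span` is given) is scored against every anchor
#' by global-local pairwise alignment (BLOSUM62), and the label of the
#' best-scoring anchor is returned. The call abstains (`"unknown"`) when
#' the best exo and endo scores tie or the best score falls below `floor`.
#'
#' @param protein_seq amino-acid string.
#' @param references anchor set from [gh6_anchors()].
#' @param span optional `c(aa_start, aa_end)` of the GH6 domain.
#' @param floor minimum alignment score to call a class (default 150;
#'   chosen above the score range of shuffled sequences against the
#'   packaged anchors — see the vignette).
#' @return `"exocellulase_nonreducing"`, `"endocellulase"`, or
#'   `"unknown"`.
#' @export
classify_gh6 <- function(protein_seq, references = gh6_anchors(),
                         span = NULL, floor = 150) {
  if (length(references$seqs) == 0) stop("empty GH6 reference set")
  if (is.null(protein_seq) || is.na(protein_seq) || !nzchar(protein_seq))
    return("unknown")
  q <- protein_seq
  if (!is.null(span)) q <- substr(q, span[1], span[2])
  scores <- vapply(references$seqs, function(ref) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(ref),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "local", scoreOnly = TRUE)
  }, numeric(1))
  best_exo <- suppressWarnings(max(scores[references$labels == "exo"]))
  best_endo <- suppressWarnings(max(scores[references$labels == "endo"]))
  best <- max(best_exo, best_endo)
  if (best < floor || best_exo == best_endo) return("unknown")
  if (best_exo > best_endo) "exocellulase_nonreducing" else "endocellulase"
}

#' Architecture type (I / II / untyped) of an exo- or GH6 endocellulase
#'
#' For GH48 and GH6 exocellulases, an N-terminal CBM marks type I
#' (*Thermobifida*-like) and a C-terminal CBM type II
#' (*Cellulomonas*-like). For GH6 non-processive endocellulases the
#' arrangement is reversed: a C-terminal CBM marks type I and an
#' N-terminal CBM type II. Proteins with no CBM, or CBMs on both sides of
#' the catalytic domain, are untyped.
#'
#' @param gh_family `"GH48"` or `"GH6"`.
#' @param activity activity class string of the catalytic domain.
#' @param layout domain family names in N-to-C order.
#' @return `"I"`, `"II"`, or `"untyped"`.
#' @export
architecture_type <- function(gh_family, activity, layout) {
  if (!gh_family %in% c("GH48", "GH6")) return("untyped")
  cat_pos <- which(layout == gh_family)[1]
  if (is.na(cat_pos)) return("untyped")
  cbm_pos <- which(layout %in% CBM_FAMILIES)
  has_n <- any(cbm_pos < cat_pos)
  has_c <- any(cbm_pos > cat_pos)
  if (!has_n && !has_c) return("untyped")
  if (has_n && has_c) return("untyped")
  exo_like <- gh_family == "GH48" ||
    activity %in% c("exocellulase_nonreducing", "exocellulase_reducing")
  if (exo_like) {
    if (has_n) "I" else "II"
  } else {                       # GH6 endocellulase: reversed placement
    if (has_c) "I" else "II"
  }
}

#' Call cellulases for a genome
#'
#' Drives family assignment and activity/architecture classification over
#' a whole domain table. One row is produced per catalytic domain of a
#' cellulase family (GH5, GH6, GH8, GH9, GH12, GH48, GH51); a protein with
#' two catalytic domains yields two rows. Pseudogene calls are produced
#' and flagged but are excluded from summary totals downstream.
#'
#' @param g genome object.
#' @param domains domain table from [read_domain_table()].
#' @param references GH6 anchor set, see [gh6_anchors()].
#' @param family_map label -> family map.
#' @return data frame (`cellulase_calls`): `locus_tag`, `gh_family`,
#'   `activity`, `architecture_type`, `cbm_layout`, `is_pseudo`,
#'   `evidence`.
#' @export
call_cellulases <- function(g, domains, references = gh6_anchors(),
                            family_map = default_family_map()) {
  rows <- list()
  for (tag in unique(domains$locus_tag)) {
    dp <- domains[domains$locus_tag == tag, , drop = FALSE]
    dp <- dp[order(dp$aa_start), , drop = FALSE]
    layout <- map_labels(dp$domain_label, family_map)
    layout <- layout[!is.na(layout)]
    fams <- assign_gh_families(dp, family_map)
    gene <- g$genes[g$genes$locus_tag == tag, ]
    is_pseudo <- if (nrow(gene) == 1) gene$is_pseudo else FALSE
    pseq <- if (nrow(gene) == 1) gene$protein_seq else NA_character_
    for (k in seq_len(nrow(fams))) {
      fam <- fams$gh_family[k]
      if (!fam %in% CELLULASE_FAMILIES) next
      evidence <- "family membership"
      activity <- switch(fam,
        GH48 = "exocellulase_reducing",
        GH9 = {
          evidence <- "Theme-B architecture test"
          classify_gh9(layout)
        },
        GH6 = {
          evidence <- "nearest GH6 anchor"
          classify_gh6(pseq, references,
                       span = c(fams$aa_start[k], fams$aa_end[k]))
        },
        "endocellulase")
      arch <- architecture_type(fam, activity, layout)
      rows[[length(rows) + 1]] <- data.frame(
        locus_tag = tag, gh_family = fam, activity = activity,
        architecture_type = arch,
        cbm_layout = paste(layout, collapse = ","),
        is_pseudo = is_pseudo, evidence = evidence,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_tag = character(0), gh_family = character(0),
               activity = character(0), architecture_type = character(0),
               cbm_layout = character(0), is_pseudo = logical(0),
               evidence = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Auxiliary cellobiose-utilization enzyme inventory
#'
#' Counts beta-glucosidases (GH1, and GH3 when the product string says
#' so), beta-glucan glucohydrolases (GH3 by product string), unresolved
#' GH3 proteins, and GH94 cellobiose phosphorylases. Counts are per
#' protein; pseudogenes are excluded.
#'
#' @param g genome object.
#' @param domains domain table.
#' @param family_map label -> family map.
#' @return named integer vector: `beta_glucosidase`,
#'   `beta_glucan_glucohydrolase`, `gh3_unresolved`,
#'   `cellobiose_phosphorylase`.
#' @export
inventory_auxiliary <- function(g, domains,
                                family_map = default_family_map()) {
  counts <- c(beta_glucosidase = 0L, beta_glucan_glucohydrolase = 0L,
              gh3_unresolved = 0L, cellobiose_phosphorylase = 0L)
  for (tag in unique(domains$locus_tag)) {
    gene <- g$genes[g$genes$locus_tag == tag, ]
    if (nrow(gene) == 1 && gene$is_pseudo) next
    product <- if (nrow(gene) == 1) gene$product else ""
    fams <- unique(map_labels(
      domains$domain_label[domains$locus_tag == tag], family_map))
    if ("GH94" %in% fams)
      counts["cellobiose_phosphorylase"] <- counts["cellobiose_phosphorylase"] + 1L
    if ("GH1" %in% fams)
      counts["beta_glucosidase"] <- counts["beta_glucosidase"] + 1L
    else if ("GH3" %in% fams) {
      if (grepl("beta-glucosidase", product, ignore.case = TRUE))
        counts["beta_glucosidase"] <- counts["beta_glucosidase"] + 1L
      else if (grepl("glucan.*glucohydrolase|glucohydrolase", product,
                     ignore.case = TRUE))
        counts["beta_glucan_glucohydrolase"] <-
          counts["beta_glucan_glucohydrolase"] + 1L
      else counts["gh3_unresolved"] <- counts["gh3_unresolved"] + 1L
    }
  }
  counts
}

#' Summarize a genome's cellulolytic system
#'
#' Tallies cellulase calls by activity class (pseudogene calls are listed
#' separately, never in totals) and assigns the genome's architecture
#' system type: `Thermobifida_type_I` when every typed enzyme is type I,
#' `Cellulomonas_type_II` when every typed enzyme is type II, `mixed` when
#' both occur, `undetermined` when nothing is typed.
#'
#' @param calls data frame from [call_cellulases()] (one genome).
#' @param genome_id identifier for the summary.
#' @param auxiliary optional counts from [inventory_auxiliary()].
#' @return list (`genome_system_summary`): `genome_id`, `counts` (named,
#'   by activity), `total_cellulases`, `system_type`, `auxiliary`,
#'   `pseudogenes`.
#' @export
system_type <- function(calls, genome_id = "genome", auxiliary = NULL) {
  live <- calls[!calls$is_pseudo, , drop = FALSE]
  classes <- c("endocellulase", "exocellulase_reducing",
               "exocellulase_nonreducing", "processive_endocellulase",
               "unknown")
  counts <- vapply(classes, function(cl) sum(live$activity == cl), integer(1))
  typed <- live$architecture_type[live$architecture_type %in% c("I", "II")]
  stype <- if (length(typed) == 0) "undetermined"
  else if (all(typed == "I")) "Thermobifida_type_I"
  else if (all(typed == "II")) "Cellulomonas_type_II"
  else "mixed"
  structure(list(
    genome_id = genome_id,
    counts = counts,
    total_cellulases = sum(counts),
    system_type = stype,
    auxiliary = auxiliary,
    pseudogenes = unique(calls$locus_tag[calls$is_pseudo])),
    class = "genome_system_summary")
}

#' @export
print.genome_system_summary <- function(x, ...) {
  cat(sprintf("<genome_system_summary> %s: %d cellulases, system %s\n",
              x$genome_id, x$total_cellulases, x$system_type))
  print(x$counts)
  if (length(x$pseudogenes))
    cat("pseudogenes (excluded):", paste(x$pseudogenes, collapse = ", "), "\n")
  invisible(x)
}

#' Packaged catalogue of known and predicted actinobacterial cellulases
#'
#' A transcription of the published per-organism cellulase inventory for
#' thirteen actinobacterial genomes (locus tag, GH family, activity class,
#' pseudogene and predicted-regulation flags), shipped as TSV.
#'
#' @return data frame with columns `organism`, `locus_tag`, `gh_family`,
#'   `activity`, `is_pseudo`, `regulated`.
#' @export
read_cellulase_table <- function() {
  path <- system.file("extdata", "actinobacteria_cellulases.tsv",
                      package = "celluminer")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Per-organism cellulase totals from the packaged catalogue
#'
#' Counts predicted cellulases per organism (one per catalytic domain),
#' excluding pseudogenes from all totals.
#'
#' @return data frame: `organism`, `endocellulase`, `exocellulase`,
#'   `processive`, `total`, `n_pseudo`.
#' @export
cellulase_totals <- function() {
  tab <- read_cellulase_table()
  out <- lapply(split(tab, tab$organism), function(d) {
    live <- d[!d$is_pseudo, , drop = FALSE]
    data.frame(
      organism = d$organism[1],
      endocellulase = sum(live$activity == "endocellulase"),
      exocellulase = sum(live$activity == "exocellulase"),
      processive = sum(live$activity == "processive"),
      total = nrow(live),
      n_pseudo = sum(d$is_pseudo),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
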