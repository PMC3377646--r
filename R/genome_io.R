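# Reading annotated genomes and domain tables into the internal model, and
# writing site/operon/regulon reports.
#
# Internal coordinate convention, used everywhere downstream: 0-based,
# half-open [start, end), strands "+"/"-". Conversion from the 1-based
# inclusive GenBank/GFF3 dialects happens here and only here.

#' Construct a genome object
#'
#' @param genome_id identifier string.
#' @param contigs named character vector of contig sequences (A/C/G/T/N).
#' @param genes data frame with columns `locus_tag`, `contig_id`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `strand` (`+`/`-`),
#'   `product`, `is_pseudo`, `protein_seq` (NA when absent).
#' @return an object of class `genome`; genes are validated and sorted by
#'   (contig_id, start).
#' @export
new_genome <- function(genome_id, contigs, genes) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  required <- c("locus_tag", "contig_id", "start", "end", "strand",
                "product", "is_pseudo", "protein_seq")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$locus_tag)) {
    dup <- genes$locus_tag[duplicated(genes$locus_tag)][1]
    stop("duplicate locus_tag: ", dup)
  }
  bad <- which(genes$end <= genes$start)
  if (length(bad))
    stop("gene with end <= start: ", genes$locus_tag[bad[1]])
  clen <- nchar(contigs)
  bad <- which(!(genes$contig_id %in% names(contigs)) |
                 genes$start < 0L |
                 genes$end > clen[genes$contig_id])
  if (length(bad))
    stop("gene outside its contig: ", genes$locus_tag[bad[1]])
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  genes <- genes[order(genes$contig_id, genes$start), required, drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %d bp, %d genes\n",
              x$genome_id, length(x$contigs), sum(nchar(x$contigs)),
              nrow(x$genes)))
  invisible(x)
}

#' Read an annotated genome
#'
#' Parses CDS features from either a GenBank flat file or a GFF3 + FASTA
#' pair into the internal 0-based half-open coordinate model. Pseudogenes
#' are retained and flagged, never dropped. Multi-contig (draft) assemblies
#' are supported; each GenBank record / FASTA entry becomes one contig.
#'
#' @param path GenBank flat file, or the GFF3 file when
#'   `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta FASTA file with contig sequences (required for GFF3 input).
#' @param genome_id identifier; defaults to the file name without extension.
#' @return a [new_genome()] object, genes sorted by (contig, start).
#' @export
read_annotated_genome <- function(path, format = c("genbank", "gff3"),
                                  fasta = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "genbank") read_genbank(path, genome_id)
  else {
    if (is.null(fasta)) stop("format='gff3' requires a fasta= file")
    if (!file.exists(fasta)) stop("input file not found: ", fasta)
    read_gff3_fasta(path, fasta, genome_id)
  }
}

# --- GenBank flat file ------------------------------------------------------
# Minimal reader for the subset of the flat-file grammar the pipeline needs:
# LOCUS name, CDS features with simple or complement() spans, /locus_tag,
# /product, /pseudo, /translation qualifiers, and the ORIGIN sequence block.

read_genbank <- function(path, genome_id) {
  lines <- readLines(path, warn = FALSE)
  rec_breaks <- c(0, which(trimws(lines) == "//"))
  contigs <- character(0)
  genes <- list()
  for (r in seq_len(length(rec_breaks) - 1)) {
    rec <- lines[(rec_breaks[r] + 1):(rec_breaks[r + 1] - 1)]
    if (!length(rec)) next
    locus_line <- grep("^LOCUS", rec, value = TRUE)
    if (!length(locus_line)) stop("GenBank record without LOCUS line")
    contig_id <- strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]

    origin_at <- grep("^ORIGIN", rec)
    if (!length(origin_at)) stop("GenBank record without ORIGIN: ", contig_id)
    seq_lines <- rec[(origin_at[1] + 1):length(rec)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[contig_id] <- seq

    feat_at <- grep("^FEATURES", rec)
    if (length(feat_at)) {
      body <- rec[(feat_at[1] + 1):(origin_at[1] - 1)]
      genes[[length(genes) + 1]] <-
        parse_genbank_cds(body, contig_id, nchar(seq))
    }
  }
  genes <- do.call(rbind, genes)
  if (is.null(genes)) genes <- empty_gene_table()
  new_genome(genome_id, contigs, genes)
}

parse_genbank_cds <- function(body, contig_id, contig_len) {
  # feature starts: 5 spaces + key; qualifier/continuation lines are deeper
  starts <- grep("^ {5}\\S", body)
  if (!length(starts)) return(empty_gene_table())
  ends <- c(starts[-1] - 1, length(body))
  rows <- list()
  for (i in seq_along(starts)) {
    block <- body[starts[i]:ends[i]]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (key != "CDS") next
    loc <- trimws(sub("^\\s*CDS", "", block[1]))
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2) stop("unsupported CDS location: ", loc)
    start1 <- min(nums); end1 <- max(nums)

    quals <- parse_genbank_qualifiers(block[-1])
    tag <- quals[["locus_tag"]] %||% sprintf("%s_cds%d", contig_id, i)
    if (end1 <= start1 - 1 || end1 > contig_len)
      stop("CDS coordinates invalid for locus ", tag)
    rows[[length(rows) + 1]] <- data.frame(
      locus_tag = tag, contig_id = contig_id,
      start = as.integer(start1 - 1), end = as.integer(end1),
      strand = strand,
      product = quals[["product"]] %||% "",
      is_pseudo = "pseudo" %in% names(quals),
      protein_seq = quals[["translation"]] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_gene_table())
  do.call(rbind, rows)
}

parse_genbank_qualifiers <- function(lines) {
  quals <- list()
  cur_name <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_name)) {
      v <- gsub("\"", "", paste(cur_val, collapse = " "))
      if (cur_name == "translation") v <- gsub(" ", "", v)
      quals[[cur_name]] <<- v
    }
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (startsWith(t, "/")) {
      flush()
      eq <- regexpr("=", t, fixed = TRUE)
      if (eq > 0) {
        cur_name <- substring(t, 2, eq - 1)
        cur_val <- substring(t, eq + 1)
      } else {
        cur_name <- substring(t, 2)
        cur_val <- ""
      }
    } else if (!is.null(cur_name)) {
      cur_val <- c(cur_val, t)
    }
  }
  flush()
  quals
}

empty_gene_table <- function() {
  data.frame(locus_tag = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             product = character(0), is_pseudo = logical(0),
             protein_seq = character(0), stringsAsFactors = FALSE)
}

# --- GFF3 + FASTA -----------------------------------------------------------

read_gff3_fasta <- function(gff_path, fasta_path, genome_id) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  contigs <- setNames(as.character(seqs), names(seqs))
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr)) {
    md <- S4Vectors::mcols(gr)
    tag <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag)
           else as.character(md$ID)
    pseudo_col <- if ("pseudo" %in% names(md)) {
      p <- as.character(md$pseudo)
      !is.na(p) & p %in% c("true", "TRUE", "1")
    } else rep(FALSE, length(gr))
    genes <- data.frame(
      locus_tag = tag,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based
      end = GenomicRanges::end(gr),            # inclusive -> exclusive
      strand = as.character(GenomicRanges::strand(gr)),
      product = if ("product" %in% names(md)) {
        p <- as.character(md$product); ifelse(is.na(p), "", p)
      } else "",
      is_pseudo = pseudo_col,
      protein_seq = NA_character_,
      stringsAsFactors = FALSE)
  } else genes <- empty_gene_table()
  new_genome(genome_id, contigs, genes)
}

# --- writers ----------------------------------------------------------------

#' Write a genome as a GenBank flat file
#'
#' Emits one record per contig with CDS features (locus_tag, product,
#' pseudo flag, translation when present). Round-trips through
#' [read_annotated_genome()].
#'
#' @param g a genome object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in names(g$contigs)) {
    seq <- g$contigs[[cid]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                       cid, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s synthetic contig.", g$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    genes <- g$genes[g$genes$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      gn <- genes[i, ]
      loc <- sprintf("%d..%d", gn$start + 1L, gn$end)
      if (gn$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", gn$locus_tag), con)
      if (nzchar(gn$product))
        writeLines(sprintf("                     /product=\"%s\"", gn$product), con)
      if (gn$is_pseudo)
        writeLines("                     /pseudo", con)
      if (!is.na(gn$protein_seq))
        writeLines(sprintf("                     /translation=\"%s\"", gn$protein_seq), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1, nchar(seq), by = 60)
    writeLines(sprintf("%9d %s", pos,
                       tolower(substring(seq, pos, pmin(pos + 59, nchar(seq))))),
               con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome as a GFF3 + FASTA pair
#'
#' @param g a genome object.
#' @param gff_path,fasta_path output files.
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(g, gff_path, fasta_path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    attrs <- sprintf("ID=%s;locus_tag=%s", gn$locus_tag, gn$locus_tag)
    if (nzchar(gn$product)) attrs <- paste0(attrs, ";product=", gn$product)
    if (gn$is_pseudo) attrs <- paste0(attrs, ";pseudo=true")
    lines <- c(lines, paste(gn$contig_id, "celluminer", "CDS",
                            gn$start + 1L, gn$end, ".", gn$strand, "0",
                            attrs, sep = "\t"))
  }
  writeLines(lines, gff_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(g$contigs), fasta_path)
  invisible(gff_path)
}

# --- domain tables ----------------------------------------------------------

#' Read a protein domain annotation table
#'
#' TSV in the style of post-processed hmmscan/InterProScan output with
#' header columns `locus_tag`, `domain_label`, `aa_start`, `aa_end`,
#' `score` (amino-acid coordinates 1-based inclusive).
#'
#' @param path TSV file.
#' @param genome optional genome object; rows whose locus_tag is not in the
#'   genome are dropped with a warning giving the skipped count.
#' @return data frame of annotations, grouped by locus_tag and ordered by
#'   `aa_start` within each protein.
#' @export
read_domain_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("locus_tag", "domain_label", "aa_start", "aa_end", "score")
  if (!all(required %in% names(tab)))
    stop("domain table must have columns: ", paste(required, collapse = ", "))
  if (nrow(tab) == 0) return(tab[required])
  bad <- which(is.na(tab$aa_start) | is.na(tab$aa_end) |
                 tab$aa_start > tab$aa_end | is.na(tab$score))
  if (length(bad))
    stop(sprintf("malformed domain table row at line %d", bad[1] + 1L))
  if (!is.null(genome)) {
    unknown <- !(tab$locus_tag %in% genome$genes$locus_tag)
    if (any(unknown)) {
      warning(sprintf("skipped %d domain row(s) with unknown locus_tag",
                      sum(unknown)))
      tab <- tab[!unknown, , drop = FALSE]
    }
  }
  tab <- tab[order(match(tab$locus_tag, unique(tab$locus_tag)), tab$aa_start),
             required, drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write motif hits as BED6
#'
#' 0-based half-open intervals; name column is the consensus id, score the
#' mismatch count, strand `+`/`-` or `.` for palindrome-deduplicated loci.
#'
#' @param hits data frame from [scan_genome()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_sites <- function(hits, path) {
  if (nrow(hits) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(hits$contig_id, hits$start,
                    hits$start + nchar(hits$matched_seq),
                    hits$consensus_id, hits$mismatches, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware translation of a gene's genomic span
#'
#' Extracts the spanned contig sequence (reverse-complemented on `-`) and
#' translates it with the bacterial reading of the standard code. Used to
#' check coordinate-convention integrity against annotated translations.
#'
#' @param g genome object.
#' @param locus_tag gene to translate.
#' @return amino-acid string (without a trailing stop).
#' @export
translate_gene <- function(g, locus_tag) {
  gn <- g$genes[g$genes$locus_tag == locus_tag, ]
  if (nrow(gn) != 1) stop("unknown locus_tag: ", locus_tag)
  dna <- substr(g$contigs[[gn$contig_id]], gn$start + 1L, gn$end)
  if (gn$strand == "-") dna <- revcomp(dna)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
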