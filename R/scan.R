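# Genome scanning for degenerate operator sites within a mismatch budget.
#
# The scanner works positionwise on an integer-encoded contig: for each of
# the w pattern positions a logical lookup marks disallowed bases, and the
# per-window mismatch count is the sum of w shifted indicator vectors. This
# is O(w * L) with vectorized inner operations, and is checked against a
# naive window-enumeration oracle in the test suite.

SCAN_ALPHABET <- c("A", "C", "G", "T", "N")

encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, SCAN_ALPHABET)
  idx[is.na(idx)] <- 5L   # any non-ACGT symbol behaves like N
  idx
}

# 5 x width logical matrix: allowed[code, k] is TRUE iff base `code` is in
# the allowed set at position k. Row 5 (N) is always FALSE.
allowed_matrix <- function(c) {
  m <- matrix(FALSE, nrow = 5, ncol = c$width)
  for (k in seq_len(c$width))
    m[match(c$positions[[k]], SCAN_ALPHABET), k] <- TRUE
  m
}

# Mismatch counts of every window of `code` against the allowed matrix.
window_mismatches <- function(code, allowed) {
  w <- ncol(allowed)
  L <- length(code)
  n <- L - w + 1
  if (n < 1) return(integer(0))
  mm <- integer(n)
  for (k in seq_len(w))
    mm <- mm + !allowed[code[k:(k + n - 1)], k]
  mm
}

#' Scan a genome for occurrences of a degenerate consensus
#'
#' Reports every window, on either strand of every contig, with at most
#' `max_mismatch` mismatches against the consensus. For a palindromic
#' consensus the forward and reverse-strand matches at a locus are the
#' same biological site, so they are collapsed into one hit with strand
#' `"."` carrying the forward-strand mismatch count. For non-palindromic
#' patterns both strands are reported separately as (start, strand) loci.
#'
#' @param g a [genome][read_annotated_genome] object (only `$contigs` is
#'   used, so a bare named character vector of contig sequences also works).
#' @param c a [degenerate_consensus()].
#' @param max_mismatch non-negative mismatch budget (default 1, the
#'   conventional budget for CelR-site searches).
#' @return data frame of hits with columns `consensus_id`, `contig_id`,
#'   `start` (0-based), `strand` (`+`/`-`/`.`), `mismatches`,
#'   `matched_seq` (the strand-adjusted genome substring), sorted by
#'   (contig, start, strand).
#' @export
scan_genome <- function(g, c, max_mismatch = 1) {
  stopifnot(inherits(c, "degenerate_consensus"), max_mismatch >= 0)
  contigs <- if (is.list(g) && !is.null(g$contigs)) g$contigs else g
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  pal <- is_palindrome(c)
  fwd <- allowed_matrix(c)
  rev <- allowed_matrix(revcomp_consensus(c))
  w <- c$width

  out <- list()
  for (cid in names(contigs)) {
    code <- encode_dna(contigs[[cid]])
    mm_f <- window_mismatches(code, fwd)
    hit_f <- which(mm_f <= max_mismatch)
    rows <- list()
    if (length(hit_f)) {
      rows[[1]] <- data.frame(
        consensus_id = c$consensus_id, contig_id = cid,
        start = hit_f - 1L,
        strand = if (pal) "." else "+",
        mismatches = mm_f[hit_f],
        matched_seq = substring(contigs[[cid]], hit_f, hit_f + w - 1L),
        stringsAsFactors = FALSE)
    }
    if (!pal) {
      mm_r <- window_mismatches(code, rev)
      hit_r <- which(mm_r <= max_mismatch)
      if (length(hit_r)) {
        rows[[2]] <- data.frame(
          consensus_id = c$consensus_id, contig_id = cid,
          start = hit_r - 1L,
          strand = "-",
          mismatches = mm_r[hit_r],
          matched_seq = revcomp(substring(contigs[[cid]], hit_r, hit_r + w - 1L)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) out[[cid]] <- do.call(rbind, rows)
  }
  if (!length(out)) {
    return(data.frame(consensus_id = character(0), contig_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), matched_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
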