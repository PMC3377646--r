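# Shared fixtures and independent oracles, built in code at test time.

# Brute-force scanner oracle: enumerate every window on both strands and
# apply count_mismatches, with the same palindromic-collapse reporting
# contract as scan_genome. Deliberately naive.
brute_scan <- function(contigs, cns, budget) {
  pal <- is_palindrome(cns)
  w <- cns$width
  rows <- list()
  for (cid in names(contigs)) {
    s <- contigs[[cid]]
    L <- nchar(s)
    for (j in seq_len(L - w + 1)) {
      win <- substr(s, j, j + w - 1)
      mf <- count_mismatches(win, cns)
      if (pal) {
        if (mf <= budget)
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = cid, start = j - 1L, strand = ".", mismatches = mf,
            stringsAsFactors = FALSE)
      } else {
        if (mf <= budget)
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = cid, start = j - 1L, strand = "+", mismatches = mf,
            stringsAsFactors = FALSE)
        mr <- count_mismatches(celluminer:::revcomp(win), cns)
        if (mr <= budget)
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = cid, start = j - 1L, strand = "-", mismatches = mr,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0))
  out[order(out$contig_id, out$start, out$strand), , drop = FALSE]
}

random_contig <- function(n, gc = 0.6) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# 300 bp sequences each carrying one planted consensus instance at 0-1
# mismatches -- the standard motif-discovery fixture.
planted_upstream_set <- function(seed, n_seq = 20, cns = celr_consensus(),
                                 mismatches = 0:1) {
  set.seed(seed)
  w <- cns$width
  setNames(vapply(seq_len(n_seq), function(i) {
    s <- random_contig(300, gc = 0.5)
    win <- mutate_to_mismatch(cns, sample(mismatches, 1))
    pos <- sample.int(300 - w, 1)
    substr(s, pos, pos + w - 1) <- win
    s
  }, character(1)), paste0("s", seq_len(n_seq)))
}

# Minimal hand-built genome: explicit genes on one contig.
toy_genome <- function(genes, contig_len = NULL, seed = 1,
                       genome_id = "toy") {
  set.seed(seed)
  if (is.null(contig_len)) contig_len <- max(genes$end) + 500L
  contigs <- setNames(random_contig(contig_len), "c1")
  genes$contig_id <- "c1"
  defaults <- list(product = "", is_pseudo = FALSE,
                   protein_seq = NA_character_)
  for (nm in names(defaults))
    if (is.null(genes[[nm]])) genes[[nm]] <- defaults[[nm]]
  new_genome(genome_id, contigs, genes)
}
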