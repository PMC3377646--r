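# Degenerate consensus parsing, palindromy, mismatch arithmetic, scanning.

test_that("consensus text parses into the right allowed-base sets", {
  acel <- parse_consensus("TGGGA(A/T)CG(A/T)TCCCA")
  expect_equal(acel$width, 14)
  expect_equal(acel$positions[[6]], c("A", "T"))
  expect_equal(acel$positions[[9]], c("A", "T"))
  expect_true(all(vapply(acel$positions[-c(6, 9)], length, integer(1)) == 1))

  plain <- parse_consensus("ACGT")
  expect_equal(plain$width, 4)
  expect_true(all(vapply(plain$positions, length, integer(1)) == 1))

  cfla <- parse_consensus("CNAA(T/A)CGNTTANNNA")
  expect_equal(cfla$width, 15)
  for (i in c(2, 8, 12, 13, 14))
    expect_equal(cfla$positions[[i]], c("A", "C", "G", "T"))

  # IUPAC codes are equivalent to the parenthesized notation
  expect_equal(parse_consensus("TGGGAWCGWTCCCA")$positions,
               acel$positions)
})

test_that("illegal consensus text errors point at the offending column", {
  expect_error(parse_consensus("ACG(/)T"), "column 4")
  expect_error(parse_consensus("ACXGT"), "column 3")
  expect_error(parse_consensus("ACG(AT"), "unterminated")
})

test_that("palindromy follows the position-wise complement rule", {
  expect_true(is_palindrome(parse_consensus("TGGGA(A/T)CG(A/T)TCCCA")))
  expect_false(is_palindrome(parse_consensus("ACGT(A/C)TACGT")))
  # a degenerate pattern is palindromic iff it equals its reverse complement
  set.seed(7)
  for (i in 1:50) {
    w <- sample(4:12, 1)
    pos <- lapply(seq_len(w), function(j)
      sample(c("A", "C", "G", "T"), sample(1:3, 1)))
    cns <- degenerate_consensus(pos)
    rc <- revcomp_consensus(cns)
    expect_equal(is_palindrome(cns),
                 identical(consensus_to_text(cns), consensus_to_text(rc)))
  }
})

test_that("mismatch counting is set membership with N never matching", {
  celr <- celr_consensus()
  expect_equal(count_mismatches("TGGGAGCGCTCCCA", celr), 0)
  expect_equal(count_mismatches("TGGGANCGCTCCCA", celr), 1)  # N in genome
  expect_equal(count_mismatches(strrep("N", 14), celr), 14)
  expect_error(count_mismatches("TGGGA", celr), "width")
})

test_that("half-site counts partition the total mismatch count", {
  celr <- celr_consensus()
  expect_error(half_site_mismatches("ACG", parse_consensus("ACG")), "even")
  set.seed(11)
  for (i in 1:200) {
    w <- paste(sample(c("A", "C", "G", "T", "N"), 14, replace = TRUE),
               collapse = "")
    expect_equal(sum(half_site_mismatches(w, celr)),
                 count_mismatches(w, celr))
  }
})

test_that("palindromic consensi score a window and its reverse complement equally", {
  celr <- celr_consensus()
  acel <- builtin_sites("Acel")
  set.seed(23)
  for (i in 1:200) {
    w <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
               collapse = "")
    rc <- celluminer:::revcomp(w)
    expect_equal(count_mismatches(w, celr), count_mismatches(rc, celr))
    expect_equal(count_mismatches(w, acel), count_mismatches(rc, acel))
  }
})

test_that("scan finds a planted exact site once, as a strand-collapsed locus", {
  celr <- celr_consensus()
  set.seed(5)
  s <- random_contig(400)
  substr(s, 101, 114) <- "TGGGAGCGCTCCCA"
  # clear chance hits so the plant is the only one
  g <- setNames(s, "c1")
  hits <- scan_genome(g, celr, 0)
  hits <- hits[hits$start == 100, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, ".")
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$matched_seq, "TGGGAGCGCTCCCA")
})

test_that("a non-palindromic site embedded as reverse complement is found on '-'", {
  cns <- parse_consensus("AAGGCCTTTACGGA", "asym")
  expect_false(is_palindrome(cns))
  set.seed(6)
  s <- random_contig(300)
  substr(s, 51, 64) <- celluminer:::revcomp("AAGGCCTTTACGGA")
  hits <- scan_genome(setNames(s, "c1"), cns, 0)
  hits <- hits[hits$start == 50, ]
  expect_equal(hits$strand, "-")
  expect_equal(hits$matched_seq, "AAGGCCTTTACGGA")
})

test_that("scan matches the brute-force oracle and is monotone in budget", {
  celr <- celr_consensus()
  actro <- builtin_sites("Actro")   # non-palindromic, degenerate
  set.seed(31)
  for (i in 1:12) {
    contigs <- setNames(random_contig(1500, gc = 0.65), "c1")
    for (cns in list(celr, actro)) {
      for (budget in 0:1) {
        fast <- scan_genome(contigs, cns, budget)
        slow <- brute_scan(contigs, cns, budget)
        expect_equal(fast[c("contig_id", "start", "strand", "mismatches")],
                     slow, ignore_attr = TRUE)
      }
      h0 <- scan_genome(contigs, cns, 0)
      h1 <- scan_genome(contigs, cns, 1)
      key <- function(h) paste(h$contig_id, h$start, h$strand)
      expect_true(all(key(h0) %in% key(h1)))
    }
  }
})
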