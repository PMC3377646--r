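# Upstream-set compilation and ZOOPS-EM motif discovery.

test_that("one upstream sequence per operon, on the coding strand", {
  # two targets in one '+' operon -> one sequence, the leader's window
  g <- toy_genome(data.frame(locus_tag = c("a", "b"),
                             start = c(1000L, 1450L),
                             end = c(1400L, 1900L), strand = "+"),
                  contig_len = 2500L)
  us <- compile_upstream_set(g, c("a", "b"))
  expect_length(us, 1)
  expect_equal(names(us), "a")
  expect_equal(unname(nchar(us)), 300L)
  expect_equal(as.character(us), substr(g$contigs[["c1"]], 701, 1000))

  # '-' strand leader: the window is reverse-complemented
  gm <- toy_genome(data.frame(locus_tag = "m", start = 300L, end = 900L,
                              strand = "-"), contig_len = 1400L)
  usm <- compile_upstream_set(gm, "m")
  expect_equal(as.character(usm),
               celluminer:::revcomp(substr(gm$contigs[["c1"]], 901, 1200)))

  # target at the contig start: truncated but retained
  gt <- toy_genome(data.frame(locus_tag = "t", start = 40L, end = 400L,
                              strand = "+"), contig_len = 800L)
  ust <- compile_upstream_set(gt, "t")
  expect_equal(unname(nchar(ust)), 40L)

  expect_error(compile_upstream_set(g, c("a", "nope")), "nope")
})

test_that("planted upstream sites fall inside the compiled regions", {
  syn <- generate_synthetic_genome(synthetic_spec(seed = 8))
  truth <- syn$truth$sites
  truth <- truth[!is.na(truth$target_leader), ]
  us <- compile_upstream_set(syn$genome, truth$target_leader)
  for (i in seq_len(nrow(truth))) {
    seq <- us[[truth$target_leader[i]]]
    hits <- scan_genome(setNames(seq, "u"), celr_consensus(), 1)
    expect_gte(nrow(hits), 1)
  }
})

test_that("EM recovers a planted motif with a monotone likelihood trace", {
  seqs <- planted_upstream_set(101)
  m <- discover_motif(seqs, seed = 101)
  got <- c(m$consensus, celluminer:::revcomp(m$consensus))
  expect_true("TGGGAGCGCTCCCA" %in% got)
  expect_true(all(diff(m$logL_trace) >= -1e-8))
  expect_gt(m$pwm$site_prior, 0.8)
  expect_true(all(abs(rowSums(m$pwm$probs) - 1) < 1e-9))
})

test_that("discovery is deterministic given the seed", {
  seqs <- planted_upstream_set(55)
  a <- discover_motif(seqs, seed = 9)
  b <- discover_motif(seqs, seed = 9)
  expect_identical(a$pwm, b$pwm)
  expect_identical(a$logL, b$logL)
})

test_that("presence posteriors separate sequences with and without sites", {
  set.seed(77)
  with_sites <- planted_upstream_set(77, n_seq = 10)
  without <- setNames(vapply(1:10, function(i) random_contig(300, 0.5),
                             character(1)), paste0("bg", 1:10))
  m <- discover_motif(c(with_sites, without), seed = 77)
  post <- m$posteriors
  planted <- grepl("^s", post$name)
  expect_gte(mean(post$presence[planted] > 0.5), 0.9)
  expect_gte(mean(post$presence[!planted] < 0.5), 0.9)
})

test_that("background-only input yields a lower-information model", {
  ic <- function(m) {
    p <- m$pwm$probs
    sum(p * log2(pmax(p, 1e-12) / 0.25)) / m$pwm$width
  }
  planted <- discover_motif(planted_upstream_set(31), seed = 31)
  set.seed(32)
  bg <- setNames(vapply(1:20, function(i) random_contig(300, 0.5),
                        character(1)), paste0("b", 1:20))
  null <- discover_motif(bg, seed = 32)
  expect_gt(ic(planted), ic(null))
})

test_that("reverse-complemented input recovers the mirrored motif", {
  # an asymmetric planted motif so strand is identifiable
  cns <- parse_consensus("TTGACGGCATAACC", "asym")
  seqs <- planted_upstream_set(61, cns = cns, mismatches = 0)
  m1 <- discover_motif(seqs, seed = 61)
  m2 <- discover_motif(vapply(seqs, celluminer:::revcomp, character(1)),
                       seed = 61)
  expect_true(m2$consensus %in%
                c(m1$consensus, celluminer:::revcomp(m1$consensus)))
})

test_that("PWM columns convert to allowed-base sets by threshold", {
  p <- rbind(c(0.5, 0, 0, 0.5),
             c(0.97, 0.01, 0.01, 0.01),
             c(0.24, 0.26, 0.26, 0.24))
  cns <- pwm_to_consensus(p)
  expect_equal(cns$positions[[1]], c("A", "T"))
  expect_equal(cns$positions[[2]], "A")
  expect_equal(cns$positions[[3]], c("C", "G"))

  # recovered consensus admits every planted window within 1 mismatch
  seqs <- planted_upstream_set(91)
  m <- discover_motif(seqs, seed = 91)
  rec <- pwm_to_consensus(m$pwm)
  celr <- celr_consensus()
  for (s in seqs) {
    hits <- scan_genome(setNames(s, "u"), celr, 1)
    planted_win <- hits$matched_seq[1]
    win <- c(planted_win, celluminer:::revcomp(planted_win))
    expect_true(any(vapply(win, function(x)
      count_mismatches(x, rec) <= 1, logical(1))))
  }
})
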