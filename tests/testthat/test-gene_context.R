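# Operon partitioning, upstream windows, hit assignment, cluster detection.

test_that("the <100 bp gap rule is strict at the boundary", {
  g99 <- toy_genome(data.frame(locus_tag = c("a", "b"),
                               start = c(100L, 499L), end = c(400L, 800L),
                               strand = "+"))
  ops <- build_operons(g99)     # gap = 99
  expect_equal(nrow(ops$operons), 1)
  expect_equal(ops$operons$leader, "a")

  g100 <- toy_genome(data.frame(locus_tag = c("a", "b"),
                                start = c(100L, 500L), end = c(400L, 800L),
                                strand = "+"))
  ops <- build_operons(g100)    # gap = 100
  expect_equal(nrow(ops$operons), 2)
})

test_that("operons never span strands and always form a true partition", {
  g <- toy_genome(data.frame(locus_tag = c("a", "b", "c"),
                             start = c(100L, 450L, 800L),
                             end = c(400L, 750L, 1100L),
                             strand = c("+", "-", "-")))
  ops <- build_operons(g)
  expect_equal(nrow(ops$operons), 2)          # strand switch splits a<50>b
  expect_setequal(ops$genes$locus_tag, c("a", "b", "c"))
  expect_equal(anyDuplicated(ops$genes$locus_tag), 0)
  # '-' operon transcribes right to left: leader is the rightmost gene
  minus <- ops$operons[ops$operons$strand == "-", ]
  expect_equal(minus$leader, "c")
})

test_that("raising the gap threshold never increases the operon count", {
  set.seed(13)
  for (rep in 1:10) {
    syn <- generate_synthetic_genome(synthetic_spec(seed = rep * 3,
                                                    background_scrub = FALSE))
    counts <- vapply(c(20, 60, 100, 200, 400), function(th)
      nrow(build_operons(syn$genome, th)$operons), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("recovered operon partitions equal the generator's ground truth", {
  for (seed in 1:20) {
    syn <- generate_synthetic_genome(synthetic_spec(seed = seed,
                                                    background_scrub = FALSE))
    ops <- build_operons(syn$genome)
    truth <- sort(vapply(syn$truth$operons, paste, character(1),
                         collapse = ","))
    rec <- vapply(split(seq_len(nrow(ops$genes)), ops$genes$operon_id),
                  function(i) paste(ops$genes$locus_tag[i][
                    order(ops$genes$tx_order[i])], collapse = ","),
                  character(1))
    expect_equal(sort(unname(rec)), truth)
  }
})

test_that("upstream regions sit 5' of the leader start and truncate at edges", {
  g <- toy_genome(data.frame(locus_tag = "a", start = 1000L, end = 1600L,
                             strand = "+"), contig_len = 2000L)
  ops <- build_operons(g)
  reg <- upstream_region(ops$operons[1, ], g)
  expect_equal(reg[c("start", "end")], list(start = 700L, end = 1000L))

  # '-' leader ending at 500 on a 600 bp contig: truncated to 100 bp
  gm <- toy_genome(data.frame(locus_tag = "a", start = 100L, end = 500L,
                              strand = "-"), contig_len = 600L)
  opm <- build_operons(gm)
  regm <- upstream_region(opm$operons[1, ], gm)
  expect_equal(regm[c("start", "end", "strand")],
               list(start = 500L, end = 600L, strand = "-"))
})

test_that("hits assign upstream of leaders, to both divergent operons, or intragenic", {
  # divergent pair: <-a   b->, site in between within 300 of both starts
  g <- toy_genome(data.frame(locus_tag = c("a", "b"),
                             start = c(100L, 900L), end = c(500L, 1400L),
                             strand = c("-", "+")), contig_len = 2000L)
  ops <- build_operons(g)
  hit <- data.frame(consensus_id = "CelR", contig_id = "c1", start = 650L,
                    strand = ".", mismatches = 0L,
                    matched_seq = strrep("A", 14))
  rep <- assign_hits(hit, ops, g)
  expect_equal(nrow(rep), 2)
  expect_setequal(rep$relation, "upstream")
  expect_true(all(rep$offset >= 1 & rep$offset <= 300))

  # fully inside a CDS, upstream of nothing: intragenic
  hit2 <- transform(hit, start = 1000L)
  rep2 <- assign_hits(hit2, ops, g)
  expect_equal(rep2$relation, "intragenic")
  expect_equal(rep2$target, "b")

  # far from everything: unassigned
  hit3 <- transform(hit, start = 1900L)
  rep3 <- assign_hits(hit3, ops, g)
  expect_equal(rep3$relation, "unassigned")
})

test_that("widening the assignment window only adds upstream rows", {
  syn <- generate_synthetic_genome(synthetic_spec(seed = 37))
  hits <- scan_genome(syn$genome, celr_consensus(), 1)
  ops <- build_operons(syn$genome)
  key <- function(r) paste(r$start, r$target)
  up300 <- subset(assign_hits(hits, ops, syn$genome, 300),
                  relation == "upstream")
  up500 <- subset(assign_hits(hits, ops, syn$genome, 500),
                  relation == "upstream")
  expect_true(all(key(up300) %in% key(up500)))
})

test_that("planted regulon assignments are recovered without spurious rows", {
  for (seed in c(2, 14, 41)) {
    syn <- generate_synthetic_genome(synthetic_spec(seed = seed))
    hits <- scan_genome(syn$genome, celr_consensus(), 1)
    ops <- build_operons(syn$genome)
    rep <- assign_hits(hits, ops, syn$genome)
    up <- rep[rep$relation == "upstream", ]
    truth <- syn$truth$sites[!is.na(syn$truth$sites$target_leader), ]
    # every planted upstream site maps to the operon led by its target
    for (i in seq_len(nrow(truth))) {
      oid <- ops$operons$operon_id[ops$operons$leader ==
                                     truth$target_leader[i]]
      expect_true(any(up$start == truth$start[i] & up$target == oid))
    }
    expect_equal(nrow(up), nrow(truth))   # nothing spurious after scrub
  }
})

test_that("cellobiose clusters are detected with their optional members flagged", {
  syn <- generate_synthetic_genome(synthetic_spec(seed = 42))
  cb <- detect_cellobiose_operon(syn$genome, syn$domains)
  expect_length(cb, 1)
  expect_setequal(cb[[1]]$locus_tags, syn$truth$cellobiose$locus_tags)
  expect_true("beta_glucosidase" %in% cb[[1]]$optional_present)
  expect_true("regulator" %in% cb[[1]]$optional_present)

  syn2 <- generate_synthetic_genome(
    synthetic_spec(seed = 7, cellobiose_operon = "cflavigena_like"))
  cb2 <- detect_cellobiose_operon(syn2$genome, syn2$domains)
  expect_length(cb2, 1)
  expect_true("beta_glucosidase" %in% cb2[[1]]$optional_absent)

  # permeases with no substrate-binding protein anywhere: no candidates
  g <- toy_genome(data.frame(locus_tag = c("p1", "p2"),
                             start = c(100L, 1200L), end = c(1000L, 2100L),
                             strand = "+"), contig_len = 2500L)
  doms <- data.frame(locus_tag = c("p1", "p2"),
                     domain_label = "BPD_transp_1",
                     aa_start = 1L, aa_end = 200L, score = 100)
  expect_length(detect_cellobiose_operon(g, doms), 0)
})
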