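# GH family assignment, activity and architecture classification,
# auxiliary inventory, per-genome summaries.

test_that("family assignment returns catalytic domains in N-to-C order", {
  doms <- data.frame(locus_tag = "p", domain_label = c("GH12", "GH6"),
                     aa_start = c(400L, 10L), aa_end = c(600L, 350L),
                     score = c(90, 200))
  fams <- assign_gh_families(doms)
  expect_equal(fams$gh_family, c("GH6", "GH12"))

  cbm_only <- data.frame(locus_tag = "p", domain_label = "CBM2",
                         aa_start = 1L, aa_end = 90L, score = 50)
  expect_equal(nrow(assign_gh_families(cbm_only)), 0)

  odd <- data.frame(locus_tag = "p", domain_label = "Glyco_hydro_999",
                    aa_start = 1L, aa_end = 90L, score = 50)
  expect_message(out <- assign_gh_families(odd), "Glyco_hydro_999")
  expect_equal(nrow(out), 0)
})

test_that("Theme-B layouts are processive, all other GH9 layouts are not", {
  expect_equal(classify_gh9(c("GH9", "CBM3", "fn3", "CBM2")),
               "processive_endocellulase")
  expect_equal(classify_gh9(c("GH9", "CBM3", "fn3", "CBM3")),
               "processive_endocellulase")
  expect_equal(classify_gh9("GH9"), "endocellulase")
  expect_equal(classify_gh9(c("GH9", "CBM2")), "endocellulase")
  expect_equal(classify_gh9(c("CBM3", "GH9", "fn3", "CBM2")),
               "endocellulase")   # CBM3 must follow the catalytic domain
})

test_that("GH6 nearest-anchor classification recovers anchor labels", {
  refs <- gh6_anchors()
  # identity: an anchor classified against the full set is its own label
  endo_seq <- refs$seqs[refs$labels == "endo"][1]
  expect_equal(classify_gh6(endo_seq, refs), "endocellulase")

  # leave-one-out over the shipped set
  ok <- 0
  for (i in seq_along(refs$seqs)) {
    loo <- list(seqs = refs$seqs[-i], labels = refs$labels[-i])
    got <- classify_gh6(refs$seqs[[i]], loo)
    want <- if (refs$labels[i] == "exo") "exocellulase_nonreducing"
            else "endocellulase"
    ok <- ok + (got == want)
  }
  expect_gte(ok / length(refs$seqs), 0.9)

  # a shuffled sequence scores below the floor and abstains
  set.seed(3)
  shuffled <- paste(sample(strsplit(refs$seqs[[1]], "")[[1]]), collapse = "")
  expect_equal(classify_gh6(shuffled, refs), "unknown")
})

test_that("architecture typing encodes the exo/endo CBM placement rules", {
  expect_equal(architecture_type("GH48", "exocellulase_reducing",
                                 c("CBM2", "GH48")), "I")
  expect_equal(architecture_type("GH48", "exocellulase_reducing",
                                 c("GH48", "CBM3")), "II")
  expect_equal(architecture_type("GH6", "exocellulase_nonreducing",
                                 c("CBM2", "GH6")), "I")
  # GH6 endocellulases are reversed: C-terminal CBM is type I
  expect_equal(architecture_type("GH6", "endocellulase",
                                 c("GH6", "CBM2")), "I")
  expect_equal(architecture_type("GH6", "endocellulase",
                                 c("CBM3", "GH6")), "II")
  expect_equal(architecture_type("GH6", "exocellulase_nonreducing",
                                 "GH6"), "untyped")
  expect_equal(architecture_type("GH48", "exocellulase_reducing",
                                 c("CBM2", "GH48", "CBM3")), "untyped")
})

test_that("calls depend on domain order, not absolute coordinates", {
  syn <- generate_synthetic_genome(synthetic_spec(seed = 19))
  calls <- call_cellulases(syn$genome, syn$domains)
  shifted <- syn$domains
  shifted$aa_start <- shifted$aa_start + 100L
  shifted$aa_end <- shifted$aa_end + 100L
  calls2 <- call_cellulases(syn$genome, shifted)
  expect_equal(calls[c("locus_tag", "gh_family", "activity",
                       "architecture_type")],
               calls2[c("locus_tag", "gh_family", "activity",
                        "architecture_type")])
})

test_that("identical inputs give identical calls", {
  syn <- generate_synthetic_genome(synthetic_spec(seed = 23))
  a <- call_cellulases(syn$genome, syn$domains)
  b <- call_cellulases(syn$genome, syn$domains)
  expect_identical(a, b)
})

test_that("system typing separates pure, mixed, and undetermined genomes", {
  calls <- data.frame(locus_tag = c("a", "b"), gh_family = c("GH48", "GH6"),
                      activity = c("exocellulase_reducing",
                                   "exocellulase_nonreducing"),
                      architecture_type = c("I", "I"),
                      cbm_layout = "", is_pseudo = FALSE, evidence = "")
  expect_equal(system_type(calls)$system_type, "Thermobifida_type_I")
  calls$architecture_type <- c("I", "II")
  expect_equal(system_type(calls)$system_type, "mixed")
  calls$architecture_type <- "untyped"
  expect_equal(system_type(calls)$system_type, "undetermined")

  # pseudogene calls are listed but never counted
  calls$architecture_type <- c("I", "I")
  calls$is_pseudo <- c(FALSE, TRUE)
  s <- system_type(calls)
  expect_equal(s$total_cellulases, 1)
  expect_equal(s$pseudogenes, "b")
})

test_that("auxiliary inventory counts GH1/GH3/GH94 proteins by category", {
  g <- toy_genome(data.frame(
    locus_tag = c("b1", "b2", "cp", "g3a", "g3b"),
    start = c(0L, 2000L, 4000L, 7000L, 9000L) + 100L,
    end = c(1500L, 3500L, 6500L, 8500L, 10500L),
    strand = "+",
    product = c("beta-glucosidase", "beta-glucosidase",
                "cellobiose phosphorylase",
                "beta-glucan glucohydrolase", "hypothetical protein")),
    contig_len = 11000L)
  doms <- data.frame(
    locus_tag = c("b1", "b2", "cp", "g3a", "g3b"),
    domain_label = c("GH1", "GH1", "GH94", "GH3", "GH3"),
    aa_start = 1L, aa_end = 300L, score = 100)
  aux <- inventory_auxiliary(g, doms)
  expect_equal(unname(aux["beta_glucosidase"]), 2L)
  expect_equal(unname(aux["beta_glucan_glucohydrolase"]), 1L)
  expect_equal(unname(aux["gh3_unresolved"]), 1L)
  expect_equal(unname(aux["cellobiose_phosphorylase"]), 1L)

  empty <- inventory_auxiliary(g, doms[0, ])
  expect_true(all(empty == 0))
})

test_that("the packaged catalogue counts one call per catalytic domain", {
  tab <- read_cellulase_table()
  # a dual-domain protein appears once per catalytic domain
  expect_equal(sum(tab$locus_tag == "Acel_0615"), 2)
  totals <- cellulase_totals()
  expect_setequal(
    totals$organism[totals$n_pseudo > 0], "T_curvata")
  expect_equal(totals$exocellulase[totals$organism == "T_curvata"], 0)
})
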