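test_that("record filter applies the AF / CADD / GERP branches", {
  recs <- rbind(
    make_variant(gene = "G1", consequence = "frameshift", af = 0.0036,
                 gerp = 4.8, cadd = 5),               # frameshift: GERP rules
    make_variant(gene = "G2", consequence = "other-coding", af = 0.001,
                 cadd = 9.9),                         # benign CADD
    make_variant(gene = "G3", consequence = "frameshift", gerp = 3.9),
    make_variant(gene = "G3b", consequence = "other-coding", cadd = 20,
                 gerp = 3.9),                         # same scores, other branch
    make_variant(gene = "G4", af = 0.05),             # common
    make_variant(gene = "G5", autosomal = FALSE),     # sex chromosome
    make_variant(gene = "G6", af = NA))               # unannotated
  out <- filter_variants(recs)
  expect_setequal(out$retained$gene, c("G1", "G3b"))
  expect_equal(nrow(out$retained) + nrow(out$dropped), nrow(recs))
  reasons <- setNames(out$dropped$drop_reason, out$dropped$gene)
  expect_equal(unname(reasons[c("G2", "G3", "G4", "G5", "G6")]),
               c("benign_score", "benign_score", "common", "non_autosomal",
                 "unannotated"))
  # retain-unannotated mode
  out2 <- filter_variants(recs, keep_unannotated = TRUE)
  expect_true("G6" %in% out2$retained$gene)
})

test_that("record-level filters are order-insensitive", {
  set.seed(14)
  recs <- do.call(rbind, lapply(1:60, function(i) {
    make_variant(gene = paste0("G", i),
                 consequence = sample(c("frameshift", "other-coding"), 1),
                 af = sample(c(1e-4, 0.05, NA), 1),
                 cadd = runif(1, 0, 40), gerp = runif(1, 0, 8),
                 autosomal = runif(1) > 0.2)
  }))
  full <- filter_variants(recs)$retained
  # apply single-criterion passes in two different orders
  af_first <- recs[!is.na(recs$population_af) & recs$population_af < 0.01, ]
  af_first <- af_first[af_first$autosomal, ]
  fs <- af_first$consequence == "frameshift"
  af_first <- af_first[ifelse(fs, af_first$gerp >= 4, af_first$cadd_phred >= 10), ]
  auto_first <- recs[recs$autosomal, ]
  fs2 <- auto_first$consequence == "frameshift"
  auto_first <- auto_first[ifelse(fs2, auto_first$gerp >= 4,
                                  auto_first$cadd_phred >= 10), ]
  auto_first <- auto_first[!is.na(auto_first$population_af) &
                             auto_first$population_af < 0.01, ]
  expect_setequal(full$gene, af_first$gene)
  expect_setequal(full$gene, auto_first$gene)
})

test_that("segregation filter enforces Mendelian inheritance for homs", {
  ok <- make_variant(zygosity = "hom", gt_father = "het", gt_mother = "het")
  bad <- make_variant(zygosity = "hom", gt_father = "ref", gt_mother = "het")
  orphan <- make_variant(zygosity = "hom", gt_father = NA, gt_mother = NA)
  out <- segregation_filter(rbind(ok, bad, orphan))
  expect_equal(nrow(out$retained), 2)
  expect_equal(out$retained$segregation, c("consistent", "unphased"))
  expect_equal(out$dropped$drop_reason, "mendelian_violation")
  # het records pass through untouched
  het <- make_variant(zygosity = "het", gt_father = "ref", gt_mother = "ref")
  expect_equal(nrow(segregation_filter(het)$retained), 1)
})

test_that("compound-het pairing phases by parental descent", {
  a <- make_variant(pos = 100, gt_father = "het", gt_mother = "ref")
  b <- make_variant(pos = 200, gt_father = "ref", gt_mother = "het")
  c_ <- make_variant(pos = 300, gt_father = "het", gt_mother = "ref")
  d <- make_variant(pos = 400, gt_father = NA, gt_mother = NA)
  # trans pair: opposite parental origins, retained
  p1 <- find_compound_hets(rbind(a, b))
  expect_equal(p1$phase, "trans"); expect_true(p1$potential)
  # cis pair: both paternal, excluded from downstream counting
  p2 <- find_compound_hets(rbind(a, c_))
  expect_equal(p2$phase, "cis"); expect_false(p2$potential)
  # unknown phase: retained as potential
  p3 <- find_compound_hets(rbind(a, d))
  expect_equal(p3$phase, "unknown"); expect_true(p3$potential)
  # pairs never span genes or families
  e <- make_variant(pos = 500, gene = "OTHER")
  f <- make_variant(pos = 600, family = "F999")
  expect_equal(nrow(find_compound_hets(rbind(a, e, f))), 0)
})

test_that("control-database subtraction distinguishes co-occurrence", {
  hom <- rbind(make_variant(pos = 10, zygosity = "hom"),
               make_variant(pos = 20, zygosity = "hom"))
  pairs <- data.frame(family = "F001", gene = "G1",
                      id1 = c("chr1:100:A:T", "chr1:200:A:T", "chr1:300:A:T"),
                      id2 = c("chr1:101:A:T", "chr1:201:A:T", "chr1:301:A:T"),
                      consequence1 = "other-coding",
                      consequence2 = "other-coding",
                      phase = "unknown", potential = TRUE,
                      stringsAsFactors = FALSE)
  ctrl <- data.frame(
    variant_id = c("chr1:10:A:T",                       # hom in a control
                   "chr1:20:A:T",                       # het only in controls
                   "chr1:100:A:T", "chr1:101:A:T",      # both in SAME control
                   "chr1:200:A:T", "chr1:201:A:T",      # split across controls
                   "chr1:300:A:T"),                     # only one member seen
    individual = c("C1", "C2", "C3", "C3", "C4", "C5", "C6"),
    zygosity = c("hom", "het", "het", "het", "het", "het", "het"),
    stringsAsFactors = FALSE)
  out <- control_db_filter(hom, pairs, ctrl)
  expect_equal(variant_ids(out$hom_records), "chr1:20:A:T")  # het carrier kept
  expect_setequal(out$pairs$id1, c("chr1:200:A:T", "chr1:300:A:T"))
  # loose mode also removes the split pair
  out2 <- control_db_filter(hom, pairs, ctrl, require_same_individual = FALSE)
  expect_setequal(out2$pairs$id1, "chr1:300:A:T")
})

test_that("gene-list intersection keeps coding hits and tallies", {
  hom <- rbind(make_variant(gene = "IN1", zygosity = "hom"),
               make_variant(gene = "IN2", zygosity = "hom",
                            consequence = "deep-intronic"),
               make_variant(gene = "OUT", zygosity = "hom"))
  pairs <- data.frame(family = "F001", gene = c("IN1", "OUT"),
                      id1 = c("a", "b"), id2 = c("c", "d"),
                      consequence1 = c("frameshift", "other-coding"),
                      consequence2 = c("canonical-splice", "other-coding"),
                      phase = "trans", potential = TRUE,
                      stringsAsFactors = FALSE)
  out <- intersect_gene_set(hom, pairs, c("IN1", "IN2"))
  expect_equal(out$tallies$before, c(hom = 3L, pair = 2L))
  expect_equal(out$tallies$after, c(hom = 1L, pair = 1L))
  expect_equal(out$hom_records$gene, "IN1")   # deep-intronic excluded
  expect_error(intersect_gene_set(hom, pairs, character(0)), "empty")
})

test_that("recurrence tally counts each family once per gene", {
  hom <- rbind(make_variant(family = "F1", gene = "G1", zygosity = "hom"),
               make_variant(family = "F1", gene = "G1", pos = 999,
                            zygosity = "hom"),        # same family, same gene
               make_variant(family = "F2", gene = "G1", zygosity = "hom"),
               make_variant(family = "F4", gene = "G2", zygosity = "hom"))
  pairs <- data.frame(family = c("F3", "F1"), gene = c("G1", "G2"),
                      id1 = "x", id2 = "y", consequence1 = "other-coding",
                      consequence2 = "other-coding", phase = "unknown",
                      potential = TRUE, stringsAsFactors = FALSE)
  rec <- tally_recurrence(hom, pairs)
  expect_equal(rec$counts[["G1"]], 3L)   # F1 deduplicated
  expect_equal(rec$counts[["G2"]], 2L)
  expect_identical(rec$flagged, "G1")
})

test_that("reduction percentage reproduces the printed arithmetic", {
  expect_equal(reduction_percentage(5485, 179), 96.7)
  expect_equal(reduction_percentage(100, 100), 0)
  expect_equal(reduction_percentage(8, 2), 75)
  expect_error(reduction_percentage(0, 0), "positive")
  expect_error(reduction_percentage(5, 6), "exceeds")
})

test_that("the planted causal gene is recovered end to end", {
  for (s in c(3, 77, 2024)) {
    cfg <- simulation_config(n_genes = 400, n_families = 20, seed = s)
    co <- simulate_cohort_variants(cfg)
    res <- run_variant_pipeline(co$variants, co$control_db,
                                sprintf("G%05d", 1:400))
    expect_identical(res$flagged, co$truth$causal_gene)
    # bookkeeping: retained + per-reason drops account for every input record
    expect_equal(sum(unlist(res$summary$drop_reasons)) +
                   nrow(segregation_filter(
                     filter_variants(co$variants)$retained)$retained),
                 nrow(co$variants))
  }
})
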