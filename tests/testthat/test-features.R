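test_that("quantile normalization matches hand-computed rank means", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # tied entries share the mean of the reference values they span
  mt <- cbind(a = c(1, 1, 2), b = c(3, 4, 5))
  expect_equal(unname(quantile_normalize(mt)),
               cbind(c(2.25, 2.25, 3.5), c(2, 2.5, 3.5)))
  # columns already identically distributed are a fixed point
  mf <- cbind(a = c(5, 1, 3), b = c(1, 3, 5))
  expect_equal(quantile_normalize(mf), mf)
})

test_that("quantile normalization equalizes distributions per batch only", {
  set.seed(1)
  m <- matrix(rnorm(200), 50, 4)
  batches <- c("b1", "b1", "b2", "b2")
  q <- quantile_normalize(m, batches)
  expect_equal(sort(q[, 1]), sort(q[, 2]))
  expect_equal(sort(q[, 3]), sort(q[, 4]))
  expect_false(isTRUE(all.equal(sort(q[, 1]), sort(q[, 3]))))
  # rank order within a column is preserved
  for (j in 1:4) expect_equal(order(q[, j]), order(m[, j]))
})

test_that("quantile normalization agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(300), 60, 5)   # tie-free
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("weighted median follows the cumulative-weight definition", {
  expect_equal(weighted_median(0.7, 3), 0.7)
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  expect_equal(weighted_median(c(0, 1, 10), c(1, 1, 2)), 1)
  expect_error(weighted_median(numeric(0)), "empty")
  expect_error(weighted_median(c(1, 2), c(0, 0)), "zero")
  # equal weights: ordinary median (odd n), lower median (even n)
  set.seed(3)
  for (i in 1:20) {
    x <- sample(100, sample(2:9, 1))
    wm <- weighted_median(x)
    if (length(x) %% 2 == 1) expect_equal(wm, median(x))
    else expect_equal(wm, sort(x)[length(x) / 2])
  }
})

test_that("reagent aggregation down-weights discordant reagents", {
  one <- data.frame(gene = "G", score = 0.42)
  expect_equal(aggregate_reagents(one)$score, 0.42)
  tab <- data.frame(gene = "G", score = c(1, 1, 9))
  expect_equal(aggregate_reagents(tab)$score, 1)
  # permutation invariance
  set.seed(9)
  tab2 <- data.frame(gene = rep(c("A", "B"), each = 4), score = rnorm(8))
  perm <- tab2[sample(nrow(tab2)), ]
  a1 <- aggregate_reagents(tab2); a2 <- aggregate_reagents(perm)
  expect_equal(a1$score[match(a1$gene, a2$gene)], a2$score)
})

test_that("expression features apply quality exclusion and PCA contracts", {
  set.seed(5)
  n <- 40
  expr <- matrix(2^rnorm(n * 6, 3), n, 6,
                 dimnames = list(sprintf("G%02d", 1:n), paste0("S", 1:6)))
  samples <- data.frame(sample = paste0("S", 1:6),
                        tissue = rep(c("liver", "brain"), each = 3),
                        rin = c(5.9, 7.2, 8.0, 9, 9, 9))
  out <- expression_signature_features(expr, samples, quality_min = 6)
  expect_identical(out$excluded_samples, "S1")
  # liver keeps 2 samples => at most 1 component, loading = difference direction
  expect_lte(out$n_components[["liver"]], 1)
  qn_all <- quantile_normalize(expr[, -1])   # matches the surviving samples
  sub <- qn_all[, c("S2", "S3")]
  d <- sub[, 1] - sub[, 2]
  d <- d / sqrt(sum(d^2))
  if (out$n_components[["liver"]] == 1) {
    l <- out$features[, "liver.PC1"]
    expect_equal(abs(sum(l * d)), 1, tolerance = 1e-8)
    expect_gt(l[which.max(abs(l))], 0)      # sign convention
    expect_equal(sum(l^2), 1, tolerance = 1e-8)
  }
  # per-tissue medians present
  expect_true(all(c("liver.median", "brain.median") %in% colnames(out$features)))
})

test_that("degenerate and under-sampled tissues are handled per contract", {
  n <- 20
  base <- 2^rnorm(n, 3)
  expr <- cbind(S1 = base, S2 = base, S3 = base,
                S4 = 2^rnorm(n, 3), S5 = 2^rnorm(n, 3))
  rownames(expr) <- sprintf("G%02d", 1:n)
  samples <- data.frame(sample = colnames(expr),
                        tissue = c("flat", "flat", "flat", "var", "var"),
                        rin = rep(9, 5))
  out <- expression_signature_features(expr, samples)
  expect_equal(out$n_components[["flat"]], 0L)     # zero variance: median only
  expect_false(any(grepl("^flat\\.PC", colnames(out$features))))
  # a tissue reduced below 2 samples errors with its name
  samples$rin[4] <- 2
  expect_error(expression_signature_features(expr, samples), "var")
})

test_that("expression features are sample-order invariant up to loading sign", {
  set.seed(11)
  n <- 30
  expr <- matrix(2^rnorm(n * 8, 3), n, 8,
                 dimnames = list(sprintf("G%02d", 1:n), paste0("S", 1:8)))
  samples <- data.frame(sample = paste0("S", 1:8),
                        tissue = rep(c("t1", "t2"), each = 4), rin = 9)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  a <- expression_signature_features(expr, samples)
  b <- expression_signature_features(expr[, perm], samples[perm, ])
  common <- intersect(colnames(a$features), colnames(b$features))
  for (cn in common) {
    fa <- a$features[, cn]; fb <- b$features[, cn]
    expect_true(isTRUE(all.equal(fa, fb, tolerance = 1e-6)) ||
                  isTRUE(all.equal(fa, -fb, tolerance = 1e-6)), info = cn)
  }
})

test_that("assembly inner-joins genes and reports per-source losses", {
  r1 <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("p1", "p2")))
  r2 <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("p1", "p2")))
  cen <- data.frame(gene = c("B", "C"), score = c(0.1, 0.2))
  out <- assemble_features(list(r1, r2), centriole = cen)
  expect_identical(rownames(out$features), "B")
  expect_equal(out$report$lost_by_source,
               list(`screen-rep1` = 0L, `screen-rep2` = 1L, centriole = 1L))
  # identical coverage: nothing lost
  cen2 <- data.frame(gene = c("A", "B", "C"), score = 1:3)
  out2 <- assemble_features(list(r1, r1), centriole = cen2)
  expect_equal(unlist(out2$report$lost_by_source), c(`screen-rep1` = 0L,
                                                     `screen-rep2` = 0L,
                                                     centriole = 0L))
  expect_error(assemble_features(list(r1[1, , drop = FALSE],
                                      r2[2, , drop = FALSE])), "no gene")
})

test_that("assembled column count follows the block arithmetic", {
  cfg <- simulation_config(n_genes = 60, n_tissues = 2, samples_per_tissue = 5,
                           seed = 13)
  scr <- simulate_screen(cfg)
  ex <- simulate_expression(cfg, scr$true_ciliary)
  blk <- expression_signature_features(ex$expr, ex$samples)
  cen <- aggregate_reagents(simulate_reagents(cfg, scr$true_ciliary))
  out <- assemble_features(scr$replicates, cen, blk$features)
  expected <- 2 * cfg$n_params + 1 +
    sum(1 + blk$n_components[unique(ex$samples$tissue)])
  expect_equal(ncol(out$features), expected)
  expect_false(anyNA(out$features))
  expect_false(anyDuplicated(colnames(out$features)) > 0)
  src <- attr(out$features, "source")
  expect_equal(sum(src == "centriole"), 1)
})
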