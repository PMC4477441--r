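# shared fixture builders -- everything is generated in code, no files

make_variant <- function(family = "F001", gene = "G1", chrom = "chr1",
                         pos = 100L, ref = "A", alt = "T",
                         consequence = "other-coding", zygosity = "het",
                         gt_father = "het", gt_mother = "ref",
                         af = 1e-4, cadd = 25, gerp = 5, autosomal = TRUE) {
  data.frame(family = family, gene = gene, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt,
             consequence = consequence, zygosity = zygosity,
             gt_father = gt_father, gt_mother = gt_mother,
             population_af = af, cadd_phred = cadd, gerp = gerp,
             autosomal = autosomal, stringsAsFactors = FALSE)
}

make_score_table <- function(genes, scores, training) {
  data.frame(gene = genes, score = scores, fdr = NA_real_,
             percentile = NA_real_, high_confidence = NA,
             training = training, stringsAsFactors = FALSE)
}

# brute-force two-sided Fisher p by enumeration over all tables with the
# observed margins (probability-mass rule); independent of the implementation
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- vapply(ks, function(k) {
    choose(c1, k) * choose(N - c1, r1 - k) / choose(N, r1)
  }, 0)
  obs <- pr[ks == m[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-7)])
}
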