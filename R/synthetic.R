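#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. The defaults describe a small but realistic world: a genome-scale
#' screen shrunk to \code{n_genes} genes measured on 31 image-derived
#' parameters in two replicates, roughly one gene in ten truly ciliary,
#' informative features shifted by two within-gene standard deviations, a
#' mild additive batch offset between replicates, evidence counts that are
#' Poisson and class-correlated, tissue-structured expression, and a variant
#' cohort in which one causal gene carries a recurrent frameshift allele at
#' population frequency 0.0036 compounded with rare second hits.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_params number of screen parameters per replicate (default 31).
#' @param n_replicates number of screen replicates (default 2).
#' @param frac_positive proportion of genes that are truly ciliary.
#' @param effect_size standardized mean shift of informative features in true
#'   ciliary genes.
#' @param n_informative number of screen parameters carrying signal.
#' @param batch_shift additive offset applied to replicate r as
#'   \code{batch_shift * (r - 1)}.
#' @param noe_lambda_pos,noe_lambda_neg Poisson means for evidence counts of
#'   true ciliary / other genes.
#' @param n_tissues,samples_per_tissue expression panel dimensions.
#' @param low_quality_frac fraction of expression samples given an RNA
#'   quality score below the exclusion cutoff.
#' @param n_families number of exome-sequenced families in the cohort.
#' @param causal_gene identifier of the planted recessive gene; defaults to
#'   the first gene of the universe.
#' @param common_allele_af population allele frequency of the planted shared
#'   frameshift (default 0.0036).
#' @param seed integer master seed; each generator adds a fixed offset so one
#'   extra call never perturbs another generator's stream.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 2000, n_params = 31, n_replicates = 2,
                              frac_positive = 0.1, effect_size = 2,
                              n_informative = 10, batch_shift = 0.5,
                              noe_lambda_pos = 3, noe_lambda_neg = 0.2,
                              n_tissues = 5, samples_per_tissue = 10,
                              low_quality_frac = 0.05,
                              n_families = 20, causal_gene = NULL,
                              common_allele_af = 0.0036, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_params = as.integer(n_params),
              n_replicates = as.integer(n_replicates),
              frac_positive = frac_positive, effect_size = effect_size,
              n_informative = as.integer(n_informative),
              batch_shift = batch_shift,
              noe_lambda_pos = noe_lambda_pos, noe_lambda_neg = noe_lambda_neg,
              n_tissues = as.integer(n_tissues),
              samples_per_tissue = as.integer(samples_per_tissue),
              low_quality_frac = low_quality_frac,
              n_families = as.integer(n_families), causal_gene = causal_gene,
              common_allele_af = common_allele_af, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1 || n_params < 1 || n_replicates < 1 || n_tissues < 1 ||
        n_families < 1)
      stop("all counts must be >= 1")
    if (!(frac_positive > 0 && frac_positive < 1))
      stop("frac_positive must lie strictly between 0 and 1")
    if (n_informative > n_params)
      stop("n_informative cannot exceed n_params")
    if (noe_lambda_neg < 0 || noe_lambda_pos < noe_lambda_neg)
      stop("need noe_lambda_pos >= noe_lambda_neg >= 0")
    if (samples_per_tissue < 2)
      stop("samples_per_tissue must be >= 2 (principal components undefined)")
    if (common_allele_af <= 0 || common_allele_af >= 1)
      stop("common_allele_af must be a frequency in (0, 1)")
  })
  structure(cfg, class = "simulation_config")
}

# fixed per-generator seed offsets (design: one stream per generator)
.seed_offsets <- c(screen = 101L, evidence = 211L, expression = 307L,
                   cohort = 401L)

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate the high-content siRNA screen
#'
#' Draws per-gene Gaussian features for \code{n_replicates} replicates of
#' \code{n_params} parameters. True ciliary genes have the first
#' \code{n_informative} parameters shifted by \code{effect_size} standard
#' deviations; replicate r receives a constant batch offset
#' \code{batch_shift * (r - 1)} on every entry. The returned truth partition
#' assigns 80\% of true ciliary genes to training positives and holds the
#' rest out as benchmark candidates; 30\% of the remaining genes are known
#' negatives and the rest unknown.
#'
#' @param config a [simulation_config()].
#' @return list with \code{replicates} (list of gene-by-parameter matrices,
#'   identical gene order), \code{truth} (a [label_set()]) and
#'   \code{true_ciliary} (character vector of all genes carrying signal).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed + .seed_offsets[["screen"]], {
    n <- config$n_genes; p <- config$n_params
    genes <- gene_ids(n)
    n_pos <- max(1L, round(config$frac_positive * n))
    ciliary <- sort(sample(genes, n_pos))
    reps <- vector("list", config$n_replicates)
    shift <- c(rep(config$effect_size, config$n_informative),
               rep(0, p - config$n_informative))
    for (r in seq_len(config$n_replicates)) {
      m <- matrix(rnorm(n * p), n, p,
                  dimnames = list(genes, sprintf("param%02d", seq_len(p))))
      m[ciliary, ] <- m[ciliary, , drop = FALSE] +
        matrix(shift, length(ciliary), p, byrow = TRUE)
      reps[[r]] <- m + config$batch_shift * (r - 1)
    }
    names(reps) <- sprintf("rep%d", seq_len(config$n_replicates))

    train_pos <- ciliary[seq_len(max(1L, floor(0.8 * n_pos)))]
    held_out <- setdiff(ciliary, train_pos)
    rest <- setdiff(genes, ciliary)
    n_neg <- max(1L, round(0.3 * length(rest)))
    negatives <- sort(sample(rest, n_neg))
    unknown <- setdiff(rest, negatives)
    truth <- label_set(train_pos, negatives, held_out, unknown)
    list(replicates = reps, truth = truth, true_ciliary = ciliary)
  })
}

#' Simulate an evidence table
#'
#' Per-gene counts of independent supporting studies ("number of
#' evidences"): any-species counts are Poisson with class-dependent mean;
#' human-only counts are a binomial thinning of the any-species count, so
#' \code{NOE_human <= NOE_any} holds by construction.
#'
#' @param truth a [label_set()] or character vector giving the truly ciliary
#'   genes; all other genes of \code{universe} use the background rate.
#' @param universe character vector of all genes to report.
#' @param lambda_pos,lambda_neg Poisson means (ciliary / background).
#' @param human_frac thinning probability for the human-only count.
#' @param seed integer seed.
#' @return data frame with columns \code{gene}, \code{NOE_any},
#'   \code{NOE_human}.
#' @export
simulate_evidence <- function(truth, universe, lambda_pos, lambda_neg,
                              human_frac = 0.5, seed = 1L) {
  if (inherits(truth, "label_set"))
    truth <- c(truth$positives, truth$held_out_candidates)
  if (lambda_neg < 0 || lambda_pos < lambda_neg)
    stop("need lambda_pos >= lambda_neg >= 0")
  with_local_seed(seed + .seed_offsets[["evidence"]], {
    lam <- ifelse(universe %in% truth, lambda_pos, lambda_neg)
    any_ <- rpois(length(universe), lam)
    human <- rbinom(length(universe), any_, human_frac)
    data.frame(gene = universe, NOE_any = any_, NOE_human = human,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a tissue expression panel
#'
#' Log-normal-like RPKM values with a per-gene baseline, a per-tissue
#' per-gene profile shift, and i.i.d. noise. Truly ciliary genes (when given)
#' share an extra expression shift in the first half of the tissues, so
#' expression features carry class signal. A configurable fraction of samples
#' receives an RNA-quality (RIN-like) score below the exclusion cutoff.
#'
#' @param config a [simulation_config()].
#' @param true_ciliary optional character vector of signal genes.
#' @param quality_min exclusion cutoff the low-quality samples fall below.
#' @return list with \code{expr} (genes x samples non-negative matrix) and
#'   \code{samples} (data frame: sample, tissue, rin).
#' @export
simulate_expression <- function(config, true_ciliary = character(),
                                quality_min = 6) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed + .seed_offsets[["expression"]], {
    n <- config$n_genes; nt <- config$n_tissues; st <- config$samples_per_tissue
    genes <- gene_ids(n)
    tissues <- sprintf("tissue%02d", seq_len(nt))
    samples <- data.frame(
      sample = sprintf("S%03d", seq_len(nt * st)),
      tissue = rep(tissues, each = st),
      stringsAsFactors = FALSE)
    low <- runif(nrow(samples)) < config$low_quality_frac
    samples$rin <- ifelse(low, runif(nrow(samples), 1, quality_min - 0.1),
                          runif(nrow(samples), quality_min + 0.5, 10))
    base <- rnorm(n, mean = 3, sd = 1.5)          # log2 baseline per gene
    tissue_fx <- matrix(rnorm(n * nt, sd = 1), n, nt)   # tissue-specific profile
    cil <- genes %in% true_ciliary
    cil_tissues <- seq_len(ceiling(nt / 2))
    tissue_fx[cil, cil_tissues] <- tissue_fx[cil, cil_tissues] +
      config$effect_size / 2
    logx <- base + tissue_fx[, match(samples$tissue, tissues)] +
      matrix(rnorm(n * nrow(samples), sd = 0.5), n, nrow(samples))
    expr <- 2^logx
    dimnames(expr) <- list(genes, samples$sample)
    list(expr = expr, samples = samples)
  })
}

#' Simulate per-gene reagent scores for a centriole-type screen
#'
#' Each gene gets several siRNA reagents; reagent scores scatter around a
#' per-gene latent effect that is shifted for truly ciliary genes, and a
#' fraction of reagents are discordant outliers (off-target-like), which is
#' what weighted-median aggregation is meant to resist.
#'
#' @param config a [simulation_config()].
#' @param true_ciliary character vector of signal genes.
#' @param reagents_range integer range of reagents per gene.
#' @param outlier_frac fraction of reagents replaced by off-target noise.
#' @return data frame with columns \code{gene}, \code{reagent}, \code{score}.
#' @export
simulate_reagents <- function(config, true_ciliary = character(),
                              reagents_range = c(3L, 5L), outlier_frac = 0.1) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed + .seed_offsets[["screen"]] + 7L, {
    genes <- gene_ids(config$n_genes)
    k <- sample(seq(reagents_range[1], reagents_range[2]),
                length(genes), replace = TRUE)
    eff <- rnorm(length(genes), sd = 0.5) +
      ifelse(genes %in% true_ciliary, config$effect_size / 2, 0)
    gene_col <- rep(genes, k)
    score <- rnorm(sum(k), mean = rep(eff, k), sd = 0.4)
    out <- runif(sum(k)) < outlier_frac
    score[out] <- rnorm(sum(out), 0, 2)
    data.frame(gene = gene_col,
               reagent = unlist(lapply(k, seq_len)),
               score = score, stringsAsFactors = FALSE)
  })
}

# ---- variant cohort ---------------------------------------------------------

new_variant <- function(family, gene, chrom, pos, ref, alt, consequence,
                        zygosity, gt_father, gt_mother, af, cadd, gerp,
                        autosomal = TRUE) {
  data.frame(family = family, gene = gene, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, consequence = consequence,
             zygosity = zygosity, gt_father = gt_father, gt_mother = gt_mother,
             population_af = af, cadd_phred = cadd, gerp = gerp,
             autosomal = autosomal, stringsAsFactors = FALSE)
}

#' Simulate family exome variant tables and a control database
#'
#' Plants one recessive causal gene: two families homozygous for (distinct)
#' rare damaging variants with het/het parents, and several families compound
#' heterozygous for a shared common frameshift allele (population frequency
#' \code{common_allele_af}, GERP above the frameshift cutoff) in trans with a
#' rare second hit. Background families carry a mix of variants that fail at
#' least one cascade filter (too common, benign scores, non-coding, wrong
#' segregation, cis pairs) plus occasional qualifying but non-recurrent
#' biallelic genotypes in random genes. The control database holds common
#' variants only, some in homozygous state.
#'
#' Genotypes use the tokens \code{ref}/\code{het}/\code{hom}; \code{NA} means
#' the parent was not sequenced.
#'
#' @param config a [simulation_config()].
#' @param gene_universe character vector the causal gene must belong to.
#' @return list with \code{variants} (one data frame, one row per variant per
#'   family), \code{control_db} (data frame: variant_id, individual,
#'   zygosity), and \code{truth} (list: causal_gene, biallelic_families,
#'   shared_allele).
#' @export
simulate_cohort_variants <- function(config, gene_universe = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(gene_universe)) gene_universe <- gene_ids(config$n_genes)
  causal <- config$causal_gene
  if (is.null(causal)) causal <- gene_universe[1]
  if (!causal %in% gene_universe)
    stop("causal gene ", causal, " absent from gene universe")
  if (config$n_families < 5)
    stop("need at least 5 families to plant 4 biallelic ones")

  with_local_seed(config$seed + .seed_offsets[["cohort"]], {
    fams <- sprintf("F%03d", seq_len(config$n_families))
    rows <- list()
    af_rare <- function(k) signif(runif(k, 1e-5, 5e-4), 3)

    # the shared frameshift allele (M1-like): common enough to recur, still < 1%
    shared <- list(chrom = "chr14", pos = 428L, ref = "CA", alt = "C",
                   af = config$common_allele_af, gerp = 5.2)

    hom_fams <- fams[1:2]
    chet_fams <- fams[3:4]
    for (i in seq_along(hom_fams)) {
      rows[[length(rows) + 1]] <- new_variant(
        hom_fams[i], causal, "chr14", 1000L + i, "G", "T", "other-coding",
        "hom", "het", "het", af_rare(1), runif(1, 25, 35), runif(1, 4, 6))
    }
    for (i in seq_along(chet_fams)) {
      # shared frameshift from the father, rare second hit from the mother
      rows[[length(rows) + 1]] <- new_variant(
        chet_fams[i], causal, shared$chrom, shared$pos, shared$ref, shared$alt,
        "frameshift", "het", "het", "ref", shared$af, runif(1, 15, 25),
        shared$gerp)
      rows[[length(rows) + 1]] <- new_variant(
        chet_fams[i], causal, "chr14", 2000L + i, "C", "A", "other-coding",
        "het", "ref", "het", af_rare(1), runif(1, 25, 35), runif(1, 3, 6))
    }
    truth_fams <- c(hom_fams, chet_fams)

    # background variants in every family
    other_genes <- setdiff(gene_universe, causal)
    for (f in fams) {
      n_bg <- 25L
      g <- sample(other_genes, n_bg, replace = TRUE)
      for (j in seq_len(n_bg)) {
        kind <- sample(c("common", "benign", "noncoding", "lone_het",
                         "bad_segregation", "cis_pair", "sex_chrom"), 1)
        pos <- sample.int(9e6, 1)
        if (kind == "common") {
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr2", pos, "A", "G", "other-coding", "hom",
            "het", "het", runif(1, 0.02, 0.4), runif(1, 12, 30), runif(1, 2, 5))
        } else if (kind == "benign") {
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr3", pos, "T", "C", "other-coding",
            sample(c("het", "hom"), 1), "het", "het", af_rare(1),
            runif(1, 0, 9.5), runif(1, 0, 3))
        } else if (kind == "noncoding") {
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr4", pos, "G", "A", "deep-intronic", "hom",
            "het", "het", af_rare(1), runif(1, 12, 25), runif(1, 2, 5))
        } else if (kind == "lone_het") {
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr5", pos, "C", "T", "other-coding", "het",
            "het", "ref", af_rare(1), runif(1, 15, 30), runif(1, 3, 6))
        } else if (kind == "bad_segregation") {
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr6", pos, "A", "T", "other-coding", "hom",
            "ref", "het", af_rare(1), runif(1, 15, 30), runif(1, 3, 6))
        } else if (kind == "cis_pair") {
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr7", pos, "G", "C", "other-coding", "het",
            "het", "ref", af_rare(1), runif(1, 15, 30), runif(1, 3, 6))
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chr7", pos + 50L, "T", "G", "other-coding", "het",
            "het", "ref", af_rare(1), runif(1, 15, 30), runif(1, 3, 6))
        } else { # sex_chrom
          rows[[length(rows) + 1]] <- new_variant(
            f, g[j], "chrX", pos, "C", "G", "other-coding", "hom",
            "ref", "het", af_rare(1), runif(1, 15, 30), runif(1, 3, 6),
            autosomal = FALSE)
        }
      }
      # rare qualifying but non-recurrent biallelic hit in a random gene
      if (runif(1) < 0.3) {
        rows[[length(rows) + 1]] <- new_variant(
          f, sample(other_genes, 1), "chr8", sample.int(9e6, 1), "A", "C",
          "other-coding", "hom", "het", "het", af_rare(1),
          runif(1, 20, 35), runif(1, 4, 6))
      }
    }
    variants <- do.call(rbind, rows)
    variants$variant_id <- with(variants, paste(chrom, pos, ref, alt, sep = ":"))

    # controls: unaffected individuals carrying common variants only
    common <- unique(variants$variant_id[variants$population_af >= 0.01])
    ctrl <- data.frame(
      variant_id = rep(common, each = 3),
      individual = paste0("C", rep(seq_len(3), length(common)) +
                            3L * rep(seq_along(common) - 1L, each = 3)),
      zygosity = rep(c("het", "het", "hom"), length(common)),
      stringsAsFactors = FALSE)

    list(variants = variants, control_db = ctrl,
         truth = list(causal_gene = causal,
                      biallelic_families = truth_fams,
                      shared_allele = shared))
  })
}
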