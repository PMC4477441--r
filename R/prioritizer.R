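#' Forest configuration
#'
#' @param ntree number of trees (default 5000, as used for the real screen;
#'   tests and examples use a few hundred — the count is configuration, not
#'   logic).
#' @param mtry features tried per split; \code{NULL} means the square root of
#'   the feature count (rounded down).
#' @param min_node minimal node size to attempt a split (default 1: trees are
#'   grown to purity).
#' @param seed integer seed for bag sampling and split feature sampling.
#' @return object of class \code{forest_config}.
#' @export
forest_config <- function(ntree = 5000, mtry = NULL, min_node = 1, seed = 1L) {
  stopifnot(ntree >= 1, is.null(mtry) || mtry >= 1, min_node >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "forest_config")
}

#' Train a class-balanced bagged forest and score every gene
#'
#' Grows \code{ntree} CART-style trees. Each tree's bag holds the positive
#' training genes bootstrapped to their own count plus an equal number of
#' negatives drawn without replacement (randomized undersampling), so every
#' tree sees balanced classes however imbalanced the training set is. Every
#' gene of the feature matrix is scored by the fraction of trees voting
#' positive; for training genes only the trees whose bag excluded the gene
#' contribute (out-of-bag score), so training scores are honest
#' cross-validated predictions.
#'
#' @param features numeric gene x feature matrix (rownames = genes), e.g.
#'   from [assemble_features()].
#' @param labels a [label_set()]; only \code{positives} and \code{negatives}
#'   are used for training.
#' @param config a [forest_config()].
#' @return a score table: data frame \code{gene}, \code{score}, \code{fdr}
#'   (NA until [estimate_fdr()]), \code{percentile}, \code{high_confidence},
#'   \code{training} ("positive"/"negative"/"none"); the fitted forest and
#'   per-tree bag class sizes are attached as attributes \code{forest} and
#'   \code{bag_sizes}.
#' @export
train_balanced_forest <- function(features, labels, config = forest_config()) {
  stopifnot(is.matrix(features), inherits(labels, "label_set"),
            inherits(config, "forest_config"))
  genes <- rownames(features)
  pos <- which(genes %in% labels$positives)
  neg <- which(genes %in% labels$negatives)
  if (length(pos) < 2 || length(neg) < 2)
    stop("need >= 2 genes of each training class in the feature matrix")
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(features))))
          else min(as.integer(config$mtry), ncol(features))
  X <- unclass(features)
  fit <- cpp_rf_train(X, pos - 1L, neg - 1L, config$ntree, mtry,
                      config$min_node, config$seed)
  score <- fit$vote_sum / fit$ntree
  is_train <- seq_along(genes) %in% c(pos, neg)
  oob_ok <- fit$oob_cnt > 0
  score[is_train & oob_ok] <- (fit$oob_sum / fit$oob_cnt)[is_train & oob_ok]
  if (any(is_train & !oob_ok))
    warning("training gene(s) in every bag; falling back to in-bag score")
  tab <- data.frame(
    gene = genes, score = score, fdr = NA_real_,
    percentile = 100 * (rank(score, ties.method = "average") - 0.5) / length(score),
    high_confidence = NA,
    training = ifelse(seq_along(genes) %in% pos, "positive",
                      ifelse(seq_along(genes) %in% neg, "negative", "none")),
    stringsAsFactors = FALSE)
  attr(tab, "forest") <- fit$trees
  attr(tab, "bag_sizes") <- fit$bag_sizes
  attr(tab, "mtry") <- mtry
  tab
}

#' Score new feature data with a fitted forest
#'
#' @param score_table output of [train_balanced_forest()] (carries the
#'   forest).
#' @param features matrix with the same columns as the training matrix.
#' @return numeric vector of positive-class vote fractions, one per row.
#' @export
predict_forest <- function(score_table, features) {
  forest <- attr(score_table, "forest")
  if (is.null(forest)) stop("score table carries no fitted forest")
  cpp_rf_predict(forest, unclass(features))
}

#' Estimate a per-gene FDR from scores and training labels
#'
#' For a score threshold t, the raw FDR is the fraction of training genes at
#' or above t that are training negatives (optionally reweighted by a prior
#' odds ratio). Each gene's threshold is its own score; the raw values are
#' then monotonized by a step-down pass (running maximum from the top score
#' downward), so the reported FDR is non-increasing in score. If no training
#' gene reaches a threshold the raw FDR there is 0 by convention.
#'
#' @param score_table from [train_balanced_forest()].
#' @param prior_ratio multiplier on the negative count (default 1: plain
#'   proportion of negatives among selected training genes).
#' @return the score table with \code{fdr} filled.
#' @export
estimate_fdr <- function(score_table, prior_ratio = 1) {
  stopifnot(all(c("score", "training") %in% names(score_table)))
  tr <- score_table$training != "none"
  if (!any(tr)) stop("no training genes in score table")
  s_neg <- sort(score_table$score[score_table$training == "negative"])
  s_all <- sort(score_table$score[tr])
  n_ge <- function(sorted, t) length(sorted) - findInterval(t, sorted, left.open = TRUE)
  raw <- function(t) {
    tot <- n_ge(s_all, t)
    if (tot == 0) return(0)
    min(1, prior_ratio * n_ge(s_neg, t) / tot)
  }
  o <- order(score_table$score, decreasing = TRUE)
  r <- vapply(score_table$score[o], raw, 0)
  score_table$fdr[o] <- cummax(r)   # step-down: non-increasing in score
  score_table
}

#' Select the high-confidence candidate set
#'
#' @param score_table with \code{fdr} filled (see [estimate_fdr()]).
#' @param fdr_cutoff keep genes with \code{fdr < fdr_cutoff} (default 0.1).
#' @return list with \code{genes} (character, sorted by decreasing score) and
#'   \code{score_table} (the input with \code{high_confidence} flags set).
#' @export
select_candidates <- function(score_table, fdr_cutoff = 0.1) {
  if (anyNA(score_table$fdr)) stop("run estimate_fdr() first")
  score_table$high_confidence <- score_table$fdr < fdr_cutoff
  sel <- score_table[score_table$high_confidence, , drop = FALSE]
  sel <- sel[order(sel$score, decreasing = TRUE), , drop = FALSE]
  list(genes = sel$gene, score_table = score_table)
}

#' Cross-replicate training protocol
#'
#' Mirrors the replicate-swap evaluation of a duplicated screen: train on
#' replicate 1's features and compute the AUC of the training genes'
#' predictions on replicate 2's features, and vice versa; additionally train
#' on the column-wise combination of both replicates and report the
#' out-of-bag AUC.
#'
#' @param rep1,rep2 gene x parameter matrices over the same genes.
#' @param labels a [label_set()].
#' @param config a [forest_config()]; the two directional fits use seeds
#'   \code{seed} and \code{seed + 1}, the combined fit \code{seed + 2}.
#' @return list with \code{auc_train1_test2}, \code{auc_train2_test1},
#'   \code{auc_combined_oob}.
#' @export
cross_replicate_protocol <- function(rep1, rep2, labels,
                                     config = forest_config(ntree = 500)) {
  stopifnot(identical(rownames(rep1), rownames(rep2)))
  train_eval <- function(train_m, test_m, seed) {
    cfg <- forest_config(config$ntree, config$mtry, config$min_node, seed)
    st <- train_balanced_forest(train_m, labels, cfg)
    tr <- st$training != "none"
    pred <- predict_forest(st, test_m[tr, , drop = FALSE])
    roc_auc(pred, st$training[tr] == "positive")
  }
  comb <- cbind(rep1, rep2)
  colnames(comb) <- c(paste0("rep1.", colnames(rep1)),
                      paste0("rep2.", colnames(rep2)))
  st <- train_balanced_forest(
    comb, labels,
    forest_config(config$ntree, config$mtry, config$min_node, config$seed + 2L))
  tr <- st$training != "none"
  list(auc_train1_test2 = train_eval(rep1, rep2, config$seed),
       auc_train2_test1 = train_eval(rep2, rep1, config$seed + 1L),
       auc_combined_oob = roc_auc(st$score[tr], st$training[tr] == "positive"))
}
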