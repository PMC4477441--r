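#' Quantile normalization within batches
#'
#' Forces every column of a batch onto the same empirical distribution: the
#' vector of across-column rank means. Ties receive the average of the
#' rank-mean values over the positions they occupy, so within-column rank
#' order is preserved and tied entries stay tied.
#'
#' @param m numeric matrix (rows = genes, columns = arrays/samples).
#' @param group_by batch label per column; columns are normalized within
#'   their batch only. Default: one batch.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m, group_by = rep("batch1", ncol(m))) {
  stopifnot(is.matrix(m), is.numeric(m), length(group_by) == ncol(m))
  if (anyNA(m)) stop("quantile_normalize expects a complete matrix")
  out <- m
  for (b in unique(group_by)) {
    cols <- which(group_by == b)
    if (length(cols) == 0) stop("empty batch: ", b)
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(apply(sub, 2, sort))        # reference distribution
    for (j in seq_along(cols)) {
      x <- sub[, j]
      vals <- mu[rank(x, ties.method = "first")]
      # tied input values share the mean of the reference values they span
      out[, cols[j]] <- ave(vals, match(x, x), FUN = mean)
    }
  }
  out
}

#' Weighted median
#'
#' The smallest score s whose cumulative weight (over scores sorted
#' increasingly) reaches half the total weight. With equal weights this is
#' the ordinary median for odd counts and the lower median for even counts.
#'
#' @param scores numeric vector.
#' @param weights non-negative weights, same length; default equal.
#' @return a single numeric.
#' @export
weighted_median <- function(scores, weights = rep(1, length(scores))) {
  if (length(scores) == 0) stop("empty scores")
  if (length(weights) != length(scores)) stop("weights length mismatch")
  if (any(weights < 0)) stop("negative weights")
  tot <- sum(weights)
  if (tot <= 0) stop("weights sum to zero")
  o <- order(scores)
  cw <- cumsum(weights[o])
  scores[o][which(cw >= tot / 2)[1]]
}

# consistency weight of reagent i: inverse distance to the leave-one-out
# median, with a floor epsilon of 5% of the gene's score IQR
reagent_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  eps <- max(0.05 * stats::IQR(x), .Machine$double.eps^0.5)
  dev <- vapply(seq_len(n), function(i) abs(x[i] - median(x[-i])), 0)
  1 / (eps + dev)
}

#' Aggregate per-reagent scores to one per-gene score
#'
#' ATARiS-style consistency weighting: each reagent is weighted by the
#' inverse of its absolute deviation from the leave-one-out median of the
#' gene's other reagents (plus a small epsilon tied to the score IQR), then
#' the weighted median of the reagent scores is taken. Discordant
#' (off-target-like) reagents get small weight and cannot drag the gene
#' score.
#'
#' @param reagent_table data frame with columns \code{gene}, \code{score}
#'   (one row per reagent).
#' @return data frame with columns \code{gene}, \code{score} (one row per
#'   gene, input gene order of first appearance).
#' @export
aggregate_reagents <- function(reagent_table) {
  stopifnot(all(c("gene", "score") %in% names(reagent_table)))
  genes <- unique(reagent_table$gene)
  agg <- vapply(split(reagent_table$score, reagent_table$gene)[genes],
                function(x) weighted_median(x, reagent_weights(x)), 0)
  data.frame(gene = genes, score = unname(agg), stringsAsFactors = FALSE)
}

#' Tissue expression signature features
#'
#' Mirrors a GTEx-style feature construction: samples with RNA-quality score
#' below \code{quality_min} are excluded, the remaining matrix is quantile
#' normalized across all samples, and for each tissue the per-gene median
#' expression plus the gene loadings of the smallest set of leading principal
#' components capturing \code{variance_target} of that tissue's variance are
#' emitted. Loading vectors are unit-norm and oriented so their
#' largest-magnitude entry is positive; a tissue with zero variance
#' contributes only its median feature.
#'
#' @param expr genes x samples non-negative matrix.
#' @param samples data frame with columns \code{sample}, \code{tissue},
#'   \code{rin} matching \code{colnames(expr)}.
#' @param quality_min exclusion cutoff on the quality score (RIN-like,
#'   1-10 scale; default 6).
#' @param variance_target cumulative variance the retained components must
#'   reach (default 0.95).
#' @param max_components cap on components per tissue (default 7).
#' @return list with \code{features} (genes x features matrix, names
#'   \code{<tissue>.median} / \code{<tissue>.PC<k>}), \code{n_components}
#'   (per tissue), \code{excluded_samples}.
#' @export
expression_signature_features <- function(expr, samples, quality_min = 6,
                                          variance_target = 0.95,
                                          max_components = 7) {
  stopifnot(is.matrix(expr), nrow(samples) == ncol(expr))
  keep <- samples$rin >= quality_min
  excluded <- samples$sample[!keep]
  expr <- expr[, keep, drop = FALSE]
  samples <- samples[keep, , drop = FALSE]
  tab <- table(samples$tissue)
  if (any(tab < 2))
    stop("tissue(s) with <2 surviving samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  expr <- quantile_normalize(expr)

  blocks <- list(); ncomp <- integer()
  for (ts in unique(samples$tissue)) {
    sub <- expr[, samples$tissue == ts, drop = FALSE]
    med <- apply(sub, 1, median)
    blk <- matrix(med, ncol = 1,
                  dimnames = list(rownames(expr), paste0(ts, ".median")))
    pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
    varex <- pc$sdev^2
    totv <- sum(varex)
    if (totv > 1e-12) {
      k <- which(cumsum(varex) / totv >= variance_target)[1]
      k <- min(k, max_components, sum(varex > 1e-12))
      if (k >= 1) {
        load <- pc$rotation[, seq_len(k), drop = FALSE]
        for (j in seq_len(k)) {           # sign: largest-|entry| positive
          i <- which.max(abs(load[, j]))
          if (load[i, j] < 0) load[, j] <- -load[, j]
        }
        colnames(load) <- paste0(ts, ".PC", seq_len(k))
        blk <- cbind(blk, load)
        ncomp[ts] <- k
      } else ncomp[ts] <- 0L
    } else ncomp[ts] <- 0L
    blocks[[ts]] <- blk
  }
  list(features = do.call(cbind, blocks), n_components = ncomp,
       excluded_samples = excluded)
}

#' Assemble the fused per-gene feature matrix
#'
#' Inner-joins the gene-keyed blocks (screen replicates, centriole score,
#' expression signatures): genes missing from any block are dropped, never
#' imputed, and a join report records how many genes each block lost relative
#' to the union of all blocks.
#'
#' @param screen_reps list of gene x parameter matrices (one per replicate).
#' @param centriole data frame \code{gene}, \code{score} from
#'   [aggregate_reagents()]; optional.
#' @param expression genes x features matrix from
#'   [expression_signature_features()]; optional.
#' @return list with \code{features} (matrix, class \code{feature_matrix},
#'   column attribute \code{source}), \code{report} (list: n_union, n_joined,
#'   lost_by_source).
#' @export
assemble_features <- function(screen_reps, centriole = NULL, expression = NULL) {
  blocks <- list()
  for (r in seq_along(screen_reps)) {
    m <- screen_reps[[r]]
    colnames(m) <- paste0("screen-rep", r, ".", colnames(m))
    blocks[[paste0("screen-rep", r)]] <- m
  }
  if (!is.null(centriole)) {
    cm <- matrix(centriole$score, ncol = 1,
                 dimnames = list(centriole$gene, "centriole.score"))
    blocks[["centriole"]] <- cm
  }
  if (!is.null(expression)) blocks[["expression"]] <- expression

  gene_sets <- lapply(blocks, rownames)
  union_g <- Reduce(union, gene_sets)
  joined <- Reduce(intersect, gene_sets)
  if (length(joined) == 0) stop("no gene present in every block")
  # keep the first block's ordering for stability
  joined <- gene_sets[[1]][gene_sets[[1]] %in% joined]

  mat <- do.call(cbind, lapply(blocks, function(b) b[joined, , drop = FALSE]))
  if (anyNA(mat)) stop("assembled feature matrix contains missing values")
  if (anyDuplicated(colnames(mat))) stop("duplicate feature names")
  src <- rep(names(blocks), vapply(blocks, ncol, 0L))
  attr(mat, "source") <- src
  class(mat) <- c("feature_matrix", class(mat))
  lost <- vapply(gene_sets, function(g) length(setdiff(union_g, g)), 0L)
  list(features = mat,
       report = list(n_union = length(union_g), n_joined = length(joined),
                     lost_by_source = as.list(lost)))
}
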