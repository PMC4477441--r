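#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with ties
#' counted one half (rank formulation of the Mann-Whitney statistic).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, TRUE = positive.
#' @return AUC between 0 and 1.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall curve
#'
#' Precision and recall at every distinct score threshold, from the highest
#' score down; recall is non-decreasing as the threshold falls.
#'
#' @inheritParams roc_auc
#' @return data frame \code{threshold}, \code{precision}, \code{recall}.
#' @export
precision_recall_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0 || n1 == length(labels)) stop("both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(labels & scores >= t), 0)
  sel <- vapply(th, function(t) sum(scores >= t), 0)
  data.frame(threshold = th, precision = tp / sel, recall = tp / n1)
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Tests whether \code{x} is stochastically greater than \code{y} (or the
#' reverse). Exact p by full enumeration of rank assignments when the pooled
#' size is at most \code{exact_max} and there are no ties; otherwise a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"greater"}: x tends larger than y.
#' @param exact_max switchover size for the exact path (default 12).
#' @param method \code{"auto"}, \code{"exact"} or \code{"approximate"} (both
#'   paths are exposed for testing).
#' @return list with \code{statistic} (Mann-Whitney U of x over y),
#'   \code{p_value}, \code{method}.
#' @export
wilcoxon_one_tailed <- function(x, y, alternative = c("greater", "less"),
                                exact_max = 12,
                                method = c("auto", "exact", "approximate")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  if (alternative == "less") return(wilcoxon_one_tailed(y, x, "greater",
                                                        exact_max, method))
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  nx <- length(x); ny <- length(y); N <- nx + ny
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  use_exact <- method == "exact" || (method == "auto" && N <= exact_max && !ties)
  if (use_exact) {
    # enumerate all C(N, nx) assignments of pooled values to the x group
    sets <- combn(N, nx)
    Us <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(Us >= U - 1e-9)
    list(statistic = U, p_value = p, method = "exact")
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sig2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U - mu - 0.5) / sqrt(sig2)
    list(statistic = U, p_value = pnorm(z, lower.tail = FALSE),
         method = "approximate")
  }
}

#' Bin classifier scores by ordinal evidence counts
#'
#' @param score_table data frame with \code{gene}, \code{score} (and
#'   \code{training} when \code{exclude_training}).
#' @param evidence data frame \code{gene}, \code{NOE_any}, \code{NOE_human}.
#' @param bins increasing integer vector of bin lower values; all but the
#'   last match exactly, the last collects counts greater or equal (the
#'   printed labels ">k" are read as ">=k" so the count k itself has a bin).
#' @param human_only use the human-only evidence column.
#' @param exclude_training drop genes used to train the classifier, so the
#'   trend is assessed on predictions only.
#' @return object of class \code{binned_scores}: list of \code{labels} and
#'   \code{scores} (one numeric vector per bin, same order).
#' @export
bin_by_evidence <- function(score_table, evidence, bins = c(0:7, 8),
                            human_only = FALSE, exclude_training = FALSE) {
  stopifnot(!is.unsorted(bins, strictly = TRUE))
  col <- if (human_only) "NOE_human" else "NOE_any"
  df <- merge(score_table, evidence, by = "gene")
  if (exclude_training) {
    if (!"training" %in% names(df)) stop("no training column to exclude on")
    df <- df[df$training == "none", , drop = FALSE]
  }
  v <- df[[col]]
  k <- length(bins)
  idx <- rep(NA_integer_, length(v))
  for (i in seq_len(k - 1)) idx[v == bins[i]] <- i
  idx[v >= bins[k]] <- k
  labels <- c(as.character(bins[-k]), paste0(">=", bins[k]))
  scores <- lapply(seq_len(k), function(i) df$score[!is.na(idx) & idx == i])
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    warning(dropped, " gene(s) fell between bins and were dropped")
  structure(list(labels = labels, scores = scores), class = "binned_scores")
}

#' Jonckheere-Terpstra test for an ordered trend across bins
#'
#' The statistic sums, over every ordered pair of bins, the Mann-Whitney
#' count of higher-bin values exceeding lower-bin values (ties one half).
#' Exact p by enumeration of all group assignments when the pooled size is
#' at most \code{exact_max}; otherwise a normal approximation with the
#' tie-corrected variance and a continuity correction of one half.
#'
#' @param binned a \code{binned_scores} object (see [bin_by_evidence()]) or a
#'   plain list of numeric vectors in increasing bin order.
#' @param alternative \code{"increasing"}: scores rise with bin order.
#' @param exact_max switchover pooled size for the exact path (default 10).
#' @param method \code{"auto"}, \code{"exact"} or \code{"approximate"}.
#' @return list with \code{statistic}, \code{p_value}, \code{method}.
#' @export
jonckheere_terpstra <- function(binned,
                                alternative = c("increasing", "decreasing"),
                                exact_max = 10,
                                method = c("auto", "exact", "approximate")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  groups <- if (inherits(binned, "binned_scores")) binned$scores else binned
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >= 2 non-empty bins")
  if (alternative == "decreasing") groups <- rev(groups)

  jt_stat <- function(groups) {
    s <- 0
    k <- length(groups)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      xi <- groups[[i]]; xj <- groups[[j]]
      s <- s + sum(vapply(xj, function(v) sum(v > xi) + 0.5 * sum(v == xi), 0))
    }
    s
  }
  obs <- jt_stat(groups)
  sizes <- lengths(groups)
  N <- sum(sizes)
  pooled <- unlist(groups)
  use_exact <- method == "exact" || (method == "auto" && N <= exact_max)
  if (use_exact) {
    # enumerate all distinct assignments of pooled values into groups of the
    # given sizes (choose indices for each group in turn)
    stats_acc <- numeric(0)
    recurse <- function(remaining, built) {
      gi <- length(built) + 1
      if (gi == length(sizes)) {
        stats_acc <<- c(stats_acc,
                        jt_stat(c(built, list(pooled[remaining]))))
        return(invisible())
      }
      for (pk in combn(length(remaining), sizes[gi], simplify = FALSE))
        recurse(remaining[-pk], c(built, list(pooled[remaining[pk]])))
    }
    recurse(seq_len(N), list())
    p <- mean(stats_acc >= obs - 1e-9)
    list(statistic = obs, p_value = p, method = "exact")
  } else {
    mu <- (N^2 - sum(sizes^2)) / 4
    tie_tab <- table(pooled)
    t1 <- N * (N - 1) * (2 * N + 5) -
      sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
      sum(tie_tab * (tie_tab - 1) * (2 * tie_tab + 5))
    t2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
      sum(tie_tab * (tie_tab - 1) * (tie_tab - 2))
    t3 <- sum(sizes * (sizes - 1)) * sum(tie_tab * (tie_tab - 1))
    sig2 <- t1 / 72 + t2 / (36 * N * (N - 1) * (N - 2)) + t3 / (8 * N * (N - 1))
    z <- (obs - mu - 0.5) / sqrt(sig2)   # continuity corrected
    list(statistic = obs, p_value = pnorm(z, lower.tail = FALSE),
         method = "approximate")
  }
}

#' Fraction of held-out benchmark candidates flagged by the classifier
#'
#' @param selected character vector, the selected candidate gene list.
#' @param held_out_candidates character vector of benchmark genes.
#' @return proportion of benchmark genes inside the selection.
#' @export
benchmark_flagged_fraction <- function(selected, held_out_candidates) {
  if (length(held_out_candidates) == 0) stop("empty held-out set")
  mean(held_out_candidates %in% selected)
}

#' Hypergeometric gene-set enrichment with Benjamini-Hochberg control
#'
#' Each collection set is intersected with the background; sets outside
#' \code{[min_set, max_set]} or overlapping the query in fewer than
#' \code{min_overlap} genes are not tested. The upper-tail hypergeometric
#' p-value (probability of an overlap at least as large) is adjusted across
#' all tested sets by the Benjamini-Hochberg step-up procedure and only sets
#' below \code{fdr_max} are reported.
#'
#' @param query gene set of interest; must be contained in \code{background}.
#' @param collections named list of gene sets (e.g. from [read_gmt()]).
#' @param background gene universe the query was drawn from.
#' @param min_set,max_set set-size window after background intersection
#'   (defaults 5 and 400).
#' @param min_overlap minimal query overlap to test a set (default 3).
#' @param fdr_max report sets with adjusted FDR below this (default 0.1);
#'   \code{Inf} reports all tested sets.
#' @return data frame \code{set}, \code{overlap}, \code{set_size},
#'   \code{query_size}, \code{background_size}, \code{p_value}, \code{fdr},
#'   ordered by p-value.
#' @export
hypergeom_enrichment <- function(query, collections, background,
                                 min_set = 5, max_set = 400, min_overlap = 3,
                                 fdr_max = 0.1) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background)) stop("query must be a subset of background")
  N <- length(background); n <- length(query)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(collections[[nm]], background)
    K <- length(set)
    if (K < min_set || K > max_set) return(NULL)
    k <- length(intersect(set, query))
    if (k < min_overlap) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0)
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      background_size = integer(), p_value = numeric(),
                      fdr = numeric()))
  rows$fdr <- p.adjust(rows$p_value, method = "BH")
  rows <- rows[rows$fdr < fdr_max, , drop = FALSE]
  rows[order(rows$p_value), , drop = FALSE]
}
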