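#' Allele frequency with printed percent
#'
#' @param alt,total alternate and total allele counts.
#' @return list with \code{proportion} and \code{percent} (half-even rounded
#'   to 2 decimals, the convention used when printing e.g. "17 of 326
#'   alleles (5.21\%)").
#' @export
allele_frequency <- function(alt, total) {
  if (total <= 0) stop("total allele count must be positive")
  if (alt < 0 || alt > total) stop("need 0 <= alt <= total")
  p <- alt / total
  list(proportion = p, percent = round(100 * p, 2))
}

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)))
    stop("need a 2x2 table of non-negative counts")
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-mass definition of two-sided: the sum of probabilities, over
#' all tables with the observed margins, that are no more probable than the
#' observed table (the common convention; mid-p and doubling variants
#' differ). A degenerate margin (an all-zero row or column) gives p = 1.
#'
#' @param table 2x2 matrix of counts; rows = arms (cases/controls), columns =
#'   allele classes (carrier/non-carrier).
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  k <- lo:hi
  probs <- dhyper(k, c1, N - c1, r1)
  obs <- dhyper(m[1, 1], c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Odds ratio of a 2x2 allele-count table
#'
#' Cross-product ratio a*d / (b*c); the Haldane-Anscombe correction of 0.5
#' per cell is applied only when some cell is zero, guaranteeing a finite
#' value.
#'
#' @param table 2x2 matrix: \code{rbind(c(a, b), c(c, d))} with carriers in
#'   the first column.
#' @return odds ratio.
#' @export
odds_ratio <- function(table) {
  m <- as_2x2(table)
  if (any(m == 0)) m <- m + 0.5
  (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
}

#' Build the carrier/non-carrier allele table of two cohorts
#'
#' @param cases,controls length-2 vectors \code{c(alt, total)} of allele
#'   counts.
#' @return 2x2 matrix (rows cases/controls, columns carrier/non-carrier).
#' @export
allele_count_table <- function(cases, controls) {
  stopifnot(length(cases) == 2, length(controls) == 2,
            cases[1] <= cases[2], controls[1] <= controls[2])
  m <- rbind(cases = c(cases[1], cases[2] - cases[1]),
             controls = c(controls[1], controls[2] - controls[1]))
  colnames(m) <- c("carrier", "non_carrier")
  m
}

#' Pooled allele frequency across databases
#'
#' @param count_pairs list of \code{c(alt, total)} pairs (e.g. per-database
#'   allele counts to combine).
#' @return pooled proportion, sum(alt) / sum(total).
#' @export
pooled_frequency <- function(count_pairs) {
  if (length(count_pairs) == 0) stop("empty count list")
  alt <- sum(vapply(count_pairs, `[`, 0, 1))
  tot <- sum(vapply(count_pairs, `[`, 0, 2))
  if (tot <= 0) stop("total allele count must be positive")
  alt / tot
}
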