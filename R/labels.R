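#' Construct a label set
#'
#' A \code{label_set} partitions a gene universe into four pairwise-disjoint
#' groups: training positives, training negatives, held-out benchmark
#' candidates (never used in training) and unknown genes. Each gene carries a
#' provenance tag recording which source list it came from.
#'
#' @param positives,negatives,held_out_candidates,unknown character vectors of
#'   gene identifiers (opaque, case-sensitive).
#' @param provenance named character vector mapping gene to source tag
#'   (\code{"gold-standard"}, \code{"metabolome"}, \code{"housekeeping"},
#'   \code{"candidate"}, ...). Optional.
#' @return object of class \code{label_set}.
#' @export
label_set <- function(positives, negatives, held_out_candidates = character(),
                      unknown = character(), provenance = NULL) {
  parts <- list(positives = unique(as.character(positives)),
                negatives = unique(as.character(negatives)),
                held_out_candidates = unique(as.character(held_out_candidates)),
                unknown = unique(as.character(unknown)))
  all <- unlist(parts, use.names = FALSE)
  if (anyDuplicated(all))
    stop("label_set partitions must be pairwise disjoint; offending gene(s): ",
         paste(head(unique(all[duplicated(all)]), 5), collapse = ", "))
  structure(c(parts, list(provenance = provenance)), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("label_set:",
      length(x$positives), "positives /",
      length(x$negatives), "negatives /",
      length(x$held_out_candidates), "held-out candidates /",
      length(x$unknown), "unknown\n")
  invisible(x)
}

#' Curate training labels against an evidence table
#'
#' Cross-filters candidate source lists against a per-gene evidence table
#' (counts of independent supporting studies, "NOE"): a gold-standard gene
#' stays positive only with at least one evidence; a metabolome/housekeeping
#' gene stays negative only with zero evidences. Genes absent from the
#' evidence table count as zero evidences. Genes named by both a positive and
#' a negative source list have conflicting annotation and are dropped
#' entirely. Benchmark candidates are excluded from both training partitions
#' and kept as \code{held_out_candidates}.
#'
#' @param gold_standard character vector, positive source list.
#' @param metabolome,housekeeping character vectors, negative source lists.
#' @param candidates character vector, benchmark list excluded from training.
#' @param evidence data frame with columns \code{gene}, \code{NOE_any},
#'   \code{NOE_human} (see [simulate_evidence()]).
#' @param evidence_column which evidence count gates the positive set;
#'   any-species is the default.
#' @return a [label_set()]; genes in no source list and not held out are
#'   placed in \code{unknown} only if passed via \code{universe}.
#' @param universe optional full gene universe; remaining genes become
#'   \code{unknown}.
#' @export
curate_labels <- function(gold_standard, metabolome, housekeeping,
                          candidates = character(), evidence,
                          evidence_column = c("NOE_any", "NOE_human"),
                          universe = NULL) {
  evidence_column <- match.arg(evidence_column)
  noe <- evidence_lookup(evidence, evidence_column)

  gold <- unique(as.character(gold_standard))
  negsrc <- unique(c(as.character(metabolome), as.character(housekeeping)))
  candidates <- unique(as.character(candidates))

  conflicted <- intersect(gold, negsrc)
  gold <- setdiff(gold, conflicted)
  negsrc <- setdiff(negsrc, conflicted)

  # candidates are benchmark-only: excluded from training whatever else says
  gold <- setdiff(gold, candidates)
  negsrc <- setdiff(negsrc, candidates)

  positives <- gold[noe(gold) >= 1]
  negatives <- negsrc[noe(negsrc) == 0]
  if (length(positives) == 0 || length(negatives) == 0)
    stop("curation produced an empty training partition")

  neg_tag <- ifelse(negatives %in% metabolome, "metabolome", "housekeeping")
  prov <- c(setNames(rep("gold-standard", length(positives)), positives),
            setNames(neg_tag, negatives),
            setNames(rep("candidate", length(candidates)), candidates))
  unknown <- character()
  if (!is.null(universe))
    unknown <- setdiff(unique(as.character(universe)),
                       c(positives, negatives, candidates))
  label_set(positives, negatives, candidates, unknown, provenance = prov)
}

# closure mapping gene vectors to evidence counts, absent => 0
evidence_lookup <- function(evidence, column) {
  stopifnot(all(c("gene", column) %in% names(evidence)))
  if (any(evidence[[column]] < 0)) stop("negative evidence counts")
  tab <- setNames(evidence[[column]], as.character(evidence$gene))
  function(genes) {
    v <- tab[genes]
    v[is.na(v)] <- 0
    unname(v)
  }
}

#' Partition sizes of a label set
#'
#' @param labels a [label_set()].
#' @return named integer vector with one count per partition plus the total.
#' @export
partition_sizes <- function(labels) {
  stopifnot(inherits(labels, "label_set"))
  n <- c(positives = length(labels$positives),
         negatives = length(labels$negatives),
         held_out_candidates = length(labels$held_out_candidates),
         unknown = length(labels$unknown))
  c(n, total = sum(n))
}
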