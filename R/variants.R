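CODING_CONSEQUENCES <- c("frameshift", "other-coding", "canonical-splice")

variant_ids <- function(records) {
  if ("variant_id" %in% names(records)) return(records$variant_id)
  with(records, paste(chrom, pos, ref, alt, sep = ":"))
}

#' Record-level variant filter cascade
#'
#' Retains autosomal variants with population allele frequency below
#' \code{af_max} that look deleterious: frameshifts need a GERP score of at
#' least \code{gerp_min}, every other consequence needs a CADD-phred score of
#' at least \code{cadd_min}. Each dropped record gets exactly one
#' machine-readable reason; the filters are record-local, so the retained set
#' does not depend on application order.
#'
#' @param records variant data frame (see [simulate_cohort_variants()] for
#'   the column contract).
#' @param af_max allele-frequency cutoff (default 0.01).
#' @param cadd_min CADD-phred cutoff for non-frameshift variants (default 10).
#' @param gerp_min GERP cutoff for frameshift variants (default 4.0).
#' @param keep_unannotated retain records with missing AF instead of dropping
#'   them with reason \code{"unannotated"} (default FALSE).
#' @return list with \code{retained} and \code{dropped} (with column
#'   \code{drop_reason}).
#' @export
filter_variants <- function(records, af_max = 0.01, cadd_min = 10,
                            gerp_min = 4.0, keep_unannotated = FALSE) {
  reason <- rep(NA_character_, nrow(records))
  unann <- is.na(records$population_af)
  if (!keep_unannotated) reason[unann] <- "unannotated"
  ok_af <- !unann & records$population_af < af_max
  if (keep_unannotated) ok_af <- ok_af | unann
  reason[is.na(reason) & !records$autosomal] <- "non_autosomal"
  reason[is.na(reason) & !ok_af] <- "common"
  fs <- records$consequence == "frameshift"
  fail_del <- ifelse(fs, records$gerp < gerp_min, records$cadd_phred < cadd_min)
  reason[is.na(reason) & fail_del] <- "benign_score"
  keep <- is.na(reason)
  list(retained = records[keep, , drop = FALSE],
       dropped = cbind(records[!keep, , drop = FALSE],
                       drop_reason = reason[!keep]))
}

#' Segregation filter for homozygous variants
#'
#' Homozygous proband variants must be inherited from two carrier parents:
#' when a parent was sequenced and is homozygous-reference, the record is a
#' Mendelian violation and is dropped with a flag. Heterozygous records pass
#' through unchanged (they are resolved at the compound-het stage), as do
#' records from families without parental data, which are flagged
#' \code{"unphased"}.
#'
#' @param records variant data frame with \code{zygosity}, \code{gt_father},
#'   \code{gt_mother} (\code{NA} = parent not sequenced).
#' @return list with \code{retained} (extra column \code{segregation}) and
#'   \code{dropped} (with \code{drop_reason = "mendelian_violation"}).
#' @export
segregation_filter <- function(records) {
  n <- nrow(records)
  seg <- rep("consistent", n)
  drop <- rep(FALSE, n)
  no_parents <- is.na(records$gt_father) & is.na(records$gt_mother)
  seg[no_parents] <- "unphased"
  hom <- records$zygosity == "hom" & !no_parents
  bad <- hom & ((!is.na(records$gt_father) & records$gt_father == "ref") |
                  (!is.na(records$gt_mother) & records$gt_mother == "ref"))
  drop[bad] <- TRUE
  retained <- records[!drop, , drop = FALSE]
  retained$segregation <- seg[!drop]
  list(retained = retained,
       dropped = cbind(records[drop, , drop = FALSE],
                       drop_reason = rep("mendelian_violation", sum(drop))))
}

parental_origin <- function(gt_f, gt_m) {
  f_carrier <- !is.na(gt_f) & gt_f %in% c("het", "hom")
  m_carrier <- !is.na(gt_m) & gt_m %in% c("het", "hom")
  f_ref <- !is.na(gt_f) & gt_f == "ref"
  m_ref <- !is.na(gt_m) & gt_m == "ref"
  ifelse(f_carrier & m_ref, "paternal",
         ifelse(m_carrier & f_ref, "maternal", "unknown"))
}

#' Enumerate potential compound-heterozygous pairs
#'
#' All unordered pairs of distinct heterozygous variants in the same gene of
#' the same family. Phase is inferred by descent where parental genotypes
#' allow: opposite parental origins give \code{trans}, identical origins give
#' \code{cis}, anything else is \code{unknown}. Cis pairs are excluded from
#' downstream counting; trans and unknown pairs are retained as "potential".
#'
#' @param records variant data frame (heterozygous rows are used).
#' @return data frame, one row per pair: \code{family}, \code{gene},
#'   \code{id1}, \code{id2}, \code{phase}, \code{potential}.
#' @export
find_compound_hets <- function(records) {
  het <- records[records$zygosity == "het", , drop = FALSE]
  het$.vid <- variant_ids(het)
  out <- list()
  for (key in unique(paste(het$family, het$gene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    grp <- het[het$family == parts[1] & het$gene == parts[2], , drop = FALSE]
    grp <- grp[!duplicated(grp$.vid), , drop = FALSE]
    if (nrow(grp) < 2) next
    for (pair in combn(nrow(grp), 2, simplify = FALSE)) {
      a <- grp[pair[1], ]; b <- grp[pair[2], ]
      oa <- parental_origin(a$gt_father, a$gt_mother)
      ob <- parental_origin(b$gt_father, b$gt_mother)
      phase <- if (oa != "unknown" && ob != "unknown") {
        if (oa == ob) "cis" else "trans"
      } else "unknown"
      out[[length(out) + 1]] <- data.frame(
        family = a$family, gene = a$gene, id1 = a$.vid, id2 = b$.vid,
        consequence1 = a$consequence, consequence2 = b$consequence,
        phase = phase, potential = phase != "cis", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(family = character(), gene = character(),
                      id1 = character(), id2 = character(),
                      consequence1 = character(), consequence2 = character(),
                      phase = character(), potential = logical()))
  do.call(rbind, out)
}

#' Remove variants seen in unaffected control individuals
#'
#' A homozygous record is removed when any control individual carries the
#' same variant in homozygous state (heterozygous control carriers do not
#' disqualify a recessive allele). A compound-het pair is removed when both
#' members are carried by the same control individual — a true biallelic
#' control; a looser mode drops a pair when each member is seen in any
#' control.
#'
#' @param hom_records homozygous variant data frame.
#' @param pairs pair data frame from [find_compound_hets()].
#' @param control_db data frame \code{variant_id}, \code{individual},
#'   \code{zygosity}.
#' @param require_same_individual use the strict same-individual rule for
#'   pairs (default TRUE).
#' @return list with filtered \code{hom_records} and \code{pairs}.
#' @export
control_db_filter <- function(hom_records, pairs, control_db,
                              require_same_individual = TRUE) {
  hom_ids <- variant_ids(hom_records)
  ctrl_hom <- unique(control_db$variant_id[control_db$zygosity == "hom"])
  hom_keep <- !(hom_ids %in% ctrl_hom)

  if (nrow(pairs) > 0) {
    if (require_same_individual) {
      by_ind <- split(control_db$variant_id, control_db$individual)
      pair_drop <- vapply(seq_len(nrow(pairs)), function(i) {
        any(vapply(by_ind, function(v)
          pairs$id1[i] %in% v && pairs$id2[i] %in% v, TRUE))
      }, TRUE)
    } else {
      seen <- unique(control_db$variant_id)
      pair_drop <- pairs$id1 %in% seen & pairs$id2 %in% seen
    }
    pairs <- pairs[!pair_drop, , drop = FALSE]
  }
  list(hom_records = hom_records[hom_keep, , drop = FALSE], pairs = pairs)
}

#' Intersect surviving variants with a prioritized gene list
#'
#' Keeps homozygous records and compound-het pairs whose gene is in the list
#' and whose consequence is coding or canonical-splice (both members, for a
#' pair). Reports before/after tallies split by zygosity class.
#'
#' @param hom_records homozygous variant data frame.
#' @param pairs pair data frame.
#' @param gene_list character vector of prioritized genes.
#' @return list with \code{hom_records}, \code{pairs}, and \code{tallies}
#'   (before/after counts for homs and pairs).
#' @export
intersect_gene_set <- function(hom_records, pairs, gene_list) {
  if (length(gene_list) == 0) stop("empty gene list")
  before <- c(hom = nrow(hom_records), pair = nrow(pairs))
  hom_keep <- hom_records$gene %in% gene_list &
    hom_records$consequence %in% CODING_CONSEQUENCES
  pair_keep <- pairs$gene %in% gene_list &
    pairs$consequence1 %in% CODING_CONSEQUENCES &
    pairs$consequence2 %in% CODING_CONSEQUENCES
  hom_records <- hom_records[hom_keep, , drop = FALSE]
  pairs <- pairs[pair_keep, , drop = FALSE]
  list(hom_records = hom_records, pairs = pairs,
       tallies = list(before = before,
                      after = c(hom = nrow(hom_records), pair = nrow(pairs))))
}

#' Tally per-gene family recurrence and flag recurrent genes
#'
#' A family counts once per gene regardless of how many qualifying variants
#' or pairs it carries there.
#'
#' @param hom_records,pairs surviving records and pairs.
#' @param flag_min_families flag genes hit in at least this many families
#'   (default 3, i.e. "more than two families").
#' @return list with \code{counts} (named integer vector, decreasing) and
#'   \code{flagged} (character vector).
#' @export
tally_recurrence <- function(hom_records, pairs, flag_min_families = 3) {
  ev <- unique(rbind(
    data.frame(gene = hom_records$gene, family = hom_records$family,
               stringsAsFactors = FALSE),
    data.frame(gene = pairs$gene, family = pairs$family,
               stringsAsFactors = FALSE)))
  if (nrow(ev) == 0)
    return(list(counts = integer(0), flagged = character(0)))
  counts <- sort(table(ev$gene), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts,
       flagged = names(counts)[counts >= flag_min_families])
}

#' Percent reduction of the variant search space
#'
#' @param n_before,n_after counts before and after prioritization.
#' @return percentage, one decimal.
#' @export
reduction_percentage <- function(n_before, n_after) {
  if (n_before <= 0) stop("n_before must be positive")
  if (n_after > n_before) stop("n_after exceeds n_before")
  round(100 * (1 - n_after / n_before), 1)
}

#' Run the whole exome-intersection stage
#'
#' Applies the cascade in order: record-level filters, segregation check,
#' compound-het pairing, control-database subtraction, gene-list
#' intersection, recurrence tally. The summary reports variant counts under
#' both conventions for pairs (a pair as one unit, and as its two member
#' variants).
#'
#' @param variants cohort variant data frame (all families stacked).
#' @param control_db control individual variant database.
#' @param gene_list prioritized gene list.
#' @param flag_min_families see [tally_recurrence()].
#' @param ... passed to [filter_variants()].
#' @return list with \code{flagged}, \code{counts}, \code{summary} (before /
#'   after tallies, reduction percentages, drop reasons).
#' @export
run_variant_pipeline <- function(variants, control_db, gene_list,
                                 flag_min_families = 3, ...) {
  f1 <- filter_variants(variants, ...)
  f2 <- segregation_filter(f1$retained)
  surv <- f2$retained
  hom <- surv[surv$zygosity == "hom", , drop = FALSE]
  pairs <- find_compound_hets(surv)
  pairs <- pairs[pairs$potential, , drop = FALSE]
  f3 <- control_db_filter(hom, pairs, control_db)
  before <- c(hom = nrow(f3$hom_records), pair = nrow(f3$pairs))
  f4 <- intersect_gene_set(f3$hom_records, f3$pairs, gene_list)
  rec <- tally_recurrence(f4$hom_records, f4$pairs, flag_min_families)

  n_before_units <- sum(before)
  n_after_units <- sum(f4$tallies$after)
  drop_reasons <- table(c(as.character(f1$dropped$drop_reason),
                          as.character(f2$dropped$drop_reason)))
  list(
    flagged = rec$flagged, counts = rec$counts,
    hom_records = f4$hom_records, pairs = f4$pairs,
    summary = list(
      input_records = nrow(variants),
      drop_reasons = as.list(drop_reasons),
      before = as.list(before), after = as.list(f4$tallies$after),
      units = list(before = n_before_units, after = n_after_units,
                   reduction_pct = if (n_before_units > 0)
                     reduction_percentage(n_before_units, n_after_units)
                   else NA_real_),
      variants = list(   # pairs counted as two member variants
        before = unname(before["hom"] + 2 * before["pair"]),
        after = unname(f4$tallies$after["hom"] + 2 * f4$tallies$after["pair"]))))
}
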