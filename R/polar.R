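# Operon-relative positioning of fold changes, upstream/downstream median
# correction, operon effect classification, and the position +1
# (directly-downstream gene) statistics.

#' Assign operon-relative positions to fold changes
#'
#' Joins a replicate-averaged fold-change table with the operon structure
#' of each mutant's deleted gene. Every measured operon mate receives a
#' signed position (negative upstream, positive downstream; the deleted
#' gene itself, position 0, is excluded from the positioned table), and
#' the position +1 gene additionally receives the intergenic distance
#' between the deleted gene's stop codon and its start codon. Mutants
#' whose deleted gene is not in a multi-gene operon are routed to a
#' separate table available via [not_in_operon()].
#'
#' @param fc Fold-change data frame from [average_replicates()] (or
#'   [rna_fold_changes()] passed through it).
#' @param operons An `"operon_set"` ([read_operons()]).
#' @param deletions Named character vector: `mutant_id` -> deleted
#'   `gene_id`.
#' @param annotations Annotation data frame; used for intergenic
#'   distances of +1 genes.
#' @return Positioned data frame (`gene_id`, `mutant_id`, `condition`,
#'   `datatype`, `position`, `log2fc`, `intergenic_distance`,
#'   `n_replicates`) with the not-in-operon rows in attribute
#'   `"not_in_operon"`.
#' @export
position_fold_changes <- function(fc, operons, deletions, annotations) {
  stopifnot(inherits(operons, "operon_set"))
  validate_annotations(annotations)
  if (!"n_replicates" %in% names(fc)) fc$n_replicates <- 1L
  g2o <- gene_to_operon(operons)
  mutants <- unique(fc$mutant_id)
  unknown <- setdiff(mutants, names(deletions))
  if (length(unknown) > 0L) {
    stop("no deletion recorded for mutant(s): ",
         paste(unknown, collapse = ", "))
  }
  missing_ann <- setdiff(unlist(operons, use.names = FALSE),
                         annotations$gene_id)
  if (length(missing_ann) > 0L) {
    warning(length(missing_ann), " operon gene(s) absent from the ",
            "annotation set; intergenic distances involving them are NA")
  }
  pos_rows <- list()
  out_rows <- list()
  for (m in mutants) {
    del <- deletions[[m]]
    op_id <- g2o[del]
    rows <- fc[fc$mutant_id == m, , drop = FALSE]
    if (is.na(op_id) || length(operons[[op_id]]) < 2L) {
      out_rows[[m]] <- rows
      next
    }
    rp <- relative_positions(operons[[op_id]], del)
    idx <- match(rows$gene_id, rp$gene_id)
    keep <- !is.na(idx) & rp$position[idx] != 0L
    rows <- rows[keep, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows$position <- rp$position[idx[keep]]
    rows$intergenic_distance <- NA_integer_
    p1 <- which(rows$position == 1L)
    if (length(p1) > 0L) {
      p1_gene <- rp$gene_id[rp$position == 1L]
      d <- gene_pair_distance(annotations, del, p1_gene)
      rows$intergenic_distance[p1] <- d
    }
    pos_rows[[m]] <- rows
  }
  res <- do.call(rbind, pos_rows)
  if (is.null(res)) {
    res <- fc[0, , drop = FALSE]
    res$position <- integer(0)
    res$intergenic_distance <- integer(0)
  }
  cols <- c("gene_id", "mutant_id", "condition", "datatype", "position",
            "log2fc", "intergenic_distance", "n_replicates")
  res <- res[, intersect(cols, names(res)), drop = FALSE]
  rownames(res) <- NULL
  attr(res, "not_in_operon") <- {
    nio <- do.call(rbind, out_rows)
    if (!is.null(nio)) rownames(nio) <- NULL
    nio
  }
  res
}

gene_pair_distance <- function(annotations, deleted_id, downstream_id) {
  a <- annotations[annotations$gene_id == deleted_id, , drop = FALSE]
  b <- annotations[annotations$gene_id == downstream_id, , drop = FALSE]
  if (nrow(a) != 1L || nrow(b) != 1L) return(NA_integer_)
  tryCatch(intergenic_distance(a, b), error = function(e) NA_integer_)
}

#' Fold changes of mutants outside multi-gene operons
#'
#' @param positioned Result of [position_fold_changes()].
#' @return The rows for mutants whose deletion is not in an operon with
#'   other genes (negative-control set), or `NULL`.
#' @export
not_in_operon <- function(positioned) attr(positioned, "not_in_operon")

#' Correct fold changes for the per-side operon median
#'
#' Within each (mutant, condition, datatype), subtracts the median log2
#' fold change of all upstream genes from every upstream gene, and the
#' median of all downstream genes (positions >= +1, including +1 by
#' default) from every downstream gene. This removes the shared
#' transcriptional component of the operon so that gene-specific
#' deviations — notably the post-transcriptional effect on the +1
#' gene — stand out. Corrected values are emitted only for sides on
#' which at least `min_genes` genes are quantified.
#'
#' @param positioned Positioned table from [position_fold_changes()].
#' @param min_genes Minimum quantified genes per side (default 2).
#' @param include_p1 Include the +1 gene in the downstream median
#'   (default `TRUE`); set `FALSE` to compute the downstream median over
#'   positions >= +2 only (still subtracted from all downstream genes).
#' @return The table with an added `corrected_log2fc` column (`NA` where
#'   the side was not eligible).
#' @export
operon_median_correction <- function(positioned, min_genes = 2L,
                                     include_p1 = TRUE) {
  positioned$corrected_log2fc <- NA_real_
  key <- interaction(positioned$mutant_id, positioned$condition,
                     positioned$datatype, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    pos <- positioned$position[idx]
    for (side in c(-1, 1)) {
      side_idx <- idx[sign(pos) == side]
      if (length(side_idx) < min_genes) next
      ref_idx <- side_idx
      if (side == 1 && !include_p1) {
        ref_idx <- side_idx[positioned$position[side_idx] >= 2L]
        if (length(ref_idx) == 0L) next
      }
      med <- stats::median(positioned$log2fc[ref_idx])
      positioned$corrected_log2fc[side_idx] <-
        positioned$log2fc[side_idx] - med
    }
  }
  positioned
}

#' Classify operon-level transcriptional effects per mutant
#'
#' Takes the median uncorrected log2 fold change over downstream genes at
#' positions >= +2 — the gene directly downstream (+1) is excluded because
#' it carries an additional post-transcriptional effect — and classifies
#' the operon response of each mutant as `"up"` (median > threshold),
#' `"down"` (median < -threshold), `"none"`, or `"not_evaluable"` (no
#' gene at position >= +2 quantified).
#'
#' @param positioned Positioned table from [position_fold_changes()].
#' @param threshold_log2 Classification threshold on the absolute median
#'   log2 fold change (default 1, i.e. 2-fold; strict inequality).
#' @param exclude Optional character vector of mutant ids to drop (e.g.
#'   deletions of genes that regulate their own operon).
#' @return Data frame with one row per (mutant, condition, datatype):
#'   `median_downstream_excl_p1`, `n_downstream_excl_p1`, `class`.
#' @export
classify_operon_effects <- function(positioned, threshold_log2 = 1,
                                    exclude = character()) {
  stopifnot(threshold_log2 > 0)
  positioned <- positioned[!positioned$mutant_id %in% exclude, , drop = FALSE]
  key <- interaction(positioned$mutant_id, positioned$condition,
                     positioned$datatype, drop = TRUE)
  groups <- split(seq_len(nrow(positioned)), key)
  rows <- lapply(groups, function(idx) {
    down <- idx[positioned$position[idx] >= 2L]
    med <- if (length(down) > 0L) {
      stats::median(positioned$log2fc[down])
    } else NA_real_
    cls <- if (length(down) == 0L) "not_evaluable"
           else if (med > threshold_log2) "up"
           else if (med < -threshold_log2) "down"
           else "none"
    data.frame(mutant_id = positioned$mutant_id[idx[1L]],
               condition = positioned$condition[idx[1L]],
               datatype = positioned$datatype[idx[1L]],
               median_downstream_excl_p1 = med,
               n_downstream_excl_p1 = length(down),
               class = cls, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Summarize operon effect fractions
#'
#' @param effects Result of [classify_operon_effects()].
#' @return Data frame per (condition, datatype): number of evaluable
#'   mutants and counts/fractions of up- and downregulated operons.
#' @export
operon_effect_fractions <- function(effects) {
  key <- interaction(effects$condition, effects$datatype, drop = TRUE)
  rows <- lapply(split(effects, key), function(e) {
    ev <- e[e$class != "not_evaluable", , drop = FALSE]
    data.frame(condition = e$condition[1L], datatype = e$datatype[1L],
               n_evaluable = nrow(ev),
               n_up = sum(ev$class == "up"),
               n_down = sum(ev$class == "down"),
               frac_up = if (nrow(ev)) mean(ev$class == "up") else NA_real_,
               frac_down = if (nrow(ev)) mean(ev$class == "down") else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Test the gene directly downstream of the deletion
#'
#' Tests whether the position +1 genes (one value per mutant) differ from
#' the pooled genes at other downstream positions (>= +2) by a two-sample
#' Wilcoxon rank-sum test, on raw or median-corrected log2 fold changes.
#' A one-sample signed-rank alternative against 0 is available via
#' `comparison = "zero"`. The median linear fold change of the +1 genes
#' is reported alongside.
#'
#' @param positioned Positioned (optionally corrected) table.
#' @param datatype `"protein"` or `"rna"`.
#' @param use_corrected Use `corrected_log2fc` instead of `log2fc`.
#' @param comparison `"other_downstream"` (default, rank-sum vs pooled
#'   positions >= +2) or `"zero"` (signed-rank of +1 values against 0).
#' @param condition Optional condition filter.
#' @param alternative Passed to the test (default two-sided).
#' @return A `"polar_test"` with extra fields `median_p1_log2` and
#'   `median_p1_linear`.
#' @export
downstream_gene_test <- function(positioned, datatype = "protein",
                                 use_corrected = FALSE,
                                 comparison = c("other_downstream", "zero"),
                                 condition = NULL,
                                 alternative = "two.sided") {
  comparison <- match.arg(comparison)
  tab <- positioned[positioned$datatype == datatype, , drop = FALSE]
  if (!is.null(condition)) {
    tab <- tab[tab$condition == condition, , drop = FALSE]
  }
  val <- if (use_corrected) tab$corrected_log2fc else tab$log2fc
  p1 <- val[tab$position == 1L & !is.na(val)]
  if (length(p1) == 0L) stop("no values at position +1")
  res <- if (comparison == "other_downstream") {
    other <- val[tab$position >= 2L & !is.na(val)]
    if (length(other) == 0L) stop("no values at positions >= +2")
    rank_sum_test(p1, other, alternative = alternative)
  } else {
    wt <- stats::wilcox.test(p1, mu = 0, alternative = alternative,
                             exact = FALSE, correct = TRUE)
    new_test_result(wt$statistic, wt$p.value, length(p1), NA_integer_,
                    "Wilcoxon signed rank test vs 0 (normal approximation)")
  }
  res$median_p1_log2 <- stats::median(p1)
  res$median_p1_linear <- 2^stats::median(p1)
  res
}

#' Correlation between +1 downregulation and intergenic distance
#'
#' Spearman rank correlation between the median-corrected log2 fold
#' change of the +1 gene and the intergenic distance from the deleted
#' gene's stop codon, across mutants. A positive rho means genes closer
#' to the deletion are downregulated more.
#'
#' @param positioned Corrected table ([operon_median_correction()]).
#' @param datatype `"protein"` (default) or `"rna"`.
#' @param use_corrected Correlate corrected values (default `TRUE`).
#' @param condition Optional condition filter.
#' @return A `"polar_test"` with `estimate` = rho.
#' @export
distance_correlation <- function(positioned, datatype = "protein",
                                 use_corrected = TRUE, condition = NULL) {
  tab <- positioned[positioned$datatype == datatype &
                      positioned$position == 1L, , drop = FALSE]
  if (!is.null(condition)) {
    tab <- tab[tab$condition == condition, , drop = FALSE]
  }
  val <- if (use_corrected) tab$corrected_log2fc else tab$log2fc
  keep <- !is.na(val) & !is.na(tab$intergenic_distance)
  if (sum(keep) < 4L) {
    stop("need at least 4 mutants with corrected +1 values and distances")
  }
  spearman_test(val[keep], as.numeric(tab$intergenic_distance[keep]))
}

#' Concordance between two fold-change tables
#'
#' Pearson correlation of log2 fold changes joined on (gene, mutant),
#' e.g. protein vs RNA for mutants measured with both, or fold change vs
#' an abundance column.
#'
#' @param fc_a,fc_b Fold-change data frames (each with `gene_id`,
#'   `mutant_id`, `log2fc`).
#' @return A `"polar_test"` with `estimate` = r.
#' @export
concordance <- function(fc_a, fc_b) {
  j <- merge(fc_a[, c("gene_id", "mutant_id", "log2fc")],
             fc_b[, c("gene_id", "mutant_id", "log2fc")],
             by = c("gene_id", "mutant_id"), suffixes = c("_a", "_b"))
  if (nrow(j) < 3L) stop("fewer than 3 joined (gene, mutant) pairs")
  pearson_test(j$log2fc_a, j$log2fc_b)
}
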