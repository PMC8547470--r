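# End-to-end orchestration: raw intensities or coverage tracks to
# positioned/corrected tables, operon classifications and the +1
# statistics, with a per-stage run log.

#' Run the protein polar-effect pipeline
#'
#' Normalization, median-reference fold changes, replicate averaging,
#' operon-relative positioning, per-side median correction, operon effect
#' classification, the position +1 rank-sum tests (raw and corrected)
#' and the distance correlation.
#'
#' @param intensities An [intensity_matrix()] (raw).
#' @param annotations Annotation data frame ([read_annotations()]).
#' @param operons An `"operon_set"` ([read_operons()]).
#' @param deletions Named character vector mutant -> deleted gene.
#' @param normalization `"vsn_like"` or `"median_log"`.
#' @param min_genes Per-side eligibility for the median correction.
#' @param threshold_log2 Operon classification threshold.
#' @param exclude Mutants to exclude from classification (e.g.
#'   self-regulating operons).
#' @return List of class `"polar_run"`: `fold_changes`, `positioned`,
#'   `corrected`, `effects`, `fractions`, `p1_test`, `p1_test_corrected`,
#'   `distance_test` (or `NULL` when not computable) and `log` (stage
#'   counts).
#' @export
run_protein_pipeline <- function(intensities, annotations, operons,
                                 deletions,
                                 normalization = c("vsn_like", "median_log"),
                                 min_genes = 2L, threshold_log2 = 1,
                                 exclude = character()) {
  normalization <- match.arg(normalization)
  run_log <- list(n_proteins = nrow(intensities$values),
                  n_samples = ncol(intensities$values),
                  normalization = normalization)
  norm <- normalize_intensities(intensities, method = normalization)
  fc <- average_replicates(fold_changes_vs_median(norm))
  run_log$n_fold_changes <- nrow(fc)
  run_log$n_mutants <- length(unique(fc$mutant_id))
  positioned <- position_fold_changes(fc, operons, deletions, annotations)
  run_log$n_positioned <- nrow(positioned)
  nio <- not_in_operon(positioned)
  run_log$n_mutants_not_in_operon <-
    if (is.null(nio)) 0L else length(unique(nio$mutant_id))
  run_log$n_per_position <- table(positioned$position)
  corrected <- operon_median_correction(positioned, min_genes = min_genes)
  effects <- classify_operon_effects(positioned,
                                     threshold_log2 = threshold_log2,
                                     exclude = exclude)
  fractions <- operon_effect_fractions(effects)
  p1 <- try_test(downstream_gene_test(positioned, datatype = "protein"))
  p1c <- try_test(downstream_gene_test(corrected, datatype = "protein",
                                       use_corrected = TRUE))
  dist_test <- try_test(distance_correlation(corrected))
  structure(list(fold_changes = fc, positioned = positioned,
                 corrected = corrected, effects = effects,
                 fractions = fractions, p1_test = p1,
                 p1_test_corrected = p1c, distance_test = dist_test,
                 log = run_log),
            class = "polar_run")
}

#' Run the RNA polar-effect pipeline
#'
#' Strand-summed coverage to gene densities, the density < 1 filter,
#' median-reference fold changes, positioning, correction, classification
#' and the +1 rank-sum test.
#'
#' @param tracks Named list (by mutant) of strand track pairs
#'   `list(fwd, rev)` or pre-summed `"coverage_track"`s; alternatively
#'   the `rna_tracks` element of a [simulate_library()] result.
#' @param annotations,operons,deletions,min_genes,threshold_log2,exclude
#'   As in [run_protein_pipeline()].
#' @param density_threshold Minimum counts-per-nucleotide density
#'   (default 1).
#' @param condition Condition label for the output tables.
#' @return List of class `"polar_run"` (see [run_protein_pipeline()]);
#'   `distance_test` uses the RNA corrected values.
#' @export
run_rna_pipeline <- function(tracks, annotations, operons, deletions,
                             density_threshold = 1, min_genes = 2L,
                             threshold_log2 = 1, exclude = character(),
                             condition = "cassette") {
  densities <- gene_densities(tracks, annotations)
  run_log <- list(n_genes = nrow(annotations),
                  n_mutants = length(tracks),
                  n_quantified = nrow(densities))
  filtered <- filter_low_density(densities, threshold = density_threshold)
  run_log$n_below_density_threshold <- nrow(densities) - nrow(filtered)
  fc <- average_replicates(rna_fold_changes(filtered,
                                            condition = condition))
  run_log$n_fold_changes <- nrow(fc)
  positioned <- position_fold_changes(fc, operons, deletions, annotations)
  run_log$n_positioned <- nrow(positioned)
  run_log$n_per_position <- table(positioned$position)
  corrected <- operon_median_correction(positioned, min_genes = min_genes)
  effects <- classify_operon_effects(positioned,
                                     threshold_log2 = threshold_log2,
                                     exclude = exclude)
  fractions <- operon_effect_fractions(effects)
  p1 <- try_test(downstream_gene_test(positioned, datatype = "rna"))
  p1c <- try_test(downstream_gene_test(corrected, datatype = "rna",
                                       use_corrected = TRUE))
  dist_test <- try_test(distance_correlation(corrected, datatype = "rna"))
  structure(list(densities = filtered, fold_changes = fc,
                 positioned = positioned, corrected = corrected,
                 effects = effects, fractions = fractions, p1_test = p1,
                 p1_test_corrected = p1c, distance_test = dist_test,
                 log = run_log),
            class = "polar_run")
}

try_test <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' @export
print.polar_run <- function(x, ...) {
  cat("polar_run with", x$log$n_mutants, "mutants;",
      nrow(x$positioned), "positioned fold changes\n")
  print(x$fractions)
  if (!is.null(x$p1_test)) {
    cat("\nposition +1 vs other downstream (raw):\n")
    print(x$p1_test)
  }
  invisible(x)
}

#' Write the main outputs of a pipeline run to a directory
#'
#' Emits the positioned/corrected table, the operon effect summary and
#' the test results (JSON, p-values unadjusted).
#'
#' @param run A `"polar_run"`.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "polar_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(corrected = file.path(dir, "positioned_corrected.tsv"),
             effects = file.path(dir, "operon_effects.tsv"),
             tests = file.path(dir, "tests.json"))
  utils::write.table(run$corrected, paths[["corrected"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$effects, paths[["effects"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tests <- Filter(Negate(is.null),
                  list(p1 = run$p1_test, p1_corrected = run$p1_test_corrected,
                       distance = run$distance_test))
  jsonlite::write_json(lapply(tests, unclass), paths[["tests"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
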