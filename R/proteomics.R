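# Multiplexed proteomics: channel normalization and median-reference
# log2 fold changes.
#
# Intensities are per-protein signal sums of one TMT channel; channels are
# only comparable within a plex (one mass-spectrometry experiment), so all
# normalization and the median reference are computed per plex.

#' Construct an intensity matrix with its sample sheet
#'
#' @param values Numeric matrix, rows = proteins (rownames are gene ids),
#'   columns = samples (colnames are sample ids). Non-negative; `NA` marks
#'   a protein not quantified in a channel. Zeros are treated as missing
#'   (below detection).
#' @param samples Data frame with one row per column of `values`:
#'   `sample_id`, `mutant_id`, `replicate`, `plex_id`, `condition`.
#' @return An object of class `"intensity_matrix"`.
#' @export
intensity_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  req <- c("sample_id", "mutant_id", "replicate", "plex_id", "condition")
  stopifnot(is.data.frame(samples), all(req %in% names(samples)))
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    stop("sample sheet rows must match matrix columns (sample_id order)")
  }
  if (any(values < 0, na.rm = TRUE)) stop("negative intensities")
  if (any(is.na(samples$plex_id) | !nzchar(samples$plex_id))) {
    stop("every sample needs a plex_id")
  }
  values[!is.na(values) & values == 0] <- NA_real_
  structure(list(values = values, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$values), "proteins x",
      ncol(x$values), "samples in", length(unique(x$samples$plex_id)),
      "plex(es)\n")
  invisible(x)
}

#' Read an intensity matrix and sample sheet from TSV files
#'
#' @param matrix_path TSV/CSV, first column gene id, remaining columns one
#'   per sample.
#' @param samples_path TSV with columns `sample_id`, `mutant_id`,
#'   `replicate`, `plex_id`, `condition`.
#' @param sep Field separator for the matrix file (`"\t"` default, `","`
#'   for CSV).
#' @return An `"intensity_matrix"`.
#' @export
read_intensities <- function(matrix_path, samples_path, sep = "\t") {
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  intensity_matrix(values, samples[match(colnames(values),
                                         samples$sample_id), , drop = FALSE])
}

#' Normalize channel intensities within each plex
#'
#' `"median_log"` rescales each channel so that its median log-intensity
#' equals the plex average of channel medians (a pure per-channel scale
#' factor). `"vsn_like"` fits a per-channel affine calibration
#' (scale and offset) by iterated robust (Huber) regression of each
#' channel on the plex-wide median protein profile, converging on the
#' between-channel spread of generalized-log (`glog`) transformed
#' intensities; values are returned on the calibrated intensity scale.
#' Both methods preserve the within-channel rank order.
#'
#' @param im An [intensity_matrix()].
#' @param method `"vsn_like"` (default) or `"median_log"`.
#' @param max_iter,tol Iteration controls for the `vsn_like` fit.
#' @return A normalized `"intensity_matrix"`; the method is recorded in
#'   attribute `"normalization"`.
#' @export
normalize_intensities <- function(im, method = c("vsn_like", "median_log"),
                                  max_iter = 20L, tol = 1e-8) {
  stopifnot(inherits(im, "intensity_matrix"))
  method <- match.arg(method)
  values <- im$values
  all_missing <- colSums(!is.na(values)) == 0L
  if (any(all_missing)) {
    stop("sample(s) with no quantified proteins: ",
         paste(colnames(values)[all_missing], collapse = ", "))
  }
  for (plex in unique(im$samples$plex_id)) {
    cols <- which(im$samples$plex_id == plex)
    if (length(cols) < 2L) {
      stop("plex ", plex, " has fewer than 2 channels")
    }
    sub <- values[, cols, drop = FALSE]
    values[, cols] <- if (method == "median_log") {
      norm_median_log(sub)
    } else {
      norm_vsn_like(sub, max_iter = max_iter, tol = tol)
    }
  }
  out <- intensity_matrix(values, im$samples)
  attr(out, "normalization") <- method
  out
}

norm_median_log <- function(x) {
  med <- apply(log(x), 2L, stats::median, na.rm = TRUE)
  target <- mean(med)
  sweep(x, 2L, exp(med - target), "/")
}

glog <- function(x, c = 1) log((x + sqrt(x^2 + c^2)) / 2)

norm_vsn_like <- function(x, max_iter = 20L, tol = 1e-8) {
  nc <- ncol(x)
  # scale initialization from median log intensities; offsets start at 0
  med <- apply(log(x), 2L, stats::median, na.rm = TRUE)
  s <- exp(med - mean(med))
  o <- numeric(nc)
  c0 <- stats::median(x, na.rm = TRUE)  # glog crossover near typical signal
  spread_old <- Inf
  for (iter in seq_len(max_iter)) {
    cal <- sweep(sweep(x, 2L, o, "-"), 2L, s, "/")
    ref <- apply(cal, 1L, stats::median, na.rm = TRUE)
    for (j in seq_len(nc)) {
      ok <- !is.na(x[, j]) & !is.na(ref)
      if (sum(ok) < 3L || stats::sd(ref[ok]) == 0) next
      fit <- tryCatch(
        suppressWarnings(MASS::rlm(x[ok, j] ~ ref[ok], maxit = 100)),
        error = function(e) stats::lm(x[ok, j] ~ ref[ok]))
      co <- stats::coef(fit)
      if (is.finite(co[2L]) && co[2L] > 0) {
        o[j] <- co[1L]
        s[j] <- co[2L]
      }
    }
    # keep the overall scale: geometric mean of channel scales is 1
    g <- exp(mean(log(s)))
    s <- s / g
    o_mean <- mean(o)
    cal <- sweep(sweep(x, 2L, o, "-"), 2L, s, "/")
    resid <- glog(pmax(cal, 0), c = c0) -
      apply(glog(pmax(cal, 0), c = c0), 1L, stats::median, na.rm = TRUE)
    spread <- stats::median(abs(resid), na.rm = TRUE)
    if (abs(spread_old - spread) < tol * (1 + spread)) break
    spread_old <- spread
  }
  cal <- sweep(sweep(x, 2L, o, "-"), 2L, s, "/")
  cal[!is.na(cal) & cal <= 0] <- NA_real_  # offset pushed below detection
  cal
}

#' Per-sample log2 fold changes against the plex median
#'
#' For every protein and every sample, computes
#' `log2(intensity / median intensity of the same protein over all samples
#' of the same plex)`; the focal sample is included in the median, so the
#' per-(protein, plex) median linear fold change is 1 by construction.
#' Proteins missing in a sample yield no row; a protein whose plex median
#' is zero or missing is skipped with a warning.
#'
#' @param im A (normalized) [intensity_matrix()].
#' @return A fold-change data frame with columns `gene_id`, `mutant_id`,
#'   `condition`, `replicate`, `plex_id`, `log2fc`, `datatype`
#'   (`"protein"`).
#' @export
fold_changes_vs_median <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  out <- list()
  for (plex in unique(im$samples$plex_id)) {
    cols <- which(im$samples$plex_id == plex)
    if (length(unique(im$samples$mutant_id[cols])) < 3L) {
      warning("plex ", plex, " has fewer than 3 mutants; ",
              "the median reference is dominated by single samples")
    }
    sub <- im$values[, cols, drop = FALSE]
    med <- apply(sub, 1L, stats::median, na.rm = TRUE)
    degenerate <- !is.na(med) & med == 0
    if (any(degenerate)) {
      warning("plex ", plex, ": median intensity 0 for ",
              sum(degenerate), " protein(s); rows skipped")
      med[degenerate] <- NA_real_
    }
    lfc <- log2(sweep(sub, 1L, med, "/"))
    keep <- which(!is.na(lfc), arr.ind = TRUE)
    if (nrow(keep) == 0L) next
    sm <- im$samples[cols[keep[, 2L]], ]
    out[[plex]] <- data.frame(
      gene_id = rownames(sub)[keep[, 1L]],
      mutant_id = sm$mutant_id,
      condition = sm$condition,
      replicate = sm$replicate,
      plex_id = sm$plex_id,
      log2fc = lfc[keep],
      datatype = "protein",
      stringsAsFactors = FALSE)
  }
  fc <- do.call(rbind, out)
  rownames(fc) <- NULL
  fc
}

#' Average fold changes over replicates
#'
#' Collapses a per-sample fold-change table to one row per
#' (gene, mutant, condition, datatype). Averaging is done on the log2
#' scale by default (symmetric for up- and downregulation); `"linear"`
#' averages the linear ratios and re-logs.
#'
#' @param fc Fold-change data frame from [fold_changes_vs_median()] or
#'   [rna_fold_changes()].
#' @param scale `"log"` (default) or `"linear"`.
#' @return Fold-change data frame with columns `gene_id`, `mutant_id`,
#'   `condition`, `datatype`, `log2fc`, `n_replicates`.
#' @export
average_replicates <- function(fc, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  key <- interaction(fc$gene_id, fc$mutant_id, fc$condition, fc$datatype,
                     drop = TRUE, sep = "\r")
  val <- if (scale == "log") fc$log2fc else 2^fc$log2fc
  means <- tapply(val, key, mean)
  if (scale == "linear") means <- log2(means)
  n <- tapply(val, key, length)
  first <- fc[!duplicated(key), c("gene_id", "mutant_id", "condition",
                                  "datatype")]
  first$log2fc <- as.numeric(means[as.character(key[!duplicated(key)])])
  first$n_replicates <- as.integer(n[as.character(key[!duplicated(key)])])
  rownames(first) <- NULL
  first
}
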