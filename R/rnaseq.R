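# Transcript quantification from strand-separated WIG coverage tracks:
# per-gene coverage density, low-density filtering, and median-reference
# log2 fold changes across mutants.

#' Coverage track constructor
#'
#' A dense per-position coverage vector for one chromosome; positions are
#' 1-based and positions beyond the stored vector are implicitly 0.
#'
#' @param chrom Chromosome name.
#' @param cov Numeric vector of non-negative counts; element `i` is the
#'   count at position `i`.
#' @return An object of class `"coverage_track"`.
#' @export
coverage_track <- function(chrom, cov) {
  stopifnot(is.character(chrom), length(chrom) == 1L, is.numeric(cov))
  if (any(cov < 0, na.rm = TRUE)) stop("negative coverage counts")
  cov[is.na(cov)] <- 0
  structure(list(chrom = chrom, cov = as.numeric(cov)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$chrom, "-", length(x$cov), "positions,",
      format(sum(x$cov)), "total counts\n")
  invisible(x)
}

#' Read a UCSC WIG coverage file
#'
#' Parses `fixedStep` and `variableStep` blocks (UCSC span/step semantics)
#' into a dense per-position [coverage_track()]. Only single-chromosome
#' files are supported.
#'
#' @param path Path to a WIG file.
#' @return A `"coverage_track"`.
#' @export
read_wig <- function(path) {
  if (!file.exists(path)) stop("WIG file not found: ", path)
  gr <- rtracklayer::import(path, format = "wig")
  if (length(gr) == 0L) return(coverage_track("", numeric(0)))
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(chroms) > 1L) {
    stop("WIG file covers more than one chromosome: ", path)
  }
  starts <- GenomicRanges::start(gr)
  widths <- GenomicRanges::width(gr)
  cov <- numeric(max(GenomicRanges::end(gr)))
  pos <- sequence(widths, from = starts)
  cov[pos] <- rep(gr$score, widths)
  coverage_track(chroms, cov)
}

#' Sum forward and reverse strand coverage tracks
#'
#' @param fwd,rev `"coverage_track"` objects on the same chromosome.
#' @return A `"coverage_track"` with the positionwise sum.
#' @export
sum_strand_tracks <- function(fwd, rev) {
  stopifnot(inherits(fwd, "coverage_track"), inherits(rev, "coverage_track"))
  if (length(fwd$cov) == 0L) return(rev)
  if (length(rev$cov) == 0L) return(fwd)
  if (fwd$chrom != rev$chrom) {
    stop("chromosome mismatch: ", fwd$chrom, " vs ", rev$chrom)
  }
  n <- max(length(fwd$cov), length(rev$cov))
  cov <- numeric(n)
  cov[seq_along(fwd$cov)] <- fwd$cov
  cov[seq_along(rev$cov)] <- cov[seq_along(rev$cov)] + rev$cov
  coverage_track(fwd$chrom, cov)
}

#' Per-gene coverage density
#'
#' Sums the (strand-summed) counts over the gene body and divides by the
#' gene length (`end - start + 1`). Strand is ignored because the track is
#' already the sum of both strands; positions without coverage count 0.
#'
#' @param track A `"coverage_track"`.
#' @param gene One-row annotation data frame ([read_annotations()]).
#' @return Numeric density (counts per nucleotide).
#' @export
gene_density <- function(track, gene) {
  stopifnot(inherits(track, "coverage_track"), nrow(gene) == 1L)
  len <- gene$end - gene$start + 1L
  if (gene$start > length(track$cov)) return(0)
  idx <- gene$start:min(gene$end, length(track$cov))
  sum(track$cov[idx]) / len
}

#' Per-gene densities for a library of mutants
#'
#' @param tracks Named list (by mutant id); each element either a single
#'   strand-summed `"coverage_track"` or a list with elements `fwd` and
#'   `rev` which are summed first.
#' @param annotations Annotation data frame.
#' @return Data frame `gene_id`, `mutant_id`, `density`.
#' @export
gene_densities <- function(tracks, annotations) {
  stopifnot(!is.null(names(tracks)))
  validate_annotations(annotations)
  out <- lapply(names(tracks), function(m) {
    tr <- tracks[[m]]
    if (!inherits(tr, "coverage_track")) {
      tr <- sum_strand_tracks(tr$fwd, tr$rev)
    }
    dens <- vapply(seq_len(nrow(annotations)), function(i) {
      gene_density(tr, annotations[i, , drop = FALSE])
    }, numeric(1))
    data.frame(gene_id = annotations$gene_id, mutant_id = m,
               density = dens, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove low-coverage gene quantifications
#'
#' Drops every (gene, mutant) row whose length-normalized count density is
#' strictly below the threshold; the filter is per row, not per gene
#' globally, and runs before the median reference is computed.
#'
#' @param densities Data frame from [gene_densities()].
#' @param threshold Density cutoff (default 1 count per nucleotide).
#' @return Filtered data frame.
#' @export
filter_low_density <- function(densities, threshold = 1) {
  densities[densities$density >= threshold, , drop = FALSE]
}

#' Transcript log2 fold changes against the across-mutant median
#'
#' For each gene, `log2(density / median density over all mutants with a
#' retained quantification of that gene)`. Genes retained in fewer than
#' two mutants are skipped with a warning.
#'
#' @param densities (Filtered) data frame from [gene_densities()].
#' @param condition Condition label recorded in the output.
#' @return Fold-change data frame with `gene_id`, `mutant_id`,
#'   `condition`, `replicate`, `log2fc`, `datatype` (`"rna"`).
#' @export
rna_fold_changes <- function(densities, condition = "cassette") {
  if (length(unique(densities$mutant_id)) < 3L) {
    warning("fewer than 3 mutants; the median reference is weak")
  }
  split_d <- split(densities, densities$gene_id)
  n_per_gene <- vapply(split_d, nrow, integer(1))
  skipped <- names(split_d)[n_per_gene < 2L]
  if (length(skipped) > 0L) {
    warning(length(skipped), " gene(s) retained in fewer than 2 mutants ",
            "were skipped")
    split_d <- split_d[n_per_gene >= 2L]
  }
  out <- lapply(split_d, function(d) {
    med <- stats::median(d$density)
    if (med == 0) return(NULL)
    data.frame(gene_id = d$gene_id, mutant_id = d$mutant_id,
               condition = condition, replicate = 1L,
               plex_id = "rna",
               log2fc = log2(d$density / med), datatype = "rna",
               stringsAsFactors = FALSE)
  })
  fc <- do.call(rbind, out)
  rownames(fc) <- NULL
  fc
}

#' Write a coverage track as a variableStep WIG file
#'
#' Only positions with non-zero counts are written.
#'
#' @param track A `"coverage_track"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_wig <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  nz <- which(track$cov != 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("variableStep chrom=", track$chrom), con)
  if (length(nz) > 0L) {
    writeLines(paste(nz, format(track$cov[nz], trim = TRUE,
                                scientific = FALSE)), con)
  }
  invisible(path)
}
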