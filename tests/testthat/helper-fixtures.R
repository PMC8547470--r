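# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# minimal annotation data frame
make_ann <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], chrom = "chr", start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

# intensity matrix from a plain matrix, one plex, one replicate
make_im <- function(values, plex = "p1", mutants = NULL,
                    condition = "cassette") {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(mutants)) mutants <- colnames(values)
  plex <- rep_len(plex, ncol(values))
  intensity_matrix(values, data.frame(
    sample_id = colnames(values), mutant_id = mutants, replicate = 1L,
    plex_id = plex, condition = condition, stringsAsFactors = FALSE))
}

# positioned-table row builder: vals is a named numeric vector whose names
# are signed positions, e.g. c(`-1` = 0.2, `1` = -1.5)
make_positioned <- function(mutant, vals, datatype = "protein",
                            distance = NA_integer_) {
  pos <- as.integer(names(vals))
  data.frame(gene_id = paste0(mutant, "_pos", pos), mutant_id = mutant,
             condition = "cassette", datatype = datatype, position = pos,
             log2fc = unname(vals),
             intergenic_distance = ifelse(pos == 1L, distance, NA_integer_),
             n_replicates = 1L, stringsAsFactors = FALSE)
}

# brute-force Spearman rho with average ranks (independent of the package
# implementation: explicit rank formula + explicit Pearson sum formula)
brute_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  brute_pearson(rx, ry)
}

brute_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# brute-force Mann-Whitney U by direct pair counting
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# brute-force exact two-sided rank-sum p-value by enumerating all group
# assignments of the pooled values (pair-counting U, not rank sums)
brute_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_obs <- brute_u(x, y)
  mu <- n1 * (n - n1) / 2
  idx <- utils::combn(n, n1)
  u_all <- apply(idx, 2L, function(i) brute_u(pooled[i], pooled[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-8)
}
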