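# Synthetic mutant libraries with known ground truth: a toy bacterial
# genome of operons, one deletion mutant per operon, TMT-style protein
# intensity matrices and strand-separated RNA coverage tracks carrying
# the polar-effect structure (shared transcriptional shift of all
# downstream genes, plus a distance-dependent protein-only effect on the
# gene directly downstream of the deletion).

#' Parameters of a synthetic deletion library
#'
#' Defaults describe a mid-sized screen: 60 operons of 1-6 genes,
#' deletion mutants profiled in duplicate TMT plexes of 10 channels,
#' transcriptional operon shifts up to 4-fold up (35% of deletions) or
#' 8-fold down (30%) — with uniform magnitudes, roughly a fifth of
#' evaluable operons end up beyond the 2-fold threshold in each
#' direction — and a protein-only deficit of the +1 gene that decays
#' exponentially with intergenic distance (maximal 2-fold at distance 0,
#' length scale 30 nt; within-operon distances mostly short, frequently
#' overlapping ORFs).
#'
#' @param n_operons Number of operons.
#' @param operon_size_range Integer range of genes per operon.
#' @param gene_length_range Gene length range (nt).
#' @param intergenic_distance_range Within-operon stop-to-start distance
#'   range (nt); negative values give overlapping ORFs.
#' @param operon_gap Fixed gap between adjacent operons (nt).
#' @param p_operon_up,p_operon_down Probability that a deletion shifts
#'   the whole downstream operon up / down (`p_up + p_down <= 1`).
#' @param up_log2_range,down_log2_range Ranges the up / down shift
#'   magnitudes (log2) are drawn from.
#' @param p1_effect_max_log2 Extra protein-only log2 shift of the +1 gene
#'   at intergenic distance 0 (<= 0; 0 disables the effect).
#' @param p1_effect_lengthscale Exponential decay length of the +1 effect
#'   (nt); overlapping genes (negative distance) receive the maximal
#'   effect.
#' @param knockout_residual_log2 Log2 level of the deleted gene itself
#'   relative to baseline (a strong depletion; position 0 is excluded
#'   from all downstream statistics).
#' @param replicate_count Protein replicates per mutant.
#' @param plex_size Channels per TMT plex (>= 3).
#' @param noise_sd_log2 SD of per-(protein, channel) log2 measurement
#'   noise.
#' @param channel_scale_sd_log2 SD of the per-channel global log2 scale
#'   factor (loading differences removed by normalization).
#' @param baseline_abundance_log2_mean,baseline_abundance_log2_sd
#'   Log2-normal protein baseline intensity distribution.
#' @param rna_depth Mean RNA coverage (counts per nt) of a baseline gene.
#' @param rna_baseline_log2_sd SD of per-gene log2 expression baselines.
#' @param deletion_position `"random"`: delete a uniformly chosen
#'   non-terminal gene of each multi-gene operon; `"first"`: always the
#'   promoter-proximal gene (maximizes downstream genes).
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical libraries.
#' @return A validated list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_operons = 60L,
                              operon_size_range = c(1L, 6L),
                              gene_length_range = c(300L, 1500L),
                              intergenic_distance_range = c(-20L, 60L),
                              operon_gap = 200L,
                              p_operon_up = 0.35,
                              p_operon_down = 0.3,
                              up_log2_range = c(0, 2),
                              down_log2_range = c(-3, 0),
                              p1_effect_max_log2 = -1,
                              p1_effect_lengthscale = 30,
                              knockout_residual_log2 = -5,
                              replicate_count = 2L,
                              plex_size = 10L,
                              noise_sd_log2 = 0.2,
                              channel_scale_sd_log2 = 0.25,
                              baseline_abundance_log2_mean = 20,
                              baseline_abundance_log2_sd = 1.5,
                              rna_depth = 10,
                              rna_baseline_log2_sd = 1,
                              deletion_position = c("random", "first"),
                              seed = 1L) {
  p <- list(n_operons = as.integer(n_operons),
            operon_size_range = as.integer(operon_size_range),
            gene_length_range = as.integer(gene_length_range),
            intergenic_distance_range = as.integer(intergenic_distance_range),
            operon_gap = as.integer(operon_gap),
            p_operon_up = p_operon_up, p_operon_down = p_operon_down,
            up_log2_range = up_log2_range, down_log2_range = down_log2_range,
            p1_effect_max_log2 = p1_effect_max_log2,
            p1_effect_lengthscale = p1_effect_lengthscale,
            knockout_residual_log2 = knockout_residual_log2,
            replicate_count = as.integer(replicate_count),
            plex_size = as.integer(plex_size),
            noise_sd_log2 = noise_sd_log2,
            channel_scale_sd_log2 = channel_scale_sd_log2,
            baseline_abundance_log2_mean = baseline_abundance_log2_mean,
            baseline_abundance_log2_sd = baseline_abundance_log2_sd,
            rna_depth = rna_depth,
            rna_baseline_log2_sd = rna_baseline_log2_sd,
            deletion_position = match.arg(deletion_position),
            seed = as.integer(seed))
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  stopifnot(p$n_operons >= 1L,
            p$operon_size_range[1L] >= 1L,
            diff(p$operon_size_range) >= 0,
            p$gene_length_range[1L] >= 30L,
            diff(p$gene_length_range) >= 0,
            diff(p$intergenic_distance_range) >= 0,
            p$p_operon_up >= 0, p$p_operon_down >= 0,
            p$p_operon_up + p$p_operon_down <= 1,
            all(p$up_log2_range >= 0), diff(p$up_log2_range) >= 0,
            all(p$down_log2_range <= 0), diff(p$down_log2_range) >= 0,
            p$p1_effect_max_log2 <= 0,
            p$p1_effect_lengthscale > 0,
            p$replicate_count >= 1L,
            p$noise_sd_log2 >= 0, p$channel_scale_sd_log2 >= 0,
            p$rna_depth >= 0, p$rna_baseline_log2_sd >= 0)
  if (p$plex_size < 3L) {
    stop("plex_size must be >= 3 (the median reference needs >= 3 mutants)")
  }
  invisible(p)
}

#' Simulate a genome of operons
#'
#' Lays non-overlapping operons head-to-tail on one chromosome,
#' alternating draws of strand; within an operon, gene lengths and
#' intergenic distances are drawn from the configured ranges (negative
#' distances give overlapping ORFs). Operon gene lists are returned in
#' transcription order.
#'
#' @param params A [simulation_params()] object.
#' @return List with `annotations` (data frame) and `operons`
#'   (`"operon_set"`).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  build_genome(params)
}

build_genome <- function(params) {
  sz <- params$operon_size_range
  sizes <- sample(seq(sz[1L], sz[2L]), params$n_operons, replace = TRUE)
  strands <- sample(c("+", "-"), params$n_operons, replace = TRUE)
  gl <- params$gene_length_range
  dr <- params$intergenic_distance_range
  cursor <- 1L
  ann <- vector("list", params$n_operons)
  ops <- vector("list", params$n_operons)
  for (k in seq_len(params$n_operons)) {
    size <- sizes[k]
    lens <- sample(seq(gl[1L], gl[2L]), size, replace = TRUE)
    gaps <- if (size > 1L) {
      g <- sample(seq(dr[1L], dr[2L]), size - 1L, replace = TRUE)
      # keep start coordinates strictly increasing despite overlaps
      pmax(g, -(pmin(lens[-size], lens[-1L]) - 3L))
    } else integer(0)
    ids <- sprintf("op%03d_g%d", k, seq_len(size))
    # coordinate order: transcription order on +, reversed on -
    co_lens <- if (strands[k] == "+") lens else rev(lens)
    co_gaps <- if (strands[k] == "+") gaps else rev(gaps)
    co_ids <- if (strands[k] == "+") ids else rev(ids)
    starts <- integer(size)
    starts[1L] <- cursor
    for (j in seq_len(size - 1L)) {
      starts[j + 1L] <- starts[j] + co_lens[j] + co_gaps[j]
    }
    ends <- starts + co_lens - 1L
    ann[[k]] <- data.frame(gene_id = co_ids, chrom = "chr",
                           start = starts, end = ends,
                           strand = strands[k], stringsAsFactors = FALSE)
    ops[[k]] <- ids
    cursor <- max(ends) + params$operon_gap + 1L
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  names(ops) <- sprintf("op%03d", seq_len(params$n_operons))
  list(annotations = validate_annotations(annotations),
       operons = as_operon_set(ops))
}

#' Simulate a deletion-mutant library
#'
#' Builds the genome, creates one deletion mutant per operon (a
#' non-terminal gene of every multi-gene operon, plus the lone gene of
#' every single-gene operon as negative controls), draws the effect
#' structure and emits protein intensity matrices and per-mutant
#' strand-separated RNA coverage tracks:
#'
#' * a transcriptional operon effect (up/down/none mixture) shifts all
#'   downstream genes at RNA and protein level alike;
#' * the +1 gene additionally receives a protein-only shift
#'   `p1_effect_max_log2 * exp(-max(d, 0) / p1_effect_lengthscale)` with
#'   `d` the intergenic distance, so closer genes are hit harder;
#' * upstream genes are untouched; the deleted gene itself drops to the
#'   knockout residual (RNA and protein).
#'
#' Under `condition = "excised"` the upward component is zeroed
#' (cassette promoter removed) while downward effects and the +1 effect
#' persist.
#'
#' @param params A [simulation_params()].
#' @param condition `"cassette"` (default) or `"excised"`.
#' @param datatypes Which measurements to generate, subset of
#'   `c("protein", "rna")`.
#' @return List of class `"synthetic_library"` with `params`,
#'   `annotations`, `operons`, `deletions` (named vector mutant ->
#'   gene), `intensities` (an [intensity_matrix()] or `NULL`),
#'   `rna_tracks` (per-mutant `list(fwd, rev)` coverage tracks or
#'   `NULL`), `truth` (ground-truth tables) and `condition`.
#' @export
simulate_library <- function(params, condition = c("cassette", "excised"),
                             datatypes = c("protein", "rna")) {
  stopifnot(inherits(params, "simulation_params"))
  condition <- match.arg(condition)
  datatypes <- match.arg(datatypes, several.ok = TRUE)
  set.seed(params$seed)
  genome <- build_genome(params)
  ann <- genome$annotations
  operons <- genome$operons
  genes <- ann$gene_id
  n_genes <- length(genes)

  # one mutant per operon
  del_idx <- vapply(operons, function(g) {
    if (length(g) == 1L) 1L
    else if (params$deletion_position == "first") 1L
    else sample.int(length(g) - 1L, 1L)
  }, integer(1))
  deleted_gene <- mapply(function(g, i) g[i], operons, del_idx)
  mutants <- paste0("d_", deleted_gene)
  deletions <- stats::setNames(deleted_gene, mutants)
  n_mut <- length(mutants)
  if (n_mut < 3L) stop("need at least 3 mutants for a median reference")

  # operon-level transcriptional effects
  u <- stats::runif(n_mut)
  cls <- ifelse(u < params$p_operon_up, "up",
                ifelse(u < params$p_operon_up + params$p_operon_down,
                       "down", "none"))
  eff <- numeric(n_mut)
  eff[cls == "up"] <- stats::runif(sum(cls == "up"),
                                   params$up_log2_range[1L],
                                   params$up_log2_range[2L])
  eff[cls == "down"] <- stats::runif(sum(cls == "down"),
                                     params$down_log2_range[1L],
                                     params$down_log2_range[2L])
  if (condition == "excised") eff[cls == "up"] <- 0

  # per-gene log2 effect matrices
  e_protein <- matrix(0, n_genes, n_mut, dimnames = list(genes, mutants))
  e_rna <- e_protein
  p1_gene <- rep(NA_character_, n_mut)
  p1_distance <- rep(NA_integer_, n_mut)
  p1_extra <- rep(NA_real_, n_mut)
  op_size <- lengths(operons)
  for (m in seq_len(n_mut)) {
    op <- operons[[m]]
    i <- del_idx[m]
    gi <- match(op[i], genes)
    e_protein[gi, m] <- e_rna[gi, m] <- params$knockout_residual_log2
    if (i < length(op)) {
      down <- match(op[(i + 1L):length(op)], genes)
      e_protein[down, m] <- e_rna[down, m] <- eff[m]
      p1_gene[m] <- op[i + 1L]
      d <- gene_pair_distance(ann, op[i], op[i + 1L])
      p1_distance[m] <- d
      p1_extra[m] <- params$p1_effect_max_log2 *
        exp(-max(d, 0L) / params$p1_effect_lengthscale)
      e_protein[down[1L], m] <- e_protein[down[1L], m] + p1_extra[m]
    }
  }

  baseline_protein <- stats::rnorm(n_genes,
                                   params$baseline_abundance_log2_mean,
                                   params$baseline_abundance_log2_sd)
  baseline_rna <- stats::rnorm(n_genes, 0, params$rna_baseline_log2_sd)

  intensities <- NULL
  if ("protein" %in% datatypes) {
    intensities <- simulate_intensities(params, genes, mutants, condition,
                                        e_protein, baseline_protein)
  }
  rna_tracks <- NULL
  if ("rna" %in% datatypes) {
    rna_tracks <- simulate_rna_tracks(params, ann, mutants, e_rna,
                                      baseline_rna)
  }

  truth <- list(
    mutants = data.frame(
      mutant_id = mutants, operon_id = names(operons),
      deleted_gene = unname(deleted_gene), deleted_index = unname(del_idx),
      operon_size = unname(op_size),
      n_downstream = unname(op_size - del_idx),
      effect_class = cls, operon_effect_log2 = eff,
      p1_gene = p1_gene, p1_distance = p1_distance,
      p1_extra_log2 = p1_extra, stringsAsFactors = FALSE),
    baselines = data.frame(gene_id = genes,
                           protein_log2 = baseline_protein,
                           rna_log2 = baseline_rna,
                           stringsAsFactors = FALSE))

  structure(list(params = params, annotations = ann, operons = operons,
                 deletions = deletions, intensities = intensities,
                 rna_tracks = rna_tracks, truth = truth,
                 condition = condition),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat("synthetic_library:", length(x$deletions), "mutants,",
      nrow(x$annotations), "genes in", length(x$operons), "operons",
      paste0("(condition: ", x$condition, ")\n"))
  invisible(x)
}

simulate_intensities <- function(params, genes, mutants, condition,
                                 e_protein, baseline) {
  n_genes <- length(genes)
  n_mut <- length(mutants)
  n_plex <- ceiling(n_mut / params$plex_size)
  plex_of <- ((seq_len(n_mut) - 1L) %% n_plex) + 1L  # round-robin
  if (min(table(plex_of)) < 3L) {
    stop("plex packing leaves a plex with fewer than 3 mutants; ",
         "reduce plex count or add mutants")
  }
  cols <- list()
  samples <- list()
  for (r in seq_len(params$replicate_count)) {
    noise <- matrix(stats::rnorm(n_genes * n_mut, 0, params$noise_sd_log2),
                    n_genes, n_mut)
    chan <- stats::rnorm(n_mut, 0, params$channel_scale_sd_log2)
    vals <- 2^(baseline + e_protein + noise +
                 matrix(chan, n_genes, n_mut, byrow = TRUE))
    colnames(vals) <- sprintf("%s_r%d", mutants, r)
    cols[[r]] <- vals
    samples[[r]] <- data.frame(
      sample_id = colnames(vals), mutant_id = mutants, replicate = r,
      plex_id = sprintf("r%d_p%02d", r, plex_of), condition = condition,
      stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, cols)
  rownames(values) <- genes
  intensity_matrix(values, do.call(rbind, samples))
}

simulate_rna_tracks <- function(params, ann, mutants, e_rna, baseline_rna) {
  genome_len <- max(ann$end)
  is_fwd <- ann$strand == "+"
  tracks <- vector("list", length(mutants))
  names(tracks) <- mutants
  for (m in seq_along(mutants)) {
    mu_fwd <- numeric(genome_len)
    mu_rev <- numeric(genome_len)
    mu_gene <- params$rna_depth * 2^(baseline_rna + e_rna[, m])
    for (i in seq_len(nrow(ann))) {
      idx <- ann$start[i]:ann$end[i]
      if (is_fwd[i]) mu_fwd[idx] <- mu_fwd[idx] + mu_gene[i]
      else mu_rev[idx] <- mu_rev[idx] + mu_gene[i]
    }
    tracks[[m]] <- list(
      fwd = coverage_track("chr", stats::rpois(genome_len, mu_fwd)),
      rev = coverage_track("chr", stats::rpois(genome_len, mu_rev)))
  }
  tracks
}

#' Write a synthetic library to disk in the pipeline's input formats
#'
#' Emits annotation and operon TSVs, the intensity matrix TSV with its
#' sample sheet, per-mutant forward/reverse WIG files with an RNA sample
#' sheet, and the ground truth as JSON.
#'
#' @param lib A `"synthetic_library"`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "synthetic_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotations = file.path(dir, "annotations.tsv"),
             operons = file.path(dir, "operons.tsv"),
             deletions = file.path(dir, "deletions.tsv"),
             truth = file.path(dir, "truth.json"))
  write_annotations(lib$annotations, paths[["annotations"]])
  write_operons(lib$operons, paths[["operons"]])
  utils::write.table(
    data.frame(mutant_id = names(lib$deletions),
               gene_id = unname(lib$deletions)),
    paths[["deletions"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lib$truth, paths[["truth"]], digits = NA,
                       dataframe = "columns")
  if (!is.null(lib$intensities)) {
    paths[["intensities"]] <- file.path(dir, "intensities.tsv")
    paths[["samples"]] <- file.path(dir, "samples.tsv")
    tab <- data.frame(gene_id = rownames(lib$intensities$values),
                      lib$intensities$values, check.names = FALSE)
    utils::write.table(tab, paths[["intensities"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lib$intensities$samples, paths[["samples"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(lib$rna_tracks)) {
    wig_dir <- file.path(dir, "wig")
    dir.create(wig_dir, showWarnings = FALSE)
    sheet <- data.frame(mutant_id = names(lib$rna_tracks),
                        fwd_path = file.path("wig", paste0(names(lib$rna_tracks), "_fwd.wig")),
                        rev_path = file.path("wig", paste0(names(lib$rna_tracks), "_rev.wig")),
                        stringsAsFactors = FALSE)
    for (m in names(lib$rna_tracks)) {
      write_wig(lib$rna_tracks[[m]]$fwd,
                file.path(dir, sheet$fwd_path[sheet$mutant_id == m]))
      write_wig(lib$rna_tracks[[m]]$rev,
                file.path(dir, sheet$rev_path[sheet$mutant_id == m]))
    }
    paths[["rna_samples"]] <- file.path(dir, "rna_samples.tsv")
    utils::write.table(sheet, paths[["rna_samples"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Compare pipeline estimates against simulation ground truth
#'
#' @param lib A `"synthetic_library"`.
#' @param effects Result of [classify_operon_effects()] on the library's
#'   protein pipeline output.
#' @param corrected Median-corrected positioned table
#'   ([operon_median_correction()]).
#' @return Data frame (`parameter`, `true`, `estimated`, `error`):
#'   up/down operon fractions among evaluable mutants, the median +1
#'   protein-only log2 effect, and the sign of the distance trend.
#' @export
recovery_report <- function(lib, effects, corrected) {
  stopifnot(inherits(lib, "synthetic_library"))
  tm <- lib$truth$mutants
  # truth restricted to mutants evaluable by the pipeline's rule
  ev_est <- effects[effects$class != "not_evaluable", , drop = FALSE]
  ev_true <- tm[tm$mutant_id %in% ev_est$mutant_id, , drop = FALSE]
  thr <- 1
  true_up <- mean(ev_true$operon_effect_log2 > thr)
  true_down <- mean(ev_true$operon_effect_log2 < -thr)
  est_up <- mean(ev_est$class == "up")
  est_down <- mean(ev_est$class == "down")

  p1 <- corrected[corrected$position == 1L &
                    corrected$datatype == "protein" &
                    !is.na(corrected$corrected_log2fc), , drop = FALSE]
  est_p1 <- stats::median(p1$corrected_log2fc)
  true_p1 <- stats::median(tm$p1_extra_log2[tm$mutant_id %in% p1$mutant_id])

  est_rho_sign <- tryCatch(
    sign(suppressWarnings(distance_correlation(corrected))$estimate),
    error = function(e) NA_real_)
  true_rho_sign <- if (lib$params$p1_effect_max_log2 < 0) 1 else 0

  out <- data.frame(
    parameter = c("fraction_operons_up", "fraction_operons_down",
                  "median_p1_extra_log2", "distance_trend_sign"),
    true = c(true_up, true_down, true_p1, true_rho_sign),
    estimated = c(est_up, est_down, est_p1, est_rho_sign),
    stringsAsFactors = FALSE)
  out$error <- out$estimated - out$true
  out
}
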