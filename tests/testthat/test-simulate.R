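null_params <- function(...) {
  simulation_params(n_operons = 8L, operon_size_range = c(2L, 4L),
                    p_operon_up = 0, p_operon_down = 0,
                    p1_effect_max_log2 = 0, noise_sd_log2 = 0,
                    channel_scale_sd_log2 = 0, replicate_count = 1L,
                    plex_size = 8L, seed = 71L, ...)
}

test_that("simulated genomes respect the configured geometry", {
  p <- simulation_params(n_operons = 12L, seed = 72L)
  g <- simulate_genome(p)
  expect_equal(length(g$operons), 12L)
  expect_true(all(lengths(g$operons) >= p$operon_size_range[1]))
  expect_true(all(lengths(g$operons) <= p$operon_size_range[2]))
  lens <- g$annotations$end - g$annotations$start + 1L
  expect_true(all(lens >= p$gene_length_range[1]))
  expect_true(all(lens <= p$gene_length_range[2]))
  expect_setequal(unique(g$annotations$strand), c("+", "-"))

  # operon order is transcription order: consecutive distances are in range
  for (op in names(g$operons)) {
    genes <- g$operons[[op]]
    for (j in seq_len(length(genes) - 1L)) {
      a <- g$annotations[g$annotations$gene_id == genes[j], ]
      b <- g$annotations[g$annotations$gene_id == genes[j + 1L], ]
      d <- intergenic_distance(a, b)
      expect_gte(d, p$intergenic_distance_range[1] - 0L)
      expect_lte(d, p$intergenic_distance_range[2])
    }
  }
})

test_that("identical parameters and seed reproduce the library exactly", {
  p <- simulation_params(n_operons = 6L, seed = 73L, rna_depth = 3)
  a <- simulate_library(p)
  b <- simulate_library(p)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$intensities$values, b$intensities$values)
  expect_identical(a$rna_tracks, b$rna_tracks)
  expect_identical(a$truth, b$truth)

  # byte-identical on disk too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_library(a, d1); write_library(b, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("a null library yields exactly zero fold changes for operon mates", {
  lib <- simulate_library(null_params(), datatypes = "protein")
  # channel scales are 0 in this library, so raw channels are comparable
  fc <- average_replicates(fold_changes_vs_median(lib$intensities))
  pos <- position_fold_changes(fc, lib$operons, lib$deletions,
                               lib$annotations)
  expect_gt(nrow(pos), 0)
  expect_true(all(abs(pos$log2fc) < 1e-12))
  eff <- classify_operon_effects(pos)
  expect_true(all(eff$class %in% c("none", "not_evaluable")))

  rep0 <- recovery_report(lib, eff, operon_median_correction(pos))
  est <- stats::setNames(rep0$estimated, rep0$parameter)
  expect_equal(unname(est["fraction_operons_up"]), 0)
  expect_equal(unname(est["fraction_operons_down"]), 0)
})

test_that("a forced-down library classifies every evaluable mutant down", {
  p <- simulation_params(n_operons = 10L, operon_size_range = c(3L, 5L),
                         p_operon_up = 0, p_operon_down = 1,
                         down_log2_range = c(-2, -2),
                         p1_effect_max_log2 = 0, noise_sd_log2 = 0,
                         channel_scale_sd_log2 = 0, replicate_count = 1L,
                         deletion_position = "first", seed = 74L)
  lib <- simulate_library(p, datatypes = "protein")
  fc <- average_replicates(fold_changes_vs_median(lib$intensities))
  pos <- position_fold_changes(fc, lib$operons, lib$deletions,
                               lib$annotations)
  eff <- classify_operon_effects(pos)
  ev <- eff[eff$class != "not_evaluable", ]
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$class == "down"))
  # the median shift is recovered: every downstream gene carries -2, and
  # the plex median sits at the unaffected baseline
  expect_true(all(abs(ev$median_downstream_excl_p1 - (-2)) < 1e-10))

  rep1 <- recovery_report(lib, eff, operon_median_correction(pos))
  expect_equal(rep1$estimated[rep1$parameter == "fraction_operons_down"], 1)
})

test_that("the +1 effect is protein-only: RNA equals protein minus the extra", {
  p <- simulation_params(n_operons = 10L, operon_size_range = c(3L, 5L),
                         p_operon_up = 0.3, p_operon_down = 0.3,
                         p1_effect_max_log2 = -1.5,
                         p1_effect_lengthscale = 50,
                         intergenic_distance_range = c(0L, 80L),
                         noise_sd_log2 = 0, channel_scale_sd_log2 = 0,
                         replicate_count = 1L, rna_depth = 300,
                         rna_baseline_log2_sd = 0.3,
                         deletion_position = "first", seed = 75L)
  lib <- simulate_library(p)
  pfc <- average_replicates(fold_changes_vs_median(lib$intensities))
  ppos <- position_fold_changes(pfc, lib$operons, lib$deletions,
                                lib$annotations)
  rfc <- average_replicates(rna_fold_changes(filter_low_density(
    gene_densities(lib$rna_tracks, lib$annotations))))
  rpos <- position_fold_changes(rfc, lib$operons, lib$deletions,
                                lib$annotations)
  j <- merge(ppos[ppos$position == 1L, c("mutant_id", "log2fc")],
             rpos[rpos$position == 1L, c("mutant_id", "log2fc")],
             by = "mutant_id", suffixes = c("_prot", "_rna"))
  tm <- lib$truth$mutants
  extra <- tm$p1_extra_log2[match(j$mutant_id, tm$mutant_id)]
  # protein fold change = RNA fold change + protein-only +1 term,
  # up to Poisson counting noise in the RNA densities
  expect_gt(nrow(j), 5)
  expect_true(all(abs(j$log2fc_prot - (j$log2fc_rna + extra)) < 0.15))
})

test_that("parameter validation catches impossible settings", {
  expect_error(simulation_params(plex_size = 2L), "plex_size")
  expect_error(simulation_params(p_operon_up = 0.7, p_operon_down = 0.6))
  expect_error(simulation_params(up_log2_range = c(-1, 1)))
  expect_error(simulation_params(p1_effect_max_log2 = 0.5))
  expect_error(simulation_params(gene_length_range = c(10, 20)))
})

test_that("written libraries are readable by the file-based entry points", {
  p <- simulation_params(n_operons = 5L, operon_size_range = c(2L, 3L),
                         rna_depth = 5, seed = 76L)
  lib <- simulate_library(p)
  dir <- withr::local_tempdir()
  paths <- write_library(lib, dir)

  ann <- read_annotations(paths[["annotations"]])
  expect_equal(ann, lib$annotations)
  ops <- read_operons(paths[["operons"]])
  expect_equal(unclass(ops), unclass(lib$operons))
  im <- read_intensities(paths[["intensities"]], paths[["samples"]])
  expect_equal(im$values, lib$intensities$values, tolerance = 1e-7)
  expect_equal(im$samples$plex_id, lib$intensities$samples$plex_id)

  sheet <- utils::read.delim(paths[["rna_samples"]])
  tr <- read_wig(file.path(dir, sheet$fwd_path[1]))
  m1 <- sheet$mutant_id[1]
  orig <- lib$rna_tracks[[m1]]$fwd
  expect_equal(tr$cov, orig$cov[seq_along(tr$cov)])
})
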