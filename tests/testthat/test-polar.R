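# shared toy setting: one 3-gene and one 6-gene operon plus a lone gene
toy_setup <- function() {
  ann <- make_ann(list("A", 100, 400, "+"), list("B", 451, 900, "+"),
                  list("C", 951, 1400, "+"),
                  list("P", 2000, 2400, "+"), list("Q", 2431, 2800, "+"),
                  list("R", 2821, 3200, "+"), list("S", 3221, 3600, "+"),
                  list("T", 3651, 4000, "+"), list("U", 4021, 4400, "+"),
                  list("X", 5000, 5400, "+"))
  ops <- as_operon_set(list(op1 = c("A", "B", "C"),
                            op2 = c("P", "Q", "R", "S", "T", "U"),
                            op3 = "X"))
  list(ann = ann, ops = ops)
}

toy_fc <- function(genes, mutant, lfc) {
  data.frame(gene_id = genes, mutant_id = mutant, condition = "cassette",
             datatype = "protein", log2fc = lfc, n_replicates = 1L,
             stringsAsFactors = FALSE)
}

test_that("fold changes receive operon-relative positions and +1 distances", {
  s <- toy_setup()
  fc <- toy_fc(c("A", "C"), "dB", c(0.1, -0.8))
  pos <- position_fold_changes(fc, s$ops, c(dB = "B"), s$ann)
  expect_equal(pos$position[pos$gene_id == "A"], -1L)
  expect_equal(pos$position[pos$gene_id == "C"], 1L)
  expect_equal(pos$intergenic_distance[pos$gene_id == "C"],
               intergenic_distance(s$ann[2, ], s$ann[3, ]))
  expect_true(all(is.na(pos$intergenic_distance[pos$position != 1L])))
})

test_that("the deleted gene itself is excluded from the positioned table", {
  s <- toy_setup()
  fc <- toy_fc(c("P", "Q", "R", "S", "T", "U"), "dR", rnorm(6))
  pos <- position_fold_changes(fc, s$ops, c(dR = "R"), s$ann)
  expect_equal(sort(pos$position), c(-2L, -1L, 1L, 2L, 3L))
  expect_false("R" %in% pos$gene_id)
  expect_false(0L %in% pos$position)
})

test_that("mutants outside multi-gene operons are routed aside", {
  s <- toy_setup()
  fc <- rbind(toy_fc("X", "dX", 0.3),     # single-gene operon
              toy_fc("A", "dZ", -0.2),    # deletion not in any operon
              toy_fc(c("A", "C"), "dB", c(0, -1)))
  pos <- position_fold_changes(fc, s$ops, c(dX = "X", dZ = "Z", dB = "B"),
                               s$ann)
  expect_equal(unique(pos$mutant_id), "dB")
  nio <- not_in_operon(pos)
  expect_setequal(unique(nio$mutant_id), c("dX", "dZ"))

  expect_error(position_fold_changes(toy_fc("A", "dB", 0), s$ops,
                                     c(other = "B"), s$ann),
               "dB")
})

test_that("per-side median correction zeroes the side medians", {
  tab <- make_positioned("m1", c(`1` = -1.5, `2` = -0.4, `3` = -0.6))
  cor <- operon_median_correction(tab)
  expect_equal(cor$corrected_log2fc[order(cor$position)],
               c(-0.9, 0.2, 0.0))

  # a single gene on a side is not eligible at min_genes = 2
  tab1 <- make_positioned("m1", c(`-1` = 0.3, `1` = -1.2))
  cor1 <- operon_median_correction(tab1)
  expect_true(all(is.na(cor1$corrected_log2fc)))
  cor1b <- operon_median_correction(tab1, min_genes = 1L)
  expect_equal(cor1b$corrected_log2fc, c(0, 0))

  # downstream median may exclude the +1 gene but is subtracted everywhere
  cor2 <- operon_median_correction(tab, include_p1 = FALSE)
  expect_equal(cor2$corrected_log2fc[order(cor2$position)],
               c(-1.5, -0.4, -0.6) - (-0.5))
})

test_that("emitted corrected values have median 0 per (mutant, side)", {
  set.seed(61)
  tabs <- lapply(1:20, function(i) {
    n_up <- sample(0:4, 1); n_down <- sample(0:5, 1)
    pos <- c(rev(-seq_len(n_up)), seq_len(n_down))
    if (length(pos) == 0) return(NULL)
    make_positioned(paste0("m", i), stats::setNames(rnorm(length(pos)), pos))
  })
  tab <- do.call(rbind, tabs)
  cor <- operon_median_correction(tab)
  key <- interaction(cor$mutant_id, sign(cor$position))
  for (k in levels(key)) {
    v <- cor$corrected_log2fc[key == k]
    v <- v[!is.na(v)]
    if (length(v) > 0) expect_equal(stats::median(v), 0)
  }
})

test_that("operon classification uses the downstream median excluding +1", {
  up <- make_positioned("m1", c(`1` = 0, `2` = 1.4, `3` = 1.2))
  none <- make_positioned("m2", c(`1` = -3, `2` = -0.5))
  down <- make_positioned("m3", c(`1` = 0.2, `2` = -1.3, `3` = -1.9))
  ne <- make_positioned("m4", c(`-1` = 0.1, `1` = -2))
  eff <- classify_operon_effects(rbind(up, none, down, ne))
  got <- stats::setNames(eff$class, eff$mutant_id)
  expect_equal(got[c("m1", "m2", "m3", "m4")],
               c(m1 = "up", m2 = "none", m3 = "down", m4 = "not_evaluable"),
               ignore_attr = FALSE)
  expect_equal(eff$median_downstream_excl_p1[eff$mutant_id == "m1"], 1.3)
  expect_equal(eff$n_downstream_excl_p1[eff$mutant_id == "m4"], 0L)

  # the +1 value cannot influence the classification
  up2 <- up; up2$log2fc[up2$position == 1L] <- -50
  expect_equal(classify_operon_effects(rbind(up2, none, down, ne))$class,
               eff$class)

  # strict threshold: a median exactly at the cutoff is "none"
  border <- make_positioned("m5", c(`2` = 1, `3` = 1))
  expect_equal(classify_operon_effects(border)$class, "none")

  # exclusion list removes mutants before classification
  eff2 <- classify_operon_effects(rbind(up, none), exclude = "m1")
  expect_false("m1" %in% eff2$mutant_id)

  fr <- operon_effect_fractions(eff)
  expect_equal(fr$n_evaluable, 3L)
  expect_equal(fr$n_up, 1L)
  expect_equal(fr$n_down, 1L)
  expect_equal(fr$frac_up, 1 / 3)
})

test_that("the +1 test compares +1 genes against pooled other downstream", {
  tab <- rbind(
    make_positioned("m1", c(`1` = -1.4, `2` = 0.1, `3` = -0.2)),
    make_positioned("m2", c(`1` = -0.9, `2` = 0.3)),
    make_positioned("m3", c(`1` = -1.1, `2` = -0.1, `3` = 0.2)))
  res <- downstream_gene_test(tab)
  expect_equal(res$n1, 3L)
  expect_equal(res$n2, 5L)
  # fully separated groups: exact two-sided p = 2 * 1/C(8,3)
  expect_equal(res$p_value, 2 / choose(8, 3))
  expect_equal(res$median_p1_log2, -1.1)
  expect_equal(res$median_p1_linear, 2^-1.1)

  # +1 values identical to the rest: p = 1
  flat <- rbind(make_positioned("m1", c(`1` = 0.5, `2` = 0.5)),
                make_positioned("m2", c(`1` = 0.5, `2` = 0.5)))
  expect_equal(downstream_gene_test(flat)$p_value, 1)

  # one-sample signed-rank variant runs against zero
  z <- downstream_gene_test(tab, comparison = "zero")
  expect_true(z$p_value >= 0 && z$p_value <= 1)
  expect_match(z$method, "signed rank")

  expect_error(downstream_gene_test(tab[tab$position != 1L, ]),
               "position \\+1")
  expect_error(downstream_gene_test(tab[tab$position == 1L, ]),
               ">= \\+2")
})

test_that("distance correlation relates corrected +1 values to distance", {
  mk <- function(i, d, v) {
    make_positioned(paste0("m", i), c(`1` = v, `2` = 0.01 * i, `3` = 0),
                    distance = d)
  }
  # corrected +1 value increases with distance -> rho 1
  tab <- do.call(rbind, lapply(1:6, function(i) {
    mk(i, d = 20 * i, v = -2 + 0.25 * i)
  }))
  cor_tab <- operon_median_correction(tab)
  res <- distance_correlation(cor_tab)
  expect_equal(res$estimate, 1)
  expect_equal(res$n1, 6L)

  tab2 <- do.call(rbind, lapply(1:6, function(i) {
    mk(i, d = 20 * i, v = 0.25 * (7 - i))
  }))
  expect_equal(distance_correlation(operon_median_correction(tab2))$estimate,
               -1)

  expect_error(distance_correlation(operon_median_correction(mk(1, 5, 0))),
               "at least 4")
})

test_that("concordance joins tables on (gene, mutant) pairs", {
  fc <- data.frame(gene_id = rep(paste0("g", 1:5), 2),
                   mutant_id = rep(c("m1", "m2"), each = 5),
                   log2fc = rnorm(10))
  expect_equal(concordance(fc, fc)$estimate, 1)
  neg <- fc; neg$log2fc <- -fc$log2fc
  expect_equal(concordance(fc, neg)$estimate, -1)
  expect_error(concordance(fc[1:2, ], fc), "fewer than 3")

  # recovers a known latent correlation at large n
  set.seed(62)
  n <- 10000
  a <- rnorm(n)
  b <- 0.7 * a + sqrt(1 - 0.49) * rnorm(n)
  big <- data.frame(gene_id = paste0("g", 1:n), mutant_id = "m1", log2fc = a)
  big2 <- big; big2$log2fc <- b
  expect_lt(abs(concordance(big, big2)$estimate - 0.7), 0.02)
})
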