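test_that("Welch statistics match the hand formula", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welch_test(a, b)
  # independent evaluation of the Welch formulas
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # unequal variances engage the Satterthwaite correction
  set.seed(1)
  x <- rnorm(5); y <- rnorm(8, sd = 4)
  r2 <- welch_test(x, y)
  se2 <- var(x) / 5 + var(y) / 8
  expect_equal(r2$df, se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 8)^2 / 7),
               tolerance = 1e-12)
})

test_that("Welch test symmetry and degenerate branches", {
  a <- c(1, 2, 3); b <- c(5, 7, 6)
  r1 <- welch_test(a, b); r2 <- welch_test(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- welch_test(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
  expect_warning(r0 <- welch_test(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(r0$p, 0)
  expect_error(welch_test(1, c(1, 2)), class = "evmorph_too_few_samples")
})

test_that("null Welch p-values are uniform", {
  set.seed(202)
  p <- vapply(1:10000, function(i) {
    welch_test(rnorm(6), rnorm(6))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the differential panel recovers planted analytes with controlled errors", {
  om <- gen_omics_tables(omics_config(seed = 6))
  truth <- om$ground_truth$secretion
  de <- differential_panel(om$secretion, om$secretion_groups,
                           "NEG_CTL", "POS_CTL")
  shifted <- truth$stim_log2fc != 0
  expect_gte(sum(de$significant & shifted), 38)
  # false positives among the remaining analytes stay near alpha
  n_null <- sum(!shifted)
  expect_lte(sum(de$significant & !shifted), 0.05 * n_null + 3 * sqrt(0.05 * n_null))
  # direction follows the planted sign
  up <- truth$stim_log2fc > 0
  expect_true(all(de$direction[de$significant & up] == "increased"))
  # alpha = 0 shuts everything off
  de0 <- differential_panel(om$secretion, om$secretion_groups,
                            "NEG_CTL", "POS_CTL", alpha = 0)
  expect_equal(sum(de0$significant), 0)
})

test_that("differential direction labels are antisymmetric in the group order", {
  om <- gen_omics_tables(omics_config(seed = 12, n_proteins = 50, dap_up = 2,
                                      dap_down = 2, stim_protein_n = 5))
  d1 <- differential_panel(om$secretion, om$secretion_groups, "NEG_CTL", "POS_CTL")
  d2 <- differential_panel(om$secretion, om$secretion_groups, "POS_CTL", "NEG_CTL")
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  comparable <- !d1$untestable
  expect_true(all((d1$direction == "increased") ==
                    (d2$direction == "decreased") | !comparable))
})

test_that("sample PCA sub-profiles behave on degenerate and structured input", {
  dat <- tibble::tibble(analyte = c("A", "B"),
                        s1 = c(1, 1), s2 = c(2, 2), s3 = c(3, 3), s4 = c(5, 5))
  res <- pca_on_significant(dat, c("A", "B"))
  expect_equal(res$variance_explained[1], 100, tolerance = 1e-9)
  expect_equal(sum(res$variance_explained), 100, tolerance = 1e-6)
  expect_error(pca_on_significant(dat, "A"), class = "evmorph_too_few_analytes")

  om <- gen_omics_tables(omics_config(seed = 30))
  de <- differential_panel(om$secretion, om$secretion_groups, "POS_CTL", "POS_EV")
  sig <- de$analyte[de$significant]
  expect_gte(length(sig), 2)
  res2 <- pca_on_significant(om$secretion, sig)
  sc <- dplyr::inner_join(res2$scores, om$secretion_groups, by = "sample")
  # silhouette of the three groups in PC1/PC2 space
  pts <- as.matrix(sc[, c("PC1", "PC2")])
  dmat <- as.matrix(dist(pts))
  sil <- vapply(seq_len(nrow(pts)), function(i) {
    own <- sc$group == sc$group[i]
    a <- mean(dmat[i, own & seq_len(nrow(pts)) != i])
    b <- min(vapply(setdiff(unique(sc$group), sc$group[i]),
                    function(g) mean(dmat[i, sc$group == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("degree ranking counts distinct neighbours with alphabetical ties", {
  tri <- data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"))
  r <- degree_ranking(tri, c("A", "B", "C"))
  expect_equal(r$degree, c(2, 2, 2))
  expect_equal(r$node, c("A", "B", "C"))
  star <- data.frame(from = rep("HUB", 5), to = paste0("L", 1:5))
  r2 <- degree_ranking(star, c("HUB", paste0("L", 1:5)))
  expect_equal(r2$node[1], "HUB")
  expect_equal(r2$degree[1], 5L)
  # duplicates and self loops ignored; absent nodes get 0
  dup <- data.frame(from = c("A", "A", "B", "C"), to = c("B", "B", "A", "C"))
  r3 <- degree_ranking(dup, c("A", "B", "Z"))
  expect_equal(r3$degree[r3$node == "A"], 1L)
  expect_equal(r3$degree[r3$node == "Z"], 0L)
})

test_that("lipid class totals conserve mass and recover all shifts except LPC", {
  om <- gen_omics_tables(omics_config(seed = 1))
  totals <- lipid_class_totals(om$lipids)
  samples <- om$lipid_groups$sample
  colsums <- colSums(as.matrix(om$lipids[, samples]))
  agg <- tapply(totals$total, totals$sample, sum)
  expect_equal(as.numeric(agg[samples]), unname(colsums), tolerance = 1e-9)
  # per-class Welch test between controls
  wide <- tidyr::pivot_wider(totals, names_from = "sample", values_from = "total")
  g <- om$lipid_groups
  pvals <- vapply(seq_len(nrow(wide)), function(i) {
    welch_test(as.numeric(wide[i, g$sample[g$group == "POS_CTL"]]),
               as.numeric(wide[i, g$sample[g$group == "NEG_CTL"]]))$p
  }, numeric(1))
  names(pvals) <- wide$class
  expect_true(all(pvals[names(pvals) != "LPC"] < 0.05))
  expect_gt(pvals[["LPC"]], 0.05)
})

test_that("unknown lipid classes are binned to other with a warning", {
  dat <- tibble::tibble(species = c("PC(32:1)", "XX(1:1)"),
                        class = c("PC", "XX"), mode = "positive",
                        s1 = c(3, 1), s2 = c(4, 2))
  expect_warning(tot <- lipid_class_totals(dat), "other")
  expect_equal(tot$total[tot$class == "PC" & tot$sample == "s1"], 3)
  expect_equal(tot$total[tot$class == "other" & tot$sample == "s2"], 2)
  # two species in one class sum; empty classes never appear
  dat2 <- tibble::tibble(species = c("PC(a)", "PC(b)"), class = "PC",
                         mode = "positive", s1 = c(3, 4))
  t2 <- lipid_class_totals(dat2)
  expect_equal(t2$total, 7)
  expect_false("TG" %in% t2$class)
})
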