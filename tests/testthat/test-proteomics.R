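test_that("row z-scoring centres, scales and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- zscore_by_row(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(rowMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(zscore_by_row(z), z, tolerance = 1e-12)
  expect_warning(z2 <- zscore_by_row(rbind(a = c(1, 2, 3), flat = c(5, 5, 5))),
                 "constant")
  expect_equal(rownames(z2), "a")
})

test_that("Ward clustering reproduces an exhaustive centroid-formula oracle", {
  set.seed(88)
  for (rep in 1:5) {
    X <- matrix(rnorm(12), 6, 2)
    hc <- ward_hclust(X)
    oracle <- ward_oracle(X)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    expect_equal(hclust_merge_sets(hc), oracle$merges)
  }
})

test_that("Ward clustering merges tight pairs first with monotone heights", {
  X <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10.2, 10))
  hc <- ward_hclust(X)
  expect_equal(hc$height[1], 0) # identical points merge at height 0
  sets <- hclust_merge_sets(hc)
  expect_equal(sets[[1]], c(1L, 2L))
  expect_equal(sets[[2]], c(3L, 4L))
  set.seed(4)
  for (rep in 1:20) {
    Y <- matrix(rnorm(24), 8, 3)
    expect_true(all(diff(ward_hclust(Y)$height) >= -1e-9))
  }
  expect_error(ward_hclust(matrix(1, 1, 2)), class = "evmorph_too_few_items")
})

test_that("moderated statistics agree with the limma reference implementation", {
  library(limma)
  set.seed(55)
  n <- 300
  X <- matrix(rnorm(n * 8, sd = rep(sqrt(1 / rgamma(n, 4, 4)), 8)), n, 8)
  X[1:20, 5:8] <- X[1:20, 5:8] + 2
  rownames(X) <- sprintf("P%03d", 1:n)
  colnames(X) <- sprintf("S%d", 1:8)
  groups <- tibble::tibble(sample = colnames(X),
                           group = rep(c("CTL", "TRT"), each = 4))
  mine <- moderated_de(X, groups, contrast = c("CTL", "TRT"))
  fit <- eBayes(lmFit(X, stats::model.matrix(~ factor(groups$group))))
  expect_equal(attr(mine, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "s2_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t_moderated, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(mine$s2_posterior, unname(fit$s2.post), tolerance = 1e-8)
})

test_that("shrinkage is monotone and can be switched off", {
  set.seed(66)
  X <- matrix(rnorm(100 * 6, sd = rep(runif(100, 0.2, 2), 6)), 100, 6)
  rownames(X) <- sprintf("P%03d", 1:100)
  colnames(X) <- sprintf("S%d", 1:6)
  groups <- tibble::tibble(sample = colnames(X),
                           group = rep(c("A", "B"), each = 3))
  res <- moderated_de(X, groups, contrast = c("A", "B"))
  d0 <- attr(res, "df_prior"); s02 <- attr(res, "s2_prior")
  expect_true(is.finite(d0) && d0 > 0)
  # posterior variance lies between the residual and prior variances
  expect_true(all(res$s2_posterior >= pmin(res$s2_residual, s02) - 1e-12))
  expect_true(all(res$s2_posterior <= pmax(res$s2_residual, s02) + 1e-12))
  # |moderated t| between |ordinary t| and |t computed with s0^2|
  se <- sqrt(1 / 3 + 1 / 3)
  t_s0 <- res$log2_fc / (sqrt(s02) * se)
  expect_true(all(abs(res$t_moderated) >= pmin(abs(res$t_ordinary), abs(t_s0)) - 1e-9))
  expect_true(all(abs(res$t_moderated) <= pmax(abs(res$t_ordinary), abs(t_s0)) + 1e-9))
  # d0 = 0 disables shrinkage entirely
  off <- moderated_de(X, groups, contrast = c("A", "B"), d0_override = 0)
  expect_equal(off$t_moderated, off$t_ordinary, tolerance = 1e-12)
  # d0 = Inf pools fully: every t uses the (fully pooled) prior variance
  pool <- moderated_de(X, groups, contrast = c("A", "B"), d0_override = Inf)
  t_pool <- pool$log2_fc / (sqrt(attr(pool, "s2_prior")) * se)
  expect_equal(unname(pool$t_moderated), unname(t_pool), tolerance = 1e-9)
})

test_that("moderated DE recovers planted effects at small n", {
  set.seed(91)
  n <- 1000; n_true <- 100
  sdv <- 0.3
  X <- matrix(rnorm(n * 6, sd = sdv), n, 6)
  X[1:n_true, 4:6] <- X[1:n_true, 4:6] +
    2 * sample(c(-1, 1), n_true, replace = TRUE)
  rownames(X) <- sprintf("P%04d", 1:n); colnames(X) <- sprintf("S%d", 1:6)
  groups <- tibble::tibble(sample = colnames(X),
                           group = rep(c("A", "B"), each = 3))
  res <- moderated_de(X, groups, contrast = c("A", "B"))
  recall <- mean(res$significant[1:n_true])
  fdp <- sum(res$significant[-(1:n_true)]) / max(sum(res$significant), 1)
  expect_gte(recall, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("volcano classification applies the joint fold-change rule", {
  res <- tibble::tibble(
    log2_fc = c(1.5, 0.5, -2, 0.1),
    p_value = c(0.01, 0.001, 0.04, 0.5))
  res$significant <- res$p_value < 0.05 & abs(res$log2_fc) >= 1
  res$direction <- ifelse(!res$significant, "ns",
                          ifelse(res$log2_fc > 0, "up", "down"))
  counts <- volcano_classify(res)
  expect_equal(counts$n_up, 1)   # FC 2.83, p 0.01
  expect_equal(counts$n_down, 1) # FC 0.25, p 0.04
  expect_equal(counts$n_ns, 2)   # FC < 2 stays ns despite p < 0.05
  expect_equal(counts$n_up + counts$n_down + counts$n_ns, nrow(res))
})

test_that("flipping the contrast swaps up and down counts", {
  om <- gen_omics_tables(omics_config(seed = 14, n_proteins = 300, dap_up = 20,
                                      dap_down = 30, stim_protein_n = 20))
  a <- moderated_de(om$proteins, om$protein_groups, c("POS_CTL", "POS_EV"))
  b <- moderated_de(om$proteins, om$protein_groups, c("POS_EV", "POS_CTL"))
  ca <- volcano_classify(a); cb <- volcano_classify(b)
  expect_equal(ca$n_up, cb$n_down)
  expect_equal(ca$n_down, cb$n_up)
})

test_that("BH adjustment matches a sort-based reference", {
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_reference(p), tolerance = 1e-12)
  }
  # monotone in p-rank and bounded by 1
  p <- runif(100)
  q <- p.adjust(p, "BH")
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})
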