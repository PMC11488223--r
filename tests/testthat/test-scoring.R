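toy_profiles <- function() {
  # 8 wells, 2 groups, 2 features with known anchors
  tibble::tibble(
    well_id = sprintf("W%02d", 1:8),
    group = rep(c("NEG_CTL", "POS_CTL"), each = 4),
    f1 = c(1, 2, 3, 2, 9, 10, 11, 10),
    f2 = c(10, 12, 11, 11, 30, 31, 29, 30))
}

test_that("well medians are robust and conserve wells", {
  set.seed(314)
  rec <- tibble::tibble(
    well_id = c(rep("A01", 3), rep("A02", 701)),
    f = c(1, 2, 100, rnorm(701)))
  lay <- tibble::tibble(well_id = c("A01", "A02"), group = c("NEG_CTL", "POS_CTL"))
  prof <- aggregate_well_medians(rec, lay, min_cells = 2, features = "f")
  expect_equal(prof$f[prof$well_id == "A01"], 2)
  # one extreme outlier barely moves the median of a 701-cell well (it can
  # shift it by at most half the central inter-order-statistic spacing)
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(well_id = "A02", f = 1e9))
  prof2 <- aggregate_well_medians(rec2, lay, min_cells = 2, features = "f")
  expect_lt(abs(prof2$f[prof2$well_id == "A02"] - prof$f[prof$well_id == "A02"]),
            0.01)
  # wells under min_cells dropped with a warning
  expect_warning(
    prof3 <- aggregate_well_medians(rec, lay, min_cells = 50, features = "f"),
    "fewer than")
  expect_equal(prof3$well_id, "A02")
  expect_error(aggregate_well_medians(rec[0, ], lay), class = "evmorph_empty_input")
  expect_error(aggregate_well_medians(
    tibble::tibble(well_id = "Z99", f = 1), lay), class = "evmorph_unknown_well")
})

test_that("min-max normalization anchors control means at 0 and 1", {
  prof <- toy_profiles()
  nn <- minmax_normalize(prof, features = c("f1", "f2"))
  for (f in c("f1", "f2")) {
    expect_equal(mean(nn[[f]][nn$group == "NEG_CTL"]), 0, tolerance = 1e-9)
    expect_equal(mean(nn[[f]][nn$group == "POS_CTL"]), 1, tolerance = 1e-9)
  }
  # the exact control mean maps to its anchor, the midpoint to 0.5
  mu_n <- mean(prof$f1[prof$group == "NEG_CTL"])
  mu_p <- mean(prof$f1[prof$group == "POS_CTL"])
  probe <- dplyr::bind_rows(prof,
    tibble::tibble(well_id = c("P1", "P2", "P3"), group = "POS_EV",
                   f1 = c(mu_n, mu_p, (mu_n + mu_p) / 2), f2 = 20))
  np <- minmax_normalize(probe, features = c("f1", "f2"))
  expect_equal(np$f1[np$well_id %in% c("P1", "P2", "P3")], c(0, 1, 0.5))
})

test_that("min-max normalization is affine invariant and flags degeneracy", {
  set.seed(42)
  prof <- toy_profiles()
  prof$f3 <- rnorm(8, 5, 2)
  nn1 <- minmax_normalize(prof, features = c("f1", "f3"))
  prof2 <- prof
  prof2$f3 <- 3 * prof$f3 + 7
  nn2 <- minmax_normalize(prof2, features = c("f1", "f3"))
  expect_equal(nn1$f3, nn2$f3, tolerance = 1e-9)
  prof$flat <- rep(c(1, 1, 1, 1, 1, 1, 1, 1))
  expect_error(minmax_normalize(prof, features = c("f1", "flat")),
               class = "evmorph_degenerate_feature", regexp = "flat")
})

test_that("composite PCA concentrates variance and fixes orientation", {
  prof <- toy_profiles()
  # exactly proportional features: rank-1, PC1 explains 100%
  prof$f2 <- 3 * prof$f1
  res <- composite_pca_score(prof, features = c("f1", "f2"), standardize = FALSE)
  expect_equal(res$variance_explained[1], 100, tolerance = 1e-9)
  expect_equal(sum(res$variance_explained), 100, tolerance = 1e-6)
  expect_gte(mean(res$scores$PC1[res$scores$group == "POS_CTL"]),
             mean(res$scores$PC1[res$scores$group == "NEG_CTL"]))
  # isotropic cloud splits variance evenly
  set.seed(7)
  iso <- tibble::tibble(well_id = sprintf("I%05d", 1:10000),
                        group = rep(c("NEG_CTL", "POS_CTL"), 5000),
                        f1 = rnorm(10000), f2 = rnorm(10000))
  vi <- composite_pca_score(iso, features = c("f1", "f2"),
                            standardize = FALSE)$variance_explained
  expect_equal(vi[1], 50, tolerance = 0.04)
  expect_error(composite_pca_score(prof[1:2, ], features = c("f1", "f2")),
               class = "evmorph_too_few_wells")
  prof$flat <- 1
  expect_error(composite_pca_score(prof, features = c("f1", "flat"),
                                   standardize = TRUE),
               class = "evmorph_degenerate_feature")
})

test_that("synthetic stimulated wells score above unstimulated on PC1", {
  cells <- gen_feature_table(small_plate_config(seed = 31))
  res <- score_plate(cells, attr(cells, "layout"), min_cells = 20)
  sc <- res$scores
  expect_gt(mean(sc$PC1[sc$group == "POS_CTL"]),
            mean(sc$PC1[sc$group == "NEG_CTL"]))
  # re-running the scoring stage reproduces identical output (idempotent)
  res2 <- score_plate(cells, attr(cells, "layout"), min_cells = 20)
  expect_identical(res$scores, res2$scores)
  expect_identical(res$pca$loadings, res2$pca$loadings)
})

test_that("delta scores are linear and cancel shared batch shifts", {
  sc <- tibble::tibble(
    experiment = rep(c("E1", "E2"), each = 8),
    operator = "O1",
    group = rep(rep(c("NEG_CTL", "POS_CTL"), each = 4), 2),
    PC1 = c(0, 1, 2, 1, 5, 6, 7, 6, 10, 11, 12, 11, 15, 16, 17, 16))
  d <- delta_score(sc, "POS_CTL", "NEG_CTL")
  expect_equal(d$delta, c(5, 5)) # batch shift of +10 in E2 cancels
  # identical groups give delta 0
  sc0 <- sc; sc0$PC1 <- rep(1:4, 4)
  expect_equal(delta_score(sc0, "POS_CTL", "NEG_CTL")$delta, c(0, 0))
  # shifting group_a by c shifts delta by c
  sc1 <- sc
  sc1$PC1[sc1$group == "POS_CTL"] <- sc1$PC1[sc1$group == "POS_CTL"] + 2.5
  expect_equal(delta_score(sc1, "POS_CTL", "NEG_CTL")$delta, c(7.5, 7.5))
  # missing group in a stratum skipped with warning
  expect_warning(dd <- delta_score(sc[sc$experiment == "E1" | sc$group == "NEG_CTL", ],
                                   "POS_CTL", "NEG_CTL"),
                 "lacks group")
  expect_equal(nrow(dd), 1)
})

test_that("operator-level shifts leave the generator's delta score invariant", {
  mk <- function(shift) {
    cfg <- plate_config(n_wells_per_group = 6, cells_per_well_range = c(200, 200),
                        operators = c("O1", "O2"), operator_shift = shift,
                        seed = 77)
    cells <- gen_feature_table(cfg)
    res <- score_plate(cells, attr(cells, "layout"), min_cells = 20)
    delta_score(res$scores, "POS_CTL", "NEG_CTL", score_col = "score_norm")
  }
  d0 <- mk(0)
  d1 <- mk(0.5)
  # the same RNG stream is consumed, so the only difference is the shared
  # operator shift, which the delta cancels up to multiplicative noise
  expect_equal(d1$delta, d0$delta, tolerance = 0.05)
})

test_that("Z'-factor arithmetic matches its closed forms", {
  mk_scores <- function(neg, pos) {
    tibble::tibble(group = rep(c("NEG_CTL", "POS_CTL"), c(length(neg), length(pos))),
                   PC1 = c(neg, pos))
  }
  # zero spread: Z' = 1 exactly
  z1 <- z_factor(mk_scores(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(z1$z_factor, 1)
  expect_equal(z1$quality_label, "optimized")
  # sd = 1/12 on both sides of a unit gap: Z' = 0.5 exactly
  d <- 1 / 12
  z2 <- z_factor(mk_scores(c(-d, 0, d), c(1 - d, 1, 1 + d)))
  expect_equal(z2$z_factor, 0.5, tolerance = 1e-12)
  expect_equal(z2$sigma_neg, d, tolerance = 1e-15)
  expect_error(z_factor(mk_scores(c(1, 2), c(1, 2))),
               class = "evmorph_no_dynamic_range")
  expect_error(z_factor(mk_scores(1, c(2, 3))), class = "evmorph_too_few_wells")
  expect_lte(z_factor(mk_scores(rnorm(8), rnorm(8, 10)))$z_factor, 1)
})

test_that("Z'-factor is invariant under affine score transforms", {
  set.seed(123)
  for (i in 1:200) {
    neg <- rnorm(6); pos <- rnorm(6, 3)
    sc <- tibble::tibble(group = rep(c("NEG_CTL", "POS_CTL"), each = 6),
                         PC1 = c(neg, pos))
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- runif(1, -10, 10)
    sc2 <- sc; sc2$PC1 <- a * sc2$PC1 + b
    expect_equal(z_factor(sc2)$z_factor, z_factor(sc)$z_factor,
                 tolerance = 1e-9)
  }
})

test_that("dose-response summaries detect monotone trends and calibrate nulls", {
  sc <- tibble::tibble(ev_dose = rep(c(0.25, 0.5, 1, 2), each = 4),
                       score_norm = rep(c(0.9, 0.7, 0.5, 0.3), each = 4))
  d <- dose_response_summary(sc, n_perm = 500, seed = 1)
  expect_equal(d$spearman_rho, -1)
  expect_lt(d$p_value, 0.01)
  expect_equal(d$per_dose$mean, c(0.9, 0.7, 0.5, 0.3))
  expect_error(dose_response_summary(sc[sc$ev_dose < 0.6, ]),
               class = "evmorph_too_few_doses")
  # null: permuted labels give approximately uniform p-values
  set.seed(5)
  pv <- vapply(1:40, function(i) {
    scn <- tibble::tibble(ev_dose = rep(c(1, 2, 3, 4), each = 3),
                          score_norm = rnorm(12))
    dose_response_summary(scn, n_perm = 300, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(pv), 0.35)
  expect_lt(mean(pv), 0.70)
})

test_that("an EV titration produces a detectable monotone dose trend", {
  cfg <- plate_config(n_wells_per_group = 6, cells_per_well_range = c(200, 220),
                      ev_doses = c(0.25, 0.5, 1), ev_effect = 0.8, seed = 19)
  cells <- gen_feature_table(cfg)
  res <- score_plate(cells, attr(cells, "layout"), min_cells = 20)
  ev <- res$scores[res$scores$group == "POS_EV", ]
  d <- dose_response_summary(ev, n_perm = 2000, seed = 2)
  expect_lt(d$spearman_rho, 0) # higher dose, closer to unstimulated
  expect_lt(d$p_value, 0.01)
})
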