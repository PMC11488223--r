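# Well-level scoring: median aggregation, control-anchored min-max
# normalization, PCA composite phenotype scores, delta scores, Z'-factor and
# dose-response summaries.

#' Aggregate single-cell records into per-well median profiles
#'
#' Medians are used (rather than means) so the thousands of cells per well
#' dampen residual outliers that survive QC.
#'
#' @param records tibble of QC-passed cell records.
#' @param layout plate layout tibble (must contain `well_id`; condition
#'   columns are carried through).
#' @param min_cells wells with fewer cells are dropped with a warning
#'   (default 50; medians of fewer cells are unstable).
#' @param features feature columns to aggregate; defaults to every numeric
#'   feature column present.
#' @return Tibble with layout columns, `n_cells`, and per-well median
#'   feature values.
#' @export
aggregate_well_medians <- function(records, layout, min_cells = 50,
                                   features = NULL) {
  check_columns(records, "well_id", "`records`")
  check_columns(layout, "well_id", "`layout`")
  if (nrow(records) == 0) {
    evm_abort("no cell records supplied", "evmorph_empty_input")
  }
  bad <- setdiff(unique(records$well_id), layout$well_id)
  if (length(bad) > 0) {
    evm_abort(sprintf("records reference wells absent from the layout: %s",
                      paste(head(bad, 5), collapse = ", ")),
              "evmorph_unknown_well")
  }
  if (is.null(features)) {
    candidates <- setdiff(names(records),
                          c("experiment", "operator", "well_id", "image_id",
                            "cell_id"))
    features <- candidates[vapply(records[candidates], is.numeric, logical(1))]
  }
  prof <- records |>
    group_by(.data$well_id) |>
    summarise(n_cells = n(),
              across(all_of(features), ~ median(.x, na.rm = TRUE)),
              .groups = "drop")
  low <- prof$n_cells < min_cells
  if (any(low)) {
    warn(sprintf("dropping %d well(s) with fewer than %d cells: %s",
                 sum(low), min_cells,
                 paste(head(prof$well_id[low], 5), collapse = ", ")))
    prof <- prof[!low, , drop = FALSE]
  }
  layout |>
    inner_join(prof, by = "well_id") |>
    as_tibble()
}

#' Control-anchored min-max normalization of well profiles
#'
#' For each feature, the mean over `NEG_CTL` wells maps to 0 and the mean
#' over `POS_CTL` wells maps to 1; every other well is transformed by the
#' same affine map (values outside `[0, 1]` are allowed and meaningful).
#'
#' @param profiles well-profile tibble with a `group` column.
#' @param features feature columns to normalize; default: all numeric
#'   columns except layout/count columns.
#' @param neg,pos control group labels.
#' @return Tibble of the same shape with normalized feature values.
#' @export
minmax_normalize <- function(profiles, features = NULL,
                             neg = "NEG_CTL", pos = "POS_CTL") {
  check_columns(profiles, "group", "`profiles`")
  if (sum(profiles$group == neg) < 2 || sum(profiles$group == pos) < 2) {
    evm_abort("need at least 2 wells in each control group",
              "evmorph_insufficient_controls")
  }
  if (is.null(features)) {
    skip <- c("well_id", "row", "col", "group", "cytokine_dose_ng_ml",
              "ev_dose", "operator", "experiment", "n_cells")
    features <- setdiff(names(profiles)[vapply(profiles, is.numeric, logical(1))],
                        skip)
  }
  mu_neg <- colMeans(profiles[profiles$group == neg, features, drop = FALSE])
  mu_pos <- colMeans(profiles[profiles$group == pos, features, drop = FALSE])
  span <- mu_pos - mu_neg
  degenerate <- abs(span) <= 1e-12
  if (any(degenerate)) {
    evm_abort(sprintf("degenerate feature(s) with equal control means: %s",
                      paste(features[degenerate], collapse = ", ")),
              "evmorph_degenerate_feature")
  }
  out <- profiles
  for (f in features) {
    out[[f]] <- (profiles[[f]] - mu_neg[[f]]) / span[[f]]
  }
  out
}

#' Composite PCA phenotype score over wells
#'
#' Eigen-decomposition of the covariance (or, with `standardize = TRUE`, the
#' correlation) matrix of wells x features; the use cases are the 21
#' cellular/nuclear features (the morphological score) and the `Mito_*` set
#' (the mitochondrial score). The PC1 sign is fixed so the stimulated
#' control scores at least as high as the unstimulated control, making
#' "EV treatment shifts scores down toward unstimulated" the invariant
#' reading. With raw median profiles standardize first; min-max normalized
#' profiles are already on a common scale.
#'
#' @param profiles well-profile tibble with `group` (and `well_id`).
#' @param features feature columns; defaults to [canonical_features()].
#' @param standardize z-score features before decomposition.
#' @param fit_groups optional group subset to fit the rotation on
#'   (e.g. controls only); remaining wells are projected into that space.
#' @param neg,pos group labels anchoring the orientation.
#' @return An `evm_pca` object: list with `scores` (tibble of well ids,
#'   condition columns and PC coordinates), `loadings`, `variance_explained`
#'   (percent, sums to 100) and `orientation_sign`.
#' @export
composite_pca_score <- function(profiles, features = NULL, standardize = TRUE,
                                fit_groups = NULL,
                                neg = "NEG_CTL", pos = "POS_CTL") {
  check_columns(profiles, c("well_id", "group"), "`profiles`")
  if (is.null(features)) features <- canonical_features()
  check_columns(profiles, features, "`profiles`")
  if (nrow(profiles) < 3) {
    evm_abort("need at least 3 wells for a composite score", "evmorph_too_few_wells")
  }
  X <- as.matrix(profiles[, features, drop = FALSE])
  fit_rows <- if (is.null(fit_groups)) rep(TRUE, nrow(X)) else
    profiles$group %in% fit_groups
  if (standardize) {
    sds <- apply(X[fit_rows, , drop = FALSE], 2, sd)
    if (any(sds == 0)) {
      evm_abort(sprintf("zero-variance feature(s) with standardize = TRUE: %s",
                        paste(features[sds == 0], collapse = ", ")),
                "evmorph_degenerate_feature")
    }
  }
  fit <- prcomp(X[fit_rows, , drop = FALSE], center = TRUE, scale. = standardize)
  scores <- predict(fit, X)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  sign_flip <- 1
  if (any(profiles$group == pos) && any(profiles$group == neg)) {
    if (mean(scores[profiles$group == pos, 1]) <
        mean(scores[profiles$group == neg, 1])) {
      sign_flip <- -1
    }
  }
  scores[, 1] <- sign_flip * scores[, 1]
  rotation <- fit$rotation
  rotation[, 1] <- sign_flip * rotation[, 1]
  id_cols <- intersect(c("well_id", "group", "cytokine_dose_ng_ml", "ev_dose",
                         "operator", "experiment", "n_cells"), names(profiles))
  structure(
    list(scores = bind_cols(profiles[, id_cols, drop = FALSE],
                            as_tibble(scores)),
         loadings = bind_cols(tibble(feature = rownames(rotation)),
                              as_tibble(rotation)),
         variance_explained = ve,
         orientation_sign = sign_flip,
         standardize = standardize, features = features),
    class = "evm_pca")
}

#' @export
print.evm_pca <- function(x, ...) {
  cat(sprintf("Composite PCA score: %d wells x %d features\n",
              nrow(x$scores), length(x$features)))
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance; orientation sign %+d\n",
              x$variance_explained[1],
              ifelse(length(x$variance_explained) > 1, x$variance_explained[2], NA),
              x$orientation_sign))
  invisible(x)
}

#' Control-anchored normalization of composite scores
#'
#' Maps PC1 scores so the `NEG_CTL` mean is 0 and the `POS_CTL` mean is 1:
#' the normalized bioactivity readout. An EV treatment recovering a fraction
#' `delta` of the morphology gap scores `1 - delta` on this scale.
#'
#' @param scores score tibble (e.g. `composite_pca_score(...)$scores`) with
#'   `group` and the score column.
#' @param score_col score column name (default `"PC1"`).
#' @param neg,pos anchoring group labels.
#' @return Input tibble with an added `score_norm` column.
#' @export
anchor_scores <- function(scores, score_col = "PC1",
                          neg = "NEG_CTL", pos = "POS_CTL") {
  check_columns(scores, c("group", score_col), "`scores`")
  mu_n <- mean(scores[[score_col]][scores$group == neg])
  mu_p <- mean(scores[[score_col]][scores$group == pos])
  if (!is.finite(mu_n) || !is.finite(mu_p) || abs(mu_p - mu_n) <= 1e-12) {
    evm_abort("no dynamic range between control groups", "evmorph_no_dynamic_range")
  }
  scores$score_norm <- (scores[[score_col]] - mu_n) / (mu_p - mu_n)
  scores
}

#' Per-stratum difference in composite scores
#'
#' The differential morphological response: for each experiment x operator
#' stratum, the difference in mean PC1 between two groups with its standard
#' error. Invariant to batch shifts that move both groups equally.
#'
#' @param scores score tibble with `group`, `experiment`, `operator` and the
#'   score column.
#' @param group_a,group_b groups contrasted as `mean(a) - mean(b)`.
#' @param score_col score column name.
#' @return Tibble with one row per stratum: `experiment`, `operator`,
#'   `delta`, `se`, `n_a`, `n_b`. Strata missing either group are skipped
#'   with a warning.
#' @export
delta_score <- function(scores, group_a = "POS_CTL", group_b = "NEG_CTL",
                        score_col = "PC1") {
  check_columns(scores, c("group", "experiment", "operator", score_col),
                "`scores`")
  strata <- distinct(scores, .data$experiment, .data$operator)
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sub <- scores[scores$experiment == strata$experiment[i] &
                    scores$operator == strata$operator[i], ]
    va <- sub[[score_col]][sub$group == group_a]
    vb <- sub[[score_col]][sub$group == group_b]
    if (length(va) == 0 || length(vb) == 0) {
      warn(sprintf("stratum %s/%s lacks group %s; skipped",
                   strata$experiment[i], strata$operator[i],
                   if (length(va) == 0) group_a else group_b))
      next
    }
    out[[i]] <- tibble(experiment = strata$experiment[i],
                       operator = strata$operator[i],
                       delta = mean(va) - mean(vb),
                       se = sqrt(var(va) / length(va) + var(vb) / length(vb)),
                       n_a = length(va), n_b = length(vb))
  }
  bind_rows(out)
}

#' Z'-factor assay quality from control wells
#'
#' `Z' = 1 - (3 * sigma_pos + 3 * sigma_neg) / |mu_pos - mu_neg|` with sample
#' (n-1) standard deviations. `Z' > 0.5` denotes an optimized assay whose
#' control distributions are well separated; `Z'` is at most 1 and invariant
#' under affine transforms of the score.
#'
#' @param scores score tibble with `group` and the score column.
#' @param score_col score column name.
#' @param neg,pos control group labels.
#' @return An `evm_zfactor` object: list with `mu_pos`, `mu_neg`,
#'   `sigma_pos`, `sigma_neg`, `z_factor` and `quality_label`
#'   (`"optimized"` if `> 0.5`, `"marginal"` in `(0, 0.5]`, else
#'   `"unusable"`).
#' @export
z_factor <- function(scores, score_col = "PC1",
                     neg = "NEG_CTL", pos = "POS_CTL") {
  check_columns(scores, c("group", score_col), "`scores`")
  vp <- scores[[score_col]][scores$group == pos]
  vn <- scores[[score_col]][scores$group == neg]
  if (length(vp) < 2 || length(vn) < 2) {
    evm_abort("need at least 2 wells per control group", "evmorph_too_few_wells")
  }
  mu_p <- mean(vp); mu_n <- mean(vn)
  if (abs(mu_p - mu_n) <= 1e-12) {
    evm_abort("no dynamic range: control means are equal",
              "evmorph_no_dynamic_range")
  }
  z <- 1 - (3 * sd(vp) + 3 * sd(vn)) / abs(mu_p - mu_n)
  structure(list(mu_pos = mu_p, mu_neg = mu_n,
                 sigma_pos = sd(vp), sigma_neg = sd(vn),
                 z_factor = z,
                 quality_label = if (z > 0.5) "optimized" else
                   if (z > 0) "marginal" else "unusable"),
            class = "evm_zfactor")
}

#' @export
print.evm_zfactor <- function(x, ...) {
  cat(sprintf("Z' = %.3f (%s); mu- = %.3f, mu+ = %.3f, sigma- = %.3f, sigma+ = %.3f\n",
              x$z_factor, x$quality_label, x$mu_neg, x$mu_pos,
              x$sigma_neg, x$sigma_pos))
  invisible(x)
}

#' Dose-response summary of normalized composite scores
#'
#' Per-dose mean and sd plus a Spearman rank correlation of score against
#' dose with a seeded permutation p-value (label permutation, two-sided).
#'
#' @param scores tibble with the score and dose columns (one row per well).
#' @param dose_col dose column name.
#' @param score_col score column name (e.g. `"score_norm"`).
#' @param n_perm permutations for the p-value.
#' @param seed RNG seed for the permutations.
#' @return An `evm_dose` object: list with `per_dose` (tibble `dose`, `n`,
#'   `mean`, `sd`), `spearman_rho`, `p_value`, `n_perm`.
#' @export
dose_response_summary <- function(scores, dose_col = "ev_dose",
                                  score_col = "score_norm",
                                  n_perm = 10000, seed = 1) {
  check_columns(scores, c(dose_col, score_col), "`scores`")
  dose <- scores[[dose_col]]; y <- scores[[score_col]]
  if (length(unique(dose)) < 3) {
    evm_abort("need at least 3 distinct dose levels", "evmorph_too_few_doses")
  }
  per_dose <- scores |>
    group_by(dose = .data[[dose_col]]) |>
    summarise(n = n(), mean = mean(.data[[score_col]]),
              sd = sd(.data[[score_col]]), .groups = "drop") |>
    arrange(.data$dose)
  rho <- cor(dose, y, method = "spearman")
  perm_rho <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) cor(sample(dose), y, method = "spearman"), numeric(1))
  })
  p <- (1 + sum(abs(perm_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(list(per_dose = per_dose, spearman_rho = rho, p_value = p,
                 n_perm = n_perm),
            class = "evm_dose")
}

#' @export
print.evm_dose <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, permutation p = %.4g (%d permutations)\n",
              x$spearman_rho, x$p_value, x$n_perm))
  print(x$per_dose)
  invisible(x)
}

#' Score a plate end-to-end
#'
#' Convenience wrapper chaining the scoring stages the assay uses: QC filter,
#' per-well medians, control-anchored min-max normalization of the 21
#' canonical features, composite PCA (on the normalized features, without
#' re-standardizing) and control-anchored normalization of PC1, plus the
#' Z'-factor of the control wells.
#'
#' @param records single-cell feature tibble.
#' @param layout plate layout tibble.
#' @param min_cells minimum cells per well.
#' @param features feature set for the composite (default the 21 canonical
#'   cellular/nuclear features).
#' @return List with `scores` (well tibble incl. `PC1` and `score_norm`),
#'   `pca` (`evm_pca`), `zfactor` (`evm_zfactor`) and `qc` (kept/rejected
#'   counts).
#' @export
score_plate <- function(records, layout, min_cells = 50, features = NULL) {
  if (is.null(features)) features <- canonical_features()
  qc <- qc_filter(records)
  agg_feats <- intersect(union(features, qc_features()), names(records))
  profiles <- aggregate_well_medians(qc$kept, layout, min_cells = min_cells,
                                     features = agg_feats)
  normed <- minmax_normalize(profiles, features = features)
  pca <- composite_pca_score(normed, features = features, standardize = FALSE)
  scores <- anchor_scores(pca$scores)
  zf <- z_factor(scores, score_col = "score_norm")
  list(scores = scores, pca = pca, zfactor = zf,
       qc = list(n_kept = nrow(qc$kept), n_rejected = nrow(qc$rejected)))
}
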