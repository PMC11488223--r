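# Cellular-proteome statistics: row z-scoring, Ward.D2 clustering, and
# empirical-Bayes moderated differential abundance with the fold-change rule.

#' Z-score a matrix row-wise
#'
#' Each analyte row is centred and scaled to unit (n-1) standard deviation
#' across samples; constant rows cannot be scaled and are dropped with a
#' warning.
#'
#' @param data omics tibble (id column + sample columns) or numeric matrix.
#' @param id_col id column name when `data` is a tibble.
#' @return Object of the same kind with z-scored rows.
#' @export
zscore_by_row <- function(data, id_col = NULL) {
  if (is.matrix(data)) {
    s <- apply(data, 1, sd)
    drop <- s == 0 | !is.finite(s)
    if (any(drop)) {
      warn(sprintf("dropping %d constant row(s)", sum(drop)))
    }
    X <- data[!drop, , drop = FALSE]
    return((X - rowMeans(X)) / apply(X, 1, sd))
  }
  if (is.null(id_col)) id_col <- names(data)[1]
  X <- omics_values(data, id_col)
  Z <- zscore_by_row(X)
  bind_cols(tibble(!!id_col := rownames(Z)), as_tibble(Z))
}

#' Ward.D2 hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distances and the Ward.D2
#' criterion (squared distances inside the Lance-Williams update, merge
#' heights on the distance scale). Merge heights are non-decreasing.
#'
#' @param data numeric matrix or omics tibble.
#' @param axis cluster `"rows"` or `"cols"`.
#' @param id_col id column name when `data` is a tibble.
#' @return An `hclust` object (merge tree, heights, leaf order).
#' @export
ward_hclust <- function(data, axis = c("rows", "cols"), id_col = NULL) {
  axis <- match.arg(axis)
  if (!is.matrix(data)) {
    if (is.null(id_col)) id_col <- names(data)[1]
    data <- omics_values(data, id_col)
  }
  X <- if (axis == "rows") data else t(data)
  if (nrow(X) < 2) {
    evm_abort("need at least 2 items to cluster", "evmorph_too_few_items")
  }
  d <- dist(X)
  if (any(is.na(d))) {
    evm_abort("NaN/NA distances; check the input matrix", "evmorph_bad_input")
  }
  hclust(d, method = "ward.D2")
}

# trigamma inverse via Newton iterations (tol 1e-8), as used by the
# moderated-statistics prior fit
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated differential abundance
#'
#' Per-protein one-way linear model on the group labels (residual variance
#' pooled over all groups), with residual variances shrunk toward a common
#' prior by empirical-Bayes moment matching on `log(s_g^2)`: the prior
#' degrees of freedom `d0` solve a trigamma equation (Newton iterations) and
#' the posterior variance is `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`. The
#' moderated t uses `d0 + d_g` degrees of freedom. A protein is significant
#' when `p < alpha` and `|fold change| >= fc_threshold` jointly, and
#' classified `up` / `down` / `ns` for volcano output.
#'
#' @param data protein tibble (id + sample columns) or matrix, on log2 scale.
#' @param groups tibble `sample`, `group`.
#' @param contrast length-2 character: `c(reference, treatment)`; fold
#'   change is treatment minus reference.
#' @param fc_threshold fold-change threshold (linear scale, default 2).
#' @param alpha significance level.
#' @param d0_override optional prior df override: `0` disables shrinkage
#'   (moderated t equals the ordinary t), `Inf` fully pools.
#' @param id_col id column name.
#' @return An `evm_moderated_de` tibble (one row per protein: `log2_fc`,
#'   `t_ordinary`, `t_moderated`, `df_residual`, `p_value`, `significant`,
#'   `direction`) with attributes `df_prior` and `s2_prior`, plus columns
#'   `s2_residual`, `s2_posterior`.
#' @export
moderated_de <- function(data, groups, contrast, fc_threshold = 2,
                         alpha = 0.05, d0_override = NULL,
                         id_col = NULL) {
  if (!is.matrix(data)) {
    if (is.null(id_col)) id_col <- names(data)[1]
    data <- omics_values(data, id_col)
  }
  check_columns(groups, c("sample", "group"), "`groups`")
  groups <- groups[groups$sample %in% colnames(data), ]
  X <- data[, groups$sample, drop = FALSE]
  g <- factor(groups$group)
  if (length(contrast) != 2 || !all(contrast %in% levels(g))) {
    evm_abort("`contrast` must name two groups present in `groups`",
              "evmorph_bad_contrast")
  }
  n_per <- table(g)
  if (any(n_per[contrast] < 2)) {
    evm_abort("each contrasted group needs at least 2 samples",
              "evmorph_too_few_samples")
  }
  G <- nlevels(g); n <- ncol(X)
  df_resid <- n - G
  if (df_resid < 1) {
    evm_abort("no residual degrees of freedom", "evmorph_too_few_samples")
  }
  # group means and pooled residual variance, vectorised over proteins
  means <- sapply(levels(g), function(l) rowMeans(X[, g == l, drop = FALSE]))
  fitted <- means[, as.character(g), drop = FALSE]
  resid <- X - fitted
  s2 <- rowSums(resid^2) / df_resid
  log2_fc <- means[, contrast[2]] - means[, contrast[1]]
  se_scale <- sqrt(1 / n_per[[contrast[1]]] + 1 / n_per[[contrast[2]]])
  t_ord <- log2_fc / (sqrt(s2) * se_scale)

  # prior fit by moment matching of log s2 against a scaled-F prior
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df_resid / 2) + log(df_resid / 2)
  ebar <- mean(e)
  ne <- length(e)
  target <- mean((e - ebar)^2) * ne / (ne - 1) - trigamma(df_resid / 2)
  if (!is.null(d0_override)) {
    d0 <- d0_override
  } else if (is.finite(target) && target > 0) {
    d0 <- 2 * trigamma_inverse(target)
  } else {
    d0 <- Inf # all residual variances consistent with a single prior value
  }
  s02 <- if (is.infinite(d0)) {
    exp(ebar)
  } else if (d0 == 0) {
    NA_real_ # shrinkage disabled; no prior variance is defined
  } else {
    exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(df_resid, length(s2))
  } else {
    s2_post <- (d0 * s02 + df_resid * s2) / (d0 + df_resid)
    df_total <- rep(d0 + df_resid, length(s2))
  }
  t_mod <- log2_fc / (sqrt(s2_post) * se_scale)
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  sig <- p < alpha & abs(log2_fc) >= log2(fc_threshold)
  out <- tibble(
    protein = rownames(X),
    log2_fc = unname(log2_fc),
    t_ordinary = unname(t_ord),
    t_moderated = unname(t_mod),
    df_residual = df_resid,
    s2_residual = unname(s2),
    s2_posterior = unname(s2_post),
    p_value = unname(p),
    significant = unname(sig),
    direction = ifelse(!sig, "ns", ifelse(log2_fc > 0, "up", "down")))
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  attr(out, "contrast") <- contrast
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("evm_moderated_de", class(out))
  out
}

#' Volcano classification counts
#'
#' Partition of a differential-abundance table into upregulated,
#' downregulated and non-significant proteins under the joint
#' `p < alpha` and `|fold change| >= threshold` rule.
#'
#' @param results an [moderated_de()] result (or any tibble with
#'   `direction`).
#' @return Tibble `n_up`, `n_down`, `n_ns` (sums to the protein count).
#' @export
volcano_classify <- function(results) {
  check_columns(results, "direction", "`results`")
  tibble(n_up = sum(results$direction == "up"),
         n_down = sum(results$direction == "down"),
         n_ns = sum(results$direction == "ns"))
}
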