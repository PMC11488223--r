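# Gene set variation analysis: per-sample enrichment scores from a
# kernel-estimated expression statistic and a rank random walk, followed by
# per-set ANOVA / Tukey / Benjamini-Hochberg group comparisons.

#' Read or filter a gene-set collection
#'
#' Intersects each set with the measured ids and applies the size bounds;
#' sets falling outside the bounds are skipped with a message.
#'
#' @param gene_sets named list of id vectors.
#' @param universe measured ids.
#' @param min_size,max_size retained set size bounds after intersection
#'   (defaults 5 and 500, the conventional filter that prevents degenerate
#'   walks).
#' @return Named list of filtered sets.
#' @export
filter_gene_sets <- function(gene_sets, universe, min_size = 5, max_size = 500) {
  if (anyDuplicated(names(gene_sets)) > 0) {
    evm_abort("gene set names must be unique", "evmorph_duplicate_ids")
  }
  out <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  keep <- vapply(out, length, integer(1))
  drop <- keep < min_size | keep > max_size
  if (any(drop)) {
    inform(sprintf("skipping %d gene set(s) outside size bounds [%d, %d]",
                   sum(drop), min_size, max_size))
  }
  out[!drop]
}

#' Gene set variation analysis enrichment scores
#'
#' Unsupervised per-sample pathway activity. For each gene, a Gaussian
#' kernel CDF statistic is estimated across samples (bandwidth `s_i / 4`,
#' the gene's standard deviation over 4). Within each sample, genes are
#' ranked by the statistic (largest first) and given symmetrised rank
#' weights `|p/2 - rank|`; a random walk down the ranked list accrues
#' `|r|^tau` (normalised by the in-set sum) at set members and
#' `1 / (p - |set|)` decrements elsewhere. The enrichment score is the
#' maximum positive deviation plus the minimum negative deviation of the
#' walk when `mx_diff = TRUE` (the default), otherwise the signed deviation
#' of largest magnitude. Scores are bounded in `[-1, 1]`.
#'
#' @param data protein/gene tibble (id + sample columns) or matrix,
#'   continuous values.
#' @param gene_sets named list of id vectors.
#' @param tau rank-weight exponent.
#' @param mx_diff enrichment statistic form (see above).
#' @param min_size,max_size set size bounds after intersection.
#' @param id_col id column name.
#' @return An `evm_gsva` tibble: `set` column + one enrichment-score column
#'   per sample.
#' @export
gsva_scores <- function(data, gene_sets, tau = 1, mx_diff = TRUE,
                        min_size = 5, max_size = 500, id_col = NULL) {
  if (!is.matrix(data)) {
    if (is.null(id_col)) id_col <- names(data)[1]
    data <- omics_values(data, id_col)
  }
  sets <- filter_gene_sets(gene_sets, rownames(data), min_size, max_size)
  if (length(sets) == 0) {
    evm_abort("no gene sets retained after size filtering", "evmorph_no_sets")
  }
  p <- nrow(data)
  largest <- max(vapply(sets, length, integer(1)))
  if (p < 2 * largest) {
    evm_abort("matrix must have at least twice as many rows as the largest retained set",
              "evmorph_bad_input")
  }
  n <- ncol(data)
  # kernel CDF statistic per gene across samples
  z <- matrix(0, p, n, dimnames = dimnames(data))
  for (i in seq_len(p)) {
    x <- data[i, ]
    h <- sd(x) / 4
    if (h == 0) {
      z[i, ] <- 0.5
    } else {
      z[i, ] <- colMeans(pnorm(outer(x, x, function(a, b) (b - a) / h)))
    }
  }
  es <- matrix(0, length(sets), n,
               dimnames = list(names(sets), colnames(data)))
  set_idx <- lapply(sets, function(s) match(s, rownames(data)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rnk <- integer(p); rnk[ord] <- seq_len(p)
    r <- abs(p / 2 - rnk)
    rw <- r^tau
    for (k in seq_along(sets)) {
      member <- logical(p)
      member[set_idx[[k]]] <- TRUE
      m_ord <- member[ord]
      inc <- ifelse(m_ord, rw[ord] / sum(rw[ord][m_ord]),
                    -1 / (p - sum(member)))
      walk <- cumsum(inc)
      es[k, j] <- if (mx_diff) {
        max(c(0, walk)) + min(c(0, walk))
      } else {
        walk[which.max(abs(walk))]
      }
    }
  }
  out <- bind_cols(tibble(set = rownames(es)), as_tibble(es))
  class(out) <- c("evm_gsva", class(out))
  out
}

#' Per-gene-set ANOVA with Tukey post-hoc and BH adjustment
#'
#' One-way ANOVA of enrichment scores on the group labels for every set,
#' Tukey HSD (studentized range) p-values for all group pairs, and
#' Benjamini-Hochberg adjustment of the ANOVA p-values across sets.
#' Sets with zero within-group variance but separated means are reported
#' with `p = 0` and flagged.
#'
#' @param es an [gsva_scores()] result (or tibble `set` + sample columns).
#' @param groups tibble `sample`, `group` (>= 2 groups, >= 2 samples each).
#' @param alpha significance level on the BH-adjusted q.
#' @return Tibble: `set`, `f_statistic`, `p_anova`, `bh_q`, `significant`,
#'   `degenerate`, and a `tukey` list-column of per-pair tibbles
#'   (`comparison`, `diff`, `p_adj`).
#' @export
gene_set_anova <- function(es, groups, alpha = 0.05) {
  check_columns(es, "set", "`es`")
  check_columns(groups, c("sample", "group"), "`groups`")
  samples <- intersect(names(es), groups$sample)
  g <- factor(groups$group[match(samples, groups$sample)])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    evm_abort("need >= 2 groups with >= 2 samples each", "evmorph_too_few_samples")
  }
  rows <- vector("list", nrow(es))
  for (i in seq_len(nrow(es))) {
    y <- as.numeric(es[i, samples])
    within_var <- tapply(y, g, var)
    degenerate <- all(within_var == 0)
    if (degenerate && length(unique(tapply(y, g, mean))) > 1) {
      pairs_df <- tibble(
        comparison = combn(levels(g), 2, paste, collapse = "-"),
        diff = combn(levels(g), 2,
                     function(pr) mean(y[g == pr[2]]) - mean(y[g == pr[1]])),
        p_adj = 0)
      rows[[i]] <- tibble(set = es$set[i], f_statistic = Inf, p_anova = 0,
                          degenerate = TRUE, tukey = list(pairs_df))
      next
    }
    df <- data.frame(y = y, g = g)
    fit <- aov(y ~ g, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    rows[[i]] <- tibble(
      set = es$set[i],
      f_statistic = an[["F value"]][1],
      p_anova = an[["Pr(>F)"]][1],
      degenerate = FALSE,
      tukey = list(tibble(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"])))
  }
  out <- bind_rows(rows)
  out$bh_q <- p.adjust(out$p_anova, method = "BH")
  out$significant <- out$bh_q <= alpha
  out |> select("set", "f_statistic", "p_anova", "bh_q", "significant",
                "degenerate", "tukey")
}
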