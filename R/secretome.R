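# Differential analysis of secreted-analyte panels and lipid tables, PCA
# sub-profiles and interaction-degree ranking.

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with Welch's correction (Welch-Satterthwaite
#' degrees of freedom). Degenerate inputs are resolved explicitly: zero
#' variance in both groups gives `p = 1` when the means are equal and
#' `p = 0` (with a warning) when they differ.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    evm_abort("each group needs at least 2 observations", "evmorph_too_few_samples")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    evm_abort("inputs must be finite", "evmorph_bad_input")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(tibble(t = 0, df = NA_real_, p = 1))
    warn("zero variance in both groups with unequal means; p set to 0")
    return(tibble(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

omics_values <- function(data, id_col) {
  meta <- intersect(c(id_col, "class", "mode", "detected"), names(data))
  X <- as.matrix(data[, setdiff(names(data), meta), drop = FALSE])
  if (anyDuplicated(data[[id_col]]) > 0) {
    evm_abort(sprintf("duplicate ids in `%s`", id_col), "evmorph_duplicate_ids")
  }
  rownames(X) <- data[[id_col]]
  X
}

#' Per-analyte differential panel (Welch tests)
#'
#' Runs a Welch t-test per analyte between two groups, with log2 fold change
#' computed on group means of the raw abundances (a pseudo-count of half the
#' smallest positive value guards against zeros). The significance rule
#' defaults to the raw `p < alpha` threshold used for secretion and lipid
#' panels; set `correct = TRUE` for Benjamini-Hochberg `q < alpha` instead.
#'
#' @param data tibble: id column + one column per sample (raw abundances).
#' @param groups tibble with `sample`, `group`.
#' @param group_a,group_b groups contrasted; direction reports the change in
#'   `group_b` relative to `group_a`.
#' @param alpha significance level.
#' @param correct use BH-adjusted q-values for the significance call.
#' @param id_col name of the id column (default first column).
#' @param pseudo_count pseudo-count for the fold change; default half the
#'   smallest positive abundance in the matrix.
#' @return Tibble with per-analyte means, `log2_fold_change`, `t_statistic`,
#'   `degrees_freedom`, `p_value`, `bh_q`, `significant`, `direction`
#'   (`"increased"`/`"decreased"` in `group_b` vs `group_a`) and `untestable`
#'   (constant analytes).
#' @export
differential_panel <- function(data, groups, group_a, group_b, alpha = 0.05,
                               correct = FALSE, id_col = names(data)[1],
                               pseudo_count = NULL) {
  X <- omics_values(data, id_col)
  check_columns(groups, c("sample", "group"), "`groups`")
  sa <- groups$sample[groups$group == group_a]
  sb <- groups$sample[groups$group == group_b]
  sa <- intersect(sa, colnames(X)); sb <- intersect(sb, colnames(X))
  if (length(sa) < 2 || length(sb) < 2) {
    evm_abort("both groups need at least 2 samples present in the matrix",
              "evmorph_too_few_samples")
  }
  if (is.null(pseudo_count)) {
    pos <- X[X > 0]
    pseudo_count <- if (length(pos) > 0) min(pos) * 0.5 else 0.5
  }
  A <- X[, sa, drop = FALSE]; B <- X[, sb, drop = FALSE]
  res <- lapply(seq_len(nrow(X)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b)) {
      return(tibble(t = NA_real_, df = NA_real_, p = NA_real_, untestable = TRUE))
    }
    suppressWarnings(welch_test(b, a)) |> mutate(untestable = FALSE)
  }) |> bind_rows()
  out <- tibble(
    !!id_col := rownames(X),
    mean_a = rowMeans(A), mean_b = rowMeans(B),
    log2_fold_change = log2((rowMeans(B) + pseudo_count) /
                              (rowMeans(A) + pseudo_count)),
    t_statistic = res$t, degrees_freedom = res$df, p_value = res$p,
    untestable = res$untestable)
  out$bh_q <- p.adjust(out$p_value, method = "BH")
  crit <- if (correct) out$bh_q else out$p_value
  out$significant <- !out$untestable & !is.na(crit) & crit < alpha
  out$direction <- ifelse(out$mean_b >= out$mean_a, "increased", "decreased")
  out
}

#' PCA of samples on a selected analyte subset
#'
#' Standard sub-profile view: the selected rows are z-scored across samples
#' and the samples ordinated by PCA.
#'
#' @param data omics tibble (id column + sample columns).
#' @param ids analyte ids to use (>= 2).
#' @param id_col id column name.
#' @return An `evm_pca_samples` object: list with `scores` (tibble `sample`,
#'   PCs), `loadings`, `variance_explained` (percent, sums to 100).
#' @export
pca_on_significant <- function(data, ids, id_col = names(data)[1]) {
  X <- omics_values(data, id_col)
  ids <- intersect(ids, rownames(X))
  if (length(ids) < 2) {
    evm_abort("need at least 2 analytes for a PCA sub-profile",
              "evmorph_too_few_analytes")
  }
  if (ncol(X) < 3) {
    evm_abort("need at least 3 samples", "evmorph_too_few_samples")
  }
  Z <- X[ids, , drop = FALSE]
  mu <- rowMeans(Z); s <- apply(Z, 1, sd)
  keep <- s > 0
  if (sum(keep) < 2) {
    evm_abort("fewer than 2 non-constant analytes", "evmorph_too_few_analytes")
  }
  Z <- (Z[keep, , drop = FALSE] - mu[keep]) / s[keep]
  fit <- prcomp(t(Z), center = TRUE, scale. = FALSE)
  structure(
    list(scores = bind_cols(tibble(sample = colnames(X)), as_tibble(fit$x)),
         loadings = bind_cols(tibble(!!id_col := rownames(Z)),
                              as_tibble(fit$rotation)),
         variance_explained = 100 * fit$sdev^2 / sum(fit$sdev^2)),
    class = "evm_pca_samples")
}

#' Lipid feature PCA
#'
#' Same ordination contract as [pca_on_significant()] but over every feature
#' row, for raw lipid feature-intensity matrices where species annotation is
#' unavailable or deliberately unused.
#'
#' @inheritParams pca_on_significant
#' @return An `evm_pca_samples` object.
#' @export
lipid_feature_pca <- function(data, id_col = names(data)[1]) {
  pca_on_significant(data, ids = data[[id_col]], id_col = id_col)
}

#' Rank nodes by interaction degree
#'
#' Degree = number of distinct neighbours within the subgraph induced by the
#' node subset (duplicate edges count once, self-loops are ignored, nodes of
#' the subset absent from the edge list get degree 0). Output is sorted by
#' descending degree with alphabetical tie-break. The edge list is
#' user-supplied (e.g. exported from a protein interaction database).
#'
#' @param edges two-column data frame of undirected edges.
#' @param nodes node subset to rank.
#' @return Tibble `node`, `degree`, sorted.
#' @export
degree_ranking <- function(edges, nodes) {
  if (length(nodes) == 0) {
    evm_abort("`nodes` must be non-empty", "evmorph_bad_input")
  }
  e <- tibble(from = as.character(edges[[1]]), to = as.character(edges[[2]])) |>
    filter(.data$from != .data$to,
           .data$from %in% nodes, .data$to %in% nodes) |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    distinct(.data$a, .data$b)
  deg <- table(factor(c(e$a, e$b), levels = sort(unique(nodes))))
  tibble(node = names(deg), degree = as.integer(deg)) |>
    arrange(desc(.data$degree), .data$node)
}

#' Lipid class totals per sample, split by ionization mode
#'
#' Sums species abundances within each annotated class per sample. Classes
#' outside the nine tracked ones (PC, PE, PG, PE-P, SM, Cer, HexCer, TG,
#' LPC) are binned to `"other"` with a warning. Totals conserve mass: summed
#' over classes (including `"other"`) they equal the per-sample column sums.
#'
#' @param data lipid tibble with `species`, `class`, `mode` and sample
#'   columns.
#' @return Long tibble `class`, `mode`, `sample`, `total`.
#' @export
lipid_class_totals <- function(data) {
  check_columns(data, c("species", "class", "mode"), "`data`")
  cls <- data$class
  unknown <- setdiff(unique(cls), .evm_lipid_classes)
  if (length(unknown) > 0) {
    warn(sprintf("unknown lipid class(es) binned to \"other\": %s",
                 paste(unknown, collapse = ", ")))
    cls[cls %in% unknown] <- "other"
  }
  samples <- setdiff(names(data), c("species", "class", "mode", "detected"))
  data |>
    mutate(class = cls) |>
    pivot_longer(all_of(samples), names_to = "sample", values_to = "value") |>
    group_by(.data$class, .data$mode, .data$sample) |>
    summarise(total = sum(.data$value), .groups = "drop")
}
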