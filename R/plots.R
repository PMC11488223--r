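# ggplot2 visualisations of the result objects.

#' Plot well scores in PC space
#' @param object an `evm_pca` object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot evm_pca
#' @export
autoplot.evm_pca <- function(object, ...) {
  df <- object$scores
  ve <- object$variance_explained
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$group)) +
    geom_point(size = 2.5, alpha = 0.85) +
    labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
         y = sprintf("PC2 (%.1f%%)", ve[2]),
         colour = "group",
         title = "Composite morphology score") +
    theme_minimal()
}

#' Volcano plot of a moderated differential-abundance result
#' @param object an `evm_moderated_de` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot evm_moderated_de
#' @export
autoplot.evm_moderated_de <- function(object, ...) {
  fc <- attr(object, "fc_threshold")
  alpha <- attr(object, "alpha")
  ggplot(object, aes(x = .data$log2_fc, y = -log10(.data$p_value),
                     colour = .data$direction)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_vline(xintercept = c(-log2(fc), log2(fc)), linetype = "dashed") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                   ns = "grey60")) +
    labs(x = "log2 fold change", y = "-log10 p",
         title = "Differential protein abundance") +
    theme_minimal()
}

#' Dose-response plot of normalized composite scores
#' @param object an `evm_dose` object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot evm_dose
#' @export
autoplot.evm_dose <- function(object, ...) {
  ggplot(object$per_dose, aes(x = .data$dose, y = .data$mean)) +
    geom_pointrange(aes(ymin = .data$mean - .data$sd,
                        ymax = .data$mean + .data$sd)) +
    geom_line() +
    labs(x = "dose", y = "normalized composite score",
         subtitle = sprintf("Spearman rho = %.2f, permutation p = %.3g",
                            object$spearman_rho, object$p_value)) +
    theme_minimal()
}

#' Heatmap of gene-set enrichment scores
#' @param object an `evm_gsva` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot evm_gsva
#' @export
autoplot.evm_gsva <- function(object, ...) {
  long <- as_tibble(object) |>
    pivot_longer(-"set", names_to = "sample", values_to = "es")
  ggplot(long, aes(x = .data$sample, y = .data$set, fill = .data$es)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", high = "#b2182b", limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "ES",
         title = "Gene set variation analysis") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
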