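# broom-style tidiers for the fitted result objects.

#' Tidy a composite PCA score
#' @param x an `evm_pca` object.
#' @param ... unused.
#' @return Tibble of feature loadings per component.
#' @method tidy evm_pca
#' @export
tidy.evm_pca <- function(x, ...) {
  x$loadings |>
    pivot_longer(-"feature", names_to = "component", values_to = "loading")
}

#' One-row summary of a composite PCA score
#' @param x an `evm_pca` object.
#' @param ... unused.
#' @method glance evm_pca
#' @export
glance.evm_pca <- function(x, ...) {
  tibble(n_wells = nrow(x$scores), n_features = length(x$features),
         pc1_variance_pct = x$variance_explained[1],
         pc2_variance_pct = if (length(x$variance_explained) > 1)
           x$variance_explained[2] else NA_real_,
         orientation_sign = x$orientation_sign,
         standardized = x$standardize)
}

#' Tidy a Z'-factor result
#' @param x an `evm_zfactor` object.
#' @param ... unused.
#' @method tidy evm_zfactor
#' @export
tidy.evm_zfactor <- function(x, ...) {
  tibble(mu_neg = x$mu_neg, mu_pos = x$mu_pos,
         sigma_neg = x$sigma_neg, sigma_pos = x$sigma_pos,
         z_factor = x$z_factor, quality_label = x$quality_label)
}

#' @rdname tidy.evm_zfactor
#' @method glance evm_zfactor
#' @export
glance.evm_zfactor <- function(x, ...) tidy(x)

#' Tidy a dose-response summary
#' @param x an `evm_dose` object.
#' @param ... unused.
#' @return The per-dose tibble.
#' @method tidy evm_dose
#' @export
tidy.evm_dose <- function(x, ...) x$per_dose

#' One-row summary of a dose-response trend
#' @param x an `evm_dose` object.
#' @param ... unused.
#' @method glance evm_dose
#' @export
glance.evm_dose <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho, p_value = x$p_value,
         n_perm = x$n_perm, n_doses = nrow(x$per_dose))
}

#' One-row summary of a moderated differential-abundance fit
#' @param x an `evm_moderated_de` tibble.
#' @param ... unused.
#' @method glance evm_moderated_de
#' @export
glance.evm_moderated_de <- function(x, ...) {
  counts <- volcano_classify(x)
  tibble(n_proteins = nrow(x),
         df_prior = attr(x, "df_prior"),
         s2_prior = attr(x, "s2_prior"),
         n_up = counts$n_up, n_down = counts$n_down, n_ns = counts$n_ns)
}
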