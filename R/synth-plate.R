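# Plate layout and the image-free single-cell feature sampler.

#' Generate a plate layout
#'
#' One plate per experiment x operator combination; within a plate each group
#' receives `n_wells_per_group` wells (the `POS_EV` group is replicated once
#' per entry of `ev_doses`). Wells are laid out row-major on a 12-column
#' grid. Stimulated groups carry the cytokine dose; only `POS_EV` wells carry
#' a non-zero EV dose.
#'
#' @param config an [plate_config()] object.
#' @return Tibble with columns `well_id`, `row`, `col`, `group`,
#'   `cytokine_dose_ng_ml`, `ev_dose`, `operator`, `experiment`.
#' @export
gen_plate_layout <- function(config) {
  stopifnot(inherits(config, "evm_plate_config"))
  plates <- expand.grid(operator = config$operators,
                        experiment = config$experiments,
                        stringsAsFactors = FALSE)
  conditions <- bind_rows(lapply(config$groups, function(g) {
    if (g == "POS_EV") {
      tibble(group = g, ev_dose = config$ev_doses)
    } else {
      tibble(group = g, ev_dose = 0)
    }
  }))
  out <- vector("list", nrow(plates))
  for (p in seq_len(nrow(plates))) {
    wells <- conditions[rep(seq_len(nrow(conditions)),
                            each = config$n_wells_per_group), ]
    n <- nrow(wells)
    wells$row <- LETTERS[((seq_len(n) - 1) %/% 12) + 1]
    wells$col <- ((seq_len(n) - 1) %% 12) + 1L
    wells$operator <- plates$operator[p]
    wells$experiment <- plates$experiment[p]
    wells$cytokine_dose_ng_ml <- ifelse(wells$group == "NEG_CTL", 0,
                                        config$cytokine_dose_ng_ml)
    wells$well_id <- sprintf("%s_%s_%s%02d", wells$experiment, wells$operator,
                             wells$row, wells$col)
    out[[p]] <- wells
  }
  bind_rows(out) |>
    select("well_id", "row", "col", "group", "cytokine_dose_ng_ml",
           "ev_dose", "operator", "experiment") |>
    as_tibble()
}

# Maps latent shape parameters (means) to expected values of the canonical
# descriptor set, using an ellipse body plus tapered protrusions. The nucleus
# is a scaled copy of the body ellipse (as in the renderer), so its aspect
# ratio tracks the body elongation.
latent_feature_means <- function(lat, nucleus_ratio = 0.4) {
  r <- lat[["radius"]]; e <- lat[["elongation"]]
  k <- lat[["n_protrusions"]]; L <- lat[["protrusion_len"]]
  nucleus_aspect <- e
  a <- r * sqrt(e); b <- r / sqrt(e)
  prot_w <- max(2, r / 6)
  ell_perim <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  cell_area <- pi * a * b + k * L * prot_w * 0.6
  cell_perim <- ell_perim(a, b) + k * 2 * L * 0.95
  major <- 2 * a + 0.35 * L * min(k, 2)
  minor <- 2 * b + 0.10 * L * min(k, 2)
  nuc_area <- nucleus_ratio * cell_area
  a_n <- sqrt(nuc_area * nucleus_aspect / pi); b_n <- a_n / nucleus_aspect
  nuc_perim <- ell_perim(a_n, b_n)
  cyt_area <- cell_area - nuc_area
  cyt_perim <- cell_perim + nuc_perim
  # second-moment mixing for the annular cytoplasm axes
  l1 <- ((major / 4)^2 * cell_area - (2 * a_n / 4)^2 * nuc_area) / cyt_area
  l2 <- ((minor / 4)^2 * cell_area - (2 * b_n / 4)^2 * nuc_area) / cyt_area
  cyt_major <- 4 * sqrt(max(l1, 1e-6)); cyt_minor <- 4 * sqrt(max(l2, 1e-6))
  c(Cell_Area = cell_area, Cell_Perimeter = cell_perim,
    Cell_MajorAxisLength = major, Cell_MinorAxisLength = minor,
    Cell_FormFactor = form_factor(cell_area, cell_perim),
    Cell_AspectRatio = major / minor,
    Cell_PerimeterAreaRatio = cell_perim / cell_area,
    Nucleus_Area = nuc_area, Nucleus_Perimeter = nuc_perim,
    Nucleus_MajorAxisLength = 2 * a_n, Nucleus_MinorAxisLength = 2 * b_n,
    Nucleus_FormFactor = form_factor(nuc_area, nuc_perim),
    Nucleus_AspectRatio = nucleus_aspect,
    Nucleus_PerimeterAreaRatio = nuc_perim / nuc_area,
    Cytoplasm_Area = cyt_area, Cytoplasm_Perimeter = cyt_perim,
    Cytoplasm_MajorAxisLength = cyt_major, Cytoplasm_MinorAxisLength = cyt_minor,
    Cytoplasm_FormFactor = form_factor(cyt_area, cyt_perim),
    Cytoplasm_AspectRatio = cyt_major / cyt_minor,
    Cytoplasm_PerimeterAreaRatio = cyt_perim / cyt_area)
}

# scaling exponents of each canonical feature under an isotropic size factor
feature_size_exponents <- function() {
  per_comp <- c(Area = 2, Perimeter = 1, MajorAxisLength = 1,
                MinorAxisLength = 1, FormFactor = 0, AspectRatio = 0,
                PerimeterAreaRatio = -1)
  feats <- canonical_features()
  vapply(feats, function(f) per_comp[[sub("^[^_]+_", "", f)]], numeric(1))
}

#' Sample a single-cell feature table without rendering images
#'
#' Fast path for scoring studies: draws per-cell descriptor values directly
#' from group-conditional distributions whose well-level medians match the
#' renderer's marginal statistics. Group mean vectors for `POS_EV` wells are
#' the `POS_CTL` vector interpolated toward `NEG_CTL` by the realised EV
#' effect (`ev_effect * dose / max(dose)`), so the treatment effect is linear
#' on the feature scale by construction. Operator, experiment and well random
#' effects enter as additive shifts in units of the per-feature control gap,
#' identical for all groups of a plate. Per-cell variation is a shared
#' lognormal size factor (feature-specific exponents) times independent
#' lognormal jitter, both median-one so well medians are centred on the well
#' mean vector.
#'
#' `Cell_Solidity` is derived from a per-cell protrusion draw (cells that
#' draw zero protrusions get solidity exactly 1, emulating round debris that
#' the QC stage rejects), `NucleusCellAreaRatio` from a Beta(8, 12) clipped
#' to (0.1, 0.8), and `Cell_Eccentricity` from the drawn aspect ratio.
#'
#' @param config an [plate_config()] object.
#' @return Tibble of cell records (identifiers + features). Attributes:
#'   `"layout"` (the plate layout) and `"ground_truth"` (list with the group
#'   feature mean vectors, per-well mean vectors and batch effects, and the
#'   realised EV effect per well).
#' @export
gen_feature_table <- function(config) {
  stopifnot(inherits(config, "evm_plate_config"))
  layout <- gen_plate_layout(config)
  feats <- canonical_features()
  m_neg <- latent_feature_means(group_latents(config, "NEG_CTL")$mean)[feats]
  m_pos <- latent_feature_means(group_latents(config, "POS_CTL")$mean)[feats]
  gap <- m_pos - m_neg
  expo <- feature_size_exponents()
  max_dose <- max(config$ev_doses)
  with_seed(config$seed, {
    op_eff <- setNames(rnorm(length(config$operators), 0, config$operator_shift),
                       config$operators)
    ex_eff <- setNames(rnorm(length(config$experiments), 0, config$experiment_shift),
                       config$experiments)
    n_wells <- nrow(layout)
    well_eta <- rnorm(n_wells, 0, config$well_sd)
    delta_well <- ifelse(layout$group == "POS_EV",
                         config$ev_effect * layout$ev_dose / max_dose, 0)
    rng <- config$cells_per_well_range
    n_cells <- if (rng[1] == rng[2]) rep(rng[1], n_wells) else
      sample(seq(rng[1], rng[2]), n_wells, replace = TRUE)
    # per-well mean vectors (wells x features)
    base <- matrix(rep(m_pos, each = n_wells), n_wells)
    neg_rows <- layout$group == "NEG_CTL"
    base[neg_rows, ] <- matrix(rep(m_neg, each = sum(neg_rows)), sum(neg_rows))
    ev_rows <- layout$group == "POS_EV"
    if (any(ev_rows)) {
      base[ev_rows, ] <- matrix(rep(m_pos, each = sum(ev_rows)), sum(ev_rows)) +
        delta_well[ev_rows] %o% (m_neg - m_pos)
    }
    eta <- well_eta + op_eff[layout$operator] + ex_eff[layout$experiment]
    m_well <- base + eta %o% gap
    m_well <- pmax(m_well, 0.05 * base)
    colnames(m_well) <- feats

    total <- sum(n_cells)
    widx <- rep(seq_len(n_wells), n_cells)
    size <- exp(rnorm(total, 0, config$size_sd))
    X <- m_well[widx, , drop = FALSE] *
      exp(log(size) %o% expo) *
      matrix(exp(rnorm(total * length(feats), 0, config$noise_sd)), total)
    # QC-side features from a per-cell protrusion draw
    k_mean <- pmax(vapply(seq_len(n_wells), function(w) {
      g <- layout$group[w]
      group_latents(config, g, delta = delta_well[w])$mean[["n_protrusions"]]
    }, numeric(1)), 0.05)
    L_lat <- vapply(seq_len(n_wells), function(w) {
      g <- layout$group[w]
      group_latents(config, g, delta = delta_well[w])$mean[["protrusion_len"]]
    }, numeric(1))
    k <- rpois(total, k_mean[widx])
    L <- pmax(rnorm(total, L_lat[widx], 2), 0)
    solidity <- ifelse(k == 0, 1,
                       pmin(X[, "Cell_Area"] /
                              (X[, "Cell_Area"] + 0.25 * k * L^2), 1))
    ar <- pmax(X[, "Cell_AspectRatio"], 1)
    ecc <- sqrt(1 - 1 / ar^2)
    ratio <- pmin(pmax(rbeta(total, 8, 12), 0.1), 0.8)
    out <- as_tibble(X)
    out <- bind_cols(
      tibble(experiment = layout$experiment[widx],
             operator = layout$operator[widx],
             well_id = layout$well_id[widx],
             image_id = "IMG01",
             cell_id = sequence(n_cells)),
      out)
    out$Cell_Solidity <- solidity
    out$Cell_Eccentricity <- ecc
    out$NucleusCellAreaRatio <- ratio
    attr(out, "layout") <- layout
    attr(out, "ground_truth") <- list(
      group_feature_means = list(NEG_CTL = m_neg, POS_CTL = m_pos),
      well_means = m_well, well_eta = eta, delta_well = delta_well,
      ev_effect = config$ev_effect,
      operator_effects = op_eff, experiment_effects = ex_eff)
    out
  })
}
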