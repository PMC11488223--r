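# Configuration objects for the synthetic-data generators. The defaults are
# the assay's study conditions: 8 technical replicate wells per group,
# ~700-1000 cells per well, unstimulated cells small and round, stimulated
# cells large/elongated/ramified, EV treatment recovering a configurable
# fraction of the morphology gap.

default_morph_params <- function() {
  list(
    NEG_CTL = list(radius = c(18, 2.5), elongation = c(1.25, 0.12),
                   n_protrusions = c(2, 1), protrusion_len = c(8, 3)),
    POS_CTL = list(radius = c(27, 3.5), elongation = c(2.1, 0.25),
                   n_protrusions = c(5, 1.5), protrusion_len = c(22, 6))
  )
}

#' Synthetic plate configuration
#'
#' Bundles and validates every knob of the synthetic morphology plate:
#' group layout, per-group latent shape parameters (body radius, elongation
#' ratio, protrusion count and length, each mean + sd), the EV effect
#' (fraction of the stimulated-to-unstimulated morphology gap recovered under
#' treatment), batch structure (operators, experiments) and noise levels.
#'
#' Noise defaults are calibrated to the assay's design: a well-level random
#' effect of 0.04 of the control gap per feature (comfortably inside the
#' sigma <= gap/12 regime an optimized screening assay requires), per-cell
#' lognormal size dispersion 0.25 and per-feature jitter 0.10.
#'
#' @param n_wells_per_group wells per experimental group per plate (>= 2).
#' @param groups subset of `NEG_CTL` (unstimulated), `POS_CTL`
#'   (cytokine-stimulated), `POS_EV` (stimulated + EV-treated).
#' @param cells_per_well_range integer pair, cells simulated per well.
#' @param morph_params per-group latent shape parameter list (see
#'   `default_morph_params()`); `POS_EV` is derived by interpolation.
#' @param ev_effect fraction in `[0, 1]` of the POS_CTL to NEG_CTL gap
#'   recovered under EV treatment.
#' @param ev_doses numeric vector of relative EV doses; `POS_EV` wells are
#'   replicated per dose and the realised effect scales as `dose / max(dose)`.
#' @param cytokine_dose_ng_ml cytokine dose applied to stimulated wells.
#' @param operators,experiments label vectors; one plate is generated per
#'   experiment x operator combination.
#' @param operator_shift,experiment_shift sd of the additive batch
#'   perturbations, in units of the per-feature control gap.
#' @param well_sd sd of the well-level random effect, same units.
#' @param size_sd per-cell lognormal size-factor sd.
#' @param noise_sd per-feature multiplicative jitter sd (image-free sampler)
#'   and background intensity noise sd (renderer).
#' @param image_size canvas side in pixels for rendered wells.
#' @param min_cells_per_well retained for downstream stages.
#' @param seed integer RNG seed; identical config + seed reproduces every
#'   artifact byte-for-byte.
#' @return An `evm_plate_config` list.
#' @export
plate_config <- function(n_wells_per_group = 8,
                         groups = c("NEG_CTL", "POS_CTL", "POS_EV"),
                         cells_per_well_range = c(700, 1000),
                         morph_params = default_morph_params(),
                         ev_effect = 0.5,
                         ev_doses = 1,
                         cytokine_dose_ng_ml = 5,
                         operators = "O1",
                         experiments = "E1",
                         operator_shift = 0.10,
                         experiment_shift = 0.10,
                         well_sd = 0.04,
                         size_sd = 0.25,
                         noise_sd = 0.10,
                         image_size = 512,
                         min_cells_per_well = 50,
                         seed = 1) {
  unknown <- setdiff(groups, .evm_groups)
  if (length(unknown) > 0) {
    evm_abort(sprintf("unknown group label(s): %s (expected %s)",
                      paste(unknown, collapse = ", "),
                      paste(.evm_groups, collapse = ", ")),
              "evmorph_config_error")
  }
  if (length(groups) == 0 || anyDuplicated(groups) > 0) {
    evm_abort("`groups` must be a non-empty set of distinct labels",
              "evmorph_config_error")
  }
  if (n_wells_per_group < 2) {
    evm_abort("`n_wells_per_group` must be >= 2", "evmorph_config_error")
  }
  if (length(cells_per_well_range) != 2 || any(cells_per_well_range <= 0) ||
      diff(cells_per_well_range) < 0) {
    evm_abort("`cells_per_well_range` must be a positive ordered pair",
              "evmorph_config_error")
  }
  if (ev_effect < 0 || ev_effect > 1) {
    evm_abort("`ev_effect` must lie in [0, 1]", "evmorph_config_error")
  }
  if (any(ev_doses < 0) || length(ev_doses) == 0) {
    evm_abort("`ev_doses` must be non-negative", "evmorph_config_error")
  }
  for (g in c("NEG_CTL", "POS_CTL")) {
    p <- morph_params[[g]]
    if (is.null(p) || !all(c("radius", "elongation", "n_protrusions",
                             "protrusion_len") %in% names(p))) {
      evm_abort(sprintf("`morph_params` must define %s with radius, elongation, n_protrusions, protrusion_len", g),
                "evmorph_config_error")
    }
  }
  structure(
    list(n_wells_per_group = as.integer(n_wells_per_group), groups = groups,
         cells_per_well_range = as.integer(cells_per_well_range),
         morph_params = morph_params, ev_effect = ev_effect,
         ev_doses = ev_doses, cytokine_dose_ng_ml = cytokine_dose_ng_ml,
         operators = operators, experiments = experiments,
         operator_shift = operator_shift, experiment_shift = experiment_shift,
         well_sd = well_sd, size_sd = size_sd, noise_sd = noise_sd,
         image_size = as.integer(image_size),
         min_cells_per_well = as.integer(min_cells_per_well),
         seed = as.integer(seed)),
    class = "evm_plate_config"
  )
}

# latent means for a group, with the EV group interpolated toward NEG_CTL
group_latents <- function(config, group, delta = config$ev_effect) {
  mp <- config$morph_params
  get_means <- function(g) vapply(mp[[g]], `[`, numeric(1), 1)
  get_sds <- function(g) vapply(mp[[g]], `[`, numeric(1), 2)
  if (group == "POS_EV") {
    m <- get_means("POS_CTL") + delta * (get_means("NEG_CTL") - get_means("POS_CTL"))
    s <- get_sds("POS_CTL") + delta * (get_sds("NEG_CTL") - get_sds("POS_CTL"))
  } else {
    m <- get_means(group); s <- get_sds(group)
  }
  list(mean = m, sd = s)
}
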