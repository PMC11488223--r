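# Run configuration and the end-to-end pipeline tying the stages together.

run_config_defaults <- function() {
  list(
    stages = c("simulate", "features", "qc", "score", "secretome",
               "lipidome", "proteome"),
    seed = 1,
    out_dir = "evmorph_run",
    features_path = NULL, layout_path = NULL,
    min_cells = 50, alpha = 0.05, fc_threshold = 2,
    correct = FALSE, standardize = FALSE,
    plate = list(), omics = list()
  )
}

#' Build and validate a run configuration
#'
#' Collects every pipeline parameter (stage selection, cut-offs, seeds,
#' paths, generator settings) into a validated list. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param ... configuration entries overriding the defaults; `plate` and
#'   `omics` are argument lists forwarded to [plate_config()] and
#'   [omics_config()].
#' @param file optional YAML file whose entries are applied before `...`.
#' @return An `evm_run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- run_config_defaults()
  updates <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      evm_abort(sprintf("config file not found: %s", file),
                "evmorph_missing_file")
    }
    updates <- yaml::read_yaml(file)
  }
  updates <- modifyList(updates, list(...))
  unknown <- setdiff(names(updates), names(cfg))
  if (length(unknown) > 0) {
    evm_abort(sprintf("unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")),
              "evmorph_config_error")
  }
  cfg <- modifyList(cfg, updates)
  bad <- setdiff(cfg$stages, run_config_defaults()$stages)
  if (length(bad) > 0) {
    evm_abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
              "evmorph_config_error")
  }
  structure(cfg, class = "evm_run_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — simulate (or load) single-cell
#' features, QC, well scoring, and the secretome / lipidome / proteome
#' stages — writing every artifact under one directory together with a
#' manifest (configuration echo, seed, package and R versions) so a run can
#' be audited and reproduced. All randomness derives from `config$seed`;
#' identical configurations produce byte-identical outputs.
#'
#' @param config an [run_config()] object.
#' @return The output directory path, invisibly; artifacts as side effects.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "evm_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) name %in% config$stages

  if (stage("simulate")) {
    pc <- do.call(plate_config, modifyList(list(seed = config$seed),
                                           config$plate))
    cells <- gen_feature_table(pc)
    layout <- attr(cells, "layout")
    write_table_file(layout, file.path(config$out_dir, "layout.csv"))
    write_table_file(cells, file.path(config$out_dir, "features.csv"))
  } else {
    for (p in c(config$features_path, config$layout_path)) {
      if (is.null(p) || !file.exists(p)) {
        evm_abort(sprintf("required input file missing: %s",
                          if (is.null(p)) "(unset path)" else p),
                  "evmorph_missing_file")
      }
    }
    cells <- read_table_file(config$features_path)
    layout <- read_table_file(config$layout_path)
  }

  if (stage("qc")) {
    qc <- qc_filter(cells)
    write_table_file(qc$rejected, file.path(config$out_dir, "qc_rejected.csv"))
    cells <- qc$kept
  }

  if (stage("score")) {
    profiles <- aggregate_well_medians(cells, layout,
                                       min_cells = config$min_cells)
    normed <- minmax_normalize(profiles, features = canonical_features())
    pca <- composite_pca_score(normed, features = canonical_features(),
                               standardize = config$standardize)
    scores <- anchor_scores(pca$scores)
    zf <- z_factor(scores, score_col = "score_norm")
    write_table_file(scores, file.path(config$out_dir, "scores.csv"))
    jsonlite::write_json(
      list(variance_explained = pca$variance_explained,
           orientation_sign = pca$orientation_sign,
           loadings = pca$loadings,
           z_factor = unclass(zf)),
      file.path(config$out_dir, "scoring.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  omics <- NULL
  need_omics <- any(vapply(c("secretome", "lipidome", "proteome"), stage,
                           logical(1)))
  if (need_omics) {
    oc <- do.call(omics_config, modifyList(list(seed = config$seed),
                                           config$omics))
    omics <- gen_omics_tables(oc)
  }
  if (stage("secretome")) {
    de <- differential_panel(omics$secretion, omics$secretion_groups,
                             "NEG_CTL", "POS_CTL", alpha = config$alpha,
                             correct = config$correct)
    write_table_file(de, file.path(config$out_dir, "secretome_differential.csv"))
  }
  if (stage("lipidome")) {
    totals <- lipid_class_totals(omics$lipids)
    write_table_file(totals, file.path(config$out_dir, "lipid_class_totals.csv"))
  }
  if (stage("proteome")) {
    de <- moderated_de(omics$proteins, omics$protein_groups,
                       contrast = c("POS_CTL", "POS_EV"),
                       fc_threshold = config$fc_threshold,
                       alpha = config$alpha)
    write_table_file(as_tibble(de), file.path(config$out_dir, "proteome_de.csv"))
    es <- gsva_scores(omics$proteins, omics$gene_sets)
    write_table_file(as_tibble(es), file.path(config$out_dir, "gsva_scores.csv"))
    stats <- gene_set_anova(es, omics$protein_groups) |>
      select(-"tukey")
    write_table_file(stats, file.path(config$out_dir, "gsva_stats.csv"))
  }

  echo <- unclass(config)
  echo$out_dir <- NULL # run-local path, not part of the scientific config
  manifest <- list(
    package = "evmorph",
    package_version = as.character(utils::packageVersion("evmorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    config = echo)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
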