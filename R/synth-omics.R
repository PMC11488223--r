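# Synthetic omics tables: a 200-analyte secretion panel, a lipid species
# table with class/ionization-mode annotations, a protein abundance matrix
# with group-structured differential abundance, and gene-set collections.
# Abundances are log-normal with effects additive on the log2 scale, so
# fold-change ground truth is exact.

#' Synthetic omics configuration
#'
#' Defaults emulate the study's reported panel structure: 200 secreted
#' analytes of which 94 are detected, 40 analytes differential between the
#' unstimulated and stimulated controls (38 up / 2 down) and 24 between the
#' stimulated and EV-treated groups (10 up / 14 down); 2662 proteins with a
#' 687-protein differentially abundant subset (258 up / 429 down in the EV
#' group vs the stimulated control); nine lipid classes whose totals all rise
#' under stimulation except LPC.
#'
#' @param n_analytes,n_detected secretion panel size and detected subset.
#' @param stim_up,stim_down,ev_up,ev_down differential secretion counts.
#' @param secretion_effect_log2 absolute log2 effect of differential analytes.
#' @param secretion_sd_log2 within-group log2 sd of analyte abundances.
#' @param secretion_n,protein_n,lipid_n samples per group per assay.
#' @param n_proteins,dap_up,dap_down protein panel size and EV-vs-stimulated
#'   differential counts; `stim_protein_n` proteins also shift on stimulation.
#' @param protein_effect_range absolute log2 effect range for differential
#'   proteins (uniform draw).
#' @param protein_sd_log2 within-group log2 sd of protein abundances.
#' @param species_per_class lipid species per class.
#' @param lipid_stim_log2 log2 shift of lipid species on stimulation (applied
#'   to every class except LPC, whose shift is exactly 0).
#' @param lipid_sd_log2 within-group log2 sd of lipid abundances.
#' @param n_gene_sets,set_size_range gene-set collection shape.
#' @param seed integer RNG seed.
#' @return An `evm_omics_config` list.
#' @export
omics_config <- function(n_analytes = 200, n_detected = 94,
                         stim_up = 38, stim_down = 2,
                         ev_up = 10, ev_down = 14,
                         secretion_effect_log2 = 2,
                         secretion_sd_log2 = 0.5,
                         secretion_n = 6,
                         n_proteins = 2662, dap_up = 258, dap_down = 429,
                         stim_protein_n = 300,
                         protein_effect_range = c(1.2, 3),
                         protein_sd_log2 = 0.3,
                         protein_n = 4,
                         species_per_class = 8,
                         lipid_stim_log2 = 0.8,
                         lipid_sd_log2 = 0.4,
                         lipid_n = 4,
                         n_gene_sets = 25,
                         set_size_range = c(8, 40),
                         seed = 1) {
  if (stim_up + stim_down + ev_up + ev_down > n_detected) {
    evm_abort("differential analyte counts exceed the detected panel",
              "evmorph_config_error")
  }
  if (n_detected > n_analytes) {
    evm_abort("`n_detected` exceeds `n_analytes`", "evmorph_config_error")
  }
  if (dap_up + dap_down > n_proteins) {
    evm_abort("differential protein counts exceed the panel",
              "evmorph_config_error")
  }
  structure(as.list(environment()), class = "evm_omics_config")
}

sample_names <- function(prefix, groups, n) {
  unlist(lapply(groups, function(g) sprintf("%s_%s_S%d", prefix, g, seq_len(n))))
}

#' Generate synthetic secretion, lipid and protein tables with ground truth
#'
#' @param config an [omics_config()] object.
#' @return List with elements `secretion` (tibble, `analyte` + sample
#'   columns, raw abundances), `secretion_groups`, `lipids` (tibble,
#'   `species`, `class`, `mode` + sample columns), `lipid_groups`, `proteins`
#'   (tibble, `protein` + sample columns, log2 scale), `protein_groups`,
#'   `gene_sets` (named list of protein-id vectors) and `ground_truth`
#'   (per-table tibbles of true effects; analytes/proteins not flagged
#'   differential have exactly zero generated effect).
#' @export
gen_omics_tables <- function(config = omics_config()) {
  stopifnot(inherits(config, "evm_omics_config"))
  groups <- .evm_groups
  with_seed(config$seed, {
    ## --- secretion panel -------------------------------------------------
    analytes <- sprintf("CK%03d", seq_len(config$n_analytes))
    detected <- c(rep(TRUE, config$n_detected),
                  rep(FALSE, config$n_analytes - config$n_detected))
    idx <- seq_len(config$n_detected)
    n_diff <- config$stim_up + config$stim_down + config$ev_up + config$ev_down
    diff_idx <- idx[seq_len(n_diff)]
    stim_fc <- rep(0, config$n_analytes)
    ev_fc <- rep(0, config$n_analytes)
    pos <- 1
    take <- function(n) { out <- diff_idx[pos:(pos + n - 1)]; pos <<- pos + n; out }
    if (config$stim_up > 0) stim_fc[take(config$stim_up)] <- config$secretion_effect_log2
    if (config$stim_down > 0) stim_fc[take(config$stim_down)] <- -config$secretion_effect_log2
    if (config$ev_up > 0) ev_fc[take(config$ev_up)] <- config$secretion_effect_log2
    if (config$ev_down > 0) ev_fc[take(config$ev_down)] <- -config$secretion_effect_log2
    base <- ifelse(detected, rnorm(config$n_analytes, 10, 1.5),
                   rnorm(config$n_analytes, 2, 0.5))
    sec_samples <- sample_names("SEC", groups, config$secretion_n)
    sec_groups <- tibble(sample = sec_samples,
                         group = rep(groups, each = config$secretion_n))
    mean_log2 <- cbind(NEG_CTL = base,
                       POS_CTL = base + stim_fc,
                       POS_EV = base + stim_fc + ev_fc)
    sec <- matrix(0, config$n_analytes, length(sec_samples),
                  dimnames = list(analytes, sec_samples))
    for (j in seq_along(sec_samples)) {
      g <- sec_groups$group[j]
      sec[, j] <- 2^(mean_log2[, g] +
                       rnorm(config$n_analytes, 0, config$secretion_sd_log2))
    }
    secretion <- bind_cols(tibble(analyte = analytes), as_tibble(sec))

    ## --- lipid species table ---------------------------------------------
    neg_mode <- c("PE", "PG", "PE-P", "Cer", "HexCer")
    classes <- .evm_lipid_classes
    lip <- expand.grid(i = seq_len(config$species_per_class), class = classes,
                       stringsAsFactors = FALSE)
    lip$species <- sprintf("%s(%d:%d)", lip$class, 30 + lip$i, lip$i %% 5)
    lip$mode <- ifelse(lip$class %in% neg_mode, "negative", "positive")
    lip_stim <- ifelse(lip$class == "LPC", 0, config$lipid_stim_log2)
    lip_base <- rnorm(nrow(lip), 12, 1)
    lip_samples <- sample_names("LIP", groups, config$lipid_n)
    lip_groups <- tibble(sample = lip_samples,
                         group = rep(groups, each = config$lipid_n))
    lmat <- matrix(0, nrow(lip), length(lip_samples),
                   dimnames = list(lip$species, lip_samples))
    for (j in seq_along(lip_samples)) {
      g <- lip_groups$group[j]
      eff <- if (g == "NEG_CTL") 0 else lip_stim # EV group stays stimulated-like
      lmat[, j] <- 2^(lip_base + eff + rnorm(nrow(lip), 0, config$lipid_sd_log2))
    }
    lipids <- bind_cols(tibble(species = lip$species, class = lip$class,
                               mode = lip$mode), as_tibble(lmat))

    ## --- protein matrix (log2 scale) --------------------------------------
    prots <- sprintf("P%04d", seq_len(config$n_proteins))
    p_stim <- rep(0, config$n_proteins)
    p_ev <- rep(0, config$n_proteins)
    n_dap <- config$dap_up + config$dap_down
    dap_ids <- seq_len(n_dap)
    mag <- runif(n_dap, config$protein_effect_range[1], config$protein_effect_range[2])
    p_ev[dap_ids] <- mag * rep(c(1, -1), c(config$dap_up, config$dap_down))
    stim_ids <- seq(n_dap + 1, length.out = min(config$stim_protein_n,
                                                config$n_proteins - n_dap))
    p_stim[stim_ids] <- runif(length(stim_ids), 1, 2.5) *
      sample(c(-1, 1), length(stim_ids), replace = TRUE)
    p_base <- rnorm(config$n_proteins, 20, 2)
    prot_samples <- sample_names("PRO", groups, config$protein_n)
    prot_groups <- tibble(sample = prot_samples,
                          group = rep(groups, each = config$protein_n))
    pmean <- cbind(NEG_CTL = p_base,
                   POS_CTL = p_base + p_stim,
                   POS_EV = p_base + p_stim + p_ev)
    pmat <- matrix(0, config$n_proteins, length(prot_samples),
                   dimnames = list(prots, prot_samples))
    for (j in seq_along(prot_samples)) {
      g <- prot_groups$group[j]
      pmat[, j] <- pmean[, g] + rnorm(config$n_proteins, 0, config$protein_sd_log2)
    }
    proteins <- bind_cols(tibble(protein = prots), as_tibble(pmat))

    ## --- gene sets ---------------------------------------------------------
    gene_sets <- list()
    for (s in seq_len(config$n_gene_sets)) {
      sz <- sample(seq(config$set_size_range[1], config$set_size_range[2]), 1)
      if (s <= 5 && n_dap > 0) {
        # first sets enriched in direction-coherent differential proteins
        pool_ids <- if (s <= 3 && config$dap_up > 0) {
          seq_len(config$dap_up)
        } else {
          seq(config$dap_up + 1, length.out = config$dap_down)
        }
        n_in <- min(ceiling(0.7 * sz), length(pool_ids))
        ids <- c(sample(prots[pool_ids], n_in),
                 sample(prots[-dap_ids], sz - n_in))
      } else {
        ids <- sample(prots, sz)
      }
      gene_sets[[sprintf("SET_%02d", s)]] <- unique(ids)
    }

    list(
      secretion = secretion, secretion_groups = sec_groups,
      lipids = lipids, lipid_groups = lip_groups,
      proteins = proteins, protein_groups = prot_groups,
      gene_sets = gene_sets,
      ground_truth = list(
        secretion = tibble(analyte = analytes, detected = detected,
                           stim_log2fc = stim_fc, ev_log2fc = ev_fc),
        lipids = tibble(class = classes,
                        stim_log2fc = ifelse(classes == "LPC", 0,
                                             config$lipid_stim_log2)),
        proteins = tibble(protein = prots, stim_log2fc = p_stim,
                          ev_log2fc = p_ev,
                          is_dap = seq_along(prots) %in% dap_ids)))
  })
}
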