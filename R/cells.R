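# Per-cell feature extraction from labelled masks, and the single-cell QC
# rules applied before any well-level aggregation.

crop_bbox <- function(mask, pad = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  r <- max(1L, min(idx[, 1]) - pad):min(nrow(mask), max(idx[, 1]) + pad)
  c <- max(1L, min(idx[, 2]) - pad):min(ncol(mask), max(idx[, 2]) + pad)
  list(rows = r, cols = c)
}

#' Extract single-cell morphological (and mitochondrial) features
#'
#' Walks every label of a cell mask, pairs it with its nucleus (by shared
#' label id, falling back to majority containment), and computes the full
#' descriptor set for the `Cell`, `Nucleus` and `Cytoplasm` (cell minus
#' nucleus) compartments, plus `Cell_Solidity`, `Cell_Eccentricity` and
#' `NucleusCellAreaRatio`, and `Mito_*` features when an intensity channel is
#' supplied.
#'
#' Cells touching the image border are excluded (reason `"border"`), nuclei
#' with no enclosing cell are recorded as `"orphan_nucleus"`, and cells
#' without a nucleus as `"no_nucleus"`. The excluded objects are returned in
#' the `"dropped"` attribute of the result as a tibble of `cell_id`, `reason`.
#'
#' @param cell_labels integer matrix of cell labels (0 = background).
#' @param nucleus_labels integer matrix of nucleus labels.
#' @param mito optional numeric matrix, mitochondria channel.
#' @param well_info list or one-row data frame carrying identifier columns
#'   (`experiment`, `operator`, `well_id`, `image_id`); any subset may be
#'   supplied.
#' @return Tibble with one row per retained cell, identifier columns, then
#'   feature columns; attribute `"dropped"` lists excluded objects.
#' @export
extract_single_cell_features <- function(cell_labels, nucleus_labels,
                                         mito = NULL, well_info = list()) {
  if (!all(dim(cell_labels) == dim(nucleus_labels))) {
    evm_abort("cell and nucleus label images have different dimensions",
              "evmorph_dim_mismatch")
  }
  if (!is.null(mito) && !all(dim(mito) == dim(cell_labels))) {
    evm_abort("mito channel dimensions differ from the label images",
              "evmorph_dim_mismatch")
  }
  info <- as.list(well_info)[intersect(names(well_info),
                                       c("experiment", "operator", "well_id", "image_id"))]
  cell_ids <- sort(setdiff(unique(as.vector(cell_labels)), 0))
  nuc_ids <- sort(setdiff(unique(as.vector(nucleus_labels)), 0))
  # nucleus -> cell assignment by majority of overlapped cell pixels
  nuc_owner <- vapply(nuc_ids, function(nid) {
    under <- cell_labels[nucleus_labels == nid]
    under <- under[under != 0]
    if (length(under) == 0) return(0L)
    as.integer(names(which.max(table(under))))
  }, integer(1))
  dropped <- tibble(cell_id = integer(0), reason = character(0))
  for (nid in nuc_ids[nuc_owner == 0]) {
    dropped <- add_row(dropped, cell_id = as.integer(nid), reason = "orphan_nucleus")
  }
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  rows <- list()
  for (cid in cell_ids) {
    cmask <- cell_labels == cid
    idx <- which(cmask, arr.ind = TRUE)
    if (any(idx[, 1] %in% c(1L, nr)) || any(idx[, 2] %in% c(1L, nc))) {
      dropped <- add_row(dropped, cell_id = as.integer(cid), reason = "border")
      next
    }
    my_nucs <- nuc_ids[nuc_owner == cid]
    if (length(my_nucs) == 0) {
      dropped <- add_row(dropped, cell_id = as.integer(cid), reason = "no_nucleus")
      next
    }
    if (length(my_nucs) > 1) { # keep the largest nucleus
      sizes <- vapply(my_nucs, function(n) sum(nucleus_labels == n), numeric(1))
      my_nucs <- my_nucs[which.max(sizes)]
    }
    nmask <- (nucleus_labels == my_nucs) & cmask
    if (!any(nmask)) {
      dropped <- add_row(dropped, cell_id = as.integer(cid), reason = "no_nucleus")
      next
    }
    bb <- crop_bbox(cmask)
    cm <- cmask[bb$rows, bb$cols]
    nm <- nmask[bb$rows, bb$cols]
    rec <- tryCatch({
      f_cell <- compute_shape_descriptors(cm)
      f_nuc <- compute_shape_descriptors(nm)
      cyt <- cm & !nm
      f_cyt <- compute_shape_descriptors(cyt)
      vals <- c(
        setNames(as.list(f_cell[1, 1:7]), paste0("Cell_", names(f_cell)[1:7])),
        setNames(as.list(f_nuc[1, 1:7]), paste0("Nucleus_", names(f_nuc)[1:7])),
        setNames(as.list(f_cyt[1, 1:7]), paste0("Cytoplasm_", names(f_cyt)[1:7])),
        list(Cell_Solidity = f_cell$Solidity,
             Cell_Eccentricity = f_cell$Eccentricity,
             NucleusCellAreaRatio = f_nuc$Area / f_cell$Area)
      )
      if (!is.null(mito)) {
        vals <- c(vals, as.list(compute_mito_features(mito[bb$rows, bb$cols], cm)))
      }
      as_tibble(c(info, list(cell_id = as.integer(cid)), vals))
    }, evmorph_multi_component = function(e) NULL)
    if (is.null(rec)) {
      dropped <- add_row(dropped, cell_id = as.integer(cid),
                         reason = "fragmented_compartment")
      next
    }
    rows[[length(rows) + 1]] <- rec
  }
  out <- if (length(rows) > 0) bind_rows(rows) else tibble()
  attr(out, "dropped") <- dropped
  out
}

#' Single-cell quality-control filter
#'
#' Rejects poorly segmented objects and debris: records with
#' `Cell_Solidity >= 1 - 1e-6` (perfectly convex blobs are debris or failed
#' segmentation of a ramified cell) and/or `NucleusCellAreaRatio >= 0.85`
#' (nucleus filling the cell indicates a segmentation error). Both rules are
#' inclusive at the cutoff and can be toggled independently.
#'
#' @param records tibble of cell records.
#' @param solidity_rule,ratio_rule logical; apply the respective rule.
#' @param solidity_cutoff,ratio_cutoff numeric cutoffs (rejection is
#'   `>= cutoff`).
#' @return List with `kept` and `rejected` tibbles; `rejected` gains a
#'   `qc_reason` column (`"solidity"`, `"nucleus_ratio"`, or both joined by
#'   `";"`). Every input row appears in exactly one of the two tables.
#' @export
qc_filter <- function(records, solidity_rule = TRUE, ratio_rule = TRUE,
                      solidity_cutoff = 1 - 1e-6, ratio_cutoff = 0.85) {
  needed <- c(if (solidity_rule) "Cell_Solidity",
              if (ratio_rule) "NucleusCellAreaRatio")
  check_columns(records, needed, "`records`")
  bad_sol <- if (solidity_rule) records$Cell_Solidity >= solidity_cutoff else
    rep(FALSE, nrow(records))
  bad_rat <- if (ratio_rule) records$NucleusCellAreaRatio >= ratio_cutoff else
    rep(FALSE, nrow(records))
  reject <- bad_sol | bad_rat
  reason <- rep(NA_character_, nrow(records))
  reason[bad_sol & !bad_rat] <- "solidity"
  reason[!bad_sol & bad_rat] <- "nucleus_ratio"
  reason[bad_sol & bad_rat] <- "solidity;nucleus_ratio"
  rejected <- records[reject, , drop = FALSE]
  rejected$qc_reason <- reason[reject]
  list(kept = records[!reject, , drop = FALSE], rejected = rejected)
}
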