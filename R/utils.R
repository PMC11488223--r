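#' Canonical morphological feature names
#'
#' The assay scores wells on 21 cellular and nuclear descriptors: seven shape
#' descriptors (`Area`, `Perimeter`, `MajorAxisLength`, `MinorAxisLength`,
#' `FormFactor`, `AspectRatio`, `PerimeterAreaRatio`) for each of the three
#' compartments `Cell`, `Nucleus` and `Cytoplasm`. `Solidity`, `Eccentricity`
#' and `NucleusCellAreaRatio` travel alongside for quality control but are not
#' part of the composite-score feature set.
#'
#' @param compartments character vector of compartments to include.
#' @return Character vector of feature column names.
#' @export
#' @examples
#' canonical_features()
canonical_features <- function(compartments = c("Cell", "Nucleus", "Cytoplasm")) {
  descriptors <- c("Area", "Perimeter", "MajorAxisLength", "MinorAxisLength",
                   "FormFactor", "AspectRatio", "PerimeterAreaRatio")
  as.character(outer(compartments, descriptors, paste, sep = "_"))
}

#' QC feature names carried on every cell record
#' @return Character vector.
#' @export
qc_features <- function() {
  c("Cell_Solidity", "Cell_Eccentricity", "NucleusCellAreaRatio")
}

# group labels understood by the plate generators and scoring stages
.evm_groups <- c("NEG_CTL", "POS_CTL", "POS_EV")

# the nine lipid classes tracked explicitly; anything else is binned to "other"
.evm_lipid_classes <- c("PC", "PE", "PG", "PE-P", "SM", "Cer", "HexCer", "TG", "LPC")

evm_abort <- function(message, class, ...) {
  abort(message, class = c(class, "evmorph_error"), ...)
}

# checks `df` has the named columns, aborting with the caller-facing op name
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    evm_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "evmorph_missing_column"
    )
  }
  invisible(df)
}

# deterministic child seed derivation, kept within 32-bit integer range
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
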