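# File I/O: delimited tables, GMT gene-set collections and 16-bit label
# masks. Round-trips are exact to numeric precision.

#' Read a delimited table
#'
#' CSV or TSV (chosen by extension), header row, UTF-8, '.' decimal.
#' Malformed rows abort with the offending line number.
#'
#' @param path file path.
#' @return Tibble.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) {
    evm_abort(sprintf("input file not found: %s", path), "evmorph_missing_file")
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv
  } else {
    readr::read_csv
  }
  out <- suppressWarnings(reader(path, show_col_types = FALSE, progress = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    evm_abort(sprintf("malformed row(s) in %s, first at line %d: %s",
                      path, probs$row[1] + 1, probs$expected[1]),
              "evmorph_malformed_table")
  }
  out
}

#' Write a delimited table
#' @param x data frame.
#' @param path destination; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(x, path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name<tab>description<tab>gene1<tab>gene2...`.
#'
#' @param path file path.
#' @return Named list of gene id vectors; descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    evm_abort(sprintf("GMT file not found: %s", path), "evmorph_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad) > 0) {
    evm_abort(sprintf("malformed GMT line %d in %s (need name, description, >=1 gene)",
                      bad[1], path), "evmorph_malformed_table")
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of gene id vectors.
#' @param path destination.
#' @param descriptions optional character vector.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a label mask (16-bit TIFF)
#' @param path file path.
#' @return Integer matrix of labels (0 = background).
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    evm_abort(sprintf("mask file not found: %s", path), "evmorph_missing_file")
  }
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "integer"
  img
}

#' Write a label mask as 16-bit TIFF
#' @param mask integer matrix (labels 0..65535).
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535 || min(mask) < 0) {
    evm_abort("labels must fit 16-bit unsigned range", "evmorph_bad_input")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
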