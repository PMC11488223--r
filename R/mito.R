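# Mitochondrial channel features: intensity statistics, radial intensity
# distribution and gray-level co-occurrence texture, computed per cell mask.

# Euclidean distance of every mask pixel to the nearest background pixel,
# via brute force against the background pixels bordering the mask (exact for
# the object sizes this assay produces).
edge_distance <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # background pixels 8-adjacent to the mask (in padded coordinates)
  shifted <- Reduce(`|`, lapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                                     c(0, 1), c(1, -1), c(1, 0), c(1, 1)),
    function(d) {
      m <- matrix(FALSE, nr + 2, nc + 2)
      m[(2 + d[1]):(nr + 1 + d[1]), (2 + d[2]):(nc + 1 + d[2])] <- mask
      m
    }))
  bg <- which(shifted & !pad, arr.ind = TRUE)
  bg[, 1] <- bg[, 1] - 1L; bg[, 2] <- bg[, 2] - 1L
  if (nrow(bg) == 0) return(rep(1, nrow(idx)))
  d2 <- outer(idx[, 1], bg[, 1], `-`)^2 + outer(idx[, 2], bg[, 2], `-`)^2
  sqrt(apply(d2, 1, min))
}

glcm_stats <- function(q, mask, offset, levels = 8) {
  nr <- nrow(q); nc <- ncol(q)
  dirs <- list(c(0, offset), c(-offset, offset), c(-offset, 0), c(-offset, -offset))
  counts <- matrix(0, levels, levels)
  for (d in dirs) {
    r1 <- max(1, 1 - d[1]):min(nr, nr - d[1])
    c1 <- max(1, 1 - d[2]):min(nc, nc - d[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + d[1], c1 + d[2], drop = FALSE]
    m <- mask[r1, c1, drop = FALSE] & mask[r1 + d[1], c1 + d[2], drop = FALSE]
    if (!any(m)) next
    tab <- table(factor(a[m], levels = 1:levels), factor(b[m], levels = 1:levels))
    counts <- counts + tab + t(tab) # symmetric GLCM
  }
  if (sum(counts) == 0) {
    return(c(Contrast = NA_real_, Homogeneity = NA_real_,
             Entropy = NA_real_, Correlation = NA_real_))
  }
  p <- counts / sum(counts)
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else 0
  c(Contrast = sum((i - j)^2 * p),
    Homogeneity = sum(p / (1 + (i - j)^2)),
    Entropy = -sum(p[p > 0] * log(p[p > 0])),
    Correlation = corr)
}

#' Mitochondrial features for one cell
#'
#' Intensity statistics over the mask, mass displacement (distance between
#' the intensity-weighted and binary centroids), the fraction of total
#' intensity in four equal-width rings of normalized distance-to-edge
#' (`Mito_FracAtD_1` = outermost ring, `Mito_FracAtD_4` = innermost core),
#' and Haralick-style texture (contrast, homogeneity, entropy, correlation)
#' from symmetric 8-level gray co-occurrence matrices at pixel offsets 1 and
#' 3, averaged over four directions.
#'
#' @param mito numeric matrix of mitochondria channel intensities (finite,
#'   non-negative), covering the mask.
#' @param mask logical or 0/1 matrix for the cell.
#' @return One-row tibble of `Mito_*` features. When the channel is all zero
#'   inside the mask, intensity statistics are 0 and texture features `NA`.
#' @export
compute_mito_features <- function(mito, mask) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!all(dim(mito) == dim(mask))) {
    evm_abort("`mito` and `mask` dimensions differ", "evmorph_dim_mismatch")
  }
  vals <- mito[mask]
  if (any(!is.finite(vals)) || any(vals < 0)) {
    evm_abort("mito intensities must be finite and non-negative",
              "evmorph_bad_intensity")
  }
  idx <- which(mask, arr.ind = TRUE)
  out <- list(
    Mito_MeanIntensity = mean(vals),
    Mito_IntegratedIntensity = sum(vals),
    Mito_StdIntensity = if (length(vals) > 1) sd(vals) else 0,
    Mito_MADIntensity = median(abs(vals - median(vals)))
  )
  total <- sum(vals)
  if (total > 0) {
    wr <- sum(idx[, 1] * vals) / total
    wc <- sum(idx[, 2] * vals) / total
    out$Mito_MassDisplacement <-
      sqrt((wr - mean(idx[, 1]))^2 + (wc - mean(idx[, 2]))^2)
    d <- edge_distance(mask)
    dn <- d / max(d)
    ring <- pmin(pmax(ceiling(dn * 4), 1L), 4L)
    frac <- vapply(1:4, function(k) sum(vals[ring == k]) / total, numeric(1))
  } else {
    out$Mito_MassDisplacement <- 0
    frac <- rep(0, 4)
  }
  names(frac) <- paste0("Mito_FracAtD_", 1:4)
  out <- c(out, as.list(frac))
  rng <- range(vals)
  q <- matrix(1L, nrow(mito), ncol(mito))
  textured <- total > 0 && rng[2] > rng[1]
  if (textured) {
    q[] <- pmin(1L + as.integer(8 * (mito - rng[1]) / (rng[2] - rng[1])), 8L)
  }
  for (off in c(1, 3)) {
    st <- if (textured) glcm_stats(q, mask, off) else
      c(Contrast = NA_real_, Homogeneity = NA_real_,
        Entropy = NA_real_, Correlation = NA_real_)
    names(st) <- paste0("Mito_Texture_", names(st), "_", off)
    out <- c(out, as.list(st))
  }
  as_tibble(out)
}

#' Names of the mitochondrial feature set
#' @return Character vector of the `Mito_*` feature columns.
#' @export
mito_features <- function() {
  c("Mito_MeanIntensity", "Mito_IntegratedIntensity", "Mito_StdIntensity",
    "Mito_MADIntensity", "Mito_MassDisplacement",
    paste0("Mito_FracAtD_", 1:4),
    as.character(outer(
      paste0("Mito_Texture_", c("Contrast", "Homogeneity", "Entropy", "Correlation")),
      c(1, 3), paste, sep = "_")))
}
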