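# Rendering of synthetic wells: labelled cell and nucleus masks plus a
# mitochondria intensity channel. Cell silhouettes are an ellipse body with
# Bezier-tapered protrusions, which reproduces the round-vs-ramified contrast
# between unstimulated and stimulated microglia with four latent parameters.

fill_ellipse_px <- function(size, cx, cy, a, b, phi) {
  rr <- max(1L, floor(cy - a - 1)):min(size, ceiling(cy + a + 1))
  cc <- max(1L, floor(cx - a - 1)):min(size, ceiling(cx + a + 1))
  px <- expand.grid(row = rr, col = cc)
  x <- (px$col - cx) * cos(phi) + (px$row - cy) * sin(phi)
  y <- -(px$col - cx) * sin(phi) + (px$row - cy) * cos(phi)
  px[(x / a)^2 + (y / b)^2 <= 1, , drop = FALSE]
}

# quadratic Bezier from p0 toward direction `dir`, length L, tapered width
protrusion_px <- function(size, p0, dir, L, w0, bend) {
  p2 <- p0 + dir * L
  perp <- c(-dir[2], dir[1])
  p1 <- p0 + dir * (L / 2) + perp * bend * L
  t <- seq(0, 1, length.out = max(8L, ceiling(2 * L)))
  bez <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  w <- pmax(w0 * (1 - 0.8 * t), 0.8)
  out <- vector("list", length(t))
  for (i in seq_along(t)) {
    cx <- bez[i, 1]; cy <- bez[i, 2]; r <- w[i]
    rr <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
    cc <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
    px <- expand.grid(row = rr, col = cc)
    out[[i]] <- px[(px$col - cx)^2 + (px$row - cy)^2 <= r^2, , drop = FALSE]
  }
  do.call(rbind, out)
}

#' Render one synthetic well
#'
#' Draws each cell as an ellipse body (semi-axes `radius * sqrt(elongation)`
#' and `radius / sqrt(elongation)`) with `n_protrusions` tapered Bezier
#' protrusions of length `protrusion_len`, placed without overlap. The
#' nucleus is a concentric ellipse whose area fraction is drawn from a
#' Beta(8, 12) clipped to (0.1, 0.8), scaled so it lies strictly inside the
#' body. The mitochondria channel is a sum of Gaussian puncta confined to
#' the cell mask plus `noise_sd` background noise. `POS_EV` latent parameter
#' means are the `POS_CTL` means interpolated toward `NEG_CTL` by the
#' realised EV effect.
#'
#' @param well one row of [gen_plate_layout()] output.
#' @param config an [plate_config()] object.
#' @param n_cells optional cell count override (defaults to a draw from
#'   `cells_per_well_range`, which at the full-assay default of 700-1000
#'   cells requires a correspondingly large `image_size`).
#' @return List with `cell_mask` and `nucleus_mask` (integer label matrices
#'   sharing label ids), `mito` (numeric matrix) and `ground_truth` (tibble
#'   of per-cell latent parameters and placement).
#' @export
render_synthetic_well <- function(well, config, n_cells = NULL) {
  stopifnot(inherits(config, "evm_plate_config"))
  well <- as.list(well)
  size <- config$image_size
  delta <- if (identical(well$group, "POS_EV")) {
    config$ev_effect * well$ev_dose / max(config$ev_doses)
  } else 0
  lat <- group_latents(config, well$group, delta = delta)
  seed <- child_seed(config$seed, sum(utf8ToInt(paste0(well$well_id, well$group))))
  with_seed(seed, {
    if (is.null(n_cells)) {
      rng <- config$cells_per_well_range
      n_cells <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
    }
    exp_a <- lat$mean[["radius"]] * sqrt(lat$mean[["elongation"]])
    exp_foot <- pi * (exp_a + lat$mean[["protrusion_len"]])^2
    if (n_cells * exp_foot >= 0.3 * size^2) {
      evm_abort(sprintf(
        "expected cell footprint (%d cells x ~%.0f px) exceeds 30%% of a %dx%d image; increase `image_size` or reduce cell count",
        n_cells, exp_foot, size, size), "evmorph_generation_error")
    }
    cell_mask <- matrix(0L, size, size)
    nucleus_mask <- matrix(0L, size, size)
    mito <- matrix(0, size, size)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    truth <- list()
    failures <- 0L
    label <- 0L
    for (i in seq_len(n_cells)) {
      r <- max(rnorm(1, lat$mean[["radius"]], lat$sd[["radius"]]), 4)
      e <- max(rnorm(1, lat$mean[["elongation"]], lat$sd[["elongation"]]), 1)
      k <- max(round(rnorm(1, lat$mean[["n_protrusions"]], lat$sd[["n_protrusions"]])), 0)
      L <- max(rnorm(1, lat$mean[["protrusion_len"]], lat$sd[["protrusion_len"]]), 0)
      a <- r * sqrt(e); b <- r / sqrt(e)
      bound <- a + (if (k > 0) L else 0) + 2
      placed <- FALSE
      # seed centres so the cell body fits the frame; elongated bodies and
      # protrusions may still cross the border and are filtered downstream
      margin <- min(b + 3, size / 3)
      for (try in 1:50) {
        cx <- runif(1, margin, size - margin)
        cy <- runif(1, margin, size - margin)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                  radii + bound + 1)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) { failures <- failures + 1L; next }
      label <- label + 1L
      phi <- runif(1, 0, pi)
      body <- fill_ellipse_px(size, cx, cy, a, b, phi)
      px <- body
      if (k > 0) {
        for (p in seq_len(k)) {
          psi <- runif(1, 0, 2 * pi)
          bx <- cx + a * cos(psi) * cos(phi) - b * sin(psi) * sin(phi)
          by <- cy + a * cos(psi) * sin(phi) + b * sin(psi) * cos(phi)
          # outward normal direction of the ellipse at angle psi
          dirv <- c(cos(psi) / a * cos(phi) - sin(psi) / b * sin(phi),
                    cos(psi) / a * sin(phi) + sin(psi) / b * cos(phi))
          dirv <- dirv / sqrt(sum(dirv^2))
          w0 <- max(2, r / 6)
          px <- rbind(px, protrusion_px(size, c(bx, by), dirv,
                                        max(rnorm(1, L, L / 6), 1), w0,
                                        rnorm(1, 0, 0.15)))
        }
      }
      px <- unique(px)
      lin <- px$row + (px$col - 1L) * size
      cell_mask[lin] <- label
      centers <- rbind(centers, c(cx, cy)); radii <- c(radii, bound)
      # nucleus strictly inside the body ellipse
      rho <- min(max(rbeta(1, 8, 12), 0.1), 0.8)
      area_cell <- length(lin)
      f <- min(sqrt(rho * area_cell / (pi * a * b)), 0.85)
      nuc <- fill_ellipse_px(size, cx, cy, f * a, f * b, phi)
      nlin <- nuc$row + (nuc$col - 1L) * size
      nlin <- nlin[cell_mask[nlin] == label]
      nucleus_mask[nlin] <- label
      # mitochondrial puncta confined to the cell
      n_punct <- max(3L, round(area_cell / 60))
      pts <- lin[sample.int(length(lin), min(n_punct, length(lin)))]
      amp <- exp(rnorm(length(pts), 0, 0.3))
      pr <- (pts - 1L) %% size + 1L; pc <- (pts - 1L) %/% size + 1L
      for (s in seq_along(pts)) {
        rr <- max(1L, pr[s] - 3L):min(size, pr[s] + 3L)
        cc <- max(1L, pc[s] - 3L):min(size, pc[s] + 3L)
        g <- amp[s] * exp(-(outer((rr - pr[s])^2, (cc - pc[s])^2, `+`)) / (2 * 1.2^2))
        mito[rr, cc] <- mito[rr, cc] + g
      }
      truth[[label]] <- tibble(
        cell_id = label, group = well$group, well_id = well$well_id,
        radius = r, elongation = e, n_protrusions = k, protrusion_len = L,
        center_x = cx, center_y = cy, orientation = phi,
        nucleus_ratio = rho, ev_effect = delta)
    }
    if (failures > 0.2 * n_cells) {
      evm_abort(sprintf(
        "%d of %d cells could not be placed; increase `image_size`",
        failures, n_cells), "evmorph_generation_error")
    }
    # puncta only inside cells, then background noise
    mito[cell_mask == 0L] <- 0
    if (config$noise_sd > 0) {
      mito <- mito + matrix(pmax(rnorm(size^2, 0, config$noise_sd), 0), size)
    }
    list(cell_mask = cell_mask, nucleus_mask = nucleus_mask, mito = mito,
         ground_truth = bind_rows(truth))
  })
}
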