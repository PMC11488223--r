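# Shared fixtures, built in code.

# rasterised disk of radius r on a square canvas
make_disk <- function(r, n = 2 * r + 11) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# rasterised ellipse with semi-axes a, b rotated by phi
make_ellipse <- function(a, b, phi = 0, n = 2 * ceiling(a) + 21) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) {
    x <- (j - ctr) * cos(phi) + (i - ctr) * sin(phi)
    y <- -(j - ctr) * sin(phi) + (i - ctr) * cos(phi)
    (x / a)^2 + (y / b)^2 <= 1
  })
}

# small plate configuration for fast scoring tests
small_plate_config <- function(seed = 1, ...) {
  plate_config(n_wells_per_group = 4, cells_per_well_range = c(120, 150),
               seed = seed, ...)
}

# boundary-value QC fixture: solidity and nucleus ratio at and around the
# inclusive cutoffs
qc_boundary_fixture <- function() {
  tibble::tibble(
    cell_id = 1:8,
    Cell_Solidity = c(1.0, 1 - 1e-7, 1 - 1e-5, 0.92, 0.92, 0.92, 1.0, 0.5),
    NucleusCellAreaRatio = c(0.4, 0.4, 0.4, 0.85, 0.851, 0.8499, 0.9, 0.1),
    expected_rejected = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  )
}

# sort-based Benjamini-Hochberg reference, independent of stats::p.adjust
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
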