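# Independent reference implementations used as test oracles.

# greedy Ward oracle working directly from cluster centroids, independent of
# the Lance-Williams recursion used by the implementation under test
ward_oracle <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        A <- X[clusters[[i]], , drop = FALSE]
        B <- X[clusters[[j]], , drop = FALSE]
        nA <- nrow(A); nB <- nrow(B)
        d <- sqrt(2 * nA * nB / (nA + nB) *
                    sum((colMeans(A) - colMeans(B))^2))
        if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    merges[[length(merges) + 1]] <-
      as.integer(sort(c(clusters[[best[1]]], clusters[[best[2]]])))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

hclust_merge_sets <- function(hc) {
  n <- nrow(hc$merge) + 1
  members <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- as.integer(sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2]))))
    out[[k]] <- members[[k]]
  }
  out
}


# straight-line reimplementation of the enrichment-score recipe, kept
# deliberately naive (explicit loops) to serve as an independent oracle
gsva_oracle <- function(X, set, tau = 1, mx_diff = TRUE) {
  p <- nrow(X); n <- ncol(X)
  z <- matrix(0, p, n)
  for (i in 1:p) {
    h <- sd(X[i, ]) / 4
    for (j in 1:n) {
      acc <- 0
      for (k in 1:n) acc <- acc + pnorm((X[i, j] - X[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  es <- numeric(n)
  for (j in 1:n) {
    ord <- order(z[, j], decreasing = TRUE)
    rnk <- integer(p); rnk[ord] <- 1:p # rank in the decreasing order
    r <- abs(p / 2 - rnk)
    denom_in <- 0
    for (i in which(rownames(X) %in% set)) denom_in <- denom_in + abs(r[i])^tau
    walk <- numeric(p); lvl <- 0
    for (step in 1:p) {
      gene <- rownames(X)[ord[step]]
      if (gene %in% set) {
        lvl <- lvl + abs(r[ord[step]])^tau / denom_in
      } else {
        lvl <- lvl - 1 / (p - length(set))
      }
      walk[step] <- lvl
    }
    es[j] <- if (mx_diff) max(c(0, walk)) + min(c(0, walk)) else
      walk[which.max(abs(walk))]
  }
  es
}

toy_matrix <- function(p = 6, n = 4, seed = 100) {
  set.seed(seed)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("G%02d", 1:p), sprintf("S%d", 1:n)))
  X
}

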