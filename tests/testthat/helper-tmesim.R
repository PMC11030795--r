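# Shared fixtures and brute-force oracles (all generated in code).

# small, fast configuration for unit-level simulation runs
tinyConfig <- function() {
  cfg <- defaultParams()
  cfg$environment$width_um <- 600
  cfg$environment$height_um <- 600
  cfg$environment$bed_center_um <- c(300, 300)
  cfg$environment$bed_radius_um <- 200
  cfg$experiment$n_tumor <- 150
  cfg$experiment$n_tcell <- 6
  cfg$experiment$duration_h <- 6
  cfg
}

# O(n^2) contact-graph oracle
bruteContacts <- function(x, y, r, tol) {
  n <- length(x)
  out <- list(i = integer(0), j = integer(0), dist = numeric(0))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d <= r[i] + r[j] + tol) {
      out$i <- c(out$i, i); out$j <- c(out$j, j); out$dist <- c(out$dist, d)
    }
  }
  out
}

# brute-force k-NN window oracle: full distance sort per cell
bruteKnn <- function(x, y, labels, k, include_self = TRUE) {
  n <- length(x)
  labels <- factor(labels)
  lev <- levels(labels)
  out <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    ord <- order(d, seq_len(n))
    sel <- if (include_self) ord[seq_len(k)] else setdiff(ord, i)[seq_len(k)]
    out[i, ] <- tabulate(as.integer(labels[sel]), nbins = length(lev)) / k
  }
  out
}

# adjusted Rand index (for permutation-invariant label comparison)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expect <- ai * bj / nn
  (nij - expect) / ((ai + bj) / 2 - expect)
}

# canonical sort of contact pair lists for comparison
sortPairs <- function(p) {
  a <- pmin(p$i, p$j); b <- pmax(p$i, p$j)
  o <- order(a, b)
  list(i = a[o], j = b[o], dist = p$dist[o])
}
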