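# Shared fixtures, built in code.

# small clean cynodont-like section: c = 20 um/d, d = 1.5 um/d, R = 2
demo_section <- function(cer = 20, dsr = 1.5, n_days = 10, ...) {
  simulate_section(section_config(cer = cer, dsr = dsr, n_days = n_days, ...))
}

# brute-force all-pairs segment intersection oracle, independent of
# intersect_polylines (no prefilter, scalar loops)
brute_intersections <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      p <- a[i, ]; r <- a[i + 1, ] - a[i, ]
      q <- b[j, ]; s <- b[j + 1, ] - b[j, ]
      den <- r[1] * s[2] - r[2] * s[1]
      if (abs(den) < 1e-12) next
      t <- ((q[1] - p[1]) * s[2] - (q[2] - p[2]) * s[1]) / den
      u <- ((q[1] - p[1]) * r[2] - (q[2] - p[2]) * r[1]) / den
      if (t >= -1e-9 && t <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) {
        out <- rbind(out, c(p[1] + t * r[1], p[2] + t * r[2]))
      }
    }
  }
  out
}

# brute-force Brownian covariance: shared root-to-MRCA path length per pair
brute_phylo_cov <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge)); blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) { nodes <- c(nodes, node); node <- parent[node] }
    nodes
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(blen[shared])
    }
  }
  C
}

# naive BH step-up: adjusted p_i = min over j with p_j >= p_i of p_j * m / rank_j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    i <- o[k]
    tail_idx <- o[k:m]
    adj[i] <- min(pmin(p[tail_idx] * m / match(tail_idx, o), 1))
  }
  adj
}
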