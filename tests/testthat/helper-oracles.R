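# Independent brute-force oracles used to cross-check the implementation.

# naive union-find (no path compression) over an edge list; returns component
# edge counts sorted decreasingly
oracle_component_edge_sizes <- function(a, b, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[min(ra, rb)] <- max(ra, rb)
  }
  roots <- vapply(a, find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# recursive flood fill (explicit stack, voxel at a time) for 3-D masks
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  dist <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- as.matrix(off[switch(as.character(connectivity),
                              "6" = dist == 1, "18" = dist <= 2,
                              "26" = rep(TRUE, nrow(off))), ])
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(v, d)[1, ])
    lab[v] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(off))) {
        q <- p + off[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Benjamini-Hochberg by the step-up definition, element by element
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m))
  qq <- numeric(m); qq[o] <- pmin(q, 1)
  ks <- which(ps <= seq_len(m) / m * alpha)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  list(q = qq, reject = rej)
}

# exhaustive NBS edge p-values on a tiny cohort by direct enumeration
oracle_exact_edge_p <- function(Z, n_pat, obs_pat = seq_len(n_pat)) {
  n <- nrow(Z)
  combos <- utils::combn(n, n_pat)
  stats <- apply(combos, 2, function(s)
    abs(colMeans(Z[s, , drop = FALSE]) - colMeans(Z[-s, , drop = FALSE])))
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1)
  obs <- abs(colMeans(Z[obs_pat, , drop = FALSE]) -
               colMeans(Z[-obs_pat, , drop = FALSE]))
  vapply(seq_along(obs), function(e)
    mean(stats[e, ] >= obs[e] - 1e-12), numeric(1))
}

# small deterministic cohort for unit tests
tiny_cohort <- function(seed = 42, n_timepoints = 80, ...) {
  simulate_cohort(simulation_config(n_timepoints = n_timepoints, seed = seed, ...))
}

# FC matrices straight from the generator's series (no preprocessing), for
# tests that target the network statistics themselves
raw_fc <- function(cohort) lapply(cohort$timeseries, fc_matrix)
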