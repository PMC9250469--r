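#' Fisher-z functional connectivity matrix
#'
#' Pearson correlation between every ROI pair of a cleaned time series,
#' Fisher-z transformed (`atanh`). The diagonal is `NA`.
#'
#' @param ts a [roi_time_series()] with at least 3 frames.
#' @return symmetric ROI x ROI matrix of class `fc_matrix`.
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_time_series"))
  x <- ts$data
  if (nrow(x) < 3) stop("need at least 3 retained frames")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant ROI signal: %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  r <- stats::cor(x)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1)) {
    idx <- which(abs(r) >= 1 & upper.tri(r), arr.ind = TRUE)[1, ]
    stop(sprintf("perfectly correlated ROI pair (%s, %s): Fisher z undefined",
                 colnames(x)[idx[1]], colnames(x)[idx[2]]))
  }
  z <- atanh(r)
  diag(z) <- NA
  structure(z, class = c("fc_matrix", "matrix"))
}

#' Canonical edge list for n ROIs
#'
#' All unordered pairs (a, b) with a < b, in column-major upper-triangle order.
#'
#' @param n_rois number of ROIs.
#' @return data.frame with integer columns `a`, `b`.
#' @export
canonical_edges <- function(n_rois) {
  idx <- which(upper.tri(diag(n_rois)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(a = idx[, 1], b = idx[, 2])
}

# subjects x edges matrix of Fisher-z values
edge_matrix <- function(matrices, edges) {
  mats <- if (is.list(matrices)) matrices else
    lapply(seq_len(dim(matrices)[3]), function(i) matrices[, , i])
  Z <- t(vapply(mats, function(m) m[cbind(edges$a, edges$b)],
                numeric(nrow(edges))))
  if (nrow(edges) == 1) Z <- matrix(Z, ncol = 1)
  Z
}

as_group_factor <- function(groups, n) {
  g <- factor(groups, levels = c("patient", "control"))
  if (any(is.na(g))) stop("groups must be 'patient'/'control'")
  if (length(g) != n) stop("group labels must match the number of subjects")
  if (any(table(g) < 2)) stop("need at least 2 subjects per group")
  g
}

fc_labels <- function(matrices) {
  m1 <- if (is.list(matrices)) matrices[[1]] else matrices[, , 1]
  if (!is.null(colnames(m1))) colnames(m1) else sprintf("ROI%02d", seq_len(ncol(m1)))
}

#' Screen edges for non-zero functional connectivity
#'
#' Per edge and per group, a one-sample t-test of the Fisher-z values against
#' zero, BH-corrected across edges within each group. An edge is retained when
#' its FC differs from zero (corrected p below `alpha`) in at least one group
#' -- spurious connectivity that is null in both groups is removed before the
#' network statistics.
#'
#' @param matrices list of `fc_matrix` (one per subject) or ROI x ROI x subject
#'   array.
#' @param groups vector of "patient"/"control" per subject.
#' @param alpha FDR level.
#' @return data.frame of class `edge_set`: edge indices and labels, per-group
#'   mean FC, raw and corrected screening p-values.
#' @export
screen_edges <- function(matrices, groups, alpha = 0.05) {
  labels <- fc_labels(matrices)
  edges <- canonical_edges(length(labels))
  g <- as_group_factor(groups, if (is.list(matrices)) length(matrices) else dim(matrices)[3])
  Z <- edge_matrix(matrices, edges)
  test_group <- function(rows) {
    apply(Z[rows, , drop = FALSE], 2, function(v) t_test_one_sample(v, 0)$p_value)
  }
  p_pat <- test_group(g == "patient")
  p_con <- test_group(g == "control")
  q_pat <- fdr_bh(p_pat, alpha)$q
  q_con <- fdr_bh(p_con, alpha)$q
  out <- data.frame(
    a = edges$a, b = edges$b,
    label_a = labels[edges$a], label_b = labels[edges$b],
    mean_patient = colMeans(Z[g == "patient", , drop = FALSE]),
    mean_control = colMeans(Z[g == "control", , drop = FALSE]),
    p_patient = p_pat, q_patient = q_pat,
    p_control = p_con, q_control = q_con,
    stringsAsFactors = FALSE)
  out <- out[q_pat < alpha | q_con < alpha, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_set", "data.frame")
  attr(out, "roi_labels") <- labels
  out
}

#' Select PSI-related edges
#'
#' For each screened edge, Pearson correlation between the subjects' Fisher-z
#' FC and their PSI scores, per group. Edges with correlation p below `alpha`
#' in either group (default) or in patients only are flagged PSI-related and
#' carried into the NBS.
#'
#' @param edge_set an `edge_set` from [screen_edges()] (or any data.frame with
#'   `a`, `b`).
#' @param matrices FC matrices as in [screen_edges()].
#' @param psi per-subject PSI scores.
#' @param groups group labels per subject.
#' @param alpha correlation p-value threshold (uncorrected).
#' @param scope `"either"` group or `"patients"` only.
#' @return the PSI-related subset, with per-group correlation columns.
#' @export
select_psi_edges <- function(edge_set, matrices, psi, groups, alpha = 0.05,
                             scope = c("either", "patients")) {
  scope <- match.arg(scope)
  if (nrow(edge_set) == 0) return(edge_set)
  g <- as_group_factor(groups, length(psi))
  Z <- edge_matrix(matrices, edge_set)
  corr_p <- function(rows) {
    apply(Z[rows, , drop = FALSE], 2, function(v) {
      if (stats::sd(v) == 0) return(1)
      pearson_correlation(v, psi[rows])$p_value
    })
  }
  r_of <- function(rows) {
    apply(Z[rows, , drop = FALSE], 2, function(v) {
      if (stats::sd(v) == 0) return(0)
      stats::cor(v, psi[rows])
    })
  }
  edge_set$psi_r_patient <- r_of(g == "patient")
  edge_set$psi_p_patient <- corr_p(g == "patient")
  edge_set$psi_r_control <- r_of(g == "control")
  edge_set$psi_p_control <- corr_p(g == "control")
  keep <- if (scope == "either")
    edge_set$psi_p_patient < alpha | edge_set$psi_p_control < alpha
  else edge_set$psi_p_patient < alpha
  out <- edge_set[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union-find over an edge list; returns, per edge, its component root
uf_roots <- function(a, b, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(a, find, integer(1))
}

# size (in edges) of the largest connected component of an edge list
max_component_edges <- function(a, b, n_nodes) {
  if (length(a) == 0) return(0L)
  max(tabulate(uf_roots(a, b, n_nodes)))
}

#' Connected components of an edge list
#'
#' Component size is counted in edges, the scale on which the NBS familywise
#' threshold operates. Components are ordered by decreasing edge count, ties
#' broken by the lexically smallest member node label.
#'
#' @param edges data.frame with columns `a`, `b` (integer node indices) and
#'   optionally `label_a`, `label_b`.
#' @param n_nodes total number of nodes in the graph.
#' @return list of components; each has `nodes`, `edges` (row subset of the
#'   input), `n_edges`, `n_nodes`.
#' @export
connected_components <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_edgelist(cbind(edges$a, edges$b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  edge_comp <- memb[edges$a]
  comps <- lapply(unique(edge_comp), function(cc) {
    e <- edges[edge_comp == cc, , drop = FALSE]
    rownames(e) <- NULL
    nodes <- sort(unique(c(e$a, e$b)))
    list(nodes = nodes, edges = e, n_edges = nrow(e), n_nodes = length(nodes))
  })
  lab <- vapply(comps, function(cp) {
    if (!is.null(cp$edges$label_a))
      min(c(cp$edges$label_a, cp$edges$label_b)) else as.character(min(cp$nodes))
  }, character(1))
  comps[order(-vapply(comps, `[[`, 0L, "n_edges"), lab)]
}

#' Network-based statistic with largest-component familywise correction
#'
#' Three steps. (1) For every candidate edge the observed group difference of
#' mean Fisher-z FC is computed (absolute difference by default). (2) Subjects
#' are randomly re-allocated to two groups of the original sizes `n_perm`
#' times; each edge's p-value is the rank of its statistic within the joint
#' permutation distribution (the observed labelling is included, so p >=
#' 1/(n_perm+1)). (3) Edges with p below `edge_alpha` form the suprathreshold
#' graph; its connected components are compared against the permutation
#' distribution of the maximal suprathreshold component size (each permutation
#' is thresholded by the same rank rule). The familywise size threshold is the
#' `component_percentile` of that null distribution, and a component's p-value
#' is the fraction of relabellings whose maximal component is at least as
#' large.
#'
#' With `exact = TRUE` all distinct relabellings are enumerated instead of
#' sampled (feasible for small cohorts), and p-values are exact.
#'
#' @param matrices FC matrices (list or array), one per subject.
#' @param groups "patient"/"control" per subject.
#' @param edge_set optional data.frame with columns `a`, `b` restricting the
#'   candidate edges (e.g. the PSI-related set); default all ROI pairs.
#' @param n_perm number of random relabellings.
#' @param edge_alpha edge-level threshold on the permutation p-value.
#' @param component_percentile familywise percentile of the null maximal
#'   component size (95 keeps the top 5%).
#' @param seed RNG seed for the relabellings.
#' @param statistic `"abs_diff"` (default) or signed `"diff"` of group means.
#' @param exact enumerate all relabellings instead of sampling.
#' @return object of class `nbs_result`: per-edge table (`$edges`), the
#'   suprathreshold subset, observed `$components` each with its familywise
#'   p-value and significance flag, the null distribution of maximal component
#'   size, and the size threshold.
#' @export
nbs <- function(matrices, groups, edge_set = NULL, n_perm = 5000,
                edge_alpha = 0.05, component_percentile = 95, seed = NULL,
                statistic = c("abs_diff", "diff"), exact = FALSE) {
  statistic <- match.arg(statistic)
  labels <- fc_labels(matrices)
  n_rois <- length(labels)
  if (is.null(edge_set)) edge_set <- canonical_edges(n_rois)
  if (nrow(edge_set) == 0) stop("empty candidate edge set")
  n_subj <- if (is.list(matrices)) length(matrices) else dim(matrices)[3]
  g <- as_group_factor(groups, n_subj)
  n1 <- sum(g == "patient")
  Z <- edge_matrix(matrices, edge_set)

  # relabelling weight matrix: rows are labellings, entries +-1/n
  pat_idx <- list(which(g == "patient"))
  if (exact) {
    combos <- utils::combn(n_subj, n1)
    pat_sets <- lapply(seq_len(ncol(combos)), function(j) combos[, j])
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (n_perm < 100) stop("n_perm must be at least 100")
    pat_sets <- c(pat_idx, lapply(seq_len(n_perm), function(i) sample(n_subj, n1)))
  }
  W <- matrix(-1 / (n_subj - n1), length(pat_sets), n_subj)
  for (r in seq_along(pat_sets)) W[r, pat_sets[[r]]] <- 1 / n1
  D <- W %*% Z                       # labellings x edges mean differences
  if (statistic == "abs_diff") D <- abs(D)
  R <- nrow(D)
  obs_row <- if (exact) which(vapply(pat_sets, function(s)
    identical(sort(s), which(g == "patient")), logical(1)))[1] else 1L

  # p[r, e] = fraction of labellings with statistic >= D[r, e]
  P <- apply(D, 2, function(col) (R - rank(col, ties.method = "min") + 1) / R)
  if (nrow(edge_set) == 1) P <- matrix(P, ncol = 1)

  max_sizes <- vapply(seq_len(R), function(r) {
    sup <- P[r, ] < edge_alpha
    max_component_edges(edge_set$a[sup], edge_set$b[sup], n_rois)
  }, integer(1))

  sup_obs <- P[obs_row, ] < edge_alpha
  edges_out <- data.frame(
    a = edge_set$a, b = edge_set$b,
    label_a = labels[edge_set$a], label_b = labels[edge_set$b],
    mean_patient = colMeans(Z[g == "patient", , drop = FALSE]),
    mean_control = colMeans(Z[g == "control", , drop = FALSE]),
    statistic = D[obs_row, ], p = P[obs_row, ],
    suprathreshold = sup_obs, stringsAsFactors = FALSE)
  sup_edges <- edges_out[sup_obs, , drop = FALSE]
  comps <- connected_components(sup_edges, n_rois)
  null_sizes <- max_sizes[-obs_row]
  threshold <- as.numeric(stats::quantile(null_sizes, component_percentile / 100,
                                          type = 1))
  comps <- lapply(comps, function(cp) {
    cp$p <- if (exact) mean(max_sizes >= cp$n_edges)
            else (1 + sum(null_sizes >= cp$n_edges)) / R
    cp$significant <- cp$p <= 1 - component_percentile / 100
    cp
  })
  structure(list(edges = edges_out, suprathreshold = sup_edges,
                 components = comps, null_max_size = null_sizes,
                 threshold = threshold, edge_alpha = edge_alpha,
                 component_percentile = component_percentile,
                 n_perm = if (exact) R else n_perm, exact = exact,
                 statistic = statistic, roi_labels = labels),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: %d candidate edges, %d suprathreshold (edge p < %g, %s relabellings)\n",
              nrow(x$edges), nrow(x$suprathreshold), x$edge_alpha,
              if (x$exact) "exhaustive" else as.character(x$n_perm)))
  cat(sprintf("  familywise size threshold (top %g%%): %g edges\n",
              100 - x$component_percentile, x$threshold))
  for (cp in x$components)
    cat(sprintf("  component: %d edges / %d ROIs, p = %.4g%s\n",
                cp$n_edges, cp$n_nodes, cp$p, if (cp$significant) " *" else ""))
  invisible(x)
}

#' Correlate mean within-subnetwork connectivity strength with PSI
#'
#' Per subject, the mean absolute Fisher-z FC over a component's edges, then
#' the Pearson correlation of that summary with PSI. Patient-only by default,
#' matching how the study relates circuit disruption to processing speed.
#'
#' @param component one component from an `nbs_result` (or a data.frame with
#'   `a`, `b`).
#' @param matrices FC matrices, one per subject.
#' @param psi per-subject PSI scores.
#' @param groups optional group labels; with `subset = "patient"` only that
#'   group enters the correlation.
#' @param subset `"patient"`, `"control"`, or `"all"`.
#' @return an `ects_test` (estimate = r), plus the per-subject means in
#'   `$subject_means`.
#' @export
subnetwork_psi_correlation <- function(component, matrices, psi, groups = NULL,
                                       subset = c("patient", "control", "all")) {
  subset <- match.arg(subset)
  edges <- if (is.data.frame(component)) component else component$edges
  if (is.null(edges) || nrow(edges) == 0) stop("empty component")
  Z <- edge_matrix(matrices, edges)
  strength <- rowMeans(abs(Z))
  keep <- if (subset == "all" || is.null(groups)) rep(TRUE, length(strength))
          else groups == subset
  res <- pearson_correlation(strength[keep], psi[keep])
  res$subject_means <- strength
  res
}
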