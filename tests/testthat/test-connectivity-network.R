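fc_from_data <- function(x, tr = 2) fc_matrix(roi_time_series(x, tr = tr))

test_that("fc_matrix is atanh(correlation) with guarded degeneracies", {
  set.seed(1)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  z <- fc_from_data(x)
  r <- cor(x)
  expect_equal(unname(z[1, 2]), atanh(r[1, 2]), tolerance = 1e-12)
  expect_equal(z[upper.tri(z)], atanh(r)[upper.tri(r)], tolerance = 1e-12)
  expect_true(all(is.na(diag(z))))
  expect_equal(max(abs(z - t(z)), na.rm = TRUE), 0)
  # r = 0.5 -> z = 0.5493 closed form
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # identical ROI signals -> error naming the pair
  dup <- cbind(x, D = x[, 1])
  expect_error(fc_from_data(dup), "perfectly correlated.*A.*D")
  cst <- cbind(x, E = 5)
  expect_error(fc_from_data(cst), "constant ROI.*E")
  # independent long signals give near-zero z
  set.seed(2)
  big <- matrix(rnorm(2e4), 1e4, 2)
  expect_lt(abs(fc_from_data(big)[1, 2]), 0.05)
})

test_that("edge screening keeps edges non-null in either group", {
  set.seed(3)
  n_roi <- 6
  make_mat <- function(z) {
    m <- matrix(rnorm(n_roi^2, 0, 0.02), n_roi, n_roi,
                dimnames = list(paste0("R", 1:n_roi), paste0("R", 1:n_roi)))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m[1, 2] <- m[2, 1] <- z + m[1, 2]
    diag(m) <- NA
    m
  }
  # edge (1,2) strong in controls only; everything else pure noise
  pats <- lapply(1:10, function(i) make_mat(0))
  cons <- lapply(1:10, function(i) make_mat(0.8))
  groups <- rep(c("patient", "control"), each = 10)
  es <- screen_edges(c(pats, cons), groups)
  expect_true(any(es$a == 1 & es$b == 2))
  expect_true(all(es$a < es$b))
  expect_false(anyDuplicated(paste(es$a, es$b)) > 0)
  row12 <- es[es$a == 1 & es$b == 2, ]
  expect_lt(row12$q_control, 0.05)
})

test_that("PSI-related edge selection is calibrated under the null and finds planted coupling", {
  co <- simulate_cohort(simulation_config(n_timepoints = 100, psi_coupling = 0,
                                          edge_effect = 0, seed = 4))
  fc <- raw_fc(co)
  all_edges <- canonical_edges(16)
  all_edges$label_a <- co$atlas_table$label_name[all_edges$a]
  all_edges$label_b <- co$atlas_table$label_name[all_edges$b]
  sel <- select_psi_edges(all_edges, fc, co$subjects$psi, co$subjects$group)
  # either-group rule at alpha = 0.05: expected selected fraction ~ 1 - 0.95^2
  expect_lt(nrow(sel) / nrow(all_edges), 0.25)
  empty <- all_edges[0, ]
  expect_identical(nrow(select_psi_edges(empty, fc, co$subjects$psi,
                                         co$subjects$group)), 0L)
  # strong within-group coupling is picked up
  co2 <- simulate_cohort(simulation_config(
    n_patients = 80, n_controls = 20, n_timepoints = 150, edge_effect = 0.2,
    severity_sd = 0.5, psi_sd = 3, psi_coupling = 40, seed = 5))
  fc2 <- raw_fc(co2)
  sel2 <- select_psi_edges(all_edges, fc2, co2$subjects$psi, co2$subjects$group)
  pe <- simulation_config()$planted_edges
  hit <- sum(paste(pe[, 1], pe[, 2]) %in% paste(sel2$a, sel2$b))
  expect_gte(hit, 9)  # most of the 12 planted edges
})

test_that("connected components match the union-find oracle and order deterministically", {
  # triangle plus disjoint edge: sizes 3 and 1 in edges
  e <- data.frame(a = c(1, 2, 1, 5), b = c(2, 3, 3, 6))
  comps <- connected_components(e, 8)
  expect_equal(vapply(comps, `[[`, 0L, "n_edges"), c(3L, 1L))
  expect_equal(comps[[1]]$nodes, c(1, 2, 3))
  expect_length(connected_components(e[0, ], 8), 0)
  set.seed(6)
  for (i in 1:100) {
    n <- 30
    m <- sample(1:40, 1)
    ab <- t(replicate(m, sample(n, 2)))
    ee <- data.frame(a = pmin(ab[, 1], ab[, 2]), b = pmax(ab[, 1], ab[, 2]))
    ee <- ee[!duplicated(paste(ee$a, ee$b)), ]
    got <- sort(vapply(connected_components(ee, n), `[[`, 0L, "n_edges"),
                decreasing = TRUE)
    expect_equal(got, oracle_component_edge_sizes(ee$a, ee$b, n))
    # internal union-find used in the permutation loop agrees too
    expect_equal(max(got), ectsnet:::max_component_edges(ee$a, ee$b, n))
  }
})

test_that("NBS permutation p-values equal exhaustive enumeration on a 4-vs-3 cohort", {
  set.seed(7)
  n_roi <- 5
  mats <- lapply(1:7, function(i) {
    m <- matrix(rnorm(n_roi^2, 0, 0.3), n_roi)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- NA
    m
  })
  groups <- rep(c("patient", "control"), c(4, 3))
  res <- nbs(mats, groups, exact = TRUE)
  expect_true(res$exact)
  expect_equal(res$n_perm, choose(7, 4))
  Z <- ectsnet:::edge_matrix(mats, canonical_edges(n_roi))
  expect_equal(res$edges$p, oracle_exact_edge_p(Z, 4), tolerance = 1e-12)
  expect_true(all(res$edges$p >= 1 / choose(7, 4)))
})

test_that("NBS is deterministic under a fixed seed and recovers a planted subnetwork", {
  co <- simulate_cohort(simulation_config(n_timepoints = 150, seed = 8))
  fc <- raw_fc(co)
  r1 <- nbs(fc, co$subjects$group, n_perm = 300, seed = 9)
  r2 <- nbs(fc, co$subjects$group, n_perm = 300, seed = 9)
  expect_identical(r1$edges, r2$edges)
  expect_identical(r1$null_max_size, r2$null_max_size)
  # planted 12-edge subnetwork contained in a significant component
  pe <- simulation_config()$planted_edges
  sig <- r1$components[vapply(r1$components, `[[`, TRUE, "significant")]
  expect_gte(length(sig), 1)
  comp_edges <- paste(sig[[1]]$edges$a, sig[[1]]$edges$b)
  expect_true(all(paste(pe[, 1], pe[, 2]) %in% comp_edges))
  # signed statistic switch gives the same absolute observed values here
  r3 <- nbs(fc, co$subjects$group, n_perm = 300, seed = 9, statistic = "diff")
  expect_equal(abs(r3$edges$statistic), r1$edges$statistic, tolerance = 1e-12)
})

test_that("subnetwork-PSI correlation reduces to the edge correlation for one edge", {
  co <- simulate_cohort(simulation_config(n_timepoints = 100, seed = 10))
  fc <- raw_fc(co)
  comp <- data.frame(a = 3, b = 5)
  got <- subnetwork_psi_correlation(comp, fc, co$subjects$psi,
                                    co$subjects$group)
  pat <- co$subjects$group == "patient"
  z35 <- vapply(fc, function(m) m[3, 5], numeric(1))
  ref <- pearson_correlation(abs(z35)[pat], co$subjects$psi[pat])
  expect_equal(got$estimate, ref$estimate, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
  expect_error(subnetwork_psi_correlation(data.frame(a = integer(0), b = integer(0)),
                                          fc, co$subjects$psi), "empty")
})

test_that("generator-to-FC round trip recovers the base correlation matrix", {
  co <- simulate_cohort(simulation_config(
    n_patients = 2, n_controls = 12, n_timepoints = 4000, ar_coef = 0,
    seed = 11))
  fc <- raw_fc(co)[co$subjects$group == "control"]
  zbar <- Reduce(`+`, fc) / length(fc)
  base_z <- atanh(attr(co, "generator")$base_cor)
  diag(base_z) <- NA
  expect_lt(max(abs(zbar - base_z), na.rm = TRUE), 0.05)
})
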