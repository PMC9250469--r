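box_volume <- function(d = c(12, 12, 12), value = 1) array(value, d)

test_that("SUVR normalisation divides by the reference mean and is scale invariant", {
  v <- box_volume(value = 5)
  mask <- array(FALSE, dim(v)); mask[1:3, 1:3, 1:3] <- TRUE
  expect_equal(normalize_suvr(v, mask), box_volume(value = 1))
  # ROI mean 6 over reference mean 4 -> SUVR 1.5
  v2 <- box_volume(value = 4); v2[5:7, 5:7, 5:7] <- 6
  s <- normalize_suvr(v2, mask)
  expect_equal(unique(as.vector(s[5:7, 5:7, 5:7])), 1.5)
  for (c0 in c(0.1, 3, 250))
    expect_equal(normalize_suvr(v2 * c0, mask), s, tolerance = 1e-12)
  expect_error(normalize_suvr(v2, array(FALSE, dim(v2))), "empty")
  expect_error(normalize_suvr(-v2, mask), "positive")
})

test_that("Gaussian smoothing: identity at 0, flat invariance, sum conservation, FWHM", {
  set.seed(1)
  v <- array(rnorm(20^3, 10), c(20, 20, 20))
  expect_identical(smooth_gaussian(v, 0), v)
  flat <- box_volume(c(16, 16, 16), 7)
  expect_equal(smooth_gaussian(flat, 6, 2), flat, tolerance = 1e-12)
  sm <- smooth_gaussian(v, 6, 2)
  expect_lt(abs(sum(sm) - sum(v)) / abs(sum(v)), 1e-6)
  # delta impulse: half-maximum width of the response ~ FWHM
  imp <- array(0, c(31, 31, 31)); imp[16, 16, 16] <- 1
  resp <- smooth_gaussian(imp, 6, 2)
  prof <- resp[, 16, 16]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the crossings
  lo <- min(above); hi <- max(above)
  xl <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_vox <- xr - xl
  expect_equal(fwhm_vox * 2, 6, tolerance = 0.15)  # voxels are 2 mm
})

test_that("cluster labelling agrees with a flood-fill oracle for all connectivities", {
  set.seed(2)
  for (i in 1:6) {
    mask <- array(runif(10^3) < 0.35, c(10, 10, 10))
    for (conn in c(6, 18, 26)) {
      got <- label_clusters(mask, conn)
      orc <- oracle_flood_fill(mask, conn)
      # same partition: cluster voxel sets match up to label permutation
      expect_equal(sort(table(got[got > 0])), sort(table(orc[orc > 0])),
                   ignore_attr = TRUE)
      relabel <- tapply(orc[mask], got[mask], function(x) length(unique(x)))
      expect_true(all(relabel == 1))
    }
  }
})

test_that("voxelwise t-map finds planted blocks subject to the cluster-size threshold", {
  d <- c(14, 14, 14)
  set.seed(3)
  make_group <- function(n, effect_vox = NULL, delta = 0) {
    lapply(seq_len(n), function(i) {
      v <- array(rnorm(prod(d), 10, 0.2), d)
      if (!is.null(effect_vox)) v[effect_vox] <- v[effect_vox] - delta
      v
    })
  }
  # identical volumes -> empty map
  same <- lapply(1:4, function(i) array(7, d))
  cm0 <- voxelwise_group_tmap(same, same, min_cluster = 10)
  expect_length(cm0$clusters, 0)
  # planted 150-voxel block, strong effect -> exactly one cluster covering it
  block <- array(FALSE, d); block[3:8, 3:7, 3:7] <- TRUE  # 6*5*5 = 150
  vox <- which(block)
  cm1 <- voxelwise_group_tmap(make_group(10, vox, 2), make_group(10),
                              min_cluster = 100)
  expect_length(cm1$clusters, 1)
  expect_true(all(vox %in% cm1$clusters[[1]]$voxels))
  expect_lt(cm1$clusters[[1]]$peak_t, 0)
  # 50-voxel block under a 100-voxel threshold -> nothing reported
  small <- array(FALSE, d); small[3:7, 3:7, 3:4] <- TRUE
  cm2 <- voxelwise_group_tmap(make_group(10, which(small), 2), make_group(10),
                              min_cluster = 100)
  expect_length(cm2$clusters, 0)
  expect_error(voxelwise_group_tmap(same, lapply(1:3, function(i) array(7, c(5, 5, 5)))),
               "congruent")
})

test_that("ROI selection requires enough contiguous cluster voxels inside the ROI", {
  cm_empty <- structure(list(clusters = list(),
                             label_map = array(0L, c(10, 10, 10))),
                        class = "cluster_map")
  atlas <- array(0L, c(10, 10, 10))
  expect_length(select_rois_from_clusters(cm_empty, atlas, 100), 0)
  # a 200-voxel cluster straddling ROI A (99 voxels) and ROI B (101 voxels)
  d <- c(20, 10, 10)
  atlas <- array(0L, d)
  atlas[1:10, 1:10, 1:1] <- 1L   # 100 voxels of A in the slab...
  cl_vox <- array(FALSE, d)
  cl_vox[2:20, 1:10, 1] <- TRUE  # cluster covers 99 voxels of A
  atlas[11:20, 1:10, 1:2] <- 2L  # B: 101+ voxels under the cluster
  cl_vox[11, 1, 2] <- TRUE
  cm <- structure(list(clusters = list(list(voxels = which(cl_vox),
                                            size = sum(cl_vox), peak_t = -5)),
                       label_map = array(0L, d)), class = "cluster_map")
  sel <- select_rois_from_clusters(cm, atlas, min_voxels_in_roi = 100)
  expect_identical(sel, 2L)
  # wholly-contained cluster larger than the threshold selects its ROI
  sel2 <- select_rois_from_clusters(cm, atlas, min_voxels_in_roi = 90)
  expect_identical(sel2, c(1L, 2L))
})

test_that("regional SUVR is the GM-weighted mean over supra-threshold voxels", {
  d <- c(6, 6, 6)
  atlas <- array(0L, d); atlas[1:2, 1, 1] <- 1L
  gm <- array(0, d); gm[1, 1, 1] <- 0.8; gm[2, 1, 1] <- 0.6
  vol <- array(0, d); vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 2
  # threshold 0.5 keeps both voxels: (0.8*1 + 0.6*2) / 1.4
  tab <- regional_suvr(list(s = vol), atlas, gm, gm_threshold = 0.5)
  expect_equal(unname(tab[1, 1]), (0.8 * 1 + 0.6 * 2) / 1.4, tolerance = 1e-12)
  # unweighted switch
  tab_u <- regional_suvr(list(s = vol), atlas, gm, gm_threshold = 0.5,
                         weighted = FALSE)
  expect_equal(unname(tab_u[1, 1]), 1.5)
  # uniform ROI value is returned whatever the weights
  vol2 <- array(1.2, d)
  expect_equal(unname(regional_suvr(list(s = vol2), atlas, gm,
                                    gm_threshold = 0.5)[1, 1]), 1.2)
  # all voxels at or below the GM threshold -> ROI excluded
  expect_error(expect_warning(
    regional_suvr(list(s = vol), atlas, gm, gm_threshold = 0.8), "excluded"),
    "no ROI")
  # direct weighted-sum oracle on random volumes
  set.seed(4)
  atlas2 <- array(sample(0:3, 6^3, TRUE), d)
  gm2 <- array(runif(6^3), d)
  vol3 <- array(rnorm(6^3, 5), d)
  tab2 <- regional_suvr(list(s = vol3), atlas2, gm2, gm_threshold = 0.6)
  for (roi in colnames(tab2)) {
    i <- which(atlas2 == as.integer(roi) & gm2 > 0.6)
    expect_equal(unname(tab2[1, roi]), sum(vol3[i] * gm2[i]) / sum(gm2[i]),
                 tolerance = 1e-12)
  }
})

test_that("regional SUVR comparison flags planted hypometabolism after FDR", {
  co <- simulate_cohort(simulation_config(
    n_patients = 120, n_controls = 120, n_timepoints = 30,
    suvr_effect = 0.06, severity_sd = 0, seed = 6))
  cmp <- compare_regional_suvr(co$suvr, co$subjects$group)
  aff <- simulation_config()$suvr_affected_rois
  expect_true(all(cmp$significant[aff]))
  expect_true(all(cmp$mean_patient[aff] < cmp$mean_control[aff]))
  # single ROI: corrected p equals raw p
  one <- compare_regional_suvr(co$suvr[, 5, drop = FALSE], co$subjects$group)
  expect_equal(one$q, one$p)
})

test_that("SUVR-PSI correlation responds to the planted coupling", {
  # strong severity-driven coupling so metabolism and PSI co-vary in patients
  co <- simulate_cohort(simulation_config(
    n_patients = 150, n_controls = 20, n_timepoints = 150,
    edge_effect = 0.2, severity_sd = 0.5, suvr_effect = 0.12,
    suvr_noise_sd = 0.03, psi_sd = 4, psi_coupling = 40, seed = 7))
  res <- suvr_psi_correlation(co$suvr, co$subjects, "R_caudate")
  expect_gt(res$estimate, 0)
  expect_lt(res$p_value, 0.05)
  # perfect linear coupling between a column and PSI
  fake <- co$suvr
  fake[, 1] <- 2 * co$subjects$psi + 3
  expect_equal(suvr_psi_correlation(fake, co$subjects, 1)$estimate, 1)
})

test_that("NIfTI round trip preserves the volume", {
  set.seed(8)
  v <- array(rnorm(12^3, 5), c(12, 12, 12))
  p <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, p, voxel_mm = 2)
  expect_equal(read_volume_nifti(p), v, tolerance = 1e-6)
})
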