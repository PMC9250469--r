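#' Normalize a PET volume to SUVR using a reference region
#'
#' Every voxel is divided by the mean raw intensity inside the reference mask
#' (cerebellar gray matter in the study design), so the reference region's
#' mean SUVR is 1 by construction and the result is invariant to global
#' scaling of the raw volume.
#'
#' @param volume 3-D numeric array of raw intensities.
#' @param ref_mask logical array (same grid) marking the reference region.
#' @return SUVR array.
#' @export
normalize_suvr <- function(volume, ref_mask) {
  stopifnot(identical(dim(volume), dim(ref_mask)))
  if (!any(ref_mask)) stop("empty reference mask")
  ref_mean <- mean(volume[ref_mask])
  if (ref_mean <= 0) stop("reference-region mean intensity must be positive")
  volume / ref_mean
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along the first array dimension with reflective boundaries,
# via a dense (n x n) operator
conv_axis1 <- function(vol, kernel) {
  d <- dim(vol)
  n <- d[1]
  r <- (length(kernel) - 1) / 2
  # half-sample reflection (edge repeated): 2 1 [1 2 ... n] n n-1; this form
  # conserves total mass under a symmetric normalised kernel
  refl <- function(i) {
    repeat {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
      if (all(i >= 1 & i <= n)) return(i)
    }
  }
  A <- matrix(0, n, n)
  for (j in -r:r) {
    src <- refl(seq_len(n) + j)
    A[cbind(seq_len(n), src)] <- A[cbind(seq_len(n), src)] + kernel[j + r + 1]
  }
  out <- A %*% matrix(vol, nrow = n)
  array(out, d)
}

#' Gaussian smoothing of a 3-D volume
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` per axis,
#' specified in mm and converted through the voxel size. Boundaries are
#' handled by reflection, which conserves the total image sum. `fwhm_mm = 0`
#' is the identity.
#'
#' @param volume 3-D array.
#' @param fwhm_mm full width at half maximum in mm.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @return smoothed array.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_mm = 2) {
  stopifnot(fwhm_mm >= 0, voxel_mm > 0)
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  k <- gaussian_kernel_1d(sigma_vox)
  v <- conv_axis1(volume, k)                    # x
  v <- aperm(conv_axis1(aperm(v, c(2, 1, 3)), k), c(2, 1, 3))  # y
  aperm(conv_axis1(aperm(v, c(3, 2, 1)), k), c(3, 2, 1))       # z
}

neighbor_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d <= 2, "26" = rep(TRUE, nrow(off)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(off[keep, ])
}

#' Label connected clusters of a logical 3-D mask
#'
#' Breadth-first labelling of maximal connected components under 6-, 18- or
#' 26-connectivity (18 is the default, the SPM convention).
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array: 0 outside the mask, cluster id inside.
#' @export
label_clusters <- function(mask, connectivity = 18) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  off <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  coord <- arrayInd(idx_all, d)
  in_mask <- array(FALSE, d); in_mask[idx_all] <- TRUE
  cur <- 0L
  for (s in seq_along(idx_all)) {
    if (lab[idx_all[s]] != 0L) next
    cur <- cur + 1L
    frontier <- matrix(coord[s, ], 1)
    lab[idx_all[s]] <- cur
    while (nrow(frontier)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        sweep(frontier, 2, off[k, ], `+`)))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) break
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
      new <- in_mask[lin] & lab[lin] == 0L
      lin <- unique(lin[new])
      if (!length(lin)) break
      lab[lin] <- cur
      frontier <- arrayInd(lin, d)
    }
  }
  lab
}

#' Voxelwise two-sample t-map with cluster-size thresholding
#'
#' Per-voxel two-sample t-test (pooled variance) between patient and control
#' volumes; voxels with two-sided p below `p_thresh` are grouped into
#' connected clusters and clusters smaller than `min_cluster` voxels are
#' dropped — the whole-brain screening stage preceding regional analysis.
#'
#' @param patient_volumes,control_volumes lists of congruent 3-D arrays.
#' @param p_thresh voxelwise two-sided p threshold.
#' @param min_cluster minimum cluster size in voxels (clusters must exceed it).
#' @param connectivity cluster connectivity (6/18/26).
#' @return object of class `cluster_map`: `$clusters` (list with `voxels`
#'   linear indices, `size`, `peak_t`), `$t_map`, `$p_map`, `$label_map`.
#' @export
voxelwise_group_tmap <- function(patient_volumes, control_volumes,
                                 p_thresh = 0.05, min_cluster = 100,
                                 connectivity = 18) {
  stopifnot(length(patient_volumes) >= 2, length(control_volumes) >= 2)
  d <- dim(patient_volumes[[1]])
  for (v in c(patient_volumes, control_volumes))
    if (!identical(dim(v), d)) stop("volume grids are not congruent")
  n1 <- length(patient_volumes); n2 <- length(control_volumes)
  X1 <- vapply(patient_volumes, as.vector, numeric(prod(d)))
  X2 <- vapply(control_volumes, as.vector, numeric(prod(d)))
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  tt[se == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), n1 + n2 - 2)
  p[se == 0] <- 1
  mask <- array(p < p_thresh, d)
  lab <- label_clusters(mask, connectivity)
  t_map <- array(tt, d)
  keep_ids <- which(tabulate(lab[lab > 0]) > min_cluster)
  clusters <- lapply(keep_ids, function(id) {
    vox <- which(lab == id)
    pk <- vox[which.max(abs(t_map[vox]))]
    list(voxels = vox, size = length(vox), peak_t = t_map[pk])
  })
  label_map <- array(0L, d)
  for (i in seq_along(clusters)) label_map[clusters[[i]]$voxels] <- i
  structure(list(clusters = clusters, t_map = t_map, p_map = array(p, d),
                 label_map = label_map, p_thresh = p_thresh,
                 min_cluster = min_cluster, connectivity = connectivity),
            class = "cluster_map")
}

#' Select atlas ROIs supported by suprathreshold clusters
#'
#' An ROI is retained when a single cluster contributes at least
#' `min_voxels_in_roi` contiguous voxels inside that ROI (contiguity is
#' re-checked within the cluster-ROI intersection).
#'
#' @param cluster_map result of [voxelwise_group_tmap()].
#' @param atlas integer label array on the same grid.
#' @param min_voxels_in_roi contiguous-voxel requirement.
#' @param connectivity connectivity for the contiguity re-check.
#' @return integer vector of retained atlas labels (sorted).
#' @export
select_rois_from_clusters <- function(cluster_map, atlas,
                                      min_voxels_in_roi = 100,
                                      connectivity = 18) {
  stopifnot(inherits(cluster_map, "cluster_map"),
            identical(dim(atlas), dim(cluster_map$label_map)))
  selected <- integer(0)
  for (cl in cluster_map$clusters) {
    rois <- setdiff(unique(atlas[cl$voxels]), 0L)
    for (roi in rois) {
      inter <- array(FALSE, dim(atlas))
      inter[cl$voxels[atlas[cl$voxels] == roi]] <- TRUE
      lab <- label_clusters(inter, connectivity)
      if (any(lab > 0) && max(tabulate(lab[lab > 0])) >= min_voxels_in_roi)
        selected <- c(selected, roi)
    }
  }
  sort(unique(selected))
}

#' Gray-matter-weighted regional SUVR table
#'
#' Per subject and ROI, the weighted mean SUVR over voxels whose gray-matter
#' probability exceeds `gm_threshold`, weighted by that probability (weights
#' normalised to sum to 1 per ROI); `weighted = FALSE` gives the plain mean.
#' ROIs left empty by the GM mask are excluded with a warning.
#'
#' @param suvr_volumes named list of SUVR arrays, one per subject.
#' @param atlas integer label array.
#' @param gm_prob gray-matter probability array in [0, 1].
#' @param rois atlas labels to tabulate (default: all non-zero labels).
#' @param gm_threshold inclusion threshold on GM probability.
#' @param weighted weight voxels by GM probability.
#' @param roi_names optional names for the ROI columns (by atlas label).
#' @return subjects x ROI matrix of class `regional_suvr`; attribute
#'   `voxel_count` gives voxels used per ROI.
#' @export
regional_suvr <- function(suvr_volumes, atlas, gm_prob,
                          rois = NULL, gm_threshold = 0.60, weighted = TRUE,
                          roi_names = NULL) {
  stopifnot(identical(dim(atlas), dim(gm_prob)))
  if (is.null(rois)) rois <- sort(setdiff(unique(as.integer(atlas)), 0L))
  idx <- lapply(rois, function(roi) which(atlas == roi & gm_prob > gm_threshold))
  empty <- lengths(idx) == 0
  if (any(empty)) {
    warning(sprintf("ROI(s) empty after GM > %g masking, excluded: %s",
                    gm_threshold, paste(rois[empty], collapse = ", ")))
    rois <- rois[!empty]; idx <- idx[!empty]
  }
  if (!length(rois)) stop("no ROI survives GM masking")
  w <- lapply(idx, function(i) {
    wi <- if (weighted) gm_prob[i] else rep(1, length(i))
    wi / sum(wi)
  })
  tab <- t(vapply(suvr_volumes, function(vol) {
    stopifnot(identical(dim(vol), dim(atlas)))
    vapply(seq_along(idx), function(k) sum(vol[idx[[k]]] * w[[k]]), numeric(1))
  }, numeric(length(rois))))
  if (length(rois) == 1) tab <- matrix(tab, ncol = 1)
  colnames(tab) <- if (!is.null(roi_names)) roi_names[rois] else as.character(rois)
  rownames(tab) <- names(suvr_volumes)
  structure(tab, voxel_count = stats::setNames(lengths(idx), colnames(tab)),
            class = c("regional_suvr", "matrix"))
}

#' Compare regional SUVR between groups with FDR correction
#'
#' Per-ROI two-sample t-test (patients vs controls) over the regional SUVR
#' table, BH-corrected across the tabulated ROIs.
#'
#' @param table subjects x ROI matrix (e.g. from [regional_suvr()] or the
#'   cohort generator).
#' @param groups "patient"/"control" per subject (table row order).
#' @param variant t-test variant, see [t_test_two_sample()].
#' @param alpha FDR level for the significance flag.
#' @return data.frame: ROI, group means, t, raw p, corrected q, significant.
#' @export
compare_regional_suvr <- function(table, groups, variant = "pooled",
                                  alpha = 0.05) {
  g <- as_group_factor(groups, nrow(table))
  res <- lapply(seq_len(ncol(table)), function(k)
    t_test_two_sample(table[g == "patient", k], table[g == "control", k],
                      variant = variant))
  p <- vapply(res, `[[`, 0, "p_value")
  fdr <- fdr_bh(p, alpha)
  data.frame(
    roi = colnames(table),
    mean_patient = colMeans(table[g == "patient", , drop = FALSE]),
    mean_control = colMeans(table[g == "control", , drop = FALSE]),
    t = vapply(res, `[[`, 0, "statistic"),
    p = p, q = fdr$q, significant = fdr$reject,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate a region's SUVR with PSI in patients
#'
#' @param table subjects x ROI SUVR matrix.
#' @param subjects cohort subjects data.frame (needs `group`, `psi`, rows
#'   aligned with the table).
#' @param roi ROI column name or index.
#' @return an `ects_test` (estimate = Pearson r).
#' @export
suvr_psi_correlation <- function(table, subjects, roi) {
  stopifnot(nrow(table) == nrow(subjects))
  pat <- subjects$group == "patient"
  pearson_correlation(table[pat, roi], subjects$psi[pat])
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti for the PET stage's on-disk format.
#'
#' @param volume numeric array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param voxel_mm isotropic voxel size recorded in the header.
#' @return `write_volume_nifti` returns the path invisibly;
#'   `read_volume_nifti` returns a plain numeric array.
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = 2) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}
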