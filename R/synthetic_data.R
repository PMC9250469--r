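default_roi_labels <- function() {
  c("L_precentral", "R_precentral", "L_postcentral", "R_postcentral",
    "L_caudate", "R_caudate", "L_putamen", "R_putamen",
    "L_pallidum", "R_pallidum", "L_accumbens", "R_accumbens",
    "L_thalamus", "R_thalamus", "R_rostral_middle_frontal", "R_frontal_pole")
}

default_roi_lobes <- function() {
  c(rep("rolandic", 4), rep("striatal", 8), rep("thalamic", 2), rep("cortical", 2))
}

# Resting SUVR levels typical of pediatric FDG-PET: striatum high, pallidum
# and thalamus intermediate, frontal cortex high.
default_suvr_means <- function() {
  c(1.39, 1.39, 1.35, 1.35,
    1.24, 1.24, 1.47, 1.47, 1.19, 1.18, 1.04, 1.04,
    1.15, 1.15, 1.53, 1.44)
}

# A 12-edge connected subnetwork along the rolandic -> striatum -> thalamus ->
# frontal pathway, mirroring the circuit under study.
default_planted_edges <- function() {
  cbind(a = c(1, 1, 2, 3, 3, 4, 5,  6, 13, 13, 11, 14),
        b = c(2, 3, 4, 4, 5, 6, 13, 14, 14, 15, 13, 16))
}

#' Simulation configuration for a synthetic ECTS cohort
#'
#' Defaults reproduce the study conditions: 28 patients vs 20 controls, a
#' 16-ROI corticostriatal parcellation, a planted 12-edge connected subnetwork
#' whose correlations are lowered by `edge_effect` in patients, striatal and
#' frontal SUVR lowered by `suvr_effect`, and a processing speed index (PSI)
#' linearly coupled to each subject's planted-edge mean Fisher-z connectivity.
#' Control PSI is centred at 102.55 with SD near 13, the WISC-IV scale of the
#' study population.
#'
#' Patients additionally carry a latent severity factor (mean 1, SD
#' `severity_sd`, truncated symmetrically) that scales both the connectivity
#' and metabolic decrements, so within-patient variation in circuit disruption
#' propagates to both modalities and to PSI.
#'
#' @param n_patients,n_controls group sizes.
#' @param n_rois number of ROIs (defaults provide labelled names for 16).
#' @param n_timepoints BOLD frames acquired per subject (before any dropping).
#' @param tr_seconds repetition time in seconds.
#' @param planted_edges two-column matrix of ROI index pairs (a < b).
#' @param edge_effect correlation decrease (r units) on planted edges in patients.
#' @param suvr_affected_rois ROI indices with lowered metabolism in patients.
#' @param suvr_effect SUVR-unit decrease on affected ROIs.
#' @param psi_mean_control,psi_sd control PSI mean and residual SD (score units).
#' @param psi_coupling slope from subject planted-edge mean z to PSI.
#' @param severity_sd SD of the patient latent severity factor.
#' @param ar_coef temporal AR(1) coefficient of the BOLD series.
#' @param fd_spike_rate fraction of frames given motion spikes with FD > 0.2 mm.
#' @param suvr_noise_sd between-subject SD of regional SUVR.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_patients = 28, n_controls = 20,
                              n_rois = 16, n_timepoints = 200,
                              tr_seconds = 2,
                              planted_edges = default_planted_edges(),
                              edge_effect = 0.4,
                              suvr_affected_rois = c(5:11, 15, 16),
                              suvr_effect = 0.06,
                              psi_mean_control = 102.55, psi_sd = 13,
                              psi_coupling = 25,
                              severity_sd = 0.15,
                              ar_coef = 0.3,
                              fd_spike_rate = 0.02,
                              suvr_noise_sd = 0.08,
                              seed = 1) {
  stopifnot(n_patients >= 2, n_controls >= 2, n_rois >= 3,
            n_timepoints >= 20, tr_seconds > 0)
  if (abs(edge_effect) >= 1) stop("|edge_effect| must be < 1")
  planted_edges <- as.matrix(planted_edges)
  if (ncol(planted_edges) != 2) stop("planted_edges must have two columns")
  pe <- cbind(pmin(planted_edges[, 1], planted_edges[, 2]),
              pmax(planted_edges[, 1], planted_edges[, 2]))
  if (any(pe < 1) || any(pe > n_rois) || any(pe[, 1] == pe[, 2]))
    stop("planted edges must reference valid distinct ROI pairs")
  if (anyDuplicated(paste(pe[, 1], pe[, 2])))
    stop("duplicate planted edges")
  if (any(suvr_affected_rois < 1 | suvr_affected_rois > n_rois))
    stop("suvr_affected_rois out of range")
  labels <- if (n_rois == 16) default_roi_labels()
            else sprintf("ROI%02d", seq_len(n_rois))
  lobes <- if (n_rois == 16) default_roi_lobes()
           else rep(c("rolandic", "striatal", "thalamic", "cortical"),
                    each = ceiling(n_rois / 4))[seq_len(n_rois)]
  structure(list(
    n_patients = n_patients, n_controls = n_controls, n_rois = n_rois,
    n_timepoints = n_timepoints, tr_seconds = tr_seconds,
    planted_edges = unname(pe), edge_effect = edge_effect,
    suvr_affected_rois = suvr_affected_rois, suvr_effect = suvr_effect,
    psi_mean_control = psi_mean_control, psi_sd = psi_sd,
    psi_coupling = psi_coupling, severity_sd = severity_sd,
    ar_coef = ar_coef, fd_spike_rate = fd_spike_rate,
    suvr_noise_sd = suvr_noise_sd,
    roi_labels = labels, roi_lobes = lobes,
    suvr_means = rep_len(default_suvr_means(), n_rois),
    seed = as.integer(seed)), class = "sim_config")
}

# within-block r = 0.3, between-block r = 0.1, projected to the nearest
# positive-definite correlation matrix
base_correlation <- function(config) {
  blocks <- config$roi_lobes
  R <- outer(blocks, blocks, function(x, y) ifelse(x == y, 0.3, 0.1))
  diag(R) <- 1
  ensure_pd_correlation(R)
}

ensure_pd_correlation <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(R)
  as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
}

# patient target correlation: planted edges lowered by scale * edge_effect,
# then re-projected to positive definite
patient_correlation <- function(config, base, scale = 1) {
  R <- base
  pe <- config$planted_edges
  delta <- scale * config$edge_effect
  for (k in seq_len(nrow(pe))) {
    r <- max(min(R[pe[k, 1], pe[k, 2]] - delta, 0.99), -0.99)
    R[pe[k, 1], pe[k, 2]] <- R[pe[k, 2], pe[k, 1]] <- r
  }
  Rp <- ensure_pd_correlation(R)
  dev <- abs(Rp[pe] - R[pe])
  if (max(dev) > 0.02) {
    bad <- pe[dev > 0.02, , drop = FALSE]
    stop(sprintf(
      "planted edge set gives a non-positive-definite correlation target; offending edges: %s",
      paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " ")))
  }
  Rp
}

# zero-mean unit-variance MVN series with optional AR(1) temporal smoothing;
# the same AR coefficient on every ROI leaves lag-0 cross-correlations equal
# to the innovation correlation matrix
draw_series <- function(n_t, R, ar) {
  e <- MASS::mvrnorm(n_t, mu = rep(0, ncol(R)), Sigma = R)
  if (ar == 0) return(e)
  x <- apply(e, 2, function(col) stats::filter(col, ar, method = "recursive"))
  x * sqrt(1 - ar^2)
}

simulate_motion <- function(n_t, spike_rate) {
  step_t <- matrix(stats::rnorm(n_t * 3, 0, 0.008), n_t, 3)
  step_r <- matrix(stats::rnorm(n_t * 3, 0, 0.00016), n_t, 3)
  spikes <- stats::runif(n_t) < spike_rate
  spikes[1] <- FALSE
  step_t[spikes, ] <- step_t[spikes, ] * 30
  m <- cbind(apply(step_t, 2, cumsum), apply(step_r, 2, cumsum))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Simulate a synthetic ECTS cohort
#'
#' Draws subject records, per-subject ROI BOLD time series, and a regional
#' SUVR table under the planted group differences described in
#' [simulation_config()]. Each subject's PSI is
#' `psi_mean_control + psi_coupling * (mean planted-edge z - control
#' population mean z) + N(0, psi_sd)`, where the subject's mean z is computed
#' from their own realised series, so measured connectivity, metabolism and
#' PSI co-vary within the patient group as they do across the study cohort.
#'
#' @param config a `sim_config`.
#' @return list with `subjects` (data.frame), `timeseries` (named list of
#'   [roi_time_series()]), `suvr` (subjects x ROI matrix), `atlas_table`
#'   (ROI label table), and a `generator` attribute holding the generating
#'   correlation matrices and latent quantities for round-trip checks.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients + config$n_controls
  base <- base_correlation(config)
  pat_target <- patient_correlation(config, base)  # errors early if degenerate

  group <- rep(c("patient", "control"), c(config$n_patients, config$n_controls))
  id <- sprintf("S%03d", seq_len(n))
  gender <- ifelse(stats::runif(n) < ifelse(group == "patient", 12 / 28, 7 / 20),
                   "F", "M")
  age <- ifelse(group == "patient",
                stats::rnorm(n, 9.96, 2.62), stats::rnorm(n, 10.75, 2.07))
  age <- pmin(pmax(age, 6), 18)
  onset <- pmin(pmax(stats::rnorm(n, 7.68, 2.92), 1), age - 0.25)
  duration <- pmax((age - onset) * 12, 1)
  aed_cat <- sample(c("naive", "monotherapy", "polytherapy"), n, TRUE,
                    prob = c(7, 11, 10) / 28)
  aed_time <- ifelse(aed_cat == "naive", 0,
                     pmin(pmax(stats::rnorm(n, 19.39, 26.09), 1), duration))
  sev_lo <- max(0.25, 1 - 2 * config$severity_sd)
  sev_hi <- min(1.75, 1 + 2 * config$severity_sd)
  severity <- ifelse(group == "patient",
                     pmin(pmax(stats::rnorm(n, 1, config$severity_sd), sev_lo), sev_hi),
                     1)

  pe <- config$planted_edges
  z0 <- mean(atanh(base[pe]))
  sev_grid <- sort(unique(severity[group == "patient"]))
  sigma_for <- c(list(control = base),
                 stats::setNames(lapply(sev_grid, function(s)
                   patient_correlation(config, base, s)), paste0("s", sev_grid)))

  timeseries <- vector("list", n)
  z_planted <- numeric(n)
  for (i in seq_len(n)) {
    R <- if (group[i] == "patient") sigma_for[[paste0("s", severity[i])]]
         else sigma_for$control
    x <- draw_series(config$n_timepoints, R, config$ar_coef)
    colnames(x) <- config$roi_labels
    z_planted[i] <- mean(atanh(stats::cor(x)[pe]))
    motion <- simulate_motion(config$n_timepoints, config$fd_spike_rate)
    nuis <- matrix(stats::rnorm(config$n_timepoints * 2), ncol = 2,
                   dimnames = list(NULL, c("wm", "csf")))
    timeseries[[i]] <- roi_time_series(x, tr = config$tr_seconds,
                                       motion = motion, nuisance = nuis)
  }
  names(timeseries) <- id

  psi <- config$psi_mean_control +
    config$psi_coupling * (z_planted - z0) +
    stats::rnorm(n, 0, config$psi_sd)

  suvr <- matrix(rep(config$suvr_means, each = n), n, config$n_rois,
                 dimnames = list(id, config$roi_labels))
  aff <- config$suvr_affected_rois
  suvr[, aff] <- suvr[, aff] -
    ifelse(group == "patient", severity, 0) * config$suvr_effect
  suvr <- suvr + matrix(stats::rnorm(n * config$n_rois, 0, config$suvr_noise_sd),
                        n, config$n_rois)

  subjects <- data.frame(
    id = id, group = group, gender = gender,
    age_at_scan = round(age, 2),
    age_at_onset = ifelse(group == "patient", round(onset, 2), NA),
    seizure_duration = ifelse(group == "patient", round(duration, 1), NA),
    aed_time = ifelse(group == "patient", round(aed_time, 1), NA),
    aed_category = ifelse(group == "patient", aed_cat, NA),
    severity = severity,
    vci = round(stats::rnorm(n, 113, 20)),
    pri = round(stats::rnorm(n, 108, 14)),
    wmi = round(stats::rnorm(n, 100, 17)),
    psi = round(psi),
    fsiq = round(stats::rnorm(n, 108, 17)),
    stringsAsFactors = FALSE)

  atlas_table <- data.frame(label_id = seq_len(config$n_rois),
                            label_name = config$roi_labels,
                            lobe = config$roi_lobes,
                            stringsAsFactors = FALSE)

  out <- list(subjects = subjects, timeseries = timeseries, suvr = suvr,
              atlas_table = atlas_table)
  attr(out, "generator") <- list(base_cor = base, patient_cor = pat_target,
                                 severity = severity, z_planted = z_planted,
                                 z0 = z0, config = config)
  out
}

#' Simulate one subject's PET acquisition on a small labelled grid
#'
#' ROIs are disjoint cubes on a `grid_dim`^3 voxel grid with a cerebellar
#' reference slab at the bottom. Voxel intensity is the ROI-specific mean
#' (lowered by `suvr_effect * severity` on affected ROIs for patients) plus
#' i.i.d. Gaussian noise. A gray-matter probability volume marks ROI cores at
#' 0.9 and ROI shells at 0.5, so the GM > 60% mask is exercised.
#'
#' @param config a `sim_config`.
#' @param subject one row of the cohort subjects data.frame (needs `group`,
#'   `severity`).
#' @param grid_dim edge length of the voxel grid (20-40).
#' @param ref_intensity mean raw intensity of the reference region.
#' @param noise_sd raw-intensity noise SD.
#' @return list with `pet` (array), `atlas` (integer label array), `gm_prob`,
#'   `ref_mask` (logical array), and `voxel_mm`.
#' @export
simulate_pet_volume <- function(config, subject, grid_dim = 24,
                                ref_intensity = 50, noise_sd = 1) {
  stopifnot(inherits(config, "sim_config"), grid_dim >= 20, grid_dim <= 40)
  d <- c(grid_dim, grid_dim, grid_dim)
  atlas <- array(0L, d)
  gm <- array(0.2, d)
  # reference slab (cerebellum analogue)
  ref_mask <- array(FALSE, d)
  ref_mask[, , 1:4] <- TRUE
  gm[ref_mask] <- 0.8

  # ROI cubes on a lattice above the reference slab
  side <- 5
  starts <- seq(2, grid_dim - side, by = side + 2)
  zs <- starts[starts > 6]
  slots <- expand.grid(x = starts, y = starts, z = zs)
  if (nrow(slots) < config$n_rois)
    stop("grid too small for the requested number of ROIs")
  for (k in seq_len(config$n_rois)) {
    ix <- slots$x[k] + 0:(side - 1)
    iy <- slots$y[k] + 0:(side - 1)
    iz <- slots$z[k] + 0:(side - 1)
    if (any(atlas[ix, iy, iz] != 0L)) stop("overlapping ROI labels")
    atlas[ix, iy, iz] <- k
    gm[ix, iy, iz] <- 0.5                       # shell
    gm[ix[2:4], iy[2:4], iz[2:4]] <- 0.9        # core
  }

  means <- config$suvr_means
  if (identical(subject$group, "patient")) {
    sev <- if (!is.null(subject$severity)) subject$severity else 1
    means[config$suvr_affected_rois] <-
      means[config$suvr_affected_rois] - sev * config$suvr_effect
  }
  pet <- array(0.5 * ref_intensity, d)
  pet[ref_mask] <- ref_intensity
  for (k in seq_len(config$n_rois))
    pet[atlas == k] <- means[k] * ref_intensity
  if (noise_sd > 0)
    pet <- pet + array(stats::rnorm(prod(d), 0, noise_sd), d)
  list(pet = pet, atlas = atlas, gm_prob = gm, ref_mask = ref_mask,
       voxel_mm = 2)
}

#' Write a simulated cohort to disk as plain-text tables
#'
#' Writes `subjects.tsv`, `atlas.tsv`, and one `ts_<id>.tsv` per subject
#' (frames as rows; ROI columns followed by the six rigid-motion parameters).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("subjects.tsv", "atlas.tsv"))
  utils::write.table(cohort$subjects, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$atlas_table, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (id in names(cohort$timeseries)) {
    ts <- cohort$timeseries[[id]]
    tab <- cbind(as.data.frame(ts$data), as.data.frame(ts$motion))
    p <- file.path(dir, paste0("ts_", id, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read one subject's ROI time-series table written by [write_cohort()]
#'
#' @param path TSV path (ROI columns then six motion columns).
#' @param tr repetition time in seconds.
#' @return a [roi_time_series()].
#' @export
read_timeseries_tsv <- function(path, tr = 2) {
  tab <- utils::read.delim(path, check.names = FALSE)
  mcols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(mcols %in% names(tab)))
    stop("expected six motion-parameter columns (trans_*, rot_*)")
  roi_time_series(as.matrix(tab[, setdiff(names(tab), mcols), drop = FALSE]),
                  tr = tr, motion = as.matrix(tab[, mcols]))
}
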