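#' Monte-Carlo type-I error of the Williams test
#'
#' Simulates trivariate normal samples under the null of equal dependent
#' correlations (`r12 = r13`) and returns the rejection rate of
#' [williams_t()] at level `alpha`. Used to verify the test's calibration.
#'
#' @param n_rep Number of replicates (default 10000).
#' @param n Sample size per replicate (default 50).
#' @param r12,r13,r23 Population correlations (defaults 0.5, 0.5, 0.7 —
#'   a null configuration typical of two processing variants of one
#'   measure).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return Rejection rate (scalar).
#' @export
williams_type1_rate <- function(n_rep = 10000, n = 50, r12 = 0.5,
                                r13 = 0.5, r23 = 0.7, alpha = 0.05,
                                seed = 1L) {
  R <- matrix(c(1, r12, r13,
                r12, 1, r23,
                r13, r23, 1), 3, 3)
  L <- chol(R)
  set.seed(seed)
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    Z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
    C <- stats::cor(Z)
    ht <- williams_t(C[1, 2], C[1, 3], C[2, 3], n)
    rej[i] <- ht$p.value < alpha
  }
  mean(rej)
}

#' Familywise error of the permutation maxT threshold under the null
#'
#' Generates null Gaussian image datasets (no group difference), computes
#' the permutation maxT threshold for each, and reports the fraction of
#' datasets in which any voxel of the observed comparison exceeds it — the
#' empirical familywise error, which should be close to `alpha`.
#'
#' @param n_datasets Number of replicate datasets (default 20).
#' @param grid Cube edge in voxels (default 24; the full grid is the
#'   analysis mask).
#' @param n_per_group Subjects per group (default 12).
#' @param n_perm Permutations per dataset (default 500).
#' @param alpha Level (default 0.05).
#' @param seed Integer seed.
#' @return List with `rate` and the per-dataset logical vector `rejected`.
#' @export
fwe_null_rate <- function(n_datasets = 20, grid = 24, n_per_group = 12,
                          n_perm = 500, alpha = 0.05, seed = 1L) {
  nvox <- grid^3
  rejected <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(seed + 1000 * d)
    X <- matrix(stats::rnorm(nvox * 2 * n_per_group), nvox)
    lab <- c(rep(TRUE, n_per_group), rep(FALSE, n_per_group))
    thr <- fwe_threshold_maxT(X, lab, n_perm = n_perm, alpha = alpha,
                              seed = seed + d)
    tobs <- voxel_t_test(X[, lab, drop = FALSE], X[, !lab, drop = FALSE])
    rejected[d] <- max(tobs$t, na.rm = TRUE) > thr
  }
  list(rate = mean(rejected), rejected = rejected)
}

#' Replicated low-tertile association study
#'
#' Simulates `n_rep` cohorts through the tabular fast path and, for each,
#' compares the CSF Abeta42 correlation of the PVC-3 and no-PVC SUVRs
#' (whole-cerebellum reference) within the low tertile of the *standard*
#' (no-PVC) SUVR distribution — the shared subset a dependent-correlation
#' comparison requires. Returns per-replicate correlations and the Williams
#' t of the comparison.
#'
#' @param n_rep Number of replicate cohorts (default 50).
#' @param n Subjects per cohort (default 600).
#' @param spec Phantom specification (default [phantom_spec()]).
#' @param seed Integer base seed; replicate r uses `seed + r`.
#' @return Data frame with columns `rep`, `r_pvc3`, `r_none`, `t`, `p`.
#' @export
study_low_tertile <- function(n_rep = 50, n = 600, spec = phantom_spec(),
                              seed = 20000L) {
  maps <- build_phantom(spec)
  transfer <- suvr_transfer(maps, spec)
  rows <- lapply(seq_len(n_rep), function(r) {
    cohort <- simulate_cohort(n, spec, seed = seed + r, volumes = FALSE)
    tab <- compute_suvr_table_fast(cohort, transfer)
    cmp <- tertile_method_comparison(tab, "suvr_pvc3_wc", "suvr_none_wc")
    low <- cmp[cmp$stratum == "low", ]
    data.frame(rep = r, r_pvc3 = low$r_a, r_none = low$r_b,
               t = low$t, p = low$p)
  })
  do.call(rbind, rows)
}

#' Replicated sliding-window detection study
#'
#' Simulates `n_rep` volumetric cohorts, runs the full sliding-window
#' voxel-wise detection once with no-PVC and once with PVC-3 SUVR maps on
#' the same subjects and window plan, and records the group-mean CSF
#' Abeta42 of the earliest detecting window for each method. Higher values
#' mean earlier detection on the biomarker scale.
#'
#' @param n_rep Number of replicates (default 25).
#' @param n Subjects per cohort (default 150).
#' @param spec Phantom specification (default 48^3 grid).
#' @param q Reference quantile (default 0.15).
#' @param s Slide (default 3).
#' @param alpha FWE level (default 0.05).
#' @param k Cluster extent threshold (default 150).
#' @param n_perm Permutations per window (default 200).
#' @param seed Integer base seed.
#' @return Data frame with columns `rep`, `csf_pvc3`, `csf_none`
#'   (NA = method never detected), `win_pvc3`, `win_none`.
#' @export
study_detection_order <- function(n_rep = 25, n = 150,
                                  spec = phantom_spec(grid_shape =
                                                        c(48L, 48L, 48L)),
                                  q = 0.15, s = 3, alpha = 0.05, k = 150,
                                  n_perm = 200, seed = 30000L) {
  maps <- build_phantom(spec)
  plan <- plan_windows(n, q, s = s)
  amask <- maps$composite_cortical_mask
  rows <- lapply(seq_len(n_rep), function(r) {
    cohort <- simulate_cohort(n, spec, seed = seed + r, maps = maps,
                              volumes = TRUE)
    res <- lapply(c(none = "none", pvc3 = "pvc3"), function(m) {
      mats <- detection_maps(cohort, maps, method = m)
      sliding_window_analysis(mats, cohort$table$csf_ab42, plan,
                              alpha = alpha, k = k, n_perm = n_perm,
                              seed = seed + 101L * r,
                              analysis_mask = amask)
    })
    data.frame(rep = r,
               csf_pvc3 = res$pvc3$earliest_mean_csf,
               csf_none = res$none$earliest_mean_csf,
               win_pvc3 = ifelse(is.na(res$pvc3$earliest), NA,
                                 res$pvc3$earliest),
               win_none = ifelse(is.na(res$none$earliest), NA,
                                 res$none$earliest))
  })
  do.call(rbind, rows)
}

#' Summarize a detection study into an ordering proportion
#'
#' A replicate counts as consistent with the expected ordering when PVC-3
#' detects at a group-mean CSF level at least as high as no-PVC: both
#' detect and `csf_pvc3 >= csf_none`, PVC-3 detects while no-PVC does not,
#' or neither detects.
#'
#' @param det [study_detection_order()] output.
#' @return Proportion in `[0, 1]`.
#' @export
detection_order_proportion <- function(det) {
  ok <- mapply(function(c3, c0) {
    if (is.na(c3) && is.na(c0)) return(TRUE)
    if (is.na(c0)) return(TRUE)    # only PVC-3 detected
    if (is.na(c3)) return(FALSE)   # only no-PVC detected
    c3 >= c0
  }, det$csf_pvc3, det$csf_none)
  mean(ok)
}
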