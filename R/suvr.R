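#' Reference-region value
#'
#' Mean uptake over a reference mask, always taken from the *uncorrected*
#' PET image — the reference scalar is shared by all correction methods.
#'
#' @param pet_uncorrected Uncorrected PET volume.
#' @param ref_mask Non-empty logical mask.
#' @return Scalar mean uptake.
#' @export
reference_value <- function(pet_uncorrected, ref_mask) {
  if (!any(ref_mask)) stop("reference mask is empty")
  mean(pet_uncorrected[ref_mask])
}

#' ROI mean excluding undefined voxels
#'
#' Mean of `image` over `mask` intersected with `valid_mask`; `NaN`/`NA`
#' voxels are excluded. The fraction of ROI voxels excluded is attached as
#' attribute `"excluded_fraction"` for QC.
#'
#' @param image Volume (possibly containing `NaN` outside a PVC valid mask).
#' @param mask Logical ROI mask.
#' @param valid_mask Optional logical validity mask (default: all voxels).
#' @return Scalar mean with attribute `excluded_fraction`.
#' @export
roi_mean <- function(image, mask, valid_mask = NULL) {
  sel <- mask
  if (!is.null(valid_mask)) sel <- sel & valid_mask
  vals <- image[sel]
  keep <- is.finite(vals)
  if (!any(keep)) stop("ROI mask has no valid voxels")
  structure(mean(vals[keep]),
            excluded_fraction = 1 - sum(keep) / sum(mask))
}

#' Voxel-wise SUVR map
#'
#' Scales each voxel by the reference scalar, restricts to the gray-matter
#' mask, and smooths within the mask with a Gaussian kernel (default FWHM
#' 10 mm per axis). Smoothing uses within-mask kernel renormalization
#' (`smooth(x * m) / smooth(m)`), so a constant map stays exactly constant
#' and edge voxels are not diluted by the excluded exterior.
#'
#' @param pet Volume (corrected or uncorrected).
#' @param ref_scalar Positive reference value from [reference_value()].
#' @param gm_mask Logical gray-matter mask.
#' @param smooth_fwhm Smoothing FWHM in mm (0 disables smoothing).
#' @param voxel_size Voxel edge length in mm.
#' @return Volume with SUVR inside the mask and `NaN` outside.
#' @export
voxelwise_suvr_map <- function(pet, ref_scalar, gm_mask, smooth_fwhm = 10,
                               voxel_size = 2) {
  if (ref_scalar <= 0) stop("ref_scalar must be positive")
  m <- array(as.numeric(gm_mask), dim(pet))
  x <- pet / ref_scalar
  x[!gm_mask] <- 0
  x[gm_mask & !is.finite(x)] <- 0
  if (smooth_fwhm > 0) {
    num <- smooth_psf(x, psf_model(smooth_fwhm), voxel_size)
    den <- smooth_psf(m, psf_model(smooth_fwhm), voxel_size)
    x <- num / pmax(den, .Machine$double.eps)
  }
  x[!gm_mask] <- NaN
  x
}

#' Six-variant SUVR table for a simulated cohort (volumetric path)
#'
#' For every subject, applies the three correction methods (`none`, `pvc2`,
#' `pvc3`) to the PET volume and computes the composite cortical ROI mean
#' divided by each of the two reference values (whole cerebellum `wc` and
#' white matter `wm`, both always from uncorrected data) — six SUVR values
#' per subject.
#'
#' @param cohort An [simulate_cohort()] result with volumes.
#' @param maps Tissue maps (default: taken from the cohort).
#' @param c_wm `"estimate"` to estimate the WM activity from deep WM per
#'   subject, or `"truth"` to use the subject's true value.
#' @param erosion_mm Deep-WM erosion for the estimate (default 4).
#' @return `data.frame` of class `suvr_table` with columns `subject_id`,
#'   `burden`, `csf_ab42`, `group`, and `suvr_<method>_<ref>` for the six
#'   variants.
#' @export
compute_suvr_table <- function(cohort, maps = cohort$maps,
                               c_wm = c("estimate", "truth"),
                               erosion_mm = 4) {
  c_wm <- match.arg(c_wm)
  stopifnot(inherits(cohort, "amy_cohort"), !is.null(maps))
  spec <- cohort$spec
  psf <- psf_model(spec$psf_fwhm)
  vs <- spec$voxel_size
  wmref <- maps$wm > 0.99
  comp <- maps$composite_cortical_mask
  rows <- lapply(cohort$subjects, function(s) {
    if (is.null(s$pet)) stop("cohort was simulated without volumes")
    pet <- s$pet$volume
    cw <- if (c_wm == "truth") s$truth$c_wm else
      estimate_wm_activity(pet, maps$wm, vs, erosion_mm)
    res <- list(
      none = apply_pvc("none", pet, maps$gm, maps$wm, psf, vs),
      pvc2 = apply_pvc("pvc2", pet, maps$gm, maps$wm, psf, vs),
      pvc3 = apply_pvc("pvc3", pet, maps$gm, maps$wm, psf, vs, c_wm = cw)
    )
    refs <- c(wc = reference_value(pet, maps$cerebellum_mask),
              wm = reference_value(pet, wmref))
    out <- numeric(0)
    for (m in names(res)) for (r in names(refs)) {
      out[paste("suvr", m, r, sep = "_")] <-
        as.numeric(roi_mean(res[[m]]$corrected, comp,
                            res[[m]]$valid_mask)) / refs[[r]]
    }
    out
  })
  finish_suvr_table(cohort, do.call(rbind, rows))
}

finish_suvr_table <- function(cohort, suvr_mat) {
  tab <- cbind(cohort$table[c("subject_id", "burden", "csf_ab42")],
               group = cut(cohort$table$burden, c(-0.01, 1 / 3, 2 / 3, 1.01),
                           labels = c("low", "intermediate", "high")),
               as.data.frame(suvr_mat))
  class(tab) <- c("suvr_table", "data.frame")
  tab
}

#' @export
print.suvr_table <- function(x, ...) {
  cat("SUVR table:", nrow(x), "subjects x 6 variants",
      "({none,pvc2,pvc3} x {wc,wm})\n")
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Precompute linear SUVR transfer coefficients for the phantom
#'
#' Every noiseless ROI mean in the pipeline is linear in the subject's
#' compartment activities (per-parcel GM, cerebellar GM, WM), because PSF
#' blurring and the PVC operators (at fixed tissue maps) are linear in the
#' activity image. This precomputes, per activity basis image, the
#' composite-ROI means under each correction, the two reference means, and
#' the deep-WM mean used by the WM-activity estimator — plus the exact noise
#' covariance of these ROI functionals under the additive voxel noise model
#' (`Cov = noise_sd^2 * <K w_i, K w_j>` for ROI weight vectors `w` and PSF
#' operator `K`).
#'
#' @param maps [build_phantom()] output.
#' @param spec A [phantom_spec] (default: from `maps`).
#' @return Object of class `suvr_transfer` used by
#'   [compute_suvr_table_fast()].
#' @export
suvr_transfer <- function(maps, spec = maps$spec) {
  psf <- psf_model(spec$psf_fwhm)
  vs <- spec$voxel_size
  lab <- maps$parcel_labels
  np <- nrow(spec$parcel_defs)

  basis <- c(lapply(seq_len(np), function(j)
               maps$gm * (lab == spec$parcel_defs$label[j])),
             list(cereb = maps$gm * maps$cerebellum_mask,
                  wm = maps$wm))
  names(basis)[seq_len(np)] <- spec$parcel_defs$name
  K <- lapply(basis, smooth_psf, psf = psf, voxel_size = vs)

  sg <- smooth_psf(maps$gm, psf, vs)
  sb <- smooth_psf(maps$gm + maps$wm, psf, vs)
  sw <- K$wm
  comp <- maps$composite_cortical_mask
  m2 <- comp & (sb > 0.3)
  m3 <- comp & (sg > 0.3)
  cereb <- maps$cerebellum_mask
  wmref <- maps$wm > 0.99
  deep <- maps$deep_wm_mask

  coefs <- sapply(K, function(b) c(
    none = mean(b[comp]),
    pvc2 = mean(b[m2] / sb[m2]),
    pvc3 = mean(b[m3] / sg[m3]),
    wc = mean(b[cereb]),
    wmr = mean(b[wmref]),
    deep = mean(b[deep])
  ))
  W3 <- mean(sw[m3] / sg[m3])   # pvc3 response to the subtracted WM scalar

  ## ROI weight vectors for exact noise propagation
  wvec <- function(mask, den = NULL) {
    w <- array(0, dim(maps$gm))
    w[mask] <- if (is.null(den)) 1 / sum(mask) else 1 / (sum(mask) * den[mask])
    w
  }
  weights <- list(none = wvec(comp), pvc2 = wvec(m2, sb), pvc3 = wvec(m3, sg),
                  wc = wvec(cereb), wmr = wvec(wmref), deep = wvec(deep))
  ## pvc3 with estimated c_wm also inherits the estimator's noise
  weights$pvc3_est <- weights$pvc3 - W3 * weights$deep
  g <- lapply(weights, smooth_psf, psf = psf, voxel_size = vs)
  nm <- c("none", "pvc2", "pvc3", "pvc3_est", "wc", "wmr")
  gram <- sapply(nm, function(i) sapply(nm, function(j)
    sum(g[[i]] * g[[j]])))

  ## smooth-field contribution: functional = c_f * (F (tissue * K w))' eta
  field_cov <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (spec$field_sd > 0) {
    tissue <- maps$gm + maps$wm
    fpsf <- psf_model(spec$field_fwhm)
    h <- lapply(g, function(gi) smooth_psf(tissue * gi, fpsf, vs))
    kf <- gauss_kernel_1d(spec$field_fwhm, vs)
    cf2 <- spec$field_sd^2 / sum(kf^2)^3
    field_cov <- cf2 * sapply(nm, function(i) sapply(nm, function(j)
      sum(h[[i]] * h[[j]])))
  }

  structure(list(coefs = coefs, W3 = W3, noise_gram = gram,
                 field_cov = field_cov,
                 parcel_names = spec$parcel_defs$name, spec = spec),
            class = "suvr_transfer")
}

#' Six-variant SUVR table via the linear fast path
#'
#' Computes the same six SUVR variants as [compute_suvr_table()] without
#' synthesizing any volume: noiseless ROI means come from the precomputed
#' linear transfer coefficients, and the effect of voxel noise on each ROI
#' functional is drawn from its exactly propagated Gaussian distribution
#' (see [suvr_transfer()]). Biological between-subject variability
#' (per-subject `c_wm`, `c_gm_ns`) enters through the subject truths.
#'
#' @param cohort [simulate_cohort()] result (volumes not required).
#' @param transfer [suvr_transfer()] output for the cohort's phantom.
#' @param c_wm `"estimate"` (deep-WM estimator, including its noise) or
#'   `"truth"`.
#' @param noise If `FALSE`, suppress the propagated observation noise.
#' @return A `suvr_table` (see [compute_suvr_table()]).
#' @export
compute_suvr_table_fast <- function(cohort, transfer,
                                    c_wm = c("estimate", "truth"),
                                    noise = TRUE) {
  c_wm <- match.arg(c_wm)
  stopifnot(inherits(cohort, "amy_cohort"), inherits(transfer, "suvr_transfer"))
  spec <- cohort$spec
  co <- transfer$coefs
  nm3 <- if (c_wm == "estimate") "pvc3_est" else "pvc3"
  Cmat <- spec$noise_sd^2 * transfer$noise_gram + transfer$field_cov
  use <- c("none", "pvc2", nm3, "wc", "wmr")
  Cuse <- Cmat[use, use]
  n <- nrow(cohort$table)
  rows <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL, c("suvr_none_wc", "suvr_none_wm",
                                         "suvr_pvc2_wc", "suvr_pvc2_wm",
                                         "suvr_pvc3_wc", "suvr_pvc3_wm")))
  for (i in seq_len(n)) {
    tr <- cohort$subjects[[i]]$truth
    cvec <- c(tr$c_parcel[transfer$parcel_names], tr$c_cereb, tr$c_wm)
    vals <- drop(co %*% cvec)     # none, pvc2, pvc3, wc, wmr, deep per basis
    cw_hat <- if (c_wm == "estimate") vals[["deep"]] else tr$c_wm
    target <- c(none = vals[["none"]], pvc2 = vals[["pvc2"]],
                pvc3 = vals[["pvc3"]] - cw_hat * transfer$W3)
    refs <- c(wc = vals[["wc"]], wm = vals[["wmr"]])
    if (noise && (spec$noise_sd > 0 || spec$field_sd > 0)) {
      set.seed(cohort$table$seed[i])
      eps <- drop(MASS::mvrnorm(1, rep(0, 5), Cuse))
      target <- target + eps[1:3]
      refs <- refs + eps[4:5]
    }
    rows[i, ] <- c(target["none"] / refs, target["pvc2"] / refs,
                   target["pvc3"] / refs)
  }
  finish_suvr_table(cohort, rows)
}
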