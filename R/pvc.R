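#' Estimate white-matter activity from deep white matter
#'
#' The three-compartment correction needs a scalar WM activity. It is
#' estimated as the mean PET value over the high-confidence WM support
#' (`wm_prob > 0.99`) eroded by `erosion_mm`, so that voxels contaminated by
#' gray-matter spill-in near the GM/WM interface are excluded.
#'
#' @param pet Observed PET volume.
#' @param wm_prob WM probability volume on the same grid.
#' @param voxel_size Voxel edge length in mm.
#' @param erosion_mm Erosion radius in mm (default 4).
#' @return Scalar WM activity estimate.
#' @export
estimate_wm_activity <- function(pet, wm_prob, voxel_size, erosion_mm = 4) {
  if (!all(dim(pet) == dim(wm_prob)))
    stop("pet and wm_prob must be on one grid")
  deep <- erode_mask(wm_prob > 0.99, erosion_mm, voxel_size)
  if (!any(deep))
    stop("eroded deep-WM mask is empty; try a smaller erosion_mm")
  mean(pet[deep])
}

#' Two-compartment (Meltzer-type) partial-volume correction
#'
#' Divides the observed image by the PSF-blurred brain-tissue probability
#' `smooth(gm + wm)`, recovering signal diluted by spill-out into CSF and
#' background. White-matter spill-in is *not* modeled: a cortical voxel
#' neighbouring hot white matter keeps its spill-in contamination after
#' correction, which is the mechanistic weakness of this method for
#' white-matter-avid amyloid tracers.
#'
#' @param pet Observed PET volume.
#' @param gm_prob,wm_prob Tissue probability volumes on the same grid.
#' @param psf A [psf_model] (or FWHM in mm).
#' @param voxel_size Voxel edge length in mm.
#' @param tau_brain Validity threshold on the blurred brain probability
#'   (default 0.3); voxels below it are undefined (`NaN`).
#' @return Object of class `pvc_result`: list with `corrected`,
#'   `valid_mask`, `method`, `neg_fraction` (fraction of negative corrected
#'   voxels within the valid mask), `c_wm_est` (`NA` for this method).
#' @export
pvc2_meltzer <- function(pet, gm_prob, wm_prob, psf, voxel_size,
                         tau_brain = 0.3) {
  stopifnot(all(dim(pet) == dim(gm_prob)), all(dim(pet) == dim(wm_prob)))
  sb <- smooth_psf(gm_prob + wm_prob, psf, voxel_size)
  valid <- sb > tau_brain
  corrected <- array(NaN, dim(pet))
  corrected[valid] <- pet[valid] / sb[valid]
  new_pvc_result(corrected, valid, "pvc2", NA_real_)
}

#' Three-compartment (Mueller-Gartner-type) partial-volume correction
#'
#' Subtracts the modeled white-matter contribution `c_wm * smooth(wm)` from
#' the observed image and divides by the blurred gray-matter probability
#' `smooth(gm)`, correcting both gray-matter spill-out and white-matter
#' spill-in; the CSF compartment is assumed to carry zero activity. Negative
#' corrected voxels (possible under noise) are kept, not clipped, so ROI
#' means remain unbiased; their fraction is reported for QC.
#'
#' @inheritParams pvc2_meltzer
#' @param c_wm Scalar white-matter activity (true value or
#'   [estimate_wm_activity()] output); must be >= 0.
#' @param tau_gm Validity threshold on the blurred GM probability
#'   (default 0.3).
#' @return Object of class `pvc_result` (see [pvc2_meltzer]); `c_wm_est`
#'   records the WM activity used.
#' @export
pvc3_muller_gartner <- function(pet, gm_prob, wm_prob, psf, voxel_size,
                                c_wm, tau_gm = 0.3) {
  stopifnot(all(dim(pet) == dim(gm_prob)), all(dim(pet) == dim(wm_prob)))
  if (c_wm < 0) stop("c_wm must be >= 0")
  sg <- smooth_psf(gm_prob, psf, voxel_size)
  sw <- smooth_psf(wm_prob, psf, voxel_size)
  valid <- sg > tau_gm
  corrected <- array(NaN, dim(pet))
  corrected[valid] <- (pet[valid] - c_wm * sw[valid]) / sg[valid]
  new_pvc_result(corrected, valid, "pvc3", c_wm)
}

new_pvc_result <- function(corrected, valid, method, c_wm_est) {
  structure(list(
    corrected = corrected, valid_mask = valid, method = method,
    c_wm_est = c_wm_est,
    neg_fraction = if (any(valid)) mean(corrected[valid] < 0) else NA_real_
  ), class = "pvc_result")
}

#' @export
print.pvc_result <- function(x, ...) {
  cat("PVC result (", x$method, "): ", sum(x$valid_mask),
      " valid voxels; negative fraction ",
      signif(x$neg_fraction, 3), "\n", sep = "")
  if (!is.na(x$c_wm_est)) cat("  WM activity used:", x$c_wm_est, "\n")
  invisible(x)
}

#' Apply a named correction method
#'
#' Convenience dispatcher over the three processing strategies: `"none"`
#' (identity, valid everywhere the brain probability is positive), `"pvc2"`,
#' `"pvc3"`.
#'
#' @param method One of `"none"`, `"pvc2"`, `"pvc3"`.
#' @inheritParams pvc3_muller_gartner
#' @return A `pvc_result`.
#' @export
apply_pvc <- function(method = c("none", "pvc2", "pvc3"), pet, gm_prob,
                      wm_prob, psf, voxel_size, c_wm = NULL,
                      tau_gm = 0.3, tau_brain = 0.3) {
  method <- match.arg(method)
  switch(method,
    none = new_pvc_result(pet, array(TRUE, dim(pet)), "none", NA_real_),
    pvc2 = pvc2_meltzer(pet, gm_prob, wm_prob, psf, voxel_size, tau_brain),
    pvc3 = {
      if (is.null(c_wm))
        c_wm <- estimate_wm_activity(pet, wm_prob, voxel_size)
      pvc3_muller_gartner(pet, gm_prob, wm_prob, psf, voxel_size, c_wm,
                          tau_gm)
    })
}
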