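#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric array with attributes `voxel_size` (mm) and `affine`;
#'   undefined voxels are preserved as `NaN`.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  out <- array(as.numeric(im), dim = dim(im))
  attr(out, "voxel_size") <- unname(RNifti::pixdim(im)[1])
  attr(out, "affine") <- unclass(RNifti::xform(im))
  out
}

#' Write a volume as NIfTI-1
#'
#' The affine is `diag(voxel_size)` with the origin at the grid center;
#' undefined voxels are written as `NaN` (double datatype).
#'
#' @param volume Numeric 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = 2) {
  d <- dim(volume)
  offs <- -(d - 1) / 2 * voxel_size
  hdr <- RNifti::niftiHeader(list(
    dim = c(3L, d, 1L, 1L, 1L, 1L),
    pixdim = c(1, rep(voxel_size, 3), 0, 0, 0, 0),
    qform_code = 2L, quatern_b = 0, quatern_c = 0, quatern_d = 0,
    qoffset_x = offs[1], qoffset_y = offs[2], qoffset_z = offs[3]))
  im <- RNifti::asNifti(volume, reference = hdr, datatype = "double")
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Assemble a run configuration
#'
#' All tunables of the pipeline in one serializable list; unspecified
#' entries take the documented defaults. The resolved configuration is
#' emitted alongside every [run_pipeline()] results bundle, so a run is
#' fully described by its config and seed.
#'
#' @param ... Named overrides of the defaults.
#' @return Object of class `amy_config` (a named list).
#' @export
amy_config <- function(...) {
  defaults <- list(
    n_subjects = 30,
    grid_shape = c(48L, 48L, 48L),
    voxel_size = 2,
    cortical_thickness = 6,
    psf_fwhm = 8,
    noise_sd = 0.05,
    csf_sigma = 0.15,
    suvr_smooth_fwhm = 10,
    c_wm_source = "estimate",
    wm_erosion_mm = 4,
    tau_gm = 0.3, tau_brain = 0.3,
    ref_quantile = 0.15, slide = 3,
    alpha = 0.05, cluster_k = 150, n_perm = 500,
    sliding_knot_steps = 100,
    volumes = TRUE,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "amy_config")
}

#' Write / read a configuration as YAML
#'
#' @param config An [amy_config()].
#' @param path File path.
#' @return `read_config` returns the `amy_config`; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(amy_config, yaml::read_yaml(path))
}

## short deterministic fingerprint of a config for provenance stamping
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 997)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> PVC -> SUVR -> association statistics ->
#' (optionally) sliding-window detection, entirely in memory, and returns a
#' results bundle stamped with the resolved configuration, its hash and the
#' seed. With `config$volumes = FALSE` the SUVR table is computed through
#' the linear fast path and the voxel-wise detection stage is skipped.
#'
#' @param config An [amy_config()].
#' @param out_dir Optional directory: if given, writes `suvr.csv`,
#'   `cohort.csv`, `assoc.json`-style YAML summaries and the resolved
#'   config.
#' @return Object of class `amy_results`: list with `config`, `hash`,
#'   `cohort_table`, `suvr`, `assoc`, `detection` (or `NULL`), `timings`.
#' @export
run_pipeline <- function(config = amy_config(), out_dir = NULL) {
  stopifnot(inherits(config, "amy_config"))
  t0 <- proc.time()[["elapsed"]]
  spec <- phantom_spec(grid_shape = config$grid_shape,
                       voxel_size = config$voxel_size,
                       cortical_thickness = config$cortical_thickness,
                       psf_fwhm = config$psf_fwhm,
                       noise_sd = config$noise_sd,
                       seed = config$seed)
  spec$csf_params$sigma <- config$csf_sigma
  maps <- build_phantom(spec)
  cohort <- simulate_cohort(config$n_subjects, spec, seed = config$seed,
                            maps = maps, volumes = isTRUE(config$volumes))
  t_sim <- proc.time()[["elapsed"]]

  suvr <- if (isTRUE(config$volumes)) {
    compute_suvr_table(cohort, maps, c_wm = config$c_wm_source,
                       erosion_mm = config$wm_erosion_mm)
  } else {
    compute_suvr_table_fast(cohort, suvr_transfer(maps, spec),
                            c_wm = config$c_wm_source)
  }
  t_suvr <- proc.time()[["elapsed"]]

  assoc <- local({
    x <- zscale(suvr$suvr_pvc3_wc); y <- zscale(suvr$csf_ab42)
    x0 <- zscale(suvr$suvr_none_wc)
    list(
      spline_pvc3 = fit_linear_spline(x, y),
      spline_none = fit_linear_spline(x0, y),
      sliding_pvc3 = sliding_first_knot(x, y,
                                        steps = config$sliding_knot_steps),
      tertiles = lapply(c(none = "suvr_none_wc", pvc2 = "suvr_pvc2_wc",
                          pvc3 = "suvr_pvc3_wc"), function(cl)
        tertile_correlations(suvr[[cl]], suvr$csf_ab42)),
      williams = compare_methods(suvr),
      tertile_comparison = tertile_method_comparison(suvr)
    )
  })
  t_assoc <- proc.time()[["elapsed"]]

  detection <- NULL
  if (isTRUE(config$volumes)) {
    plan <- plan_windows(config$n_subjects, config$ref_quantile,
                         s = config$slide)
    amask <- maps$composite_cortical_mask
    detection <- lapply(c(none = "none", pvc3 = "pvc3"), function(m) {
      mats <- detection_maps(cohort, maps, method = m,
                             smooth_fwhm = config$suvr_smooth_fwhm,
                             c_wm = config$c_wm_source)
      sliding_window_analysis(mats, cohort$table$csf_ab42, plan,
                              alpha = config$alpha, k = config$cluster_k,
                              n_perm = config$n_perm, seed = config$seed,
                              analysis_mask = amask)
    })
  }
  t_det <- proc.time()[["elapsed"]]

  res <- structure(list(
    config = config, hash = config_hash(config),
    cohort_table = cohort$table, suvr = suvr, assoc = assoc,
    detection = detection,
    timings = c(simulate = t_sim - t0, suvr = t_suvr - t_sim,
                assoc = t_assoc - t_suvr, detection = t_det - t_assoc)
  ), class = "amy_results")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$table, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(suvr), file.path(out_dir, "suvr.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    summary_list <- list(
      hash = res$hash, seed = config$seed,
      williams_t = unname(assoc$williams$statistic),
      williams_p = assoc$williams$p.value,
      tertile_r = lapply(assoc$tertiles, function(z)
        z[c("r_low", "r_mid", "r_high", "r_total")]),
      earliest_mean_csf = if (!is.null(detection))
        lapply(detection, `[[`, "earliest_mean_csf") else NULL)
    yaml::write_yaml(summary_list, file.path(out_dir, "results.yaml"))
  }
  res
}

#' Voxel-wise SUVR maps for the detection stage
#'
#' Builds the per-subject voxel-wise SUVR maps (whole-cerebellum reference,
#' GM-masked, within-mask smoothed) for one correction method and returns
#' them as a masked voxel-by-subject matrix over the composite cortical
#' mask.
#'
#' @param cohort Cohort with volumes.
#' @param maps Tissue maps.
#' @param method `"none"`, `"pvc2"` or `"pvc3"`.
#' @param smooth_fwhm Map smoothing FWHM in mm (default 10).
#' @param c_wm `"estimate"` or `"truth"` for the pvc3 WM activity.
#' @return Matrix, composite-cortical voxels x subjects.
#' @export
detection_maps <- function(cohort, maps, method = "none", smooth_fwhm = 10,
                           c_wm = "estimate") {
  spec <- cohort$spec
  psf <- psf_model(spec$psf_fwhm)
  vs <- spec$voxel_size
  amask <- maps$composite_cortical_mask
  gm_mask <- maps$gm > 0.5
  ## blurred tissue maps and the mask-smoothing denominator are
  ## subject-independent: compute once
  sg <- smooth_psf(maps$gm, psf, vs)
  sw <- smooth_psf(maps$wm, psf, vs)
  sb <- sg + sw
  den <- if (smooth_fwhm > 0)
    smooth_psf(array(as.numeric(gm_mask), dim(gm_mask)),
               psf_model(smooth_fwhm), vs)
  vapply(cohort$subjects, function(s) {
    pet <- s$pet$volume
    x <- switch(method,
      none = pet,
      pvc2 = ifelse(sb > 0.3, pet / sb, 0),
      pvc3 = {
        cw <- if (c_wm == "truth") s$truth$c_wm
              else mean(pet[maps$deep_wm_mask])
        ifelse(sg > 0.3, (pet - cw * sw) / sg, 0)
      },
      stop("unknown method"))
    x <- x / reference_value(pet, maps$cerebellum_mask)
    x[!gm_mask] <- 0
    if (smooth_fwhm > 0) {
      x <- smooth_psf(x, psf_model(smooth_fwhm), vs) /
        pmax(den, .Machine$double.eps)
    }
    x[amask]
  }, numeric(sum(amask)))
}

#' @export
print.amy_results <- function(x, ...) {
  cat("amypvc pipeline results (config", x$hash, ", seed", x$config$seed,
      ")\n")
  cat("  subjects:", nrow(x$cohort_table), "\n")
  cat("  Williams t (pvc3 vs none, wc):",
      signif(unname(x$assoc$williams$statistic), 4),
      " p =", signif(x$assoc$williams$p.value, 3), "\n")
  if (!is.null(x$detection)) {
    for (m in names(x$detection)) {
      e <- x$detection[[m]]$earliest_mean_csf
      cat("  earliest detection (", m, "): ",
          if (is.na(e)) "none" else sprintf("%.0f pg/ml", e), "\n", sep = "")
    }
  }
  cat("  timings (s):", paste(names(x$timings),
                              round(x$timings, 1), collapse = ", "), "\n")
  invisible(x)
}
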