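#' Specification of the digital brain phantom
#'
#' The phantom is a nested-ellipsoid digital brain: a cerebral ellipsoid with
#' a cortical gray-matter ribbon of fixed thickness over a white-matter
#' interior, central ventricular CSF, a thin exterior CSF shell, and a
#' separate cerebellar gray-matter blob inferior to the cerebrum that serves
#' as reference region. The cortical ribbon is tiled into named parcels, each
#' with an amyloid onset threshold `a_on` and accumulation slope `k`:
#' "early" parcels (low `a_on`) begin to accumulate tracer-avid amyloid at
#' lower latent burden than "late" parcels, mimicking the regional staging of
#' cortical amyloidosis.
#'
#' Activity levels are in arbitrary activity units with florbetapir-like
#' contrast: high unspecific white-matter binding (`c_wm`, default 2.0),
#' lower nonspecific gray-matter binding (`c_gm_ns`, default 0.8, shared by
#' the cerebellum), and specific cortical binding growing with burden up to
#' `c_gm_ns + k`. Between-subject biological variability of the nonspecific
#' compartments is controlled by `sd_gm_ns` and `sd_wm`.
#'
#' @param grid_shape Integer vector of voxels per axis (default 64^3).
#' @param voxel_size Isotropic voxel edge length in mm (default 2).
#' @param cortical_thickness Cortical ribbon thickness in mm (default 6).
#' @param parcel_defs Data frame with columns `name`, `a_on` (onset burden in
#'   `[0,1)`) and `k` (activity gain at full burden, >= 0); default
#'   [default_parcels()].
#' @param psf_fwhm Scanner PSF full width at half maximum in mm (default 8).
#' @param noise_sd Additive white Gaussian noise s.d. on the blurred image,
#'   in activity units (default 0.05).
#' @param field_sd S.d. (activity units) of a per-subject smooth random
#'   field added to the tissue activity before blurring, emulating spatially
#'   structured between-subject variability (anatomy, registration,
#'   binding pattern) that white voxel noise cannot represent (default
#'   0.08; 0 disables).
#' @param field_fwhm Correlation scale (FWHM, mm) of the random field
#'   (default 12).
#' @param c_gm_ns,c_wm,c_cereb Population mean activities of nonspecific
#'   cortical GM, WM and cerebellar GM.
#' @param sd_gm_ns,sd_wm Between-subject s.d. of the nonspecific activities.
#' @param sd_spec Between-subject s.d. (log scale) of the multiplicative
#'   specific-binding factor applied to every parcel's ramp, representing
#'   inter-individual differences in tracer binding and delivery.
#' @param csf_params Parameters of the burden-to-CSF Abeta42 model, see
#'   [csf_from_burden()].
#' @param seed Default seed used by [simulate_cohort()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size = 2,
                         cortical_thickness = 6,
                         parcel_defs = default_parcels(),
                         psf_fwhm = 8,
                         noise_sd = 0.05,
                         field_sd = 0.08, field_fwhm = 12,
                         c_gm_ns = 0.8, c_wm = 2.0, c_cereb = 0.8,
                         sd_gm_ns = 0.06, sd_wm = 0.08, sd_spec = 0.25,
                         csf_params = list(U = 2400, L = 450, A0 = 0.4,
                                           s = 8, sigma = 0.15),
                         seed = 1L) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3L)
  if (any(grid_shape < 8L)) stop("grid_shape too small")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (cortical_thickness <= 0) stop("cortical_thickness must be positive")
  if (psf_fwhm <= 0) stop("psf_fwhm must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (field_sd < 0 || field_fwhm <= 0) stop("invalid random-field parameters")
  stopifnot(is.data.frame(parcel_defs),
            all(c("name", "a_on", "k") %in% names(parcel_defs)))
  if (any(parcel_defs$a_on < 0 | parcel_defs$a_on >= 1))
    stop("all parcel onsets a_on must lie in [0, 1)")
  if (any(parcel_defs$k < 0)) stop("parcel slopes k must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 cortical_thickness = cortical_thickness,
                 parcel_defs = parcel_defs, psf_fwhm = psf_fwhm,
                 noise_sd = noise_sd,
                 field_sd = field_sd, field_fwhm = field_fwhm,
                 c_gm_ns = c_gm_ns, c_wm = c_wm, c_cereb = c_cereb,
                 sd_gm_ns = sd_gm_ns, sd_wm = sd_wm, sd_spec = sd_spec,
                 csf_params = csf_params, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Digital brain phantom spec\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "),
      "voxels at", x$voxel_size, "mm\n")
  cat("  cortical ribbon:", x$cortical_thickness, "mm;",
      nrow(x$parcel_defs), "parcels\n")
  cat("  PSF FWHM:", x$psf_fwhm, "mm; noise sd:", x$noise_sd, "\n")
  cat("  activities (GM ns / WM / cerebellum):",
      x$c_gm_ns, "/", x$c_wm, "/", x$c_cereb, "\n")
  invisible(x)
}

#' Default cortical parcellation
#'
#' Six cortical parcels tiling the ribbon. The three "early" parcels
#' (medial prefrontal, precuneus, inferior temporal analogues) have low onset
#' thresholds, encoding the ordering in which cortical regions show tracer
#' signal as the latent burden grows; the remaining parcels activate later.
#'
#' @return A data frame with columns `name`, `a_on`, `k`, `label`.
#' @export
default_parcels <- function() {
  data.frame(
    name = c("medial_prefrontal", "precuneus", "inferior_temporal",
             "lateral_frontal", "parietal", "occipital"),
    a_on = c(0.05, 0.08, 0.10, 0.30, 0.40, 0.50),
    k    = rep(0.6, 6),
    label = 1:6,
    stringsAsFactors = FALSE
  )
}

## Voxel-center coordinates (mm), origin at grid center.
grid_coords <- function(grid_shape, voxel_size) {
  lapply(grid_shape, function(n) (seq_len(n) - (n + 1) / 2) * voxel_size)
}

## Squared normalized ellipsoid radius field.
ellipsoid_rho2 <- function(co, center, semi) {
  d <- lengths(co)
  x2 <- (co[[1]] - center[1])^2 / semi[1]^2
  y2 <- (co[[2]] - center[2])^2 / semi[2]^2
  z2 <- (co[[3]] - center[3])^2 / semi[3]^2
  outer(outer(x2, y2, "+"), z2, "+")
}

#' Build the phantom tissue maps
#'
#' Deterministically constructs the tissue geometry from a [phantom_spec]:
#' GM/WM/CSF probability volumes (crisp 0/1 maps that partition the brain
#' support), the parcel label volume, the composite cortical mask (union of
#' all cortical parcels), the cerebellar reference mask, and a deep-WM
#' mask (`wm > 0.99` eroded by one PSF FWHM, so that gray-matter spill-in
#' there is negligible).
#'
#' @param spec A [phantom_spec].
#' @return An object of class `tissue_maps`: list with elements `gm`, `wm`,
#'   `csf`, `parcel_labels`, `composite_cortical_mask`, `cerebellum_mask`,
#'   `deep_wm_mask`, `brain_mask`, plus `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  half <- gs * vs / 2
  co <- grid_coords(gs, vs)

  cer_center <- c(0, 0, 0.15 * half[3])
  cer_semi <- c(0.72, 0.82, 0.62) * half
  inner_semi <- cer_semi - spec$cortical_thickness
  vent_semi <- c(0.18, 0.28, 0.14) * half
  if (any(inner_semi <= vent_semi + 2 * vs))
    stop("grid too small to hold a cortical ribbon of the requested ",
         "thickness: enlarge the grid or reduce cortical_thickness")

  rho_out <- ellipsoid_rho2(co, cer_center, cer_semi)
  rho_in <- ellipsoid_rho2(co, cer_center, inner_semi)
  rho_vent <- ellipsoid_rho2(co, cer_center, vent_semi)
  shell_semi <- cer_semi + 2 * vs
  rho_shell <- ellipsoid_rho2(co, cer_center, shell_semi)

  cereb_center <- c(0, -0.45 * half[2], -0.62 * half[3])
  cereb_semi <- c(0.34, 0.26, 0.20) * half
  rho_cereb <- ellipsoid_rho2(co, cereb_center, cereb_semi)

  cerebrum <- rho_out <= 1
  ribbon <- cerebrum & rho_in > 1
  interior <- rho_in <= 1
  vent <- rho_vent <= 1
  cereb <- (rho_cereb <= 1) & !cerebrum        # carve defensively
  shell <- (rho_shell <= 1) & !cerebrum & !cereb

  gm <- array(0, gs); wm <- array(0, gs); csf <- array(0, gs)
  gm[ribbon | cereb] <- 1
  wm[interior & !vent] <- 1
  csf[vent | shell] <- 1

  ## Parcels: azimuthal sectors x superior/inferior halves of the ribbon.
  xs <- co[[1]]; ys <- co[[2]]; zs <- co[[3]]
  X <- array(rep(xs, times = gs[2] * gs[3]), gs)
  Y <- array(rep(rep(ys, each = gs[1]), times = gs[3]), gs)
  Z <- array(rep(zs, each = gs[1] * gs[2]), gs)
  theta <- atan2(Y, X)                         # (-pi, pi]
  sector <- findInterval(theta, c(-pi, -pi / 3, pi / 3), left.open = FALSE)
  upper <- Z >= cer_center[3]
  labels <- array(0L, gs)
  labels[ribbon] <- (sector[ribbon] + ifelse(upper[ribbon], 0L, 3L))
  np <- nrow(spec$parcel_defs)
  labels[labels > np] <- ((labels[labels > np] - 1L) %% np) + 1L

  ## deep WM: one PSF FWHM away from any GM; on very small grids fall back
  ## to weaker erosion so the mask is never empty
  deep <- erode_mask(wm > 0.99, spec$psf_fwhm, vs)
  if (!any(deep)) deep <- erode_mask(wm > 0.99, spec$psf_fwhm / 2, vs)
  if (!any(deep)) deep <- wm > 0.99

  structure(list(
    gm = gm, wm = wm, csf = csf,
    parcel_labels = labels,
    composite_cortical_mask = ribbon,
    cerebellum_mask = cereb,
    deep_wm_mask = deep,
    brain_mask = ribbon | interior | cereb | vent | shell,
    spec = spec
  ), class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat("Phantom tissue maps on", paste(dim(x$gm), collapse = " x "),
      "grid at", x$spec$voxel_size, "mm\n")
  cat("  GM voxels:", sum(x$gm > 0),
      "(cortical", sum(x$composite_cortical_mask),
      ", cerebellar", sum(x$cerebellum_mask), ")\n")
  cat("  WM voxels:", sum(x$wm > 0),
      "; deep WM:", sum(x$deep_wm_mask), "\n")
  invisible(x)
}

#' Regional uptake as a function of latent amyloid burden
#'
#' Each parcel follows a piecewise-linear ramp
#' `c = c_gm_ns + k * max(0, (A - a_on) / (1 - a_on))`: activity sits at the
#' nonspecific baseline until the burden reaches the parcel's onset
#' threshold, then rises linearly to `c_gm_ns + k` at full burden. Early
#' parcels (small `a_on`) therefore show elevated tracer binding first.
#'
#' @param A Latent amyloid burden in `[0, 1]`.
#' @param spec A [phantom_spec].
#' @param c_gm_ns Subject-level nonspecific GM baseline (defaults to the
#'   population value in `spec`).
#' @return Named numeric vector of per-parcel activities.
#' @export
regional_uptake <- function(A, spec, c_gm_ns = spec$c_gm_ns) {
  if (A < 0 || A > 1) stop("burden A must lie in [0, 1]")
  p <- spec$parcel_defs
  ramp <- pmax(0, (A - p$a_on) / (1 - p$a_on))
  stats::setNames(c_gm_ns + p$k * ramp, p$name)
}

#' CSF Abeta42 as a monotone noisy function of amyloid burden
#'
#' The median concentration follows a decreasing logistic curve
#' `L + (U - L) / (1 + exp(s * (A - A0)))` spanning roughly the range seen
#' in mixed normal/MCI/dementia cohorts, with median-preserving
#' multiplicative lognormal noise (`sdlog = sigma`).
#'
#' @param A Burden vector in `[0, 1]`.
#' @param params List with `U`, `L`, `A0`, `s`, `sigma` (see [phantom_spec]).
#' @param noisy If `FALSE`, return the noise-free median curve.
#' @return CSF Abeta42 concentrations in pg/ml.
#' @export
csf_from_burden <- function(A, params = phantom_spec()$csf_params,
                            noisy = TRUE) {
  if (any(A < 0 | A > 1)) stop("burden A must lie in [0, 1]")
  med <- params$L + (params$U - params$L) / (1 + exp(params$s * (A - params$A0)))
  if (noisy && params$sigma > 0)
    med <- med * exp(stats::rnorm(length(A), 0, params$sigma))
  med
}

#' Draw a subject's ground truth
#'
#' Samples the subject's nonspecific compartment activities (cerebellar GM
#' shares the cortical nonspecific baseline) and a multiplicative
#' specific-binding factor, computes per-parcel true GM activities from the
#' burden, and draws the CSF Abeta42 value. Uses the current RNG state.
#'
#' @param A Latent amyloid burden in `[0, 1]`.
#' @param spec A [phantom_spec].
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(A, spec) {
  c_gm_ns <- max(0.1, stats::rnorm(1, spec$c_gm_ns, spec$sd_gm_ns))
  c_wm <- max(0.2, stats::rnorm(1, spec$c_wm, spec$sd_wm))
  c_cereb <- c_gm_ns * (spec$c_cereb / spec$c_gm_ns)
  f_spec <- exp(stats::rnorm(1, 0, spec$sd_spec))
  base <- regional_uptake(A, spec, c_gm_ns)
  structure(list(
    burden = A,
    csf_ab42 = csf_from_burden(A, spec$csf_params),
    c_gm_ns = c_gm_ns, c_wm = c_wm, c_cereb = c_cereb, f_spec = f_spec,
    c_parcel = c_gm_ns + f_spec * (base - c_gm_ns)
  ), class = "subject_truth")
}

#' Synthesize a PET volume for one subject
#'
#' Composes the noiseless activity image (GM voxels at their parcel activity,
#' cerebellar GM at `c_cereb`, WM at `c_wm`, CSF at zero), adds the
#' subject's smooth random tissue field (if `field_sd > 0`), blurs with the
#' scanner PSF, and adds white Gaussian noise. With `noise_sd = 0` and
#' `field_sd = 0` the result equals the PSF-blurred noiseless composite
#' exactly. The blurred image is where spill-out of cortical signal and
#' spill-in of unspecific white-matter signal arise.
#'
#' @param maps [build_phantom()] output.
#' @param truth A [subject_truth].
#' @param spec A [phantom_spec] sharing the grid of `maps`.
#' @param seed Optional integer; if given, the noise stream is seeded locally
#'   so the volume is reproducible in isolation.
#' @return Object of class `synthetic_pet`: list with `volume`, `truth`,
#'   `seed`.
#' @export
synthesize_pet <- function(maps, truth, spec = maps$spec, seed = NULL) {
  stopifnot(inherits(maps, "tissue_maps"), inherits(truth, "subject_truth"))
  if (!all(dim(maps$gm) == spec$grid_shape))
    stop("maps and spec do not share one grid")
  if (spec$psf_fwhm <= 0) stop("psf_fwhm must be positive")
  act <- activity_map(maps, truth, spec)
  if (spec$noise_sd > 0 || spec$field_sd > 0) {
    if (!is.null(seed)) {
      had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
      if (had) old <- get(".Random.seed", envir = globalenv())
      set.seed(seed)
      on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
              else rm(".Random.seed", envir = globalenv()))
    }
  }
  if (spec$field_sd > 0)
    act <- act + random_field(spec) * (maps$gm + maps$wm)
  vol <- smooth_psf(act, psf_model(spec$psf_fwhm), spec$voxel_size)
  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim(vol))
  structure(list(volume = vol, truth = truth, seed = seed),
            class = "synthetic_pet")
}

## Unit-sd smooth Gaussian random field on the grid: white noise smoothed at
## field_fwhm and rescaled by the exact kernel l2 norm, then scaled to
## field_sd.
random_field <- function(spec) {
  eta <- array(stats::rnorm(prod(spec$grid_shape)), spec$grid_shape)
  sm <- smooth_psf(eta, psf_model(spec$field_fwhm), spec$voxel_size)
  k <- gauss_kernel_1d(spec$field_fwhm, spec$voxel_size)
  sm * (spec$field_sd / sqrt(sum(k^2))^3)
}

## Noiseless voxel activity image for a subject.
activity_map <- function(maps, truth, spec = maps$spec) {
  act <- array(0, dim(maps$gm))
  gm_act <- array(truth$c_gm_ns, dim(maps$gm))
  lab <- maps$parcel_labels
  for (j in seq_len(nrow(spec$parcel_defs)))
    gm_act[lab == spec$parcel_defs$label[j]] <- truth$c_parcel[j]
  gm_act[maps$cerebellum_mask] <- truth$c_cereb
  act <- maps$gm * gm_act + maps$wm * truth$c_wm
  act
}

#' Default latent-burden distribution
#'
#' Mixture emulating a mixed cognitively-normal / MCI / dementia cohort:
#' 60% "low" Beta(1.2, 4) and 40% "elevated" Beta(4, 1.5).
#'
#' @param n Number of draws.
#' @return Numeric vector in `[0, 1]`.
#' @export
burden_mixture <- function(n) {
  elevated <- stats::runif(n) < 0.4
  ifelse(elevated, stats::rbeta(n, 4, 1.5), stats::rbeta(n, 1.2, 4))
}

#' Simulate a cohort of subjects
#'
#' Draws latent burdens, per-subject ground truth and (optionally) PET
#' volumes. All randomness flows from `seed`; per-subject noise sub-streams
#' are derived deterministically so individual volumes can be regenerated.
#'
#' @param n Number of subjects.
#' @param spec A [phantom_spec].
#' @param burden_dist Function `n -> burdens`; default [burden_mixture].
#' @param seed Integer master seed (default `spec$seed`).
#' @param maps Optional prebuilt [build_phantom()] output (rebuilt if `NULL`
#'   and volumes are requested).
#' @param volumes If `FALSE`, only ground truth is generated (tabular fast
#'   path); no volumes are synthesized.
#' @return Object of class `amy_cohort`: list with `subjects` (each holding
#'   `truth` and, if requested, `pet`), `table` (subject_id, burden,
#'   csf_ab42, seed), `spec`, `seed`, and `maps` (when volumes were built).
#' @export
simulate_cohort <- function(n, spec = phantom_spec(),
                            burden_dist = burden_mixture,
                            seed = spec$seed, maps = NULL,
                            volumes = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (volumes && is.null(maps)) maps <- build_phantom(spec)
  set.seed(seed)
  burdens <- burden_dist(n)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- subject_truth(burdens[i], spec)
    pet <- if (volumes) synthesize_pet(maps, truth, spec, seed = sub_seeds[i])
    subjects[[i]] <- list(truth = truth, pet = pet)
  }
  tab <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    burden = burdens,
    csf_ab42 = vapply(subjects, function(s) s$truth$csf_ab42, numeric(1)),
    seed = sub_seeds
  )
  structure(list(subjects = subjects, table = tab, spec = spec,
                 seed = seed, maps = maps),
            class = "amy_cohort")
}

#' @export
print.amy_cohort <- function(x, ...) {
  cat("Synthetic amyloid-PET cohort:", nrow(x$table), "subjects",
      if (is.null(x$subjects[[1]]$pet)) "(truth only, no volumes)" else "",
      "\n")
  cat("  burden: median", round(stats::median(x$table$burden), 3),
      " CSF Abeta42: median", round(stats::median(x$table$csf_ab42)), "pg/ml\n")
  invisible(x)
}
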