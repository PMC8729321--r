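# Toy geometry where all six SUVR variants are exactly 1 for a constant
# image: two thick slabs (GM, WM) with ROIs deep inside each.
toy_cohort_constant <- function(c0 = 2.4) {
  n <- 40
  slab <- make_slab(n = n, bg = 4, gm_vox = 16, wm_vox = 16)
  spec <- nf_spec(grid = c(n, n, n))
  comp <- array(FALSE, c(n, n, n)); comp[13:16, 13:27, 13:27] <- TRUE
  cereb <- array(FALSE, c(n, n, n)); cereb[6:8, 15:25, 15:25] <- TRUE
  deep <- array(FALSE, c(n, n, n)); deep[28:34, 15:25, 15:25] <- TRUE
  maps <- structure(list(gm = slab$gm, wm = slab$wm,
                         csf = array(0, c(n, n, n)),
                         parcel_labels = array(0L, c(n, n, n)),
                         composite_cortical_mask = comp,
                         cerebellum_mask = cereb, deep_wm_mask = deep,
                         brain_mask = (slab$gm + slab$wm) > 0,
                         spec = spec), class = "tissue_maps")
  vol <- array(c0, c(n, n, n))
  truth <- structure(list(burden = 0, csf_ab42 = 1500, c_gm_ns = c0,
                          c_wm = c0, c_cereb = c0,
                          c_parcel = stats::setNames(rep(c0, 6),
                                                     default_parcels()$name)),
                     class = "subject_truth")
  cohort <- structure(list(
    subjects = list(list(truth = truth,
                         pet = structure(list(volume = vol, truth = truth,
                                              seed = 1),
                                         class = "synthetic_pet"))),
    table = data.frame(subject_id = "S0001", burden = 0, csf_ab42 = 1500,
                       seed = 1L),
    spec = spec, seed = 1L, maps = maps), class = "amy_cohort")
  list(cohort = cohort, maps = maps)
}

test_that("reference value and ROI mean are plain masked means with QC", {
  v <- array(seq_len(27), c(3, 3, 3))
  mask <- array(FALSE, c(3, 3, 3)); mask[c(1, 5, 9)] <- TRUE
  expect_equal(reference_value(v, mask), mean(c(1, 5, 9)))
  expect_error(reference_value(v, array(FALSE, c(3, 3, 3))), "empty")

  expect_equal(as.numeric(roi_mean(v, mask)), (1 + 5 + 9) / 3)
  v[5] <- NaN
  rm5 <- roi_mean(v, mask)
  expect_equal(as.numeric(rm5), (1 + 9) / 2)
  expect_equal(attr(rm5, "excluded_fraction"), 1 / 3)
  v[c(1, 9)] <- NA
  expect_error(roi_mean(v, mask), "no valid voxels")
})

test_that("voxel-wise SUVR maps: masking, scaling, exact constant preservation", {
  set.seed(8)
  vol <- array(rnorm(20^3, 10), c(20, 20, 20))
  mask <- array(FALSE, c(20, 20, 20)); mask[5:15, 5:15, 5:15] <- TRUE

  m0 <- voxelwise_suvr_map(vol, 1, mask, smooth_fwhm = 0, voxel_size = 2)
  expect_equal(m0[mask], vol[mask])
  expect_true(all(is.nan(m0[!mask])))

  mc <- voxelwise_suvr_map(array(3, c(20, 20, 20)), 3, mask,
                           smooth_fwhm = 10, voxel_size = 2)
  # within-mask renormalized smoothing keeps a constant exactly constant
  expect_equal(mc[mask], rep(1, sum(mask)), tolerance = 1e-12)
  expect_error(voxelwise_suvr_map(vol, 0, mask), "positive")
})

test_that("the SUVR table has the six-variant design and normalizes a constant image to 1", {
  toy <- toy_cohort_constant()
  tab <- compute_suvr_table(toy$cohort, toy$maps)
  cols <- c("suvr_none_wc", "suvr_none_wm", "suvr_pvc2_wc", "suvr_pvc2_wm",
            "suvr_pvc3_wc", "suvr_pvc3_wm")
  expect_true(all(cols %in% names(tab)))
  expect_equal(length(grep("^suvr_", names(tab))), 6)
  expect_equal(unname(unlist(tab[1, cols])), rep(1, 6), tolerance = 1e-6)
})

test_that("SUVR is invariant under global rescaling of the PET volume", {
  m <- cached("maps48", build_phantom(nf_spec()))
  spec <- m$spec
  coh <- simulate_cohort(2, spec, seed = 21, maps = m, volumes = TRUE)
  tab1 <- compute_suvr_table(coh, m)
  coh2 <- coh
  for (i in seq_along(coh2$subjects))
    coh2$subjects[[i]]$pet$volume <- 3.3 * coh2$subjects[[i]]$pet$volume
  tab2 <- compute_suvr_table(coh2, m)
  cols <- grep("^suvr_", names(tab1), value = TRUE)
  expect_equal(as.matrix(tab1[cols]), as.matrix(tab2[cols]),
               tolerance = 1e-10)
})

test_that("reference consistency and spill-out recovery direction", {
  m <- cached("maps48", build_phantom(nf_spec()))
  spec <- m$spec
  coh <- simulate_cohort(1, spec, seed = 33, maps = m, volumes = TRUE,
                         burden_dist = function(n) rep(0.9, n))
  tab <- compute_suvr_table(coh, m)
  pet <- coh$subjects[[1]]$pet$volume
  byhand <- as.numeric(roi_mean(pet, m$composite_cortical_mask)) /
    reference_value(pet, m$cerebellum_mask)
  expect_equal(tab$suvr_none_wc[1], byhand, tolerance = 1e-12)
  # high burden: c_gm > c_wm, PVC-3 recovers spill-out, so SUVR rises
  expect_gt(tab$suvr_pvc3_wc[1], tab$suvr_none_wc[1])
})

test_that("linear fast path equals the volumetric path without noise and propagates noise honestly", {
  spec <- nf_spec(grid = c(32, 32, 32))
  m <- cached("maps32nf", build_phantom(spec))
  tra <- suvr_transfer(m, spec)
  coh <- simulate_cohort(4, spec, seed = 13, maps = m, volumes = TRUE)
  tv <- compute_suvr_table(coh, m, c_wm = "estimate")
  tf <- compute_suvr_table_fast(coh, tra, c_wm = "estimate")
  cols <- grep("^suvr_", names(tv), value = TRUE)
  expect_lt(max(abs(as.matrix(tv[cols]) - as.matrix(tf[cols]))), 1e-10)

  # analytic ROI-noise sd matches volumetric simulation for a fixed truth
  spn <- phantom_spec(grid_shape = c(32, 32, 32))
  mn <- cached("maps32n", build_phantom(spn))
  tran <- suvr_transfer(mn, spn)
  set.seed(3); tr <- subject_truth(0.2, spn)
  reps <- sapply(1:30, function(i) {
    pet <- synthesize_pet(mn, tr, spn, seed = 600 + i)$volume
    mean(pet[mn$composite_cortical_mask])
  })
  C <- spn$noise_sd^2 * tran$noise_gram + tran$field_cov
  ratio <- sd(reps) / sqrt(C["none", "none"])
  expect_gt(ratio, 0.6); expect_lt(ratio, 1.6)
})
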