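maps48p <- function() cached("maps48", build_phantom(nf_spec()))

test_that("WM activity estimation from eroded deep white matter", {
  m <- maps48p()
  spec <- m$spec
  set.seed(1); tr <- subject_truth(0.2, spec)
  pet <- synthesize_pet(m, tr, spec)$volume
  est <- estimate_wm_activity(pet, m$wm, 2, erosion_mm = 6)
  expect_lt(abs(est / spec$c_wm - 1), 0.02)

  cpet <- array(1.23, dim(m$wm))
  expect_equal(estimate_wm_activity(cpet, m$wm, 2), 1.23)
  expect_error(estimate_wm_activity(pet, m$wm, 2, erosion_mm = 500),
               "empty")
})

test_that("PVC-2 equals the raw image deep inside brain tissue and corrects CSF dilution", {
  # uniform tissue block: far from any edge the denominator is exactly 1
  gm_all <- array(1, c(32, 32, 32))
  wm0 <- array(0, c(32, 32, 32))
  pet_u <- smooth_psf(array(1.7, c(32, 32, 32)), psf_model(8), 2)
  ru <- pvc2_meltzer(pet_u, gm_all, wm0, psf_model(8), 2)
  expect_equal(ru$corrected[16, 16, 16], pet_u[16, 16, 16],
               tolerance = 1e-12)
  expect_true(all(is.nan(ru$corrected[!ru$valid_mask])) ||
                all(ru$valid_mask))

  # 1-D slab: at the GM/CSF edge the corrected value moves toward truth
  slab <- make_slab(n = 48)
  act <- slab$gm * 1.4 + slab$wm * 2.0
  pet3 <- smooth_psf(act, psf_model(8), 2)
  r2 <- pvc2_meltzer(pet3, slab$gm, slab$wm, psf_model(8), 2)
  edge <- slab$gm_idx[1]   # outermost GM voxel, bordering background
  raw_err <- abs(pet3[edge, 24, 24] - 1.4)
  cor_err <- abs(r2$corrected[edge, 24, 24] - 1.4)
  expect_lt(cor_err, raw_err)

  # central mechanistic claim: PVC-2 does not remove WM spill-in
  m <- maps48p()
  sp <- m$spec; sp$c_gm_ns <- 1.4; sp$c_cereb <- 1.4
  set.seed(1); tr14 <- subject_truth(0, sp)
  pet14 <- synthesize_pet(m, tr14, sp)$volume
  r214 <- pvc2_meltzer(pet14, m$gm, m$wm, psf_model(8), 2)
  expect_gt(as.numeric(roi_mean(r214$corrected, m$composite_cortical_mask,
                                r214$valid_mask)), 1.4)
})

test_that("PVC-3 removes the modeled WM compartment and is linear", {
  m <- maps48p()
  psf <- psf_model(8)
  # image that is pure WM spill: correction must return ~0 on valid voxels
  sw <- smooth_psf(m$wm, psf, 2)
  pet_wm <- 2.0 * sw
  r3 <- pvc3_muller_gartner(pet_wm, m$gm, m$wm, psf, 2, c_wm = 2.0)
  expect_lt(max(abs(r3$corrected[r3$valid_mask])), 1e-9)

  # linearity: scaling image and c_wm scales the correction
  spec <- m$spec
  set.seed(1); tr <- subject_truth(0.4, spec)
  pet <- synthesize_pet(m, tr, spec)$volume
  a <- 2.5
  r1 <- pvc3_muller_gartner(pet, m$gm, m$wm, psf, 2, c_wm = tr$c_wm)
  ra <- pvc3_muller_gartner(a * pet, m$gm, m$wm, psf, 2, c_wm = a * tr$c_wm)
  expect_equal(ra$corrected[ra$valid_mask], a * r1$corrected[r1$valid_mask],
               tolerance = 1e-12)
  expect_error(pvc3_muller_gartner(pet, m$gm, m$wm, psf, 2, c_wm = -1),
               "c_wm")
})

test_that("both PVC operators match a dense-matrix oracle on a pseudo-1-D phantom", {
  slab <- make_slab(n = 48)
  c_g <- 1.1; c_w <- 2.0
  act1 <- slab$gm1 * c_g + slab$wm1 * c_w
  K <- dense_conv_matrix(slab$n, 8, 2)
  pet1 <- drop(K %*% act1)
  pet3 <- smooth_psf(slab$gm * c_g + slab$wm * c_w, psf_model(8), 2)

  sg1 <- drop(K %*% slab$gm1); sw1 <- drop(K %*% slab$wm1)
  ok2 <- (sg1 + sw1) > 0.3
  oracle2 <- ifelse(ok2, pet1 / (sg1 + sw1), NaN)
  ok3 <- sg1 > 0.3
  oracle3 <- ifelse(ok3, (pet1 - c_w * sw1) / sg1, NaN)

  r2 <- pvc2_meltzer(pet3, slab$gm, slab$wm, psf_model(8), 2)
  r3 <- pvc3_muller_gartner(pet3, slab$gm, slab$wm, psf_model(8), 2, c_w)
  line2 <- r2$corrected[, 24, 24]; line3 <- r3$corrected[, 24, 24]
  expect_lt(max(abs(line2[ok2] - oracle2[ok2])), 1e-8)
  expect_lt(max(abs(line3[ok3] - oracle3[ok3])), 1e-8)
  # GM-only spill-out correction (wm = 0, c_wm = 0) also matches
  petg <- smooth_psf(slab$gm * c_g, psf_model(8), 2)
  zero <- array(0, dim(slab$gm))
  rg <- pvc3_muller_gartner(petg, slab$gm, zero, psf_model(8), 2, c_wm = 0)
  oracleg <- ifelse(ok3, drop(K %*% (slab$gm1 * c_g)) / sg1, NaN)
  expect_lt(max(abs(rg$corrected[ok3, 24, 24] - oracleg[ok3])), 1e-8)
})

test_that("PVC-3 recovers true GM activity; bias grows as the ribbon thins", {
  biases <- sapply(c(2, 4, 6), function(th) {
    spec <- nf_spec(cortical_thickness = th)
    m <- cached(paste0("maps48_th", th),
                if (th == 6) maps48p() else build_phantom(spec))
    set.seed(2); tr <- subject_truth(0.5, spec)
    pet <- synthesize_pet(m, tr, spec)$volume
    r3 <- pvc3_muller_gartner(pet, m$gm, m$wm, psf_model(8), 2,
                              c_wm = tr$c_wm)
    rec <- as.numeric(roi_mean(r3$corrected, m$composite_cortical_mask,
                               r3$valid_mask))
    truth_map <- amypvc:::activity_map(m, tr, spec)
    truth <- mean(truth_map[m$composite_cortical_mask])
    abs(rec / truth - 1)
  })
  expect_lt(biases[2], 0.02)   # 2-voxel ribbon
  expect_lt(biases[3], 0.02)   # 3-voxel ribbon
  expect_true(all(diff(biases) < 0))  # monotone: thinner -> worse
})

test_that("negative corrected voxels are counted, not clipped", {
  m <- maps48p()
  psf <- psf_model(8)
  pet <- smooth_psf(m$gm * 0.5 + m$wm * 2.0, psf, 2)
  # over-subtracting WM forces negatives in thin cortex
  r3 <- pvc3_muller_gartner(pet, m$gm, m$wm, psf, 2, c_wm = 3.5)
  expect_gt(r3$neg_fraction, 0)
  expect_true(any(r3$corrected[r3$valid_mask] < 0))
})
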