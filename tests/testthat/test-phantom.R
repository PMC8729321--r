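maps48 <- function() cached("maps48", build_phantom(nf_spec()))

test_that("phantom geometry is deterministic and partitions tissue", {
  spec <- nf_spec(grid = c(32, 32, 32))
  m1 <- build_phantom(spec)
  m2 <- build_phantom(spec)
  expect_identical(m1[names(m1) != "spec"], m2[names(m2) != "spec"])

  m <- maps48()
  tot <- m$gm + m$wm + m$csf
  expect_true(all(tot >= 0 & tot <= 1 + 1e-9))
  expect_true(all(abs(tot[m$brain_mask] - 1) < 1e-6))
  expect_false(any(m$cerebellum_mask & m$composite_cortical_mask))
  expect_true(all(m$wm[m$deep_wm_mask] > 0.99))
  # parcels tile the ribbon
  expect_true(all((m$parcel_labels > 0) == m$composite_cortical_mask))
})

test_that("cortical ribbon has the requested thickness at the equator", {
  spec <- nf_spec()   # 6 mm at 2 mm voxels
  m <- build_phantom(spec)
  # walk along +x from the cerebrum center: GM run should be ~3 voxels
  cz <- round(24 + 0.15 * 24)   # grid index near the cerebrum center plane
  row <- m$gm[, 25, cz] > 0 & m$parcel_labels[, 25, cz] > 0
  runs <- rle(row)
  gm_runs <- runs$lengths[runs$values]
  expect_true(all(gm_runs %in% 2:4))
})

test_that("too-thick ribbon for the grid is rejected", {
  expect_error(build_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                          cortical_thickness = 12)),
               "grid too small")
})

test_that("regional uptake follows the onset-ramp model", {
  spec <- nf_spec()
  p <- spec$parcel_defs
  expect_equal(unname(regional_uptake(0, spec)), rep(spec$c_gm_ns, nrow(p)))
  expect_equal(unname(regional_uptake(1, spec)), spec$c_gm_ns + p$k)
  # activity is exactly baseline at each parcel's own onset
  for (j in seq_len(nrow(p))) {
    expect_equal(unname(regional_uptake(p$a_on[j], spec)[j]), spec$c_gm_ns)
  }
  expect_error(regional_uptake(1.2, spec), "burden")
})

test_that("CSF model: midpoint, monotonicity, realistic cohort range", {
  prm <- list(U = 2400, L = 450, A0 = 0.4, s = 8, sigma = 0)
  expect_equal(csf_from_burden(0.4, prm), (2400 + 450) / 2)
  expect_gt(csf_from_burden(0.1, prm), csf_from_burden(0.9, prm))
  grid <- seq(0, 1, length.out = 200)
  expect_true(all(diff(csf_from_burden(grid, prm)) < 0))
  # noise-free curve is a strictly monotone map of burden
  expect_equal(cor(grid, csf_from_burden(grid, prm), method = "spearman"), -1)

  set.seed(99)
  prm$sigma <- 0.15
  draws <- csf_from_burden(runif(1e4), prm)
  expect_gt(min(draws), 450 * 0.5)
  expect_lt(max(draws), 2400 * 1.8)
})

test_that("synthetic PET reproduces constants, matches the 1-D oracle and is seeded", {
  m <- maps48()
  spec <- m$spec
  # uniform activity c over all tissue: deep inside the brain the blurred
  # image returns c up to the residual spill into the zero-activity
  # ventricles (the deep-WM mask sits >= 8 mm from any boundary)
  sp <- spec; sp$c_gm_ns <- 2; sp$c_cereb <- 2; sp$c_wm <- 2
  set.seed(1)
  tr <- subject_truth(0, sp)
  pet <- synthesize_pet(m, tr, sp)$volume
  expect_lt(max(abs(pet[m$deep_wm_mask] - 2)), 0.025)

  # slab phantom against the independent 1-D convolution
  slab <- make_slab(n = 48)
  act <- slab$gm * 1.4 + slab$wm * 2.0
  sm <- smooth_psf(act, psf_model(8), 2)
  oracle <- conv1d_oracle(slab$gm1 * 1.4 + slab$wm1 * 2.0, 8, 2)
  expect_lt(max(abs(sm[slab$gm_idx, 24, 24] - oracle[slab$gm_idx])), 1e-6)

  # seeding: identical seed, identical volume; different seed differs
  spn <- phantom_spec(grid_shape = c(32, 32, 32))  # has noise + field
  mn <- cached("maps32n", build_phantom(spn))
  set.seed(2); trn <- subject_truth(0.3, spn)
  v1 <- synthesize_pet(mn, trn, spn, seed = 10)$volume
  v2 <- synthesize_pet(mn, trn, spn, seed = 10)$volume
  v3 <- synthesize_pet(mn, trn, spn, seed = 11)$volume
  expect_identical(v1, v2)
  expect_false(isTRUE(all.equal(v1, v3)))
})

test_that("spill-in direction on the noise-free phantom", {
  m <- maps48()
  spec <- m$spec
  # hypointense cortex (baseline contrast): WM spill-in dominates
  set.seed(1); tr_lo <- subject_truth(0, spec)
  pet_lo <- synthesize_pet(m, tr_lo, spec)$volume
  expect_gt(mean(pet_lo[m$composite_cortical_mask]), spec$c_gm_ns)
  # hyperintense cortex (c_parcel > c_wm): spill-out dominates, reverses
  sp_hi <- spec; sp_hi$c_gm_ns <- 2.6; sp_hi$c_cereb <- 0.8
  set.seed(1); tr_hi <- subject_truth(0, sp_hi)
  pet_hi <- synthesize_pet(m, tr_hi, sp_hi)$volume
  expect_lt(mean(pet_hi[m$composite_cortical_mask]), 2.6)
})

test_that("cohort simulation is reproducible with coupled burden and CSF", {
  spec <- nf_spec(grid = c(32, 32, 32))
  c1 <- simulate_cohort(50, spec, seed = 3, volumes = FALSE)
  c2 <- simulate_cohort(50, spec, seed = 3, volumes = FALSE)
  expect_identical(c1$table, c2$table)
  expect_equal(nrow(c1$table), 50)

  # point-mass at zero burden: CSF sits on the noisy upper plateau
  spec2 <- phantom_spec(grid_shape = c(32, 32, 32))
  c0 <- simulate_cohort(40, spec2, burden_dist = function(n) rep(0, n),
                        seed = 4, volumes = FALSE)
  upper <- with(spec2$csf_params, L + (U - L) / (1 + exp(-s * A0)))
  expect_true(all(c0$table$burden == 0))
  expect_gt(median(c0$table$csf_ab42), 0.8 * upper)

  # high-burden stratum has lower CSF than low-burden stratum
  cm <- simulate_cohort(500, spec2, seed = 5, volumes = FALSE)
  hi <- cm$table$burden > 0.5
  expect_lt(mean(cm$table$csf_ab42[hi]), mean(cm$table$csf_ab42[!hi]))
})
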