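tn <- magnetic_tensors()
st_fine <- spectrum_settings(gaussian_broadening_mT = 0, n_field_points = 4096)

test_that("effective g and A interpolate between principal values", {
  expect_equal(unname(effective_g_A(diag(3), tn)), c(2.0026, 3.5))
  # x parallel to the field: rotate body x onto lab z
  Rx <- spintraj:::rotvec_to_matrix(c(0, -pi / 2, 0))
  expect_equal(unname(effective_g_A(Rx, tn)), c(2.0086, 0.52),
               tolerance = 1e-9)
  # isotropic orientation average: <n_i^2> = 1/3
  set.seed(2)
  rots <- random_rotations(4000)
  ga <- vapply(seq_len(4000), function(i) effective_g_A(rots[, , i], tn),
               numeric(2))
  expect_equal(mean(ga[1, ]), tn$g_iso, tolerance = 1e-5)
  expect_equal(mean(ga[2, ]), tn$a_iso_mT, tolerance = 0.01)
  expect_error(effective_g_A(diag(c(1, 1, 2)), tn), "rotation")
})

test_that("a static z||B orientation gives three lines at the gzz position +/- Azz", {
  tr <- orientation_trajectory(array(diag(3), c(3, 3, 1)), dt_ps = 100)
  sp <- simulate_spectrum(tr, tn, st_fine)
  gzz_pos <- st_fine$B0_mT - st_fine$B0_mT * (tn$g[3] - tn$g_iso) / tn$g_iso
  pk <- absorption_peaks(sp, 3, min_sep_mT = 1.5)
  expect_equal(pk, gzz_pos + c(-3.5, 0, 3.5), tolerance = 1e-4)
})

test_that("central linewidth matches the Lorentzian closed form within 2%", {
  tn_iso <- suppressWarnings(magnetic_tensors(rep(2.0059, 3), rep(1.5, 3)))
  tr <- orientation_trajectory(array(diag(3), c(3, 3, 1)), dt_ps = 100)
  sp <- simulate_spectrum(tr, tn_iso, st_fine)
  gamma <- 2.0059 * spintraj:::MU_B / spintraj:::HBAR
  dhpp <- 2 / (sqrt(3) * gamma * st_fine$T2_ns * 1e-9) * 1e3
  expect_equal(sp$central_linewidth_mT, dhpp, tolerance = 0.02)
  expect_equal(sp$inverse_linewidth, 1 / sp$central_linewidth_mT)
})

test_that("trajectory path reproduces the rigid-limit orientation-grid reference", {
  st <- spectrum_settings()
  po <- rigid_limit_spectrum(tn, st, 10000)
  expect_equal(outer_extrema_splitting(po), 2 * tn$A_mT[3],
               tolerance = 2 * st$sweep_mT / st$n_field_points / 7)
  set.seed(17)
  trajs <- static_trajectories(random_rotations(2000))
  sp <- simulate_spectrum(trajs, tn, st)
  expect_lt(lineshape_nrms(sp$derivative, po$derivative), 0.03)
})

test_that("fast isotropic motion collapses to three lines split by a_iso", {
  trajs <- lapply(1:20, function(i) simulate_orientation(
    dynamics_params(D_rot = 80, lambda_ord = 0, dt_ps = 0.2,
                    n_steps = 40000, seed = i)))
  sp <- simulate_spectrum(trajs, tn, spectrum_settings())
  pk <- absorption_peaks(sp, 3, min_sep_mT = 0.8)
  expect_equal(mean(diff(pk)), tn$a_iso_mT, tolerance = 0.02)
  expect_equal(pk[2], 338, tolerance = 1e-4)  # g_iso position
  # agrees with the closed-form fast-limit reference up to residual width
  ff <- fast_limit_spectrum(tn, spectrum_settings())
  expect_equal(absorption_peaks(ff, 3, min_sep_mT = 0.8), pk,
               tolerance = 2e-4)
})

test_that("central linewidth narrows monotonically with faster rotation", {
  dh <- sapply(list(c(5, 2), c(20, 0.5), c(80, 0.2)), function(dd) {
    trajs <- lapply(1:10, function(i) simulate_orientation(
      dynamics_params(D_rot = dd[1], lambda_ord = 0, dt_ps = dd[2],
                      n_steps = round(4000 / dd[2]), seed = 100 + i)))
    simulate_spectrum(trajs, tn, spectrum_settings())$central_linewidth_mT
  })
  expect_true(all(diff(dh) < 0))
})

test_that("Gaussian broadening widens the central line monotonically", {
  tr <- orientation_trajectory(array(diag(3), c(3, 3, 1)), dt_ps = 100)
  d1 <- simulate_spectrum(tr, tn, spectrum_settings(
    gaussian_broadening_mT = 0.1))$central_linewidth_mT
  d2 <- simulate_spectrum(tr, tn, spectrum_settings(
    gaussian_broadening_mT = 0.2))$central_linewidth_mT
  expect_gt(d2, d1)
})

test_that("total absorption is conserved across dynamic regimes", {
  st <- spectrum_settings()
  step <- st$sweep_mT / (st$n_field_points - 1)
  tot <- sapply(c(0.2, 5), function(D) {
    trajs <- lapply(1:10, function(i) simulate_orientation(
      dynamics_params(D_rot = D, lambda_ord = 0, dt_ps = 2, n_steps = 2000,
                      seed = 30 + i)))
    sum(simulate_spectrum(trajs, tn, st)$absorption) * step
  })
  expect_equal(tot[1], tot[2], tolerance = 0.01)
})

test_that("spectra of isotropic ensembles are invariant under a global rotation", {
  set.seed(23)
  rots <- random_rotations(2000)
  sp1 <- simulate_spectrum(static_trajectories(rots), tn, spectrum_settings())
  Q <- spintraj:::rotvec_to_matrix(c(0.4, -1.1, 0.7))
  rots2 <- rots
  for (i in 1:2000) rots2[, , i] <- Q %*% rots[, , i]
  sp2 <- simulate_spectrum(static_trajectories(rots2), tn,
                           spectrum_settings())
  expect_lt(lineshape_nrms(sp1$derivative, sp2$derivative), 0.05)
})

test_that("mobile/immobile spectral weights separate the dynamic regimes", {
  st <- spectrum_settings()
  fast <- fast_limit_spectrum(tn, st)
  rigid <- rigid_limit_spectrum(tn, st, 4000)
  w_fast <- classify_components(fast)
  w_rigid <- classify_components(rigid)
  expect_lt(w_fast$immobile_weight, 0.05)
  expect_gt(w_rigid$immobile_weight, 2 * w_fast$immobile_weight)
  # 50/50 mixture of the two absorptions sits between the pure cases
  mix <- fast
  mix$absorption <- 0.5 * fast$absorption + 0.5 * rigid$absorption
  w_mix <- classify_components(mix)
  expect_true(w_mix$immobile_weight > w_fast$immobile_weight &&
                w_mix$immobile_weight < w_rigid$immobile_weight)
  expect_error(classify_components(fast, immobile_window = c(300, 305)),
               "outside")
})

test_that("settings and preconditions are enforced", {
  expect_error(spectrum_settings(T2_ns = 50, fid_ns = 100), "5 \\* T2")
  expect_error(simulate_spectrum(
    orientation_trajectory(array(diag(3), c(3, 3, 1)), 100), tn,
    spectrum_settings(sweep_mT = 5)), "sweep too narrow")
  # per-step phase increment guard: huge dt violates the 0.5 rad bound
  tr_coarse <- orientation_trajectory(array(diag(3), c(3, 3, 1)),
                                      dt_ps = 2e6)
  expect_error(simulate_spectrum(tr_coarse, tn, st_fine), "finer")
})
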