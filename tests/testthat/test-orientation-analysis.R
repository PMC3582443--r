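test_that("mode-axis estimate recovers the center of concentrated samples", {
  # all z identical: the axis itself
  R <- build_frame(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))$rotation
  tr_same <- orientation_trajectory(array(R, c(3, 3, 12)), 1,
                                    validate = FALSE)
  expect_equal(estimate_mode_axis(tr_same), R[, 3], tolerance = 1e-9)

  # 10-degree cone about a tilted axis: mode within 2 degrees
  u <- c(1, 2, 0.5) / sqrt(sum(c(1, 2, 0.5)^2))
  tr_cone <- cone_trajectory(u, 10, 4000, seed = 2)
  m <- estimate_mode_axis(tr_cone)
  expect_lt(acos(min(1, sum(m * u))) * 180 / pi, 2)

  expect_error(estimate_mode_axis(
    orientation_trajectory(array(R, c(3, 3, 5)), 1, validate = FALSE)),
    "at least 10")
})

test_that("antipodal tie rule picks the first frame's hemisphere", {
  u <- c(0, 0, 1)
  a <- cone_trajectory(u, 5, 200, seed = 3)
  b <- cone_trajectory(-u, 5, 200, seed = 4)
  rot <- array(NA_real_, c(3, 3, 400))
  rot[, , seq(1, 399, 2)] <- a$rotations
  rot[, , seq(2, 400, 2)] <- b$rotations
  tr <- orientation_trajectory(rot, 1, validate = FALSE)
  m <- estimate_mode_axis(tr)
  expect_gt(sum(m * zaxes(tr)[1, ]), 0)
})

test_that("beta is the arc distance from the mode axis", {
  Rz <- diag(3)                                    # z along mode
  Rx <- spintraj:::rotvec_to_matrix(c(0, pi / 2, 0))  # z tilted 90 deg
  Rf <- spintraj:::rotvec_to_matrix(c(0, pi, 0))      # z flipped
  tr <- orientation_trajectory(array(c(Rz, Rx, Rf), c(3, 3, 3)), 1,
                               validate = FALSE)
  b <- beta_series(tr, c(0, 0, 1))
  expect_equal(b$angles, c(0, 90, 180), tolerance = 1e-9)
  expect_error(beta_series(tr, c(0, 0, 2)), "unit")
})

test_that("Gaussian fit of the beta histogram recovers moments and FWHM", {
  set.seed(21)
  bs <- structure(list(angles = rnorm(2e5, 20, 10), mode_axis = c(0, 0, 1),
                       dt_ps = 1), class = "beta_series")
  bd <- beta_distribution(bs)
  expect_false(bd$flagged)
  expect_equal(bd$gaussian_mu, 20, tolerance = 0.02)
  expect_equal(bd$gaussian_sigma, 10, tolerance = 0.02)
  expect_equal(bd$fwhm, 2 * sqrt(2 * log(2)) * 10, tolerance = 0.02)
  # density normalization: sum(density) * bin width = 1
  expect_equal(sum(bd$density) * bd$bin_width_deg, 1, tolerance = 1e-12)
})

test_that("degenerate beta distributions are flagged with a bounded FWHM", {
  bs <- structure(list(angles = rep(33.3, 500), mode_axis = c(0, 0, 1),
                       dt_ps = 1), class = "beta_series")
  bd <- beta_distribution(bs)
  expect_true(bd$flagged)
  expect_gte(bd$fwhm, bd$bin_width_deg)
  expect_lte(bd$fwhm, 2 * bd$bin_width_deg)
})

test_that("free diffusion gives the uniform-sphere beta statistics", {
  tr <- simulate_orientation(dynamics_params(D_rot = 4, lambda_ord = 0,
                                             dt_ps = 1, n_steps = 2e5,
                                             seed = 6))
  b <- beta_series(tr, c(0, 0, 1))
  expect_equal(mean(b$angles), 90, tolerance = 0.03)  # E beta = pi/2
  # msf near the uniform-sphere reference -> normalized mobility near 1
  expect_gt(mobility_parameter(b)$normalized_mobility, 0.85)
})

test_that("mobility parameter is a variance with a rotation-invariant value", {
  bs_const <- structure(list(angles = rep(12, 10), mode_axis = c(0, 0, 1),
                             dt_ps = 1), class = "beta_series")
  expect_equal(mobility_parameter(bs_const)$msf_beta, 0)

  set.seed(31)
  ang <- rnorm(1e5, 40, 7)
  bs <- structure(list(angles = ang, mode_axis = c(0, 0, 1), dt_ps = 1),
                  class = "beta_series")
  expect_equal(mobility_parameter(bs)$msf_beta, 49, tolerance = 0.02)

  # restricted label is less mobile than a free one
  tr_free <- simulate_orientation(dynamics_params(lambda_ord = 0,
                                                  n_steps = 2e4, seed = 8))
  tr_rest <- simulate_orientation(dynamics_params(lambda_ord = 10,
                                                  n_steps = 2e4, seed = 8))
  m_free <- mobility_parameter(beta_series(tr_free))$msf_beta
  m_rest <- mobility_parameter(beta_series(tr_rest))$msf_beta
  expect_gt(m_free, m_rest)

  # msf is invariant under a global rotation of the whole trajectory
  rot <- randomize_directors(list(tr_rest), seed = 5)[[1]]
  expect_equal(mobility_parameter(beta_series(rot))$msf_beta, m_rest,
               tolerance = 1e-6)
})

test_that("beta FWHM widens as the orienting potential weakens", {
  # strong-to-zero ordering (the weak-ordering regime in between populates
  # both wells of the symmetric potential and is not a unimodal family)
  fwhm <- sapply(c(10, 5, 0), function(lam) {
    tr <- simulate_orientation(dynamics_params(D_rot = 1, lambda_ord = lam,
                                               dt_ps = 2, n_steps = 3e4,
                                               seed = 13))
    beta_distribution(beta_series(tr))$fwhm
  })
  expect_true(all(diff(fwhm) > 0))
})
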