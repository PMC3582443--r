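test_that("generator parameter validation enforces the step-size bound", {
  expect_error(dynamics_params(D_rot = 80, dt_ps = 0.25), "0.2")
  expect_error(dynamics_params(D_rot = -1), "D_rot")
  p <- dynamics_params(D_rot = 1, lambda_ord = 2, dt_ps = 2, n_steps = 10)
  expect_s3_class(p, "dynamics_params")
})

test_that("simulation is bit-reproducible and produces valid rotations", {
  p <- dynamics_params(n_steps = 500, seed = 77)
  t1 <- simulate_orientation(p)
  t2 <- simulate_orientation(p)
  expect_identical(t1$rotations, t2$rotations)
  # frames stay proper orthonormal over many steps
  expect_no_error(orientation_trajectory(t1$rotations, p$dt_ps,
                                         validate = TRUE))
})

test_that("order parameter converges to the Boltzmann quadrature value", {
  # free diffusion: S ~ 0; strong field: S -> 1; lambda = 5 vs oracle
  s0 <- mean(sapply(1:3, function(s) order_parameter(simulate_orientation(
    dynamics_params(D_rot = 1, lambda_ord = 0, dt_ps = 2, n_steps = 5e4,
                    seed = s)))))
  expect_lt(abs(s0), 0.05)

  s_big <- order_parameter(simulate_orientation(
    dynamics_params(D_rot = 1, lambda_ord = 50, dt_ps = 1, n_steps = 2e4,
                    seed = 4)))
  expect_gt(s_big, 0.95)

  s5 <- mean(sapply(1:3, function(s) order_parameter(simulate_orientation(
    dynamics_params(D_rot = 1, lambda_ord = 5, dt_ps = 2, n_steps = 1e5,
                    seed = s)))))
  expect_lt(abs(s5 - oracle_order_parameter(5)), 0.025)
  # the package's own quadrature agrees with the independent oracle
  expect_equal(maier_saupe_order_parameter(5), oracle_order_parameter(5),
               tolerance = 1e-8)
})

test_that("two-state exchange assigns modes with the configured weight", {
  mob <- dynamics_params(D_rot = 2, lambda_ord = 0, dt_ps = 2, n_steps = 50,
                         seed = 1)
  imm <- dynamics_params(D_rot = 0.05, lambda_ord = 10, dt_ps = 2,
                         n_steps = 50, seed = 2)
  all_mob <- simulate_exchange(exchange_params(mob, imm, 1), n_traj = 20)
  expect_true(all(all_mob$labels == "mobile"))

  half <- simulate_exchange(exchange_params(mob, imm, 0.5), n_traj = 200)
  n_mob <- sum(half$labels == "mobile")
  expect_lt(abs(n_mob - 100), 3 * sqrt(200 * 0.25))  # binomial 3 sigma

  expect_error(exchange_params(mob, imm, 1.2))
})

test_that("distance generator reproduces its mixture targets", {
  # unimodal: mean 27.2 A, FWHM about 2 A
  d1 <- simulate_distance_series(list(c(27.2, 0.85, 1)), 20000, seed = 3)
  expect_equal(mean(d1), 27.2, tolerance = 0.01)
  expect_equal(2 * sqrt(2 * log(2)) * sd(d1), 2.0, tolerance = 0.05)

  # bimodal: histogram maxima near 7.3 and 9.0
  d2 <- simulate_distance_series(list(c(7.3, 0.3, 0.65), c(9, 0.3, 0.35)),
                                 20000, seed = 3)
  h <- hist(d2, breaks = seq(5, 11, 0.25), plot = FALSE)
  lo <- h$mids < 8.15
  expect_lt(abs(h$mids[lo][which.max(h$counts[lo])] - 7.3), 0.3)
  expect_lt(abs(h$mids[!lo][which.max(h$counts[!lo])] - 9.0), 0.3)

  # zero variance: all samples equal the mean; positivity after truncation
  expect_true(all(simulate_distance_series(list(c(5, 0, 1)), 50) == 5))
  d3 <- simulate_distance_series(list(c(0.5, 1, 1)), 500, seed = 1)
  expect_true(all(d3 > 0))

  expect_error(simulate_distance_series(list(c(7, 1, 0.6), c(9, 1, 0.5)),
                                        100), "sum")
})

test_that("CA ensemble generator honors segment geometry and determinism", {
  seg <- data.frame(start = c(1, 11), end = c(10, 30), sd = c(0, 0))
  ens <- simulate_ca_ensemble(seg, 4, seed = 9)
  expect_equal(ens$n_models, 4L)
  expect_equal(ens$n_atoms, 30L)
  # all-zero sd: identical models, consecutive CA spacing 3.8 A
  expect_true(all(apply(ens$xyz, 2, function(col) diff(range(col)) == 0)))
  co <- model_coords(ens)
  expect_equal(sqrt(rowSums(diff(co)^2)), rep(3.8, 29), tolerance = 1e-9)

  e1 <- simulate_ca_ensemble(seg, 3, seed = 5, rigid_motion = TRUE)
  e2 <- simulate_ca_ensemble(seg, 3, seed = 5, rigid_motion = TRUE)
  expect_identical(e1$xyz, e2$xyz)

  expect_error(simulate_ca_ensemble(
    data.frame(start = c(1, 5), end = c(10, 20), sd = c(1, 1)), 2),
    "overlap")
  expect_error(simulate_ca_ensemble(
    data.frame(start = c(1, 15), end = c(10, 20), sd = c(1, 1)), 2),
    "contiguous")
})

test_that("director randomization preserves per-trajectory statistics", {
  p <- dynamics_params(D_rot = 1, lambda_ord = 10, dt_ps = 2, n_steps = 2000,
                       seed = 3)
  tr <- simulate_orientation(p)
  rnd <- randomize_directors(list(tr, tr), seed = 12)
  # the two copies get different directors
  expect_gt(max(abs(rnd[[1]]$rotations - rnd[[2]]$rotations)), 0.1)
  # but beta statistics relative to the (rotated) mode are unchanged
  m0 <- mobility_parameter(beta_series(tr))
  m1 <- mobility_parameter(beta_series(rnd[[1]]))
  expect_equal(m1$msf_beta, m0$msf_beta, tolerance = 1e-6)
})
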