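seg3 <- data.frame(start = c(1, 21, 41), end = c(20, 40, 60),
                   sd = c(0.5, 2, 0.5))

test_that("superposition removes pure rigid motion exactly", {
  ens <- simulate_ca_ensemble(data.frame(start = 1, end = 30, sd = 0),
                              n_models = 6, seed = 2, rigid_motion = TRUE)
  sup <- superpose(ens)
  prof <- rmsf(sup)
  expect_lt(max(prof$rmsf), 1e-6)
})

test_that("reflection-related models are fitted with a proper rotation only", {
  ens0 <- simulate_ca_ensemble(data.frame(start = 1, end = 30, sd = 0.3),
                               n_models = 1, seed = 4)
  co <- model_coords(ens0)
  mirrored <- co %*% diag(c(1, 1, -1))
  ens <- coord_ensemble(ens0$atoms,
                        rbind(as.numeric(t(co)), as.numeric(t(mirrored))))
  sup <- superpose(ens)
  # the mirror image cannot be superposed by rotation alone
  expect_gt(max(rmsf(sup)$rmsf), 0.05)
  # and the fit never applied a reflection: chirality of the trace preserved
  tri <- function(m) det(rbind(m[2, ] - m[1, ], m[3, ] - m[1, ],
                               m[4, ] - m[1, ]))
  expect_equal(sign(tri(model_coords(sup, 2))), sign(tri(mirrored)))
})

test_that("superposition does not increase the mean-square deviation", {
  for (s in 1:5) {
    ens <- simulate_ca_ensemble(data.frame(start = 1, end = 25, sd = 1),
                                n_models = 8, seed = s, rigid_motion = TRUE)
    msd <- function(e) {
      dev <- sweep(e$xyz, 2, colMeans(e$xyz))
      mean(rowSums(dev^2))
    }
    expect_lte(msd(superpose(ens)), msd(ens) + 1e-9)
  }
})

test_that("collinear or tiny selections are rejected", {
  # collinear trace: points on a line
  atoms <- data.frame(serial = 1:5, name = "CA", resno = 1:5, resid = "ALA",
                      chain = "A", b = 0)
  line <- as.numeric(t(cbind(3.8 * (0:4), 0, 0)))
  ens <- coord_ensemble(atoms, rbind(line, line))
  expect_error(superpose(ens), "collinear")
  expect_error(superpose(coord_ensemble(atoms[1:2, ],
                                        rbind(line[1:6], line[1:6]))),
               "at least 3")
})

test_that("RMSF separates loop from helix fluctuations", {
  ens <- simulate_ca_ensemble(seg3, n_models = 30, seed = 7,
                              rigid_motion = TRUE)
  prof <- rmsf(superpose(ens))
  helix <- prof$rmsf[prof$resno <= 20 | prof$resno >= 41]
  loop <- prof$rmsf[prof$resno >= 21 & prof$resno <= 40]
  expect_gt(mean(loop), 2 * mean(helix))
  expect_equal(nrow(prof), 60L)
})

test_that("rmsf satisfies the variance decomposition and two-point identities", {
  # alternate displacement +/- d of one residue -> rmsf = d
  atoms <- data.frame(serial = 1:4, name = "CA", resno = 1:4, resid = "ALA",
                      chain = "A", b = 0)
  base <- cbind(c(0, 3.8, 3.8, 0), c(0, 0, 3.8, 3.8), 0)
  m1 <- base; m2 <- base
  m1[2, 3] <- 1.25; m2[2, 3] <- -1.25
  ens <- coord_ensemble(atoms, rbind(as.numeric(t(m1)), as.numeric(t(m2))))
  prof <- rmsf(ens)
  expect_equal(prof$rmsf[2], 1.25, tolerance = 1e-12)
  expect_equal(prof$rmsf[c(1, 3, 4)], rep(0, 3))

  # sum of rmsf^2 equals the total mean-square deviation of the selection
  ens2 <- simulate_ca_ensemble(seg3, n_models = 10, seed = 3)
  prof2 <- rmsf(ens2)
  dev <- sweep(ens2$xyz, 2, colMeans(ens2$xyz))
  expect_equal(sum(prof2$rmsf^2), sum(dev^2) / ens2$n_models,
               tolerance = 1e-9)
})

test_that("a common rigid motion applied to all models leaves RMSF unchanged", {
  ens <- simulate_ca_ensemble(seg3, n_models = 10, seed = 9)
  prof0 <- rmsf(superpose(ens))
  set.seed(10)
  Q <- random_rotations(1)[, , 1]
  shift <- c(5, -3, 8)
  xyz2 <- t(apply(ens$xyz, 1, function(row) {
    as.numeric(t(matrix(row, ncol = 3, byrow = TRUE) %*% t(Q) +
                   matrix(shift, ens$n_atoms, 3, byrow = TRUE)))
  }))
  prof1 <- rmsf(superpose(coord_ensemble(ens$atoms, xyz2)))
  expect_equal(prof1$rmsf, prof0$rmsf, tolerance = 1e-9)
})

test_that("pairwise least-squares fit agrees with an independent fit (bio3d)", {
  ens <- simulate_ca_ensemble(seg3, n_models = 2, seed = 12,
                              rigid_motion = TRUE)
  P <- model_coords(ens, 2)
  Q <- model_coords(ens, 1)
  R <- spintraj:::kabsch_rotation(sweep(P, 2, colMeans(P)),
                                  sweep(Q, 2, colMeans(Q)))
  fitted_ours <- sweep(sweep(P, 2, colMeans(P)) %*% R, 2, colMeans(Q), "+")
  rmsd_ours <- sqrt(mean(rowSums((fitted_ours - Q)^2)))
  fitted_b3d <- bio3d::fit.xyz(fixed = ens$xyz[1, ], mobile = ens$xyz[2, ],
                               fixed.inds = seq_len(ncol(ens$xyz)),
                               mobile.inds = seq_len(ncol(ens$xyz)))
  rmsd_b3d <- sqrt(mean((fitted_b3d - ens$xyz[1, ])^2) * 3)
  # both reach the same (optimal) RMSD and the same fitted coordinates
  expect_equal(rmsd_ours, rmsd_b3d, tolerance = 1e-6)
  expect_lt(max(abs(as.numeric(t(fitted_ours)) - as.numeric(fitted_b3d))),
            1e-4)
})
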