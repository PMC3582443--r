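#' Parameters for restricted rotational Brownian dynamics
#'
#' Defines one dynamic mode of a nitroxide: isotropic rotational diffusion
#' of the body frame with an optional uniaxial orienting potential
#' U/kT = -lambda_ord * cos^2(beta) about the lab z-axis (Maier-Saupe form),
#' where beta is the polar angle of the body z-axis. \code{lambda_ord = 0}
#' is free diffusion (order parameter S = 0); large \code{lambda_ord} pins
#' beta near 0 (S -> 1). Temperature is bookkeeping only: the potential is
#' expressed in kT units, so thermal softening is modeled by lowering
#' \code{lambda_ord}.
#'
#' The defaults represent a ~30 ns room-temperature run of a moderately
#' restricted label sampled every 2 ps.
#'
#' @param D_rot rotational diffusion coefficient, rad^2/ns.
#' @param lambda_ord orienting-potential strength, dimensionless, >= 0.
#' @param dt_ps time step, ps.
#' @param n_steps number of steps.
#' @param temperature_K nominal temperature (bookkeeping).
#' @param seed RNG seed.
#' @return object of class \code{dynamics_params}.
#' @export
dynamics_params <- function(D_rot = 0.5, lambda_ord = 3, dt_ps = 2,
                            n_steps = 15000, temperature_K = 300,
                            seed = 1L) {
  stopifnot(D_rot > 0, lambda_ord >= 0, dt_ps > 0, n_steps >= 1)
  D_dt <- D_rot * dt_ps / 1000  # rad^2 per step
  if (sqrt(2 * D_dt) >= 0.2) {
    stop(sprintf(paste0("per-step angular displacement sd %.3f rad >= 0.2; ",
                        "reduce dt_ps or D_rot"), sqrt(2 * D_dt)))
  }
  structure(list(D_rot = D_rot, lambda_ord = lambda_ord, dt_ps = dt_ps,
                 n_steps = as.integer(n_steps),
                 temperature_K = temperature_K, seed = as.integer(seed)),
            class = "dynamics_params")
}

#' Simulate an orientation trajectory by rotational Brownian dynamics
#'
#' Euler-scheme integration on SO(3): each step applies a random lab-frame
#' rotation whose rotation-vector components are iid Normal(0, 2*D_rot*dt),
#' followed by a deterministic drift rotation of the body z-axis toward the
#' nearer potential minimum by D_rot*lambda_ord*sin(2*beta)*dt. The
#' stationary distribution of the z-axis is the Boltzmann density
#' proportional to exp(lambda_ord*cos^2(beta)) on the sphere (up to Euler
#' discretization bias, controlled by the step-size precondition).
#' Bit-reproducible for a given parameter set (the seed is part of the
#' parameters). The initial orientation is drawn uniformly.
#'
#' @param params a [dynamics_params()].
#' @return an [orientation_trajectory()].
#' @seealso [maier_saupe_order_parameter()] for the closed quadrature form
#'   of the order parameter this process converges to.
#' @export
simulate_orientation <- function(params) {
  stopifnot(inherits(params, "dynamics_params"))
  set.seed(params$seed)
  R0 <- random_rotations(1)[, , 1]
  D_dt <- params$D_rot * params$dt_ps / 1000
  rot <- rotbd_simulate_cpp(params$n_steps, D_dt, params$lambda_ord, R0)
  dim(rot) <- c(3, 3, params$n_steps)
  orientation_trajectory(rot, params$dt_ps, validate = FALSE)
}

#' Two-state mobile/immobile exchange parameters
#'
#' @param mobile,immobile [dynamics_params()] for the two dynamic modes.
#' @param weight_mobile fraction of labels in the mobile mode, in [0, 1].
#' @return object of class \code{exchange_params}.
#' @export
exchange_params <- function(mobile, immobile, weight_mobile = 0.5) {
  stopifnot(inherits(mobile, "dynamics_params"),
            inherits(immobile, "dynamics_params"),
            weight_mobile >= 0, weight_mobile <= 1)
  structure(list(mobile = mobile, immobile = immobile,
                 weight_mobile = weight_mobile),
            class = "exchange_params")
}

#' Simulate an ensemble of trajectories under two-state exchange
#'
#' Each trajectory is independently assigned to the mobile mode with
#' probability \code{weight_mobile}, otherwise to the immobile mode, then
#' simulated with its own RNG stream (master seed plus a fixed per-trajectory
#' increment, so the ensemble is reproducible as a whole). Slow exchange is
#' assumed: a label stays in its mode for the whole trajectory, which is what
#' produces two-component superimposed spectra.
#'
#' @param params an [exchange_params()].
#' @param n_traj number of trajectories.
#' @param seed master seed for mode assignment and trajectory streams;
#'   defaults to the mobile component's seed.
#' @return object of class \code{trajectory_ensemble}: list with
#'   \code{trajectories} (list of [orientation_trajectory()]) and
#'   \code{labels} (character, "mobile"/"immobile").
#' @export
simulate_exchange <- function(params, n_traj = 100, seed = NULL) {
  stopifnot(inherits(params, "exchange_params"), n_traj >= 1)
  if (is.null(seed)) seed <- params$mobile$seed
  set.seed(seed)
  is_mobile <- stats::runif(n_traj) < params$weight_mobile
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    base <- if (is_mobile[i]) params$mobile else params$immobile
    pi_i <- base
    pi_i$seed <- as.integer((seed + 1000L * i) %% .Machine$integer.max)
    trajs[[i]] <- simulate_orientation(pi_i)
  }
  structure(list(trajectories = trajs,
                 labels = ifelse(is_mobile, "mobile", "immobile")),
            class = "trajectory_ensemble")
}

#' Sample inter-label distances from a Gaussian mixture
#'
#' Emulates fluctuating inter-nitroxide distances: unimodal (one component)
#' or bimodal (a label hopping between two conformations), truncated at zero.
#'
#' @param components list of numeric triples \code{c(mean, sd, weight)} in
#'   Angstrom; weights must sum to 1 within 1e-9.
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @return numeric vector of distances (Angstrom).
#' @examples
#' d <- simulate_distance_series(list(c(7.3, 0.3, 0.65), c(9, 0.3, 0.35)),
#'                               2000, seed = 1)
#' @export
simulate_distance_series <- function(components, n_samples, seed = 1L) {
  comp <- do.call(rbind, lapply(components, function(x) {
    stopifnot(length(x) == 3)
    x
  }))
  if (any(comp[, 1] <= 0) || any(comp[, 2] < 0) || any(comp[, 3] < 0)) {
    stop("component means must be > 0, sds >= 0, weights >= 0")
  }
  if (abs(sum(comp[, 3]) - 1) > 1e-9) {
    stop(sprintf("component weights sum to %.12g, not 1", sum(comp[, 3])))
  }
  set.seed(seed)
  ids <- sample.int(nrow(comp), n_samples, replace = TRUE, prob = comp[, 3])
  x <- stats::rnorm(n_samples, comp[ids, 1], comp[ids, 2])
  # truncation at 0 by re-drawing (distances are positive)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), comp[ids[bad], 1], comp[ids[bad], 2])
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate a helix/loop-patterned C-alpha coordinate ensemble
#'
#' Builds an idealized C-alpha trace (a helical coil with consecutive
#' C-alpha atoms 3.8 Angstrom apart, so the trace is non-collinear) and
#' produces models by adding per-residue isotropic Gaussian displacements
#' whose standard deviation is set per segment — small for helices, large
#' for loops — optionally composed with a random global rigid motion per
#' model (which superposition should remove downstream).
#'
#' @param segments data.frame with columns \code{start}, \code{end},
#'   \code{sd} (residue range, fluctuation sd in Angstrom). Ranges must be
#'   contiguous and non-overlapping.
#' @param n_models number of models.
#' @param seed RNG seed.
#' @param rigid_motion apply a random global rotation + translation to each
#'   model.
#' @return a [coord_ensemble()] of CA atoms (residue ALA, chain "A").
#' @export
simulate_ca_ensemble <- function(segments, n_models, seed = 1L,
                                 rigid_motion = FALSE) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "sd") %in% names(segments)),
            all(segments$sd >= 0), all(segments$end >= segments$start),
            n_models >= 1)
  o <- order(segments$start)
  segments <- segments[o, ]
  if (nrow(segments) > 1) {
    gaps <- segments$start[-1] - segments$end[-nrow(segments)]
    if (any(gaps <= 0)) stop("segment ranges overlap")
    if (any(gaps != 1)) stop("segment ranges must be contiguous")
  }
  resno <- seq(segments$start[1], segments$end[nrow(segments)])
  n_res <- length(resno)
  sd_res <- numeric(n_res)
  for (k in seq_len(nrow(segments))) {
    sd_res[resno >= segments$start[k] & resno <= segments$end[k]] <- segments$sd[k]
  }
  # generic coil: 100 deg turn and 1.5 A rise per residue; radius chosen so
  # consecutive C-alpha atoms are 3.8 A apart
  phi <- (seq_len(n_res) - 1) * 100 * pi / 180
  radius <- sqrt(3.8^2 - 1.5^2) / (2 * sin(50 * pi / 180))
  base <- cbind(radius * cos(phi), radius * sin(phi),
                1.5 * (seq_len(n_res) - 1))
  set.seed(seed)
  xyz <- matrix(NA_real_, n_models, 3 * n_res)
  for (m in seq_len(n_models)) {
    co <- base + matrix(stats::rnorm(3 * n_res, sd = rep(sd_res, 3)), n_res, 3)
    if (rigid_motion) {
      Q <- random_rotations(1)[, , 1]
      tr <- stats::runif(3, -10, 10)
      co <- co %*% t(Q) + matrix(tr, n_res, 3, byrow = TRUE)
    }
    xyz[m, ] <- as.numeric(t(co))
  }
  atoms <- data.frame(serial = seq_len(n_res), name = "CA", resno = resno,
                      resid = "ALA", chain = "A", b = 0,
                      stringsAsFactors = FALSE)
  coord_ensemble(atoms, xyz)
}

#' Randomize the ordering directors of a trajectory ensemble
#'
#' Left-composes every frame of each trajectory with one fixed random
#' rotation per trajectory. For trajectories generated in an orienting
#' potential about the lab z-axis this turns a macroscopically aligned
#' ensemble into an isotropic one — each label now librates about its own
#' random director, as labels on randomly oriented proteins in a real
#' sample do — without changing any single-trajectory orientational
#' statistics relative to its own director. Restricted labels then produce
#' powder-like (broad) spectra and mobile labels motionally narrowed ones.
#'
#' @param trajectories list of [orientation_trajectory()] or a
#'   \code{trajectory_ensemble}.
#' @param seed RNG seed for the director draw.
#' @return same structure with rotated frames.
#' @export
randomize_directors <- function(trajectories, seed = 1L) {
  ens <- inherits(trajectories, "trajectory_ensemble")
  trajs <- if (ens) trajectories$trajectories else trajectories
  if (inherits(trajs, "orientation_trajectory")) trajs <- list(trajs)
  set.seed(seed)
  Q <- random_rotations(length(trajs))
  out <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    rot <- array(NA_real_, dim(tr$rotations))
    for (t in seq_len(tr$n_frames)) {
      rot[, , t] <- Q[, , i] %*% tr$rotations[, , t]
    }
    orientation_trajectory(rot, tr$dt_ps, validate = FALSE)
  })
  if (ens) {
    trajectories$trajectories <- out
    trajectories
  } else out
}

#' Equilibrium order parameter of the uniaxial orienting potential
#'
#' Boltzmann average S(lambda) = <P2(cos beta)> under the density
#' proportional to exp(lambda * cos^2 beta) * sin(beta), evaluated by 1-D
#' quadrature. This is the value the order parameter estimated from
#' [simulate_orientation()] converges to.
#'
#' @param lambda orienting-potential strength (>= 0).
#' @return order parameter in [0, 1].
#' @export
maier_saupe_order_parameter <- function(lambda) {
  vapply(lambda, function(lam) {
    num <- stats::integrate(function(u) (3 * u^2 - 1) / 2 * exp(lam * u^2),
                            -1, 1, rel.tol = 1e-10)$value
    den <- stats::integrate(function(u) exp(lam * u^2),
                            -1, 1, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
}

#' Order parameter of a trajectory about a given axis
#'
#' S = <P2(cos beta)> over frames, with beta the angle between the body
#' z-axis and \code{axis}.
#'
#' @param traj an [orientation_trajectory()].
#' @param axis reference axis (default: lab z, the potential axis of the
#'   synthetic generator).
#' @return scalar order parameter.
#' @export
order_parameter <- function(traj, axis = c(0, 0, 1)) {
  u <- zaxes(traj) %*% unit(axis)
  mean((3 * u^2 - 1) / 2)
}
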