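# Physical constants (SI)
MU_B <- 9.2740100783e-24   # Bohr magneton, J/T
HBAR <- 1.054571817e-34    # reduced Planck constant, J s

#' Nitroxide magnetic tensors
#'
#' Principal values of the g and 14N hyperfine (A) tensors in the nitroxide
#' molecular frame (x along N-O, z along the nitrogen p orbital). Defaults
#' are literature-standard MTSSL values at X band; all values are
#' configurable. The 14N nuclear spin is 1, so the spectrum has three
#' hyperfine manifolds m_I = -1, 0, +1.
#'
#' @param g_principal numeric triple (gxx, gyy, gzz).
#' @param A_principal_mT numeric triple (Axx, Ayy, Azz) in mT. For
#'   nitroxides Azz is the largest component (warned if violated).
#' @return object of class \code{magnetic_tensors} with derived
#'   \code{g_iso} and \code{a_iso_mT}.
#' @export
magnetic_tensors <- function(g_principal = c(2.0086, 2.0066, 2.0026),
                             A_principal_mT = c(0.52, 0.52, 3.5)) {
  stopifnot(length(g_principal) == 3, length(A_principal_mT) == 3)
  if (any(g_principal <= 0) || any(A_principal_mT <= 0)) {
    stop("tensor principal values must be positive")
  }
  if (A_principal_mT[3] < max(A_principal_mT[1:2])) {
    warning("Azz is not the largest hyperfine component; unusual for a nitroxide")
  }
  structure(list(g = g_principal, A_mT = A_principal_mT,
                 g_iso = mean(g_principal), a_iso_mT = mean(A_principal_mT),
                 nuclear_spin = 1L),
            class = "magnetic_tensors")
}

#' Spectrum acquisition settings
#'
#' Field axis and relaxation/broadening parameters for simulated cw X-band
#' spectra. The free-induction-decay window must be at least 5 relaxation
#' times long so the decay is complete within it.
#'
#' @param B0_mT center field, mT.
#' @param sweep_mT sweep width, mT.
#' @param n_field_points points on the field axis.
#' @param T2_ns homogeneous relaxation time, ns.
#' @param gaussian_broadening_mT standard deviation of the Gaussian
#'   inhomogeneous broadening convolved into the absorption, mT.
#' @param fid_ns length of the simulated free induction decay, ns.
#' @param n_trajectories default ensemble size for generators that need one.
#' @return object of class \code{spectrum_settings}.
#' @export
spectrum_settings <- function(B0_mT = 338, sweep_mT = 12,
                              n_field_points = 1024, T2_ns = 50,
                              gaussian_broadening_mT = 0.1, fid_ns = 500,
                              n_trajectories = 100) {
  stopifnot(B0_mT > 0, sweep_mT > 0, n_field_points >= 64, T2_ns > 0,
            gaussian_broadening_mT >= 0, fid_ns > 0, n_trajectories >= 1)
  if (fid_ns < 5 * T2_ns) {
    stop("fid_ns must be at least 5 * T2_ns so the FID decays within the window")
  }
  structure(list(B0_mT = B0_mT, sweep_mT = sweep_mT,
                 n_field_points = as.integer(n_field_points), T2_ns = T2_ns,
                 gaussian_broadening_mT = gaussian_broadening_mT,
                 fid_ns = fid_ns, n_trajectories = as.integer(n_trajectories)),
            class = "spectrum_settings")
}

#' Orientation-dependent effective g factor and hyperfine coupling
#'
#' First-order secular values for a given nitroxide orientation: with
#' n = R' z_lab the lab field direction expressed in the nitroxide frame,
#' g_eff = sum_i g_ii n_i^2 and A_eff = sum_i A_ii n_i^2. The same quadratic
#' form is used for g and A so that the motional-narrowing limit averages
#' exactly to (g_iso, a_iso).
#'
#' @param R 3x3 proper rotation matrix (body axes as columns in the lab
#'   frame).
#' @param tensors a [magnetic_tensors()].
#' @return named numeric vector \code{c(g_eff, A_eff_mT)}.
#' @export
effective_g_A <- function(R, tensors = magnetic_tensors()) {
  if (!is_rotation_matrix(R)) stop("R must be a proper rotation matrix")
  n2 <- R[3, ]^2  # (z_lab . body axis i)^2
  c(g_eff = sum(tensors$g * n2), A_eff_mT = sum(tensors$A_mT * n2))
}

# Angular-frequency offsets (rad/s) of one trajectory: list with the g-shift
# term dwg(t) and the hyperfine term wA(t) (to be scaled by m_I).
traj_omega_series <- function(traj, tensors, settings) {
  n2 <- t(traj$rotations[3, , , drop = TRUE]^2)
  if (traj$n_frames == 1) n2 <- matrix(traj$rotations[3, , 1]^2, 1, 3)
  g_eff <- as.numeric(n2 %*% tensors$g)
  A_eff <- as.numeric(n2 %*% tensors$A_mT)
  g_ref <- tensors$g_iso
  gamma_ref <- g_ref * MU_B / HBAR  # rad s^-1 T^-1
  list(dwg = (MU_B * settings$B0_mT * 1e-3 / HBAR) * (g_eff - g_ref),
       wA = gamma_ref * A_eff * 1e-3)
}

#' Simulate a first-derivative cw EPR spectrum from orientation trajectories
#'
#' Implements the trajectory-based lineshape calculation: for every
#' trajectory and every 14N manifold m_I in \{-1, 0, +1\}, the resonance
#' offset \eqn{\Delta\omega(t) = (\mu_B B_0/\hbar)(g_{eff}(t) - g_{ref}) +
#' m_I \gamma A_{eff}(t)} is integrated into a phase, the free induction
#' decay \eqn{\langle e^{-i\phi(t)}\rangle e^{-t/T_2}} is averaged over the
#' ensemble and manifolds (equal weights), and the absorption spectrum is
#' the real part of its Fourier transform mapped to field units via
#' \eqn{\Delta B = -\Delta\omega \hbar/(g_{ref}\mu_B)} with
#' \eqn{g_{ref} = g_{iso}}. The absorption is then convolved with a
#' Gaussian of the configured width and differentiated with respect to
#' field. Trajectories shorter than the FID window are extended by periodic
#' continuation of the phase increments (phase-continuous by construction).
#'
#' The FID is accumulated at the trajectory time step (the per-step phase
#' increment must stay below 0.5 rad) but stored at a coarser, automatically
#' chosen sampling interval whose Nyquist range still covers the spectral
#' content; the transform is zero-padded so the field grid resolves the
#' homogeneous linewidth.
#'
#' @param trajectories an [orientation_trajectory()], a list of them, or a
#'   \code{trajectory_ensemble} from [simulate_exchange()].
#' @param tensors a [magnetic_tensors()].
#' @param settings a [spectrum_settings()].
#' @return object of class \code{epr_spectrum}: \code{field_mT},
#'   \code{absorption}, \code{derivative} (a.u.), \code{central_linewidth_mT}
#'   (peak-to-peak width of the m_I = 0 line, NA if unresolved),
#'   \code{inverse_linewidth} and the inputs used.
#' @export
simulate_spectrum <- function(trajectories, tensors = magnetic_tensors(),
                              settings = spectrum_settings()) {
  if (inherits(trajectories, "orientation_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (inherits(trajectories, "trajectory_ensemble")) {
    trajectories <- trajectories$trajectories
  }
  stopifnot(length(trajectories) >= 1,
            all(vapply(trajectories, inherits, logical(1),
                       "orientation_trajectory")))
  check_sweep(tensors, settings)
  g_ref <- tensors$g_iso
  gamma_ref <- g_ref * MU_B / HBAR

  # content bound (rad/s) -> coarse FID sampling interval
  w_max <- (MU_B * settings$B0_mT * 1e-3 / HBAR) *
    max(abs(tensors$g - g_ref)) + gamma_ref * max(tensors$A_mT) * 1e-3
  w_lim <- max(w_max, gamma_ref * settings$sweep_mT / 2 * 1e-3)
  dt_target_s <- pi / (2.5 * w_lim)

  first <- TRUE
  for (traj in trajectories) {
    dt_s <- traj$dt_ps * 1e-12
    om <- traj_omega_series(traj, tensors, settings)
    dphi_g <- om$dwg * dt_s
    dphi_A <- om$wA * dt_s
    if (max(abs(dphi_g) + abs(dphi_A)) >= 0.5) {
      stop("per-step phase increment >= 0.5 rad; use a finer trajectory time step")
    }
    if (first) {
      stride <- max(1L, floor(dt_target_s / dt_s))
      n_fine <- max(stride, ceiling(settings$fid_ns * 1e3 / traj$dt_ps))
      n_fid <- n_fine %/% stride
      n_fine <- n_fid * stride
      dt_fid_s <- stride * dt_s
      acc <- matrix(0 + 0i, n_fid + 1, 3)  # manifolds -1, 0, +1
      first <- FALSE
    } else if (abs(traj$dt_ps * 1e-12 - dt_s) > 0) {
      stop("all trajectories must share the same time step")
    }
    sel <- stride * seq_len(n_fid)
    if (traj$n_frames == 1L) {
      phi_g <- dphi_g[1] * sel
      phi_A <- dphi_A[1] * sel
    } else {
      phi_g <- cumsum(rep_len(dphi_g, n_fine))[sel]
      phi_A <- cumsum(rep_len(dphi_A, n_fine))[sel]
    }
    for (k in 1:3) {
      m <- k - 2L
      acc[, k] <- acc[, k] + c(1 + 0i, exp(-1i * (phi_g + m * phi_A)))
    }
  }
  fid <- rowSums(acc) / (3 * length(trajectories))
  tt <- (0:n_fid) * dt_fid_s
  fid <- fid * exp(-tt / (settings$T2_ns * 1e-9))
  fid[1] <- fid[1] / 2  # trapezoid end weight for the one-sided transform

  n_fft <- 2^ceiling(log2(length(fid)))
  # pad so the transform grid is finer than the requested field axis
  repeat {
    dB_grid <- 2 * pi / (n_fft * dt_fid_s) * HBAR / (g_ref * MU_B) * 1e3
    if (dB_grid <= settings$sweep_mT / settings$n_field_points || n_fft >= 2^21) break
    n_fft <- n_fft * 2L
  }
  raw <- stats::fft(c(fid, rep(0 + 0i, n_fft - length(fid))), inverse = TRUE)
  k <- 0:(n_fft - 1)
  omega <- 2 * pi * k / (n_fft * dt_fid_s)
  omega[k > n_fft / 2] <- omega[k > n_fft / 2] - 2 * pi / dt_fid_s
  absn <- Re(raw) * dt_fid_s
  dB <- -omega * HBAR / (g_ref * MU_B) * 1e3
  ord <- order(dB)

  field <- seq(settings$B0_mT - settings$sweep_mT / 2,
               settings$B0_mT + settings$sweep_mT / 2,
               length.out = settings$n_field_points)
  ab <- stats::approx(settings$B0_mT + dB[ord], absn[ord], xout = field,
                      rule = 2)$y
  finish_spectrum(field, ab, tensors, settings)
}

# sweep must cover the full hyperfine extent plus broadening
check_sweep <- function(tensors, settings) {
  if (settings$sweep_mT / 2 <
      tensors$A_mT[3] + 3 * settings$gaussian_broadening_mT) {
    stop("sweep too narrow: must cover +/- (Azz + 3 * gaussian broadening)")
  }
  invisible(TRUE)
}

# Gaussian smoothing + field derivative + central-line measurement shared by
# the trajectory path and the closed-form reference spectra.
finish_spectrum <- function(field, absorption, tensors, settings) {
  step <- field[2] - field[1]
  absorption <- gaussian_smooth(absorption, step,
                                settings$gaussian_broadening_mT)
  deriv <- field_derivative(absorption, step)
  spec <- structure(list(field_mT = field, absorption = absorption,
                         derivative = deriv, field_step_mT = step,
                         B0_mT = settings$B0_mT, tensors = tensors,
                         settings = settings,
                         central_linewidth_mT = NA_real_,
                         inverse_linewidth = NA_real_),
                    class = "epr_spectrum")
  lw <- tryCatch(central_linewidth(spec), error = function(e) NULL)
  if (!is.null(lw)) {
    spec$central_linewidth_mT <- lw[["dH0_mT"]]
    spec$inverse_linewidth <- lw[["inv_dH0"]]
  }
  spec
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf("<epr_spectrum> %d points, %.6g..%.6g mT, dH0 = %s mT\n",
              length(x$field_mT), min(x$field_mT), max(x$field_mT),
              format(x$central_linewidth_mT, digits = 4)))
  invisible(x)
}

gaussian_smooth <- function(y, step, sd_mT) {
  if (sd_mT <= 0) return(y)
  half <- max(1L, ceiling(4 * sd_mT / step))
  kx <- (-half:half) * step
  kern <- exp(-kx^2 / (2 * sd_mT^2))
  kern <- kern / sum(kern)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, kern, sides = 2))[(half + 1):(half + n)]
}

field_derivative <- function(y, step) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * step)
  d[1] <- (y[2] - y[1]) / step
  d[n] <- (y[n] - y[n - 1]) / step
  d
}

# parabolic (3-point) refinement of an extremum position on a uniform grid
refine_extremum <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < 1e-300) return(x[i])
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[2] - x[1])
}

#' Rigid-limit (powder) reference spectrum by orientation-grid summation
#'
#' Independent field-domain reference for the trajectory path: sums
#' closed-form Lorentzian absorption lines (half-width \eqn{\hbar/(g_{ref}
#' \mu_B T_2)}) at the static resonance fields of a deterministic
#' near-uniform orientation grid, then applies the same Gaussian broadening
#' and differentiation. For nitroxides the outer derivative extrema of this
#' powder pattern are separated by 2 Azz.
#'
#' @param tensors a [magnetic_tensors()].
#' @param settings a [spectrum_settings()].
#' @param n_orientations grid size (Fibonacci sphere).
#' @return an \code{epr_spectrum}.
#' @export
rigid_limit_spectrum <- function(tensors = magnetic_tensors(),
                                 settings = spectrum_settings(),
                                 n_orientations = 10000) {
  check_sweep(tensors, settings)
  u2 <- fibonacci_sphere(n_orientations)^2
  g_eff <- as.numeric(u2 %*% tensors$g)
  A_eff <- as.numeric(u2 %*% tensors$A_mT)
  g_ref <- tensors$g_iso
  hw <- HBAR / (g_ref * MU_B * settings$T2_ns * 1e-9) * 1e3  # HWHM, mT
  field <- seq(settings$B0_mT - settings$sweep_mT / 2,
               settings$B0_mT + settings$sweep_mT / 2,
               length.out = settings$n_field_points)
  dBg <- -settings$B0_mT * (g_eff - g_ref) / g_ref
  ab <- numeric(length(field))
  for (m in -1:1) {
    centers <- settings$B0_mT + dBg - m * A_eff
    # chunked Lorentzian summation to bound memory
    for (ch in split(centers, ceiling(seq_along(centers) / 2000))) {
      ab <- ab + colSums((hw / pi) /
                           (outer(ch, field, function(c, f) (f - c)^2) + hw^2))
    }
  }
  ab <- ab / (3 * n_orientations)
  finish_spectrum(field, ab, tensors, settings)
}

#' Fast-motion (isotropic) reference spectrum
#'
#' Motional-narrowing limit: three Lorentzian lines of equal intensity at
#' the isotropic g position split by a_iso = (Axx + Ayy + Azz)/3.
#'
#' @inheritParams rigid_limit_spectrum
#' @return an \code{epr_spectrum}.
#' @export
fast_limit_spectrum <- function(tensors = magnetic_tensors(),
                                settings = spectrum_settings()) {
  check_sweep(tensors, settings)
  g_ref <- tensors$g_iso
  hw <- HBAR / (g_ref * MU_B * settings$T2_ns * 1e-9) * 1e3
  field <- seq(settings$B0_mT - settings$sweep_mT / 2,
               settings$B0_mT + settings$sweep_mT / 2,
               length.out = settings$n_field_points)
  ab <- numeric(length(field))
  for (m in -1:1) {
    ctr <- settings$B0_mT - m * tensors$a_iso_mT
    ab <- ab + (hw / pi) / ((field - ctr)^2 + hw^2)
  }
  finish_spectrum(field, ab / 3, tensors, settings)
}

#' Peak-to-peak width of the central resonance line
#'
#' The peak-to-peak field separation of the derivative extrema of the
#' central (m_I = 0) line, and its inverse — the conventional empirical
#' mobility measure. The search window is centered on the isotropic-g field
#' position and excludes the outer hyperfine lines; extremum positions are
#' refined by parabolic interpolation. If the window contains no positive
#' lobe followed by a negative lobe (unresolved central line), an error is
#' raised rather than a width guessed.
#'
#' @param spectrum an \code{epr_spectrum}.
#' @return named numeric vector \code{c(dH0_mT, inv_dH0)}.
#' @export
central_linewidth <- function(spectrum) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  f <- spectrum$field_mT
  d <- spectrum$derivative
  half <- 0.6 * spectrum$tensors$a_iso_mT
  win <- which(abs(f - spectrum$B0_mT) <= half)
  if (length(win) < 5) stop("field axis too coarse around the center field")
  dmax_i <- win[which.max(d[win])]
  after <- win[win > dmax_i]
  if (!length(after)) stop("no resolved central line: no negative lobe after the maximum")
  dmin_i <- after[which.min(d[after])]
  if (!(d[dmax_i] > 0 && d[dmin_i] < 0)) {
    stop("no resolved central line: derivative does not change sign near center")
  }
  b_up <- refine_extremum(f, d, dmax_i)
  b_dn <- refine_extremum(f, d, dmin_i)
  dH0 <- b_dn - b_up
  c(dH0_mT = dH0, inv_dH0 = 1 / dH0)
}

#' Spectral weight in mobile and immobile field windows
#'
#' Integrated (non-negative) absorption weight in two diagnostic field
#' windows, normalized by the total absorption: an "immobile" window at the
#' low-field hyperfine extreme (near center - Azz), populated only when
#' labels are motionally restricted, and a "mobile" window around the
#' central line. Purely descriptive.
#'
#' @param spectrum an \code{epr_spectrum}.
#' @param immobile_window,mobile_window numeric \code{c(lo, hi)} in mT;
#'   defaults are derived from the spectrum's tensors.
#' @return list with \code{immobile_weight}, \code{mobile_weight} and the
#'   windows used.
#' @export
classify_components <- function(spectrum, immobile_window = NULL,
                                mobile_window = NULL) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  B0 <- spectrum$B0_mT
  Azz <- spectrum$tensors$A_mT[3]
  if (is.null(immobile_window)) immobile_window <- c(B0 - Azz - 1, B0 - Azz + 1)
  if (is.null(mobile_window)) mobile_window <- c(B0 - 0.7, B0 + 0.7)
  f <- spectrum$field_mT
  rng <- range(f)
  for (w in list(immobile_window, mobile_window)) {
    if (w[1] < rng[1] || w[2] > rng[2]) {
      stop("classification window outside the field sweep")
    }
  }
  ab <- pmax(spectrum$absorption, 0)
  total <- sum(ab)
  wgt <- function(w) sum(ab[f >= w[1] & f <= w[2]]) / total
  list(immobile_weight = wgt(immobile_window),
       mobile_weight = wgt(mobile_window),
       immobile_window = immobile_window, mobile_window = mobile_window)
}

#' Field separation of the outermost derivative extrema
#'
#' Locates the leftmost local maximum and the rightmost local minimum of the
#' derivative spectrum whose amplitudes exceed a threshold relative to the
#' global extremum, refined by parabolic interpolation. For a rigid-limit
#' nitroxide powder pattern this separation equals 2 Azz.
#'
#' @param spectrum an \code{epr_spectrum}.
#' @param min_rel_amp amplitude threshold as a fraction of max(|derivative|).
#' @return separation in mT.
#' @export
outer_extrema_splitting <- function(spectrum, min_rel_amp = 0.03) {
  d <- spectrum$derivative
  f <- spectrum$field_mT
  n <- length(d)
  thr <- min_rel_amp * max(abs(d))
  i <- 2:(n - 1)
  loc_max <- i[d[i] > d[i - 1] & d[i] >= d[i + 1] & d[i] > thr]
  loc_min <- i[d[i] < d[i - 1] & d[i] <= d[i + 1] & d[i] < -thr]
  if (!length(loc_max) || !length(loc_min)) {
    stop("no extrema above the amplitude threshold")
  }
  refine_extremum(f, d, max(loc_min)) - refine_extremum(f, d, min(loc_max))
}

#' Positions of the strongest absorption peaks
#'
#' Finds local maxima of the absorption, keeps the strongest ones subject to
#' a minimum mutual separation, and refines their positions parabolically.
#' Used e.g. to read the three-line splitting off a motionally narrowed
#' spectrum.
#'
#' @param spectrum an \code{epr_spectrum}.
#' @param n number of peaks to return.
#' @param min_sep_mT minimum separation between reported peaks.
#' @return sorted numeric vector of peak fields (mT).
#' @export
absorption_peaks <- function(spectrum, n = 3, min_sep_mT = 0.5) {
  a <- spectrum$absorption
  f <- spectrum$field_mT
  i <- 2:(length(a) - 1)
  cand <- i[a[i] > a[i - 1] & a[i] >= a[i + 1]]
  cand <- cand[order(a[cand], decreasing = TRUE)]
  picked <- integer()
  for (j in cand) {
    if (length(picked) == n) break
    if (all(abs(f[j] - f[picked]) >= min_sep_mT)) picked <- c(picked, j)
  }
  if (length(picked) < n) stop(sprintf("found only %d peaks", length(picked)))
  sort(vapply(picked, function(j) refine_extremum(f, a, j), numeric(1)))
}
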