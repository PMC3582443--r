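#' Mode of the orientational distribution of the nitroxide z-axis
#'
#' Estimates the modal direction of the z-axis density on the sphere by a
#' Fisher-kernel density estimate evaluated at the sample directions
#' themselves, followed by a few fixed-point (mean-shift) refinements. The
#' kernel concentration is 1 / (circular variance of the z sample), where
#' circular variance = 1 - mean resultant length. Deterministic for a fixed
#' input: candidates and kernel samples are thinned by fixed stride when the
#' trajectory is long, and the documented tie rule orients the result into
#' the hemisphere of the first frame's z-axis.
#'
#' @param traj an [orientation_trajectory()] with at least 10 frames.
#' @param max_candidates,max_samples caps on the KDE evaluation grid and
#'   kernel sample (deterministic thinning by stride).
#' @return unit 3-vector.
#' @export
estimate_mode_axis <- function(traj, max_candidates = 1000,
                               max_samples = 20000) {
  z <- zaxes(traj)
  n <- nrow(z)
  if (n < 10) stop("mode-axis estimation needs at least 10 frames")
  zs <- z[unique(round(seq(1, n, length.out = min(n, max_samples)))), ,
          drop = FALSE]
  cand <- z[unique(round(seq(1, n, length.out = min(n, max_candidates)))), ,
            drop = FALSE]
  rbar <- sqrt(sum(colMeans(zs)^2))
  kappa <- 1 / max(1e-3, 1 - rbar)
  # exp(kappa*(cos - 1)) keeps the kernel numerically bounded at large kappa
  dens <- as.numeric(exp(kappa * (cand %*% t(zs) - 1)) %*%
                       rep(1, nrow(zs)))
  mode <- cand[which.max(dens), ]
  for (i in 1:10) {
    w <- as.numeric(exp(kappa * (zs %*% mode - 1)))
    m_new <- colSums(zs * w)
    nm <- sqrt(sum(m_new^2))
    if (nm < 1e-12) break
    m_new <- m_new / nm
    if (sum((m_new - mode)^2) < 1e-16) {
      mode <- m_new
      break
    }
    mode <- m_new
  }
  if (sum(mode * z[1, ]) < 0) mode <- -mode  # tie rule: first frame's hemisphere
  unit(mode)
}

#' Beta-angle time series of a trajectory
#'
#' beta_t is the angular deviation of the nitroxide z-axis from the mode of
#' its orientational distribution: beta_t = acos(z_t . mode), in degrees.
#'
#' @param traj an [orientation_trajectory()].
#' @param mode_axis unit 3-vector; typically from [estimate_mode_axis()].
#' @return object of class \code{beta_series}: list with \code{angles}
#'   (degrees, in [0, 180]), \code{mode_axis}, \code{dt_ps}.
#' @export
beta_series <- function(traj, mode_axis = estimate_mode_axis(traj)) {
  if (abs(sum(mode_axis^2) - 1) > 1e-6) stop("mode_axis must be unit norm")
  cosb <- pmin(1, pmax(-1, zaxes(traj) %*% mode_axis))
  structure(list(angles = as.numeric(acos(cosb)) * 180 / pi,
                 mode_axis = mode_axis, dt_ps = traj$dt_ps),
            class = "beta_series")
}

#' Histogram and Gaussian fit of a beta-angle series
#'
#' Bins beta on [0, 180] degrees, normalizes to a density, and fits a
#' Gaussian a*exp(-(x-mu)^2/(2*sigma^2)) to (bin center, density) by
#' unweighted least squares — the red-curve-on-histogram procedure used for
#' such distributions. The full width at half maximum follows from the
#' fitted sigma (FWHM = 2*sqrt(2*ln 2)*sigma). If the fit fails or the
#' distribution is degenerate, the result is flagged and the FWHM falls back
#' to the empirical half-maximum crossing width (bounded below by one bin).
#'
#' @param series a [beta_series()].
#' @param bin_width_deg histogram bin width in degrees, in (0, 30].
#' @return object of class \code{beta_distribution}: \code{bin_centers},
#'   \code{density} (deg^-1, sums x bin width to 1), \code{gaussian_mu},
#'   \code{gaussian_sigma}, \code{fwhm} (deg), \code{fit_residual} (RMS),
#'   \code{flagged}.
#' @export
beta_distribution <- function(series, bin_width_deg = 2) {
  stopifnot(inherits(series, "beta_series"),
            bin_width_deg > 0, bin_width_deg <= 30)
  lo <- min(0, floor(min(series$angles) / bin_width_deg) * bin_width_deg)
  breaks <- seq(lo, 180 + bin_width_deg, by = bin_width_deg)
  h <- graphics::hist(series$angles, breaks = breaks, plot = FALSE)
  centers <- h$mids
  dens <- h$counts / (sum(h$counts) * bin_width_deg)
  # fit around the dominant peak: a minority antipodal population (labels
  # that crossed to the equivalent well of the symmetric potential) must not
  # drag a global fit away from the main orientation mode
  mu0 <- centers[which.max(dens)]
  win <- abs(centers - mu0) <= 60
  wd <- dens[win] / max(sum(dens[win]) * bin_width_deg, 1e-12)
  mu_w <- sum(centers[win] * wd) * bin_width_deg
  s0 <- sqrt(max(bin_width_deg^2 / 12,
                 sum((centers[win] - mu_w)^2 * wd) * bin_width_deg))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ a * exp(-(x - mu)^2 / (2 * s^2)),
      data = data.frame(x = centers[win], d = dens[win]),
      start = list(a = max(dens), mu = mu0, s = s0),
      lower = c(0, 0, 1e-3), upper = c(Inf, 180, 120),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  flagged <- FALSE
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    mu <- unname(cf["mu"]); sg <- abs(unname(cf["s"]))
    fwhm <- 2 * sqrt(2 * log(2)) * sg
    resid_rms <- sqrt(mean(stats::resid(fit)^2))
    # a "fit" collapsing to sub-bin width on non-degenerate data is degenerate
    if (fwhm < bin_width_deg) flagged <- TRUE
  } else {
    flagged <- TRUE
    mu <- mu0; sg <- NA_real_
    resid_rms <- NA_real_
  }
  if (flagged) {
    fwhm <- max(empirical_fwhm(centers, dens), bin_width_deg)
    if (is.na(sg)) sg <- fwhm / (2 * sqrt(2 * log(2)))
  }
  structure(list(bin_centers = centers, density = dens,
                 gaussian_mu = mu, gaussian_sigma = sg, fwhm = fwhm,
                 fit_residual = resid_rms, flagged = flagged,
                 bin_width_deg = bin_width_deg),
            class = "beta_distribution")
}

# Width at half maximum by linear interpolation of the crossings of the
# (possibly ragged) density profile; 0 if fewer than two crossings exist.
empirical_fwhm <- function(x, y) {
  ymax <- max(y)
  if (ymax <= 0) return(0)
  half <- ymax / 2
  above <- y >= half
  if (!any(above)) return(0)
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  x_lo <- if (i1 == 1) x[1] else {
    x[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (x[i1] - x[i1 - 1])
  }
  x_hi <- if (i2 == length(x)) x[length(x)] else {
    x[i2] + (y[i2] - half) / (y[i2] - y[i2 + 1]) * (x[i2 + 1] - x[i2])
  }
  x_hi - x_lo
}

#' Mean-square fluctuation mobility parameter of a beta series
#'
#' The mean-square fluctuation amplitude of the nitroxide orientation,
#' msf = <(beta_t - mean(beta))^2> in deg^2, is the simulation-side mobility
#' measure: the larger it is, the more flexible the label side chain. A
#' normalized variant divides by the free-diffusion reference — the beta
#' variance of a uniform distribution on the sphere, (pi^2/4 - 2) rad^2 —
#' and clips to [0, 1], mapping rigid to 0 and freely diffusing to 1.
#'
#' @param series a [beta_series()] with at least 2 frames.
#' @return list with \code{msf_beta} (deg^2) and \code{normalized_mobility}.
#' @export
mobility_parameter <- function(series) {
  stopifnot(inherits(series, "beta_series"), length(series$angles) >= 2)
  msf <- mean((series$angles - mean(series$angles))^2)
  ref <- (pi^2 / 4 - 2) * (180 / pi)^2  # uniform-sphere beta variance, deg^2
  list(msf_beta = msf,
       normalized_mobility = min(1, max(0, msf / ref)))
}
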