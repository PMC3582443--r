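#' Build the nitroxide molecular frame from three atoms
#'
#' The nitroxide coordinate system has x along the N-O bond and z
#' perpendicular to the plane of the nitroxide ring (the direction of the
#' nitrogen p orbital carrying the unpaired spin density); y completes a
#' right-handed frame. The label position used for inter-label distances is
#' the midpoint of the N-O bond, where the spin density is shared between
#' the two atoms.
#'
#' @param N,O,ring_ref 3-vectors (Angstrom): the nitroxide nitrogen, the
#'   nitroxide oxygen, and a ring atom bonded to N that fixes the ring
#'   plane (conventionally the ring carbon next to N).
#' @return object of class \code{nitroxide_frame}: list with \code{rotation}
#'   (3x3, columns are the body x, y, z axes in the lab frame, det = +1)
#'   and \code{origin} (N-O bond midpoint).
#' @examples
#' f <- build_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' f$rotation  # identity
#' @export
build_frame <- function(N, O, ring_ref) {
  N <- as.numeric(N); O <- as.numeric(O); ring_ref <- as.numeric(ring_ref)
  stopifnot(length(N) == 3, length(O) == 3, length(ring_ref) == 3)
  if (sqrt(sum((O - N)^2)) < 1e-8 || sqrt(sum((ring_ref - N)^2)) < 1e-8) {
    stop("nitroxide frame atoms must be distinct")
  }
  x <- unit(O - N)
  v <- unit(ring_ref - N)
  zc <- cross3(x, v)
  if (sqrt(sum(zc^2)) < 1e-8) {
    stop("nitroxide frame atoms are collinear; ring plane undefined")
  }
  z <- unit(zc)
  y <- cross3(z, x)
  R <- cbind(x, y, z)
  dimnames(R) <- NULL
  structure(list(rotation = R, origin = (N + O) / 2),
            class = "nitroxide_frame")
}

#' Nitroxide frames for every model of a coordinate ensemble
#'
#' Locates the three frame-defining atoms of a labeled residue in each model
#' and returns the resulting rotation-matrix time series, bridging structural
#' snapshot ensembles to the orientational (beta-angle) analysis.
#'
#' @param ensemble a [coord_ensemble()].
#' @param residue residue number carrying the label.
#' @param atom_names character triple \code{c(N, O, ring_ref)} naming the
#'   frame atoms; defaults to \code{c("N1", "O1", "C2")} (adjust to the
#'   label topology in use).
#' @param dt_ps time step to attach to the trajectory (snapshot spacing).
#' @param chain optional chain identifier.
#' @return an [orientation_trajectory()] with one frame per model; the label
#'   origins (N-O midpoints, n x 3) are attached as attribute
#'   \code{"origins"}.
#' @export
frames_from_ensemble <- function(ensemble, residue,
                                 atom_names = c("N1", "O1", "C2"),
                                 dt_ps = 1, chain = NULL) {
  stopifnot(length(atom_names) == 3)
  at <- ensemble$atoms
  sel <- at$resno == residue
  if (!is.null(chain)) sel <- sel & at$chain == chain
  idx <- vapply(atom_names, function(nm) {
    i <- which(sel & at$name == nm)
    if (!length(i)) NA_integer_ else i[1]
  }, integer(1))
  if (anyNA(idx)) {
    stop(sprintf("atoms %s not found for residue %d",
                 paste(atom_names[is.na(idx)], collapse = ", "), residue))
  }
  n <- ensemble$n_models
  rot <- array(NA_real_, c(3, 3, n))
  org <- matrix(NA_real_, n, 3)
  for (m in seq_len(n)) {
    co <- model_coords(ensemble, m)
    if (!all(is.finite(co[idx, ]))) {
      stop(sprintf("frame atoms missing or non-finite in model %d", m))
    }
    fr <- build_frame(co[idx[1], ], co[idx[2], ], co[idx[3], ])
    rot[, , m] <- fr$rotation
    org[m, ] <- fr$origin
  }
  traj <- orientation_trajectory(rot, dt_ps, validate = FALSE)
  attr(traj, "origins") <- org
  traj
}
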