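# Kabsch least-squares rotation (proper, det = +1) mapping P onto Q after
# centering; returns the 3x3 rotation.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose all models of an ensemble onto a common reference
#'
#' Rigid-body least-squares superposition of every model onto the first
#' model, then once more onto the mean structure of the first pass (one
#' refinement iteration keeps the reference deterministic). The optimal
#' rotation is the standard SVD solution with the determinant constrained
#' to +1, so reflections are never applied. The fit uses the selected atoms;
#' the returned transforms are applied to all atoms.
#'
#' @param ensemble a [coord_ensemble()] with at least 2 models.
#' @param selection atom name(s) used for fitting (default "CA").
#' @return superposed \code{coord_ensemble} with attribute
#'   \code{"reference"} = "iterated mean (CA fit)".
#' @export
superpose <- function(ensemble, selection = "CA") {
  stopifnot(ensemble$n_models >= 2)
  sel <- which(ensemble$atoms$name %in% selection)
  if (length(sel) < 3) stop("need at least 3 selected atoms for superposition")
  # collinearity check on the reference selection
  ref0 <- model_coords(ensemble, 1)[sel, ]
  svd2 <- svd(scale(ref0, scale = FALSE))$d
  if (svd2[2] < 1e-8 * max(svd2[1], 1)) {
    stop("selected atoms are (near-)collinear; superposition is degenerate")
  }
  fit_all <- function(ens, ref_sel) {
    ref_c <- colMeans(ref_sel)
    ref0 <- sweep(ref_sel, 2, ref_c)
    xyz <- ens$xyz
    for (m in seq_len(ens$n_models)) {
      co <- model_coords(ens, m)
      mob <- co[sel, , drop = FALSE]
      mob_c <- colMeans(mob)
      R <- kabsch_rotation(sweep(mob, 2, mob_c), ref0)
      co_new <- sweep(sweep(co, 2, mob_c) %*% R, 2, ref_c, "+")
      xyz[m, ] <- as.numeric(t(co_new))
    }
    coord_ensemble(ens$atoms, xyz)
  }
  pass1 <- fit_all(ensemble, model_coords(ensemble, 1)[sel, , drop = FALSE])
  mean_sel <- matrix(colMeans(pass1$xyz), ncol = 3, byrow = TRUE)[sel, ,
                                                                  drop = FALSE]
  out <- fit_all(pass1, mean_sel)
  attr(out, "reference") <- "iterated mean (selection fit)"
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' rmsf_i = sqrt(<|r_i(m) - <r_i>_m|^2>_m) for each selected atom over the
#' models of a (superposed) ensemble. Fluctuations are about the ensemble
#' mean position, so sum(rmsf^2) equals the total mean-square deviation of
#' the selection.
#'
#' @param ensemble a [coord_ensemble()], normally from [superpose()].
#' @param selection atom name(s) (default "CA").
#' @param skip_models number of leading models to drop (equilibration trim).
#' @return data.frame of class \code{rmsf_profile} with columns
#'   \code{resno}, \code{rmsf} (Angstrom).
#' @export
rmsf <- function(ensemble, selection = "CA", skip_models = 0L) {
  sel <- which(ensemble$atoms$name %in% selection)
  if (!length(sel)) stop("no atoms match the selection")
  models <- (skip_models + 1L):ensemble$n_models
  stopifnot(length(models) >= 2)
  xyz_cols <- as.numeric(t(outer(sel - 1L, 1:3, function(a, k) 3L * a + k)))
  sub <- ensemble$xyz[models, xyz_cols, drop = FALSE]
  dev2 <- sweep(sub, 2, colMeans(sub))^2
  msd_per_coord <- colMeans(dev2)
  msf <- rowSums(matrix(msd_per_coord, ncol = 3, byrow = TRUE))
  out <- data.frame(resno = ensemble$atoms$resno[sel], rmsf = sqrt(msf))
  class(out) <- c("rmsf_profile", "data.frame")
  out
}
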