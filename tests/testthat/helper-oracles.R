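# Independent quadrature oracle for the equilibrium order parameter of the
# uniaxial orienting potential: Boltzmann average of P2(cos beta) over the
# sphere, parameterized by the polar angle (implemented independently of the
# package's substitution form).
oracle_order_parameter <- function(lambda) {
  p2 <- function(th) (3 * cos(th)^2 - 1) / 2
  num <- integrate(function(th) p2(th) * exp(lambda * cos(th)^2) * sin(th),
                   0, pi, rel.tol = 1e-10)$value
  den <- integrate(function(th) exp(lambda * cos(th)^2) * sin(th),
                   0, pi, rel.tol = 1e-10)$value
  num / den
}

# One fixed-width PDB ATOM record (wwPDB v3.3 columns), built by hand so the
# parser tests do not depend on the package's own writer.
pdb_atom_line <- function(serial, name, resno, xyz, alt = " ", resid = "ALA",
                          chain = "A", b = 0, record = "ATOM  ") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, name4, alt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1, b)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Single-frame ("static") trajectories from an array of rotations.
static_trajectories <- function(rotations, dt_ps = 100) {
  n <- dim(rotations)[3]
  lapply(seq_len(n), function(i) {
    orientation_trajectory(rotations[, , i, drop = FALSE], dt_ps,
                           validate = FALSE)
  })
}

# Trajectory whose z-axes are drawn uniformly in a spherical cone of the
# given half-angle about `axis` (closed-form cone sampling).
cone_trajectory <- function(axis, half_angle_deg, n, seed = 1) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  cth <- 1 - runif(n) * (1 - cos(half_angle_deg * pi / 180))
  ang <- acos(cth)
  phi <- runif(n, 0, 2 * pi)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  rot <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    z <- cos(ang[i]) * axis + sin(ang[i]) * (cos(phi[i]) * e1 + sin(phi[i]) * e2)
    x <- c(z[2] * e1[3] - z[3] * e1[2],
           z[3] * e1[1] - z[1] * e1[3],
           z[1] * e1[2] - z[2] * e1[1])
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    rot[, , i] <- cbind(x, y, z)
  }
  orientation_trajectory(rot, 1, validate = FALSE)
}

# normalized RMS difference between two derivative lineshapes
lineshape_nrms <- function(a, b) {
  sqrt(mean((a / max(abs(a)) - b / max(abs(b)))^2))
}
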