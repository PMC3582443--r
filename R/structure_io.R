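#' Coordinate ensemble constructor
#'
#' A coordinate ensemble holds one set of atom metadata shared by all models
#' (as in a multi-model PDB file, where MODEL blocks repeat the same atoms)
#' and an \code{n_models x 3*n_atoms} coordinate matrix in Angstrom, one
#' model per row, coordinates interleaved x1, y1, z1, x2, ...
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{resno}, \code{resid}, \code{chain}, \code{b}.
#' @param xyz numeric matrix, \code{n_models x 3*nrow(atoms)}.
#' @return object of class \code{coord_ensemble}.
#' @export
coord_ensemble <- function(atoms, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3L * nrow(atoms), nrow(xyz) >= 1L)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  structure(list(atoms = atoms, xyz = xyz,
                 n_models = nrow(xyz), n_atoms = nrow(atoms)),
            class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("<coord_ensemble> %d model(s), %d atoms, residues %d..%d\n",
              x$n_models, x$n_atoms, min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Extract one model's coordinates as an n_atoms x 3 matrix
#'
#' @param ensemble a \code{coord_ensemble}.
#' @param model 1-based model index.
#' @return numeric matrix with one row per atom.
#' @export
model_coords <- function(ensemble, model = 1L) {
  stopifnot(model >= 1L, model <= ensemble$n_models)
  matrix(ensemble$xyz[model, ], ncol = 3, byrow = TRUE)
}

# Pre-scan a PDB file for the error conditions the reader reports:
# malformed ATOM coordinate fields (error names the line) and inconsistent
# ATOM counts across MODEL blocks.
validate_pdb_text <- function(lines, path) {
  is_atom <- startsWith(lines, "ATOM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54
    if (ok) {
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      ok <- !anyNA(xyz)
    }
    if (!ok) stop(sprintf("malformed ATOM record at line %d of '%s'", i, path))
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) < length(model_starts)) {
      model_ends <- c(model_ends, length(lines))
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1) {
      stop(sprintf("inconsistent atom count across models in '%s': %s",
                   path, paste(counts, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB file into a coordinate ensemble
#'
#' Parses ATOM records of a PDB file (wwPDB v3.3 fixed columns, via
#' \pkg{bio3d}); each MODEL block becomes one model of the ensemble (a single
#' model if the file has none). HETATM records are ignored. Alternate
#' locations other than blank or 'A' are dropped so that derived distances
#' are deterministic. Residue numbering is kept exactly as deposited.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; \code{NULL} keeps all chains.
#' @return a [coord_ensemble()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("PDB file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "ATOM"))) {
    stop(sprintf("no ATOM records in '%s'", path))
  }
  validate_pdb_text(lines, path)
  utils::capture.output(
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE)))
  at <- pdb$atom
  keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!any(keep)) stop("no atoms left after chain/altloc selection")
  idx <- which(keep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, bio3d::atom2xyz(idx), drop = FALSE]
  atoms <- data.frame(
    serial = at$eleno[idx],
    name   = at$elety[idx],
    resno  = at$resno[idx],
    resid  = at$resid[idx],
    chain  = ifelse(is.na(at$chain[idx]), " ", at$chain[idx]),
    b      = ifelse(is.na(at$b[idx]), 0, at$b[idx]),
    stringsAsFactors = FALSE
  )
  coord_ensemble(atoms, xyz)
}

#' First chain whose residues cover a given range
#'
#' Utility for structures where the relevant chain is identified only by the
#' residue range it must contain (the five-helix bundle spans residues
#' 879-1066 in the vinculin tail numbering).
#'
#' @param ensemble a \code{coord_ensemble}.
#' @param from,to residue-number range the chain must cover.
#' @return single chain identifier.
#' @export
chain_covering <- function(ensemble, from, to) {
  for (ch in unique(ensemble$atoms$chain)) {
    rn <- ensemble$atoms$resno[ensemble$atoms$chain == ch]
    if (min(rn) <= from && max(rn) >= to) return(ch)
  }
  stop(sprintf("no chain covers residues %d..%d", from, to))
}

#' Write an ensemble to PDB with mobility values in the B-factor column
#'
#' All B-factor values are set to zero, then the mobility value of each
#' listed residue (optionally scaled) replaces the zero for every atom of
#' that residue. Coordinates and every other field are written unchanged, so
#' the output differs from a plain write-out only in the B-factor column.
#'
#' @param ensemble a \code{coord_ensemble}.
#' @param bfactor_map named numeric vector, names are residue numbers,
#'   values the mobility (0 = rigid to 1 = mobile). May be empty.
#' @param scale positive multiplier applied to every mapped value (e.g. 1.5
#'   to bring experimental inverse linewidths onto the simulated scale).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb_bfactor <- function(ensemble, bfactor_map = numeric(), scale = 1,
                              path) {
  stopifnot(scale > 0)
  b <- rep(0, ensemble$n_atoms)
  if (length(bfactor_map)) {
    if (is.null(names(bfactor_map))) stop("bfactor_map must be named by residue number")
    if (!all(is.finite(bfactor_map))) stop("non-finite values in bfactor_map")
    res <- as.integer(names(bfactor_map))
    missing <- setdiff(res, unique(ensemble$atoms$resno))
    if (length(missing)) {
      warning(sprintf("residues not in structure, values skipped: %s",
                      paste(missing, collapse = ", ")))
    }
    for (i in seq_along(res)) {
      hit <- ensemble$atoms$resno == res[i]
      if (any(hit)) b[hit] <- scale * bfactor_map[i]
    }
  }
  write_ensemble_pdb(ensemble, path, b = b)
  invisible(path)
}

# Shared PDB writer (bio3d backend); multi-row xyz becomes MODEL blocks.
write_ensemble_pdb <- function(ensemble, path, b = NULL) {
  if (is.null(b)) b <- ensemble$atoms$b
  bio3d::write.pdb(file = path,
                   xyz = ensemble$xyz,
                   type = rep("ATOM", ensemble$n_atoms),
                   resno = ensemble$atoms$resno,
                   resid = ensemble$atoms$resid,
                   eleno = ensemble$atoms$serial,
                   elety = ensemble$atoms$name,
                   chain = ensemble$atoms$chain,
                   o = rep(1, ensemble$n_atoms),
                   b = b)
  invisible(path)
}

#' Orientation trajectory constructor
#'
#' An orientation trajectory is a time series of proper rotation matrices
#' giving the nitroxide body frame in the lab frame (columns = body x, y, z
#' axes), with a fixed time step.
#'
#' @param rotations 3x3xn array of rotation matrices.
#' @param dt_ps time step in picoseconds.
#' @param validate check orthonormality (max |R'R - I| < 1e-6, det > 0) of
#'   every frame; the error names the offending frame.
#' @return object of class \code{orientation_trajectory}.
#' @export
orientation_trajectory <- function(rotations, dt_ps, validate = TRUE) {
  if (length(dim(rotations)) != 3 || any(dim(rotations)[1:2] != 3)) {
    stop("rotations must be a 3x3xn array")
  }
  stopifnot(dt_ps > 0)
  n <- dim(rotations)[3]
  if (validate) {
    for (i in seq_len(n)) {
      if (!is_rotation_matrix(rotations[, , i])) {
        stop(sprintf("frame %d is not a proper rotation matrix", i))
      }
    }
  }
  structure(list(rotations = rotations, dt_ps = dt_ps, n_frames = n),
            class = "orientation_trajectory")
}

#' @export
print.orientation_trajectory <- function(x, ...) {
  cat(sprintf("<orientation_trajectory> %d frames, dt = %g ps (%.3g ns total)\n",
              x$n_frames, x$dt_ps, x$n_frames * x$dt_ps / 1000))
  invisible(x)
}

#' Nitroxide z-axis directions of a trajectory
#'
#' @param traj an \code{orientation_trajectory}.
#' @return n x 3 matrix of unit vectors (third column of each frame matrix).
#' @export
zaxes <- function(traj) {
  t(traj$rotations[, 3, ])
}

#' Write / read the plain-text orientation-trajectory format
#'
#' Format: a header line \code{dt_ps <value>}, then one line per frame with
#' nine reals, the rotation matrix in row-major order. Written with 12
#' significant digits, so a write/read round trip reproduces matrices to
#' better than 1e-9.
#'
#' @param traj an \code{orientation_trajectory}.
#' @param path file path.
#' @return \code{path} (write) or an \code{orientation_trajectory} (read).
#' @export
write_orientation_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("dt_ps %.12g", traj$dt_ps), con)
  rows <- vapply(seq_len(traj$n_frames), function(i) {
    paste(sprintf("%.12g", t(traj$rotations[, , i])), collapse = " ")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' @rdname write_orientation_trajectory
#' @export
read_orientation_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "dt_ps")) {
    stop("orientation trajectory must start with a 'dt_ps <value>' header")
  }
  dt_ps <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]][2])
  if (!is.finite(dt_ps) || dt_ps <= 0) stop("invalid dt_ps header value")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  if (any(lengths(vals) != 9)) {
    stop(sprintf("frame %d does not have 9 values",
                 which(lengths(vals) != 9)[1]))
  }
  n <- length(vals)
  rot <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) rot[, , i] <- matrix(vals[[i]], 3, 3, byrow = TRUE)
  orientation_trajectory(rot, dt_ps, validate = TRUE)
}

#' Download a PDB entry from the RCSB archive
#'
#' Convenience helper for obtaining deposited structures (e.g. the vinculin
#' tail entry 1ST6); requires network access and is not used by the test
#' suite's synthetic fixtures.
#'
#' @param id 4-character PDB accession.
#' @param destdir directory to save into.
#' @return path to the downloaded file.
#' @export
fetch_pdb_structure <- function(id, destdir = tempdir()) {
  stopifnot(nchar(id) == 4)
  dest <- file.path(destdir, paste0(tolower(id), ".pdb"))
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) 1L, warning = function(w) 1L
  )
  if (!identical(status, 0L) || !file.exists(dest)) {
    stop(sprintf("could not download PDB entry %s", id))
  }
  dest
}
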