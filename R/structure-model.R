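#' Bondi van der Waals radii by element, in nm
#'
#' Element-keyed radii used to decide whether a grid point overlaps an atom
#' and as the default overlap rule of the pocket-volume grid. Values are the
#' Bondi set for the elements common in proteins.
#'
#' @format Named numeric vector, names are element symbols, values in nm.
#' @export
vdw_radii_nm <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152,
  S = 0.180, P = 0.180, F = 0.147, CL = 0.175,
  BR = 0.185, I = 0.198
)

# Fallback radius (nm) for elements missing from vdw_radii_nm.
.default_vdw_nm <- 0.170

#' Construct a structure model
#'
#' The internal coordinate model: a table of atoms (name, element, residue,
#' chain, vdW radius) plus one xyz position per atom. All lengths are nm;
#' conversion from the Angstrom convention of PDB files happens at the I/O
#' boundary ([read_structure()]).
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `resno`
#'   (integer residue number), `resid` (3-letter residue name), `chain`,
#'   and `radius` (vdW radius, nm).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  need <- c("atom_name", "element", "resno", "resid", "chain", "radius")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  m <- structure(list(atoms = atoms, xyz = xyz), class = "structure_model")
  validate_structure_model(m)
  m
}

#' Validate a structure model
#'
#' Checks the class invariants: one coordinate per atom, unique
#' (chain, residue number, atom name) triples, strictly positive radii.
#'
#' @param m a `structure_model`.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_structure_model <- function(m) {
  stopifnot(inherits(m, "structure_model"))
  if (nrow(m$xyz) != nrow(m$atoms))
    stop("atom count (", nrow(m$atoms), ") != coordinate count (",
         nrow(m$xyz), ")")
  if (ncol(m$xyz) != 3L)
    stop("coordinates must have 3 columns")
  key <- paste(m$atoms$chain, m$atoms$resno, m$atoms$atom_name)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (chain, resno, atom_name) triple: ", dup)
  }
  if (any(!is.finite(m$atoms$radius)) || any(m$atoms$radius <= 0))
    stop("all vdW radii must be positive")
  invisible(m)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

#' Number of atoms in a structure model
#' @param m a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Construct a trajectory
#'
#' Time-ordered coordinate frames over a fixed topology. Frames are stored
#' bio3d-style as a matrix with one row per frame and 3 * n_atoms columns
#' (x1, y1, z1, x2, ...), in nm.
#'
#' @param topology a `structure_model`.
#' @param xyz numeric matrix, frames x (3 * n_atoms), nm.
#' @param frame_times numeric vector of frame times in ns, strictly
#'   increasing.
#' @param replica_id text label for the replica.
#' @param replica_bounds optional integer vector: the last frame index of
#'   each constituent replica (set by [concatenate_trajectories()]).
#' @return An object of class `kin_trajectory`.
#' @export
trajectory <- function(topology, xyz, frame_times, replica_id = "replica-1",
                       replica_bounds = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("each frame must have exactly one coordinate per topology atom ",
         "(expected ", 3L * n_atoms(topology), " values, got ", ncol(xyz), ")")
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != nrow(xyz))
    stop("frame_times length must equal frame count")
  if (length(frame_times) > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing within a replica")
  if (is.null(replica_bounds)) replica_bounds <- nrow(xyz)
  structure(list(topology = topology, xyz = xyz, frame_times = frame_times,
                 replica_id = as.character(replica_id),
                 replica_bounds = as.integer(replica_bounds)),
            class = "kin_trajectory")
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("kin_trajectory:", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms [", x$replica_id, "]\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `kin_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#'
#' @param traj a `kin_trajectory`.
#' @param i frame index (1-based).
#' @return numeric matrix n_atoms x 3, nm.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# Flatten an n x 3 coordinate matrix to the row layout used in traj$xyz.
.flatten_xyz <- function(coords) as.numeric(t(coords))

#' Atom selector
#'
#' Addresses exactly one atom by residue number and atom name, optionally
#' disambiguated by chain.
#'
#' @param resno integer residue number (author numbering, as in the file).
#' @param atom_name PDB atom name, e.g. `"CA"`, `"NZ"`.
#' @param chain optional chain identifier.
#' @return An object of class `atom_selector`.
#' @export
atom_selector <- function(resno, atom_name, chain = NULL) {
  stopifnot(length(resno) == 1L, length(atom_name) == 1L)
  structure(list(resno = as.integer(resno),
                 atom_name = as.character(atom_name),
                 chain = if (is.null(chain)) NULL else as.character(chain)),
            class = "atom_selector")
}

#' @export
print.atom_selector <- function(x, ...) {
  cat("atom_selector:",
      if (is.null(x$chain)) "" else paste0(x$chain, "/"),
      x$resno, "/", x$atom_name, "\n", sep = "")
  invisible(x)
}

#' Resolve an atom selector to an atom index
#'
#' @param model a `structure_model`.
#' @param selector an `atom_selector` (or a list with `resno`, `atom_name`,
#'   optional `chain`).
#' @return The unique matching atom index (integer).
#' @export
select_atom <- function(model, selector) {
  a <- model$atoms
  hit <- a$resno == selector$resno & a$atom_name == selector$atom_name
  if (!is.null(selector$chain)) hit <- hit & a$chain == selector$chain
  idx <- which(hit)
  if (length(idx) == 0L)
    stop("no atom matches selector (resno ", selector$resno, ", atom ",
         selector$atom_name, ")")
  if (length(idx) > 1L)
    stop("selector is ambiguous: ", length(idx), " atoms match (resno ",
         selector$resno, ", atom ", selector$atom_name,
         "); specify a chain")
  idx
}
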