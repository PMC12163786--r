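# File I/O sits on bio3d; everything downstream works in nm on the
# structure_model / kin_trajectory containers.

.A_PER_NM <- 10

# Infer an element symbol from a PDB atom name when the element column is
# absent. Handles hydrogen names with leading digits ("1HB") and two-letter
# elements present in the radius table.
.infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  vapply(nm, function(s) {
    if (nchar(s) == 0L) return("C")
    two <- substr(s, 1L, 2L)
    if (two %in% c("CL", "BR") && nchar(s) >= 2L) return(two)
    substr(s, 1L, 1L)
  }, character(1L), USE.NAMES = FALSE)
}

# Element -> radius (nm), warning once per unknown element.
.radius_for <- function(element, fallback = .default_vdw_nm) {
  element <- toupper(element)
  r <- unname(vdw_radii_nm[element])
  unknown <- unique(element[is.na(r)])
  if (length(unknown))
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using fallback vdW radius ", fallback, " nm", call. = FALSE)
  r[is.na(r)] <- fallback
  r
}

#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (via bio3d), converts coordinates from Angstrom to nm,
#' assigns element-based Bondi vdW radii, and by default drops waters, ions
#' and other heteroatoms so that only the protein remains.
#'
#' @param path path to a PDB file.
#' @param keep_het keep HETATM records (default `FALSE`).
#' @param fallback_radius vdW radius in nm assigned, with a warning, to
#'   elements missing from [vdw_radii_nm].
#' @return A [structure_model].
#' @export
read_structure <- function(path, keep_het = FALSE,
                           fallback_radius = .default_vdw_nm) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  keep <- if (keep_het) rep(TRUE, nrow(at)) else at$type == "ATOM"
  keep <- keep & at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after filtering: ", path)
  element <- at$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- .infer_element(at$elety[bad])
  element <- toupper(trimws(element))
  atoms <- data.frame(
    atom_name = trimws(at$elety), element = element,
    resno = as.integer(at$resno), resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    radius = .radius_for(element, fallback_radius),
    stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z) / .A_PER_NM
  structure_model(atoms, xyz)
}

#' Write a structure model (optionally multi-frame) to a PDB file
#'
#' Coordinates are converted back from nm to Angstrom. When `xyz_frames`
#' is given, a multi-model PDB is written with one MODEL per frame.
#'
#' @param model a [structure_model].
#' @param path output path.
#' @param xyz_frames optional matrix of frames (rows) x 3*n_atoms columns,
#'   nm; default writes the model's own coordinates as a single model.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, xyz_frames = NULL) {
  validate_structure_model(model)
  if (is.null(xyz_frames)) xyz_frames <- matrix(.flatten_xyz(model$xyz), 1L)
  a <- model$atoms
  one <- function(xyz_nm, file) {
    bio3d::write.pdb(file = file, xyz = xyz_nm * .A_PER_NM,
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$atom_name, elesy = a$element)
    grep("^(ATOM|HETATM|TER)", readLines(file), value = TRUE)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  nfr <- nrow(xyz_frames)
  out <- character(0)
  for (i in seq_len(nfr)) {
    body <- one(xyz_frames[i, ], tmp)
    out <- c(out,
             if (nfr > 1L) sprintf("MODEL     %4d", i),
             body,
             if (nfr > 1L) "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read one or more trajectory files over a topology
#'
#' Accepts multi-model PDB and DCD files; frames are appended in file
#' order. Frame times are assigned as a uniform grid starting at 0 ns with
#' spacing `frame_interval`.
#'
#' @param topology a [structure_model] defining the atom order.
#' @param paths character vector of trajectory files (.pdb or .dcd).
#' @param frame_interval time between frames, ns (default 1).
#' @param replica_id label for the resulting trajectory.
#' @return A [trajectory].
#' @export
read_trajectory <- function(topology, paths, frame_interval = 1,
                            replica_id = paste(basename(paths),
                                               collapse = "+")) {
  stopifnot(frame_interval > 0)
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    ext <- tolower(tools::file_ext(p))
    xyz <- switch(ext,
      pdb = bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz,
      dcd = bio3d::read.dcd(p, verbose = FALSE),
      stop("unsupported trajectory format '.", ext, "' for ", p,
           " (supported: multi-model PDB, DCD)"))
    xyz <- as.matrix(xyz)
    if (ncol(xyz) != 3L * n_atoms(topology))
      stop("atom count mismatch: ", p, " has ", ncol(xyz) / 3,
           " atoms per frame, topology has ", n_atoms(topology))
    # both formats carry Angstrom on disk by field convention
    xyz / .A_PER_NM
  })
  xyz <- do.call(rbind, frames)
  times <- (seq_len(nrow(xyz)) - 1L) * frame_interval
  trajectory(topology, xyz, times, replica_id = replica_id)
}

#' Concatenate replica trajectories into one frame population
#'
#' Frames are appended in input order and the replica boundaries recorded;
#' downstream occupancy statistics treat the result as a single frame
#' population, mirroring how replicate simulations of one variant are
#' pooled before computing combined occupancies. Frame times are re-laid
#' on a single increasing grid preserving each replica's spacing.
#'
#' @param trajs list of [trajectory] objects over identical topologies.
#' @return A single [trajectory] with `replica_bounds` marking the last
#'   frame of each input.
#' @export
concatenate_trajectories <- function(trajs) {
  if (inherits(trajs, "kin_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  ref <- trajs[[1L]]$topology
  for (tr in trajs) {
    stopifnot(inherits(tr, "kin_trajectory"))
    if (n_atoms(tr$topology) != n_atoms(ref) ||
        !identical(tr$topology$atoms[c("atom_name", "resno", "chain")],
                   ref$atoms[c("atom_name", "resno", "chain")]))
      stop("topology mismatch between replicas")
  }
  if (length(trajs) == 1L) return(trajs[[1L]])
  xyz <- do.call(rbind, lapply(trajs, function(t) t$xyz))
  # shift each replica's clock so the global time axis stays increasing
  times <- numeric(0)
  offset <- 0
  for (tr in trajs) {
    tt <- tr$frame_times - tr$frame_times[1L]
    step <- if (length(tt) > 1L) tt[2L] - tt[1L] else 1
    times <- c(times, offset + tt)
    offset <- offset + tt[length(tt)] + step
  }
  trajectory(ref, xyz, times,
             replica_id = paste(vapply(trajs, `[[`, "", "replica_id"),
                                collapse = "+"),
             replica_bounds = cumsum(vapply(trajs, n_frames, integer(1L))))
}
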