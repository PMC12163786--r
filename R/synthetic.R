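# Desk-scale synthetic fixtures with exact ground truth for every
# downstream statistic: a rigid toy kinase, angle-sweep trajectories,
# scheduled-contact trajectories, and countable cavity frames. Purely
# geometric constructions -- no physical realism intended.

# run expr under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# one residue's atoms laid out around an anchor point (nm); offsets chosen
# so intra-residue geometry is chemically plausible but inert (no
# inter-residue contacts at the default residue spacing)
.res_atoms <- function(resno, resid, anchor, extra = NULL) {
  atoms <- data.frame(atom_name = "CA", element = "C",
                      resno = resno, resid = resid, chain = "A",
                      stringsAsFactors = FALSE)
  xyz <- matrix(anchor, ncol = 3)
  if (!is.null(extra)) {
    atoms <- rbind(atoms,
                   data.frame(atom_name = extra$name, element = extra$elem,
                              resno = resno, resid = resid, chain = "A",
                              stringsAsFactors = FALSE))
    xyz <- rbind(xyz, sweep(extra$off, 2L, anchor, "+"))
  }
  list(atoms = atoms, xyz = xyz)
}

#' Build the rigid toy kinase fixture
#'
#' A minimal, fully deterministic structure that carries every anchor the
#' default [kinase_motif_map()] expects: alpha-carbons for the angle
#' triple 1980/1997/2103 and the pocket center 2026; charged side-chain
#' atoms (Lys NZ, Arg NE/NH1/NH2, Asp OD1/OD2, Glu OE1/OE2) for
#' salt-bridge tests; N-H donors and carbonyl/carboxylate acceptors for
#' hydrogen-bond tests; and side-chain carbons on the hydrophobic partner
#' residues 1951, 1959, 1978, 2010, 2026, 2086 plus the F2103 ring.
#' Residues are spread ~1.5 nm apart on a coarse helix so no interaction
#' is present until a generator schedules one. Two calls return identical
#' coordinates.
#'
#' @return A [structure_model].
#' @export
make_toy_kinase <- function() {
  # anchor layout: coarse helix, radius 1.5 nm, pitch 0.4 nm/residue
  defs <- list(
    list(1951L, "LEU", extra = list(
      name = c("CB", "CG", "CD1", "CD2"), elem = rep("C", 4),
      off = rbind(c(.15, 0, 0), c(.25, .1, 0), c(.35, .2, 0),
                  c(.35, 0, .1)))),
    list(1959L, "VAL", extra = list(
      name = c("CB", "CG1", "CG2"), elem = rep("C", 3),
      off = rbind(c(.15, 0, 0), c(.25, .1, 0), c(.25, -.1, 0)))),
    list(1976L, "LYS", extra = list(
      name = "NZ", elem = "N", off = rbind(c(.35, 0, 0)))),
    list(1978L, "ALA", extra = list(
      name = "CB", elem = "C", off = rbind(c(.15, 0, 0)))),
    list(1980L, "LYS", extra = list(
      name = "NZ", elem = "N", off = rbind(c(.35, 0, 0)))),
    list(1997L, "GLU", extra = list(
      name = c("OE1", "OE2"), elem = c("O", "O"),
      off = rbind(c(.3, .05, 0), c(.3, -.05, 0)))),
    list(2010L, "LEU", extra = list(
      name = c("CB", "CG", "CD1", "CD2"), elem = rep("C", 4),
      off = rbind(c(.15, 0, 0), c(.25, .1, 0), c(.35, .2, 0),
                  c(.35, 0, .1)))),
    list(2026L, "LEU", extra = list(
      name = c("CB", "CG", "CD1", "CD2"), elem = rep("C", 4),
      off = rbind(c(.15, 0, 0), c(.25, .1, 0), c(.35, .2, 0),
                  c(.35, 0, .1)))),
    list(2077L, "HIS", extra = list(
      name = c("ND1", "NE2"), elem = c("N", "N"),
      off = rbind(c(.2, .1, 0), c(.3, -.1, 0)))),
    list(2078L, "ARG", extra = list(
      name = c("NE", "HE", "NH1", "NH2"), elem = c("N", "H", "N", "N"),
      off = rbind(c(.3, 0, 0), c(.3, .1, 0), c(.5, .2, 0),
                  c(.5, -.2, 0)))),
    list(2079L, "ASP", extra = list(
      name = c("OD1", "OD2"), elem = c("O", "O"),
      off = rbind(c(.25, .05, 0), c(.25, -.05, 0)))),
    list(2086L, "LEU", extra = list(
      name = c("CB", "CG", "CD1", "CD2"), elem = rep("C", 4),
      off = rbind(c(.15, 0, 0), c(.25, .1, 0), c(.35, .2, 0),
                  c(.35, 0, .1)))),
    list(2101L, "GLY", extra = list(
      name = c("N", "H", "O"), elem = c("N", "H", "O"),
      off = rbind(c(-.1, .05, 0), c(-.1, .15, 0), c(.1, -.1, 0)))),
    list(2102L, "ASP", extra = list(
      name = c("OD1", "OD2"), elem = c("O", "O"),
      off = rbind(c(.25, .05, 0), c(.25, -.05, 0)))),
    list(2103L, "PHE", extra = list(
      name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      elem = rep("C", 7),
      off = rbind(c(.15, 0, 0), c(.27, .05, 0), c(.33, .17, 0),
                  c(.33, -.07, .05), c(.45, .19, 0), c(.45, -.05, .05),
                  c(.51, .07, .02)))),
    list(2104L, "GLY", extra = list(
      name = c("N", "H"), elem = c("N", "H"),
      off = rbind(c(-.1, .05, 0), c(-.1, .15, 0)))),
    list(2105L, "LEU", extra = list(
      name = c("N", "H", "CB"), elem = c("N", "H", "C"),
      off = rbind(c(-.1, .05, 0), c(-.1, .15, 0), c(.15, 0, 0)))),
    list(2143L, "ASP", extra = list(
      name = c("OD1", "OD2"), elem = c("O", "O"),
      off = rbind(c(.25, .05, 0), c(.25, -.05, 0))))
  )
  parts <- lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    theta <- i * 2.2
    anchor <- c(1.5 * cos(theta), 1.5 * sin(theta), 0.4 * i)
    .res_atoms(d[[1L]], d[[2L]], anchor, d$extra)
  })
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  atoms$radius <- .radius_for(atoms$element)
  structure_model(atoms, xyz)
}

#' Angle-sweep specification
#'
#' @param angle_schedule target angles in degrees, one per frame, each in
#'   (0, 180).
#' @param arm_length arm length about the vertex, nm.
#' @param noise_sd Gaussian jitter applied to each frame's angle, degrees.
#' @param seed RNG seed making the sweep reproducible.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(angle_schedule, arm_length = 1, noise_sd = 0,
                       seed = 1L) {
  angle_schedule <- as.numeric(angle_schedule)
  if (length(angle_schedule) == 0L) stop("angle schedule is empty")
  if (any(angle_schedule <= 0 | angle_schedule >= 180))
    stop("all target angles must lie strictly inside (0, 180) degrees")
  structure(list(angle_schedule = angle_schedule, arm_length = arm_length,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Generate a DFG-angle sweep trajectory
#'
#' Frame t of the output places the 1980 and 2103 alpha-carbons on arms of
#' fixed length about the 1997 alpha-carbon, in the xy-plane, so the
#' 1980-1997-2103 angle equals `angle_schedule[t]` plus Gaussian jitter
#' (jitter applied to the angle itself, making the ground truth exact).
#' All other atoms stay rigid at their toy-kinase positions. The realized
#' per-frame angles are attached as the `ground_truth` attribute and
#' mirror what the generator wrote, so tests never re-derive them.
#'
#' @param spec a [sweep_spec].
#' @param base topology to animate (default [make_toy_kinase()]).
#' @param frame_interval frame spacing, ns.
#' @return A [trajectory] with attribute `ground_truth`
#'   (data.frame: frame, target_deg, realized_deg).
#' @export
make_dfg_sweep_trajectory <- function(spec, base = make_toy_kinase(),
                                      frame_interval = 1) {
  stopifnot(inherits(spec, "sweep_spec"))
  i80 <- select_atom(base, atom_selector(1980, "CA"))
  i97 <- select_atom(base, atom_selector(1997, "CA"))
  i03 <- select_atom(base, atom_selector(2103, "CA"))
  nfr <- length(spec$angle_schedule)
  jitter <- if (spec$noise_sd > 0)
    .with_seed(spec$seed, stats::rnorm(nfr, 0, spec$noise_sd))
  else rep(0, nfr)
  realized <- pmin(180 - 1e-9, pmax(1e-9, spec$angle_schedule + jitter))
  v <- base$xyz[i97, ]
  xyz <- matrix(rep(.flatten_xyz(base$xyz), nfr), nrow = nfr, byrow = TRUE)
  for (f in seq_len(nfr)) {
    th <- realized[f] * pi / 180
    # arm 1 fixed along +x from the vertex; arm 2 rotated by the target
    xyz[f, (3 * (i80 - 1) + 1):(3 * i80)] <- v + c(spec$arm_length, 0, 0)
    xyz[f, (3 * (i03 - 1) + 1):(3 * i03)] <-
      v + spec$arm_length * c(cos(th), sin(th), 0)
  }
  tr <- trajectory(base, xyz, (seq_len(nfr) - 1L) * frame_interval,
                   replica_id = "dfg-sweep")
  attr(tr, "ground_truth") <- data.frame(frame = seq_len(nfr),
                                         target_deg = spec$angle_schedule,
                                         realized_deg = realized)
  tr
}

#' Contact schedule
#'
#' Declares that a given atom pair is "in contact" (separated by
#' `on_distance`) in exactly the frames of `present_frames` and separated
#' by `off_distance` otherwise.
#'
#' @param selector_a,selector_b [atom_selector]s for the two atoms; the
#'   second atom is the one moved.
#' @param present_frames integer frame indices (1-based) where the
#'   contact is on.
#' @param on_distance,off_distance separations in nm; for a detector with
#'   cutoff c, choose on < c < off.
#' @param align_h when atom B is a donor with a bonded hydrogen, re-aim
#'   that hydrogen along the B-to-A axis in every frame so scheduled
#'   contacts also satisfy an H-donor-acceptor angle criterion (default
#'   `TRUE`; no effect when B carries no hydrogen).
#' @return An object of class `contact_schedule`.
#' @export
contact_schedule <- function(selector_a, selector_b, present_frames,
                             on_distance = 0.35, off_distance = 0.60,
                             align_h = TRUE) {
  stopifnot(on_distance > 0, off_distance > on_distance)
  structure(list(a = selector_a, b = selector_b,
                 present_frames = as.integer(present_frames),
                 on_distance = on_distance, off_distance = off_distance,
                 align_h = isTRUE(align_h)),
            class = "contact_schedule")
}

#' Generate a trajectory realizing contact schedules
#'
#' For each schedule, frame by frame, atom B (and any other atom of its
#' residue, moved rigidly) is placed along the fixed A-to-B direction of
#' the base structure at `on_distance` from atom A in the scheduled
#' frames and `off_distance` elsewhere. Ground-truth occupancies
#' (|present_frames| / n_frames per pair) are attached as the
#' `ground_truth` attribute.
#'
#' @param base a [structure_model] containing all scheduled atoms.
#' @param schedules list of [contact_schedule]s.
#' @param n_frames number of frames to emit.
#' @param frame_interval frame spacing, ns.
#' @return A [trajectory] with attribute `ground_truth`
#'   (data.frame: res_a, res_b, occupancy).
#' @export
make_contact_schedule_trajectory <- function(base, schedules, n_frames,
                                             frame_interval = 1) {
  stopifnot(n_frames >= 1L)
  for (s in schedules)
    if (any(s$present_frames > n_frames | s$present_frames < 1L))
      stop("present_frames indices must lie in 1..n_frames")
  xyz <- matrix(rep(.flatten_xyz(base$xyz), n_frames),
                nrow = n_frames, byrow = TRUE)
  gt <- data.frame(res_a = integer(0), res_b = integer(0),
                   occupancy = numeric(0))
  for (s in schedules) {
    ia <- select_atom(base, s$a)
    ib <- select_atom(base, s$b)
    pa <- base$xyz[ia, ]
    dir <- base$xyz[ib, ] - pa
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm < 1e-12) c(1, 0, 0) else dir / nrm
    res_b_atoms <- which(base$atoms$resno == base$atoms$resno[ib] &
                           base$atoms$chain == base$atoms$chain[ib])
    # bonded hydrogen of atom B, if any, for donor-geometry alignment
    h_idx <- NA_integer_
    if (s$align_h && base$atoms$element[ib] %in% c("N", "O")) {
      hs <- res_b_atoms[base$atoms$element[res_b_atoms] == "H"]
      if (length(hs)) {
        dh <- sqrt(rowSums(sweep(base$xyz[hs, , drop = FALSE], 2L,
                                 base$xyz[ib, ])^2))
        if (min(dh) <= 0.125) {
          h_idx <- hs[which.min(dh)]
          h_len <- min(dh)
        }
      }
    }
    for (f in seq_len(n_frames)) {
      d <- if (f %in% s$present_frames) s$on_distance else s$off_distance
      pb_new <- pa + d * dir
      shift <- pb_new - base$xyz[ib, ]
      for (j in res_b_atoms) {
        cols <- (3 * (j - 1) + 1):(3 * j)
        xyz[f, cols] <- base$xyz[j, ] + shift
      }
      if (!is.na(h_idx)) {
        cols <- (3 * (h_idx - 1) + 1):(3 * h_idx)
        xyz[f, cols] <- pb_new + h_len * (pa - pb_new) / d
      }
    }
    gt <- rbind(gt, data.frame(
      res_a = min(base$atoms$resno[ia], base$atoms$resno[ib]),
      res_b = max(base$atoms$resno[ia], base$atoms$resno[ib]),
      occupancy = length(unique(s$present_frames)) / n_frames))
  }
  tr <- trajectory(base, xyz, (seq_len(n_frames) - 1L) * frame_interval,
                   replica_id = "contact-schedule")
  attr(tr, "ground_truth") <- gt
  tr
}

#' Brute-force free-grid-point count (independent oracle)
#'
#' Literal enumeration: every voxel-center grid point of the box is tested
#' against every atom, point by point and atom by atom, and counted free
#' when no atom center lies strictly closer than its radius. Deliberately
#' naive (no pruning, no vectorized geometry) so it can serve as an
#' independent check of [pocket_volume()].
#'
#' @param center box center, numeric xyz (nm).
#' @param atoms_xyz n x 3 atom coordinates (nm); may have zero rows.
#' @param radii per-atom overlap radii (nm).
#' @param box_edge,spacing grid geometry as in [pocket_grid_spec()].
#' @return Integer count of free grid points.
#' @export
count_free_grid_points <- function(center, atoms_xyz, radii,
                                   box_edge = 1.5, spacing = 0.1) {
  n <- round(box_edge / spacing)
  ax <- (-box_edge / 2) + (seq_len(n) - 0.5) * spacing
  atoms_xyz <- as.matrix(atoms_xyz)
  free <- 0L
  for (ix in seq_len(n)) for (iy in seq_len(n)) for (iz in seq_len(n)) {
    p <- center + c(ax[ix], ax[iy], ax[iz])
    covered <- FALSE
    for (a in seq_len(nrow(atoms_xyz))) {
      if (sum((p - atoms_xyz[a, ])^2) < radii[a]^2) {
        covered <- TRUE
        break
      }
    }
    if (!covered) free <- free + 1L
  }
  free
}

#' Cavity specification
#'
#' @param shell_xyz n x 3 matrix of shell atom positions (nm), relative to
#'   the box center.
#' @param shell_radii per-atom overlap radii (nm).
#' @param center box center position in the laboratory frame (nm).
#' @return An object of class `cavity_spec`.
#' @export
cavity_spec <- function(shell_xyz = matrix(numeric(0), 0, 3),
                        shell_radii = numeric(0),
                        center = c(5, 5, 5)) {
  shell_xyz <- as.matrix(shell_xyz)
  if (nrow(shell_xyz) != length(shell_radii))
    stop("one radius per shell atom required")
  structure(list(shell_xyz = shell_xyz, shell_radii = shell_radii,
                 center = center),
            class = "cavity_spec")
}

#' Build a countable cavity frame
#'
#' Constructs a single-frame structure whose pocket box contains an
#' exactly countable set of atom-free grid points. A marker "CA" site
#' (residue 2026) defines the box center; it is typed as hydrogen so the
#' heavy-atom overlap convention ignores it and only the scheduled shell
#' atoms shape the cavity. The expected volume is computed by the
#' brute-force oracle [count_free_grid_points()] over exactly the atoms
#' the pocket detector will see (the shell).
#'
#' @param spec a [cavity_spec].
#' @param box_edge,spacing grid geometry (defaults 1.5 / 0.1 nm).
#' @return list(model = [structure_model], expected_volume (nm^3),
#'   expected_free_points (integer)).
#' @export
make_cavity_frame <- function(spec, box_edge = 1.5, spacing = 0.1) {
  ns <- nrow(spec$shell_xyz)
  # marker site defining the box center; typed H so the heavy-atom overlap
  # convention of pocket_volume() ignores it
  atoms <- data.frame(
    atom_name = c("CA", if (ns) paste0("X", seq_len(ns))),
    element = c("H", rep("C", ns)),
    resno = c(2026L, rep(1L, ns)),
    resid = c("LEU", rep("UNK", ns)),
    chain = c("A", rep("B", ns)),
    radius = c(vdw_radii_nm[["H"]], spec$shell_radii),
    stringsAsFactors = FALSE)
  xyz <- rbind(spec$center,
               if (ns) sweep(spec$shell_xyz, 2L, spec$center, "+"))
  model <- structure_model(atoms, xyz)
  shell_abs <- xyz[-1L, , drop = FALSE]
  k <- count_free_grid_points(spec$center, shell_abs, spec$shell_radii,
                              box_edge = box_edge, spacing = spacing)
  list(model = model, expected_volume = k * spacing^3,
       expected_free_points = k)
}

#' Write a fixture set to disk
#'
#' Emits a trajectory as topology PDB + multi-model PDB frames plus a CSV
#' sidecar holding the generator's ground truth, so downstream checks can
#' be run from files alone.
#'
#' @param traj a [trajectory] carrying a `ground_truth` attribute.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(traj, dir, stem = "fixture") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  topo <- file.path(dir, paste0(stem, "-topology.pdb"))
  frames <- file.path(dir, paste0(stem, "-frames.pdb"))
  sidecar <- file.path(dir, paste0(stem, "-ground-truth.csv"))
  write_structure(traj$topology, topo)
  write_structure(traj$topology, frames, xyz_frames = traj$xyz)
  gt <- attr(traj, "ground_truth")
  if (is.null(gt)) gt <- data.frame(note = "no ground truth attached")
  utils::write.csv(gt, sidecar, row.names = FALSE)
  invisible(c(topology = topo, frames = frames, ground_truth = sidecar))
}
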