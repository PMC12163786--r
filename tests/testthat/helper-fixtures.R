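# shared fixture builders; everything is generated in code at test time

# minimal model with the angle-triple alpha-carbons at given positions (nm)
angle_model <- function(p1980, p1997, p2103) {
  structure_model(
    data.frame(atom_name = "CA", element = "C",
               resno = c(1980L, 1997L, 2103L),
               resid = c("LYS", "GLU", "PHE"), chain = "A",
               radius = 0.17, stringsAsFactors = FALSE),
    rbind(p1980, p1997, p2103))
}

# single-frame trajectory over a model
one_frame_traj <- function(model, t0 = 0) {
  trajectory(model, matrix(as.numeric(t(model$xyz)), 1L), t0)
}

# n identical frames over a model
static_traj <- function(model, n, dt = 1) {
  trajectory(model, matrix(rep(as.numeric(t(model$xyz)), n),
                           nrow = n, byrow = TRUE),
             (seq_len(n) - 1L) * dt)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

# apply a rigid transform (rotation R then translation s) to a trajectory
transform_traj <- function(traj, R, s) {
  xyz <- t(apply(traj$xyz, 1L, function(row) {
    m <- matrix(row, ncol = 3L, byrow = TRUE)
    as.numeric(t(sweep(m %*% t(R), 2L, s, "+")))
  }))
  trajectory(traj$topology, xyz, traj$frame_times,
             replica_id = traj$replica_id)
}

# tiny two-residue model for salt-bridge geometry tests: Lys NZ vs a
# partner atom at a prescribed separation (nm)
charged_pair_model <- function(separation, partner_resid = "ASP",
                               partner_atom = "OD1") {
  structure_model(
    data.frame(atom_name = c("NZ", partner_atom),
               element = c("N", substr(partner_atom, 1L, 1L)),
               resno = c(1980L, 2102L),
               resid = c("LYS", partner_resid), chain = "A",
               radius = 0.16, stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(separation, 0, 0)))
}

# donor(N-H, residue in the DFG motif) / acceptor(O) model with prescribed
# donor-acceptor distance and H-donor-acceptor angle (degrees)
hbond_geometry_model <- function(dist, angle_deg, donor_resno = 2102L,
                                 acceptor_resno = 1997L) {
  th <- angle_deg * pi / 180
  structure_model(
    data.frame(atom_name = c("N", "H", "O"),
               element = c("N", "H", "O"),
               resno = c(donor_resno, donor_resno, acceptor_resno),
               resid = c("ASP", "ASP", "GLU"), chain = "A",
               radius = c(0.155, 0.12, 0.152), stringsAsFactors = FALSE),
    rbind(c(0, 0, 0),
          0.1 * c(cos(th), sin(th), 0),   # H at the prescribed angle
          c(dist, 0, 0)))                 # acceptor along +x
}

# two-variant on-disk pipeline fixture: an "active" variant sweeping 31
# degrees with a 5/6-occupancy K1980-E1997 salt bridge, and an "inactive"
# variant at 72 degrees with no salt bridge
make_pipeline_inputs <- function(dir) {
  base <- make_toy_kinase()
  variants <- list(
    list(label = "wt-active", angles = rep(31, 6), contact_frames = 1:5),
    list(label = "wt-inactive", angles = rep(72, 6),
         contact_frames = integer(0)))
  specs <- lapply(variants, function(v) {
    tr <- make_dfg_sweep_trajectory(sweep_spec(v$angles), base = base)
    sch <- contact_schedule(atom_selector(1997, "OE1"),
                            atom_selector(1980, "NZ"),
                            v$contact_frames, 0.35, 0.60)
    trc <- make_contact_schedule_trajectory(base, list(sch),
                                            n_frames = length(v$angles))
    # merge: the schedule moves residue 1980, the sweep places the two
    # angle-arm alpha-carbons; start from the schedule frames and
    # overwrite the arm atoms
    i80 <- select_atom(base, atom_selector(1980, "CA"))
    i03 <- select_atom(base, atom_selector(2103, "CA"))
    xyz <- trc$xyz
    for (i in c(i80, i03)) {
      cols <- (3 * (i - 1) + 1):(3 * i)
      xyz[, cols] <- tr$xyz[, cols]
    }
    merged <- trajectory(base, xyz, tr$frame_times, replica_id = v$label)
    topo <- file.path(dir, paste0(v$label, "-topo.pdb"))
    frames <- file.path(dir, paste0(v$label, "-frames.pdb"))
    write_structure(base, topo)
    write_structure(base, frames, xyz_frames = merged$xyz)
    list(label = v$label, topology = topo, trajectories = list(frames))
  })
  list(variants = specs,
       params = list(frame_interval_ns = 1),
       output_dir = file.path(dir, "out"),
       seed = 1)
}
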