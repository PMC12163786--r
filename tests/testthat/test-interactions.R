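test_that("salt bridges respect the heavy-atom distance cutoff", {
  expect_equal(nrow(salt_bridge_contacts(charged_pair_model(0.39))), 1L)
  expect_equal(nrow(salt_bridge_contacts(charged_pair_model(0.41))), 0L)
  # two acidic residues are never a salt bridge however close
  asp_glu <- structure_model(
    data.frame(atom_name = c("OD1", "OE1"), element = "O",
               resno = c(2102L, 1997L), resid = c("ASP", "GLU"),
               chain = "A", radius = 0.152, stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_equal(nrow(salt_bridge_contacts(asp_glu)), 0L)
})

test_that("salt-bridge pairs are canonical and symmetric", {
  m <- charged_pair_model(0.30)
  sb <- salt_bridge_contacts(m)
  expect_equal(sb$res_a, 1980L)   # lower residue number first
  expect_equal(sb$res_b, 2102L)
  # swapping the atom order in the model changes nothing
  m2 <- structure_model(m$atoms[2:1, ], m$xyz[2:1, ])
  expect_equal(salt_bridge_contacts(m2)$pair, sb$pair)
})

test_that("enlarging the salt-bridge cutoff never removes a pair", {
  base <- make_toy_kinase()
  sch <- list(
    contact_schedule(atom_selector(1997, "OE1"), atom_selector(1980, "NZ"),
                     1L, on_distance = 0.30, off_distance = 0.55),
    contact_schedule(atom_selector(2079, "OD1"), atom_selector(1976, "NZ"),
                     1L, on_distance = 0.39, off_distance = 0.70))
  tr <- make_contact_schedule_trajectory(base, sch, 1)
  x <- frame_coords(tr, 1)
  prev <- character(0)
  for (cut in c(0.2, 0.3, 0.4, 0.5, 0.6)) {
    cur <- salt_bridge_contacts(tr$topology, x,
                                salt_bridge_criteria(cutoff = cut))$pair
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hydrogen bonds need distance, angle, and motif membership", {
  # 0.30 nm and a 10-degree H-donor-acceptor angle: reported
  expect_equal(nrow(hbond_contacts(hbond_geometry_model(0.30, 10))), 1L)
  # same distance, 45-degree angle: rejected
  expect_equal(nrow(hbond_contacts(hbond_geometry_model(0.30, 45))), 0L)
  # distance beyond 0.35 nm: rejected
  expect_equal(nrow(hbond_contacts(hbond_geometry_model(0.40, 5))), 0L)
  # perfect geometry but neither residue in the DFG/HRD restriction set
  outside <- hbond_geometry_model(0.30, 10, donor_resno = 1500L,
                                  acceptor_resno = 1600L)
  # restriction must resolve somewhere in the model, so add a DFG residue
  far <- structure_model(
    rbind(outside$atoms,
          data.frame(atom_name = "CA", element = "C", resno = 2103L,
                     resid = "PHE", chain = "A", radius = 0.17)),
    rbind(outside$xyz, c(50, 50, 50)))
  expect_equal(nrow(hbond_contacts(far)), 0L)
  # an empty restriction set is an error
  expect_error(hbond_contacts(outside), "zero residues")
})

test_that("hydrogen-free topologies fall back to distance-only, warned", {
  m <- hbond_geometry_model(0.30, 10)
  noH <- structure_model(m$atoms[m$atoms$element != "H", ],
                         m$xyz[m$atoms$element != "H", ])
  expect_warning(hb <- hbond_contacts(noH), "no hydrogens")
  expect_equal(nrow(hb), 1L)
})

test_that("hydrophobic contacts report partners within the cutoff", {
  base <- make_toy_kinase()
  # schedule partners 1951 and 2026 against the F2103 ring
  sch <- list(
    contact_schedule(atom_selector(2103, "CZ"), atom_selector(1951, "CD1"),
                     1L, on_distance = 0.40, off_distance = 0.90),
    contact_schedule(atom_selector(2103, "CZ"), atom_selector(2026, "CD1"),
                     1L, on_distance = 0.42, off_distance = 0.90))
  tr <- make_contact_schedule_trajectory(base, sch, 2)
  hit <- hydrophobic_contacts(tr$topology, frame_coords(tr, 1))
  expect_equal(nrow(hit), 2L)
  expect_setequal(setdiff(c(hit$res_a, hit$res_b), 2103L), c(1951L, 2026L))
  # frame 2: everything far away
  expect_equal(nrow(hydrophobic_contacts(tr$topology,
                                         frame_coords(tr, 2))), 0L)
})

test_that("contact sets are invariant under rigid motion", {
  set.seed(77)
  base <- make_toy_kinase()
  sch <- list(
    contact_schedule(atom_selector(1997, "OE1"), atom_selector(1980, "NZ"),
                     1L, 0.35, 0.60),
    contact_schedule(atom_selector(2102, "OD1"), atom_selector(2078, "NE"),
                     1L, 0.30, 0.60))
  tr <- make_contact_schedule_trajectory(base, sch, 1)
  x <- frame_coords(tr, 1)
  R <- random_rotation()
  s <- c(3, -2, 7)
  x2 <- sweep(x %*% t(R), 2L, s, "+")
  expect_equal(salt_bridge_contacts(tr$topology, x2)$pair,
               salt_bridge_contacts(tr$topology, x)$pair)
  expect_equal(hbond_contacts(tr$topology, x2)$pair,
               hbond_contacts(tr$topology, x)$pair)
  expect_equal(hydrophobic_contacts(tr$topology, x2)$pair,
               hydrophobic_contacts(tr$topology, x)$pair)
})

test_that("occupancy equals the scheduled fraction exactly", {
  base <- make_toy_kinase()
  mk <- function(frames, n) {
    tr <- make_contact_schedule_trajectory(
      base, list(contact_schedule(atom_selector(1997, "OE1"),
                                  atom_selector(1980, "NZ"), frames,
                                  0.35, 0.60)), n)
    interaction_occupancy(tr, function(m, x) salt_bridge_contacts(m, x),
                          "v")
  }
  expect_equal(mk(c(2, 5, 9), 10)$occupancy, 0.30)
  expect_equal(mk(1:10, 10)$occupancy, 1.0)
  # never-present pairs are absent from the table entirely
  expect_equal(nrow(mk(integer(0), 10)), 0L)
})

test_that("concatenated replicas pool into one frame population", {
  base <- make_toy_kinase()
  mk <- function(frames) make_contact_schedule_trajectory(
    base, list(contact_schedule(atom_selector(1997, "OE1"),
                                atom_selector(1980, "NZ"), frames,
                                0.35, 0.60)), 10)
  cc <- concatenate_trajectories(list(mk(1:10), mk(integer(0))))
  occ <- interaction_occupancy(cc, function(m, x)
    salt_bridge_contacts(m, x), "v")
  expect_equal(occ$occupancy, 0.5)
  expect_equal(occ$n_frames, 20L)
})

test_that("the occupancy filter keeps pairs strictly above threshold", {
  tab <- function(variant, occ) {
    d <- data.frame(pair = "LYS1980-GLU1997", res_a = 1980L, res_b = 1997L,
                    variant = variant, occupancy = occ, n_frames = 10L,
                    stringsAsFactors = FALSE)
    class(d) <- c("interaction_occupancy", "data.frame")
    d
  }
  # above threshold in one variant: retained with every variant's value
  w <- filter_occupancy_matrix(list(tab("a", 0.20), tab("b", 0.05),
                                    tab("c", 0.05)))
  expect_equal(nrow(w), 1L)
  expect_equal(unlist(w[1, c("a", "b", "c")], use.names = FALSE),
               c(0.20, 0.05, 0.05))
  # exactly 0.15 everywhere: dropped by the strict rule
  expect_equal(nrow(filter_occupancy_matrix(
    list(tab("a", 0.15), tab("b", 0.15)))), 0L)
  # nothing above threshold is an empty matrix, not an error
  expect_equal(nrow(filter_occupancy_matrix(list(tab("a", 0.01)))), 0L)
  expect_error(filter_occupancy_matrix(list()), "no occupancy tables")
})

test_that("the filtered matrix is a subset of the per-variant union", {
  base <- make_toy_kinase()
  mk <- function(frames, label) {
    tr <- make_contact_schedule_trajectory(
      base, list(contact_schedule(atom_selector(1997, "OE1"),
                                  atom_selector(1980, "NZ"), frames,
                                  0.35, 0.60),
                 contact_schedule(atom_selector(2079, "OD1"),
                                  atom_selector(1976, "NZ"),
                                  seq_len(min(1, length(frames))),
                                  0.35, 0.60)), 10)
    interaction_occupancy(tr, function(m, x) salt_bridge_contacts(m, x),
                          label)
  }
  tabs <- list(mk(1:8, "wt"), mk(1:2, "mut"))
  w <- filter_occupancy_matrix(tabs, threshold = 0.15)
  union_pairs <- unique(unlist(lapply(tabs, `[[`, "pair")))
  expect_true(all(w$pair %in% union_pairs))
  # missing variants fill with zero occupancy
  expect_true(all(c("wt", "mut") %in% names(w)))
})

test_that("radar tables report occupancy as percentages", {
  base <- make_toy_kinase()
  tr <- make_contact_schedule_trajectory(
    base, list(contact_schedule(atom_selector(2102, "OD1"),
                                atom_selector(2078, "NE"), 1:5,
                                0.30, 0.60)), 10)
  hb <- interaction_occupancy(tr, function(m, x) hbond_contacts(m, x),
                              "wt-active")
  r <- radar_table(list(hb))
  expect_equal(r[["wt-active"]], 50)
})
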