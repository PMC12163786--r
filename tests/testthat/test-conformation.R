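test_that("rotation angle reproduces hand-constructed geometries", {
  # orthogonal arms about the vertex
  m <- angle_model(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  s <- dfg_rotation_angle(one_frame_traj(m))
  expect_equal(s$values, 90, tolerance = 1e-6)
  # collinear atoms
  m2 <- angle_model(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0))
  expect_equal(dfg_rotation_angle(one_frame_traj(m2))$values, 180,
               tolerance = 1e-6)
  # synthetic sweep schedule, noise-free
  tr <- make_dfg_sweep_trajectory(sweep_spec(c(30, 70, 110)))
  expect_equal(dfg_rotation_angle(tr)$values, c(30, 70, 110),
               tolerance = 1e-6)
})

test_that("degenerate vertex geometry yields NaN with a warning", {
  m <- angle_model(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_warning(s <- dfg_rotation_angle(one_frame_traj(m)), "degenerate")
  expect_true(is.nan(s$values))
})

test_that("the angle is invariant under rigid rotation and translation", {
  set.seed(101)
  tr <- make_dfg_sweep_trajectory(
    sweep_spec(seq(20, 160, length.out = 8), noise_sd = 5, seed = 3L))
  ref <- dfg_rotation_angle(tr)$values
  for (rep in 1:5) {
    moved <- transform_traj(tr, random_rotation(), stats::rnorm(3, sd = 5))
    expect_lt(max(abs(dfg_rotation_angle(moved)$values - ref)), 1e-6)
  }
})

test_that("state classification applies the strict-less threshold rule", {
  s <- structure(list(values = c(30, 70), frame_times = c(0, 1),
                      variant_label = "x"), class = "angle_series")
  cls <- classify_state(s, threshold_deg = 50)
  expect_equal(as.character(cls$labels), c("DFG-in", "DFG-out"))
  # values exactly at the threshold are DFG-out
  s2 <- structure(list(values = c(50, 50), frame_times = c(0, 1),
                       variant_label = "x"), class = "angle_series")
  expect_equal(as.character(classify_state(s2, 50)$labels),
               rep("DFG-out", 2))
  s3 <- structure(list(values = c(NaN, NaN), frame_times = c(0, 1),
                       variant_label = "x"), class = "angle_series")
  expect_error(classify_state(s3), "NaN")
})

test_that("label counts plus NaN count equal the frame count", {
  vals <- c(30, NaN, 70, 49.9, 50.1, NaN)
  s <- structure(list(values = vals, frame_times = seq_along(vals) - 1,
                      variant_label = "x"), class = "angle_series")
  cls <- classify_state(s, 50)
  expect_equal(sum(cls$labels == "DFG-in", na.rm = TRUE) +
                 sum(cls$labels == "DFG-out", na.rm = TRUE) +
                 sum(is.na(cls$labels)),
               length(vals))
})

test_that("two-population recovery matches the normal tail-mass oracle", {
  # 600 frames ~ N(31, 6) and 400 ~ N(72, 8): the expected DFG-in
  # fraction is 0.6 * P(N(31,6) < 50) + 0.4 * P(N(72,8) < 50)
  n1 <- 600L; n2 <- 400L
  # build the mixture by scheduling per-frame target angles drawn from
  # the two populations (exact ground truth: jitter lives in the schedule)
  set.seed(5)
  sched <- c(rep(31, n1) + rnorm(n1, 0, 6), rep(72, n2) + rnorm(n2, 0, 8))
  sched <- pmin(179.9, pmax(0.1, sched))
  tr <- make_dfg_sweep_trajectory(sweep_spec(sched))
  cls <- classify_state(dfg_rotation_angle(tr), 50)
  expected_in <- (n1 * stats::pnorm(50, 31, 6) +
                    n2 * stats::pnorm(50, 72, 8)) / (n1 + n2)
  se <- sqrt(expected_in * (1 - expected_in) / (n1 + n2))
  expect_lt(abs(cls$summary$frac_dfg_in - expected_in), 3 * se)
})

test_that("noise-free sweeps classify with 100 percent accuracy", {
  sched <- c(25, 35, 45, 55, 65, 75)
  tr <- make_dfg_sweep_trajectory(sweep_spec(sched))
  cls <- classify_state(dfg_rotation_angle(tr), 50)
  expect_equal(as.character(cls$labels),
               ifelse(sched < 50, "DFG-in", "DFG-out"))
})

test_that("angle histograms bin over [0, 180] and conserve counts", {
  s <- structure(list(values = c(10, 10, 20), frame_times = 0:2,
                      variant_label = "x"), class = "angle_series")
  h <- angle_histogram(s, bin_width = 10)
  expect_equal(h$count[h$bin_lo == 10], 2)
  expect_equal(h$count[h$bin_lo == 20], 1)
  expect_equal(sum(h$count), 3)
  expect_equal(min(h$bin_lo), 0)
  expect_equal(max(h$bin_hi), 180)
  # empty series -> all-zero histogram
  s0 <- structure(list(values = numeric(0), frame_times = numeric(0),
                       variant_label = "x"), class = "angle_series")
  expect_true(all(angle_histogram(s0, 10)$count == 0))
  # NaN frames are excluded from the count total
  s1 <- structure(list(values = c(10, NaN), frame_times = 0:1,
                       variant_label = "x"), class = "angle_series")
  expect_equal(sum(angle_histogram(s1, 10)$count), 1)
})

test_that("the summary mode tracks the dominant population", {
  set.seed(9)
  sched <- pmin(179.9, pmax(0.1, rnorm(500, 72, 8)))
  tr <- make_dfg_sweep_trajectory(sweep_spec(sched))
  cls <- classify_state(dfg_rotation_angle(tr), 50)
  expect_lt(abs(cls$summary$mode_deg - 72), 10)
})

test_that("RMSD is zero for identical frames and after rigid motion", {
  m <- make_toy_kinase()
  tr <- static_traj(m, 4)
  expect_equal(trajectory_rmsd(tr), rep(0, 4), tolerance = 1e-8)
  # rotate+translate one frame: superposition removes the rigid motion
  R <- random_rotation()
  xyz <- tr$xyz
  moved <- sweep(m$xyz %*% t(R), 2L, c(1, 2, 3), "+")
  xyz[2, ] <- as.numeric(t(moved))
  tr2 <- trajectory(m, xyz, tr$frame_times)
  expect_lt(trajectory_rmsd(tr2)[2], 1e-6)
})

test_that("RMSD matches the hand-computed value for a one-atom shift", {
  # 4 atoms, one moves 0.2 nm; the others pin the superposition close to
  # identity only if fitting is disabled, so measure without fitting
  m <- structure_model(
    data.frame(atom_name = c("CA", "CB", "CG", "CD"), element = "C",
               resno = 1:4, resid = "ALA", chain = "A", radius = 0.17,
               stringsAsFactors = FALSE),
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  xyz <- rbind(as.numeric(t(m$xyz)),
               as.numeric(t(rbind(c(0, 0, 0.2), c(1, 0, 0), c(0, 1, 0),
                                  c(0, 0, 1)))))
  tr <- trajectory(m, xyz, 0:1)
  expect_equal(trajectory_rmsd(tr, fit = FALSE)[2], 0.2 / sqrt(4),
               tolerance = 1e-9)
})

test_that("RMSF is non-negative and superposition needs 3+ atoms", {
  m <- make_toy_kinase()
  set.seed(4)
  xyz <- matrix(rep(as.numeric(t(m$xyz)), 5), nrow = 5, byrow = TRUE) +
    rnorm(5 * 3 * n_atoms(m), sd = 0.01)
  tr <- trajectory(m, xyz, 0:4)
  f <- trajectory_rmsf(tr)
  expect_true(all(f$rmsf_nm >= 0))
  expect_equal(nrow(f), n_atoms(m))
  expect_error(trajectory_rmsd(tr, selection = 1:2), "at least 3")
  expect_error(trajectory_rmsf(tr, selection = 1L), "at least 3")
})
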