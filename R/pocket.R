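# Grid-based ATP-binding-pocket volume: a cubic box of grid points is
# centered on the pocket-center atom, points overlapping any protein atom
# are deleted, and the volume is free points x voxel volume.

#' Pocket grid specification
#'
#' A cubic box of edge `box_edge` centered on the pocket-center atom
#' (hinge residue L2026 alpha-carbon by default), filled with grid points
#' at `spacing` resolution. Points sit at voxel centers, so there are
#' `round(box_edge / spacing)` points per axis (15^3 = 3,375 at the
#' defaults) and the empty-box volume is exactly `n_points * spacing^3`
#' (3.375 nm^3). A point is deleted when its distance to an atom center is
#' strictly less than that atom's overlap radius: the per-atom element vdW
#' radius by default, or a fixed radius. Hydrogens are excluded from the
#' overlap test by default (heavy-atom convention). The box is
#' axis-aligned in the laboratory frame and follows the center atom, so
#' the volume is translation-equivariant but not rotation-invariant.
#'
#' @param center [atom_selector] for the box center atom.
#' @param box_edge cube edge, nm (default 1.5).
#' @param spacing grid resolution, nm (default 0.1); must divide
#'   `box_edge` to within 1e-9.
#' @param fixed_radius if non-NULL, a single overlap radius in nm used for
#'   every atom instead of the per-atom vdW radii.
#' @param include_h include hydrogens in the overlap test.
#' @return An object of class `pocket_grid_spec`.
#' @export
pocket_grid_spec <- function(center = atom_selector(2026, "CA"),
                             box_edge = 1.5, spacing = 0.1,
                             fixed_radius = NULL, include_h = FALSE) {
  stopifnot(box_edge > 0, spacing > 0, spacing <= box_edge)
  n <- round(box_edge / spacing)
  if (abs(n * spacing - box_edge) > 1e-9)
    stop("spacing must divide box_edge exactly (", spacing, " vs ",
         box_edge, ")")
  structure(list(center = center, box_edge = box_edge, spacing = spacing,
                 n_per_axis = as.integer(n), fixed_radius = fixed_radius,
                 include_h = include_h),
            class = "pocket_grid_spec")
}

# voxel-center offsets along one axis, relative to the box center
.grid_axis <- function(spec) {
  n <- spec$n_per_axis
  (-spec$box_edge / 2) + (seq_len(n) - 0.5) * spec$spacing
}

#' Pocket volume of one frame
#'
#' Re-centers the grid box on the center atom's position in this frame,
#' deletes every grid point lying strictly inside any protein atom's
#' overlap radius, and returns the remaining free volume. Only atoms
#' within reach of the box (half-edge plus the largest radius) are tested;
#' this pruning cannot change the result.
#'
#' @param model a [structure_model] (topology of the frame).
#' @param coords n_atoms x 3 coordinates, nm (default the model's own).
#' @param spec a [pocket_grid_spec].
#' @return Volume in nm^3 (free grid points x spacing^3).
#' @export
pocket_volume <- function(model, coords = model$xyz,
                          spec = pocket_grid_spec()) {
  center_idx <- select_atom(model, spec$center)
  ctr <- coords[center_idx, ]
  ax <- .grid_axis(spec)
  gx <- ctr[1L] + ax; gy <- ctr[2L] + ax; gz <- ctr[3L] + ax
  radii <- if (is.null(spec$fixed_radius)) model$atoms$radius
           else rep(spec$fixed_radius, nrow(model$atoms))
  use <- rep(TRUE, nrow(model$atoms))
  if (!spec$include_h) use <- model$atoms$element != "H"
  # prune atoms that cannot reach any grid point
  half <- spec$box_edge / 2
  reach <- half + radii
  near <- use &
    abs(coords[, 1L] - ctr[1L]) <= reach &
    abs(coords[, 2L] - ctr[2L]) <= reach &
    abs(coords[, 3L] - ctr[3L]) <= reach
  n <- spec$n_per_axis
  if (!any(near)) return(n^3 * spec$spacing^3)
  axyz <- coords[near, , drop = FALSE]
  ar2 <- radii[near]^2
  # squared distance from every grid point to every near atom, axis-separated
  dx2 <- outer(gx, axyz[, 1L], "-")^2          # n x m
  dy2 <- outer(gy, axyz[, 2L], "-")^2
  dz2 <- outer(gz, axyz[, 3L], "-")^2
  xy2 <- dx2[rep(seq_len(n), times = n), , drop = FALSE] +
         dy2[rep(seq_len(n), each = n), , drop = FALSE]   # (n^2) x m
  free <- 0L
  for (k in seq_len(n)) {                      # z-slabs keep memory flat
    covered <- rowSums(sweep(xy2, 2L, dz2[k, ] - ar2, "+") < 0) > 0
    free <- free + sum(!covered)
  }
  free * spec$spacing^3
}

#' Pocket-volume time series
#'
#' Evaluates [pocket_volume()] on frames sampled every `stride` ns,
#' starting at the first frame (a frame is sampled when its time, measured
#' from the first frame, falls within one frame interval past a stride
#' multiple). A stride below the frame interval samples every frame, with
#' a warning.
#'
#' @param traj a [trajectory].
#' @param spec a [pocket_grid_spec].
#' @param stride sampling period, ns (default 1).
#' @param variant_label label carried into the result.
#' @return A `pocket_volume_series`: `values` (nm^3), `frame_times` (ns),
#'   `variant_label`.
#' @export
pocket_volume_series <- function(traj, spec = pocket_grid_spec(),
                                 stride = 1,
                                 variant_label = traj$replica_id) {
  stopifnot(stride > 0)
  tt <- traj$frame_times - traj$frame_times[1L]
  dt <- if (length(tt) > 1L) min(diff(tt)) else stride
  if (stride < dt) {
    warning("stride (", stride, " ns) is below the frame interval (", dt,
            " ns); every frame is used", call. = FALSE)
    keep <- seq_along(tt)
  } else {
    keep <- which((tt %% stride) < dt - 1e-9 | (tt %% stride) > stride - 1e-9)
  }
  vals <- vapply(keep, function(f)
    pocket_volume(traj$topology, frame_coords(traj, f), spec), numeric(1L))
  structure(list(values = vals, frame_times = traj$frame_times[keep],
                 variant_label = variant_label),
            class = "pocket_volume_series")
}

#' @export
print.pocket_volume_series <- function(x, ...) {
  cat("pocket_volume_series [", x$variant_label, "]: ",
      length(x$values), " frames, mean ", round(mean(x$values), 2),
      " nm^3, SD ", round(stats::sd(x$values), 2), " nm^3\n", sep = "")
  invisible(x)
}

#' Joint DFG-angle / pocket-volume table
#'
#' Pairs an angle series with a (typically strided) volume series by frame
#' time and appends per-variant means and SDs of both columns as a summary
#' attribute. Angle frames with no matching volume sample are dropped.
#'
#' @param angles an `angle_series`.
#' @param volumes a `pocket_volume_series` sampled at a subset of the
#'   angle frame times.
#' @return data.frame (`frame_time_ns`, `angle_deg`, `volume_nm3`) with a
#'   `summary` attribute (variant, means, SDs, n).
#' @export
joint_angle_volume <- function(angles, volumes) {
  m <- match(round(volumes$frame_times, 9), round(angles$frame_times, 9))
  ok <- !is.na(m)
  if (!any(ok)) stop("no overlapping frame times between the two series")
  out <- data.frame(frame_time_ns = volumes$frame_times[ok],
                    angle_deg = angles$values[m[ok]],
                    volume_nm3 = volumes$values[ok])
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  attr(out, "summary") <- data.frame(
    variant = angles$variant_label, n = nrow(out),
    angle_mean_deg = mean(out$angle_deg), angle_sd_deg = sd0(out$angle_deg),
    volume_mean_nm3 = mean(out$volume_nm3),
    volume_sd_nm3 = sd0(out$volume_nm3),
    stringsAsFactors = FALSE)
  out
}
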