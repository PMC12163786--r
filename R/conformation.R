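# DFG rotation angle, per-frame state classification, histogramming, and
# RMSD/RMSF plumbing.

# Planar angle (degrees) at vertex v subtended by points a and b.
.angle_deg <- function(a, v, b) {
  u1 <- a - v
  u2 <- b - v
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-12 || n2 < 1e-12) return(NaN)
  cosang <- sum(u1 * u2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' DFG rotation-angle series
#'
#' For every frame, the planar angle (degrees) at the alpha-carbon of the
#' vertex residue of the motif map's angle triple (alphaC-helix residue
#' 1997 by default), subtended by the alpha-carbons of the beta4 residue
#' 1980 and the DFG phenylalanine 2103. Small in the DFG-in (active)
#' state, large when the Phe side chain rotates into the ATP pocket
#' (DFG-out). Invariant under rigid motion of the frame. Frames with
#' degenerate geometry (vertex coincident with an arm atom) yield NaN with
#' a warning.
#'
#' @param traj a [trajectory].
#' @param motifs a [kinase_motif_map].
#' @param variant_label label carried into the result.
#' @return An `angle_series`: list with `values` (degrees, one per frame),
#'   `frame_times` (ns) and `variant_label`.
#' @export
dfg_rotation_angle <- function(traj, motifs = kinase_motif_map(),
                               variant_label = traj$replica_id) {
  idx <- vapply(motifs$angle_triple, function(s)
    select_atom(traj$topology, s), integer(1L))
  cols <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  a <- traj$xyz[, cols(idx[1L]), drop = FALSE]
  v <- traj$xyz[, cols(idx[2L]), drop = FALSE]
  b <- traj$xyz[, cols(idx[3L]), drop = FALSE]
  vals <- vapply(seq_len(nrow(a)), function(f)
    .angle_deg(a[f, ], v[f, ], b[f, ]), numeric(1L))
  if (anyNA(vals) || any(is.nan(vals)))
    warning("degenerate angle geometry in ",
            sum(is.nan(vals)), " frame(s); NaN emitted", call. = FALSE)
  structure(list(values = vals, frame_times = traj$frame_times,
                 variant_label = variant_label),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  ok <- x$values[!is.nan(x$values)]
  cat("angle_series [", x$variant_label, "]: ", length(x$values),
      " frames, mean ", round(mean(ok), 1), " deg, SD ",
      round(stats::sd(ok), 1), " deg\n", sep = "")
  invisible(x)
}

#' Classify frames as DFG-in or DFG-out
#'
#' A frame is DFG-in iff its rotation angle is strictly below the
#' threshold; angles at or above it are DFG-out. The default 50 degrees
#' sits midway between the active and inactive population means (31 and 72
#' degrees). NaN angles give NA labels and are excluded from summaries.
#'
#' @param series an `angle_series` from [dfg_rotation_angle()].
#' @param threshold_deg classification threshold, degrees.
#' @param mode_bin_width bin width (degrees) for the histogram mode in the
#'   summary.
#' @return A `state_classification`: per-frame `labels`
#'   (factor DFG-in/DFG-out), `threshold_deg`, and `summary`
#'   (mean, sd, mode of the non-NaN angles, counts).
#' @export
classify_state <- function(series, threshold_deg = 50,
                           mode_bin_width = 2.5) {
  vals <- series$values
  ok <- vals[!is.nan(vals)]
  if (length(ok) == 0L) stop("all angles are NaN; nothing to classify")
  labels <- factor(ifelse(is.nan(vals), NA,
                          ifelse(vals < threshold_deg, "DFG-in", "DFG-out")),
                   levels = c("DFG-in", "DFG-out"))
  h <- angle_histogram(series, bin_width = mode_bin_width)
  mode_center <- h$bin_mid[which.max(h$count)]
  structure(list(
    labels = labels, threshold_deg = threshold_deg,
    summary = data.frame(
      variant = series$variant_label,
      n_frames = length(vals), n_nan = sum(is.nan(vals)),
      mean_deg = mean(ok), sd_deg = stats::sd(ok),
      mode_deg = mode_center,
      frac_dfg_in = sum(labels == "DFG-in", na.rm = TRUE) / length(vals),
      frac_dfg_out = sum(labels == "DFG-out", na.rm = TRUE) / length(vals),
      stringsAsFactors = FALSE)),
    class = "state_classification")
}

#' @export
print.state_classification <- function(x, ...) {
  s <- x$summary
  cat("state_classification [", s$variant, "]: ",
      round(100 * s$frac_dfg_in, 1), "% DFG-in / ",
      round(100 * s$frac_dfg_out, 1), "% DFG-out at ",
      x$threshold_deg, " deg\n", sep = "")
  invisible(x)
}

#' Histogram of an angle series over [0, 180] degrees
#'
#' Left-closed bins of fixed width covering 0-180 degrees (the final bin
#' also includes 180). Counts sum to the number of non-NaN frames.
#'
#' @param series an `angle_series`.
#' @param bin_width bin width in degrees (> 0).
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `count`.
#' @export
angle_histogram <- function(series, bin_width = 2.5) {
  stopifnot(bin_width > 0)
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  vals <- series$values[!is.nan(series$values)]
  # [lo, hi) bins; top edge folded into the last bin
  bin <- findInterval(vals, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1L
  counts <- tabulate(bin, nbins = nb)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             bin_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = counts)
}

#' Per-frame RMSD after optimal superposition
#'
#' Root-mean-square deviation of selected atoms against a reference frame,
#' after least-squares rigid-body (Kabsch) superposition on that selection.
#'
#' @param traj a [trajectory].
#' @param reference reference frame index (default 1).
#' @param selection integer atom indices used both for fitting and for the
#'   deviation; at least 3 atoms.
#' @param fit superpose before measuring (default `TRUE`).
#' @return numeric vector, one RMSD in nm per frame.
#' @export
trajectory_rmsd <- function(traj, reference = 1L,
                            selection = seq_len(n_atoms(traj$topology)),
                            fit = TRUE) {
  if (length(selection) < 3L)
    stop("superposition needs a selection of at least 3 atoms")
  xyz_inds <- bio3d::atom2xyz(selection)
  as.numeric(bio3d::rmsd(traj$xyz[reference, ], traj$xyz,
                         a.inds = xyz_inds, b.inds = xyz_inds, fit = fit))
}

#' Per-atom RMSF about the mean structure
#'
#' Frames are superposed onto the first frame over the selection, then the
#' root-mean-square fluctuation of each selected atom about its mean
#' position is reported.
#'
#' @param traj a [trajectory].
#' @param selection integer atom indices (default: all); at least 3.
#' @return data.frame with `atom_index`, `resno`, `atom_name`, `rmsf_nm`.
#' @export
trajectory_rmsf <- function(traj,
                            selection = seq_len(n_atoms(traj$topology))) {
  if (length(selection) < 3L)
    stop("superposition needs a selection of at least 3 atoms")
  xyz_inds <- bio3d::atom2xyz(selection)
  fitted <- bio3d::fit.xyz(traj$xyz[1L, ], traj$xyz,
                           fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  f <- bio3d::rmsf(fitted[, xyz_inds, drop = FALSE])
  data.frame(atom_index = selection,
             resno = traj$topology$atoms$resno[selection],
             atom_name = traj$topology$atoms$atom_name[selection],
             rmsf_nm = as.numeric(f))
}
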