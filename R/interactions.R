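# Per-frame interaction detectors and occupancy aggregation over
# concatenated replicas. Detectors take (model, coords) for one frame and
# return a data.frame of canonical residue pairs; occupancy() maps any
# detector over a trajectory.

# side-chain charged-atom definitions for the salt-bridge screen
.acidic_atoms_default <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_atoms_default  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.his_atoms <- c("ND1", "NE2")

#' Salt-bridge detection criteria
#'
#' A salt bridge is counted when any side-chain carboxylate oxygen of an
#' acidic residue lies within the heavy-atom cutoff of any side-chain
#' nitrogen of a basic residue. Histidine is excluded by default (its
#' protonation state in the screen is not asserted); set
#' `include_his = TRUE` to admit ND1/NE2.
#'
#' @param cutoff heavy-atom distance cutoff, nm (default 0.4).
#' @param acidic_atoms named list: residue type -> carboxylate oxygen names.
#' @param basic_atoms named list: residue type -> side-chain nitrogen names.
#' @param include_his admit His ND1/NE2 to the basic set.
#' @return An object of class `salt_bridge_criteria`.
#' @export
salt_bridge_criteria <- function(cutoff = 0.4,
                                 acidic_atoms = .acidic_atoms_default,
                                 basic_atoms = .basic_atoms_default,
                                 include_his = FALSE) {
  stopifnot(cutoff > 0)
  if (include_his) basic_atoms$HIS <- .his_atoms
  structure(list(cutoff = cutoff, acidic_atoms = acidic_atoms,
                 basic_atoms = basic_atoms),
            class = "salt_bridge_criteria")
}

#' Hydrogen-bond detection criteria
#'
#' Geometric screen: donor-acceptor heavy-atom distance at most `cutoff`
#' and hydrogen-donor-acceptor angle at most `angle_cutoff`, with at least
#' one partner residue inside the restriction set (by default the DFG and
#' HRD motif residues of the motif map). The defaults mirror the
#' conventional GROMACS geometric criteria.
#'
#' @param cutoff donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cutoff H-donor-acceptor angle cutoff, degrees (default 30).
#' @param restriction integer residue numbers; `NULL` means no restriction.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(cutoff = 0.35, angle_cutoff = 30,
                           restriction = NULL) {
  stopifnot(cutoff > 0, angle_cutoff >= 0, angle_cutoff <= 90)
  structure(list(cutoff = cutoff, angle_cutoff = angle_cutoff,
                 restriction = if (is.null(restriction)) NULL
                               else as.integer(restriction)),
            class = "hbond_criteria")
}

# canonical residue-pair table: lower residue number first
.pair_table <- function(res_a, res_b, resid_a, resid_b, detail = "") {
  if (length(res_a) == 0L)
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      pair = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  swap <- res_a > res_b
  tmp <- res_a[swap]; res_a[swap] <- res_b[swap]; res_b[swap] <- tmp
  tmpn <- resid_a[swap]; resid_a[swap] <- resid_b[swap]
  resid_b[swap] <- tmpn
  d <- data.frame(res_a = res_a, res_b = res_b,
                  pair = paste0(resid_a, res_a, "-", resid_b, res_b),
                  detail = detail, stringsAsFactors = FALSE)
  d <- d[!duplicated(d$pair), , drop = FALSE]
  d[order(d$res_a, d$res_b), , drop = FALSE]
}

.pairwise_dists <- function(xa, xb) {
  # xa: n x 3, xb: m x 3 -> n x m distance matrix
  sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
}

#' Salt bridges present in one frame
#'
#' Reports every acidic/basic residue pair whose side-chain carboxylate
#' oxygen and side-chain nitrogen come within the heavy-atom cutoff.
#' Residues missing their charged side-chain atoms are silently ineligible.
#'
#' @param model a [structure_model] (topology of the frame).
#' @param coords n_atoms x 3 coordinate matrix, nm (default the model's own
#'   coordinates).
#' @param criteria a [salt_bridge_criteria].
#' @return data.frame of canonical pairs: `res_a`, `res_b`, `pair`,
#'   `detail`.
#' @export
salt_bridge_contacts <- function(model, coords = model$xyz,
                                 criteria = salt_bridge_criteria()) {
  a <- model$atoms
  pick <- function(defs) {
    hit <- rep(FALSE, nrow(a))
    for (res in names(defs))
      hit <- hit | (a$resid == res & a$atom_name %in% defs[[res]])
    which(hit)
  }
  ai <- pick(criteria$acidic_atoms)
  bi <- pick(criteria$basic_atoms)
  if (length(ai) == 0L || length(bi) == 0L)
    return(.pair_table(integer(0), integer(0), character(0), character(0)))
  d <- .pairwise_dists(coords[ai, , drop = FALSE],
                       coords[bi, , drop = FALSE])
  hit <- which(d <= criteria$cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(.pair_table(integer(0), integer(0), character(0), character(0)))
  ia <- ai[hit[, 1L]]
  ib <- bi[hit[, 2L]]
  keep <- a$resno[ia] != a$resno[ib] | a$chain[ia] != a$chain[ib]
  ia <- ia[keep]; ib <- ib[keep]
  .pair_table(a$resno[ia], a$resno[ib], a$resid[ia], a$resid[ib],
              detail = "salt-bridge")
}

# donor heavy atoms: N/O with a hydrogen of the same residue within bond
# range; returns data.frame(donor_idx, h_idx)
.find_donors <- function(model, coords, bond_cut = 0.125) {
  a <- model$atoms
  hi <- which(a$element == "H")
  di <- which(a$element %in% c("N", "O"))
  if (length(hi) == 0L || length(di) == 0L)
    return(data.frame(donor = integer(0), h = integer(0)))
  out_d <- integer(0); out_h <- integer(0)
  for (h in hi) {
    same <- di[a$resno[di] == a$resno[h] & a$chain[di] == a$chain[h]]
    if (length(same) == 0L) next
    dd <- sqrt(colSums((t(coords[same, , drop = FALSE]) - coords[h, ])^2))
    j <- which.min(dd)
    if (dd[j] <= bond_cut) {
      out_d <- c(out_d, same[j]); out_h <- c(out_h, h)
    }
  }
  data.frame(donor = out_d, h = out_h)
}

#' Hydrogen bonds present in one frame
#'
#' Donors are N/O heavy atoms with a covalently bound hydrogen (inferred by
#' proximity within the residue); acceptors are all N/O heavy atoms. A
#' bond is reported when the donor-acceptor distance and the
#' H-donor-acceptor angle both pass, and at least one partner residue lies
#' in the restriction set. For hydrogen-free topologies the screen falls
#' back to the distance criterion alone, with a warning: this is not
#' equivalent to the full geometric screen.
#'
#' @param model a [structure_model] (must include hydrogens for the full
#'   screen).
#' @param coords n_atoms x 3 coordinates, nm.
#' @param criteria an [hbond_criteria].
#' @param motifs a [kinase_motif_map]; when `criteria$restriction` is NULL
#'   the restriction defaults to the union of the map's DFG and HRD
#'   residues.
#' @return data.frame of canonical pairs with donor/acceptor atom detail.
#' @export
hbond_contacts <- function(model, coords = model$xyz,
                           criteria = hbond_criteria(),
                           motifs = kinase_motif_map()) {
  a <- model$atoms
  restrict <- criteria$restriction
  if (is.null(restrict))
    restrict <- c(motifs$dfg_residues, motifs$hrd_residues)
  if (!any(a$resno %in% restrict))
    stop("H-bond restriction set resolves to zero residues in this model")
  donors <- .find_donors(model, coords)
  has_h <- any(a$element == "H")
  if (!has_h) {
    warning("topology has no hydrogens; H-bond screen falls back to the ",
            "donor-acceptor distance criterion only", call. = FALSE)
    donors <- data.frame(donor = which(a$element %in% c("N", "O")),
                         h = NA_integer_)
  }
  acceptors <- which(a$element %in% c("N", "O"))
  if (nrow(donors) == 0L || length(acceptors) == 0L)
    return(.pair_table(integer(0), integer(0), character(0), character(0)))
  res_a <- integer(0); res_b <- integer(0)
  nam_a <- character(0); nam_b <- character(0); det <- character(0)
  for (k in seq_len(nrow(donors))) {
    dON <- donors$donor[k]
    dd <- sqrt(colSums((t(coords[acceptors, , drop = FALSE]) -
                          coords[dON, ])^2))
    cand <- acceptors[dd <= criteria$cutoff]
    cand <- cand[a$resno[cand] != a$resno[dON] |
                   a$chain[cand] != a$chain[dON]]
    for (acc in cand) {
      if (!(a$resno[dON] %in% restrict || a$resno[acc] %in% restrict))
        next
      if (has_h) {
        ang <- .angle_deg(coords[donors$h[k], ], coords[dON, ],
                          coords[acc, ])
        # H-donor-acceptor angle must be small for a near-linear bond
        if (is.nan(ang) || ang > criteria$angle_cutoff) next
      }
      res_a <- c(res_a, a$resno[dON]); res_b <- c(res_b, a$resno[acc])
      nam_a <- c(nam_a, a$resid[dON]); nam_b <- c(nam_b, a$resid[acc])
      det <- c(det, paste0(a$atom_name[dON], ">", a$atom_name[acc]))
    }
  }
  .pair_table(res_a, res_b, nam_a, nam_b, detail = det)
}

#' Hydrophobic contacts of the DFG phenylalanine side chain
#'
#' Reports each partner residue with any side-chain carbon within the
#' heavy-atom cutoff of any side-chain heavy atom of the center residue
#' (F2103 by default). Pairs are canonical center-partner residue pairs.
#'
#' @param model a [structure_model].
#' @param coords n_atoms x 3 coordinates, nm.
#' @param motifs a [kinase_motif_map] naming center and partners.
#' @param cutoff heavy-atom contact cutoff, nm (default 0.45).
#' @return data.frame of canonical pairs.
#' @export
hydrophobic_contacts <- function(model, coords = model$xyz,
                                 motifs = kinase_motif_map(),
                                 cutoff = 0.45) {
  a <- model$atoms
  backbone <- c("N", "CA", "C", "O", "OXT")
  ci <- which(a$resno == motifs$hydrophobic_center &
                !(a$atom_name %in% backbone) & a$element != "H")
  if (length(ci) == 0L)
    stop("hydrophobic center residue ", motifs$hydrophobic_center,
         " has no side-chain heavy atoms in this model")
  res_a <- integer(0); res_b <- integer(0)
  nam_a <- character(0); nam_b <- character(0)
  for (p in motifs$hydrophobic_partners) {
    pi <- which(a$resno == p & a$element == "C" &
                  !(a$atom_name %in% backbone))
    if (length(pi) == 0L) next
    d <- .pairwise_dists(coords[ci, , drop = FALSE],
                         coords[pi, , drop = FALSE])
    if (any(d <= cutoff)) {
      res_a <- c(res_a, motifs$hydrophobic_center); res_b <- c(res_b, p)
      nam_a <- c(nam_a, a$resid[ci[1L]]); nam_b <- c(nam_b, a$resid[pi[1L]])
    }
  }
  .pair_table(res_a, res_b, nam_a, nam_b, detail = "hydrophobic")
}

#' Interaction occupancy over a (concatenated) trajectory
#'
#' Runs a per-frame detector over every frame and reports, for each pair
#' ever observed, the fraction of frames in which it is present. Replicas
#' concatenated with [concatenate_trajectories()] are treated as one frame
#' population, so the result is the combined occupancy across replicas.
#'
#' @param traj a [trajectory].
#' @param detector function(model, coords) -> pair data.frame, e.g.
#'   [salt_bridge_contacts()] wrapped with fixed criteria.
#' @param variant_label label attached to every row.
#' @return An `interaction_occupancy` data.frame: `pair`, `res_a`, `res_b`,
#'   `variant`, `occupancy` in \[0, 1\], `n_frames`.
#' @export
interaction_occupancy <- function(traj, detector,
                                  variant_label = traj$replica_id) {
  nf <- n_frames(traj)
  stopifnot(nf >= 1L)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hits <- detector(traj$topology, frame_coords(traj, f))
    for (i in seq_len(nrow(hits))) {
      key <- hits$pair[i]
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      if (is.null(meta[[key]]))
        meta[[key]] <- c(hits$res_a[i], hits$res_b[i])
    }
  }
  keys <- ls(counts)
  out <- data.frame(
    pair = keys,
    res_a = vapply(keys, function(k) meta[[k]][1L], integer(1L)),
    res_b = vapply(keys, function(k) meta[[k]][2L], integer(1L)),
    variant = rep(variant_label, length(keys)),
    occupancy = vapply(keys, function(k) counts[[k]] / nf, numeric(1L)),
    n_frames = rep(nf, length(keys)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_occupancy", "data.frame")
  # keep the variant identity even when no pair was ever observed
  attr(out, "variant") <- variant_label
  out
}

#' Cross-variant occupancy matrix with a presence filter
#'
#' Combines per-variant occupancy tables into a wide pair x variant matrix
#' and keeps a pair iff its occupancy strictly exceeds the threshold in at
#' least one variant (the "exceeding 15 percent" rule). Retained pairs
#' report an occupancy for every variant, zero where never observed; rows
#' are sorted by residue numbers.
#'
#' @param tables list of `interaction_occupancy` tables (one per variant).
#' @param threshold retention threshold as a fraction (default 0.15);
#'   strictly-greater comparison.
#' @return data.frame: `pair`, `res_a`, `res_b`, then one occupancy column
#'   per variant. Zero rows (not an error) when nothing passes.
#' @export
filter_occupancy_matrix <- function(tables, threshold = 0.15) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(tables) == 0L) stop("no occupancy tables supplied")
  long <- do.call(rbind, lapply(tables, as.data.frame))
  variants <- unique(unlist(lapply(tables, function(t) {
    v <- attr(t, "variant")
    if (is.null(v)) unique(t$variant) else v
  })))
  pairs <- unique(long[c("pair", "res_a", "res_b")])
  wide <- pairs
  for (v in variants) {
    sub <- long[long$variant == v, ]
    wide[[v]] <- sub$occupancy[match(wide$pair, sub$pair)]
    wide[[v]][is.na(wide[[v]])] <- 0
  }
  occ <- as.matrix(wide[, variants, drop = FALSE])
  keep <- apply(occ, 1L, function(r) any(r > threshold))
  wide <- wide[keep, , drop = FALSE]
  wide <- wide[order(wide$res_a, wide$res_b), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

#' Radar-style occupancy table (percent)
#'
#' Long-to-wide reshaping of H-bond (or any) occupancy tables into a
#' bond-label x variant table of occupancy percentages, the layout of a
#' radar/spider chart of interaction-network dynamics.
#'
#' @param tables list of `interaction_occupancy` tables.
#' @param threshold optional retention threshold (fraction) applied as in
#'   [filter_occupancy_matrix()]; default 0 keeps every observed pair.
#' @return data.frame: `pair` then one percent column per variant.
#' @export
radar_table <- function(tables, threshold = 0) {
  wide <- filter_occupancy_matrix(tables, threshold = threshold)
  vars <- setdiff(names(wide), c("pair", "res_a", "res_b"))
  out <- wide[, c("pair", vars), drop = FALSE]
  out[vars] <- lapply(out[vars], function(x) 100 * x)
  out
}
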