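#' Kinase motif map
#'
#' Named residue/atom anchors that drive every analysis, defaulting to the
#' ROS1 kinase-domain numbering: the DFG rotation angle is subtended at the
#' alpha-carbon of the alphaC-helix residue 1997 by the alpha-carbons of the
#' beta4-strand residue 1980 and the DFG phenylalanine 2103; the ATP-pocket
#' grid box is centered on the hinge residue L2026 alpha-carbon; the DFG
#' (2102-2104) and HRD (2077-2079) motifs restrict the hydrogen-bond screen;
#' and the hydrophobic cluster pairs the F2103 side chain against partners
#' on the G-loop, beta strands and hinge.
#'
#' @param angle_triple list of three [atom_selector]s; the middle one is the
#'   angle vertex.
#' @param pocket_center [atom_selector] for the pocket-box center atom.
#' @param dfg_residues,hrd_residues integer residue numbers of the DFG and
#'   HRD motifs.
#' @param motif_flank residues adjacent to the DFG motif admitted to
#'   motif-restricted screens (DFG-1 = 2101, DFG+1 = 2105).
#' @param hydrophobic_center residue number whose side-chain heavy atoms
#'   anchor the hydrophobic-contact detector (DFG Phe, 2103).
#' @param hydrophobic_partners residue numbers screened for contact with
#'   the center side chain.
#' @return An object of class `kinase_motif_map`.
#' @export
kinase_motif_map <- function(
    angle_triple = list(atom_selector(1980, "CA"),
                        atom_selector(1997, "CA"),
                        atom_selector(2103, "CA")),
    pocket_center = atom_selector(2026, "CA"),
    dfg_residues = c(2102L, 2103L, 2104L),
    hrd_residues = c(2077L, 2078L, 2079L),
    motif_flank = c(2101L, 2105L),
    hydrophobic_center = 2103L,
    hydrophobic_partners = c(1951L, 1959L, 1978L, 2010L, 2026L, 2086L)) {
  stopifnot(length(angle_triple) == 3L)
  resnos <- vapply(angle_triple, `[[`, integer(1L), "resno")
  if (anyDuplicated(resnos))
    stop("angle_triple members must be distinct residues")
  structure(list(angle_triple = angle_triple,
                 pocket_center = pocket_center,
                 dfg_residues = as.integer(dfg_residues),
                 hrd_residues = as.integer(hrd_residues),
                 motif_flank = as.integer(motif_flank),
                 hydrophobic_center = as.integer(hydrophobic_center),
                 hydrophobic_partners = as.integer(hydrophobic_partners)),
            class = "kinase_motif_map")
}

#' @export
print.kinase_motif_map <- function(x, ...) {
  tri <- vapply(x$angle_triple, `[[`, integer(1L), "resno")
  cat("kinase_motif_map: angle", paste(tri, collapse = "-"),
      "| pocket center", x$pocket_center$resno,
      "| DFG", paste(x$dfg_residues, collapse = ","),
      "| HRD", paste(x$hrd_residues, collapse = ","), "\n")
  invisible(x)
}
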