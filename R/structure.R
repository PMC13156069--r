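## Protein-ligand interaction geometry from coordinate files.
##
## Structures are consumed, never produced: PDB-format files (ATOM records
## for the protein, HETATM records for the docked/cocrystal ligand) are read
## with bio3d.

#' Load a protein-ligand structure from a PDB file
#'
#' @param path path to a PDB-format file.
#' @param structure_id identifier carried into downstream features; defaults
#'   to the file name.
#' @param exclude_het HETATM residue names that are not the ligand
#'   (solvent/ions), excluded from ligand atoms.
#' @return An `ssep_structure` list with `protein` and `ligand` coordinate
#'   data.frames (`x`, `y`, `z`, `resno`, `elety`, `elesy`).
#' @export
read_structure <- function(path, structure_id = basename(path),
                           exclude_het = c("HOH", "WAT", "NA", "CL", "K", "MG", "ZN")) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  heavy <- is.na(at$elesy) | toupper(at$elesy) != "H"
  prot <- at[at$type == "ATOM" & heavy, , drop = FALSE]
  lig <- at[at$type == "HETATM" & heavy &
              !(at$resid %in% exclude_het), , drop = FALSE]
  structure(list(
    structure_id = structure_id,
    protein = prot[, c("x", "y", "z", "resno", "elety", "elesy")],
    ligand = lig[, c("x", "y", "z", "resno", "elety", "elesy")]
  ), class = "ssep_structure")
}

#' @export
print.ssep_structure <- function(x, ...) {
  cat(sprintf("<ssep_structure> %s: %d protein heavy atoms, %d ligand heavy atoms\n",
              x$structure_id, nrow(x$protein), nrow(x$ligand)))
  invisible(x)
}

#' Distance-based protein-ligand interaction features for a mutated residue
#'
#' Computes the minimum heavy-atom Euclidean distance between the residue at
#' `residue_position` and the ligand, the number of ligand heavy atoms
#' within the contact cutoff of any residue heavy atom, and binding-site
#' membership (minimum distance at or below the binding-site cutoff).
#'
#' @param struct an [read_structure()] result, or a list with `protein` and
#'   `ligand` coordinate data.frames.
#' @param residue_position 1-based residue number in structure numbering.
#' @param offset added to `residue_position` to map variant numbering onto
#'   structure numbering (default 0).
#' @param contact_cutoff contact distance in Angstrom (default 4.0).
#' @param site_cutoff binding-site membership distance in Angstrom
#'   (default 5.0).
#' @return An `interaction_features` list: `min_heavy_atom_distance`,
#'   `contact_count`, `in_binding_site`, `structure_id`.
#' @export
interaction_features <- function(struct, residue_position, offset = 0,
                                 contact_cutoff = 4.0, site_cutoff = 5.0) {
  res <- struct$protein[struct$protein$resno == residue_position + offset, ,
                        drop = FALSE]
  lig <- struct$ligand
  if (nrow(lig) == 0L)
    stop("structure has no ligand heavy atoms", call. = FALSE)
  if (nrow(res) == 0L)
    stop(sprintf("structure-coverage error: residue %d absent from coordinates",
                 residue_position + offset), call. = FALSE)
  rx <- as.matrix(res[, c("x", "y", "z")])
  lx <- as.matrix(lig[, c("x", "y", "z")])
  # all residue-ligand heavy-atom pair distances
  d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
  d <- sqrt(pmax(d2, 0))
  min_d <- min(d)
  structure(list(
    min_heavy_atom_distance = min_d,
    contact_count = sum(apply(d, 2, min) <= contact_cutoff),
    in_binding_site = min_d <= site_cutoff,
    structure_id = struct$structure_id %||% NA_character_
  ), class = "interaction_features")
}
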