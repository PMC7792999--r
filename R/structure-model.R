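# Altloc- and deuterium-aware coordinate model. A structure_model holds one
# atom table shared by >= 1 frames (crystal models or ensemble snapshots).

.known_elements <- c(
  "H", "D", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG",
  "AL", "SI", "P", "S", "CL", "AR", "K", "CA", "MN", "FE", "CO", "NI",
  "CU", "ZN", "SE", "BR", "I", "MO", "W", "CD", "HG")

#' Construct a structure model
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc` (single
#'   character, `""` for none), `resname`, `chain`, `resno` (integer author
#'   numbering), `inscode`, `element` (including `"D"` for deuterium),
#'   `occupancy` in \[0, 1\], `b` (isotropic B, angstrom^2), and a `hetatm`
#'   logical flag.
#' @param xyz coordinates: an n_atoms x 3 matrix (single frame) or an
#'   n_atoms x 3 x n_frames array (ensemble; constant atom table).
#' @param cell unit cell (a, b, c, alpha, beta, gamma) or `NULL`.
#' @param spacegroup space-group label or `NULL`.
#' @param source provenance string.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, cell = NULL, spacegroup = NULL,
                            source = "in-memory") {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "altloc", "resname", "chain", "resno",
            "inscode", "element", "occupancy", "b", "hetatm")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$inscode[is.na(atoms$inscode)] <- ""
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (dim(xyz)[1] != nrow(atoms))
    stop("xyz has ", dim(xyz)[1], " atoms but the atom table has ", nrow(atoms),
         call. = FALSE)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in model", call. = FALSE)
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol for atom serial ",
         atoms$serial[which(!nzchar(atoms$element))[1]], call. = FALSE)
  bad_el <- setdiff(unique(toupper(atoms$element)), .known_elements)
  if (length(bad_el)) stop("unknown element symbol(s): ", paste(bad_el, collapse = ", "),
                           call. = FALSE)
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy outside [0, 1]", call. = FALSE)
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop("duplicate atom key: ", key[duplicated(key)][1], call. = FALSE)
  if (!is.null(cell) && any(cell[1:3] <= 0)) stop("non-positive cell lengths", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz, cell = cell, spacegroup = spacegroup,
                 source = source),
            class = "structure_model")
}

atom_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$inscode, atoms$name, atoms$altloc, sep = "|")

#' Number of frames in a model
#' @param model a `structure_model`.
#' @export
n_frames <- function(model) dim(model$xyz)[3]

#' Number of atoms in a model
#' @param model a `structure_model`.
#' @export
n_atoms <- function(model) dim(model$xyz)[1]

#' Coordinates of one frame (or of selected atoms across frames)
#'
#' @param model a `structure_model`.
#' @param frame frame index (default 1).
#' @param sel optional integer atom indices.
#' @return n x 3 coordinate matrix.
#' @export
coords <- function(model, frame = 1L, sel = NULL) {
  if (frame < 1L || frame > n_frames(model)) stop("frame out of range", call. = FALSE)
  m <- model$xyz[, , frame, drop = FALSE]
  dim(m) <- dim(model$xyz)[1:2]
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Per-frame trace of one atom across all frames
#'
#' @param model a `structure_model`.
#' @param atom single atom index.
#' @return n_frames x 3 matrix.
#' @export
atom_trace <- function(model, atom) {
  stopifnot(length(atom) == 1L)
  t(model$xyz[atom, , ])
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  prot <- !at$hetatm
  cat(sprintf("structure_model: %d atoms, %d frame(s) [%s]\n",
              n_atoms(x), n_frames(x), x$source))
  cat(sprintf("  residues: %d protein, %d hetero (%s)\n",
              length(unique(paste(at$chain, at$resno, at$inscode)[prot])),
              length(unique(paste(at$chain, at$resno, at$inscode)[at$hetatm])),
              paste(unique(at$resname[at$hetatm]), collapse = ", ")))
  if (!is.null(x$spacegroup)) cat("  space group:", x$spacegroup, "\n")
  invisible(x)
}

#' Summarize residue content of a model
#'
#' Counts protein residues, solvent molecules (waters split into those with
#' resolved hydrogen/deuterium and oxygen-only), and hetero ligands/ions.
#'
#' @param model a `structure_model`.
#' @param water_resnames residue names treated as solvent.
#' @return list with counts `protein_residues`, `waters`, `waters_with_d`,
#'   `waters_o_only`, and `ligands` (named counts of other hetero residues).
#' @export
residue_summary <- function(model, water_resnames = c("HOH", "DOD", "WAT")) {
  at <- model$atoms
  rid <- paste(at$chain, at$resno, at$inscode, sep = "|")
  is_wat <- at$resname %in% water_resnames
  wat_ids <- unique(rid[is_wat])
  has_h <- vapply(wat_ids, function(id)
    any(at$element[rid == id & is_wat] %in% c("H", "D")), logical(1))
  prot_ids <- unique(rid[!at$hetatm & !is_wat])
  lig <- at[at$hetatm & !is_wat, , drop = FALSE]
  lig_ids <- unique(paste(lig$resname, lig$chain, lig$resno))
  list(protein_residues = length(prot_ids),
       waters = length(wat_ids),
       waters_with_d = sum(has_h),
       waters_o_only = sum(!has_h),
       ligands = table(vapply(strsplit(lig_ids, " "), `[`, "", 1L)))
}
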