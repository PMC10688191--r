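#' Selected-atom table for the 20 standard residues
#'
#' Residues are treated as rigid bodies described by a small set of selected
#' heavy atoms (backbone N, CA, C, O plus CB, side-chain branch points and
#' terminal heteroatoms; intermediate ring carbons are dropped).  All
#' three-atom angles among the selected atoms of a residue summarize its
#' internal geometry: a residue with k selected atoms yields choose(k, 3)
#' angles, e.g. 35 for TYR's 7-atom selection instead of 220 for its full
#' 12 heavy atoms.
#'
#' @param path Optional path to a YAML file mapping 3-letter residue codes to
#'   ordered atom-name lists, replacing the built-in table.
#' @return Named list of character vectors (atom names in topological order).
#' @examples
#' length(selection_table()$TYR)  # 7
#' @export
selection_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "selection_table.yaml",
                        package = "switchscan", mustWork = TRUE)
  }
  tab <- yaml::read_yaml(path)
  for (res in names(tab)) {
    atoms <- as.character(tab[[res]])
    if (any(atoms %in% c("TRUE", "FALSE", "NA")))
      stop("selection table entry for ", res, " contains a YAML boolean; ",
           'quote atom names (bare N parses as a boolean - write "N")')
    if (anyDuplicated(atoms))
      stop("selection table entry for ", res, " has duplicate atom names")
    if (length(atoms) < 3L)
      stop("selection table entry for ", res, " has fewer than 3 atoms")
    tab[[res]] <- atoms
  }
  tab
}

#' Atoms selected for one residue type
#'
#' @param residue_name 3-letter amino-acid code (case-insensitive).
#' @param table Selection table from [selection_table()].
#' @return Character vector of atom names in topological order
#'   (N, CA, CB, side chain outward, C, O).
#' @examples
#' selected_atoms("TYR")  # N CA CB CG OH C O
#' @export
selected_atoms <- function(residue_name, table = selection_table()) {
  key <- toupper(residue_name)
  if (!key %in% names(table))
    stop("no atom selection for residue '", residue_name,
         "'; known residues: ", paste(names(table), collapse = ", "))
  table[[key]]
}

#' Enumerate the canonical three-atom triplets of a selection
#'
#' Every unordered combination of three selected atoms defines one angle.
#' The triplet is canonicalized by topological order: the middle atom is the
#' vertex of the angle, the outer two are the arms.  Output order is
#' lexicographic in topological indices, so enumeration is deterministic.
#'
#' @param atoms Character vector of atom names in topological order, or a
#'   3-letter residue code (resolved through [selected_atoms()]).
#' @return data.frame with columns `atom_a`, `vertex`, `atom_b`; exactly
#'   choose(k, 3) rows for k atoms.
#' @examples
#' nrow(enumerate_triplets("ALA"))  # 10
#' nrow(enumerate_triplets("ARG"))  # 120
#' @export
enumerate_triplets <- function(atoms) {
  if (is.character(atoms) && length(atoms) == 1L) {
    atoms <- selected_atoms(atoms)  # a single string is a residue code
  }
  k <- length(atoms)
  if (k < 3L) stop("need at least 3 atoms to form a triplet, got ", k)
  idx <- utils::combn(k, 3L)
  data.frame(atom_a = atoms[idx[1L, ]],
             vertex = atoms[idx[2L, ]],
             atom_b = atoms[idx[3L, ]],
             stringsAsFactors = FALSE)
}

#' Number of enumerable angles for a residue type
#'
#' @inheritParams selected_atoms
#' @return choose(k, 3) for the residue's k selected atoms.
#' @export
n_angles <- function(residue_name, table = selection_table()) {
  choose(length(selected_atoms(residue_name, table)), 3L)
}

triplet_id <- function(atom_a, vertex, atom_b) {
  paste(atom_a, vertex, atom_b, sep = "-")
}
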