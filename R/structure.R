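#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

STRUCTURE_COLS <- c(
  "serial", "name", "element", "chain", "resno", "resname",
  "x", "y", "z", "radius", "charge"
)

#' Default van der Waals radii (Angstrom)
#'
#' Bondi-style element radii used for SASA, volume and collision
#' cross-section calculations. Elements absent from the table fall back to
#' the `default` entry (with a warning at parse time).
#'
#' @return Named numeric vector of radii in Angstrom, including a
#'   `default` entry.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    default = 1.70)
}

#' Validate an atom table
#'
#' Checks that a data frame carries the atom columns used throughout the
#' package (`serial`, `name`, `element`, `chain`, `resno`, `resname`,
#' `x`, `y`, `z`, `radius`, `charge`), that radii are positive and that
#' coordinates are finite.
#'
#' @param atoms A data frame of atoms.
#' @return The input, invisibly, as a tibble.
#' @export
validate_structure <- function(atoms) {
  missing <- setdiff(STRUCTURE_COLS, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("empty structure: zero atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite atom coordinates")
  if (any(atoms$radius <= 0)) abort("van der Waals radii must be positive")
  invisible(tibble::as_tibble(atoms))
}

#' Extract the coordinate matrix of an atom table
#'
#' @param atoms Atom tibble (see [validate_structure()]).
#' @return Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @export
atom_coords <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of an atom table
#'
#' @param atoms Atom tibble.
#' @param coords `n x 3` matrix of new coordinates (Angstrom).
#' @return Atom tibble with updated `x`, `y`, `z`.
#' @export
set_atom_coords <- function(atoms, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(atoms), ncol(coords) == 3)
  atoms$x <- coords[, 1]
  atoms$y <- coords[, 2]
  atoms$z <- coords[, 3]
  atoms
}

#' Net formal charge of a structure
#'
#' @param atoms Atom tibble with a `charge` column (elementary charges per
#'   atom; by convention the residue formal charge is stored on one atom of
#'   the charged group).
#' @return Integer net charge in elementary charges.
#' @export
net_charge <- function(atoms) {
  as.integer(round(sum(atoms$charge)))
}

#' Chain identifiers of a structure
#'
#' @param atoms Atom tibble.
#' @return Character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(atoms) {
  unique(atoms$chain)
}

#' Per-chain residue sequences
#'
#' @param atoms Atom tibble.
#' @return Named list (one element per chain) of 3-letter residue codes in
#'   residue-number order.
#' @export
chain_sequences <- function(atoms) {
  res <- atoms %>%
    dplyr::distinct(.data$chain, .data$resno, .data$resname) %>%
    dplyr::arrange(.data$chain, .data$resno)
  split(res$resname, res$chain)
}

#' Residue table of a structure
#'
#' One row per residue with chain, residue number and name.
#'
#' @param atoms Atom tibble.
#' @return Tibble with columns `chain`, `resno`, `resname`.
#' @export
residue_table <- function(atoms) {
  atoms %>%
    dplyr::distinct(.data$chain, .data$resno, .data$resname) %>%
    dplyr::arrange(match(.data$chain, chain_ids(atoms)), .data$resno)
}

#' Select atoms by a simple selection expression
#'
#' Supported selections: `"all"`, `"heavy"` (non-hydrogen), `"calpha"`
#' (CA atoms, one per residue), `"chain=X"`, and residue ranges
#' `"resno=a-b"` (1-based, inclusive, applied in every chain). Multiple
#' space-separated clauses are intersected, e.g. `"chain=A resno=69-77"`.
#'
#' @param atoms Atom tibble.
#' @param selection Selection string.
#' @param require_n Minimum number of atoms the caller needs; an error is
#'   raised if fewer match (default 1).
#' @return Ascending integer vector of row indices into `atoms`.
#' @export
select_atoms <- function(atoms, selection = "all", require_n = 1) {
  keep <- rep(TRUE, nrow(atoms))
  for (clause in strsplit(trimws(selection), "\\s+")[[1]]) {
    if (clause == "all") {
      next
    } else if (clause == "heavy") {
      keep <- keep & toupper(atoms$element) != "H"
    } else if (clause == "calpha") {
      keep <- keep & atoms$name == "CA"
    } else if (grepl("^chain=", clause)) {
      keep <- keep & atoms$chain == sub("^chain=", "", clause)
    } else if (grepl("^resno=\\d+-\\d+$", clause)) {
      rng <- as.integer(strsplit(sub("^resno=", "", clause), "-")[[1]])
      keep <- keep & atoms$resno >= rng[1] & atoms$resno <= rng[2]
    } else {
      abort(paste0("malformed selection clause: '", clause, "'"))
    }
  }
  idx <- which(keep)
  if (length(idx) < require_n) {
    abort(paste0("selection '", selection, "' matched ", length(idx),
                 " atom(s); at least ", require_n, " required"))
  }
  idx
}

#' Default protonation-state rules at pH 7
#'
#' Residue-level formal charges implied by side-chain pKa values at neutral
#' pH: aspartate and glutamate carry -1, lysine and arginine +1, histidine
#' 0; every chain additionally gets +1 on its N-terminus and -1 on its
#' C-terminus.
#'
#' @return Named integer vector mapping 3-letter codes to formal charges.
#' @export
default_charge_rules <- function() {
  c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L, HIS = 0L)
}

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Assign solution-state formal charges
#'
#' Sets residue formal charges from a pH-7 rule table
#' ([default_charge_rules()]) plus charged termini (+1 on the first residue
#' of each chain, -1 on the last). The residue charge is stored on the first
#' atom of the residue; all other atoms get 0, so [net_charge()] sums
#' correctly. Idempotent: charges are recomputed from scratch on every call.
#'
#' @param atoms Atom tibble.
#' @param pH Solution pH; only 7 is tabulated (the rule table itself can be
#'   swapped for other conditions).
#' @param rules Named integer vector of residue formal charges.
#' @param termini Logical; add +1/-1 on chain termini (default TRUE).
#' @return Atom tibble with the `charge` column filled in.
#' @export
assign_solution_charges <- function(atoms, pH = 7,
                                    rules = default_charge_rules(),
                                    termini = TRUE) {
  validate_structure(atoms)
  res <- residue_table(atoms)
  unknown <- setdiff(unique(res$resname),
                     union(STANDARD_AA, names(rules)))
  if (length(unknown) > 0) {
    warn(paste0("non-standard residue(s) assigned charge 0: ",
                paste(unknown, collapse = ", ")))
  }
  rq <- ifelse(res$resname %in% names(rules),
               rules[res$resname], 0L)
  if (termini) {
    for (ch in unique(res$chain)) {
      i <- which(res$chain == ch)
      rq[i[1]] <- rq[i[1]] + 1L
      rq[i[length(i)]] <- rq[i[length(i)]] - 1L
    }
  }
  key <- paste(res$chain, res$resno)
  charge_by_res <- stats::setNames(as.integer(rq), key)
  atom_key <- paste(atoms$chain, atoms$resno)
  first_atom <- !duplicated(atom_key)
  atoms$charge <- ifelse(first_atom, charge_by_res[atom_key], 0L)
  atoms$charge <- as.integer(atoms$charge)
  atoms
}

#' Per-residue formal charges
#'
#' @param atoms Atom tibble with charges assigned.
#' @return Tibble `chain`, `resno`, `resname`, `charge` (sum over the
#'   residue's atoms).
#' @export
residue_charges <- function(atoms) {
  atoms %>%
    dplyr::group_by(.data$chain, .data$resno, .data$resname) %>%
    dplyr::summarise(charge = as.integer(sum(.data$charge)),
                     .groups = "drop") %>%
    dplyr::arrange(match(.data$chain, chain_ids(atoms)), .data$resno)
}
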