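#' Construct an atom table
#'
#' The atom table is the static half of a trajectory: one row per atom with
#' its identity (name, element), residue membership and mass. Residue names
#' follow the generator's convention (\code{DPPS}, \code{DPPG}, \code{SOL},
#' \code{NA}) but any names are accepted; waters are recognised by
#' \code{water_residues}.
#'
#' @param atom_name character vector of atom names
#' @param element character vector of element symbols
#' @param residue_name character vector of residue names
#' @param residue_id integer vector of residue indices
#' @param mass atomic masses in amu; looked up from \code{element} if NULL
#' @param atom_id integer ids; defaults to \code{1:n}. Must be unique and
#'   contiguous starting at 1.
#' @param validate check invariants (unique contiguous ids, positive masses,
#'   waters with exactly one O and two H)
#' @return a \code{data.frame} of class \code{atom_table}
#' @export
atom_table <- function(atom_name, element, residue_name, residue_id,
                       mass = NULL, atom_id = NULL, validate = TRUE) {
  n <- length(atom_name)
  if (is.null(atom_id)) atom_id <- seq_len(n)
  if (is.null(mass)) mass <- element_mass(element)
  at <- data.frame(
    atom_id = as.integer(atom_id),
    atom_name = as.character(atom_name),
    element = as.character(element),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    mass = as.numeric(mass),
    stringsAsFactors = FALSE
  )
  class(at) <- c("atom_table", "data.frame")
  if (validate) validate_atom_table(at)
  at
}

#' Residue names treated as water
#' @export
water_residues <- c("SOL", "HOH", "TIP3", "WAT")

validate_atom_table <- function(at) {
  n <- nrow(at)
  if (anyDuplicated(at$atom_id))
    stop("atom_ids must be unique (duplicate id ",
         at$atom_id[anyDuplicated(at$atom_id)], ")")
  if (!identical(sort(at$atom_id), seq_len(n)))
    stop("atom_ids must be contiguous 1..n")
  if (any(!is.finite(at$mass)) || any(at$mass <= 0))
    stop("every atom must have a positive mass")
  wat <- at[at$residue_name %in% water_residues, ]
  if (nrow(wat)) {
    tab <- table(wat$residue_id, wat$element)
    if (!("O" %in% colnames(tab)) || !("H" %in% colnames(tab)) ||
        any(tab[, "O"] != 1L) || any(tab[, "H"] != 2L))
      stop("water residues must contain exactly 1 O and 2 H atoms")
  }
  invisible(at)
}

#' @export
print.atom_table <- function(x, ...) {
  cat(sprintf("<atom_table> %d atoms, %d residues (%s)\n",
              nrow(x), length(unique(x$residue_id)),
              paste(names(sort(table(x$residue_name), decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param coords n x 3 numeric matrix of positions in nm
#' @param box orthorhombic edge lengths (Lx, Ly, Lz) in nm
#' @param time frame time in ps
#' @return object of class \code{md_frame}
#' @export
md_frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory
#'
#' @param atoms an \code{atom_table}
#' @param frames list of \code{md_frame}s sharing the atom table
#' @param timestep nominal spacing between frames, ps
#' @return object of class \code{md_trajectory}
#' @export
md_trajectory <- function(atoms, frames, timestep = NA_real_) {
  stopifnot(inherits(atoms, "atom_table"))
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- nrow(atoms)
  for (f in frames) {
    if (!inherits(f, "md_frame")) stop("frames must be md_frame objects")
    if (nrow(f$coords) != n)
      stop("frame coordinate count (", nrow(f$coords),
           ") does not match atom table (", n, ")")
  }
  tms <- vapply(frames, `[[`, numeric(1), "time")
  if (length(tms) > 1 && any(diff(tms) <= 0))
    stop("frame times must be strictly increasing")
  if (is.na(timestep) && length(tms) > 1) timestep <- diff(tms)[1]
  structure(list(atoms = atoms, frames = frames, timestep = timestep),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms x %d frames (dt = %s ps)\n",
              nrow(x$atoms), length(x$frames), format(x$timestep)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{md_trajectory}
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)

#' Select atoms by attribute
#'
#' Returns integer indices into the atom table; every supplied filter is
#' combined with AND. This is the light-weight selection used across all
#' analysis functions.
#'
#' @param atoms an \code{atom_table} or \code{md_trajectory}
#' @param residue_name,atom_name,element optional character filters
#' @param residue_id optional integer filter
#' @param label selection label carried on the result
#' @return integer vector with attribute \code{label}
#' @export
select_atoms <- function(atoms, residue_name = NULL, atom_name = NULL,
                         element = NULL, residue_id = NULL,
                         label = NULL) {
  if (inherits(atoms, "md_trajectory")) atoms <- atoms$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(residue_name)) keep <- keep & atoms$residue_name %in% residue_name
  if (!is.null(atom_name)) keep <- keep & atoms$atom_name %in% atom_name
  if (!is.null(element)) keep <- keep & atoms$element %in% element
  if (!is.null(residue_id)) keep <- keep & atoms$residue_id %in% residue_id
  idx <- which(keep)
  attr(idx, "label") <- label %||%
    paste(c(residue_name, atom_name, element), collapse = "/")
  idx
}

check_selection <- function(idx, atoms, what = "selection") {
  if (!length(idx)) stop(what, " is empty")
  if (anyDuplicated(idx)) stop(what, " contains duplicate indices")
  if (any(idx < 1L | idx > nrow(atoms))) stop(what, " has out-of-range indices")
  invisible(idx)
}

#' Water oxygen selection helper
#' @param atoms an \code{atom_table} or \code{md_trajectory}
#' @return indices of water oxygen atoms
#' @export
select_water_oxygens <- function(atoms) {
  select_atoms(atoms, residue_name = water_residues, element = "O",
               label = "water O")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract coordinates of a selection as a frames x atoms x 3 array
#'
#' @param traj an \code{md_trajectory}
#' @param selection integer atom indices (default: all atoms)
#' @return numeric array \code{[frame, atom, xyz]}
#' @export
coords_array <- function(traj, selection = NULL) {
  sel <- selection %||% seq_len(nrow(traj$atoms))
  nf <- n_frames(traj)
  arr <- array(NA_real_, dim = c(nf, length(sel), 3))
  for (i in seq_len(nf)) arr[i, , ] <- traj$frames[[i]]$coords[sel, , drop = FALSE]
  arr
}
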