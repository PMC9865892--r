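#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Computes the displacement \code{b - a} wrapped so that every component
#' lies in \code{(-L/2, L/2]}. Inputs may be single positions (length-3
#' vectors) or n x 3 matrices.
#'
#' @param a,b positions in nm
#' @param box orthorhombic edge lengths (Lx, Ly, Lz), nm
#' @return displacement vector or n x 3 matrix
#' @export
minimum_image <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must have three positive edge lengths")
  va <- is.null(dim(a)); vb <- is.null(dim(b))
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("a and b must have matching row counts")
  out <- cpp_min_image(a, b, box)
  if (va && vb) drop(out) else out
}

#' Wrap coordinates into the primary periodic cell
#'
#' Maps each coordinate into \code{[origin, origin + L)} per axis. Analyses
#' that histogram positions call this internally so that trajectories stored
#' unwrapped (as the generator writes them, for diffusion) remain valid input.
#'
#' @param coords n x 3 matrix, nm
#' @param box edge lengths, nm
#' @param origin lower corner of the cell; defaults to \code{-box/2}
#'   (bilayer midplane centred at z = 0)
#' @return wrapped n x 3 matrix
#' @export
wrap_coords <- function(coords, box, origin = -box / 2) {
  box <- as.numeric(box)
  out <- coords
  for (k in 1:3) {
    out[, k] <- origin[k] + (coords[, k] - origin[k]) %% box[k]
  }
  out
}

#' Unwrap a trajectory across periodic boundaries
#'
#' Reconstructs continuous atom paths from wrapped coordinates by adding
#' box-length image offsets whenever an atom jumps by more than half a box
#' between consecutive frames. Per-atom image counters are carried along,
#' so Einstein-relation diffusion estimates are meaningful afterwards.
#'
#' @param traj an \code{md_trajectory} with wrapped coordinates
#' @return an \code{md_trajectory} with unwrapped coordinates
#' @export
unwrap_trajectory <- function(traj) {
  nf <- n_frames(traj)
  if (nf < 2) return(traj)
  frames <- traj$frames
  images <- matrix(0, nrow(traj$atoms), 3)  # per-atom image counters
  prev <- frames[[1]]$coords
  for (i in 2:nf) {
    box <- frames[[i]]$box
    raw <- frames[[i]]$coords
    step <- raw + images %*% diag(box) - prev
    jump <- round(sweep(step, 2, box, "/"))
    images <- images - jump
    frames[[i]]$coords <- raw + images %*% diag(box)
    prev <- frames[[i]]$coords
  }
  traj$frames <- frames
  traj
}

#' Wrap all frames of a trajectory into the primary cell
#' @param traj an \code{md_trajectory}
#' @param origin passed to [wrap_coords()]
#' @return wrapped trajectory
#' @export
wrap_trajectory <- function(traj, origin = NULL) {
  traj$frames <- lapply(traj$frames, function(f) {
    f$coords <- wrap_coords(f$coords, f$box, origin %||% (-f$box / 2))
    f
  })
  traj
}

#' Assign lipids to leaflets
#'
#' Splits lipids into an upper and a lower leaflet by the z coordinate of a
#' reference atom (default the phosphorus pseudo-atom) relative to the
#' bilayer midplane, taken as the mean reference-atom z. The assignment is
#' invariant under rigid z-translation of the whole system.
#'
#' @param frame an \code{md_frame}
#' @param atoms the matching \code{atom_table}
#' @param lipid_selection indices of lipid atoms (any atoms of the lipids to
#'   classify); their residues define the lipid set
#' @param ref_atom_name name of the reference atom within each lipid
#' @param midplane bilayer midplane z; defaults to the mean reference-atom z
#' @return named character vector "upper"/"lower", names = lipid residue_id
#' @export
assign_leaflets <- function(frame, atoms, lipid_selection,
                            ref_atom_name = "P", midplane = NULL) {
  check_selection(lipid_selection, atoms, "lipid_selection")
  lip_res <- unique(atoms$residue_id[lipid_selection])
  ref <- which(atoms$residue_id %in% lip_res & atoms$atom_name == ref_atom_name)
  if (!length(ref))
    stop("no atoms named '", ref_atom_name, "' in the lipid selection")
  z <- frame$coords[ref, 3]
  mid <- midplane %||% mean(z)
  lab <- ifelse(z > mid, "upper", "lower")
  if (length(unique(lab)) == 1L)
    warning("all reference atoms on one side of the midplane; ",
            "single leaflet assigned")
  names(lab) <- atoms$residue_id[ref]
  lab
}

# bilayer midplane: mean z of P atoms if present, else box centre of mass z
bilayer_midplane <- function(frame, atoms) {
  p <- which(atoms$atom_name == "P")
  if (length(p)) mean(frame$coords[p, 3]) else
    stats::weighted.mean(frame$coords[, 3], atoms$mass)
}
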