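#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair counts as hydrogen bonded when the donor-acceptor
#' distance is below \code{distance} and the hydrogen-donor-acceptor angle
#' (vertex at the donor) is below \code{angle}. The alternative
#' donor-H...acceptor convention is deliberately not used.
#'
#' @param distance maximum donor-acceptor distance, nm
#' @param angle maximum H-donor-acceptor angle, degrees
#' @return object of class \code{hbond_criteria}
#' @export
hbond_criteria <- function(distance = 0.3, angle = 30) {
  if (distance <= 0) stop("distance cutoff must be positive")
  if (angle <= 0 || angle >= 90) stop("angle cutoff must lie in (0, 90)")
  structure(list(distance = distance, angle = angle),
            class = "hbond_criteria")
}

#' Default donor table: O/N heavy atoms with their bound hydrogens
#'
#' Bound hydrogens are inferred from the generator's naming convention
#' (waters: OW with HW1/HW2; lipid ammonium: N with HN1..HN3; any OG-type
#' hydroxyl with matching HG name). For real topologies supply an explicit
#' two-column data.frame (donor, hydrogen) of atom indices.
#'
#' @param atoms an [atom_table()]
#' @return data.frame with integer columns \code{donor} and \code{hydrogen}
#' @export
default_donor_table <- function(atoms) {
  out <- list()
  # waters
  ow <- which(atoms$atom_name == "OW")
  if (length(ow)) {
    hw <- which(atoms$atom_name %in% c("HW1", "HW2"))
    m <- split(hw, atoms$residue_id[hw])
    res <- as.character(atoms$residue_id[ow])
    out[[1]] <- data.frame(donor = rep(ow, lengths(m[res])),
                           hydrogen = unlist(m[res], use.names = FALSE))
  }
  # lipid ammonium N-H3
  nn <- which(atoms$atom_name == "N")
  if (length(nn)) {
    hn <- which(grepl("^HN", atoms$atom_name))
    m <- split(hn, atoms$residue_id[hn])
    res <- as.character(atoms$residue_id[nn])
    keep <- res %in% names(m)
    out[[2]] <- data.frame(donor = rep(nn[keep], lengths(m[res[keep]])),
                           hydrogen = unlist(m[res[keep]], use.names = FALSE))
  }
  dt <- do.call(rbind, out)
  if (is.null(dt)) data.frame(donor = integer(0), hydrogen = integer(0))
  else dt
}

#' Default acceptor selection: all O and N atoms
#' @param atoms an [atom_table()]
#' @return integer atom indices
#' @export
default_acceptors <- function(atoms) {
  select_atoms(atoms, element = c("O", "N"), label = "O/N acceptors")
}

#' Detect hydrogen bonds in one frame
#'
#' Finds all (donor, hydrogen, acceptor) triples satisfying the geometric
#' criteria under minimum-image distances. A donor may bond to several
#' acceptors, and each of its hydrogens is tested independently.
#'
#' @param frame an [md_frame()]
#' @param atoms the matching [atom_table()]
#' @param donors two-column data.frame (donor, hydrogen) of atom indices;
#'   defaults to [default_donor_table()]
#' @param acceptors acceptor atom indices; defaults to [default_acceptors()]
#' @param criteria an [hbond_criteria()]
#' @return data.frame with \code{donor}, \code{hydrogen}, \code{acceptor},
#'   \code{distance} (nm), \code{angle} (degrees)
#' @export
detect_hbonds <- function(frame, atoms, donors = NULL, acceptors = NULL,
                          criteria = hbond_criteria()) {
  donors <- donors %||% default_donor_table(atoms)
  acceptors <- acceptors %||% default_acceptors(atoms)
  if (!nrow(donors)) stop("donor table is empty")
  if (anyNA(donors$hydrogen))
    stop("donor without hydrogens: atom ",
         donors$donor[which(is.na(donors$hydrogen))[1]])
  check_selection(acceptors, atoms, "acceptors")
  co <- wrap_coords(frame$coords, frame$box)
  dset <- sort(unique(donors$donor))
  pr <- cpp_pairs_within(co[dset, , drop = FALSE],
                         co[acceptors, , drop = FALSE],
                         frame$box, criteria$distance)
  if (!length(pr$i))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  d_atom <- dset[pr$i]
  a_atom <- acceptors[pr$j]
  keep <- d_atom != a_atom & pr$d < criteria$distance  # strict cutoff
  d_atom <- d_atom[keep]; a_atom <- a_atom[keep]; dd <- pr$d[keep]
  if (!length(d_atom))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  # expand over the hydrogens of each donor
  hs <- split(donors$hydrogen, donors$donor)
  hlist <- hs[as.character(d_atom)]
  reps <- lengths(hlist)
  di <- rep(d_atom, reps); ai <- rep(a_atom, reps); dd <- rep(dd, reps)
  hi <- unlist(hlist, use.names = FALSE)
  vh <- cpp_min_image(co[di, , drop = FALSE], co[hi, , drop = FALSE],
                      frame$box)
  va <- cpp_min_image(co[di, , drop = FALSE], co[ai, , drop = FALSE],
                      frame$box)
  cosang <- rowSums(vh * va) /
    pmax(sqrt(rowSums(vh^2)) * sqrt(rowSums(va^2)), .Machine$double.eps)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- ang < criteria$angle
  data.frame(donor = di[ok], hydrogen = hi[ok], acceptor = ai[ok],
             distance = dd[ok], angle = ang[ok])
}

#' Default lipid-moiety group map
#'
#' Assigns lipid oxygen atoms to the chemical moieties used to classify
#' water-lipid hydrogen bonds: phosphate (PO2: OP1/OP2), ester carbonyl
#' (C=O: OE1/OE2), carboxylate (COO: OC1/OC2) and glycerol (OG1/OG2).
#'
#' @param atoms an [atom_table()]
#' @return named list of integer atom-index vectors
#' @export
default_group_map <- function(atoms) {
  lip <- atoms$residue_name %in% c("DPPS", "DPPG")
  list(
    PO2 = which(lip & atoms$atom_name %in% c("OP1", "OP2")),
    `C=O` = which(lip & atoms$atom_name %in% c("OE1", "OE2")),
    COO = which(lip & atoms$atom_name %in% c("OC1", "OC2")),
    glycerol = which(lip & atoms$atom_name %in% c("OG1", "OG2"))
  )
}

#' Hydrogen-bond counts by chemical class
#'
#' Frame-resolved hydrogen-bond counts for the class pairs lipid-lipid,
#' water-water, water-lipid and water-moiety (phosphate, carbonyl,
#' carboxylate, glycerol; subsets of water-lipid), with frame means and
#' SDs. Lipid-lipid bonds within one molecule are excluded by default.
#' Per-molecule normalisations (lipid-lipid / lipid count, water-water /
#' water count) are included.
#'
#' @param traj an [md_trajectory()]
#' @param criteria an [hbond_criteria()]
#' @param group_map named list of lipid-moiety atom indices; defaults to
#'   [default_group_map()]
#' @param donors,acceptors as in [detect_hbonds()]
#' @param exclude_intramolecular drop lipid-lipid bonds within one residue
#' @param frames frame window
#' @return an \code{hbond_report}: list with \code{per_frame} (data.frame),
#'   \code{summary} (class, mean, sd, per_molecule) and counts metadata
#' @export
count_by_class <- function(traj, criteria = hbond_criteria(),
                           group_map = NULL, donors = NULL, acceptors = NULL,
                           exclude_intramolecular = TRUE, frames = NULL) {
  atoms <- traj$atoms
  frames <- frames %||% seq_len(n_frames(traj))
  group_map <- group_map %||% default_group_map(atoms)
  donors <- donors %||% default_donor_table(atoms)
  acceptors <- acceptors %||% default_acceptors(atoms)
  is_wat <- atoms$residue_name %in% water_residues
  is_lip <- atoms$residue_name %in% c("DPPS", "DPPG")
  n_lip <- length(unique(atoms$residue_id[is_lip]))
  n_wat <- length(unique(atoms$residue_id[is_wat]))
  classes <- c("lipid-lipid", "water-water", "water-lipid",
               paste0("water-", names(group_map)))
  per <- matrix(0, length(frames), length(classes),
                dimnames = list(NULL, classes))
  for (k in seq_along(frames)) {
    hb <- detect_hbonds(traj$frames[[frames[k]]], atoms, donors, acceptors,
                        criteria)
    dw <- is_wat[hb$donor]; aw <- is_wat[hb$acceptor]
    dl <- is_lip[hb$donor]; al <- is_lip[hb$acceptor]
    ll <- dl & al
    if (exclude_intramolecular)
      ll <- ll & atoms$residue_id[hb$donor] != atoms$residue_id[hb$acceptor]
    per[k, "lipid-lipid"] <- sum(ll)
    per[k, "water-water"] <- sum(dw & aw)
    wl <- (dw & al) | (dl & aw)
    per[k, "water-lipid"] <- sum(wl)
    for (g in names(group_map)) {
      gi <- group_map[[g]]
      per[k, paste0("water-", g)] <-
        sum(wl & (hb$acceptor %in% gi | hb$donor %in% gi))
    }
  }
  means <- colMeans(per)
  sds <- apply(per, 2, stats::sd)
  per_mol <- rep(NA_real_, length(classes))
  names(per_mol) <- classes
  if (n_lip > 0)
    per_mol["lipid-lipid"] <- normalize_per_molecule(means["lipid-lipid"],
                                                     n_lip)$value
  if (n_wat > 0)
    per_mol["water-water"] <- normalize_per_molecule(means["water-water"],
                                                     n_wat)$value
  structure(list(
    per_frame = data.frame(frame = frames, per, check.names = FALSE),
    summary = data.frame(class = classes, mean = unname(means),
                         sd = unname(sds), per_molecule = unname(per_mol)),
    n_lipids = n_lip, n_waters = n_wat, criteria = criteria),
    class = "hbond_report")
}

#' Normalise a bond count per molecule
#'
#' @param total_count total number of bonds
#' @param n_molecules number of molecules (> 0)
#' @return list with \code{value} (exact quotient) and \code{value_2dp}
#'   (rounded to two decimals, as conventionally reported)
#' @export
normalize_per_molecule <- function(total_count, n_molecules) {
  if (n_molecules <= 0) stop("n_molecules must be positive")
  v <- total_count / n_molecules
  list(value = unname(v), value_2dp = round(unname(v), 2))
}

#' Cation contacts with a lipid group
#'
#' Per-frame count of ion-atom pairs within the cutoff (default 0.32 nm,
#' a typical first-shell minimum for Na+ against oxygen), with frame mean
#' and SD.
#'
#' @param traj an [md_trajectory()]
#' @param ion_selection cation atom indices (default: residue "NA")
#' @param group_selection lipid-group atom indices (default: carboxylate O)
#' @param cutoff contact distance, nm
#' @param frames frame window
#' @return list with \code{per_frame}, \code{mean}, \code{sd}
#' @export
ion_contacts <- function(traj, ion_selection = NULL, group_selection = NULL,
                         cutoff = 0.32, frames = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ion_selection <- ion_selection %||%
    select_atoms(traj, residue_name = "NA", label = "cations")
  group_selection <- group_selection %||% default_group_map(traj$atoms)$COO
  check_selection(ion_selection, traj$atoms, "ion_selection")
  check_selection(group_selection, traj$atoms, "group_selection")
  frames <- frames %||% seq_len(n_frames(traj))
  cnt <- vapply(frames, function(fi) {
    f <- traj$frames[[fi]]
    pr <- cpp_pairs_within(
      wrap_coords(f$coords[ion_selection, , drop = FALSE], f$box),
      wrap_coords(f$coords[group_selection, , drop = FALSE], f$box),
      f$box, cutoff)
    length(pr$i)
  }, numeric(1))
  list(per_frame = data.frame(frame = frames, contacts = cnt),
       mean = mean(cnt), sd = stats::sd(cnt))
}
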