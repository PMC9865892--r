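#' Radial distribution function
#'
#' Minimum-image pair-distance histogram between a reference and a target
#' selection, normalised by the spherical shell volume and the target bulk
#' number density, averaged over frames. For an ideal gas g(r) tends to 1.
#'
#' @param traj an [md_trajectory()]
#' @param ref_selection,target_selection integer atom indices
#' @param r_max histogram range, nm; must not exceed half the smallest box
#'   edge
#' @param dr bin width, nm
#' @param frames frame window
#' @return an \code{rdf_result}: data.frame with \code{r} (bin centre) and
#'   \code{g}; selections and parameters in attributes
#' @export
rdf <- function(traj, ref_selection, target_selection, r_max = 1.0,
                dr = 0.002, frames = NULL) {
  check_selection(ref_selection, traj$atoms, "ref_selection")
  check_selection(target_selection, traj$atoms, "target_selection")
  frames <- frames %||% seq_len(n_frames(traj))
  nb <- ceiling(r_max / dr)
  acc <- numeric(nb)
  denom <- 0
  same <- identical(sort(ref_selection), sort(target_selection))
  for (fi in frames) {
    f <- traj$frames[[fi]]
    if (r_max > min(f$box) / 2)
      stop("r_max (", r_max, ") exceeds half the smallest box edge (",
           round(min(f$box) / 2, 3), ")")
    A <- wrap_coords(f$coords[ref_selection, , drop = FALSE], f$box)
    B <- wrap_coords(f$coords[target_selection, , drop = FALSE], f$box)
    acc <- acc + cpp_dist_hist(A, B, f$box, r_max, nb,
                               exclude_same_index = same)
    rho <- (length(target_selection) - if (same) 1 else 0) / prod(f$box)
    denom <- denom + length(ref_selection) * rho
  }
  edges <- seq(0, nb) * dr
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- acc / (denom * shell)
  out <- data.frame(r = (edges[-1] + edges[-(nb + 1)]) / 2, g = g)
  class(out) <- c("rdf_result", "data.frame")
  attr(out, "r_max") <- r_max
  attr(out, "dr") <- dr
  attr(out, "ref_label") <- attr(ref_selection, "label")
  attr(out, "target_label") <- attr(target_selection, "label")
  attr(out, "counts") <- acc
  attr(out, "n_frames") <- length(frames)
  out
}

#' First-shell water selection
#'
#' Waters whose oxygen lies within \code{cutoff} (minimum image) of any
#' reference atom; 0.3 nm is the first minimum of the water-oxygen RDF
#' around lipid headgroups and hence the edge of the first hydration shell.
#'
#' @param frame an [md_frame()]
#' @param atoms the matching [atom_table()]
#' @param ref_selection reference atom indices
#' @param cutoff shell radius, nm
#' @return indices of water oxygen atoms inside the shell
#' @export
shell_waters <- function(frame, atoms, ref_selection, cutoff = 0.3) {
  check_selection(ref_selection, atoms, "ref_selection")
  ow <- select_water_oxygens(atoms)
  if (!length(ow)) stop("no water oxygens in the system")
  O <- wrap_coords(frame$coords[ow, , drop = FALSE], frame$box)
  R <- wrap_coords(frame$coords[ref_selection, , drop = FALSE], frame$box)
  nn <- cpp_nearest(O, R, frame$box)
  idx <- ow[nn$distance <= cutoff]
  attr(idx, "label") <- sprintf("shell waters (<= %g nm)", cutoff)
  idx
}

# per-water O index, H indices, O coords, dipole (O -> H-midpoint) vectors
water_vectors <- function(frame, atoms, ow = NULL) {
  ow <- ow %||% select_water_oxygens(atoms)
  key <- paste(atoms$residue_id, atoms$element)
  h_all <- which(atoms$residue_name %in% water_residues & atoms$element == "H")
  hs <- split(h_all, atoms$residue_id[h_all])
  res <- as.character(atoms$residue_id[ow])
  if (any(lengths(hs[res]) != 2L))
    stop("water residue without exactly 2 hydrogens")
  h1 <- vapply(hs[res], `[`, integer(1), 1)
  h2 <- vapply(hs[res], `[`, integer(1), 2)
  O <- frame$coords[ow, , drop = FALSE]
  mid <- (frame$coords[h1, , drop = FALSE] +
            frame$coords[h2, , drop = FALSE]) / 2
  list(ow = ow, O = O, dipole = mid - O)
}

#' Angular distribution of first-shell waters
#'
#' For each shell water, v1 points from the nearest reference heavy atom to
#' the water oxygen and v2 from the oxygen to the midpoint of its two
#' hydrogens; the histogram of cos(theta) between v1 and v2 is averaged
#' over frames. Randomly oriented waters give a flat density; interfacial
#' ordering concentrates the density (around cos 130 deg = -0.64 for
#' headgroup-oriented water).
#'
#' @param traj an [md_trajectory()]
#' @param ref_selection reference (headgroup) atom indices; defaults to
#'   [select_headgroup_atoms()]
#' @param cutoff first-shell radius, nm
#' @param n_bins histogram bins on \[-1, 1\]
#' @param frames frame window
#' @return data.frame with \code{cos_theta} (bin centre) and \code{density}
#'   (integrates to 1)
#' @export
angular_distribution <- function(traj, ref_selection = NULL, cutoff = 0.3,
                                 n_bins = 40L, frames = NULL) {
  ref_selection <- ref_selection %||% select_headgroup_atoms(traj$atoms)
  check_selection(ref_selection, traj$atoms, "ref_selection")
  frames <- frames %||% seq_len(n_frames(traj))
  edges <- seq(-1, 1, length.out = n_bins + 1)
  acc <- numeric(n_bins)
  for (fi in frames) {
    ct <- costheta_of_frame(traj$frames[[fi]], traj$atoms, ref_selection)
    keep <- ct$distance <= cutoff
    h <- graphics::hist(ct$cos_theta[keep], breaks = edges, plot = FALSE)
    acc <- acc + h$counts
  }
  total <- sum(acc)
  if (total == 0) stop("no waters found inside the shell cutoff")
  width <- diff(edges)[1]
  data.frame(cos_theta = (edges[-1] + edges[-(n_bins + 1)]) / 2,
             density = acc / (total * width))
}

# cos(theta) + distance to nearest reference atom for every water in a frame
costheta_of_frame <- function(frame, atoms, ref_selection) {
  wv <- water_vectors(frame, atoms)
  O <- wrap_coords(wv$O, frame$box)
  R <- wrap_coords(frame$coords[ref_selection, , drop = FALSE], frame$box)
  nn <- cpp_nearest(O, R, frame$box)
  v1 <- cpp_min_image(R[nn$index, , drop = FALSE], O, frame$box)
  v2 <- wv$dipole
  ct <- rowSums(v1 * v2) /
    pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), .Machine$double.eps)
  list(cos_theta = pmin(1, pmax(-1, ct)), distance = nn$distance, ow = wv$ow)
}

#' Water orientation versus distance from the membrane
#'
#' Mean cos(theta) binned by the distance of each water oxygen to the
#' nearest reference atom, plus the cumulative sum of per-water cos(theta)
#' over distance-ordered waters (whose final value is the total sum over
#' all waters). Both are averaged over frames.
#'
#' @inheritParams angular_distribution
#' @param r_max largest distance binned, nm
#' @param dr distance bin width, nm
#' @return list with \code{profile} (data.frame r, mean_cos_theta, n) and
#'   \code{cumulative} (data.frame r, cum_cos_theta)
#' @export
costheta_vs_distance <- function(traj, ref_selection = NULL, r_max = NULL,
                                 dr = 0.05, frames = NULL) {
  ref_selection <- ref_selection %||% select_headgroup_atoms(traj$atoms)
  check_selection(ref_selection, traj$atoms, "ref_selection")
  frames <- frames %||% seq_len(n_frames(traj))
  r_max <- r_max %||% (max(vapply(traj$frames[frames],
                                  function(f) f$box[3], numeric(1))) / 2)
  nb <- ceiling(r_max / dr)
  edges <- seq(0, nb) * dr
  sum_ct <- n_ct <- numeric(nb)
  for (fi in frames) {
    ct <- costheta_of_frame(traj$frames[[fi]], traj$atoms, ref_selection)
    bi <- findInterval(ct$distance, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb
    s <- rowsum(ct$cos_theta[ok], bi[ok])
    ids <- as.integer(rownames(s))
    sum_ct[ids] <- sum_ct[ids] + s[, 1]
    n_ct[ids] <- n_ct[ids] + tabulate(bi[ok], nb)[ids]
  }
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  profile <- data.frame(r = centers,
                        mean_cos_theta = ifelse(n_ct > 0, sum_ct / n_ct, NA),
                        n = n_ct)
  cumulative <- data.frame(r = edges[-1],
                           cum_cos_theta = cumsum(sum_ct) / length(frames))
  list(profile = profile, cumulative = cumulative)
}

#' Water dipole tilt profile along the membrane normal
#'
#' Mean cosine of the angle phi between each water dipole (O to H-midpoint
#' direction) and the +z axis, binned by the water oxygen's z coordinate
#' (centred on the bilayer midplane), averaged over frames.
#'
#' @param traj an [md_trajectory()]
#' @param bin_width z-bin width, nm
#' @param frames frame window
#' @return data.frame with \code{z} (bin centre) and \code{mean_cos_phi}
#' @export
dipole_tilt_profile <- function(traj, bin_width = 0.1, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  zmax <- max(vapply(traj$frames[frames], function(f) f$box[3], numeric(1))) / 2
  nb <- ceiling(2 * zmax / bin_width)
  edges <- seq(-nb / 2, nb / 2) * bin_width
  sum_c <- n_c <- numeric(nb)
  for (fi in frames) {
    f <- traj$frames[[fi]]
    wv <- water_vectors(f, traj$atoms)
    mid <- bilayer_midplane(f, traj$atoms)
    z <- wv$O[, 3] - mid
    z <- z - f$box[3] * round(z / f$box[3])
    cphi <- wv$dipole[, 3] / sqrt(rowSums(wv$dipole^2))
    bi <- findInterval(z, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb
    s <- rowsum(cphi[ok], bi[ok])
    ids <- as.integer(rownames(s))
    sum_c[ids] <- sum_c[ids] + s[, 1]
    n_c[ids] <- n_c[ids] + tabulate(bi[ok], nb)[ids]
  }
  data.frame(z = (edges[-1] + edges[-(nb + 1)]) / 2,
             mean_cos_phi = ifelse(n_c > 0, sum_c / n_c, NA),
             n = n_c)
}

#' Water self-diffusion coefficient (Einstein relation)
#'
#' Three-dimensional mean square displacement of the selected water
#' oxygens over multiple time origins; D is the fitted slope divided by 6
#' on the configured lag window (default 10-50\% of the trajectory).
#' Requires unwrapped coordinates.
#'
#' @param traj an [md_trajectory()] with unwrapped coordinates
#' @param water_selection water oxygen indices (default: all water O)
#' @param lag_window,n_lags fit-window configuration
#' @return a \code{diffusion_estimate}: list with \code{D_cm2s},
#'   \code{D_nm2ps}, standard errors, the MSD curve and fit window
#' @export
water_diffusion <- function(traj, water_selection = NULL,
                            lag_window = c(0.1, 0.5), n_lags = 25L) {
  water_selection <- water_selection %||% select_water_oxygens(traj$atoms)
  check_selection(water_selection, traj$atoms, "water_selection")
  arr <- coords_array(traj, water_selection)
  check_unwrapped(arr, traj$frames[[1]]$box)
  dt <- traj$timestep
  if (is.na(dt)) stop("trajectory has no timestep")
  fit <- einstein_fit(arr, dt, dims = 1:3, lag_window = lag_window,
                      n_lags = n_lags)
  structure(c(list(D_cm2s = nm2ps_to_cm2s(fit$D_nm2ps),
                   D_nm2ps = fit$D_nm2ps,
                   D_se_cm2s = nm2ps_to_cm2s(fit$D_se_nm2ps)),
              fit[c("msd", "lag_window")]),
            class = "diffusion_estimate")
}
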