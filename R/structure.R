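#' Area per lipid time series
#'
#' APL per frame is the box cross-section Lx * Ly divided by the number of
#' lipids in one leaflet.
#'
#' @param traj an [md_trajectory()]
#' @param lipids_per_leaflet lipids in one leaflet
#' @param frames integer frame window (default: all frames)
#' @return list with \code{series} (data.frame time, apl), \code{mean},
#'   \code{sd} (nm^2)
#' @export
area_per_lipid <- function(traj, lipids_per_leaflet, frames = NULL) {
  if (lipids_per_leaflet <= 0) stop("lipids_per_leaflet must be positive")
  frames <- frames %||% seq_len(n_frames(traj))
  if (!length(frames)) stop("frame window is empty")
  apl <- vapply(traj$frames[frames],
                function(f) f$box[1] * f$box[2] / lipids_per_leaflet,
                numeric(1))
  tms <- vapply(traj$frames[frames], `[[`, numeric(1), "time")
  list(series = data.frame(time = tms, apl = apl),
       mean = mean(apl), sd = stats::sd(apl))
}

#' Mass density profile along the membrane normal
#'
#' Mass-weighted histogram of the selection's z coordinates (wrapped into
#' the primary cell and centred on the bilayer midplane, the mean z of the
#' P atoms), averaged over frames and converted to kg m^-3. With
#' \code{symmetrize = TRUE} the z and -z halves are averaged.
#'
#' @param traj an [md_trajectory()]
#' @param selection integer atom indices
#' @param bin_width z-bin width, nm (0.05 suits bulk profiles; use 0.01 for
#'   sharp P-plane peaks)
#' @param symmetrize average the profile with its mirror image
#' @param frames frame window (default all)
#' @return a \code{density_profile}: data.frame with \code{z} (bin centre,
#'   nm) and \code{density} (kg m^-3); bin width and flags in attributes
#' @export
density_profile <- function(traj, selection, bin_width = 0.05,
                            symmetrize = FALSE, frames = NULL) {
  check_selection(selection, traj$atoms)
  frames <- frames %||% seq_len(n_frames(traj))
  mass <- traj$atoms$mass[selection]
  zmax <- max(vapply(traj$frames[frames], function(f) f$box[3], numeric(1))) / 2
  nb <- ceiling(2 * zmax / bin_width)
  edges <- seq(-nb / 2, nb / 2) * bin_width
  acc <- numeric(nb); volsum <- 0
  for (fi in frames) {
    f <- traj$frames[[fi]]
    mid <- bilayer_midplane(f, traj$atoms)
    z <- f$coords[selection, 3] - mid
    z <- z - f$box[3] * round(z / f$box[3])  # wrap around the midplane
    bi <- findInterval(z, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb
    binned <- rowsum(mass[ok], bi[ok])
    acc[as.integer(rownames(binned))] <-
      acc[as.integer(rownames(binned))] + binned[, 1]
    volsum <- volsum + f$box[1] * f$box[2] * bin_width
  }
  dens <- acc / volsum * unit_constants$amu_per_nm3_to_kg_per_m3
  if (symmetrize) dens <- (dens + rev(dens)) / 2
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(z = centers, density = dens)
  class(out) <- c("density_profile", "data.frame")
  attr(out, "bin_width") <- bin_width
  attr(out, "symmetrized") <- symmetrize
  attr(out, "n_frames") <- length(frames)
  out
}

# 3-point parabolic refinement of the maximum of (x, y) around index i
parabolic_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(x[i])
  x[i] + 0.5 * (x[2] - x[1]) * (y[i - 1] - y[i + 1]) / denom
}

#' Membrane thickness from P-atom density peaks
#'
#' Thickness is the distance between the two P-density peak maxima (one
#' per leaflet), each localised by 3-point parabolic interpolation on the
#' histogram; the error is the absolute difference between the symmetrized
#' and unsymmetrized estimates.
#'
#' @param traj an [md_trajectory()]
#' @param p_selection P-atom indices (default: atoms named "P")
#' @param bin_width histogram bin width, nm
#' @param frames frame window
#' @return list with \code{thickness}, \code{error} (nm) and the two peak
#'   positions
#' @export
membrane_thickness <- function(traj, p_selection = NULL, bin_width = 0.01,
                               frames = NULL) {
  p_selection <- p_selection %||% select_atoms(traj, atom_name = "P")
  check_selection(p_selection, traj$atoms, "P-atom selection")
  one <- function(sym) {
    prof <- density_profile(traj, p_selection, bin_width = bin_width,
                            symmetrize = sym, frames = frames)
    up <- prof$z > 0; dn <- prof$z < 0
    if (!any(prof$density[up] > 0) || !any(prof$density[dn] > 0))
      stop("fewer than two P-density peaks; not a bilayer?")
    iu <- which(up)[which.max(prof$density[up])]
    id <- which(dn)[which.max(prof$density[dn])]
    c(parabolic_peak(prof$z, prof$density, iu),
      parabolic_peak(prof$z, prof$density, id))
  }
  pk <- one(FALSE)
  pk_s <- one(TRUE)
  th <- pk[1] - pk[2]
  list(thickness = th, error = abs(th - (pk_s[1] - pk_s[2])),
       peak_upper = pk[1], peak_lower = pk[2])
}

#' Default acyl-chain atom map for generator lipids
#'
#' @param chain_length carbons per chain
#' @return named list of chains; each chain is a list of entries
#'   \code{list(carbon, hydrogens)}
#' @export
default_chain_map <- function(chain_length = 16L) {
  mk <- function(tag) lapply(seq_len(chain_length), function(i)
    list(carbon = paste0("C", i, tag),
         hydrogens = paste0("H", i, tag, 1:2)))
  list(sn1 = mk("A"), sn2 = mk("B"))
}

#' Deuterium order parameters -S_CD per chain carbon
#'
#' S_CD = <3 cos^2(beta) - 1> / 2 with beta the angle between each C-H
#' bond and the membrane normal (z axis), averaged over lipids, hydrogens
#' and frames; reported with the conventional sign flip as -S_CD.
#'
#' @param traj an [md_trajectory()]
#' @param chain_map per-chain carbon/hydrogen naming, as from
#'   [default_chain_map()]
#' @param frames frame window
#' @return data.frame with \code{chain}, \code{carbon} (position index) and
#'   \code{minus_scd}
#' @export
order_parameters <- function(traj, chain_map = NULL, frames = NULL) {
  spec <- attr(traj, "spec")
  chain_map <- chain_map %||%
    default_chain_map(spec$chain_length %||% 16L)
  frames <- frames %||% seq_len(n_frames(traj))
  at <- traj$atoms
  key <- paste(at$residue_id, at$atom_name)
  out <- list()
  for (chain in names(chain_map)) {
    for (entry in chain_map[[chain]]) {
      cpos <- which(at$atom_name == entry$carbon)
      if (!length(cpos)) next
      hidx <- lapply(entry$hydrogens, function(h)
        match(paste(at$residue_id[cpos], h), key))
      if (all(is.na(unlist(hidx))))
        stop("carbon ", entry$carbon, " has no mapped hydrogens")
      s_acc <- 0; n_acc <- 0
      for (fi in frames) {
        co <- traj$frames[[fi]]$coords
        for (h in hidx) {
          ok <- !is.na(h)
          if (!any(ok)) next
          v <- co[h[ok], , drop = FALSE] - co[cpos[ok], , drop = FALSE]
          c2 <- (v[, 3]^2) / rowSums(v^2)
          s_acc <- s_acc + sum((3 * c2 - 1) / 2)
          n_acc <- n_acc + sum(ok)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        chain = chain,
        carbon = as.integer(sub("^C(\\d+).*$", "\\1", entry$carbon)),
        minus_scd = -s_acc / n_acc)
    }
  }
  if (!length(out)) stop("chain_map matched no atoms")
  do.call(rbind, out)
}

# ---- mean-square-displacement machinery (shared with water_diffusion) ----

# MSD over multiple time origins; arr = [frame, atom, xyz], dims = axes used
msd_multi_origin <- function(arr, lags, dims = 1:3, origin_stride = 1L) {
  nf <- dim(arr)[1]
  vapply(lags, function(L) {
    orig <- seq.int(1L, nf - L, by = origin_stride)
    d <- arr[orig + L, , dims, drop = FALSE] - arr[orig, , dims, drop = FALSE]
    sum(d * d) / (length(orig) * dim(arr)[2])
  }, numeric(1))
}

# guard against wrapped input: any single-frame displacement > half box
check_unwrapped <- function(arr, box) {
  nf <- dim(arr)[1]
  if (nf < 2) return(invisible(TRUE))
  step <- arr[-1, , , drop = FALSE] - arr[-nf, , , drop = FALSE]
  for (k in 1:3) {
    if (max(abs(step[, , k])) > box[k] / 2)
      stop("coordinates appear wrapped (jump > L/2 detected); ",
           "unwrap the trajectory first (unwrap_trajectory)")
  }
  invisible(TRUE)
}

# shared Einstein-relation fit: slope of MSD vs lag time over a lag window
einstein_fit <- function(arr, dt, dims, lag_window = c(0.1, 0.5),
                         n_lags = 25L, origin_stride = NULL) {
  nf <- dim(arr)[1]
  if (nf < 3) stop("need at least 3 frames for a diffusion estimate")
  lags <- unique(pmax(1L, round(seq(lag_window[1], lag_window[2],
                                    length.out = n_lags) * (nf - 1))))
  # stride 1 unless the origins x atoms x lags workload gets large
  origin_stride <- origin_stride %||%
    max(1L, ceiling(length(lags) * nf * dim(arr)[2] / 2e7))
  msd <- msd_multi_origin(arr, lags, dims, origin_stride)
  tau <- lags * dt
  fit <- stats::lm(msd ~ tau)
  slope <- stats::coef(fit)[["tau"]]
  se <- summary(fit)$coefficients["tau", "Std. Error"]
  ndim <- length(dims)
  list(D_nm2ps = slope / (2 * ndim), D_se_nm2ps = se / (2 * ndim),
       msd = data.frame(tau = tau, msd = msd),
       lag_window = lag_window, n_origins_stride = origin_stride)
}

#' Lateral diffusion coefficient of lipids
#'
#' D_xy from the slope/4 of the in-plane mean square displacement of the
#' selected atoms (by default lipid P atoms), computed over multiple time
#' origins and fitted by least squares on the configured lag window
#' (default 10-50\% of the trajectory, the usual compromise between
#' statistics and short-time/plateau contamination). Requires unwrapped
#' coordinates.
#'
#' @param traj an [md_trajectory()] with unwrapped coordinates
#' @param selection atom indices (default: atoms named "P")
#' @param lag_window fraction of trajectory length used for the fit
#' @param n_lags number of lag values sampled inside the window
#' @return list with \code{D_nm2ns}, \code{D_cm2s}, standard errors, the
#'   MSD curve and fit metadata
#' @export
lateral_diffusion <- function(traj, selection = NULL,
                              lag_window = c(0.1, 0.5), n_lags = 25L) {
  selection <- selection %||% select_atoms(traj, atom_name = "P")
  check_selection(selection, traj$atoms)
  arr <- coords_array(traj, selection)
  check_unwrapped(arr, traj$frames[[1]]$box)
  dt <- traj$timestep
  if (is.na(dt)) stop("trajectory has no timestep")
  fit <- einstein_fit(arr, dt, dims = 1:2, lag_window = lag_window,
                      n_lags = n_lags)
  c(list(D_nm2ns = nm2ps_to_nm2ns(fit$D_nm2ps),
         D_cm2s = nm2ps_to_cm2s(fit$D_nm2ps),
         D_se_nm2ns = nm2ps_to_nm2ns(fit$D_se_nm2ps),
         D_se_cm2s = nm2ps_to_cm2s(fit$D_se_nm2ps)),
    fit[c("msd", "lag_window")])
}
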