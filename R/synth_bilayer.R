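#' Specification of a synthetic solvated bilayer
#'
#' Describes the stated world the generator emulates: a 128-lipid anionic
#' bilayer (122 DPPS + 6 DPPG, 64 lipids per leaflet) neutralised by
#' monovalent cations and solvated by a 3-site water slab whose thickness
#' distinguishes the unilamellar (UL, thick slab) from the multilamellar
#' (ML, thin slab) regime. All geometric targets (area per lipid, P-P
#' thickness, box height) and dynamical targets (water D, lipid D_xy,
#' chain order) are ground truth that the analysis modules must recover.
#'
#' @param n_dpps,n_dppg lipid counts (defaults 122 and 6)
#' @param lipids_per_leaflet lipids in one leaflet (default 64)
#' @param apl_target area per lipid, nm^2; fixes Lx = Ly =
#'   sqrt(apl_target * lipids_per_leaflet)
#' @param pp_thickness target P-plane separation, nm
#' @param chain_length acyl-chain carbons per chain (16 = palmitoyl)
#' @param chain_order target -S_CD per carbon; scalar or vector of
#'   length \code{chain_length}, each in \[0, 0.5\]
#' @param z_box box height, nm (must exceed \code{pp_thickness})
#' @param n_waters number of 3-site waters
#' @param n_cations neutralising cations; \code{NULL} auto-neutralises to
#'   \code{n_dpps + n_dppg}
#' @param water_orientation orientation model: \code{orientation_isotropic()}
#'   or \code{orientation_shell(angle_deg, kappa, range)}
#' @param water_D water self-diffusion coefficient, cm^2 s^-1
#' @param lipid_Dxy lipid lateral diffusion coefficient, cm^2 s^-1
#' @param temperature_C nominal temperature, degrees C (metadata only)
#' @param area_jitter_frac relative SD of per-frame box area applied by
#'   [evolve()] to emulate barostat area fluctuations (0 = fixed box)
#' @param lattice_jitter in-plane lipid placement jitter, nm (SD)
#' @param seed default seed used when generator calls omit one
#' @return object of class \code{bilayer_spec}
#' @export
bilayer_spec <- function(n_dpps = 122L, n_dppg = 6L, lipids_per_leaflet = 64L,
                         apl_target = 0.458, pp_thickness = 4.514,
                         chain_length = 16L, chain_order = 0.28,
                         z_box = 11.2, n_waters = 6400L, n_cations = NULL,
                         water_orientation = orientation_shell(),
                         water_D = 3.12e-5, lipid_Dxy = 0.91e-7,
                         temperature_C = 35, area_jitter_frac = 0.007,
                         lattice_jitter = 0.03, seed = 1L) {
  if (is.null(n_cations)) n_cations <- n_dpps + n_dppg
  spec <- list(n_dpps = as.integer(n_dpps), n_dppg = as.integer(n_dppg),
               lipids_per_leaflet = as.integer(lipids_per_leaflet),
               apl_target = apl_target, pp_thickness = pp_thickness,
               chain_length = as.integer(chain_length),
               chain_order = chain_order, z_box = z_box,
               n_waters = as.integer(n_waters),
               n_cations = as.integer(n_cations),
               water_orientation = water_orientation, water_D = water_D,
               lipid_Dxy = lipid_Dxy, temperature_C = temperature_C,
               area_jitter_frac = area_jitter_frac,
               lattice_jitter = lattice_jitter, seed = as.integer(seed))
  class(spec) <- "bilayer_spec"
  validate_bilayer_spec(spec)
  spec
}

validate_bilayer_spec <- function(spec) {
  with(spec, {
    if (n_dpps + n_dppg != 2L * lipids_per_leaflet)
      stop("n_dpps + n_dppg must equal 2 * lipids_per_leaflet")
    if (apl_target <= 0 || pp_thickness <= 0 || z_box <= 0)
      stop("geometric targets must be positive")
    if (pp_thickness >= z_box) stop("pp_thickness must be < z_box")
    if (any(chain_order < 0 | chain_order > 0.5))
      stop("chain_order (-S_CD targets) must lie in [0, 0.5]")
    if (!length(chain_order) %in% c(1L, chain_length))
      stop("chain_order must be scalar or one value per chain carbon")
    if (n_waters < 0 || n_cations < 0) stop("counts must be non-negative")
  })
  invisible(spec)
}

#' Water orientation models for the generator
#'
#' \code{orientation_isotropic()} draws water dipoles uniformly on the
#' sphere. \code{orientation_shell()} orients waters relative to the vector
#' from the nearest headgroup heavy atom to the water oxygen: within the
#' first hydration shell (\code{cutoff}) the cosine of the angle between
#' that vector and the dipole concentrates around \code{cos(angle_deg)}
#' (Gaussian of SD \code{1/sqrt(kappa)}, reflected into \[-1, 1\]); between
#' \code{cutoff} and \code{range} the oriented fraction decays linearly to
#' zero, beyond \code{range} waters are isotropic. The default 130 degrees
#' reproduces the interfacial maximum at cos(theta) = -0.64.
#'
#' @param angle_deg preferred angle between headgroup->O vector and dipole
#' @param kappa concentration (inverse variance of cos(theta))
#' @param cutoff first-shell radius, nm
#' @param range distance at which orientation decays to isotropic, nm
#' @return a list describing the model
#' @export
orientation_shell <- function(angle_deg = 130, kappa = 40,
                              cutoff = 0.3, range = 1.2) {
  list(mode = "shell_oriented", angle_deg = angle_deg, kappa = kappa,
       cutoff = cutoff, range = range)
}

#' @rdname orientation_shell
#' @export
orientation_isotropic <- function() list(mode = "isotropic")

#' Preset bilayer specifications
#'
#' Four stated-world presets: UL (6400 waters, thick slab) and ML (2781
#' waters, thin slab) at 35 degrees C (gel: low APL, high thickness, high
#' chain order) and 65 degrees C (fluid). Geometry targets, diffusion
#' coefficients and area-fluctuation levels are the systems' reported
#' values; chain-order plateaus are 0.28 (gel) and 0.12 (fluid).
#'
#' @param preset one of "UL35", "UL65", "ML35", "ML65"
#' @param ... overrides passed on to [bilayer_spec()]
#' @return a \code{bilayer_spec}
#' @export
preset_bilayer_spec <- function(preset = c("UL35", "UL65", "ML35", "ML65"),
                                ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    UL35 = list(apl_target = 0.458, pp_thickness = 4.514, z_box = 11.2,
                n_waters = 6400L, chain_order = 0.28, water_D = 3.12e-5,
                lipid_Dxy = 0.91e-7, temperature_C = 35,
                area_jitter_frac = 0.003 / 0.458),
    UL65 = list(apl_target = 0.578, pp_thickness = 4.057, z_box = 9.4,
                n_waters = 6400L, chain_order = 0.12, water_D = 4.16e-5,
                lipid_Dxy = 4.24e-7, temperature_C = 65,
                area_jitter_frac = 0.013 / 0.578),
    ML35 = list(apl_target = 0.462, pp_thickness = 4.516, z_box = 7.5,
                n_waters = 2781L, chain_order = 0.28, water_D = 1.83e-5,
                lipid_Dxy = 0.25e-7, temperature_C = 35,
                area_jitter_frac = 0.004 / 0.462),
    ML65 = list(apl_target = 0.563, pp_thickness = 4.194, z_box = 6.5,
                n_waters = 2781L, chain_order = 0.12, water_D = 2.30e-5,
                lipid_Dxy = 3.94e-7, temperature_C = 65,
                area_jitter_frac = 0.013 / 0.563))
  args <- utils::modifyList(base, list(...))
  do.call(bilayer_spec, args)
}

# rigid 3-site water geometry (nm): O-H 0.09572, H-O-H 104.5 degrees
.water_geom <- local({
  half <- 104.5 / 2 * pi / 180
  list(d_mid = 0.09572 * cos(half), half_hh = 0.09572 * sin(half))
})

# headgroup heavy atoms anchoring the water-orientation vector v1
#' Default headgroup reference selection (P, carboxylate C, glycerol O)
#' @param atoms an [atom_table()] or [md_trajectory()]
#' @return integer atom indices
#' @export
select_headgroup_atoms <- function(atoms) {
  select_atoms(atoms, atom_name = c("P", "CC", "OG1", "OG2"),
               label = "headgroup")
}

# unit rows of a matrix
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# random unit vectors
random_unit <- function(n) unit_rows(matrix(stats::rnorm(3 * n), ncol = 3))

# reflect values into [-1, 1]
reflect_unit <- function(x) {
  x <- (x + 1) %% 4
  ifelse(x > 2, 3 - x, x - 1)
}

# for each axis row (unit), a unit vector at the given cos(angle) to it,
# uniform azimuth
vector_at_angle <- function(axis, cos_ang) {
  n <- nrow(axis)
  ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  swap <- abs(axis[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  e1 <- unit_rows(cross3(axis, ref))
  e2 <- cross3(axis, e1)
  phi <- stats::runif(n, 0, 2 * pi)
  sin_ang <- sqrt(pmax(0, 1 - cos_ang^2))
  axis * cos_ang + (e1 * cos(phi) + e2 * sin(phi)) * sin_ang
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# draw dipole directions for waters given the orientation model
draw_dipoles <- function(o_coords, ref_coords, model, box) {
  n <- nrow(o_coords)
  if (model$mode == "isotropic" || !nrow(ref_coords)) return(random_unit(n))
  nn <- cpp_nearest(o_coords, ref_coords, box)
  v1 <- unit_rows(cpp_min_image(ref_coords[nn$index, , drop = FALSE],
                                o_coords, box))
  w <- rep(0, n)
  w[nn$distance <= model$cutoff] <- 1
  mid <- nn$distance > model$cutoff & nn$distance < model$range
  w[mid] <- (model$range - nn$distance[mid]) / (model$range - model$cutoff)
  oriented <- stats::runif(n) < w
  cosT <- stats::runif(n, -1, 1)
  if (any(oriented)) {
    t0 <- cos(model$angle_deg * pi / 180)
    cosT[oriented] <- reflect_unit(
      t0 + stats::rnorm(sum(oriented), 0, 1 / sqrt(model$kappa)))
  }
  u <- vector_at_angle(v1, cosT)
  u[!oriented, ] <- random_unit(sum(!oriented))
  u
}

# place the two hydrogens of each water from O positions + dipole directions
water_hydrogens <- function(o_coords, dipoles) {
  n <- nrow(o_coords)
  mid <- o_coords + dipoles * .water_geom$d_mid
  # random in-plane axis perpendicular to the dipole
  perp <- unit_rows(cross3(dipoles, random_unit(n)))
  h1 <- mid + perp * .water_geom$half_hh
  h2 <- mid - perp * .water_geom$half_hh
  list(h1 = h1, h2 = h2)
}

# C-H unit vectors on the cone giving -S_CD = s exactly:
# cos^2(beta) = (1 - 2 s) / 3 with beta the C-H / z angle
chain_ch_vectors <- function(n, s) {
  cosb <- sqrt(pmax(0, (1 - 2 * s) / 3)) * sample(c(-1, 1), n, replace = TRUE)
  phi <- stats::runif(n, 0, 2 * pi)
  sinb <- sqrt(pmax(0, 1 - cosb^2))
  cbind(sinb * cos(phi), sinb * sin(phi), cosb)
}

# per-lipid headgroup template: name, element, dx, dy, dz (dz > 0 = outward)
.lipid_head_template <- data.frame(
  name = c("P", "OP1", "OP2", "N", "HN1", "HN2", "HN3",
           "CC", "OC1", "OC2", "CG", "OG1", "OG2",
           "CE1", "OE1", "CE2", "OE2"),
  element = c("P", "O", "O", "N", "H", "H", "H",
              "C", "O", "O", "C", "O", "O",
              "C", "O", "C", "O"),
  dx = c(0, 0.095, -0.095, -0.05, 0.04, -0.10, -0.10,
         0.05, 0.17, -0.05, 0, 0.10, -0.10,
         0.15, 0.24, -0.15, -0.24),
  dy = c(0, 0, 0, -0.12, -0.12, -0.04, -0.20,
         0.12, 0.12, 0.19, 0.05, 0.05, 0.05,
         -0.05, -0.05, 0.05, 0.05),
  dz = c(0, 0.03, 0.03, 0.20, 0.26, 0.26, 0.26,
         0.22, 0.26, 0.26, -0.20, -0.24, -0.24,
         -0.35, -0.31, -0.31, -0.31),
  stringsAsFactors = FALSE
)

#' Build a single-frame synthetic bilayer configuration
#'
#' Lipids are coarse pseudo-molecules (phosphate P/OP, serine N-H3 and
#' carboxylate C/O, glycerol C/O, two ester carbonyls, and two acyl chains
#' of carbons carrying two explicit pseudo-hydrogens each) placed on a
#' jittered square lattice at the target area per lipid, with P planes at
#' +/- \code{pp_thickness/2}. Chain C-H vectors are drawn on the cone that
#' realises the requested -S_CD exactly in expectation. Waters fill the
#' remaining z-slab at uniform density with dipoles from the configured
#' orientation model; cations sit just outside the headgroup planes. The
#' midplane is at z = 0 and the box spans \[-L/2, L/2\] per axis.
#'
#' @param spec a [bilayer_spec()]
#' @param seed RNG seed (defaults to \code{spec$seed})
#' @return a single-frame [md_trajectory()]; the bilayer_spec and achieved water
#'   density are attached as attributes \code{"spec"} and
#'   \code{"water_density"}
#' @export
build_bilayer <- function(spec = bilayer_spec(), seed = spec$seed) {
  validate_bilayer_spec(spec)
  with_seed(seed, {
    npl <- spec$lipids_per_leaflet
    L <- sqrt(spec$apl_target * npl)
    box <- c(L, L, spec$z_box)
    half_pp <- spec$pp_thickness / 2

    # lattice positions per leaflet
    nx <- ceiling(sqrt(npl))
    gx <- (seq_len(nx) - 0.5) * L / nx
    grid <- expand.grid(x = gx, y = gx)[seq_len(npl), ] - L / 2

    nlip <- spec$n_dpps + spec$n_dppg
    # distribute DPPG evenly within each leaflet
    per_leaf_g <- c(floor(spec$n_dppg / 2), ceiling(spec$n_dppg / 2))
    resnames <- character(nlip)

    head_t <- .lipid_head_template
    ncarb <- spec$chain_length
    s_per_carbon <- rep(spec$chain_order, length.out = ncarb)
    dz_c <- max(0.06, (half_pp - 0.55) / ncarb)

    name_l <- el_l <- resn_l <- character(0)
    resi_l <- integer(0)
    xyz <- NULL
    rows <- list(); resi <- list(); nm <- list(); el <- list(); rn <- list()
    lip_id <- 0L
    for (leaf in 1:2) {
      sgn <- if (leaf == 1) 1 else -1
      ng <- per_leaf_g[leaf]
      g_slots <- if (ng > 0) round(seq(1, npl, length.out = ng)) else integer(0)
      for (k in seq_len(npl)) {
        lip_id <- lip_id + 1L
        resname <- if (k %in% g_slots) "DPPG" else "DPPS"
        ox <- grid$x[k] + stats::rnorm(1, 0, spec$lattice_jitter)
        oy <- grid$y[k] + stats::rnorm(1, 0, spec$lattice_jitter)
        pz <- sgn * (half_pp + stats::rnorm(1, 0, 0.01))
        # headgroup block
        hx <- ox + head_t$dx
        hy <- oy + head_t$dy
        hz <- pz + sgn * head_t$dz
        cn <- head_t$name; ce <- head_t$element
        # chains
        for (ch in c("A", "B")) {
          cxo <- ox + if (ch == "A") 0.15 else -0.15
          cyo <- oy + if (ch == "A") -0.02 else 0.02
          ci <- seq_len(ncarb)
          cz <- pz - sgn * (0.45 + (ci - 1) * dz_c)
          cxyz <- cbind(cxo, cyo, cz)
          hvec1 <- chain_ch_vectors(ncarb, s_per_carbon)
          hvec2 <- chain_ch_vectors(ncarb, s_per_carbon)
          h1 <- cxyz + 0.109 * hvec1
          h2 <- cxyz + 0.109 * hvec2
          hx <- c(hx, rbind(cxyz[, 1], h1[, 1], h2[, 1]))
          hy <- c(hy, rbind(cxyz[, 2], h1[, 2], h2[, 2]))
          hz <- c(hz, rbind(cxyz[, 3], h1[, 3], h2[, 3]))
          cn <- c(cn, rbind(paste0("C", ci, ch), paste0("H", ci, ch, "1"),
                            paste0("H", ci, ch, "2")))
          ce <- c(ce, rbind(rep("C", ncarb), rep("H", ncarb), rep("H", ncarb)))
        }
        rows[[lip_id]] <- cbind(hx, hy, hz)
        nm[[lip_id]] <- cn
        el[[lip_id]] <- ce
        rn[[lip_id]] <- rep(resname, length(cn))
        resi[[lip_id]] <- rep(lip_id, length(cn))
      }
    }

    # water slab capacity check (max ~40 molecules / nm^3)
    slab_h <- spec$z_box - spec$pp_thickness - 0.2
    slab_vol <- L * L * slab_h
    achieved_density <- spec$n_waters / slab_vol
    if (achieved_density > 40)
      stop("requested water count (", spec$n_waters,
           ") exceeds slab capacity at liquid density (",
           round(40 * slab_vol), " waters max)")

    nw_up <- ceiling(spec$n_waters / 2)
    nw_dn <- spec$n_waters - nw_up
    zlo <- half_pp + 0.1
    zhi <- spec$z_box / 2
    wz <- c(stats::runif(nw_up, zlo, zhi), -stats::runif(nw_dn, zlo, zhi))
    wo <- cbind(stats::runif(spec$n_waters, -L / 2, L / 2),
                stats::runif(spec$n_waters, -L / 2, L / 2), wz)

    # cations hug the headgroup planes
    if (spec$n_cations > 0) {
      nc_up <- ceiling(spec$n_cations / 2)
      nc_dn <- spec$n_cations - nc_up
      cz <- c(half_pp + 0.25 + stats::rnorm(nc_up, 0, 0.08),
              -(half_pp + 0.25 + stats::rnorm(nc_dn, 0, 0.08)))
      ion <- cbind(stats::runif(spec$n_cations, -L / 2, L / 2),
                   stats::runif(spec$n_cations, -L / 2, L / 2), cz)
    } else ion <- matrix(numeric(0), 0, 3)

    lip_xyz <- do.call(rbind, rows)
    lip_nm <- unlist(nm); lip_el <- unlist(el)
    lip_rn <- unlist(rn); lip_ri <- unlist(resi)

    wat_ri <- nlip + rep(seq_len(spec$n_waters), each = 3)
    ion_ri <- nlip + spec$n_waters + seq_len(spec$n_cations)

    atoms <- atom_table(
      atom_name = c(lip_nm, rep(c("OW", "HW1", "HW2"), spec$n_waters),
                    rep("NA", spec$n_cations)),
      element = c(lip_el, rep(c("O", "H", "H"), spec$n_waters),
                  rep("Na", spec$n_cations)),
      residue_name = c(lip_rn, rep("SOL", 3 * spec$n_waters),
                       rep("NA", spec$n_cations)),
      residue_id = c(lip_ri, wat_ri, ion_ri))

    # orient waters relative to the headgroup reference atoms
    head_idx_local <- which(lip_nm %in% c("P", "CC", "OG1", "OG2"))
    dip <- draw_dipoles(wo, lip_xyz[head_idx_local, , drop = FALSE],
                        spec$water_orientation, box)
    hh <- water_hydrogens(wo, dip)
    wat_xyz <- matrix(NA_real_, 3 * spec$n_waters, 3)
    wat_xyz[seq(1, by = 3, length.out = spec$n_waters), ] <- wo
    wat_xyz[seq(2, by = 3, length.out = spec$n_waters), ] <- hh$h1
    wat_xyz[seq(3, by = 3, length.out = spec$n_waters), ] <- hh$h2

    coords <- rbind(lip_xyz, wat_xyz, ion)
    dimnames(coords) <- NULL
    traj <- md_trajectory(atoms, list(md_frame(coords, box, time = 0)),
                          timestep = NA_real_)
    attr(traj, "spec") <- spec
    attr(traj, "water_density") <- achieved_density
    traj
  })
}

#' Propagate a synthetic bilayer with known-coefficient Brownian dynamics
#'
#' Waters perform unbiased Gaussian random walks with per-step variance
#' \code{2 D dt} per dimension (D converted from cm^2/s to nm^2/ps); lipids
#' perform rigid 2-D walks in the membrane plane at \code{lipid_Dxy};
#' cations follow the water coefficient. Water dipoles and chain C-H
#' vectors are re-sampled each frame from the configured models, so
#' orientational statistics stay stationary while positions diffuse.
#' Coordinates are stored unwrapped (required by Einstein-relation
#' estimators); analyses that histogram positions wrap internally. With
#' \code{area_jitter_frac > 0} the box x/y lengths fluctuate around the
#' target area (coordinates are left untouched), emulating barostat area
#' fluctuations for the APL / compressibility estimators.
#'
#' @param traj single-frame trajectory from [build_bilayer()]
#' @param n_steps number of frames to generate
#' @param dt time step between stored frames, ps
#' @param spec the generating [bilayer_spec()]; defaults to the one
#'   attached to \code{traj}
#' @param seed RNG seed
#' @return an [md_trajectory()] with \code{n_steps + 1} frames
#' @export
evolve <- function(traj, n_steps, dt, spec = attr(traj, "spec"),
                   seed = spec$seed) {
  if (dt <= 0) stop("dt must be positive")
  if (n_frames(traj) != 1L)
    stop("evolve() expects the single-frame output of build_bilayer()")
  if (is.null(spec)) stop("no bilayer_spec available")
  with_seed(seed, {
    atoms <- traj$atoms
    box0 <- traj$frames[[1]]$box
    coords <- traj$frames[[1]]$coords

    ow <- which(atoms$atom_name == "OW")
    wat_atoms <- which(atoms$residue_name %in% water_residues)
    ion <- which(atoms$residue_name == "NA")
    lip_res_ids <- unique(atoms$residue_id[
      atoms$residue_name %in% c("DPPS", "DPPG")])
    lip_rows <- split(which(atoms$residue_id %in% lip_res_ids),
                      atoms$residue_id[atoms$residue_id %in% lip_res_ids])
    head_idx <- select_headgroup_atoms(atoms)
    carbons <- grep("^C\\d+[AB]$", atoms$atom_name)
    cidx <- as.integer(sub("^C(\\d+)[AB]$", "\\1", atoms$atom_name[carbons]))
    # atom names repeat across residues: key H lookups by (residue, name)
    key <- paste(atoms$residue_id, atoms$atom_name)
    h1 <- match(paste(atoms$residue_id[carbons],
                      sub("^C(\\d+)([AB])$", "H\\1\\21",
                          atoms$atom_name[carbons])), key)
    h2 <- match(paste(atoms$residue_id[carbons],
                      sub("^C(\\d+)([AB])$", "H\\1\\22",
                          atoms$atom_name[carbons])), key)
    s_per_carbon <- rep(spec$chain_order, length.out = spec$chain_length)
    s_of_carbon <- s_per_carbon[cidx]

    sd_w <- sqrt(2 * cm2s_to_nm2ps(spec$water_D) * dt)
    sd_l <- sqrt(2 * cm2s_to_nm2ps(spec$lipid_Dxy) * dt)

    frames <- vector("list", n_steps + 1L)
    frames[[1]] <- traj$frames[[1]]
    t0 <- traj$frames[[1]]$time
    for (step in seq_len(n_steps)) {
      # waters (all three sites ride on O), ions
      if (length(ow)) {
        dw <- matrix(stats::rnorm(3 * length(ow), 0, sd_w), ncol = 3)
        coords[ow, ] <- coords[ow, , drop = FALSE] + dw
      }
      if (length(ion)) {
        coords[ion, ] <- coords[ion, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(ion), 0, sd_w), ncol = 3)
      }
      # rigid lateral lipid displacement
      if (length(lip_rows)) {
        dl <- matrix(stats::rnorm(2 * length(lip_rows), 0, sd_l), ncol = 2)
        for (li in seq_along(lip_rows)) {
          rr <- lip_rows[[li]]
          coords[rr, 1] <- coords[rr, 1] + dl[li, 1]
          coords[rr, 2] <- coords[rr, 2] + dl[li, 2]
        }
      }
      # per-frame box area jitter
      box <- box0
      if (spec$area_jitter_frac > 0) {
        f <- sqrt(pmax(0.5, 1 + stats::rnorm(1, 0, spec$area_jitter_frac)))
        box[1:2] <- box0[1:2] * f
      }
      # re-sample water dipoles against current headgroup positions
      if (length(ow)) {
        dip <- draw_dipoles(coords[ow, , drop = FALSE],
                            coords[head_idx, , drop = FALSE],
                            spec$water_orientation, box)
        hh <- water_hydrogens(coords[ow, , drop = FALSE], dip)
        coords[ow + 1L, ] <- hh$h1
        coords[ow + 2L, ] <- hh$h2
      }
      # re-sample chain C-H vectors
      if (length(carbons)) {
        u1 <- chain_ch_vectors(length(carbons), s_of_carbon)
        u2 <- chain_ch_vectors(length(carbons), s_of_carbon)
        coords[h1, ] <- coords[carbons, , drop = FALSE] + 0.109 * u1
        coords[h2, ] <- coords[carbons, , drop = FALSE] + 0.109 * u2
      }
      frames[[step + 1L]] <- md_frame(coords, box, time = t0 + step * dt)
    }
    out <- md_trajectory(atoms, frames, timestep = dt)
    attr(out, "spec") <- spec
    attr(out, "water_density") <- attr(traj, "water_density")
    out
  })
}
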