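# In-code fixtures and brute-force oracles shared across test files.

# a bare trajectory of n "P" walker atoms (one lipid residue each) whose
# positions are supplied per frame as a list of n x 3 matrices
walker_traj <- function(frames_coords, box = c(50, 50, 50), dt = 1) {
  n <- nrow(frames_coords[[1]])
  at <- atom_table(atom_name = rep("P", n), element = rep("P", n),
                   residue_name = rep("DPPS", n), residue_id = seq_len(n))
  frames <- lapply(seq_along(frames_coords), function(i)
    md_frame(frames_coords[[i]], box, time = (i - 1) * dt))
  md_trajectory(at, frames, timestep = dt)
}

# Gaussian random-walk coordinate list: n walkers, nf frames, per-dim step SD
walk_coords <- function(n, nf, sd_step, dims = 3, start = NULL) {
  start <- start %||% matrix(0, n, 3)
  out <- vector("list", nf)
  cur <- start
  for (i in seq_len(nf)) {
    if (i > 1) {
      step <- matrix(0, n, 3)
      step[, seq_len(dims)] <- stats::rnorm(n * dims, 0, sd_step)
      cur <- cur + step
    }
    out[[i]] <- cur
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# water-only system: n waters with given O positions and dipole directions
water_system <- function(O, dipoles = NULL, box = c(10, 10, 10)) {
  n <- nrow(O)
  dipoles <- dipoles %||% {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u / sqrt(rowSums(u^2))
  }
  half <- 104.5 / 2 * pi / 180
  d_mid <- 0.09572 * cos(half); half_hh <- 0.09572 * sin(half)
  ref <- matrix(stats::rnorm(3 * n), ncol = 3)
  perp <- cbind(dipoles[, 2] * ref[, 3] - dipoles[, 3] * ref[, 2],
                dipoles[, 3] * ref[, 1] - dipoles[, 1] * ref[, 3],
                dipoles[, 1] * ref[, 2] - dipoles[, 2] * ref[, 1])
  perp <- perp / sqrt(rowSums(perp^2))
  mid <- O + dipoles * d_mid
  coords <- matrix(NA_real_, 3 * n, 3)
  coords[seq(1, by = 3, length.out = n), ] <- O
  coords[seq(2, by = 3, length.out = n), ] <- mid + perp * half_hh
  coords[seq(3, by = 3, length.out = n), ] <- mid - perp * half_hh
  at <- atom_table(atom_name = rep(c("OW", "HW1", "HW2"), n),
                   element = rep(c("O", "H", "H"), n),
                   residue_name = rep("SOL", 3 * n),
                   residue_id = rep(seq_len(n), each = 3))
  md_trajectory(at, list(md_frame(coords, box, 0)))
}

# small, fast bilayer spec for pipeline-level tests; any field overridable
small_bilayer_spec <- function(...) {
  base <- list(n_dpps = 28, n_dppg = 4, lipids_per_leaflet = 16,
               apl_target = 0.5, pp_thickness = 3.0, z_box = 9,
               chain_length = 6, chain_order = 0.28, n_waters = 300,
               water_D = 2.5e-5, lipid_Dxy = 1e-7,
               area_jitter_frac = 0, seed = 1)
  do.call(bilayer_spec, utils::modifyList(base, list(...)))
}

# ---- brute-force oracles ----

# minimum image by explicit enumeration of periodic images (wide enough to
# cover test points several boxes apart)
brute_min_image <- function(a, b, box) {
  best <- NULL; bestn <- Inf
  for (ix in -6:6) for (iy in -6:6) for (iz in -6:6) {
    d <- (b + c(ix, iy, iz) * box) - a
    nn <- sum(d^2)
    if (nn < bestn) { bestn <- nn; best <- d }
  }
  best
}

brute_pair_distance <- function(p, q, box) {
  sqrt(sum(brute_min_image(p, q, box)^2))
}

# all A-B pairs within cutoff by double loop
brute_pairs_within <- function(A, B, box, cutoff) {
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- brute_pair_distance(A[i, ], B[j, ], box)
    if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
  }
  if (!length(out)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}

# hydrogen bonds by triple loop over donors, their hydrogens and acceptors
brute_hbonds <- function(coords, donors, acceptors, box, criteria) {
  out <- list()
  for (r in seq_len(nrow(donors))) {
    d <- donors$donor[r]; h <- donors$hydrogen[r]
    for (a in acceptors) {
      if (a == d) next
      da <- brute_pair_distance(coords[d, ], coords[a, ], box)
      if (da >= criteria$distance) next
      vh <- brute_min_image(coords[d, ], coords[h, ], box)
      va <- brute_min_image(coords[d, ], coords[a, ], box)
      ang <- acos(min(1, max(-1, sum(vh * va) /
                               (sqrt(sum(vh^2)) * sqrt(sum(va^2)))))) * 180 / pi
      if (ang < criteria$angle)
        out[[length(out) + 1]] <- c(d, h, a)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

# 3-atom water GRO fixture written on the fly
write_tiny_gro <- function(path) {
  writeLines(c(
    "tiny water",
    "    3",
    "    1SOL    OW    1   1.000   1.000   1.000",
    "    1SOL   HW1    2   1.080   1.000   1.030",
    "    1SOL   HW2    3   0.950   1.060   1.030",
    "   3.00000   3.00000   3.00000"), path)
  path
}
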