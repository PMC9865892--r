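test_that("area per lipid is the box cross-section per leaflet lipid", {
  at <- atom_table(c("OW", "HW1", "HW2"), c("O", "H", "H"),
                   rep("SOL", 3), rep(1L, 3))
  mk <- function(L) md_frame(matrix(0, 3, 3), c(L, L, 5), time = L)
  traj <- md_trajectory(at, list(mk(5.414)))
  res <- area_per_lipid(traj, 64)
  expect_equal(res$mean, 5.414^2 / 64, tolerance = 1e-12)  # 0.458 nm^2
  expect_equal(round(res$mean, 3), 0.458)

  # constant box -> SD exactly 0
  traj2 <- md_trajectory(at, list(mk(5), mk(5 + 1e-9)))
  expect_equal(area_per_lipid(traj2, 64)$sd, 0, tolerance = 1e-9)
  expect_error(area_per_lipid(traj, 64, frames = integer(0)), "empty")
  expect_error(area_per_lipid(traj, 0), "positive")

  # generator run at the fluid ML target recovers the mean within 1%
  spec <- preset_bilayer_spec("ML65", seed = 21)
  b <- build_bilayer(spec, seed = 21)
  tr <- evolve(b, 30, 5, seed = 22)
  expect_equal(area_per_lipid(tr, 64)$mean, 0.563, tolerance = 0.01)
})

test_that("density profiles are flat for ideal gas and conserve mass", {
  set.seed(5)
  n <- 4000
  box <- c(4, 4, 6)
  at <- atom_table(atom_name = rep("AR", n), element = rep("C", n),
                   residue_name = rep("GAS", n), residue_id = seq_len(n))
  co <- cbind(stats::runif(n, 0, 4), stats::runif(n, 0, 4),
              stats::runif(n, -3, 3))
  traj <- md_trajectory(at, list(md_frame(co, box)))
  prof <- density_profile(traj, seq_len(n), bin_width = 0.5)
  # flat within counting noise (3 SD of a Poisson bin count)
  counts <- prof$density / (12.011 * unit_constants$amu_per_nm3_to_kg_per_m3 /
                              (4 * 4 * 0.5))
  lambda <- n / length(counts)
  expect_true(all(abs(counts - lambda) < 3.5 * sqrt(lambda)))
  # mass conservation: integral x area = total mass within 1%
  total <- sum(prof$density) * 0.5 * 16 /
    unit_constants$amu_per_nm3_to_kg_per_m3
  expect_equal(total, n * 12.011, tolerance = 0.01)

  # symmetrized profile of a symmetric input matches unsymmetrized closely
  spec <- small_bilayer_spec(seed = 31)
  b <- build_bilayer(spec, seed = 31)
  psel <- select_atoms(b, atom_name = "P")
  u <- density_profile(b, psel, bin_width = 0.1)
  s <- density_profile(b, psel, bin_width = 0.1, symmetrize = TRUE)
  expect_lt(max(abs(u$density - s$density)) / max(u$density), 0.5)
  expect_error(density_profile(b, integer(0)), "empty")
})

test_that("thickness equals the P-plane separation with parabolic peaks", {
  # delta-like planes at +-2.257 nm
  n <- 64
  at <- atom_table(atom_name = rep("P", n), element = rep("P", n),
                   residue_name = rep("DPPS", n), residue_id = seq_len(n))
  z <- rep(c(2.257, -2.257), each = n / 2)
  traj <- md_trajectory(at, list(md_frame(cbind(0, 0, z), c(6, 6, 10))))
  th <- membrane_thickness(traj, bin_width = 0.01)
  expect_equal(th$thickness, 4.514, tolerance = 0.011)
  expect_lt(th$error, 0.011)

  # generator target recovered within the bin resolution + jitter
  spec <- small_bilayer_spec(seed = 41)
  b <- build_bilayer(spec, seed = 41)
  th2 <- membrane_thickness(b)
  expect_equal(th2$thickness, 3.0, tolerance = 0.03)

  # parabolic peak against a fine-grid argmax oracle
  x <- seq(-1, 1, by = 0.05)
  y <- exp(-((x - 0.123) / 0.3)^2)
  fine <- seq(-1, 1, by = 1e-4)
  oracle <- fine[which.max(exp(-((fine - 0.123) / 0.3)^2))]
  est <- lamellipid:::parabolic_peak(x, y, which.max(y))
  expect_lt(abs(est - oracle), 0.025)  # within half a bin
})

test_that("order parameters hit their closed-form limits and targets", {
  # all-trans chain along z: C-H perpendicular to z -> -S_CD = 0.5 exactly
  n <- 10
  nm <- c(rbind(paste0("C", 1:n, "A"), paste0("H", 1:n, "A1"),
                paste0("H", 1:n, "A2")))
  at <- atom_table(atom_name = nm,
                   element = rep(c("C", "H", "H"), n),
                   residue_name = rep("DPPS", 3 * n),
                   residue_id = rep(1L, 3 * n))
  co <- matrix(0, 3 * n, 3)
  ci <- seq(1, by = 3, length.out = n)
  co[ci, 3] <- seq_len(n) * 0.127
  co[ci + 1, ] <- co[ci, ] + matrix(rep(c(0.109, 0, 0), n), ncol = 3,
                                    byrow = TRUE)
  co[ci + 2, ] <- co[ci, ] + matrix(rep(c(0, 0.109, 0), n), ncol = 3,
                                    byrow = TRUE)
  traj <- md_trajectory(at, list(md_frame(co, c(5, 5, 5))))
  cm <- list(sn1 = lapply(seq_len(n), function(i)
    list(carbon = paste0("C", i, "A"), hydrogens = paste0("H", i, "A", 1:2))))
  scd <- order_parameters(traj, cm)
  expect_equal(scd$minus_scd, rep(0.5, n), tolerance = 1e-12)

  # isotropic C-H orientations -> -S_CD ~ 0 (1e5 samples via many carbons)
  set.seed(77)
  m <- 50000  # m carbons x 2 H = 1e5 samples
  u <- matrix(stats::rnorm(3 * 2 * m), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  nm <- c(rbind(paste0("C", 1, "A"), paste0("H", 1, "A1"),
                paste0("H", 1, "A2")))
  at3 <- atom_table(atom_name = rep(nm, m), element = rep(c("C", "H", "H"), m),
                    residue_name = rep("DPPS", 3 * m),
                    residue_id = rep(seq_len(m), each = 3))
  co <- matrix(0, 3 * m, 3)
  ci <- seq(1, by = 3, length.out = m)
  co[ci + 1, ] <- 0.109 * u[seq_len(m), ]
  co[ci + 2, ] <- 0.109 * u[m + seq_len(m), ]
  traj3 <- md_trajectory(at3, list(md_frame(co, c(5, 5, 5))))
  cm1 <- list(sn1 = list(list(carbon = "C1A", hydrogens = c("H1A1", "H1A2"))))
  scd3 <- order_parameters(traj3, cm1)
  expect_lt(abs(scd3$minus_scd), 0.01)

  # generator with a 0.28 plateau recovers 0.28 +- 0.01
  spec <- small_bilayer_spec(seed = 51)
  b <- build_bilayer(spec, seed = 51)
  tr <- evolve(b, 5, 2, seed = 52)
  scd4 <- order_parameters(tr)
  expect_true(all(abs(scd4$minus_scd - 0.28) < 0.01))
  expect_equal(nrow(scd4), 2 * spec$chain_length)

  # unmapped hydrogens error names the atom
  cm_bad <- list(sn1 = list(list(carbon = "C1A", hydrogens = "HXX")))
  expect_error(order_parameters(b, cm_bad), "C1A")

  # -S_CD bounds respected on arbitrary input
  expect_true(all(scd4$minus_scd >= -0.5 & scd4$minus_scd <= 1.0))
})

test_that("lateral diffusion recovers known walks and flags wrapped input", {
  # static atoms -> D = 0
  static <- walker_traj(rep(list(matrix(0, 8, 3)), 10))
  expect_equal(lateral_diffusion(static)$D_cm2s, 0, tolerance = 1e-15)

  # 64 walkers x 1000 steps at the stated tolerance (10%)
  spec <- bilayer_spec(n_dpps = 60, n_dppg = 4, lipids_per_leaflet = 32,
                       apl_target = 0.5, pp_thickness = 3, z_box = 12,
                       n_waters = 50, chain_length = 3, water_D = 2.3e-5,
                       lipid_Dxy = 1e-7,
                       water_orientation = orientation_isotropic(),
                       area_jitter_frac = 0, seed = 42)
  b <- build_bilayer(spec, seed = 42)
  tr <- evolve(b, 1000, 10, seed = 142)
  dl <- lateral_diffusion(tr)
  expect_equal(dl$D_cm2s, 1e-7, tolerance = 0.10)

  # doubling dt at fixed per-step variance halves the fitted D
  set.seed(8)
  steps <- walk_coords(32, 400, 0.05, dims = 2)
  t1 <- walker_traj(steps, dt = 1)
  t2 <- walker_traj(steps, dt = 2)
  d1 <- lateral_diffusion(t1)$D_cm2s
  d2 <- lateral_diffusion(t2)$D_cm2s
  expect_equal(d1 / d2, 2, tolerance = 1e-9)

  # wrapped jumps are detected
  wrapped <- wrap_trajectory(walker_traj(walk_coords(4, 30, 1.2),
                                         box = c(2, 2, 2)))
  expect_error(lateral_diffusion(wrapped), "unwrap")
})

test_that("APL and thickness are anti-correlated at fixed chain volume", {
  apls <- c(0.46, 0.52, 0.58)
  ths <- vapply(apls, function(a) {
    # fixed 'lipid volume': P-P distance scaled down as APL grows
    spec <- small_bilayer_spec(apl_target = a, pp_thickness = 1.5 / a,
                               seed = 61)
    membrane_thickness(build_bilayer(spec, seed = 61))$thickness
  }, numeric(1))
  expect_true(all(diff(ths) < 0))
})
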