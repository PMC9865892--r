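test_that("rdf is 1 for an ideal gas and matches brute-force enumeration", {
  set.seed(3)
  n <- 3000
  box <- c(5, 5, 5)
  at <- atom_table(atom_name = rep("AR", n), element = rep("C", n),
                   residue_name = rep("GAS", n), residue_id = seq_len(n))
  frames <- lapply(1:3, function(i)
    md_frame(matrix(stats::runif(3 * n, 0, 5), ncol = 3), box, time = i))
  traj <- md_trajectory(at, frames)
  g <- rdf(traj, seq_len(n), seq_len(n), r_max = 1.5, dr = 0.1)
  counts <- attr(g, "counts")
  expected <- counts / pmax(g$g, 1e-12)  # expected counts per bin
  expect_true(all(abs(g$g[-1] - 1) < 3.5 / sqrt(expected[-1]) + 0.02))

  # 10-atom configuration against a brute-force pair histogram
  set.seed(4)
  A <- matrix(stats::runif(30, 0, 3), ncol = 3)
  B <- matrix(stats::runif(30, 0, 3), ncol = 3)
  atf <- atom_table(atom_name = c(rep("X", 10), rep("Y", 10)),
                    element = rep("C", 20), residue_name = rep("GAS", 20),
                    residue_id = 1:20)
  trj <- md_trajectory(atf, list(md_frame(rbind(A, B), c(3, 3, 3))))
  g2 <- rdf(trj, 1:10, 11:20, r_max = 1.4, dr = 0.05)
  bp <- brute_pairs_within(A, B, c(3, 3, 3), 1.4)
  oracle <- table(factor(findInterval(bp[, 3], seq(0, 1.4, by = 0.05),
                                      rightmost.closed = TRUE),
                         levels = 1:28))
  expect_equal(as.numeric(attr(g2, "counts")), as.numeric(oracle))

  # two atoms at 0.27 nm occupy exactly that bin
  tr2 <- md_trajectory(
    atom_table(c("X", "Y"), c("C", "C"), c("GAS", "GAS"), 1:2),
    list(md_frame(rbind(c(1, 1, 1), c(1, 1, 1.27)), c(4, 4, 4))))
  g3 <- rdf(tr2, 1L, 2L, r_max = 0.5, dr = 0.02)
  expect_equal(g3$r[which(attr(g3, "counts") > 0)], 0.27)

  expect_error(rdf(tr2, 1L, 2L, r_max = 3), "half the smallest box")
})

test_that("shell assignment respects the cutoff and the brute-force count", {
  mk <- function(d) {
    O <- rbind(c(1 + d, 1, 1))
    ws <- water_system(O, box = c(6, 6, 6))
    # add one reference atom at (1,1,1)
    at <- atom_table(
      atom_name = c(ws$atoms$atom_name, "P"),
      element = c(ws$atoms$element, "P"),
      residue_name = c(ws$atoms$residue_name, "DPPS"),
      residue_id = c(ws$atoms$residue_id, 2L))
    co <- rbind(ws$frames[[1]]$coords, c(1, 1, 1))
    list(frame = md_frame(co, c(6, 6, 6)), atoms = at, ref = 4L)
  }
  near <- mk(0.29)
  expect_length(shell_waters(near$frame, near$atoms, near$ref, 0.3), 1)
  far <- mk(0.31)
  expect_length(shell_waters(far$frame, far$atoms, far$ref, 0.3), 0)

  # random configurations against a double loop
  set.seed(9)
  for (rep in 1:5) {
    nw <- 40
    O <- matrix(stats::runif(3 * nw, 0, 4), ncol = 3)
    ws <- water_system(O, box = c(4, 4, 4))
    nr <- 5
    refc <- matrix(stats::runif(3 * nr, 0, 4), ncol = 3)
    at <- atom_table(
      atom_name = c(ws$atoms$atom_name, rep("P", nr)),
      element = c(ws$atoms$element, rep("P", nr)),
      residue_name = c(ws$atoms$residue_name, rep("DPPS", nr)),
      residue_id = c(ws$atoms$residue_id, nw + seq_len(nr)))
    co <- rbind(ws$frames[[1]]$coords, refc)
    fr <- md_frame(co, c(4, 4, 4))
    got <- shell_waters(fr, at, 3 * nw + seq_len(nr), 0.5)
    want <- which(vapply(seq_len(nw), function(i) {
      any(vapply(seq_len(nr), function(j)
        brute_pair_distance(O[i, ], refc[j, ], c(4, 4, 4)) <= 0.5,
        logical(1)))
    }, logical(1)))
    expect_equal(sort(got), sort(3 * (want - 1) + 1))
  }
})

test_that("angular distribution reflects the imposed orientation model", {
  set.seed(14)
  # isotropic: flat density (chi-square uniformity at alpha = 0.01)
  nw <- 4000
  O <- matrix(stats::runif(3 * nw, 0, 6), ncol = 3)
  ws <- water_system(O, box = c(6, 6, 6))
  nr <- 30
  refc <- matrix(stats::runif(3 * nr, 0, 6), ncol = 3)
  at <- atom_table(
    atom_name = c(ws$atoms$atom_name, rep("P", nr)),
    element = c(ws$atoms$element, rep("P", nr)),
    residue_name = c(ws$atoms$residue_name, rep("DPPS", nr)),
    residue_id = c(ws$atoms$residue_id, nw + seq_len(nr)))
  co <- rbind(ws$frames[[1]]$coords, refc)
  traj <- md_trajectory(at, list(md_frame(co, c(6, 6, 6))))
  ref_idx <- 3 * nw + seq_len(nr)
  ang <- angular_distribution(traj, ref_idx, cutoff = 3, n_bins = 20)
  counts <- ang$density * nw * 0.1
  p <- stats::chisq.test(round(counts))$p.value
  expect_gt(p, 0.01)

  # tight orientation at 130 degrees: density maximum at cos(130) = -0.64
  spec <- small_bilayer_spec(
    water_orientation = orientation_shell(130, kappa = 1000), seed = 71)
  b <- build_bilayer(spec, seed = 71)
  ang2 <- angular_distribution(b, cutoff = 0.4, n_bins = 40)
  expect_equal(ang2$cos_theta[which.max(ang2$density)], cos(130 * pi / 180),
               tolerance = 0.06)

  # all dipoles parallel to v1: single occupied bin at +1
  O1 <- rbind(c(2, 2, 2.5))
  d1 <- rbind(c(0, 0, 1))  # v1 from ref below points +z; dipole +z
  ws1 <- water_system(O1, d1, box = c(4, 4, 4))
  at1 <- atom_table(
    atom_name = c(ws1$atoms$atom_name, "P"),
    element = c(ws1$atoms$element, "P"),
    residue_name = c(ws1$atoms$residue_name, "DPPS"),
    residue_id = c(ws1$atoms$residue_id, 2L))
  co1 <- rbind(ws1$frames[[1]]$coords, c(2, 2, 2.25))
  tr1 <- md_trajectory(at1, list(md_frame(co1, c(4, 4, 4))))
  ang3 <- angular_distribution(tr1, 4L, cutoff = 0.3, n_bins = 10)
  expect_equal(which(ang3$density > 0), 10L)

  # water without two hydrogens errors
  bad <- atom_table(c("OW", "HW1", "HW2", "P"), c("O", "H", "H", "P"),
                    c("SOL", "SOL", "SOL", "DPPS"), c(1L, 1L, 1L, 2L))
  bad2 <- bad[-2, ]; class(bad2) <- class(bad)
  fr <- md_frame(matrix(0, 3, 3), c(2, 2, 2))
  expect_error(
    angular_distribution(md_trajectory(
      atom_table(c("OW", "HW1", "P"), c("O", "H", "P"),
                 c("SOL", "SOL", "DPPS"), c(1L, 1L, 2L),
                 validate = FALSE),
      list(fr)), 3L),
    "2 hydrogens")
})

test_that("cos(theta) vs distance separates shell from bulk", {
  # oriented shell + isotropic bulk from the generator
  spec <- small_bilayer_spec(
    water_orientation = orientation_shell(130, kappa = 200,
                                          cutoff = 0.3, range = 0.5),
    seed = 81)
  b <- build_bilayer(spec, seed = 81)
  tr <- evolve(b, 5, 2, seed = 84)
  res <- costheta_vs_distance(tr, dr = 0.1)
  prof <- res$profile
  near <- prof$mean_cos_theta[prof$r < 0.3 & prof$n > 10]
  far_i <- prof$r > 1.0 & prof$n > 50
  expect_true(all(near < -0.3))
  # beyond the orientation range the mean is zero within counting noise
  bound <- 3.5 / sqrt(3 * prof$n[far_i])   # var(cos theta) = 1/3
  expect_true(all(abs(prof$mean_cos_theta[far_i]) < bound + 0.02))

  # cumulative curve ends at the total sum over all waters
  res1 <- costheta_vs_distance(b, dr = 0.1)
  ct <- lamellipid:::costheta_of_frame(
    b$frames[[1]], b$atoms, select_headgroup_atoms(b$atoms))
  expect_equal(utils::tail(res1$cumulative$cum_cos_theta, 1),
               sum(ct$cos_theta), tolerance = 1e-9)

  # isotropic waters: profile ~ 0 everywhere it is sampled
  spec2 <- small_bilayer_spec(water_orientation = orientation_isotropic(),
                              n_waters = 1000, z_box = 14, seed = 82)
  b2 <- build_bilayer(spec2, seed = 82)
  tr2 <- evolve(b2, 4, 2, seed = 83)
  prof2 <- costheta_vs_distance(tr2, dr = 0.25)$profile
  ok <- prof2$n > 200
  bound2 <- 3.5 / sqrt(3 * prof2$n[ok])
  expect_true(all(abs(prof2$mean_cos_theta[ok]) < bound2 + 0.02))
})

test_that("dipole tilt profile hits closed forms and generator symmetry", {
  # all dipoles along +z
  set.seed(15)
  O <- matrix(stats::runif(60, 0, 4), ncol = 3)
  up <- matrix(rep(c(0, 0, 1), each = 20), ncol = 3)
  ws <- water_system(O, up, box = c(4, 4, 4))
  tilt <- dipole_tilt_profile(ws, bin_width = 0.5)
  expect_true(all(abs(tilt$mean_cos_phi[tilt$n > 0] - 1) < 1e-9))

  # isotropic: ~0 within noise
  nw <- 5000
  O2 <- matrix(stats::runif(3 * nw, 0, 6), ncol = 3)
  ws2 <- water_system(O2, box = c(6, 6, 6))
  tilt2 <- dipole_tilt_profile(ws2, bin_width = 2)
  expect_lt(max(abs(tilt2$mean_cos_phi[tilt2$n > 100])), 3 / sqrt(1000))

  # shell-oriented generator: antisymmetric about the midplane
  spec <- preset_bilayer_spec("ML35", seed = 91,
    water_orientation = orientation_shell(130, kappa = 100, range = 1.5))
  b <- build_bilayer(spec, seed = 91)
  tr <- evolve(b, 10, 2, seed = 92)
  tilt3 <- dipole_tilt_profile(tr, bin_width = 0.25)
  keep <- tilt3$n > 500 & rev(tilt3$n) > 500
  asym <- tilt3$mean_cos_phi[keep] + rev(tilt3$mean_cos_phi)[keep]
  expect_lt(max(abs(asym)), 0.05)
})

test_that("water diffusion recovers the generator coefficient", {
  # static waters -> D = 0
  O <- matrix(stats::runif(30, 0, 5), ncol = 3)
  ws <- water_system(O, box = c(5, 5, 5))
  f0 <- ws$frames[[1]]
  frames <- lapply(0:9, function(i) md_frame(f0$coords, f0$box, time = i))
  static <- md_trajectory(ws$atoms, frames)
  expect_equal(water_diffusion(static)$D_cm2s, 0, tolerance = 1e-15)

  # 1000 walkers x 1000 steps: recovered within 5%
  D <- 2.30e-5
  spec <- bilayer_spec(n_dpps = 6, n_dppg = 2, lipids_per_leaflet = 4,
                       apl_target = 0.5, pp_thickness = 2, z_box = 60,
                       chain_length = 3, n_waters = 1000L, water_D = D,
                       lipid_Dxy = 0,
                       water_orientation = orientation_isotropic(),
                       area_jitter_frac = 0, seed = 42)
  b <- build_bilayer(spec, seed = 42)
  tr <- evolve(b, 1000, 2, seed = 1042)
  est <- water_diffusion(tr)
  expect_equal(est$D_cm2s, D, tolerance = 0.05)
  expect_equal(est$msd$msd[1] > 0, TRUE)

  # disjoint halves agree within 3 fitted SEs
  half1 <- md_trajectory(tr$atoms, tr$frames[1:500], timestep = 2)
  half2 <- md_trajectory(tr$atoms, tr$frames[501:1001], timestep = 2)
  e1 <- water_diffusion(half1)
  e2 <- water_diffusion(half2)
  se <- sqrt(e1$D_se_cm2s^2 + e2$D_se_cm2s^2)
  expect_lt(abs(e1$D_cm2s - e2$D_cm2s), 3 * max(se, 0.02 * D))
})

test_that("UL/ML presets produce the expected orientation and mobility
           contrast", {
  range_ext <- orientation_shell(130, kappa = 60, cutoff = 0.3, range = 1.6)
  ul <- build_bilayer(preset_bilayer_spec("UL35",
                                          water_orientation = range_ext,
                                          seed = 30), seed = 30)
  ml <- build_bilayer(preset_bilayer_spec("ML35",
                                          water_orientation = range_ext,
                                          seed = 30), seed = 30)
  pu <- costheta_vs_distance(ul, dr = 0.2)$profile
  pm <- costheta_vs_distance(ml, dr = 0.2)$profile
  # ML: waters stay oriented across the whole thin gap
  ok_m <- pm$n > 30
  expect_true(all(pm$mean_cos_theta[ok_m & pm$r < 1.4] < -0.05))
  # UL: bulk region decays towards zero
  far_u <- pu$mean_cos_theta[pu$n > 30 & pu$r > 2]
  expect_lt(mean(abs(far_u)), 0.1)

  # estimator preserves the generator's D ordering (UL > ML)
  ul_t <- evolve(ul, 150, 5, seed = 31)
  ml_t <- evolve(ml, 150, 5, seed = 31)
  expect_gt(water_diffusion(ul_t)$D_cm2s, water_diffusion(ml_t)$D_cm2s)
})
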