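# build a bare frame from explicit atoms for hydrogen-bond geometry cases
hb_frame <- function(names, elements, resnames, resids, coords,
                     box = c(5, 5, 5)) {
  at <- atom_table(names, elements, resnames, as.integer(resids),
                   validate = FALSE)
  list(atoms = at, frame = md_frame(coords, box))
}

test_that("criteria validation and textbook geometries behave", {
  expect_error(hbond_criteria(distance = 0), "positive")
  expect_error(hbond_criteria(angle = 95), "0, 90")

  # linear O-H...O at d(O,O) = 0.28, angle 0 -> one bond
  case <- function(doo, hoff) {
    s <- hb_frame(c("OW", "HW1", "HW2", "OX"), c("O", "H", "H", "O"),
                  c("SOL", "SOL", "SOL", "LIP"), c(1, 1, 1, 2),
                  rbind(c(1, 1, 1), c(1, 1, 1.0957), c(1, 1.09, 0.97),
                        c(1 + hoff, 1, 1 + doo)))
    donors <- data.frame(donor = 1L, hydrogen = 2L)
    detect_hbonds(s$frame, s$atoms, donors, acceptors = 4L)
  }
  expect_equal(nrow(case(0.28, 0)), 1)
  expect_equal(nrow(case(0.31, 0)), 0)
  # 35 degrees at d = 0.25 -> rejected
  d <- 0.25
  off <- d * sin(35 * pi / 180)
  dz <- d * cos(35 * pi / 180)
  s <- hb_frame(c("OW", "HW1", "HW2", "OX"), c("O", "H", "H", "O"),
                c("SOL", "SOL", "SOL", "LIP"), c(1, 1, 1, 2),
                rbind(c(1, 1, 1), c(1, 1, 1.0957), c(1, 1.09, 0.97),
                      c(1 + off, 1, 1 + dz)))
  hb <- detect_hbonds(s$frame, s$atoms, data.frame(donor = 1L, hydrogen = 2L),
                      acceptors = 4L)
  expect_equal(nrow(hb), 0)
  # same geometry at 25 degrees passes
  off <- d * sin(25 * pi / 180); dz <- d * cos(25 * pi / 180)
  s2 <- hb_frame(c("OW", "HW1", "HW2", "OX"), c("O", "H", "H", "O"),
                 c("SOL", "SOL", "SOL", "LIP"), c(1, 1, 1, 2),
                 rbind(c(1, 1, 1), c(1, 1, 1.0957), c(1, 1.09, 0.97),
                       c(1 + off, 1, 1 + dz)))
  hb2 <- detect_hbonds(s2$frame, s2$atoms,
                       data.frame(donor = 1L, hydrogen = 2L), acceptors = 4L)
  expect_equal(nrow(hb2), 1)
})

test_that("detection matches the brute-force triple loop on random configs", {
  for (seed in 1:6) {
    set.seed(seed)
    nw <- 16  # 48 water atoms
    O <- matrix(stats::runif(3 * nw, 0, 2.2), ncol = 3)
    ws <- water_system(O, box = c(2.2, 2.2, 2.2))
    crit <- hbond_criteria(0.35, 35)
    donors <- default_donor_table(ws$atoms)
    acceptors <- default_acceptors(ws$atoms)
    got <- detect_hbonds(ws$frames[[1]], ws$atoms, donors, acceptors, crit)
    want <- brute_hbonds(ws$frames[[1]]$coords, donors, acceptors,
                         c(2.2, 2.2, 2.2), crit)
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(cbind(got$donor, got$hydrogen, got$acceptor)),
                     key(want))
  }
})

test_that("rigid rotation+translation leaves the bond set unchanged", {
  set.seed(33)
  nw <- 20
  O <- matrix(stats::runif(3 * nw, 1.5, 3.5), ncol = 3)  # away from edges
  ws <- water_system(O, box = c(40, 40, 40))  # effectively non-periodic
  crit <- hbond_criteria(0.35, 35)
  hb0 <- detect_hbonds(ws$frames[[1]], ws$atoms, criteria = crit)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  co2 <- ws$frames[[1]]$coords %*% t(Rz)
  co2 <- sweep(co2, 2, c(3, -2, 1.5), "+")
  f2 <- md_frame(co2, c(40, 40, 40))
  hb1 <- detect_hbonds(f2, ws$atoms, criteria = crit)
  ord <- function(h) h[order(h$donor, h$hydrogen, h$acceptor), ]
  expect_equal(ord(hb1)$acceptor, ord(hb0)$acceptor)
  expect_equal(ord(hb1)$distance, ord(hb0)$distance, tolerance = 1e-9)
  expect_equal(ord(hb1)$angle, ord(hb0)$angle, tolerance = 1e-6)
})

test_that("tightening either criterion never increases counts", {
  set.seed(44)
  nw <- 30
  O <- matrix(stats::runif(3 * nw, 0, 2.5), ncol = 3)
  ws <- water_system(O, box = c(2.5, 2.5, 2.5))
  counts <- sapply(c(0.40, 0.35, 0.30, 0.25), function(d)
    sapply(c(40, 30, 20), function(a)
      nrow(detect_hbonds(ws$frames[[1]], ws$atoms,
                         criteria = hbond_criteria(d, a)))))
  # rows: angle loosest->tightest per column; columns: distance tightening
  expect_true(all(apply(counts, 1, diff) <= 0))
  expect_true(all(apply(counts, 2, diff) <= 0))
})

test_that("class counting distinguishes chemistry and normalises exactly", {
  # a pure water box: only water-water is populated
  set.seed(55)
  O <- matrix(stats::runif(45, 0, 1.8), ncol = 3)
  ws <- water_system(O, box = c(1.8, 1.8, 1.8))
  rep_w <- count_by_class(ws, hbond_criteria(0.35, 40))
  sm <- rep_w$summary
  expect_gt(sm$mean[sm$class == "water-water"], 0)
  expect_true(all(sm$mean[sm$class != "water-water"] == 0))
  # per-molecule equals mean / molecule count exactly
  expect_equal(sm$per_molecule[sm$class == "water-water"],
               sm$mean[sm$class == "water-water"] / 15)

  # one water donating to one phosphate oxygen: water-lipid = water-PO2 = 1
  at <- atom_table(
    atom_name = c("OW", "HW1", "HW2", "P", "OP1", "OP2"),
    element = c("O", "H", "H", "P", "O", "O"),
    residue_name = c("SOL", "SOL", "SOL", "DPPS", "DPPS", "DPPS"),
    residue_id = c(1L, 1L, 1L, 2L, 2L, 2L))
  co <- rbind(c(1, 1, 1), c(1, 1, 1.0957), c(1, 1.09, 0.97),
              c(2.5, 2.5, 2.5), c(1, 1, 1.27), c(2.5, 2.5, 2.2))
  tr <- md_trajectory(at, list(md_frame(co, c(5, 5, 5))))
  rep1 <- count_by_class(tr)
  s1 <- rep1$summary
  expect_equal(s1$mean[s1$class == "water-lipid"], 1)
  expect_equal(s1$mean[s1$class == "water-PO2"], 1)
  expect_equal(s1$mean[s1$class == "water-COO"], 0)

  # moiety classes sum to at most water-lipid on a real system
  spec <- small_bilayer_spec(seed = 66)
  b <- build_bilayer(spec, seed = 66)
  repb <- count_by_class(b)
  sb <- repb$summary
  grp <- sum(sb$mean[sb$class %in% paste0("water-",
                                          c("PO2", "C=O", "COO", "glycerol"))])
  expect_lte(grp, sb$mean[sb$class == "water-lipid"] + 1e-9)

  # permutation invariance: shuffling residue order preserves all counts
  n_res <- max(b$atoms$residue_id)
  set.seed(8)
  perm <- sample(n_res)
  ord <- order(match(b$atoms$residue_id, perm), b$atoms$atom_id)
  at2 <- b$atoms[ord, ]
  at2$atom_id <- seq_len(nrow(at2))
  at2$residue_id <- match(at2$residue_id, unique(at2$residue_id))
  class(at2) <- class(b$atoms)
  tr2 <- md_trajectory(at2, list(md_frame(b$frames[[1]]$coords[ord, ],
                                          b$frames[[1]]$box)))
  expect_equal(count_by_class(tr2)$summary$mean, repb$summary$mean)
})

test_that("report means concatenate frame-weighted", {
  spec <- small_bilayer_spec(seed = 67)
  b <- build_bilayer(spec, seed = 67)
  tr <- evolve(b, 5, 2, seed = 68)
  r_all <- count_by_class(tr, frames = 1:6)
  r_a <- count_by_class(tr, frames = 1:2)
  r_b <- count_by_class(tr, frames = 3:6)
  expect_equal(r_all$summary$mean,
               (2 * r_a$summary$mean + 4 * r_b$summary$mean) / 6)
})

test_that("per-molecule normalisation reproduces printed quotients", {
  expect_equal(normalize_per_molecule(217, 128)$value_2dp, 1.70)
  expect_equal(normalize_per_molecule(9604, 6400)$value_2dp, 1.50)
  expect_equal(normalize_per_molecule(0, 10)$value, 0)
  expect_error(normalize_per_molecule(5, 0), "positive")
})

test_that("ion contacts count pairs within the cutoff", {
  at <- atom_table(
    atom_name = c("NA", "CC", "OC1", "OC2"),
    element = c("Na", "C", "O", "O"),
    residue_name = c("NA", "DPPS", "DPPS", "DPPS"),
    residue_id = c(1L, 2L, 2L, 2L))
  co <- rbind(c(1, 1, 1), c(3, 3, 3), c(1, 1, 1.30), c(3, 3, 2.6))
  tr <- md_trajectory(at, list(md_frame(co, c(6, 6, 6))))
  expect_equal(ion_contacts(tr, cutoff = 0.32)$mean, 1)
  # ion far from every carboxylate oxygen -> 0
  co2 <- co; co2[1, ] <- c(5, 5, 5)
  tr2 <- md_trajectory(at, list(md_frame(co2, c(6, 6, 6))))
  expect_equal(ion_contacts(tr2, cutoff = 0.32)$mean, 0)
  expect_error(ion_contacts(tr, cutoff = 0))

  # brute-force pair loop equality on random configurations
  set.seed(77)
  for (rep in 1:5) {
    ni <- 12; ng <- 18
    ion <- matrix(stats::runif(3 * ni, 0, 3), ncol = 3)
    grp <- matrix(stats::runif(3 * ng, 0, 3), ncol = 3)
    atr <- atom_table(
      atom_name = c(rep("NA", ni), rep("OC1", ng)),
      element = c(rep("Na", ni), rep("O", ng)),
      residue_name = c(rep("NA", ni), rep("DPPS", ng)),
      residue_id = seq_len(ni + ng))
    trr <- md_trajectory(atr, list(md_frame(rbind(ion, grp), c(3, 3, 3))))
    got <- ion_contacts(trr, seq_len(ni), ni + seq_len(ng), cutoff = 0.45)
    want <- nrow(brute_pairs_within(ion, grp, c(3, 3, 3), 0.45))
    expect_equal(got$mean, want)
  }
})
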