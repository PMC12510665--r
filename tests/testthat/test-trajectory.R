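test_that("binding energy is E_complex minus the component energies", {
  e <- data.frame(e_complex = -100, e_protein = -60, e_rna = -30)
  expect_equal(binding_energy_series(e)$series, -10)
  e2 <- data.frame(e_complex = c(-90, -85), e_protein = c(-60, -55),
                   e_rna = c(-30, -30))
  expect_equal(binding_energy_series(e2)$series, c(0, 0))
  set.seed(3)
  e3 <- data.frame(e_complex = rnorm(20, -100), e_protein = rnorm(20, -60),
                   e_rna = rnorm(20, -30))
  bs <- binding_energy_series(e3)
  expect_equal(bs$mean, mean(e3$e_complex - e3$e_protein - e3$e_rna))
  expect_equal(bs$sd, sd(e3$e_complex - e3$e_protein - e3$e_rna))
})

hb_frame <- function(acceptor_xyz) {
  atoms <- data.frame(
    name = c("N", "H", "O"), element = c("N", "H", "O"),
    chain_tag = c("protein", "protein", "rna"),
    mass = c(14.007, 1.008, 15.999),
    resname = c("GLY", "GLY", "A"), resid = c(1L, 1L, 2L),
    stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), acceptor_xyz)
  prot2rna:::new_trajectory(atoms, list(xyz))
}

test_that("hydrogen bonds demand both the distance and the angle criterion", {
  # D-A 4.4 A, angle 180 degrees: inside both cutoffs
  expect_equal(detect_hbonds(hb_frame(c(4.4, 0, 0))), 1L)
  # D-A 4.6 A, angle 180: distance fails
  expect_equal(detect_hbonds(hb_frame(c(4.6, 0, 0))), 0L)
  # close distance but D-H...A angle ~41 degrees (< 150): angle fails
  acc <- c(1 + 2 * cos(pi * 139 / 180), 2 * sin(pi * 139 / 180), 0)
  expect_lt(sqrt(sum(acc^2)), 4.5)
  expect_equal(detect_hbonds(hb_frame(acc)), 0L)
  # just past the angle cutoff (151 degrees) counts
  acc151 <- c(1 + 2 * cos(pi * 29 / 180), 2 * sin(pi * 29 / 180), 0)
  expect_equal(detect_hbonds(hb_frame(acc151)), 1L)
  # topology without hydrogens is an error
  atoms <- data.frame(name = c("N", "O"), element = c("N", "O"),
                      chain_tag = c("protein", "rna"),
                      mass = c(14.007, 15.999),
                      resname = c("GLY", "A"), resid = c(1L, 2L),
                      stringsAsFactors = FALSE)
  traj <- prot2rna:::new_trajectory(atoms, list(rbind(c(0, 0, 0),
                                                      c(3, 0, 0))))
  expect_error(detect_hbonds(traj), "pre-protonated")
})

test_that("contacts count cross-chain pairs within 4.5 Angstrom", {
  two <- function(d) {
    atoms <- data.frame(name = c("CA", "P"), element = c("C", "P"),
                        chain_tag = c("protein", "rna"),
                        mass = c(12.011, 30.973762),
                        resname = c("GLY", "A"), resid = c(1L, 2L),
                        stringsAsFactors = FALSE)
    prot2rna:::new_trajectory(atoms, list(rbind(c(0, 0, 0), c(d, 0, 0))))
  }
  expect_equal(count_contacts(two(4.4)), 1L)
  expect_equal(count_contacts(two(4.6)), 0L)
})

test_that("contact counting equals brute force on random 50-atom frames", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 50L
    tags <- sample(c("protein", "rna"), n, replace = TRUE)
    atoms <- data.frame(name = "CA", element = "C", chain_tag = tags,
                        mass = 12.011,
                        resname = ifelse(tags == "protein", "GLY", "A"),
                        resid = seq_len(n), stringsAsFactors = FALSE)
    xyz <- matrix(runif(n * 3L, 0, 15), n, 3L)
    traj <- prot2rna:::new_trajectory(atoms, list(xyz))
    expect_equal(count_contacts(traj), oracle_contacts(xyz, tags))
  }
})

test_that("hydrogen-bond detection equals brute force on toy trajectories", {
  toy <- make_toy_trajectory(n_frames = 4L, n_hbonds = 3L,
                             n_bad_distance = 2L, n_bad_angle = 2L,
                             seed = 5L)
  counts <- detect_hbonds(toy$trajectory)
  expect_equal(counts, rep(3L, 4L))
  for (f in 1:4)
    expect_equal(counts[f],
                 oracle_hbonds(toy$trajectory$frames[[f]],
                               toy$trajectory$atoms))
})

test_that("RMSD removes rigid motion only under superposition", {
  toy <- make_toy_trajectory(n_frames = 3L, seed = 8L)
  traj <- toy$trajectory
  expect_equal(rmsd_series(traj, "all"), rep(0, 3L), tolerance = 1e-6)
  # translate frame 2 rigidly by (3, 0, 0)
  traj$frames[[2L]] <- traj$frames[[2L]] +
    matrix(c(3, 0, 0), nrow(traj$atoms), 3L, byrow = TRUE)
  expect_equal(rmsd_series(traj, "all", superpose = TRUE)[2L], 0,
               tolerance = 1e-6)
  expect_equal(rmsd_series(traj, "all", superpose = FALSE)[2L], 3,
               tolerance = 1e-9)
  expect_error(rmsd_series(traj, integer()), "empty")
})

test_that("radius of gyration matches the direct formula", {
  atoms <- data.frame(name = c("X", "Y"), element = c("C", "C"),
                      chain_tag = c("protein", "protein"),
                      mass = c(1, 1), resname = "GLY", resid = 1:2,
                      stringsAsFactors = FALSE)
  traj <- prot2rna:::new_trajectory(atoms, list(rbind(c(0, 0, 0),
                                                      c(2, 0, 0))))
  expect_equal(rg_series(traj, "all"), 1)            # two unit masses 2 A apart
  expect_equal(rg_series(traj, 1L), 0)               # single atom
  set.seed(30)
  n <- 12L
  atoms <- data.frame(name = "CA", element = sample(c("C", "N", "O"), n,
                                                    replace = TRUE),
                      chain_tag = "protein", mass = NA, resname = "GLY",
                      resid = seq_len(n), stringsAsFactors = FALSE)
  atoms$mass <- c(C = 12.011, N = 14.007, O = 15.999)[atoms$element]
  xyz <- matrix(rnorm(n * 3L), n, 3L)
  traj <- prot2rna:::new_trajectory(atoms, list(xyz))
  ctr <- colSums(xyz * atoms$mass) / sum(atoms$mass)
  want <- sqrt(sum(atoms$mass * rowSums((xyz - matrix(ctr, n, 3L,
                                                      byrow = TRUE))^2)) /
                 sum(atoms$mass))
  expect_equal(rg_series(traj, "all"), want)
})

test_that("free-energy landscapes follow -kT ln P with the minimum at zero", {
  # uniform occupancy: flat landscape, depth 0
  fel <- free_energy_landscape(c(0.25, 0.25, 0.75, 0.75),
                               c(0.25, 0.75, 0.25, 0.75),
                               bins = 2L, sigma_bins = 0)
  expect_equal(fel$depth, 0)
  expect_true(all(abs(fel$F[is.finite(fel$F)]) < 1e-12))

  # two-state occupancy 0.9 / 0.1 at T = 310 K: depth kT ln 9
  rmsd <- c(rep(1, 9L), rep(3, 1L))
  rg <- rep(5, 10L)
  fel2 <- free_energy_landscape(rmsd, rg, bins = 2L, sigma_bins = 0,
                                temperature = 310)
  kT <- 0.0019872 * 310
  expect_equal(fel2$depth, kT * log(9), tolerance = 1e-12)
  expect_equal(sum(fel2$P), 1)
  expect_equal(min(fel2$F, na.rm = TRUE), 0)

  # sigma = 0 equals the raw histogram landscape; smoothing changes it
  set.seed(91)
  r1 <- rnorm(300); r2 <- rnorm(300, 1)
  raw <- free_energy_landscape(r1, r2, bins = 10L, sigma_bins = 0)
  smo <- free_energy_landscape(r1, r2, bins = 10L, sigma_bins = 1)
  expect_false(isTRUE(all.equal(raw$F, smo$F)))
  expect_equal(sum(smo$P), 1, tolerance = 1e-12)

  # depth is invariant to frame order
  idx <- sample(300L)
  shuffled <- free_energy_landscape(r1[idx], r2[idx], bins = 10L,
                                    sigma_bins = 1)
  expect_equal(shuffled$depth, smo$depth)

  # all points identical: single-bin grid, depth 0
  flat <- free_energy_landscape(rep(2, 5L), rep(7, 5L))
  expect_equal(dim(flat$P), c(1L, 1L))
  expect_equal(flat$depth, 0)
})

test_that("per-frame metric tables line up with the energy table", {
  toy <- make_toy_trajectory(n_frames = 5L, drift_per_frame = 0.5,
                             delta_e = c(-5, -4, -3, -2, -1), seed = 14L)
  df <- trajectory_metrics(toy$trajectory, toy$energies)
  expect_equal(nrow(df), 5L)
  expect_equal(df$delta_e, c(-5, -4, -3, -2, -1))
  expect_equal(df$hbonds, rep(3L, 5L))
  bad <- toy$energies[1:3, ]
  expect_error(trajectory_metrics(toy$trajectory, bad), "do not match")
})
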