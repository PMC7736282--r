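test_that("constructed donor geometry is detected at the criteria", {
  # O-H...O with d = 0.29 nm and a 10 degree angle: one bond
  atoms <- data.frame(atom_name = c("OG", "HG", "OD1"),
                      element = c("O", "H", "O"),
                      res_name = c("SER", "SER", "ASP"),
                      res_no = c(1L, 1L, 2L), chain = "A",
                      sidechain = TRUE)
  hdir <- c(sin(10 * pi / 180), cos(10 * pi / 180), 0)
  xyz <- rbind(c(0, 0, 0), 0.10 * hdir, c(0, 0.29, 0))
  hb <- detect_hbonds(atoms, xyz)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, 1L)
  expect_equal(hb$acceptor, 3L)
  expect_equal(hb$angle, 10, tolerance = 1e-6)
  # same geometry at 0.40 nm: no bond
  xyz2 <- xyz; xyz2[3, 2] <- 0.40
  expect_equal(nrow(detect_hbonds(atoms, xyz2)), 0L)
  # angle beyond 30 degrees: no bond
  xyz3 <- xyz; xyz3[2, ] <- 0.10 * c(sin(0.6), cos(0.6), 0)
  expect_equal(nrow(detect_hbonds(atoms, xyz3)), 0L)
})

test_that("hydrogen-bond detection equals the brute-force oracle", {
  crit <- hbond_criteria()
  for (seed in 1:100) {
    fr <- random_frame(50, seed = seed)
    got <- detect_hbonds(fr$atoms, fr$xyz, criteria = crit)
    got <- got[order(got$donor, got$hydrogen, got$acceptor),
               c("donor", "hydrogen", "acceptor")]
    rownames(got) <- NULL
    want <- oracle_hbonds(fr$atoms, fr$xyz, crit)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("saturating criteria register every hydrogen-bearing donor pair", {
  fr <- random_frame(30, seed = 7)
  crit <- hbond_criteria(max_distance = 100, max_angle = 90)
  got <- detect_hbonds(fr$atoms, fr$xyz, criteria = crit)
  want <- oracle_hbonds(fr$atoms, fr$xyz, crit)
  expect_equal(nrow(got), nrow(want))
})

test_that("planted schedules give exact occupancies", {
  sch <- list(list(pair = c(1, 2), frames = 1:30))
  tt <- gen_toy_trajectory(n_residues = 4, n_frames = 100,
                           hbond_schedule = sch, seed = 1)
  net <- occurrence_network(tt$trajectory, residue_set = 1:4,
                            equilibration = 0)
  expect_equal(net$frames_analysed, 100L)
  expect_equal(nrow(net$pairs), 1L)
  expect_equal(net$pairs$occupancy, 0.30)
  # a pair never within the cutoff has no edge
  expect_false(any(net$pairs$res_a == 3 | net$pairs$res_b == 3))
  expect_equal(igraph::ecount(net$graph), 1L)
})

test_that("pooling replicates conserves counts", {
  t1 <- gen_toy_trajectory(n_residues = 3, n_frames = 50, replicate = 1,
                           hbond_schedule = list(list(pair = c(1, 2),
                                                      frames = 1:20)))
  t2 <- gen_toy_trajectory(n_residues = 3, n_frames = 50, replicate = 2,
                           hbond_schedule = list(list(pair = c(1, 2),
                                                      frames = 1:10)))
  net <- occurrence_network(list(t1$trajectory, t2$trajectory),
                            residue_set = 1:3, equilibration = 0)
  expect_equal(net$frames_analysed, 100L)
  expect_equal(net$pairs$count, 30L)
  expect_equal(net$pairs$count_rep_1, 20L)
  expect_equal(net$pairs$count_rep_2, 10L)
  expect_equal(net$pairs$occupancy, 0.30)
})

test_that("per-frame bond counts use the even-count median convention", {
  # bond present in alternating frames: median 0.5
  sch <- list(list(pair = c(1, 2), frames = seq(1, 100, by = 2)))
  tt <- gen_toy_trajectory(n_residues = 2, n_frames = 100,
                           hbond_schedule = sch)
  hc <- hbond_count_series(tt$trajectory, 1, 2)
  pooled <- hc$summary[hc$summary$replicate == "pooled", ]
  expect_equal(pooled$median, 0.5)
  # never in contact: median 0
  tt0 <- gen_toy_trajectory(n_residues = 2, n_frames = 20)
  hc0 <- hbond_count_series(tt0$trajectory, 1, 2)
  expect_equal(hc0$summary$median, c(0, 0))
})

test_that("distance series are exact and symmetric in their arguments", {
  sch <- list(list(pair = c(1, 2), frames = 1:10))
  tt <- gen_toy_trajectory(n_residues = 2, n_frames = 25,
                           hbond_schedule = sch)
  d <- atom_distance_series(tt$trajectory, 1, "OG", 2, "OG")
  expect_equal(d$distance[1:10], rep(0.29, 10))
  expect_equal(d$distance[11:25], rep(0.45, 15))
  d2 <- atom_distance_series(tt$trajectory, 2, "OG", 1, "OG")
  expect_equal(d2$distance, d$distance)
  expect_error(atom_distance_series(tt$trajectory, 1, "OG", 1, "OG"),
               "same atom")
  expect_error(atom_distance_series(tt$trajectory, 1, "XX", 2, "OG"),
               "no atom")
})

test_that("side-chain RMSD is zero for identical and rigidly moved frames", {
  tt <- gen_toy_trajectory(n_residues = 4, n_frames = 10)
  rs <- sidechain_rmsd_series(tt$trajectory, residue_set = 1:4)
  expect_true(all(rs$series$rmsd < 1e-10))
  # rigid rotation + translation of every frame
  traj <- tt$trajectory
  for (f in seq_len(dim(traj$coords)[3])) {
    motion <- random_rigid_motion(seed = f)
    traj$coords[, , f] <- apply_rigid(traj$coords[, , f], motion)
  }
  rs2 <- sidechain_rmsd_series(traj, residue_set = 1:4,
                               reference = tt$truth$reference)
  expect_true(all(rs2$series$rmsd < 1e-10))
})

test_that("RMSD grows monotonically with planted fluctuation", {
  sigmas <- c(0.01, 0.02, 0.05, 0.1)
  medians <- vapply(seq_along(sigmas), function(i) {
    tt <- gen_toy_trajectory(n_residues = 4, n_frames = 150,
                             sigma = sigmas[i], seed = 100 + i)
    rs <- sidechain_rmsd_series(tt$trajectory, residue_set = 1:4,
                                reference = tt$truth$reference)
    rs$summary$median[rs$summary$replicate == "pooled"]
  }, numeric(1))
  expect_true(all(diff(medians) > 0))
})

test_that("mean RMSD matches the closed-form isotropic expectation", {
  # 4 measured side-chain atoms, each coordinate N(0, sigma^2) about an
  # exact reference: E[RMSD^2] = 3 sigma^2
  sigma <- 0.05
  tt <- gen_toy_trajectory(n_residues = 4, n_frames = 1000, sigma = sigma,
                           seed = 77)
  rs <- sidechain_rmsd_series(tt$trajectory, residue_set = 1:4,
                              reference = tt$truth$reference)
  expect_equal(sqrt(mean(rs$series$rmsd^2)), sqrt(3) * sigma,
               tolerance = 0.05)
})

test_that("trajectories round-trip through multi-model PDB in Angstrom", {
  sch <- list(list(pair = c(1, 2), frames = 1:5))
  tt <- gen_toy_trajectory(n_residues = 3, n_frames = 8,
                           hbond_schedule = sch, sigma = 0.01, seed = 3)
  frames <- tempfile(fileext = ".pdb")
  top <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tt$trajectory, frames, topology_path = top)
  back <- read_trajectory(top, frames, dt_ps = 10)
  expect_equal(dim(back$coords)[3], 8L)
  # PDB stores Angstrom at 3 decimals; internal nm should match to 1e-4
  expect_equal(back$coords, tt$trajectory$coords, tolerance = 1e-3)
  # the planted bond survives the round trip
  net <- occurrence_network(back, residue_set = 1:3, equilibration = 0)
  expect_equal(net$pairs$count, 5L)
  unlink(c(frames, top))
})

test_that("atom-count mismatches between topology and frames error", {
  tt3 <- gen_toy_trajectory(n_residues = 3, n_frames = 4)
  tt4 <- gen_toy_trajectory(n_residues = 4, n_frames = 4)
  f3 <- tempfile(fileext = ".pdb"); t4 <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tt3$trajectory, f3)
  write_trajectory_pdb(tt4$trajectory, tempfile(fileext = ".pdb"),
                       topology_path = t4)
  expect_error(read_trajectory(t4, f3), "mismatch")
  unlink(c(f3, t4))
})

test_that("equilibration detection keeps stable toy trajectories whole", {
  tt <- gen_toy_trajectory(n_residues = 3, n_frames = 60, sigma = 0.01,
                           dt_ps = 100, seed = 12)
  expect_equal(detect_equilibration(tt$trajectory), 1L)
  net <- occurrence_network(tt$trajectory, residue_set = 1:3)
  expect_equal(net$frames_analysed, 60L)
})

test_that("heavy-atom-only topologies fall back to the proxy criterion", {
  atoms <- data.frame(atom_name = c("OG", "CB", "OD1"),
                      element = c("O", "C", "O"),
                      res_name = c("SER", "ASP", "ASP"),
                      res_no = c(1L, 2L, 2L), chain = "A", sidechain = TRUE)
  # donor O, acceptor O at 0.30 nm, antecedent carbon behind the acceptor
  xyz <- rbind(c(0, 0, 0), c(0, 0.44, 0), c(0, 0.30, 0))
  hb <- detect_hbonds(atoms, xyz)
  expect_equal(attr(hb, "mode"), "heavy_only")
  expect_equal(nrow(hb), 2L)  # both directions, no hydrogens to orient
  expect_true(all(is.na(hb$hydrogen)))
})
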