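test_that("dihedral handles the symmetric planar cases", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, -1, 1)), 180)
})

test_that("dihedral matches the two-normal oracle on random quadruples", {
  set.seed(101)
  for (i in 1:100) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral is rigid-motion invariant and mirror-antisymmetric", {
  set.seed(102)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    R <- random_rotation(); t <- rnorm(3)
    q <- sweep(p %*% t(R), 2, t, "+")
    d0 <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), d0, tolerance = 1e-9)
    m <- p; m[, 1] <- -m[, 1]
    expect_equal(dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -d0, tolerance = 1e-9)
  }
})

test_that("degenerate dihedral geometry raises errors", {
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               class = "gpcrtraj_geometry_error")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "gpcrtraj_geometry_error")
})

test_that("chi series recover constructed side-chain angles", {
  spec <- synthetic_spec(n_frames = 4, n_residues = 15, seed = 3, noise_sigma = 0,
                         chi_schedules = list(
                           chi_schedule(211, "chi2", tibble::tibble(frame = 1, value = 90),
                                        residue_name = "TRP")),
                         background_waters = 0)
  traj <- build_bundle(spec)$trajectory
  s <- chi_series(traj, 211, "chi2")
  expect_equal(s$value, rep(90, 4), tolerance = 1e-6)
  # identical coordinates every frame -> constant series
  expect_equal(length(unique(round(s$value, 9))), 1)
})

test_that("residues without the requested chi are rejected", {
  atoms <- atom_row(c("N", "CA", "C", "O"), "GLY", 1)
  traj <- make_traj(atoms, list(matrix(rnorm(12), 4, 3)))
  expect_error(chi_series(traj, 1, "chi1"), class = "gpcrtraj_definition_error")
  atoms2 <- atom_row(c("N", "CA", "C", "O", "CB", "OG"), "SER", 1)
  traj2 <- make_traj(atoms2, list(matrix(rnorm(18), 6, 3)))
  expect_error(chi_series(traj2, 1, "chi2"), class = "gpcrtraj_definition_error")
})

test_that("helix axis fit recovers known directions", {
  X <- ideal_helix_ca(1:10)
  ax <- fit_helix_axis(X)
  expect_gt(sum(ax$direction * c(0, 0, 1)), cos(1 * pi / 180))
  set.seed(7)
  R <- random_rotation()
  ax2 <- fit_helix_axis(X %*% t(R))
  expect_gt(sum(ax2$direction * drop(R %*% c(0, 0, 1))), cos(1 * pi / 180))
  expect_error(fit_helix_axis(X[1:3, ]), class = "gpcrtraj_insufficient_data_error")
})

test_that("kink angle reads 180 for straight and tracks planted bends", {
  traj <- kinked_ca_traj(c(0, 25, 50))
  h <- helix_def(1, 1, 15, anchor_seq = 8, intracellular_end = "start")
  kk <- kink_series(traj, h, pivot_seq = 8, window = 7, smooth_frames = 0)
  expect_equal(kk$kink[1], 180, tolerance = 2)
  expect_equal(kk$kink[2], 155, tolerance = 2)
  expect_equal(kk$kink[3], 130, tolerance = 2)
})

test_that("kink is monotone in the constructed bend over 0-90 degrees", {
  bends <- seq(0, 90, by = 10)
  traj <- kinked_ca_traj(bends)
  h <- helix_def(1, 1, 15, anchor_seq = 8, intracellular_end = "start")
  kk <- kink_series(traj, h, pivot_seq = 8, window = 7, smooth_frames = 0)
  expect_true(all(diff(kk$kink) < 0))
})

test_that("kink arms must fit inside the helix", {
  traj <- kinked_ca_traj(0)
  h <- helix_def(1, 1, 15, anchor_seq = 8, intracellular_end = "start")
  expect_error(kink_series(traj, h, pivot_seq = 8, window = 8),
               class = "gpcrtraj_insufficient_data_error")
  expect_error(kink_series(traj, h, pivot_seq = 8, window = 3),
               class = "gpcrtraj_insufficient_data_error")
})

test_that("superposition is exact for rigidly moved copies", {
  set.seed(201)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(); t <- rnorm(3)
  Y <- sweep(X %*% t(R), 2, t, "+")
  sp <- superpose(X, Y)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$fitted, X, tolerance = 1e-9)
  # returned transform maps mobile onto ref
  expect_equal(sweep(Y %*% t(sp$rotation), 2, sp$translation, "+"), X,
               tolerance = 1e-9)
})

test_that("superposition RMSD equals a brute-force rotation search", {
  set.seed(202)
  for (i in 1:8) {
    A <- matrix(rnorm(12), 4, 3)
    B <- matrix(rnorm(12), 4, 3)
    expect_equal(superpose(A, B)$rmsd, rmsd_bruteforce(A, B), tolerance = 1e-6)
  }
})

test_that("superposition agrees with the bio3d reference fit", {
  set.seed(203)
  for (i in 1:10) {
    A <- matrix(rnorm(45), 15, 3)
    B <- A + matrix(rnorm(45, sd = 0.5), 15, 3)
    # bio3d::rmsd prints at 3 decimals
    expect_equal(superpose(A, B)$rmsd,
                 suppressWarnings(bio3d::rmsd(as.vector(t(A)), as.vector(t(B)),
                                              fit = TRUE)),
                 tolerance = 1e-3)
  }
})

test_that("degenerate superposition input raises geometry errors", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "gpcrtraj_geometry_error")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), class = "gpcrtraj_geometry_error")
})

test_that("rmsd series is zero under per-frame rigid motion", {
  set.seed(204)
  X <- matrix(rnorm(60), 20, 3)
  atoms <- atom_row(rep("CA", 20), rep("ALA", 20), 1:20)
  frames <- lapply(1:5, function(k) {
    R <- random_rotation()
    sweep(X %*% t(R), 2, rnorm(3, sd = 5), "+")
  })
  traj <- make_traj(atoms, c(list(X), frames))
  rr <- rmsd_series(traj, "name CA")
  expect_equal(rr$rmsd, rep(0, 6), tolerance = 1e-6)
})

test_that("rmsd series equals the explicit formula after reference fitting", {
  set.seed(205)
  X <- matrix(rnorm(60), 20, 3)
  atoms <- atom_row(rep("CA", 20), rep("ALA", 20), 1:20)
  frames <- lapply(1:5, function(k) X + matrix(rnorm(60, sd = 0.3), 20, 3))
  traj <- make_traj(atoms, c(list(X), frames))
  rr <- rmsd_series(traj, "name CA")
  for (k in 2:6) {
    Y <- matrix(traj$coords[k, , ], ncol = 3)
    # independent oracle: bio3d superposition + explicit sqrt(sum d^2 / n)
    fitted <- matrix(suppressWarnings(bio3d::fit.xyz(as.vector(t(X)), as.vector(t(Y)))),
                     ncol = 3, byrow = TRUE)
    expect_equal(rr$rmsd[k], sqrt(sum((fitted - X)^2) / nrow(X)), tolerance = 1e-6)
  }
  expect_error(rmsd_series(traj, "water"), class = "gpcrtraj_selection_error")
})

test_that("end distances equal constructed centroid separations", {
  # two straight vertical helices 10 A apart, plus a third for the triple
  n <- 8
  mk <- function(dx, dy) cbind(rep(dx, n), rep(dy, n), 1.5 * (1:n))
  atoms <- dplyr::bind_rows(
    atom_row(rep("CA", n), rep("ALA", n), 301:308),
    atom_row(rep("CA", n), rep("ALA", n), 601:608),
    atom_row(rep("CA", n), rep("ALA", n), 701:708))
  X <- rbind(mk(0, 0), mk(10, 0), mk(0, 24))
  traj <- make_traj(atoms, list(X))
  hel <- list(helix_def(3, 301, 308, 304, intracellular_end = "start"),
              helix_def(6, 601, 608, 604, intracellular_end = "start"),
              helix_def(7, 701, 708, 704, intracellular_end = "start"))
  ed <- end_distance_series(traj, hel, end_length = 4)
  expect_equal(ed$tm3_tm6[1], 10, tolerance = 1e-6)
  expect_equal(ed$tm7_tm3[1], 24, tolerance = 1e-6)
  expect_equal(ed$tm6_tm7[1], sqrt(10^2 + 24^2), tolerance = 1e-6)
  # end_length = 1 reduces to the single terminal Calpha distance
  ed1 <- end_distance_series(traj, hel, end_length = 1)
  expect_equal(ed1$tm3_tm6[1], 10, tolerance = 1e-9)
  expect_error(end_distance_series(traj, hel, end_length = 9),
               class = "gpcrtraj_range_error")
})

test_that("end distances match a direct centroid oracle on random frames", {
  set.seed(206)
  spec <- condition_spec("agonist", n_frames = 12, seed = 9)
  traj <- build_bundle(spec)$trajectory
  hel <- synthetic_helix_defs(spec)[c(3, 6, 7)]
  ed <- end_distance_series(traj, hel, end_length = 4)
  cent <- function(k, h) {
    res <- (h * 100 + 1):(h * 100 + 4)
    idx <- which(traj$topology$atoms$resid %in% res & traj$topology$atoms$name == "CA" &
                   traj$topology$atoms$chain == "A")
    colMeans(matrix(traj$coords[k, idx, ], ncol = 3))
  }
  for (k in c(1, 7, 12)) {
    expect_equal(ed$tm7_tm3[k], sqrt(sum((cent(k, 7) - cent(k, 3))^2)), tolerance = 1e-9)
    expect_equal(ed$tm3_tm6[k], sqrt(sum((cent(k, 3) - cent(k, 6))^2)), tolerance = 1e-9)
    expect_equal(ed$tm6_tm7[k], sqrt(sum((cent(k, 6) - cent(k, 7))^2)), tolerance = 1e-9)
  }
  # triangle inequality holds per frame
  expect_true(all(ed$tm7_tm3 <= ed$tm3_tm6 + ed$tm6_tm7 + 1e-9))
  expect_true(all(ed$tm3_tm6 <= ed$tm7_tm3 + ed$tm6_tm7 + 1e-9))
  expect_true(all(ed$tm6_tm7 <= ed$tm7_tm3 + ed$tm3_tm6 + 1e-9))
})

test_that("geometric observables are invariant under a global rigid motion", {
  set.seed(207)
  spec <- condition_spec("agonist", n_frames = 6, seed = 13)
  b <- build_bundle(spec)
  traj <- b$trajectory
  R <- random_rotation(); tr <- rnorm(3, sd = 20)
  coords2 <- traj$coords
  for (k in seq_len(n_frames(traj)))
    coords2[k, , ] <- sweep(matrix(traj$coords[k, , ], ncol = 3) %*% t(R), 2, tr, "+")
  traj2 <- gpcrtraj:::new_trajectory(traj$topology, coords2, traj$times)
  hel <- synthetic_helix_defs(spec)
  expect_equal(kink_series(traj2, hel[[7]], 713, smooth_frames = 0)$kink,
               kink_series(traj, hel[[7]], 713, smooth_frames = 0)$kink,
               tolerance = 1e-6)
  expect_equal(chi_series(traj2, 611, "chi2")$value,
               chi_series(traj, 611, "chi2")$value, tolerance = 1e-6)
  expect_equal(end_distance_series(traj2, hel[c(3, 6, 7)]),
               end_distance_series(traj, hel[c(3, 6, 7)]), tolerance = 1e-6)
  expect_equal(rmsd_series(traj2, "backbone")$rmsd,
               rmsd_series(traj, "backbone")$rmsd, tolerance = 1e-6)
})
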