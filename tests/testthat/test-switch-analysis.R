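angle_tibble <- function(values, dt = 1) {
  tibble::tibble(frame = seq_along(values), time_ns = (seq_along(values) - 1) * dt,
                 value = values)
}

test_that("rotamer bins cover the circle and classify canonical angles", {
  b <- rotamer_bins()
  expect_equal(sum(gpcrtraj:::bin_width(b$lo, b$hi)), 360)
  st <- classify_rotamers(angle_tibble(rep(-60, 30)), filter_window = 0)
  expect_true(all(st$state == "g-"))
  st2 <- classify_rotamers(angle_tibble(rep(65, 30)), filter_window = 0)
  expect_true(all(st2$state == "g+"))
  # circular continuity at the trans boundary
  st3 <- classify_rotamers(angle_tibble(c(179.9, -179.9, 175, -175)), filter_window = 0)
  expect_true(all(st3$state == "t"))
})

test_that("two-center toggle bins split the circle at midpoints", {
  b <- rotamer_bins_from_centers(c(down = 0, up = 90))
  st <- classify_rotamers(angle_tibble(c(10, 40, 50, 100, -100, -140)), b,
                          filter_window = 0)
  # circular nearest-center assignment: -100 is closer to 0, -140 closer to 90
  expect_equal(st$state, c("down", "down", "up", "up", "down", "up"))
})

test_that("invalid bin sets are rejected", {
  overlap <- tibble::tibble(label = c("a", "b"), lo = c(-180, -90), hi = c(0, 180))
  expect_error(classify_rotamers(angle_tibble(0), overlap),
               class = "gpcrtraj_definition_error")
  gap <- tibble::tibble(label = c("a", "b"), lo = c(0, 90), hi = c(80, 0))
  expect_error(classify_rotamers(angle_tibble(0), gap),
               class = "gpcrtraj_definition_error")
  expect_error(classify_rotamers(angle_tibble(rep(0, 5)), filter_window = 4),
               class = "gpcrtraj_definition_error")
})

test_that("planted two-state schedules are recovered frame by frame", {
  set.seed(31)
  truth <- rep(c(0, 90, 0), times = c(200, 250, 150))
  noisy <- truth + rnorm(length(truth), 0, 10)
  st <- classify_rotamers(angle_tibble(noisy),
                          rotamer_bins_from_centers(c(down = 0, up = 90)),
                          filter_window = 21)
  truth_lab <- ifelse(truth == 0, "down", "up")
  # away from the filter half-window around transitions, labels match truth
  half <- 10
  trans <- c(201, 451)
  guard <- unlist(lapply(trans, function(tr) (tr - half):(tr + half)))
  core <- setdiff(seq_along(truth), guard)
  expect_true(all(st$state[core] == truth_lab[core]))
})

test_that("switch events fire at step onsets and ignore short excursions", {
  flat <- classify_rotamers(angle_tibble(rep(-60, 300)), filter_window = 0)
  expect_equal(nrow(detect_switches(flat, 50)), 0)

  step <- classify_rotamers(angle_tibble(rep(c(-60, 60), c(499, 301))),
                            filter_window = 0)
  ev <- detect_switches(step, 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 500)
  expect_equal(ev$from_state, "g-")
  expect_equal(ev$to_state, "g+")
  expect_gte(ev$post_dwell, 50)

  blip <- classify_rotamers(angle_tibble(rep(c(-60, 60, -60), c(400, 10, 390))),
                            filter_window = 0)
  expect_equal(nrow(detect_switches(blip, 50)), 0)
})

test_that("event detection is invariant to prepending initial-state frames", {
  base <- rep(c(-60, 60), c(300, 200))
  ev1 <- detect_switches(classify_rotamers(angle_tibble(base), filter_window = 0), 50)
  ev2 <- detect_switches(classify_rotamers(angle_tibble(c(rep(-60, 150), base)),
                                           filter_window = 0), 50)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(ev2$frame, ev1$frame + 150)
  expect_equal(ev1$from_state, ev2$from_state)
  expect_equal(ev1$to_state, ev2$to_state)
})

# micro-fixture: donor O with one H, acceptor O placed at a chosen
# distance/angle
hbond_fixture <- function(da_dist, dha_angle) {
  d <- c(0, 0, 0)
  h <- c(1.0, 0, 0)
  # acceptor placed so the D-H...A angle at H equals dha_angle
  th <- (180 - dha_angle) * pi / 180
  a_dir <- c(cos(th), sin(th), 0)
  # solve |D-A| = da_dist with A = H + r * a_dir
  f <- function(r) sqrt(sum((h + r * a_dir - d)^2)) - da_dist
  r <- uniroot(f, c(0.01, 10))$root
  a <- h + r * a_dir
  atoms <- dplyr::bind_rows(
    atom_row(c("OG", "HG"), "SER", 1, element_override = c("O", "H")),
    atom_row("O", "GLY", 2, element_override = "O"))
  make_traj(atoms, list(rbind(d, h, a)))
}

test_that("hydrogen bonds follow the distance + angle criterion", {
  t1 <- hbond_fixture(2.8, 170)
  s1 <- hbond_series(t1, list(residue = 1, atom = "OG"), list(residue = 2, atom = "O"))
  expect_true(all(s1$present))
  expect_equal(attr(s1, "mode"), "hydrogen")
  expect_equal(attr(s1, "occupancy"), 1)

  t2 <- hbond_fixture(4.0, 170)
  s2 <- hbond_series(t2, list(residue = 1, atom = "OG"), list(residue = 2, atom = "O"))
  expect_false(any(s2$present))

  t3 <- hbond_fixture(2.8, 120)
  s3 <- hbond_series(t3, list(residue = 1, atom = "OG"), list(residue = 2, atom = "O"))
  expect_false(any(s3$present))
})

test_that("hydrogen-free donors fall back to the flagged heavy-atom criterion", {
  atoms <- dplyr::bind_rows(atom_row("OG", "SER", 1), atom_row("O", "GLY", 2))
  traj <- make_traj(atoms, list(rbind(c(0, 0, 0), c(3.0, 0, 0))))
  s <- hbond_series(traj, list(residue = 1, atom = "OG"), list(residue = 2, atom = "O"))
  expect_equal(attr(s, "mode"), "heavy")
  expect_true(all(s$present))
  expect_error(hbond_series(traj, list(residue = 1, atom = "XX"),
                            list(residue = 2, atom = "O")),
               class = "gpcrtraj_selection_error")
})

test_that("contact occupancy flags exactly the residues within the cutoff", {
  atoms <- dplyr::bind_rows(
    atom_row("C1", "LIG", 900),
    atom_row("CA", "ALA", 1), atom_row("CA", "ALA", 2), atom_row("CA", "ALA", 3))
  X <- rbind(c(0, 0, 0), c(3, 0, 0), c(7, 0, 0), c(20, 0, 0))
  traj <- make_traj(atoms, list(X))
  ct <- contact_occupancy(traj, "resname LIG", cutoff = 4.0)
  expect_equal(ct$occupancy[ct$residue_seq == 1], 1)
  expect_equal(ct$occupancy[ct$residue_seq == 2], 0)
  expect_equal(ct$occupancy[ct$residue_seq == 3], 0)
  # cutoff zero -> nothing in contact
  ct0 <- contact_occupancy(traj, "resname LIG", cutoff = 0)
  expect_true(all(ct0$occupancy == 0))
  expect_error(contact_occupancy(traj, "resname XYZ"),
               class = "gpcrtraj_selection_error")
})

test_that("contact occupancy equals a brute-force all-pairs scan", {
  set.seed(33)
  n_res <- 30
  atoms <- dplyr::bind_rows(
    atom_row(rep("C1", 4), "LIG", 900),
    atom_row(rep("CA", n_res), "ALA", seq_len(n_res)))
  frames <- lapply(1:5, function(k)
    rbind(matrix(runif(12, 0, 20), 4, 3), matrix(runif(n_res * 3, 0, 20), n_res, 3)))
  traj <- make_traj(atoms, frames)
  ct <- contact_occupancy(traj, "resname LIG", cutoff = 4.0)
  # oracle: direct distance scan
  occ <- sapply(seq_len(n_res), function(r) {
    mean(sapply(1:5, function(k) {
      L <- frames[[k]][1:4, , drop = FALSE]
      p <- frames[[k]][4 + r, ]
      any(sqrt(colSums((t(L) - p)^2)) <= 4.0)
    }))
  })
  expect_equal(ct$occupancy[order(ct$residue_seq)], occ)
  # occupancy is frame-permutation invariant
  traj2 <- make_traj(atoms, frames[c(3, 1, 5, 2, 4)])
  ct2 <- contact_occupancy(traj2, "resname LIG", cutoff = 4.0)
  expect_equal(ct2$occupancy, ct$occupancy)
})
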