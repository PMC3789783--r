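test_that("zero-noise constant schedules are recovered exactly", {
  spec <- synthetic_spec(
    n_frames = 6, n_residues = 20, seed = 2, noise_sigma = 0,
    chi_schedules = list(
      chi_schedule(305, "chi1", tibble::tibble(frame = 1, value = -60), "TYR"),
      chi_schedule(411, "chi2", tibble::tibble(frame = 1, value = 90), "TRP")),
    kink_schedules = list(
      kink_schedule(7, 10, tibble::tibble(frame = 1, kappa = 150))),
    background_waters = 0)
  b <- build_bundle(spec)
  expect_equal(chi_series(b$trajectory, 305, "chi1")$value, rep(-60, 6),
               tolerance = 1e-6)
  expect_equal(chi_series(b$trajectory, 411, "chi2")$value, rep(90, 6),
               tolerance = 1e-6)
  hel <- synthetic_helix_defs(spec)
  kk <- kink_series(b$trajectory, hel[[7]], 710, window = 6, smooth_frames = 0)
  expect_equal(kk$kink, rep(150, 6), tolerance = 0.1)
})

test_that("alternating water schedules are realised exactly at zero noise", {
  counts <- rep(c(3L, 9L), 10)
  spec <- synthetic_spec(n_frames = 20, seed = 3, noise_sigma = 0,
                         water_schedules = list(water_schedule(213, 4.0, counts)),
                         background_waters = 10)
  b <- build_bundle(spec)
  s <- water_count_series(b$trajectory, "resid 213 and heavy", cutoff = 4.0)
  expect_identical(s$count, counts)
})

test_that("a linear kink drift is recovered at its endpoints under noise", {
  spec <- synthetic_spec(n_frames = 300, seed = 5, noise_sigma = 0.2,
                         kink_schedules = list(
                           kink_schedule(7, 13, tibble::tibble(frame = c(1, 300),
                                                               kappa = c(155, 130)))),
                         background_waters = 0)
  b <- build_bundle(spec)
  hel <- synthetic_helix_defs(spec)
  kk <- kink_series(b$trajectory, hel[[7]], 713, window = 7)
  expect_equal(kk$kink[1], 155, tolerance = 2)
  expect_equal(kk$kink[300], 130, tolerance = 2)
  # mid-run tracks the schedule too
  expect_equal(kk$kink[150], b$truth$kink$kappa[150], tolerance = 2.5)
})

test_that("planted chi segment means and flip times are recovered", {
  n <- 300
  spec <- synthetic_spec(n_frames = n, seed = 6, noise_sigma = 0.2,
                         chi_schedules = list(
                           chi_schedule(611, "chi2",
                                        tibble::tibble(frame = c(1, 150), value = c(0, 90)),
                                        "TRP")),
                         background_waters = 0)
  b <- build_bundle(spec)
  s <- chi_series(b$trajectory, 611, "chi2")
  # segment-mean recovery
  expect_equal(mean(s$value[1:130]), 0, tolerance = 3)
  expect_equal(mean(s$value[170:n]), 90, tolerance = 3)
  # flip-time recovery within the filter half-window
  st <- classify_rotamers(s, rotamer_bins_from_centers(c(down = 0, up = 90)),
                          filter_window = 21)
  ev <- detect_switches(st, min_dwell = 50)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$frame - 150), 11)
})

test_that("identical specs and seeds give byte-identical fixture files", {
  d1 <- file.path(tempdir(), "suiteA"); d2 <- file.path(tempdir(), "suiteB")
  s1 <- write_fixture_suite(d1, n_frames = 30, seed = 99)
  s2 <- write_fixture_suite(d2, n_frames = 30, seed = 99)
  expect_equal(nrow(s1), 3)
  expect_setequal(s1$condition, c("apo", "antagonist", "agonist"))
  for (i in 1:3) {
    expect_identical(readLines(s1$pdb[i]), readLines(s2$pdb[i]))
    expect_identical(readLines(s1$manifest[i]), readLines(s2$manifest[i]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the agonist-like manifest plants all three activation states", {
  spec <- condition_spec("agonist", n_frames = 60, seed = 4)
  b <- build_bundle(spec)
  expect_setequal(unique(b$truth$states$state),
                  c("inactive", "intermediate", "active"))
  expect_equal(nrow(b$truth$states), 60)
  # and the generated file parses with a standards-conforming reader
  f <- tempfile(fileext = ".pdb")
  write_trajectory(b$trajectory, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, multi = TRUE, verbose = FALSE))
  expect_equal(nrow(pdb$atom), nrow(b$trajectory$topology$atoms))
  expect_equal(nrow(pdb$xyz), 60)
})

test_that("infeasible or dangling schedules raise spec errors", {
  expect_error(
    end_state_schedule(tibble::tibble(state = "x", frames = 1, tm7_tm3 = 30,
                                      tm3_tm6 = 5, tm6_tm7 = 5)),
    class = "gpcrtraj_spec_error")
  expect_error(
    synthetic_spec(n_frames = 5, chi_schedules = list(
      chi_schedule(999, "chi1", tibble::tibble(frame = 1, value = 0)))),
    class = "gpcrtraj_spec_error")
  expect_error(
    synthetic_spec(n_frames = 5, kink_schedules = list(
      kink_schedule(9, 13, tibble::tibble(frame = 1, kappa = 150)))),
    class = "gpcrtraj_spec_error")
  expect_error(
    synthetic_spec(n_frames = 5, kink_schedules = list(
      kink_schedule(7, 2, tibble::tibble(frame = 1, kappa = 150)))),
    class = "gpcrtraj_spec_error")
})
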