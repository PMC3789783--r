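# the three study conditions as synthetic specs, and the fixture suite

#' Synthetic spec for a study condition
#'
#' Ready-made [synthetic_spec()]s emulating the three simulated conditions
#' of an S1P receptor activation study, with schedule timings expressed as
#' fractions of the run so shorter test trajectories keep the same shape:
#'
#' * `apo` — early chi1 flip of the 2.57 tyrosine analogue (at 1/7 of the
#'   run), stable 6.48/6.44 side chains, low hydration (3-4 waters) of the
#'   2.50 shell.
#' * `antagonist` — late 2.57 flip (at 11/14 of the run), a 6.48 chi2 that
#'   toggles between 0 and 90 degrees over the first ~70% of the run,
#'   medium hydration (5-7).
#' * `agonist` — stable 2.57, unstable 6.48/6.44 (planted flips at 150/700,
#'   400/700 and 300/700 of the run), high hydration (8-10), a TM7 kink
#'   drifting linearly 155 to 130 degrees, and a three-phase
#'   inactive/intermediate/active end-distance schedule.
#'
#' @param condition `"apo"`, `"antagonist"` or `"agonist"`.
#' @param n_frames Number of frames (default 700, 1 ns per frame).
#' @param seed Integer seed.
#' @param noise_sigma Coordinate noise in Angstrom.
#' @return A `synthetic_spec`.
#' @export
condition_spec <- function(condition = c("apo", "antagonist", "agonist"),
                           n_frames = 700, seed = 1, noise_sigma = 0.2) {
  condition <- match.arg(condition)
  n <- as.integer(n_frames)
  at_frac <- function(x) max(2L, min(n, as.integer(round(x * n))))
  y257 <- synth_resid(2, 20)   # tyrosine at generic position 2.57
  w648 <- synth_resid(6, 11)   # tryptophan at 6.48
  f644 <- synth_resid(6, 7)    # phenylalanine at 6.44
  d250 <- synth_resid(2, 13)   # hydration target at 2.50

  chi_const <- function(res, angle, val, rn)
    chi_schedule(res, angle, tibble::tibble(frame = 1, value = val), residue_name = rn)
  y_flip <- function(frac)
    chi_schedule(y257, "chi1",
                 tibble::tibble(frame = c(1, at_frac(frac)), value = c(-60, 60)),
                 residue_name = "TYR")

  if (condition == "apo") {
    chi <- list(y_flip(100 / 700),
                chi_const(w648, "chi2", 0, "TRP"),
                chi_const(f644, "chi1", -60, "PHE"))
    wat <- list(water_schedule(d250, 4.0, list(min = 3, max = 4)))
    kinks <- list(); eds <- NULL
  } else if (condition == "antagonist") {
    toggles <- c(0.10, 0.20, 0.32, 0.44, 0.58, 0.71)
    wvals <- tibble::tibble(frame = c(1, vapply(toggles, at_frac, integer(1))),
                            value = c(0, 90, 0, 90, 0, 90, 0))
    chi <- list(y_flip(550 / 700),
                chi_schedule(w648, "chi2", wvals, residue_name = "TRP"),
                chi_const(f644, "chi1", -60, "PHE"))
    wat <- list(water_schedule(d250, 4.0, list(min = 5, max = 7)))
    kinks <- list(); eds <- NULL
  } else {
    chi <- list(chi_const(y257, "chi1", -60, "TYR"),
                chi_schedule(w648, "chi2",
                             tibble::tibble(frame = c(1, at_frac(150 / 700), at_frac(400 / 700)),
                                            value = c(0, 90, 0)),
                             residue_name = "TRP"),
                chi_schedule(f644, "chi1",
                             tibble::tibble(frame = c(1, at_frac(300 / 700)),
                                            value = c(-60, 60)),
                             residue_name = "PHE"))
    wat <- list(water_schedule(d250, 4.0, list(min = 8, max = 10)))
    kinks <- list(kink_schedule(7, 13,
                                tibble::tibble(frame = c(1, n), kappa = c(155, 130))))
    eds <- end_state_schedule(
      phases = tibble::tibble(
        state = c("inactive", "intermediate", "active"),
        frames = c(0.35, 0.30, 0.35),
        tm7_tm3 = c(22.0, 23.5, 25.5),
        tm3_tm6 = c(22.0, 23.0, 24.0),
        tm6_tm7 = c(10.0, 11.5, 13.5)),
      jitter_sd = 0.25)
  }
  synthetic_spec(n_frames = n, dt_ns = 700 / n, seed = seed,
                 noise_sigma = noise_sigma,
                 kink_schedules = kinks, chi_schedules = chi,
                 water_schedules = wat, end_distance_schedule = eds,
                 background_waters = 20)
}

truth_to_json <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    kink = truth$kink, chi = truth$chi, water = truth$water,
    states = truth$states, transitions = truth$transitions,
    spec = list(n_frames = truth$spec$n_frames, dt_ns = truth$spec$dt_ns,
                n_helices = truth$spec$n_helices,
                n_residues = truth$spec$n_residues,
                noise_sigma = truth$spec$noise_sigma)
  )
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the standard synthetic fixture suite
#'
#' Emits one multi-model PDB trajectory plus a JSON ground-truth manifest
#' for each of the apo-like, antagonist-like and agonist-like conditions
#' (see [condition_spec()]). Output is byte-identical for identical
#' arguments.
#'
#' @param output_dir Directory (created if needed).
#' @param n_frames Frames per trajectory.
#' @param seed Base seed; conditions use `seed`, `seed + 1`, `seed + 2`.
#' @param noise_sigma Coordinate noise in Angstrom.
#' @return Tibble with columns `condition`, `pdb`, `manifest`.
#' @export
write_fixture_suite <- function(output_dir, n_frames = 700, seed = 42,
                                noise_sigma = 0.2) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- c("apo", "antagonist", "agonist")
  out <- purrr::imap_dfr(setNames(conds, conds), function(cond, nm) {
    spec <- condition_spec(cond, n_frames = n_frames,
                           seed = seed + match(cond, conds) - 1L,
                           noise_sigma = noise_sigma)
    bundle <- build_bundle(spec)
    pdb <- file.path(output_dir, paste0(cond, ".pdb"))
    man <- file.path(output_dir, paste0(cond, "_truth.json"))
    write_trajectory(bundle$trajectory, pdb)
    truth_to_json(bundle$truth, man)
    tibble::tibble(condition = cond, pdb = pdb, manifest = man)
  })
  out
}
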