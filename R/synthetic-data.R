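# synthetic 7-helix-bundle trajectories with planted, scheduled observables

#' Schedule builders for synthetic trajectories
#'
#' `kink_schedule()` plants a helix kink whose angle follows a
#' piecewise-linear path through `breakpoints` (frame, kappa in degrees;
#' 180 = straight). `chi_schedule()` plants a side-chain dihedral path
#' (step interpolation by default, so a two-row table is a rotamer flip).
#' `water_schedule()` plants per-frame water-shell occupancies around one
#' residue: `counts` is an integer vector (length 1 or `n_frames`) or a
#' `list(min =, max =)` range sampled uniformly per frame.
#' `end_state_schedule()` plants conformational states as target triples of
#' intracellular end distances (TM7-TM3, TM3-TM6, TM6-TM7 in Angstrom)
#' held for `frames` weighted spans, with Gaussian jitter `jitter_sd`.
#'
#' @param helix_id,pivot_index Helix and residue index (within the helix,
#'   1-based from the intracellular N-terminus) of the kink pivot.
#' @param breakpoints Data frame with columns `frame` and `kappa` (or
#'   `value` for chi) in degrees.
#' @param residue_seq,angle_name,residue_name Planted residue: its sequence
#'   number in the synthetic numbering, the chi angle scheduled, and the
#'   residue type used (controls the side-chain atom names).
#' @param interpolate `"step"` (hold until next breakpoint) or `"linear"`.
#' @param cutoff,counts Shell radius and occupancy schedule.
#' @param phases Data frame with columns `state`, `frames` (relative span
#'   weights) and the three distance targets `tm7_tm3`, `tm3_tm6`,
#'   `tm6_tm7`.
#' @param jitter_sd Per-frame Gaussian jitter of the distance targets (A).
#' @name synthetic_schedules
NULL

#' @rdname synthetic_schedules
#' @export
kink_schedule <- function(helix_id, pivot_index, breakpoints) {
  stopifnot(all(c("frame", "kappa") %in% names(breakpoints)))
  if (any(breakpoints$kappa <= 0 | breakpoints$kappa > 180))
    rlang::abort("kink angles must be in (0, 180]", class = "gpcrtraj_spec_error")
  list(helix_id = as.integer(helix_id), pivot_index = as.integer(pivot_index),
       breakpoints = tibble::as_tibble(breakpoints))
}

#' @rdname synthetic_schedules
#' @export
chi_schedule <- function(residue_seq, angle_name = "chi1", breakpoints,
                         residue_name = "TYR", interpolate = "step") {
  stopifnot(all(c("frame", "value") %in% names(breakpoints)))
  list(residue_seq = as.integer(residue_seq), angle_name = angle_name,
       residue_name = toupper(residue_name),
       breakpoints = tibble::as_tibble(breakpoints), interpolate = interpolate)
}

#' @rdname synthetic_schedules
#' @export
water_schedule <- function(residue_seq, cutoff = 4.0, counts) {
  list(residue_seq = as.integer(residue_seq), cutoff = cutoff, counts = counts)
}

#' @rdname synthetic_schedules
#' @export
end_state_schedule <- function(phases, jitter_sd = 0.25) {
  need <- c("state", "frames", "tm7_tm3", "tm3_tm6", "tm6_tm7")
  if (!all(need %in% names(phases)))
    rlang::abort(paste("phases needs columns", paste(need, collapse = ", ")),
                 class = "gpcrtraj_spec_error")
  d <- phases
  bad <- d$tm7_tm3 > d$tm3_tm6 + d$tm6_tm7 | d$tm3_tm6 > d$tm7_tm3 + d$tm6_tm7 |
    d$tm6_tm7 > d$tm7_tm3 + d$tm3_tm6
  if (any(bad))
    rlang::abort("end-distance targets violate the triangle inequality",
                 class = "gpcrtraj_spec_error")
  list(phases = tibble::as_tibble(phases), jitter_sd = jitter_sd)
}

#' Specification of a synthetic trajectory
#'
#' Describes a toy 7-helix bundle: ideal alpha-helices (Calpha rise 1.5 A,
#' 100 degrees/residue twist, helix radius 2.3 A) stood on a circle of
#' radius `bundle_radius`, with scheduled kinks, side-chain dihedrals,
#' water-shell occupancies and end-distance states planted on top, and
#' i.i.d. Gaussian noise of `noise_sigma` added to every coordinate.
#' Everything is deterministic given `seed`.
#'
#' @param n_frames Number of frames.
#' @param dt_ns Frame spacing in nanoseconds.
#' @param seed Integer seed.
#' @param n_helices,n_residues Bundle size (residues per helix).
#' @param bundle_radius Circle radius in Angstrom.
#' @param noise_sigma Coordinate noise s.d. in Angstrom.
#' @param kink_schedules,chi_schedules,water_schedules Lists of schedules,
#'   see [synthetic_schedules].
#' @param end_distance_schedule Optional [end_state_schedule()].
#' @param background_waters Number of far-field waters (negative controls
#'   for shell counting).
#' @return A `synthetic_spec` list, input for [build_bundle()].
#' @export
synthetic_spec <- function(n_frames = 700, dt_ns = 1, seed = 1,
                           n_helices = 7, n_residues = 26, bundle_radius = 12,
                           noise_sigma = 0.2,
                           kink_schedules = list(), chi_schedules = list(),
                           water_schedules = list(),
                           end_distance_schedule = NULL,
                           background_waters = 20) {
  spec <- structure(list(
    n_frames = as.integer(n_frames), dt_ns = dt_ns, seed = as.integer(seed),
    n_helices = as.integer(n_helices), n_residues = as.integer(n_residues),
    bundle_radius = bundle_radius, noise_sigma = noise_sigma,
    kink_schedules = kink_schedules, chi_schedules = chi_schedules,
    water_schedules = water_schedules,
    end_distance_schedule = end_distance_schedule,
    background_waters = as.integer(background_waters)
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

# residue sequence numbers of helix h: h*100 + (1..n)
synth_resid <- function(helix_id, index) helix_id * 100L + as.integer(index)

#' Helix definitions of a synthetic bundle
#'
#' The helix table matching [synthetic_spec()] numbering: helix `h` spans
#' residues `h*100 + 1 .. h*100 + n_residues`, anchored at index 13
#' (generic position 50), intracellular end at the N-terminus.
#'
#' @param spec A `synthetic_spec`.
#' @return List of [helix_def()] objects.
#' @export
synthetic_helix_defs <- function(spec) {
  lapply(seq_len(spec$n_helices), function(h)
    helix_def(h, synth_resid(h, 1), synth_resid(h, spec$n_residues),
              anchor_seq = synth_resid(h, 13), anchor_position = 50,
              intracellular_end = "start"))
}

validate_synthetic_spec <- function(spec) {
  probs <- character(0)
  if (spec$n_frames < 1) probs <- c(probs, "n_frames must be >= 1")
  if (spec$n_residues < 8) probs <- c(probs, "need at least 8 residues per helix")
  for (ks in spec$kink_schedules) {
    if (ks$helix_id > spec$n_helices)
      probs <- c(probs, sprintf("kink schedule references helix %d (bundle has %d)",
                                ks$helix_id, spec$n_helices))
    if (ks$pivot_index < 5 || ks$pivot_index > spec$n_residues - 4)
      probs <- c(probs, sprintf("kink pivot index %d leaves an arm shorter than 4 residues",
                                ks$pivot_index))
  }
  for (cs in spec$chi_schedules) {
    h <- cs$residue_seq %/% 100L; i <- cs$residue_seq %% 100L
    if (h < 1 || h > spec$n_helices || i < 1 || i > spec$n_residues)
      probs <- c(probs, sprintf("chi schedule references residue %d outside the bundle",
                                cs$residue_seq))
  }
  for (ws in spec$water_schedules) {
    h <- ws$residue_seq %/% 100L; i <- ws$residue_seq %% 100L
    if (h < 1 || h > spec$n_helices || i < 1 || i > spec$n_residues)
      probs <- c(probs, sprintf("water schedule references residue %d outside the bundle",
                                ws$residue_seq))
  }
  if (!is.null(spec$end_distance_schedule) && spec$n_helices < 7)
    probs <- c(probs, "end-distance schedules need the full 7-helix bundle (TM3/TM6/TM7)")
  if (length(probs) > 0)
    rlang::abort(paste0("invalid synthetic spec:\n", paste("-", probs, collapse = "\n")),
                 class = "gpcrtraj_spec_error")
  invisible(spec)
}

# piecewise interpolation of a breakpoint table over 1..n frames
interp_schedule <- function(breakpoints, value_col, n, method = "linear") {
  bp <- breakpoints[order(breakpoints$frame), ]
  if (nrow(bp) == 1) return(rep(bp[[value_col]], n))
  stats::approx(bp$frame, bp[[value_col]], xout = seq_len(n),
                method = if (method == "step") "constant" else "linear",
                rule = 2)$y
}

resolve_water_counts <- function(ws, n) {
  cnt <- ws$counts
  if (is.list(cnt)) {
    if (is.null(cnt$min) || is.null(cnt$max))
      rlang::abort("water count range needs min and max", class = "gpcrtraj_spec_error")
    out <- sample(cnt$min:cnt$max, n, replace = TRUE)
  } else if (length(cnt) == 1) {
    out <- rep(as.integer(cnt), n)
  } else if (length(cnt) == n) {
    out <- as.integer(cnt)
  } else {
    rlang::abort("water counts must have length 1 or n_frames, or be a min/max range",
                 class = "gpcrtraj_spec_error")
  }
  if (any(out < 0)) rlang::abort("water occupancies must be >= 0",
                                 class = "gpcrtraj_spec_error")
  out
}

# base backbone geometry of one straight helix (N, CA, C, O, CB per residue)
synth_helix_backbone <- function(h, n_res, bundle_radius) {
  phi <- 2 * pi * (h - 1) / 7
  ch <- c(bundle_radius * cos(phi), bundle_radius * sin(phi), 0)
  i <- seq_len(n_res)
  th <- deg2rad(100 * i) + phi
  ca <- cbind(ch[1] + 2.3 * cos(th), ch[2] + 2.3 * sin(th), 1.5 * i)
  nn <- cbind(ch[1] + 1.55 * cos(th - deg2rad(28)),
              ch[2] + 1.55 * sin(th - deg2rad(28)), 1.5 * i - 0.9)
  cc <- cbind(ch[1] + 1.52 * cos(th + deg2rad(27)),
              ch[2] + 1.52 * sin(th + deg2rad(27)), 1.5 * i + 0.55)
  # carbonyl O radially out from the local helix axis
  rad <- cbind(cos(th + deg2rad(27)), sin(th + deg2rad(27)), 0)
  oo <- cc + 1.23 * rad
  cb <- t(vapply(i, function(j) place_atom(nn[j, ], cc[j, ], ca[j, ],
                                           1.53, 110.5, 122.6), numeric(3)))
  list(N = nn, CA = ca, C = cc, O = oo, CB = cb)
}

#' Build a synthetic trajectory with planted ground truth
#'
#' Realises a [synthetic_spec()]: scheduled chi angles are built exactly
#' (before noise) by internal-coordinate placement of side-chain
#' pseudo-atoms, kinks by rigid rotation of the intracellular arm about the
#' pivot Calpha, end-distance targets by whole-helix translations (which
#' preserve planted kinks), and water-shell occupancies by placing
#' single-oxygen waters inside the shell; surplus shell waters are parked
#' far outside, and background waters sit well beyond every shell.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `trajectory` (a `gt_trajectory`) and `truth`, a
#'   manifest holding the per-frame planted kink angles, chi values, shell
#'   occupancies and state labels, plus the seed and spec echo.
#' @export
build_bundle <- function(spec) {
  validate_synthetic_spec(spec)
  n <- spec$n_frames
  nres <- spec$n_residues
  nh <- spec$n_helices

  # which residues get side-chain pseudo-atoms, and their names
  chi_by_res <- split(spec$chi_schedules,
                      vapply(spec$chi_schedules, function(s) s$residue_seq, integer(1)))
  sched_res <- as.integer(names(chi_by_res))
  res_names <- setNames(rep("ALA", nh * nres),
                        as.character(unlist(lapply(seq_len(nh), function(h)
                          synth_resid(h, seq_len(nres))))))
  side_atoms <- list()
  for (rs in sched_res) {
    sch <- chi_by_res[[as.character(rs)]]
    rn <- sch[[1]]$residue_name
    res_names[as.character(rs)] <- rn
    has_chi2 <- any(vapply(sch, function(s) s$angle_name == "chi2", logical(1)))
    g <- chi_atom_names(rn, "chi1")[4]
    atoms <- g
    if (has_chi2) atoms <- c(atoms, chi_atom_names(rn, "chi2")[4])
    side_atoms[[as.character(rs)]] <- atoms
  }
  for (ks in spec$kink_schedules) {
    rs <- synth_resid(ks$helix_id, ks$pivot_index)
    if (res_names[as.character(rs)] == "ALA") res_names[as.character(rs)] <- "PRO"
  }

  # ---- topology ----
  bb_names <- c("N", "CA", "C", "O", "CB")
  atom_rows <- list()
  for (h in seq_len(nh)) {
    for (i in seq_len(nres)) {
      rs <- synth_resid(h, i)
      nm <- c(bb_names, side_atoms[[as.character(rs)]])
      atom_rows[[length(atom_rows) + 1]] <- tibble::tibble(
        name = nm, resname = res_names[as.character(rs)], resid = rs, chain = "A")
    }
  }
  n_shell <- vapply(spec$water_schedules, function(ws) {
    cnt <- ws$counts
    if (is.list(cnt)) as.integer(cnt$max) else as.integer(max(cnt))
  }, integer(1))
  n_wat <- sum(n_shell) + spec$background_waters
  if (n_wat > 0)
    atom_rows[[length(atom_rows) + 1]] <- tibble::tibble(
      name = "O", resname = "HOH", resid = seq_len(n_wat), chain = "W")
  at <- dplyr::bind_rows(atom_rows)
  at$serial <- seq_len(nrow(at))
  at$element <- infer_element(at$name)
  at$is_heavy <- at$element != "H"
  top <- new_topology(at[, c("serial", "name", "resname", "resid", "chain",
                             "element", "is_heavy")])

  # index helpers over the fixed topology
  prot <- which(at$chain == "A")
  idx_of <- function(rs, nm) which(at$chain == "A" & at$resid == rs & at$name == nm)
  helix_atoms <- lapply(seq_len(nh), function(h)
    which(at$chain == "A" & at$resid %/% 100L == h))
  wat_idx <- which(at$chain == "W")

  # ---- base protein coordinates ----
  base <- matrix(0, nrow(at), 3)
  for (h in seq_len(nh)) {
    bb <- synth_helix_backbone(h, nres, spec$bundle_radius)
    for (i in seq_len(nres)) {
      rs <- synth_resid(h, i)
      base[idx_of(rs, "N"), ] <- bb$N[i, ]
      base[idx_of(rs, "CA"), ] <- bb$CA[i, ]
      base[idx_of(rs, "C"), ] <- bb$C[i, ]
      base[idx_of(rs, "O"), ] <- bb$O[i, ]
      base[idx_of(rs, "CB"), ] <- bb$CB[i, ]
    }
  }

  # ---- per-frame schedule values ----
  kink_vals <- lapply(spec$kink_schedules, function(ks)
    interp_schedule(ks$breakpoints, "kappa", n, "linear"))
  chi_vals <- lapply(spec$chi_schedules, function(cs)
    interp_schedule(cs$breakpoints, "value", n, cs$interpolate))

  eds <- spec$end_distance_schedule
  if (!is.null(eds)) {
    wts <- eds$phases$frames / sum(eds$phases$frames)
    bounds <- round(cumsum(wts) * n)
    state_of <- rep(as.character(eds$phases$state[nrow(eds$phases)]), n)
    lo <- 1
    for (p in seq_len(nrow(eds$phases))) {
      hi <- bounds[p]
      if (hi >= lo) state_of[lo:hi] <- as.character(eds$phases$state[p])
      lo <- hi + 1
    }
    phase_idx <- match(state_of, as.character(eds$phases$state))
  }

  end_len <- 4L  # one turn, matching the analysis default
  end_ca_idx <- lapply(seq_len(nh), function(h)
    vapply(seq_len(end_len), function(i) idx_of(synth_resid(h, i), "CA"), integer(1)))

  coords <- array(NA_real_, dim = c(n, nrow(at), 3))
  truth_kink <- list(); truth_chi <- list(); truth_wat <- list()
  truth_states <- NULL

  with_seed(spec$seed, {
    wat_counts <- lapply(spec$water_schedules, resolve_water_counts, n = n)
    # background waters: fixed far-field positions
    zc <- 1.5 * nres / 2
    if (spec$background_waters > 0) {
      u <- matrix(rnorm(3 * spec$background_waters), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      bg <- u * runif(spec$background_waters, 55, 75)
      bg[, 3] <- bg[, 3] + zc
    }
    ed_targets <- if (!is.null(eds)) {
      tg <- as.matrix(eds$phases[phase_idx, c("tm7_tm3", "tm3_tm6", "tm6_tm7")])
      tg + matrix(rnorm(3 * n, 0, eds$jitter_sd), ncol = 3)
    } else NULL
    if (!is.null(ed_targets)) {
      bad <- ed_targets[, 1] > ed_targets[, 2] + ed_targets[, 3] |
        ed_targets[, 2] > ed_targets[, 1] + ed_targets[, 3] |
        ed_targets[, 3] > ed_targets[, 1] + ed_targets[, 2]
      if (any(bad))
        rlang::abort("jittered end-distance targets became infeasible",
                     class = "gpcrtraj_spec_error")
    }

    for (f in seq_len(n)) {
      P <- base
      # planted kinks: rigid rotation of the intracellular arm
      for (j in seq_along(spec$kink_schedules)) {
        ks <- spec$kink_schedules[[j]]
        kappa <- kink_vals[[j]][f]
        arm_res <- synth_resid(ks$helix_id, seq_len(ks$pivot_index - 1))
        arm <- which(at$chain == "A" & at$resid %in% arm_res)
        pivot_ca <- P[idx_of(synth_resid(ks$helix_id, ks$pivot_index), "CA"), ]
        phi <- 2 * pi * (ks$helix_id - 1) / 7
        tangent <- c(-sin(phi), cos(phi), 0)
        P[arm, ] <- rotate_about(P[arm, , drop = FALSE], pivot_ca, tangent, 180 - kappa)
      }
      # planted end-distance targets: whole-helix translations of TM6, TM7
      if (!is.null(ed_targets)) {
        e <- lapply(c(3L, 6L, 7L), function(h) colMeans(P[end_ca_idx[[h]], , drop = FALSE]))
        d73 <- ed_targets[f, 1]; d36 <- ed_targets[f, 2]; d67 <- ed_targets[f, 3]
        u <- unitv(e[[2]] - e[[1]])
        e6n <- e[[1]] + d36 * u
        w0 <- (e[[3]] - e[[1]]) - sum((e[[3]] - e[[1]]) * u) * u
        w <- if (sqrt(sum(w0^2)) < 1e-8) unitv(cross3(u, c(0, 0, 1))) else unitv(w0)
        x <- (d73^2 - d67^2 + d36^2) / (2 * d36)
        y2 <- d73^2 - x^2
        e7n <- e[[1]] + x * u + sqrt(max(0, y2)) * w
        P[helix_atoms[[6]], ] <- sweep(P[helix_atoms[[6]], , drop = FALSE], 2, e6n - e[[2]], "+")
        P[helix_atoms[[7]], ] <- sweep(P[helix_atoms[[7]], , drop = FALSE], 2, e7n - e[[3]], "+")
      }
      # planted side-chain dihedrals (exact before noise)
      for (rs in sched_res) {
        key <- as.character(rs)
        sch <- chi_by_res[[key]]
        vals <- vapply(seq_along(spec$chi_schedules), function(q)
          if (spec$chi_schedules[[q]]$residue_seq == rs) chi_vals[[q]][f] else NA_real_,
          numeric(1))
        names(vals) <- vapply(spec$chi_schedules, function(s) s$angle_name, character(1))
        vals <- vals[!is.na(vals)]
        chi1 <- if ("chi1" %in% names(vals)) vals[["chi1"]] else -60
        rn <- res_names[key]
        gname <- chi_atom_names(rn, "chi1")[4]
        gi <- idx_of(rs, gname)
        P[gi, ] <- place_atom(P[idx_of(rs, "N"), ], P[idx_of(rs, "CA"), ],
                              P[idx_of(rs, "CB"), ], 1.52, 114, chi1)
        if ("chi2" %in% names(vals)) {
          dname <- chi_atom_names(rn, "chi2")[4]
          P[idx_of(rs, dname), ] <- place_atom(P[idx_of(rs, "CA"), ],
                                               P[idx_of(rs, "CB"), ], P[gi, ],
                                               1.45, 115, vals[["chi2"]])
        }
      }
      # waters: scheduled shells, parked surplus, background
      if (n_wat > 0) {
        W <- matrix(0, n_wat, 3)
        slot <- 0L
        for (j in seq_along(spec$water_schedules)) {
          ws <- spec$water_schedules[[j]]
          tgt <- which(at$chain == "A" & at$resid == ws$residue_seq & at$is_heavy)
          cf <- wat_counts[[j]][f]
          for (q in seq_len(n_shell[j])) {
            if (q <= cf) {
              ta <- P[tgt[sample.int(length(tgt), 1)], ]
              dir <- unitv(rnorm(3))
              # stay well inside the shell so coordinate noise cannot eject
              hi <- max(2.6, min(3.2, ws$cutoff - 0.8))
              W[slot + q, ] <- ta + runif(1, min(2.5, hi - 0.1), hi) * dir
            } else {
              W[slot + q, ] <- c(120 + 5 * (slot + q), 0, zc)  # parked far away
            }
          }
          slot <- slot + n_shell[j]
        }
        if (spec$background_waters > 0)
          W[(slot + 1):n_wat, ] <- bg
        P[wat_idx, ] <- W
      }
      # i.i.d. coordinate noise
      if (spec$noise_sigma > 0)
        P <- P + matrix(rnorm(length(P), 0, spec$noise_sigma), nrow(P), 3)
      coords[f, , ] <- P
    }
  })

  times <- (seq_len(n) - 1) * spec$dt_ns
  for (j in seq_along(spec$kink_schedules))
    truth_kink[[j]] <- tibble::tibble(helix_id = spec$kink_schedules[[j]]$helix_id,
                                      frame = seq_len(n), kappa = kink_vals[[j]])
  for (j in seq_along(spec$chi_schedules))
    truth_chi[[j]] <- tibble::tibble(residue_seq = spec$chi_schedules[[j]]$residue_seq,
                                     angle_name = spec$chi_schedules[[j]]$angle_name,
                                     frame = seq_len(n), value = chi_vals[[j]])
  for (j in seq_along(spec$water_schedules))
    truth_wat[[j]] <- tibble::tibble(residue_seq = spec$water_schedules[[j]]$residue_seq,
                                     cutoff = spec$water_schedules[[j]]$cutoff,
                                     frame = seq_len(n), count = wat_counts[[j]])
  if (!is.null(eds)) {
    truth_states <- tibble::tibble(frame = seq_len(n), state = state_of,
                                   tm7_tm3 = ed_targets[, 1],
                                   tm3_tm6 = ed_targets[, 2],
                                   tm6_tm7 = ed_targets[, 3])
  }
  truth <- list(
    kink = if (length(truth_kink)) dplyr::bind_rows(truth_kink) else NULL,
    chi = if (length(truth_chi)) dplyr::bind_rows(truth_chi) else NULL,
    water = if (length(truth_wat)) dplyr::bind_rows(truth_wat) else NULL,
    states = truth_states,
    transitions = if (!is.null(truth_states)) {
      r <- rle(truth_states$state)
      st <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
      if (length(r$values) > 1)
        tibble::tibble(frame = st[-1], from = r$values[-length(r$values)],
                       to = r$values[-1])
      else NULL
    } else NULL,
    seed = spec$seed, spec = spec
  )
  list(trajectory = new_trajectory(top, coords, times), truth = truth)
}
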