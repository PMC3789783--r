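#' Rotamer state bins
#'
#' Circular bins used to discretise a chi-angle series into rotamer states.
#' `rotamer_bins()` returns the standard three-state set: gauche- (-120, 0],
#' gauche+ (0, 120] and trans (120, -120] (wrapping through 180).
#' `rotamer_bins_from_centers()` builds bins with boundaries midway between
#' adjacent centers on the circle — e.g. `c("down" = 0, "up" = 90)` for a
#' tryptophan 6.48-style two-state toggle whose chi2 alternates between
#' roughly 0 and 90 degrees.
#'
#' @return Tibble with columns `label`, `lo`, `hi`; each bin is the circular
#'   interval (lo, hi], with `lo > hi` indicating wrap-around.
#' @export
rotamer_bins <- function() {
  tibble::tibble(label = c("g-", "g+", "t"),
                 lo = c(-120, 0, 120), hi = c(0, 120, -120))
}

#' @rdname rotamer_bins
#' @param centers Named numeric vector of bin centers in degrees; names are
#'   the state labels.
#' @export
rotamer_bins_from_centers <- function(centers) {
  if (length(centers) < 2 || is.null(names(centers)) || any(!nzchar(names(centers))))
    rlang::abort("`centers` must be a named vector of at least two angles",
                 class = "gpcrtraj_definition_error")
  o <- order(wrap_angle(centers))
  cen <- wrap_angle(centers)[o]
  labs <- names(centers)[o]
  k <- length(cen)
  # boundary between center i and the next (circularly)
  gaps <- c(diff(cen), 360 - (cen[k] - cen[1]))
  his <- wrap_angle(cen + gaps / 2)
  tibble::tibble(label = labs, lo = c(his[k], his[-k]), hi = his)
}

bin_width <- function(lo, hi) {
  w <- (hi - lo) %% 360
  ifelse(w == 0, 360, w)
}

validate_bins <- function(bins) {
  if (!all(c("label", "lo", "hi") %in% names(bins)) || nrow(bins) < 1)
    rlang::abort("bins need columns label, lo, hi", class = "gpcrtraj_definition_error")
  if (abs(sum(bin_width(bins$lo, bins$hi)) - 360) > 1e-6)
    rlang::abort("bins must cover the circle exactly once (widths must sum to 360)",
                 class = "gpcrtraj_definition_error")
  o <- order(wrap_angle(bins$lo))
  b <- bins[o, ]
  nxt <- c(seq_len(nrow(b))[-1], 1)
  if (any(abs(wrap_angle(b$hi - b$lo[nxt])) > 1e-6))
    rlang::abort("bins overlap or leave gaps on the circle",
                 class = "gpcrtraj_definition_error")
  bins
}

bin_of <- function(values, bins) {
  v <- wrap_angle(values)
  out <- rep(NA_character_, length(v))
  for (i in seq_len(nrow(bins))) {
    lo <- wrap_angle(bins$lo[i]); hi <- wrap_angle(bins$hi[i])
    inbin <- if (lo < hi) v > lo & v <= hi else v > lo | v <= hi
    out[inbin] <- bins$label[i]
  }
  out
}

# unwrap a circular degree series so temporal filters can act on it
unwrap_angles <- function(x) {
  if (length(x) <= 1) return(x)
  cumsum(c(x[1], wrap_angle(diff(x))))
}

#' Classify a dihedral series into rotamer states
#'
#' Applies an optional running-median filter (on the unwrapped angles, so
#' the trans boundary at +-180 is handled continuously) and assigns each
#' frame to the circular bin containing its angle.
#'
#' @param series Tibble from [chi_series()] (columns `frame`, `time_ns`,
#'   `value`).
#' @param bins Bin table, see [rotamer_bins()].
#' @param filter_window Odd width (frames) of the median filter; 0 or 1
#'   disables it.
#' @return The series with added columns `filtered` and `state`; bins and
#'   the originating residue/angle are carried as attributes.
#' @export
classify_rotamers <- function(series, bins = rotamer_bins(), filter_window = 21) {
  validate_bins(bins)
  if (filter_window > 1 && filter_window %% 2 == 0)
    rlang::abort("filter_window must be odd", class = "gpcrtraj_definition_error")
  filt <- wrap_angle(partial_runmed(unwrap_angles(series$value), filter_window))
  out <- dplyr::mutate(series, filtered = filt, state = bin_of(filt, bins))
  attr(out, "bins") <- bins
  attr(out, "filter_window") <- filter_window
  attr(out, "residue_seq") <- attr(series, "residue_seq")
  attr(out, "angle_name") <- attr(series, "angle_name")
  out
}

#' Detect rotamer switch events
#'
#' A switch is reported at the first frame of each maximal run of a new
#' state lasting at least `min_dwell` frames; shorter excursions are
#' ignored. A constant series yields no events, and prepending frames of
#' the initial state leaves the event list unchanged.
#'
#' @param states Tibble from [classify_rotamers()] (columns `frame`,
#'   `time_ns`, `state`).
#' @param min_dwell Minimum run length, in frames, for a state to count.
#' @return Tibble of events: `residue_seq`, `angle_name`, `frame`,
#'   `time_ns`, `from_state`, `to_state`, `pre_dwell`, `post_dwell`.
#' @export
detect_switches <- function(states, min_dwell = 50) {
  if (min_dwell < 1)
    rlang::abort("min_dwell must be >= 1", class = "gpcrtraj_definition_error")
  r <- rle(states$state)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_dwell
  empty <- tibble::tibble(residue_seq = integer(0), angle_name = character(0),
                          frame = integer(0), time_ns = numeric(0),
                          from_state = character(0), to_state = character(0),
                          pre_dwell = integer(0), post_dwell = integer(0))
  if (sum(keep) <= 1) return(empty)
  vals <- r$values[keep]; lens <- r$lengths[keep]; sts <- starts[keep]
  # collapse consecutive accepted runs of the same state
  grp <- cumsum(c(TRUE, vals[-1] != vals[-length(vals)]))
  vals2 <- tapply(vals, grp, `[`, 1)
  lens2 <- as.integer(tapply(lens, grp, sum))
  sts2 <- as.integer(tapply(sts, grp, `[`, 1))
  if (length(vals2) <= 1) return(empty)
  i <- 2:length(vals2)
  tibble::tibble(
    residue_seq = attr(states, "residue_seq") %||% NA_integer_,
    angle_name = attr(states, "angle_name") %||% NA_character_,
    frame = sts2[i],
    time_ns = states$time_ns[sts2[i]],
    from_state = as.character(vals2[i - 1]),
    to_state = as.character(vals2[i]),
    pre_dwell = lens2[i - 1],
    post_dwell = lens2[i]
  )
}

#' Hydrogen-bond presence time series
#'
#' Geometric criterion: the bond is present in a frame when the
#' donor-acceptor heavy-atom distance is at most `dist_cutoff` and, when
#' the donor carries hydrogens (inferred from a D-H distance <= 1.2 A in
#' the first frame), the largest D-H...A angle is at least `angle_cutoff`.
#' Without hydrogens the angle term is dropped and the result is flagged
#' (`attr(x, "mode") == "heavy"`).
#'
#' @param traj A `gt_trajectory`.
#' @param donor,acceptor Lists `list(residue =, atom =)` naming the heavy
#'   donor/acceptor atoms.
#' @param dist_cutoff,angle_cutoff Distance (Angstrom) and angle (degrees)
#'   thresholds.
#' @param chain Optional chain id.
#' @return Tibble with `frame`, `time_ns`, `dist`, `present`; the fraction
#'   of frames present is in `attr(x, "occupancy")`.
#' @export
hbond_series <- function(traj, donor, acceptor, dist_cutoff = 3.5,
                         angle_cutoff = 150, chain = NULL) {
  stop_if_not_trajectory(traj)
  di <- atom_index1(traj$topology, donor$residue, donor$atom, chain)
  ai <- atom_index1(traj$topology, acceptor$residue, acceptor$atom, chain)
  at <- traj$topology$atoms
  # hydrogens bound to the donor, inferred from frame-1 geometry
  hcand <- which(at$element == "H" & at$resid == at$resid[di] & at$chain == at$chain[di])
  if (length(hcand) > 0) {
    X1 <- frame_coords(traj, 1)
    dh <- sqrt(rowSums((X1[hcand, , drop = FALSE] -
                          matrix(X1[di, ], length(hcand), 3, byrow = TRUE))^2))
    hidx <- hcand[dh <= 1.2]
  } else hidx <- integer(0)
  f <- n_frames(traj)
  D <- matrix(traj$coords[, di, ], ncol = 3)
  A <- matrix(traj$coords[, ai, ], ncol = 3)
  dist_da <- sqrt(rowSums((D - A)^2))
  present <- dist_da <= dist_cutoff
  mode <- "heavy"
  if (length(hidx) > 0) {
    mode <- "hydrogen"
    best <- rep(-Inf, f)
    for (h in hidx) {
      H <- matrix(traj$coords[, h, ], ncol = 3)
      v1 <- D - H; v2 <- A - H
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      best <- pmax(best, rad2deg(acos(pmin(1, pmax(-1, cosang)))))
    }
    present <- present & best >= angle_cutoff
  }
  out <- tibble::tibble(frame = seq_len(f), time_ns = traj$times,
                        dist = dist_da, present = present)
  attr(out, "occupancy") <- mean(present)
  attr(out, "mode") <- mode
  attr(out, "donor") <- donor
  attr(out, "acceptor") <- acceptor
  out
}

#' Ligand-receptor contact occupancy
#'
#' Per receptor residue, the fraction of frames in which any heavy-atom
#' pair between the ligand selection and the residue is within `cutoff`.
#' For designated frames (e.g. first and last, to compare initial and
#' final binding modes) the per-frame contact lists are attached as
#' attribute `"frame_contacts"`.
#'
#' @param traj A `gt_trajectory`.
#' @param ligand_selection Selection string or atom indices for the ligand.
#' @param receptor_residues Optional integer vector of residue numbers to
#'   scan; default all non-water residues outside the ligand selection.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4).
#' @param report_frames Frames for which explicit contact lists are kept.
#' @return Tibble `chain`, `residue_seq`, `residue_name`, `occupancy`.
#' @export
contact_occupancy <- function(traj, ligand_selection, receptor_residues = NULL,
                              cutoff = 4.0, report_frames = NULL) {
  stop_if_not_trajectory(traj)
  at <- traj$topology$atoms
  lig <- resolve_selection(traj, ligand_selection)
  lig <- lig[at$is_heavy[lig]]
  if (length(lig) == 0)
    rlang::abort("empty ligand selection", class = "gpcrtraj_selection_error")
  rec <- which(at$is_heavy & !(at$resname %in% traj$topology$water_names) &
                 !(seq_len(nrow(at)) %in% lig))
  if (!is.null(receptor_residues)) rec <- rec[at$resid[rec] %in% receptor_residues]
  key <- paste(at$chain[rec], at$resid[rec], sep = "|")
  groups <- split(rec, key)
  f <- n_frames(traj)
  hit <- matrix(FALSE, f, length(groups))
  if (cutoff > 0) {
    for (k in seq_len(f)) {
      X <- frame_coords(traj, k)
      L <- X[lig, , drop = FALSE]
      for (j in seq_along(groups)) {
        Rg <- X[groups[[j]], , drop = FALSE]
        d2 <- outer(rowSums(L^2), rowSums(Rg^2), "+") - 2 * (L %*% t(Rg))
        if (min(d2) <= cutoff^2) hit[k, j] <- TRUE
      }
    }
  }
  first_atom <- vapply(groups, `[`, integer(1), 1)
  out <- tibble::tibble(chain = at$chain[first_atom],
                        residue_seq = at$resid[first_atom],
                        residue_name = at$resname[first_atom],
                        occupancy = colMeans(hit))
  out <- dplyr::arrange(out, .data$chain, .data$residue_seq)
  if (!is.null(report_frames)) {
    fc <- purrr::map_dfr(report_frames, function(k) {
      j <- which(hit[k, ])
      fa <- first_atom[j]
      tibble::tibble(frame = k, chain = at$chain[fa],
                     residue_seq = at$resid[fa], residue_name = at$resname[fa])
    })
    attr(out, "frame_contacts") <- fc
  }
  attr(out, "cutoff") <- cutoff
  out
}
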