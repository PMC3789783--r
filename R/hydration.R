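# water-shell counting around selected residues/motifs

# indices of one oxygen per water residue
water_oxygen_indices <- function(topology) {
  at <- topology$atoms
  wat <- which(at$resname %in% topology$water_names & at$element == "O")
  key <- paste(at$chain[wat], at$resid[wat], sep = "|")
  wat[!duplicated(key)]
}

# F x W logical: water oxygen within cutoff of any of the target atoms
shell_membership <- function(traj, water_idx, target_idx, cutoff) {
  f <- n_frames(traj)
  w <- length(water_idx)
  within <- matrix(FALSE, f, w)
  cut2 <- cutoff^2
  WX <- traj$coords[, water_idx, 1, drop = FALSE]
  WY <- traj$coords[, water_idx, 2, drop = FALSE]
  WZ <- traj$coords[, water_idx, 3, drop = FALSE]
  dim(WX) <- dim(WY) <- dim(WZ) <- c(f, w)
  for (t in target_idx) {
    d2 <- (WX - traj$coords[, t, 1])^2 + (WY - traj$coords[, t, 2])^2 +
      (WZ - traj$coords[, t, 3])^2
    within <- within | (d2 <= cut2)
  }
  within
}

#' Water count in a hydration shell
#'
#' Per frame, the number of water molecules whose oxygen lies within
#' `cutoff` of any heavy atom of the target selection (each water counted
#' once). This is the observable used to distinguish activation states by
#' the hydration of conserved residues — e.g. the 4 A shell around the
#' 2.50 aspartate, or around the NPxxY motif at the intracellular end of
#' TM7.
#'
#' @param traj A `gt_trajectory`.
#' @param target_selection Selection string or atom indices; hydrogens are
#'   excluded automatically.
#' @param cutoff Shell radius in Angstrom (default 4).
#' @param label Optional label stored on the result (e.g. `"D91(2.50)"`).
#' @return Tibble with `frame`, `time_ns`, `count` (non-negative integers).
#' @export
water_count_series <- function(traj, target_selection, cutoff = 4.0, label = NULL) {
  stop_if_not_trajectory(traj)
  at <- traj$topology$atoms
  tgt <- resolve_selection(traj, target_selection)
  tgt <- tgt[at$is_heavy[tgt] & !(at$resname[tgt] %in% traj$topology$water_names)]
  if (length(tgt) == 0)
    rlang::abort("empty target selection", class = "gpcrtraj_selection_error")
  wat <- water_oxygen_indices(traj$topology)
  f <- n_frames(traj)
  if (length(wat) == 0) {
    rlang::warn("topology contains no water; returning all-zero counts")
    counts <- rep(0L, f)
  } else {
    counts <- as.integer(rowSums(shell_membership(traj, wat, tgt, cutoff)))
  }
  out <- tibble::tibble(frame = seq_len(f), time_ns = traj$times, count = counts)
  attr(out, "label") <- label %||% "hydration"
  attr(out, "cutoff") <- cutoff
  out
}

#' Water bridges between two selections
#'
#' A water bridges selections A and B in a frame when its oxygen is within
#' `cutoff` of a heavy atom of A and of a heavy atom of B simultaneously —
#' the geometric signature of solvent-mediated hydrogen-bond networks
#' between conserved residues (e.g. the 1.50/2.50/7.49 triad).
#'
#' @param traj A `gt_trajectory`.
#' @param selection_a,selection_b Disjoint selections (strings or indices).
#' @param cutoff Distance cutoff in Angstrom (default 4).
#' @return Tibble with `frame`, `time_ns`, `n_bridging`, and a list column
#'   `waters` of the bridging water residue numbers.
#' @export
bridging_waters <- function(traj, selection_a, selection_b, cutoff = 4.0) {
  stop_if_not_trajectory(traj)
  at <- traj$topology$atoms
  ia <- resolve_selection(traj, selection_a); ia <- ia[at$is_heavy[ia]]
  ib <- resolve_selection(traj, selection_b); ib <- ib[at$is_heavy[ib]]
  if (length(ia) == 0 || length(ib) == 0)
    rlang::abort("empty selection", class = "gpcrtraj_selection_error")
  if (length(intersect(ia, ib)) > 0)
    rlang::abort("selections A and B must be disjoint", class = "gpcrtraj_selection_error")
  wat <- water_oxygen_indices(traj$topology)
  f <- n_frames(traj)
  if (length(wat) == 0) {
    return(tibble::tibble(frame = seq_len(f), time_ns = traj$times,
                          n_bridging = 0L,
                          waters = replicate(f, integer(0), simplify = FALSE)))
  }
  inA <- shell_membership(traj, wat, ia, cutoff)
  inB <- shell_membership(traj, wat, ib, cutoff)
  bridge <- inA & inB
  wres <- at$resid[wat]
  tibble::tibble(
    frame = seq_len(f), time_ns = traj$times,
    n_bridging = as.integer(rowSums(bridge)),
    waters = purrr::map(seq_len(f), function(k) wres[bridge[k, ]])
  )
}
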