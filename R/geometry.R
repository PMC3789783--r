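#' Signed dihedral angle
#'
#' IUPAC-signed torsion defined by four points: 0 for a cis (eclipsed)
#' arrangement, 180 for trans, sign flipped by mirror reflection, invariant
#' under rigid motion.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  unname(drop(dihedral_mat(rbind(p1), rbind(p2), rbind(p3), rbind(p4))))
}

# vectorised torsion over F x 3 matrices; projection formulation (the test
# oracle uses the plane-normal formulation instead)
dihedral_mat <- function(P1, P2, P3, P4) {
  U1 <- P2 - P1
  U2 <- P3 - P2
  U3 <- P4 - P3
  l1 <- sqrt(rowSums(U1^2)); l2 <- sqrt(rowSums(U2^2)); l3 <- sqrt(rowSums(U3^2))
  if (any(l1 < 1e-9) || any(l2 < 1e-9) || any(l3 < 1e-9))
    rlang::abort("coincident consecutive points in dihedral",
                 class = "gpcrtraj_geometry_error")
  W <- U2 / l2
  # perpendicular components of the outer bonds; the first bond vector
  # points from p2 toward p1 (IUPAC convention)
  A <- W * rowSums(U1 * W) - U1
  B <- U3 - W * rowSums(U3 * W)
  la <- sqrt(rowSums(A^2)); lb <- sqrt(rowSums(B^2))
  if (any(la < 1e-9 * l1) || any(lb < 1e-9 * l3))
    rlang::abort("collinear consecutive points in dihedral",
                 class = "gpcrtraj_geometry_error")
  WxA <- cbind(W[, 2] * A[, 3] - W[, 3] * A[, 2],
               W[, 3] * A[, 1] - W[, 1] * A[, 3],
               W[, 1] * A[, 2] - W[, 2] * A[, 1])
  x <- rowSums(A * B)
  y <- rowSums(WxA * B)
  ang <- rad2deg(atan2(y, x))
  ifelse(ang <= -180, ang + 360, ang)
}

# internal NeRF atom placement: position D with |C-D| = bond,
# angle(B,C,D) = angle_deg and dihedral(A,B,C,D) = dihedral_deg
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  th <- deg2rad(angle_deg); ph <- deg2rad(dihedral_deg)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ---- side-chain chi atom tables (IUPAC naming) -------------------------------

chi_atom_names <- function(resname, angle_name) {
  resname <- toupper(resname)
  g1 <- c(SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1", ILE = "CG1",
          ARG = "CG", LYS = "CG", MET = "CG", GLU = "CG", GLN = "CG",
          ASP = "CG", ASN = "CG", HIS = "CG", PHE = "CG", TYR = "CG",
          TRP = "CG", LEU = "CG", PRO = "CG")
  if (angle_name == "chi1") {
    if (!resname %in% names(g1))
      rlang::abort(paste0(resname, " has no chi1 angle"), class = "gpcrtraj_definition_error")
    return(c("N", "CA", "CB", g1[[resname]]))
  }
  if (angle_name == "chi2") {
    d1 <- list(PHE = c("CG", "CD1"), TYR = c("CG", "CD1"), TRP = c("CG", "CD1"),
               LEU = c("CG", "CD1"), HIS = c("CG", "ND1"), ASN = c("CG", "OD1"),
               ASP = c("CG", "OD1"), MET = c("CG", "SD"), ILE = c("CG1", "CD1"),
               ARG = c("CG", "CD"), LYS = c("CG", "CD"), GLU = c("CG", "CD"),
               GLN = c("CG", "CD"), PRO = c("CG", "CD"))
    gd <- d1[[resname]]
    if (is.null(gd))
      rlang::abort(paste0(resname, " has no chi2 angle"), class = "gpcrtraj_definition_error")
    return(c("CA", "CB", gd))
  }
  rlang::abort(paste0("unknown chi angle: ", angle_name), class = "gpcrtraj_definition_error")
}

# index of one named atom of one residue; errors if absent or ambiguous
atom_index1 <- function(topology, residue_seq, name, chain = NULL) {
  at <- topology$atoms
  hit <- which(at$resid == residue_seq & at$name == name &
                 (if (is.null(chain)) TRUE else at$chain == chain))
  if (length(hit) == 0)
    rlang::abort(sprintf("atom %s of residue %d not found", name, residue_seq),
                 class = "gpcrtraj_selection_error")
  if (length(hit) > 1)
    rlang::abort(sprintf("atom %s of residue %d is ambiguous (specify chain)",
                         name, residue_seq),
                 class = "gpcrtraj_selection_error")
  hit
}

residue_name_of <- function(topology, residue_seq, chain = NULL) {
  at <- topology$atoms
  hit <- at$resname[at$resid == residue_seq &
                      (if (is.null(chain)) TRUE else at$chain == chain)]
  if (length(hit) == 0)
    rlang::abort(sprintf("residue %d not in topology", residue_seq),
                 class = "gpcrtraj_selection_error")
  unique(hit)[1]
}

#' Side-chain or backbone dihedral time series
#'
#' Computes a chi1/chi2 (or phi/psi) angle for one residue in every frame.
#' Atom names follow the IUPAC convention (chi1 = N-CA-CB-G, chi2 =
#' CA-CB-G-D, with G/D resolved per residue type; chi2 of Phe/Tyr/Trp uses
#' CD1). Residue types lacking the requested angle are rejected.
#'
#' @param traj A `gt_trajectory`.
#' @param residue_seq Residue sequence number.
#' @param angle_name One of `"chi1"`, `"chi2"`, `"phi"`, `"psi"`.
#' @param chain Optional chain id to disambiguate duplicated numbering.
#' @return Tibble with columns `frame`, `time_ns`, `value` (degrees in
#'   (-180, 180]); the residue and angle are carried in attributes
#'   `residue_seq` and `angle_name`.
#' @export
chi_series <- function(traj, residue_seq, angle_name = "chi1", chain = NULL) {
  stop_if_not_trajectory(traj)
  top <- traj$topology
  if (angle_name %in% c("chi1", "chi2")) {
    resname <- residue_name_of(top, residue_seq, chain)
    nms <- chi_atom_names(resname, angle_name)
    idx <- vapply(nms, function(nm) atom_index1(top, residue_seq, nm, chain), integer(1))
  } else if (angle_name == "phi") {
    idx <- c(atom_index1(top, residue_seq - 1, "C", chain),
             atom_index1(top, residue_seq, "N", chain),
             atom_index1(top, residue_seq, "CA", chain),
             atom_index1(top, residue_seq, "C", chain))
  } else if (angle_name == "psi") {
    idx <- c(atom_index1(top, residue_seq, "N", chain),
             atom_index1(top, residue_seq, "CA", chain),
             atom_index1(top, residue_seq, "C", chain),
             atom_index1(top, residue_seq + 1, "N", chain))
  } else {
    rlang::abort(paste0("unknown angle_name: ", angle_name),
                 class = "gpcrtraj_definition_error")
  }
  P <- lapply(idx, function(i) matrix(traj$coords[, i, ], ncol = 3))
  vals <- dihedral_mat(P[[1]], P[[2]], P[[3]], P[[4]])
  out <- tibble::tibble(frame = seq_len(n_frames(traj)),
                        time_ns = traj$times, value = vals)
  attr(out, "residue_seq") <- residue_seq
  attr(out, "angle_name") <- angle_name
  out
}

# ---- helix axes and kink -----------------------------------------------------

# smoothing kernel cancelling the 100 deg/residue helical phase:
# weights w with sum_j w_j * exp(i * 100deg * j) = 0
helix_kernel <- local({
  w0 <- (cos(100 * pi / 180) + cos(200 * pi / 180)) / (-(1 + cos(300 * pi / 180)))
  k <- c(w0, 1, 1, w0)
  k / sum(k)
})

#' Fit a helix axis
#'
#' Estimates the axis direction of an alpha-helical segment from its Calpha
#' positions. The positions are first smoothed with a 4-residue kernel whose
#' taps cancel the 100-degrees-per-residue helical phase, so the smoothed
#' points lie on the axis for ideal geometry; the principal component of the
#' smoothed points is the axis. For the minimum segment length (4 residues)
#' the local-axis cross product of successive bisectors is used instead.
#' The sign points from the first toward the last residue (N to C).
#'
#' @param calpha_coords `n x 3` matrix of Calpha coordinates, `n >= 4`, in
#'   N-to-C order.
#' @return List with unit `direction` and `centroid`.
#' @export
fit_helix_axis <- function(calpha_coords) {
  X <- as.matrix(calpha_coords)
  n <- nrow(X)
  if (is.null(n) || n < 4)
    rlang::abort("need at least 4 Calpha positions to fit a helix axis",
                 class = "gpcrtraj_insufficient_data_error")
  if (n == 4) {
    b1 <- unitv((X[1, ] - X[2, ]) + (X[3, ] - X[2, ]))
    b2 <- unitv((X[2, ] - X[3, ]) + (X[4, ] - X[3, ]))
    v <- cross3(b1, b2)
  } else {
    S <- t(vapply(seq_len(n - 3), function(i) colSums(X[i:(i + 3), ] * helix_kernel),
                  numeric(3)))
    if (nrow(S) == 2) {
      v <- S[2, ] - S[1, ]
    } else {
      Sc <- scale(S, scale = FALSE)
      v <- svd(Sc)$v[, 1]
    }
  }
  d <- X[n, ] - X[1, ]
  if (sum(v * d) < 0) v <- -v
  list(direction = unitv(v), centroid = colMeans(X))
}

#' Helix kink angle time series
#'
#' Per frame, fits axes to the two arms flanking a pivot residue (`window`
#' residues each, pivot excluded) and reports the kink angle
#' `kappa = 180 - acos(u . v)` in degrees: a straight helix reads ~180 and
#' kappa falls as the helix bends, matching the convention in which a TM7
#' kink at the 7.50 proline drifts from ~155 to ~130 degrees on activation.
#' The per-frame series is smoothed with a running median (partial windows
#' at the edges); set `smooth_frames = 0` for raw values.
#'
#' @param traj A `gt_trajectory`.
#' @param helix A [helix_def()].
#' @param pivot_seq Pivot residue sequence number (e.g. the 7.50 proline).
#' @param window Residues per arm (default 7, about two helical turns).
#' @param smooth_frames Odd width of the temporal running median
#'   (default 21).
#' @param chain Optional chain id.
#' @return Tibble with columns `frame`, `time_ns`, `kink` (degrees).
#' @export
kink_series <- function(traj, helix, pivot_seq, window = 7,
                        smooth_frames = 21, chain = NULL) {
  stop_if_not_trajectory(traj)
  if (window < 4)
    rlang::abort("arm window must be at least 4 residues",
                 class = "gpcrtraj_insufficient_data_error")
  n_res <- c(pivot_seq - window, pivot_seq + window)
  if (n_res[1] < helix$start || n_res[2] > helix$end)
    rlang::abort(sprintf("arms of %d residues do not fit within TM%d (%d-%d) around pivot %d",
                         window, helix$helix_id, helix$start, helix$end, pivot_seq),
                 class = "gpcrtraj_insufficient_data_error")
  seq_n <- (pivot_seq - window):(pivot_seq - 1)
  seq_c <- (pivot_seq + 1):(pivot_seq + window)
  idx_n <- vapply(seq_n, function(r) atom_index1(traj$topology, r, "CA", chain), integer(1))
  idx_c <- vapply(seq_c, function(r) atom_index1(traj$topology, r, "CA", chain), integer(1))
  f <- n_frames(traj)
  kap <- vapply(seq_len(f), function(k) {
    u <- fit_helix_axis(matrix(traj$coords[k, idx_n, ], ncol = 3))$direction
    v <- fit_helix_axis(matrix(traj$coords[k, idx_c, ], ncol = 3))$direction
    180 - rad2deg(acos(pmin(1, pmax(-1, sum(u * v)))))
  }, numeric(1))
  tibble::tibble(frame = seq_len(f), time_ns = traj$times,
                 kink = partial_runmed(kap, smooth_frames))
}

# ---- superposition and RMSD --------------------------------------------------

#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the rotation and translation that minimise the (optionally
#' weighted) RMSD between `mobile` and `ref`.
#'
#' @param ref,mobile `n x 3` coordinate matrices, `n >= 3`, matched row by
#'   row.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `fitted` (`mobile` after superposition); the transform
#'   maps a mobile row x to `rotation %*% x + translation`.
#' @export
superpose <- function(ref, mobile, weights = NULL) {
  R0 <- as.matrix(ref); M0 <- as.matrix(mobile)
  n <- nrow(R0)
  if (n < 3 || nrow(M0) != n)
    rlang::abort("need matched coordinate sets with at least 3 atoms",
                 class = "gpcrtraj_geometry_error")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    rlang::abort("invalid weights", class = "gpcrtraj_geometry_error")
  w <- w / sum(w)
  rbar <- colSums(R0 * w); mbar <- colSums(M0 * w)
  A <- sweep(R0, 2, rbar); B <- sweep(M0, 2, mbar)
  sv <- svd(t(B * w) %*% A)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    rlang::abort("degenerate (collinear) coordinates: superposition not unique",
                 class = "gpcrtraj_geometry_error")
  d <- sign(det(sv$v %*% t(sv$u)))
  Rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(B %*% t(Rot), 2, rbar, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - R0)^2)))
  list(rotation = Rot, translation = drop(rbar - Rot %*% mbar),
       rmsd = rmsd, fitted = fitted)
}

resolve_selection <- function(traj, selection) {
  if (is.character(selection)) select_atoms(traj$topology, selection)
  else as.integer(selection)
}

#' RMSD time series after per-frame superposition
#'
#' Each frame is independently least-squares superposed onto the reference
#' frame over the selection before the RMSD is taken, the standard way of
#' monitoring backbone drift of TM regions along a trajectory.
#'
#' @param traj A `gt_trajectory`.
#' @param selection Selection string (see [select_atoms()]) or integer atom
#'   indices; default all backbone atoms.
#' @param reference_frame 1-based index of the reference frame (default the
#'   first frame, i.e. the equilibrated starting structure).
#' @return Tibble with columns `frame`, `time_ns`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection = "backbone", reference_frame = 1) {
  stop_if_not_trajectory(traj)
  idx <- resolve_selection(traj, selection)
  if (length(idx) == 0)
    rlang::abort("empty atom selection for RMSD", class = "gpcrtraj_selection_error")
  ref <- matrix(traj$coords[reference_frame, idx, ], ncol = 3)
  f <- n_frames(traj)
  vals <- vapply(seq_len(f), function(k) {
    superpose(ref, matrix(traj$coords[k, idx, ], ncol = 3))$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(f), time_ns = traj$times, rmsd = vals)
}

# ---- intracellular helix-end distances ---------------------------------------

helix_end_residues <- function(helix, end_length) {
  len <- helix$end - helix$start + 1
  if (end_length < 1 || end_length > len)
    rlang::abort(sprintf("end_length %d exceeds TM%d length %d",
                         end_length, helix$helix_id, len),
                 class = "gpcrtraj_range_error")
  if (helix$intracellular_end == "start") helix$start:(helix$start + end_length - 1)
  else (helix$end - end_length + 1):helix$end
}

#' Distances between intracellular helix ends
#'
#' Per frame, the Euclidean distance between the Calpha centroids of the
#' `end_length` most intracellular residues of each pair of helices.
#' With the canonical TM3/TM6/TM7 trio the columns are ordered
#' `tm7_tm3`, `tm3_tm6`, `tm6_tm7`, the feature space in which activation
#' states separate.
#'
#' @param traj A `gt_trajectory`.
#' @param helices List of exactly three [helix_def()] objects with distinct
#'   `helix_id`s and declared intracellular ends.
#' @param end_length Number of end residues averaged (default 4, one turn).
#' @param chain Optional chain id.
#' @return Tibble with columns `frame`, `time_ns` and the three distances
#'   (Angstrom).
#' @export
end_distance_series <- function(traj, helices, end_length = 4, chain = NULL) {
  stop_if_not_trajectory(traj)
  if (length(helices) != 3 || !all(purrr::map_lgl(helices, inherits, "helix_def")))
    rlang::abort("`helices` must be three helix_def objects",
                 class = "gpcrtraj_definition_error")
  ids <- purrr::map_int(helices, "helix_id")
  if (anyDuplicated(ids))
    rlang::abort("helix ids must be distinct", class = "gpcrtraj_definition_error")
  helices <- helices[order(ids)]
  ids <- sort(ids)  # (a, b, c); columns: c-a, a-b, b-c
  cent <- lapply(helices, function(h) {
    res <- helix_end_residues(h, end_length)
    idx <- vapply(res, function(r) atom_index1(traj$topology, r, "CA", chain), integer(1))
    # F x 3 centroid of the end Calphas
    if (length(idx) == 1) matrix(traj$coords[, idx, ], ncol = 3)
    else apply(traj$coords[, idx, , drop = FALSE], c(1, 3), mean)
  })
  dist_f <- function(P, Q) sqrt(rowSums((P - Q)^2))
  out <- tibble::tibble(
    frame = seq_len(n_frames(traj)), time_ns = traj$times,
    d1 = dist_f(cent[[3]], cent[[1]]),
    d2 = dist_f(cent[[1]], cent[[2]]),
    d3 = dist_f(cent[[2]], cent[[3]])
  )
  names(out)[3:5] <- c(sprintf("tm%d_tm%d", ids[3], ids[1]),
                       sprintf("tm%d_tm%d", ids[1], ids[2]),
                       sprintf("tm%d_tm%d", ids[2], ids[3]))
  out
}
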