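# programmatic fixtures: micro PDB files, hand-built trajectories, oracles

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     record = "ATOM  ", alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resname, chain, resid, x, y, z, 1, 0, element)
}

write_micro_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# ten-atom single-residue-per-atom fixture
ten_atom_pdb <- function() {
  lines <- vapply(1:10, function(i)
    pdb_line(i, "CA", "ALA", "A", i, i * 1.0, 0, 0), character(1))
  write_micro_pdb(lines)
}

# aspartate-like residue with 8 heavy atoms + wiggle room for selections
asp_pdb <- function() {
  nm <- c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2")
  lines <- c(
    vapply(seq_along(nm), function(i)
      pdb_line(i, nm[i], "ASP", "A", 91, i * 1.2, 0, 0), character(1)),
    pdb_line(9, "O", "HOH", "W", 1, 30, 0, 0, record = "HETATM"),
    pdb_line(10, "CA", "GLY", "A", 92, 0, 5, 0)
  )
  write_micro_pdb(lines)
}

# build a gt_trajectory directly from an atom table and per-frame coords
make_traj <- function(atoms, coords_list, water_names = water_residue_names(),
                      dt_ns = 1) {
  atoms$serial <- seq_len(nrow(atoms))
  atoms$element <- gpcrtraj:::infer_element(atoms$name)
  if (!is.null(atoms$element_override))
    atoms$element <- ifelse(is.na(atoms$element_override), atoms$element,
                            atoms$element_override)
  atoms$is_heavy <- atoms$element != "H"
  top <- gpcrtraj:::new_topology(
    atoms[, c("serial", "name", "resname", "resid", "chain", "element", "is_heavy")],
    water_names)
  f <- length(coords_list)
  coords <- array(NA_real_, dim = c(f, nrow(atoms), 3))
  for (k in seq_len(f)) coords[k, , ] <- coords_list[[k]]
  gpcrtraj:::new_trajectory(top, coords, times = (seq_len(f) - 1) * dt_ns)
}

atom_row <- function(name, resname, resid, chain = "A", element_override = NA) {
  tibble::tibble(name = name, resname = resname, resid = resid, chain = chain,
                 element_override = element_override)
}

# ideal alpha-helix Calpha positions for integer residue offsets i
ideal_helix_ca <- function(i, radius = 2.3, rise = 1.5, twist = 100) {
  cbind(radius * cos(twist * pi / 180 * i),
        radius * sin(twist * pi / 180 * i),
        rise * i)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

cross3_ <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# independent torsion oracle: plane normals + atan2 (n1 from bonds 1->2->3,
# n2 from 2->3->4; signed about the central bond)
dihedral_oracle <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  n1 <- cross3_(u1, u2); n2 <- cross3_(u2, u3)
  y <- sum(cross3_(n1, n2) * u2 / sqrt(sum(u2^2)))
  a <- atan2(y, sum(n1 * n2)) * 180 / pi
  if (a <= -180) a + 360 else a
}

# brute-force minimum RMSD over rotations (Euler angles, multi-start optim)
rmsd_bruteforce <- function(ref, mobile) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(mobile, 2, colMeans(mobile))
  obj <- function(th) {
    Rz1 <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, 3)
    Rz2 <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
    R <- Rz1 %*% Ry %*% Rz2
    sqrt(mean(rowSums((B %*% t(R) - A)^2)))
  }
  best <- Inf
  for (s in seq_len(12)) {
    th0 <- runif(3, -pi, pi)
    o <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS", control = list(maxit = 500))
    best <- min(best, o$value)
  }
  best
}

# helix-bundle-free trajectory of bare Calphas for kink construction:
# residues 1..(2*window+1), pivot in the middle, arm below pivot rotated
kinked_ca_traj <- function(bend_angles, window = 7) {
  n <- 2 * window + 1
  pivot <- window + 1
  base <- ideal_helix_ca(seq_len(n))
  piv <- base[pivot, ]
  frames <- lapply(bend_angles, function(th) {
    X <- base
    if (th != 0) {
      arm <- seq_len(pivot - 1)
      X[arm, ] <- gpcrtraj:::rotate_about(X[arm, , drop = FALSE], piv, c(1, 0, 0), th)
    }
    X
  })
  atoms <- atom_row(rep("CA", n), rep("ALA", n), seq_len(n))
  make_traj(atoms, frames)
}
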