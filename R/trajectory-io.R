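#' Default water residue names
#'
#' Residue names treated as water when building a topology. Covers the tags
#' written by the common simulation packages; override via the `water_names`
#' argument of [read_structure()] or in the analysis config.
#'
#' @return Character vector of residue names.
#' @export
water_residue_names <- function() c("HOH", "WAT", "TIP3", "SOL", "SPC")

new_topology <- function(atoms, water_names = water_residue_names()) {
  stopifnot(is.data.frame(atoms))
  atoms <- tibble::as_tibble(atoms)
  if (anyDuplicated(atoms$serial))
    rlang::abort("atom serial numbers must be unique", class = "gpcrtraj_format_error")
  structure(list(atoms = atoms, water_names = water_names),
            class = "gt_topology")
}

#' Residue table of a topology
#'
#' @param topology A `gt_topology`.
#' @return Tibble with one row per residue (`chain`, `resid`, `resname`) in
#'   file order.
#' @export
residues <- function(topology) {
  at <- topology$atoms
  dplyr::distinct(at, .data$chain, .data$resid, .data$resname)
}

#' @export
print.gt_topology <- function(x, ...) {
  res <- residues(x)
  nwat <- sum(res$resname %in% x$water_names)
  cat(sprintf("<gt_topology> %d atoms, %d residues (%d water)\n",
              nrow(x$atoms), nrow(res), nwat))
  invisible(x)
}

new_trajectory <- function(topology, coords, times) {
  stopifnot(inherits(topology, "gt_topology"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    rlang::abort("coords must be an F x A x 3 array", class = "gpcrtraj_type_error")
  if (dim(coords)[2] != nrow(topology$atoms))
    rlang::abort("coordinate atom count does not match topology",
                 class = "gpcrtraj_consistency_error")
  if (!all(is.finite(coords)))
    rlang::abort("non-finite coordinates", class = "gpcrtraj_consistency_error")
  if (length(times) != dim(coords)[1] || is.unsorted(times, strictly = TRUE))
    rlang::abort("times must be strictly increasing, one per frame",
                 class = "gpcrtraj_consistency_error")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "gt_trajectory")
}

#' @export
print.gt_trajectory <- function(x, ...) {
  cat(sprintf("<gt_trajectory> %d frames x %d atoms, t = %.3g..%.3g ns\n",
              n_frames(x), nrow(x$topology$atoms),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `gt_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj A `gt_trajectory`.
#' @param frame 1-based frame index.
#' @return A numeric `A x 3` matrix in Angstrom.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  matrix(traj$coords[frame, , ], ncol = 3)
}

infer_element <- function(name, elesy = NA_character_) {
  if (length(elesy) == 1) elesy <- rep(elesy, length(name))
  out <- toupper(ifelse(is.na(elesy) | elesy == "", NA_character_, elesy))
  miss <- is.na(out)
  if (any(miss)) {
    nm <- gsub("[0-9'\"]", "", name[miss])
    first <- toupper(substr(nm, 1, 1))
    # hydrogens may be written 1HB etc. (digits already stripped)
    out[miss] <- ifelse(first == "", "X", first)
  }
  out
}

#' Read a PDB structure
#'
#' Parses a PDB file (via \pkg{bio3d}) into a single-frame trajectory holding
#' the topology and the first model's coordinates. Alternate locations other
#' than blank/'A' are dropped; HETATM records (ligands, waters) are retained;
#' hydrogens are kept when present.
#'
#' @param path Path to a PDB file.
#' @param water_names Residue names identifying water molecules.
#' @return A `gt_trajectory` with one frame.
#' @export
read_structure <- function(path, water_names = water_residue_names()) {
  if (!file.exists(path))
    rlang::abort(paste0("cannot read file: ", path), class = "gpcrtraj_io_error")
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    rlang::abort("no ATOM/HETATM records found: not a PDB structure",
                 class = "gpcrtraj_format_error")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep, , drop = FALSE]
  atoms <- tibble::tibble(
    serial  = as.integer(at$eleno),
    name    = at$elety,
    resname = at$resid,
    resid   = as.integer(at$resno),
    chain   = ifelse(is.na(at$chain), " ", at$chain),
    element = infer_element(at$elety, at$elesy)
  )
  atoms$is_heavy <- atoms$element != "H"
  top <- new_topology(atoms, water_names)
  coords <- array(NA_real_, dim = c(1, nrow(atoms), 3))
  coords[1, , ] <- cbind(at$x, at$y, at$z)
  new_trajectory(top, coords, times = 0)
}

# split raw PDB lines into per-model character vectors of atom lines
split_models <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) return(list(lines[is_atom]))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    rlang::abort("unbalanced MODEL/ENDMDL records", class = "gpcrtraj_format_error")
  purrr::map2(model_starts, model_ends, function(s, e) {
    blk <- lines[s:e]
    blk[grepl("^(ATOM  |HETATM)", blk)]
  })
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL block becomes one frame; per-model atom names and counts must
#' match `topology` exactly. Frame times are `dt_ns * (model index - 1)`
#' because PDB files carry no time stamps.
#'
#' @param topology A `gt_topology`, normally from [read_structure()] on the
#'   same file or on a matching single-frame structure.
#' @param path Path to a (multi-model) PDB file.
#' @param dt_ns Time between frames in nanoseconds.
#' @return A `gt_trajectory`.
#' @export
read_trajectory <- function(topology, path, dt_ns = 1) {
  if (!file.exists(path))
    rlang::abort(paste0("cannot read file: ", path), class = "gpcrtraj_io_error")
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  if (length(models) == 0 || all(lengths(models) == 0))
    rlang::abort("no ATOM/HETATM records found", class = "gpcrtraj_format_error")
  nat <- nrow(topology$atoms)
  bad <- which(lengths(models) != nat)
  if (length(bad) > 0)
    rlang::abort(sprintf("model %d has %d atoms; topology has %d",
                         bad[1], lengths(models)[bad[1]], nat),
                 class = "gpcrtraj_consistency_error")
  allx <- unlist(models, use.names = FALSE)
  nm <- trimws(substr(allx, 13, 16))
  if (!all(nm == rep(topology$atoms$name, times = length(models))))
    rlang::abort("per-model atom order does not match topology",
                 class = "gpcrtraj_consistency_error")
  xyz <- cbind(as.numeric(substr(allx, 31, 38)),
               as.numeric(substr(allx, 39, 46)),
               as.numeric(substr(allx, 47, 54)))
  f <- length(models)
  coords <- array(NA_real_, dim = c(f, nat, 3))
  for (k in seq_len(f)) coords[k, , ] <- xyz[((k - 1) * nat + 1):(k * nat), ]
  new_trajectory(topology, coords, times = (seq_len(f) - 1) * dt_ns)
}

pdb_atom_name <- function(name, element) {
  # PDB convention: element right-justified in cols 13-14, so short names
  # of single-letter elements start in column 14
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 2, sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the standard PDB precision (0.001 Angstrom);
#' write-then-read round-trips are exact at that precision. Output is
#' byte-deterministic for identical input.
#'
#' @param traj A `gt_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stop_if_not_trajectory(traj)
  at <- traj$topology$atoms
  is_het <- at$resname %in% traj$topology$water_names
  rec <- ifelse(is_het, "HETATM", "ATOM  ")
  nm <- pdb_atom_name(at$name, at$element)
  f <- n_frames(traj)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (k in seq_len(f)) {
    X <- frame_coords(traj, k)
    body <- sprintf("%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, at$serial, nm, at$resname, at$chain, at$resid,
                    X[, 1], X[, 2], X[, 3], 1, 0, at$element)
    writeLines(c(sprintf("MODEL     %4d", k), body, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
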