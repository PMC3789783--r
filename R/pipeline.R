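# one-config orchestration of the full analysis

default_bins_for <- function(spec) {
  if (is.null(spec) || identical(spec, "default")) return(rotamer_bins())
  if (identical(spec, "toggle")) return(rotamer_bins_from_centers(c(down = 0, up = 90)))
  if (is.data.frame(spec)) return(tibble::as_tibble(spec))
  rlang::abort("bins must be 'default', 'toggle' or a lo/hi/label table",
               class = "gpcrtraj_config_error")
}

config_helices <- function(cfg) {
  lapply(cfg$helices, function(h)
    helix_def(h$helix_id, h$start, h$end, h$anchor_seq,
              h$anchor_position %||% 50,
              h$intracellular_end %||% "end"))
}

#' Read and validate an analysis configuration
#'
#' The YAML config names the inputs and every stage's parameters; any
#' stage key may be omitted to disable that stage. See the package
#' vignette for the schema and the shipped example
#' (`system.file("extdata", "example_config.yaml", package = "gpcrtraj")`).
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("config not found: ", path), class = "gpcrtraj_io_error")
  cfg <- yaml::read_yaml(path)
  cfg$dt_ns <- cfg$dt_ns %||% 1
  structure(cfg, class = "analysis_config")
}

# every problem is reported, not just the first
validate_config <- function(cfg, top) {
  probs <- character(0)
  res <- residues(top)
  has_res <- function(r) any(res$resid == r & !(res$resname %in% top$water_names))
  for (h in cfg$helices %||% list()) {
    for (r in c(h$start, h$end, h$anchor_seq))
      if (!has_res(r)) probs <- c(probs, sprintf("helix %s residue %d not in topology",
                                                 h$helix_id, r))
  }
  for (sw in cfg$switches %||% list())
    if (!has_res(sw$residue))
      probs <- c(probs, sprintf("switch residue %d not in topology", sw$residue))
  for (hb in cfg$hbonds %||% list()) {
    for (side in list(hb$donor, hb$acceptor))
      if (!has_res(side$residue))
        probs <- c(probs, sprintf("h-bond residue %d not in topology", side$residue))
  }
  for (hy in cfg$hydration %||% list()) {
    ok <- tryCatch(length(select_atoms(top, hy$selection)) > 0,
                   error = function(e) FALSE)
    if (!ok) probs <- c(probs, sprintf("hydration selection '%s' is invalid or empty",
                                       hy$selection))
    if (!is.null(hy$cutoff) && hy$cutoff <= 0)
      probs <- c(probs, sprintf("hydration cutoff must be positive (got %s)", hy$cutoff))
  }
  if (!is.null(cfg$kink)) {
    hid <- cfg$kink$helix_id
    if (!any(vapply(cfg$helices %||% list(), function(h) h$helix_id == hid, logical(1))))
      probs <- c(probs, sprintf("kink references undefined helix %s", hid))
  }
  if (!is.null(cfg$clustering)) {
    ids <- cfg$clustering$helix_ids %||% c(3, 6, 7)
    have <- vapply(cfg$helices %||% list(), function(h) h$helix_id, numeric(1))
    miss <- setdiff(ids, have)
    if (length(miss)) probs <- c(probs, sprintf("clustering references undefined helices: %s",
                                                paste(miss, collapse = ", ")))
  }
  if (length(probs) > 0)
    rlang::abort(paste0("invalid analysis config:\n", paste("-", probs, collapse = "\n")),
                 class = "gpcrtraj_config_error")
  invisible(cfg)
}

stage_log <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[gpcrtraj] %-14s %.2fs", stage,
                    as.numeric(Sys.time()) - t0))
}

write_tsv_ <- function(x, path) {
  df <- as.data.frame(x)
  listcols <- vapply(df, is.list, logical(1))
  df <- df[, !listcols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full trajectory analysis
#'
#' Executes, in order, the stages enabled by the config: I/O, BW numbering,
#' chi series + rotamer switch detection, hydrogen bonds, hydration shells,
#' ligand contacts, helix kink, RMSD, intracellular end distances and state
#' clustering, then writes per-stage TSVs and a JSON summary with a
#' provenance block (config hash, seeds, package version, the parameter
#' defaults in force).
#'
#' @param config An `analysis_config` (from [read_analysis_config()]) or an
#'   equivalent list.
#' @param output_dir Output directory (created if needed).
#' @param verbose Log per-stage timings to standard error.
#' @return A `result_bundle` list (invisible file paths under
#'   `$files`, per-stage results under their own names).
#' @export
run_analysis <- function(config, output_dir, verbose = TRUE) {
  t0 <- as.numeric(Sys.time())
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  if (is.null(cfg$structure))
    rlang::abort("config must name a structure file", class = "gpcrtraj_config_error")
  wn <- cfg$water_names %||% water_residue_names()
  struct <- read_structure(cfg$structure, water_names = wn)
  traj_path <- cfg$trajectory %||% cfg$structure
  traj <- read_trajectory(struct$topology, traj_path, dt_ns = cfg$dt_ns %||% 1)
  validate_config(cfg, traj$topology)
  stage_log(verbose, "io", t0)

  files <- character(0)
  res <- list(config = cfg)

  helices <- config_helices(cfg)
  helix_by_id <- setNames(helices, vapply(helices, function(h) h$helix_id, integer(1)))
  bw_map <- if (length(helices)) assign_bw(helices) else NULL
  if (!is.null(bw_map))
    files["bw_map"] <- write_tsv_(bw_map, file.path(output_dir, "bw_map.tsv"))
  res$bw_map <- bw_map
  bw_of <- function(r) {
    if (is.null(bw_map)) return(NA_character_)
    hit <- bw_map$bw[bw_map$residue_seq == r]
    if (length(hit)) hit[1] else NA_character_
  }
  stage_log(verbose, "bw", t0)

  # chi series, rotamer states, switch events
  events <- list(); states_list <- list()
  for (sw in cfg$switches %||% list()) {
    ser <- chi_series(traj, sw$residue, sw$angle %||% "chi1")
    st <- classify_rotamers(ser, bins = default_bins_for(sw$bins),
                            filter_window = sw$filter_window %||% 21)
    ev <- detect_switches(st, min_dwell = sw$min_dwell %||% 50)
    ev$bw <- bw_of(sw$residue)
    key <- sprintf("chi_%d_%s", sw$residue, sw$angle %||% "chi1")
    files[key] <- write_tsv_(st, file.path(output_dir, paste0(key, ".tsv")))
    events[[key]] <- ev
    states_list[[key]] <- st
  }
  events <- dplyr::bind_rows(events)
  if (length(cfg$switches %||% list()) > 0)
    files["switch_events"] <- write_tsv_(events,
                                         file.path(output_dir, "switch_events.tsv"))
  res$events <- events
  res$rotamer_states <- states_list
  stage_log(verbose, "switches", t0)

  # hydrogen bonds
  hbonds <- list()
  for (i in seq_along(cfg$hbonds %||% list())) {
    hb <- cfg$hbonds[[i]]
    ser <- hbond_series(traj, hb$donor, hb$acceptor,
                        dist_cutoff = hb$dist_cutoff %||% 3.5,
                        angle_cutoff = hb$angle_cutoff %||% 150)
    key <- sprintf("hbond_%d_%d", hb$donor$residue, hb$acceptor$residue)
    files[key] <- write_tsv_(ser, file.path(output_dir, paste0(key, ".tsv")))
    hbonds[[key]] <- ser
  }
  res$hbonds <- hbonds
  stage_log(verbose, "hbonds", t0)

  # hydration shells
  hydration <- list()
  for (hy in cfg$hydration %||% list()) {
    lab <- hy$label %||% hy$selection
    ser <- water_count_series(traj, hy$selection, cutoff = hy$cutoff %||% 4.0,
                              label = lab)
    key <- paste0("hydration_", gsub("[^A-Za-z0-9._-]", "_", lab))
    files[key] <- write_tsv_(ser, file.path(output_dir, paste0(key, ".tsv")))
    hydration[[lab]] <- ser
  }
  res$hydration <- hydration
  stage_log(verbose, "hydration", t0)

  # ligand contacts
  if (!is.null(cfg$contacts)) {
    ct <- contact_occupancy(traj, cfg$contacts$ligand,
                            cutoff = cfg$contacts$cutoff %||% 4.0,
                            report_frames = c(1, n_frames(traj)))
    files["contacts"] <- write_tsv_(ct, file.path(output_dir, "contacts.tsv"))
    res$contacts <- ct
  }
  stage_log(verbose, "contacts", t0)

  # helix kink
  if (!is.null(cfg$kink)) {
    kh <- helix_by_id[[as.character(cfg$kink$helix_id)]]
    pivot <- cfg$kink$pivot
    if (is.character(pivot)) pivot <- lookup_bw(bw_map, pivot)
    kk <- kink_series(traj, kh, pivot, window = cfg$kink$window %||% 7,
                      smooth_frames = cfg$kink$smooth_frames %||% 21)
    key <- sprintf("kink_tm%d", kh$helix_id)
    files[key] <- write_tsv_(kk, file.path(output_dir, paste0(key, ".tsv")))
    res$kink <- kk
  }
  stage_log(verbose, "kink", t0)

  # RMSD
  if (!is.null(cfg$rmsd)) {
    sel <- cfg$rmsd$selection %||% "backbone"
    rr <- rmsd_series(traj, sel, reference_frame = cfg$rmsd$reference_frame %||% 1)
    files["rmsd"] <- write_tsv_(rr, file.path(output_dir, "rmsd.tsv"))
    res$rmsd <- rr
  }
  stage_log(verbose, "rmsd", t0)

  # end distances + state clustering
  if (!is.null(cfg$clustering)) {
    ids <- cfg$clustering$helix_ids %||% c(3, 6, 7)
    hl <- helix_by_id[as.character(ids)]
    ed <- end_distance_series(traj, hl, end_length = cfg$clustering$end_length %||% 4)
    files["end_distances"] <- write_tsv_(ed, file.path(output_dir, "end_distances.tsv"))
    fit <- cluster_states(ed, k = cfg$clustering$k %||% 3,
                          seed = cfg$clustering$seed %||% 1)
    files["state_assignment"] <- write_tsv_(augment(fit),
                                            file.path(output_dir, "state_assignment.tsv"))
    res$end_distances <- ed
    res$states <- fit
  }
  stage_log(verbose, "clustering", t0)

  # summary + provenance
  summ <- list(
    n_frames = n_frames(traj),
    events = if (nrow(events %||% tibble::tibble()) > 0) events else NULL,
    hydration_mean = if (length(hydration))
      purrr::imap(hydration, function(s, nm) mean(s$count)) else NULL,
    hbond_occupancy = if (length(hbonds))
      purrr::map(hbonds, function(s) attr(s, "occupancy")) else NULL,
    states = if (!is.null(res$states)) list(
      fractions = as.list(res$states$sizes / nrow(res$states$assignment)),
      silhouette = res$states$silhouette,
      centroids = res$states$centroids,
      medoid_frames = setNames(as.list(state_summary(res$states)$medoid_frame),
                               as.character(state_summary(res$states)$state))
    ) else NULL,
    provenance = list(
      package = "gpcrtraj",
      version = as.character(utils::packageVersion("gpcrtraj")),
      config_hash = rlang::hash(unclass(cfg)),
      structure = cfg$structure,
      parameters = list(
        dt_ns = cfg$dt_ns %||% 1,
        hydration_cutoff = vapply(cfg$hydration %||% list(),
                                  function(h) h$cutoff %||% 4.0, numeric(1)),
        min_dwell = vapply(cfg$switches %||% list(),
                           function(s) s$min_dwell %||% 50, numeric(1)),
        kink_window = if (!is.null(cfg$kink)) cfg$kink$window %||% 7 else NULL,
        clustering_k = if (!is.null(cfg$clustering)) cfg$clustering$k %||% 3 else NULL,
        clustering_seed = if (!is.null(cfg$clustering)) cfg$clustering$seed %||% 1 else NULL
      )
    )
  )
  summ <- summ[!vapply(summ, is.null, logical(1))]
  files["summary"] <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summ, files["summary"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  stage_log(verbose, "summary", t0)
  res$files <- files
  res$output_dir <- output_dir
  class(res) <- "result_bundle"
  invisible(res)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %d output files in %s\n",
              length(x$files), x$output_dir))
  invisible(x)
}

#' Reload an analysis output directory as a result bundle
#'
#' Reconstructs the comparable parts of a [run_analysis()] output (hydration
#' series with their cutoffs, kink and RMSD series) from the TSVs and the
#' JSON summary, so runs from different sessions can be fed to
#' [compare_conditions()].
#'
#' @param dir An output directory written by [run_analysis()].
#' @return A `result_bundle`.
#' @export
read_result_bundle <- function(dir) {
  summ_path <- file.path(dir, "summary.json")
  if (!file.exists(summ_path))
    rlang::abort(paste0("no summary.json in ", dir), class = "gpcrtraj_io_error")
  summ <- jsonlite::read_json(summ_path)
  res <- list(output_dir = dir, files = character(0))
  hyd <- list()
  labs <- names(summ$hydration_mean)
  cuts <- unlist(summ$provenance$parameters$hydration_cutoff)
  for (i in seq_along(labs)) {
    key <- paste0("hydration_", gsub("[^A-Za-z0-9._-]", "_", labs[i]))
    p <- file.path(dir, paste0(key, ".tsv"))
    s <- tibble::as_tibble(utils::read.delim(p))
    attr(s, "label") <- labs[i]
    attr(s, "cutoff") <- cuts[i]
    hyd[[labs[i]]] <- s
    res$files[key] <- p
  }
  res$hydration <- hyd
  kinks <- list.files(dir, pattern = "^kink_tm[0-9]+\\.tsv$", full.names = TRUE)
  if (length(kinks) == 1) res$kink <- tibble::as_tibble(utils::read.delim(kinks))
  rp <- file.path(dir, "rmsd.tsv")
  if (file.exists(rp)) res$rmsd <- tibble::as_tibble(utils::read.delim(rp))
  res$files["summary"] <- summ_path
  class(res) <- "result_bundle"
  res
}

#' Compare result bundles across conditions
#'
#' Aligns the time-resolved observables of several analysis runs (e.g.
#' apo vs antagonist vs agonist) into one long table and summarises each
#' hydration target per condition, the overlay-style comparison used to
#' contrast water influx across ligand states.
#'
#' @param bundles List of `result_bundle` objects from [run_analysis()].
#' @param labels Condition labels, one per bundle.
#' @return List with `long` (condition, observable, frame, time_ns, value)
#'   and `hydration_summary` (per condition and target: mean and
#'   quartiles).
#' @export
compare_conditions <- function(bundles, labels = names(bundles)) {
  if (length(bundles) == 0)
    rlang::abort("no bundles to compare", class = "gpcrtraj_comparison_error")
  if (is.null(labels) || length(labels) != length(bundles))
    rlang::abort("need one label per bundle", class = "gpcrtraj_comparison_error")
  if (!all(vapply(bundles, inherits, logical(1), "result_bundle")))
    rlang::abort("bundles must come from run_analysis()",
                 class = "gpcrtraj_comparison_error")
  # observable definitions must agree
  defs <- lapply(bundles, function(b)
    lapply(b$hydration, function(s) attr(s, "cutoff")))
  for (i in seq_along(defs)[-1]) {
    if (!identical(sort(names(defs[[i]])), sort(names(defs[[1]]))) ||
        !identical(defs[[i]][sort(names(defs[[i]]))], defs[[1]][sort(names(defs[[1]]))]))
      rlang::abort("bundles define different hydration targets or cutoffs",
                   class = "gpcrtraj_comparison_error")
  }
  long <- purrr::map2_dfr(bundles, labels, function(b, lab) {
    parts <- list()
    for (nm in names(b$hydration))
      parts[[paste0("hydration:", nm)]] <-
        dplyr::transmute(b$hydration[[nm]], frame = .data$frame,
                         time_ns = .data$time_ns, value = as.numeric(.data$count))
    if (!is.null(b$kink))
      parts[["kink"]] <- dplyr::transmute(b$kink, frame = .data$frame,
                                          time_ns = .data$time_ns, value = .data$kink)
    if (!is.null(b$rmsd))
      parts[["rmsd"]] <- dplyr::transmute(b$rmsd, frame = .data$frame,
                                          time_ns = .data$time_ns, value = .data$rmsd)
    purrr::imap_dfr(parts, function(df, obs)
      dplyr::mutate(df, condition = lab, observable = obs, .before = 1))
  })
  hyd <- dplyr::filter(long, startsWith(.data$observable, "hydration:"))
  hydration_summary <- if (nrow(hyd)) {
    dplyr::summarise(
      dplyr::group_by(hyd, .data$condition, .data$observable),
      mean = mean(.data$value), q25 = stats::quantile(.data$value, 0.25),
      median = median(.data$value), q75 = stats::quantile(.data$value, 0.75),
      .groups = "drop")
  } else tibble::tibble()
  list(long = long, hydration_summary = hydration_summary)
}
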