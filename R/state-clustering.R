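state_labels_for_k <- function(k) {
  if (k == 3) c("inactive", "intermediate", "active")
  else paste0("state_", seq_len(k))
}

#' Cluster frames into conformational states
#'
#' Partitions frames of an intracellular end-distance series into `k`
#' states by k-means (squared-distance minimisation, 50 seeded restarts,
#' deterministic for a fixed seed). Features are used raw, in Angstrom.
#' State labels are assigned by ascending centroid coordinate sum:
#' activation opens the intracellular face, so the smallest-sum cluster is
#' `inactive` and the largest `active` (for `k = 3`; otherwise
#' `state_1..state_k`). The mean silhouette coefficient quantifies the
#' separation of the clusters.
#'
#' @param distances Tibble from [end_distance_series()] — columns `frame`,
#'   `time_ns` plus numeric feature columns — or any data frame of numeric
#'   features.
#' @param k Number of states (default 3).
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of random restarts (default 50).
#' @return A `state_fit` object; see [tidy.state_fit()], [glance.state_fit()],
#'   [augment.state_fit()], [state_summary()] and [autoplot.state_fit()].
#' @export
cluster_states <- function(distances, k = 3, seed = 1, nstart = 50) {
  distances <- tibble::as_tibble(distances)
  feat_cols <- setdiff(names(distances)[vapply(distances, is.numeric, logical(1))],
                       c("frame", "time_ns"))
  if (length(feat_cols) == 0)
    rlang::abort("no numeric feature columns found", class = "gpcrtraj_data_error")
  X <- as.matrix(distances[, feat_cols])
  if (!all(is.finite(X)))
    rlang::abort("distances must be finite", class = "gpcrtraj_data_error")
  f <- nrow(X)
  if (f < k)
    rlang::abort(sprintf("cannot form %d clusters from %d frames", k, f),
                 class = "gpcrtraj_data_error")
  if (all(apply(X, 2, function(col) diff(range(col)) == 0)))
    rlang::abort("zero-variance input: all frames identical",
                 class = "gpcrtraj_degenerate_data_error")
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = nstart, iter.max = 200))
  ord <- order(rowSums(km$centers))
  labels <- state_labels_for_k(k)
  relab <- integer(k); relab[ord] <- seq_len(k)
  state <- factor(labels[relab[km$cluster]], levels = labels)
  sil <- if (k > 1) mean(cluster::silhouette(relab[km$cluster], stats::dist(X))[, 3])
         else NA_real_
  assignment <- dplyr::bind_cols(
    tibble::tibble(frame = distances$frame %||% seq_len(f),
                   time_ns = distances$time_ns %||% as.numeric(seq_len(f) - 1)),
    tibble::as_tibble(X), tibble::tibble(state = state))
  centroids <- tibble::as_tibble(km$centers[ord, , drop = FALSE])
  centroids <- dplyr::bind_cols(tibble::tibble(state = factor(labels, levels = labels)),
                                centroids)
  structure(list(
    assignment = assignment,
    centroids = centroids,
    sizes = setNames(as.integer(table(state)), labels),
    silhouette = sil,
    seed = seed, k = k,
    feature_names = feat_cols,
    tot_withinss = km$tot.withinss
  ), class = "state_fit")
}

#' @export
print.state_fit <- function(x, ...) {
  cat(sprintf("<state_fit> k = %d states over %d frames (seed %d)\n",
              x$k, nrow(x$assignment), x$seed))
  cat("  sizes:", paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n")
  if (!is.na(x$silhouette))
    cat(sprintf("  mean silhouette: %.3f\n", x$silhouette))
  invisible(x)
}

#' Summarise a state assignment
#'
#' Per-state frame counts and fractions, first and last frame, centroid
#' coordinates, and the medoid frame — the member minimising the summed
#' distance to its cluster, the "central structure" representative of each
#' state.
#'
#' @param fit A `state_fit` from [cluster_states()].
#' @return Tibble with one row per state.
#' @export
state_summary <- function(fit) {
  stopifnot(inherits(fit, "state_fit"))
  asg <- fit$assignment
  X <- as.matrix(asg[, fit$feature_names])
  D <- as.matrix(stats::dist(X))
  per <- purrr::map_dfr(levels(asg$state), function(s) {
    idx <- which(asg$state == s)
    med <- if (length(idx) == 0) NA_integer_
           else idx[which.min(rowSums(D[idx, idx, drop = FALSE]))]
    tibble::tibble(state = s, n_frames = length(idx),
                   fraction = length(idx) / nrow(asg),
                   first_frame = if (length(idx)) min(asg$frame[idx]) else NA_integer_,
                   last_frame = if (length(idx)) max(asg$frame[idx]) else NA_integer_,
                   medoid_frame = if (is.na(med)) NA_integer_ else asg$frame[med])
  })
  per$state <- factor(per$state, levels = levels(asg$state))
  dplyr::left_join(per, fit$centroids, by = "state")
}

#' Tidy a state clustering
#'
#' @param x A `state_fit`.
#' @param ... Unused.
#' @return One row per state: label, size and centroid coordinates.
#' @method tidy state_fit
#' @export
tidy.state_fit <- function(x, ...) {
  dplyr::bind_cols(x$centroids,
                   tibble::tibble(size = as.integer(x$sizes[as.character(x$centroids$state)])))
}

#' One-row summary of a state clustering
#'
#' @param x A `state_fit`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_frames`, `silhouette`, `tot_withinss`,
#'   `seed`.
#' @method glance state_fit
#' @export
glance.state_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n_frames = nrow(x$assignment),
                 silhouette = x$silhouette,
                 tot_withinss = x$tot_withinss, seed = x$seed)
}

#' Per-frame state assignments
#'
#' @param x A `state_fit`.
#' @param ... Unused.
#' @return Tibble with `frame`, `time_ns`, the feature columns and `state`.
#' @method augment state_fit
#' @export
augment.state_fit <- function(x, ...) x$assignment

#' Plot a state clustering
#'
#' Pairwise scatter panels of the three end-distance features, coloured by
#' assigned state, with centroids marked.
#'
#' @param object A `state_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot state_fit
#' @export
autoplot.state_fit <- function(object, ...) {
  fn <- object$feature_names
  pairs <- utils::combn(fn, 2, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(panel = paste(p[1], "vs", p[2]),
                   x = object$assignment[[p[1]]],
                   y = object$assignment[[p[2]]],
                   state = object$assignment$state)
  })
  cent <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(panel = paste(p[1], "vs", p[2]),
                   x = object$centroids[[p[1]]],
                   y = object$centroids[[p[2]]],
                   state = object$centroids$state)
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_point(data = cent, shape = 4, size = 4, stroke = 1.5,
                        colour = "black") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "distance (Å)", y = "distance (Å)",
                  colour = "state") +
    ggplot2::theme_minimal()
}
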