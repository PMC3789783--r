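# internal helpers shared across modules

#' @importFrom rlang abort warn %||%
#' @importFrom stats median sd setNames
#' @importFrom utils head tail
NULL

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) abort("zero-length vector", class = "gpcrtraj_geometry_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angle in degrees into (-180, 180]
wrap_angle <- function(x) {
  w <- x - 360 * floor(x / 360)  # [0, 360)
  ifelse(w > 180, w - 360, w)
}

# rotation matrix: angle degrees about unit axis (Rodrigues), for row-vector
# coordinates use X %*% t(rotmat(...)) or sweep-based rotate_about()
rotmat <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# rotate an n x 3 block about a point
rotate_about <- function(X, point, axis, angle_deg) {
  R <- rotmat(axis, angle_deg)
  sweep(sweep(X, 2, point) %*% t(R), 2, point, "+")
}

# evaluate code with a temporary RNG state seeded at `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# running median with partial windows at the series edges; window is the
# full (odd) width, 0 or 1 disables smoothing
partial_runmed <- function(x, window) {
  if (window <= 1) return(x)
  h <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    median(x[lo:hi])
  }, numeric(1))
}

stop_if_not_trajectory <- function(traj) {
  if (!inherits(traj, "gt_trajectory"))
    abort("`traj` must be a gt_trajectory (see read_trajectory()/build_bundle())",
          class = "gpcrtraj_type_error")
  invisible(traj)
}
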