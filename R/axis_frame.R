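# axis_frame: helical-axis trace (midpoints of paired backbone points) and
# the discrete Frenet frame along it.

#' Helical-axis trace of a paired duplex
#'
#' The helical axis is the discrete curve of midpoints between paired backbone
#' representative points of the two strands. Backbone coordinates arrive in
#' angstrom and are converted to nanometres here, once; every downstream
#' quantity (arc steps, curvature, torsion) is in nm-based units.
#'
#' @param pairing a `duplex_pairing` from [pair_strands()].
#' @param min_step minimal allowed distance between consecutive axis points
#'   (nm); closer points indicate degenerate geometry and raise an error.
#' @return `axis_trace`: list with `points` (n x 3 matrix, nm), `steps`
#'   (length n-1; `steps[k]` is the distance between points k and k+1, nm) and
#'   `cumulative_arc` (length n, nm, starting at 0).
#' @export
axis_trace <- function(pairing, min_step = 0.01) {
  if (nrow(pairing$pairs) < 2L) stop("pairing must contain at least 2 pairs", call. = FALSE)
  la <- pairing$trace_a$points[pairing$pairs[, "a"], , drop = FALSE]
  lb <- pairing$trace_b$points[pairing$pairs[, "b"], , drop = FALSE]
  pts <- (la + lb) / 2 / ANGSTROM_PER_NM
  n <- nrow(pts)
  steps <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (any(steps < min_step)) {
    stop("degenerate axis geometry: consecutive axis points closer than ",
         min_step, " nm at step(s) ", paste(which(steps < min_step), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(points = pts, steps = steps, cumulative_arc = c(0, cumsum(steps))),
    class = "axis_trace"
  )
}

#' Orient an axis trace along +z
#'
#' zyz Euler angles are taken about the laboratory z axis, so the sign of the
#' per-step twist depends on whether the chain runs up or down that axis. This
#' canonicalization applies a proper rotation (180 degrees about x) whenever
#' the end-to-end vector of the trace points toward -z, so that the 5'->3'
#' direction of the reference strand always advances along +z. A mirror image
#' of a duplex thereby becomes an upright helix of the opposite handedness and
#' its per-step twist changes sign exactly.
#'
#' @param axis an `axis_trace` (or a bare n x 3 point matrix).
#' @return an object of the same kind, possibly rotated; attribute `flipped`
#'   records whether the rotation was applied.
#' @export
orient_axis <- function(axis) {
  pts <- if (inherits(axis, "axis_trace")) axis$points else axis
  n <- nrow(pts)
  flipped <- (pts[n, 3L] - pts[1L, 3L]) < 0
  if (flipped) {
    pts <- pts %*% diag(c(1, -1, -1))  # Rx(pi): proper rotation
  }
  if (inherits(axis, "axis_trace")) {
    axis$points <- pts
    attr(axis, "flipped") <- flipped
    axis
  } else {
    structure(pts, flipped = flipped)
  }
}

#' Discrete Frenet frame along an ordered point series
#'
#' At interior site i the tangent is the normalized chord to the next point,
#' the binormal is the normalized cross product of the incoming and outgoing
#' tangents, and the in-surface normal completes the right-handed triple:
#' \deqn{t_i = \frac{r_{i+1}-r_i}{|r_{i+1}-r_i|},\quad
#'       b_i = \frac{t_{i-1}\times t_i}{|t_{i-1}\times t_i|},\quad
#'       n_i = b_i \times t_i.}
#' Tangents exist at sites 1..n-1; full frames at sites 2..n-1. Sites where
#' consecutive tangents are (anti)parallel, `|t_{i-1} x t_i| < tol`, get no
#' frame and are marked invalid; they are excluded from downstream statistics.
#'
#' @param points n x 3 matrix (n >= 3) of ordered axis points.
#' @param tol degeneracy tolerance on the tangent cross product.
#' @return `frame_set`: list with `tangents`, `binormals`, `normals` (n x 3
#'   matrices, NA rows where undefined), `valid` (logical per site) and
#'   `site_range` (first and last site with a frame).
#' @export
build_frames <- function(points, tol = 1e-8) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points to build a frame", call. = FALSE)
  tg <- matrix(NA_real_, n, 3L)
  bn <- matrix(NA_real_, n, 3L)
  nm <- matrix(NA_real_, n, 3L)
  valid <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    tg[i, ] <- unitize(points[i + 1L, ] - points[i, ])
  }
  for (i in 2:(n - 1L)) {
    cr <- cross3(tg[i - 1L, ], tg[i, ])
    if (vnorm(cr) >= tol) {
      bn[i, ] <- cr / vnorm(cr)
      nm[i, ] <- unitize(cross3(bn[i, ], tg[i, ]))
      valid[i] <- TRUE
    }
  }
  vs <- which(valid)
  structure(
    list(
      tangents = tg, binormals = bn, normals = nm, valid = valid,
      site_range = if (length(vs)) range(vs) else c(NA_integer_, NA_integer_)
    ),
    class = "frame_set"
  )
}

# 3x3 matrix with columns (n, b, t): the proper rotation taking the lab basis
# (x, y, z) onto the frame (n, b, t); its zyz angles place the frame in the lab.
frame_matrix <- function(frames, i) {
  cbind(frames$normals[i, ], frames$binormals[i, ], frames$tangents[i, ])
}

#' Dump a frame set as TSV
#'
#' @param frames a `frame_set`.
#' @param axis the `axis_trace` the frames were built on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(frames, axis, path) {
  n <- nrow(axis$points)
  df <- data.frame(site = seq_len(n))
  for (nmcol in c("x", "y", "z")) df[[paste0("r_", nmcol, "_nm")]] <- NA_character_
  comp <- function(m) lapply(1:3, function(j) num10(m[, j]))
  rc <- comp(axis$points); tc <- comp(frames$tangents)
  bc <- comp(frames$binormals); nc <- comp(frames$normals)
  for (j in 1:3) {
    ax <- c("x", "y", "z")[j]
    df[[paste0("r_", ax, "_nm")]] <- rc[[j]]
    df[[paste0("t_", ax)]] <- tc[[j]]
    df[[paste0("b_", ax)]] <- bc[[j]]
    df[[paste0("n_", ax)]] <- nc[[j]]
  }
  df$valid <- frames$valid
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
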