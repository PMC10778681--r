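# euler_series: transfer rotations between frames, zyz Euler angles, and
# period-corrected angle differences including the gauge potential.

#' Compose a zyz Euler rotation matrix
#'
#' Standard zyz composition `Rz(alpha) Ry(beta) Rz(gamma)`: equivalently the
#' intrinsic sequence z, then the rotated y', then the twice-rotated z''.
#'
#' @param alpha,beta,gamma Euler angles (rad).
#' @return 3 x 3 rotation matrix.
#' @export
zyz_matrix <- function(alpha, beta, gamma) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  matrix(c(
    ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
    sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
    -sb * cg,                sb * sg,                cb
  ), nrow = 3L, byrow = TRUE)
}

#' Extract zyz Euler angles from a rotation matrix
#'
#' Inverts [zyz_matrix()]: `alpha = atan2(r23, r13)`,
#' `beta = atan2(sqrt(r13^2 + r23^2), r33)`, `gamma = atan2(r32, -r31)`, each
#' shifted by `+2*pi` where atan2 lands negative so all three angles lie in
#' `[0, 2*pi)`. The zyz chart is singular when `sin(beta)` vanishes (gimbal
#' lock); there the two z rotations merge and only their sum is defined. The
#' convention used here assigns the whole z angle to `gamma` with
#' `alpha = 0` — `gamma` is the angle that carries the accumulated helical
#' twist of a z-aligned duplex, so the gauge potential stays well defined
#' through the singularity (the sum `alpha + gamma` is continuous either way).
#'
#' @param R 3 x 3 rotation matrix (orthogonal, det +1).
#' @param tol gimbal-lock tolerance on `sqrt(r13^2 + r23^2)`.
#' @return numeric `c(alpha, beta, gamma)`, each in `[0, 2*pi)`.
#' @export
extract_zyz <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || any(dim(R) != 3L)) stop("R must be a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(R) - diag(3L))) > 1e-6 || det(R) < 0) {
    stop("R is not a proper rotation matrix", call. = FALSE)
  }
  sb <- sqrt(R[1L, 3L]^2 + R[2L, 3L]^2)
  if (sb < tol) {
    alpha <- 0
    if (R[3L, 3L] > 0) {
      beta <- 0
      gamma <- atan2(R[2L, 1L], R[1L, 1L])
    } else {
      beta <- pi
      gamma <- atan2(R[2L, 1L], -R[1L, 1L])
    }
  } else {
    alpha <- atan2(R[2L, 3L], R[1L, 3L])
    beta <- atan2(sb, R[3L, 3L])
    gamma <- atan2(R[3L, 2L], -R[3L, 1L])
  }
  out <- c(alpha = alpha, beta = beta, gamma = gamma)
  out[out < 0] <- out[out < 0] + 2 * pi
  out
}

#' Period-corrected differences of an angle series
#'
#' For angles stored in `[0, 2*pi)`, the consecutive difference
#' `theta[i+1] - theta[i]` is wrapped into `(-pi, pi]` — the minimal signed
#' rotation. At the period edge this adds the `+2*pi` cycle a right-handed
#' rotation requires, and symmetrically subtracts it for a left-handed
#' (negative) rotation.
#'
#' @param theta numeric vector of angles (rad), length >= 2.
#' @return numeric vector of length `length(theta) - 1` in `(-pi, pi]`.
#' @export
periodic_difference <- function(theta) {
  if (length(theta) < 2L) stop("need at least 2 angles", call. = FALSE)
  wrap_angle(diff(theta))
}

#' Transfer rotations along a frame set
#'
#' The transfer rotation between consecutive frames is the lab-frame rotation
#' carrying frame i onto frame i+1: with `C_i` the matrix whose columns are
#' `(n_i, b_i, t_i)`, `R_{i+1,i} = C_{i+1} C_i^T`, so `C_{i+1} = R_{i+1,i} C_i`.
#' Cumulative products `R_{i,base} = R_{i,i-1} ... R_{base+1,base}` are
#' anchored at the first valid frame of each run; runs of invalid frames split
#' the series into segments.
#'
#' @param frames a `frame_set` from [build_frames()].
#' @return `rotation_series`: list with `segments`, each a list holding
#'   `sites` (axis indices of consecutive valid frames), `relative` (list of
#'   3 x 3 rotations between consecutive frames) and `cumulative` (list of
#'   3 x 3 rotations relative to the segment's first frame; the first entry is
#'   the identity).
#' @export
rotation_series <- function(frames) {
  vs <- which(frames$valid)
  if (length(vs) < 2L) stop("no two valid frames available", call. = FALSE)
  runs <- split(vs, cumsum(c(1L, diff(vs) != 1L)))
  runs <- Filter(function(r) length(r) >= 2L, runs)
  if (length(runs) == 0L) {
    stop("no two consecutive valid frames available", call. = FALSE)
  }
  segments <- lapply(runs, function(sites) {
    m <- length(sites)
    Cs <- lapply(sites, function(i) frame_matrix(frames, i))
    relative <- lapply(seq_len(m - 1L), function(j) Cs[[j + 1L]] %*% t(Cs[[j]]))
    cumulative <- vector("list", m)
    cumulative[[1L]] <- diag(3L)
    for (j in seq_len(m - 1L)) {
      cumulative[[j + 1L]] <- relative[[j]] %*% cumulative[[j]]
    }
    list(sites = sites, relative = relative, cumulative = cumulative)
  })
  names(segments) <- NULL
  structure(list(segments = segments), class = "rotation_series")
}

#' zyz Euler angles of the cumulative transfer rotations
#'
#' Applies [extract_zyz()] to every cumulative rotation of every segment and
#' adds the z-twist angle `chi = (alpha + gamma) mod 2*pi`, the net rotation
#' about the decomposition z axis relative to the segment's base frame. `chi`
#' is continuous across the gimbal singularity, where it coincides with the
#' third Euler angle under this package's lock convention, and its per-step
#' difference is the gauge potential.
#'
#' @param rotations a `rotation_series`.
#' @return list of per-segment data frames with columns `site`, `alpha`,
#'   `beta`, `gamma`, `chi` (rad, `[0, 2*pi)`).
#' @export
cumulative_euler <- function(rotations) {
  lapply(rotations$segments, function(seg) {
    ang <- t(vapply(seg$cumulative, extract_zyz, numeric(3L)))
    locked <- vapply(seg$cumulative,
                     function(R) sqrt(R[1L, 3L]^2 + R[2L, 3L]^2) < 1e-8,
                     logical(1L))
    data.frame(
      site = seg$sites,
      alpha = ang[, 1L],
      beta = ang[, 2L],
      gamma = ang[, 3L],
      chi = (ang[, 1L] + ang[, 3L]) %% (2 * pi),
      locked = locked
    )
  })
}

#' Euler-angle series of a framed axis
#'
#' Combines two zyz readings of the frame set, each doing the job it is suited
#' for:
#' \itemize{
#'   \item \emph{orientation angles} `alpha`, `beta`: the zyz angles of each
#'     frame matrix relative to the laboratory axes. `alpha` is the azimuth
#'     and `beta` the polar angle of the tangent, the discrete counterpart of
#'     the continuous curved-surface frame chart, and their differences drive
#'     the curvature and torsion formulas;
#'   \item \emph{gauge angle} `chi`: the z-twist of the cumulative transfer
#'     rotation relative to the first valid frame ([cumulative_euler()]).
#'     Its period-corrected difference `d_chi` is the per-step rotation angle
#'     between consecutive base pairs; the gauge potential is identified with
#'     it, `d_rho = d_chi` — positive for a right-handed helix, negative for
#'     a left-handed one.
#' }
#' The first frame of each segment anchors the cumulative rotation, so its
#' angles are a pinned reference rather than a measurement; angle differences
#' therefore start one site later. On a clean n-site axis the evaluable sites
#' are `3..n-2`: the four terminal sites (two per end) are blind spots.
#'
#' @param frames a `frame_set`.
#' @param rotations optionally, a precomputed [rotation_series()] for `frames`.
#' @return `euler_series`: list of per-site vectors (`NA` where undefined)
#'   `alpha`, `beta`, `gamma_lab`, `chi`, differences `d_alpha`, `d_beta`,
#'   `d_chi`, `d_rho` (all in `(-pi, pi]`, stored at the site `i` of the
#'   difference `i+1,i`), logical `evaluable`, and counts `n_sites`,
#'   `n_evaluable`, `n_invalid`, `n_blind`, `n_gimbal` (cumulative rotations
#'   extracted on the gimbal-lock branch).
#' @export
euler_series <- function(frames, rotations = rotation_series(frames)) {
  n <- length(frames$valid)
  cum <- cumulative_euler(rotations)
  alpha <- beta <- gamma_lab <- chi <- rep(NA_real_, n)
  d_alpha <- d_beta <- d_chi <- rep(NA_real_, n)
  evaluable <- rep(FALSE, n)
  n_gimbal <- 0L
  for (i in which(frames$valid)) {
    lab <- extract_zyz(frame_matrix(frames, i))
    alpha[i] <- lab[1L]
    beta[i] <- lab[2L]
    gamma_lab[i] <- lab[3L]
  }
  for (seg in cum) {
    chi[seg$site] <- seg$chi
    n_gimbal <- n_gimbal + sum(seg$locked)
    m <- nrow(seg)
    if (m < 3L) next
    # differences at sites s_2..s_{m-1}; s_1 is the cumulative reference
    for (j in 2:(m - 1L)) {
      i <- seg$site[j]
      nxt <- seg$site[j + 1L]
      d_alpha[i] <- wrap_angle(alpha[nxt] - alpha[i])
      d_beta[i] <- wrap_angle(beta[nxt] - beta[i])
      d_chi[i] <- wrap_angle(chi[nxt] - chi[i])
      evaluable[i] <- TRUE
    }
  }
  n_invalid <- sum(!frames$valid[2:(n - 1L)])
  structure(
    list(
      alpha = alpha, beta = beta, gamma_lab = gamma_lab, chi = chi,
      d_alpha = d_alpha, d_beta = d_beta, d_chi = d_chi, d_rho = d_chi,
      evaluable = evaluable,
      n_sites = n,
      n_evaluable = sum(evaluable),
      n_invalid = n_invalid,
      n_blind = n - sum(evaluable) - n_invalid,
      n_gimbal = n_gimbal
    ),
    class = "euler_series"
  )
}

#' @export
print.euler_series <- function(x, ...) {
  cat(sprintf("euler_series: %d sites, %d evaluable, %d invalid, %d blind\n",
              x$n_sites, x$n_evaluable, x$n_invalid, x$n_blind))
  if (x$n_evaluable > 0L) {
    cat(sprintf("  mean gauge potential d_rho: %+.4f rad/step\n",
                mean(x$d_rho[x$evaluable])))
  }
  invisible(x)
}

#' Dump an Euler series as TSV
#'
#' @param euler an `euler_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_euler_tsv <- function(euler, path) {
  df <- data.frame(site = seq_len(euler$n_sites))
  for (f in c("alpha", "beta", "chi", "d_alpha", "d_beta", "d_chi", "d_rho")) {
    df[[paste0(f, "_rad")]] <- num10(euler[[f]])
  }
  df$evaluable <- euler$evaluable
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
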