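# Shared fixture builders and independent oracle helpers.

# seeded proper rotation, independent of the package's rotation code
random_rotation <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_dec)
  Q %*% diag(c(1, 1, det(Q)))  # force det +1
}

# exhaustive +/- 2*pi candidate search: the minimal signed angle equivalent
wrap_oracle <- function(d) {
  vapply(d, function(x) {
    cands <- x + 2 * pi * (-3:3)
    cands[cands > -pi + 1e-12 & cands <= pi + 1e-12][1L]
  }, numeric(1L))
}

# fixed-column PDB ATOM record writer for hand-made fixtures
pdb_atom_line <- function(serial, name, alt, resid, chain, resno, xyz, occ = 1) {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resid, chain, resno, xyz[1], xyz[2], xyz[3], occ, 0)
}

# n nucleotides on a gentle curve, one chain, all four backbone atoms
write_mini_chain_pdb <- function(path, n = 3L, chain = "A", resid = "DA",
                                 spread = 0.3) {
  lines <- character(0L)
  serial <- 0L
  for (i in seq_len(n)) {
    centre <- c(2 * i, 0.3 * i^2, 3.4 * i)
    offs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * spread
    for (k in 1:4) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, c("C3'", "C4'", "O3'", "C1'")[k],
                                      " ", resid, chain, i, centre + offs[k, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# a frame_set built directly from a list of 3x3 column matrices [n | b | t]
make_frame_set <- function(mats, n_sites = length(mats) + 2L, first_site = 2L) {
  tg <- bn <- nm <- matrix(NA_real_, n_sites, 3L)
  valid <- rep(FALSE, n_sites)
  for (j in seq_along(mats)) {
    i <- first_site + j - 1L
    nm[i, ] <- mats[[j]][, 1L]
    bn[i, ] <- mats[[j]][, 2L]
    tg[i, ] <- mats[[j]][, 3L]
    valid[i] <- TRUE
  }
  structure(list(tangents = tg, binormals = bn, normals = nm, valid = valid,
                 site_range = range(which(valid))),
            class = "frame_set")
}

# minimal hand-built euler_series / axis_trace pair for direct formula tests:
# one evaluable site (site 3 of 6) with prescribed values
make_single_site_inputs <- function(d_alpha, d_beta, d_chi, beta, step) {
  n <- 6L
  eu <- structure(list(
    alpha = rep(NA_real_, n), beta = rep(NA_real_, n),
    gamma_lab = rep(NA_real_, n), chi = rep(NA_real_, n),
    d_alpha = rep(NA_real_, n), d_beta = rep(NA_real_, n),
    d_chi = rep(NA_real_, n), d_rho = rep(NA_real_, n),
    evaluable = rep(FALSE, n), n_sites = n,
    n_evaluable = 1L, n_invalid = 0L, n_blind = n - 1L, n_gimbal = 0L
  ), class = "euler_series")
  eu$beta[3L] <- beta
  eu$d_alpha[3L] <- d_alpha
  eu$d_beta[3L] <- d_beta
  eu$d_chi[3L] <- d_chi
  eu$d_rho[3L] <- d_chi
  eu$evaluable[3L] <- TRUE
  pts <- cbind(0, 0, cumsum(c(0, rep(step, n - 1L))))
  axis <- structure(list(points = pts, steps = rep(step, n - 1L),
                         cumulative_arc = c(0, cumsum(rep(step, n - 1L)))),
                    class = "axis_trace")
  list(euler = eu, axis = axis)
}

# raw axis points -> geometry series via the package pipeline stages
points_to_geometry <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  steps <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  axis <- structure(list(points = P, steps = steps,
                         cumulative_arc = c(0, cumsum(steps))),
                    class = "axis_trace")
  frames <- build_frames(P)
  euler <- euler_series(frames)
  list(axis = axis, frames = frames, euler = euler,
       geometry = geometry_series(euler, axis))
}

# dense sampling of a circular helix (radius nm, pitch-per-radian nm)
helix_points <- function(radius, pitch_per_radian, dtheta, turns = 3) {
  th <- seq(0, 2 * pi * turns, by = dtheta)
  cbind(radius * cos(th), radius * sin(th), pitch_per_radian * th)
}
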