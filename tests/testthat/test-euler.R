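# euler_series: zyz matrices, angle extraction, transfer rotations,
# periodic differences.

Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                         3L, byrow = TRUE)

test_that("zyz_matrix composes the standard zyz rotation", {
  expect_equal(zyz_matrix(0, 0, 0), diag(3L))
  # gimbal identity: (alpha, 0, gamma) == Rz(alpha + gamma)
  for (ag in list(c(0.3, 1.1), c(4.9, 2.2), c(5.5, 5.0))) {
    expect_lt(max(abs(zyz_matrix(ag[1], 0, ag[2]) - Rz(sum(ag)))), 1e-12)
  }
  M <- zyz_matrix(0.5, 0.3, 0.2)
  expect_equal(M[3L, 3L], cos(0.3))
  expect_equal(M[1L, 3L], cos(0.5) * sin(0.3))
  expect_equal(M[1L, 1L], cos(0.5) * cos(0.3) * cos(0.2) - sin(0.5) * sin(0.2))
  expect_equal(det(M), 1)
})

test_that("extract_zyz inverts zyz_matrix over a dense grid", {
  angles_z <- c(0.1, 1.2, 2.4, 3.3, 4.4, 5.9)  # all four atan2 quadrants
  betas <- c(0.05, 0.3, 1.5, 2.4, 3.0)
  worst <- 0
  for (a in angles_z) for (b in betas) for (g in angles_z) {
    got <- extract_zyz(zyz_matrix(a, b, g))
    worst <- max(worst, max(abs(got - c(a, b, g))))
  }
  expect_lt(worst, 1e-10)
})

test_that("extract_zyz handles the gimbal singularity by convention", {
  expect_equal(unname(extract_zyz(diag(3L))), c(0, 0, 0))
  # pure z rotation: whole angle carried by gamma, alpha pinned to 0
  e <- extract_zyz(Rz(0.6))
  expect_equal(unname(e), c(0, 0, 0.6))
  e <- extract_zyz(Rz(-0.6))
  expect_equal(unname(e), c(0, 0, 2 * pi - 0.6))
  # beta = pi branch round-trips
  e <- extract_zyz(zyz_matrix(0, pi, 1.3))
  expect_equal(unname(e), c(0, pi, 1.3))
  expect_error(extract_zyz(matrix(1:9, 3L)), "not a proper rotation")
})

test_that("periodic_difference wraps into the minimal signed rotation", {
  expect_equal(periodic_difference(c(0.1, 0.7)), 0.6)
  # right-handed step across the period edge: + 2*pi correction
  expect_equal(periodic_difference(c(6.2, 0.1)), 0.1 + 2 * pi - 6.2)
  # left-handed step: symmetric negative wrap
  expect_equal(periodic_difference(c(0.1, 5.9)), wrap_oracle(5.8))
  set.seed(31)
  th <- runif(50L, 0, 2 * pi)
  expect_equal(periodic_difference(th), wrap_oracle(diff(th)))
  # closed cycle: the wrapped increments sum to 0 mod 2*pi
  cyc <- c(th, th[1L])
  s <- sum(periodic_difference(cyc))
  expect_lt(min(abs(s - 2 * pi * (-8:8))), 1e-9)
})

test_that("rotation_series composes transfer rotations correctly", {
  # identical frames: identity transfers
  C0 <- random_rotation(2)
  fr <- make_frame_set(rep(list(C0), 5L))
  ro <- rotation_series(fr)
  for (R in ro$segments[[1L]]$relative) expect_lt(max(abs(R - diag(3L))), 1e-12)
  for (R in ro$segments[[1L]]$cumulative) expect_lt(max(abs(R - diag(3L))), 1e-12)

  # frames advanced by a fixed Rz(0.6): cumulative[k] = Rz(0.6 k)
  mats <- lapply(0:5, function(k) Rz(0.6 * k) %*% C0)
  ro <- rotation_series(make_frame_set(mats))
  for (k in 0:5) {
    expect_lt(max(abs(ro$segments[[1L]]$cumulative[[k + 1L]] - Rz(0.6 * k))), 1e-9)
  }

  # random frame sequence: C_{k+1} = cumulative[k+1] . C_1 to 1e-9
  mats <- lapply(1:6, random_rotation)
  ro <- rotation_series(make_frame_set(mats))
  seg <- ro$segments[[1L]]
  for (k in seq_along(mats)) {
    expect_lt(max(abs(mats[[k]] - seg$cumulative[[k]] %*% mats[[1L]])), 1e-9)
    # orthogonal, det +1, and cumulative equals the ordered relative product
    expect_lt(max(abs(crossprod(seg$cumulative[[k]]) - diag(3L))), 1e-9)
    expect_equal(det(seg$cumulative[[k]]), 1, tolerance = 1e-9)
  }
  prod_check <- diag(3L)
  for (j in seq_along(seg$relative)) {
    prod_check <- seg$relative[[j]] %*% prod_check
    expect_lt(max(abs(seg$cumulative[[j + 1L]] - prod_check)), 1e-9)
  }
})

test_that("rotation_series splits on invalid frames and needs two valid ones", {
  mats <- lapply(1:6, random_rotation)
  fr <- make_frame_set(mats, n_sites = 10L)
  fr$valid[4L] <- FALSE  # break the run between sites 2..3 and 5..7
  fr$tangents[4L, ] <- NA_real_
  ro <- rotation_series(fr)
  expect_length(ro$segments, 2L)
  expect_equal(ro$segments[[1L]]$sites, 2:3)
  expect_equal(ro$segments[[2L]]$sites, 5:7)

  fr1 <- make_frame_set(mats[1L], n_sites = 5L)
  expect_error(rotation_series(fr1), "valid frames")
})

test_that("cumulative_euler recovers a pure z-screw", {
  C0 <- diag(3L)
  mats <- lapply(0:7, function(k) Rz(0.6 * k) %*% C0)
  ce <- cumulative_euler(rotation_series(make_frame_set(mats)))[[1L]]
  expect_equal(ce$beta, rep(0, 8L))
  expect_equal(ce$chi, (0.6 * (0:7)) %% (2 * pi))
  # gimbal identity: alpha + gamma carries the z angle at every site
  expect_equal((ce$alpha + ce$gamma) %% (2 * pi), (0.6 * (0:7)) %% (2 * pi))
})

test_that("euler series leaves exactly four blind sites on clean duplexes", {
  for (n in c(10L, 20L, 37L)) {
    st <- ideal_duplex(helix_spec("B", n_bp = n, seed = n))
    an <- run_pipeline(st)
    expect_equal(an$euler$n_evaluable, n - 4L)
    expect_equal(an$euler$n_blind, 4L)
    expect_equal(an$euler$n_invalid, 0L)
    expect_equal(unname(an$summary$counts["evaluable"] +
                          an$summary$counts["invalid"] +
                          an$summary$counts["blind"]),
                 unname(an$summary$counts["n_sites"]))
  }
})

test_that("stored angles and differences respect their ranges", {
  an <- run_pipeline(ideal_duplex(helix_spec("B", n_bp = 24L, seed = 2L)))
  eu <- an$euler
  ok <- !is.na(eu$alpha)
  expect_true(all(eu$alpha[ok] >= 0 & eu$alpha[ok] < 2 * pi))
  expect_true(all(eu$beta[ok] >= 0 & eu$beta[ok] < 2 * pi))
  expect_true(all(eu$chi[ok] >= 0 & eu$chi[ok] < 2 * pi))
  for (f in c("d_alpha", "d_beta", "d_chi")) {
    d <- eu[[f]][eu$evaluable]
    expect_true(all(d > -pi & d <= pi))
  }
  expect_identical(eu$d_rho, eu$d_chi)
})

test_that("mirroring a duplex negates the mean gauge potential exactly", {
  st <- ideal_duplex(helix_spec("B", n_bp = 40L, atom_jitter = 0, seed = 8L))
  m_orig <- run_pipeline(st)$summary$mean_d_rho
  m_mirr <- run_pipeline(mirror_structure(st))$summary$mean_d_rho
  expect_gt(m_orig, 0)
  expect_lt(abs(m_orig + m_mirr), 1e-9)
})
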