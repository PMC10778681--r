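# energy: elastic constants, free-energy density, chirality, summaries.

test_that("elastic constants follow the persistence-length scaling", {
  p <- energy_params(b = 50, c_twist = 100)
  el <- elastic_constants(0.34, p)
  expect_equal(el$B, (50 / 0.34) * 1e-1 * 4.1e-21, tolerance = 1e-12)
  expect_equal(el$C, (100 / 0.34) * 1e-1 * 4.1e-21, tolerance = 1e-12)

  p_eq <- energy_params(b = 70, c_twist = 70)
  el_eq <- elastic_constants(0.42, p_eq)
  expect_equal(el_eq$B, el_eq$C)

  el2 <- elastic_constants(2 * 0.34, p)
  expect_equal(el2$B, el$B / 2)
  expect_equal(el2$C, el$C / 2)
  expect_error(elastic_constants(0, p), "positive")
  expect_error(elastic_constants(-0.3, p), "positive")
})

test_that("energy_params derives d1 and validates inputs", {
  p <- energy_params()
  expect_equal(p$d1, 4.1e-21 / 0.36)
  expect_equal(p$tau_c, -7.9e-21)
  expect_error(energy_params(b = -1), "b > 0")
})

test_that("free energy vanishes for flat geometry and zero gauge potential", {
  inp <- make_single_site_inputs(d_alpha = 0, d_beta = 0, d_chi = 0,
                                 beta = 0, step = 0.34)
  g <- geometry_series(inp$euler, inp$axis)
  en <- free_energy_series(g, inp$euler, inp$axis)
  expect_equal(en$F_total[3L], 0)
  expect_equal(en$Fs[3L], 0)
})

test_that("a pure gauge step reproduces the independent three-term sum", {
  # only d_rho = d_chi = 0.6 rad over ds = 0.34 nm; no bending, no tau_g
  inp <- make_single_site_inputs(d_alpha = 0, d_beta = 0, d_chi = 0.6,
                                 beta = 0, step = 0.34)
  g <- geometry_series(inp$euler, inp$axis)
  en <- free_energy_series(g, inp$euler, inp$axis)

  # independent evaluation, no shared helpers
  C_i <- (100 / 0.34) * 1e-1 * 4.1e-21
  d1 <- 4.1e-21 / 0.6^2
  term_C <- C_i / 2 * (0 + 0.6 / 0.34 - 0.6)^2
  term_d1 <- d1 / 2 * (0.6 / 0.34)^2
  term_tc <- -7.9e-21 * 0.6
  expect_equal(term_tc, -4.74e-21)
  expect_gt(term_C, 0)
  expect_gt(term_d1, 0)
  expect_equal(en$F_total[3L], term_C + term_d1 + term_tc, tolerance = 1e-12)
  expect_equal(en$Fs[3L], term_C, tolerance = 1e-12)
})

test_that("negating the gauge potential flips only the critical-torque term", {
  pos <- make_single_site_inputs(d_alpha = 0.2, d_beta = 0.1, d_chi = 0.6,
                                 beta = 0.9, step = 0.34)
  neg <- make_single_site_inputs(d_alpha = -0.2, d_beta = 0.1, d_chi = -0.6,
                                 beta = 0.9, step = 0.34)
  g_pos <- geometry_series(pos$euler, pos$axis)
  g_neg <- geometry_series(neg$euler, neg$axis)
  # tau_g flips with d_alpha; quadratic terms are even
  en_pos <- free_energy_series(g_pos, pos$euler, pos$axis)
  en_neg <- free_energy_series(g_neg, neg$euler, neg$axis)
  expect_equal(en_pos$Fs[3L], en_neg$Fs[3L], tolerance = 1e-12)
  expect_equal(en_pos$F_total[3L] - en_neg$F_total[3L],
               2 * (-7.9e-21) * 0.6, tolerance = 1e-12)
})

test_that("pipeline free energy matches an independent term-by-term oracle", {
  an <- run_pipeline(ideal_duplex(helix_spec("B", n_bp = 30L, seed = 17L)))
  eu <- an$euler
  g <- an$geometry
  for (i in which(eu$evaluable)) {
    ds <- an$axis$steps[i - 1L]
    B_i <- 50 / ds * 1e-1 * 4.1e-21
    C_i <- 100 / ds * 1e-1 * 4.1e-21
    oracle <- B_i / 2 * (g$k_n[i]^2 + g$k_g[i]^2) +
      C_i / 2 * (g$tau_g[i] + eu$d_chi[i] / ds - eu$d_rho[i])^2 +
      (4.1e-21 / 0.36) / 2 * (eu$d_rho[i] / ds)^2 +
      (-7.9e-21) * eu$d_rho[i]
    expect_equal(an$energy$F_total[i], oracle, tolerance = 1e-12)
    expect_equal(an$energy$F_total[i], an$energy$Fs[i] + an$energy$potential[i],
                 tolerance = 1e-12)
  }
})

test_that("chirality classification follows the sign of the mean gauge potential", {
  mk <- function(val) {
    inp <- make_single_site_inputs(0, 0, val, 0.3, 0.34)
    inp$euler
  }
  expect_equal(classify_chirality(mk(0.6))$handedness, "right")
  expect_equal(classify_chirality(mk(0.6))$form, "B-type")
  expect_equal(classify_chirality(mk(-0.6))$handedness, "left")
  expect_equal(classify_chirality(mk(-0.6))$form, "Z-type")
  expect_equal(classify_chirality(mk(0))$handedness, "ambiguous")
  expect_equal(classify_chirality(mk(0.04))$handedness, "ambiguous")
  expect_equal(classify_chirality(mk(0.04), threshold = 0.01)$handedness, "right")
})

test_that("summaries account for every site and collapse on uniform input", {
  an <- run_pipeline(ideal_duplex(helix_spec("B", n_bp = 20L, atom_jitter = 0,
                                             seed = 4L)))
  s <- an$summary
  expect_equal(unname(s$counts["evaluable"]), 16L)
  expect_equal(unname(s$counts["blind"]), 4L)
  expect_equal(s$handedness, "right")
  # ideal duplex: per-site values identical, so IQR collapses to zero
  expect_equal(s$stats["d_rho", "q1"], s$stats["d_rho", "q3"], tolerance = 1e-12)
  expect_equal(s$stats["F", "mean"], s$stats["F", "median"], tolerance = 1e-9)
})

test_that("right-handed duplexes have lower free energy than matched left-handed", {
  spec_r <- helix_spec("B", n_bp = 40L, atom_jitter = 0, seed = 9L)
  spec_l <- helix_spec("B", n_bp = 40L, twist = -spec_r$twist, atom_jitter = 0,
                       seed = 9L)
  f_r <- run_pipeline(ideal_duplex(spec_r))$summary$stats["F", "mean"]
  f_l <- run_pipeline(ideal_duplex(spec_l))$summary$stats["F", "mean"]
  expect_lt(f_r, f_l)
  # the gap is exactly twice the critical-torque work per step
  expect_equal(f_l - f_r, 2 * 7.9e-21 * 2 * pi / 10.5, tolerance = 1e-6)
})

test_that("the geometric part dominates the free energy on generator duplexes", {
  for (form in c("B", "Z")) {
    an <- run_pipeline(ideal_duplex(helix_spec(form, n_bp = 40L, seed = 3L)))
    v <- an$euler$evaluable
    expect_gt(abs(mean(an$energy$Fs[v])),
              abs(mean(an$energy$F_total[v] - an$energy$Fs[v])))
  }
})
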