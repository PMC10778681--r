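# energy: per-site critical-state free-energy density, chirality call,
# and per-structure summary statistics.

#' Elastic and effective-potential parameters
#'
#' Bundles the physical constants of the critical-state free energy.
#' `b` and `c` are the bending and twisting persistence lengths (nm) that set
#' the per-site elastic constants via [elastic_constants()]; literature-typical
#' B-DNA values are the defaults. `kT_R = 4.1e-21 J` is the thermal energy at
#' room temperature. The effective potential uses `d1 = D1 / omega0^2` with
#' `D1 = 4.1e-21 J` and `omega0 = 0.6` rad per base pair (the unstressed
#' helical rotation), and the critical torque `tau_c = -7.9e-21 J`, whose
#' negative sign biases the free energy toward right-handed twist.
#'
#' @param b bending persistence length (nm).
#' @param c_twist twisting persistence length (nm).
#' @param kT_R thermal constant (J).
#' @param D1 effective-potential stiffness scale (J).
#' @param omega0 unstressed twist (rad per base pair).
#' @param tau_c critical torque (J).
#' @return `energy_params` list, including the derived `d1` (J rad^-2).
#' @export
energy_params <- function(b = 50, c_twist = 100, kT_R = 4.1e-21,
                          D1 = 4.1e-21, omega0 = 0.6, tau_c = -7.9e-21) {
  stopifnot(b > 0, c_twist > 0, omega0 > 0, kT_R > 0, D1 > 0)
  structure(
    list(b = b, c_twist = c_twist, kT_R = kT_R, D1 = D1, omega0 = omega0,
         tau_c = tau_c, d1 = D1 / omega0^2),
    class = "energy_params"
  )
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    "energy_params: b = %g nm, c = %g nm, D1 = %g J, omega0 = %g rad/bp, tau_c = %g J, d1 = %g J/rad^2\n",
    x$b, x$c_twist, x$D1, x$omega0, x$tau_c, x$d1))
  invisible(x)
}

#' Per-site elastic constants
#'
#' The isotropic bending elasticity and the torsional elasticity at a site
#' scale the persistence lengths by the local arc step:
#' \deqn{B_i = (b/\Delta s_{i,i-1}) \times 10^{-1} \times 4.1\times10^{-21}\ J,
#'  \quad C_i = (c/\Delta s_{i,i-1}) \times 10^{-1} \times 4.1\times10^{-21}\ J.}
#'
#' @param step arc step(s) `Delta s` (nm), positive.
#' @param params an [energy_params()] object.
#' @return list with vectors `B` and `C` (J), same length as `step`.
#' @export
elastic_constants <- function(step, params = energy_params()) {
  if (any(step <= 0, na.rm = TRUE)) stop("arc step must be positive", call. = FALSE)
  list(B = (params$b / step) * 1e-1 * params$kT_R,
       C = (params$c_twist / step) * 1e-1 * params$kT_R)
}

#' Critical-state free-energy density per site
#'
#' Evaluates the discretized free-energy density
#' \deqn{F_i = \frac{B_i}{2}(k_{n,i}^2 + k_{g,i}^2)
#'   + \frac{C_i}{2}\Big(\tau_{g,i} + \frac{\Delta\chi}{\Delta s}
#'     - \Delta\rho\Big)^2
#'   + \frac{d_1}{2}\Big(\frac{\Delta\rho}{\Delta s}\Big)^2
#'   + \tau_c\,\Delta\rho,}
#' with the gauge identification \eqn{\Delta\rho = \Delta\chi} enforced
#' upstream. `Fs` collects the first two (purely geometric) terms; the
#' remainder is the effective potential. The `tau_c` term is the only one odd
#' in the gauge potential, so right-handed twist (positive gauge potential)
#' lowers the free energy while left-handed twist raises it.
#'
#' @param geom a `geometry_series`.
#' @param euler the matching `euler_series`.
#' @param axis the matching `axis_trace`.
#' @param params an [energy_params()] object.
#' @return `energy_series`: per-site vectors `F_total`, `Fs` (geometric part),
#'   `potential` (= `F_total - Fs`), `B_i`, `C_i` (all J per site; `NA` off the
#'   evaluable range), logical `valid`, and the `params` used.
#' @export
free_energy_series <- function(geom, euler, axis, params = energy_params()) {
  n <- euler$n_sites
  if (length(geom$valid) != n || nrow(axis$points) != n) {
    stop("geometry, euler and axis series are misaligned", call. = FALSE)
  }
  F_total <- Fs <- potential <- B_i <- C_i <- rep(NA_real_, n)
  for (i in which(euler$evaluable)) {
    ds <- geom$step[i]
    el <- elastic_constants(ds, params)
    B_i[i] <- el$B
    C_i[i] <- el$C
    bend <- el$B / 2 * (geom$k_n[i]^2 + geom$k_g[i]^2)
    twist <- el$C / 2 * (geom$tau_g[i] + euler$d_chi[i] / ds - euler$d_rho[i])^2
    Fs[i] <- bend + twist
    potential[i] <- params$d1 / 2 * (euler$d_rho[i] / ds)^2 + params$tau_c * euler$d_rho[i]
    F_total[i] <- Fs[i] + potential[i]
  }
  structure(
    list(F_total = F_total, Fs = Fs, potential = potential,
         B_i = B_i, C_i = C_i, valid = euler$evaluable, params = params),
    class = "energy_series"
  )
}

#' Classify helix chirality from the gauge potential
#'
#' The mean per-step gauge potential is positive for a right-handed
#' (B-type) helix and negative for a left-handed (Z-type) helix; values within
#' `threshold` of zero are called ambiguous.
#'
#' @param euler an `euler_series` with at least one evaluable site.
#' @param threshold decision threshold (rad), default 0.05.
#' @return list with `handedness` (`"right"`, `"left"` or `"ambiguous"`),
#'   `form` (`"B-type"`, `"Z-type"` or `NA`) and `mean_d_rho` (rad).
#' @export
classify_chirality <- function(euler, threshold = 0.05) {
  if (euler$n_evaluable < 1L) stop("no evaluable gauge-potential values", call. = FALSE)
  m <- mean(euler$d_rho[euler$evaluable])
  handedness <- if (m > threshold) "right" else if (m < -threshold) "left" else "ambiguous"
  form <- switch(handedness, right = "B-type", left = "Z-type", NA_character_)
  list(handedness = handedness, form = form, mean_d_rho = m)
}

quartile_stats <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Per-structure summary statistics
#'
#' Aggregates the per-site series over the evaluable sites: means and
#' quartiles of the free-energy density, gauge potential, overall curvature
#' and torsion, and the absolute geodesic and normal curvatures; plus the
#' chirality call and the site accounting (evaluable + invalid + blind =
#' number of axis sites).
#'
#' @param axis an `axis_trace`.
#' @param frames the `frame_set` built on it.
#' @param euler the `euler_series`.
#' @param geom the `geometry_series`.
#' @param energy the `energy_series`.
#' @param threshold chirality threshold passed to [classify_chirality()].
#' @return `duplex_summary`: list with `stats` (matrix of mean/q1/median/q3 per
#'   quantity), `handedness`, `form`, `mean_d_rho`, and `counts`.
#' @export
summarize_duplex <- function(axis, frames, euler, geom, energy, threshold = 0.05) {
  v <- euler$evaluable
  stats <- rbind(
    F = quartile_stats(energy$F_total[v]),
    Fs = quartile_stats(energy$Fs[v]),
    d_rho = quartile_stats(euler$d_rho[v]),
    k = quartile_stats(geom$k_total[v]),
    tau = quartile_stats(geom$tau_total[v]),
    abs_k_g = quartile_stats(abs(geom$k_g[v])),
    abs_k_n = quartile_stats(abs(geom$k_n[v]))
  )
  chir <- classify_chirality(euler, threshold)
  counts <- c(
    n_sites = euler$n_sites,
    evaluable = euler$n_evaluable,
    invalid = euler$n_invalid,
    blind = euler$n_blind
  )
  structure(
    list(stats = stats, handedness = chir$handedness, form = chir$form,
         mean_d_rho = chir$mean_d_rho, counts = counts),
    class = "duplex_summary"
  )
}

#' @export
print.duplex_summary <- function(x, ...) {
  cat(sprintf("duplex_summary: %s helix (%s), mean gauge potential %+.4f rad/step\n",
              x$handedness, ifelse(is.na(x$form), "form undetermined", x$form),
              x$mean_d_rho))
  cat(sprintf("  sites: %d total = %d evaluable + %d invalid + %d blind\n",
              x$counts["n_sites"], x$counts["evaluable"],
              x$counts["invalid"], x$counts["blind"]))
  cat(sprintf("  mean F = %.4g J/site (Fs = %.4g), mean k = %.4f 1/nm, mean tau = %.4f\n",
              x$stats["F", "mean"], x$stats["Fs", "mean"],
              x$stats["k", "mean"], x$stats["tau", "mean"]))
  invisible(x)
}
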