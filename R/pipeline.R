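# cli_report: end-to-end orchestration, per-site CSV and summary JSON
# writers, and the simulate entry point. A thin command-line front-end
# wrapping these functions ships in inst/cli/helixframe.R.

#' Run the full analysis pipeline on an in-memory structure
#'
#' Chains together backbone extraction, antiparallel pairing, helical-axis
#' construction, chain-direction canonicalization ([orient_axis()]), discrete
#' Frenet frames, transfer rotations, Euler-angle series, curvature/torsion
#' geometry, free-energy evaluation and the per-structure summary.
#'
#' @param structure a `nuc_structure` (from [read_structure()] or
#'   [ideal_duplex()]).
#' @param chains character vector of two chain IDs; default: the first two
#'   chains of the structure.
#' @param params an [energy_params()] object.
#' @param step_pairing passed to [geometry_series()].
#' @param frame_tol degeneracy tolerance passed to [build_frames()].
#' @param chirality_threshold passed to [classify_chirality()] (rad).
#' @return `helix_analysis`: list with every intermediate (`pairing`, `axis`,
#'   `frames`, `euler`, `geometry`, `energy`) plus `summary` and the
#'   configuration used.
#' @export
run_pipeline <- function(structure, chains = NULL, params = energy_params(),
                         step_pairing = c("trailing", "forward"),
                         frame_tol = 1e-8, chirality_threshold = 0.05) {
  step_pairing <- match.arg(step_pairing)
  if (is.null(chains)) {
    if (length(structure$chains) < 2L) {
      stop("structure has fewer than two chains; specify `chains`", call. = FALSE)
    }
    chains <- names(structure$chains)[1:2]
  }
  if (length(chains) != 2L) stop("`chains` must name exactly two chains", call. = FALSE)
  trace_a <- backbone_trace(structure, chains[1L])
  trace_b <- backbone_trace(structure, chains[2L])
  pairing <- pair_strands(trace_a, trace_b)
  if (nrow(pairing$pairs) < 5L) {
    stop("too short: only ", nrow(pairing$pairs),
         " usable base pairs (need at least 5)", call. = FALSE)
  }
  axis <- orient_axis(axis_trace(pairing))
  frames <- build_frames(axis$points, tol = frame_tol)
  rotations <- rotation_series(frames)
  euler <- euler_series(frames, rotations)
  geometry <- geometry_series(euler, axis, step_pairing)
  energy <- free_energy_series(geometry, euler, axis, params)
  summary <- summarize_duplex(axis, frames, euler, geometry, energy,
                              chirality_threshold)
  structure(
    list(
      source = structure$source, chains = chains, pairing = pairing,
      axis = axis, frames = frames, rotations = rotations, euler = euler,
      geometry = geometry, energy = energy, summary = summary,
      config = list(
        chains = chains, step_pairing = step_pairing, frame_tol = frame_tol,
        chirality_threshold = chirality_threshold,
        length_unit = "nm", energy_unit = "J",
        b_nm = params$b, c_nm = params$c_twist, kT_R_J = params$kT_R,
        D1_J = params$D1, omega0_rad_per_bp = params$omega0,
        tau_c_J = params$tau_c, d1_J_per_rad2 = params$d1
      )
    ),
    class = "helix_analysis"
  )
}

#' @export
print.helix_analysis <- function(x, ...) {
  cat("helix_analysis of", x$source, "\n")
  print(x$summary)
  invisible(x)
}

#' Per-site table of an analysis
#'
#' @param analysis a `helix_analysis`.
#' @return data frame with one row per axis site: arc step, curvature and
#'   torsion components, gauge potential, elastic constants and free-energy
#'   terms (units in the column names).
#' @export
site_table <- function(analysis) {
  eu <- analysis$euler
  ge <- analysis$geometry
  en <- analysis$energy
  data.frame(
    site = seq_len(eu$n_sites),
    step_nm = ge$step,
    k_g_per_nm = ge$k_g,
    k_n_per_nm = ge$k_n,
    tau_g_per_nm = ge$tau_g,
    k_per_nm = ge$k_total,
    tau_model_units = ge$tau_total,
    d_rho_rad = eu$d_rho,
    B_J = en$B_i,
    C_J = en$C_i,
    Fs_J = en$Fs,
    F_J = en$F_total,
    evaluable = eu$evaluable
  )
}

summary_payload <- function(analysis) {
  s <- analysis$summary
  stats <- lapply(rownames(s$stats), function(r) as.list(s$stats[r, ]))
  names(stats) <- rownames(s$stats)
  list(
    source = analysis$source,
    handedness = s$handedness,
    form = s$form,
    mean_d_rho_rad = s$mean_d_rho,
    stats = stats,
    counts = as.list(s$counts),
    log = list(
      invalid_frames = analysis$euler$n_invalid,
      gimbal_lock_sites = analysis$euler$n_gimbal,
      non_complementary_pairs = sum(!analysis$pairing$complementarity_ok),
      blind_sites = analysis$euler$n_blind,
      axis_flipped_to_plus_z = isTRUE(attr(analysis$axis, "flipped"))
    ),
    config = analysis$config
  )
}

#' Write the per-site CSV and summary JSON of an analysis
#'
#' Numbers are serialized with 10 significant digits; identical analyses give
#' byte-identical files (no timestamps).
#'
#' @param analysis a `helix_analysis`.
#' @param out_dir output directory (created if missing).
#' @param name file-name stem; default: basename of the structure source.
#' @return named character vector with the paths written, invisibly.
#' @export
write_analysis <- function(analysis, out_dir, name = NULL) {
  if (is.null(name)) {
    name <- gsub("[^A-Za-z0-9._-]", "_",
                 sub("\\.pdb$", "", basename(analysis$source), ignore.case = TRUE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, paste0(name, "_sites.csv"))
  json_path <- file.path(out_dir, paste0(name, "_summary.json"))
  df <- site_table(analysis)
  num_cols <- vapply(df, is.numeric, logical(1L)) & names(df) != "site"
  df[num_cols] <- lapply(df[num_cols], num10)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary_payload(analysis), json_path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Analyze a batch of PDB files
#'
#' Runs the full pipeline on each input. Per-structure failures are caught and
#' reported; the batch continues. The exit contract for scripted use: the
#' attribute `failures` lists the inputs that failed with their messages.
#'
#' @param paths character vector of PDB file paths (at least one).
#' @param chains two chain IDs to analyze in each file.
#' @param model_index model selector for multi-model files.
#' @param params an [energy_params()] object.
#' @param step_pairing passed to [geometry_series()].
#' @param out_dir if non-`NULL`, per-site CSV and summary JSON are written
#'   there for every structure that succeeds.
#' @param verbose print a one-line summary per structure.
#' @return named list of `helix_analysis` objects (successes only), with
#'   attribute `failures`: a named character vector of error messages.
#' @export
analyze <- function(paths, chains = c("A", "B"), model_index = 1L,
                    params = energy_params(),
                    step_pairing = c("trailing", "forward"),
                    out_dir = NULL, verbose = FALSE) {
  if (length(paths) == 0L) stop("no input files given", call. = FALSE)
  step_pairing <- match.arg(step_pairing)
  results <- list()
  failures <- character(0L)
  for (p in paths) {
    res <- tryCatch({
      st <- read_structure(p, model_index)
      an <- run_pipeline(st, chains = chains, params = params,
                         step_pairing = step_pairing)
      if (!is.null(out_dir)) write_analysis(an, out_dir)
      an
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[p] <- conditionMessage(res)
      if (verbose) message(p, ": FAILED (", conditionMessage(res), ")")
    } else {
      results[[p]] <- res
      if (verbose) {
        message(sprintf("%s: %s, mean d_rho = %+.4f rad", p,
                        res$summary$handedness, res$summary$mean_d_rho))
      }
    }
  }
  attr(results, "failures") <- failures
  results
}

#' Generate an ideal duplex and write it as PDB
#'
#' Deterministic given the spec (including its seed): identical calls produce
#' byte-identical files.
#'
#' @param spec a [helix_spec()].
#' @param out output PDB path.
#' @return `out`, invisibly.
#' @export
simulate_duplex <- function(spec = helix_spec(), out) {
  write_duplex_pdb(ideal_duplex(spec), out)
  invisible(out)
}
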