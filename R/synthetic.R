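# synthetic: ideal duplex generator (writable as PDB), mirror reflection,
# and the closed-form circular-helix curvature/torsion oracles.

# unit tetrahedral directions; they sum to zero, so the mean of the four
# pseudo-atoms equals the backbone point at any jitter
TETRAHEDRON <- rbind(
  c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
) / sqrt(3)

#' Specification of an ideal synthetic duplex
#'
#' Canonical fiber-diffraction-style helical parameters, overridable field by
#' field. The B form uses +2*pi/10.5 rad of twist per base pair (right-handed,
#' 10.5 bp/turn), 0.34 nm rise and a 154-degree phase gap between the two
#' backbone points of a pair (groove asymmetry: the midpoint axis is then a
#' genuine small-radius helix rather than a straight line). The Z form uses
#' -2*pi/12 rad (left-handed, 12 bp/turn), 0.37 nm rise and a 160-degree
#' phase gap, with an alternating CG sequence.
#'
#' @param form `"B"` or `"Z"`; sets the defaults below.
#' @param n_bp number of base pairs (>= 5).
#' @param twist helical rotation per base pair (rad, signed; > 0 right-handed).
#' @param rise axial rise per base pair (nm, > 0).
#' @param backbone_radius radius of the backbone helices (nm, > 0).
#' @param strand_phase_gap angular offset between the two paired backbone
#'   points (rad).
#' @param atom_jitter spread of the four pseudo-atoms around each backbone
#'   point (nm, >= 0); their mean is exact at any jitter.
#' @param seed integer seed for the generated sequence.
#' @param sequence optional explicit base sequence (character vector of
#'   A/C/G/T, length `n_bp`) overriding the seeded/alternating default.
#' @return `helix_spec` list.
#' @export
helix_spec <- function(form = c("B", "Z"), n_bp = 50L,
                       twist = NULL, rise = NULL, backbone_radius = 0.94,
                       strand_phase_gap = NULL, atom_jitter = 0.04,
                       seed = 1L, sequence = NULL) {
  form <- match.arg(form)
  if (is.null(twist)) twist <- if (form == "B") 2 * pi / 10.5 else -2 * pi / 12
  if (is.null(rise)) rise <- if (form == "B") 0.34 else 0.37
  if (is.null(strand_phase_gap)) {
    strand_phase_gap <- if (form == "B") 154 * pi / 180 else 160 * pi / 180
  }
  if (n_bp < 5L) stop("n_bp must be at least 5", call. = FALSE)
  if (rise <= 0) stop("rise must be positive", call. = FALSE)
  if (backbone_radius <= 0) stop("backbone_radius must be positive", call. = FALSE)
  if (abs(twist) >= pi) stop("|twist| must be below pi", call. = FALSE)
  if (atom_jitter < 0) stop("atom_jitter must be non-negative", call. = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (length(sequence) != n_bp || !all(sequence %in% c("A", "C", "G", "T"))) {
      stop("sequence must be ", n_bp, " letters from A/C/G/T", call. = FALSE)
    }
  }
  structure(
    list(form = form, n_bp = as.integer(n_bp), twist = twist, rise = rise,
         backbone_radius = backbone_radius, strand_phase_gap = strand_phase_gap,
         atom_jitter = atom_jitter, seed = as.integer(seed), sequence = sequence),
    class = "helix_spec"
  )
}

spec_sequence <- function(spec) {
  if (!is.null(spec$sequence)) return(spec$sequence)
  if (spec$form == "Z") {
    return(rep_len(c("C", "G"), spec$n_bp))
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    code
  }
  withr_seed(sample(c("A", "C", "G", "T"), spec$n_bp, replace = TRUE))
}

#' Generate an ideal duplex structure
#'
#' Builds a two-chain `nuc_structure` (the same class [read_structure()]
#' returns, so the whole analysis pipeline runs on it unchanged). The backbone
#' point of strand A pair i sits at angle `i * twist` and height `i * rise` on
#' a cylinder of radius `backbone_radius`; the paired strand B point sits at
#' the same height, offset by `strand_phase_gap` in angle. Strand B carries
#' the complementary base and its residues are emitted in reversed order
#' (antiparallel 5'->3'). Each residue gets four pseudo-atoms named C3', C4',
#' O3', C1' at fixed tetrahedral offsets scaled by `atom_jitter`, so their
#' arithmetic mean reproduces the backbone point exactly.
#'
#' @param spec a [helix_spec()].
#' @return a `nuc_structure` with chains `A` and `B`.
#' @export
ideal_duplex <- function(spec = helix_spec()) {
  n <- spec$n_bp
  bases_a <- spec_sequence(spec)
  bases_b_paired <- unname(WC_COMPLEMENT[bases_a])
  theta <- (seq_len(n) - 1L) * spec$twist
  z <- (seq_len(n) - 1L) * spec$rise
  pa <- cbind(spec$backbone_radius * cos(theta),
              spec$backbone_radius * sin(theta), z) * ANGSTROM_PER_NM
  pb <- cbind(spec$backbone_radius * cos(theta + spec$strand_phase_gap),
              spec$backbone_radius * sin(theta + spec$strand_phase_gap),
              z) * ANGSTROM_PER_NM
  offsets <- TETRAHEDRON * spec$atom_jitter * ANGSTROM_PER_NM

  make_unit <- function(chain_id, res_index, base, centre) {
    coords <- lapply(seq_len(4L), function(k) unname(centre + offsets[k, ]))
    names(coords) <- BACKBONE_ATOMS
    new_nucleotide_unit(chain_id, as.integer(res_index), paste0("D", base), coords)
  }
  units_a <- lapply(seq_len(n), function(i) make_unit("A", i, bases_a[i], pa[i, ]))
  # strand B file order is its own 5'->3': residue j pairs with A residue n+1-j
  units_b <- lapply(seq_len(n), function(j) {
    i <- n + 1L - j
    make_unit("B", j, bases_b_paired[i], pb[i, ])
  })
  structure(
    list(chains = list(A = list(chain_id = "A", units = units_a),
                       B = list(chain_id = "B", units = units_b)),
         source = sprintf("ideal_duplex(%s, n_bp = %d)", spec$form, n),
         spec = spec),
    class = "nuc_structure"
  )
}

#' Mirror a structure through the xy-plane
#'
#' Negates the z coordinate of every atom. Distances are preserved (the map is
#' an isometry) but handedness is inverted: the mirror image of a right-handed
#' duplex is a valid left-handed duplex.
#'
#' @param structure a `nuc_structure`.
#' @return the reflected `nuc_structure`.
#' @export
mirror_structure <- function(structure) {
  structure$chains <- lapply(structure$chains, function(ch) {
    ch$units <- lapply(ch$units, function(u) {
      u$atom_coords <- lapply(u$atom_coords, function(p) p * c(1, 1, -1))
      u
    })
    ch
  })
  structure$source <- paste0("mirror(", structure$source, ")")
  structure
}

#' Write a structure as a PDB file
#'
#' Serializes all chains as standard ATOM records (via \pkg{bio3d}),
#' coordinates in angstrom to the 0.001-angstrom PDB precision.
#'
#' @param structure a `nuc_structure`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_duplex_pdb <- function(structure, path) {
  rows <- list()
  for (ch in structure$chains) {
    for (u in ch$units) {
      for (an in names(u$atom_coords)) {
        rows[[length(rows) + 1L]] <- list(
          chain = ch$chain_id, resno = u$residue_index, resid = u$residue_name,
          elety = an, xyz = u$atom_coords[[an]]
        )
      }
    }
  }
  # vapply gives a 3 x n matrix; column-major flattening yields the
  # interleaved (x1, y1, z1, x2, ...) layout write.pdb expects
  xyz <- as.numeric(vapply(rows, function(r) r$xyz, numeric(3L)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = vapply(rows, function(r) r$resno, numeric(1L)),
    resid = vapply(rows, function(r) r$resid, character(1L)),
    chain = vapply(rows, function(r) r$chain, character(1L)),
    elety = vapply(rows, function(r) r$elety, character(1L)),
    eleno = seq_along(rows),
    o = rep(1, length(rows)), b = rep(0, length(rows))
  )
  invisible(path)
}

#' Closed-form curvature and torsion of a circular helix
#'
#' A circular helix of radius \eqn{R_h} and pitch-per-radian \eqn{c}
#' (so one turn climbs \eqn{2\pi c}) has constant Frenet curvature
#' \eqn{R_h/(R_h^2+c^2)} and torsion \eqn{c/(R_h^2+c^2)}. These are the
#' continuous limits of the discrete estimators and serve as analytic oracles
#' in convergence tests.
#'
#' @param radius helix radius \eqn{R_h} (nm, > 0).
#' @param pitch_per_radian axial climb per radian of turn (nm; 0 for a circle).
#' @return list with `curvature` and `torsion` (1/nm).
#' @export
continuous_helix_forms <- function(radius, pitch_per_radian) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  d <- radius^2 + pitch_per_radian^2
  list(curvature = radius / d, torsion = pitch_per_radian / d)
}
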