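# structure_io: PDB input, per-nucleotide backbone representative points,
# and antiparallel strand pairing.

# The four deoxyribose/backbone atoms whose mean defines the backbone
# representative point of a nucleotide.
BACKBONE_ATOMS <- c("C3'", "C4'", "O3'", "C1'")

# residue-name -> base letter, covering the PDB v3 names, one-letter legacy
# names, three-letter legacy names and terminal 5'/3' variants
NUCLEOTIDE_BASES <- c(
  DA = "A", DC = "C", DG = "G", DT = "T",
  A = "A", C = "C", G = "G", T = "T",
  ADE = "A", CYT = "C", GUA = "G", THY = "T",
  DA5 = "A", DC5 = "C", DG5 = "G", DT5 = "T",
  DA3 = "A", DC3 = "C", DG3 = "G", DT3 = "T"
)

WC_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

SOLVENT_RESIDUES <- c("HOH", "WAT", "DOD", "NA", "CL", "MG", "K", "ZN", "CA", "MN", "SO4", "PO4")

#' Normalize a PDB atom name to the primed convention
#'
#' Legacy PDB files name sugar atoms with a trailing asterisk (`C3*`); newer
#' files (and some tools) use an ASCII or typographic prime. All are mapped to
#' the canonical ASCII-primed form (`C3'`), with surrounding whitespace removed.
#'
#' @param x character vector of atom names.
#' @return character vector of canonical atom names.
#' @examples
#' normalize_atom_name(c("C3*", " O3' ", "C1′"))
#' @export
normalize_atom_name <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  x <- gsub("\\*", "'", x)
  gsub("′", "'", x)
}

base_letter <- function(residue_name) {
  unname(NUCLEOTIDE_BASES[toupper(residue_name)])
}

new_nucleotide_unit <- function(chain_id, residue_index, residue_name, atom_coords) {
  missing_atoms <- setdiff(BACKBONE_ATOMS, names(atom_coords))
  structure(
    list(
      chain_id = chain_id,
      residue_index = residue_index,
      residue_name = residue_name,
      base = base_letter(residue_name),
      atom_coords = atom_coords,
      usable = length(missing_atoms) == 0L,
      missing_atoms = missing_atoms
    ),
    class = "nucleotide_unit"
  )
}

#' Read the nucleic-acid content of a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) and returns every nucleotide residue
#' grouped by chain, in file order. A residue counts as a nucleotide if it has
#' a standard DNA residue name (or common alias) or if it carries all four
#' backbone atoms C3', C4', O3', C1' (modified nucleotides). Waters, ions and
#' protein residues are excluded. Alternate locations are resolved to the
#' highest-occupancy copy. Of a multi-model file only the model selected by
#' `model_index` is used.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based model number for multi-model files (default 1).
#' @return An object of class `nuc_structure`: a list with `chains`, a named
#'   list of chains, each of which is a list with `chain_id` and `units`
#'   (a list of `nucleotide_unit` objects). Units missing any of the four
#'   backbone atoms are flagged `usable = FALSE`, never dropped.
#' @seealso [backbone_point()], [backbone_trace()], [ideal_duplex()]
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path, call. = FALSE)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range: file has ", n_models,
         " model(s)", call. = FALSE)
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  atoms$x <- xyz[, 1L]
  atoms$y <- xyz[, 2L]
  atoms$z <- xyz[, 3L]
  atoms$elety <- normalize_atom_name(atoms$elety)
  atoms$resid <- toupper(gsub("[[:space:]]", "", atoms$resid))
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms <- atoms[!(atoms$resid %in% SOLVENT_RESIDUES), , drop = FALSE]

  # resolve altlocs: within one (chain, residue, atom name) keep the
  # highest-occupancy record; ties resolved by file order
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]

  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  chains <- list()
  for (rk in unique(res_key)) {
    sel <- res_key == rk
    resid <- atoms$resid[sel][1L]
    names_sel <- atoms$elety[sel]
    has_backbone <- all(BACKBONE_ATOMS %in% names_sel)
    if (is.na(base_letter(resid)) && !has_backbone) next  # not a nucleotide
    coords <- lapply(which(sel), function(i) c(atoms$x[i], atoms$y[i], atoms$z[i]))
    names(coords) <- names_sel
    cid <- atoms$chain[sel][1L]
    unit <- new_nucleotide_unit(cid, atoms$resno[sel][1L], resid, coords)
    if (is.null(chains[[cid]])) chains[[cid]] <- list(chain_id = cid, units = list())
    chains[[cid]]$units <- c(chains[[cid]]$units, list(unit))
  }
  if (length(chains) == 0L) {
    seen <- unique(pdb$atom$chain)
    seen[is.na(seen)] <- " "
    stop("no nucleic-acid chain found in ", path, "; chains seen: ",
         paste(sort(unique(seen)), collapse = ", "), call. = FALSE)
  }
  structure(list(chains = chains, source = path), class = "nuc_structure")
}

#' @export
print.nuc_structure <- function(x, ...) {
  cat("nuc_structure:", length(x$chains), "chain(s)\n")
  for (ch in x$chains) {
    usable <- sum(vapply(ch$units, function(u) u$usable, logical(1L)))
    cat(sprintf("  chain %s: %d nucleotide(s), %d usable\n",
                ch$chain_id, length(ch$units), usable))
  }
  invisible(x)
}

#' Backbone representative point of a nucleotide
#'
#' The representative point of a deoxynucleotide is the arithmetic mean of its
#' C3', C4', O3' and C1' atom positions: the deoxyribose is the unit linking
#' base and phosphate backbone, so this average localizes the residue on the
#' backbone strand.
#'
#' @param unit a `nucleotide_unit` (see [read_structure()]).
#' @return numeric length-3 vector, in the input coordinate unit (angstrom).
#' @export
backbone_point <- function(unit) {
  missing <- setdiff(BACKBONE_ATOMS, names(unit$atom_coords))
  if (length(missing) > 0L) {
    stop(sprintf("residue %s %s/%s is missing backbone atom(s): %s",
                 unit$residue_name, unit$chain_id, unit$residue_index,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pts <- do.call(rbind, unit$atom_coords[BACKBONE_ATOMS])
  colMeans(pts)
}

#' Backbone trace of one strand
#'
#' Reduces a chain to the ordered series of backbone representative points
#' (5'->3', file order), recording residues that could not be reduced and gaps
#' in the author residue numbering.
#'
#' @param structure a `nuc_structure`.
#' @param chain_id chain identifier to extract.
#' @return `backbone_trace`: list with `chain_id`, `points` (n x 3 matrix,
#'   angstrom), `residue_indices`, `residue_names`, `bases`, `skipped`
#'   (residue indices flagged unusable) and `gaps` (residue numbering jumps).
#' @export
backbone_trace <- function(structure, chain_id) {
  ch <- structure$chains[[chain_id]]
  if (is.null(ch)) {
    stop("chain '", chain_id, "' not present; available: ",
         paste(names(structure$chains), collapse = ", "), call. = FALSE)
  }
  usable <- vapply(ch$units, function(u) u$usable, logical(1L))
  units <- ch$units[usable]
  skipped <- vapply(ch$units[!usable], function(u) u$residue_index, integer(1L))
  if (length(units) == 0L) {
    stop("chain '", chain_id, "' has no usable nucleotides", call. = FALSE)
  }
  pts <- t(vapply(units, backbone_point, numeric(3L)))
  idx <- vapply(units, function(u) u$residue_index, integer(1L))
  gaps <- which(diff(idx) != 1L)
  structure(
    list(
      chain_id = chain_id,
      points = pts,
      residue_indices = idx,
      residue_names = vapply(units, function(u) u$residue_name, character(1L)),
      bases = vapply(units, function(u) if (is.na(u$base)) NA_character_ else u$base,
                     character(1L)),
      skipped = skipped,
      gaps = gaps
    ),
    class = "backbone_trace"
  )
}

#' @export
print.backbone_trace <- function(x, ...) {
  cat(sprintf("backbone_trace: chain %s, %d points", x$chain_id, nrow(x$points)))
  if (length(x$skipped)) cat(",", length(x$skipped), "residue(s) skipped")
  if (length(x$gaps)) cat(",", length(x$gaps), "numbering gap(s)")
  cat("\n")
  invisible(x)
}

#' Pair two antiparallel strands positionally
#'
#' Position `i` of strand A is paired with position `n_b + 1 - i` of strand B
#' (index reversal: the strands are antiparallel). If the strands differ in
#' length the overhang is trimmed from the longer strand's 3' end. Watson-Crick
#' complementarity is checked per pair and recorded as a validation flag;
#' non-complementary pairs are flagged but kept.
#'
#' @param trace_a,trace_b `backbone_trace` objects for the two strands.
#' @return `duplex_pairing`: list with `trace_a`, `trace_b`, `pairs` (m x 2
#'   index matrix, strictly increasing in A, strictly decreasing in B) and
#'   `complementarity_ok` (logical per pair).
#' @export
pair_strands <- function(trace_a, trace_b) {
  na <- nrow(trace_a$points)
  nb <- nrow(trace_b$points)
  if (na == 0L || nb == 0L) stop("cannot pair an empty backbone trace", call. = FALSE)
  m <- min(na, nb)
  ia <- seq_len(m)
  ib <- nb + 1L - ia
  comp <- mapply(function(a, b) {
    ba <- trace_a$bases[a]
    bb <- trace_b$bases[b]
    !is.na(ba) && !is.na(bb) && identical(unname(WC_COMPLEMENT[ba]), bb)
  }, ia, ib)
  if (na != nb) {
    message(sprintf("strands differ in length (%d vs %d): trimmed to %d pairs", na, nb, m))
  }
  structure(
    list(
      trace_a = trace_a,
      trace_b = trace_b,
      pairs = cbind(a = ia, b = ib),
      complementarity_ok = as.logical(comp)
    ),
    class = "duplex_pairing"
  )
}

#' @export
print.duplex_pairing <- function(x, ...) {
  cat(sprintf("duplex_pairing: %d pairs (%s/%s), %d non-complementary\n",
              nrow(x$pairs), x$trace_a$chain_id, x$trace_b$chain_id,
              sum(!x$complementarity_ok)))
  invisible(x)
}

#' Write backbone points as TSV
#'
#' @param trace a `backbone_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_backbone_tsv <- function(trace, path) {
  df <- data.frame(
    chain = trace$chain_id,
    residue_index = trace$residue_indices,
    x_angstrom = num10(trace$points[, 1L]),
    y_angstrom = num10(trace$points[, 2L]),
    z_angstrom = num10(trace$points[, 3L]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
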