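#' Read atoms from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] returning the ATOM/HETATM records as
#' a tibble, one row per atom, with the fields needed for pocket-coordinate
#' extraction (record type, atom name, altloc, residue name/number, insertion
#' code, chain, coordinates in Angstrom).
#'
#' @param path Path to a PDB-format file.
#' @return A tibble with columns `type`, `atom`, `alt`, `resid`, `chain`,
#'   `position`, `insert`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  tibble::tibble(
    type = at$type,
    atom = at$elety,
    alt = at$alt,
    resid = at$resid,
    chain = at$chain,
    position = as.integer(at$resno),
    insert = at$insert,
    x = at$x, y = at$y, z = at$z
  )
}

#' Extract pocket residue coordinates from a structure
#'
#' Pulls one representative 3D coordinate per pocket position from a parsed
#' structure, in ascending position order. These coordinate sets are the input
#' to the structural-similarity channel ([superpose_rmsd()]).
#'
#' The representative atom is the alpha-carbon by default; `atom = "centroid"`
#' instead averages all heavy atoms of the residue. When a residue carries
#' alternate locations, the first altloc in file order is used. Residues with
#' insertion codes are rejected: the pocket position numbering assumes plain
#' beta-chain numbers.
#'
#' @param atoms A tibble from [read_structure()] (or any data frame with the
#'   same columns).
#' @param chain_id Chain identifier of the beta chain.
#' @param pocket Pocket index (1-9) or a one-row subset of
#'   [pocket_definitions()].
#' @param atom `"CA"` (default) or `"centroid"`.
#' @param source_id Label recorded on the result (e.g. a PDB ID).
#'
#' @return A `pocket_structure`: a tibble with columns `position`, `residue`,
#'   `x`, `y`, `z` and attributes `pocket` and `source_id`.
#' @export
extract_pocket_coordinates <- function(atoms, chain_id, pocket,
                                       atom = c("CA", "centroid"),
                                       source_id = "structure") {
  atom <- match.arg(atom)
  def <- resolve_pocket(pocket)
  pos <- sort(def$positions[[1]])

  atoms <- dplyr::filter(atoms, .data$type == "ATOM")
  if (!chain_id %in% atoms$chain) {
    abort(paste0("Chain '", chain_id, "' absent from structure."))
  }
  atoms <- dplyr::filter(atoms, .data$chain == chain_id)

  rows <- purrr::map(pos, function(p) {
    res <- dplyr::filter(atoms, .data$position == p)
    if (nrow(res) == 0) {
      abort(paste0("Residue ", p, " absent from chain '", chain_id, "'."))
    }
    ins <- unique(res$insert)
    ins <- ins[!is.na(ins) & ins != ""]
    if (length(ins) > 0) {
      abort(paste0("Residue ", p, " carries an insertion code ('",
                   ins[1], "'); pocket numbering assumes none."))
    }
    alts <- res$alt
    alts[is.na(alts)] <- ""
    if (any(alts != "")) {
      first_alt <- alts[alts != ""][1]  # first altloc by file order
      res <- res[alts == "" | alts == first_alt, , drop = FALSE]
    }
    if (atom == "CA") {
      ca <- dplyr::filter(res, .data$atom == "CA")
      if (nrow(ca) == 0) {
        abort(paste0("Residue ", p, " has no CA representative atom."))
      }
      coord <- c(ca$x[1], ca$y[1], ca$z[1])
    } else {
      heavy <- dplyr::filter(res, !stringr::str_detect(.data$atom, "^H"))
      if (nrow(heavy) == 0) {
        abort(paste0("Residue ", p, " has no heavy atoms for a centroid."))
      }
      coord <- c(mean(heavy$x), mean(heavy$y), mean(heavy$z))
    }
    if (!all(is.finite(coord))) {
      abort(paste0("Residue ", p, " has non-finite coordinates."))
    }
    tibble::tibble(
      position = p,
      residue = residue_letter(res$resid[1]),
      x = coord[1], y = coord[2], z = coord[3]
    )
  })
  out <- dplyr::bind_rows(rows)
  new_pocket_structure(out, pocket = def$pocket, source_id = source_id)
}

new_pocket_structure <- function(tbl, pocket, source_id) {
  structure(tbl,
    class = c("pocket_structure", class(tibble::as_tibble(tbl))),
    pocket = as.integer(pocket), source_id = source_id
  )
}

#' @export
print.pocket_structure <- function(x, ...) {
  cat("<pocket_structure> pocket ", attr(x, "pocket"),
      ", source ", attr(x, "source_id"), "\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

residue_letter <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% AA_ALPHABET] <- "X"
  out
}

# Coordinate matrix (n x 3) from a pocket_structure, matrix, or x/y/z frame.
coord_matrix <- function(s) {
  if (is.matrix(s)) {
    if (ncol(s) != 3) abort("Coordinate matrices must have 3 columns.")
    return(unname(s))
  }
  if (is.data.frame(s) && all(c("x", "y", "z") %in% names(s))) {
    return(unname(cbind(s$x, s$y, s$z)))
  }
  abort("Expected a pocket_structure, an n x 3 matrix, or a data frame with x/y/z.")
}

#' Write pocket coordinates as a minimal PDB file
#'
#' Emits one CA ATOM record per coordinate, using glycine as residue name.
#' Used by the synthetic-fixture generator and handy for visual inspection of
#' synthesized pocket geometries.
#'
#' @param coords An n x 3 coordinate matrix (Angstrom).
#' @param path Output file path.
#' @param chain_id Chain identifier (single character).
#' @param positions Residue numbers, one per coordinate row.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(coords, path, chain_id = "B",
                             positions = seq_len(nrow(coords))) {
  coords <- coord_matrix(coords)
  if (length(positions) != nrow(coords)) {
    abort("`positions` must match the number of coordinate rows.")
  }
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), chain_id, positions,
    coords[, 1], coords[, 2], coords[, 3]
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
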