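#' Read an NCBI-format substitution matrix
#'
#' Parses the standard whitespace-separated matrix text format (`#` comments,
#' a header row of letters, one labelled row per letter) and returns the
#' sub-matrix over the 20 canonical amino acids, symmetric, in the file's
#' letter order. Extended letters (B, Z, X, `*`, ...) are dropped.
#'
#' @param path Path to a matrix file. The default is the bundled BLOSUM62.
#' @return A 20 x 20 named numeric matrix.
#' @examples
#' m <- read_substitution_matrix()
#' m["N", "V"]
#' @export
read_substitution_matrix <- function(path = NULL) {
  path <- path %||% system.file("extdata", "BLOSUM62.txt", package = "drpocket")
  if (!file.exists(path)) abort(paste0("Matrix file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("Matrix file has no header/rows.")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[[`, character(1), 1)
  vals <- lapply(rows, function(r) as.numeric(r[-1]))
  if (any(lengths(vals) != length(header))) {
    abort("Matrix rows do not match the header length.")
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, header)
  keep_r <- rownames(m) %in% AA_ALPHABET
  keep_c <- colnames(m) %in% AA_ALPHABET
  m <- m[keep_r, keep_c, drop = FALSE]
  if (!identical(sort(rownames(m)), sort(AA_ALPHABET)) ||
      !identical(sort(colnames(m)), sort(AA_ALPHABET))) {
    abort("Matrix must cover all 20 canonical amino acids.")
  }
  m <- m[, rownames(m), drop = FALSE]  # align columns to row order
  if (!isTRUE(all.equal(m, t(m)))) abort("Substitution matrix must be symmetric.")
  m
}

#' Encode a pocket pseudosequence as a substitution-matrix vector
#'
#' Each residue of an n-letter pseudosequence is replaced by its full row of
#' the substitution matrix, giving a 20n-dimensional real vector. Two
#' pseudosequences encoded this way can be compared by Euclidean distance:
#' similar residues have similar substitution rows, so conservative
#' differences move the encoding less than radical ones.
#'
#' @param pseudoseq A pseudosequence string over the canonical amino acids.
#' @param matrix A 20 x 20 substitution matrix (see
#'   [read_substitution_matrix()]).
#' @return A numeric vector of length `20 * nchar(pseudoseq)`.
#' @examples
#' v <- encode_pseudosequence("NVGF")
#' length(v)
#' @export
encode_pseudosequence <- function(pseudoseq, matrix = read_substitution_matrix()) {
  if (!is.character(pseudoseq) || length(pseudoseq) != 1 || !nzchar(pseudoseq)) {
    abort("`pseudoseq` must be a single non-empty string.")
  }
  res <- strsplit(toupper(pseudoseq), "")[[1]]
  bad <- setdiff(res, rownames(matrix))
  if (length(bad) > 0) {
    abort(paste0("Cannot encode residue(s) ", paste(unique(bad), collapse = ", "),
                 ": not in the substitution alphabet."))
  }
  as.numeric(t(matrix[res, , drop = FALSE]))
}
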