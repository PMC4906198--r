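#' The nine-pocket model of the HLA-DR binding groove
#'
#' The peptide-binding groove of an HLA-DR molecule accommodates a 9-residue
#' core, each position sitting in a sub-cavity ("pocket") lined by a fixed set
#' of beta-chain residues. `pocket_definitions()` returns the canonical map
#' from pocket index to the beta-chain positions lining it, together with the
#' anchor flag: pockets 1, 4, 6, 7 and 9 are the anchors that dominate binding
#' specificity.
#'
#' Positions use the conventional beta-chain numbering of solved HLA-DR
#' structures; no renumbering is attempted.
#'
#' @param pockets Optional integer vector restricting the result to a subset
#'   of pocket indices (1-9).
#'
#' @return A tibble with columns `pocket` (integer), `positions`
#'   (list-column of strictly increasing integer vectors) and `is_anchor`
#'   (logical).
#' @examples
#' pocket_definitions()
#' pocket_definitions(c(4, 9))
#' @export
pocket_definitions <- function(pockets = 1:9) {
  pockets <- as.integer(pockets)
  if (length(pockets) == 0 || anyNA(pockets) || !all(pockets %in% 1:9)) {
    abort("`pockets` must be a non-empty subset of 1:9.")
  }
  defs <- tibble::tibble(
    pocket = 1:9,
    positions = list(
      c(82L, 85L, 86L, 89L),
      c(77L, 78L, 81L, 82L),
      78L,
      c(11L, 13L, 26L, 28L, 70L, 71L, 74L, 78L),
      c(11L, 13L, 28L, 70L, 71L, 74L),
      c(11L, 13L, 28L, 70L, 71L, 74L),
      c(11L, 28L, 30L, 47L, 61L, 67L, 70L, 71L),
      c(60L, 61L),
      c(9L, 30L, 37L, 57L, 60L, 61L)
    ),
    is_anchor = 1:9 %in% ANCHOR_POCKETS
  )
  defs[match(pockets, defs$pocket), ]
}

# Normalise a beta chain given as a named character vector (names = residue
# numbers) or a data frame with `position` and `residue` columns into a named
# vector of single upper-case letters.
as_chain <- function(chain) {
  if (is.data.frame(chain)) {
    if (!all(c("position", "residue") %in% names(chain))) {
      abort("A chain data frame needs `position` and `residue` columns.")
    }
    res <- setNames(as.character(chain$residue), as.character(chain$position))
  } else if (is.character(chain) && !is.null(names(chain))) {
    res <- chain
  } else {
    abort("`chain` must be a named character vector or a position/residue data frame.")
  }
  if (anyDuplicated(names(res))) {
    dup <- unique(names(res)[duplicated(names(res))])
    abort(paste0("Duplicated chain positions: ", paste(dup, collapse = ", "), "."))
  }
  toupper(res)
}

#' Extract a pocket pseudosequence from a beta chain
#'
#' Reads the residues at the beta-chain positions lining one pocket, in
#' ascending position order, and concatenates them into the pocket
#' pseudosequence. Alleles sharing a pocket pseudosequence share that pocket's
#' binding profile, which is what makes pan-specific profile synthesis
#' possible.
#'
#' @param chain A residue-numbered beta chain: either a named character vector
#'   (names are residue numbers, values one-letter residues) or a data frame
#'   with `position` and `residue` columns.
#' @param pocket A pocket index (1-9) or a one-row subset of
#'   [pocket_definitions()] (so custom position sets can be used).
#'
#' @return A single string over the amino-acid alphabet, one letter per pocket
#'   position. Nonstandard residues are passed through as given (typically
#'   `"X"`); they are rejected later at encoding time.
#' @examples
#' chain <- c(`82` = "N", `85` = "V", `86` = "G", `89` = "F")
#' extract_pseudosequence(chain, 1)
#' @export
extract_pseudosequence <- function(chain, pocket) {
  def <- resolve_pocket(pocket)
  chain <- as_chain(chain)
  pos <- sort(def$positions[[1]])
  missing <- pos[!as.character(pos) %in% names(chain)]
  if (length(missing) > 0) {
    abort(paste0(
      "Position", if (length(missing) > 1) "s" else "", " ",
      paste(missing, collapse = ", "), " absent from chain (pocket ",
      def$pocket, ")."
    ))
  }
  paste(chain[as.character(pos)], collapse = "")
}

resolve_pocket <- function(pocket) {
  if (is.data.frame(pocket)) {
    if (nrow(pocket) != 1 || !all(c("pocket", "positions") %in% names(pocket))) {
      abort("`pocket` data frame must be one row with `pocket` and `positions` columns.")
    }
    pos <- as.integer(pocket$positions[[1]])
    if (length(pos) == 0 || is.unsorted(pos, strictly = TRUE)) {
      abort("Pocket positions must be non-empty and strictly increasing.")
    }
    return(pocket)
  }
  pocket_definitions(pocket)
}

#' Extract pseudosequences for several pockets at once
#'
#' @inheritParams extract_pseudosequence
#' @param pockets Integer vector of pocket indices.
#' @return A tibble with columns `pocket` and `pseudoseq`.
#' @examples
#' chain <- setNames(rep("A", 99), 1:99)
#' extract_pseudosequences(chain, c(4, 6, 7, 9))
#' @export
extract_pseudosequences <- function(chain, pockets = SYNTH_POCKETS) {
  defs <- pocket_definitions(pockets)
  tibble::tibble(
    pocket = defs$pocket,
    pseudoseq = purrr::map_chr(
      seq_len(nrow(defs)),
      function(i) extract_pseudosequence(chain, defs[i, ])
    )
  )
}
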