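#' Kyte-Doolittle hydropathy scale
#'
#' The 1982 Kyte-Doolittle hydropathy index for the 20 standard amino acids.
#' Positive values are hydrophobic (isoleucine, 4.5, is the most hydrophobic),
#' negative values hydrophilic (arginine, -4.5, the most hydrophilic). The
#' grand average of hydropathy (GRAVY) of a peptide is the arithmetic mean of
#' these per-residue values, so a negative GRAVY marks a hydrophilic peptide.
#'
#' @return A named numeric vector of length 20 (one-letter residue codes).
#' @seealso [gravy()], [read_hydropathy_scale()]
#' @export
#' @examples
#' kyte_doolittle()[["I"]] # 4.5
kyte_doolittle <- function() {
  c(
    I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
  )
}

#' Read a hydropathy scale from a two-column TSV
#'
#' The file must have a header line `residue<TAB>value` and exactly one row
#' per standard amino acid. Use this to swap in an alternative hydropathy
#' index for [gravy()].
#'
#' @param path Path to a tab-separated file with columns `residue`, `value`.
#' @return A named numeric vector of length 20, validated like
#'   [kyte_doolittle()].
#' @export
read_hydropathy_scale <- function(path) {
  if (!file.exists(path)) {
    abort_peptiter(sprintf("Hydropathy scale file not found: %s", path),
                   "peptiter_io_error")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab))) {
    abort_peptiter("Hydropathy scale file needs columns `residue` and `value`.",
                   "peptiter_format_error")
  }
  scale <- stats::setNames(as.numeric(tab$value), toupper(tab$residue))
  validate_scale(scale)
  scale
}

validate_scale <- function(scale) {
  if (!setequal(names(scale), AA_STANDARD) || length(scale) != 20L) {
    abort_peptiter(
      "A hydropathy scale must cover exactly the 20 standard residues.",
      "peptiter_validation_error"
    )
  }
  if (!all(is.finite(scale))) {
    abort_peptiter("Hydropathy values must all be finite.",
                   "peptiter_validation_error")
  }
  invisible(scale)
}
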