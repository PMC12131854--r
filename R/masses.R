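# Monoisotopic residue masses for the 20 canonical amino acids (Da),
# plus the physical constants used throughout the m/z arithmetic.
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS  <- 18.010565

.residue_masses <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(AA_MONO))
  if (length(bad) > 0L) {
    stop("non-canonical residue(s) in '", sequence, "': ",
         paste(unique(bad), collapse = ", "))
  }
  unname(AA_MONO[aa])
}

#' Monoisotopic precursor m/z of a peptide
#'
#' Computes (sum of residue monoisotopic masses + H2O + charge protons) /
#' charge, the standard m/z of a protonated peptide.
#'
#' @param sequence Peptide sequence using the 20 canonical one-letter codes.
#' @param charge Positive integer charge state.
#' @return Numeric m/z in Thomson.
#' @examples
#' peptide_mz("IDPNAWVER", 2)
#' @export
peptide_mz <- function(sequence, charge = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L, charge >= 1L)
  (sum(.residue_masses(sequence)) + WATER_MASS + charge * PROTON_MASS) / charge
}

#' Monoisotopic fragment-ion m/z
#'
#' m/z of a backbone fragment of a peptide: b ions are N-terminal prefixes
#' (residue sum + protons), y ions are C-terminal suffixes (residue sum +
#' H2O + protons).
#'
#' @param sequence Peptide sequence.
#' @param ion_type `"y"` or `"b"`.
#' @param index Fragment index, `1 <= index < nchar(sequence)`.
#' @param charge Positive integer product charge.
#' @return Numeric m/z in Thomson.
#' @examples
#' fragment_mz("IDPNAWVER", "y", 4, 1)
#' @export
fragment_mz <- function(sequence, ion_type = c("y", "b"), index, charge = 1L) {
  ion_type <- match.arg(ion_type)
  n <- nchar(sequence)
  if (index < 1L || index >= n) {
    stop("fragment index must satisfy 1 <= index < peptide length")
  }
  stopifnot(charge >= 1L)
  masses <- .residue_masses(sequence)
  if (ion_type == "b") {
    (sum(masses[seq_len(index)]) + charge * PROTON_MASS) / charge
  } else {
    (sum(masses[seq.int(n - index + 1L, n)]) + WATER_MASS +
       charge * PROTON_MASS) / charge
  }
}
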