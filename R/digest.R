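# In-silico tryptic digestion and peptide eligibility filtering.

#' Tryptic digestion of protein sequences
#'
#' Cleaves each protein C-terminal to K or R with zero missed cleavages.
#' By the common trypsin convention, cleavage is suppressed when the residue
#' following K/R is proline (configurable via `proline_rule`). Sequences
#' containing non-canonical residues yield peptides flagged ineligible
#' rather than an error, so one odd database entry cannot abort a digest.
#'
#' @param sequences Named character vector of protein sequences (names are
#'   protein identifiers), or a `Biostrings::AAStringSet`.
#' @param proline_rule Suppress cleavage after K/R when followed by P
#'   (default `TRUE`).
#' @return A data.frame with columns `protein`, `peptide`, `start`
#'   (0-based offset in the parent), and `eligible_residues` (FALSE when the
#'   peptide contains a non-canonical residue).
#' @examples
#' digest(c(prot1 = "AAAKGGGR"))
#' @export
digest <- function(sequences, proline_rule = TRUE) {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all protein sequences must be named")
  }
  if (any(nchar(sequences) == 0L)) stop("empty protein sequence")

  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    seq_i <- sequences[[i]]
    aa <- strsplit(seq_i, "", fixed = TRUE)[[1L]]
    n <- length(aa)
    cut_after <- aa %in% c("K", "R")
    if (proline_rule && n > 1L) {
      followed_by_p <- c(aa[-1L] == "P", FALSE)
      cut_after <- cut_after & !followed_by_p
    }
    cut_after[n] <- FALSE             # C-terminus ends the last peptide anyway
    ends <- c(which(cut_after), n)
    starts <- c(1L, ends[-length(ends)] + 1L)
    peps <- substring(seq_i, starts, ends)
    out[[i]] <- data.frame(
      protein = names(sequences)[i],
      peptide = peps,
      start = starts - 1L,
      eligible_residues = vapply(
        peps,
        function(p) all(strsplit(p, "", fixed = TRUE)[[1L]] %in% names(AA_MONO)),
        logical(1L), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Filter tryptic peptides for MRM suitability
#'
#' Retains peptides of length 6 to 30 residues containing neither cysteine
#' nor methionine (to avoid alkylation/oxidation variability), mapping to
#' exactly one protein in the supplied digest. Proteins left with fewer than
#' `min_peptides` surviving peptides are dropped entirely; the reasons are
#' returned for audit.
#'
#' @param peptides Digest data.frame from [digest()] over the whole database
#'   (uniqueness is database-relative).
#' @param min_length,max_length Allowed peptide length range.
#' @param min_peptides Minimum surviving peptides per retained protein.
#' @return A list with `peptides` (surviving rows), `dropped_proteins`
#'   (data.frame protein/reason), and `rejected` (peptide-level reasons).
#' @export
filter_peptides <- function(peptides, min_length = 6L, max_length = 30L,
                            min_peptides = 2L) {
  if (nrow(peptides) == 0L) stop("empty database digest")
  pep <- peptides
  len <- nchar(pep$peptide)
  has_cm <- grepl("[CM]", pep$peptide)
  # database-relative uniqueness: peptide sequence seen under > 1 protein
  parents <- tapply(pep$protein, pep$peptide,
                    function(x) length(unique(x)))
  shared <- names(parents)[parents > 1L]

  reason <- rep(NA_character_, nrow(pep))
  reason[!pep$eligible_residues] <- "non-canonical residue"
  reason[is.na(reason) & (len < min_length | len > max_length)] <- "length"
  reason[is.na(reason) & has_cm] <- "contains C or M"
  reason[is.na(reason) & pep$peptide %in% shared] <- "not unique"

  keep <- is.na(reason)
  surviving <- pep[keep, , drop = FALSE]
  rejected <- data.frame(protein = pep$protein[!keep],
                         peptide = pep$peptide[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)

  counts <- table(surviving$protein)
  too_few <- names(counts)[counts < min_peptides]
  no_pep <- setdiff(unique(pep$protein), surviving$protein)
  dropped <- data.frame(
    protein = c(no_pep, too_few),
    reason = c(rep("no eligible peptides", length(no_pep)),
               rep(sprintf("fewer than %d unique peptides", min_peptides),
                   length(too_few))),
    stringsAsFactors = FALSE
  )
  surviving <- surviving[!(surviving$protein %in% too_few), , drop = FALSE]
  rownames(surviving) <- NULL
  list(peptides = surviving, dropped_proteins = dropped, rejected = rejected)
}
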