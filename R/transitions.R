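# MRM transition selection and the end-to-end design pipeline.

#' Select MRM transitions for one peptide
#'
#' Candidate products are singly charged y and b ions of the peptide at a
#' doubly charged precursor (by default). Only products whose m/z exceeds the
#' precursor m/z are eligible — products below the precursor window can be
#' contaminated by co-isolated ions. Among eligible candidates exactly
#' `n_transitions` are kept, ranked by fragment index descending (longer
#' fragments carry more sequence evidence) with y before b at equal index.
#' Peptides with fewer than `n_transitions` eligible products return an empty
#' set, signalling the peptide should be dropped.
#'
#' @param sequence Peptide sequence.
#' @param protein Protein identifier carried into the records.
#' @param precursor_charge Precursor charge state (default 2).
#' @param product_charge Product charge state (default 1).
#' @param n_transitions Number of transitions to design per peptide.
#' @return A data.frame of transition records (possibly 0 rows) with columns
#'   `protein`, `peptide`, `precursor_charge`, `precursor_mz`, `ion`,
#'   `fragment_index`, `product_charge`, `product_mz`.
#' @export
select_transitions <- function(sequence, protein = NA_character_,
                               precursor_charge = 2L, product_charge = 1L,
                               n_transitions = 3L) {
  n <- nchar(sequence)
  prec <- peptide_mz(sequence, precursor_charge)
  idx <- seq_len(n - 1L)
  cand <- data.frame(
    ion = rep(c("y", "b"), each = n - 1L),
    fragment_index = c(idx, idx),
    stringsAsFactors = FALSE
  )
  cand$product_mz <- mapply(function(ion, i)
    fragment_mz(sequence, ion, i, product_charge),
    cand$ion, cand$fragment_index)
  cand <- cand[cand$product_mz > prec, , drop = FALSE]
  if (nrow(cand) < n_transitions) {
    return(.transition_frame()[0L, ])
  }
  # rank: longer fragments first; y before b on ties
  ord <- order(-cand$fragment_index, match(cand$ion, c("y", "b")))
  cand <- cand[ord[seq_len(n_transitions)], , drop = FALSE]
  data.frame(
    protein = protein,
    peptide = sequence,
    precursor_charge = as.integer(precursor_charge),
    precursor_mz = prec,
    ion = cand$ion,
    fragment_index = as.integer(cand$fragment_index),
    product_charge = as.integer(product_charge),
    product_mz = cand$product_mz,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

.transition_frame <- function() {
  data.frame(protein = character(), peptide = character(),
             precursor_charge = integer(), precursor_mz = numeric(),
             ion = character(), fragment_index = integer(),
             product_charge = integer(), product_mz = numeric(),
             stringsAsFactors = FALSE)
}

#' Design an MRM transition list from a protein database
#'
#' Runs the full design pipeline: tryptic digestion with no missed cleavages,
#' peptide eligibility filtering (length 6-30, no C/M, database-unique,
#' at least two peptides per protein), and per-peptide transition selection.
#' Proteins whose peptide count falls below two after transition selection
#' are dropped, so every retained protein is represented by at least two
#' peptides with exactly `n_transitions` transitions each.
#'
#' @param fasta Path to a FASTA file, or a named character vector of protein
#'   sequences. FASTA headers are truncated at the first whitespace to give
#'   the protein identifier.
#' @param precursor_charge,product_charge,n_transitions Passed to
#'   [select_transitions()].
#' @param proline_rule Passed to [digest()].
#' @return Object of class `transition_design`: a list with `transitions`
#'   (the transition records), `peptides` (retained peptides), and `log`
#'   (drop reasons at each stage).
#' @export
design_transitions <- function(fasta, precursor_charge = 2L,
                               product_charge = 1L, n_transitions = 3L,
                               proline_rule = TRUE) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1L), 1L)
    sequences <- stats::setNames(as.character(aa), names(aa))
  } else {
    sequences <- fasta
  }
  dig <- digest(sequences, proline_rule = proline_rule)
  filt <- filter_peptides(dig)
  peps <- filt$peptides
  trans <- .transition_frame()
  dropped_peps <- data.frame(protein = character(), peptide = character(),
                             reason = character(), stringsAsFactors = FALSE)
  if (nrow(peps) > 0L) {
    per_pep <- lapply(seq_len(nrow(peps)), function(i)
      select_transitions(peps$peptide[i], peps$protein[i],
                         precursor_charge, product_charge, n_transitions))
    ok <- vapply(per_pep, nrow, integer(1L)) > 0L
    dropped_peps <- data.frame(
      protein = peps$protein[!ok], peptide = peps$peptide[!ok],
      reason = rep(sprintf("fewer than %d products above precursor m/z",
                           n_transitions), sum(!ok)),
      stringsAsFactors = FALSE)
    trans <- do.call(rbind, c(per_pep[ok], list(.transition_frame())))
    peps <- peps[ok, , drop = FALSE]
  }
  # re-impose the >= 2 peptides per protein rule after transition selection
  counts <- table(unique(trans[c("protein", "peptide")])$protein)
  lost <- names(counts)[counts < 2L]
  if (length(lost) > 0L) {
    dropped_peps <- rbind(dropped_peps, data.frame(
      protein = peps$protein[peps$protein %in% lost],
      peptide = peps$peptide[peps$protein %in% lost],
      reason = "protein below 2 designable peptides",
      stringsAsFactors = FALSE))
    trans <- trans[!(trans$protein %in% lost), , drop = FALSE]
    peps <- peps[!(peps$protein %in% lost), , drop = FALSE]
  }
  rownames(trans) <- NULL
  rownames(peps) <- NULL
  structure(list(transitions = trans, peptides = peps,
                 log = list(dropped_proteins = filt$dropped_proteins,
                            rejected_peptides = filt$rejected,
                            dropped_after_selection = dropped_peps)),
            class = "transition_design")
}

#' @export
print.transition_design <- function(x, ...) {
  cat("MRM transition design\n")
  cat("  proteins retained:", length(unique(x$transitions$protein)), "\n")
  cat("  peptides retained:", nrow(x$peptides), "\n")
  cat("  transitions designed:", nrow(x$transitions), "\n")
  cat("  proteins dropped in filtering:", nrow(x$log$dropped_proteins), "\n")
  invisible(x)
}

#' Write / read a transition list
#'
#' Plain comma-separated layout compatible with a dynamic-MRM import sheet;
#' round-trips losslessly through [read_transition_list()].
#'
#' @param records Transition data.frame (as in `design_transitions()$transitions`).
#' @param path Output file path.
#' @export
write_transition_list <- function(records, path) {
  cols <- c("protein", "peptide", "precursor_mz", "precursor_charge",
            "ion", "fragment_index", "product_mz", "product_charge")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_list
#' @export
read_transition_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(protein = "character",
                                       peptide = "character",
                                       ion = "character"))
  df$precursor_charge <- as.integer(df$precursor_charge)
  df$fragment_index <- as.integer(df$fragment_index)
  df$product_charge <- as.integer(df$product_charge)
  df
}
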