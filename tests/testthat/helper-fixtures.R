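# Shared fixtures: tiny protein databases, designs and truths built in code.

# random tryptic-looking protein: blocks of canonical residues ending in K/R
random_protein <- function(n_peptides = 4L, len_range = c(6L, 14L)) {
  res <- setdiff(c("G", "A", "S", "P", "V", "T", "L", "I", "N", "D",
                   "Q", "E", "H", "F", "Y", "W"), "P")  # no P after K/R risk
  paste(vapply(seq_len(n_peptides), function(i) {
    len <- sample(seq(len_range[1L], len_range[2L]), 1L)
    paste0(paste(sample(res, len - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1L)), collapse = "")
}

random_database <- function(n_proteins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setNames(vapply(seq_len(n_proteins), function(i)
    random_protein(sample(3:6, 1L)), character(1L)),
    sprintf("PROT%03d", seq_len(n_proteins)))
}

write_tmp_fasta <- function(sequences, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(sequences), function(nm)
    c(paste0(">", nm, " synthetic test protein"), sequences[[nm]]))), path)
  path
}

# a compact transition list over two synthetic proteins (2 peptides each)
small_transition_list <- function() {
  peps <- list(
    TGT1 = c("LNDGLTAFESK", "GVDLNSFIEQR"),
    TGT2 = c("AEDLNSVGWTK", "FNELDQSGVYR")
  )
  do.call(rbind, lapply(names(peps), function(pr)
    do.call(rbind, lapply(peps[[pr]], select_transitions, protein = pr))))
}

default_truth <- function(effects1 = numeric(), effects2 = numeric(), ...) {
  ground_truth(marker_effects = list(PDR_vs_NPDR = effects1,
                                     NVG_vs_PDR = effects2), ...)
}
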