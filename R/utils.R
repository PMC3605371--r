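# Internal helpers shared across modules.
#
# Coordinate convention used throughout the package: residue indices and MSA
# columns are 0-based; intervals are half-open [start, end).  This keeps the
# reading-frame arithmetic uniform (residue_index = floor(coding_offset / 3),
# phase = coding_offset %% 3) and is stated once here and in the docs.

gs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gs_error")))
}

input_error <- function(msg) gs_error(msg, "gs_input_error")
alignment_error <- function(msg) gs_error(msg, "gs_alignment_error")
logic_error <- function(msg) gs_error(msg, "gs_logic_error")

#' @noRd
split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Degap a sequence string
#' @noRd
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Strip one trailing stop symbol '*' if present
#' @noRd
strip_stop <- function(x) sub("\\*$", "", x)

# Standard genetic code, indexed by codon.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate a coding nucleotide string (standard code, '*' for stops,
#' 'X' for ambiguous/partial codons).
#' @noRd
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  n_cod <- n %/% 3L
  if (n_cod == 0L) return("")
  codons <- substring(nt, seq(1L, by = 3L, length.out = n_cod),
                      seq(3L, by = 3L, length.out = n_cod))
  tab <- codon_table()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# One codon per amino acid, used when reverse-translating synthetic proteins.
aa_to_codon <- function() {
  tab <- codon_table()
  # first codon per amino acid, in fixed codon-table order -> deterministic
  split_cod <- split(names(tab), tab)
  vapply(split_cod, `[`, character(1L), 1L)
}

# bio3d one/three letter conversions for writing toy PDB files
aa_one_to_three <- function(aa) {
  three <- bio3d::aa123(aa)
  three[is.na(three) | three == "XXX"] <- "UNK"
  three
}

fmt_num <- function(x) formatC(x, format = "f", digits = 2)
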