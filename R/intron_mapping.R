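# Converting introns to (coding-nucleotide offset, phase) and anchoring them
# onto MSA columns of their gene's aligned row.
#
# All residue indices and MSA columns are 0-based (see utils.R).  A phase-1 or
# phase-2 intron interrupts the codon of residue floor(coding_offset / 3) and
# is anchored to that residue's column, with the phase kept separately, so
# that "same position" comparisons are exact (column, phase) comparisons and
# split codons need no fractional coordinates.

#' Extract intron records from a gene structure
#'
#' Walks the segments 5'->3', counting coding nucleotides (exon, seqshift and
#' nominal assembly-gap lengths all count, so downstream phases stay
#' consistent with the gene's translation).  Each intron becomes one record
#' with `coding_offset` (coding nt strictly 5' of the intron) and
#' `phase = coding_offset %% 3`.  Introns downstream of an assembly gap of
#' unknown sequence are flagged `reliable = FALSE` and later excluded from
#' clustering.
#'
#' @param gene A [gene_structure()].
#' @return `data.frame` with columns `gene`, `coding_offset`, `phase`,
#'   `nt_len`, `nt_seq`, `reliable`, in 5'->3' order.
#' @export
extract_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_structure"))
  segs <- gene$segments
  coding <- 0L
  unreliable <- FALSE
  out <- vector("list", sum(segs$kind == "intron"))
  k <- 0L
  for (i in seq_len(nrow(segs))) {
    kind <- segs$kind[i]
    if (kind == "intron") {
      k <- k + 1L
      out[[k]] <- data.frame(
        gene = gene$name, coding_offset = coding,
        phase = coding %% 3L, nt_len = segs$nt_len[i],
        nt_seq = segs$nt_seq[i], reliable = !unreliable,
        stringsAsFactors = FALSE)
    } else {
      coding <- coding + segs$nt_len[i]
      if (kind == "gap") unreliable <- TRUE
    }
  }
  res <- if (k > 0L) do.call(rbind, out) else
    data.frame(gene = character(), coding_offset = integer(),
               phase = integer(), nt_len = integer(), nt_seq = character(),
               reliable = logical(), stringsAsFactors = FALSE)
  max_off <- 3L * nchar(gene$protein_seq) + 3L
  if (nrow(res) && any(res$coding_offset > max_off))
    logic_error(sprintf(
      "gene '%s': intron coding offset beyond the coding region", gene$name))
  res
}

#' Map an ungapped residue index to its MSA column
#'
#' Returns the 0-based alignment column of the `residue_index`-th (0-based)
#' non-gap character of the row.  `residue_index` equal to the ungapped length
#' addresses the virtual terminal column (the aligned width), used for introns
#' after the final codon.
#'
#' @param row Aligned sequence string (gaps as `-`).
#' @param residue_index 0-based residue index, `0 <= i <= ungapped length`.
#' @return 0-based MSA column (integer).
#' @export
ungapped_to_column <- function(row, residue_index) {
  chars <- split_chars(row)
  pos <- which(chars != "-")
  n <- length(pos)
  if (residue_index < 0L || residue_index > n)
    logic_error(sprintf("residue index %d out of range [0, %d]",
                        residue_index, n))
  if (residue_index == n) return(nchar(row))
  pos[residue_index + 1L] - 1L
}

#' Map all introns of a gene family onto MSA columns
#'
#' Each intron of each validated gene becomes exactly one mapped record with
#' `residue_index = floor(coding_offset / 3)` and the MSA column where that
#' residue sits in the gene's gapped row.  An optional half-open column
#' interval `range = c(start, end)` drops introns anchored outside it;
#' coordinates of kept introns remain absolute.
#'
#' @param genes Named list of `gene_structure` objects (as returned in
#'   `validate_inputs()$genes`).
#' @param msa A `gs_msa` containing a row for every gene.
#' @param range Optional integer vector `c(start, end)`, 0-based half-open
#'   column interval.
#' @return `data.frame` with the [extract_introns()] columns plus
#'   `residue_index` and `msa_column`.
#' @export
map_introns <- function(genes, msa, range = NULL) {
  stopifnot(inherits(msa, "gs_msa"))
  if (!is.null(range)) {
    range <- as.integer(range)
    stopifnot(length(range) == 2L, range[1L] <= range[2L])
  }
  rows <- lapply(genes, function(g) {
    ir <- extract_introns(g)
    if (!nrow(ir)) {
      ir$residue_index <- integer()
      ir$msa_column <- integer()
      return(ir)
    }
    row <- unclass(msa)[[g$name]]
    ir$residue_index <- ir$coding_offset %/% 3L
    n_res <- nchar(g$protein_seq)
    ir$residue_index <- pmin(ir$residue_index, n_res)  # introns inside the stop codon
    ir$msa_column <- vapply(ir$residue_index, function(r)
      as.integer(ungapped_to_column(row, r)), integer(1L))
    ir
  })
  mapped <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(mapped)) mapped <- rows[[1L]]
  if (!is.null(range) && nrow(mapped))
    mapped <- mapped[mapped$msa_column >= range[1L] &
                       mapped$msa_column < range[2L], , drop = FALSE]
  rownames(mapped) <- NULL
  mapped
}
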