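# Plain-text views of the gene-structure alignment: the cluster-level text
# dialects (bars/spaces/phase digits), the interleaved MSA annotation, and
# the binary presence/absence FASTA matrix.

TEXT_DIALECTS <- c("bars_and_dashes", "bars_only", "phase_digits")

#' Render the cluster-level text alignment
#'
#' One output column per intron cluster; a gene shows `|` (or the phase digit
#' in the `phase_digits` dialect) in a cluster column iff it carries that
#' intron, and the spacer character otherwise (`-` for exonic sequence, or a
#' space in `bars_only`, where only introns are pictured).  Between
#' consecutive cluster columns a spacer run is inserted; its length is
#' `max(1, round(spacer_k * column distance))`, so the default `spacer_k = 0`
#' gives the compact one-spacer form while `spacer_k > 0` gives runs
#' proportional to the MSA-column distances.  Exons and introns are
#' represented independent of their physical lengths.
#'
#' @param clusters An `intron_clusters` object.
#' @param genes Ordered character vector of gene names.
#' @param dialect One of `"bars_and_dashes"` (default), `"bars_only"`,
#'   `"phase_digits"`.
#' @param spacer_k Spacer proportionality constant (default 0 = compact).
#' @return Object of class `text_alignment`: list with `rows` (named
#'   character vector, equal lengths), `dialect` and `column_map`
#'   (`data.frame(out_col, kind, cluster_id)`, `out_col` 0-based).
#' @export
render_intron_alignment <- function(clusters, genes,
                                    dialect = c("bars_and_dashes",
                                                "bars_only", "phase_digits"),
                                    spacer_k = 0) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(clusters, "intron_clusters"), spacer_k >= 0)
  cl <- clusters$clusters
  mem <- clusters$members
  spacer <- if (dialect == "bars_only") " " else "-"
  # layout: cluster columns separated by spacer runs
  kinds <- character(0); cids <- integer(0)
  n <- nrow(cl)
  for (j in seq_len(n)) {
    if (j > 1L) {
      run <- max(1L, as.integer(round(
        spacer_k * (cl$msa_column[j] - cl$msa_column[j - 1L]))))
      kinds <- c(kinds, rep("spacer", run))
      cids <- c(cids, rep(NA_integer_, run))
    }
    kinds <- c(kinds, "cluster")
    cids <- c(cids, cl$cluster_id[j])
  }
  column_map <- data.frame(out_col = seq_along(kinds) - 1L, kind = kinds,
                           cluster_id = cids, stringsAsFactors = FALSE)
  rows <- vapply(genes, function(g) {
    chars <- rep(spacer, length(kinds))
    idx <- which(kinds == "cluster")
    for (j in seq_len(n)) {
      if (any(mem$gene == g & mem$cluster_id == cl$cluster_id[j])) {
        chars[idx[j]] <- if (dialect == "phase_digits")
          as.character(cl$phase[j]) else "|"
      }
    }
    paste(chars, collapse = "")
  }, character(1L))
  structure(list(rows = rows, dialect = dialect, column_map = column_map),
            class = "text_alignment")
}

#' @export
print.text_alignment <- function(x, ...) {
  w <- max(nchar(names(x$rows)), 0L)
  for (g in names(x$rows))
    cat(formatC(g, width = w, flag = "-"), " ", x$rows[[g]], "\n", sep = "")
  invisible(x)
}

#' Serialise a text alignment to a file
#' @param x A `text_alignment`.
#' @param path Output file.
#' @export
write_text_alignment <- function(x, path) {
  w <- max(nchar(names(x$rows)), 0L)
  lines <- paste0(formatC(names(x$rows), width = w, flag = "-"), "  ", x$rows)
  writeLines(lines, path)
  invisible(path)
}

#' Interleave intron annotations with the protein MSA
#'
#' For every MSA row an annotation line of exactly the aligned width is
#' produced, carrying `|` (or the intron's phase digit) at the MSA column of
#' each of that gene's introns and spaces elsewhere.  Introns anchored at the
#' virtual terminal column (after the last codon) are drawn at the last real
#' column and listed in a trailing comment.  Serialisation wraps sequence and
#' annotation lines together at `wrap` characters so vertical correspondence
#' survives wrapping; the annotation line sits directly above its sequence.
#'
#' @param msa A `gs_msa`.
#' @param mapped `data.frame` from [map_introns()].
#' @param use_phase_digits Annotate with phase digits instead of bars.
#' @param wrap Line-wrap width for serialisation (default 80).
#' @param position Place the annotation line `"above"` (default) or
#'   `"below"` its sequence line.
#' @return Object of class `msa_annotation`: list with `annotations` (named
#'   character vector, full aligned width), `lines` (wrapped text lines) and
#'   `terminal_notes`.
#' @export
render_msa_interleaved <- function(msa, mapped, use_phase_digits = FALSE,
                                   wrap = 80L,
                                   position = c("above", "below")) {
  position <- match.arg(position)
  stopifnot(inherits(msa, "gs_msa"))
  width <- msa_width(msa)
  notes <- character()
  annotations <- vapply(names(msa), function(g) {
    chars <- rep(" ", width)
    sub <- mapped[mapped$gene == g, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      col <- sub$msa_column[i]
      mark <- if (use_phase_digits) as.character(sub$phase[i]) else "|"
      if (col >= width) {
        col <- width - 1L
        notes <<- c(notes, sprintf(
          "gene '%s': intron after the final codon drawn at the last column", g))
      }
      chars[col + 1L] <- mark
    }
    paste(chars, collapse = "")
  }, character(1L))
  name_w <- max(nchar(names(msa)))
  lines <- character()
  starts <- seq(1L, max(width, 1L), by = wrap)
  for (s in starts) {
    e <- min(s + wrap - 1L, width)
    for (g in names(msa)) {
      ann_line <- paste0(strrep(" ", name_w), "  ",
                         substr(annotations[[g]], s, e))
      seq_line <- paste0(formatC(g, width = name_w, flag = "-"), "  ",
                         substr(unclass(msa)[[g]], s, e))
      lines <- c(lines, if (position == "above") c(ann_line, seq_line) else
        c(seq_line, ann_line))
    }
    lines <- c(lines, "")
  }
  if (length(notes)) lines <- c(lines, paste("#", unique(notes)))
  structure(list(annotations = annotations, lines = lines,
                 terminal_notes = unique(notes)),
            class = "msa_annotation")
}

#' @export
print.msa_annotation <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' Write the binary common-intron matrix as FASTA
#'
#' Presence of a common intron is denoted `1`, absence `0`; one record per
#' gene, in the given gene order.  The result is itself a valid gapless
#' alignment and can be fed to phylogeny programs.
#'
#' @param matrix Named character vector from [binary_matrix()].
#' @param path Optional output file.
#' @return The FASTA text, invisibly when `path` is given.
#' @export
write_phylo_fasta <- function(matrix, path = NULL) {
  txt <- paste0(">", names(matrix), "\n", matrix, "\n", collapse = "")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}
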