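# Reading and writing the external formats: FASTA MSA, Scipio-style YAML gene
# structures, and PDB chains; plus the name-correspondence validation that
# pairs every gene structure with its MSA row.

#' Read a protein multiple sequence alignment from FASTA
#'
#' Reads an aligned protein FASTA file.  Gap characters `.` are normalised to
#' `-`; residues are upper-cased.  All rows must have identical aligned length
#' and unique names (the name is the first whitespace-delimited token of the
#' FASTA header).
#'
#' @param path Path to a FASTA file.
#' @return An object of class `gs_msa`: a named character vector of aligned
#'   rows, all of equal width.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) input_error(sprintf("MSA file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) input_error(sprintf(
                    "cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) input_error(sprintf("empty FASTA file: %s", path))
  rows <- toupper(as.character(set))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  names(rows) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1L), 1L)
  as_gs_msa(rows)
}

#' Construct/validate an MSA object
#'
#' @param rows Named character vector of aligned rows.
#' @return `gs_msa` object.
#' @export
as_gs_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    input_error("all MSA rows must be named")
  if (anyDuplicated(names(rows)))
    input_error(sprintf("duplicate sequence names in MSA: %s",
                        paste(unique(names(rows)[duplicated(names(rows))]),
                              collapse = ", ")))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L)
    alignment_error(sprintf(
      "aligned sequences differ in length (%s) - not a valid alignment",
      paste(sort(unique(widths)), collapse = " vs ")))
  structure(rows, class = "gs_msa")
}

#' @export
print.gs_msa <- function(x, ...) {
  cat(sprintf("Protein MSA: %d sequences, %d columns\n",
              length(x), msa_width(x)))
  shown <- utils::head(seq_along(x), 6L)
  for (i in shown) {
    row <- unclass(x)[i]
    cat(sprintf("  %-15s %s%s\n", names(row),
                substr(row, 1L, 50L), if (nchar(row) > 50L) "..." else ""))
  }
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' Aligned width of an MSA
#' @param msa A `gs_msa` object.
#' @export
msa_width <- function(msa) {
  if (length(msa) == 0L) return(0L)
  nchar(msa[[1L]])
}

#' Write an MSA (or any named set of sequences) to FASTA
#'
#' @param msa Named character vector / `gs_msa`.
#' @param path Output file.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::BStringSet(stats::setNames(as.character(msa), names(msa)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene structures (Scipio-style YAML subset)
#
# Documented schema subset (see inst/extdata/gene-structure-schema.md):
#   name:        optional gene name (defaults to the file stem)
#   translation: optional ungapped protein sequence
#   matchings:   ordered list of segments, each with
#     type:   one of exon | intron | gap | seqshift
#     seq:    nucleotide string (may be absent/empty for assembly gaps)
#     nt_len: segment length; required when seq is absent
# Segments are listed 5'->3' in coding direction.

SEGMENT_KINDS <- c("exon", "intron", "gap", "seqshift")
CODING_KINDS <- c("exon", "seqshift", "gap")

#' Construct a gene structure
#'
#' @param name Gene name (must match an MSA row name for pairing).
#' @param segments `data.frame` with columns `kind` (exon/intron/gap/seqshift),
#'   `nt_seq`, `nt_len`, ordered 5'->3'.
#' @param protein_seq Ungapped protein sequence; if `NULL`, translated from
#'   the concatenated coding nucleotides (trailing stop dropped).
#' @return Object of class `gene_structure`.
#' @export
gene_structure <- function(name, segments, protein_seq = NULL) {
  stopifnot(is.data.frame(segments),
            all(c("kind", "nt_seq", "nt_len") %in% names(segments)))
  segments$kind <- as.character(segments$kind)
  segments$nt_seq <- toupper(as.character(segments$nt_seq))
  segments$nt_len <- as.integer(segments$nt_len)
  bad <- setdiff(unique(segments$kind), SEGMENT_KINDS)
  if (length(bad))
    input_error(sprintf("gene '%s': unknown segment type(s): %s",
                        name, paste(bad, collapse = ", ")))
  has_seq <- nzchar(segments$nt_seq)
  if (any(has_seq & nchar(segments$nt_seq) != segments$nt_len))
    input_error(sprintf("gene '%s': nt_len disagrees with seq length", name))
  if (any(segments$kind == "exon" & !has_seq))
    input_error(sprintf("gene '%s': exon segment without nucleotide sequence",
                        name))
  is_int <- segments$kind == "intron"
  if (any(is_int[-1L] & is_int[-length(is_int)]))
    input_error(sprintf("gene '%s': two adjacent intron segments", name))
  if (is.null(protein_seq)) {
    cds <- paste(segments$nt_seq[segments$kind %in% c("exon", "seqshift")],
                 collapse = "")
    protein_seq <- strip_stop(translate_cds(cds))
  }
  protein_seq <- strip_stop(toupper(protein_seq))
  coding_nt <- sum(segments$nt_len[segments$kind %in% CODING_KINDS])
  if (coding_nt < 3L * (nchar(protein_seq) - 1L))
    input_error(sprintf(
      "gene '%s': %d coding nt cannot encode %d residues",
      name, coding_nt, nchar(protein_seq)))
  structure(list(name = name, segments = segments, protein_seq = protein_seq),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  tab <- table(factor(x$segments$kind, levels = SEGMENT_KINDS))
  cat(sprintf("Gene structure '%s': %d aa, %s\n", x$name,
              nchar(x$protein_seq),
              paste(sprintf("%d %s(s)", tab, names(tab))[tab > 0],
                    collapse = ", ")))
  invisible(x)
}

#' Read a Scipio-style YAML gene structure
#'
#' Parses the documented YAML subset (top-level `matchings` list with `type`,
#' `seq` and optional `nt_len` per segment; optional gene-level `translation`).
#'
#' @param path Path to a YAML file.  The gene name defaults to the file stem
#'   when the document carries no `name` key.
#' @return A [gene_structure()] object.
#' @export
read_gene_structure <- function(path) {
  if (!file.exists(path))
    input_error(sprintf("gene structure file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) input_error(sprintf(
                    "cannot parse YAML '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$matchings) || !length(doc$matchings))
    input_error(sprintf("'%s': no 'matchings' list", path))
  segs <- lapply(doc$matchings, function(m) {
    if (is.null(m$type))
      input_error(sprintf("'%s': matching without 'type'", path))
    seq <- if (is.null(m$seq)) "" else toupper(as.character(m$seq))
    len <- if (!is.null(m$nt_len)) as.integer(m$nt_len) else nchar(seq)
    if (!nzchar(seq) && is.null(m$nt_len) && m$type != "gap")
      input_error(sprintf("'%s': %s segment without seq or nt_len",
                          path, m$type))
    data.frame(kind = as.character(m$type), nt_seq = seq, nt_len = len,
               stringsAsFactors = FALSE)
  })
  segments <- do.call(rbind, segs)
  name <- if (!is.null(doc$name)) as.character(doc$name) else
    sub("\\.(ya?ml)$", "", basename(path))
  translation <- if (!is.null(doc$translation)) as.character(doc$translation)
  gene_structure(name, segments, protein_seq = translation)
}

#' Write a gene structure back to the YAML subset
#'
#' Inverse of [read_gene_structure()]: parse -> write -> parse is the identity
#' on the documented schema subset.
#'
#' @param gene A `gene_structure`.
#' @param path Output file.
#' @export
write_gene_structure_yaml <- function(gene, path) {
  matchings <- lapply(seq_len(nrow(gene$segments)), function(i) {
    s <- gene$segments[i, ]
    m <- list(type = s$kind)
    if (nzchar(s$nt_seq)) m$seq <- s$nt_seq else m$nt_len <- s$nt_len
    m
  })
  doc <- list(name = gene$name, translation = gene$protein_seq,
              matchings = matchings)
  yaml::write_yaml(doc, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PDB chains

#' Read one chain of a PDB file
#'
#' Uses the ATOM records of the first model only (resolved residues; SEQRES is
#' deliberately ignored because intron sites can only be painted on residues
#' that are present in the structure).  Residue numbering gaps are preserved;
#' non-standard residues map to `X`.
#'
#' @param path PDB file.
#' @param chain Single-character chain identifier (default `"A"`).
#' @return Object of class `pdb_chain`: list with `path`, `chain` and
#'   `residues`, a `data.frame(resno, insert, aa, id)` in ATOM-record order.
#' @export
read_pdb_chain <- function(path, chain = "A") {
  if (!file.exists(path)) input_error(sprintf("PDB file not found: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atoms)) input_error(sprintf("'%s': no ATOM records", path))
  avail <- unique(atoms$chain)
  if (!chain %in% avail)
    input_error(sprintf("chain '%s' not present in '%s'; available chains: %s",
                        chain, path, paste(avail, collapse = ", ")))
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste0(atoms$resno, ins)
  first <- !duplicated(key)
  resno <- atoms$resno[first]
  insert <- ins[first]
  resid <- atoms$resid[first]
  aa <- suppressWarnings(bio3d::aa321(resid))
  aa[is.na(aa) | !aa %in% c(LETTERS)] <- "X"
  residues <- data.frame(resno = as.integer(resno), insert = insert, aa = aa,
                         id = paste0(resno, insert), stringsAsFactors = FALSE)
  structure(list(path = path, chain = chain, residues = residues),
            class = "pdb_chain")
}

#' @export
print.pdb_chain <- function(x, ...) {
  cat(sprintf("PDB chain %s (%s): %d resolved residues (%s..%s)\n",
              x$chain, basename(x$path), nrow(x$residues),
              x$residues$id[1L], x$residues$id[nrow(x$residues)]))
  invisible(x)
}

#' One-letter sequence of a PDB chain
#' @param chain A `pdb_chain`.
#' @export
pdb_chain_seq <- function(chain) paste(chain$residues$aa, collapse = "")

# ---------------------------------------------------------------------------

#' Pair gene structures with their MSA rows by name
#'
#' Every gene structure must match an MSA row of the same name, and its
#' protein sequence must equal the ungapped MSA row (trailing `*` stripped on
#' both sides).  Mismatching genes are excluded with a warning naming the
#' first divergent residue; a run without any valid pairing is fatal.
#'
#' @param msa A `gs_msa`.
#' @param genes List of `gene_structure` objects.
#' @return List with `pairs` (`data.frame(gene, msa_name)`), `genes` (the
#'   validated structures, named), `excluded` (`data.frame(gene, reason)`) and
#'   `messages` (character vector of warnings emitted).
#' @export
validate_inputs <- function(msa, genes) {
  stopifnot(inherits(msa, "gs_msa"))
  msgs <- character()
  keep <- list()
  excluded <- data.frame(gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (g in genes) {
    if (!g$name %in% names(msa)) {
      reason <- sprintf("no MSA sequence named '%s'", g$name)
      excluded <- rbind(excluded, data.frame(gene = g$name, reason = reason))
      msgs <- c(msgs, sprintf("excluding gene '%s': %s", g$name, reason))
      next
    }
    row_seq <- strip_stop(degap(unclass(msa)[[g$name]]))
    prot <- strip_stop(g$protein_seq)
    if (!identical(row_seq, prot)) {
      n <- min(nchar(row_seq), nchar(prot))
      a <- split_chars(substr(row_seq, 1L, n))
      b <- split_chars(substr(prot, 1L, n))
      pos <- if (n > 0L && any(a != b)) which(a != b)[1L] else n + 1L
      reason <- sprintf(
        "translation disagrees with ungapped MSA sequence at residue %d", pos)
      excluded <- rbind(excluded, data.frame(gene = g$name, reason = reason))
      msgs <- c(msgs, sprintf("excluding gene '%s': %s", g$name, reason))
      next
    }
    keep[[g$name]] <- g
  }
  for (m in msgs) warning(m, call. = FALSE)
  if (!length(keep))
    input_error("no gene structure could be paired with an MSA sequence")
  unmatched_rows <- setdiff(names(msa), names(keep))
  list(pairs = data.frame(gene = names(keep), msa_name = names(keep),
                          stringsAsFactors = FALSE),
       genes = keep,
       excluded = excluded,
       unmatched_msa = unmatched_rows,
       messages = msgs)
}
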