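# Mapping consensus intron positions onto a protein 3-D structure: a global
# (Needleman-Wunsch) alignment of a reference MSA sequence against the PDB
# chain sequence -- by default with free end gaps, because the crystallised
# construct and the full-length reference routinely differ in length (single
# domains, purification tags, unresolved loops) -- followed by projection of
# cluster columns onto PDB residue numbers and generation of the two PyMOL
# colouring scripts.

#' Global pairwise alignment with optional free end gaps
#'
#' Linear gap costs; identity scoring by default (the reference and the chain
#' sequence are near-identical, diverging mainly by missing stretches).  With
#' `penalize_endgaps = FALSE` (the default) the first DP row/column cost
#' nothing and the optimum is taken over the last row/column (semi-global
#' alignment), so leading/trailing overhangs are free.  Traceback ties break
#' deterministically: diagonal, then up (gap in `seq_b`), then left.
#'
#' @param seq_a,seq_b Non-empty uppercase amino-acid strings (`X` allowed).
#' @param match,mismatch,gap Scores (defaults +2 / -1 / -2, linear gaps).
#' @param penalize_endgaps Charge end gaps as internal gaps (default `FALSE`).
#' @return Object of class `structure_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, and `pairs`
#'   (`data.frame(a_index, b_index)`, 0-based indices of aligned
#'   match/mismatch columns).
#' @export
needleman_wunsch <- function(seq_a, seq_b, match = 2, mismatch = -1,
                             gap = -2, penalize_endgaps = FALSE) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    input_error("alignment requires two non-empty sequences")
  stopifnot(match > mismatch, gap < 0)
  a <- split_chars(toupper(seq_a))
  b <- split_chars(toupper(seq_b))
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  if (penalize_endgaps) {
    S[, 1L] <- gap * (0:n)
    S[1L, ] <- gap * (0:m)
  }
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  if (penalize_endgaps) {
    i <- n; j <- m
    score <- S[n + 1L, m + 1L]
  } else {
    # optimum over last row/column; ties -> larger i, then larger j
    cand <- rbind(data.frame(i = 0:n, j = m), data.frame(i = n, j = 0:m))
    sc <- S[cbind(cand$i + 1L, cand$j + 1L)]
    best <- which(sc == max(sc))
    best <- best[order(cand$i[best], cand$j[best], decreasing = TRUE)][1L]
    i <- cand$i[best]; j <- cand$j[best]
    score <- max(sc)
  }
  al_a <- character(0); al_b <- character(0)
  # trailing free gaps
  if (!penalize_endgaps) {
    if (i < n) {
      al_a <- a[(i + 1L):n]; al_b <- rep("-", n - i)
    } else if (j < m) {
      al_a <- rep("-", m - j); al_b <- b[(j + 1L):m]
    }
  }
  pairs_a <- integer(0); pairs_b <- integer(0)
  while (i > 0L && j > 0L) {
    sub <- if (a[i] == b[j]) match else mismatch
    if (S[i + 1L, j + 1L] == S[i, j] + sub) {
      al_a <- c(a[i], al_a); al_b <- c(b[j], al_b)
      pairs_a <- c(i - 1L, pairs_a); pairs_b <- c(j - 1L, pairs_b)
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      al_a <- c(a[i], al_a); al_b <- c("-", al_b)
      i <- i - 1L
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j], al_b)
      j <- j - 1L
    }
    if (!penalize_endgaps && (i == 0L || j == 0L)) break
  }
  if (penalize_endgaps) {
    while (i > 0L) { al_a <- c(a[i], al_a); al_b <- c("-", al_b); i <- i - 1L }
    while (j > 0L) { al_a <- c("-", al_a); al_b <- c(b[j], al_b); j <- j - 1L }
  } else {
    if (i > 0L) { al_a <- c(a[1:i], al_a); al_b <- c(rep("-", i), al_b) }
    if (j > 0L) { al_a <- c(rep("-", j), al_a); al_b <- c(b[1:j], al_b) }
  }
  structure(list(aligned_a = paste(al_a, collapse = ""),
                 aligned_b = paste(al_b, collapse = ""),
                 score = score,
                 pairs = data.frame(a_index = pairs_a, b_index = pairs_b)),
            class = "structure_alignment")
}

#' @export
print.structure_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment, score %g, %d aligned columns\n",
              x$score, nrow(x$pairs)))
  cat(" ", substr(x$aligned_a, 1L, 70L), "\n ",
      substr(x$aligned_b, 1L, 70L), "\n", sep = "")
  invisible(x)
}

#' Align a reference sequence to a PDB chain
#'
#' Convenience wrapper: aligns the (ungapped) reference sequence to the
#' chain's resolved-residue sequence and builds the partial map from
#' reference residue index to PDB residue number, defined exactly on the
#' aligned (match/mismatch) columns.
#'
#' @param ref_seq Ungapped reference protein sequence.
#' @param chain A [read_pdb_chain()] object.
#' @inheritParams needleman_wunsch
#' @return The `structure_alignment`, extended with `ref_to_pdb`
#'   (`data.frame(ref_index, resno, id)`) and `chain`.
#' @export
align_ref_to_chain <- function(ref_seq, chain, match = 2, mismatch = -1,
                               gap = -2, penalize_endgaps = FALSE) {
  stopifnot(inherits(chain, "pdb_chain"))
  al <- needleman_wunsch(ref_seq, pdb_chain_seq(chain), match, mismatch, gap,
                         penalize_endgaps)
  al$ref_to_pdb <- data.frame(
    ref_index = al$pairs$a_index,
    resno = chain$residues$resno[al$pairs$b_index + 1L],
    id = chain$residues$id[al$pairs$b_index + 1L],
    stringsAsFactors = FALSE)
  al$chain <- chain
  al
}

#' Project consensus intron clusters onto PDB residue numbers
#'
#' Each cluster's MSA column is translated to a reference residue index via
#' the reference row's gap structure (a column where the reference is gapped
#' anchors to the next reference residue to the right; terminal positions
#' fall back to the last residue), then to the PDB residue numbers flanking
#' the splice.  A phase-0 intron sits between residues `r-1 | r`; a phase-1/2
#' intron splits the codon of residue `r`, whose flanks are taken as
#' `(r, r+1)`.  Clusters landing on unresolved/unaligned residues are
#' reported with `mappable = FALSE`, never silently dropped.
#'
#' @param consensus An `intron_clusters` object (typically after
#'   [consensus_filter()]).
#' @param msa The `gs_msa` containing the reference row.
#' @param reference Name of the reference MSA sequence.
#' @param alignment Result of [align_ref_to_chain()] against that reference.
#' @return `data.frame(cluster_id, msa_column, phase, support, conservation,
#'   cut_index, pdb_before, pdb_after, mappable, conserved_in_reference,
#'   note)`, ordered by column; `pdb_before`/`pdb_after` are PDB residue
#'   numbers (insertion-code ids in `id_before`/`id_after`).
#' @export
project_clusters <- function(consensus, msa, reference, alignment) {
  stopifnot(inherits(consensus, "intron_clusters"),
            inherits(alignment, "structure_alignment"))
  if (!reference %in% names(msa))
    input_error(sprintf("reference '%s' is not an MSA sequence", reference))
  row <- unclass(msa)[[reference]]
  chars <- split_chars(row)
  L <- sum(chars != "-")
  map <- alignment$ref_to_pdb
  lookup <- function(ref_index) {
    hit <- match(ref_index, map$ref_index)
    if (is.na(hit)) c(NA_integer_, NA_character_) else
      c(map$resno[hit], map$id[hit])
  }
  cl <- consensus$clusters
  mem <- consensus$members
  out <- lapply(seq_len(nrow(cl)), function(k) {
    col <- cl$msa_column[k]; phase <- cl$phase[k]
    note <- ""
    # residue index of the reference residue at/right of the column
    r <- if (col >= nchar(row)) L else sum(chars[seq_len(col)] != "-")
    if (col < nchar(row) && chars[col + 1L] == "-")
      note <- "reference gapped at cluster column; anchored to next residue"
    cut <- if (phase == 0L) r else r + 1L
    if (cut < 1L) { cut <- 1L; note <- "before first reference residue" }
    if (cut > L - 1L && L > 1L) {
      if (cut > L) note <- "after last reference residue"
      cut <- min(cut, L)
    }
    before <- lookup(cut - 1L)
    after <- if (cut <= L - 1L) lookup(cut) else c(NA_integer_, NA_character_)
    if (cut > L - 1L && note == "")
      note <- "splice after the last reference residue"
    mappable <- !is.na(before[1L]) && !is.na(after[1L])
    data.frame(cluster_id = cl$cluster_id[k], msa_column = col, phase = phase,
               support = cl$support[k], conservation = cl$conservation[k],
               cut_index = cut,
               pdb_before = as.integer(before[1L]),
               pdb_after = as.integer(after[1L]),
               id_before = before[2L], id_after = after[2L],
               mappable = mappable,
               conserved_in_reference = any(
                 mem$cluster_id == cl$cluster_id[k] & mem$gene == reference),
               note = note, stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = integer(), msa_column = integer(),
               phase = integer(), support = integer(),
               conservation = numeric(), cut_index = integer(),
               pdb_before = integer(), pdb_after = integer(),
               id_before = character(), id_after = character(),
               mappable = logical(), conserved_in_reference = logical(),
               note = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

PHASE_COLOURS <- c(`0` = "red", `1` = "yellow", `2` = "blue")
EXON_SEGMENT_PALETTE <- c("skyblue", "salmon", "palegreen", "lightorange",
                          "lightpink", "palecyan", "wheat", "violet")

# compress sorted residue numbers into PyMOL resi selections like "5-9+12"
resi_selection <- function(resno) {
  resno <- sort(unique(resno))
  if (!length(resno)) return("")
  brk <- c(0L, which(diff(resno) > 1L), length(resno))
  parts <- vapply(seq_len(length(brk) - 1L), function(k) {
    run <- resno[(brk[k] + 1L):brk[k + 1L]]
    if (length(run) == 1L) as.character(run) else
      sprintf("%d-%d", run[1L], run[length(run)])
  }, character(1L))
  paste(parts, collapse = "+")
}

#' Generate the two PyMOL colouring scripts
#'
#' `color_exons.py` colours runs of residues between consecutive mapped
#' splice sites (one colour per putative exon segment, cycling a fixed
#' palette); `color_splicesites.py` colours only the residue pairs flanking
#' each splice, by a fixed three-colour phase scheme (phase 0 red, 1 yellow,
#' 2 blue).  Everything else — unused chains, unaligned or unresolved
#' residues — stays grey.  Both scripts are standalone (they load the PDB and
#' select the chain) and are emitted as text only; PyMOL is never executed.
#' Unmappable clusters are recorded as comments.
#'
#' @param projection Result of [project_clusters()].
#' @param chain The [read_pdb_chain()] object used for the alignment.
#' @param alignment The [align_ref_to_chain()] result (for the mapped range).
#' @param consensus_threshold Threshold recorded in the script header.
#' @return Object of class `pymol_scripts`: list with `exon_script` and
#'   `splice_script` (character vectors of lines).
#' @export
emit_pymol_scripts <- function(projection, chain, alignment,
                               consensus_threshold = 0.8) {
  stopifnot(inherits(chain, "pdb_chain"))
  header <- function(what) c(
    sprintf("# %s -- PyMOL colouring of intron positions", what),
    sprintf("# structure: %s  chain: %s  consensus threshold: > %g",
            basename(chain$path), chain$chain, consensus_threshold),
    "from pymol import cmd",
    sprintf('cmd.load(r"%s", "structure")', chain$path),
    'cmd.hide("everything")',
    'cmd.show("cartoon", "structure")',
    'cmd.color("grey80", "structure")',
    'cmd.bg_color("white")')
  sel <- function(resi) sprintf('"structure and chain %s and resi %s"',
                                chain$chain, resi)
  mapped <- projection[projection$mappable, , drop = FALSE]
  unmapped <- projection[!projection$mappable, , drop = FALSE]
  notes <- if (nrow(unmapped)) sprintf(
    "# unmappable cluster: column %d phase %d (%s)",
    unmapped$msa_column, unmapped$phase,
    ifelse(nzchar(unmapped$note), unmapped$note,
           "no resolved residue at the splice")) else character(0)
  obscured <- if (nrow(mapped)) sprintf(
    "# splice site: column %d phase %d -> residues %s|%s",
    mapped$msa_column, mapped$phase, mapped$id_before, mapped$id_after)
    else character(0)

  map <- alignment$ref_to_pdb
  exon_lines <- character(0)
  if (nrow(mapped) && nrow(map)) {
    cuts <- sort(unique(mapped$cut_index))
    ref_idx <- sort(map$ref_index)
    seg_id <- findInterval(ref_idx, cuts) + 1L
    segs <- split(ref_idx, seg_id)
    k <- 0L
    for (s in segs) {
      k <- k + 1L
      resno <- map$resno[match(s, map$ref_index)]
      colour <- EXON_SEGMENT_PALETTE[((k - 1L) %%
                                        length(EXON_SEGMENT_PALETTE)) + 1L]
      exon_lines <- c(exon_lines, sprintf('cmd.color("%s", %s)', colour,
                                          resi_selection(resno) |> sel()))
    }
  }
  splice_lines <- character(0)
  for (i in seq_len(nrow(mapped))) {
    colour <- PHASE_COLOURS[[as.character(mapped$phase[i])]]
    resi <- resi_selection(c(mapped$pdb_before[i], mapped$pdb_after[i]))
    splice_lines <- c(splice_lines,
                      sprintf('cmd.color("%s", %s)', colour, sel(resi)))
  }
  structure(list(
    exon_script = c(header("color_exons.py"), notes, obscured, exon_lines),
    splice_script = c(header("color_splicesites.py"), notes, obscured,
                      splice_lines)),
    class = "pymol_scripts")
}

#' Write the PyMOL scripts under their canonical file names
#' @param scripts A `pymol_scripts` object.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_pymol_scripts <- function(scripts, dir) {
  stopifnot(inherits(scripts, "pymol_scripts"))
  p1 <- file.path(dir, "color_exons.py")
  p2 <- file.path(dir, "color_splicesites.py")
  writeLines(scripts$exon_script, p1)
  writeLines(scripts$splice_script, p2)
  invisible(c(p1, p2))
}
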