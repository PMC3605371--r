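# Synthetic gene-family generator: an ancestor protein with planted introns,
# descendant genes with controlled intron loss/gain, frame-shift (seqshift)
# and assembly-gap artefacts, per-gene MSA indels, plus a toy PDB of the
# reference sequence.  Every planted intron's (gene, residue index, phase,
# MSA column) is recorded in a ground-truth table, against which the full
# pipeline can be checked exactly.

#' Specification of a synthetic gene family
#'
#' Defaults emulate a mid-sized eukaryotic protein family as this kind of
#' analysis typically sees it: ~8 homologs of a 120-residue protein, five
#' ancestral introns of 40-200 nt, moderate intron loss (15% per gene and
#' site), occasional lineage-specific gains, and low rates of assembly
#' artefacts and alignment indels.
#'
#' @param n_genes Number of genes (>= 2).
#' @param protein_length Ancestor protein length in residues (>= 2).
#' @param n_ancestral_introns Number of introns planted in the ancestor.
#' @param loss_prob Per-gene, per-site probability of losing an ancestral
#'   intron.
#' @param gain_prob Per-gene probability of gaining one lineage-specific
#'   intron (gains never collide with an existing (column, phase) key).
#' @param intron_length_range Intron length interval in nt (min >= 4, so the
#'   canonical GT...AG dinucleotides fit).
#' @param seqshift_prob Per-gene probability of one single-nucleotide
#'   frame-shift artefact inside an exon.
#' @param assembly_gap_prob Per-gene probability of one 3-nt assembly gap of
#'   unknown sequence inside an exon (introns downstream of it are excluded
#'   from the truth clusters, mirroring the pipeline's rule).
#' @param msa_gap_prob Per-column, per-gene probability of an alignment indel
#'   (split evenly between deletions and gene-specific insertions).
#' @param substitution_prob Per-residue probability of a substitution
#'   relative to the ancestor.
#' @param pdb Also build a toy PDB chain covering part of the first gene.
#' @param seed Integer seed; the same spec yields byte-identical outputs.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(n_genes = 8L, protein_length = 120L,
                        n_ancestral_introns = 5L, loss_prob = 0.15,
                        gain_prob = 0.1, intron_length_range = c(40L, 200L),
                        seqshift_prob = 0.1, assembly_gap_prob = 0.05,
                        msa_gap_prob = 0.03, substitution_prob = 0.1,
                        pdb = TRUE, seed = 1L) {
  if (protein_length < 2L) input_error("protein_length must be >= 2")
  if (n_genes < 2L) input_error("n_genes must be >= 2")
  probs <- c(loss_prob, gain_prob, seqshift_prob, assembly_gap_prob,
             msa_gap_prob, substitution_prob)
  if (any(probs < 0 | probs > 1)) input_error("probabilities must be in [0, 1]")
  if (intron_length_range[1L] < 4L)
    input_error("minimum intron length is 4 nt (GT..AG)")
  if (n_ancestral_introns > protein_length - 2L)
    input_error("too many ancestral introns for this protein length")
  structure(list(n_genes = as.integer(n_genes),
                 protein_length = as.integer(protein_length),
                 n_ancestral_introns = as.integer(n_ancestral_introns),
                 loss_prob = loss_prob, gain_prob = gain_prob,
                 intron_length_range = as.integer(intron_length_range),
                 seqshift_prob = seqshift_prob,
                 assembly_gap_prob = assembly_gap_prob,
                 msa_gap_prob = msa_gap_prob,
                 substitution_prob = substitution_prob,
                 pdb = isTRUE(pdb), seed = as.integer(seed)),
            class = "family_spec")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_intron <- function(len) {
  body <- if (len > 4L)
    paste(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE),
          collapse = "") else ""
  paste0("GT", body, "AG")
}

#' Generate a synthetic gene family with ground truth
#'
#' Builds the MSA (homologous residues share columns by construction), one
#' gene structure per gene, the ground-truth intron/cluster tables, and
#' optionally a toy PDB chain covering the middle portion of the first gene
#' (residue numbering offset by +9, so PDB numbers differ from sequence
#' indices).
#'
#' @param spec A [family_spec()].
#' @return Object of class `gene_family`: list with `spec`, `msa` (`gs_msa`),
#'   `genes` (named list of `gene_structure`), `truth` (list of `introns`,
#'   `clusters`, `members` data frames; columns 0-based), `reference`,
#'   `pdb_chain`/`pdb_lines`/`pdb_ref_range` when a structure is built.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  L <- spec$protein_length
  n <- spec$n_genes
  gene_names <- sprintf("gene%02d", seq_len(n))
  ancestor <- sample(AA20, L, replace = TRUE)

  # core residues: substitutions and deletions per gene
  core <- matrix(rep(ancestor, each = n), nrow = n,
                 dimnames = list(gene_names, NULL))
  subs <- matrix(stats::runif(n * L) < spec$substitution_prob, n, L)
  core[subs] <- sample(AA20, sum(subs), replace = TRUE)
  dels <- matrix(stats::runif(n * L) < spec$msa_gap_prob / 2, n, L)
  # the reference gene keeps all core residues so the PDB covers real sites
  dels[1L, ] <- FALSE
  # never delete a whole column
  full_col_del <- colSums(dels) == n
  dels[, full_col_del] <- FALSE
  core[dels] <- "-"

  # gene-specific insertions: each becomes its own alignment column
  col_list <- lapply(seq_len(L), function(c0) core[, c0])
  col_is_core <- rep(TRUE, L)
  for (g in seq_len(n)) {
    n_ins <- stats::rbinom(1L, L, spec$msa_gap_prob / 2)
    if (n_ins == 0L) next
    at <- sort(sample(seq_along(col_list), n_ins, replace = TRUE))
    for (k in rev(seq_len(n_ins))) {
      newcol <- rep("-", n)
      newcol[g] <- sample(AA20, 1L)
      pos <- at[k]
      col_list <- append(col_list, list(newcol), after = pos)
      col_is_core <- append(col_is_core, FALSE, after = pos)
    }
  }
  mat <- do.call(cbind, col_list)
  rownames(mat) <- gene_names
  n_col <- ncol(mat)
  rows <- apply(mat, 1L, paste, collapse = "")
  msa <- as_gs_msa(rows)

  # ancestral intron sites on core columns (0-based final columns)
  core_cols <- which(col_is_core)
  anc_core <- if (spec$n_ancestral_introns > 0L)
    sort(sample(2:(L - 1L), spec$n_ancestral_introns)) else integer(0)
  anc_col <- core_cols[anc_core] - 1L
  anc_phase <- if (length(anc_core))
    sample(0:2, length(anc_core), replace = TRUE) else integer(0)
  used_keys <- paste(anc_col, anc_phase, sep = "/")

  intron_rows <- list()
  for (g in seq_len(n)) {
    gname <- gene_names[g]
    has_res <- mat[g, ] != "-"
    for (k in seq_along(anc_col)) {
      col0 <- anc_col[k]
      if (!has_res[col0 + 1L]) next          # deleted residue: site lost
      if (stats::runif(1L) < spec$loss_prob) next
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        gene = gname, msa_column = col0, phase = anc_phase[k],
        ancestral = TRUE, stringsAsFactors = FALSE)
    }
    if (stats::runif(1L) < spec$gain_prob) {
      cand_cols <- which(has_res) - 1L
      for (attempt in seq_len(20L)) {
        col0 <- sample(cand_cols, 1L)
        ph <- sample(0:2, 1L)
        key <- paste(col0, ph, sep = "/")
        if (!key %in% used_keys) {
          used_keys <- c(used_keys, key)
          intron_rows[[length(intron_rows) + 1L]] <- data.frame(
            gene = gname, msa_column = col0, phase = ph, ancestral = FALSE,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  introns <- if (length(intron_rows)) do.call(rbind, intron_rows) else
    data.frame(gene = character(), msa_column = integer(), phase = integer(),
               ancestral = logical(), stringsAsFactors = FALSE)
  introns$residue_index <- rep(NA_integer_, nrow(introns))
  introns$coding_offset <- rep(NA_integer_, nrow(introns))
  introns$nt_len <- rep(NA_integer_, nrow(introns))
  introns$reliable <- rep(NA, nrow(introns))

  codon_map <- aa_to_codon()
  genes <- list()
  for (g in seq_len(n)) {
    gname <- gene_names[g]
    res_cols <- which(mat[g, ] != "-")
    prot <- paste(mat[g, res_cols], collapse = "")
    Lg <- length(res_cols)
    cds <- paste(codon_map[mat[g, res_cols]], collapse = "")
    cds <- paste0(cds, "TAA")

    gi <- introns[introns$gene == gname, , drop = FALSE]
    if (nrow(gi)) {
      gi$residue_index <- match(gi$msa_column + 1L, res_cols) - 1L
      gi$coding_offset <- 3L * gi$residue_index + gi$phase
      gi <- gi[order(gi$coding_offset), , drop = FALSE]
    } else {
      gi$residue_index <- integer(0)
      gi$coding_offset <- integer(0)
    }
    cuts <- gi$coding_offset
    gi$nt_len <- if (nrow(gi))
      sample(spec$intron_length_range[1L]:spec$intron_length_range[2L],
             nrow(gi), replace = TRUE) else integer(0)

    # artefact codons: fully interior to an exon piece (no cut strictly
    # inside or at the codon edges) and away from the stop codon
    codon_ok <- vapply(seq_len(Lg), function(k) {
      s <- 3L * (k - 1L); e <- s + 3L
      !any(cuts >= s & cuts <= e)
    }, logical(1L))
    special <- data.frame(pos = integer(), len = integer(), kind = character(),
                          stringsAsFactors = FALSE)
    if (any(codon_ok) && stats::runif(1L) < spec$seqshift_prob) {
      k <- sample(which(codon_ok), 1L)
      codon_ok[k] <- FALSE
      special <- rbind(special, data.frame(pos = 3L * (k - 1L) + 1L, len = 1L,
                                           kind = "seqshift"))
    }
    if (any(codon_ok) && stats::runif(1L) < spec$assembly_gap_prob) {
      k <- sample(which(codon_ok), 1L)
      special <- rbind(special, data.frame(pos = 3L * (k - 1L), len = 3L,
                                           kind = "gap"))
    }
    special <- special[order(special$pos), , drop = FALSE]

    # truth reliability: introns downstream of an assembly gap are excluded
    gap_pos <- special$pos[special$kind == "gap"]
    gi$reliable <- if (length(gap_pos))
      gi$coding_offset <= min(gap_pos) else rep(TRUE, nrow(gi))

    # assemble segments by walking coding positions
    events <- rbind(
      if (nrow(gi)) data.frame(pos = gi$coding_offset, len = 0L,
                               kind = "intron", idx = seq_len(nrow(gi))),
      if (nrow(special)) cbind(special, idx = NA_integer_))
    events <- if (!is.null(events))
      events[order(events$pos, events$kind != "intron"), , drop = FALSE] else
      data.frame(pos = integer(), len = integer(), kind = character(),
                 idx = integer())
    segs <- list()
    cursor <- 0L
    add_exon <- function(from, to) {
      if (to > from)
        segs[[length(segs) + 1L]] <<- data.frame(
          kind = "exon", nt_seq = substr(cds, from + 1L, to),
          nt_len = to - from, stringsAsFactors = FALSE)
    }
    for (e in seq_len(nrow(events))) {
      ev <- events[e, ]
      add_exon(cursor, ev$pos)
      cursor <- max(cursor, ev$pos)
      if (ev$kind == "intron") {
        segs[[length(segs) + 1L]] <- data.frame(
          kind = "intron", nt_seq = random_intron(gi$nt_len[ev$idx]),
          nt_len = gi$nt_len[ev$idx], stringsAsFactors = FALSE)
      } else if (ev$kind == "seqshift") {
        segs[[length(segs) + 1L]] <- data.frame(
          kind = "seqshift", nt_seq = substr(cds, ev$pos + 1L,
                                             ev$pos + ev$len),
          nt_len = ev$len, stringsAsFactors = FALSE)
        cursor <- cursor + ev$len
      } else {
        segs[[length(segs) + 1L]] <- data.frame(
          kind = "gap", nt_seq = "", nt_len = ev$len,
          stringsAsFactors = FALSE)
        cursor <- cursor + ev$len
      }
    }
    add_exon(cursor, nchar(cds))
    segments <- do.call(rbind, segs)
    genes[[gname]] <- gene_structure(gname, segments, protein_seq = prot)
    introns$residue_index[introns$gene == gname] <-
      gi$residue_index[match(paste(introns$msa_column[introns$gene == gname],
                                   introns$phase[introns$gene == gname]),
                             paste(gi$msa_column, gi$phase))]
    introns$coding_offset[introns$gene == gname] <-
      gi$coding_offset[match(paste(introns$msa_column[introns$gene == gname],
                                   introns$phase[introns$gene == gname]),
                             paste(gi$msa_column, gi$phase))]
    introns$nt_len[introns$gene == gname] <-
      gi$nt_len[match(paste(introns$msa_column[introns$gene == gname],
                            introns$phase[introns$gene == gname]),
                      paste(gi$msa_column, gi$phase))]
    introns$reliable[introns$gene == gname] <-
      gi$reliable[match(paste(introns$msa_column[introns$gene == gname],
                              introns$phase[introns$gene == gname]),
                        paste(gi$msa_column, gi$phase))]
  }

  rel <- introns[introns$reliable, , drop = FALSE]
  if (nrow(rel)) {
    key <- paste(rel$msa_column, rel$phase, sep = "/")
    ord <- order(rel$msa_column, rel$phase, rel$gene)
    rel <- rel[ord, ]; key <- key[ord]
    uniq <- !duplicated(key)
    truth_clusters <- data.frame(
      msa_column = rel$msa_column[uniq], phase = rel$phase[uniq],
      support = as.integer(table(factor(key, levels = key[uniq]))),
      stringsAsFactors = FALSE)
    truth_members <- data.frame(msa_column = rel$msa_column, phase = rel$phase,
                                gene = rel$gene, stringsAsFactors = FALSE)
  } else {
    truth_clusters <- data.frame(msa_column = integer(), phase = integer(),
                                 support = integer())
    truth_members <- data.frame(msa_column = integer(), phase = integer(),
                                gene = character(), stringsAsFactors = FALSE)
  }

  fam <- list(spec = spec, msa = msa, genes = genes,
              truth = list(introns = introns, clusters = truth_clusters,
                           members = truth_members),
              reference = gene_names[1L])
  if (spec$pdb) {
    ref_prot <- genes[[1L]]$protein_seq
    Lr <- nchar(ref_prot)
    from <- max(1L, floor(0.2 * Lr))
    to <- min(Lr, ceiling(0.85 * Lr))
    fam$pdb_ref_range <- c(from, to)        # 1-based residue interval
    fam$pdb_lines <- toy_pdb_lines(substr(ref_prot, from, to),
                                   start_resno = from + 9L)
  }
  structure(fam, class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf(
    "Synthetic gene family: %d genes, %d aa ancestor, %d MSA columns\n",
    x$spec$n_genes, x$spec$protein_length, msa_width(x$msa)))
  cat(sprintf("  %d planted introns in %d truth clusters (seed %d)\n",
              nrow(x$truth$introns), nrow(x$truth$clusters), x$spec$seed))
  invisible(x)
}

# Minimal CA-only PDB text for a synthetic chain (labelled synthetic: this is
# not a real structure, just resolved-residue bookkeeping for the mapping).
toy_pdb_lines <- function(protein_seq, start_resno = 1L, chain = "A") {
  aa <- split_chars(protein_seq)
  three <- aa_one_to_three(aa)
  n <- length(aa)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), three, chain, start_resno + seq_len(n) - 1L,
    3.8 * seq_len(n), 0, 0)
  c(lines, "TER", "END")
}

#' Write a generated family to disk
#'
#' Emits `msa.fasta`, one `<gene>.yaml` per gene, `truth_introns.tsv`,
#' `truth_clusters.tsv` and (when present) `synthetic_structure.pdb`.
#'
#' @param fam A `gene_family`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_family <- function(fam, dir) {
  stopifnot(inherits(fam, "gene_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_msa(fam$msa, file.path(dir, "msa.fasta"))
  for (g in fam$genes)
    write_gene_structure_yaml(g, file.path(dir, paste0(g$name, ".yaml")))
  utils::write.table(fam$truth$introns, file.path(dir, "truth_introns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fam$truth$clusters, file.path(dir, "truth_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fam$pdb_lines))
    writeLines(fam$pdb_lines, file.path(dir, "synthetic_structure.pdb"))
  invisible(dir)
}
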