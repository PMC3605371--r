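# Shared fixture builders.  Everything is generated in code; no binary files.

# A tiny hand-built two-gene family with known intron placement:
#   geneA: exons 9 | intron(6) | 6 nt        -> intron at offset 9, phase 0
#   geneB: exons 10 | intron(8) | 5 nt       -> intron at offset 10, phase 1
tiny_gene <- function(name, exon_lens, intron_lens, intron_seqs = NULL) {
  stopifnot(length(exon_lens) == length(intron_lens) + 1L)
  nts <- c("A", "C", "G", "T")
  segs <- list()
  cds <- character(0)
  for (i in seq_along(exon_lens)) {
    seq <- paste(rep(nts, length.out = exon_lens[i]), collapse = "")
    segs[[length(segs) + 1L]] <- data.frame(kind = "exon", nt_seq = seq,
                                            nt_len = exon_lens[i])
    cds <- c(cds, seq)
    if (i <= length(intron_lens)) {
      iseq <- if (!is.null(intron_seqs)) intron_seqs[i] else
        paste0("GT", strrep("A", intron_lens[i] - 4L), "AG")
      segs[[length(segs) + 1L]] <- data.frame(kind = "intron", nt_seq = iseq,
                                              nt_len = intron_lens[i])
    }
  }
  gene_structure(name, do.call(rbind, segs))
}

# gapless MSA consistent with a list of gene structures (requires identical
# protein sequences, which tiny_gene of equal total exon nt yields)
msa_from_genes <- function(genes) {
  rows <- vapply(genes, function(g) g$protein_seq, character(1))
  names(rows) <- vapply(genes, function(g) g$name, character(1))
  as_gs_msa(rows)
}

small_spec <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 6L, protein_length = 60L,
                   n_ancestral_introns = 4L, loss_prob = 0.2, gain_prob = 0.2,
                   seqshift_prob = 0.2, assembly_gap_prob = 0.1,
                   msa_gap_prob = 0.05, intron_length_range = c(20L, 80L),
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(family_spec, args)
}

# independent oracle: maximum alignment score by exhaustive recursion over
# all alignments (no DP matrix); strict global scoring
enum_global_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (av[i] == bv[j]) match else mismatch))
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# free-end-gap oracle: best strict-global score over all substring pairs in
# which one sequence keeps its start and one keeps its end; the empty overlap
# (each sequence entirely inside the other's free end gaps) scores 0
enum_free_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in 1:(n + 0)) for (j1 in 1:(m + 0)) {
    if (i1 != 1L && j1 != 1L) next
    for (i2 in i1:n) for (j2 in j1:m) {
      if (i2 != n && j2 != m) next
      best <- max(best, enum_global_score(substr(a, i1, i2),
                                          substr(b, j1, j2),
                                          match, mismatch, gap))
    }
  }
  best
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# all sequences over an alphabet up to a maximum length
all_seqs <- function(max_len, alphabet = c("A", "C")) {
  out <- character(0)
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

expect_same_clusters <- function(clusters, truth) {
  got <- clusters$clusters[, c("msa_column", "phase", "support")]
  rownames(got) <- NULL
  want <- truth$clusters[order(truth$clusters$msa_column,
                               truth$clusters$phase), ]
  rownames(want) <- NULL
  expect_equal(got, want)
  got_mem <- clusters$members[order(clusters$members$msa_column,
                                    clusters$members$phase,
                                    clusters$members$gene),
                              c("msa_column", "phase", "gene")]
  want_mem <- truth$members[order(truth$members$msa_column,
                                  truth$members$phase, truth$members$gene), ]
  rownames(got_mem) <- rownames(want_mem) <- NULL
  expect_equal(got_mem, want_mem)
}

run_family_pipeline <- function(fam, range = NULL) {
  val <- validate_inputs(fam$msa, fam$genes)
  mapped <- map_introns(val$genes, fam$msa, range = range)
  cluster_introns(mapped, n_genes = length(val$genes))
}
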