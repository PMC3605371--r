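two_cluster_setup <- function() {
  m <- rbind(
    data.frame(gene = "a", coding_offset = 15L, phase = 0L, nt_len = 60L,
               nt_seq = "", reliable = TRUE, residue_index = 5L,
               msa_column = 5L),
    data.frame(gene = "a", coding_offset = 29L, phase = 2L, nt_len = 80L,
               nt_seq = "", reliable = TRUE, residue_index = 9L,
               msa_column = 9L),
    data.frame(gene = "b", coding_offset = 15L, phase = 0L, nt_len = 40L,
               nt_seq = "", reliable = TRUE, residue_index = 5L,
               msa_column = 5L))
  cluster_introns(m, n_genes = 2L)
}

test_that("cluster-level text dialects render membership and phases", {
  cl <- two_cluster_setup()
  bars <- render_intron_alignment(cl, c("a", "b"))
  expect_equal(unname(bars$rows), c("|-|", "|--"))

  phases <- render_intron_alignment(cl, c("a", "b"), dialect = "phase_digits")
  expect_equal(unname(phases$rows), c("0-2", "0--"))

  spaces <- render_intron_alignment(cl, c("a", "b"), dialect = "bars_only")
  expect_equal(unname(spaces$rows), c("| |", "|  "))

  # single shared cluster, no spacers at all
  m1 <- two_cluster_setup()$members[c(1, 3), ]
  m1 <- rbind(
    data.frame(gene = "a", coding_offset = 15L, phase = 0L, nt_len = 60L,
               nt_seq = "", reliable = TRUE, residue_index = 5L,
               msa_column = 5L),
    data.frame(gene = "b", coding_offset = 15L, phase = 0L, nt_len = 40L,
               nt_seq = "", reliable = TRUE, residue_index = 5L,
               msa_column = 5L))
  cl1 <- cluster_introns(m1, 2L)
  expect_equal(unname(render_intron_alignment(cl1, c("a", "b"))$rows),
               c("|", "|"))
})

test_that("text dialect invariants hold on generated families", {
  fam <- generate_family(small_spec(seed = 17L))
  cl <- run_family_pipeline(fam)
  genes <- names(fam$genes)
  for (k in c(0, 1.5)) {
    bars <- render_intron_alignment(cl, genes, "bars_and_dashes", spacer_k = k)
    spaces <- render_intron_alignment(cl, genes, "bars_only", spacer_k = k)
    digits <- render_intron_alignment(cl, genes, "phase_digits", spacer_k = k)
    # equal row lengths in every dialect
    for (ta in list(bars, spaces, digits))
      expect_equal(length(unique(nchar(ta$rows))), 1L)
    # bars_only equals bars_and_dashes under '-' -> ' ' substitution
    expect_identical(unname(spaces$rows),
                     gsub("-", " ", unname(bars$rows), fixed = TRUE))
    # cluster columns vertically aligned and consistent with membership
    cmap <- bars$column_map
    cluster_cols <- cmap$out_col[cmap$kind == "cluster"]
    expect_equal(length(cluster_cols), nrow(cl$clusters))
    for (i in seq_along(cluster_cols)) {
      cid <- cmap$cluster_id[cmap$kind == "cluster"][i]
      members <- cl$members$gene[cl$members$cluster_id == cid]
      phase <- cl$clusters$phase[cl$clusters$cluster_id == cid]
      for (g in genes) {
        ch_bar <- substr(bars$rows[[g]], cluster_cols[i] + 1L,
                         cluster_cols[i] + 1L)
        ch_dig <- substr(digits$rows[[g]], cluster_cols[i] + 1L,
                         cluster_cols[i] + 1L)
        if (g %in% members) {
          expect_equal(ch_bar, "|")
          expect_equal(ch_dig, as.character(phase))
        } else {
          expect_equal(ch_bar, "-")
        }
      }
    }
  }
})

test_that("interleaved MSA annotation marks intron columns", {
  msa <- as_gs_msa(c(g = "MKV"))
  mapped <- data.frame(gene = "g", coding_offset = 3L, phase = 0L,
                       nt_len = 50L, nt_seq = "", reliable = TRUE,
                       residue_index = 1L, msa_column = 1L)
  ann <- render_msa_interleaved(msa, mapped)
  expect_equal(unname(ann$annotations[["g"]]), " | ")
  ann2 <- render_msa_interleaved(msa, transform(mapped, phase = 2L),
                                 use_phase_digits = TRUE)
  expect_equal(unname(ann2$annotations[["g"]]), " 2 ")

  # terminal intron flagged in a trailing comment
  mapped3 <- transform(mapped, residue_index = 3L, msa_column = 3L)
  ann3 <- render_msa_interleaved(msa, mapped3)
  expect_equal(unname(ann3$annotations[["g"]]), "  |")
  expect_match(ann3$terminal_notes, "final codon")

  # every annotation line has exactly the aligned width; wrapping keeps
  # annotation and sequence lines paired
  fam <- generate_family(small_spec(seed = 23L))
  mapped_f <- map_introns(fam$genes, fam$msa)
  af <- render_msa_interleaved(fam$msa, mapped_f, wrap = 40L)
  expect_true(all(nchar(af$annotations) == msa_width(fam$msa)))
  body <- af$lines[nzchar(af$lines) & !startsWith(af$lines, "#")]
  expect_equal(length(body) %% 2L, 0L)
})

test_that("binary FASTA matrix round-trips through read_msa", {
  fam <- generate_family(small_spec(seed = 29L))
  cl <- run_family_pipeline(fam)
  bm <- binary_matrix(cl, names(fam$genes))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_phylo_fasta(bm, f)
  back <- read_msa(f)
  expect_identical(unclass(back), bm)
  # per-record '1' count equals the gene's reliable intron count
  ones <- vapply(strsplit(bm, ""), function(x) sum(x == "1"), integer(1))
  truth_counts <- table(factor(
    fam$truth$introns$gene[fam$truth$introns$reliable],
    levels = names(fam$genes)))
  expect_equal(unname(ones), as.integer(truth_counts))
})
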