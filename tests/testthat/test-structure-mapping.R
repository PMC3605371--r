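test_that("needleman_wunsch handles identity and substring cases", {
  al <- needleman_wunsch("MKVAID", "MKVAID", match = 1, mismatch = -1,
                         gap = -2)
  expect_equal(al$score, 6)
  expect_equal(al$aligned_a, "MKVAID")
  expect_equal(al$aligned_b, "MKVAID")

  # contiguous substring with free end gaps: ungapped placement
  al2 <- needleman_wunsch("MKVAIDERW", "VAID", match = 1, mismatch = -1,
                          gap = -2, penalize_endgaps = FALSE)
  expect_equal(al2$score, 4)
  expect_equal(al2$aligned_b, "--VAID---")
  expect_equal(al2$pairs$a_index, 2:5)
  expect_error(needleman_wunsch("", "A"), class = "gs_input_error")
})

test_that("DP scores equal the exhaustive-enumeration oracle", {
  # exhaustive over all pairs of short sequences on a 2-letter alphabet
  seqs <- all_seqs(3L, c("A", "C"))
  for (a in seqs) for (b in seqs) {
    expect_equal(needleman_wunsch(a, b, penalize_endgaps = TRUE)$score,
                 enum_global_score(a, b),
                 label = sprintf("global %s/%s", a, b))
    expect_equal(needleman_wunsch(a, b, penalize_endgaps = FALSE)$score,
                 enum_free_score(a, b),
                 label = sprintf("free %s/%s", a, b))
  }
  # sampled longer pairs on a 4-letter alphabet
  set.seed(7)
  for (rep in 1:60) {
    a <- random_seq(sample(1:6, 1))
    b <- random_seq(sample(1:6, 1))
    expect_equal(needleman_wunsch(a, b, penalize_endgaps = TRUE)$score,
                 enum_global_score(a, b), label = paste("global", a, b))
  }
  for (rep in 1:40) {
    a <- random_seq(sample(1:5, 1))
    b <- random_seq(sample(1:5, 1))
    expect_equal(needleman_wunsch(a, b, penalize_endgaps = FALSE)$score,
                 enum_free_score(a, b), label = paste("free", a, b))
  }
})

test_that("free end gaps never score below penalized end gaps", {
  set.seed(11)
  for (rep in 1:150) {
    a <- random_seq(sample(1:12, 1), c("A", "C", "G"))
    b <- random_seq(sample(1:12, 1), c("A", "C", "G"))
    free <- needleman_wunsch(a, b, penalize_endgaps = FALSE)
    pen <- needleman_wunsch(a, b, penalize_endgaps = TRUE)
    expect_gte(free$score, pen$score)
    # alignments reproduce their sequences when degapped
    expect_equal(gsub("-", "", free$aligned_a), a)
    expect_equal(gsub("-", "", free$aligned_b), b)
    expect_equal(gsub("-", "", pen$aligned_a), a)
    expect_equal(gsub("-", "", pen$aligned_b), b)
    expect_equal(nchar(free$aligned_a), nchar(free$aligned_b))
  }
})

test_that("DP scores agree with an independent aligner on longer pairs", {
  set.seed(13)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  for (rep in 1:20) {
    a <- random_seq(sample(20:60, 1))
    b <- random_seq(sample(20:60, 1))
    for (mode in c(TRUE, FALSE)) {
      ours <- needleman_wunsch(a, b, match = 2, mismatch = -1, gap = -2,
                               penalize_endgaps = mode)$score
      ref <- Biostrings::pairwiseAlignment(
        a, b, type = if (mode) "global" else "overlap",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
        scoreOnly = TRUE)
      expect_equal(ours, ref, label = sprintf("mode penalize=%s", mode))
    }
  }
})

structure_fixture <- function(seed = 61L, from_frac = 0.2, to_frac = 0.85) {
  fam <- generate_family(small_spec(seed = seed, protein_length = 90L,
                                    msa_gap_prob = 0.04))
  val <- validate_inputs(fam$msa, fam$genes)
  cl <- cluster_introns(map_introns(val$genes, fam$msa),
                        n_genes = length(val$genes))
  pdb_file <- withr::local_tempfile(fileext = ".pdb",
                                    .local_envir = parent.frame())
  writeLines(fam$pdb_lines, pdb_file)
  chain <- read_pdb_chain(pdb_file, "A")
  ref_seq <- fam$genes[[fam$reference]]$protein_seq
  al <- align_ref_to_chain(ref_seq, chain)
  list(fam = fam, cl = cl, chain = chain, al = al, ref_seq = ref_seq)
}

test_that("cluster projection maps consensus introns onto PDB numbering", {
  s <- structure_fixture()
  proj <- project_clusters(consensus_filter(s$cl, 0), s$fam$msa,
                           s$fam$reference, s$al)
  expect_equal(nrow(proj), nrow(s$cl$clusters))
  # direct index arithmetic: the toy chain covers reference residues
  # [from, to] (1-based) renumbered to start at from + 9
  from <- s$fam$pdb_ref_range[1]; to <- s$fam$pdb_ref_range[2]
  for (i in seq_len(nrow(proj))) {
    cut <- proj$cut_index[i]   # 0-based ref index of the downstream flank
    inside <- (cut - 1L) >= (from - 1L) && cut <= (to - 1L)
    expect_equal(proj$mappable[i], inside)
    if (inside) {
      expect_equal(proj$pdb_before[i], (cut - 1L) + 10L)
      expect_equal(proj$pdb_after[i], cut + 10L)
    }
  }
  # order preserved: PDB numbers non-decreasing over clusters by column
  m <- proj[proj$mappable, ]
  expect_true(all(diff(m$pdb_before) >= 0))
  # with default consensus every projected cluster is conserved in > 80%
  proj80 <- project_clusters(consensus_filter(s$cl, 0.8), s$fam$msa,
                             s$fam$reference, s$al)
  expect_true(all(proj80$conservation > 0.8))
})

test_that("reference gap columns anchor to the next residue to the right", {
  msa <- as_gs_msa(c(ref = "MK--VID", other = "MKAAVID"))
  m <- data.frame(gene = "other", coding_offset = 9L, phase = 0L,
                  nt_len = 50L, nt_seq = "", reliable = TRUE,
                  residue_index = 3L, msa_column = 3L)
  cl <- cluster_introns(m, n_genes = 2L)
  chain_file <- withr::local_tempfile(fileext = ".pdb")
  writeLines(genestructr:::toy_pdb_lines("MKVID", start_resno = 1L),
             chain_file)
  chain <- read_pdb_chain(chain_file)
  al <- align_ref_to_chain("MKVID", chain)
  proj <- project_clusters(consensus_filter(cl, 0), msa, "ref", al)
  # column 3 is a reference gap; next residue right is V (index 2) -> splice
  # between K (resno 2) and V (resno 3)
  expect_equal(proj$cut_index, 2L)
  expect_equal(proj$pdb_before, 2L)
  expect_equal(proj$pdb_after, 3L)
  expect_match(proj$note, "anchored to next residue")
})

test_that("PyMOL scripts are standalone, lintable and segment correctly", {
  s <- structure_fixture(seed = 67L)
  cons <- consensus_filter(s$cl, 0)
  proj <- project_clusters(cons, s$fam$msa, s$fam$reference, s$al)
  scripts <- emit_pymol_scripts(proj, s$chain, s$al, consensus_threshold = 0)
  for (script in list(scripts$exon_script, scripts$splice_script)) {
    expect_true(any(grepl("cmd.load", script, fixed = TRUE)))
    expect_true(any(grepl('cmd.color("grey80"', script, fixed = TRUE)))
    # every residue number referenced exists in the chain
    sels <- regmatches(script, gregexpr("resi [-0-9+]+", script))
    nums <- unlist(lapply(unlist(sels), function(s0) {
      parts <- strsplit(sub("resi ", "", s0), "+", fixed = TRUE)[[1]]
      unlist(lapply(parts, function(p) {
        r <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
        if (length(r) == 2L) r[1]:r[2] else r
      }))
    }))
    expect_true(all(nums %in% s$chain$residues$resno))
  }
  # unmappable clusters appear as comments, never as selections
  if (any(!proj$mappable))
    expect_true(any(grepl("# unmappable cluster", scripts$exon_script)))

  # n mapped splice sites delimit n + 1 exon segments
  n_cuts <- length(unique(proj$cut_index[proj$mappable]))
  n_segments <- sum(grepl('^cmd.color\\("(?!grey)', scripts$exon_script,
                          perl = TRUE))
  if (n_cuts > 0L) expect_equal(n_segments, n_cuts + 1L)

  # zero consensus clusters: both scripts just load and colour grey
  empty <- consensus_filter(s$cl, 1)
  proj0 <- project_clusters(empty, s$fam$msa, s$fam$reference, s$al)
  sc0 <- emit_pymol_scripts(proj0, s$chain, s$al, 1)
  expect_false(any(grepl('resi', sc0$exon_script)))
  expect_false(any(grepl('resi', sc0$splice_script)))
  expect_true(any(grepl('cmd.color\\("grey80"', sc0$exon_script)))
})
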