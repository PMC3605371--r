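svg_family <- function(seed = 31L, ...) {
  fam <- generate_family(small_spec(seed = seed, ...))
  val <- validate_inputs(fam$msa, fam$genes)
  mapped <- map_introns(val$genes, fam$msa)
  cl <- cluster_introns(mapped, n_genes = length(val$genes))
  list(fam = fam, genes = val$genes, cl = cl)
}

test_that("fifty/fifty scaling splits the width between exons and introns", {
  s <- svg_family()
  model <- build_render_model(s$genes, s$fam$msa, s$cl, "fifty_fifty",
                              width = 1000)
  exon_roles <- c("exon_plain", "exon_green", "exon_orange", "gap_in_exon")
  for (tr in model$tracks) {
    exon_px <- sum(tr$width[tr$role %in% exon_roles])
    intron_px <- sum(tr$width[!tr$role %in% exon_roles])
    expect_lt(abs(exon_px - intron_px), 0.5)
    expect_lt(abs(exon_px + intron_px - 1000), 0.5)
  }
  # intron-gap deficit arithmetic: member width + gap width = slot width
  for (j in seq_len(nrow(model$clusters))) {
    cid <- model$clusters$cluster_id[j]
    slot <- model$cluster_x[model$cluster_x$cluster_id == cid, ]
    for (g in names(model$tracks)) {
      tr <- model$tracks[[g]]
      blocks <- tr[!is.na(tr$cluster_id) & tr$cluster_id == cid, ]
      expect_lt(abs(sum(blocks$width) - (slot$x1 - slot$x0)), 1e-9)
    }
  }
})

test_that("per-gene total widths are equal across genes", {
  s <- svg_family(seed = 37L)
  for (policy in c("fifty_fifty", "exon_only")) {
    model <- build_render_model(s$genes, s$fam$msa, s$cl, policy)
    totals <- vapply(model$tracks, function(tr) sum(tr$width), numeric(1))
    expect_lt(max(totals) - min(totals), 0.5)
  }
})

test_that("cluster glyphs are vertically aligned across all genes", {
  s <- svg_family(seed = 41L)
  for (policy in c("fifty_fifty", "exon_only")) {
    model <- build_render_model(s$genes, s$fam$msa, s$cl, policy)
    for (j in seq_len(nrow(model$clusters))) {
      cid <- model$clusters$cluster_id[j]
      slot <- model$cluster_x[model$cluster_x$cluster_id == cid, ]
      members <- s$cl$members$gene[s$cl$members$cluster_id == cid]
      for (g in names(model$tracks)) {
        tr <- model$tracks[[g]]
        blocks <- tr[!is.na(tr$cluster_id) & tr$cluster_id == cid, ]
        expect_equal(min(blocks$x0), slot$x0, tolerance = 1e-12)
        expect_equal(max(blocks$x1), slot$x1, tolerance = 1e-12)
        if (g %in% members) {
          expect_true("intron" %in% blocks$role)
          expect_false("exon_placeholder" %in% blocks$role)
        } else {
          expect_equal(blocks$role, "exon_placeholder")
        }
      }
    }
  }
})

test_that("colour semantics follow the roles and the cluster palette", {
  s <- svg_family(seed = 43L)
  ff <- build_render_model(s$genes, s$fam$msa, s$cl, "fifty_fifty")
  for (tr in ff$tracks) {
    expect_true(all(tr$colour[tr$role == "intron"] == "#d62728"))     # red
    expect_true(all(tr$colour[tr$role == "intron_gap"] == "#ff00ff")) # magenta
    expect_true(all(tr$colour[tr$role == "gap_in_exon"] == "#1f77b4")) # blue
    expect_true(all(tr$colour[tr$role == "exon_placeholder"] == "#d3d3d3"))
  }
  # exon-scale mode: same cluster, same colour; different clusters cycle a
  # deterministic palette
  ex <- build_render_model(s$genes, s$fam$msa, s$cl, "exon_only")
  per_cluster <- list()
  for (tr in ex$tracks) {
    ib <- tr[tr$role == "intron", ]
    for (i in seq_len(nrow(ib)))
      per_cluster[[as.character(ib$cluster_id[i])]] <-
        c(per_cluster[[as.character(ib$cluster_id[i])]], ib$colour[i])
  }
  expect_true(all(vapply(per_cluster, function(x)
    length(unique(x)) == 1L, logical(1))))
  ranks <- order(ex$clusters$cluster_id)
  expected <- genestructr:::CLUSTER_PALETTE[
    ((seq_len(nrow(ex$clusters)) - 1L) %% 12L) + 1L]
  got <- vapply(as.character(ex$clusters$cluster_id),
                function(k) per_cluster[[k]][1L], character(1))
  expect_identical(unname(got), expected[ranks])
})

test_that("exon stretches classify into green, orange and coral", {
  # single gene, one intron: stretch before the intron is orange, after green
  g <- tiny_gene("solo", c(30L, 30L), 12L)
  msa <- msa_from_genes(list(g))
  cl <- cluster_introns(map_introns(list(solo = g), msa), n_genes = 1L)
  roles <- classify_exon_blocks(list(solo = g), msa, cl)
  expect_equal(roles$role, c("exon_orange", "exon_green"))
  expect_equal(roles$nt_start, c(0L, 30L))
  expect_equal(roles$nt_end, c(30L, 60L))

  # two genes with disjoint introns: spans containing the other's cluster
  # cannot be green
  a <- tiny_gene("a", c(15L, 30L), 10L)   # intron at nt 15
  b <- tiny_gene("b", c(30L, 15L), 10L)   # intron at nt 30
  msa2 <- msa_from_genes(list(a, b))
  genes2 <- list(a = a, b = b)
  cl2 <- cluster_introns(map_introns(genes2, msa2), n_genes = 2L)
  r2 <- classify_exon_blocks(genes2, msa2, cl2)
  # a's downstream stretch [15, 45) contains b's cut at 30 -> coral
  a2 <- r2[r2$gene == "a" & r2$nt_start == 15L, ]
  expect_equal(a2$role, "exon_plain")
  # b's first stretch [0, 30) contains a's cut at 15, but ends at its own
  # intron: orange precedence
  b1 <- r2[r2$gene == "b" & r2$nt_start == 0L, ]
  expect_equal(b1$role, "exon_orange")
  # a's first stretch ends at its own intron -> orange even though clean
  a1 <- r2[r2$gene == "a" & r2$nt_start == 0L, ]
  expect_equal(a1$role, "exon_orange")
  # b's downstream stretch [30, 45) has no cuts or gaps inside -> green
  b2 <- r2[r2$gene == "b" & r2$nt_start == 30L, ]
  expect_equal(b2$role, "exon_green")
})

test_that("rendered SVG is well-formed XML and byte-deterministic", {
  s <- svg_family(seed = 47L)
  for (policy in c("fifty_fifty", "exon_only", "balanced_average")) {
    model <- build_render_model(s$genes, s$fam$msa, s$cl, policy)
    doc <- render_svg(model)
    parsed <- xml2::read_xml(doc)
    expect_equal(xml2::xml_name(parsed), "svg")
    rects <- xml2::xml_find_all(parsed, ".//*[local-name() = 'rect']")
    expect_gt(length(rects), 0L)
    doc2 <- render_svg(build_render_model(s$genes, s$fam$msa, s$cl, policy))
    expect_identical(doc, doc2)
  }
  # single exon sanity: one 300 nt exon at 1 px/nt gives one 300 px rect
  g <- tiny_gene("one", 300L, integer(0))
  msa1 <- msa_from_genes(list(g))
  cl1 <- cluster_introns(map_introns(list(one = g), msa1), n_genes = 1L)
  m1 <- build_render_model(list(one = g), msa1, cl1, "exon_only",
                           width = 300)
  expect_equal(sum(m1$tracks$one$width), 300)
  # empty model (no genes) still renders a valid canvas
  empty <- structure(list(policy = "exon_only", width = 100,
                          s_exon = 1, s_intron = NA_real_,
                          tracks = list(), clusters = NULL,
                          cluster_x = NULL),
                     class = "render_model")
  expect_no_error(xml2::read_xml(render_svg(empty)))
})

test_that("balanced scaling equalises mean exon and intron screen lengths", {
  fam <- generate_family(small_spec(seed = 53L, assembly_gap_prob = 0))
  model <- build_render_model(fam$genes, fam$msa,
                              run_family_pipeline(fam), "balanced_average")
  for (g in names(model$tracks)) {
    tr <- model$tracks[[g]]
    if (!any(tr$role == "intron")) next
    mean_exon <- mean(tr$width[tr$role %in% c("exon_plain", "gap_in_exon")])
    mean_intron <- mean(tr$width[tr$role == "intron"])
    segs <- fam$genes[[g]]$segments
    # scaled means match the balancing identity up to block splitting
    s <- model$per_gene_scales[[g]]
    expect_equal(s[["s_exon"]] * mean(segs$nt_len[segs$kind != "intron"]),
                 s[["s_intron"]] * mean(segs$nt_len[segs$kind == "intron"]),
                 tolerance = 1e-9)
  }
})
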