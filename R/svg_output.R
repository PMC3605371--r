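# SVG rendering of gene-structure alignments.
#
# Layout model: the drawing is a sequence of "slots" shared by all genes, so
# homologous features sit in identical x-intervals in every track.  Each MSA
# column contributes 3 nt of exonic width; a column holding intron clusters is
# split at the phase positions (a phase-1 intron splits its codon 1 nt | 2 nt)
# and an intron slot is inserted at each split.  Genes lacking a cluster fill
# its slot with a light-grey placeholder; genes whose intron is shorter than
# the cluster maximum are padded with a magenta "intron gap".  Alignment gaps
# inside exons occupy their columns as thin bars.  This realises, at single
# nucleotide resolution, the vertical alignment of corresponding exonic
# sequence across all genes.

SVG_ROLES <- c("exon_plain", "exon_green", "exon_orange", "gap_in_exon",
               "intron", "intron_gap", "exon_placeholder")
THIN_ROLES <- c("gap_in_exon", "intron", "intron_gap", "exon_placeholder")

CLUSTER_PALETTE <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
                     "#a65628", "#f781bf", "#17becf", "#bcbd22", "#8c564b",
                     "#2ca02c", "#d62728")

role_colour <- function(role, policy, cluster_rank = NA_integer_) {
  switch(role,
    exon_green = "#2ca02c",
    exon_orange = "#ff7f0e",
    exon_plain = switch(policy, fifty_fifty = "#f08080",
                        exon_only = "#808080", balanced_average = "#696969"),
    gap_in_exon = if (policy == "exon_only") "#000000" else "#1f77b4",
    intron = switch(policy,
                    fifty_fifty = "#d62728",
                    exon_only = CLUSTER_PALETTE[((cluster_rank - 1L) %%
                                                  length(CLUSTER_PALETTE)) + 1L],
                    balanced_average = "#c0c0c0"),
    intron_gap = "#ff00ff",
    exon_placeholder = "#d3d3d3",
    stop("unknown role: ", role))
}

#' Classify exonic stretches into green / orange / coral roles
#'
#' A stretch is a maximal run of one gene's exonic sequence delimited by its
#' own introns and its own alignment gaps.  A stretch is *orange* when it is
#' the last uninterrupted exonic run immediately 5' of one of the gene's own
#' introns; *green* when no other gene has an alignment gap within the
#' stretch's column span and no intron cluster falls strictly inside it;
#' *coral* (role `exon_plain`) otherwise.  Orange takes precedence over green
#' (its purpose — flagging the exon end before an intron — would be defeated
#' otherwise).  Coordinates are global exonic nucleotides, with column `c`
#' occupying `[3c, 3c+3)`.
#'
#' @param genes Named list of validated `gene_structure` objects.
#' @param msa A `gs_msa`.
#' @param clusters An `intron_clusters` object.
#' @return `data.frame(gene, nt_start, nt_end, start_col, end_col, role)`,
#'   half-open nt intervals, 0-based columns (end_col inclusive).
#' @export
classify_exon_blocks <- function(genes, msa, clusters) {
  stopifnot(inherits(msa, "gs_msa"), inherits(clusters, "intron_clusters"))
  n_col <- msa_width(msa)
  mem <- clusters$members
  cl <- clusters$clusters
  all_cuts <- 3L * cl$msa_column + cl$phase
  gap_cols <- lapply(names(msa), function(g)
    which(split_chars(unclass(msa)[[g]]) == "-") - 1L)
  names(gap_cols) <- names(msa)
  out <- list()
  for (g in names(genes)) {
    row_gaps <- gap_cols[[g]]
    res_cols <- setdiff(0:(n_col - 1L), row_gaps)
    other_gaps <- sort(unique(unlist(gap_cols[setdiff(names(msa), g)])))
    own_cuts <- sort(3L * mem$msa_column[mem$gene == g] + mem$phase[mem$gene == g])
    if (!length(res_cols)) next
    # maximal runs of consecutive residue columns
    brk <- c(0L, which(diff(res_cols) > 1L), length(res_cols))
    for (r in seq_len(length(brk) - 1L)) {
      run <- res_cols[(brk[r] + 1L):brk[r + 1L]]
      nt_s <- 3L * run[1L]
      nt_e <- 3L * run[length(run)] + 3L
      cuts_in <- own_cuts[own_cuts > nt_s & own_cuts < nt_e]
      bounds <- c(nt_s, cuts_in, nt_e)
      for (k in seq_len(length(bounds) - 1L)) {
        s <- bounds[k]; e <- bounds[k + 1L]
        span_cols <- (s %/% 3L):((e - 1L) %/% 3L)
        orange <- e %in% own_cuts
        green <- !orange &&
          !any(other_gaps %in% span_cols) &&
          !any(all_cuts > s & all_cuts < e)
        role <- if (orange) "exon_orange" else if (green) "exon_green" else
          "exon_plain"
        out[[length(out) + 1L]] <- data.frame(
          gene = g, nt_start = s, nt_end = e,
          start_col = s %/% 3L, end_col = (e - 1L) %/% 3L, role = role,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the layout-ready render model
#'
#' Computes per-gene ordered blocks with roles, pixel widths and x-intervals
#' under one of three scaling policies:
#' \describe{
#'   \item{`fifty_fifty`}{nucleotide-level view: exons and introns each take
#'     50\% of the drawing width; introns red, intron gaps magenta, exon
#'     colours green/orange/coral, alignment gaps blue.}
#'   \item{`exon_only`}{exons to scale (3 nt per MSA column), introns as
#'     fixed-width glyphs coloured per cluster from a deterministic palette.}
#'   \item{`balanced_average`}{standalone per-gene schemes where introns are
#'     rescaled so the average scaled intron length equals the average scaled
#'     exon length (keeps short exons visible next to long introns).}
#' }
#'
#' @param genes Named list of validated `gene_structure` objects.
#' @param msa A `gs_msa`.
#' @param clusters An `intron_clusters` object.
#' @param policy Scaling policy (see above).
#' @param width Drawing width in px (default 1000).
#' @param glyph_px Fixed intron glyph width for `exon_only` (default 12).
#' @return Object of class `render_model`.
#' @export
build_render_model <- function(genes, msa, clusters,
                               policy = c("fifty_fifty", "exon_only",
                                          "balanced_average"),
                               width = 1000, glyph_px = 12) {
  policy <- match.arg(policy)
  stopifnot(inherits(msa, "gs_msa"), inherits(clusters, "intron_clusters"))
  if (policy == "balanced_average")
    return(build_render_model_per_gene(genes, width))
  n_col <- msa_width(msa)
  cl <- clusters$clusters
  mem <- clusters$members
  total_exon_nt <- 3 * n_col
  total_intron_nt <- sum(cl$max_len)
  if (policy == "fifty_fifty") {
    if (total_intron_nt > 0) {
      s_exon <- (width / 2) / total_exon_nt
      s_intron <- (width / 2) / total_intron_nt
    } else {
      s_exon <- width / total_exon_nt
      s_intron <- 0
    }
    slot_w <- function(j) cl$max_len[j] * s_intron
  } else {
    s_exon <- (width - glyph_px * nrow(cl)) / total_exon_nt
    if (s_exon <= 0)
      input_error("drawing width too small for the number of clusters")
    s_intron <- NA_real_
    slot_w <- function(j) glyph_px
  }
  # shared slot sequence
  slots <- list()
  for (c0 in 0:(n_col - 1L)) {
    here <- which(cl$msa_column == c0)
    phases <- cl$phase[here]
    cut <- 0L
    for (p in 0:2) {
      j <- here[phases == p]
      if (length(j)) {
        if (p > cut) {
          slots[[length(slots) + 1L]] <- list(kind = "codon", col = c0,
                                              nt = p - cut)
          cut <- p
        }
        slots[[length(slots) + 1L]] <- list(kind = "intron", cluster = j)
      }
    }
    if (cut < 3L)
      slots[[length(slots) + 1L]] <- list(kind = "codon", col = c0,
                                          nt = 3L - cut)
  }
  terminal <- which(cl$msa_column >= n_col)
  for (j in terminal[order(cl$phase[terminal])])
    slots[[length(slots) + 1L]] <- list(kind = "intron", cluster = j)
  # slot x-intervals (identical for every gene)
  x <- 0
  for (i in seq_along(slots)) {
    w <- if (slots[[i]]$kind == "codon") slots[[i]]$nt * s_exon else
      slot_w(slots[[i]]$cluster)
    slots[[i]]$x0 <- x
    slots[[i]]$x1 <- x + w
    x <- x + w
  }
  roles <- if (policy == "fifty_fifty")
    classify_exon_blocks(genes, msa, clusters) else NULL
  gap_chars <- lapply(names(msa), function(g) split_chars(unclass(msa)[[g]]))
  names(gap_chars) <- names(msa)
  tracks <- list()
  for (g in names(genes)) {
    chars <- gap_chars[[g]]
    grole <- if (!is.null(roles)) roles[roles$gene == g, , drop = FALSE] else NULL
    blocks <- list()
    nt_cursor <- integer(n_col)  # nt consumed per column so far
    for (sl in slots) {
      if (sl$kind == "codon") {
        c0 <- sl$col
        if (chars[c0 + 1L] == "-") {
          role <- "gap_in_exon"; rank <- NA_integer_
        } else if (!is.null(grole)) {
          nt_g <- 3L * c0 + nt_cursor[c0 + 1L]
          hit <- grole$nt_start <= nt_g & grole$nt_end > nt_g
          role <- if (any(hit)) grole$role[which(hit)[1L]] else "exon_plain"
          rank <- NA_integer_
        } else {
          role <- "exon_plain"; rank <- NA_integer_
        }
        nt_cursor[c0 + 1L] <- nt_cursor[c0 + 1L] + sl$nt
        blocks[[length(blocks) + 1L]] <- data.frame(
          role = role, x0 = sl$x0, x1 = sl$x1, cluster_id = NA_integer_,
          colour = role_colour(role, policy), stringsAsFactors = FALSE)
      } else {
        j <- sl$cluster
        cid <- cl$cluster_id[j]
        member <- any(mem$cluster_id == cid & mem$gene == g)
        if (member) {
          own_len <- mem$nt_len[mem$cluster_id == cid & mem$gene == g][1L]
          if (policy == "fifty_fifty") {
            iw <- own_len * s_intron
            blocks[[length(blocks) + 1L]] <- data.frame(
              role = "intron", x0 = sl$x0, x1 = sl$x0 + iw, cluster_id = cid,
              colour = role_colour("intron", policy, j),
              stringsAsFactors = FALSE)
            if (sl$x1 - (sl$x0 + iw) > 1e-9)
              blocks[[length(blocks) + 1L]] <- data.frame(
                role = "intron_gap", x0 = sl$x0 + iw, x1 = sl$x1,
                cluster_id = cid, colour = role_colour("intron_gap", policy),
                stringsAsFactors = FALSE)
          } else {
            blocks[[length(blocks) + 1L]] <- data.frame(
              role = "intron", x0 = sl$x0, x1 = sl$x1, cluster_id = cid,
              colour = role_colour("intron", policy, j),
              stringsAsFactors = FALSE)
          }
        } else {
          blocks[[length(blocks) + 1L]] <- data.frame(
            role = "exon_placeholder", x0 = sl$x0, x1 = sl$x1,
            cluster_id = cid,
            colour = role_colour("exon_placeholder", policy),
            stringsAsFactors = FALSE)
        }
      }
    }
    tr <- do.call(rbind, blocks)
    tr$width <- tr$x1 - tr$x0
    tracks[[g]] <- tr
  }
  cluster_x <- do.call(rbind, lapply(slots, function(sl)
    if (sl$kind == "intron")
      data.frame(cluster_id = cl$cluster_id[sl$cluster], x0 = sl$x0,
                 x1 = sl$x1) else NULL))
  structure(list(policy = policy, width = width, s_exon = s_exon,
                 s_intron = s_intron, glyph_px = glyph_px, n_col = n_col,
                 clusters = cl, cluster_x = cluster_x, tracks = tracks),
            class = "render_model")
}

# Standalone per-gene schemes with balanced average exon/intron scaling.
build_render_model_per_gene <- function(genes, width = 1000) {
  tracks <- list()
  scales <- list()
  for (g in names(genes)) {
    segs <- genes[[g]]$segments
    exon_nt <- segs$nt_len[segs$kind %in% c("exon", "seqshift", "gap")]
    intron_nt <- segs$nt_len[segs$kind == "intron"]
    ratio <- if (length(intron_nt) && mean(intron_nt) > 0)
      mean(exon_nt) / mean(intron_nt) else 1
    virt <- sum(exon_nt) + sum(intron_nt) * ratio
    s_exon <- width / virt
    s_intron <- s_exon * ratio
    x <- 0
    blocks <- list()
    for (i in seq_len(nrow(segs))) {
      kind <- segs$kind[i]
      role <- switch(kind, exon = "exon_plain", seqshift = "exon_plain",
                     gap = "gap_in_exon", intron = "intron")
      w <- segs$nt_len[i] * (if (kind == "intron") s_intron else s_exon)
      blocks[[length(blocks) + 1L]] <- data.frame(
        role = role, x0 = x, x1 = x + w, cluster_id = NA_integer_,
        colour = role_colour(role, "balanced_average"),
        stringsAsFactors = FALSE)
      x <- x + w
    }
    tr <- do.call(rbind, blocks)
    tr$width <- tr$x1 - tr$x0
    tracks[[g]] <- tr
    scales[[g]] <- c(s_exon = s_exon, s_intron = s_intron)
  }
  structure(list(policy = "balanced_average", width = width,
                 s_exon = NA_real_, s_intron = NA_real_,
                 per_gene_scales = scales, tracks = tracks,
                 clusters = NULL, cluster_x = NULL),
            class = "render_model")
}

#' @export
print.render_model <- function(x, ...) {
  cat(sprintf("Render model (%s): %d track(s), width %g px\n",
              x$policy, length(x$tracks), x$width))
  invisible(x)
}

#' Render a model to an SVG 1.1 document
#'
#' Deterministic text output: identical models render to byte-identical
#' documents.  Exonic bars are drawn thick, introns / gaps / placeholders as
#' thin lines; each track carries its gene name; scale bars for exons and
#' introns are emitted when the two scale factors differ.
#'
#' @param model A `render_model`.
#' @param path Optional output file.
#' @param track_height Vertical pitch per gene track (default 20 px).
#' @param label_width Reserved width for gene names (default 150 px).
#' @return The SVG document as a single character string (invisibly when
#'   `path` is given).
#' @export
render_svg <- function(model, path = NULL, track_height = 20,
                       label_width = 150) {
  stopifnot(inherits(model, "render_model"))
  n <- length(model$tracks)
  scale_bar <- !is.na(model$s_exon) && !is.na(model$s_intron) &&
    model$s_intron > 0 && abs(model$s_exon - model$s_intron) > 1e-12
  height <- n * track_height + (if (scale_bar) 40 else 10)
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'version="1.1" width="%s" height="%s">'),
                   fmt_num(label_width + model$width), fmt_num(height)))
  y <- 0
  for (g in names(model$tracks)) {
    out <- c(out, sprintf(
      '<text x="2" y="%s" font-family="monospace" font-size="11">%s</text>',
      fmt_num(y + track_height / 2 + 4), xml_escape(g)))
    tr <- model$tracks[[g]]
    for (i in seq_len(nrow(tr))) {
      if (tr$width[i] <= 0) next
      thin <- tr$role[i] %in% THIN_ROLES
      h <- if (thin) 4 else 12
      ry <- y + (track_height - h) / 2
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s</title></rect>',
        fmt_num(label_width + tr$x0[i]), fmt_num(ry),
        fmt_num(tr$width[i]), fmt_num(h), tr$colour[i], tr$role[i]))
    }
    y <- y + track_height
  }
  if (scale_bar) {
    bar_px <- 100
    exon_nt <- bar_px / model$s_exon
    intron_nt <- bar_px / model$s_intron
    yb <- y + 18
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="%s" height="3" fill="#404040"/>',
              fmt_num(label_width), fmt_num(yb), fmt_num(bar_px)),
      sprintf(paste0('<text x="%s" y="%s" font-family="monospace" ',
                     'font-size="10">exon: %s nt</text>'),
              fmt_num(label_width + bar_px + 6), fmt_num(yb + 4),
              fmt_num(exon_nt)),
      sprintf('<rect x="%s" y="%s" width="%s" height="3" fill="#d62728"/>',
              fmt_num(label_width + model$width / 2), fmt_num(yb),
              fmt_num(bar_px)),
      sprintf(paste0('<text x="%s" y="%s" font-family="monospace" ',
                     'font-size="10">intron: %s nt</text>'),
              fmt_num(label_width + model$width / 2 + bar_px + 6),
              fmt_num(yb + 4), fmt_num(intron_nt)))
  }
  out <- c(out, "</svg>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    cat(doc, file = path)
    return(invisible(doc))
  }
  doc
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
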