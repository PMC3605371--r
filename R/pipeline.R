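# The single entry point wiring all stages in order: validate name pairing ->
# map introns onto MSA columns -> cluster by (column, phase) -> render the
# selected outputs.  Deterministic end to end: identical inputs yield
# byte-identical output trees.

#' Align gene structures on a protein MSA and render the outputs
#'
#' Runs the full pipeline.  `msa` and `genes` may be in-memory objects or
#' paths (a FASTA file; a directory of YAML files, file stem = gene name, or
#' an explicit vector of YAML paths).
#'
#' @param msa A `gs_msa` or path to an aligned FASTA file.
#' @param genes Named list of `gene_structure` objects, a directory
#'   containing `<gene>.yaml` files, or a character vector of YAML paths.
#' @param out_dir Output directory; `NULL` computes everything in memory
#'   without writing files.
#' @param text Character vector of text dialects to render (subset of
#'   `"bars_and_dashes"`, `"bars_only"`, `"phase_digits"`).
#' @param interleaved Emit the intron-annotated MSA (`-a` style output).
#' @param phylo Emit the binary presence/absence FASTA matrix.
#' @param svg Character vector of SVG styles (subset of `"exon_only"`,
#'   `"fifty_fifty"`, `"balanced_average"`).
#' @param range Optional 0-based half-open MSA column interval
#'   `c(start, end)`; introns anchored outside it are ignored and genes with
#'   no residue inside it leave the conservation denominator.
#' @param consensus Conservation threshold for structure projection
#'   (strictly-greater semantics; default 0.8).
#' @param pdb Optional PDB file path to project consensus introns onto.
#' @param chain PDB chain identifier (default `"A"`).
#' @param pdb_prot Reference MSA sequence for the structure mapping
#'   (default: first sequence in the alignment).
#' @param penalize_endgaps Use strict global alignment instead of free end
#'   gaps for the reference/chain alignment.
#' @param spacer_k Spacer proportionality for the text dialects (default 0).
#' @param phase_digits_interleaved Use phase digits in the interleaved MSA.
#' @param svg_width Drawing width in px (default 1000).
#' @return Object of class `gene_painting` with all intermediate results
#'   (`validation`, `mapped`, `clusters`, `consensus`, renderings, `log`,
#'   `files`).
#' @export
paint_genes <- function(msa, genes, out_dir = NULL,
                        text = "bars_and_dashes", interleaved = FALSE,
                        phylo = FALSE, svg = character(0), range = NULL,
                        consensus = 0.8, pdb = NULL, chain = "A",
                        pdb_prot = NULL, penalize_endgaps = FALSE,
                        spacer_k = 0, phase_digits_interleaved = FALSE,
                        svg_width = 1000) {
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  if (!inherits(msa, "gs_msa") && is.character(msa)) msa <- read_msa(msa)
  if (is.character(genes)) {
    paths <- if (length(genes) == 1L && dir.exists(genes))
      list.files(genes, pattern = "\\.ya?ml$", full.names = TRUE) else genes
    if (!length(paths)) input_error("no gene structure YAML files found")
    genes <- lapply(sort(paths), read_gene_structure)
  }
  if (!is.null(consensus) &&
      (!is.numeric(consensus) || consensus < 0 || consensus > 1))
    input_error("consensus must be in [0, 1]")

  val <- withCallingHandlers(
    validate_inputs(msa, genes),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note(sprintf("validated %d of %d gene(s)", length(val$genes),
               length(genes)))
  mapped <- map_introns(val$genes, msa, range = range)
  if (!is.null(range)) {
    all_mapped <- map_introns(val$genes, msa, range = NULL)
    dropped <- nrow(all_mapped) - nrow(mapped)
    if (dropped > 0L)
      note(sprintf("%d intron(s) outside column range [%d, %d) ignored",
                   dropped, range[1L], range[2L]))
  }
  in_scope <- names(val$genes)
  if (!is.null(range)) {
    in_scope <- Filter(function(g) {
      chars <- split_chars(unclass(msa)[[g]])
      cols <- which(chars != "-") - 1L
      any(cols >= range[1L] & cols < range[2L])
    }, in_scope)
    if (length(in_scope) < length(val$genes))
      note(sprintf("%d gene(s) have no residue inside the column range",
                   length(val$genes) - length(in_scope)))
  }
  clusters <- cluster_introns(mapped[mapped$gene %in% in_scope, , drop = FALSE],
                              n_genes = length(in_scope))
  if (clusters$n_excluded_unreliable > 0L)
    note(sprintf(
      "%d intron(s) downstream of assembly gaps excluded from clustering",
      clusters$n_excluded_unreliable))
  note(sprintf("%d intron cluster(s) from %d mapped intron(s) over %d gene(s)",
               nrow(clusters$clusters), nrow(mapped), length(in_scope)))

  res <- list(msa = msa, validation = val, mapped = mapped,
              clusters = clusters, range = range,
              gene_order = names(val$genes), files = character())
  gene_names <- intersect(names(val$genes), in_scope)

  res$text <- lapply(stats::setNames(text, text), function(d)
    render_intron_alignment(clusters, gene_names, dialect = d,
                            spacer_k = spacer_k))
  if (interleaved)
    res$interleaved <- render_msa_interleaved(
      msa, mapped, use_phase_digits = phase_digits_interleaved)
  if (phylo)
    res$phylo <- binary_matrix(clusters, gene_names)
  if (length(svg)) {
    res$models <- lapply(stats::setNames(svg, svg), function(style)
      build_render_model(val$genes[gene_names], msa, clusters,
                         policy = style, width = svg_width))
    res$svg <- lapply(res$models, render_svg)
  }

  if (!is.null(pdb)) {
    reference <- if (is.null(pdb_prot)) names(msa)[1L] else pdb_prot
    note(sprintf("structure mapping: reference '%s', chain '%s'",
                 reference, chain))
    pdb_chain <- if (inherits(pdb, "pdb_chain")) pdb else
      read_pdb_chain(pdb, chain)
    ref_seq <- strip_stop(degap(unclass(msa)[[reference]]))
    al <- align_ref_to_chain(ref_seq, pdb_chain,
                             penalize_endgaps = penalize_endgaps)
    cons <- consensus_filter(clusters, consensus)
    proj <- project_clusters(cons, msa, reference, al)
    for (i in which(!proj$mappable))
      note(sprintf("cluster at column %d phase %d not mappable onto the structure",
                   proj$msa_column[i], proj$phase[i]))
    res$consensus <- cons
    res$structure <- list(reference = reference, chain = pdb_chain,
                          alignment = al, projection = proj)
    res$pymol <- emit_pymol_scripts(proj, pdb_chain, al,
                                    consensus_threshold = consensus)
  }
  res$log <- log
  class(res) <- "gene_painting"
  if (!is.null(out_dir)) res <- write_outputs(res, out_dir)
  res
}

# serialise every computed rendering under out_dir
write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  dial_file <- c(bars_and_dashes = "intron_alignment_bars.txt",
                 bars_only = "intron_alignment_spaces.txt",
                 phase_digits = "intron_alignment_phases.txt")
  for (d in names(res$text)) {
    p <- file.path(out_dir, dial_file[[d]])
    write_text_alignment(res$text[[d]], p)
    files <- c(files, p)
  }
  if (!is.null(res$interleaved)) {
    p <- file.path(out_dir, "msa_interleaved.txt")
    writeLines(res$interleaved$lines, p)
    files <- c(files, p)
  }
  if (!is.null(res$phylo)) {
    p <- file.path(out_dir, "intron_matrix.fasta")
    write_phylo_fasta(res$phylo, p)
    files <- c(files, p)
  }
  style_file <- c(exon_only = "alignment_exon_scale.svg",
                  fifty_fifty = "alignment_nt_level.svg",
                  balanced_average = "genes_balanced.svg")
  for (s in names(res$svg)) {
    p <- file.path(out_dir, style_file[[s]])
    cat(res$svg[[s]], file = p)
    files <- c(files, p)
  }
  if (!is.null(res$pymol))
    files <- c(files, write_pymol_scripts(res$pymol, out_dir))
  p <- file.path(out_dir, "run_report.txt")
  writeLines(c("# gene-structure alignment run report", res$log), p)
  files <- c(files, p)
  res$files <- files
  res
}

#' @export
print.gene_painting <- function(x, ...) {
  cat("Gene-structure alignment\n")
  cat(sprintf("  %d gene(s) validated, %d mapped intron(s), %d cluster(s)\n",
              length(x$validation$genes), nrow(x$mapped),
              nrow(x$clusters$clusters)))
  if (nrow(x$clusters$clusters)) {
    cons <- x$clusters$clusters$conservation
    cat(sprintf("  conservation: %d cluster(s) > 80%%, max support %d/%d\n",
                sum(cons > 0.8), max(x$clusters$clusters$support),
                x$clusters$n_genes))
  }
  if (!is.null(x$structure))
    cat(sprintf("  structure mapping: %d/%d consensus cluster(s) mappable\n",
                sum(x$structure$projection$mappable),
                nrow(x$structure$projection)))
  if (length(x$files))
    cat(sprintf("  %d file(s) written\n", length(x$files)))
  invisible(x)
}

#' @export
summary.gene_painting <- function(object, ...) {
  print(object)
  if (nrow(object$clusters$clusters)) {
    cat("\nClusters (column, phase, support, conservation):\n")
    print(object$clusters$clusters[, c("msa_column", "phase", "support",
                                       "conservation")], row.names = FALSE)
  }
  invisible(object)
}

#' Command-line style runner
#'
#' Thin wrapper used by the `exec/genepaint` script: runs [paint_genes()] and
#' translates failures into exit codes (2 = unreadable/invalid inputs,
#' 3 = no gene could be paired with the MSA).
#'
#' @param args Named list of [paint_genes()] arguments.
#' @return List with `status` (0/2/3) and `result` (or error `message`).
#' @export
run_cli <- function(args) {
  res <- tryCatch(
    do.call(paint_genes, args),
    gs_input_error = function(e) e,
    gs_alignment_error = function(e) e)
  if (inherits(res, "condition")) {
    msg <- conditionMessage(res)
    status <- if (grepl("paired with an MSA", msg)) 3L else 2L
    return(list(status = status, message = msg))
  }
  list(status = 0L, result = res)
}
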