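# Grouping mapped introns into common-intron clusters keyed by identical
# (MSA column, phase), and consensus filtering by conservation.

#' Cluster mapped introns by identical alignment position and phase
#'
#' Introns from different genes form one common intron only when they sit at
#' the exact same MSA column with the exact same reading-frame phase; no
#' tolerance window is applied.  Records flagged unreliable (downstream of an
#' assembly gap) are excluded before grouping.
#'
#' @param mapped `data.frame` from [map_introns()].
#' @param n_genes Number of genes in scope (the conservation denominator:
#'   genes that survived validation and, when a column range is set, have at
#'   least one residue inside it).
#' @return Object of class `intron_clusters`: list with
#'   `clusters` (`data.frame(cluster_id, msa_column, phase, support,
#'   conservation, max_len)` ordered by (column, phase)),
#'   `members` (`data.frame(cluster_id, gene, nt_len, coding_offset,
#'   residue_index, msa_column, phase)`),
#'   `n_genes`, `threshold` (NULL until [consensus_filter()]), and
#'   `n_excluded_unreliable`.
#' @export
cluster_introns <- function(mapped, n_genes) {
  stopifnot(is.data.frame(mapped), n_genes >= 1L)
  n_unrel <- if (nrow(mapped)) sum(!mapped$reliable) else 0L
  rel <- if (nrow(mapped)) mapped[mapped$reliable, , drop = FALSE] else mapped
  if (nrow(rel)) {
    key <- paste(rel$msa_column, rel$phase, sep = "/")
    if (anyDuplicated(paste(rel$gene, key)))
      logic_error("a gene carries two introns at the same (column, phase)")
    ord <- order(rel$msa_column, rel$phase, rel$gene)
    rel <- rel[ord, , drop = FALSE]
    key <- key[ord]
    uniq <- !duplicated(key)
    clusters <- data.frame(
      cluster_id = cumsum(uniq)[uniq],
      msa_column = rel$msa_column[uniq],
      phase = rel$phase[uniq],
      stringsAsFactors = FALSE)
    cid <- cumsum(uniq)
    clusters$support <- as.integer(tabulate(cid, nbins = nrow(clusters)))
    clusters$conservation <- clusters$support / n_genes
    clusters$max_len <- as.integer(
      vapply(split(rel$nt_len, cid), max, numeric(1L)))
    members <- data.frame(cluster_id = cid,
                          gene = rel$gene, nt_len = rel$nt_len,
                          coding_offset = rel$coding_offset,
                          residue_index = rel$residue_index,
                          msa_column = rel$msa_column, phase = rel$phase,
                          stringsAsFactors = FALSE)
  } else {
    clusters <- data.frame(cluster_id = integer(), msa_column = integer(),
                           phase = integer(), support = integer(),
                           conservation = numeric(), max_len = integer())
    members <- data.frame(cluster_id = integer(), gene = character(),
                          nt_len = integer(), coding_offset = integer(),
                          residue_index = integer(), msa_column = integer(),
                          phase = integer(), stringsAsFactors = FALSE)
  }
  rownames(clusters) <- rownames(members) <- NULL
  structure(list(clusters = clusters, members = members, n_genes = n_genes,
                 threshold = NULL, n_excluded_unreliable = n_unrel),
            class = "intron_clusters")
}

#' @export
print.intron_clusters <- function(x, ...) {
  cat(sprintf("%d intron cluster(s) over %d gene(s)%s\n",
              nrow(x$clusters), x$n_genes,
              if (!is.null(x$threshold))
                sprintf(" (consensus > %g)", x$threshold) else ""))
  if (nrow(x$clusters))
    print(utils::head(x$clusters, 12L), row.names = FALSE)
  invisible(x)
}

#' Filter clusters by conservation (consensus introns)
#'
#' Keeps clusters whose conservation is *strictly greater* than `threshold`
#' ("more than" semantics); `threshold = 0` therefore keeps every cluster,
#' including singletons.
#'
#' @param clusters An `intron_clusters` object.
#' @param threshold Fraction in `[0, 1]`; default 0.8.
#' @return A filtered `intron_clusters` with `threshold` recorded.
#' @export
consensus_filter <- function(clusters, threshold = 0.8) {
  stopifnot(inherits(clusters, "intron_clusters"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    input_error("consensus threshold must be a single number in [0, 1]")
  keep <- clusters$clusters$conservation > threshold
  out <- clusters
  out$clusters <- clusters$clusters[keep, , drop = FALSE]
  out$members <- clusters$members[
    clusters$members$cluster_id %in% out$clusters$cluster_id, , drop = FALSE]
  out$threshold <- threshold
  rownames(out$clusters) <- rownames(out$members) <- NULL
  out
}

#' Binary presence/absence matrix of common introns
#'
#' One row per gene, one column per cluster (ordered by (column, phase));
#' character `j` is `"1"` iff the gene is a member of cluster `j`.  The rows
#' form a valid gapless alignment over `{0,1}` suitable for phylogenetic
#' inference from gene-structure data.
#'
#' @param clusters An `intron_clusters` object.
#' @param genes Ordered character vector of gene names (row order).
#' @return Named character vector of bit strings.
#' @export
binary_matrix <- function(clusters, genes) {
  stopifnot(inherits(clusters, "intron_clusters"))
  cl <- clusters$clusters
  mem <- clusters$members
  vapply(genes, function(g) {
    bits <- ifelse(cl$cluster_id %in% mem$cluster_id[mem$gene == g], "1", "0")
    paste(bits, collapse = "")
  }, character(1L))
}
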