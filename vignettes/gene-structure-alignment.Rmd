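---
title: "Aligning gene structures on protein multiple sequence alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning gene structures on protein multiple sequence alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genestructr)
```

## The problem

Spliceosomal introns interrupt eukaryotic protein-coding genes at positions
that are often conserved over very long evolutionary times, which makes the
exon/intron layout of a gene family an informative character set for
phylogenetics and a useful diagnostic when curating protein alignments.
Comparing gene structures directly is brittle: exon lengths drift with every
insertion and deletion in the encoded protein.  The robust coordinate system
is the protein multiple sequence alignment (MSA) itself.  This package
projects every intron of every gene onto the columns of a user-supplied
protein MSA and calls two introns *common* only when they occupy the exact
same column with the exact same reading-frame phase.

## Model and coordinate conventions

For an intron with `c` coding nucleotides 5' of its splice site,

* `phase = c mod 3` — 0 between codons, 1 after the first nucleotide of a
  codon, 2 after the second;
* `residue_index = floor(c / 3)` — the (0-based) residue whose codon
  contains, or immediately follows, the splice.

A phase-1 or phase-2 intron splits the codon of `residue_index` between two
exons.  The intron is anchored to that residue's MSA column with the phase
stored alongside, so split codons never need fractional coordinates and the
"same position" test is an exact comparison of `(column, phase)` pairs.  All
residue indices and columns in the package are 0-based with half-open
intervals; an intron after the final codon maps to the virtual terminal
column (the aligned width).

Clustering is deliberately exact: no tolerance window groups introns at
neighbouring positions, because genuinely short exons would otherwise be
collapsed into spurious common introns.  Introns lying downstream of an
assembly gap of unknown sequence in the same gene are excluded from
clustering — their coding offsets depend on the gap's nominal length, so
their positions are not trustworthy.  Frame-shift (`seqshift`) nucleotides,
by contrast, stand in for coding positions one-for-one and are counted, which
keeps downstream phases consistent with the translation.

Per-cluster *conservation* is the member count divided by the number of genes
in scope — genes that survived validation and, when a column range is
restricted, have at least one residue inside it.  Excluded genes do not
dilute conservation.  The consensus filter keeps clusters *strictly greater*
than the threshold ("conserved in more than 80%" at the default 0.8), so a
cluster at exactly the threshold is dropped; `consensus = 0` keeps every
cluster including singletons.

## A worked example

```{r example}
fam <- generate_family(family_spec(n_genes = 8, protein_length = 120,
                                   n_ancestral_introns = 5, seed = 42))
res <- paint_genes(fam$msa, fam$genes,
                   text = c("bars_and_dashes", "phase_digits"),
                   phylo = TRUE, svg = "fifty_fifty")
summary(res)
print(res$text$bars_and_dashes)
```

Vertically aligned `|` marks are common introns; phases replace bars in the
`phase_digits` dialect.  `res$phylo` holds the binary presence/absence
matrix (FASTA records over `{0,1}`) for gene-structure phylogenetics.

## Tunable parameters

* `consensus` (fraction, default 0.8): conservation threshold for structure
  projection, strict-greater semantics.
* `range` (`c(start, end)`, 0-based half-open columns): restricts the
  analysis to part of the alignment, e.g. a single domain of a multi-domain
  protein; kept coordinates stay absolute.
* `spacer_k` (default 0): text dialects place one spacer between consecutive
  cluster columns; `spacer_k > 0` scales spacer runs with
  `max(1, round(spacer_k * column distance))`.  Spacer lengths are cosmetic
  — the dialects represent exons and introns independent of physical length —
  so the compact form is the canonical, deterministic default.
* `svg_width` (px, default 1000) and the scaling policies below.
* Alignment scores for the structure mapping (`match = 2`, `mismatch = -1`,
  `gap = -2`, linear): identity-style scoring, appropriate because the
  reference and the crystallised sequence are near-identical; the end-gap
  mode matters far more than the matrix here, and the parameters are
  exposed in `needleman_wunsch()`.

## SVG scaling policies

Intron lengths span orders of magnitude more than exon lengths, so unscaled
drawings make exons vanish.  Three policies are provided:

* `exon_only` — exons to scale (3 nt per alignment column), introns as
  fixed-width glyphs, one deterministic palette colour per cluster so equal
  positions share a colour.
* `fifty_fifty` — nucleotide-level view in which exon widths and intron
  widths each sum to half the drawing width; introns are red, the magenta
  "intron gap" pads an intron to the longest intron of its cluster, blue
  bars mark alignment gaps inside exonic sequence, and light-grey
  placeholders fill cluster slots in genes lacking the intron, so
  corresponding exonic sequence stays vertically aligned across all genes.
* `balanced_average` — standalone per-gene schemes where intron widths are
  rescaled so the mean scaled intron length equals the mean scaled exon
  length.  Balancing is an explicit per-run mode, not an automatic decision,
  so a drawing never silently changes scale.

Exonic colour semantics in the nucleotide-level view: a stretch (a maximal
exonic run delimited by the gene's own introns and own alignment gaps) is
*green* when no intron cluster falls strictly inside it and no other gene has
an alignment gap in its column span; *orange* when it is the last
uninterrupted run before one of the gene's own introns; *coral* otherwise.
Orange takes precedence over green: its purpose is to flag exon ends before
very short introns, which greenness would hide.  Widths are computed in real
numbers and rounded only at paint time.

## Structure mapping

One MSA sequence (default: the first; `pdb_prot` to change) is aligned to
the resolved residues of a PDB chain (default `A`) with a Needleman–Wunsch
alignment whose end gaps are free by default, because crystallised constructs
differ from full-length sequences by missing domains, tags and unresolved
loops; `penalize_endgaps = TRUE` restores the strict global mode.  Traceback
ties break deterministically (diagonal, then gap in the chain sequence, then
gap in the reference), so outputs are reproducible byte for byte.  ATOM
records, not SEQRES, define the chain sequence: intron sites can only be
painted on residues that exist in the model.

Consensus clusters are translated column → reference residue → PDB residue
numbers.  A column where the reference row is gapped anchors to the next
reference residue to the right (terminal positions fall back to the last
residue).  The residues flanking a splice are `(r - 1, r)` for phase 0 and
`(r, r + 1)` for a split codon at residue `r` — the last partially-encoded
residue of the upstream exon and the first full residue of the downstream
exon.  Clusters landing outside the aligned/resolved range are reported as
unmappable (and listed as comments in the scripts), never silently dropped.
`color_exons.py` colours the runs of residues between consecutive mapped
splice sites; `color_splicesites.py` colours only the flanking pairs, phase
0/1/2 → red/yellow/blue; everything unmapped stays grey.  The scripts are
plain text for PyMOL; this package never executes PyMOL.

## What the synthetic generator emulates — and what it does not

`generate_family()` plants introns in an ancestor and evolves descendants
under per-gene intron loss, collision-free lineage-specific gain, residue
substitutions, per-gene alignment indels, single-nucleotide frame shifts and
3-nt assembly gaps, with canonical `GT...AG` intron boundaries.  Homologous
residues share columns *by construction*, so the generator's MSA is exact.
Real alignments are estimated, and misaligned regions displace intron columns
in ways no ground truth can certify; passing the round-trip test therefore
shows the projection/clustering machinery is exact given the MSA, not that
inferences from a poor MSA are safe.  The generator also uses a single codon
per amino acid and no substitution model — sequence realism is irrelevant to
the coordinate arithmetic being tested.  Default generator settings (8 genes,
120 residues, 5 ancestral introns of 40–200 nt, 15% loss, 10% gain, low
artefact rates) reflect a typical mid-sized family study; the test suite
sweeps 50 seeded families of 6–30 genes and 0–12 ancestral introns.

## Numerical and degenerate-input choices

* Zero clusters: text dialects render empty rows, the binary matrix has
  zero columns, SVG draws exons only, and both PyMOL scripts colour the
  whole chain grey.
* A gene with no introns yields an all-zero matrix row of full cluster
  count.
* Duplicate `(gene, column, phase)` introns indicate an illegal gene
  structure and raise a logic error rather than being merged.
* The 50/50 width identity is tested pre-rounding to ±0.5 px; SVG numbers
  are printed with two decimals for byte determinism.
* Validation compares each gene's translation with its ungapped MSA row
  (trailing `*` stripped); mismatching genes are excluded with a warning
  naming the first divergent residue — repair is never attempted, because a
  wrong pairing would silently corrupt every downstream column.

## Problem sizes used in the checks

The shipped tests and the acceptance script run 50 synthetic families
(6–30 genes, proteins of 50–120 residues), exhaustive alignment-oracle
enumeration for sequence pairs up to length 3 and sampled pairs up to
length 6 (global) / 5 (free end gaps), plus cross-checks against
`Biostrings::pairwiseAlignment` on pairs up to length 60.  These sizes keep
the enumeration oracle exact while exercising every code path; the DP scales
routinely to full chain lengths (hundreds of residues) in the pipeline
itself.

## Known limitations

* Only the documented YAML subset is parsed; full Scipio documents with
  additional keys parse as long as `matchings` follows the subset.
* GFF/GTF input is not supported (it lacks the nucleotide sequence needed
  for phase arithmetic), and no network retrieval is performed.
* No tolerance-window clustering of near-neighbouring introns; positions
  must match exactly.
* The binary matrix is emitted for downstream phylogenetics; no tree is
  inferred here.
* PDB parsing uses the first model only; mmCIF is not supported.
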