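# genestructr

Aligning eukaryotic gene structures (exon/intron layouts) across a protein
family, using the protein multiple sequence alignment (MSA) as the common
coordinate system.

Intron positions are remarkably conserved across deep evolutionary time,
which makes the exon/intron layout of a gene family evidence for
phylogenetics and a diagnostic for alignment curation — but raw gene
structures cannot be compared directly, because exon lengths drift with
every indel in the encoded protein.  `genestructr` projects each intron of
each gene onto the MSA columns of its protein and groups introns from
different genes into a *common intron* only when they sit at the **exact
same alignment column with the exact same reading-frame phase**:

* `phase = c mod 3`, where `c` is the number of coding nucleotides 5' of the
  splice site (phase 0 between codons; phases 1 and 2 split a codon);
* `residue_index = floor(c / 3)` — the residue whose codon contains or
  follows the splice — anchored to its MSA column, so split codons are
  handled without fractional coordinates.

From the resulting clusters the package renders:

* fixed-width **text alignments** (`|` bars over `-` spacers, a spaces-only
  variant, and a phase-digit variant), plus an intron-annotated interleaved
  MSA;
* a **binary presence/absence FASTA matrix** (intron present `1` / absent
  `0`) for gene-structure phylogenetics;
* **SVG diagrams** — exon-scale with cluster-coloured intron glyphs,
  a nucleotide-level view in which exons and introns each take 50% of the
  width (red introns, magenta intron-gap padding, green/orange/coral exon
  classification, blue alignment-gap bars), and standalone per-gene schemes
  with balanced exon/intron scaling;
* **PyMOL scripts** (`color_exons.py`, `color_splicesites.py`) that paint
  consensus intron positions (conserved in more than 80% of genes by
  default) onto a PDB chain, via an end-gap-free Needleman–Wunsch alignment
  of a reference sequence against the chain's resolved residues.

Inputs: a protein MSA in FASTA, one Scipio-style YAML gene structure per
sequence (documented subset in `inst/extdata/gene-structure-schema.md`), and
optionally a PDB file.  A synthetic-family generator
(`generate_family()`) produces ground-truth-annotated test inputs.

## Worked example

```r
library(genestructr)
fam <- generate_family(family_spec(n_genes = 8, protein_length = 120,
                                   n_ancestral_introns = 5, seed = 42))
res <- paint_genes(fam$msa, fam$genes,
                   text = c("bars_and_dashes", "phase_digits"),
                   phylo = TRUE, svg = "fifty_fifty")
summary(res)
```

```
Gene-structure alignment
  8 gene(s) validated, 33 mapped intron(s), 5 cluster(s)
  conservation: 2 cluster(s) > 80%, max support 8/8

Clusters (column, phase, support, conservation):
 msa_column phase support conservation
         15     0       6        0.750
         20     2       7        0.875
        103     1       6        0.750
        112     2       6        0.750
        120     1       8        1.000
```

Five common-intron clusters were found; the one at column 120 (phase 1) is
present in all 8 genes, the one at column 20 (phase 2) in 7 of 8.  The text
dialect shows one column per cluster, members marked `|`:

```r
print(res$text$bars_and_dashes)
```

```
gene01 |-|-|-|-|
gene02 --|-|-|-|
gene03 |-|-----|
gene04 |-|-|-|-|
gene05 |-|-|---|
gene06 ----|-|-|
gene07 |-|---|-|
gene08 |-|-|-|-|
```

Bars beneath each other are introns at the same position and phase; with the
`phase_digits` dialect the marks become `0`/`1`/`2`.  `res$phylo` holds the
binary matrix (`>gene01` / `11111`, `>gene02` / `01111`, ...), and
`res$svg$fifty_fifty` the nucleotide-level SVG.  Passing
`out_dir = "out/"` writes every selected rendering plus a run report;
`pdb = "structure.pdb"` adds the two PyMOL scripts.

A command-line wrapper is included:

```sh
exec/genepaint --msa msa.fasta --genes structures/ --out out \
  --text bars,phases --phylo --svg nt_level --pdb structure.pdb
```

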