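# Gene-structure YAML subset

`read_gene_structure()` consumes one YAML document per gene, a documented
subset of the Scipio/WebScipio gene-structure format.  The file stem is the
gene name unless a `name` key is present; the name must match one sequence in
the protein MSA.

## Schema (JSON-Schema style)

```
type: object
required: [matchings]
properties:
  name:
    type: string          # optional; defaults to the file stem
  translation:
    type: string          # optional ungapped protein sequence; when absent
                          # it is translated from the coding nucleotides
  matchings:              # ordered 5'->3' in coding direction
    type: array
    minItems: 1
    items:
      type: object
      required: [type]
      properties:
        type:
          enum: [exon, intron, gap, seqshift]
        seq:
          type: string    # nucleotide sequence; may be absent for 'gap'
                          # segments of unknown sequence
        nt_len:
          type: integer   # required when seq is absent; must equal the
                          # sequence length when both are given
```

## Semantics

* `exon` — coding sequence; a non-empty `seq` is mandatory.
* `intron` — spliced sequence; contributes nothing to the coding offset.
* `seqshift` — 1-2 nucleotides standing in for coding positions affected by
  a sequencing frame-shift error; counted as coding so downstream phases stay
  consistent with the translation.
* `gap` — genome-assembly gap of unknown sequence inside the coding region;
  its nominal `nt_len` is counted as coding, and introns downstream of it in
  the same gene are excluded from clustering as unreliable.
* Two `intron` segments never adjoin.  A final exon may carry a trailing stop
  codon (3 nt beyond 3 x protein length), which is ignored by the phase
  arithmetic.

## Example

```yaml
name: toy
translation: MKVID
matchings:
- type: exon
  seq: ATGAAAGTA
- type: intron
  seq: GTAAGCCTAG
- type: exon
  seq: ATTGACTAA
```
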