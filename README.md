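# tgeclass

Classification and peptide-level confirmation of translated genomic
elements (TGEs) for proteomics-informed-by-transcriptomics (PIT)
workflows.

In PIT, MS/MS spectra are searched against open reading frames predicted
from de novo assembled transcripts of the same sample; ORFs supported by
at least two identified peptides are TGEs. Because the search space comes
from the sample itself, PIT can observe protein forms absent from any
reference database — but it also surfaces assembly artefacts that look
like variants. `tgeclass` separates the two. It is aimed at proteogenomics
practitioners, particularly for non-model organisms where no catalogue of
known variants exists.

## What it computes

Per TGE, against a reference proteome:

* **Main class** — `known_protein`, `known_isoform`,
  `known_with_polymorphism`, `novel_isoform` (16 subclasses: 15 terminal
  classes from the N/C-terminal truncated/extended/alternative grid, plus
  `SV`), or `novel_tge`. Exact sequence equality decides known classes; a
  best BLAST/Smith–Waterman hit with e ≤ 1e-30 under BLOSUM80 (affine
  gaps 10/1) qualifies a candidate variant; anything else is novel.
* **Polymorphism events** from the alignment midline: SAP/SSAP (single
  substitutions, SSAP when BLOSUM80 > 0), ALT/SALT (2–9 column runs),
  INS/DEL, and SV for any variation of ≥ 10 columns (exon scale).
* **Alternative starts** — non-methionine aligned starts, discounted when
  the preceding reference residue is K/R (tryptic-boundary artefact), with
  N-terminal Met removal reported separately.
* **Peptide evidence** — identified peptides mapped by exact substring
  search, flagged for variant-region overlap, uniqueness within the
  sample's TGE set, and junction status.
* **Variant-vs-reference score** — with V/R the tryptic peptides unique to
  the variant/reference sides of the variant regions, A/B their identified
  and A′/B′ their unidentified subsets:

  $$score_{variant} = \frac{1}{|V|+|R|}\Big(\sum_{A}(1-q_a)
    - \sum_{B}\tfrac{1-q_b}{4} + \sum_{B'}\tfrac{s_b}{8}
    - \sum_{A'}\tfrac{s_a}{8}\Big)$$

  (symmetrically for $score_{reference}$), where q is the peptide's
  minimum q-value and s its detectability calibrated on the sample's own
  known-protein identifications (decile binning + isotonic regression).
  The decision is `variant` when the score difference exceeds the margin
  (default 0).
* **Evidence rating** 1–5, from "retained" up to "unique peptide on a
  variant region".

## Worked example

Everything below is synthetic and self-contained — the fixture generator
plans a class for each TGE, edits a reference protein to realise it, and
simulates the PSM table:

```r
library(tgeclass)
ref  <- make_reference(n_reference = 30, isoform_fraction = 0.2, seed = 7)
plan <- c(known_protein = 4, SAP = 2, SV = 1, N_truncated = 2, novel_tge = 1)
fx   <- make_variant_tges(ref, plan, seed = 7)
psms <- simulate_psms(fx$orfs, seed = 7)
res  <- run_pipeline(fx$orfs, psms, ref)
res$classification[, c("tge_id", "main_class", "subclass",
                       "n_variant_peptides", "score_variant",
                       "score_reference", "decision", "rating")]
```

```
     tge_id              main_class    subclass n_variant_peptides score_variant score_reference  decision rating
 tge0001.p1           known_protein        <NA>                  0            NA              NA      <NA>      2
 tge0002.p1           known_protein        <NA>                  0            NA              NA      <NA>      2
 tge0003.p1           known_protein        <NA>                  0            NA              NA      <NA>      2
 tge0004.p1           known_protein        <NA>                  0            NA              NA      <NA>      2
 tge0005.p1 known_with_polymorphism        <NA>                  1         0.524          -0.151   variant      5
 tge0006.p1 known_with_polymorphism        <NA>                  0         0.000           0.000 undecided      2
 tge0007.p1           novel_isoform          SV                  0         0.014          -0.014   variant      3
 tge0008.p1           novel_isoform N_truncated                  0         0.000           0.000 undecided      1
 tge0009.p1           novel_isoform N_truncated                  0         0.034          -0.034   variant      3
 tge0010.p1               novel_tge        <NA>                  0            NA              NA      <NA>      2
```

Reading it: the four planted known proteins match a reference exactly and
rate 2 (complete ORF, nothing variant to confirm). `tge0005` carries a
planted SAP (`res$events` shows reference P replaced by C at position 110
of REF0020) covered by
an identified unique peptide — rating 5, and the score strongly favours
the variant (0.524 vs −0.151). `tge0006` carries a SAP whose peptide
happened not to be identified; with no discriminating evidence either way
the scores are ~0 and it stays `undecided`. `tge0007`/`tge0009` have no
variant-covering peptide but are still confirmed by the score (rating 3):
their reference-side peptides, which calibration says should have been
seen if the reference form were present, were not observed. Known/novel
classes, events, peptide flags and per-class summary counts are in
`res$events`, `res$evidence` and `res$summary`, and `write_reports()`
emits `classification.tsv`, `variation_events.tsv`,
`peptide_evidence.tsv` and `novel_tges.fasta`.

A command-line wrapper with `run`, `simulate`, `digest` and `qvalues`
subcommands is installed at
`system.file("scripts", "tgeclass", package = "tgeclass")`; it accepts a
YAML config file and mirrors every tunable as a flag
(`--psm-fdr`, `--evalue-threshold`, `--score-margin`, …). Precomputed
BLAST XML (`blastp -outfmt 5`) can replace the internal aligner via
`--blast-xml`.

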