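---
title: "Classifying translated genomic elements and confirming variants with peptide evidence"
author: "tgeclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying translated genomic elements and confirming variants with peptide evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgeclass)
```

## The problem

Proteomics informed by transcriptomics (PIT) searches tandem-MS spectra
against open reading frames (ORFs) predicted from de novo assembled
transcripts of the *same* sample, instead of against a reference proteome.
Any ORF supported by at least two identified peptides is a *translated
genomic element* (TGE). Because the ORFs come from the sample itself, PIT
can observe protein forms that no reference database contains — sequence
polymorphisms, splice isoforms, entirely novel proteins — which makes it
attractive for non-model organisms. The flip side is that transcript
assembly is error-prone: many apparent "variants" are artefacts of
sequencing or assembly, and the peptides that support a TGE do not
necessarily touch the part of the sequence that differs from the reference.

`tgeclass` post-processes a PIT identification run. It answers, per TGE:

1. **What is it?** Known protein, known isoform, known protein with
   polymorphisms, novel isoform (16 subclasses), or novel TGE.
2. **What exactly differs?** A list of polymorphism events with coordinates
   on both the TGE and its reference protein.
3. **Is the variant actually there?** Peptide evidence mapped onto the
   variant regions, plus a detectability-calibrated score comparing the
   variant against its reference counterpart.

## Classification by homology

Each TGE is compared to the reference proteome by optimal local alignment
under BLOSUM80 (chosen because TGE and reference are closely related
sequences) with affine gap costs, open 10 / extend 1. A TGE exactly equal
to a reference sequence is a *known protein* (or *known isoform* if the
reference entry is isoform-flagged); exact equality takes precedence over
any alignment ranking. A TGE whose best hit has e-value above `1e-30` — or
no hit at all — is a *novel TGE*. Everything in between is a candidate
variant, resolved by looking at the alignment in detail.

The e-value boundary is treated as *qualifying hit iff e ≤ 1e-30*; this is
the only reading that keeps the mapping rule and the novelty rule
consistent at the boundary itself.

When a precomputed BLAST XML is supplied, its alignments and statistics are
authoritative. The internal aligner is a fallback for running without
BLAST; its e-values use the Karlin–Altschul form `E = K·m·n·exp(−λS)` with
the gapped BLOSUM80/(10,1) constants λ = 0.299, K = 0.071 from the NCBI
BLAST source distribution, which is an approximation (no composition-based
adjustment). Only the best HSP per subject is used; combining multiple HSPs
by sum statistics is deliberately out of scope, so fragmented homology
(e.g. a short TGE matching subsections of several proteins) falls through
to *novel TGE*, which is the behaviour we want for assembly fragments.
Before alignment, subjects are pre-screened by shared 6-mers, mirroring
BLAST's word seeding; a query that seeds no subject is aligned against
nothing.

## Polymorphism events

Events are read off the aligned columns, grouped into maximal runs of one
mechanism:

| run                         | length | label                         |
|-----------------------------|--------|-------------------------------|
| substitution columns        | 1      | SAP, or **SSAP** if BLOSUM80 > 0 |
| substitution columns        | 2–9    | ALT, or **SALT** if every column scores > 0 |
| substitution columns        | ≥ 10   | SV (splice-scale variation)   |
| TGE-only residues (subject gap) | 1–9 | INS                          |
| reference-only residues (query gap) | 1–9 | DEL                      |
| either gap mechanism        | ≥ 10   | SV                            |

The similarity call (`+` in the BLAST midline) is exactly "positive BLOSUM80
score", so SSAP/SALT mark chemically conservative replacements. The 9/10
boundary reflects the shortest biologically plausible exon: an internal
variation of ten or more residues is treated as an alternative-splicing
scale event rather than a point polymorphism. We apply that rule to
insertions and deletions as well as substitution runs, because exon
skipping and intron retention manifest as long indels.

Two conventions worth knowing:

* adjacent runs of different mechanisms (a mismatch run abutting a gap run)
  are *not* merged — events map one-to-one onto alignment column runs;
* a deletion has no extent on the TGE, so its TGE anchor is the residue
  immediately left of the gap (0 at the start); insertions are anchored on
  the reference the same way. For peptide-overlap purposes a deletion
  contributes the two residues flanking its anchor.

## Terminal classes

The relationship of each terminus to the reference is read from the
alignment ends: reaching both sequence ends is *identical*; a reference
overhang only is *truncated*; a TGE overhang only is *extended*; overhangs
on both sides is *alternative*. A candidate variant whose two terminals are
identical is a *known protein with polymorphism* — unless it carries an SV
event, which makes it a novel isoform of subclass `SV`. Any non-identical
terminal makes it a novel isoform named by the non-identical termini
(`N_truncated`, `C_extended`, `N_alternative+C_truncated`, …). The 4 × 4
terminal grid minus the identical/identical cell gives 15 terminal
subclasses; with `SV` that is 16 novel-isoform subclasses, and with the
polymorphism and novel classes the classifier emits 17 variant types
overall — the counting that reconciles the various totals quoted for this
taxonomy.

## Alternative starts

A TGE whose first residue is aligned (`q_start = 1`) and is not methionine
is an alternative-start candidate. If the reference residue *preceding*
the aligned start position is lysine or arginine, the candidate is
discounted: trypsin cleaves after K/R, so a truncated ORF whose N-terminus
happens to coincide with a tryptic boundary would look exactly like this.
A TGE aligned from reference position 2 whose reference starts with
methionine is reported separately as N-terminal Met removal
(co-translational Met excision); since M is neither K nor R the discount
rule never applies to it.

## Peptide evidence

PSMs are filtered at 1% global PSM-level q-value, peptides are located in
ORF sequences by exact substring search (input accession lists are not
trusted), ORFs with fewer than two distinct identified peptides are
dropped, and ORFs with identical sequence are merged into one TGE.
Uniqueness is defined against the sample's own TGE set — the question the
evidence answers is "does this peptide pin down *this* TGE among the
sample's identifications", not "is it absent from the reference proteome".
Protein ambiguity groups collect TGEs with identical identified-peptide
sets and attach TGEs whose peptide set is a strict subset of a group's.

A peptide occurrence *overlaps a variant* when its interval intersects the
union of event intervals and terminal overhangs; it is a *junction
peptide* when it additionally covers at least one residue of
aligned-identical sequence, i.e. it spans a variation boundary. Junction
peptides are the strongest simple evidence for alternative and extended
termini, because they cannot come from either the reference form or the
overhang alone.

## Variant-versus-reference scoring

Demanding a variant-specific peptide for every variant is conservative:
LC-MS/MS sequence coverage is low, and some variants are covered by a
single peptide that may simply not be detectable. The scoring model
weighs what *was* seen against what *should have been* seen.

Let V be the tryptic peptides of the TGE overlapping its variant regions
and R the reference tryptic peptides overlapping the reference-side
projection of those regions — in both cases minus peptides shared between
the two digests, because shared peptides cannot discriminate. With A ⊆ V
and B ⊆ R identified (q = minimum q-value over the peptide's PSMs) and
A′, B′ unidentified (s = calibrated detectability):

$$score_{variant} = \frac{1}{|V|+|R|}\left(\sum_{a \in A}(1-q_a)
  - \sum_{b \in B}\frac{1-q_b}{4}
  + \sum_{b \in B'}\frac{s_b}{8}
  - \sum_{a \in A'}\frac{s_a}{8}\right)$$

and symmetrically for $score_{reference}$. The denominator 4 keeps the two
scores close when *both* variant- and reference-specific peptides are
observed (both forms present, e.g. heterozygosity); the denominator 8
encodes an anticipated peptide-level coverage of 12.5%, so an unobserved
peptide is only weak evidence of absence. Both constants are named
parameters. The decision is *variant* when
$score_{variant} - score_{reference}$ exceeds the margin (default 0),
*reference* symmetric, else *undecided*. Useful algebraic properties, both
enforced by tests: the sum of the two scores is
$\tfrac{3}{4}\sum_{A\cup B}(1-q)/(|V|+|R|)$, each score lies in
$[-\tfrac14, 1]$, and with nothing identified the scores are exact
negatives of each other.

### Detectability and calibration

The raw detectability predictor bundled here is a deliberately simple,
fully documented logistic model of peptide length (bell penalty outside
8–25 residues), mean Kyte–Doolittle hydropathy, charged-residue fraction
and proline count, with fixed coefficients. Machine-learned predictors
exist, but their trained models are external artefacts; the design keeps
the predictor *pluggable* (any function peptide → [0, 1] can be passed)
and leans on calibration to make absolute raw scores secondary.

Calibration anchors the raw score to *this sample's* empirical behaviour:
all candidate tryptic peptides of TGEs already classified as known
proteins are binned into deciles of raw score, each bin's s is the
fraction of its peptides actually identified, the bin means are made
monotone by pool-adjacent-violators (`stats::isoreg`), and the transform
interpolates linearly between bin centres, constant beyond them. Deciles
plus PAVA keep the transform robust at the small n a single sample
provides. With no known proteins the transform degrades to identity with a
warning; if every bin is equal it is constant. Identified peptides whose
q-value exceeds the PSM FDR threshold are treated as unidentified, for
consistency with the retention filter.

### Evidence rating

Each TGE gets a 1–5 rating: 5 for a unique variant-overlapping peptide,
4 for any variant-overlapping peptide, 3 for a score-based variant
decision without variant-overlapping peptides, 2 for a complete-ORF TGE
without variant evidence, 1 otherwise. Known proteins land on 2 or 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q_threshold` | 0.01 | global PSM q-value cut-off (1% FDR) |
| `min_peptides` | 2 | distinct peptides to retain an ORF as a TGE |
| `e_threshold` | 1e-30 | qualifying-homology e-value |
| `gap_open`, `gap_extend` | 10, 1 | affine gap costs (BLOSUM80) |
| `sv_min_length` | 10 | columns promoting an event to SV |
| `alt_max_length` | 9 | longest ALT/SALT run |
| `missed_cleavages` | 0 | tryptic missed cleavages for candidate peptides |
| `min_pep_len`, `max_pep_len` | 7, 45 | MS-observable candidate peptide window |
| `score_margin` | 0 | decision margin on the score difference |
| `ref_denominator` | 4 | identified-counter-evidence damping |
| `undetected_denominator` | 8 | absence-evidence damping (12.5% coverage) |

The digestion window 7–45 and 0 missed cleavages bracket typical
MS-observable tryptic peptides; identified peptides from the input are
used as given regardless of these bounds, which only shape candidate
enumeration. The classic KP/RP suppression rule is on by default and
configurable.

## The synthetic fixture generator

Every pipeline stage is testable without external data through
`make_reference()`, `make_variant_tges()` and `simulate_psms()`:

* **References** are random proteins of 150–250 residues starting with M,
  i.i.d. uniform over the 20 letters (classification logic is
  frequency-agnostic, so a Swiss-Prot composition would add realism but no
  discriminative power). A fraction carry a derived isoform (`-2`
  accession, C-terminal 30-residue swap). Every generated protein is
  required to yield several tryptic peptides in the 7–45 window — a
  protein without observable peptides could never be identified, and a TGE
  is by definition supported by two.
* **Variant TGEs** realise exactly one planned class each: SAP/SSAP pick a
  substitution partner by BLOSUM80 sign; ALT/SALT use a 5-column run;
  SV a 12-column replacement; INS/DEL are 3 residues; terminal classes
  truncate or extend by 25 residues; alternative-start cases truncate at a
  reference position chosen by the preceding residue (G for accepted, K/R
  for discounted, position 2 of an M-initial reference for Met removal).
  Edits avoid K/R at and around their boundaries so the tryptic peptide
  frame is stable across the edit, and replacement/overhang residues are
  drawn so they score strictly negatively against every nearby opposing
  reference residue. That last constraint is what makes the planned label
  *provably* the alignment-optimal reading: no shifted or gapped
  realignment of the edit can score better, so ground truth does not
  depend on aligner tie-breaking.
* **PSM simulation** digests the sequence actually present in the
  simulated sample (which may be the reference form, to emulate an
  assembly artefact), draws each candidate peptide with a ground-truth
  detection probability that is monotone in the raw detectability score
  (floor 0.05, ceiling 0.95), gives identified peptides q-values uniform
  on [0, 0.009], and can append decoy PSMs to exercise target-decoy
  q-value computation. Every TGE meant to be retained is guaranteed two
  observed peptides that map into its ORF.

What the generator does **not** emulate: real spectra and their score
distributions, retention behaviour, shared peptides from homologous gene
families, I/L ambiguity, transcript-assembly error modes beyond sequence
edits, and biologically realistic overhang composition (the
adversarially dissimilar overhangs are low-complexity). Passing the
round-trip therefore demonstrates the *logic* of classification, mapping
and scoring — not performance on real LC-MS/MS data.

## Problem sizes and numerical choices

The bundled checks run the full round trip on 28 labels × 10 TGEs against
60 references, score algebra on 10³ random instances at 1e-12 tolerance,
the digestion and event-extraction oracles on 100 and 500 random cases,
the alignment oracle on all pairs of 30 random sequences up to length 30,
calibration recovery on 10⁴ peptides, and the isoform-confirmation
analogue on 40 isoform TGEs (half truly present, half assembly artefacts,
classified against a canonical-only reference). These sizes keep the whole
suite in a few minutes on one core while leaving each statistical check
comfortably powered.

Tie-breaking and degenerate inputs: best-hit selection orders by e-value,
then bit score, then accession, so results are independent of input order;
empty V and R make scoring *undecided* rather than an error; an empty
calibration set degrades to the identity transform with a warning; decoy
PSMs are removed after q-value assignment; duplicate-sequence ORFs merge
with the lexicographically smallest member id as the TGE id.

## Known limitations

* Internal e-values are approximate; supply BLAST XML when exact BLAST
  statistics matter.
* Single best HSP per subject: genuinely multi-HSP homology (large
  rearrangements) is read as terminal variation or novelty.
* The default detectability model is intentionally simple; for serious
  use plug in a trained predictor — calibration will absorb monotone
  miscalibration but not a wrong ranking.
* Uniqueness ignores the reference proteome by design; if you need
  reference-aware uniqueness, digest the reference and intersect.
* Whether the original method restricted V/R peptides to MS-observable
  lengths is not recoverable; here the bounds are explicit parameters.
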