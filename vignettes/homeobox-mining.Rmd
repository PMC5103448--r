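---
title: "Mining Hox and ParaHox genes from assembled transcriptomes: methods and design"
author: "hoxminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining Hox and ParaHox genes from assembled transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxminer)
```

## The problem

De novo transcriptome assemblies of non-model animals (the motivating
case: marine mollusks spanning aplacophorans, chitons, scaphopods,
bivalves and gastropods) contain homeobox transcription factors —
notably the Hox and ParaHox families that pattern the
anterior–posterior axis and the gut — but no annotation. Recovering
them takes a chain of steps: find the one true coding region per
transcript among many spurious open reading frames, remove assembly
redundancy, locate the ~60-residue DNA-binding homeodomain, and decide
*which* Hox or ParaHox gene a sequence is. The last step is the hard
one: homeodomains are so conserved that overall similarity often cannot
separate paralog groups, while short diagnostic residues and flanking
motifs can. `hoxminer` implements this chain as a tested, fully offline
pipeline, together with a seeded synthetic-transcriptome generator so
that every stage has ground truth.

The classifier's label set is the putative ancestral lophotrochozoan
toolkit of 11 Hox genes (Hox1–Hox5, Lox5, Antp, Lox4, Lox2, Post2,
Post1) and 3 ParaHox genes (Gsx, Xlox, Cdx).

## The procedure, stage by stage

**CDS selection.** Every transcript is translated in all six frames;
each maximal ATG-to-stop ORF longer than 50 amino acids is a candidate
(the bound is strict: a 50-aa peptide fails; within a frame only the
longest ORF per stop codon is kept, and a terminal stop is required).
Candidates are then voted on by independent evidence sources, and the
unique CDS per transcript is the candidate with the most positive
sources. Two sources are built in and need no network or databases: a
homeodomain-profile scan and a shared-k-mer comparison against the
packaged reference homeodomains (k = 5, ≥ 10 shared distinct k-mers).
A third source ingests external similarity-search tables (TSV) and
calls a candidate positive when any hit reaches E ≤ 1e-06, so real
blastp/hmmsearch/rps-blast output can be plugged in. Ties are broken by
longer peptide, then 5'-most start, then frame order +1, +2, +3, −1,
−2, −3. Transcripts whose best candidate has zero evidence are dropped
by default (`keep_longest` retains and flags them instead).

**Deduplication.** Proteins are clustered at 100 % identity, with
identity defined as matches divided by alignment columns of the global
alignment (match 1, mismatch 0, unit gap penalty). The default `exact`
mode merges string-equal peptides; because "100 % identity over aligned
columns" is ambiguous for substrings, a `containment` mode that also
absorbs exact substrings into their superstring is exposed as an
option. Representatives are the longest member, ties by smallest id.

**Homeodomain localization.** A 60-column position-specific scoring
profile is built from an alignment of homeodomains:
`score(col, aa) = log2(((count + 1) / (N_col + 20)) / q_aa)` with a
Laplace pseudocount of 1 and a uniform background `q_aa = 0.05` (both
configurable; gapped sequences are excluded per column, so the
denominator is per-column). Scanning slides the profile over a peptide
and reports every window at or above a bit threshold. The best hit
fixes the canonical coordinate frame used everywhere else: homeodomain
positions 1–60, C-flank offsets +1, +2, … after position 60, N-flank
offsets −1, −2, … before position 1. Unknown residues (`X`) contribute
0 bits and never satisfy any diagnostic pattern.

The default threshold is calibrated empirically: the 99.9th percentile
of the best window score over 1000 random 200-aa peptides at a fixed
seed. Calibrating on per-peptide maxima (rather than on the pooled
window-score distribution) is deliberate: it controls the probability
that an unrelated *protein* produces any hit (≤ ~0.1 %), which is the
quantity that matters for the evidence vote; a pooled per-window
percentile would let ~13 % of 200-aa peptides through by chance.

**Classification.** A declarative catalog anchors diagnostic features
to homeodomain coordinates. The shipped default contains exactly the
features whose residues are printed in the literature:

| Group | Feature | Region |
|---|---|---|
| Hox1 | non-basic residues (not K/R/H) at positions 2–3 | homeodomain |
| Hox2, Hox3 | position 4 bracketed by basic residues at 3 and 5 | homeodomain |
| Hox3 | `AL` at positions 36–37 (lophotrochozoan) | homeodomain |
| Hox4, Hox5 | hexapeptide `YPWM` | N-flank window |
| Hox4 | `LPNTK` | C-flank window |
| Hox5 | `HIAKNM` at offset +1 (molluscan) | C-flank, exact offset |
| Gsx | `LRTCD` (lophotrochozoan) | C-flank window |

Features the literature localizes but does not print (Hox1 positions
6–8/29/56 and C-flank +1/+2; Hox2 positions 2/24/58–59; Hox3 position
14; the Antp Hox-PBC region; the Lox5/Ubd-A parapeptides; Post1/Post2
residues; Xlox/Cdx flank peptides) ship as *placeholders*: empty
patterns with weight 0, excluded from scoring until a user fills them —
for example from `discover_signatures()` on their own reference
alignment. This is a deliberate anti-guessing stance: the package never
invents residues, so groups with only placeholder features are honestly
reported `AMBIGUOUS` or `UNCLASSIFIED` rather than by fabricated rules.

Scoring sums the weights (default 1 per feature) of matched features
per group; a missing `required` feature zeroes its group (nothing is
required by default). The winner must reach `min_score` (default 1) and
lead the runner-up by `min_margin` (default 0). Exact score ties are
broken in favour of the group whose scoring feature set is most fully
matched: a peptide matching only the shared position-4 predicate
explains Hox2 completely (1/1 features) but Hox3 only partially (1/2),
so it is assigned Hox2, whereas `YPWM` alone matches Hox4 and Hox5
equally (1/2 each) and stays `AMBIGUOUS {Hox4, Hox5}` — mirroring the
biology, where the hexapeptide genuinely cannot separate paralog groups
4 and 5. Remaining ties and sub-threshold scores are `AMBIGUOUS`; no
homeodomain hit, or no matched feature at all, is `UNCLASSIFIED`. The
default `min_margin` of 0 is what lets the coverage tie-break act; a
margin of 1 would force every score tie to `AMBIGUOUS`.

**Signature discovery.** The classifier's features can be *derived*:
given a labeled alignment, a column is diagnostic for a group with
residue `a` when the gap-excluded in-group frequency of `a` is at least
`tau_in` (default 0.9) and its frequency in every other group is at
most `tau_out` (default 0.1). Columns with more than 50 % gaps in a
group, or fewer than two ungapped residues, are uncallable for it.
Adjacent calls for the same label merge into exact motifs (`AL` at
36–37 from two adjacent calls; a 6–8 run into a 3-mer). Whether strict
absence (`tau_out = 0`) should be demanded in out-groups is left as a
parameter. Raising `tau_in` or lowering `tau_out` never adds a call.

**Completeness.** A simplified single-copy marker-recovery metric
reproduces complete / duplicated / fragmented / missing semantics: each
marker is Smith–Waterman-aligned (BLOSUM62, linear gap penalty 8)
against every protein; with identity ≥ 0.4, coverage ≥ 0.9 of the
marker is a full hit (exactly one → complete, several → duplicated),
coverage in [0.3, 0.9) → fragmented, else missing. The completeness
percentage counts complete markers only. The thresholds are this
package's own defaults — the semantics, not any external tool's trained
cutoffs — and all are configurable. A 20-marker synthetic fixture ships
for tests; real marker sets are user-supplied FASTA.

## The synthetic-data generator

The generator emulates what matters about assembled transcripts while
staying fully seeded and self-contained. Each planted transcript is
5' UTR + CDS + 3' UTR on a uniformly chosen strand; the CDS
reverse-translates (uniform synonymous codons) a peptide of the form
`M` + random N-flank (15–40 aa) + group consensus homeodomain + random
C-flank (12–30 aa), with every non-placeholder catalog feature of the
group inserted at its declared region and offset. UTRs are 30–150 nt of
random sequence, with an in-frame stop planted at the end of the 5' UTR
so the planted ATG starts the maximal ORF of its frame. Artifact knobs:

- `decoy_rate` — transcripts of random nucleotides, rejection-sampled
  to contain no ATG-initiated ORF above the 50-aa filter;
- `duplicate_rate` — exact copies of an already-emitted translated
  peptide under a new id (fresh codons and UTRs), exercising dedup;
- `hd_mut_rate` — per-position substitutions inside the homeodomain,
  never at catalog-diagnostic positions;
- `frameshift_rate` — 1–3 single-nucleotide indels in the CDS, modeling
  homopolymer errors of pyrosequencing; these transcripts are expected
  to fail selection or classification, and the truth table records the
  indel positions so tests can assert exactly that.

The per-group homeodomain consensus is a fixed synthetic 60-mer set
(shipped as `hd_consensus_synthetic.faa`): a shared homeodomain-like
backbone, distinct between groups only at catalog-diagnostic positions.
This makes label recovery well-posed without downloading curated
alignments, and makes signature discovery's expected output computable
from the fixtures themselves. What the generator does *not* emulate —
read-level errors, expression variation, chimeric or fragmented
assemblies beyond the artifacts above, and real homeodomain sequence
diversity — bounds what passing tests show: they validate the
*machinery* (coordinates, voting, scoring, thresholds, bookkeeping) on
data whose structure matches real transcriptomes, not the biological
sensitivity of the shipped profile on real sequences, for which users
should train a profile on a curated alignment.

A truth table accompanies every simulation (planted group, CDS
coordinates as 0-based half-open forward-strand intervals, frame,
homeodomain offset, duplicate provenance, frameshift positions), and
`evaluate_against_truth()` traces each planted transcript through
selection, dedup and classification.

## Numerical and interface choices

- Internal coordinates are 0-based half-open; all written reports are
  1-based inclusive.
- Peptide length excludes the stop codon and includes the initial M;
  ORF nt intervals include the stop codon, so
  `aa_length = (nt_end - nt_start)/3 - 1`.
- Both a start and a stop codon are required for an ORF; open-ended
  partial CDS at transcript edges are not extracted. This is recorded
  as a divergence risk against extractors that accept partial ORFs.
- FASTA I/O wraps Biostrings with a strict contract (unique ids,
  alphabet validation with position-of-error, `*` only as terminal
  stop); pairwise alignment is Biostrings `pairwiseAlignment`
  (Needleman–Wunsch for identity, Smith–Waterman for markers); the
  genetic code is Biostrings' standard table, with N-containing codons
  translated to `X` without affecting stop detection.
- Flank search windows default to 60 residues upstream of position 1
  and 30 downstream of position 60 — generous but bounded, since the
  literature does not delimit them.
- All stochastic components take explicit integer seeds; the generator
  is a pure function of (spec, catalog, seed), and pipeline reports are
  byte-identical across reruns.
- Problem sizes used by the shipped analyses and checks: a 60-transcript
  simulated transcriptome (3 per label, 20 % decoys, 10 % duplicates),
  500 proteins for the noisy-recovery estimate, 1000 random peptides
  for threshold calibration, 100 random 2-kb transcripts for the ORF
  oracle comparison.

## Known limitations

- Only six of the fourteen labels carry printed diagnostic residues, so
  only those six (Hox1–Hox5, Gsx) are assignable with the default
  catalog; the rest require user-supplied signatures. This is by
  design, not a defect.
- The scan profile has no insert/delete states and no E-value model; it
  is a PSSM over exactly 60 columns. Homeodomains with indels relative
  to the canonical frame will score poorly.
- Classification is presence/absence of short motifs; it does not
  attempt phylogenetic confirmation of orthology.
- The completeness metric reproduces category semantics with its own
  thresholds; its percentages are not comparable to any external tool's
  trained numbers.
- Sub-100 % clustering and large-scale greedy centroid search are out
  of scope for dedup.
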