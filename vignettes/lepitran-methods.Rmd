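---
title: "Methods: tiered homology annotation and expression analysis for de novo insect transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered homology annotation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepitran)
```

## Scope and model

`lepitran` implements the desk-scale analysis chain used to characterize a
de novo lepidopteran midgut transcriptome under bacterial infection: read
quality control, alignment-based rRNA depletion, homology tiering of
assembled transcripts (PUTs — putatively unique transcripts), functional
annotation rollups, two-condition digital gene expression (DGE), and
qRT-PCR relative expression. Assembly itself, repeat masking, and the
execution of external aligners (BLASTX, Blat, hmmscan) are out of scope:
the package consumes their standard tabular outputs and, for testing,
generates those outputs itself from a synthetic world with planted ground
truth.

## Read quality control

Qualities are Phred scores ($Q = -10\log_{10} p_{\mathrm{err}}$; Q20 is a
1% error rate). The cleaning chain is, in order:

1. **Offset conversion** — raw ASCII codes minus the declared offset (33
   or 64). Autodetection is deliberately absent: a mis-declared offset is
   an error, never a silent guess, so results are bit-reproducible.
2. **Artifact purge** — reads whose bases, ignoring N, are all one
   nucleotide are removed. The upstream toolkit's "artifact" rule is
   undocumented, so this conservative stand-in is used; it is an
   approximation, not a literal reproduction.
3. **Terminal clipping** — maximal spans of bases with $Q \le 20$ are
   removed from *both* ends. The source protocol does not name the ends;
   both-end clipping matches how end-trimmers operate and the aggressive
   base attrition the protocol reports.
4. **Length filter** — post-clip reads shorter than 36 nt are discarded.
5. **Fraction filter** — at least 90% of remaining bases must have
   $Q \ge 21$ (boundary inclusive). Evaluated *before* masking, so a
   surviving read has at most 10% of its bases masked.
6. **Masking** — remaining bases with $Q \le 20$ become `N`; quality
   values are kept.

The order clip → length → fraction → mask follows the protocol's phrase
structure ("of the remaining reads, all bases ... were masked"). The
pipeline is idempotent: rerunning it on its own output changes nothing,
which the test suite checks property-style.

## rRNA depletion

Reads aligned to an rRNA reference (PSL alignments, e.g. from Blat) are
discarded when any alignment reaches `min_matches` matched bases
(default 30, mirroring the aligner's default minimum reportable score).
The acceptance rule upstream is a configuration choice rather than a
published constant, so the threshold is exposed. The module consumes PSL
rather than running an aligner; `align_exact()` provides a naive
exact-substring matcher for building fixtures only.

## Homology tiers

Each PUT's BLASTX records are grouped per subject, the top hit is chosen
by bitscore (ties: lower E-value, then smaller subject id), and a
demotion cascade assigns exactly one tier:

| tier | criteria |
|------|----------|
| gold | single HSP; PUT ≥ 300 nt; subject ≥ 100 aa; positives/aligned ≥ 0.75; subject span/subject length ≥ 0.90 |
| silver | PUT ≥ 100 nt; merged subject coverage ≥ 0.75 |
| bronze | PUT ≥ 100 nt; merged subject coverage ≥ 0.30 |
| none | otherwise |

Design choices where the rules were genuinely open:

* "Hit length" is measured in subject (amino-acid) coordinates, since it
  is compared to the subject protein's length in residues.
* Silver/bronze do not re-apply the single-HSP or positives criteria
  (only length and coverage are stated for them); multi-HSP coverage is
  the union of subject intervals, overlaps counted once, frames ignored.
* A PUT failing gold remains eligible for silver, then bronze — the
  cascade maximizes information retention while keeping the tiers
  mutually disjoint.

Gold PUTs are trimmed to the aligned query span (reverse-complemented for
minus frames) and translated under the standard genetic code; trailing
partial codons are dropped, internal stops render as `*`, and codons
containing masked `N` bases render as `X` so upstream masking propagates
visibly.

## Functional annotation

* **Pfam top hits** from hmmscan `--domtblout`: per query, the family
  with the lowest full-sequence E-value at or below $10^{-2}$; ties go
  to bitscore, then accession. Full-sequence E-value (not per-domain
  score) matches the scanner's default ranking.
* **Six-frame translation / longest ORF** for the complete PUT set: the
  ORF is the maximal stop-free peptide substring over all six frames,
  with no start-codon requirement; the upstream protocol's arbitrary tie
  choice is made deterministic (frame order `+1,+2,+3,-1,-2,-3`, then
  leftmost).
* **pfam2go / kegg2go** are consumed in the GO Consortium's standard
  external2go line format; a family can contribute zero, one or several
  GO terms, each counted per hit.
* **GO-Slim** terms are the *penultimate ancestors*: direct `is_a`
  children of a domain root lying on some `is_a` path from the term to
  its root. Roots themselves are uninformative and return the empty
  set. Only `is_a` edges are traversed. Terms with several root paths
  return all their penultimate ancestors; whether a rollup counts them
  once per term or once per occurrence is exposed as the
  `mode = "set" / "multiset"` switch of `go_slim_tally()`.

## Digital gene expression

A read counts toward a PUT only under near-perfect evidence: zero
mismatches within aligned blocks *and* matched bases ≥
`ceiling(0.95 × read length)` — the closest literal reading of "at least
95% of its length aligned with perfect sequence identity". Each read is
assigned to at most one PUT (most matched bases; ties broken
lexicographically for reproducibility instead of arbitrarily). Counts
accumulate from PUTs to their NR proteins, are normalized by the
*total* reads of the sample (not the assigned subset), and fold changes
are ranked as `max/min` of the normalized values with a direction
relative to infection. Genes detected in one condition only get no
finite fold (no pseudocount) and are listed separately as exclusive.
No significance testing is performed — with one library per condition
there is no replication to support it.

## qRT-PCR

Relative expression is per-sample $2^{-\Delta C_t}$, where $\Delta C_t$
is the gene's technical-replicate mean minus the mean of the pooled
technical $C_t$s of the endogenous controls (two controls pooled on the
$C_t$ scale). Summaries report the per-biological-replicate values,
their mean, and SEM ($s/\sqrt{n}$). Fold changes between condition
means use the signed convention $+r$ for $r \ge 1$, $-(1/r)$ otherwise.
ΔΔCt is deliberately not used; the quantity of interest is the
per-sample relative expression itself. No technical-replicate outlier
rule is applied by default.

## The synthetic world

`make_world()` generates every input with planted ground truth:

* Proteins are uniform-random 100–250 aa sequences; per-destiny
  transcripts back-translate protein windows using **one fixed codon per
  amino acid**, so translated frames are exact and alignment geometry is
  computable without an aligner.
* Gold transcripts cover ≥ 90% of a ≥ 100 aa protein in one block, are
  ≥ 300 nt, and half are placed on the minus strand. Silver transcripts
  either split their match into two HSPs (disqualifying gold by HSP
  count) or derive from a < 100 aa protein with a < 300 nt PUT. Bronze
  covers 30–60%. None-destined transcripts are pure noise and emit no
  record.
* Transcripts take *distinct* source proteins while any remain: with a
  fixed codon table, two transcripts from one protein would share exact
  nucleotide sequence, cross-mapping simulated reads between PUTs and
  diluting planted per-protein fold changes.
* Planted DGE folds are embedded exactly on the abundance scale: a
  planted transcript gets control fraction $c = \min(0.01, 0.4/f)$ and
  infected fraction $cf$; background transcripts absorb the
  renormalization through one shared background fold. This keeps each
  planted ratio exact rather than approximately correct.
* Reads copy their source exactly (no substitution errors — realistic
  error profiles and paired ends are non-goals); qualities follow a
  two-state model (baseline ~Q38, geometric-length terminal spans at
  ~Q15), the minimal model that gives clipping, the fraction filter and
  masking real work.
* The toy ontology has the three standard roots, `depth` levels of
  `branching` terms, and a 30% chance of a second parent below the first
  level so multi-path GO-Slim rollups are exercised.
* Ct tables center the control-condition $\Delta C_t$ at 0 and shift the
  infected condition by $-\log_2(\mathrm{fold})$, with Gaussian
  technical noise; at zero noise planted folds are recovered exactly.
* All randomness flows from one integer seed; worlds are byte-identical
  across calls, and the caller's RNG stream is left untouched.

Because reads are error-free, condition libraries are unreplicated, and
abundances are exact multinomials, passing tests demonstrate the
*correctness of the decision rules and estimators*, not robustness to
sequencing error, overdispersion between biological replicates (exposed
as generator parameters rather than asserted), or assembler artifacts.

## Problem sizes and numerical choices

The shipped checks run at desk scale as the package's own choice of
study conditions: 10,000 randomized hit geometries against a
direct-inequality tier oracle (with explicit 299/300 nt, 0.899/0.900
coverage, 0.749/0.750 positives boundaries); a 200-transcript world
(50 per destiny) through the full file path; 1,000 mixed-quality reads
against a brute-force QC oracle; 100,000 reads per condition × 10
simulation seeds for DGE recovery of planted folds {2, 5, 10, 100}
(±20% band, direction always recovered); 1,000 random sequences ≤ 300 nt
against an exhaustive ORF scan; and 20 qPCR panels at noise 0.2 cycles
for planted folds {0.1, 1, 10, 427} (recovered within 0.5 log2 units).
Interval unions use integer arithmetic; all tie-breaks are lexicographic
and documented; boundary comparisons are inclusive exactly where the
protocol's wording is inclusive ("21 or higher", "20 or less", "at
least").

## Known limitations

* The headline counts of the original study (tens of millions of reads,
  tier sizes, Pfam family tables) depend on the real read data and
  database versions and are not reproduced here; the package reproduces
  the *method*, validated on planted truth.
* The FASTX artifact rule and the Blat acceptance threshold are
  documented stand-ins for under-specified upstream behavior.
* One pooling mode for endogenous controls (arithmetic on the Ct scale)
  is implemented.
* The fixture aligner reports forward-strand exact full-length matches
  only; it is not a general-purpose aligner.
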