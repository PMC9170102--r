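---
title: "Spidroin repeat catalogs and silk-gland expression: methods and design"
author: "silkmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spidroin repeat catalogs and silk-gland expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkmotifs)
```

## The problem

Spider silk proteins (spidroins) share a three-part architecture: a conserved
N-terminal domain (NTD, roughly 100 residues, carrying a MAFAS-like anchor
near its start), a very long repetitive core, and a conserved C-terminal
domain (CTD). The core is what gives each silk its mechanical character, and
it is built from short repetitive *motif variants* (roughly 4–41 residues:
poly-alanine tracts, GPGQQ- and GPGPQGPS-like units, glycine-rich runs) that
assemble into *cassettes* — higher-order runs of 2–6 adjacent motifs. Because
spidroin genes are enormous, highly repetitive, and often fragmented in draft
assemblies, cataloging their repeat architecture and comparing catalogs
between species requires explicit, reproducible rules for every step.

`silkmotifs` implements that pipeline end to end: candidate screening by
terminal-domain homology and signature motifs, fragment categorization, motif
discovery and painting on masked cores, cassette detection and curation,
two-species sharing summaries, and 2^-ddCt relative expression across
silk-gland panels — plus a synthetic spidroin generator that makes every
stage testable against known ground truth.

## Screening and fragment categories

Candidates are screened by Smith–Waterman local alignment
(`localHomologySearch`) against a curated NTD/CTD reference library, using
BLOSUM62 with affine gaps (open 11, extend 1). Significance is expressed as a
Karlin–Altschul expectation value `E = K·m·n·exp(-λS)` with the standard
gapped-search constants (λ = 0.267, K = 0.041), `m` the searched query
region and `n` the summed library length; hits are retained at `E ≤ 1e-6`.
For queries longer than 300 residues, the NTD search is confined to the first
150 residues and the CTD search to the last 150: terminal domains are ~100
residues, and a repetitive core is alignment bait (a periodic sequence can
accumulate spurious chained matches), so restricting the windows removes the
dominant false-positive mode.

Each candidate receives exactly one of five fragment categories
(`categorizeFragments`): *complete* (both termini, no internal gap),
*internal gap* (both termini plus gap evidence — a run of ≥ 10 `X` residues,
the translated footprint of an assembly gap), *5′ end* (NTD only), *3′ end*
(CTD only), or *repetitive* (neither terminus). Because "repeats only" is
qualitative, the repetitive call is backed by explicit evidence: at least 3
GPGQQ repeats, a poly-A run of ≥ 6, or ≥ 30 % of residues covered by catalog
motifs when a painted catalog is available. Class assignment (`assignClass`)
uses evidence precedence — concordant NTD/CTD homology, then internal motif
votes, then the silk gland of highest expression; conflicting terminal labels
with no tiebreaker yield "unclassified" with the conflicting evidence
recorded.

## Masking, motif discovery, and painting

Terminal domains are masked with a hard cutoff of 100 residues per end
(`maskTerminalDomains`); all motif work happens inside the remaining core
span, in 0-based half-open coordinates (1-based closed coordinates appear
only in display output).

`discoverMotifs` enumerates repeated substrings of the cores within the 4–41
residue bounds and keeps those with at least `minTotalOccurrences = 3`
leftmost-greedy non-overlapping occurrences across all cores. Two pruning
rules keep the catalog non-redundant:

* **right-maximality** — a pattern all of whose occurrences are followed by
  the same residue is dropped in favor of its one-residue extension, provided
  the extension itself still meets the occurrence threshold;
* **subsumption** — a pattern contained in a longer catalog pattern with the
  identical occurrence set (equal counts, every occurrence inside an
  occurrence of the longer pattern) is dropped.

The occurrence threshold of 3 is the package's own default: two occurrences
of a short word arise constantly by chance in low-complexity sequence, while
genuine silk repeats recur many times. Counting within a variant is
leftmost-greedy and non-overlapping so that tandem repeats are not
double-counted at shifted offsets; different variants may overlap freely.
Variant ids are assigned deterministically (length descending, then
lexicographic pattern), so identical inputs always give identical catalogs.

`paintSequences` locates every catalog variant in every core, treating `x`
and `z` as wildcard positions matching any residue. Grouping
(`groupMotifs`) first assigns a fixed, ordered list of residue-composition
classes — poly-A (A ≥ 75 %), GA-dinucleotide-like (G+A ≥ 80 %, both present),
glycine-rich (G ≥ 35 %), Ser/Thr/Val-rich (≥ 50 %), Gln/Pro-rich (≥ 50 %) —
and then clusters the remainder by single-linkage on normalized edit distance
(threshold 0.25, i.e. at most one edit per four residues of the longer
pattern); similarity clusters of one stay "unassigned". Sub-groups are the
edit-distance clusters within each group. `collapseVariantDescriptions`
merges equal-length sub-group members differing at one position into
wildcard descriptions (`x` first, `z` for a second independent position,
`x` always naming the left-most wildcard), iterated to a fixpoint — the rule
that turns {APGPQ, GPGPQ, SPGPQ} into xPGPQ.

## Cassettes

`detectCassettes` chains motif occurrences per gene whenever consecutive,
non-overlapping occurrences are separated by at most 20 residues, then
segments each maximal chain leftmost-first into windows of at most 6
components; a trailing window with fewer than 2 components is discarded. A
component tuple becomes a cassette *type* only when it occurs at least twice
dataset-wide (`minTypeSupport = 2`, the operational reading of "enriched");
cassette occurrences never share a motif occurrence. `curateCassettes`
removes occurrences violating the gap limit or extending outside the core
span and re-applies the support threshold, with full occurrence accounting.

One behavioral consequence of this segmentation deserves a note: raising the
gap limit can *merge* two adjacent chains into one, so the total occurrence
count is not monotone in `maxGap`. What is monotone — and what the test suite
asserts — is that a gene carrying a cassette at a stricter gap limit still
carries one at a looser limit.

## Sharing statistics

`summarizeSharing` compares two single-species occurrence tables: a type is
*shared* when it occurs at least once in each species, otherwise private.
Type identity across species is pattern equality after wildcard collapse
(collapse first, then compare), which in practice means painting both species
with one joint catalog. Percentages are always recomputed from counts and
rounded half-up to one decimal; `sharingFromCounts` exposes the same
arithmetic for externally tallied counts. `originBreakdown` splits each
species' private types into single-gene, within-class, and across-class bins
(a strict partition), and `rankTopMotifs` produces top-k panels with a
cross-class flag for shared motifs whose dominant using class differs between
species.

## Relative expression (2^-ddCt)

`relativeQuantities` implements the standard relative quantification:
ΔCt = Ct(target) − Ct(reference gene) per tissue,
ΔΔCt = ΔCt(tissue) − ΔCt(calibrator tissue), RQ = 2^−ΔΔCt. Defaults follow
the silk-gland panel design: reference gene RPL13a, calibrator tissue legs
(both configurable). Replicates are averaged over non-censored wells;
"Undetermined" wells are censored at 40 cycles and *never* imputed into a
numeric RQ — imputing would fabricate expression where none was measured.
Replicate variability is propagated in quadrature over the four standard
errors entering ΔΔCt and reported as `sd_ddct`; no significance testing is
attached because none is defined for this design. No
amplification-efficiency correction is applied (pure 2^-ddCt). The
calibrator's RQ is exactly 1 by construction, and `rankGlands` orders
quantifiable tissues by RQ with stable ties, feeding the top gland back into
class assignment as expression evidence.

## The synthetic generator: what it emulates, and what it does not

`generateSpidroin` builds NTD + (cassette instances with sampled spacers) +
CTD from a `SpidroinGrammar`, recording every planted motif and cassette
occurrence. The default grammar uses motifs from the silk literature
(GPGPQGPS, GPGQQ, a 7-residue poly-A tract, [GGP]₃, GYGGQ, GGSGGGL, a
Ser/Val/Thr-rich unit, a DT.SY.TGEY-like unit) in 3-component templates, each
carrying at least one GPGQQ or poly-A component so that repeats-only
fragments retain detectable signatures. Intra-cassette spacers are 1–6
residues; between-cassette spacers are 21–25 residues, deliberately above the
20-residue adjacency limit so planted cassettes remain distinct higher-order
units. Genes carry 4–8 cassette instances, with templates cycled round-robin
across a generated set so every template reaches the support threshold.

Three idealizations matter for interpreting test results:

* **Spacer alphabet disjointness.** Spacer residues are drawn from
  {N, K, R, H, F, M}, an alphabet disjoint from the motif-pool letters. This
  makes the planted occurrence set the *unique* ground truth — no spurious or
  junction-spanning matches — which is what allows the suite to demand exact
  painting recovery and 100 % cassette recovery. Real spidroin spacers share
  residues with motifs, so on real data painting recall is exact by
  construction but the discovered catalog will additionally contain
  boundary-extended variants that a curator would trim.
* **Non-repetitive terminal templates.** The fixed NTD/CTD templates are
  deliberately aperiodic; a periodic template acts as an alignment decoy
  against repetitive cores and corrupts fragment categorization.
* **No sequencing artifacts.** The generator models neither assembly error,
  codon structure, nor within-motif mutation; recovery rates measured here
  are therefore upper bounds for real assemblies, and passing tests certify
  the *rules*, not field performance.

The two-species generator draws a universe of distinct, mutually
non-substring motif types, marks each as shared with the planted probability,
and builds each species' genes from its own pool; the realized shared
fraction is binomial around the planted value, which sets the tolerance (3
binomial standard errors) used in the recovery checks. Ct tables are
generated as `baseCt − log2(fold) + N(0, sd)` per replicate with a
constant-mean reference gene; per-component seeds derived from one master
seed keep all generators byte-reproducible.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; conversion to
  display coordinates adds exactly (+1, 0).
* Rounding of percentages is half-up to one decimal (base `round` is
  half-to-even and would disagree on printed values).
* Tie-breaks are always explicit and deterministic: best homology hits by
  score, then E-value, then reference id; variants by length then pattern;
  ranked motifs by count then id; RQ ties keep input order.
* Empty inputs degrade gracefully: an empty FASTA yields an empty set, an
  empty catalog paints nothing, empty occurrence tables give zero-count
  reports; an empty reference library, by contrast, is an error.
* Sequences shorter than two terminal windows have an empty core and simply
  produce no motifs.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use desk-scale instances chosen to
finish in seconds while still exercising every rule: 6–8 synthetic genes
(~400–600 residues each) for discovery/painting/cassette recovery, 200 motif
types and 25 genes per species for sharing recovery, 200 truncated fragments
for categorization accuracy, and 200–500 seeds for qPCR calibration. The
published catalog totals themselves (2,771 motif types, 2,268 cassette types)
came from MEME seeding plus manual curation and are not bit-reproducible by
any deterministic surrogate; what is reproducible — and what the acceptance
layer checks — is the summary arithmetic on the printed counts and the
deposited occurrence tallies, plus the ground-truth recovery properties
above.

## Known limitations

* The discovery thresholds (minimum 3 occurrences, composition classes, edit
  threshold 0.25) are reproducible surrogates for a manual curation step; on
  real catalogs they will not reproduce hand-curated counts exactly.
* Whether same-variant occurrences may overlap is resolved here as "no"
  (leftmost-greedy), and cassette chains never share motif occurrences; both
  are package decisions where the field has no stated convention.
* The E-value model uses fixed gapped-search constants rather than
  sequence-specific estimation; at the 1e-6 threshold and library sizes used
  this changes no decision, but E-values should be read as calibrated scores,
  not probabilities.
* No nucleotide-level handling (scaffolds, gene models, SAM/BAM) and no
  probabilistic motif models (PWMs) — both out of scope by design.
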