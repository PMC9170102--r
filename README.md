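# silkmotifs

Tools for characterizing the repetitive architecture of spider silk proteins
(spidroins) and their silk-gland expression.

Spidroins are enormous silk genes built as a conserved N-terminal domain
(~100 aa, with a MAFAS-like anchor), a long repetitive core, and a conserved
C-terminal domain. The core is assembled from short repetitive **motif
variants** (4–41 residues: poly-alanine tracts, GPGQQ / GPGPQGPS-like units,
glycine-rich runs) that combine into **cassettes** — higher-order runs of 2–6
adjacent motifs separated by at most 20 residues. `silkmotifs` is for
researchers cataloging these repeats from translated gene models and
comparing catalogs between species (e.g. an orb-weaver of interest against a
reference catalog such as *Trichonephila clavipes*).

The package implements, as tested and deterministic code:

* **Candidate screening** — Smith–Waterman local homology of queries against
  curated NTD/CTD reference libraries (BLOSUM62, gap open 11 / extend 1),
  with Karlin–Altschul expectation values `E = K·m·n·e^(−λS)` and retention
  at `E ≤ 1e-6`; signature annotation (MAFAS, GPGQQ repeats, poly-A runs);
  five-way fragment categorization (complete / internal gap / 5′ end / 3′
  end / repetitive); silk-class assignment with evidence precedence
  NTD=CTD > internal motifs > expression.
* **Motif catalogs** — terminal masking at a hard 100-residue cutoff;
  discovery of repeated core substrings (4–41 aa, ≥ 3 non-overlapping
  occurrences, right-maximal, subsumption-pruned); leftmost-greedy painting
  of occurrences (wildcards `x`/`z` match any residue); composition-based
  grouping and wildcard collapse of descriptions (APGPQ + GPGPQ + SPGPQ →
  xPGPQ).
* **Cassettes** — chaining of adjacent motif occurrences (gap ≤ 20),
  segmentation into 2–6-component windows, dataset-wide support filtering,
  grouping by component motif groups, and curation against gap/terminal
  constraints.
* **Sharing statistics** — a two-species summary table (types private to
  each species, shared types, occurrence split, all percentages recomputed
  from counts with half-up rounding), per-species origin breakdowns
  (single-gene / within-class / across-class), and top-k motif rankings with
  cross-class usage flags.
* **Expression** — relative transcript abundance by 2^−ΔΔCt (ΔCt =
  Ct_target − Ct_reference per tissue; ΔΔCt against a calibrator tissue;
  RQ = 2^−ΔΔCt), with reference gene RPL13a and leg-tissue calibrator as
  defaults, censoring-aware replicate aggregation, and per-target gland
  ranking.
* **Synthetic data** — a grammar-driven spidroin generator with complete
  ground truth (planted motif/cassette occurrences, class labels, two-species
  sharing fractions, qPCR fold-change matrices), so every stage above is
  testable without any external data.

## Worked example

```r
library(silkmotifs)

## synthetic spidroins with known ground truth
g   <- defaultGrammar()
gen <- generateSpidroinSet(g, nGenes = 6, seed = 42, species = "Cdar")
gen$set
#> SpidroinSet with 6 gene(s) [species: Cdar]
#>   syn_001               440 aa  MaSp
#>   syn_002               380 aa  MaSp
#>   syn_003               476 aa  MaSp
#>   ...

## mask termini, discover the repeat catalog
spans <- maskTerminalDomains(gen$set)          # hard 100-residue cutoff
discoverMotifs(gen$set, spans)
#> MotifCatalog with 85 variant(s) (lengths 4-11; 0 grouped)

## paint a curated catalog and detect cassettes
curated <- groundTruthCatalog(g)
painted <- paintSequences(gen$set, curated, spans)   # 108 occurrences
det     <- detectCassettes(painted, catalog = curated)
det$types[1:3, c("cassette_id", "description", "support")]
#>   cassette_id                 description support
#> 1       C0001    DTASYLTGEY_GPGQQ_GGSGGGL       6
#> 2       C0002 SVSVVSTTIS_AAAAAAA_GPGPQGPS       6
#> 3       C0003       GGPGGPGGP_GYGGQ_GPGQQ       6

## two-species sharing with a planted 30% shared fraction
ts <- generateTwoSpecies(sharedFraction = 0.3, nGenes = 25, seed = 17,
                         nMotifTypes = 200)
summarizeSharing(ts$occurrencesA, ts$occurrencesB)
#> motif sharing summary: Cdar vs Tcla
#>   Types detected                     200
#>   Private to Cdar                     72 (36.0%)
#>   Private to Tcla                     71 (35.5%)
#>   Shared                              57 (28.5%)
#>   Occurrences Cdar / Tcla        420 / 459 (47.8% in Cdar)

## qPCR: a major-ampullate-dominant target across silk glands
fc <- matrix(c(8, 2, 1, 1), 1, 4,
             dimnames = list("MaSp1_B", c("MA", "MI", "FL", "AG")))
rq <- relativeQuantities(generateCtTable(fc, noiseSd = 0.2, seed = 1))
rankGlands(rq, tissues = c("MA", "MI", "FL", "AG"))
#>   tissue       rq
#> 1     MA 6.868597
#> 2     MI 2.022523
#> 3     AG 1.173747
#> 4     FL 1.050205
```

The discovered catalog contains the 8 planted motif types plus
boundary-extended by-products of the repeat structure (the description counts
in the catalog show how often each occurs); painting recovers every planted
occurrence, the cassette descriptions read component motifs joined with `_`
wherever a spacer was observed, the sharing summary's 57/200 = 28.5 % shared
types sit within binomial error of the planted 30 %, and the gland ranking
recovers the planted MA-dominant profile (fold 8 planted, ~6.9 recovered
under Ct noise).

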