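---
title: "Profiling the secretome of granular biofilms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the secretome of granular biofilms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretome)
library(dplyr)
```

## The analysis problem

Dense microbial granules — such as the *Ca.* Accumulibacter-enriched
aggregates used in enhanced biological phosphorus removal — are held
together by an extracellular matrix in which secreted proteins are thought
to play a structural role. Quantifying that secreted metaproteome is hard:
bulk lysis of whole granules swamps the signal with cytoplasmic proteins,
so complementary approaches are used — lysis of whole granules, limited
proteolysis ("shaving") of intact granules that releases semi-specific
peptides from surface-exposed proteins, and proteomics of the culture
supernatant. This package implements the downstream computational
analysis: converting per-approach intensities to iBAQ, reconciling protein
groups across approaches, accounting for where the protein biomass resides
(secretion evidence, subcellular location, taxonomy, function), and
screening for extracellular proteins whose physicochemical extremes
suggest they help aggregate the biofilm matrix.

The raw mass-spectrometry stages (peptide identification, FDR control,
protein inference) are out of scope: the pipeline consumes a protein
catalogue (FASTA), per-approach quantification tables, and annotation
tables produced by external predictors (signal peptides, transmembrane
domains, two subcellular-location predictors, taxonomy, COG categories,
and per-residue structure predictions).

## In-silico digestion and iBAQ

Four protease regimes are supported. The cleavage rules follow the
standard Expasy conventions, which the package treats as fixed
definitions:

* trypsin — after K or R, blocked when the next residue is P;
* chymotrypsin (high specificity) — after F, W or Y, blocked before P;
* LysC — after K, *not* blocked by proline (its documented distinction
  from trypsin);
* LysC/trypsin — the union of the two site sets.

Peptide coordinates are 0-based half-open internally; emitted tables carry
1-based inclusive coordinates alongside. In `specific` mode every peptide
is bounded by cleavage sites or protein termini; `semispecific` mode (the
search setting appropriate for shaved samples, where one terminus is
created by the shaving protease and the other by the folded substrate's
accessibility) additionally emits every peptide with exactly one enzymatic
terminus. The missed-cleavage limit counts internal sites spanned by the
peptide and applies identically in both modes — note this means a
semi-specific peptide that spans an internal cleavage site requires a
missed-cleavage allowance even when one terminus is free.

iBAQ conversion divides each row's intensity by the protein's *theoretical
peptide count* under the protease regime of that row. The count is defined
as the number of fully specific, zero-missed-cleavage peptides of length
7–30 residues — the common convention for iBAQ denominators; the window is
configurable because search engines differ. Because whole-granule
replicates may have been digested with different proteases, the regime can
be supplied per (approach, replicate).

```{r digest-example}
digest("MKRPLAK", "trypsin", max_missed = 0, mode = "specific",
       length_range = c(1, 30))
theoretical_peptide_count("MKAAAAAAKLLLLLLLR", "trypsin")
```

## Experiment-wide protein grouping

Each approach's search produces its own protein groups. Two proteins are
placed in the same experiment-wide group when they share an
approach-specific group in at least one approach and are never assigned to
*different* groups within any single approach. This pairwise rule can be
transitively inconsistent (A links p1–p2, B links p2–p3, C separates p1
and p3), and no total order of merges is implied by the definition. The
package makes the rule total and deterministic by processing candidate
merges in canonical lexicographic order (approach, group id, protein id)
and skipping — and logging — any merge that would co-locate proteins
carrying different group ids in one approach. The skipped-merge log
surfaces every inconsistency so it can be inspected. Experiment-wide group
ids are the lexicographically smallest member id prefixed `EG_`, which is
stable across runs and readable.

## Properties, ranks, and the aggregate screen

Eight properties describe each protein: GRAVY (mean Kyte–Doolittle
hydropathy; the ambiguity residue X has no scale value and is excluded
from numerator and denominator), aromaticity (F/W/Y fraction of the full
length), net charge, cysteine fraction, length, and three structural
aggregates — beta-sheet fraction, mean relative surface accessibility
(RSA) and mean disorder — computed as simple per-residue means of the
supplied structure table. Per-protein means were chosen because no
aggregation rule is canonical for these predictors; means are transparent
and monotone in the underlying per-residue signal.

Net charge uses a Henderson–Hasselbalch sum over ionizable side chains
plus the two terminal groups, with the EMBOSS pKa set (N-terminus 8.6,
C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1) at pH
7.0 by default. Both the pH and the pKa table are configuration entries —
the culture in the motivating system was operated at pH 7.2, and
`default_config(charge = list(pH = 7.2))` reproduces that condition. The
choice of pH shifts all charges coherently and has little effect on
rank-based screening.

Properties are converted to average-rank percentiles in (0, 1] over *all
measured proteins* (not merely the later candidates); ties share the
average rank so boundary-straddling ties move as a block. Charge is ranked
twice: by absolute value for the selection rule — both strongly positive
and strongly negative proteins can cross-link a matrix — and signed for
clustering, where sign carries chemical meaning.

A protein becomes an aggregate-forming candidate when all three clauses
hold:

1. at least one property is extreme — in the top 10% (GRAVY, beta-sheet
   fraction, cysteine fraction, aromaticity, length, |charge|) or bottom
   10% (RSA, disorder). The boundary is strict on the top side
   (percentile > 0.9) and inclusive on the bottom (percentile ≤ 0.1),
   which keeps the two directions symmetric and deterministic under ties;
2. its abundance percentile exceeds 0.5 among the proteins quantified in
   at least one approach (absence from an approach is not rank zero — the
   universe is per approach);
3. it is predicted secreted or extracellular, operationalized as a
   predicted signal peptide *or* an extracellular call from either
   location predictor. The components of this disjunction are reported
   individually, so stricter alternatives (signal peptide only, one
   predictor only) remain recoverable from the outputs.

Candidates are clustered on their 8 rank percentiles (signed charge) with
Euclidean distances and complete linkage, and the tree is cut into `k`
clusters, `k = 9` by default. The cut criterion is a configuration choice:
a fixed `k` is transparent and reproducible, whereas height-based cuts are
sensitive to the exact tie structure of rank data. Cluster ids are
relabelled 1..k by decreasing size (ties by smallest member id), and
candidates are sorted by id before clustering, so the assignment is
invariant to input order.

## Biomass accounting

All shares are computed on replicate-averaged iBAQ per approach; a protein
missing from a replicate contributes zero to its mean, which is the
conservative reading when missingness usually means "below detection".
Shares by secretion category (SP / TM / SP+TM / None), by each location
predictor's labels, by taxonomy (phylum, class, genus; `unclassified` is
its own key) and by COG category are label-summed iBAQ over total iBAQ per
approach. COG categories use full allocation: a protein annotated with
several categories contributes its entire iBAQ to each, so COG shares can
exceed 1 in total — category shares then answer "what fraction of the
biomass carries this function" rather than partitioning the biomass.
Proteins with no COG are reported under `NA`, kept distinct from category
S (function unknown). The cumulative-coverage statistic reports, for each
threshold, the minimal number of top proteins whose summed abundance
reaches that fraction of the secreted biomass, with deterministic
id-ordered tie-breaks.

## The synthetic study system

Real granule metaproteomes require raw MS data and a commercial search
stack, so the package ships a generator that emulates the statistical
structure the analysis relies on, with planted ground truth:

* a catalogue of `n_proteins = 500` proteins with log-normal lengths
  (median 300 aa, sigma 0.5) and composition-driven random sequences —
  per-residue draws from background amino-acid frequencies suffice
  because every downstream sequence property is composition-driven;
* true subcellular locations drawn from a prior (cytoplasmic 0.6, the
  five exported compartments 0.1 each), signal-peptide flags consistent
  with location (P(SP | extracellular) = 0.9, P(SP | cytoplasmic) = 0.02),
  and two location predictors that are correct with probability 0.8;
* per-protein log10 abundance N(0, 1.5), multiplied by a location-by-
  approach enrichment matrix (secreted compartments enriched in shaved
  and supernatant, cytoplasmic depleted) and by per-replicate log-normal
  noise (sigma 0.1); detection probabilities also favour exported
  proteins in the surface-targeting approaches;
* structure tables whose per-protein targets come from Beta
  distributions — background beta-sheet fraction Beta(2, 8) versus
  Beta(8, 2) for beta-extreme planted proteins, and analogously shifted
  distributions for the low-RSA and low-disorder extremes;
* 25 planted true candidates (secreted, abundant, one extreme property
  each, cycling through nine extreme types) and 25 decoys — extreme but
  cytoplasmic, or extreme and secreted but at vanishing abundance. The
  planted extremes are strong enough that recovery is exact by
  construction, which is what makes them useful as a regression oracle;
* approach-specific group ids derived from true groups with a small rate
  of injected cross-approach merge evidence and of deliberate conflicts
  that the canonical-order merge must skip.

All randomness flows from one seed through named substreams (roles,
sequences, abundances, annotations, structure, grouping), so the same
seed reproduces every file byte-identically and individual stages can be
regenerated independently.

What passing tests on this generator do **not** show: real metaproteomes
have correlated properties (signal peptides bias composition; membrane
beta-barrels couple beta-sheet content with location), shared-peptide
ambiguity that makes protein groups much larger, abundance distributions
with heavier tails, and predictors whose errors are systematic rather than
independent. The generator validates the pipeline's logic, determinism and
bookkeeping — not biological effect sizes.

## Numerical choices and degenerate inputs

* Percentile ties use average ranks everywhere (properties, abundance),
  so permuting input rows never changes a result.
* Proteins lacking a structure table are excluded from the rankings of
  the three structural properties only, and from the candidate universe
  (which requires a complete property vector); they remain in all biomass
  accounting.
* Quantification rows whose protein has no theoretical peptide under its
  protease regime cannot be iBAQ-converted; they are dropped and logged.
* An all-X sequence has no GRAVY value and is a hard error, as is a
  zero-abundance approach in share computation.
* Coverage thresholds use a 1e-12 slack on the cumulative sum to absorb
  floating-point drift at exact-fraction thresholds.
* Problem sizes in the shipped tests (catalogues of 120–500 proteins,
  brute-force digestion oracles on sequences up to 200 residues, 1000
  random grouping instances) were chosen so the full suite exercises
  every invariant in a couple of minutes on one core.

## Known limitations

The screen nominates candidates by physicochemical extremeness; it makes
no claim that selected proteins form aggregates in vivo. The secretion
predicate inherits the biases of the upstream predictors, and the pipeline
deliberately does not re-derive localization from sequence. Selection
percentiles are computed on the pooled protein list, not per approach —
the pooled choice matches the screen's definition of "all measured
proteins", but per-approach ranking would be a defensible variant and can
be emulated by filtering the input tables. The fixed-`k` dendrogram cut
requires the analyst to choose `k`; inspecting the emitted merge tree
(`linkage`) is recommended before settling on a value.
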