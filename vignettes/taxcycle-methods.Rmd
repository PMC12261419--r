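---
title: "Predicting coarse-grained biogeochemical functions from taxonomic affiliations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting coarse-grained biogeochemical functions from taxonomic affiliations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxcycle)
```

## The problem

Metabarcoding surveys (16S rRNA and similar markers) tell us *who* is in
an environmental microbial community, but not *what the community can
do*. For questions about biogeochemistry — does this community produce
methane, consume acetate, reduce sulfate? — the taxonomy must be
translated into metabolic potential. Shotgun metagenomics answers this
directly but is often impractical for low-DNA environmental samples
(subsurface brines, salt caverns, aquifers), where amplicon sequencing
remains the method of choice.

`taxcycle` implements that translation as a chain of small, testable
steps:

1. **Taxonomic resolution.** Each observation (OTU/ASV) carries an
   ordered lineage. It is resolved against a precomputed archive of
   per-taxon *consensus proteomes* — representative protein-cluster
   sequences derived from the public proteomes of each taxon — at the
   most specific rank the archive covers, falling back to broader ranks
   otherwise.
2. **Marker detection.** Each resolved taxon's consensus proteome is
   scanned with profile hidden Markov models of marker enzymes
   (*mcrA*, *dsrA/dsrB*, *acsB*, *fthfs*, ...) and hits are called
   against per-profile bit-score cutoffs.
3. **Function calling.** Boolean AND/OR formulas over the marker
   profiles decide coarse-grained functions per taxon (methanogenesis,
   Wood-Ljungdahl acetogenesis, sulfate reduction, ...).
4. **Community aggregation.** Per sample, each function receives an
   *occurrence* (fraction of member taxa possessing it) and, when an
   abundance table is supplied, a *relative abundance* (summed abundance
   of possessing taxa over the summed abundance of members).
5. **Projection.** The per-sample values are projected onto carbon,
   nitrogen and sulfur cycle diagrams (SVG templates whose edges are
   functions), onto a heatmap table, and onto a polar-plot summary of
   the major functions.

## The database archive and rank fallback

The archive is a zip with a root `index.tsv`
(`taxon_name`, `rank`, `proteome_count`, `proteome_path`,
`annotation_path`) and per-taxon FASTA/TSV members. Inclusion requires
`proteome_count >= min_proteomes`; the default is **5 source
proteomes**, configurable in `build_taxon_db()`. A taxon represented by
fewer proteomes yields a consensus proteome too unstable to trust, which
is why sparsely covered taxa are excluded and their observations fall
back to a broader rank.

Resolution walks the lineage from its most specific element to its
broadest and takes the first `(name, rank)` pair present in the index.
Matching is exact after whitespace trimming and case-sensitive; homonyms
at different ranks are disambiguated by the pair. Synonym resolution
against a taxonomy service is deliberately out of scope — the archive
index is the single source of truth, which keeps resolution
deterministic and offline.

Observations the index cannot resolve are excluded from **both** the
numerator and denominator of occurrence and abundance, and reported
separately as a per-sample `resolved_fraction` (abundance-weighted when
abundances are given). Including them in denominators would silently
deflate every fraction by an amount that has nothing to do with the
community's metabolism.

Lineages without explicit rank labels are placed positionally on the
seven-slot ladder kingdom → species, anchored at the broadest rank
(`align = "broad"`), so `Bacteria;Bacillota;Clostridia` ends at rank
class. Anchoring at the species end is available (`align =
"specific"`) for genus-to-species tables.

## HMM scoring

Profiles are plan7-style models read from HMMER3 ASCII files (stored
negative natural logs; `*` is probability zero). Scoring uses a **unihit
local Viterbi** convention: a path enters the profile at any match
state and leaves from any match state at zero cost, follows
match/insert/delete transitions inside, and scores emissions in
log2-odds against the background plus log2 transition probabilities.
This convention was chosen because it is exact and desk-verifiable: an
independent oracle (`brute_force_score()`) enumerates *every* legal
path for small problems, and the dynamic program is required to agree
with it exactly over hundreds of random profiles. The DP inner loop is
implemented in C++ (as scoring kernels in this field invariably are);
the oracle stays in plain R so the two routes share no code.

Numerical conventions worth knowing:

* The background is uniform (1/20): HMMER3 files carry no null model,
  and the packaged toy profiles are written against a uniform null. The
  `COMPO` line is parsed and kept but not used for scoring.
* Ambiguity codes (`B`, `Z`, `X`, `J`, `U`, `O`) score log-odds 0 for
  both match and insert emissions — neutral, never a hit driver; `*`
  characters in a sequence are skipped.
* A hit passes when `bit_score >= cutoff`, where the cutoff is taken
  from a user cutoff table, else the model's `GA` line, else a default
  of **40 bits** (a conservative, METABOLIC-style per-HMM threshold).
  Scores are compared unrounded; only written tables round to 3
  decimals.
* A sequence none of whose residues can be emitted by any match state
  scores `-Inf` with an empty span; a single neutral residue scores 0.

Forward/posterior scoring, E-values, domain envelopes and multihit
alignment are out of scope: presence/absence against a curated cutoff
is what the function-calling layer needs.

## Boolean function rules

The rule grammar is `identifier | expr AND expr | expr OR expr |
(expr)` with AND binding tighter than OR and identifiers matching
`[A-Za-z0-9_./-]+`. There is deliberately **no NOT operator**: function
calls are monotone in the marker-presence set, which gives a clean
invariant (adding markers can never remove a function) and matches how
marker-based calling is used in practice. The packaged rule set
(`inst/extdata/rules/metabolic_functions.tsv`) covers the classic
carbon/nitrogen/sulfur functions; it is data, not code — users studying
other environments should edit or replace it. Formula identifiers with
no profile in the collection warn once and evaluate false.

## Occurrence, abundance and their invariants

For a sample with member set $M$ (resolved observations with strictly
positive abundance):

$$\mathrm{occ}(f) = \frac{|\{t \in M : f(t)\}|}{|M|}, \qquad
\mathrm{ab}(f) = \frac{\sum_{t \in M,\, f(t)} a_t}{\sum_{t \in M} a_t}$$

Four properties follow and are enforced by tests: all values lie in
$[0,1]$; if members partition over a function set, both measures sum
to 1; scaling a sample's abundance column changes nothing; and uniform
abundances collapse abundance to occurrence. Occurrence counts
*observations*, not distinct database taxa: two ASVs resolving to the
same genus are two community members that happen to share a proteome.

## Diagrams and display

Cycle diagrams are data: an SVG template with `{{anchor.label}}` /
`{{anchor.class}}` placeholders plus a TSV edge map
(`function_name`, `anchor_id`, `substrate`, `product`). Rendering is a
pure string substitution, so output bytes depend only on the inputs.
Labels are whole percentages with **half-up** rounding (0.5% → 1%;
base R's half-even rounding would print 0.005 as 0%), and zero-weight
edges keep their label in a grey `weight zero` class so an absent
function is visibly absent rather than missing. The polar summary
applies a display threshold (default **0.10**): a function is shown iff
it reaches the threshold in at least one selected sample, and then
shows its values in all of them.

## The synthetic community generator

`fixture_spec()` + `make_community_fixture()` generate complete,
seeded input sets with known ground truth: toy profiles around random
consensus peptides (sharpness 1.0, length 8 by default, cutoff = half
the consensus score), proteomes containing one planted motif per
planted marker plus uniform-background decoys, a taxonomy, integer
abundance tables (integers keep expected fractions exactly rational),
rules, and truth tables computed analytically from the design.

The margins are engineered, not hoped for: a planted motif scores
exactly twice its profile's cutoff; decoys are rejection-sampled until
they score below 0.45× cutoff on every profile (strictly inside the
half-cutoff margin, so file-format rounding of cutoffs cannot flip a
boundary case); consensus peptide sets are redrawn until no peptide
reaches another marker's cutoff; and planted-motif flanks are redrawn
until the planted sequence passes only its own profile. Recovery tests
therefore expect *exact* presence matrices, not approximate ones.

What the generator does **not** emulate: sequencing error, chimeras,
PCR and 16S copy-number bias, taxonomic mis-assignment, and realistic
proteome sizes or evolutionary divergence between a motif and its
profile. Passing the end-to-end tests shows the pipeline's bookkeeping
and scoring are correct under clean conditions; it does not certify
predictions on real communities, where database coverage and marker
divergence dominate.

## Determinism and parallelism

The per-taxon HMM search is the parallel unit (`cores` argument,
forked workers); results merge in sorted taxon order, so every file
under the numbered stage directories (`0_resolution/` … `4_diagrams/`)
is byte-identical for any worker count and across reruns.
`run_report.json` is a log — it records versions, counts, warnings and
wall-clock stage timings, and is the one output excluded from the
byte-stability contract. Archives are built with pinned member
timestamps so identical inputs produce byte-identical zips.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen once as comfortable for
the properties they exercise: 200+ random profile/sequence pairs
(M ≤ 4, L ≤ 6) for the scoring oracle; 50 random formulas with full
truth tables for the rule engine; 20 seeded communities of 5 taxa ×
2 samples × 8 decoys per proteome for end-to-end recovery; and
1-core vs 4-core runs for worker invariance. The published
precomputed-database summary shipped with the package records 2404
included taxa over six ranks; its grand-total arithmetic is recomputed
by `db_grand_totals()`.

## Known limitations

* Predicted functions are *metabolic potential*, not activity; an
  encoded enzyme may be silent in situ.
* Prediction quality degrades for little-studied clades: rank fallback
  uses increasingly distant consensus proteomes, and divergent marker
  enzymes may fall below profile cutoffs.
* 16S copy-number variation biases abundance weighting; no correction
  is applied.
* The unihit local scoring convention is simpler than a full
  HMMER-compatible pipeline (no multihit, no E-values); the scoring
  engine sits behind `call_hits()` so a different backend can be
  substituted without touching the calling layers.
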