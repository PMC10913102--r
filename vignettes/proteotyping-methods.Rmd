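---
title: "Cascade proteotyping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade proteotyping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxoproteo)
library(data.table)
```

## The inference problem

Tandem-mass-spectrometry proteotyping identifies a cultured microbial
isolate from the taxonomic signal carried by its detected peptides. An
isolate's tryptic peptidome overlaps strongly with the proteomes of its
close relatives and progressively less with more distant taxa, so every
peptide-to-spectrum match (PSM) carries information about where in the tree
of life the isolate sits. Two summaries drive the inference:

* **TSM** (taxon-to-spectrum match): a PSM counts toward a taxon when its
  peptide occurs in at least one organism below that taxon. Sibling taxa
  sharing a peptide therefore share its TSMs; this is deliberate, and it is
  what makes TSM profiles comparable across ranks.
* **spePEP** (taxon-specific peptide): a distinct observed peptide sequence
  that occurs in the organisms of exactly one taxon at a given rank.
  spePEPs are counted at the peptide level, not the PSM level, because
  specificity is a property of the sequence.

The *attribution rate* is `100 * TSM / recorded spectra`, rounded half-up
to one decimal. Both the count of recorded spectra and the count of total
PSMs are reported, since either denominator appears in practice.

## The cascade search

Searching every spectrum against a comprehensive reference is expensive and
statistically wasteful. The pipeline therefore runs three searches with
shrinking databases and tightening validation thresholds:

1. a capped batch of spectra (default 10,000, in scan order) against the
   species-dereplicated reference at precursor tolerance 3 ppm and
   validation p < 0.3; the genera of all matched organisms are retained;
2. all spectra against the database restricted to those genera and their
   descendants, at 5 ppm and p < 0.15; matched species are retained;
3. all spectra against the species-restricted database at 5 ppm and
   p < 0.05. These final PSMs feed the TSM/spePEP profile.

Digestion is tryptic (cleavage after K or R, not before P), up to two
missed cleavages, carbamidomethylation of cysteine fixed (+57.02146 Da) and
oxidation of methionine variable (+15.99491 Da); fragment tolerance is
0.02 Da and precursor charges 2+ and 3+ are considered. Because the
step-1 subsample is "the first *cap* spectra in scan order", the whole
cascade is deterministic. Steps 2 and 3 restrict the *dereplicated*
database built for step 1 rather than re-deriving a new one; profile
attribution and specificity are always assessed against the full
dereplicated index so that reduced search spaces cannot inflate
specificity.

Some defaults are conventions rather than community constants and are
exposed in `digest_params()`: peptide length bounds 7–35 residues (common
tryptic-search bounds; engines differ and rarely document them), no special
N-terminal methionine cleavage, and isoleucine/leucine folded onto one key
(`il_equivalent = TRUE`) because the two residues are mass-identical in
MS/MS and search engines cannot distinguish them.

## The built-in matcher

The package includes a small spectrum-to-peptide matcher so the cascade's
thresholds can be exercised end to end without a commercial engine.
Candidates are filtered by precursor neutral mass within the ppm tolerance
(including oxidised-methionine mass variants), scored by the number of
singly charged b/y fragments found within the fragment tolerance, and
assigned the binomial tail p-value $P(X \ge k)$ with
$X \sim \mathrm{Bin}(n_{frag}, p_0)$ and $p_0 = 2\,\mathrm{tol}\,m /
\mathrm{span}$ for a spectrum of $m$ peaks. This null is calibratable (the
test suite checks it against its analytic expectation on uniform-random
spectra) but it is *not* a reimplementation of any commercial score;
fragment m/z values are computed from fixed-modification residues only,
with variable oxidation entering through the precursor mass. External
search-engine output can bypass this module entirely: `run_cascade()`
accepts a PSM table (`spectrum_id`, `peptide`, `charge`, `p_value`) and
recomputes step membership from the taxa of the peptides retained at each
threshold. Ties between candidates break by smaller p-value, then more
matched fragments, then lexicographic peptide key, so results are
bit-identical across runs.

## Rank calling

Interpretation follows the rule that when similar numbers of TSMs and
spePEPs are spread over several closely related taxa, only the shallower
rank is valid. `call_params()` operationalises this with three documented
thresholds:

* `min_spepep = 50`: a confident taxon must carry at least 50 specific
  peptides. Below that, specificity is too sparse to exclude a sibling
  whose genome is simply missing from the database.
* `spepep_dominance = 5`: the top taxon must hold five times the runner-up's
  spePEP count at the same rank. Ambiguous profiles (e.g. three genera with
  351/108/49 specific peptides) fail this and push the call shallower.
* `species_tsm_dominance = 0.90`: the top species must retain at least 90%
  of its genus' TSMs. A sharp genus-to-species TSM drop is the signature of
  an unsequenced species. This ratio test applies at the species rank only:
  at shallower ranks TSM totals are increasingly dominated by conserved
  peptides and the ratio stops being informative, so confidence there rests
  on the spePEP tests.

The caller walks ranks species-first and returns the first confident rank.
Flags: `potential_new_species` when the call stops at genus;
`potential_new_genus` when the genus rank is ambiguous while at least two
genera each carry `min_spepep` specific peptides (decoupled from family
confidence — a genuinely novel genus typically makes its *family* rank
marginal too, as the bundled SS13 profile shows, where the family spePEP
ratio is 694/139, just under the dominance threshold);
`db_gap_suspected` when the top species holds under half the genus TSMs
but over 90% of the genus spePEPs, i.e. the database lacks a sibling
genome rather than the species itself. Expert judgment is replaced by
these explicit defaults; they reproduce the documented calls on the
bundled isolate profiles and are all configurable. Raising
`species_tsm_dominance` can only move calls shallower (the test suite
checks this monotone conservativeness).

Ties for the best taxon at a rank break by larger TSM, then larger spePEP,
then name — determinism again.

## Marker-gene concordance

16S rRNA percent identities classify with inclusive lower bounds:
≥ 98.7% species match, 95–98.7% potential new species (genus-level
identification only), < 95% potential new genus. ANI values use the
95–96% band (below: distinct species; above: same; inside: ambiguous) and
dDDH uses 70%. Only threshold classification of supplied values is in
scope; computing identities from sequences is not. `concordance()`
tallies genus/species name agreement (case-insensitive exact match — no
taxonomy-identifier mapping exists for marker hits) and novelty calls per
method, mirroring the usual concordance-table layout.

## The simulator: what it emulates, and what it does not

`simulate_reference()` evolves an ancestral proteome down a fixed-shape
taxonomy by per-residue substitution: 0.15 along family branches, 0.08
along genus branches, 0.02 along species branches. Those rates produce the
feature the inference consumes — tryptic-peptide sharing that decays with
phylogenetic distance (a 10-residue peptide survives a 0.02-rate branch
with probability ≈ 0.82 but a 0.15-rate branch with probability ≈ 0.2).
Amino acids are drawn with Swiss-Prot-like frequencies so tryptic site
density, and hence peptide length, is realistic.

`simulate_isolate()` samples per-spectrum source peptides with a power-law
skew (exponent 1.5) over proteins, emulating the dominance of abundant
proteins in spectral counts. Defaults are sized to the conditions of a
typical isolate run: 10,000 recorded spectra per isolate of which 60% are
noise (decoy peptides), so roughly 40% of recorded spectra yield validated
PSMs, matching commonly observed isolate attribution rates. The
`novel_species` scenario evolves a fresh sister branch inside a genus; the
`novel_genus` scenario mixes the ancestral proteomes of two genera of one
family and mutates the mixture at the between-genera rate, giving an
isolate whose specific peptides split across several database genera while
remaining family-coherent.

What the simulator does **not** model: insertions/deletions and gene
gain/loss, codon-level evolution, isotope envelopes, co-isolation,
intensity structure, chimeric spectra, or retention-time information.
Passing tests on simulated cohorts therefore demonstrate the correctness
of the accounting and the calibration of the decision rules under the
assumed sharing structure — not search-engine-grade identification
performance on real spectra.

## Numerical choices and degenerate inputs

* Percent rounding is half-up to one decimal everywhere
  (`round_half_up()`), matching how attribution rates are conventionally
  printed; banker's rounding would flip boundary cases such as 1.25%.
* Monoisotopic residue masses are tabulated to 5 decimals with water at
  18.0105646863 Da and the proton at 1.007276466879 Da.
* Lineages missing a canonical rank resolve to deterministic placeholder
  nodes named `unclassified <nearest-named-ancestor>_<rank>`, so per-rank
  accounting is total; the same lineage always yields the same placeholder
  identifier. Input ranks outside the canonical seven are kept as
  pass-through internal nodes and collapse onto the nearest canonical
  ancestor during lineage resolution (only empty ranks are rejected: a
  taxonomy dump's auxiliary ranks should not be load errors).
* A taxonomy with no explicit organism-rank nodes treats its species
  leaves as organisms, so minimal hand-written tables work unchanged.
* Species dereplication keeps the lexicographically smallest organism
  identifier per species — an arbitrary but reproducible representative.
* An empty database after a cascade reduction raises an error naming the
  step; an empty candidate set for a single spectrum is a non-match, not
  an error.

## Problem sizes

The bundled checks run the full cascade on cohorts of 2 families × 3
genera × 3 species with 200 proteins of mean length 300 per species and
10,000 spectra per isolate — about 300,000 indexed peptides per reference —
with 20 known-species and 10 novel-genus seeded replicates. These sizes
give stable recovery statistics while keeping a full replicate under ten
seconds; the structure of the inference does not change with database
scale, only the density of specific peptides does, which is exactly the
quantity the caller's thresholds guard.

## Known limitations

* spePEP counts depend strongly on reference density: a sparsely sequenced
  clade inflates specificity, a densely sequenced one deflates it. The
  caller's flags mitigate but cannot remove this.
* The binomial-null matcher ignores peak intensities and higher fragment
  charges; treat its p-values as calibrated ranks, not engine-equivalent
  significance.
* Name-based concordance cannot see through synonyms or reclassified
  genera; supply harmonised names.
* The attribution-rate denominator (recorded spectra vs total PSMs) varies
  between reports in the literature; both are available, and users should
  state which they quote.
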