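---
title: "Identifying fungal species from PCR-RFLP profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fungal species from PCR-RFLP profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpid)
```

## The problem

Ecological surveys of culturable yeasts routinely produce hundreds to
thousands of isolates that must be assigned to species cheaply before any
deeper characterization. PCR-RFLP of the ITS1-5.8S-ITS2 rDNA barcode is the
classical screen: the region is amplified with the universal ITS1/ITS4
primers, digested with a restriction endonuclease, and the resulting band
pattern on an agarose gel is compared to reference patterns. `rflpid`
implements the whole in-silico side of that workflow:

1. extract, from genome or ITS sequences, the exact amplicon the primer
   pair would produce (`extract_amplicon()`);
2. digest it in silico with any panel of enzymes (`digest()`) and collect a
   species-by-enzyme database of fragment-length profiles
   (`build_profile_db()`);
3. quantify how well each enzyme, or tuple of enzymes, separates the
   species (`rank_enzymes()`, `combined_stats()`,
   `indistinguishability_graph()`);
4. calibrate a model of gel sizing error (`fit_lm()`, `fit_varpow()`) and
   identify unknowns from measured band sizes by progressive selection
   (`identify_species()`);
5. search for small enzyme combinations that identify a species set
   precisely (`search_combinations()`).

A synthetic-data generator (`synth_genomes()`, `synth_calibration()`,
`simulate_measured_profile()`) produces genomes with planted primer and
restriction sites and gel-noise-corrupted measurements, so every step can
be validated against exact known truth without any external download.

## Amplicon extraction

Primer matching is substitution-only (Hamming) within the aligned window: a
window matches when its mismatch count is at most
`floor(error_rate * matched_length)`. Defaults follow common practice for
ITS amplification screens: `max_error_rate = 0.1`, with a relaxed pass at
`0.2`, a minimum end-overlap of 18 nt when a primer hangs off a sequence
end, and a minimum accepted span of 200 nt (genuine ITS1-5.8S-ITS2
amplicons are longer; shorter spans are treated as spurious). Indels are
deliberately not modelled: for 19-20-nt primers at these error rates a
one-base slip almost always costs more mismatches than the budget allows,
and substitution-only semantics are exactly testable against a
sliding-window oracle.

Extraction looks for a forward-primer match and, downstream, the reverse
complement of the reverse primer, and returns the convergent span
(coordinates are 0-based, half-open). Passes are attempted in order: strict
rate on the given strand, relaxed rate, then both again on the reverse
complement, the result re-oriented forward; `extraction_flags` records
which fallback fired. When several convergent pairings exist (multiple rDNA
copies), the 5'-most, innermost span is returned and a warning lists the
alternative span lengths. The reported length includes both primer binding
sites by default (`include_primers_in_length = TRUE`), matching what a gel
measures for the PCR product; the option exists because trimming-style
extraction would exclude them and the convention used by any given
reference database is rarely documented.

## Digestion and the profile database

A recognition site with IUPAC ambiguity codes denotes the set of all its
concrete expansions (`expand_iupac()`); every occurrence, overlapping ones
included, contributes a cut at `start + cut_offset`, and fragments are the
consecutive differences of the cut coordinates. Only top-strand coordinates
are modelled: the few-nucleotide overhang asymmetry of sticky ends is far
below gel resolution, and all comparisons downstream are on lengths.
Ambiguous bases in the *subject* sequence never match a site (conservative
and deterministic; a warning is emitted). Site-isoschizomers — enzymes
sharing a site but cutting at different offsets — are distinct entries by
default; `collapse_isoschizomers()` merges them into one entry per site,
since their length shifts (a few nt) are also sub-resolution.

`build_profile_db()` keeps the first record with a valid amplicon per
species, reports skipped inputs, drops enzymes whose site occurs in no
amplicon (they carry no information for the database; homing endonucleases
with 18-30-nt sites are the typical casualties), and groups species with
byte-identical amplicons — such species are indistinguishable under every
possible enzyme, and the build asserts exactly that. The database
serializes to a greppable TSV (one row per species x enzyme) plus a JSON
sidecar carrying sequences, parameters and the panel; the round trip is
lossless and byte-deterministic.

## Discriminative power

Two species are indistinguishable under an enzyme tuple when their fragment
multisets agree for every enzyme (`profile_key()`). An enzyme *identifies*
a species when that species' profile class is a singleton; this is the only
reading under which "profiles associated with a single species" is a
coherent count. Joint profiles refine partitions, so identifiability can
only grow as enzymes are added — an invariant the tests assert over random
databases. The indistinguishability graph restricts attention to species no
single enzyme identifies; edges join pairs identical under at least one
enzyme, weighted by the percentage of the retained panel under which they
are identical, so duplicate-sequence groups appear as 100 % cliques. The
weight denominator is the panel *after* zero-site exclusions — those
enzymes were never really "tested" on this database.

## The size-error model

Gel sizing errors grow with fragment size, and bands in one lane are sized
from the same fitted migration curve, so their errors are serially
correlated. The calibration regresses measured on expected size —
`measured = beta0 + beta1 * expected + e` — in two variants:

* **lm**: ordinary least squares, iid errors (`delta = phi = 0`);
* **varpow**: `Var(e_i) = sigma^2 * |mu_i|^(2 * delta)` with AR(1)
  correlation `phi^|rank_i - rank_j|` within a lane, ranks being migration
  order (descending size). The fit maximizes the Gaussian likelihood via
  generalized least squares (`nlme::gls` with `varPower` and `corAR1`
  structures, ML); since lm is nested at `delta = phi = 0`, the varpow
  log-likelihood can never be worse, and both models report ML
  log-likelihoods on the same scale. `calibration_loglik()` re-evaluates
  the block-diagonal likelihood independently of the fitting machinery and
  is used as a cross-check in the tests.

The regression is oriented physically (noise lives on the measurement);
identification needs the reverse question — which *true* sizes are
compatible with a measured one — so `permissive_range()` inverts the
level-0.95 prediction band `mu(x) +/- z * sigma * |mu(x)|^delta`
numerically (both band edges are monotone in `x` for a positive slope; the
roots are found by bracketed root-finding with tolerance 1e-8). With
`sigma = 0` the range collapses to a point. The band is plug-in: parameter
uncertainty of the calibration is not propagated, which is accurate for
calibration sets of a few hundred points and keeps coverage exactly nominal
under self-simulation (the suite checks 95 % +/- 2 % on 10^4 draws). The
interval level (0.95) and the detection limit (100 nt — fragments shorter
than that are not reliably seen on horizontal agarose gels and are excluded
from both query and reference profiles during identification) are
parameters of the model object.

## Progressive identification

A query consists of a measured amplicon length and measured profiles for
one or more enzymes, in a chosen order. Stage 0 keeps species whose
in-silico amplicon length falls in the permissive range of the measured
length. Each profile stage scores the surviving species and keeps the
maximum scorers (ties keep everyone: the output is a candidate set, not a
forced single answer). The score is the size of a maximum one-to-one
matching between measured and reference fragments, a pair being compatible
when the reference length lies in the measured fragment's permissive range
— computed exactly with augmenting-path bipartite matching (profiles have
at most a couple dozen fragments). Unmatched reference fragments do not
penalize by default, because faint bands are routinely missed on real gels;
`penalize_unmatched_reference = TRUE` switches to the stricter score.
Candidate sets therefore never grow, and an empty stage ends the run with
no identification — no backtracking, mirroring how an over-tight selection
behaves at the bench. With a zero-noise model, every database species
identifies itself from its own profiles, a property the suite asserts on a
100-species synthetic database.

Performance metrics follow the field's conventions: *identification* means
the true species is in the final candidate set; *precision* is the number
of species co-selected with it (lower is better).

## Combination search and pruning

Testing all ordered 5-tuples of a 143-enzyme panel would take
`count_ordered_selections(143, 5)` — about 5.6e10 — runs per query
species, so the search prunes. Stage-1 candidates are enzymes that alone
identify every sampled query species with fewer than 50 co-selected species
(capped at 80 by median co-selection); later-stage candidates are enzymes
that, in some pair with a stage-1 enzyme, improve the median co-selection
count by at least 25 % over the better single enzyme of the pair (capped at
22). Tuples take their first element from the first panel and the rest from
the later panel. Queries are the database's own in-silico profiles — the
uncertainty enters through the calibration model's permissive ranges — and
the query sample is seeded and recorded. On small instances the pruned
results are verified to be a subset of, and identical on survivors to, the
fully exhaustive enumeration (`prune = FALSE`). The per-enzyme aggregation
rules ("identifies every query", "median co-selection") are our reading of
selection criteria that are usually stated loosely; both thresholds are
exposed in `combo_config()`.

## What the synthetic data does and does not emulate

`synth_genomes()` builds each genome as
`pad + forward primer + core + revcomp(reverse primer) + pad`, with
restriction sites planted at known offsets into an otherwise site-free core
(rejection sampling against the planted enzymes' expanded site sets, with
verification over the assembled amplicon by an independent fixed-string
scan), so amplicon and fragment truth are exact by construction. Defaults
are chosen to look like a real ITS database: cores of 200-1000 nt (real
ITS1-5.8S-ITS2 amplicons span roughly 220-1020 nt), ~10 % of species
sharing another species' amplicon verbatim (real databases contain such
cross-species identical barcodes at about that rate), half the genomes on
the reverse strand, and 0-2 substitutions planted in the forward-primer
copy so the relaxed-rate and reverse-complement fallbacks are genuinely
exercised. The generator does **not** emulate phylogenetically correlated
sequence evolution, intragenomic rDNA copy variation, or realistic base
composition — so passing tests demonstrate the correctness of the
machinery, not the discriminative power any particular real enzyme panel
will achieve on real fungi.

`synth_calibration()` draws per-lane expected sizes, orders them by
migration, and applies the noise model with standardized AR(1) innovations;
its defaults (`beta0 = 2`, `beta1 = 0.97`, `sigma = 1.5`, `delta = 0.6`,
`phi = 0.4`) give a sizing error of roughly 10-25 % of fragment size
across the 100-1000-nt range — the coarse end of horizontal agarose gel
densitometry, deliberately pessimistic so that identification has to work
through wide permissive ranges — with clearly visible heteroscedasticity
and autocorrelation for the varpow model to recover.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open everywhere; cut coordinates at 0 or at
  the amplicon length produce no fragment and are discarded.
* Site scanning uses regular-expression lookahead over IUPAC character
  classes, so overlapping occurrences all cut; identical cut coordinates
  from different expansions are deduplicated.
* Ranking and search outputs are totally ordered (counts, then names) so
  every run is byte-reproducible.
* `fit_varpow()` requires at least two lanes with three points each;
  degenerate designs (a single expected value) are refused rather than
  silently fitted.
* All generator randomness flows from explicit seeds; building a database
  twice from the same FASTA yields byte-identical files.

## Validation problem sizes

The shipped suite validates digestion against a naive expanded-site scan on
1000 random sequence/enzyme pairs, extraction on 100 planted genomes over
both strands with 0-2 primer mismatches, partition refinement over all
enzyme pairs of a 50-species database, varpow parameter recovery on 50
replicates of a 40-lane x 8-band calibration design, permissive-range
coverage on 10^4 draws, self-identification on a 100-species database, and
pruning soundness on an 8-enzyme x 20-species instance. These sizes give
stable, seed-robust statistics while keeping a full run in the low minutes
on a laptop; `scripts/acceptance.R` recomputes the same quantities from
scratch at any seed.

## Known limitations

Thermodynamic PCR behaviour (melting temperature, amplification efficiency,
chimeras) is out of scope, as are methylation sensitivity, star activity,
partial digestion, and enzymes cutting outside their recognition site
(offsets outside the site are rejected). Primer matching tolerates
substitutions only. Taxonomy attached to database records is free metadata
and is not validated. The identification pipeline assumes one amplicon per
isolate; mixed templates (multiple co-amplified species) are not modelled.
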