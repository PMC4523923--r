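---
title: "Scoring, robustness and network integration of AP-MS screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, robustness and network integration of AP-MS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsweep)
library(dplyr)
```

apmsweep reimplements, as reusable and tested R functions, the
computational workflow used to mine a tandem-affinity-purification
mass-spectrometry (TAP-MS) screen of the cytosolic iron-sulfur protein
assembly (CIA) machinery for protein-protein interactions: probabilistic
scoring of bait-prey spectral counts, a parameter-sweep robustness
analysis, evidence-integrated network assembly, anchored-cluster term
enrichment, and a ribosome-footprint start-site correction. Every input
can be produced by a seeded synthetic-data generator, so all claims made
here are backed by recovery tests the package itself runs.

## The two-component Poisson interaction score

Spectral counts are semi-quantitative: the number of MS/MS spectra
assigned to a prey protein in one purification grows with its abundance
in the pulled-down complex. The scorer treats each bait-prey pair's
replicate counts as draws from one of two Poisson distributions -- a
background (contaminant) component with rate $\lambda_f$ and a true
interaction component with rate $\lambda_t$ -- and reports the posterior
probability of the true component:

$$
P(\text{true} \mid x) \;=\;
\frac{\pi\,\mathrm{Pois}(x \mid \lambda_t)}
     {\pi\,\mathrm{Pois}(x \mid \lambda_t) +
      (1-\pi)\,\mathrm{Pois}(x \mid \lambda_f)},
$$

evaluated per replicate (replicates where the prey was not observed
contribute $x = 0$) and averaged into `avg_score`. This concrete
posterior is this package's own contract: published probabilistic
scorers of this family state only that they model spectral counts with
Poisson distributions, so the component definitions below are
documented design choices, not a reimplementation of any specific
hierarchical model.

* $\lambda_f$ is estimated per prey from every purification in which it
  could appear spuriously -- all no-bait control runs plus the
  purifications of all *other* baits -- as
  $(S + a)/(n + a)$ with pooled count $S$, purification count $n$ and
  pseudocount $a = 0.5$. A floor of $0.01$ guards preys absent
  everywhere from degenerate posteriors.
* $\lambda_t = \max(\bar{x},\, 2\,\lambda_f)$, the pair's mean replicate
  count floored at twice the background. The factor 2
  (`min_enrichment`) keeps the two components identifiable for weak
  pairs; without it $\lambda_t \to \lambda_f$ and the posterior
  collapses to the prior for every count.
* $\pi$ (`prior_true`) defaults to 0.1: interactions are expected to be
  rare among observed pairs.

Purification universes (which replicates and control runs exist) are
fixed from the unfiltered tables: filtering discards records, not the
purifications that produced them.

Three switchable preprocessing options form the sweep's binary and
threshold axes:

* **Identification-score filtering** (`id_score_min`): records whose
  search-engine identification score falls below a threshold $m$ are
  dropped. Applied per record, i.e. at the protein level per
  purification -- whether the original filtering acted on peptides or
  proteins is not documented, and the synthetic data carries
  protein-level scores.
* **High-count capping** (`cap_high_counts`): counts above the 0.95
  empirical quantile of the retained nonzero counts are replaced by that
  quantile (type-7 linear-interpolation quantile, then floored).
  Whether "taking extremely high counts into account" meant capping,
  down-weighting or excluding is not documented; capping is this
  package's choice and is deterministic and bit-reproducible.
* **Spectral-count normalization** (`normalize`): each purification's
  counts are rescaled so its total matches the median purification
  total of its table, then rounded to nearest integer with ties to
  even. The median target is scale-free and deterministic.

## The parameter sweep and the robustness fraction

`build_parameter_grid()` enumerates the full cross of score thresholds
$\tau \in \{0.80, 0.81, \ldots, 0.95\}$, identification-score thresholds
$m \in \{10, 20, 30, 40, 50\}$, and both binary axes:
$16 \times 5 \times 2 \times 2 = 320$ combinations. The $\tau$ values
are built by integer index arithmetic (`lo + i * step`), not repeated
addition, so the grid has exactly 16 thresholds regardless of
floating-point drift. Scoring depends only on $(m, \text{cap},
\text{norm})$; $\tau$ decides calling, so `run_sweep()` scores the
dataset 20 times and thresholds 320 times.

A pair is *called* in a combination when `avg_score` $\ge \tau$
(inclusive: the source describes a "threshold" without strictness, and
inclusivity preserves the endpoint 0.95). Its **robustness fraction** is
the number of calling combinations divided by 320. Pairs reaching an
average score above 0.8 in at least one combination are **candidates**;
candidates with robustness $\ge 0.5$ are **robust**, others **low**.
The Methods text of the source says "$\ge 0.5$" where its figure legend
prints "$> 0.5$"; this package follows the Methods. At 320 combinations
the distinction matters only for a pair called exactly 160 times.

Bait-prey pairs are directional during scoring (each bait is scored
against its own purifications); reciprocal bait-bait observations are
merged at the network stage keeping the maximum robustness and score,
because reported edges are undirected.

## The five-class edge taxonomy

`assemble_network()` merges the robustness records with an external
evidence table (STRING-like: node pairs, confidence scores in $[0,1]$,
an `experimental`/`other` channel) into an undirected typed network:

| class | meaning |
|---|---|
| `TAPMS_SUPPORTED` | robust candidate with experimental evidence (any score) |
| `TAPMS_ROBUST` | robust candidate without external support |
| `TAPMS_LOW` | candidate with robustness < 0.5 |
| `TAPMS_MARGINAL_SUPPORTED` | max score in (0.7, 0.8] and experimentally supported |
| `EXTERNAL_ONLY` | evidence-only edge imported at score >= 0.9 |

For pairs observed in the screen, experimental evidence counts at any
confidence score; evidence-only edges are imported only at or above 0.9
(again following the Methods' "(0.9)" over the legend's ">0.9") and only
when they touch a screen bait or prey. Whether imported nodes may chain
through other imported nodes is ambiguous in the source
("reported connections to baits and preys"); the default is one-step
attachment, with chaining available via `chain_imports = TRUE`.
"High confidence interactions observed by TAP-MS" in the supported class
is read as *robust candidates*, paralleling the unsupported robust class
and differing only in external support. Where duplicate edges arise the
highest-precedence class (table order) wins; self-pairs (a bait pulling
itself) are dropped.

## Anchored clusters and term enrichment

Imported nodes with network degree exactly one whose sole neighbour is a
screen bait or prey are grouped into a cluster anchored at that
neighbour (`define_clusters()`); the membership is a partition by
construction. The source also curated additional clusters manually from
common neighbourhoods -- manual curation is not implementable and such
clusters can instead be supplied directly to `enrich_terms()`.

Enrichment uses the minimal standard reading of "GO enrichment
analysis", since test, correction and universe are unstated in the
source: a one-sided hypergeometric upper-tail p-value per term
(over-representation), Benjamini-Hochberg adjustment across terms
within each cluster, universe defaulting to all annotated nodes.
Terms are opaque labels; no ontology propagation is performed.

## Footprint binning and the start-site caller

Ribosome footprint 5' ends over a gene region (0-based, half-open
coordinates throughout) are counted into fixed windows, 30 bp by
default, matching the binning used in the source's footprint figure.
The original start-site correction -- a 108 bp (36-codon) shift of the
annotated start -- was called by visual inspection of the binned
profile; `call_start_codon()` operationalises that judgment with a
configurable rule: walking candidate start codons upstream to
downstream, choose the most upstream candidate whose mean per-bin
density downstream exceeds `ratio_min = 5` times the mean per-bin
density between the annotated start and the candidate, flooring the
upstream mean at one pseudoread per bin so empty leaders cannot yield
infinite ratios. Bins straddling a boundary are allocated pro rata by
base-pair overlap. If no candidate passes, the annotated start is
reported as supported with offset 0. A consequence of the "most
upstream passing candidate" rule: a decoy candidate inside an entirely
untranslated leader is indistinguishable from the true start when the
region between them is also empty, so candidates should be actual ATG
positions.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults chosen as the study conditions: 8 baits x 200 preys, 4
replicate purifications per bait, 4 no-bait control runs, a contaminant
background of 2 spectral counts per present prey, a 10-fold enrichment
of planted true pairs, and a planted density of 0.05.

* **Counts**: Poisson with rate `depth * background_rate * r`, where
  `r` is the enrichment for planted pairs and the presence indicator
  for contaminants. Zero counts are not emitted, as in real search
  output.
* **Depth factors**: log-normal per purification ($\sigma = 0.3$), so
  the normalization option has variation to correct -- without it the
  normalization axis of the sweep would be vacuous.
* **Sticky contaminants**: 30% of preys appear in most purifications
  (presence 0.9), including controls; the rest appear sporadically
  (presence 0.25). This gives the background estimator realistic
  structure, in lieu of any published description of the no-bait
  control strain's count distribution.
* **Identification scores**: each record's score is
  `count * U(5, 60)` -- a uniform per-spectrum score accumulated over
  the record's spectra, so a single-spectrum identification spans the
  5-60 interval while abundant true interactors exceed every threshold
  of the 10-50 sweep axis, as search-engine protein scores do. Scores
  *independent* of abundance would make the threshold axis delete
  true-pair records at random; with four replicates, one deleted record
  caps the average posterior at 0.75, which would contradict the
  intended behaviour of the sweep rather than probe it.
* **Evidence, annotations, footprints**: planted pairs gain
  experimental-channel edges with probability `support_prob`; imported
  `IMP` nodes attach to anchor nodes at scores >= 0.9; the planted
  annotation term covers a chosen subset plus background at 5%;
  footprint reads fall uniformly downstream of the true start except a
  `leak` fraction (1%) scattered over the whole region.

What the generator does **not** emulate: peptide-level identification
and protein inference, saturation of spectral counts for very abundant
proteins, correlated contaminant structure across purifications beyond
stickiness, bait-specific background, or the actual published footprint
profile of the corrected gene. Passing recovery tests therefore show
the pipeline is correct and well-calibrated *under its own assumptions*,
not that it would reproduce any specific biological interactome.

## Analysis choices worth knowing

* When scoring generator output outside the sweep, normalization should
  be on: the planted depth variation is exactly what it corrects, and a
  single low-depth replicate can otherwise pull a true pair's average
  posterior just below 0.8. Inside the sweep both settings are explored
  by construction.
* A prey planted as a true interactor of several baits contaminates its
  own background estimate (the other baits' purifications enter
  $\lambda_f$). At the default density this inflates $\lambda_f$
  mildly; in small screens with few baits it is the dominant cause of
  missed planted pairs.
* Problem sizes used by the test-suite recovery checks: full 320-combo
  sweeps on 8 x 200 screens for three seeds, 100-seed Monte-Carlo loops
  for scoring and enrichment, 20-seed loops for the start caller, and a
  codon-resolution (3 bp window) binning for the codon-offset property,
  since a 30 bp bin cannot resolve a sub-window extension.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
manifest <- run_pipeline(cfg, outdir = "apmsweep_demo")

sim <- simulate_apms(synth_config(seed = 1))
sw <- run_sweep(sim$counts, sim$controls, build_parameter_grid())
tidy(sw)        # per-pair robustness records
glance(sw)      # sweep summary
autoplot(sw)    # robustness histogram
```
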