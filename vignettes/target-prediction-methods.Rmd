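---
title: "Ligand-based target prediction: models, evaluation, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based target prediction: models, evaluation, and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetfishr)
library(dplyr)
```

## The problem

Target fishing asks: given a small molecule, which proteins is it likely to
act on? targetfishr implements a complete ligand-based answer as a
pipeline of tidy data frames: bioactivity records are curated into a
knowledge base of labeled compound-target pairs, two rankers order all
candidate targets for a query compound, and an evaluation layer measures
how reliable those rankings are as a function of how far the query sits
from the knowledge base.

## Curation model

Raw records carry ChEMBL-style annotation fields. A record survives
extraction only if its assay maps confidently to a single protein or
complex (confidence score 7 or 9), its validity and duplicate flags are
clean, its endpoint is one of Kd, Potency, AC50, IC50, Ki or EC50, its
activity comment is not inconclusive, and it is not a censored lower bound
below 20 µM (`>`-type relations with values under 20,000 nM carry no usable
evidence of activity or inactivity). Each removed record is attributed to
the first failing rule so the audit sums to the input count; the kept set
does not depend on rule order, since a record must pass every rule.

Values reported in µg/mL are converted to nM through the molecular weight
(`value × 10^6 / MW`). When curating real SMILES, the weight is computed
from the standardized structure's formula; we default to the monoisotopic
convention and expose `mass = "average"` as an alternative, since either
reading is defensible and the choice only shifts converted values by well
under one percent.

Measurements of the same stereochemistry-free structure against the same
target are consolidated to their median (mean of the two central values for
even counts). Pairs at or below 10,000 nM are *active*; at or above
20,000 nM *inactive*; the ambiguous band strictly in between is discarded.
The knowledge/test split is at compound level — all annotations of a
compound travel together, so no query can leak its own structure into the
reference data. Each compound's side is decided by a uniform draw from an
RNG seeded with (seed, structure key), and the draws are ranked so the
split hits the requested 90:10 ratio exactly up to rounding.

Structure standardization delegates to OpenBabel: salts are stripped to the
largest fragment whose elements sit on a configurable allow-list (default:
the organic subset H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I), compounds
with off-list elements are rejected, and stereo/isotope markings are
removed before canonicalization, so stereoisomers share one structure key.

## The two rankers

Both rankers operate on 0/1 fingerprint vectors. For real molecules the
package computes a radius-2 circular hashed fingerprint (the
Morgan2/ECFP4 family, default 2048 bits) over the atom/bond graph; every
synthetic workflow supplies raw bit vectors directly, which keeps the whole
pipeline testable without a molecular parser.

**Similarity ranker.** A target's score against a query is its similarity
profile: the Tanimoto coefficients between the query and each of the
target's active ligands, sorted descending. Targets are ordered
lexicographically on these profiles — the first entry is the familiar
maxTC; ties consume the next-nearest neighbor, then the one after, until
ranks are unambiguous. Two deliberate conventions close the gaps the
lexicographic rule leaves open: when one profile is a strict prefix of
another, the longer profile wins only if its next entry is positive
(extra neighbors at similarity zero are not evidence); and profiles equal
to exhaustion fall back to the alphabetical target id, because a ranking
must be deterministic to be testable. The Tanimoto coefficient of two
empty fingerprints is defined as 0.

**Random-forest ranker.** Binary relevance: one probability forest per
target with at least 25 active ligands (the threshold is a parameter;
raising it trades coverage for per-model data). Each training set holds
the target's actives, all of its confirmed inactives, and — unless
confirmed inactives already exceed ten times the actives — presumed
inactives sampled uniformly from knowledge-base compounds with no
annotation of either sign for that target, topping the class up to exactly
10:1. Hyperparameters (trees in {200, 500, 1000} × depth in
{25, 45, 50, 75, 100}) are picked per target by mean Matthews correlation
coefficient over stratified 10-fold cross-validation; the fold partition is
fixed per seed and shared across the grid so cells differ only in
hyperparameters. Folds are stratified by class because unstratified folds
on 10:1 imbalance can lose the active class entirely; a degenerate MCC
denominator is defined as 0; score ties on the grid resolve toward fewer
trees, then smaller depth (the cheapest adequate model). Queries are
ranked by each model's probability of the active class, with exact
probability ties resolved by the similarity profiles and, ultimately, the
id tie-break. Probabilities are compared exactly — forests of equal size
produce rational scores, so exact ties are real and the rule matters.

Every stochastic step derives its RNG stream from a hash of the global
seed and the entity's identity (target id, compound key), so any single
target or compound can be reproduced in isolation, in any processing
order.

## Evaluation framework

Two metrics at each rank cutoff k: the **success rate** (share of queries
with at least one known target in the top k) and the **recovery rate**
(share of known (query, target) pairs whose target lands in the top k).
Three scenarios select the evaluation set: an external random split of the
processed data; a time-split restricted to later-release queries with at
least one target covered by the knowledge base; and a close-to-real-world
setting that keeps every later-release query and pair, including those
whose targets the knowledge base cannot represent — such pairs are
unrecoverable by construction and deliberately stay in the denominators.
Queries missing a ranking are failures in the real-world scenario and an
error elsewhere.

Both metrics are deconvoluted by similarity to the knowledge base: a pair
is binned by its own maxTC, a query by the median maxTC over its covered
targets (high > 0.66, medium 0.33–0.66, low < 0.33, plus half-open
width-0.2 bins with TC = 1 closed into the top bin). Queries with no
covered target form an explicit `uncovered` bin rather than being dropped,
so per-bin numerators and denominators always partition the overall
counts, and every rate is reported with its integer counts.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defines the study conditions; `simulate_study()` runs
them. Each target is a ligand cluster built from a core bit pattern with
independent per-position flips; activity values are log-uniform on the
active (≤ 10 µM) and inactive (≥ 20 µM) sides with a slice of ambiguous
values in between; a configurable number of records violating each
extraction rule is planted with known counts; and a later-release
increment draws new queries at prescribed similarity bands plus a fraction
annotated only to novel targets.

The defaults are 20 targets × 40 ligands on 256-bit vectors, 48-bit cores,
4% flips, 5 confirmed inactives per target, 5% ambiguous values, 20
planted violations per rule, and 40 release queries per band with 10%
novel-only queries. Two calibration choices matter and were fixed once, by
design: 90% of core positions are drawn from a shared pool of 48 positions,
and release-query edits add bits drawn from the occupied positions of the
knowledge base (those set in at least 5% of compounds). Together they give
clusters genuine mutual confusability — queries distant from their true
target drift into other targets' bit space and rank near-randomly, while
close queries still rank their target first. Without them, a query with
maxTC 0.4 to its target and ~0.2 to everything else would be trivially
easy, and the similarity deconvolution would show nothing.

Problem sizes throughout the test suite and the acceptance script are desk
scale (tens of targets, hundreds of compounds, 256-bit vectors), chosen so
the full study — curation, split, both rankers, three scenarios — runs in
seconds to minutes on a single core; the reference forests in the
qualitative band-ordering study are trained at fixed hyperparameters
(200 trees, depth 25) rather than with the full grid, which is exercised
separately on the separable benchmark.

What passing synthetic tests shows: the machinery is correct — filters
remove exactly what they should, rankers agree with brute-force oracles,
rates are exact fractions with partitioning bins, and the qualitative
high > medium > low reliability ordering emerges for both rankers. What it
does not show: real chemical space has scaffold structure, activity cliffs
and target families that independent bit flips cannot mimic, so absolute
rates on synthetic data say nothing about absolute rates on real
databases.

## Numerical and degenerate-input conventions

* Tanimoto of two all-zero fingerprints: 0; empty ligand sets are an error
  (a target without active ligands has no similarity scope).
* Median of an even count: arithmetic mean of the two central values.
* Unicode `≥` and ASCII `>=` are the same censored relation; comment
  matching is literal in case ("Active"/"active" rescue a missing
  relation, "ACTIVE" does not).
* Records in units other than nM and µg/mL, and µg/mL records whose
  molecular weight cannot be computed, are discarded with their own audit
  category — silently keeping them would corrupt labels.
* Rejection sampling for banded queries errors after a bounded number of
  edit attempts rather than looping forever.

## Limitations

The ML ranker restricted to small targets (few actives) is sensitive to
the presumed-inactive sample; only the seed protocol makes it
reproducible. The evaluation assumes one ranking per query per method;
ensemble fusion across rankers is out of scope, as are alternative
fingerprints, other learners, and statistical tests between methods.

## A worked run

```{r run, eval = FALSE}
study <- simulate_study(synthetic_spec(seed = 1))
truth <- build_truth(study$release$pairs, study$kb, study$release$query_fp) |>
  scenario_filter("time_split_covered")
rankings <- rank_targets_similarity(study$release$query_fp, study$kb)
report <- evaluate_rankings(rankings, truth, "time_split_covered")
glance(report)
autoplot(report)
```
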