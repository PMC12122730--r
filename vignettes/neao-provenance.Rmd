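---
title: "Describing electrophysiology analyses with NEAO: model, capture, and queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Describing electrophysiology analyses with NEAO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neaokg)
```

This vignette is the package's account of its science: the ontology model and
the inference rules it commits to, how provenance is captured and mapped, what
the synthetic session does and does not emulate, and the numerical and design
choices made where the design was genuinely open.

## The model

NEAO describes an analysis as a sequence of atomic **analysis steps**. Three
classes carry the model: `AnalysisStep` (a process that generates, transforms,
or characterizes data), `Data` (what steps consume and produce), and
`AnalysisParameter` (a value that modulates a step's behavior without being
data). Steps link to data via `hasInput`/`hasOutput`, to parameters via
`usesParameter`, and to their code via `isImplementedIn` (a `Function` or
`Program`) and `isImplementedInPackage` (a `SoftwarePackage` with name and
version literals). Every class carries one `skos:prefLabel`, a comment,
optional `skos:altLabel` synonyms and `abbreviation` literals (so "PSD",
"spectrum", and "power spectral density" all resolve to one class via
`lookup_term()`), and method classes point to bibliographic-reference
individuals with a citation string and a resolvable identifier.

Cross-cutting groupings use Rector normalization: a grouping class such as
`FunctionalConnectivityAnalysis` is declared *equivalent* to a value
restriction (`hasPurpose` value `FunctionalConnectivityPurpose`), and method
branches such as `CoherenceAnalysis` are declared *subclasses* of the same
restriction. A reasoner then infers the grouping without it ever being
asserted in the primary taxonomy. The same pattern with the boolean-valued
`isDirected` property yields `DirectedAnalysis` / `NonDirectedAnalysis`.

### Inference: a bounded rule set, not a full reasoner

`materialize_inferences()` computes the least fixpoint of four rules in the
spirit of the OWL2-RL profile:

1. subclass reflexivity and transitivity;
2. if class *C* is asserted under a value restriction *r* and grouping class
   *G* is equivalent to *r*, then *C* ⊑ *G*;
3. individual typing is closed over the inferred hierarchy;
4. any individual with at least one `hasSubstep` assertion is typed
   `CompoundAnalysis`.

These four rules are exactly what the package's queries require; full
description-logic reasoning (consistency checking, arbitrary
`someValuesFrom` classification) is out of scope. The fixpoint is monotone,
so adding axioms can only add entailments — the test suite checks this
property, and checks the whole materialization against an independent
brute-force fixpoint on small random ontologies.

Two modeling points were left open by the source material and were decided
here:

- `hasSubstep` is treated as **non-transitive**; nothing in the competency
  questions requires nesting.
- The axiom connecting `ExecuteASSETAnalysis` to its substeps is stored as an
  **existential** marker (`hasSubstep` some `ASSETAnalysisSubstep`). The
  compound classification itself is operational (rule 4), which matches how
  the class is actually used: an individual with substeps *is* a compound
  analysis.
- `SpikeTrainSurrogateGeneration` is deliberately **not** a subclass of
  `ArtificialDataGeneration`: the "files that used artificial data" query
  must return only the artificial-process results, not the surrogate
  results, so the two branches sit side by side under `AnalysisStep`.

## Provenance capture and the knowledge graph

`track_execution()` runs a routine exactly once and records a PROV-style
execution: `prov:used` edges to input entities, `prov:generated` edges to
outputs, parameter nodes with name/value/unit literals, a function node with
the function name and package name/version, and `prov:hadMember` pairs when a
routine returns a container of semantically annotated objects (e.g. 30
surrogate spike trains). File writes and reads are separate save/load steps
anchored on file nodes keyed by the (run-relative) path.

Entity identity is **content addressing within a run**: the IRI embeds a
SHA-256 digest of the value's serialization, so the same array reappearing in
a run maps to one node, giving stable join keys without object identity.
Identity is scoped to the run on purpose. Numerically identical intermediates
across different analysis variants are not rare coincidences but systematic:
the two Welch parameterizations produce bit-identical spectra, and a
trial-shifted surrogate whose shift wraps no spike has exactly the original
interspike-interval vector. Global content addressing would merge such
derivation chains across analyses and corrupt per-file attribution; file
nodes (keyed by path) remain the cross-run join points, which is what the
derived-file queries actually need. Parameter values are stored as typed
literals with the unit as a separate literal, plus a pre-formatted text
rendering (e.g. `"250.0 Hz"`) that the mapping exposes through `rdf:value`
for query tables. Random seeds are recorded as ordinary (unclassed)
parameters so runs are replayable without seeds appearing in parameter
tables.

`build_knowledge_graph()` merges provenance with the ontology and
materializes the subclass closure and individual-type closure into the graph
(the in-process analogue of loading into a triple store with an RL ruleset).
The mapping rules — `hasInput` from `prov:used`, `hasOutput` from
`prov:generated` (guarded by `Data` typing), `usesParameter` from the capture
parameter edges (guarded by `AnalysisParameter` typing), software individuals
from the captured function/package info, and the container-output rule — are
implemented twice: as vectorized native traversals and as SPARQL UPDATE texts
shipped under `inst/sparql/`. The test suite asserts the two forms produce
identical graphs; parameter and software nodes use deterministic (skolemized)
IRIs rather than blank nodes so query CSVs are byte-stable.

Queries are native traversals over the triple table, with igraph providing
reachability on the derivation relation (entity → execution via used,
execution → entity via generated, container → member). Chain queries are
checked against an independent breadth-first search, and representative
queries also ship as SPARQL text executed by a small built-in engine (basic
graph patterns with property paths; no FILTER/OPTIONAL). Row order is
lexicographic on all columns — the published tables are unordered, but
deterministic ordering makes outputs reproducible.

## The synthetic session

The demo analyses run on a generated session emulating the *structure* of a
142-correct-of-161-trial multi-electrode reach-to-grasp recording:

- 161 trials of 5-channel continuous signal at 1000 Hz; trial duration 4 s,
  except trial 142 at 0.3 s — shorter than the 0.5 s Welch window at 500 Hz,
  so the spectral step fails with an "insufficient data" error and the
  runner skips it. The 160-file count per PSD variant is therefore produced
  by the skip logic, not a hard-coded list. Trial 142 is also among the 19
  trials flagged behaviorally incorrect, so the surrogate analysis (correct
  trials only) never sees the short segment.
- Continuous signals are white noise (SD 1) plus a 20 Hz sinusoid of
  amplitude 2 with random phase per channel — enough structure for PSDs to
  show a verifiable peak at a known bin.
- Ten spiking units, Poisson at their annotated rates
  (20, 25, 16, 3, 18, 22, 30, 17, 15, 19 Hz) with SNR annotations
  (6.1, 2.0, 5.0, 7.3, 5.5, 9.0, 4.2, 8.1, 6.7, 3.0). The selection filter
  (SNR ≥ 5 and rate ≥ 15 Hz) passes exactly units 1, 3, 5, 6, 8, 9 — six
  units, by construction of the annotation lists, the way unit selection
  operates on annotations in the published dataset.

What the generator does **not** emulate: real LFP spectra (1/f shape,
oscillatory bursts), spike waveforms or actual SNR computation, behavioral
structure beyond a correct/incorrect flag, non-stationary firing rates, or
the NIX/Neo data model (the session is serialized with `saveRDS()`). Passing
tests therefore demonstrate that the *description machinery* — annotation,
capture, mapping, querying — behaves correctly on realistically shaped
pipelines, not that any scientific conclusion about neural data holds.

## The demo analyses and their parameters

| Analysis | Step | Parameters (defaults) |
|---|---|---|
| 1.1 | Welch PSD, resolution form | frequency resolution 2 Hz, overlap factor 0.5, hann |
| 1.2 | multitaper PSD | 4 tapers, time-bandwidth 4 |
| 1.3 | Welch PSD, samples form | fs 500, window 250 samples, overlap 125 samples, hann |
| 1.* | preprocessing | Butterworth order 4, low-pass 250 Hz; downsample to 500 Hz |
| 2.1 | uniform spike dithering | dither 25 ms, 30 surrogates/trial, ISIH bins 5 ms |
| 2.2 | trial shifting | dither 30 ms, 30 surrogates/trial, ISIH bins 5 ms |
| 3 | Poisson + gamma(1) trains | 100 + 100 trains, 10 Hz, 100 s, ISIH bins 10 ms |

Notes on the open or derived choices:

- **Dither time for uniform dithering.** The source material states both
  15 ms and 25 ms in different places; the configuration tables and methods
  agree on 25 ms, so the demo uses 25 ms. The discrepancy is documented, not
  resolved.
- **Zero-phase filtering.** Only order and cutoff are prescribed;
  forward–backward application was chosen to match common toolbox behavior.
  Two passes square the magnitude response: DC gain is exactly 1 and the
  gain at the cutoff is 0.5 (−3 dB twice). The implementation filters an
  odd-reflection extension of the segment so edge transients decay inside
  the padding (pad length `max(9·(order+1), 6·fs/fc)` samples, capped at the
  segment length).
- **Welch conventions.** Periodic Hann window; one-sided density
  normalization `2/(fs·Σw²)` with DC and Nyquist bins not doubled; no
  detrending. Both parameterizations call one estimator core, so equivalent
  settings are bit-identical — the result objects record *which* entry point
  produced them, mirroring the fact that different toolboxes return
  different result types even when the numbers agree (and keeping the two
  variants' provenance distinct).
- **Multitaper.** DPSS tapers come from the standard symmetric tridiagonal
  eigenproblem (dense `eigen()`, cached per segment length; ~2 s once for
  2000-sample segments). No published multitaper parameters exist for the
  scenario, so the defaults (4 tapers, NW = 4) claim only estimator-class
  behavior, verified by Parseval and single-taper reduction tests. The demo
  applies the same 0.5 s minimum-segment rule as the Welch variants, so the
  short trial is skipped in all three PSD variants.
- **Trial shifting wraps circularly** within the trial window. The method's
  defining property is that it preserves the ISI distribution; a circular
  wrap changes at most two intervals of the multiset (tested), while a
  non-wrapping shift would lose edge spikes.
- **Histograms** are half-open `[0, t_max)` bins; intervals at or beyond
  `t_max` are discarded. `t_max` is 0.25 s for the surrogate analysis (50
  bins of 5 ms; unit rates ≥ 15 Hz put essentially all mass below 250 ms)
  and 1 s for the artificial trains (100 bins of 10 ms at 10 Hz).
- **CV2** is the mean of `2|I(i+1) − I(i)| / (I(i+1) + I(i))` over
  consecutive interval pairs; it errors below two intervals. Its expectation
  for a stationary Poisson process is 1, which the tests verify against a
  Monte-Carlo oracle.
- **Seeds.** Each run derives per-trial/per-surrogate seeds from its master
  seed by a counter (`derive_seed()`, kept below 2³¹), and the seeds are
  recorded as parameters, so every run is exactly replayable.
- **Rendering.** Plots are drawn behind a renderer interface: the default
  uses a PNG graphics device; a headless fallback still writes valid PNG
  files so file-count semantics are testable without a display.

## Problem sizes and scope

The full study conditions (161 trials × 5 channels, 6 units × 142 trials ×
30 surrogates × 2 variants, 200 artificial trains) run end-to-end in a few
minutes on one CPU and produce a knowledge graph of about a million triples;
the acceptance checks run at exactly these conditions. Module tests use a
scaled-down session (6 trials, 3 units, 3 surrogates) since they exercise
machinery, not the study conditions.

Known limitations: the SPARQL engine covers only the pattern fragment the
shipped queries need; the ontology subset implements the classes the demo
analyses require (plus the grouping examples and the ASSET axioms), not the
complete released vocabulary; no OBO/BFO or unit-ontology alignment is
attempted; and provenance capture does not introspect object internals
beyond content digests and container membership.
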