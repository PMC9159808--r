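---
title: "Molecular holograms and PLS-DA for transporter-inhibition classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular holograms and PLS-DA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`holopls` classifies small molecules as inhibitors (1) or non-inhibitors
(0) of the ABCG2 efflux transporter from 2D structure alone. This vignette
is the package's own account of the science: the model, its assumptions,
the tunable parameters, the numerical conventions, what the synthetic data
do and do not establish, and the design decisions taken where the
underlying method description left the design open.

## 1. The molecular hologram

A hologram is a fixed-length integer vector of hashed fragment counts.

**Fragments** are connected *vertex-induced* subgraphs of the heavy-atom
graph with atom count inside a window `[min_atoms, max_atoms]`. Induced
subgraphs (all parent bonds among the selected atoms included) naturally
cover linear, branched and cyclic fragments and keep the enumeration
well-defined; edge-subgraph enumeration was rejected as combinatorially
redundant. Enumeration uses the ESU algorithm (each subgraph visited
exactly once) in compiled code, with a per-molecule occurrence cap
(default 2×10⁶) guarding pathological inputs; drug-like molecules do not
approach it.

**Fragment identity** is a canonical key of the labelled subgraph. Element
and formal charge always label atoms; the distinction flags add:

| flag | adds to identity | default |
|------|------------------|---------|
| A    | aromatic flag on atoms | on |
| B    | bond orders on edges (aromatic as its own class) | off |
| C    | the atom's heavy-atom degree *in the parent molecule* | on |
| D    | hydrogen-bond donor/acceptor classification | off |
| H    | hydrogens as explicit fragment atoms | off |

The flag semantics beyond the letter key are not published; they follow
the HQSAR convention and are fixed here as documented. Canonicalization
finds the lexicographically minimal "connected ordering" code of the
labelled graph by backtracking (branching only on ties), which is exact
for the fragment sizes allowed (≤ 11 atoms); the unit suite cross-checks
it against an independent BLISS-based oracle (igraph) on an
edge-subdivided coloured graph.

**Hashing.** Each unique key string receives a CRC-32 checksum (IEEE
polynomial, zlib-compatible, verified against frozen zlib values and an
independent bitwise implementation) and occupies bin
`CRC32(key) mod L + 1`. Colliding fragments share a bin; no de-collision
is attempted — faithful to hologram hashing, and the reason hologram
lengths are primes/prime-like values (allowed set: 53, 59, 61, 71, 83, 97,
151, 199, 257, 307, 353, 401). Bit-for-bit compatibility with the
commercial HQSAR implementation is a non-goal (its CRC variant is
unpublished); internal consistency is the contract, and total occurrence
counts are invariant to `L` by construction.

**Defaults** (`hologram_config()`): size 5–8, distinctions A/C, L = 353 —
the best-performing configuration of the parameter screens this package
re-implements (the `sweep` CLI subcommand reruns both screens: ten
distinction sets at size 4–7, and eight size windows 1–4 … 8–11 at A/C).
The screens' source description mentions ten size models but prints only
eight; the sweep covers the printed eight.

## 2. PLS-DA

The 0/1 response is regressed on the hologram matrix by PLS1/NIPALS after
auto-scaling (per-column mean/SD with ddof = 1; zero-variance bins dropped
and recorded). Coefficients are reconstructed as `b = W(PᵀW)⁻¹q`, so at
full component count they coincide with ordinary least squares — the test
suite asserts agreement with an `lm` oracle to 1e-8. Degenerate deflation
stops early with a warning rather than fabricating components.

Component count is selected by stratified k-fold cross-validated accuracy
(default 10 folds), ties towards the smallest k, all randomness seeded.
Design choices the method description left open, fixed here once:

* response coding 0/1 with cutoff 0.5; scores exactly at the cutoff
  classify as 1 (documented boundary convention);
* stratified folds (class imbalance would otherwise risk single-class
  folds; plain k-fold rejected for that reason);
* selection criterion = CV accuracy, not PRESS/Q², because every model
  comparison in the source screens is accuracy-based;
* component cap `k_max = min(15, rank bound)`; the screens do not report
  chosen component counts.

Models serialize to JSON at 17 significant digits, which round-trips IEEE
doubles exactly: a reloaded model reproduces predictions bit-for-bit on
the same platform.

## 3. Descriptor-side machinery

**Stepwise selection** reproduces the descriptor-table protocol: ordinary
linear regression of the *binary* class labels (deliberately not
"improved" to logistic regression — the original selection is linear),
forward steps adding the smallest partial-F p-value ≤ 0.02, backward steps
removing any variable with p ≥ 0.10, iterated to a fixed point,
deterministic with ties broken by column order. That no variable happened
to be removed in the original run is treated as an empirical outcome, not
a constraint: the removal step is implemented and exercised (on collinear
designs it demonstrably fires and the result matches an exhaustive
best-subset oracle).

**The threshold rule.** The published rule — BV12-DRY > −0.1 ⇒ inhibitor —
is a `rule_model` with strict inequality (equality → 0). BV12-DRY itself
(a GRID/VolSurf "best hydrophobic volume" descriptor) is proprietary and
never computed here; its values arrive as a CSV column.
`calibrate_threshold()` generalizes the by-inspection choice: it scans all
midpoints of adjacent sorted unique values and maximizes balanced accuracy
(mean of SEN and SPE), ties towards the smallest threshold, direction by
whichever sign scores higher.

## 4. The integrative classifier and its central design decision

The published two-stage integration re-evaluates the *misclassified*
compounds with the rule — a label-aware procedure that cannot run on
unknown data. The package therefore ships both:

* `oracle_eval` — the faithful label-aware mode, for mirroring the
  published evaluation; its output is flagged `label_aware` and by
  construction its accuracy is ≥ the PLS-DA-alone accuracy (asserted);
* `deploy` — a label-blind variant: compounds whose continuous PLS-DA
  score falls inside an ambiguity band `[cutoff − δ, cutoff + δ]`
  (default δ = 0.15) are re-assigned by the rule.

This split is the central gap between the published procedure and a
deployable artifact. Whether the published improvement would survive a
label-blind integration is untested in the source; the deploy mode's
benefit is therefore reported on synthetic data only, and no claim is made
that the band mode reproduces the published integrative accuracies.

## 5. Metrics

ACC, SEN, SPE and MCC follow the standard confusion-matrix definitions
with positive class = inhibitor. Conventions: SEN/SPE with an empty
denominator are reported as missing with a warning (never a silently
optimistic value); an MCC denominator of zero yields 0 by convention,
logged. Report display rounds half-up to 2 decimals (matching the source
tables); machine outputs keep full precision.

One cell of the source tables is internally inconsistent: the rule model's
internal-validation row (TP=144, TN=144, FP=46, FN=34) prints MCC = 0.56,
but those counts give exactly 19172/33820 = 0.5669 → 0.57 at 2 dp, and no
consistent rounding produces 0.56 (truncation would contradict the ACC in
the first external-validation row). The acceptance suite asserts the
printed value and is deliberately left red on exactly that expectation;
the unit suite asserts the arithmetic-correct value.

`repeated_split_eval()` implements the 1000-times repeated random-split
robustness protocol; the split proportion is unstated in the source, so
the default mirrors the 2:1 training/validation division of the dataset.

## 6. Atomic contribution maps

For each fragment occurrence, every atom receives the PLS coefficient of
the fragment's bin divided by the fragment's atom count; an atom's score
sums over the occurrences containing it (occurrences, not unique keys: an
atom participating in many fragments accumulates more). Coefficients are
taken on the original count scale (`coef_original`); dropped bins
contribute zero. Conservation — Σ atom scores = Σ occurrence
coefficients — holds exactly and is asserted molecule-by-molecule. When
the H flag places explicit hydrogens in fragments, each hydrogen's share
folds into its bonded heavy atom, keeping conservation exact (scores are
defined over heavy atoms). Colliding fragments share a coefficient — the
known, documented caveat of hashed holograms. Scores are emitted raw
(whether the original colour-coding normalized is unstated).

## 7. The synthetic world

The fixture generator emulates the two statistical structures the models
assume, with every default fixed before any acceptance measurement:

* **Planted fragments**: class 1 built from aromatic biphenyl, quinoline
  and chromene scaffolds (the fragment families reported as
  high-contribution), class 0 from aliphatic/small-polar scaffolds
  (cyclohexane, morpholine, short chains), each with random substituents
  at template sites (decoration rate 0.5 — unstated anywhere, chosen once
  as a middle-of-the-road decoration density);
* **Surrogate descriptor**: Normal(0.4, 0.35) vs Normal(−0.6, 0.35),
  placing the Bayes boundary at −0.1 so the published rule threshold is
  meaningful on synthetic data *by construction* — a design convenience,
  not a claim about real BV12-DRY distributions;
* **Label noise** 0.05, so perfect scores cannot mask bugs.

All outputs are bytewise deterministic in the seed. What a green synthetic
test establishes: the pipeline recovers a strong planted fragment-class
association (held-out accuracy ≥ 0.85) and the descriptor rule performs at
its Gaussian-overlap level (≈ Φ(0.5/0.35) ≈ 0.92 before label noise,
asserted inside [0.70, 0.95]). What it does not establish: performance on
real chemical space, the published screen accuracies (Tables of the
source require the unpackaged 1,104-compound dataset and proprietary
descriptors), or any property of real BV12-DRY values.

## 8. Other numerical choices and limitations

* SMILES support covers the organic subset, brackets with charge/explicit
  H, ring closures (incl. `%nn`), branches and dot-disconnection; stereo
  marks are parsed and discarded (no distinction flag uses chirality).
  Aromaticity is taken from the input (lowercase/bond type 4), with
  unspecified bonds between aromatic atoms aromatic only inside rings.
  3D geometry, charge assignment and force-field minimization are out of
  scope: every descriptor computed here is 2D.
* Salt stripping keeps the largest fragment by heavy-atom count; ties
  break by the lexicographically smallest canonical serialization.
* Circular fingerprints (radius 3 = ECFP_6 diameter, 2048 bits — width
  unstated in the source, config-exposed) are an internally consistent
  re-implementation used for Tanimoto diversity ranking; they are not
  bit-compatible with any vendor ECFP. MaxMin selection seeds its first
  pick uniformly (the commercial protocol's start rule is unknown,
  also config-exposed) and breaks ties by input order.
* The metrics engine deliberately omits ROC/AUC (not used in the source
  evaluation protocol).
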