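---
title: "Methods: from product-information text to an oral-absorption classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from product-information text to an oral-absorption classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pharmforge turns semistructured drug-product documents — SmPC-style texts
whose numbered sections carry the composition (2), pharmaceutical form (3),
pharmacokinetics (5.2) and excipients (6.1) — into a relational database of
drugs, products, formulations and excipients, and then analyses that
database three ways: drug-likeness rulesets over the curated parent
structures, association-rule mining over excipient compositions, and binary
classification of the human oral fraction absorbed (Fa). This vignette
documents the models, conventions and numerical choices; the README shows
the worked end-to-end example.

## The synthetic corpus and what it does (and does not) emulate

Because the genuine corpus for this kind of work is a regulatory register
plus thousands of downloaded documents, the package ships a generator that
produces a register, per-product documents and an identifier dictionary
with *retained ground truth*, so the entire pipeline is testable offline.
The generator's defaults are the package's reference study conditions and
are deliberately fixed:

* **200 products**, each with 1–3 strengths of one dosage form (about 60%
  immediate-release tablets, with modified-release tablets, capsules and
  infusion products making up the rest), plus four veterinary/biological
  decoy register rows that the register filter must remove.
* **Substances**: parents are drawn from an embedded library of 35 real
  drug-like molecules (hand-curated SMILES, always chemically valid so
  descriptor computation never fails on fixtures) plus three oversized
  (>1000 g/mol) mock structures that exercise the molecular-weight filter.
  35% of substances are decorated as salts — neutral-acid counterions
  (hydrochloride, mesylate, ...) for basic drugs, sodium salts of a stored
  pre-deprotonated anion for acids, with divalent anions written as the
  doubled formula unit in the pemetrexed-disodium convention — and 15% as
  solvates (mono/di/trihydrate, ethanolate). The salt and solvent lists are
  the same data files the curation module strips against: the generator can
  only add what curation knows how to remove.
* **Excipient transactions** over a 40-item universe taken from the
  shipped controlled vocabulary. Background items enter independently
  (p = 0.12), so their pairwise lifts concentrate on 1; two planted rules
  echo associations reported for amorphous-solid-dispersion polymers
  (hypromellose acetate succinate ⇒ croscarmellose sodium, support 0.05,
  confidence 0.7; sorbitan monolaurate ⇒ copovidone, support 0.02,
  confidence 0.9, hence high lift).
* **Fa labels**: `Fa = logistic(2.8 + b·z(x) + e)` with weights
  `(mw −0.6, logp +1.0, tpsa −1.2, hbd −0.8)` on z-scored parent
  descriptors and `e ~ N(0, 0.1)` on the logit scale. A design note: one
  part of the internal specification called for additive noise on the
  logistic output; we follow the explicit formula (noise on the logit),
  which is equally monotone-signal-preserving and needs no clipping. The
  intercept 2.8 was chosen once, by inspecting the noiseless logit
  distribution over the embedded library, so that roughly three quarters of
  drugs are well absorbed — mirroring the strong class imbalance real
  curated Fa sets show. The weights' signs encode the standard absorption
  intuitions (permeability falls with polarity and size, rises with
  lipophilicity); their magnitudes are otherwise arbitrary.
* **Pharmacokinetic text** is rendered in several dialects — point values,
  ranges ("50 to 60%"), lower bounds ("at least 70% ... is absorbed"),
  urinary-recovery mass-balance statements, and a combined
  absorption-plus-bioavailability phrasing — to exercise the annotation
  rules below.

What passing tests on this corpus *do not* show: real documents have far
messier section headers, multilingual text, OCR noise, combination
products, and excipient spellings outside any vocabulary. The corpus
demonstrates that the machinery is correct, not that the regexes are
exhaustive for production registers.

## Parsing conventions

Section extraction is line-anchored: a header is a line starting with a
section number followed by a dot (top level) or containing a dotted number
(subsections), so "see section 6.1" in prose never splits a document. A
section's payload runs to the next header of equal or higher level.
Missing sections are flagged, never silently empty; duplicated headers
keep the first occurrence and log the conflict.

Units are standardized to mg (mass), hours (Tmax), proportion (Fa) and
percent (absolute bioavailability, %F). The pharmacokinetic annotation
rules are fixed: a range maps to the arithmetic mean of its limits
(`range_mean`), "at least X" maps to X (`lower_bound`), absorption stated
only via recovery of a radiolabelled dose maps to the recovered fraction
(`inferred_mass_balance`). Wording that conflates absorption with
bioavailability is never auto-resolved — each extracted value keeps its own
flag, following the curation precedent set by the raloxifene-style
statements where "60% of an oral dose is absorbed" coexists with a 2%
absolute bioavailability.

Excipient normalization maps surface forms through an editable ~100-term
starter vocabulary in which polymer classes that differ only by chain
length or viscosity grade (macrogols, povidones, hypromelloses) share one
canonical identifier; unmapped lines are queued for review, never dropped.
For every brand, only the highest-strength formulation per dosage form is
kept, comparing on the first listed active substance with ties kept at
first occurrence and logged.

## Structure curation

The administered structure (drug + counterions + solvents, a
multi-component SMILES) is reduced in a fixed order: solvents are removed
first (giving the *desolvated* form, whose total mass divided by the
number of parent copies is the salt-inclusive "formula weight"), then
counterions; remaining protonation-state charges are neutralized, and
identical components are deduplicated, so a disodium salt written as two
equivalent anions collapses to one neutral parent. Neutralization only
touches components with nonzero net formal charge, which protects
internally charge-separated groups such as nitro. If several distinct
components survive stripping, the longest SMILES string is taken as the
active component — with a warning, since a large coformer can defeat that
heuristic. Products whose parent exceeds 1000 g/mol are excluded with a
log. Cocrystal-versus-salt discrimination is not attempted.

Identifier resolution is an offline dictionary lookup; identifiers use the
InChIKey *format* as an opaque join key (the package never computes the
hash, and synthetic corpora use deterministic synthetic keys).

## Drug-likeness

The six rule descriptors are molecular weight, Wildman–Crippen logP,
H-bond donors and acceptors in the simple convention (OH/NH donors, N+O
acceptors — recorded in code so stricter definitions can be swapped),
rotatable bonds, and TPSA, all computed on the parent form via Open Babel.
Ruleset bounds are inclusive ("no more than" semantics) and ship as
editable data: Ro5 and Veber use the classic published limits; the
extended and contemporary Rule-of-Five bounds are transcribed from their
citations as understood and are marked from-citation in
`default_rulesets()` — users reproducing a specific publication should
verify them. Conformance summaries count molecular weight both ways: the
parent weight and the desolvated formula weight per parent molecule.

Chemical-space projection uses PCA on z-scored descriptors (z-scoring
chosen over min-max; flagged as a choice, not a given) and t-SNE on MACCS
Tanimoto distances. No R t-SNE implementation is available among the
package's dependencies, so an exact O(n²) t-SNE is implemented in-repo:
perplexity calibration by bisection, early exaggeration (factor 12 for the
first half of optimisation, capped at 250 iterations), momentum gradient
descent (0.5 then 0.8), seeded initialisation, and the final KL divergence
reported. At the corpus sizes involved (hundreds of compounds) the exact
formulation is appropriate; Barnes–Hut approximations are not.

## Excipient mining and the descriptor screen

Apriori is implemented in-repo — levelwise candidate generation with
anti-monotone pruning — because support/confidence/lift arithmetic is the
analytical core of the module; the test suite holds it against an
exhaustive power-set oracle up to 12 items. Default thresholds are support
0.01, confidence 0.6 and lift strictly above 1, with mining scoped to oral
immediate-release tablets. Rule neighbourhoods around focus excipients
(one antecedent, one consequent) become directed graphs with arrows toward
the consequent.

The hypothesis screen compares each descriptor's distribution between
drugs formulated with and without each excipient used by at least ten
drugs, using the two-sided Mann–Whitney U test in its tie-corrected normal
approximation (the common library behaviour at these group sizes; exact
enumeration appears only as a test oracle). All p-values are adjusted
jointly by an in-repo Benjamini–Hochberg step-up, with significance at
adjusted p < 0.05. This is exploratory screening: absence of a detected
association does not imply absence of a trend, and no correction beyond
FDR control is applied.

## Fa classification

Dataset assembly: oral formulations with an Fa value; the greatest Fa per
parent across products and salt forms (different salts of one drug
typically quote one Fa); parents still containing a component separator
are excluded; the positive class is Fa ≥ 0.8, boundary inclusive.

Feature sets (each records its exact roster in output metadata, since
descriptor availability is toolkit-dependent): 166 MACCS keys; ECFP6
folded to 2048 bits; an 18-descriptor H-bond/flexibility/ring set; a wider
2D physicochemical set (~38 descriptors: bulk properties plus SMARTS-based
functional-group and element counts); and the 2D set extended with nine 3D
shape descriptors (gyration tensor and inertia measures) from one
conformer per molecule. Conformers come from seeded distance-geometry
embedding with MMFF94 minimisation (at most 500 iterations) via the RDKit
toolkit in a subprocess — chosen because it is deterministic under a fixed
seed, which the alternative generator in the R chemistry stack is not.
Embedding failures leave the 3D block missing-coded.

The modelability index is the mean over the two classes of the fraction of
samples whose single nearest neighbour (excluding self, ties to the lowest
index) shares their class; values above 0.65 suggest a modelable endpoint.
Real-valued sets are z-scored over all samples first; fingerprints use
Tanimoto distance (a choice — the index's distance for bit vectors is not
standardized).

The protocol is a stratified 80/20 split, 10-fold stratified grid-search
cross-validation selecting on mean balanced accuracy, a refit of the
winning configuration on the full training set, and one test-set
evaluation. Four families are searched with small declared grids (under
40 candidates each, sized for desk-scale runs): CART decision trees
(criterion, depth, minsplit, minbucket — rpart exposes no per-split
feature subsampling, so the complexity dimension of the grid differs from
feature-subsampled tree implementations), random forests (ranger),
adaptive boosting (SAMME with depth-limited rpart base learners,
implemented in-repo because no boosting package for classification trees
is available in the dependency set), and gradient boosting (xgboost).
Non-finite feature values are imputed with training-fold column medians
only, to avoid leakage. The split/fold/model seed is a required, logged
argument (default 42). A model is *acceptable* when test balanced accuracy
is at least 0.6 and sensitivity, specificity, PPV and NPV are all at least
0.5. A label-permutation null (repeated CV on shuffled labels) provides
the chance reference a signal must beat.

## Numerical choices and degenerate inputs

Tanimoto distance between two all-zero fingerprints is defined as 0.
PCA explained-variance ratios sum to one by construction; signs of
components are not stabilised. The apriori join step assumes items sorted
within itemsets (enforced internally). Confusion-matrix metrics with a
zero denominator are missing-coded and make a model unacceptable. Empty
transactions are redrawn at generation (mined transactions are non-empty
by definition); this conditions the background-item marginals negligibly.
Balanced accuracy is always the arithmetic mean of sensitivity and
specificity, checked to machine precision in the tests.

## Problem sizes

The reference corpus is 200 products (≈360 SmPC blocks); mining
calibration uses 2000 transactions; the classifier demonstration uses 200
samples over the 35-parent library with the phys2d feature set. These
sizes give stable statistics for every quantity the package reports while
keeping a full run on one CPU in minutes.

## Known limitations

The excipient vocabulary is a starter canon, not the full curated
vocabulary a production register needs. The regex dialects cover the
rendered corpus and common real phrasings, not the full variety of
regulatory text. Neutralization is rule-based (protonation states only);
exotic organometallics would need a real standardizer. The eRo5/cRo5
bounds are transcriptions, flagged as such. Multi-active combination
products are supported through explicit per-product overrides
(pipe-delimited actives split into one row per component; named components
droppable when the partner is marketed separately), not through automatic
detection.
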