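---
title: "Screening proteomes for energy-reserve pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for energy-reserve pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservescan)
```

## The screening problem

Bacteria accumulate five major energy reserves — polyphosphate (polyP),
glycogen, wax esters (WE), triacylglycerols (TAG) and
polyhydroxyalkanoates (PHA) — and the presence of a reserve in a species
can be predicted from whether its proteome encodes the pathway's key
enzymes. `reservescan` implements that prediction as a pipeline:

1. build a position-specific profile model for each key enzyme,
2. score every protein of every proteome against every model,
3. accept homologs under strict E-value and coverage thresholds,
4. call pathway presence/absence from the accepted copy numbers,
5. contrast proteome sizes between pathway-positive and -negative groups,
6. export taxonomy-tree annotation layers for circular-tree viewers.

The enzyme set (`seed_registry()`) covers PPK1/PPK2/PPX for polyP, the
classical (GlgC-GlgA-GlgB) and trehalose-derived (TreS-Pep2-GlgE-GlgB)
glycogen routes plus Rv3032 and the two branching-enzyme families
(glycoside-hydrolase families GH13 and GH57), PhaA/PhaB/PhaC with the two
Pfam-defined PhaC groups (Abhydrolase_1 vs PhaC_N) and four auxiliary PHA
routes, the bifunctional WS/DGAT for WE/TAG, and the eukaryotic-type PDAT.

**Synthetic seed sequences.** The registry carries the documented genes,
reference species, UniProt accessions, lengths and Pfam domain
compositions, but the attached amino-acid sequences are *synthetic*
(deterministic random sequences of the documented lengths). This keeps the
whole package runnable and testable offline; users with network access
should substitute the real UniProt sequences, and everything downstream is
unchanged.

## Model construction

For each enzyme the registry records a model policy. Enzymes whose
reference proteins have more than two non-redundant domains, or whose Pfam
domains are very short or of unknown function (PPK1, both GlgB families,
TreS, Pep2, GlgE), get a single **full-sequence de novo model**; all
others are screened through **per-domain models**, one per listed Pfam
domain.

De novo construction follows the classical recipe:

* **Dereplication** (`dereplicate()`): greedy, in input order; a homolog is
  dropped iff its global-alignment identity to an already-kept
  representative exceeds 0.98. Greedy order-dependence is deliberate — it
  is deterministic and mirrors common clustering tools. Identity is
  computed on a global alignment (match +1, mismatch −1, linear gap 2 per
  position) because homolog sets are full-length; the identity value is
  matches over all alignment columns.
* **Progressive alignment** (`build_msa()`): the sequence with the highest
  mean pairwise identity seeds the profile and the rest join in decreasing
  identity to it, via profile-sequence dynamic programming (match +2,
  mismatch −1, linear gap −2). Deleting gaps from any row always recovers
  the input sequence.
* **Terminal trimming** (`trim_termini()`): alignment ends are the least
  reliable part of automatic alignments, and hand-editing them is neither
  deterministic nor testable. The automated stand-in removes leading and
  trailing runs of columns whose non-gap occupancy is below 0.5; interior
  columns are never touched.
* **Model estimation** (`build_profile()`): match states are columns with
  occupancy ≥ 0.5. Emissions and transitions use background-weighted
  Dirichlet pseudocounts with a single weight `w` (default 1):
  `(count + w·q_a)/(n + w)` — as `w → 0` this recovers empirical column
  frequencies; insert states emit the background. Insert↔delete
  transitions are forbidden (the usual profile-HMM simplification).

Because the real Pfam profiles are an external database, the per-domain
model store is **synthesized** by segmenting each seed and its homolog set
into contiguous per-domain blocks (seed length split evenly over its
domains) and building one model per block. Domain models are keyed
`enzyme:domain` rather than by domain alone: with synthetic seeds, a Pfam
id shared by two enzymes (PF00534 appears in both GlgA and Rv3032) does
not denote one shared sequence family. Externally built HMMER3 profiles
can be imported with `read_hmmer_profile()` and plugged in under the same
keys.

## Search model and acceptance thresholds

`score_sequence()` computes the best **local** alignment of a protein to a
model by Viterbi over match/insert/delete states against a background
null: free entry to and exit from any match state, inserts emitting at
background (log-odds 0). Scores are base-2 log-odds (bits). On models with
few states and short proteins the implementation is verified against
exhaustive enumeration of every legal state path.

E-values use the standard Gumbel tail. `calibrate()` scores `n_random`
(default 200) background-sampled sequences of the model's consensus length
and fits a Gumbel by maximum likelihood;
`E = n_targets · exp(−λ(s − µ))`, capped at `n_targets`. The number of
targets defaults to the per-proteome protein count (`PER_PROTEOME`), since
each proteome is searched independently; a `FIXED_N` policy is available
when E-values must be comparable across proteomes of different sizes.

A hit is accepted iff **E-value < 1e-10** and **query coverage > 60%**,
both strict, where query coverage is the aligned span on the *query model*
divided by the model's length — the model, not the target, is the
denominator. Copy number of an enzyme is the number of distinct accepted
proteins: tandem hits on one protein count once, and a multi-domain
Pfam-policy enzyme requires *every* listed domain model to hit the same
protein (an OR rule would inflate counts; the reference proteins carry all
listed domains on one chain). Coordinates are 0-based half-open
throughout.

## Pathway calls and the call matrix

A pathway is called present iff every required enzyme has copy number ≥ 1
(`call_pathway()`, AND semantics; set-based, no operon or co-localization
requirement). The PhaC slot of the PhaABC pathway accepts either Pfam
group; the PhaC group label itself (GROUP1/GROUP2/BOTH/NONE) is reported
separately. The branching-enzyme slot of both glycogen pathways defaults
to the dominant bacterial GH13 family, with `pathway_definitions(glgb =
"either")` to let GH57 satisfy it — the two families are tracked
separately and the default follows the family that dominates in bacteria.
polyP metabolism is reported as a three-way status (complete / partial /
absent-all) because both the all-three and the none-of-three cohorts are
scientifically meaningful contrast groups.

## Group-size statistics

`compare_by_pathway()` contrasts proteome sizes of pathway-positive vs
pathway-negative proteomes with an unpaired two-tailed t-test, pooled
variance by default ("Student's" test) and a Welch option since group
variances plausibly differ. For polyP the contrast is complete vs
absent-all, excluding partial proteomes. No multiple-testing correction is
applied across pathways. `size_contrast_pvalues()` runs Monte-Carlo
type-I-error and power sweeps directly on the generator's proteome-size
model (the decoy-count sampler plus the planted effect): the contrast
consumes only sizes, so replicated sweeps do not need sequence-level
cohorts.

## The synthetic cohort generator

`generate_cohort()` produces proteomes with full ground truth:

* **Planted homologs**: full-length mutated copies of the seed at an exact
  target identity (substitutions at positions chosen without replacement,
  uniform over the 19 alternative residues; no indels, so the identity
  contract is exact within rounding of one substitution).
* **Decoys**: i.i.d. residues, uniform over the 20 amino acids by default
  — uniform decoys are maximally dissimilar from any trained profile,
  which makes false-positive tests conservative; a Robinson-Robinson table
  is available via `background_frequencies("robinson")`.
* **Clades**: a toy three-rank taxonomy whose default scenarios emulate
  the observed broad patterns: an Actinobacteria-like clade carrying the
  trehalose pathway, WS/DGAT, complete polyP and Group 1 PhaC; a
  Proteobacteria-like clade carrying the classical glycogen pathway,
  PhaABC (Group 2), complete polyP, WS/DGAT and the auxiliary enzymes; and
  an enzyme-free Mollicutes-like clade.
* **Size effect**: added to the decoy counts of pathway-positive proteomes
  only, so enzyme content and proteome size are independently
  controllable.

Default conditions: 100 proteomes, homolog identity 0.85–0.95, 50–80
decoys per proteome of length 80–500, size effect +20 decoys. These sizes
make the full pipeline run in a couple of minutes on one core while
leaving thousands of enzyme-level decisions per cohort.

What the generator does **not** emulate: phylogenetic sequence evolution
(no substitution-matrix or tree-based models), indels in homologs (an
optional exercise left out of the identity contract), compositional bias,
and real domain architectures — synthetic "domains" are contiguous equal
segments. Passing the planted-truth tests therefore demonstrates that the
machinery is correct and the thresholds behave as specified, not that
sensitivity on real remote homologs equals 1; on real data, detection
power is bounded by the quality of the homolog sets behind each model,
exactly as with any profile-HMM screen.

## Numerical choices and degenerate inputs

* Probability vectors are validated to sum to 1 within 1e-9.
* Gumbel fitting uses the standard profile-likelihood iteration for the
  scale with a moment start; a zero-variance score sample is a calibration
  error.
* Ambiguous residues (X/B/Z/U) score as background (log-odds 0).
* Alignment tie-breaks are fixed (diagonal preferred), making every stage
  byte-reproducible under a fixed seed.
* Degenerate alignments (no column reaching occupancy 0.5, or trimming
  that would empty the alignment) are errors, not silent fallbacks.
* Two zero-variance groups return t = 0, p = 1 when their means are equal
  (a null result) and t = ±Inf, p = 0 when they differ, rather than an
  error.
* The taxonomy tree collapses unary ranks onto their child, allows
  polytomies, sorts siblings lexicographically, and omits branch lengths
  (it is a rank tree); emitted Newick is byte-stable under parse/re-emit.

## Problem sizes used in validation

The shipped validation suite runs the full pipeline on the default
100-proteome cohort (~7,000 proteins against 28 models), checks the
scoring engine against exhaustive path enumeration on 500 tiny cases
(≤ 6 match states × ≤ 12 residues), sweeps threshold monotonicity over 50
small cohorts, and sizes the t-test at 1000 null replicates of 200 + 200
proteomes. These sizes were chosen so the whole suite completes in a few
minutes on a single core while still exercising every decision path.

## Known limitations

* Not a full Plan7 implementation: no forward-algorithm posteriors, no
  multi-hit envelope resolution, no local/glocal entry-exit tuning; one
  best local hit per protein-model pair.
* Homolog collection from reference databases (the step upstream of
  dereplication) is out of scope; homolog sets are provided or
  synthesized.
* The all-domains rule for multi-domain enzymes is a design decision, not
  an observed convention; switchable behavior would require per-enzyme
  evidence that is not available.
* Degradation enzymes (GlgP/GlgX, PhaZ) are not modeled; the screen covers
  the synthesis-side key enzymes plus the named degradation enzymes of
  polyP.
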