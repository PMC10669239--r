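---
title: "Methods: curation, clade-vote reannotation and model-organism proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, clade-vote reannotation and model-organism proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mmphylo` implements a complete protein-family phylogenetics workflow for
the mammalian matrix metalloproteinases: curation of a bulk database
retrieval, tree construction, automatic clade-based class (re)annotation,
and ranking of candidate model organisms by evolutionary proximity to a
reference species. This vignette documents the models and procedures, the
parameters that matter, the synthetic-data design that the test suite is
built on, and the design decisions taken where more than one reasonable
choice existed.

## The curation cascade

Bulk protein retrievals mix full-length enzymes with fragments,
non-family members and redundant entries. The cascade applies three
filters, each exactly once and in a fixed order, because the first filter
changes the statistics the others would see:

1. **Length window** (`filter_by_length`, `window = 0.5`). A sequence is
   kept iff `(1 - w)·mean ≤ L ≤ (1 + w)·mean`, with the mean computed at
   full precision over the *input* set and bounds inclusive. The window is
   intentionally crude — its job is to remove alignment-wrecking outliers
   (a 14,000-residue titin-like sequence, a 30-residue fragment), not to
   call domain boundaries. Running it twice would move the mean and
   therefore the window, so the pipeline never re-enters a stage; a run
   that removes every record raises an error rather than passing an empty
   set downstream.
2. **Domain architecture** (`filter_by_domains`, `min_families = 3`). The
   input is an RPSBlast-against-CDD tabular hit file. Hits are mapped to
   four diagnostic families — matrixin (the ~170-aa catalytic domain),
   hemopexin (C-terminal repeats), pg-binding (the ~80-aa propeptide that
   keeps the protease latent) and fibronectin type II (three repeats
   inserted in the catalytic domain, found only in gelatinases). A
   sequence survives with hits in at least three *distinct* families.
   Counting families rather than raw hits is deliberate: matrixin models
   often hit multiple times, and raw-hit counting would let a
   single-domain fragment through. The known cost is that genuine
   two-domain MMPs (matrilysins MMP-7/26, which lack the hemopexin
   domain) cannot survive; that trade-off is inherent to the ≥3 rule.
3. **Duplicate removal** (`deduplicate`, `mode = "exact"`). Records with
   identical residue strings (case-insensitive) collapse to the one with
   the lexicographically smallest accession — a deterministic, auditable
   reading of "100% identity" that makes output independent of input
   order. Identity-level clustering tools additionally absorb sequences
   contained in longer ones; `mode = "substring"` reproduces that
   behaviour but is off by default because it removes genuinely shorter
   isoforms, not only redundancy.

Each stage emits a trace (survivor statistics plus per-sequence removal
reasons); `stage_stats_table()` assembles the four-row report (input +
three stages). Means and standard deviations are kept at full precision
internally and rounded half-away-from-zero only for display. The standard
deviation is the sample (n−1) estimate, 0 for a single sequence.

## Distances and the bundled tree

The bundled builder is classic neighbor joining (via `ape::nj`) on
pairwise-deletion p-distances: `d(i,j)` is the fraction of mismatching
sites over the columns where *both* rows carry an unambiguous residue
(gaps, `X`, `B`, `Z` are skipped per pair; selenocysteine `U` is folded
into `C` so the 20-state alphabet stays closed, though it is preserved on
write). Pairwise deletion rather than complete deletion keeps ragged
fragments comparable. The mismatch counting runs in a small C++ kernel;
a pair with zero comparable columns is an error naming the pair.

Negative NJ branch-length estimates are clamped to zero without
redistribution: the non-negativity of patristic distances is an invariant
every downstream step relies on, and redistribution schemes buy nothing
at the scales involved. NJ is consistent on additive matrices, which the
test suite exercises directly (200 random trees, distance matrix by path
sums, zero Robinson–Foulds distance required in 200/200).

`jc20_correct()` inverts the 20-state equal-rates (Poisson) model,
`d = -(19/20)·ln(1 - (20/19)·p)`, and errors at `p ≥ 19/20` where the
model saturates. The *pipeline does not correct distances by default*:
the Archaeal outgroup sits near saturation against every ingroup sequence
(two unrelated sequences agree at ≈ 1/20 of sites), so correction is
reserved for the model-closure property tests where divergences are
controlled. Because the proximity criterion only compares distances
within a class, the monotone p-scale is sufficient for ranking.

Maximum-likelihood trees are explicitly supported as *imported* newick
files — the pipeline consumes the file and never shells out to external
aligners or tree builders, which keeps the package hermetic and the
toolchain pluggable. Rooting places the root at the midpoint of the
outgroup's pendant edge; every leaf-to-leaf patristic distance is
unchanged by rooting (a tested invariant).

## Clade-vote (re)annotation

The reference procedure for phylogeny-guided reannotation is visual:
colour leaves by class, find leaves sitting in a clade of the wrong
colour, fix them. `annotate()` formalizes this as a k-nearest-ancestral
vote so it is reproducible and parameterized:

* walk the query leaf's ancestors root-ward, accumulating concretely
  labelled leaves (the query itself, generic/unassigned leaves and the
  outgroup never vote) until at least `k = 10` votes are collected or the
  root is reached;
* the modal label wins with fraction ≥ `f = 0.8`; an exact modal tie
  means no winner;
* a generic/unassigned leaf with a winner becomes that class
  (*class annotation*); a concretely labelled leaf whose winner differs
  becomes the winner (*reannotation*) — unless its prior class has at
  most `min_class_size = 3` members, in which case it is only *flagged*.

All votes are computed against the **prior** labels in a single pass:
changes never cascade, and the outcome is independent of leaf iteration
order (tested by shuffling). The rare-class guard exists because a
genuinely rare class — a singleton collagenase, say — will always sit
inside some larger clade and would otherwise be absorbed by it; flagging
leaves the call to the analyst. `k` trades locality against robustness:
smaller k reacts to tight clades but is vulnerable to a couple of nearby
mislabels; `k = 10` with `f = 0.8` tolerates ~2 discordant voters in the
neighbourhood. Raising `f` can only reduce the number of changed labels
(a tested monotonicity property).

Prior labels are parsed from free-text descriptions: an explicit
`MMP-N`-style token wins; otherwise a case-insensitive keyword list
(`zinc`, `metalloproteinase`, `metallopeptidase`, `matrix`,
`uncharacterized`) marks the record `GENERIC`, and anything else is
`UNASSIGNED`. The keyword list is configurable because generic phrasing
is database-specific.

## Model-organism proximity

`organism_proximity()` ranks, within each scoped class (default: the
collagenases MMP-1/8/13 and gelatinases MMP-2/9), every scoped organism by
its distance to the reference (*Homo sapiens*): the **minimum** patristic
distance over all (organism-leaf, reference-leaf) pairs of that class.
Minimum linkage, not centroid or average, because "the closest organism"
reads most naturally as the closest ortholog pair; average linkage is one
flag away for sensitivity analysis. Each class is evaluated on its own
pruned subtree (`ape::keep.tip`), which provably preserves leaf-to-leaf
distances and mirrors the collapse-other-classes view used when such
trees are inspected by eye.

Organism matching is species-level: the first two words of the binomial,
case-insensitively, so `Canis lupus familiaris` counts as `Canis lupus`.
Organisms with no leaf in a class are listed as absent rather than
dropped — absence of a class/organism combination in the source database
is itself a finding. Distances equal within `rel_tol = 1e-9` (relative)
share a tie-group rank, giving "joint second" semantics. A class with no
reference leaf, or no candidate leaf, is reported non-rankable with a
reason instead of raising. A topological metric (number of internal nodes
on the path; sister leaves at 1) is provided as a second criterion; on
clock-like trees the two agree (tested), and where they disagree on real
data the package reports both rather than adjudicating.

The pipeline feeds proximity with the **annotated** labels (the stage
order is curate → tree → root → annotate → scope → proximity), so labels
corrected by the clade vote participate; `organism_proximity()` itself
accepts any leaf table, so running it on the original annotations instead
is a one-line variant.

## The simulator: what it emulates, and what it does not

`generate_dataset()` builds one clock-like gene-family tree: one clade
per class hung on a caterpillar backbone, and inside each clade the
scoped organisms on a caterpillar species tree with within-species
duplication cherries. Defaults define the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `sites` | 450 | residues per sequence, the scale of a curated MMP |
| `organisms` | 7 | the dentistry-relevant species, Homo sapiens reference |
| `classes` | 21 + 2 | all recovered MMP classes plus matrilysin-like distractors |
| `leaves_per` | 3 | gene copies per (class, organism) |
| `cherry_depth` | 0.015 | within-species duplication depth (subst./site) |
| `species_step` | 0.03 | successive species-join depth increments |
| `class_stem`, `backbone_step` | 0.55, 0.03 | inter-class separation |
| `outgroup_branch` | 1.5 | Archaeal outgroup pendant length |
| `rate_jitter_sd` | 0.1 | per-branch log-normal rate jitter |
| `fragment/duplicate/mislabel rates` | 0.05 | corruption rates |
| `generic_rate` | 0.10 | generic-label rate |

Each class designates a *planted nearest* organism, implemented by join
order: the reference and the planted species split first (at
`species_step`), the remaining organisms at successive depths in a fixed
alphabetical order. Defaults plant *Oryctolagus cuniculus* everywhere
except MMP-13 (*Canis lupus*) and MMP-2 (*Rattus norvegicus*). A shared
backbone with per-class rate multipliers — rather than independent gene
trees — keeps the planted ordering controlled while per-branch jitter
adds realism without breaking it in expectation. With the default
geometry the inter-class separation (≥ 2 × 0.55 substitutions/site)
exceeds five times the intra-class depth (≈ 0.2), so classes form
well-separated clades, and the deepest leaf pairs stay below the 19/20
saturation ceiling of the p-distance.

Sequences evolve site-independently under the 20-state Poisson model:
substitution probability `p(t) = (19/20)(1 - e^{-(20/19)µt})`, replacement
uniform over the 19 alternatives. Corruptions are then injected on
disjoint record sets (fragments to a uniform 10–40% span — below the 50%
length window by construction; duplicates under fresh accessions;
mislabels swapped to another class *present in the dataset*; generic
phrases replacing descriptions), every action recorded in a manifest that
covers each emitted record exactly once. Domain hits are emitted from
per-class architectures laid out fractionally on the sequence frame, with
gelatinases carrying the three fibronectin repeats and distractors only
two families; fragments keep only hits fully inside the retained span,
shifted into fragment coordinates. The verbatim Archaeal outgroup record
(345 aa) is appended to every dataset; when the co-simulated records are
used directly as an alignment it is right-padded with gaps, which the
pairwise-deletion distance handles.

What the simulator does **not** model: indels (so real alignments must
come from an aligner), site-rate heterogeneity, empirical amino-acid
exchangeabilities, compositional bias, and annotation errors more subtle
than token swaps. Passing the recovery tests therefore demonstrates that
the *procedures* are correct and well-calibrated under their stated
assumptions — not that real UniProt retrievals will be curated with the
same accuracy.

## Problem sizes and determinism

The test suite and the acceptance script run at sizes chosen to exercise
the asymptotic claims while staying desk-sized: the default dataset is
~508 records of 450 sites (≈ 420 survivors, a 421-leaf tree); NJ
consistency uses 200 random 5–12-leaf trees; the patristic oracle 100
trees up to 20 leaves; model closure 10,000 sites; label recovery 50
datasets of 8 classes × 30 leaves (stem widened to 0.75 so the ≥5×
separation condition holds at 10 organisms); planted-organism recovery
100 full pipeline replicates. Every stochastic step flows from a single
seed (`sim_params(seed = ...)`), and regeneration under the same seed is
byte-identical — the pipeline itself is deterministic given its inputs.

## Known limitations

* The length window presumes a unimodal length distribution; a retrieval
  dominated by fragments would drag the mean down and invert the filter's
  intent (the manifest-prediction logic documents the same assumption).
* Exact-mode deduplication does not collapse a fragment into its
  full-length source; substring mode does, at the cost of removing true
  short isoforms.
* The clade vote inherits the tree's errors: with poorly resolved class
  clades the vote abstains (fraction < f) far more often than it
  mislabels, which is the intended failure direction.
* Proximity rankings are tree distances, not claims of biological model
  suitability; and where patristic and topological criteria disagree, the
  package reports both.
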