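---
title: "Aligning species-specific phenotype ontologies: lexical matching vs. EQ reasoning"
author: "phenomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning species-specific phenotype ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

## The model

Let $O_1$ and $O_2$ be two phenotype ontologies with named concept sets
$C(O_1)$ and $C(O_2)$, each a DAG under `is_a`. A *mapping* is a set of
axioms of the form $A \sqsubseteq B$, $B \sqsubseteq A$ or $A \equiv B$
with $A \in C(O_1)$, $B \in C(O_2)$. `phenomap` produces such axiom sets by
two routes and then propagates both the same way:

1. **Lexical seeds.** Every concept contributes its primary name and all
   synonyms, normalized (lowercase, Unicode punctuation and hyphens to
   spaces, whitespace collapsed). Exact equality of normalized strings
   between the two ontologies yields an equivalence seed; evidence is
   recorded with the priority name–name > name–synonym > synonym–name >
   synonym–synonym. There is deliberately no stemming or edit distance:
   the strict-matching regime is itself the object of study, and the
   package records which evidence class produced each pair. Many-to-many
   seeds are allowed; obsolete concepts never match.

2. **EQ structural subsumption.** A formal definition grounds a phenotype
   concept as a conjunction of (quality, entity) pairs over two shared
   support ontologies (the PATO role for qualities, a cross-species
   anatomy role for entities). A conjunct $(q_1, e_1)$ is subsumed by
   $(q_2, e_2)$ iff $q_2$ is an ancestor-or-self of $q_1$ and $e_2$ of
   $e_1$; definition $d_2$ subsumes $d_1$ iff every conjunct of $d_2$
   generalizes some conjunct of $d_1$. For this flat
   conjunction-of-pairs fragment the structural test is sound and
   complete, so a description-logic reasoner is unnecessary; the decision
   procedure is checked against exhaustive conjunct-assignment enumeration
   in the test suite. EQ modifiers, relational qualities ("towards") and
   nested entity expressions are not modeled; real-world definitions using
   them would be skipped and counted.

**Propagation.** Both ontologies are imported into one directed graph:
`is_a` child-to-parent edges, subclass axioms sub-to-super, equivalences in
both directions. The mapping entry of a source concept is every
target-ontology concept reachable from it — its equivalent and super
concepts across the bridge. Three consequences matter:

* entries are ancestor-closed in the target ontology (target roots are
  retained by default; `dropRoots` removes them);
* mappings are direction-specific and genuinely asymmetric, because the
  two taxonomies differ in shape;
* concepts without a definition (or without a matched label) can still be
  mapped through a defined/seeded ancestor, which is why mapped counts
  exceed definition coverage.

**Comparison.** For each concept mapped by *both* methods, the lexical
target set $L$ and formal target set $F$ fall into exactly one of five
categories: `exact` ($L = F$), `formal_subset_of_lexical` ($F \subsetneq
L$), `lexical_subset_of_formal` ($L \subsetneq F$), `overlap` (neither,
intersection non-empty), `nothing` (disjoint). Subset categories mean
*proper* subset; `exact` is its own category, so the five cases partition
all doubly-mapped concepts and the counts sum to the total. Concepts
mapped by only one method are reported separately as coverage-only counts:
the published overlap totals sit well below either method's individual
coverage, so intersection semantics is the only reading consistent with
them, and we adopt it explicitly.

**Evaluation.** Disease annotations live in $O_1$ space, mouse-model
annotations in $O_2$ space; a mapping translates one side into the other
(union of entry sets over the annotated concepts). Phenotype similarity is
the cosine of the binary presence/absence vectors, which reduces to
$|A \cap B| / \sqrt{|A| |B|}$; annotation sets carry no weights, so
nothing more elaborate is justified. All disease × model combinations are
scored and pooled into one ranking; a pair is positive iff the human
ortholog of the model's gene is associated with the disease in the gold
standard. The ROC uses the block-tie convention (tied scores advance as
one threshold step) and trapezoidal AUC, which makes the AUC identical to
the Mann–Whitney concordance statistic — a property the tests verify on
every evaluation instance.

## Numerical and degenerate-input conventions

* An empty translated annotation set scores similarity 0 and *stays in the
  ranking*; silently dropping such pairs would shift the FPR denominator.
* Ranking ties break lexicographically on (disease, model) so output is
  deterministic.
* No ancestor closure is applied to the untranslated side's annotations;
  the translated side is ancestor-closed by construction of the mapping.
  This asymmetry is the method's own: the mapping, not the annotation
  model, supplies the generalization.
* Coverage percentages and mean mapped-set sizes are presentation-rounded
  half-up to two decimals (`roundHalfUp`); zero mapped concepts reports an
  undefined mean (`NA`).
* ROC evaluation refuses rankings without at least one positive and one
  negative.
* Obsolete terms are parsed but excluded from matching, mapping and
  translation; relationship types other than `is_a` are ignored with a
  warning, because propagation here is purely taxonomic. Definition-count
  totals likewise exclude obsolete classes.

## What the generator emulates

`generatorConfig()` fixes the study conditions; `presetConfig()` provides
the two canonical ones. The generator builds, from one seed:

* **Support ontologies** — complete rooted trees (depth × branching) for
  the entity and quality roles. Trees rather than DAGs keep ancestor sets
  transparent; real anatomies are DAG-shaped, which this does not emulate.
* **Species ontologies** — each species samples `nConcepts` distinct
  (entity, quality) pairs from the common pool, with a `fracSharedEQ`
  overlap shared between the species, so identical-EQ counterparts exist
  by construction. `is_a` edges are asserted exactly where EQ subsumption
  holds among the sampled definitions (transitive reduction, plus a
  species root), so each ontology is logically coherent with its
  definitions and the formal aligner's output is predictable from the
  bookkeeping — which is what makes exact oracle tests possible.
* **Definitions** — `fracDefined1`/`fracDefined2` of each species'
  concepts keep their definition. Coverage is correlated across species on
  the shared-EQ pairs: species 1 fills its budget first from concepts
  whose counterpart is defined in species 2. Real cross-species EQ
  definitions come from one shared curation effort, so correlated coverage
  is the realistic regime; it is also what makes formal mapping coverage
  dominate raw definition coverage, since undefined concepts then inherit
  mappings through defined ancestors.
* **Labels** — by default species-distinct. A `fracSharedLabels` fraction
  of counterpart pairs receives an identical label, chosen with
  probability proportional to concept depth: specific phenotypes are the
  ones most likely to be worded identically in both species (the
  "Eosinophilia" effect), and this depth bias is what reproduces the
  qualitative contrast of interest — the lexical method maps fewer but
  deeper concepts whose target sets are larger, while the formal method
  maps broadly but lands on more general concepts with shorter ancestor
  chains. On the second species the shared string lands on the name or on
  an EXACT synonym with equal probability, exercising both evidence
  classes.
* **Corpus** — each model carries one gene (multi-gene genotypes are out
  of scope); orthology is 1:1. For each planted (gene, disease)
  association the disease's annotations are the identical-EQ counterparts
  of that gene's model's annotations, with an `annotationNoise` fraction
  resampled uniformly; other diseases are annotated uniformly at random.
  The gold standard is exactly the planted set. With zero noise and full
  sharing, every planted pair's translated similarity dominates the
  ranking and both methods recover the signal at AUC 1; as noise rises to
  1 the disease annotations carry no signal and the AUC collapses to
  chance. The test suite checks this degradation as a monotone trend in
  the mean over 20 seeds.

All randomness flows from the configuration seed through `withr`-scoped
RNG; the corpus stage uses a fixed offset of the same seed so the bundle
is a pure function of the configuration and `writeBundle()` output is
byte-identical across runs.

### Preset conditions

| parameter | small | paper-shaped |
|---|---|---|
| entity tree (depth × branching) | 3 × 4 (85 nodes) | 2 × 6 (43 nodes) |
| quality tree | 2 × 3 (13 nodes) | 2 × 2 (7 nodes) |
| concepts per species | 150 | 150 |
| definition coverage | 100% / 100% | 48% / 63% |
| shared EQ fraction | 0.7 | 0.7 |
| shared label fraction | 1.0 | 0.3 |
| genes / models / diseases | 15 / 15 / 12 | 20 / 20 / 15 |
| annotations per model | 4–6 | 4–6 |
| planted associations | 8 | 10 |
| annotation noise | 0 | 0.25 |

The `small` preset is the clean-recovery condition. The `paper-shaped`
preset sets definition coverage near the published 48%/63% regime and
uses bushier supports so that cross-ontology subsumption is dense enough
for undefined concepts to inherit mappings — the regime in which the
formal method's coverage advantage and the lexical method's specificity
advantage both emerge. Problem sizes (150 concepts per species, 300
ranked pairs) were chosen as the smallest at which all of the pipeline's
qualitative contrasts are stable across seeds.

## What passing tests do and do not show

The generator plants exact, bookkeeping-verifiable structure, so the test
suite can hold the pipeline to sharp oracles: brute-force path
enumeration for ancestor closure, boolean-matrix closure for merged
reachability, all-pairs string comparison for lexical matching, exhaustive
conjunct assignment for subsumption, and Mann–Whitney concordance for the
AUC. Passing these shows the *machinery* is correct under the stated
conditions. It does not show that either method is adequate on real
HP/MP releases: real label distributions are far messier than exact
shared strings, real EQ definitions use modifiers and nested expressions
this package skips, real anatomies are DAGs with multiple inheritance,
and real annotation corpora are heavily imbalanced. Published coverage
counts and AUCs from the real ontologies are therefore not reproduction
targets here; only their internal arithmetic is.

## Known limitations

* Only `is_a` is traversed; part-of and other relations are ignored.
* LOOM-style fuzzy normalization is approximated by documented exact
  matching on normalized strings; `exactSynonymsOnly` is the only
  strictness knob.
* The structural subsumption procedure covers only flat
  conjunction-of-(quality, entity) definitions.
* One gene per model; no deduplication of multiple models of one gene
  before ROC pooling (all models stay in the ranking).
* The generator does not emulate imbalanced synonym distributions or
  species-specific anatomy bridging; supports are shared verbatim.
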