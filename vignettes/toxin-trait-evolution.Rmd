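---
title: "Methods: parsimony, conservatism and monophyly for mutually exclusive toxin traits"
author: "toxitrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony, conservatism and monophyly for mutually exclusive toxin traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxitrait)
```

## The problem

Muscarine (a parasympathomimetic alkaloid) and psilocybin (a
hallucinogenic tryptamine) occur scattered across the mushroom family
Inocybaceae, and — as far as any assay has shown — never together in
one species. Questions about such traits are phylogenetic: is the
toxin ancestral for the family or derived? How many independent gains
and losses does the tip distribution require? Is the trait conserved
on the tree or indistinguishable from a random tip labelling? Are the
toxin-positive species a clade?

Three features of real datasets shape every method in this package:

1. **The tree is uncertain.** Inference uses a Bayesian posterior
   sample of hundreds to thousands of correlated, rooted, dated trees,
   not a single estimate, so every statistic is computed per tree and
   summarized across the sample.
2. **Most tips have no data.** Only on the order of 20% of accepted
   species have ever been assayed; the state of the rest is `?`, a
   full state set, not a zero.
3. **The traits exclude each other.** A species confirmed to produce
   one toxin is coded negative for the other.

## Coding assay reports

An assay record is one published report: species, region, toxin,
present/absent, source, and an optional reliability flag for methods
prone to false positives (unreliable records are dropped before any
vote). Conflicting reports for one species are resolved by strict
majority; an exact tie codes `?`. We chose the tie-to-ambiguity rule
because, absent further reports, ambiguity is the conservative
encoding — it feeds the downstream algorithms a full state set rather
than a coin flip.

Because sequenced material and assayed material often come from
different continents, a tip is coded only from records in its own
region or in a region declared *proximate*. Proximity is a
configurable symmetric relation over region tokens (default: identical
region only), because published practice applies proximity judgement
case by case rather than by a formal rule; an explicit table (e.g.
Europe ~ Eurasia) makes each such judgement auditable. Species
synonyms are handled by an explicit mapping table applied before
matching — no fuzzy name matching, ever.

Mutual exclusivity is enforced last: muscarine-positive tips become
psilocybin-negative and vice versa; a `(1,1)` tip in the input is an
error naming the tip, never silently repaired.

## Parsimony ancestral states, gains and losses

For a binary character with ambiguity, `parsimony_score` runs the
standard dynamic programme over (node, state): the cost of a subtree
given its root's state is the sum over children of the child's cost in
the same state, or in the other state plus one. Summing over children
handles polytomies exactly (Hartigan's generalization); binary Fitch
is the two-child special case. We allow polytomies because posterior
samples can contain effectively zero-length branches that users may
collapse. `?` tips enter with cost 0 for both states — missing data
participates, it is not pruned (the randomization test, by contrast,
excludes `?` tips from the shuffle; a flagless design difference that
follows each method's logic).

`mpr_state_sets` adds an up-pass: a state belongs to a node's set iff
some most parsimonious reconstruction (MPR) assigns it. Tips with
observed states return singletons; `?` tips return the states they can
take in an MPR.

`count_gains_losses` extends the programme lexicographically over
(changes, gains): among minimum-change solutions it tracks the minimum
and maximum number of 0→1 edges. Since every change is a gain or a
loss, each MPR satisfies gains + losses = score, giving the identities
min_gains + max_losses = score and max_gains + min_losses = score. The
root state is left free — both root states are considered among MPRs —
because no root-state prior is defensible for these traits; a reported
range like "1–4 losses" therefore has two distinct sources of spread,
MPR ambiguity within a tree and topological variation across the
posterior, and the per-tree table keeps them separable.

All three quantities are verified in the test suite against exhaustive
enumeration of every internal labelling (and every `?` completion) on
trees of up to 8 tips, and the score additionally against an
independent implementation (`phangorn::parsimony`).

## The conservatism randomization test

The observed parsimony score is compared to the null distribution
obtained by uniformly permuting the 0/1 states among the scored tips,
leaving `?` tips untouched. The default p estimator is the plain
proportion of null scores ≤ the observed score. Two deliberate
choices:

* **Ties count as extreme** (≤, not <): the conservative direction.
* **The plain proportion can be zero.** With 100 permutations per tree
  an average p far below 0.01 is only expressible if per-tree p can be
  0; the add-one estimator (minimum 1/101) is available via
  `add_one = TRUE` for users who prefer a never-zero estimate.

The test is one-sided for conservatism (low scores extreme); an
anti-conservatism tail is not offered because a high parsimony score
has no biological reading for these traits beyond "not conserved".

Sample-level runs derive per-tree seeds from one master seed
(`sample.int` under `set.seed(master)`), so a full analysis is
reproducible bit for bit and trees could be processed in any order.

Because the parsimony score is integer-valued, the permutation p is
discrete and the test is conservative when few distinct scores are
achievable: with only a few dozen scored tips, the actual level at
α = 0.05 can drop to 0.01 or below. The level-calibration experiment
in the acceptance material therefore uses a 200-tip tree with 120
scored tips (50 positive), a design with enough score resolution for
the empirical level to sit near nominal; users testing small trait
matrices should expect — and welcome — conservative p-values.

## Posterior monophyly

Each tree is pruned to the scored tips (branch lengths summed through
removed unifurcations, root-to-tip path lengths preserved; the stem
lost above the retained tips' MRCA is kept in `root.edge`), and the
positive tips are tested for monophyly by a single postorder count: a
clade with exactly the positive tips exists iff some node has as many
descendant tips as marked descendant tips as there are positives.
Pruning happens per tree, though with shared tip sets the result
equals pruning once. A singleton positive group, or one equal to the
whole scored set, is monophyletic by convention and flagged with a
warning — real analyses should treat such results as vacuous. Trees
are used as rooted, as sampled; no rerooting.

## The synthetic-data generator

The generator exists so that every pipeline stage can be exercised,
with logged ground truth, on data whose statistical shape matches the
real study system. Defaults of `sim_config()`:

| parameter | default | why |
|---|---|---|
| `n_tips` | 150 | the real dated trees hold 100–500 tips; 150 keeps full-pipeline runs fast |
| `birth_rate` | 1 /unit time | Yule prior; only sets the time scale |
| `gain_M`, `loss_M` | 0.02, 0.08 | expected total tree length is ≈ `n_tips`/λ, so loss events land in the low tens — a conserved, repeatedly lost trait |
| `gain_P`, `loss_P` | 0.015, 0.01 | psilocybin arises rarely, from toxin-free lineages only |
| `root_state` | `"M"` | a muscarine-positive ancestor is the hypothesis under test |
| `missing_fraction` | 0.8 | ≈ 20% of accepted species have assay data |
| `n_trees`, `n_nni` | 100, 2 | a posterior-like sample of correlated topologies |

Trees are simulated by the fixed-*n* Yule construction (exponential
epochs with rate *k*λ while *k* lineages exist, a uniformly chosen
lineage splitting at each event, plus one final epoch at rate *n*λ),
because analyses are parameterized by taxon count; the closed-form
mean depth Σ 1/(*k*λ) is checked against simulation. Traits evolve by
exponential waiting times along branches with every event logged, so
the true gain and loss counts are known exactly; replaying the log
from the root must reproduce the tip states, and the parsimony score
can never exceed the logged event count — both are tested invariants.

The exclusive pair is a three-state chain M ⇄ N ⇄ P with no direct
M ↔ P edge: losing muscarine is a structural prerequisite for gaining
psilocybin, and no lineage ever carries both toxins at any instant.

Posterior correlation is emulated by applying a small number of random
rooted NNI moves to one base tree and redrawing internal-node ages
uniformly below the (kept) root age, rather than drawing independent
Yule trees — tree-to-tree correlation is what makes across-sample
ranges narrow, as in a real posterior. Independent draws are available
via a flag. Missingness is uniform at random by default; real
missingness is clustered (whole unassayed tropical clades), which
uniform masking does not emulate — conclusions about robustness to
*clustered* missingness are outside what passing tests show.

What passing tests on synthetic data do **not** show: robustness to
assay error structure beyond independent flips, to clustered
missingness, to non-ultrametric trees, or to trait-dependent
diversification. They do show that each algorithm computes exactly
what its definition says, on data where the truth is known.

## Numerical and degenerate-input choices

* Generation-0 MCMC samples are excluded from retained-tree counts:
  `n_runs × (chain_length − burnin) / sample_interval`; this is the
  convention under which five 50M-generation runs sampled every 5000
  with 30M burn-in retain 20 000 trees.
* Branch lengths are optional in `phylo` input; operations that need
  them (trait simulation, path lengths) raise a defined error rather
  than assuming length 1.
* Newick dialect: labels with spaces or punctuation are single-quoted
  (`''` escapes a quote) and round-trip bit-exactly; underscores in
  unquoted labels are verbatim, never turned into spaces; negative
  branch lengths and duplicate tip labels are parse errors naming the
  offending position.
* Thinning a posterior beyond burn-in removal is exposed
  (`discard_burnin`, subsetting) but never applied by default.
* Fewer than 2 scored tips makes the permutation test undefined — an
  error, not a p of 1. An empty positive group makes monophyly
  undefined; the pipeline records it as `NA` rather than failing the
  whole report.

## Problem sizes used in the shipped checks

Test and acceptance runs use 200 random ≤ 8-tip instances for oracle
equivalence, 10 000 permutations for the exact-p comparison, 1000
simulated tests at 199 permutations for level calibration, 20–50 tree
samples of 60–100 tips for power and monophyly, 10 000 replicates for
simulator calibration, and 10^5 tips for the exclusivity invariant —
sizes chosen so the whole suite completes in about two minutes on one
core while keeping Monte-Carlo standard errors well inside the
asserted bands.

## Known limitations

* Parsimony only: no likelihood or stochastic-mapping ancestral
  states, no branch-length-aware signal statistics (λ, K, D). On a
  dated tree, parsimony ignores the information in branch lengths.
* With ~80% missing tips, gain/loss ranges are lower bounds on event
  counts among *scored* lineages; unassayed clades contribute nothing.
* The monophyly proportion is a posterior odds summary, not a test
  with a null distribution; values near 0 or 1 are its only crisp
  readings.
* The mutual-exclusivity rule is a coding constraint taken from
  biochemistry (different precursor pathways), not something inferred
  from data; if a doubly positive species were ever confirmed, the
  coding step would reject the dataset by design.
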