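---
title: "Models and methods behind stemdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stemdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stemdiv)
```

`stemdiv` analyses diversification on dated family-level phylogenies in
which every tip is a terminally unresolved clade: a family with known
standing species richness S but unknown internal topology. This vignette
is the package's own account of the models it fits, the parameters that
matter, the design decisions that were genuinely open, and what the
simulation-based tests do and do not establish.

## Data model

A dataset is an ultrametric rooted tree (branch lengths in millions of
years, tips contemporaneous at the present) plus a per-family richness
table. Ages are measured backward from the present. Every node — tip or
internal — defines a clade with:

* **crown age**: the node's own age (0 for tips, by convention: a family's
  within-family divergences are unobserved);
* **stem age**: the age of the parent node, i.e. the split from the
  sister lineage;
* **richness**: the family's S, or the sum over member families.

The root has no subtending branch; its stem age is defined equal to its
crown age so that the whole-tree clade can carry a rate estimate without
inventing an unobserved stem branch. Ultrametricity is checked as a
relative spread of root-to-tip path lengths: deviations up to `1e-6` of
tree height pass silently, up to `1e-3` warn (dating pipelines emit
numerical jitter), and larger deviations are rejected. Polytomies are
accepted; the 2n−1 clade-count identity applies only to bifurcating
trees.

## Richness correction

Nomenclatural evaluation splits a family's proposed names into accepted
(S_A), rejected synonyms (S_R) and unevaluated (S_U). Assuming
unevaluated names are accepted at the same rate as evaluated ones,

$$S = S_A + S_A\,S_U/(S_A + S_R),$$

which satisfies \(S_A \le S \le S_A + S_U\) and is undefined when no
name has been evaluated (such families need a direct published
estimate — the workflow supports override tables that take precedence).
S is kept real-valued throughout the rate analyses; it is rounded to the
nearest integer (at least 1) only where the birth–death likelihood
requires an integer count. Totals are reported both unrounded and
rounded, since the choice is not forced by the estimator.

## Stem-age net diversification rates

For a clade of richness S and stem age t under relative extinction
\(\epsilon = \mu/\lambda\):

$$\hat r = \log[S(1-\epsilon)+\epsilon]/t,$$

with the natural logarithm (the whole-tree consistency check
\(\ln S_T\) and the estimator's provenance both require ln, not log10).
The two conventional regimes \(\epsilon = 0\) and \(\epsilon = 0.9\)
bracket the estimate; \(\hat r\) is non-increasing in \(\epsilon\) and
exactly 0 for monotypic clades under every regime. Rankings (e.g. the
top-k overlap between regimes) break ties by the stable clade
identifier, so output is invariant to input order. Crown-age variants
are deliberately not implemented: tip clades have no observed crown age.

## Age-window regressions

The time-for-speciation hypothesis predicts a positive slope of ln S on
stem age among clades of comparable depth. Clades are binned into
half-open 10-My windows \([lo, lo+10)\) for lo in 20…90 My; ages
below 20 or at/above 100 My are excluded by default (configurable) —
the tree is node-poor and highly nested at depth, and the printed-table
convention starts at 20 My. Within a window, nested (ancestor–
descendant) clades are statistically dependent, so one member of every
overlapping pair is removed — once keeping the older member, once the
younger. Because clades on a tree are either nested or disjoint, overlap
reduces to subset containment, and a deterministic greedy scan
(descending stem age, ties by clade id, keep a clade iff it overlaps no
already-kept clade; ascending for the younger-kept variant) implements
the pairwise drop rule exactly. Slope p-values from the per-window OLS
are adjusted with Benjamini–Hochberg jointly across all 16
window × variant tests: treating the two variants as one family is the
reading consistent with identical adjusted values recurring across both
subtables of this analysis's conventional presentation. Windows with
fewer than 3 clades or zero age variance are flagged unfit and excluded
from the BH family. Monotypic clades (ln S = 0) are retained.
Phylogenetic regression is deliberately not used: nested clades are by
definition poorer than the clades containing them, which is exactly the
dependence the pruning removes.

## The rate–richness correlation and its randomization null

Regressing ln S on \(\hat r\) across clades quantifies how much richness
variation the rate estimates capture — but \(\hat r\) is a deterministic
function of S, so a strong correlation is expected with no biology at
all. The null makes this explicit: per replicate, richness values are
permuted across clades (ages fixed; permuting ages instead is identical
in distribution), rates are recomputed from the permuted values and the
regression refit. Under permutation \(\ln S'\) is independent of
\(u = 1/t\), and the expected permuted R² has a closed form

$$R^2 = \frac{1}{1 + q\,\mathrm{cv}^2(u)}, \qquad
  q = 1 + (\mathrm{mean}/\mathrm{sd})^2 \text{ of } \ln S,$$

verified against direct simulation in development. Two consequences are
worth stating. First, any clade table with substantial richness variance
yields a permuted R² far above zero — the test suite asserts a floor of
0.3 on study-scale synthetic tables — so observed correlations of this
kind should never be read as evidence by themselves. Second, the exact
level depends sharply on the spread of 1/t: with the generator's
defaults the suite measures mean permuted R² around 0.35–0.45, and
values much higher than that would require clade ages far more
concentrated than a deep, family-level tree provides. The replicate
stream is fully seeded; the default regime is \(\epsilon = 0\)
(configurable).

## Birth–death likelihood with unresolved tips

The shift analysis needs the likelihood of a dated tree whose tips carry
integer richness. The package parametrises models by net rate
\(r = \lambda - \mu > 0\) and relative extinction
\(\epsilon = \mu/\lambda \in [0, 1)\), and conditions on the root
(crown) age and on each observed lineage having extant descendants.
With survival probability \(P_s(t) = (1-\epsilon)/(1-\epsilon e^{-rt})\):

* an **unresolved tip** of stem age t and richness S contributes the
  geometric law \(P(S) = (1-\beta)\beta^{S-1}\),
  \(\beta = (e^{rt}-1)/(e^{rt}-\epsilon)\) (Yule:
  \(\beta = 1-e^{-\lambda t}\)) — the classic stem-clade richness
  probability conditional on survival;
* an **internal branch** spanning ages \(t_1 > t_2\) contributes
  \(A(t_1,t_2) = [P_s(t_1)/P_s(t_2)]\,e^{-r(t_1-t_2)}\), the probability
  that an observed lineage leaves exactly one observed descendant
  lineage across the interval;
* each **internal node** except the root contributes the observed-split
  intensity \(\lambda P_s(x) = r/(1-\epsilon e^{-rx})\) at its age x.

All three factors are probabilities or bounded intensities for every
admissible \((r, \epsilon)\). This matters: the equivalent
*unconditional* factorisation (per-branch ratios of
\(p_1(t) = P_s(t)^2 e^{-rt}\) with a bare \(\lambda\) per node) has the
same total for a single-model tree but is unbounded partition-by-
partition — \(\log\lambda \to \infty\) as \(\epsilon \to 1\) in a
partition holding internal nodes but few tips — which destabilises any
model-selection search over partitions. The conditioned form was chosen
for exactly this reason. For pure-birth models the two coincide, and the
maximum-likelihood \(\lambda\) on a fully resolved tree (all richness 1)
reproduces the standard Yule estimator, which the tests cross-check
against `ape::yule`.

All formulas are evaluated on the log scale with `log1p`/`expm1`-style
identities, so they remain finite for large \(rt\) and accurate for
small. Optimisation works on \((\log r, \mathrm{logit}\,\epsilon)\):
pure-birth fits use 1-D golden-section search on
\(\log r \in [\log 10^{-7}, \log 20]\); birth–death fits use
Nelder–Mead (relative tolerance 1e-12) from a small multistart grid in
\(\epsilon\) plus, during the stepwise search, the parent partition's
fitted values — initialising new partitions from the model they were
carved from avoids poor local optima near the \(\epsilon\) bound.
\(\epsilon\) is capped at \(1 - 10^{-6}\); fits pinned at any bound are
flagged, since near-unit relative extinction implies lineage turnover
faster than is biologically defensible.

## Stepwise rate-shift search

The search starts from one constant-rate model for the whole tree, then
repeatedly tries every node (internal nodes and tip stems,
exhaustively — a deterministic and strictly more thorough version of
randomised break-point proposals) as a break-point: the node's
subtending branch and all descendants still governed by its current
model are carved into a new model, both affected partitions are refit
(each retaining the better of the allowed model kinds), and the single
best candidate by total AICc is considered. AICc uses
\(-2\ell + 2k + 2k(k+1)/(n_{obs}-k-1)\) with \(n_{obs}\) = resolved
internal nodes + unresolved tips, and k counts one or two rate
parameters per model plus one parameter per break-point.

**Stopping rule.** A break-point is retained only if it improves the
AICc by more than `aicc_threshold`, default 4 units — the conventional
"substantial support" cutoff in information-theoretic model selection,
and the retention rule used by the original stepwise rate-shift
literature. The choice is deliberate: scanning ~2n candidate nodes is a
sup-likelihood-ratio test, and accepting arbitrarily small improvements
plants spurious shifts on the large majority of single-rate trees (the
package's null simulations reproduce this). Setting
`aicc_threshold = 0` recovers the literal any-improvement rule. The
accepted-step AICc sequence is strictly decreasing by construction;
`max_models` caps runaway searches with a warning rather than an error.

Unresolved tips are stem-conditioned (the geometric term above), the
default consistent with the stem-age rate estimator used everywhere
else in the package.

## What the simulators emulate — and what they do not

* `simulate_bd_tree()` is an event-driven (Gillespie) constant-rate
  birth–death simulation from a **single origin lineage**, stopping at a
  fixed number of concurrently alive lineages or at a fixed age; it
  returns the complete and the reconstructed (extant-only) tree. From
  one origin lineage the fixed-age expectation is
  \(E[N] = e^{\lambda T}\), which the tests assert. Whole-tree
  extinction triggers a retry (cap 100), then an explicit error — never
  a silent correction.
* `plant_shifts()` changes one lineage's rates (speciation multiplier,
  optional new \(\epsilon\)) at a given time or when a given number of
  lineages is alive; descendants inherit the shift, and nested shifts
  apply innermost-tipward. The realised shifted clade and its MRCA in
  the reconstructed tree are returned for recovery testing.
* `collapse_to_families()` slices an extant tree at a cutoff age
  (default 30 My): every crossing branch becomes a family tip whose
  richness is its extant species count and whose stem age is preserved.
  Families are defined by the time slice, not by taxonomy — the only
  structure the downstream analysis uses is stem age plus richness.
* `simulate_taxonomic_counts()` draws a Poisson number of synonyms
  (mean `synonym_rate` per true species) and evaluates each name
  independently with probability `eval_fraction`, labelling evaluated
  names by their true status. The richness correction is approximately
  unbiased under this process, which the tests verify by simulation.
* `simulate_family_dataset()` generates data exactly under the fitted
  likelihood: a (possibly shifted) backbone plus geometric tip richness
  under each tip's governing model. It is the well-specified generating
  process used to validate the constant-rate fit and the shift search;
  recovery results on it do not speak to model misspecification on real
  trees.
* `simulate_clade_table()` produces study-scale clade tables: a
  pure-birth backbone rescaled to a 330-My root with a 25-My floor on
  internal-node ages (a family-level tree is a tree collapsed at the
  family-origination depth, so it has no near-present splits), and
  independent log-normal family richness (meanlog 4.0, sdlog 2.3 —
  chosen so the clade-table mean and maximum of ln S, and the total
  richness, are of the order seen in seed-plant family data).
  `shuffle_richness = TRUE` permutes richness across clades after
  enumeration, giving the null case (richness independent of age) for
  the window analysis.

None of the generators emulate dating uncertainty, fossil calibration,
taxonomic error in tip assignment, or time-varying rates within a model;
passing recovery tests therefore shows internal consistency of the
estimators with their assumed processes, not robustness to violations
of those assumptions.

## Simulation scales used by the test suite

The suite validates behaviour at the scales the analyses are designed
for: clade tables of 300–425 families (599–849 clades) for the window
and randomization analyses (100 null seeds for the false-positive check;
1000 permutation replicates), and 64-family trees for the shift search
(100 single-rate seeds for specificity, 100 planted-shift seeds — 5×
multiplier on a ≥20-tip subclade — for sensitivity, with pure-birth
candidate models since the generating process is pure-birth). Parameter
recovery of the constant-rate fit uses 96-family trees. These sizes were
chosen as representative of family-level datasets.

## Known limitations

* The stem-age estimator ignores within-clade rate variation; its upper
  tail on real data is outlier-prone and should be read cautiously.
* The shift search is greedy: it does not revisit earlier break-points,
  and break-point placement between a node and its immediate neighbours
  is only weakly identified when the subtending branch is short.
* The backbone likelihood assumes the tree is complete at the family
  level (every family sampled) and exactly ultrametric after the
  tolerance check.
* The AICc retention threshold trades sensitivity for specificity at a
  conventional value; it is a tunable, not a law.
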