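---
title: "Nested-growth time slicing and topology-based shift detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested-growth time slicing and topology-based shift detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fossil-rich clades such as Crocodyliformes pose a specific question: when,
and on which branches, did diversification rate shift?  With no usable
branch lengths — supertrees of fossil taxa carry topology and stratigraphic
first appearances, nothing more — the evidence has to come from *tree
shape*: under the equal-rates Markov (ERM, or Yule) null, in which every
lineage speciates at the same rate, a clade of $m$ tips splits into
daughters of $i$ and $m-i$ tips with probability

$$P_0(i \mid m) = \frac{1}{m-1}, \qquad i = 1, \dots, m-1,$$

so persistent, localized imbalance is evidence of rate variation.

Mixing fossil and extant taxa in one tree violates the ERM premise that
all tips coexist.  `nestshift` implements the nested-growth remedy: taxa
are binned into ordered stratigraphic intervals by their oldest record
(`assign_bins()`, the oldest-record rule), and one tree is built per bin
(`nested_series()`) in which taxa enter at their first appearance and are
never removed.  A clade made entirely of later arrivals is collapsed to a
single *ghost leaf* (`GHOST:<representative>`): its lineage is inferred to
exist — its sister is sampled in the bin — but its later diversity must not
leak into earlier tree shapes.  This is why a ghost is one leaf and not
the whole younger clade.  The series simulates speciation but not
extinction; the final slice is the full tree.  A classic non-nested
variant (`timeslice_series()`, taxa drop out after their last appearance)
is provided for comparison.

## The shift statistic

For an internal branch $b$ with parent node subtending $m$ tips, focal
clade of $k$ tips, and focal daughters of $l$ and $r$ tips, the two-rate
alternative uses the tilted-geometric partition law

$$P_\rho(k \mid m) = \frac{\rho^{\,k-1}}{\sum_{j=1}^{m-1} \rho^{\,j-1}},$$

the exact conditional law of two independent pure-birth sister clades
with rate ratio $\rho$ given their combined tip count; $\rho = 1$ recovers
the ERM value.  With $\hat L_1(k \mid m) = \sup_\rho \log P_\rho(k \mid m)$
(`tilted_split_ml()`; at the boundary partitions $k \in \{1, m-1\}$ the
supremum is exactly $0$, no epsilon regularization),

$$\Delta_1(b) = \hat L_1(k \mid m) - \log P_0(k \mid m)$$

measures support for a shift along $b$ from the parent partition alone,
and

$$\Delta_2(b) = \bigl[\hat L_1(k \mid m) + \log P_0(j \mid k)\bigr] -
  \bigl[\log P_0(k \mid m) + \hat L_1(j \mid k)\bigr], \quad j = \max(l, r),$$

discounts support better explained by a rival shift nested just inside
the focal clade.  A pendant focal clade takes $\Delta_2 = 0$ by
convention ($\Delta_1$ is still reported, as a diagnostic only).

Soft polytomies are resolved by Monte-Carlo ERM resolution
(`resolve_polytomies()`: uniformly random pairwise joins of each
polytomy's children), and the statistics are averaged over the resolution
sample.  Significance is Monte-Carlo: `branch_shift_scan()` simulates ERM
null trees with the same tip count (ghost leaves count as ordinary tips)
and reports, per branch,

* `p_tree` — the fraction of null trees whose **maximum $\Delta_2$
  anywhere** reaches the branch's value (familywise control over the
  whole-tree survey; the headline criterion), and
* `p_local` — the same comparison restricted to null branches whose focal
  clades fall in the branch's dyadic size class,
  $\mathrm{class}(k) = \lfloor \log_2 k \rfloor$ (a diagnostic; the size
  class makes near-boundary branches compete with their own kind).

Both use the add-one estimator $(1 + \#\{\cdot\})/(G+1)$, so they are
never exactly zero.  Whether the original survey corrected per branch or
tree-wide is not recorded anywhere we could consult; both values are
reported and the tree-wide one drives `detect_shifts()`, which is the
defensible reading of a whole-tree survey.

### A known limitation of the max-$\Delta_2$ correction

Raw $\Delta_2$ is not on a common scale across branch contexts.  A branch
whose sibling is a single pendant tip sits at the boundary
($k = m - 1$, $\hat L_1 = 0$) and scores $\Delta_1 = \log(m-1)$; if its
interior happens to be balanced, $\Delta_2$ approaches $\log(m-1)$ as
well.  The null maximum is therefore dominated by such configurations,
while a genuine stem shift — whose clade-internal root split is itself
ERM-uniform, making the nested-shift discount large at random — typically
scores far lower.  The consequence, which the acceptance suite measures
rather than hides: the tree-wide test is well calibrated under the null,
and its power is monotone in the planted rate ratio, but the minimal-`p_tree`
branch localizes a planted stem shift to within one branch only in a
minority of replicates.  Users who need localization should read the
ranked `p_local` values alongside `p_tree` and treat the flagged region,
not the single best branch, as the detection.

## Tracking and the artefact rule

Every slice is a collapse of one full tree, so a slice clade — ghosts
expanded to the clades they collapse — is a full-tree clade, and its stem
node identifies "the same shift" across bins (`track_shifts()`); records
merge on that stem, and punctual detections (found, then lost) remain
visible as `bins_detected` sets with gaps.  At the first-detection bin
$t$, the fraction of *older* taxa,

$$\frac{\#\{\text{members with fad} < t\}}{\#\{\text{members with fad} \le t\}},$$

is computed over sampled members only (ghosts are unsampled lineages, not
species records) and over the shift clade's own richness, not the whole
tree's — the rule is applied clade by clade.  `classify()` marks a record
*genuine* when this fraction does not exceed the threshold (default 0.10,
boundary inclusive) and otherwise an *artefact*: a shift produced by the
extinction of older lineages rather than elevated speciation.  No
rock-record sampling-bias correction exists for this framework; that
caveat transfers to every classification.

## The supertree stage

The optional MRP stage assembles the input topology the analysis
presumes.  `encode_mrp()` codes each non-root clade of each source tree
as a binary character (members 1, other taxa of that tree 0, absent taxa
missing); repeated sources weight by repetition.  `heuristic_search()` is
a deliberately desk-scale parsimony search — random-addition starting
trees, hill climbing under NNI, SPR, or TBR (SPR plus reconnection-point
enumeration over the pruned clade's rerootings), Fitch length with
missing as a free wildcard — with the full-scale settings (10 000
replicates, hold 20, TBR) reachable by argument; it is not a general
search engine, and ties keep earlier-found trees so results are
deterministic per seed.  Fitch length is invariant to rerooting, so the
matrix alone cannot anchor the root: `encode_mrp()` keeps the
source-polarized coding by default (per-column polarization by each
source tree's root), while `mrp_supertree()` adds the classic all-zero
hypothetical outgroup by default, roots the optima on it, strips it, and
returns the strict consensus.  `prune_unstable()` re-implements the
observable contract of iterative positional-congruence pruning as greedy
reduced-consensus leaf removal: repeatedly delete the taxon whose removal
most increases consensus resolution, reporting each removed taxon's
alternative attachment positions.  `graft()` replaces a summarized crown
terminal with its resolved subtree.

## The synthetic generator

`sim_spec()` + `yule_tree()`/`shifted_tree()` simulate the event-driven
pure-birth(-death) process the null assumes; planted shifts are selected
reproducibly as "the standing clade whose tip share is closest to `frac`
when `at_ntip` lineages exist", multiply the speciation rate from that
moment on, and are returned as true stems for recovery scoring.
`fossilize()` lays Poisson($\psi \times$ branch duration) fossil finds
along terminal branches (lineage-path sampling is a flag; terminal-branch
sampling matches species-level records), bins the oldest and youngest
find, and keeps unsampled taxa with a flagged fallback age so trees and
age tables always align.  `make_source_trees()` produces overlapping,
partly erroneous induced subtrees for supertree tests.

The generator emulates the statistical structure the analysis assumes —
ERM shape, rate shifts localized to stems, incomplete fossil sampling —
and nothing else: no rock-record heterogeneity through time, no
correlated taxonomic practice, no morphological characters, and
categorical bins rather than numeric ages.  Green tests therefore show
the machinery is faithful to its model, not that the model captures any
particular empirical record.

For the half-the-tips planted-shift scenario the selector is fixed at
`at_ntip = 32`, `frac = 0.0625` for `n_tips = 128`: a two-lineage clade
selected at a quarter of the final richness, whose expected final share
under a fivefold rate is one half (the deterministic growth calculation
$2e^{5\lambda s} + 30e^{\lambda s} = 128$ gives a share of 0.52; the
realized mean share is 0.49).

## Numerical choices

* $\hat L_1$ maximization: `stats::optimize` on $\log \rho \in [-40, 40]$,
  tolerance $10^{-10}$; values are cached, and the branch scan reads a
  precomputed triangular table so a scan costs one table lookup per
  branch.
* Null simulation draws ERM split sizes directly (a clade of $s$ splits
  uniformly), never building tree objects; one `runif` block per tree.
* All user-facing sampling is seeded; a master seed is split into
  substreams (one per bin, per resolution batch, per null batch) so any
  slice of the pipeline can be reproduced in isolation and reruns are
  byte-identical.
* Degenerate slices (fewer than two leaves, or fewer than two sampled
  taxa before the series starts) are skipped with a logged warning, not
  an error.
* Reporting ties (equal minimal p) break toward larger $\Delta_2$, then
  the larger focal clade, then lexicographic clade id.

Test and acceptance problem sizes are desk-scale by design: calibration
uses 200 trees of 64 tips with 1000 null trees each; power and recovery
use 100 replicates of 128 tips per rate ratio; oracle equivalences run
exhaustively at $\le 8$ taxa (parsimony) and $\le 12$ leaves (ghost
collapse).  The full-scale Monte-Carlo budgets (10 000 resolutions per
node, 1 000 000 whole-tree) remain available through `null_settings()`.

## Known limitations

* The $\Delta$ statistics are a canonical reconstruction of the cited
  shift-statistic family from its published description; algebraic
  equivalence with the original program's internals is not asserted
  anywhere, and validation is by calibration, power and oracle
  properties.
* Localization of the tree-wide test is weak (see above); detection
  regions, not single branches, are the robust output.
* The artefact rule is the stated quantitative 10% criterion only; the
  original usage also weighed qualitative fossil-record arguments, which
  remain the user's to adjudicate.
* Nested-growth mode ignores last appearances by construction, so true
  extinction signal is only visible through the artefact classification,
  never through the series itself.
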