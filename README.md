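# nestshift

Topology-based detection of diversification-rate shifts on phylogenies of
fossil and living taxa — the kind of tree a supertree of Crocodyliformes
is: a taxon-labelled topology with stratigraphic first appearances and no
usable branch lengths.

`nestshift` implements the full nested-growth workflow:

* **Time slicing with ghost lineages.** Taxa are binned into ordered
  stratigraphic intervals by their oldest record; one tree is built per
  bin, taxa entering at first appearance and never leaving (speciation
  without extinction). Clades made entirely of later arrivals collapse to
  single `GHOST:` leaves — lineages inferred to exist because their
  sisters are sampled.
* **Shift detection under the equal-rates Markov (Yule) null.** Under ERM
  a clade of *m* tips splits (*i*, *m−i*) with probability 1/(m−1). For
  each internal branch the statistic
  Δ₂ = [L̂₁(k|m) + log P₀(j|k)] − [log P₀(k|m) + L̂₁(j|k)], with
  L̂₁ the supremum over ρ of the tilted-geometric partition likelihood
  ρ^(k−1)/Σ ρ^(j−1) and j = max(l, r), scores a stem shift against the
  rival of a shift nested just inside the focal clade. Polytomies are
  resolved by Monte-Carlo ERM resolution; significance comes from ERM
  null trees (tree-wide `p_tree`, familywise; per-size-class `p_local`,
  diagnostic).
* **Tracking and the artefact rule.** Detections are merged across bins by
  their stem node in the full tree. At first detection, a shift whose
  members include more than 10% taxa older than the detection bin is
  classified an extinction-driven **artefact**; otherwise a **genuine**
  radiation ("does not exceed": the 10% boundary counts genuine).
* **MRP supertree assembly** (optional stage): Baum–Ragan coding of source
  trees, seeded random-addition + NNI/SPR/TBR parsimony search, strict
  consensus, greedy pruning of unstable (rogue) taxa, and grafting of a
  resolved crown group onto its backbone terminal.
* **A synthetic-data generator**: pure-birth(-death) chronograms with
  planted stem shifts, Poisson fossil sampling into bins, and noisy
  overlapping source trees — so every stage is testable without external
  data.

## Worked example

A balanced 32-species clade radiates in the second of three intervals,
against a sparse outgroup:

```r
library(nestshift)

crown <- ape::stree(32, type = "balanced")
crown$tip.label <- sprintf("sp%02d", 1:32)
full <- graft(ape::read.tree(text = "(out1,PLACE);"), crown, "PLACE")

ages <- data.frame(
  taxon   = full$tip.label,
  fad_bin = ifelse(full$tip.label %in% c("out1", "sp01", "sp02"), 1L, 2L),
  lad_bin = NA)

cfg <- pipeline_config(full, ages, bins = c("early", "middle", "late"),
                       settings = null_settings(null_trees = 1000, seed = 42))
res <- run_pipeline(cfg)

attr(res$detections, "series")
#> Time-slice series (nested mode), 3 slices over 3 bins
#>   bin  1 (early): 3 taxa + 4 ghost lineage(s)
#>   bin  2 (middle): 33 taxa + 0 ghost lineage(s)
#>   bin  3 (late): 33 taxa + 0 ghost lineage(s)

subset(as.data.frame(res$detections), significant,
       select = c(bin, k, delta2, p_tree))
#>    bin  k   delta2      p_tree
#> 6    2 32 3.465736 0.002997003
#> 37   3 32 3.465736 0.002997003

res$records[[1]]
#> Shift record: 32 taxa, first bin 2 (detected in 2,3): genuine
#>   (older fraction 0.062, threshold 0.10)
```

Reading the output: in the *early* slice only three taxa are sampled and
four ghost lineages stand in for later diversity — nothing is
significant. Once the crown clade appears, its stem branch (focal clade
k = 32 against a single-tip sibling, balanced inside) reaches Δ₂ = 3.47
with a tree-wide Monte-Carlo p of 0.003, and stays significant in the
following bin. The merged record first appears in bin 2 with 2 of 32
members (6.2%) older than the detection bin — under the 10% rule, a
genuine radiation, not an extinction artefact.

`run_pipeline()` with an `out_dir` additionally writes one Newick per
slice, `ghosts.tsv`, the per-branch `shifts.tsv`, the per-record
`summary.tsv` and a `manifest.json`; reruns with the same manifest are
byte-identical. A YAML config (`read_config()`) mirrors
`pipeline_config()`.

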