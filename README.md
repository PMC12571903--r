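# tcellrepair

Reusable, tested re-implementation of the computational core of a
single-cell study of T-cell-mediated tissue repair: how the co-inhibitory
receptor TIGIT relates to a tissue-repair gene program (with *Areg* as the
key effector) in T cells from wild-type (WT) and *Tigit*-knockout (KO)
mice, naive or LCMV-infected, in spleen and lung. It is written for
computational immunologists who want to run, audit or extend these
analyses on their own data — or on fully synthetic data with known ground
truth.

Three analysis engines sit on top of a common data model
(10x-style MTX count triplets, AUCell-style activity matrices, 10x/AIRR
contig tables):

* **Repair-signature scoring & coexpression.** Cells are QC-filtered
  (mitochondrial fraction > 7% removed), depth-normalized
  (`x = ln(1 + 10^4·c/total)`), and the signature genes are scaled to unit
  variance without centering; the per-cell repair score is
  `score(c) = Σ_g x̃(c,g)`. Coexpression heat maps report pairwise Pearson
  r per cell type with average-linkage dendrogram ordering, and
  pseudo-replicate analysis splits each stratum into ten random cell
  pools, pooling expression as `log10(mean cpk + 1)`.
* **Differential regulon activity.** On a randomized 5,000-cell subset,
  regulons with > 70% zeros in all conditions are removed; per cell
  subset and condition the WT−KO difference in mean activity
  `T = mean(WT) − mean(KO)` is tested against a two-sided permutation
  null (exact enumeration for small strata, otherwise B = 10,000
  relabelings with the add-one estimator
  `p = (1+#{|T*|≥|T|})/(1+B)`), corrected per family by Holm–Bonferroni,
  with effect size `log2((mean_WT+ε)/(mean_KO+ε))`.
* **TCR clonality.** Clonotypes are assembled on the all-chain CDR3
  nucleotide key, transgenic (Smarta-1/P14-like) receptors excluded by
  CDR3 blacklist, clones with ≥ 2 cells classified as expanded, cells
  split by Tigit/Areg positivity (count ≥ 1), and repertoire overlap
  computed as the Jaccard index `J = |A∩B|/|A∪B|` over exact CDR3β
  amino-acid matches (single-pair filtered for cross-dataset use).

A synthetic-data module simulates all three input types with planted
structure — a latent activation factor coupling *Tigit* to the signature
at a calibrated correlation ρ, zero-inflated Beta regulon activities with
planted WT−KO shifts, and geometric clone-size repertoires with public
clones, spike-ins and chain anomalies — each with a truth table that the
test suite scores the pipeline against.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → preprocess/score → regulon test → TCR), writing tables under
`results/`. Running them with seed 1:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_preprocess_score.R 1
Rscript analysis/03_regulon_test.R 1
Rscript analysis/04_tcr_clonality.R
```

prints, among other things:

```
QC: kept 19154 of 20160 cells (1006 removed for >7% mitochondrial reads)
Pooled Tigit-vs-repair-score correlation (WT pools):
  CD4conv: r = 0.855, two-sided p = 1.57e-06
  CD8: r = 0.799, two-sided p = 2.39e-05
  Treg: r = 0.936, two-sided p = 1.43e-09
400 (regulon, subset, condition) tests; 40 Holm-significant at alpha = 0.05
Planted shifted regulons recovered: 10/10; false positive regulons: 0
WT_spleen: 1000 cells -> 960 after transgenic exclusion; 230 expanded clones
```

Reading: the QC filter removed exactly the simulated high-mitochondria
cells; the pooled correlation between *Tigit* and the repair score is
strongly positive in every T-cell subset (the generator planted a
single-cell coupling of ρ = 0.6, and pooling averages away single-cell
noise); the permutation/Holm machinery recovered all 10 planted regulon
shifts in each of the 4 subset × condition families with no false
positives; and the blacklist removed exactly the 40 spiked transgenic
cells per sample before expansion analysis.

The same run is available as one call —
`run_pipeline(out_dir = "results", seed = 1)` — which also writes a
`manifest.json` (seed, configuration, stage order, versions); identical
configuration and seed give byte-identical result tables.

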