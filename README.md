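# tcrtrace

Donor–recipient T-cell repertoire tracking and immune-remodeling analysis for
allogeneic hematopoietic stem cell transplantation (allo-HSCT).

## The problem

After allo-HSCT, a recipient's T cells are rebuilt along two routes:
**peripheral** reconstitution (homeostatic expansion of mature donor T cells
transferred in the graft) and **central** reconstitution (de novo naive
T cells from the recipient's thymus). Paired donor–recipient single-cell TCR
sequencing separates the two: defining a clonotype by its CDR3 amino-acid
sequence, a clonotype observed in *both* members of a pair is **consistent**
(peripheral proxy) and a clonotype observed in only one member is **unique**
(a recipient-unique clonotype proxies thymic output). Comparing provenance
per T-cell subset between HLA-matched sibling (MSDT) and haploidentical
(haplo-SCT) transplantation reveals how strongly each setting relies on each
pathway.

`tcrtrace` is for computational immunologists analysing such cohorts. It
implements:

- **Repertoire IO** — 10x `filtered_contig_annotations.csv` and AIRR
  rearrangement TSV parsing, the "at least one productive TRA or TRB" cell
  filter, deterministic collapse to paired clonotype keys
  (`TRA:<aa>|TRB:<aa>`).
- **Clonotype provenance** — consistent/unique classification per pair
  (`classify_clonotypes`), per-subset fraction tables
  (`provenance_by_subset`), exact rank-sum group contrasts
  (`group_provenance_contrast`).
- **Diversity** — Shannon index `H = -Σ p_i ln p_i` and Pielou evenness per
  sample or sample × subset, with optional seeded rarefaction.
- **Expression scores** — library-size normalization to 10⁴ + log1p, binned
  dispersion HVG selection, one-vs-rest Wilcoxon marker ranking (log2FC >
  0.1, BH-adjusted p < 0.05), top-10 signature programs excluding TCR-locus
  genes, a rank-based per-cell program score
  `max(0, 1 − U/(n·r_max))` with `U = Σ rᵢ − n(n+1)/2`, and
  "more than one read" gene-positivity calling.
- **Composition statistics** — cell-type proportion tables and
  empirical-Bayes **moderated** paired (recipient vs donor) and unpaired
  (haplo vs MSDT) t-tests with method-of-moments variance shrinkage
  `s̃² = (d₀s₀² + df·s²)/(d₀ + df)`.
- **Deconvolution** — cell-type centroids of log-normalized expression,
  multi-objective (min inter-centroid correlation / max distance)
  evolutionary marker-gene selection, and non-negative least-squares mixture
  estimation with paired contrasts of estimated proportions.
- **Synthetic cohorts** — generators for paired repertoires with known
  peripheral/central origin per cell, negative-binomial count matrices with
  known marker genes, and pseudobulk mixtures with known weights, so every
  stage is testable against hidden truth without access to patient data.

## Worked example

Simulate one haplo-SCT donor–recipient pair, classify clonotype provenance,
and summarise:

```r
library(tcrtrace)

cfg  <- sim_config(n_donor_cells = 1500, n_recipient_cells = 1500)
pr   <- simulate_pair(cfg, regime = "haplo", seed = 42, pair_id = "PT01")
pair <- classify_clonotypes(pr$donor_cells, pr$recipient_cells)
pair
#> provenance_pair 'PT01' (haplo): 58 consistent clonotype(s)
#>       role n_cells n_clonotypes n_cells_consistent n_cells_unique
#>      donor    1500          424                834            666
#>  recipient    1500          876                308           1192

subset(provenance_by_subset(pair), role == "recipient",
       select = c(subset, n_cells, n_clonotypes, unique_cell_fraction))
#>  subset n_cells n_clonotypes unique_cell_fraction
#>     all    1500          876                0.795
#>     Tcm     396          300                0.778
#>    Teff     373          238                0.660
#>     Tem     351          266                0.781
#>  Tnaive     380          338                0.958
```

58 clonotypes are shared (consistent); under the haplo regime most recipient
cells — 79.5% overall, 96% of naive cells — carry recipient-unique clonotypes,
i.e. are central-pathway (thymic) output in the simulation's ground truth.
The classification agrees with the generator's hidden origin label for every
cell (`collision_rate = 0` makes provenance an exact oracle). Repertoire
diversity per subject:

```r
rbind(diversity_by_group(pr$donor_cells, "per_sample"),
      diversity_by_group(pr$recipient_cells, "per_sample"))
#>  subject_id n_cells n_clonotypes shannon pielou
#>      PT01-D    1500          424   4.899 0.8098
#>      PT01-R    1500          876   6.241 0.9211
```

The whole pipeline (simulate → provenance → diversity → score → compose →
deconvolve) runs as one call and writes TSV/JSON outputs plus a
`manifest.json` with the seed, thresholds and row counts:

```r
pipeline_run("all", pipeline_config(paths = list(out_dir = "demo_run"),
                                    seed = 1))
```

or from a shell via `inst/scripts/run_pipeline.R`.

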