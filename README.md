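# celldyn

Tools for asking a simple developmental question of multi-age single-cell
RNA-seq data: **which cell classes reorganize their transcriptomic identity
across a time course, and which stay stable?**

During early postnatal development of the mouse prefrontal cortex,
intratelencephalic (IT) excitatory neurons mature dramatically — immature
subtypes present at birth are progressively replaced by adult expression
programs — while deep-layer classes (PT, CT, NP) and interneurons keep a
largely constant identity. `celldyn` implements the cross-age
transcriptomic-dynamics framework that quantifies this:

1. **Label transfer.** For each pair of consecutive ages, a supervised
   classifier (gradient-boosted trees by default) is trained to predict
   subtype labels from normalized expression over highly variable genes at
   the earlier age, then applied to every cell of the later age.
2. **Dynamic score.** For each cell class *c*, restrict to the later-age
   cells whose true class is *c* and compare two partitions of those cells:
   their true subtype labels vs the transferred labels. With Rand index

   RI = (a + b) / C(n, 2),

   where *a* counts cell pairs co-grouped in both partitions and *b* pairs
   separated in both, the **dynamic score is 1 − RI**: 0 when subtype
   structure transfers perfectly across the pair of ages (stable identity),
   approaching 1 under complete reorganization. Because it compares
   partitions, renaming subtypes between ages ("Im L2/3 IT" → "L2/3 IT")
   does not affect it.
3. **Correspondence map.** Row-normalized confusion matrices give
   Sankey-style edges (source subtype → target subtype, weight = cells,
   similarity = fraction of the target subtype) linking subtypes across ages.

Around this core the package provides the supporting single-cell toolkit —
QC filters (cells: ≥1000 counts, ≥1000 detected genes, ≤15% mitochondrial;
genes: detected in ≥3 cells, mito/ribo removed), per-cell scaling to 10,000
counts with log1p, dispersion-based selection of 2000 highly variable genes,
Wilcoxon rank-sum differential expression with a |log2 FC| > 0.25 threshold,
subtype proportion time courses with coefficients of variation — plus a
spatial module (k = 5 nearest-neighbor ligand–receptor colocalization
scoring of segmented-cell fields, argmax spot annotation of deconvolution
abundances) and a negative-binomial multi-age simulator whose `drift`
parameter controls how far each subtype's expression program is replaced
across the age axis, so every stage is testable without any external data.

## Worked example

Simulate a four-age course in which three immature IT subtypes drift toward
independent adult programs (`drift = 0.8`) while two deep-layer subtypes
stay fixed, then run the full framework:

```r
library(celldyn)

subtypes <- c(
  lapply(c("Im L2/3 IT", "Im L5 IT", "Im L6 IT"), function(s)
    subtype_spec(s, class_name = "IT", drift = 0.8, proportion_schedule = 0.2)),
  lapply(c("L5 PT", "L6 CT"), function(s)
    subtype_spec(s, class_name = "deep", drift = 0, proportion_schedule = 0.2)))
cfg <- timecourse_config(ages = c("P1", "P4", "P10", "Adult"),
                         subtypes = subtypes, n_cells_per_age = 300,
                         n_genes = 400, seed = 1)
course <- generate_timecourse(cfg)

prep <- lapply(course, function(stage) {
  qc <- qc_config(min_counts_per_cell = 500, min_genes_per_cell = 50)
  kept <- filter_genes(filter_cells(stage$counts, qc)$counts, qc)
  ann <- stage$annotation[match(colnames(kept), stage$annotation$cell_id), ]
  list(norm = normalize_counts(kept, qc), ann = ann)
})

spec <- classifier_spec("gradient_boosting", seed = 1)
transfers <- lapply(1:3, function(i)
  transfer_labels(prep[[i]]$norm, prep[[i]]$ann,
                  prep[[i + 1]]$norm, prep[[i + 1]]$ann,
                  spec, hvgs = select_hvgs(prep[[i]]$norm)))

class_map <- setNames(vapply(subtypes, `[[`, "", "class_name"),
                      vapply(subtypes, `[[`, "", "name"))
dyn <- dynamic_scores(transfers, class_map)
dyn
#> Cross-age transcriptomic dynamics
#>   3 age pair(s), 2 class(es)
#>   IT           mean dynamic score 0.016 (sd 0.022, 3 pairs)
#>   deep         mean dynamic score 0.011 (sd 0.013, 3 pairs)
print(dyn$pairs[, c("pair", "class", "n_cells", "dynamic_score")], row.names = FALSE)
#>       pair class n_cells dynamic_score
#>      P1-P4  deep     117   0.008399646
#>      P1-P4    IT     175   0.040788177
#>     P4-P10  deep     120   0.000000000
#>     P4-P10    IT     176   0.007467532
#>  P10-Adult  deep     116   0.025487256
#>  P10-Adult    IT     175   0.000000000
```

The drifting IT class scores highest exactly where its reorganization is
steepest (P1–P4, score 0.041 vs 0.008 for the stable class). A single seed
is noisy at this scale — per-class contrasts should be read from replicate
simulations, as `scripts/acceptance.R` does (20 seeds; the drifting class
outranks the stable one in 20/20). The correspondence edges behind the
Sankey diagram:

```r
head(sankey_edges(transfers)[, 3:6], 5)
#>    source_subtype target_subtype weight similarity
#> 1      Im L2/3 IT     Im L2/3 IT     55  0.9322034
#> 7        Im L5 IT       Im L5 IT     58  0.9666667
#> 13       Im L6 IT       Im L6 IT     54  0.9642857
#> 19          L5 PT          L5 PT     59  1.0000000
#> 25          L6 CT          L6 CT     57  0.9827586
```

Spatial ligand–receptor colocalization on a simulated field with a
co-expression patch (per-cell score = strongest ligand–receptor product
between the cell and its 5 spatial nearest neighbors):

```r
sp  <- generate_spatial(spatial_config(n_cells = 1000, coloc_fraction = 0.3, seed = 1))
fld <- lr_score(sp, k = 5)
cmp <- compare_fields(fld[sp$in_patch, ], fld[!sp$in_patch, ])
#> median inside 0.275 vs outside 0.0016, Wilcoxon p = 4.1e-135
```

`run_demo(pipeline_config(out_dir = "out", seed = 0))` chains all stages —
simulation, QC, dynamics, differential expression, proportions, spatial
scoring — and writes `dynamics.json`, `sankey.csv`, `de.csv`,
`lr_scores.csv`, `proportions.csv` and a log.

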