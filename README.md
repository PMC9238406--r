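# microhorizon

Horizon plots for longitudinal compositional microbiome data.

Time-series microbiome datasets hold thousands of taxa whose relative
abundances differ by orders of magnitude, which makes stacked line or
stream graphs nearly unreadable: proportionally large swings in rare taxa
vanish next to abundant ones. `microhorizon` draws **horizon plots**
instead — compact faceted charts in which each taxon's deviations from an
origin are folded into mirrored, color-graded bands — so sustained shifts,
comovement between taxa, and periodicity stand out across many taxa and
many subjects at once. It is aimed at microbiome researchers doing
exploratory analysis of longitudinal 16S or shotgun profiles, from aligned
intervention studies to opportunistically sampled wildlife cohorts.

## The method

For a taxon with percent abundances \(v_i\) at days \(t_i\), origin \(o\)
(default: the median of observed values), band thickness \(w\) (default:
\(\max_i |v_i - o| / n\)), and \(n = 4\) bands per side, each deviation
\(d_i = v_i - o\) maps to

- band index \(b_i = \mathrm{sign}(d_i)\,\min(\lceil |d_i|/w\rceil,\, n)\),
  clamped to \(\pm 4\);
- band fills \(f_{ik} = \mathrm{clamp}(|d_i| - (k-1)w,\ 0,\ w)\),
  \(k = 1,\dots,n\), with \(\sum_k f_{ik} = \min(|d_i|, nw)\).

Band \(k\) is drawn as an area of height \(f_{ik}\) from the facet floor —
blues above the origin, reds mirrored upward below it, darker means further
from the origin. The pipeline also handles the surrounding chores: reading
OTU/ASV tables (counts or relative abundance) with metadata and taxonomy,
prevalence/abundance filtering, and linear-interpolation regularization of
irregular sampling with axis breaks at gaps longer than `max_gap` days.
See `vignettes/horizon-methods.Rmd` for the full account.

## Worked example

A built-in 5-sample bundle whose numbers are hand-checkable:

```r
library(microhorizon)
we <- generate_worked_example()          # 3 taxa, 5 weekly samples, percent
ps <- horizon_panels(we$table, we$metadata, we$taxonomy,
                     selection = selection_spec("Subject_WE"),
                     labels_by_taxonomy = TRUE)
ps
#> <panel_set> 3 panel(s), 4 bands, days 0..28
#>   facets: Faecalibacterium, Bacteroides, Blautia

ps$panels[[2]]
#> <horizon_bands> OTU_001 / Subject_WE: origin 30, thickness 5, 4 bands, 5 points
ps$panels[[2]]$band_index
#> [1] -4 -2  0  2  4
ps$panels[[2]]$fills
#>      [,1] [,2] [,3] [,4]
#> [1,]    5    5    5    5
#> [2,]    5    5    0    0
#> [3,]    0    0    0    0
#> [4,]    5    5    0    0
#> [5,]    5    5    5    5

render_panels(ps, "worked_example.svg")   # faceted horizon figure
write_geometry(ps, "worked_example.tsv")  # machine-readable band geometry
```

`OTU_001` runs 10, 20, 30, 40, 50 percent, so its median origin is 30 and
the automatic thickness is 5 (extreme deviation 20 over 4 bands). The first
sample sits 20 below the origin (band −4, all four red bands full at 5),
the second 10 below (band −2: two bands full), the midpoint on the origin
(band 0, no fill), and the last saturates band +4. Panels are ordered by
descending mean abundance and labeled by the finest resolved taxonomic
rank.

## Command line

```sh
Rscript inst/cli/microhorizon.R simulate --out-dir fixtures/ --seed 42
Rscript inst/cli/microhorizon.R plot \
  --otu-table fixtures/otu_table.tsv --metadata fixtures/metadata.tsv \
  --taxonomy fixtures/taxonomy.tsv --subject Subject_01 \
  --thresh-abundance 0.75 --facet-labels-by-taxonomy \
  --regular-interval 25 --max-gap 75 \
  --output plot.svg --geometry-out geom.tsv
```

`plot` supports `--single-otu` (one taxon across subjects), `--otu-list`,
`--origin` / `--band-thickness` / `--n-bands` / `--fixed-scale`, and a YAML
`--config` whose keys are overridden by explicit flags.

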