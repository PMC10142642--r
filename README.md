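# sortgauge

Quantitative evaluation of continuous-flow microfluidic particle sorters
by flow cytometry.

Devices that split a suspension into an inner (target) and an outer
(waste) outlet — inertial spirals, zigzag channels and similar sorters
built to enrich large rare cells such as circulating tumour cells and
their clusters — are hard to validate with imaging or manual counting,
especially in complex, high-concentration mixtures. Flow cytometry of the
two collected fractions solves this when the analysis chain is right:
hierarchical gating identifies each particle/cell population,
pulse processing (scatter area vs height) splits each population into
singlets and doublets/clusters, and counting beads spiked in equal
quantity into equal-volume tubes normalize per-file counts for unequal
acquisition volumes.

`sortgauge` implements that chain end to end:

* **Synthetic data with ground truth** — a labeled event generator for
  the validation samples (five-size bead mixture; CD45-stained diluted
  blood spiked with 10/15/20 µm beads) and a probabilistic two-outlet
  sorter whose per-population inner-outlet probabilities are the known
  truth the pipeline must recover.
* **Event IO** — a minimal FCS 3.0 (float, list-mode) writer/reader and a
  TSV dialect, exact on round trip.
* **Gating** — rectangle/polygon gates with linear/log10 axes, shipped
  hierarchical strategies for the bead and blood samples, automatic
  area/height doublet discrimination.
* **Quantification** — counting-bead correction factors, Separation
  Efficiency and Purity per population × {singlet, doublet, total},
  collection-ratio QC and replicate aggregation.

For population *i* in cluster class *c*, with volume-corrected counts
*n*:

```
SE_ic = 100 · n_ic(target) / (n_ic(target) + n_ic(other))        [%]
P_i   = 100 · n_i(target)  / Σ_j n_j(target)                     [% of total]
```

with correction factors derived from the recorded counting beads per tube
(`A_ref / A_j` by default; the literal worked-example convention
`A_j / A_ref` is available as `correction_mode = "paper_literal"`).

## Worked example

Simulate the five-bead validation mixture through the 0.8 mL/min operating
point of a size-selective device, gate it and report performance:

```r
library(sortgauge)
res <- run_pipeline("bead_mix", "flow_0.8", volume_ml = 5e-3, seed = 1,
                    strategy = "beads", accudrop_per_tube = 20000)
res$report
#> <performance_report> target 'inner', correction 'volume_consistent', purity 'freq_total'
#> collection ratio 0.333 (QC pass)
#> Separation Efficiency (%):
#>  population   class      se
#>    bead_3um singlet   4.960
#>    bead_3um doublet   5.641
#>    bead_3um   total   4.994
#>    bead_7um singlet   7.432
#>    bead_7um doublet   4.682
#>    bead_7um   total   7.262
#>   bead_10um singlet  23.191
#>   bead_10um doublet  30.918
#>   bead_10um   total  23.684
#>   bead_15um singlet  98.365
#>   bead_15um doublet  90.062
#>   bead_15um   total  98.037
#>   bead_20um singlet  99.270
#>   bead_20um doublet 100.000
#>   bead_20um   total  99.310
#> Purity of target outlet:
#>  population purity
#>    bead_3um 60.012
#>    bead_7um  5.855
#>   bead_10um 11.241
#>   bead_15um 14.520
#>   bead_20um  8.372
```

Reading the output: the device captures essentially all 15 and 20 µm
beads in the central outlet (SE ≈ 98–99%) while rejecting the small sizes
(SE ≈ 5–7%) — the configured behaviour of this operating point — and the
doublet rows quantify cluster behaviour separately (15 µm doublets are
captured less efficiently than singlets). The collection-ratio QC
confirms the expected one-third central volume split. Purity shows the
composition of the inner outlet; the abundant 3 µm beads dominate it even
at low SE, which is exactly why an SE/P pair is needed to describe a
sorter.

File-based workflows mirror this with `run_simulate()` (writes per-outlet
FCS/TSV plus ground-truth sidecars and a manifest) and `run_evaluate()`
(reads, gates, writes `report.tsv`/`report.json`). A thin command-line
front-end lives at `inst/cli/sortgauge.R`
(`simulate` / `evaluate` / `run-all` / `validate-strategy`). Shipped YAML
fixtures for populations, scenarios and gating strategies are under
`inst/extdata/`.

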