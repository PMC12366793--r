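# paoscope

Simulation and analysis toolkit for warming experiments on soil
phosphorus-cycling microbial communities. `paoscope` generates synthetic
16S/function/single-cell-Raman data with planted treatment effects that mimic
a warming-by-clipping grassland field experiment, identifies putative
polyphosphate-accumulating organisms (PAOs), and quantifies how warming
reshapes their diversity, co-occurrence network architecture, and
stability-functioning linkages.

## Scientific problem

Climate warming changes which soil microbes cycle phosphorus and how they
interact. Field studies of this question share one analysis skeleton:

1. **Community identification.** Amplicon OTUs are filtered (relative
   abundance ≥ 0.01 %, identification e-score ≥ 99, genus-level taxonomy
   required) and PAOs are retained only when their predicted gene complement
   carries all four polyphosphate/PHA cycling markers (*ppk1*, *ppx*,
   *phaZ*, *phaC*).
2. **Diversity and effect sizes.** Per-sample Shannon diversity
   `H = −Σᵢ pᵢ ln pᵢ` feeds a linear mixed model
   `H ~ warming × clipping + (1 | block)` (REML, Satterthwaite df);
   functional redundancy for a function category is the summed contribution
   of its taxa divided by the number of contributing taxa.
3. **Single-cell phenotyping.** Raman spectra (400–2000 cm⁻¹) are
   baseline-corrected (asymmetric least squares), binned in 6 cm⁻¹
   intervals, vector-normalized, and clustered into operational phenotypic
   units (OPUs) with cosine correlation distance, average linkage, and a
   0.6 tree cutoff; PAO phenotypes are confirmed by polyP, PHA,
   peptidoglycan and amide band areas.
4. **Co-occurrence networks.** Pairwise correlations of PAO abundances are
   thresholded either at a fixed value or by random matrix theory (the
   smallest threshold whose adjacency spectrum shows Poisson
   nearest-neighbour spacings instead of Wigner level repulsion). The metric
   panel covers complexity (clustering coefficient C, transitivity T,
   density D, geodesic efficiency E_g, harmonic distance H_g = 1/E_g,
   degree centralization C_D, maximal degree/betweenness/stress, Louvain
   modularity M, NODF nestedness N with degree-preserving null relatives,
   Zi/Pi node roles) and stability (robustness R = mean fraction of
   surviving taxa that keep a partner after random 50 % taxon loss,
   vulnerability V = largest relative efficiency drop from deleting one
   node, positive/negative cohesion from null-corrected connectedness).
5. **Linkage to functioning.** Soil organic matter from loss-on-ignition
   (%OM = 0.7·%LOI − 0.23, floored at 0), gross primary production
   GPP = ER − NEE, correlation screens (|r| ≥ 0.6, p < 0.05) between metric
   panels, and a linear-vs-logarithmic contest for the
   functionality–biodiversity curve (a better log fit signals functional
   redundancy).

The package implements all five layers plus a seeded synthetic generator
whose defaults reproduce the study design: 24 samples (4 treatments × 6
replicates, blocked), 4800 single cells (24 samples × 2 droplets × 100
cells), 300 OTUs of which 150 are planted PAOs, and a planted warming
effect of +0.536 on PAO Shannon diversity.

## Worked example

```r
library(paoscope)

design <- gen_design()                 # 24 samples: 4 treatments x 6 reps
params <- synth_params(seed = 7)

gen <- gen_otu_table(design, params)   # planted PAO community
fn  <- gen_function_table(gen$table, params)
pao <- require_pao_genes(filter_otus(gen$table), fn)
pao
#> <pao_otu_table> 150 taxa x 24 samples

h <- apply(relative_abundance(pao), 2, shannon)[design$sample_id]
round(tapply(h, design$warming, mean), 3)
#>     0     1
#> 3.281 3.822

fit_lmm(h, design)
#>          term    beta     se        p
#> 1     warming  0.5200 0.0257 2.66e-12
#> 2    clipping -0.0160 0.0257 5.44e-01
#> 3 interaction  0.0413 0.0363 2.73e-01
```

Warming raises PAO Shannon diversity by 0.52 ± 0.03 (planted: 0.536) while
clipping and the interaction stay at noise level. The warming co-occurrence
network is larger, more positive, more robust and less vulnerable than the
ambient one:

```r
ids_w <- design$sample_id[design$warming == 1]
corr  <- correlation_matrix(pao$counts[, ids_w])
net   <- build_network(corr, s_star = 0.78)
net
#> <co_network> 148 nodes, 1754 edges (s* = 0.78)

cm <- complexity_metrics(net, seed = substream_seed(7, "cm_warming"))
round(c(L_pos = cm$L_pos, C = cm$C, E_g = cm$E_g), 3)
#> L_pos     C   E_g
#> 0.900 0.648 0.471

round(c(R = robustness(net, seed = substream_seed(7, "rob_warming")),
        V = vulnerability(net)), 3)
#>     R     V
#> 0.991 0.008
```

(The ambient network at the same seed has 228 edges, positive-edge ratio
0.81, robustness 0.83 and vulnerability 0.26.)

The full pipeline — synthesis, filtering, diversity, OPU clustering,
networks, linkage — runs end to end from one config and writes a manifest
with md5 hashes (identical configs reproduce identical hashes):

```r
man <- run_pipeline(default_config(seed = 1))
```

## Package layout

- `R/synth.R` — seeded generators: design, OTU/function tables, Raman
  spectra, environment, coupling panels.
- `R/otu-table.R`, `R/filter.R` — OTU container, filtering rules, PAO gene
  requirement, FACS enrichment, replicate pooling.
- `R/diversity.R` — Shannon, functional redundancy, mixed-model effect
  sizes, renormalization, curve-shape comparison.
- `R/spectra.R` — ALS baseline, binning, biomarker band areas, PAO
  confirmation, OPU clustering.
- `R/network.R` — correlation matrices, RMT thresholding, NNSD test,
  complexity/stability metric panel, cohesion, Zi/Pi.
- `R/linkage.R` — %OM and GPP conversions, correlation screens.
- `R/pipeline.R` — configurable end-to-end pipeline with manifest.
- `vignettes/` — methods vignette (source only).
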