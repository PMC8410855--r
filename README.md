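# modflex

Modular pharmacology of multi-target drugs from bulk co-expression
networks.

Multi-target drugs — combination products, biologics with pleiotropic
action, multi-component botanical injections — rarely act through one gene.
A more faithful unit of analysis is the **co-expression module**: a group of
genes whose expression moves together across patients. `modflex` implements
a module-level analysis of two-arm, two-timepoint transcriptomic trials
that asks three questions:

1. **Which modules does the drug rewire?** Modules are detected WGCNA-style
   (soft-thresholded correlation adjacency `a_ij = |cor(x_i, x_j)|^β`,
   topological overlap clustering, eigengene summaries). Each module is then
   scored in a second network with a permutation composite
   `Z_summary = (Z_density + Z_connectivity) / 2`, where `Z_density`
   standardizes the module's mean test-network adjacency and
   `Z_connectivity` the cross-network agreement of intramodular
   connectivity and of edge weights, against random gene sets of the same
   size. A module with `Z_summary < 0` is a **differentially expressed
   module (DEM)** — a drug-targeted module.
2. **Which module carries the clinical effect?** Treated subjects are
   stratified by response `ΔAF` (change from baseline in the Seattle Angina
   Questionnaire angina-frequency score: best ≥ 40, mild 20–40, none < 20).
   Module eigengene changes are correlated with `ΔAF` in the best stratum;
   the significant module (`|r| ≥ 0.3`, `p < 0.05`) with the highest `|r|`
   is the **most effective therapeutic module (METM)**.
3. **How flexible is that module across responders?** The METM's gene set is
   re-instantiated in per-response-bin networks; each instantiation's
   topology (density, clustering coefficient, characteristic path length,
   normalized mean degree) is compared to the best-responder reference by a
   Euclidean distance **D**, and `D` and the edge count are regressed on the
   bin's mean `ΔAF`. A negative `D` slope with a positive edge slope says
   the module's wiring converges to the reference as the effect grows.

The package also builds the DEM-level network (nodes = modules, edges =
connectivity scores) and reports its density, characteristic path length,
clustering coefficient and small-world coefficient, and calls
differentially expressed genes (`p < 0.05` and ≥ 1.5-fold change) for
comparison with the module-level picture.

Because patient-level trial data are not redistributable, `modflex` ships a
first-class synthetic-study generator: planted one-factor modules with a
chosen within-module correlation, treatment-induced dissolution of selected
modules at follow-up, true differentially expressed genes, and a `ΔAF`
phenotype coupled to the causal module's eigengene change. Every stage of
the pipeline is tested against this generator's ground truth.

## Worked example

```r
library(modflex)

report <- run_pipeline(pipeline_config(seed = 1), out_dir = "modflex_out")
print(report)
```

```
<modflex_report> 2000 genes, 124 samples
  modules: 5  |  DEMs: 2  |  DEGs: 104
  module graph: 5 nodes, 0 edges, density 0.000
  METM: M1 (r = 0.796, best-stratum n = 14)
  flexibility: slope(D) = -0.0055 (r2 = 0.719), slope(edges) = 22.01 (r2 = 0.718)
```

Reading the output: the default synthetic study plants five modules and
dissolves two of them in the treated arm at follow-up; both dissolved
modules — and only those — are called DEMs (`Z_summary < 0` against the
baseline network). 104 genes pass the DEG rule (90 are planted). Among the
14 treated subjects with the best effect (`ΔAF ≥ 40`), the eigengene change
of module M1 — the planted causal module — correlates with `ΔAF` at
r = 0.796, so M1 is selected as the METM. Across response bins, the METM's
topological distance to the best-responder instantiation falls (negative
`D` slope) while its edge count rises, i.e. the module re-coheres in
responders. The module graph is empty here because planted modules are
mutually independent by construction — their eigengene connectivity scores
sit below the 0.3 edge threshold.

Lower-level entry points mirror the stages: `simulate_study()`,
`call_degs()`, `build_network()`, `detect_modules()`,
`module_preservation()`, `build_module_graph()` / `topology_features()`,
`stratify()` / `module_trait_correlation()` / `select_metm()`,
`flexibility_profiles()` / `flexibility_regression()`. Results are tibbles
(with `tidy()` / `glance()` methods for fitted objects) and each result
type has an `autoplot()` method. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

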