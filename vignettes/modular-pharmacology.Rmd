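---
title: "Module-level pharmacology: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-level pharmacology: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modflex)
```

`modflex` analyses two-arm, two-timepoint expression studies of multi-target
drugs at the level of co-expression modules: which modules the treatment
rewires, which rewired module carries the clinical response, and how that
module's internal wiring varies across response strata. This vignette is the
package's own account of the models behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## The co-expression model

All network stages start from a genes-by-samples matrix of log-scale
expression. The weighted network is the classical soft-threshold
construction: unsigned adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$
(signed variant $((1+r)/2)^\beta$ behind a flag), topological overlap

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj},\;
  k_i = \sum_{u \neq i} a_{iu},$$

and average-linkage clustering of $1-\mathrm{TOM}$. Pearson correlation is
used throughout (a biweight variant is a possible extension, not
implemented). The soft power defaults to 6, the common unsigned-network
choice; `power = "auto"` scans candidates and takes the smallest power whose
connectivity distribution fits a scale-free form with $R^2 \ge 0.85$ and a
negative slope, falling back to the best negative-slope fit with a warning.
Note that strongly coherent low-rank data (for example a few large
one-factor modules and little else) is *not* scale-free; on such data the
automatic scan lands in the fallback branch, typically at a small power.

**Module detection** cuts the dendrogram statically at `cut_height`
(default 0.99 on the $1-\mathrm{TOM}$ scale), discards clusters below
`min_module_size` (default 30) to an `"unassigned"` pool, and then
iteratively merges modules whose eigengenes correlate at
$\ge 1 -$ `merge_height` (default correlation 0.75). A static cut was chosen
over the dynamic hybrid tree cut: it is deterministic, has two transparent
parameters, and recovers planted modules reliably at the scales this package
targets. Its known cost is precision, not recall: genes that correlate with
a module's factor by chance attach to that module, inflating module size
somewhat while leaving the planted cores intact. The **module eigengene** is
the first principal component of the per-gene standardized module
submatrix, scaled to unit variance and sign-anchored to correlate
non-negatively with the module's mean standardized expression — this makes
the eigengene invariant to gene order and reproducible across runs.

## Differentially expressed modules (Z_summary)

A module detected in a reference network is scored in a test network with a
permutation composite. Three observed statistics are computed on the
module's gene set: mean within-module test adjacency (density branch), the
gene-wise correlation of intramodular connectivity between reference and
test, and the pairwise correlation of within-module adjacency entries
between the two networks (connectivity branch). Each is standardized
against `n_permutations` (default 100, minimum 50) random gene sets of the
same size drawn from the shared gene universe — sets may overlap the module,
which matters: the null must carry the universe's real structure, otherwise
a dissolved module is indistinguishable from noise. Then

$$Z_{\mathrm{summary}} = \tfrac{1}{2}\left(Z_{\mathrm{density}} +
  \mathrm{median}\{Z_{\mathrm{cor\,kIM}}, Z_{\mathrm{cor\,adj}}\}\right),$$

and a module with $Z_{\mathrm{summary}} < 0$ (strictly) is a differentially
expressed module (DEM). This is a deliberately reduced composite — two
branches, three statistics — of the full preservation-statistic panel;
results are qualitatively, not numerically, comparable with the
seven-statistic original. Two behaviours are worth knowing. First, for
strongly preserved modules $Z_{\mathrm{density}}$ is huge (the null sd of
mean adjacency is tiny), so magnitudes far above zero are not
interpretable — only the sign is. Second, the connectivity branch of a
*homogeneous* one-factor module hovers near or below its null even when the
module is intact, because within such a module the edge-weight variation is
pure sampling noise while random sets inherit genuine cross-network
structure; the density branch is what cleanly separates intact from
dissolved modules, and the DEM call (the sign of the mean) follows it.

## The module-level network

DEMs become nodes of a module graph whose edge weights are **connectivity
scores**: by default the absolute correlation of module eigengenes (bounded,
symmetric, cheap), with mean inter-module adjacency as an alternative. The
formula behind the original connectivity score is not fully specified in
the method literature this package follows, so the default is documented as
a divergence-risk point. Edges require `cs >= 0.3`, mirroring the $|r| \ge
0.3$ significance rule used for module–trait correlation; the threshold is
a config key because no principled value exists. Graph topology is reported
as density, characteristic path length (mean shortest path over reachable
unordered pairs, unreachable pairs excluded with a message), mean local
clustering (degree-<2 nodes contribute 0), and a small-world coefficient
$\sigma = (C/C_{\mathrm{rand}})/(L/L_{\mathrm{rand}})$ against 20 seeded
Erdős–Rényi graphs with matched node and edge counts. For any graph of
diameter $\le 2$, CPL $= 2 - \mathrm{density}$ exactly — a useful analytic
cross-check on near-complete module networks.

## Responder stratification and the METM

Treated subjects are stratified by `delta_af`, the change from baseline in
the Seattle Angina Questionnaire angina-frequency score (0–100 scale,
higher is better): best effect $\ge 40$, mild $[20, 40)$, none $< 20$;
intervals are half-open and lower-inclusive, and custom bins must not
overlap. Module–response correlation uses the **per-subject eigengene
change** (follow-up minus baseline, modules defined at baseline): the
phenotype is itself a change score, and coupling a change to a level would
conflate baseline variation with response. The METM is the significant
module ($|r| \ge 0.3$, $p < 0.05$, two-sided $t$ on $n-2$ df) with the
largest $|r|$ in the best stratum, ties broken by smaller $p$ then label.
The pipeline gates METM candidates on the global DEM list by default
(`metm_scope = "dems"`); `"all"` lifts the gate, which is the right setting
when the causal module need not be drug-dissolved.

## Modular flexibility

The METM's gene set is re-instantiated in per-stratum networks: treated
follow-up subjects are split into `n_response_bins` (default 6) equal-width
`delta_af` bins (bins under `min_bin_size = 4` subjects are dropped), a
within-bin adjacency is built on the METM genes, and a binary graph keeps
pairs with adjacency $\ge \tau_g$. The default $\tau_g = 0.3^\beta$, i.e.
$|r| \ge 0.3$ again. An anchoring rule that sets $\tau_g$ to the reference
bin's minimum within-module adjacency (making the reference instantiation a
complete graph, density 1) is available as `tau_g = "anchor"`, but it is not
the default because it degenerates at realistic bin sizes: with 5–11
samples per bin the minimum sampled $|r|^\beta$ over thousands of pairs is
effectively 0, and every stratum's instantiation becomes complete.

Each instantiation is summarized by a bounded feature vector — density,
mean local clustering, $\min(\mathrm{CPL}/2, 1)$ (set to 1 when the graph
has no path), and mean degree normalized by $n-1$ — and compared to the
highest-response bin's instantiation by the Euclidean distance $D$. For
simple graphs the normalized mean degree equals the density, so the recipe
effectively double-weights density; the recipe is kept as a package-level
definition (it is explicit and config-extensible) rather than a claim about
the original feature set, which the source literature does not reproduce.
$D$ and the instantiated edge count are each regressed on the bin mean
`delta_af` by ordinary least squares; the method's qualitative signature of
response-graded rewiring is slope$(D) < 0$ together with
slope$(\mathrm{edges}) > 0$.

## The synthetic-study generator

`simulate_study()` emulates the trial design the analysis assumes: 41
treated and 21 control subjects, two timepoints, 2000 genes of which five
planted modules (100/80/60/50/40 genes) follow a one-factor Gaussian model
— gene $i$ of module $k$ is $\sqrt{\rho_k} f_k + \sqrt{1-\rho_k}
\varepsilon_i$ with standard-normal factor and noise, so the expected
within-module correlation is exactly $\rho_k$ (default 0.7). Background
genes are independent noise. At follow-up in the treated arm, dissolved
modules (default modules 1 and 5) have $\rho$ multiplied by
`dissolution_factor` (default 0.1), and 90 background genes gain a
`deg_log2fc = 0.75` mean shift (true DEGs; 90 matches the DEG count scale
reported for this kind of trial at day 30). Values are on a log2-like
Gaussian scale, so a mean shift $d$ means a $2^d$ fold change.

The phenotype for treated subject $s$ is
$\Delta AF_s = 18 + 40\,\beta_{\mathrm{ph}} (f_{c,1} - f_{c,0})_s +
\varepsilon_s$, coupling the response to the causal module's factor change;
control subjects get placebo noise centred at 10. Defaults
$\beta_{\mathrm{ph}} = 0.5$ and noise sd 10 give a response sd near 30
points and a best-effect stratum of roughly 8–14 subjects — consistent with
what a best-stratum correlation of $r \approx 0.9$ at $p \approx 0.005$
implies about that stratum's size. The treated shift (+18) and the placebo
centre (+10) are the package's own choices of a realistic treatment and
placebo response on this instrument. After noise, `delta_af` is clipped to
`daf_range`, default $(-25, 100)$: the instrument is a 0–100 scale, so
change scores are bounded by $\pm 100$ in principle; a tighter ceiling
(e.g. 60) was rejected because under strong coupling it pins most
best-stratum subjects to the boundary, destroying the within-stratum
correlation the responder analysis measures — a saturation no real cohort
with high observed best-stratum correlations could have exhibited.

For flexibility analysis the base model is insufficient: dissolving a
module at the arm level makes every response bin statistically identical.
`graded_dissolution = TRUE` therefore draws a latent response $u_s \sim
U(0,1)$ per treated subject, scales the causal module's follow-up coherence
as $\rho_s = \rho\,(\text{factor} + (1-\text{factor})\,u_s)$, and derives
`delta_af` from $u_s$ — non-responders carry a dissolved module,
best responders an intact one.

What the generator does *not* emulate: count-level noise (sequencing data
enter as an already-normalized log matrix), inter-module correlation
(planted factors are independent, so module-graph edges are near zero on
synthetic data — the module-network topology code is instead validated on
constructed graphs with known density, path length and clustering),
mean–variance relationships, batch effects, or missing data beyond the
reader's drop-any-missing rule. Passing tests on this generator therefore
demonstrate the statistical machinery — module recovery, DEM sign
behaviour, METM selection, flexibility direction — not robustness to
real-data artefacts.

## Differential expression

`call_degs()` applies the field's simple screen: two-sided Welch $t$ per
gene on log2 values (paired $t$ within subjects for the within-arm
contrast), fold change $2^{|\Delta|}$, and the rule $p < 0.05$ with at
least 1.5-fold change, boundary inclusive. P values are unadjusted by
default because the module analysis, not the gene list, is the inferential
unit; `adjust_method = "BH"` is available. At the generator's defaults (41
vs 21, unit noise, 0.75 log2 shift) this rule recovers about 70–75% of
planted DEGs with a false-positive rate near 3% among null genes — the
fold-change filter, not the $p$ threshold, is what controls the false
positives.

## Numerical choices and degenerate inputs

Zero-variance genes are errors in network construction (filter first), are
excluded with a warning from eigengenes and correlations, and make a trait
correlation `NA`. A permutation null with zero variance (e.g. a constant
adjacency) is an explicit error suggesting more permutations or flagging a
degenerate network, not a silent `Inf`. Modules under 4 genes are skipped in
preservation with a warning. Ties in variance filtering break by gene ID;
ties in METM selection break by $p$ then label; all permutation and
random-graph draws are seeded, and a fixed seed plus configuration
reproduces every output byte for byte. Problem sizes in the test suite are
chosen so the full suite and the reproduction script each run in minutes on
a single core: unit tests use 300–400-gene studies; the end-to-end checks
use the full 2000-gene design with 10 seeds per property.

## Known limitations

The static tree cut trades precision for determinism (see above); at small
gene counts detected modules absorb hub-correlated noise genes. The reduced
Z_summary composite is sign-faithful but not magnitude-comparable to the
full preservation panel. The connectivity-score and $D$-value feature
recipes are package-level definitions where the upstream literature is
underspecified. The module count of any given dataset (e.g. "38 modules")
is parameter- and data-dependent and is not a reproduction target; the
analytically fixed quantities (complete-graph edge counts, density and path
length of a given node/edge configuration) are, and are covered by tests
and the reproduction script.
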