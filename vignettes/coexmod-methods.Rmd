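---
title: "Methods: coexpression modules, preservation and module-level differential expression"
author: "coexmod authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression modules, preservation and modDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`coexmod` analyses normalized, log2-scale gene-by-sample expression from
multi-tissue bulk experiments — the motivating setting is effector T cells
sorted from many anatomical compartments (blood, spleen, lymph nodes, bone
marrow, liver, gut, dermis, epidermis) under different transplant
conditions, with about three replicates per tissue/condition cell. The
package assumes preprocessing (background correction, normalization,
probe summarization) has already happened; its own pipeline is

1. weighted coexpression network construction and module discovery,
2. module–trait association mapping and module classification,
3. cross-dataset module preservation (permutation Z statistics),
4. module-level differential expression (modDE),
5. signature enrichment (hypergeometric overlap, preranked GSEA, ssGSEA),
6. classical MDS sample maps,

validated end to end on a synthetic multi-tissue generator with planted
modules.

Expression lives in an `ExpressionDataset` (a `SummarizedExperiment`
subclass; assay `"log2expr"`, traits in `colData`). Missing values are
resolved at load time (`drop_gene` by default), so all downstream
correlation machinery can assume complete matrices — masked-correlation
variants would complicate every step for little gain at these sample
sizes. Duplicate gene ids collapse to the highest-variance row, the usual
array-probe convention.

# Network construction and module detection

Pairwise Pearson correlation on log2 values is soft-thresholded into an
adjacency. The default mode is `signed_hybrid`
(\(a_{ij} = r_{ij}^\beta\) for \(r_{ij} > 0\), else 0): in multi-tissue
data, programs that are *oppositely* regulated across compartments are
strongly anti-correlated, and an unsigned network would fuse them into
single modules. `unsigned` (\(|r|^\beta\)) is available for fidelity to
older conventions.

The soft power \(\beta\) defaults to 6 and can be chosen by
`pickSoftPower()`, which scans candidates for approximate scale-free
topology (R² of the log–log regression of the binned connectivity
distribution, threshold 0.8, smallest qualifying power wins). Two guards
matter in practice and are part of the qualification rule:

* the regression slope must be negative (a power law with *increasing*
  frequency at high connectivity is not scale-free behavior);
* the mean connectivity must stay above `minMeanK` (default 0.01). A
  near-empty network — everything raised to a high power — has a
  connectivity distribution that fits a line in log–log space spuriously
  well, so without this floor pure noise would "qualify" at high powers.

When no candidate qualifies the scan falls back to power 6 with a warning,
which is the canonical default at these sample sizes.

The topological overlap matrix

\[
TOM_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_u a_{iu}
\]

smooths the adjacency by shared-neighbor structure; `1 - TOM` is the
clustering dissimilarity and TOM entries weight exported hub subnetworks.

## Adaptive tree cut

`detectModules()` clusters `1 - TOM` by average-linkage hierarchical
clustering and decomposes the dendrogram as follows:

1. **Static cut** at `cutHeight` (default 0.995): branches joining above
   it are always followed downward. With soft-thresholded TOM
   dissimilarities, background genes merge very close to 1, so this step
   mostly strips noise.
2. **Recursive branch splitting** below the static cut: a branch is split
   only when both children could stand as modules (`minSize`, default 30)
   *and* their eigengene dissimilarity exceeds `mergeThreshold` (default
   0.25) — i.e. only splits that would survive the later merging step are
   taken. Undersized siblings are shed as strays. This self-consistent
   rule replaces a fixed branch-height heuristic: a fixed static cut alone
   cannot separate correlated modules, because between-module join heights
   concentrate near 1 regardless of module structure.
3. **Quality gate:** a candidate cluster becomes a module only if its mean
   member kME reaches `0.5 - 0.1 * deepSplit` (so `deepSplit`, 0–4,
   default 2, controls detection sensitivity: larger values admit looser
   clusters). On pure-noise data the first principal component of a large
   random cluster correlates with its members at roughly
   \(\sqrt{\lambda_1 / p}\approx 0.15\) for 60 samples, far below the
   default gate of 0.3, which is why noise ends up unassigned.
4. **PAM-like membership pass:** every gene joins its best-kME module if
   that kME clears `kmeCut` (default 0.4), else module 0. At 60 samples
   the sampling sd of a null kME is ~0.13, so 0.4 keeps the expected
   number of false members per module in the low single digits while
   retaining genes with true loadings ≥ 0.5. Modules dropping below
   `minSize` dissolve.
5. **Eigengene merging:** modules whose eigengenes correlate above
   `1 - mergeThreshold` merge iteratively (closest pair first).

Module ids are relabeled 1..k by descending size ("M1" the largest),
mirroring the usual naming convention; 0 is background. The procedure is
fully deterministic — `seed` is only recorded for provenance — and
invariant to sample reordering.

## Eigengenes and kME

A module eigengene is the first principal component of the standardized
member expression, scaled to mean 0 and unit variance and oriented so that
the mean member correlation (kME) is positive. An exactly balanced module
(mean correlation 0, e.g. a two-gene module of x and −x) is oriented by
the loading sign of the lexicographically first member — an arbitrary but
reproducible tie-break. kME p-values use the t transform
\(t = r\sqrt{(n-2)/(1-r^2)}\); q-values are BH within module across genes,
matching per-module FDR coloring of hub displays. `driverGenes()` ranks
members by own-module kME (ties lexicographic).

# Module–trait mapping

Traits enter as 0/1 indicators (one column per tissue, condition and
configured tissue group), and `moduleTraitMatrix()` reports the Pearson
(point-biserial) correlation of each eigengene with each indicator plus
its two-sided p. Tissues are never encoded ordinally. Constant indicator
columns yield r = 0, p = 1 with a warning rather than an error, since they
arise naturally in subset analyses. `rankModulesByTrait()` applies the
conventional \(-\log_{10}(p) > 2\) cutoff and splits by sign;
`classifyModules()` labels modules `tissue_specific`, `group_selective`,
`bridging` (significant positive correlation in both of two tissue
compartments, e.g. lymphoid and target organs) or `unassociated` using
positive correlations only — negative associations are reported but do not
drive labels.

`classicalMds()` is Torgerson MDS (double-centered squared distances, top
eigenvectors scaled by \(\sqrt{\lambda}\)) on Euclidean distances over the
top 500 most variable genes by default; correlation distance is available.
Negative eigenvalues are clamped to zero with a warning.

# Module preservation

`modulePreservation()` asks whether a module found in a reference dataset
keeps its topology in an independent test dataset, with two statistics per
module:

* **density** — mean off-diagonal adjacency among the module's genes in
  the *test* data;
* **connectivity** — Pearson correlation between the intramodular
  connectivity vectors (kIM, row sums of the intramodular adjacency)
  computed in reference vs test over the shared module genes.

The null re-evaluates both on `nPerm` (default 200) random gene sets of
matched size drawn from the genes shared by both datasets, *excluding the
module under test* so module signal cannot leak into its own null;
\(Z = (obs - \mu_{null})/\sigma_{null}\) and
\(Z_{summary} = (Z_{density} + Z_{connectivity})/2\). The usual
thresholds label modules: below 2 not preserved, 2–10 weak to moderate,
≥ 10 strong. This is a deliberate simplification of the reference
composite (medians over larger statistic families) that keeps the
threshold semantics.

Two practical notes. First, preservation of a dataset against itself makes
the connectivity statistic identically 1 for every null draw; the sd-zero
guard flags the component degenerate and Z_summary falls back to the mean
of the remaining components (here: density, which is very large). Second,
when planted loadings span a narrow range, the kIM gradient within a
module is dominated by sampling noise of \(r^\beta\), and the null sets —
which may contain genes of *other*, possibly preserved modules — can show
higher ref–test kIM correlation than a single module does internally; the
density component then carries the preservation signal. Both behaviors are
exercised in the tests.

# Module-level differential expression (modDE)

Per gene, `geneDE()` runs a Welch two-sample t test between two arms of a
design contrast (robust and assumption-light at ~3 samples/arm; moderated
variants would be a natural extension) and converts it to a signed z,
\(z = \Phi^{-1}(1 - p/2)\,\mathrm{sign}(effect)\).

For module m with members g, orientation \(s_g = \mathrm{sign}(kME_{g,m})\)
and weight \(w_g = |kME_{g,m}|\) give the consistency statistic

\[
T_m = \frac{\sum_g w_g s_g z_g}{\sqrt{\sum_g w_g^2}},
\]

a kME-signed, kME-weighted Stouffer combination: genes that move *with*
their correlation structure reinforce T, genes that move against it cancel.
Significance comes from a sample-label permutation null (condition labels
permuted within tissue strata whenever several tissues are present, so
condition effects are not confounded with tissue), with the add-one
two-sided empirical p. The permutation respects inter-gene correlation —
an analytic Stouffer null would not: the member z's share the module
factor, inflating \(\mathrm{var}(T)\) by roughly
\(1 + (m-1)\bar\rho\), and ignoring that would be grossly anticonservative.
Designs admitting fewer than 20 distinct relabelings are rejected.

Alongside, the **excess** component counts member genes with p below
`alpha0` (default 0.05) against the hypergeometric expectation over all
genes. The headline module p is the consistency component; the excess p is
reported, not multiplied in, because the two are dependent and no
principled combination rule is assumed. BH q is computed across modules
per component.

The two components separate exactly the cases they should: a coherent
perturbation (a latent-factor shift) drives both; a magnitude-matched
perturbation with gene-wise random signs drives the excess component while
the consistency component stays null — direction consistency, not effect
size, is what T detects.

# Enrichment

* `hypergeomOverlap()`: upper-tail \(P[X \ge k]\) overlap test within an
  explicit universe; symmetric in the two sets.
* `gseaPreranked()`: weighted KS running sum (hit steps
  \(\propto |score|^{weight}\), miss steps uniform; ES = extreme
  deviation; the degenerate all-hit walk is defined as ES = 1). The null
  permutes gene labels — the intended use ranks one list against module
  sets, so there are no phenotype replicates to permute. NES divides by
  the mean |null ES| of the same sign; FDR q uses the sign-stratified
  pooled-null convention (plain BH available).
* `ssgsea()`: per-sample rank-weighted ECDF difference with weight
  \((N - i + 1)^\alpha\) at descending-rank position i, \(\alpha = 0.25\);
  optional normalization by the global score range. Rankings break ties
  lexicographically by gene id so results are platform-independent.
* `moduleConservationTest()` maps module sets through an explicit
  orthology table (upper-case fallback for mouse→human symbol style) and
  runs preranked GSEA per module, skipping modules that map to fewer than
  5 list genes.

# The synthetic generator

`generateSynthetic()` draws, per module m, one latent factor per sample
\(f_m(s) = effect \cdot 1[trait(s)] + \delta \cdot 1[perturbed(s)] +
N(0,1)\) and member genes \(x_g(s) = \lambda_g f_m(s) + N(0, \sigma^2)\),
with \(\lambda_g \sim U[\lambda_{lo}, \lambda_{hi}]\); background genes are
pure noise. Defaults: \(\sigma = 1\) (so a loading of 0.8 gives
within-module correlations near 0.4 — typical of tight bulk coexpression
modules), trait effect 2.0 on the latent scale, 10 tissues × 2–3
conditions × 3 replicates, mirroring a multi-tissue sorted-cell study.
The incoherent perturbation adds \(\delta \lambda_g r_g\),
\(r_g \in \{\pm1\}\) i.i.d., directly to member genes in perturbed
samples: the per-gene effect magnitude matches the coherent mode exactly
while bypassing the factor, which isolates direction consistency — the
property modDE claims to detect. A second dataset regenerates factors with
identical loadings for preserved modules and re-seats non-preserved
modules on random background genes.

The `modde_coherent`/`modde_incoherent` presets perturb the
epidermis-linked module in the depleted arm of an allo vs allo+depletion
contrast across all tissues with \(\delta = 1.5\) — on the latent scale a
strong depletion phenotype (~1.2 log2 units per typical gene). The
module-level information in T is equivalent to a two-sample test on the
latent factor itself, so at 30 vs 30 samples this effect size yields
factor-level \(t \approx 5.8\) and permutation p comfortably at the
\(10^{-4}\) floor of \(10^4\) permutations; a shift confined to a single
tissue (3 vs 3) could never reach such significance under any
label-permutation null (only \(\binom{6}{3} = 20\) distinct relabelings
exist within one tissue), which is why the presets spread the perturbed
condition across tissues.

What the generator does **not** emulate: heteroskedastic, intensity-
dependent noise; correlated background (shared technical factors);
nested or overlapping module structure; count-based mean–variance
relationships. Passing tests therefore demonstrate correctness of the
machinery under a clean single-factor model, not robustness to every
artifact of real microarray/RNA-seq data.

# Problem sizes and numerical choices

The validation suite runs at the standard study scale: module recovery on
3000 genes × 60 samples over 20 seeds (mean adjusted Rand index ≥ 0.9),
trait-map power/calibration over 50 seeds, preservation at 200
permutations over 20 seeds, modDE calibration over 1000 null module tests
and its discrimination at \(10^4\) permutations, all exact-oracle
comparisons at 1e-12. Correlation p-values are clamped into
\((10^{-308}, 1]\) so downstream \(-\log_{10}\) transforms stay finite;
TOM is symmetrized against floating-point asymmetry; eigengene signs are
tie-broken deterministically; permutation p-values carry the add-one
correction and are therefore bounded below by \(1/(n_{perm}+1)\).

# Known limitations

* The dynamic tree cut is a simplified, self-consistent variant, not a
  reimplementation of the reference hybrid algorithm; very unbalanced or
  nested module structures may be cut differently.
* Z_summary averages two statistics; the reference composite uses medians
  over larger families and can rank borderline modules differently.
* Welch-t gene statistics at n = 3/arm have modest power; the modDE
  consistency component compensates at module level, but single-gene
  calls should not be over-read.
* Biweight midcorrelation and phenotype-permutation GSEA are not
  implemented.
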