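---
title: "Models and methods behind omicsconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omicsconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`omicsconcord` analyses a four-group gonad study design — first-generation
captive-bred (F1) and wild-type (wt) fish of both sexes — across three omic
layers, and asks how consistently RNA-level changes propagate to the protein
level. This vignette documents the statistical models, the parameters that
matter, the synthetic study generator, and the numerical and design choices
that were genuinely open.

## RNA differential expression

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $s_j \mu_{g,\mathrm{group}(j)}$ and dispersion $\alpha_g$.

**Size factors.** Median-of-ratios: $s_j$ is the median over reference genes
(positive in all samples) of $K_{gj} / (\prod_j K_{gj})^{1/n}$, then the
vector is rescaled so its geometric mean is 1. There is no pseudo-reference
fallback: if no gene is positive everywhere the input is too sparse for this
normalisation and the function says so.

**Dispersion.** A per-gene method-of-moments estimate on normalised counts,
with variances pooled within groups,
$\hat\alpha_g = \max(0, (s^2_g - \bar\mu_g)/\bar\mu_g^2)$, a robust
parametric trend $\alpha_{tr}(\mu) = a_0 + a_1/\mu$ fitted by iterated
outlier trimming, and a final value
$\exp\{\tfrac12 \log\hat\alpha_g + \tfrac12 \log \alpha_{tr}(\bar\mu_g)\}$,
floored at $10^{-8}$. Genes with zero moment estimate (e.g. constant counts)
fall back to the trend and are flagged. The equal-weight log-space blend is
deliberately simple and fixed; its cost is that dispersion-estimation noise
leaks into the Wald statistic, making the plug-in test mildly
anti-conservative (null rejection at the 5% level is typically 5–7% at
five-versus-five replicates). The unit tests therefore check calibration of
the Wald machinery at the generating dispersion, and the calibration suite
checks the full plug-in behaviour.

**Test.** Per gene, an NB GLM with log link and design intercept + group is
fitted by IRLS **on size-factor-normalised counts**. With the saturated
two-group design the fixed point is the normalised group mean, so the
log2 fold change is a pure function of normalised counts — multiplying any
one sample's counts by a constant changes only its size factor and leaves
every fold change untouched (this exact invariance is the reason for
fitting on the normalised scale rather than using offsets on raw counts).
The Wald p-value uses the coefficient's asymptotic normal with the NB
information weights $w = \mu/(1+\alpha\mu)$; BH runs per contrast over the
tested genes (all-zero genes are excluded from the test and the BH family).
Genes empty in one group do not converge within 100 iterations and are
reported untested, which is the honest answer for an unpenalised NB MLE.
A DEG satisfies $|\log_2 FC| \ge 1$ and FDR $< 0.05$; the sign convention
is numerator-group-on-top throughout (positive means higher in the
first-named group of the contrast).

Numerical parity with full production NB pipelines is a non-goal: there is
no Cox–Reid adjustment, no fold-change shrinkage, no independent filtering
and no outlier refitting.

## Protein differential abundance

LFQ intensities are strictly positive where observed; an observed zero is
an input error, not a missing value, so dropout and zero can never be
silently conflated. Filtering applies contaminant removal, then the
two-unique-peptides rule, then missingness above 30% (strict: a protein
missing in exactly 30% of samples stays). The order only affects which
reason a doubly-failing protein is attributed to in the report; the
retained set is order-independent. The published filter is stated over all
samples; a per-group mode is available behind a flag because the phrase
"30% of biological replicates" admits both readings.

After log2 transformation and per-sample median-centring, each contrast is
an available-case two-group comparison: the log2 fold change is the
difference of group means over present values, and the pooled variance
$s^2_g$ has available-case degrees of freedom $d_g = n_1 + n_2 - 2$.
Missing values are never imputed: dropout is intensity-dependent (missing
not at random), and imputation under MNAR biases fold changes in exactly
the low-abundance range where proteomic effects live. Proteins with fewer
than two present values in either group are excluded from the contrast and
flagged.

The empirical-Bayes prior $(d_0, s_0^2)$ is estimated by moment matching on
$z_g = \log s^2_g$: with
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$, the excess variance of $e$ over
$\mathrm{E}[\psi'(d_g/2)]$ identifies $d_0$ through a Newton inversion of
the trigamma function (tolerance $10^{-8}$), capped at $10^6$ which is
numerically infinite shrinkage. The posterior variance
$\tilde s^2 = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ gives a moderated t on
$d_0 + d_g$ degrees of freedom. The published DEP rule is printed one-sided
($\log_2 FC \ge 0.5$) yet down-regulated proteins are reported alongside
it, so the rule is applied symmetrically: $|\log_2 FC| \ge 0.5$ and FDR
$< 0.05$.

## Gene–protein integration

Pairs are built per contrast from a protein-to-gene correspondence map:
one row per protein that was tested at the protein level and whose gene was
tested at the RNA level. Genes with several mapped proteins contribute one
row per protein — the pair universe is contrast-specific because
testability differs between contrasts, which is why pair counts vary across
comparisons; an optional collapsing mode keeps the highest-mean-intensity
representative per gene.

Each pair falls in exactly one of six classes. Concordance requires
significance at **both** layers with matching sign — the strictest reading
of the scatter-plot legend convention; directional agreement without dual
significance lands in the exclusive classes. Correlations (Pearson, and
Spearman as Pearson on mid-ranks) are computed over **all** mapped pairs,
not only significant ones, matching how per-contrast correlations are
conventionally reported next to the full pair count. Concordance
percentages are reported to one decimal, except two decimals below 0.1% so
a single concordant pair among over a thousand does not round to zero.

## Enrichment

The over-representation test is the upper-tail hypergeometric against a
universe of **tested** features (not the genome): using the detected,
tested universe avoids spurious enrichment driven by detection bias. The
ranked-list mode evaluates each term at nested prefixes
$L \in \{10, 20, \dots, \min(n, 1000)\}$ of the fold-change ordering, takes
the best prefix, and pays for the scan with a Bonferroni factor over the
number of prefixes before BH across terms. This correction is fully
specified and testable; parity with proprietary web-tool corrections is a
non-goal. Directional analyses run the descending and ascending orderings
separately, and cross-layer concordant terms are those significant in the
same direction at both layers.

## Differential methylation

CpGs are kept when every sample of both contrast groups has strictly more
than 8 reads and the pooled proportion is informative (not exactly 0 or 1 —
the published "variability" filter is not quantified, so this minimal
exclusion is used, with a hook for a minimum-range filter). Counts are then
pooled within groups into a 2×2 table and tested with a two-sided Fisher
exact test, BH-adjusted, significant at FDR $< 0.01$. Pooling discards
between-replicate variability; a replicate-aware model would be stricter,
and this limitation is deliberate — the pooled Fisher test is the simplest
fully-specified choice. Effects are reported both as the proportion
difference $\Delta$ and as a log2 ratio with proportions clamped to
$[1/(T+1), T/(T+1)]$, because which of the two scales a printed methylation
"fold change" refers to is ambiguous.

Feature annotation assigns exactly one label per CpG with precedence
promoter > exon > first intron > other intron > intergenic across all
overlapping transcripts. The promoter window is TSS−2000 to TSS+500 in
transcript orientation — a conventional default, exposed as an argument
since no single window is canonical. BED input (0-based half-open) is
converted to the package's 1-based inclusive coordinates on read; CpG
strand is ignored for assignment while transcript strand orients the
promoter and the first intron.

## Exploratory views

PCA treats samples as observations; features are centred but, by default,
not unit-scaled — on log-abundance data the per-feature variance is itself
biologically meaningful (scaling is a switch). Constant features are
dropped with a warning. The matched-universe restriction (genes with a
mapped protein) is applied by the pipeline before RNA PCA. Heatmap
orderings z-score features (zero-variance rows become zeros, flagged) and
cluster rows and columns agglomeratively on Euclidean distance with average
or complete linkage.

## The synthetic study generator

The generator is the package's test surface and encodes the emulated study
conditions once:

* ~30,000 genes, 2,000 of them mapped to quantified proteins; RNA
  replicates 5/5/5/4 and protein replicates 5/5/5/3 across
  F1F/F1M/wtF/wtM; methylation shares the RNA design.
* A sex effect on 10% of genes (mean $|\log_2 FC|$ = 2) versus origin
  effects on 1% per sex (mean 1): sex dominance is structural, with at
  least five-fold more planted sex-DE genes than origin-DE genes.
* Effects are assigned deterministically (the first
  $\lfloor \mathrm{frac} \times n \rfloor$ genes of a seeded shuffle), so
  planted counts are exact and testable; magnitudes are random-sign
  exponentials, guaranteeing some effects exceed the thresholds.
* Protein effects couple to RNA effects as
  $c \cdot \beta_{RNA} + \sqrt{1-c^2}\, e$ with $e$ an independent sparse
  vector of the same fraction and scale, so the true fold-change
  correlation per contrast equals the configured coupling. The four
  canonical contrasts span only three free effects (they satisfy one linear
  dependency), so the couplings attach to the three structural effects —
  sex via wtF vs wtM (default 0.10), origin-in-females via F1F vs wtF
  (0.09), origin-in-males via F1M vs wtM (0.19) — and the F1F-vs-F1M entry
  (0.25) is implied rather than imposed. Defaults sit in the weak
  correlation range (r ≈ 0.0–0.3) such integrations report.
* Protein dropout is logistic in the realised log2 intensity (MNAR),
  calibrated so most proteins stay at least 70% complete and the 30%
  filter removes a minority; ~10% of proteins get a single unique peptide
  and ~2% a contaminant flag so the filters are exercised.
* CpG baselines are Beta(0.4, 0.4) (bimodal, as CpG methylation is), with
  logit-scale planted shifts, negative-binomial coverage (mean 30), and a
  global positive female offset so female groups are more methylated
  overall. The default of 10,000 CpGs is a desk-scale emulation chosen so
  the full pipeline and its determinism check run comfortably on one CPU;
  the real CpG universe of an RRBS study is orders of magnitude larger and
  depends on deposited reads.
* One root seed; each stage derives its own stream by a fixed offset, so
  adding a stage never perturbs earlier draws and every output is a pure
  function of the configuration.

What passing tests on this generator do **not** show: the simulator has no
batch effects, no peptide-level structure, no outlier samples of the kind
real gonad data contain, and NB/log-normal noise that is cleaner than real
measurements — so recovery rates here are upper bounds, not forecasts, for
real data.

## Problem sizes and determinism

The test suite runs null calibrations at 2,000 features, coupling recovery
at 2,000 mapped proteins with couplings {0, 0.5, 0.9}, enumeration-oracle
checks of the hypergeometric and Fisher tails for universes up to 60, the
BH step-up against a brute-force oracle on 1,000 random vectors, and the
default end-to-end pipeline twice to confirm byte-identical manifests.
These sizes were chosen as the smallest at which the Monte-Carlo bands are
meaningful. `scripts/acceptance.R` reruns the default study from scratch at
full size (30,000 genes) and reports every headline quantity it computes.

## Known limitations

* The NB Wald test is asymptotic and mildly anti-conservative at five
  replicates; it is not a drop-in replacement for shrinkage-based
  production tools.
* The pooled Fisher methylation test ignores replicate-level variance.
* The ranked-enrichment correction (Bonferroni over prefixes × BH over
  terms) is conservative by construction.
* The gene–protein map is treated as authoritative; identifier resolution
  and accession normalisation are out of scope.
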