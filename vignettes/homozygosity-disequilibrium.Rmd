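---
title: "Scanning for homozygosity disequilibrium: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for homozygosity disequilibrium: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdscan)
```

## The problem

Runs of homozygosity (ROH) are stretches of consecutive homozygous genotypes
along a chromosome. When sizable runs occur more often than a random
arrangement of homozygotes and heterozygotes would produce, the genome shows
*homozygosity disequilibrium* (HD). HD arises from autozygosity (both
chromosome copies inherited from a common ancestor), natural selection and
chromosomal aberrations, and carries association signal for complex traits.
`hdscan` estimates where and how strongly each individual's genome is
homozygous, calls sizable HD regions, and tests them for association with
quantitative traits, binary traits and transcript abundance in
pedigree-structured samples.

Sequencing data complicate the classical ROH definition: most variant sites
are rare (minor allele frequency, MAF, below 0.05), and almost every
individual is homozygous for the common allele at a rare site. Such
homozygotes carry almost no information about autozygosity. Treating all
sites equally therefore biases homozygosity estimates upward wherever rare
variants cluster. The estimator below addresses this by weighting sites by
their information content.

## The double-weight local polynomial model

For one individual and one chromosome with sites at physical positions
$x_1 < \dots < x_m$, let $Y_i \in \{0, 1\}$ indicate that the genotype at
site $i$ is homozygous. The homozygosity intensity at a position $x$ is the
smooth function $\lambda(x) = \Pr(Y = 1 \mid x)$, estimated by local
polynomial regression: choose coefficients $\alpha_0, \dots, \alpha_p$
minimizing

$$
\sum_{i=1}^{m} K\!\left(\frac{x_i - x}{h}\right) L(x_i)
  \left\{ Y_i - \sum_{j=0}^{p} \alpha_j (x_i - x)^j \right\}^2 ,
$$

and report $\hat\lambda(x) = \hat\alpha_0$, the fitted value at the anchor.
Two weights enter the criterion:

* the **kernel weight** $K(u) = (1 - |u|^3)^3$ for $|u| < 1$ (zero outside),
  which concentrates the fit on sites physically close to the anchor — this
  is the tricube kernel familiar from LOWESS;
* the **locus weight** $L$, equal to 1 for sites with MAF $\ge$ 0.05 and
  MAF/0.05 below that, which down-weights rare sites in proportion to how
  uninformative their common homozygotes are. A monomorphic site (MAF 0)
  contributes nothing; a site with all calls missing likewise gets weight 0.

Windows are built by the nearest-neighbor method: each anchor's window
contains the $b\% $ of the chromosome's sites nearest in physical distance
(default $b = 5$), so the bandwidth $h$ adapts to local marker density. The
window size is $k = \lceil b/100 \cdot m \rceil$; distance ties break toward
the lower position, and $h$ is set to $(1 + 10^{-9})$ times the distance of
the farthest member so that every member receives a strictly positive kernel
weight (at $|u| = 1$ the tricube weight would annihilate the boundary site).

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `b_percent` | 5 | % of sites | window = 5% of the chromosome's SNVs |
| `degree` | 1 | — | local linear: the standard bias/variance compromise; the criterion is written for general $p$, and 0–3 are supported |
| `anchor_stride` | 1 | sites | evaluate at every SNV; experiments thin to every 10th (below) |
| `threshold` | 0.9 | intensity | HD region rule, inclusive |
| `min_length_mb` | 5 | Mb | HD region rule, inclusive |
| FDR level | 0.05 | — | Benjamini–Hochberg across all windows per response |

### Numerical choices

* $\hat\alpha_0$ is clamped into $[0, 1]$; an unclamped local-linear fit can
  leave the interval near steep transitions. Clamping is the minimal
  mechanism that keeps the profile interpretable as a probability.
* Sites with a missing indicator get total weight zero — no imputation.
* If fewer than `degree + 1` member sites have positive weight, or the
  polynomial design is singular (e.g. two members at nearly identical
  offsets), the window falls back to degree 0, i.e. the weighted mean. If no
  member has positive weight the intensity is `NA` and a warning counts the
  affected windows. `NA` anchors break HD runs rather than bridging them.
* Within a window the weights are shared across individuals, so the fit for
  all individuals without missing members reduces to one matrix–vector
  product; only individuals with missing members are refit individually.

## Calling regions of HD

An HD region for an individual is a maximal run of consecutive anchors with
intensity at or above 0.9 spanning at least 5 Mb. Both cutoffs are
inclusive. Run length is measured anchor-to-anchor (first to last qualifying
anchor); window half-widths do not extend the span — the conservative,
reproducible reading. Summaries report the carrier fraction and the
five-number summaries (type-7 quantiles) of region lengths and of
per-individual totals. Regions are never merged across individuals; familial
overlap is visible in the per-individual table.

## Association testing in pedigrees

Individuals within a pedigree are correlated, so window-wise tests use
generalized estimating equations: at each anchor the marginal model

$$ g\{E(\text{response})\} = \beta_0 + \beta_1 \cdot \text{intensity}
   + \beta_2 \cdot \text{age} + \beta_3 \cdot \text{sex} $$

is fit with pedigrees as clusters, an exchangeable working correlation, and
the robust sandwich covariance; the Wald test of $\beta_1$ is reported.
Blood pressure responses use the identity link after a natural-log transform
and 1% winsorization (type-7 quantiles, applied after the log); hypertension
uses the logit link. Phenotype preprocessing follows clinical convention:
DBP/SBP of medicated individuals are raised by 5/10 mm Hg before analysis,
and hypertension is defined from raw values as medication use, DBP above 90,
or SBP above 140 (strict inequalities). P-values are Benjamini–Hochberg
adjusted across all windows genome-wide per response; a significant region
of HD is a maximal run of adjusted-significant windows, with bounds at the
first and last significant anchors.

No GEE implementation was available among the package's permitted
dependencies, so `gee_fit()` implements the standard Fisher-scoring GEE with
moment estimation of the exchangeable correlation. The exchangeable inverse
is applied in closed form and all per-cluster sums are accumulated with
`rowsum()`, which keeps a genome scan fast. With singleton clusters the fit
reduces exactly to the GLM with HC0 robust covariance, which the tests use
as an independent oracle (via `sandwich`). The exchangeable structure is the
standard choice for pedigree clusters when no kinship matrix is modeled; the
sandwich estimator keeps the test valid when the true familial correlation
is not exchangeable.

Windows where intensity does not vary are reported as untestable (missing
p-value) rather than silently dropped, so the output keeps one row per
window. For the transcript analysis, each individual's intensity within a
candidate region is summarized by its mean over the region's anchors; each
transcript is then tested with the identity link and FDR across transcripts.
The reported fold change — the log2 ratio of mean expression between
individuals with region intensity $\ge$ 0.9 and the rest — is a descriptive
volcano-plot axis only and plays no role in the test.

## The simulator and what it does (not) emulate

`simulate_genotypes()` produces pedigree-clustered diploid genotypes by gene
dropping: founders draw two haplotypes with independent Bernoulli(MAF)
alternate alleles, and each non-founder inherits one uniformly chosen allele
from each parent, independently across sites. Site positions are cumulative
exponential spacings (mean 50 kb, so 2,000 sites span roughly 100 Mb); 30%
of sites are rare with MAF uniform on (0.005, 0.05), the rest common with
MAF uniform on (0.05, 0.5). The default pedigree is three generations — a
founding couple, six married children, four to seven grandchildren per
couple — about 45 members, and 20 pedigrees give a sample of roughly 950.
These defaults were fixed when the simulator was designed, as a desk-scale
analogue of a large family study.

The trait $Q_1$ is drawn i.i.d. normal (default mean 10, sd 2) on a random
stream separate from the genotype stream, hence independent of the genome.
Trait-associated HD is implanted by the logistic model
$\operatorname{logit}(p) = b_0 + b_1 Q_1$: with probability $p$ an
individual's every genotype in a target region is replaced by a homozygote
(heterozygotes become the homozygote of the site's major allele; existing
homozygotes are untouched), and with probability $1 - p$ the individual is
left alone. With the default trait distribution the grids $b_0 \in
\{-25, \dots, -10\}$ and $b_1 \in \{0.3, \dots, 1.0\}$ span replacement
probabilities from near zero to near one. `select_rv_percentile_regions()`
picks target regions at chosen percentiles of local rare-variant density.
Genotype, trait, implantation and covariate draws each use a named
sub-stream derived from the base seed, so every experiment is bit-reproducible
and regenerating one component does not perturb the others.

What the simulator does **not** emulate: linkage disequilibrium and
recombination within a chromosome (sites segregate independently given the
pedigree), a realistic site-frequency spectrum, genotyping error and
missingness, and ascertainment. Passing tests on these data show that the
estimator, the region caller and the clustered test behave correctly under
the stated model — not that real-data results (carrier rates, region-length
distributions, specific loci) are reproduced.

## Experiments

`type1_experiment()` simulates one genotype panel, estimates its profile
once, then re-draws the trait 200 times; each replicate runs the full scan
and records the fraction of testable windows significant after FDR. This
mirrors a null study in which genotypes are fixed and only the trait is
resimulated. `power_experiment()` re-draws the trait and re-implants per
replicate on a fixed base panel; a replicate counts as a detection when at
least one FDR-significant window anchor lies inside the implanted region.

Experiments default to `anchor_stride = 10`: adjacent 5%-windows share 99%
of their member sites, so a 10-site stride retains about tenfold coverage of
every position while cutting the scan cost by an order of magnitude. The
shipped experiments use 20 pedigrees (~950 individuals) or 500 unrelated
individuals, 2,000 sites and 200 replicates — sizes chosen so a full
experiment completes in minutes on one core while keeping Monte-Carlo error
on a rate near 0.005 below 0.001.

Observed behavior (computed by `scripts/acceptance.R` and the test suite):
the null scan's mean type-I error sits well below the nominal 0.05 — as
expected for Benjamini–Hochberg adjustment of a scan whose overlapping
windows are positively dependent — and the strong-signal setting
($b_0 = -10$, $b_1 = 1$, $Q_1 \sim N(10, 2)$, 500 individuals) is detected
in every replicate.

## Known limitations

* The exchangeable working correlation ignores the kinship gradient within
  large pedigrees; efficiency (not validity) is lost relative to a
  kinship-aware mixed model.
* With few clusters the sandwich estimator is slightly anti-conservative;
  at 20 pedigrees the FDR step keeps the genome-wide error well controlled,
  but single-window p-values near the threshold should be read with care.
* Run length is anchor-to-anchor, so a region whose true boundary falls
  between anchors is shortened by up to one inter-anchor gap; at stride 1
  this is one inter-site gap.
* The CSV genotype dialect is a documented stand-in for site-by-individual
  matrices exported from family studies; VCF is the interchange format.
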