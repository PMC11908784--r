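---
title: "Detecting somatic mosaicism in sorted cell populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mosaicism in sorted cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicall)
```

## The problem

Post-zygotic (somatic) mutations create genetically distinct cell clones
within one tissue. In deep targeted sequencing of flow-sorted nuclear
populations from post-mortem brain (myeloid/microglial, neuronal, and
double-negative glial nuclei, plus matched blood), pathogenic clones can
sit at variant allele fractions (VAF) well below 1%, far inside the raw
sequencing error rate of any single site. Detecting them requires a
*site-specific* error model: the error rate of a given base change at a
given position varies by orders of magnitude across the panel, so a
global threshold either drowns in false positives or misses real clones.

`mosaicall` implements the full desk-side analysis: a beta-binomial
site-specific background error model with likelihood-ratio calling and
FDR control, the fixed post-calling filter cascade, pathogenicity
classification from ClinVar/OncoKB-style labels, panel-normalized
mutational burden, and the cohort-level statistics (nonparametric group
comparisons, carrier logistic regression, mixed-effects burden modeling,
hypergeometric gene-set enrichment). Because the motivating study's
sequencing data are access-controlled, a synthetic-cohort generator with
planted ground truth stands in for them; every stage is exercised
against that generator.

## The error model and the test

At each site, alt-read counts across a panel of "normal" samples are
modeled as beta-binomial: a binomial draw whose per-sample success
probability varies around a site mean $\mu$ with overdispersion
$\rho \in [0, 1)$, via shape parameters $a = \mu(1/\rho - 1)$,
$b = (1-\mu)(1/\rho - 1)$. As $\rho \to 0$ this is exactly the binomial,
which makes the no-overdispersion limit explicit and testable
(`beta_binomial_loglik()`).

Because every sorted population shares the library and sequencing
protocol, the "normal" panel for each test cell type is the pool of the
*other* cell types (`background_design()`): microglia are tested against
neurons + glia, and so on. A true clone confined to one cell type is
invisible to its own background; an artifact shared by all cell types is
absorbed into the background fit and not called.

Calling is a one-sided likelihood-ratio test for an *excess* of alt
reads in the test sample over the background model, with
$\lambda = 2(\ell_1 - \ell_0)$ referred to $\tfrac12\chi^2_1$ (the
halved tail implements one-sidedness; $p = 1$ whenever the test rate
does not exceed the background rate). P-values are Benjamini–Hochberg
adjusted within one cell-type batch — all (site, sample) tests of a
cell type form one family — and calls pass at $q \le 0.01$.

### Two routes to the statistic

`lrt_one_sample()` is the exact route: the null fits one shared
$(\mu, \rho)$ on background plus test sample by full maximum likelihood
(bounded quasi-Newton from a method-of-moments start, floors $10^{-8}$);
the alternative adds a separate rate for the test sample with shared
$\rho$, one extra free parameter, hence 1 df.

`call_variants()` (the default `"fast"` path) estimates per-site $\rho$
by maximum likelihood on the background pool with pooled-proportion
plug-in rate estimates, then evaluates both likelihoods directly — the
estimator strategy of the established deep error-model callers in this
field, and roughly a thousandfold faster. It reduces *exactly* to the
binomial likelihood-ratio test as the fitted $\rho$ hits its floor, and
the suite cross-checks its decisions against the full-ML route. The two
deliberately differ in one respect: with full ML the null can absorb
part of a true signal by inflating its free $\rho$, costing power; the
fixed-$\rho$ route does not. Fixing $\rho$ from the background is
therefore not only faster but statistically preferable here, and is the
default.

### What "calibrated" means for this test

The test statistic is discrete (integer counts) and one-sided ($p = 1$
when there is no excess — roughly 70% of null tests at 1100x and error
rate $10^{-3}$). Its p-value distribution under the null therefore
*cannot* be uniform on $(0, 1]$; the meaningful requirement, which the
suite enforces, is that p-values are stochastically no smaller than
uniform — no excess of small p-values. Concretely: two-sided KS distance
below 0.02 on the calling region $(0, 0.01]$ where $q \le 0.01$
decisions are made, no anti-conservatism anywhere on $(0, 0.5]$, and
zero $q \le 0.01$ calls on all-null cohorts in at least 95% of seeds.
Measured on the default null world, $F(t) \le t$ everywhere and the
fraction of seeds with any false call matches the Benjamini–Hochberg
family-wise expectation (~4–5%).

## The filter cascade

Nine independent predicates follow calling; a call is retained iff it
fails none, and each call carries the full set of flags it fails, so
evaluation order is irrelevant and the cascade provably equals the
brute-force conjunction (property-tested):

| flag | rule | default |
|---|---|---|
| `germline` | pooled VAF across the pooling scope > 20% | 0.20 |
| `low_coverage` | depth < 50x | 50 |
| `high_vaf` | VAF > 35% | 0.35 |
| `low_vaf` | VAF <= 0.3% | 0.003 |
| `few_alt_reads` | fewer than 4 alt reads | 4 |
| `strand` | missing support on either strand | on |
| `near_indel` | within 10 bp of an indel (inclusive) | 10 |
| `common_population_allele` | population AF >= 0.01 | 0.01 |
| `fdr` | q > 0.01 | 0.01 |

Design choices that the sources left open:

* **Germline pooling scope.** "Across samples" does not say whether
  reads pool within a donor or across the cohort. The default is
  per-donor (`germline_scope = "donor"`): a heterozygous donor shows
  VAF ~0.5 in *their* samples, so per-donor pooling flags essentially
  100% of hets, whereas with three or more donors a single donor's het
  can never reach 20% of cohort-wide reads. Cohort-wide pooling remains
  available (`"cohort"`) and corresponds to a design where germline
  variants recur across many donors (common SNPs).
* **Indel proximity** is inclusive at exactly 10 bp ("within 10 bp"
  states no boundary convention).
* **Population-AF lookup** is a local table; absent entries mean AF 0
  (absent from databases), never an error.
* The 0.3% VAF floor is applied as an explicit final filter although the
  sources report it as a property of the reported set.
* Coordinates are 1-based fully closed (VCF convention) throughout.

`merge_callsets()` unions two callers' outputs on
(sample, chrom, pos, ref, alt), keeps per-call statistics from caller A
when both called, and treats a reference-allele conflict at one key as a
data-integrity error.

## Classification, burden, cohort statistics

A variant is a pathogenic SNV (P-SNV) iff ClinVar says
pathogenic/likely pathogenic **or** OncoKB says oncogenic/likely/
predicted oncogenic (case-insensitive, joined on gene + protein change
with a genomic-key fallback). The exome-predictor consensus rule
(`classify_candidate_deleterious()`) is the strict four-way AND of
PolyPhen-2, SIFT, CADD-MSC and FATHMM-XF; any missing predictor fails.

Burden is variants per megabase: retained calls matching a selector
(all SNVs, P-SNVs, or a gene-set restriction) divided by the sample's
own sequenced footprint — the footprint is a per-sample metadata column,
never a constant, because real cohorts mix panels (2.88 vs 3.43–3.44
Mb). Donor-level burden is the arithmetic mean over the donor's samples
within a cell type; samples with zero calls contribute zeros, donors
with no samples are absent rather than zero. Synonymous variants count
toward all-SNV burden but are never P-SNVs.

Cohort inference mirrors the field's conventions:

* **Two groups**: unpaired two-tailed Mann–Whitney U, exact for combined
  n <= 20 without ties, normal approximation with tie correction
  otherwise. **Multiple groups**: Kruskal–Wallis plus Dunn pairwise
  z-tests; Dunn p-values are BH-adjusted (the adjustment was unnamed in
  the sources; BH is used consistently everywhere in the package).
* **Carrier association**: logistic regression
  `status ~ carrier + age + sex`, Wald CIs on the log-odds scale (the
  CI method was unstated); separation raises an explicit error rather
  than returning a degenerate fit.
* **Burden model**: linear mixed model, ML, burden per *sample* with a
  donor random intercept (`burden ~ status + age + (1 | donor)`); each
  fixed effect is judged by a likelihood-ratio test against the nested
  model dropping it (1 df). Conditional R² uses the variance-partition
  definition — (fixed-effect variance + random-intercept variance) /
  total — since the source quotes a value without a formula. Donor-mean
  analyses are a separate option used for the two-group tests, matching
  plots where each dot is a donor.
* **Enrichment**: upper-tail cumulative hypergeometric against a custom
  background (the sequenced panel), sets intersected with the background
  first; a set is reported when p < 0.05, overlap >= 3 and enrichment
  factor > 1.5. The classical MAPK set is the 15 RASopathy genes.

Normality pre-testing is deliberately not automated: silently switching
between parametric and nonparametric tests is a reproducibility hazard,
so the package always exposes the nonparametric result and lets
configuration choose.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` generates the world the pipeline assumes:

* 45 case and 27 control donors (the motivating cohort's split), four
  sorted populations per donor, 1–2 samples per population; ages uniform
  on 60–95.
* Depth: negative binomial around 1100x with excess dispersion 0.28,
  chosen so the depth spread matches the reported coverage quantiles
  (10th percentile ~276x, 90th ~1181x around a 668x mean at mutant
  sites); 0 gives constant depth.
* Per-site error rates: beta prior with mean $10^{-3}$ and
  overdispersion 0.002 (shape $a = 0.5$), spreading site error rates
  over roughly $10^{-5}$–$10^{-2}$ as deep targeted panels show.
* Germline: 5% of sites are common-SNP positions (population AF uniform
  on 0.1–0.5); donors are het with probability $2p(1-p)$ and show VAF
  0.5 in every one of their samples.
* Clones: each donor is a carrier with probability 0.44 (case) / 0.15
  (control) — the carrier split implied by the motivating cohort's 2x2
  carrier table; carriers get 1–3 clones (the per-carrier count was
  unreported; several donors carried multiple variants) at VAF uniform
  on 1–6% (the reported microglial clone range), confined to the
  donor's microglia samples, in a classical-MAPK gene half the time.
  Clone insertion *replaces* the binomial draw at the target rate, so
  the expected VAF is exact. All planted clones carry pathogenic
  annotations; decoy benign/VUS rows exercise the classifier.
* Strand assignment is a fair per-read coin (a bias knob exists to
  exercise the strand filter). Region labels are decorative; no
  region effect is simulated (none was found in the data this emulates).
* Between-sample overdispersion at a site (`error_site_dispersion`)
  defaults to **0**: desk-scale background pools of 14–60 samples
  cannot estimate per-site $\rho$ from counts this sparse, whereas the
  real design pools >400 background samples. With the knob at its
  realistic nonzero value the caller loses calibration for lack of
  background — a faithful reproduction of why the original method needs
  a large panel, and available as a stress test.

Not simulated: read-level artifacts (mapping error, strand-specific
chemistry error), indels (indel positions are supplied as an auxiliary
list for the proximity filter), multi-allelic sites, contamination.
A green test against this generator therefore establishes the
statistical machinery — error-model fitting, test calibration and
power, filter logic, burden arithmetic, cohort models — not robustness
to alignment artifacts.

## Numerical choices

* Floors: $\mu, \rho \ge 10^{-8}$; boundary fits (all-zero counts)
  return the floors with `converged = TRUE`.
* The fast path's per-site $\rho$ is a golden-section ML search on
  $\log\rho \in [\log 10^{-8}, \log 0.9]$, with an explicit comparison
  against the binomial boundary so ties go to $\rho$ at the floor.
* p-values are floored at $10^{-300}$ so q-values stay in $(0, 1]$.
* $\lambda$ is clipped at 0 (plug-in estimates can produce tiny negative
  values; the full-ML route starts the alternative at the null optimum
  so the clip is a no-op up to optimizer tolerance).
* Ties in BH are handled by the step-up `cummin`; adjusted values are
  order-preserving and capped at 1.
* `simulate_error_profile()` rejects dispersion <= 0 and short-circuits
  dispersion < 1e-12 to an exact point mass at the prior mean.

## Known limitations

* The fast caller's per-site $\rho$ uses plug-in rates; at extremely
  high alt fractions in a small background the estimate can differ from
  full ML. The `method = "full"` route exists for exactness at small
  scale.
* Mixed-model LRT p-values rely on the $\chi^2_1$ asymptotics; at very
  few donors they are mildly anticonservative (the type-I test bounds
  this at the nominal 5% ± 2%).
* The synthetic cohort plants at most one alt allele per site and no
  indels; the Mutect-style second caller is consumed as an input, never
  re-implemented.
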