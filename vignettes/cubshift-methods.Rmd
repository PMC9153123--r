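---
title: "Quantifying shifts in selection on codon usage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shifts in selection on codon usage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubshift)
```

## The model

Synonymous codon usage is shaped jointly by mutation bias, natural
selection and genetic drift. cubshift models the probability that a
gene $g$ with protein production rate $\phi_g$ uses codon $i$ of an
amino acid with $n_{aa}$ synonyms as

$$
p_{i,g} \;=\;
\frac{e^{-\Delta M_i - \Delta\eta_i\,\phi_g}}
     {\sum_{j}^{n_{aa}} e^{-\Delta M_j - \Delta\eta_j\,\phi_g}} ,
$$

a selection–mutation–drift equilibrium in multinomial-logit form.

* $\Delta M_i$ is the **mutation bias**: the log ratio of mutation
  rates between codon $i$ and its family's reference codon
  (dimensionless).
* $\Delta\eta_i$ is the **selection coefficient** relative to the
  reference, in units of $sN_e$ for a gene of average expression;
  smaller values are more favored, and the gene-level strength scales
  as $sN_e = \Delta\eta_i\,\phi_g$.
* $\phi_g$ is the **evolutionary-average protein production rate**,
  scaled so that the genome mean is 1. At $\phi = 0$ selection is
  absent and mutation bias alone sets codon frequencies; at $\phi = 1$
  frequencies balance mutation and drift-scaled selection.

Sites are independent given $\phi_g$, so per-gene, per-family codon
counts are sufficient statistics. Because the model assumes weak
selection, serine — whose six codons are separated by two non-
synonymous mutational steps between the TCN and AGY boxes — is split
into two families (S4 = TCA/TCC/TCG/TCT, S2 = AGC/AGT). That yields 19
families over 59 codons and $59 - 19 = 40$ free parameters per
parameter class, one reference codon (fixed at $\Delta M =
\Delta\eta = 0$) per family. During fitting the reference is the
alphabetically first codon of each family — a pure reparameterization;
for presentation, estimates are rescaled to the most selectively
favored codon of a genome-wide null fit (see below).

All softmax evaluations subtract the row maximum before
exponentiating, so probabilities and likelihoods are overflow-safe for
any finite parameters and $\phi$ up to the largest values a lognormal
expression distribution produces.

## Fitting

Region fits estimate the 40 free $\Delta\eta$ with $\Delta M$ and
$\phi$ **fixed** (at genome-wide estimates on real data, at truth in
simulation studies). Given fixed $\Delta M$ and $\phi$, families are
conditionally independent, so each family runs as its own chain;
aligned kept draws are valid joint posterior draws. The full
genome-wide fit (`fit_full()`) samples $\Delta M$, $\Delta\eta$ and
per-gene $\phi$ jointly and renormalizes $\phi$ to mean 1 after every
sweep, rescaling $\Delta\eta$ by the same factor so the products
$\Delta\eta_i \phi_g$ — the only quantities the likelihood sees — are
untouched while the $E[\phi] = 1$ constraint holds exactly.

Sampler and priors (the source publications for this class of model do
not state theirs; these are documented package defaults, not claims
about any other software):

* adaptive scalar random-walk Metropolis, proposal scales adapted
  every 50 iterations during burn-in toward 30% acceptance and frozen
  afterwards; defaults 20,000 iterations, 50% burn-in, thin 10, one
  chain;
* independent $N(0, 10^2)$ priors on each free $\Delta M$ and
  $\Delta\eta$ — weakly informative, and they keep families with zero
  counts finite (such families return prior draws with a warning);
* lognormal prior on $\phi$ with $\text{meanlog} = -\sigma^2/2$;
* in the joint fit, an additional correlated "ridge" move proposes
  $(\Delta M_j + \delta,\ \Delta\eta_j - \delta)$: near $\phi \approx
  1$ only the sum $\Delta M_j + \Delta\eta_j \phi$ is strongly
  identified, and the ridge move mixes the contrast between the two
  parameters far faster than axis-aligned updates alone.

Whether $\Delta M$ and $\Delta\eta$ can be separated at all rests on
expression variation: with all $\phi$ equal the two are confounded,
and the posterior for $\Delta\eta$ correctly widens to the prior scale
(this is tested).

## Model comparison

Grouping schemes (e.g. helix/sheet/coil merged vs separate) are
compared with the Deviance Information Criterion, classic form:
$\bar D$ the mean posterior deviance, $\hat D$ the deviance at the
per-parameter posterior means, $p_D = \bar D - \hat D$, $\mathrm{DIC}
= \bar D + p_D$ (the variance-based $p_V = \operatorname{var}(D)/2$ is
available as an option). Deviances add over the independent groups of
a scheme. Comparability requires every scheme to cover the identical
multiset of codons; `build_partitions()` enforces this by dropping
unassigned codons from *every* scheme and `compare_models()` refuses
models whose total counts differ. $\Delta\mathrm{DIC} =
\mathrm{DIC}_i - \mathrm{DIC}_{best} \in [0, \infty)$ is annotated
with the usual support bands (<2 substantial, 2–4 strong, 4–7 less,
$\geq$10 essentially none).

The first 35 codons of every gene are excluded by default before
partitioning, to avoid contaminating region contrasts with the
distinct (weaker) selection regime near the 5' end of genes. The
initiator ATG counts as codon 1 of the 35 (the natural reading; an
offset argument exposes alternatives). Structure segments overlapping
the excluded window are truncated rather than dropped, which preserves
the exclusion rule exactly.

## Comparing selection between regions

For presentation and shift calls, $\Delta\eta$ draws are rescaled,
draw by draw, relative to each family's **most selectively favored
codon** from the null-model fit (minimal posterior-mean $\Delta\eta$;
exact ties break alphabetically and are logged). In the null fit the
favored codon then sits at exactly 0 with synonyms $\geq 0$; in a
region fit a negative rescaled value signals a region-specific change
in which codon is favored.

* **Overall shifts** are summarized by a Deming (errors-in-variables)
  regression of region-B means on region-A means; slope 1 means no
  general shift, slope $-1$ a systematic reversal. The error-variance
  ratio $\lambda$ defaults to the ratio of the regions' mean posterior
  variances ($\lambda = 1$ available as the textbook default), and the
  95% CI is a leave-one-out jackknife.
* **Codon-specific shifts** are called when 95% equal-tailed posterior
  intervals are disjoint; intervals sharing an endpoint count as
  overlapping (the conservative reading). No multiplicity correction
  is applied beyond this device plus an exact one-tailed binomial
  audit of the shift-call count against a 5% false-positive rate,
  computed as $P(X \geq k)$ for $X \sim \mathrm{Bin}(n, 0.05)$.

One subtlety discovered while validating the mixed-selection
experiment: in a region where half the sites carry sign-flipped
selection, the fitted $\Delta\eta$ is essentially independent of the
truth selection but acquires a small pull of roughly $-0.1\,\Delta M$
— with heavy-tailed expression, the half/half mixture drives high-
$\phi$ frequencies toward 50/50, which a single-$\Delta\eta$ model can
only imitate by partially cancelling the mutation bias. Regressing in
the fitting parameterization leaves this artifact uncorrelated with
the region-A estimates (slope near 0, as expected for the 50% design).
Rescaling both regions to the favored codons *before* regressing,
however, couples the regions through the argmin choice of favored
codon and converts the artifact into spurious per-family covariance,
inflating the slope's spread several-fold. The package therefore
computes validation slopes on the fitting parameterization and uses
the favored-codon rescaling for presentation and shift calls only.

## Position-wise enrichment and its evolutionary null

`position_odds_ratio()` tests enrichment of externally classified
"non-optimal" codons at helix-relative positions: a 2×2 table of
(non-optimal, optimal) at position $p$ versus pooled over the other
aligned positions (pooling only positions beyond the analysis window
is available; the choice of stratum is not standardized in the
literature, and the all-others default is the minimal construction).
The reported odds ratio is the sample cross-product $ad/bc$; the
conditional-MLE estimate of the exact test is available by flag. The
p-value is two-sided Fisher's exact.

The crucial companion is `null_or_distribution()`: re-simulating the
genome many times under *uniform* selection (identical $\Delta\eta$ at
every position) and recomputing the odds ratios. Amino-acid
composition biases at particular positions, interacting with gene
expression and mutation bias, displace these null odds ratios from 1
even though selection is identical everywhere — so an observed odds
ratio should be compared with the simulated null distribution, not
with 1. The acceptance suite demonstrates this at desk scale:
enriching helix positions 2–3 for families whose favored codon is
classed non-optimal moves the null median odds ratio at those
positions far outside [0.9, 1.1] without any positional difference in
selection (and displaces positions 1 and 4 oppositely, because the
enriched positions sit inside their comparison stratum).

## The synthetic world

The generator stands in for all real-genome inputs and is itself
first-class, tested code. It draws:

* $\phi \sim$ lognormal with $\text{meanlog} = -\text{sdlog}^2/2$
  (so $E[\phi] = 1$ exactly), default sdlog 1 — a spread of roughly
  three decades, as observed for protein synthesis rates in
  fast-growing microbes;
* truth parameters $\Delta M \sim N(0, 1)$ and $\Delta\eta \sim
  N(0, 0.4^2)$ on non-reference codons — magnitudes comparable to
  genome-wide fits in budding yeast and *E. coli*, fixed once as the
  package's stated world;
* gene lengths Poisson around the requested mean (default 300
  codons), floored at 10;
* structure labels as alternating segments with
  minimum-plus-geometric lengths and per-label amino-acid
  compositions over the 19 family symbols (plus verbatim M/W); one
  label may override the composition at chosen segment-relative head
  positions. The final segment of a gene may be truncated by the gene
  boundary; interior segments always respect the minimum;
* heterogeneous-selection regions: exactly
  $\operatorname{round}(f \cdot N)$ of a region's amino-acid sites
  (round-half-to-even, sampled without replacement, so the fraction is
  honored exactly in every replicate) carry $\Delta\eta$ multiplied by
  $-1$ for all synonyms at that site;
* codons directly from the equilibrium probabilities — there is no
  generational dynamics; the model's stationary distribution *is* the
  sampling distribution.

What it does **not** emulate: real amino-acid sequences and their
covariation with structure, phylogenetic correlation, sequencing or
annotation error, GC-biased gene conversion, context-dependent
mutation, or expression measurement noise. A green test therefore
establishes that the estimators recover the model's own world at the
stated sizes — parameter recovery, DIC model selection, false-positive
calibration, and the confounding mechanism — not that any biological
claim about a particular genome is reproduced.

## Numerical and design choices

* Log-sum-exp stabilization everywhere Eq.-style softmaxes appear.
* Codon families and codons within families are ordered
  alphabetically; all tie-breaks are alphabetical and logged.
* Ambiguous nucleotides are rejected, not guessed; internal stop
  codons are errors; a trailing stop is stripped on FASTA read and
  recorded.
* Termini splitting: segments shorter than the minimum are excluded
  entirely; segments long enough to include but too short for two
  disjoint termini raise an error rather than silently double-label.
* All randomized entry points take explicit seeds; replicate seeds
  derive deterministically from a master seed; every CLI output
  directory carries a JSON manifest (command, options, seed, package
  version, wall time).
* Scale-downs: the validation experiments run at ~300 genes × 300
  codons (heterogeneous-selection recovery) and 80 genes × 150 codons
  × 10 replicates (null model selection and false-positive audit),
  with 2,000–10,000-iteration chains — the posteriors at these counts
  are tight enough that longer chains change estimates by far less
  than a posterior standard deviation.

## Known limitations

* Selection within a region is a single $\Delta\eta$ per codon; mixed
  selective pressures are recovered only as the weighted average, with
  the mutation-bias pull described above.
* DIC is computed conditional on the fixed $\Delta M$ and $\phi$ of
  region fits; it compares groupings, not the full joint model.
* One chain by default; the deviance trace is exposed for split-chain
  diagnostics but automated convergence assessment is minimal.
* No codon-context dependence, no amino-acid substitution modeling,
  no downstream-offset shifting of structure labels (an offset
  argument exists but defaults to 0 and is untested against data).
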