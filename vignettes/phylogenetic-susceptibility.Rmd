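---
title: "Modelling phage susceptibility on a host phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phage susceptibility on a host phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagephylo)
```

## The question and the model

A phage screened against a panel of bacterial strains shows variable
susceptibility. If closely related strains present similar cellular
environments — receptors, restriction systems, prophage content — then
susceptibility should track the host phylogeny. `phagephylo` quantifies
this with a multivariate phylogenetic generalised linear mixed model
over the susceptibility traits measured by different assays.

For strain $h$, trait $m$ and biological replicate $i$:

$$y_{him} = \beta_{1m} + \mu_{p:hm} + \mu_{s:hm} + e_{him}$$

with the strain term $\mu_s$ optional. Random effects and residuals are
multivariate normal with mean zero and covariances
$\mathbf{V}_p \otimes \mathbf{A}$, $\mathbf{V}_s \otimes \mathbf{I}$ and
$\mathbf{V}_e \otimes \mathbf{I}$. $\mathbf{A}$ is the relatedness
matrix: $A_{ij}$ is the branch length shared by the root-to-tip paths of
strains $i$ and $j$, the Brownian-motion trait covariance up to a rate
constant. Trees enter unscaled by default so that variance components
are per unit branch length and subtree analyses (via `drop_tips()`)
remain comparable; `scale_to_unit_depth = TRUE` is available for
cross-checks. Because each biological replicate is measured by a single
assay, cross-trait residual covariances cannot be estimated and are
fixed at zero.

Plaque-assay data are zero-inflated: many strains yield no plaques at
all, and titres among permissive strains span orders of magnitude. The
pipeline therefore splits the plaque trait hurdle-style into
`PA_binary` (any plaques, modelled on a probit latent liability whose
residual variance is fixed at 1, the only identifiable choice) and
`PA_cont` (titre, present only for permissive replicates). The joint
model's phylogenetic and strain covariances link the two parts, so the
missingness of `PA_cont` is governed by `PA_binary` exactly as the
hurdle construction implies; beyond that, imputation assumes missing at
random.

An optional per-trait fixed slope on patristic distance from the
propagation host (`distance_from`) tests whether apparent phylogenetic
signal is merely adaptation of the phage to its production strain.

## Priors and the sampler

Covariance matrices get parameter-expanded priors: an inverse-Wishart on
a *working* covariance $\tilde{\mathbf V}$ (scale $\nu V$, defaults
$V = \mathbf I_T$, $\nu = T - 1 + 0.002$) combined with independent
normal working-scale parameters $\alpha_m \sim N(0, 1000)$, the
data-scale covariance being
$\mathbf V = D_\alpha \tilde{\mathbf V} D_\alpha$. Marginally this is a
heavy-tailed scaled-F family with the working variance (1000) setting
the scale, weakly informative across the many orders of magnitude that
susceptibility variances can span. A plain inverse-Wishart switch
(`parameter_expansion = FALSE`) supports prior-sensitivity checks.
Gaussian residual variances get inverse-gamma(0.002, 0.002) priors;
intercepts an essentially flat normal prior (precision $10^{-8}$,
implemented as a ridge on the mixed-model equations).

One Gibbs iteration does:

1. a **joint** Gaussian draw of all intercepts, slopes and random
   effects from the mixed-model equations, assembled from per-cell
   count/sum sufficient statistics plus the Kronecker prior precisions
   $\mathbf V_p^{-1} \otimes \mathbf A^{-1}$ and
   $\mathbf V_s^{-1} \otimes \mathbf I$, solved by one Cholesky
   factorisation per iteration;
2. parameter-expanded covariance updates: conjugate inverse-Wishart on
   the working covariance given the rescaled effects
   $\tilde u = u/\alpha$, then Gaussian draws of each $\alpha_m$ from
   its likelihood conditional. The working scales are *persistent
   state* across iterations — resetting them to 1 each iteration would
   let the inverse-Wishart prior scale swamp small variances (OD
   variances here are of order $10^{-1}$ against a prior scale of 1)
   and visibly bias heritabilities downward; with persistent scales the
   data term dominates and recovery is unbiased in our checks;
3. conjugate inverse-gamma residual-variance updates;
4. truncated-normal liability updates for probit observations, by
   inverse-CDF sampling with probabilities clamped away from 0/1 for
   numerical safety.

Missing trait values (unbalanced replicates, structurally missing
conditional titres, masked strains) are simply excluded from the
likelihood; the linear predictor over the full strain-by-trait grid is
recorded every retained iteration, which is where out-of-sample
predictions are read.

Chain defaults are desk-scale: 40,000 iterations, burn-in 10,000,
thinning 20 — the same burn-in and thinning proportions as a
full-fidelity run of 13 million generations with 3 million burn-in
sampled every 5,000, at a length suited to interactive work. Multiple
chains get deterministically derived seeds; `check_convergence()`
reports PSRF (via coda) and effective sample sizes, flagging PSRF > 1.1
or ESS < 200.

## Trait construction choices

* **OD change** is $(u - i)/u$ for paired uninfected/infected OD600
  readings; negative values (infected grew more) are retained unless
  flagged. Outliers are flagged per strain across biological replicates
  with Tukey fences at 1.5 (minor) or 3 (major) times the IQR.
  Quartiles use linear interpolation between order statistics (type 7)
  — the convention matters for points near a fence, so it is fixed and
  tested. Single-pass flagging is used; with heavy-tailed contamination
  a second pass could flag further points (masking), which is why the
  severity level is an explicit pipeline option.
* **Plaque titres**: per biological replicate the most-diluted spot
  whose count lies in a countable window (default 1–200 per spot) is
  converted to PFU/µL. `PA_cont` is log10-transformed by default; raw
  titres span orders of magnitude and are strongly right-skewed, which
  sits badly with the Gaussian trait assumption. A raw-scale switch
  (`log10 = FALSE`) exists for fidelity comparisons.
* **qPCR**: records failing to amplify, lacking a melt peak, or with
  peaks more than 1.5 °C from the reference (the modal peak of positive
  samples, computed as the centre of the most populated 0.5 °C window)
  are excluded. Plate effects are removed with an additive two-factor
  least-squares model (sample + plate), subtracting plate deviations
  centred to mean zero so corrected Ct values stay on the original
  scale and every sample's cross-plate mean is preserved. Technical
  replicate pairs are then averaged and converted to
  $\log_{10} 2^{-\Delta C_t}$ against the inoculum Ct.

## Derived statistics

All ratio statistics — repeatability $V_p/(V_p+V_e)$, heritabilities
$V_p/(V_p+V_s)$ and $V_p/(V_p+V_s+V_e)$, correlations and slopes from
$\mathbf V_p$ — are computed per posterior draw and then summarised
(posterior mean and 95% highest-posterior-density interval, the
shortest window of sorted draws). Ratios of posterior means would be
biased for skewed posteriors and are deliberately not used. Draws with
numerically zero denominators are excluded and counted in the output
rather than clipped. For the binary trait these statistics are on the
latent liability scale with $V_e = 1$; no observed-scale transformation
is applied.

## Ancestral reconstruction

`reconstruct_ancestral()` assigns each internal node the exact
Brownian-motion conditional expectation given **all** tip values:
$E[\text{node}] = \hat\mu + c^\top C^{-1}(y - \hat\mu)$ with $C$ the
tip–tip covariance, $c$ the node–tip covariances (both built from node
depths and patristic distances) and $\hat\mu$ the GLS root estimate.
Global conditioning, not recursive local averaging: every tip informs
every node, and the root equals the phylogenetic mean. The BM rate
cancels in the conditional mean; supplying `sigma2` (or `"profile"`)
adds conditional standard deviations. Tip inputs default to each
strain's posterior mean linear predictor from the fitted model, which
shrinks noisy strain means appropriately; a raw-mean mode exists for
model-free use. Plots colour each branch by linear interpolation in
branch-length units between parent and child values — the smooth
fixed-rate transitions Brownian motion implies; the interpolation
resolution only affects rendering, not estimates.

## Leave-one-out prediction

Holding out a strain removes **all** of its observations across all
traits simultaneously, so cross-trait correlations cannot leak
information about the held-out strain. The phylogenetic prediction is
the posterior mean linear predictor of the masked strain (for the
binary trait, the posterior mean of $\Phi(\eta)$, a probability); the
null model is intercept-only — the training grand mean for Gaussian
traits and the training permissive frequency for the binary trait.
Binary accuracy counts a strain correct when the thresholded prediction
(default 0.5) matches its majority observed permissiveness, ties broken
toward permissive. Error distributions are compared with two-sided
Wilcoxon rank-sum tests: exact by enumeration for tie-free samples with
$n_1 n_2 \le 400$, otherwise the normal approximation with tie and
continuity corrections.

`mode = "full"` refits the whole model per held-out strain.
`mode = "fast"` (default) fits once on the full data, then fixes the
covariance matrices at their posterior means and re-runs only the
conditional effect/liability draws per strain. This ignores
covariance-parameter uncertainty in the refits — a deliberate
approximation that makes a 64-strain leave-one-out run interactive; on
Gaussian fixtures the two modes agree well within the posterior spread
of the predictions.

## The synthetic-data generator

`simulate_traits()` draws strain-level effects from exactly the model's
covariance structure ($\mathbf V_p \otimes \mathbf A$ via matrix-normal
Cholesky factors, $\mathbf V_s \otimes \mathbf I$), builds replicate
observations with Gaussian residuals, observes the binary trait as the
sign of its liability, and emits the conditional titre only for
permissive replicates — zero inflation generated through the liability,
not an independent Bernoulli, so generator and model agree by
construction. Yule trees (`ape::rphylo`, unit birth rate) provide
clade-structured panels resembling a bacterial family spanning two main
clades; the tree model is configurable and irrelevant to inference
correctness. Replicate counts default to 4–6 per strain, weighted
towards 6, matching panels where most strains reach the full count. The
`"paper-like"` preset sets OD repeatability 0.98, qPCR 0.99, a 0.9
phylogenetic correlation among the binary, OD and qPCR traits, a barely
heritable conditional titre, strain variance one ninth of phylogenetic
variance ($h^2 = 0.9$), and a 1% OD outlier rate (aberrant large
negative shifts); `"null"` zeroes the phylogenetic and strain
covariances; `"gaussian-pair"` is the two-Gaussian-trait subset used
for parameter-recovery checks.

What the generator deliberately does **not** emulate: plate layouts and
position effects, melt-curve failures, dilution-series mechanics
(these enter only through the packaged raw-record fixture), phylogenetic
uncertainty, or non-Brownian evolution. Passing tests therefore show
that the implementation is internally correct and recovers known
truth under the model's own assumptions — not that real assay data meet
those assumptions.

## Numerical choices and problem sizes

Cholesky factorisations throughout; the relatedness matrix must be
positive definite (identical tips or zero pendant branches are
rejected with an explicit error). A $10^{-8}$ ridge stabilises the
flat-prior fixed-effect block. Working scales are kept away from exact
zero ($|\alpha| \ge 10^{-8}$). Binary majority ties break toward
permissive. Test and acceptance runs use 64-strain panels with 2,500 —
3,000 iterations for recovery checks, 32-strain panels for
leave-one-out properties, and 2,000 retained draws for
conditional-mean oracles; these sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping a full suite run
interactive.

## Known limitations

* Single fixed tree: phylogenetic uncertainty is not propagated.
* REML/ML fitting is out of scope; everything is MCMC.
* The additive sample+plate correction is a documented stand-in for the
  published plate-correction model, whose exact parameterisation is not
  reproducible from the methods text.
* Binary-trait heritabilities are reported on the latent scale only.
* The fast leave-one-out mode underestimates predictive uncertainty
  (point predictions are nearly unaffected in our checks).
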