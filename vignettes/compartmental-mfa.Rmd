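---
title: "Compartmentalized 13C metabolic flux analysis with compflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmentalized 13C metabolic flux analysis with compflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compflux)
```

## The problem

Intracellular reaction rates cannot be measured directly. 13C metabolic
flux analysis (13C-MFA) infers them by feeding cells isotopically labeled
nutrients, measuring the resulting mass isotopomer distributions (MIDs) of
intracellular metabolites by GC-MS, and fitting a mathematical model of the
metabolic network — its stoichiometry and its carbon (atom-transition)
maps — to the labeling patterns together with measured nutrient uptake and
product secretion rates.

`compflux` implements this workflow for a compartmentalized model of
mammalian central carbon metabolism, built for the comparison of
proliferating (P) and contact-inhibited quiescent (Q) fibroblasts: the
model distinguishes extracellular, cytosolic and mitochondrial pools, with
pyruvate, acetyl-CoA, citrate, alpha-ketoglutarate, malate, oxaloacetate,
alanine, glutamate and aspartate present in both intracellular
compartments. Because cell extraction homogenizes the compartments, the
model represents each measured pool of a dually compartmented metabolite
as a *mixing reaction* blending the cytosolic and mitochondrial pools with
a fitted fraction $f \in [0,1]$. Dilution of intracellular labeling by
unlabeled material is modeled explicitly: CO2 fixed by pyruvate
carboxylase draws from an unlabeled extracellular pool, and unlabeled
glutamate, aspartate and pyruvate enter from the medium through dedicated
inflow reactions whose fluxes are free parameters.

## The forward model

At isotopic steady state the labeling of every pool is constant while
metabolism proceeds. For a network with known fluxes the fragment MIDs are
computed by elementary metabolite unit (EMU) decomposition: working
backwards from each measured fragment, the decomposition collects the
minimal set of carbon-atom subsets whose labeling must be known, and
groups them by size. Within size $k$ the steady-state balance is linear,

$$A(v)\,X = B(v)\,Y,$$

where rows of $X$ are the unknown size-$k$ EMU mass distributions and $Y$
collects tracer EMUs and convolutions of smaller EMUs. The cascade is
solved by ascending size with dense LU factorizations (implemented in
C++). Reversible reactions are simulated as forward/backward flux pairs,
`fwd = exch + max(net, 0)` and `bwd = exch + max(-net, 0)`. Rotationally
symmetric metabolites (succinate) are handled by splitting every producing
reaction into two half-flux variants with mirrored atom maps.

A brute-force validation oracle (`isotopomer_mids()`) solves the full
$2^n$ positional-isotopomer balance by damped Gauss–Seidel iteration with
a simplex projection per sweep (the bilinear recycle system admits
spurious sub-stochastic fixed points that the projection removes). The
EMU path must agree with the oracle to $10^{-8}$; this is enforced by the
test suite on randomized networks and on the full reconstruction.

```{r forward}
net <- mef_network()
net
fx <- build_fixture("P")
sim <- simulate_mids(net, fx$flux, fx$tracers$glc12,
                     fragments = mef_fragments())
head(sim)
```

## Measured fragments

The twelve measured metabolites (pyruvate, lactate, alanine, malate,
aspartate, alpha-ketoglutarate, glutamine, citrate, glycerol 3-phosphate,
phosphoenolpyruvate, 3-phosphoglycerate, ribose) are represented by their
full-backbone `[M-57]+` TBDMS fragments plus partial-backbone ions
(`mal234`, `asp234`, `akg2345`, the C1-carboxyl-loss series). The partial
fragments matter: full-backbone mass distributions are blind to the
positional scrambling introduced by symmetric succinate, and without them
the split between mitochondrially exported malate and cytosolically
produced malate (hence the MDH1 flux) is structurally much harder to
resolve. The exact ion list of any given instrument differs; the shipped
fragment table and its elemental formulas are a documented reconstruction
from the standard MOX-TBDMS derivatization chemistry, and both the
fragment map and formulas are user-replaceable arguments throughout.

## Natural-abundance correction

Raw GC-MS intensity patterns include mass shifts contributed by naturally
occurring heavy isotopes of every atom in the derivatized fragment
(dominated by Si and C of the TBDMS groups). `build_correction_matrix()`
constructs the matrix whose column $j$ is the isotope pattern of the
fragment with $j$ backbone carbons forced to 13C — the convolution of the
per-element natural-abundance distributions over all atoms except the
backbone carbons — truncated to the measured window (default
$M+0 \ldots M+(n{+}1)$, which captures most of the Si tail).
`correct_mid()` then recovers the tracer MID by non-negative least squares
and renormalization; NNLS rather than matrix inversion tolerates window
truncation and noise while guaranteeing a valid distribution. The isotope
table uses IUPAC representative abundances, recorded in
`isotope_abundances()`.

## External rates

Per-cell uptake and secretion rates come from spent-media concentration
time courses (samples at 0, 6, 18 and 24 h, triplicate wells) and cell
counts. For exponentially growing cultures the concentration change is
integrated against the growing biomass,
$q = \mu\,\Delta C / (X_0\,(e^{\mu \Delta t} - 1))$, while for quiescent
(constant-density) cultures $q = \Delta C/(X\,\Delta t)$; the former
converges to the latter as $\mu \to 0$ and `external_rates()` selects the
estimator from the fitted growth rate. Rate SDs are propagated first-order
from the replicate scatter of the consumed amount. No evaporation
correction is applied (an explicit assumption). Units are
nmol/10^6 cells/h throughout.

## Flux estimation

`fit_fluxes()` minimizes the variance-weighted sum of squared residuals
over every MID entry of every parallel-labeling dataset (two tracers —
[1,2-13C2]glucose and [U-13C5]glutamine — times two biological
replicates, fitted simultaneously) and every external rate. Free
parameters are the net fluxes (through a null-space basis of the balanced
stoichiometry, so steady state holds exactly), one exchange flux per
reversible reaction on a log scale, and one mixing fraction per
dually compartmented measured pool on a logit scale.

Numerical design choices that proved decisive:

* **Smoothness.** The net/exchange decomposition is computed through the
  softplus identity `fwd = ex + sp(v)`, `bwd = ex + sp(-v)` with
  `sp(v) = log(1 + exp(5 v))/5`, which reproduces `max(v, 0)` away from
  zero but removes the kink at `v = 0`; irreversibility is enforced by a
  smooth penalty `3 sp(-v)`. A tiny diagonal ridge (1e-8) keeps the EMU
  systems solvable at degenerate trial points.
* **Exact derivatives.** The residual Jacobian is computed analytically by
  forward sensitivities of the EMU cascade (the sensitivity systems share
  the factorization of the state systems), then chained through the
  parameter transforms. This is both much faster than finite differences
  and qualitatively more reliable in the narrow curved valleys typical of
  MFA objectives.
* **Bounded nuisance transforms.** Weak regularizers on the mixing logits
  (`m/20`) and log-exchanges (`e/50`) remove the zero-gradient plateaus of
  the transforms; without them single parameters can drift to extreme
  magnitudes and freeze the Levenberg–Marquardt step-size test.
* **Multi-start with trust-region cycling.** Each restart runs LM repeatedly
  with a re-initialized damping schedule until the SSR stops improving
  (a single pass frequently stalls long before the valley floor). Starts
  are drawn per the study protocol — net fluxes log-uniform in
  [0.1, 500] nmol/10^6 cells/h with random signs for reversible
  reactions — and are projected onto the steady-state cone near the
  measured rates (a linear, data-driven completion), plus one
  deterministic data-informed start. After a fast scanning phase the three
  leading candidates are driven to convergence, the best is kept (ties
  break to the smaller flux norm), and a mixing-fraction flip sweep guards
  against the mirrored local modes of the blended pools.

Goodness of fit is assessed by a two-sided chi-square test at
$\alpha = 0.05$: the SSR must fall between the 2.5% and 97.5% quantiles
with degrees of freedom equal to the number of *independent* measurements
(each renormalized fragment MID carries its length minus one) minus the
number of free parameters. The two-sided form flags both lack-of-fit and
overfitting.

Confidence intervals use the profile-likelihood (SSR-sensitivity) method:
the target flux is stepped away from its optimum, all other parameters
re-optimized, and the 95% bound located by bisection where the SSR
exceeds its minimum by `qchisq(0.95, 1) = 3.84`; unbounded directions are
reported as infinite.

## The synthetic study generator

`build_fixture()` constructs complete steady-state flux maps for the P and
Q conditions. The anchored reactions carry the published values — ME1
(cytosolic malate to pyruvate) 31.6 vs 0, MDH1 net +24.4 (OAA to malate)
vs −86.6 (reversed), PCK1 7.4 vs 104 nmol/10^6 cells/h — and every other
flux is completed deterministically by bounded least squares around a
prior that encodes the qualitative physiology: quiescent cells with
roughly halved glycolysis and 4-fold lower lactate secretion but modestly
reduced glucose uptake, strongly increased mitochondrial pyruvate uptake,
TCA flux and pyruvate carboxylase anaplerosis (about 15-fold), induced
mitochondrial malate export, and elevated proline synthesis. Where the
study reports no number, the prior values are one-time choices of
plausible fibroblast magnitudes and are recorded in `fixture_prior()`;
exchange fluxes and mixing fractions are likewise fixture choices.
`simulate_study()` then emulates the full campaign: two tracers times two
replicates of steady-state MIDs with additive Gaussian noise
(SD 0.3 mol%, clipped at zero and renormalized), spent-media
concentrations at 0/6/18/24 h in triplicate wells with 2% lognormal
noise, cell counts with 3% noise (exponential growth at
$\mu = \ln 2/24\,\mathrm{h}^{-1}$ for P, constant density for Q), and a
rate table at 10% CV. Everything is reproducible from one seed.

What the generator does *not* emulate: chromatographic peak shapes and
integration errors, tracer impurity, correlated (systematic) MID biases,
inter-batch variability, and medium evaporation. Passing round-trip tests
therefore demonstrates the self-consistency and statistical calibration of
the pipeline under its own error model, not robustness to every artifact
of real GC-MS data.

## Identifiability limits

Profile analysis of the reconstruction shows that the Q-state anchors and
the P-state PCK1 and ME1 fluxes are well determined by the parallel
glucose/glutamine design, whereas the magnitude of the P-state MDH1 flux
is only weakly identified: cytosolic oxaloacetate inherits the
succinate-scrambled mass patterns of the TCA cycle, so at the small
P-state anaplerotic flux the contrast between mitochondrially exported
malate and MDH1-produced malate is carried almost entirely by the partial
fragments and the dilution structure. Its profile interval is
correspondingly wide (and honest): point estimates scatter across the
interval from seed to seed even though the interval covers the true
value. The original study resolves this flux with its own (unpublished)
model and measurement set; reproducing that resolution is outside what
this reconstruction can claim.

## Worked example

```{r pipeline, eval = FALSE}
fx <- build_fixture("Q")
study <- simulate_study(fx, seed = 1)
out <- run_pipeline(study, net = fx$net, tracers = fx$tracers,
                    restarts = 50, seed = 1,
                    ci_reactions = c("ME1", "MDH1", "PCK1"))
out$report
tidy(out$fit)
autoplot(out$fit, reactions = c("ME1", "MDH1", "PCK1", "MPC", "PC"))
```

Problem sizes used by the shipped validation: EMU-versus-oracle agreement
on 100 randomized small networks and on the full reconstruction;
correction round trips over all fragment formulas; chi-square calibration
over 100 and interval coverage over 200 simulated studies of a two-branch
toy network (chosen so a single study fits in well under a second); and
one full P and Q round trip at the study's conditions with 50 restarts.
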