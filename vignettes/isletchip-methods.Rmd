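---
title: "Modelling glucose-insulin homeostasis in a liver-islet chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose-insulin homeostasis in a liver-islet chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletchip)
```

## The system and the model

The package models a microphysiological system in which 3D liver
microtissues (HepaRG/HHSteC spheroids) and human pancreatic islet
microtissues sit in two 300 µL medium compartments connected in a closed
loop by a micropump (average flow 4.94 µL/min, i.e. a ~2 h medium
turnover). Cultures run for 15 days under a fixed glycemic regime —
hyperglycemia (11 mM glucose), normoglycemia (5.5 mM) or hypoglycemia
(2.8 mM) — with insulin-free medium exchanged after 24 h and then every
48 h. Glucose tolerance tests (GTTs) at day 1 and day 13 follow an
exchange with 15 µL samples drawn at 0, 8, 24 and 48 h; the day-13 GTT
always doses 11 mM regardless of regime.

The model couples a fast (hours) and a slow (weeks) component. The fast
component tracks molecule amounts of glucose and insulin in each
compartment's medium under well-mixed mass balances: hepatic glucose uptake
$V_\mathrm{HepaRG}\,(E_{G0} + S_I(t)\,I_\mathrm{liver})\,G_\mathrm{liver}$,
Hill-type glucose-stimulated insulin secretion
$V_\beta \sigma(t)\, G^2/(EC50_I^2 + G^2)$, first-order hepatic insulin
clearance $CL_I V_\mathrm{HepaRG} I_\mathrm{liver}$, and symmetric flow
exchange $Q(\cdot_\mathrm{other} - \cdot_\mathrm{self})$ between
compartments. Endogenous glucose production is structurally present but
fixed at zero: observed glucose falls below normoglycemia in this system,
which rules out an appreciable hepatic glucose output. The liver-insulin
balance contains only clearance and flow (no hepatic insulin production);
this is the only closure of the insulin mass balance consistent with the
whole-medium elimination arithmetic used in the human translation
(17.81 × 0.34 / 1.5 ≈ 4.04 1/h).

The slow component drives disease-like progression:

* **Insulin resistance.** The running integral $G_\mathrm{int}$ of
  liver-compartment glucose above the 5.5 mM normoglycemic threshold
  (a ramp: negative excess contributes nothing) depresses insulin
  sensitivity sigmoidally,
  $S_I = S_{I0}\,(1 - I_{max,Si}\, G_\mathrm{int}/(EC50_{Si} +
  G_\mathrm{int}))$, bounded below by $S_{I0}(1 - I_{max,Si})$.
* **β-cell adaptation.** Total β-cell volume follows a Topp-type net
  growth law $k_v(-d_0 + r_1 G_\mathrm{slow} - r_2 G_\mathrm{slow}^2)\,
  V_\beta$ in the daily-average pancreas glucose $G_\mathrm{slow}$
  (first-order average with $\tau_\mathrm{slow} = 500$ h). With the
  standard constants ($d_0 = 2.5\cdot10^{-3}$, $r_1 = 6.3\cdot10^{-4}$,
  $r_2 = 3.24\cdot10^{-5}$) the two roots sit at 5.556 and 13.889 mM:
  mild hyperglycemia expands β-cell volume, while normoglycemic or severe
  hyperglycemic averages shrink it. Only the identifiable sums $r_1$ and
  $r_2$ of the underlying replication/apoptosis coefficients are
  represented.
* **Secretion decay.** Per-volume secretion capacity declines in absolute
  culture time, $\sigma(t) = \sigma_{max}(1 - t^2/(\alpha + t^2))$; the
  clock is shared across regimes and GTTs.

Compartment mix-ups are easy to make and deliberately pinned down:
$G_\mathrm{int}$ is driven by the *liver* compartment concentration,
$G_\mathrm{slow}$ by the *pancreas* compartment. Units are globally fixed
to mmol, mIU, L and h (concentrations mmol/L and mIU/L); no conversion
happens inside the core.

## Parameters and defaults

Fixed constants use their standard values: $G_\mathrm{normo}$ 5.5 mmol/L,
$EC50_I$ 7.86 mmol/L, $d_0$, $r_1$, $r_2$ as above, $\tau_\mathrm{slow}$
500 h, $V_\beta(0) = 8.8\cdot10^{-9}$ L (10 spherical 150 µm islets, half
β cells — `islet_beta_volume()`). The twelve experiment-specific
parameters default to a representative calibrated hyperglycemic co-culture
($E_{G0}$ 1.47 1/h, $CL_I$ 17.81 1/h, $S_{I0}$ 5·10⁻³ L/mIU/h,
$\sigma_{max}$ 6·10⁶ mIU/L/h). Four of them have no published reference
value; the package fixes representative magnitudes once — $I_{max,Si} =
0.7$ and $EC50_{Si} = 300$ mmol·h/L so that a 15-day hyperglycemic
exposure ($G_\mathrm{int}$ reaching roughly 10³ mmol·h/L) produces a
pronounced but partial sensitivity loss, $\alpha = 5\cdot10^4$ h² so the
secretion capacity falls to roughly a quarter by day 15, and $k_v = 1$.
These choices produce the qualitative fingerprints expected of the chip
(declining glucose tolerance between the day-1 and day-13 GTTs, growing
β-cell volume under mild hyperglycemia) and are not revisited by tests.

## Protocol and event handling

Protocols are explicit, time-ordered discrete events. Media exchanges
reset both compartments' concentrations to the dose (plus the GTT offset
parameters $\Delta G$, $\Delta I$, which absorb systematic exchange errors
at the day-1 and day-13 GTT starts) and restore the nominal 300 µL
volumes; the 315 µL exchange volume of the real bench protocol is modelled
as this reset. Slow variables are continuous across events. The time
origin is co-culture start, and "day k" means $t = 24k$ h, which makes the
24 h + 48 h exchange cadence land exactly on day 13. The 0 h GTT sample is
taken immediately *after* its exchange (offsets applied first); a GTT's
closing 48 h sample that coincides with the next exchange precedes that
exchange. Whether the day-1 GTT sampling preceded or followed the first
scheduled exchange is not documented for the bench protocol; the
coincidence convention here is a package choice.

Sampling removes 15 µL per compartment without changing concentrations.
Volume tracking is on by default (amounts and volumes shrink
proportionally); a flag switches to the constant-volume idealisation,
because whether the reference simulations tracked sampling losses is not
documented — both modes are provided and differ by well under the
measurement noise. Pooled measurements are the arithmetic mean of the two
compartment concentrations (equal sample volumes from each compartment).

## Numerics

The system is non-stiff at realistic parameters. The contract solver is
adaptive lsoda with `rtol = 1e-8`, `atol = 1e-14` (the tiny absolute
tolerance keeps the 10⁻⁹ L-scale β-cell volume honest), integrating
piecewise between events with the right-hand side compiled in C; a pure-R
reference implementation of the derivative is kept and the two are
cross-checked. The test suite validates the adaptive path against an
independent hand-written fixed-step RK4 oracle (Δt = 10⁻³ h over a 48-h
GTT, agreement better than 0.1% in every state variable) and checks exact
conservation of total glucose and insulin when all reactions are switched
off, plus the closed-form two-compartment mixing rate $2Q/V_m \approx
1.97$ 1/h. Tiny negative solver excursions are clipped at zero; excursions
beyond `1e-9` of the state scale raise an error instead. During
calibration a coarser `rtol = 1e-6` and output only at sampled times keep
a full 15-day two-condition cost evaluation at ~25 ms.

## Calibration

The cost is $V(p) = \sum_i \sum_t (y - \hat y)^2 / SEM^2$ over all time
series. Because 4–10 replicates estimate SEM poorly, SEMs below 5% of
their mean are replaced by the largest SEM in the dataset (or all set to
10% of mean when every point falls below the bound) before fitting. A fit
is *acceptable* when $V < \chi^2_{0.95}(df)$ with df equal to the number
of data points; the df composition is a property of each dataset, never
hard-coded.

Search runs in log10 space for positive-scale parameters and linearly for
$I_{max,Si}$ and the offsets (bounds ±3 decades around representative
magnitudes, offsets in ±3). In joint multi-regime fits all kinetic
parameters are shared and glucose offsets are estimated per condition;
insulin offsets are shared. The optimiser is a single-coordinate Gaussian
simulated annealer (proposals at 5% of each range, reflection at bounds,
Metropolis acceptance, geometric cooling) followed by a deterministic
Nelder–Mead polish; every evaluated vector below the χ² threshold joins
the accepted set, which is the basis for pointwise min/max uncertainty
envelopes of both observables and mechanistic variables. The accepted-set
construction mirrors the "set of acceptable parameters" idea; the exact
annealing variant used in the original analyses is not documented, so the
schedule here is the package's own and fully configurable. The long-run
default (4000 proposals × 5 restarts, cooling 0.95 per 100) suits
overnight fits; short-budget runs converge far better with an initial
temperature of the order of the χ² threshold and faster cooling, which is
what the recovery harness uses (T0 = 50, cooling 0.9 per 50, 1500
proposals, one restart).

## The synthetic-data generator

Real chip measurements exist only as figures, so the generator is the
package's testbed: it simulates each condition with known true parameters
and draws replicate values as truth × (1 + ε), ε ~ N(0, CV) truncated at
−90%, recording mean, SEM = SD/√n and n. Defaults mirror the study
conditions: 5 replicates (range 4–10), CV 10% (the magnitude of the SEM
fallback rule), hyper+normo co-cultures with GTTs at days 1/13 and 13.
Insulin at the 0 h GTT sample is identically zero right after an
insulin-free exchange and is therefore not reported (no assay would
resolve it, and a zero-SEM point would be weightless anyway). What the
generator does *not* emulate: assay chemistry, inter-platform correlation,
additive noise floors, donor covariates — so passing recovery tests shows
the pipeline is self-consistent, not that real chips are this kind.

The recovery harness frees the six kinetic parameters ($E_{G0}$, $CL_I$,
$S_{I0}$, $\sigma_{max}$, $\alpha$, $k_v$) with ±1-decade bounds around
round prior magnitudes, keeping offsets at their true zero and the
resistance pair ($I_{max,Si}$, $EC50_{Si}$) at its default: a single noisy
15-day design carries little information about the shape of the
resistance sigmoid, and freeing weakly identified parameters only blurs
the recovery of the well-identified ones. The χ²-coherence property is
scored with the *population* SEM (CV·truth/√n): with n = 5 the
sample-SEM-standardised residual is t₄-distributed, so the ~95% pass-rate
statement holds only for known weights.

## Translation to human scale

`scale_to_human()` multiplies the organoid volumes by the 10⁵
miniaturisation factor, sets the circulating medium to the human plasma
volume (5.1 L blood × 58% plasma, conventionally rounded to a 3 L total,
i.e. 1.5 L per compartment) and the flow to a 5-min turnover of the
unrounded plasma volume (35.5 L/h — the rounded and unrounded volumes are
deliberately used where each reproduces the established value). Hepatic
uptake parameters ($E_{G0}$, $S_{I0}$) are inflated by 1/0.45 because the
liver performs ~45% of postprandial glucose disposal; the factor is
applied to $S_{I0}$ and propagates through the resistance dynamics.
Insulin clearance doubles (liver ≈ 50% of total clearance) and is further
corrected by 4.23, the ratio between the human hepatic elimination rate
and the value implied by the chip constant
(`effective_elimination_rate(17.81, 0.34, 1.5)` = 4.037 1/h). The scaled
$E_{G0}$ is 1.47/0.45 = 3.267; a reference table rounds this to 3.25 — the
computed value is used. `sigma_scale` (default 1) optionally halves
$\sigma_{max}$ to reproduce the secretion-reduced human scenario. A human
bolus (glucose into both compartments at t = 0; there is no intestinal
compartment) then plays out in hours instead of ~48 h; because endogenous
glucose production stays zero, late glucose undershoots normoglycemia — a
known structural artefact, not a bug.

## Problem sizes used by the test suite

The suite's heavier checks are sized for a desk run: the RK4 oracle
comparison integrates one 48-h GTT at Δt = 10⁻³ h; the recovery study
runs 5 trials of 1500 annealing proposals plus polish on a 21-point
joint hyper+normo design (CV 5%, n = 5), a few minutes in total.

## Known limitations

* Only mean flow is modelled — no pulsatility, channel dead volume or
  spatial gradients.
* No glucagon, incretins, or intracellular hepatic metabolism; EGP is
  structurally zero.
* The accepted-set envelope is an optimisation by-product, not a
  posterior; no profile-likelihood or mixed-effects machinery.
* The liver-compartment insulin equation is validated only against the
  whole-medium elimination worked example; alternative closures with
  hepatic insulin production would require washout data to distinguish.
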