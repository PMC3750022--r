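---
title: "Modeling bistable switching in the PhoQ/PhoP circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bistable switching in the PhoQ/PhoP circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoswitch)
```

## The circuit and the question

The PhoQ/PhoP two-component system is a prototypical bacterial signaling
module: the bifunctional sensor kinase PhoQ phosphorylates the response
regulator PhoP and, through a separate phosphatase activity, also
dephosphorylates PhoP-P. PhoP-P is a transcription factor that activates
its own operon, so both proteins are positively autoregulated. A single
point substitution in PhoQ (T281R) abolishes the phosphatase activity and
weakens the kinase. `phoswitch` models why that one mutation converts the
circuit's graded, unimodal response into a bistable switch with heritable
OFF and ON states, deterministic "priming" of OFF cells under slow growth,
irreversibility of the ON state, and epigenetic trapping of populations in
a low-fitness state.

## Deterministic models

Three deterministic models share one production function, the
autoregulated promoter activity

$$f(P^*) = V_0 + V_f \frac{{P^*}^h}{K_f^h + {P^*}^h},$$

bounded in $[V_0, V_0 + V_f]$ and monotone in the PhoP-P concentration
$P^*$.

**Reduced model** (`reduced_rhs`): three species $P$ (PhoP), $Q$ (PhoQ),
$P^*$ (PhoP-P). $P$ and $Q$ are co-produced at rate $f(P^*)$ (one operon),
the kinase flux is $k_k P Q$, the phosphatase flux $k_p P^* Q$ (both
bilinear: each reaction needs the substrate *and* the enzyme), and every
species is lost only by growth-mediated dilution at rate $\lambda$ — these
are stable proteins, so growth is the only sink.

**Detailed model** (`detailed_rhs`): six species, adding PhoQ-P and the
two enzymatic intermediates, with autophosphorylation
$Q \to Q^*$ ($k_a$), phosphotransfer
$P + Q^* \rightleftharpoons C_t \to P^* + Q$, and the phosphatase complex
$P^* + Q \rightleftharpoons C_p \to P + Q$. Complexes dilute at $\lambda$
like everything else (the alternative — complexes immune to dilution — has
no physical motivation for stable cytosolic proteins). In the
fast-exchange limit the effective kinase constant is $k_{cat,t}/K_t$ with
$K_t = (k_{off,t} + k_{cat,t} + \lambda)/k_{on,t}$, and the detailed
steady states converge to the reduced ones (verified to 5% in the test
suite). No explicit mRNA is carried in either model: transcription and
translation are lumped into one production rate, keeping the two models
in exact correspondence.

**Decoupled model** (`decoupled_rhs`): *phoP* stays autoregulated while
total PhoQ is clamped at `Q_tot` (constitutive, inducer-controlled
expression). Optionally PhoP-P and PhoQ form a catalytically inert
complex with dissociation constant `K_d`; with `K_d = Inf` no complex
forms. This variant represents the strain in which *phoQ* transcription
was removed from feedback control.

**Variants** (`make_variant`): the T281R substitution maps to
$k_p = 0$ (or $k_{cat,p} = 0$) with the kinase rate scaled by
$\kappa = 0.1$; the additional deletion of the constitutive operon
promoter scales $V_0$ by $\delta = 0.1$ — not to zero, since residual
basal transcription remains. $\kappa$ and $\delta$ are calibration knobs,
not measured quantities.

### Why the default Hill coefficient is 1

The feedback nonlinearity only needs to saturate; it does not need binding
cooperativity. With $h = 1$ the model cleanly separates the two sources of
effective nonlinearity that the analysis turns on: (i) the bilinear
kinase/phosphatase fluxes combined with co-regulation of both proteins
(production enters the kinase flux twice), and (ii) promoter saturation.
This has a sharp consequence for the decoupled variant: its steady-state
balance is a concave function minus a line, which provably has exactly one
root — the decoupled circuit *cannot* be bistable without the
sequestration nonlinearity, exactly the architecture property the package
is built to exhibit. With $h \ge 2$ the *phoP*-only loop can switch on its
own, which would blur the architectural comparison; `h` remains a free
parameter for users who want to explore that regime.

## Steady states, stability, regimes

At steady state, production balances dilution for each conserved protein
family, so total PhoP and total PhoQ both equal $f(P^*)/\lambda$.
Eliminating all other species leaves a single scalar balance $g(P^*) = 0$;
for the detailed model the elimination needs one inner one-dimensional
solve (the PhoQ-P balance) per evaluation. `find_steady_states` brackets
every sign change of $g$ on a log-spaced grid (4000 points by default)
over the admissible window $[0, (V_0 + V_f)/\lambda]$ and polishes each
bracket with alternating secant/bisection steps to relative width
$10^{-13}$. Residuals are checked against the model right-hand side,
normalized by the total flux magnitude at the state (the large kinase and
phosphatase fluxes cancel at a root, which bounds the achievable absolute
residual). The test suite verifies root counts and locations against an
independently coded dense-grid (2×10^5 points) scan-and-bisect oracle on
hundreds of random circuits.

Stability is read from the eigenvalues of a central-difference Jacobian;
real parts within $10^{-9}$ (relative) of zero are flagged `"marginal"`
and excluded from regime classification. A set with two stable states is
`bistable`; one stable state is `monostable_off` or `monostable_on`
depending on a reference scale. Because the field's branch diagrams label
regimes relative to their own OFF/ON branches, `bifurcation_sweep` uses
the geometric mean of the two stable branches at the nearest bistable grid
point as that reference, falling back to $K_f$ when the sweep has no
bistable window.

`bifurcation_sweep` localizes fold (saddle-node) points by bisecting the
sweep parameter between grid cells where the root count changes (relative
tolerance $10^{-6}$). `bistability_scan` maps regimes over two parameter
grids; monostable cells carry the stable $P^*$ clamped below at $10^{-4}$
for logarithmic display, bistable cells are left `NA` (plotted black in
the conventional style). Both are deterministic: identical configurations
reproduce bit-identical tables.

## Calibrated defaults

No rate measurements exist for this circuit in the units of the model, so
the package ships a dimensionless parameter set, located once by
bistability scans and stored as plain-text configuration
(`inst/extdata/params/`), not hard-coded:

| field | base (wild type) | T281R | meaning |
|---|---|---|---|
| `k_k` | 0.01 | 0.001 | kinase rate constant |
| `k_p` | 1 | 0 | phosphatase rate constant |
| `V_0` | 0.005 | 0.005 | basal production |
| `V_f` | 1 | 1 | maximal feedback production |
| `K_f` | 5 | 5 | feedback half-saturation |
| `h` | 1 | 1 | Hill coefficient |
| `lam` | 0.02 | 0.02 | growth rate |

At these values the T281R variant sits inside its bistable window at
$\lambda = 0.02$ (OFF $P^* \approx 0.0042$, ON $P^* \approx 29.3$, an
unstable state at $0.18$), the kinase-rate sweep crosses
OFF → bistable → ON with two folds, and the wild type is monostable for
every kinase rate. The decoupled configuration uses `k_k = 0.1`
(reflecting its strong inducible-promoter context); with `K_d = 0.1` a
bistable band in `Q_tot` appears by molecular titration — free PhoP-P
stays near zero until total PhoP-P exceeds the PhoQ pool, creating the
threshold that the non-cooperative feedback alone cannot supply — and
with weak binding the same scan has no bistable cell anywhere.

`rescale_time` multiplies every rate-dimension field by a common factor;
steady states are invariant, which also encodes the equivalence between
slowing growth and upscaling all kinetic parameters.

## Stochastic engine

`build_network` converts a parameter set into a discrete reaction network
with system size $\Omega$ (counts = concentration × $\Omega$; default
$\Omega = 100$ for ensemble work, $10^4$ for deterministic-limit checks).
The production propensity uses the promoter form in the PhoP-P *count*
with $C_{P1} = V_f \Omega$ and $C_{P2} = V_0 \Omega$; binary propensities
carry rate $k/\Omega$. Phosphatase-dead variants contain no phosphatase
catalysis reaction, and the decoupled network's *phoQ* production is a
constant-rate reaction. The default scheme is the three-species one, which
keeps the deterministic-limit check exact against `reduced_rhs`; the
six-species scheme is available via `scheme = "detailed"`.

`gillespie_run` is an exact direct-method simulation (Rcpp core, R's RNG,
so `set.seed` reproducibility carries through). Growth is handled by the
division policy: by default generations have fixed duration
$\ln 2/\lambda$ and at each boundary every molecule count is partitioned
binomially ($p = 1/2$) into the followed daughter — the "generations"
framing with realistic partitioning noise. A continuous first-order
dilution policy is selectable; it is the policy whose ensemble mean
converges exactly to the rate equations, so the SSA/ODE agreement tests
use it, while retention/priming experiments use division. The endpoint
statistic for a run is the time-averaged PhoP-P count over the final
generation, not the instantaneous final value.

On top of ensembles (`run_ensemble`, deterministic given a base seed):
`priming_fraction` (percent of runs above a threshold; the natural
threshold is the geometric mean of the OFF/ON deterministic references),
`detect_switch` (hysteresis-band event detection — chatter inside the
band produces no events), and `bimodality_report` (fractions near the
OFF/ON references within one decade on the log scale, versus
intermediate).

## Culture protocols in silico

`priming_assay` integrates a `phase_schedule` — ordered growth phases with
per-phase growth rate and parameter overrides — and classifies the final
state against the baseline OFF/ON references. Exponential-phase histories
(constant $\lambda$ in the bistable regime) preserve the OFF state; a
slow-growth (stationary-phase analogue) interlude crosses into the
monostable-ON regime and the cell exits primed, with hysteresis holding it
ON afterwards. Magnesium is represented *only* as a kinase-rate or
expression multiplier in overrides: the models carry no explicit ion
binding, and the mutant's inverted magnesium response is an input
scenario, not a mechanism. Schedules are expressed in generations, which
makes assay outcomes invariant under `rescale_time` of the whole
parameter set.

`induction_hysteresis` emulates the induction experiment on the decoupled
strain: stochastic ensembles started from uninduced and fully induced
states, grown ~15 generations across an induction grid, summarized by
endpoint medians ± SE. The high-`K_d` decoupled circuit converges from
both starts everywhere (no hysteresis); the autoregulated mutant, run as
a control inside its bistable window, stays start-dependent.

`lineage_simulation` is a two-state population process, not per-cell SSA:
serial-dilution days at colony scale involve ~10^9 cells, where only the
OFF/ON composition matters. Each day draws `n_b = 2000` founders
binomially from the previous composition (an unbiased bottleneck), grows
them `log2(dilution)` ≈ 20 generations with per-generation switching
probabilities, then applies stationary-phase selection as a survival
factor `s_on` on ON cells. The defaults (`p_on_off = 1e-4`,
`s_on = 0.5`) were chosen once to sit in the metastable regime: ON
lineages stay near 100% ON for days, then diverge replicate-by-replicate
as rare switches are amplified by selection. Neither probability is a
measured quantity; both are explicit inputs.

## Quantification statistics

Single cells are classified by the ratio of the PhoP-P-responsive
reporter (YFP) to a constitutive normalizer (CFP); the default threshold
is the geometric midpoint of a two-component split of the log-ratio
distribution, so classification is invariant under common illumination
rescaling. Summaries are the median and geometric mean of the ratio.
Competition outcomes use the competitive ratio
$CR = C(10)L(0) / (C(0)L(10))$ from selective/plain plate counts — for a
1:1 design bounded by 2 (sensitive eliminated), 1 when neutral — and the
competitive index $CI$, which is unbounded and deliberately errors when
the sensitive population is below detection. Serial-dilution arithmetic:
$\log_2$ of the dilution factor gives generations per day;
$1 - (1-f)^n$ gives the probability a transfer of $n$ cells contains a
minority at fraction $f$.

## Synthetic data

`simulate_cells` draws the structure the quantification assumes: latent
OFF/ON labels, lognormal channels with log-scale CV 0.3 (multiplicative
microscopy noise, chosen to keep the default 60-fold mode separation
clearly resolved), state-independent CFP, and truncated-normal widths
with ON cells narrower. Optional features, both off by default: a YFP
saturation ceiling (the reporter promoter saturates in the ON state) and
exponential YFP-dilution memory for recently switched cells.
`simulate_competition` builds plate counts for a requested true CR with
optional Poisson plating noise; `simulate_switch_trajectory` builds
piecewise-constant trajectories with known events. Every generated
parameter is recoverable by the corresponding statistic within sampling
error — that is a tested contract, not an aspiration.

What the generator does *not* emulate: cell-to-cell extrinsic noise
beyond the two-state mixture, segmentation artifacts, background
gradients, or reporter maturation kinetics. Tests passing on synthetic
data therefore validate the statistical machinery, not microscopy
pipelines.

## Problem sizes and numerical choices

The shipped analyses use deliberately modest sizes: 100–200 stochastic
runs per condition over 35 generations at $\Omega = 100$ (the scale at
which division noise is visible but state retention is still sharp),
25-run ensembles at $\Omega = 10^4$ for the deterministic-limit check,
200 random circuits for the oracle comparison, and 10^4 synthetic cells
for recovery checks. Fold localization bisects to $10^{-6}$ relative;
root polishing to $10^{-13}$; steady-state residuals are accepted below
$10^{-8}$ of the local flux scale. Degenerate inputs are handled
explicitly: zero production collapses the search window to the origin,
`Q_tot = 0` removes the kinase flux entirely, and empty tables or
inverted thresholds raise errors rather than returning numbers.

## Known limitations

- All parameters are dimensionless calibrations, not fits; quantitative
  agreement with any particular wet experiment is out of scope.
- Magnesium sensing, ATP cycling, membrane localization and PhoQ
  dimerization are not modeled.
- The lineage process treats growth as deterministic doubling with
  selection only in stationary phase; growth-rate differences between
  states during exponential phase default to zero.
- The detailed model's inner elimination assumes a single admissible free
  PhoQ value per $P^*$; the residual check guards against silent failure
  of that assumption.
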