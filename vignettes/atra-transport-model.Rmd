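---
title: "Modelling fluid and atRA transport across the choroid and sclera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fluid and atRA transport across the choroid and sclera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

All-*trans* retinoic acid (atRA) is a signalling molecule implicated in the
retinoscleral signalling cascade that regulates scleral growth and hence
myopia development. atRA is highly hydrophobic and travels through the
extravascular space almost entirely bound to serum albumin (SA). `atraflux`
implements a one-dimensional, steady model of the tissues exterior to the
retinal pigment epithelium (RPE): the choroid (thickness $L_C$), the
suprachoroidal space (SCS, treated as an interface), and the sclera
(thickness $L_S$), with the coordinate $x$ pointing outward from the RPE.

**Fluid.** Both layers are porous media obeying Darcy's law,
$u_M = -(K_M/\mu)\,\mathrm{d}p_M/\mathrm{d}x$. The sclera has no fluid
sources, so $p_S$ is affine. In the choroid, fluid exchanges with the
choriocapillaris by Starling filtration,
$$q_C(x) = a(x)\,L_p^*\left[(p_B - p_C) - \sigma R T\,(c_B - c(x))\right],$$
where $a(x)$ is a smoothed indicator of the choriocapillaris (the inner
fraction $\alpha$ of the choroid),
$a(x) = \alpha^{-1}\bigl[1 - (1+e^{-\Gamma(x/L_C-\alpha)})^{-1}\bigr]$ with
$\Gamma = 100$, $p_B = \mathrm{IOP} + \Delta P_\text{blood}$ the choroidal
blood pressure, and the osmotic term driven by the albumin pool
($c = c_2 + c_3$, reflection coefficient $\sigma = 1$). Boundary
conditions: RPE pumping flux $u(0) = u_\text{RPE}$; pressure continuity and
a velocity jump $Q_u/A_S$ at the SCS (unconventional aqueous inflow);
orbital pressure at the outer scleral surface. The intraocular pressure is
not an input: it is closed self-consistently through the Goldmann balance
$Q_u(\mathrm{IOP}) = Q_\text{prod} - C\,(\mathrm{IOP} - \mathrm{EVP})$
together with the SCS offset $p(L_C) = \mathrm{IOP} - \Delta P_\text{SCS}$.

**Solutes.** Free SA ($c_2$) and the atRA:SA complex ($c_3$) obey steady
advection–diffusion–reaction,
$\mathrm{d}(u c_i)/\mathrm{d}x - D_i c_i'' = r_i + b_i$. Choroidal cells
synthesize atRA at rate $k_\text{prod} a(x)$; because binding to SA
equilibrates fast (association constant $K_a \sim 10^5$–$10^6\,
\mathrm{M^{-1}}$, so only 0.2–1.5% of atRA is unbound at tissue albumin
levels of $2\times10^{-4}$ M), free atRA is never transported: synthesis
enters directly as a $+k_\text{prod}a(x)$ source for $c_3$ and an equal
sink for $c_2$. Both species leak across capillary walls at rate
$\beta\,(c_{i,B} - c_i)\,a(x)$. In the sclera, CYP26 enzymes degrade
atRA:SA with an induced first-order rate
$$r_3 = -k_\text{CYP}\,\frac{\mathrm{Ind}_\text{max}\,(c_3/f_u)}
{\mathrm{Ind}_{C50} + c_3/f_u}\,c_3,$$
releasing the albumin back to the free pool. Boundary conditions: no solute
flux across the (tight) RPE, total-flux and concentration continuity at the
SCS, and zero concentration gradient at the orbit (well-mixed orbital
tissue). Total-flux continuity at the SCS means the aqueous inflow carries
no albumin — consistent with the protein-poor composition of aqueous
humour, and required for the observed flat scleral SA profile with a
nonzero SA gradient in the outer choroid.

The two solvers are coupled through the osmotic term (tissue albumin
reduces the suction into the capillaries) and iterate to a fixed point.

## Parameters

`atra_params()` ships the three simulated cases — mouse control, mouse
with atRA feeding, human control — with every quantity converted to strict
SI units at construction (1 mmHg = 133.322 Pa, 1 µl/min = 1e-9/60 m³/s,
1 mM = 1 mol/m³). The feeding preset differs from mouse control only in
the blood atRA:SA concentration, 11.67 nmol/ml (the measured serum level
90 min after feeding) versus 1.25 pmol/ml. `parameter_units()` records the
unit and uncertainty category of every field; the "extremely uncertain"
category ($\beta$, $L_p^*$, $k_\text{prod}$, $k_\text{CYP}$) marks the
parameters that calibration may adjust.

Two quantities are not printed in the primary parameter table and were
fixed here once:

* **$A_S$** (choroid–sclera interface area): back-solved from the
  published per-area velocity balance and the integrated synthesis rates,
  which pin it to $1.49\times10^{-3}\,\mathrm{m^2}$ (human) and
  $3.2\times10^{-5}\,\mathrm{m^2}$ (mouse); both consistency checks agree
  to about 1%.
* **$K_a$**: the literature range is $3.3\times10^5$–$2.3\times10^6\,
  \mathrm{M^{-1}}$; the upper value is the default, and the full range is
  retained in the unbound-fraction diagnostic. $K_a$ does not enter the
  transport equations (the bound pool is the transported state), so this
  choice affects no transported quantity.

$a(x)$ is used exactly as defined; its integral over the choroid deviates
from $L_C$ by less than 1% (worst for the human $\alpha = 0.034$), which is
within every tolerance used here, and keeping the closed form preserves the
exact half-height identity $a(\alpha L_C) = 1/(2\alpha)$.

## Numerics

* **Mesh** (`make_grid()`): both layers are meshed with second-order
  finite differences on a graded mesh; choroidal nodes concentrate around
  $x = \alpha L_C$ (Gaussian grading of width $5L_C/\Gamma$) so the
  capillary step's 90%→10% falloff always spans well over ten nodes. The
  production resolution is 400 intervals per layer; doubling it moves IOP
  by under $10^{-3}$ mmHg. Cheaper meshes (60–150 per layer) are used
  where thousands of solves are needed (calibration, sensitivity
  analysis); rankings and recovered parameters are insensitive to this.
* **Fluid solve** (`solve_fluid()`): for frozen concentrations the
  pressure problem is linear in $(p, \mathrm{IOP})$, so the discretized
  equations, the interface flux jump (which contains $Q_u(\mathrm{IOP})$),
  and the SCS closure row are assembled as one augmented sparse system and
  solved directly — no shooting. Rows are equilibrated to unit maximum
  magnitude because Laplacian rows ($\sim h^{-2}$) and the Goldmann row
  ($\sim C/A_S$) differ by ~25 orders of magnitude.
* **Solute solve** (`solve_solute()`): one transport operator per species
  is assembled per fluid field; the nonlinear CYP26 sink is handled by
  Picard iteration on the frozen induction bracket (relative tolerance
  $10^{-10}$), with adaptive under-relaxation — full steps while the
  iteration contracts, halved steps otherwise — and warm starts from the
  previous coupling iterate. Advection is centrally differenced; cell
  Péclet numbers are far below one everywhere in the study conditions, so
  no upwinding is needed.
* **Osmotic coupling** (`solve_steady_state()`): fluid and solute solves
  alternate, starting from a zero osmotic gradient. The feedback is
  leading-order physics (without it the human Starling balance is
  filtration-dominated and IOP comes out above 35 mmHg), and the plain
  alternation oscillates, so the concentration update is damped starting
  at 0.5 and adapted by the observed contraction; convergence is declared
  at $10^{-6}$ mmHg in IOP and $10^{-8}$ of the blood albumin scale in the
  profiles, typically within ~20 iterations.
* **Degenerate inputs**: the rate-like parameters ($L_p^*$, $\beta$,
  $u_\text{RPE}$, $k_\text{prod}$, $k_\text{CYP}$, $c_{3,B}$) may be
  exactly zero, giving analytic limits used by the tests (closed-form IOP,
  zero concentrations). Negative concentrations beyond $10^{-8}$ of scale
  abort a checked solve; tiny undershoots are clamped to zero. At extreme
  parameter corners (for example $L_p^*$ tripled in the mouse) the model
  has no physical steady state — scleral flow reverses and IOP falls below
  orbital pressure — and the converged, clamped state is only accepted
  where explicitly requested (sensitivity analysis).

The consumption-rate profile reported in `r3` includes the scleral-side
limit at the interface node so that trapezoidal quadrature of the
consumption integral remains second-order accurate.

## Calibration

`fit_uncertain_parameters()` minimizes the weighted sum of squared
*relative* deviations between model observables and targets (targets span
four orders of magnitude, so absolute residuals would be meaningless) over
log-transformed parameters with a restarted Nelder–Mead simplex inside a
$[10^{-2}, 10^{2}]\times$ box. The default is two stages that exploit the
one-way dependence of trace atRA on the fluid/SA problem: $(L_p^*, \beta)$
against IOP, the unconventional-outflow fraction and the scleral SA ratio
(with atRA transport switched off entirely), then
$(k_\text{prod}, k_\text{CYP})$ against the mean atRA:SA concentration.
For the latter pair a single control-condition concentration cannot
identify two parameters; the mean atRA:SA level is therefore targeted
under both control and feeding conditions (feeding changes only the blood
concentration), which separates synthesis from degradation because feeding
makes local synthesis negligible. With noiseless synthetic targets the
two-stage fit recovers all four parameters to well under 1%.

## Sensitivity analysis

`efast_total_index()` implements the extended Fourier Amplitude
Sensitivity Test: each parameter in turn drives the search curve at
$\omega_1 = \lfloor (n-1)/(2M) \rfloor$ while the complementary parameters
receive frequencies at most $\omega_1/(2M)$; the total-order index is one
minus the spectral power below $\omega_1/2$ over the total variance,
averaged over resampling curves with random phases. Effect directions are
Spearman correlation signs with $|\rho| > 0.1$, else indeterminate. An
inert `dummy` factor is appended to every standard design: its index
estimates the bias floor from harmonic interference, and a ranking is only
meaningful above it.

Design sizes: the Ishigami benchmark uses $n = 513$, $M = 6$ (at $M = 4$
the harmonic-rich benchmark leaks enough complementary power to bias the
middle index by ~0.05). The transport-model analyses use $M = 4$ with
$n = 65$ per curve for the six-factor fluid/SA set and $n = 129$ for the
ten-factor atRA set — with ten complementary parameters, $n = 65$ would
force all of them onto frequency 1 and inflate the dummy floor to ~0.2.
Model evaluations run on a coarser mesh (60–100 intervals per layer)
with unphysical-corner states accepted as described above; evaluations
that fail outright are imputed from the nearest successful sample on the
same curve, within a 5% failure budget.

## Synthetic data

`generate_serum_timecourse()` emulates the serum atRA measurements that
set the model's blood concentrations: the control cohort draws from a
positive-truncated normal (mean 1.25, SD 0.54 pmol/ml), and the fed
cohort follows a Hill-type sigmoid rise
$C(t) = C_p\,t^h/(t_{50}^h + t^h)$ with $C_p = 12$ nmol/ml and $(h,
t_{50})$ pinned by the two measured anchors 4.1 nmol/ml at 30 min and
11.67 nmol/ml at 90 min, plateauing near 12 nmol/ml by 120 min. A simple
saturating exponential cannot pass through both anchors and the plateau —
the measured rise is delayed-then-steep — which is why the sigmoid form
was chosen. Multiplicative log-normal noise (default CV 20%, mean
preserving) models assay error on strictly positive concentrations.
`generate_calibration_targets()` produces (optionally noisy) target tuples
from a known ground-truth parameter set for parameter-recovery studies.

What the generators deliberately do not reproduce: per-animal
pharmacokinetic variability structure (some measured cohorts had a single
animal), absorption/elimination mechanisms behind the empirical rise, or
any spatial tissue data — so passing recovery tests demonstrates the
calibration machinery, not the identifiability of real-tissue data.

## Fidelity and known limitations

At the published reference parameters the forward model reproduces the
published transport observables closely (scleral atRA:SA means within
~0.3%, the feeding orbit concentration 277.97 vs 278 nM, consumption
fractions 40.3%/97.4% vs 40%/98%, SA leak rates within ~1%) and IOP within
0.8%. The unconventional-outflow *fraction* is an amplified functional of
IOP — $Q_u/Q_\text{prod}$ moves ten times faster than IOP in relative
terms — and lands 1.1–1.3 percentage points from the published values
(18.9% vs 20% human, 21.2% vs 19.9% mouse). This residual is within the
envelope induced by the printed precision of the inputs: the published
values of the fitted conductivities and of $u_\text{RPE}$ carry 1–3
significant figures, and the rounding interval of $u_\text{RPE}$ alone
spans ±0.24 mmHg (mouse) to ±1.5 mmHg (human) in IOP, an order of
magnitude more than the observed IOP mismatch. The package therefore
reports these quantities as computed and does not tune any input toward
the published numbers.

Structural limitations, shared with the model the package implements: the
domain is a one-dimensional "average" slice (no anteroposterior or
azimuthal variation); the model is strictly steady; signalling interior to
the RPE, intracellular carriers (CRABP2), and carriers other than serum
albumin are not represented; CYP26 induction is a static saturating
bracket, not enzyme dynamics; and the human feeding scenario is not
simulated.
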