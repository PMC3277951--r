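---
title: "Robust multi-target therapy screening by structured singular value analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust multi-target therapy screening by structured singular value analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

`mudrug` screens combinatorial parameter perturbations ("therapies") of a
biochemical reaction network for their ability to restore a healthy output in
a diseased condition — robustly, under bounded uncertainty in every rate
parameter.  The bundled case study is a negative-feedback enzymatic motif: a
substrate X is converted to a product Y by an enzyme U through a complex UX,
and Y inhibits its own production.  The deterministic model is

$$
\begin{aligned}
\dot x  &= k_3 - k_1 u\, x + k_{-1}\, ux - k_{-3}\, x\\
\dot{ux} &= k_1 u\, x - k_{-1}\, ux - k_2\, ux\, \varphi(y)\\
\dot y  &= k_2\, ux\, \varphi(y) - k_4 y,
\qquad \varphi(y) = \frac{1}{1 + k_5 y},\qquad u = u_{tot} - ux,
\end{aligned}
$$

with nominal parameters $k_1=1$, $k_2=2$, $k_3=10$, $k_4=0.5$, $k_5=0.5$,
$k_{-1}=3$, $k_{-3}=1$.  The constant total enzyme concentration $u_{tot}$ is
the input: $u_{tot,h}=0.2$ is the healthy level, and $u_{tot,d}=2$ produces a
diseased, up-regulated output ($y_{ss}$ rises from $\approx 0.444$ to
$\approx 2.48$).  The model is declared in a data file
(`inst/extdata/case_study.model`), including the *placement and form of the
feedback factor*, so a different feedback structure is a data change, not a
code change.

A therapy re-parameterizes a subset of rate constants (up to 4 of the 6 that
appear in the linearized model; the zeroth-order production constant $k_3$
drops out of the Jacobian and is excluded).  The pipeline runs five stages:

1. **Performance envelope.** Healthy-condition "experimental variability" is
   emulated by Gillespie simulation; the envelope is
   $y_{ss,h} \pm f\, s_{mean}$ with $f = 1.6$ and $s_{mean}$ the
   time-averaged ensemble standard deviation.
2. **Therapy fitting.** Each of the $\sum_{i=1}^{4}\binom{6}{i} = 56$ target
   subsets is fitted by bounded least squares
   ($C = \sum_{i=1}^{20} (y_{dt}(t_i)-y_h(t_i))^2$, bounds $\pm 100\%$ of
   nominal, diseased-steady-state initial condition).
3. **Nominal screen.** A therapy passes if, started from the healthy steady
   state under the diseased input,
   $|y_{dt}(t_i)-y_h(t_i)| \le (y_{ub}-y_{lb})/2$ at all 20 test times.
4. **Robust screen.** Real $\pm 45\%$ perturbations of all six parameters
   are pulled out of the linearized deviation model into M–$\Delta$ form and
   the structured singular value $\mu_{RP}$ is bounded over frequency; the
   therapy is certified robust iff the peak upper bound is below one.
5. **Local sensitivity analysis** of the diseased steady-state output, for
   comparison with the robustness ranking.

```{r}
library(mudrug)
report <- run_pipeline(pipeline_config(seed = 1))
report
```

## Stochastic envelope: what it emulates and what it does not

The ensemble stage converts concentrations to molecule counts with a system
size $\Omega$ (molecules per concentration unit), runs the direct-method
stochastic simulation algorithm (100 runs, last-value interpolation onto 100
regular time points), and measures per-time-point mean and sample (n−1)
standard deviation.  Propensities use the standard rescaling
$k\,\Omega^{1-\text{order}}$ with falling-factorial counts, and the feedback
factor is evaluated at the output concentration $y/\Omega$; the enzyme pool
count is conserved exactly by construction.  All runs derive from one global
integer seed through a deterministic per-run substream (a scrambled 64-bit
Mersenne-Twister independent of R's RNG, so trajectories are bit-reproducible
across platforms).

The generator emulates *intrinsic* copy-number noise around the healthy
operating point.  It does not emulate extrinsic cell-to-cell variability,
measurement error, or non-stationary perturbations; an experimental envelope
would fold all of these into $s_{mean}$.  Passing tests therefore show that
the screening machinery is faithful to its inputs — not that the specific
envelope width is the biologically correct one.

**The system size is the one genuinely unidentifiable constant in the
workflow.** The published study of this motif reports its screen (56
candidate therapies, 41 nominal-pass, 5 robust-pass) without stating the
molecule-number conversion, and the envelope width scales as
$s_{mean} \propto 1/\sqrt{\Omega}$, so the absolute gate counts are not
reproducible in principle — only the procedure is.  This package fixes
$\Omega = 1000$ as its default (a cell-scale copy number for the output
species, $y_{ss,h}\Omega \approx 444$ molecules) and reports every
envelope-dependent count together with $(\Omega, f, \text{seed})$.  At this
default the envelope half-width is $\approx 0.03$ concentration units
($\approx 7\%$ of the healthy output), the nominal screen passes 23 of 56
(the input-step transient of $\approx 0.05$–$0.2$ exceeds the tight band for
many otherwise-recovering therapies), and no therapy is certified robust
under $\pm 45\%$ parameter uncertainty — at a 7% output tolerance that level
of parameter uncertainty is simply not survivable.  Reproducing the published
counts requires a substantially smaller system size — by the tested
$1/\sqrt{\Omega}$ scaling, one at which the envelope half-width becomes a
sizeable fraction of the output scale; the chain
56 → nominal → robust and all of its structural properties (gate
monotonicity, multi-target-only robustness) are invariant to this choice.
The `omega` entry of `pipeline_config()` exposes the constant.

## Therapy fitting

The 20 cost evaluation times are $t_i = i\,T/20$, $i=1..20$, over the
simulation horizon $T = 50$ time units (all case-study trajectories are well
within 0.5% of their final steady state at $T$; the horizon is
configurable).  The healthy reference $y_h(t)$ is the constant steady-state
output $y_{ss,h}$ — the healthy model started at its own steady state stays
there.  Fitting minimizes $C$ with `optim`'s bounded quasi-Newton method
(multiplier parameterization on $[0, 2]$ per target) from the nominal point
plus 4 seeded random restarts; a failed optimizer leaves the therapy at
nominal values with its cost recorded.  The landscape is multi-modal for
some subsets (e.g. $\{k_1, k_{-3}\}$ admits both mild and extreme
re-parameterizations with similar cost); restarts make the selected optimum
reproducible under the pinned seed, not globally optimal.

## Linearization and the deviation model

Each therapy's vector field is linearized analytically (Jacobians of the
declared rate laws) *around the healthy steady state* with the healthy input
level, giving deviation-variable state-space matrices $A, B, C, D$ with
$D = 0$ and $B = k_1 x_{ss}(-1, 1, 0)^T$.  Because the therapy's parameters
differ from the healthy ones, the healthy steady state is not an equilibrium
of the therapy vector field; the residual is a constant bias that the
nonlinear nominal screen already polices, so `linearize()` waives its
equilibrium check for this use (`check_equilibrium = FALSE`), and the
robustness analysis addresses the input-channel gain.  The deviation model
between a therapy branch and the healthy branch reduces to the therapy model
alone, since the healthy branch has zero input in deviation variables; the
general two-branch difference interconnection is implemented and tested all
the same.

The robust-performance criterion normalizes the deviation output by
$w_p = \frac{(y_{ub}-y_{lb})/2}{u_{tot,d}-u_{tot,h}}$, so that a weighted
closed-loop gain below one is exactly the envelope condition for the input
step of size 1.8.

## Uncertainty embedding and the mu computation

Each parameter is written $k = k_{mean}(1 + r_k \delta_k)$ with real
$|\delta_k|\le 1$ and $r_k = 0.45$, applied to the *therapy's own* fitted
values (the therapy model is the plant whose parameters fluctuate).  The
perturbed Jacobians are affinized to first order in each $\delta_k$ with the
operating point frozen at nominal: $A(\delta) \approx A_0 + \sum_k \delta_k
A_k$.  Two approximations are standing here, both deliberate: (i) the true
steady state shifts with the parameters, which a linear fractional transform
of the fixed-point linearization cannot represent; (ii) the $k_5$ dependence
through the feedback factor is rational, not affine.  Both are the price of
the standard M–$\Delta$ machinery; the sampling oracle
(`worst_case_gain_oracle()`) quantifies their effect by rebuilding the
affinized system at sampled $\delta$ and never disagreed with the certified
verdicts in testing.

Each coefficient matrix $[A_k\ B_k; C_k\ D_k]$ is rank-factorized (all six
are rank one here), the rank setting the repetition count of that
parameter's real scalar block in $\Delta$; a 1×1 complex performance block
is appended.  Closing the loop at $\delta = 0$ recovers the weighted nominal
model exactly, and closing at any sampled $\delta$ reproduces the directly
affinized system to machine precision (a tested invariant).

The $\mu$ upper bound is computed per frequency point:

* a **complex-mu D-scaling bound** $\inf_D \bar\sigma(DMD^{-1})$ (Perron
  initialization, quasi-Newton polish on $\log d$) — always valid, treats
  the real blocks as complex, hence conservative;
* a **mixed-mu D,G bound**: $\beta$ is certified when block-diagonal
  $D \succ 0$ and real diagonal $G$ (on the real blocks) exist with
  $M^\ast D M + j(GM - M^\ast G) - \beta^2 D \preceq 0$.  Feasibility is
  sought by quasi-Newton descent of the scale-normalized top eigenvalue
  (analytic eigenvalue gradients) and *certified by an exact eigenvalue
  check* at the candidate scalings; $\beta$ is then bisected.  An
  inaccurate inner search can only make the bound more conservative, never
  invalid.

The mixed refinement is applied where the complex bound exceeds a threshold
(default 0.7): below it, the cheaper conservative bound already decides the
verdict margin.  Bounds are normalized by $\bar\sigma(M)$ first, which makes
the scaling law $\mu(\alpha M) = |\alpha|\mu(M)$ exact by construction.

The **lower bound** searches the real perturbations (hypercube vertices plus
coordinate ascent) with the complex block closed analytically: $\beta$ is
achieved when some admissible $\delta$ makes the closed complex channel gain
reach $\beta$; the returned witness $\Delta$ is normalized and satisfies
$\det(I - \mu^{-1} M \Delta) \approx 0$.  The verdict, however, always uses
the *upper* bound — a therapy is robust only if certified.

Frequency handling: the published method computes $\mu_{RP}$ with a
commercial solver whose internal frequency handling is unspecified; this
package evaluates $\omega = 0$ plus 120 log-spaced points in
$[10^{-4}, 10^3]$ rad/time (the case-study dynamics live within
$10^{-1}$–$10^{1.5}$), refines the grid locally around the peak twice, and
reports the peak upper bound.  For these low-order rational responses the
sweep resolves the peak to well within the bisection tolerance
(`tol_rel = 2e-3`).

Real-mu discontinuity: purely real structures can make the lower-bound
search discontinuous in $\omega$.  The performance block keeps one complex
block in every screen here, which regularizes the search; an optional
complex "fattening" of real blocks was considered and rejected as
unnecessary for this structure.

## Local sensitivity analysis

$S_i = (k_i / y_{ss,d})\, \partial y_{ss,d} / \partial k_i$ is computed both
by central differences on the re-solved steady state (relative step
$10^{-4}$) and by the implicit-function derivative $-C A^{-1}\partial_k f$;
the two must agree to $10^{-4}$ relative (enforced with a warning, asserted
in tests).  On the case study the two largest magnitudes are $S_{k_2} > 0$
and $S_{k_4} < 0$ — the production/degradation axis of the output — which is
exactly the pair that single-target therapies would pick, and the robust
screen shows why that is insufficient: single-target therapies are never
certified robust.

## Numerical choices and degenerate inputs

* Steady states: damped Newton on the analytic Jacobian to an
  $\infty$-norm residual of $10^{-10}$, with deterministic alternative
  starts and a long-integration fallback; negative iterates are rejected.
* ODE integration: stiff solver (`lsoda`) at rtol $10^{-8}$ / atol
  $10^{-10}$, through a compiled right-hand side; the pure-R rate evaluation
  with analytic Jacobian is retained and cross-checked (agreement
  $\sim 10^{-9}$).  These tolerances keep every screening decision
  insensitive to the integrator.
* Fitting simulations that fail (extreme parameter corners) score a large
  penalty rather than aborting the optimizer.
* A parameter whose coefficient matrix is numerically zero (e.g. $r_k = 0$)
  is dropped from $\Delta$ with a warning; with an empty parametric
  $\Delta$, $\mu_{RP}$ reduces to the weighted nominal H$_\infty$ norm.
* A degenerate envelope ($s_{mean} = 0$) warns at construction and is an
  error in `performance_weight()` — the robust criterion is unsatisfiable.
* Problem sizes used by the test-suite replications: 100-run ensembles for
  envelopes, 40-run ensembles for noise-scaling checks, 200 runs at
  $\Omega = 10^4$ for the thermodynamic-limit check, 50 random matrices for
  the mu-bound property checks, 200-sample oracles.

## Known limitations

* The affine uncertainty embedding freezes the operating point; large
  simultaneous parameter excursions are represented only to first order.
* MIMO performance blocks are carried in the data model but untested beyond
  unit level; the lower-bound search supports at most one complex block.
* The fitted therapies are local least-squares optima under a pinned
  multistart; a global optimizer could select different representatives of
  the same target set.
* Gate counts inherit the unidentifiable system size $\Omega$ as described
  above; comparisons across studies must pin $(\Omega, f, r_k, T)$.
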