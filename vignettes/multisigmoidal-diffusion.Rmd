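---
title: "Inference and first-passage times for the multisigmoidal logistic diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference and first-passage times for the multisigmoidal logistic diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msldiff)
```

## The model

Many growth phenomena — fruit ripening, epidemic waves, software fault
counts — saturate only after several distinct stages. The classical
logistic curve has a single inflection; `msldiff` works with its
*multisigmoidal* generalisation, in which the exponent of the logistic
function is a polynomial
$$Q_\beta(t) = \sum_{i=1}^{p} \beta_i t^i, \qquad \beta_p > 0,$$
with derivative $P_\beta = Q_\beta'$. The curve
$$l_m(t) = l_0\,\frac{\eta + e^{-Q_\beta(t_0)}}{\eta + e^{-Q_\beta(t)}}$$
solves $l_m'(t) = h_\theta(t)\, l_m(t)$ with relative growth rate
$h_\theta(t) = P_\beta(t)e^{-Q_\beta(t)} / (\eta + e^{-Q_\beta(t)})$,
may rise and fall several times, and saturates at the carrying capacity
$l_0(\eta + e^{-Q_\beta(t_0)})/\eta$, which — unlike in the classical
model — depends on the initial level $l_0$.

The stochastic version is the Itô diffusion
$$dX(t) = h_\theta(t)X(t)\,dt + \sigma X(t)\,dW(t),$$
a non-homogeneous *lognormal* process: with
$$H_\xi(s,t) = \log\frac{\eta + e^{-Q_\beta(s)}}{\eta + e^{-Q_\beta(t)}}
  - \frac{\sigma^2}{2}(t-s),$$
the conditional law of $X(t)$ given $X(s) = z$ is lognormal with
log-mean $\log z + H_\xi(s,t)$ and log-variance $\sigma^2(t-s)$, and the
mean $E[X(t)]$ is again a multisigmoidal logistic curve. The initial
state is either degenerate at $x_0$ or lognormal
$\Lambda(\mu_1, \sigma_1^2)$. Everything the package does rests on these
closed forms; no stochastic integral is ever discretised.

Parameters and their roles:

* `eta` ($\eta > 0$, dimensionless): sets the carrying capacity
  $C/\eta$; large $\eta$ means early saturation.
* `beta` ($\beta_1..\beta_p$, units $t^{-1}..t^{-p}$): shape of the
  growth phases; the sign pattern of $P_\beta$ creates the successive
  accelerations. $\beta_p > 0$ is required for saturation and is
  enforced at construction.
* `sigma2` ($\sigma^2$, units $t^{-1}$): squared multiplicative noise
  intensity. The study designs use $\sigma \in \{0.01, 0.05\}$.

Times are plain numbers on whatever clock the data use; all internal
formulas work on absolute times, so a panel need not start at $t = 0$
(the study panels do).

## What the simulator emulates

`simulate_paths()` draws exact lognormal transitions along the supplied
grid — no Euler bias — with one master seed and per-path substreams, so
path $i$ is reproducible regardless of how many paths are drawn.
`make_case_panel()` reproduces the simulation study design: 32
parameter combinations crossing $\beta_1 \in \{0.1, 0.5\}$,
$\beta_2 \in \{-0.009, -0.007\}$, $\beta_3 \in \{0.0002, 0.0003\}$,
$\eta \in \{e^{-1}, e^{-3}\}$, $\sigma \in \{0.01, 0.05\}$, each with
$x_0 = 5$ on an equidistant grid of 501 points over $[0, 50]$ and 200
paths by default.

The generator produces exactly the model's law. Real panels (case
counts, growth measurements) carry features it does not emulate —
observation error on top of process noise, reporting artefacts,
non-lognormal shocks, grids that differ across units. Passing tests
therefore demonstrate correctness of the machinery under the model, not
robustness to misspecification.

## Maximum likelihood

After the change of variables
$v_{ij} = \Delta_{ij}^{-1/2}\log(x_{i,j+1}/x_{ij})$ the log-likelihood
of $d$ paths separates into an initial-state part, maximised in closed
form by `alpha_mle()` (mean of $\log x_{i1}$ and its mean squared
deviation with divisor $d$), and the reduced part
$$\tilde L(\xi) = -\frac{n}{2}\log\sigma^2 -
  \frac{Z_1 + \Phi_\xi - 2\Gamma_\xi}{2\sigma^2},$$
which `reduced_log_likelihood()` evaluates from a table of *unique*
steps — on a common grid all $d$ paths share the same step set, making
one evaluation $O(N)$ instead of $O(dN)$, which is what keeps simulated
annealing affordable.

Two fitting routes are provided.

**Newton–Raphson** (`fit_newton_raphson()`) solves the $p+2$ score
equations (`system_residuals()`). Design choices:

* Jacobian by central finite differences with relative step $10^{-6}$
  per coordinate (the score is available in closed form, its derivative
  is not).
* Damped steps: halve up to 50 times until the residual sup-norm
  decreases and $\eta, \sigma^2$ stay positive; stop at
  $\|F\|_\infty < 10^{-10}$ or step $< 10^{-12}$, at most 200
  iterations. Non-convergence is reported via `converged = FALSE`,
  never silently.
* A profiled variant substitutes the closed-form
  $\sigma^2(\theta)$ (`sigma2_given_theta()`, the only admissible root
  of the variance equation) each iteration; it agrees with the full
  solve on well-posed problems and conditions better near degeneracy.
* Starting values: regress $-\log(m_N/m_j - 1)$ on $(t_j, .., t_j^p)$,
  treating the last sample mean $m_N$ as the carrying capacity, and
  read $\sigma^2$ off a through-the-origin regression of
  $2\log(m_j/m_j^g) - \sigma_0^2$ on $t_j - t_0$. Pairs with
  $m_j \ge m_N$ are dropped, and also pairs with
  $m_N/m_j - 1 \le 0.02$: on the plateau the response diverges
  logarithmically and a handful of terminal points would otherwise
  dominate the regression. The 2% guard is the point where, in the
  study designs, mean-level noise becomes comparable to the distance to
  the plateau; it is a fixed numerical guard, not a tuning knob.

**Simulated annealing** (`fit_simulated_annealing()`) minimises
$-\tilde L$ over a bounded box (`parameter_bounds()`): $\eta$ between
the extreme per-path endpoint ratios $(x_{i,n_i}/x_{i,1}-1)^{-1}$,
$\beta$ inside 0.999-level intervals of the bounds regression (same
plateau guard), $\sigma^2 \in (0, 0.01)$. Cooling is geometric
($\gamma = 0.95$), chains of $L = 50$ moves per stage, initial
temperature $-\overline{\Delta f^+}/\log 0.9$ from a 100-step pilot
walk, stop at $T \le 10^{-7}$, 1000 stages, or $L$ consecutive accepted
values within $10^{-12}$ (floating-point "equality"). Proposals are
uniform in a box of half-width 0.1 interval-lengths, clipped to the
bounds — clipping rather than rejecting keeps every move useful. Ten
independent runs are averaged (a `best_of` switch returns the best run;
an optional single Newton polish is off by default). Note the box is a
*search* region, not a confidence set: its regression intervals inherit
the bias of the $m_N$-as-capacity approximation, so the true parameters
can sit just outside it while the constrained optimum remains within a
few percent of them.

## Uncertainty

`fisher_information()` assembles the $(p+2)\times(p+2)$ information
matrix from the per-step gradients of the conditional log-mean
$H_\xi$ — computed analytically — with corner entry
$n/(2\sigma^2) - Z_3/4$ and an overall $1/\sigma^2$ factor.
`asymptotic_ci()` inverts it at the estimate (plug-in convention;
pseudo-inverse with a warning past condition number $10^{12}$ — raw
polynomial bases over short windows are nearly collinear) and
`delta_method_ci()` propagates to smooth parameter functions. The
initial-law estimates have exact small-sample laws: normal for
$\hat\mu_1$, chi-square ($d-1$) pivot for $\hat\sigma_1^2$
(`initial_law_ci()`). In repeated-sampling checks on study panels the
95% intervals for $\beta_1$ cover at about the nominal rate.

## Degree selection

`select_degree()` fits each candidate degree and tabulates RAE, AIC,
BIC and the resistor-average distance $D_{RA}$ (harmonic mean of the
two directed Kullback–Leibler divergences between per-time lognormal
laws, against the sample law or the known generating law). The decision
rule is deterministic: BIC first, then AIC, then median $D_{RA}$, then
the smallest degree. RAE is reported but never decisive — it improves
essentially monotonically with degree. On cubic study panels the rule
returns $p = 3$ reliably; the distance measures separate underfitting
sharply but rank converged overfits within noise of the true degree,
which is why they only break ties.

## First-passage times

For the boundary $S > x_0$ the hitting time of $X$ equals the hitting
time of a standard Wiener process through the moving boundary
$b(u) = [\log(S/x_0) - H_\xi(t_0, t_0+u)]/\sigma$, because
$\log X(t)$ is a deterministically shifted Brownian motion. The FPT
density then solves a second-kind Volterra equation with the classical
Wiener kernel
$$\Psi(t \mid y, \tau) = \tfrac12\Big[b'(t) - \frac{b(t) - y}{t - \tau}\Big]
 \frac{\varphi\big((b(t)-y)/\sqrt{t-\tau}\big)}{\sqrt{t-\tau}},$$
solved by the composite trapezoid recursion (the diagonal kernel value
vanishes). The reduction to the Wiener kernel was cross-checked two
independent ways: against the closed-form inverse-Gaussian density in
the constant-boundary case, and against a 20,000-path Monte-Carlo
crossing experiment (Kolmogorov–Smirnov distance below 0.005 in the
worked example).

The quadratic-cost recursion runs only where the mass lives. The FPTL
function $1 - \Phi(C(t))$ — the probability that $X(t)$ already exceeds
$S$ — localises the window: it opens where FPTL first exceeds
$\varepsilon = 10^{-4}$ and closes where FPTL has fallen back below
$\varepsilon \cdot \max$ after its maximum. When the boundary sits
below the carrying capacity that decay happens on the very slow
$\sigma^{-2}$ time scale, long after the FPT mass is exhausted, so the
window is then closed one growth-interval width beyond the FPTL
maximum ($2t_{\max} - t_{\text{lower}}$): the mass concentrates in the
FPTL growth phase, which is the premise of the localisation idea.
Defaults: 4000 grid intervals over the window; halving the step moves
the worked example's summaries by under $10^{-5}$.

Summaries (`fpt_summaries()`) are taken from the *normalised* density
(refused below mass 0.99): trapezoid moments for mean and standard
deviation, a three-point parabolic fit around the grid argmax for the
mode, linear interpolation of the cumulative for deciles. One caveat
worth knowing: when $X(t) \to 0$ almost surely at long times, the FPT
is defective — a small probability of never crossing — so the *second*
moment over an ever-longer horizon keeps drifting while mode and
deciles are completely stable. Quote the standard deviation together
with the window it was computed on.

## Numerical choices, in one place

* $\log(\eta + e^{-Q})$ via log-sum-exp everywhere: transiently
  decreasing $Q$ makes $e^{-Q}$ overflow otherwise.
* Polynomials by Horner's scheme; inflection points by a 2000-point
  sign scan refined with bisection to $10^{-10}$ (the inflection
  equation has no closed form beyond $p = 1$).
* Degenerate initial samples (all paths from one $x_0$) have
  $\hat\sigma_1^2 = 0$; the likelihood then counts only the transition
  factors, so information criteria remain finite and comparable across
  degrees.
* Tiny negative density values from the trapezoid recursion (round-off)
  are clipped at zero; a drop below $-10^{-9}$ raises a warning
  instead.
* Tie-breaks in `select_degree()` and the clipping rule in annealing
  are stated above; both are deterministic.

## Problem sizes used by the test suite

The packaged checks run the worked FPT example at 4000/8000 grid
intervals, parameter recovery on 50-path, 201-point panels, coverage on
200 replicate 50-path panels, degree selection on a 200-path, 501-point
panel, and the simulate–fit–FPT chain on 50 paths at step 0.1 — sizes
chosen so the whole suite completes in a few minutes while each check
retains clear statistical resolution.

## Limitations

* Only constant boundaries with $S > x_0$; time-varying boundaries are
  an extension point of the kernel, downward crossings are not handled.
* The annealing box inherits regression bias (see above); treat it as a
  heuristic search region.
* Asymptotic intervals rely on the plug-in information matrix; no
  bootstrap or profile-likelihood alternatives are provided.
* Raw-power polynomial bases become ill-conditioned beyond $p \approx
  6$ on long windows; fits there may legitimately fail and are reported
  as such.
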