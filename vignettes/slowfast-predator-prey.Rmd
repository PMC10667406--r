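---
title: "Methods: stability and bifurcations of the discrete slow-fast ratio-dependent predator-prey map"
author: "slowfastpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability and bifurcations of the discrete slow-fast ratio-dependent predator-prey map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowfastpp)
```

## The model and its assumptions

The package studies the planar map

$$
x_{n+1} = x_n\, e^{\,1 - x_n - a y_n/(x_n+y_n)}, \qquad
y_{n+1} = y_n\, e^{\,\epsilon\,(x_n/(x_n+y_n) - \delta)},
$$

a discrete-time predator–prey model in which the trophic interaction is
*ratio-dependent*: the per-capita predation pressure depends on the prey
share $x/(x+y)$ rather than on prey density alone, capturing predator
interference when prey are scarce.  The map arises from a continuous
slow–fast system — prey reproducing on the fast time scale, predators on a
slower one, with $\epsilon \in (0,1)$ the ratio of the two intrinsic rates —
by semidiscretization: the state-dependent per-capita rates are frozen at
integer times (piecewise-constant arguments) and the resulting linear
equations are integrated exactly over each unit interval.  Two consequences
matter in practice:

* the map is *positivity-preserving by construction* (each update multiplies
  by an exponential), so no step-size artifacts of Euler-type schemes occur
  and there is no step-size parameter at all;
* the state $(0,0)$ is a removable singularity of the ratio terms.  We adopt
  the continuity convention `map_step(c(0,0)) = c(0,0)` so the extinction
  equilibrium E0 is representable; the Jacobian is *not* defined there and
  `map_jacobian` refuses the origin — E0's saddle character is established
  by limit analysis instead (prey invade along the x-axis, predators die out
  along the y-axis).

Parameters, all dimensionless: `a` (predation intensity, $>0$), `delta`
(predator mortality over maximal predator growth rate, $>0$), `epsilon`
(time-scale ratio, constrained to $(0,1)$ because prey are assumed the
faster population).  `model_params()` validates all three at construction.

Fixed points: $E_0=(0,0)$ and $E_1=(1,0)$ always; the coexistence point
$E_2 = \left(1-a+a\delta,\; (1-a+a\delta)(1-\delta)/\delta\right)$ exists
iff $\max\{0,(a-1)/a\} < \delta < 1$.  Both exponents vanish identically at
$E_2$, which is why `fixed_points()` can promise a fixed-point residual
below $10^{-12}$.

## Stability classification

Stability of a planar fixed point is read off the characteristic polynomial
$F(\lambda)=\lambda^2 - p\lambda + q$ of its Jacobian.
`classify_quadratic_roots()` implements the standard Jury/Schur–Cohn-type
case analysis for $F(\lambda)=\lambda^2+B\lambda+C$ **purely from signs** of
$F(1)$, $F(-1)$, $C-1$ and $B\mp2$ — it never solves for roots.  The twelve
case labels cover both roots inside/outside the unit circle, the split
cases (distinguishing whether the outside root lies beyond $+1$ or below
$-1$), roots at $\pm1$, and the conjugate pair on the unit circle.

Equalities such as $F(1)=0$ are measure-zero, so exact floating-point
comparison is meaningless.  All decisive quantities are compared at the
relative tolerance `tol * max(1, |F(1)|, |F(-1)|, |C|)` with `tol = 1e-9`;
within tolerance the *boundary* label is preferred and `boundary_flag` is
raised.  The test suite checks the classifier against a brute-force oracle
(roots via `polyroot`, then moduli) on $10^4$ random coefficient pairs,
restricted to non-boundary cases where the oracle is trustworthy.

For the map itself:

* **E0** is always a saddle.
* **E1** has eigenvalues $0$ and $e^{\epsilon(1-\delta)}$: a saddle for
  $\delta<1$, non-hyperbolic at $\delta=1$, a stable node for $\delta>1$.
* **E2** is governed by the determinant identity
  $q \gtrless 1 \iff \epsilon \lessgtr \epsilon_0$ with
  $$\epsilon_0 = \frac{a(1-\delta^2)-1}{a\,\delta\,(1-\delta)^2},$$
  so `classify_fixed_point()` reduces the whole case analysis to comparing
  $\epsilon$ with $\epsilon_0$: source below, sink above, non-hyperbolic at
  the critical value.  $\epsilon_0$ is returned *raw* even outside $(0,1)$;
  its sign cases encode the regimes ($\epsilon_0\le 0$ iff
  $\delta^2 \ge (a-1)/a$, covering both $a\le1$ and large $\delta$, where E2
  is a sink for every admissible $\epsilon$; $\epsilon_0\ge1$ iff
  $\delta \le \delta^*(a)$, where E2 is a source).

$\delta^*(a)$ is the unique root of
$f(\delta)=\delta^3-\delta^2+\delta-(a-1)/a$ on
$((a-1)/a, \sqrt{(a-1)/a})$ for $a>1$; uniqueness follows from
$f'(\delta)=3\delta^2-2\delta+1>0$.  `delta_star()` brackets the root with
`stats::uniroot` (the bracket endpoints have provably opposite signs) and
polishes with Newton steps until $|f|\le 10^{-12}$.

At the shared endpoints of the closed classification intervals
($\delta=\delta^*$, $\delta=\sqrt{(a-1)/a}$, $\epsilon=\epsilon_0$) the
verdict is genuinely ambiguous at working precision; the implementation
reports `non_hyperbolic` with `boundary_flag` rather than guessing a side.

## Exact symbolic differentiation

Every Taylor coefficient in the two bifurcation analyses is obtained by
repeated application of base R's symbolic derivative `D()` to quoted map
expressions, evaluated at the expansion point (`R/taylor-engine.R`).
Coefficient tables store *series* coefficients — partial derivatives divided
by factorials — consistently throughout; the documented partial derivatives
(e.g. $\bar F_{XX}=2e_{20}$) are recovered from them by the matching
factorials.  Nothing is transcribed from printed coefficient tables, which
in this model family circulate with mixed conventions; the closed forms
appear only in tests, as oracles.  The tests back the symbolic route with
two independent numerical routes: tensor central-difference stencils with
double Richardson extrapolation for all series coefficients, and a Fourier
circle-sampling extraction of the complex normal-form coefficients.

## Transcritical bifurcation at E1

The critical mortality is fixed at $\delta_0 = 1$.  Three independent facts
force this value: the linear coefficient of $v$ in the extended map at E1
equals $e^{\epsilon(1-\delta_0)}$ and must be $1$; E1 is non-hyperbolic
precisely at $\delta=1$; and E2 collides with E1 as $\delta\to1^-$ (its
predator coordinate vanishes).  A formula of the shape $r/(a+1)$ sometimes
quoted for this critical value contains a rate symbol that does not exist in
the dimensionless map and is treated as an erratum.

The analysis extends the shifted map by the frozen perturbation
$\delta^\ast=\delta-\delta_0$ as a third state variable, applies the linear
change of variables $T=\begin{pmatrix}1&-a&0\\0&1&0\\0&0&1\end{pmatrix}$
aligning $X$ with the eigenvalue-$0$ direction and $Y$ with the center
direction, and solves the quadratic coefficient-matching equations of the
invariance condition for the center-manifold graph
$X = h_{20}Y^2 + h_{11}Y\delta^\ast + h_{02}\delta^{\ast2}$.
`center_manifold_e1()` reports *polynomial* coefficients of this graph; for
this model

$$h_{20} = a - a^2 - a\epsilon,\qquad h_{11} = -a\epsilon,\qquad h_{02}=0,$$

computed symbolically and verified by an invariance-residual oracle: a point
on the quadratic graph maps back onto the graph with residual $O(Y^3)$,
which pins the quadratic coefficient uniquely (any perturbed coefficient
leaves an $O(Y^2)$ residual).  The restricted one-dimensional map
$f(Y,\delta^\ast)$ then satisfies the transcritical conditions

$$f(0,0)=0,\quad f_Y=1,\quad f_{\delta^\ast}=0,\quad
  f_{Y\delta^\ast}=-\epsilon\neq0,\quad f_{YY}=-2\epsilon\neq0$$

for every $\epsilon\in(0,1)$: the predator-free and coexistence branches
exchange stability as mortality crosses $1$.  Only these five quantities
are the testable surface of the analysis; the intermediate coefficient
tables are implementation detail.  A dynamical cross-check fits a quadratic
to one-step images of points seeded on the manifold and recovers $f_{YY}$
to within 1%.

## Neimark–Sacker bifurcation at E2

On $S_{E_+}=\{a>1,\ \delta^*(a)<\delta<\sqrt{(a-1)/a},\ \epsilon\in(0,1)\}$
the characteristic polynomial along the path
$\epsilon=\epsilon_0+\epsilon^\ast$ has $q(0)=1$ and $p(0)^2-4q(0)<0$: a
conjugate pair $\lambda_{1,2}=\alpha_1\pm i\alpha_2$ sits on the unit circle
at criticality and crosses it with speed

$$\left.\frac{d|\lambda|}{d\epsilon^\ast}\right|_0
  = -\tfrac12 a\delta(1-\delta)^2 \;<\;0 .$$

The sign matters: the pair crosses *inward* as $\epsilon$ increases, i.e.
E2 is unstable below $\epsilon_0$ and stable above — consistent with the
sink/source classification.  `eigen_path()` refuses parameters outside
$S_{E_+}$ with a message naming the violated inequality.

The normal form is computed with $\epsilon$ pinned to $\epsilon_0$ (a
different user-supplied $\epsilon$ is ignored with a warning; the normal
form is meaningless away from criticality).  The pipeline: third-order
symbolic expansion of the shifted map; the linear change of variables
$T=\begin{pmatrix}c_{01}&0\\ \alpha_1-c_{10}&-\alpha_2\end{pmatrix}$
bringing the linear part to the rotation–scaling
$\begin{pmatrix}\alpha_1&-\alpha_2\\ \alpha_2&\alpha_1\end{pmatrix}$
(the transform requires $\alpha_2\neq0$, guaranteed in $S_{E_+}$); the
complex resonance coefficients $\zeta_{20},\zeta_{11},\zeta_{02},\zeta_{21}$
— exactly the $z^j\bar z^k$ series coefficients of
$\bar F + i\bar G$ in $z = X+iY$ — and the discriminant

$$L = -\mathrm{Re}\!\left(\frac{(1-2\lambda_1)\lambda_2^2}{1-\lambda_1}
      \zeta_{20}\zeta_{11}\right)
      - \tfrac12|\zeta_{11}|^2 - |\zeta_{02}|^2
      + \mathrm{Re}(\lambda_2\zeta_{21}).$$

**Direction convention.**  Because the crossing is inward, a negative $L$
(supercritical on the unstable side) places the *attracting* invariant
closed curve at $\epsilon<\epsilon_0$, where E2 is a source; a positive $L$
would place a repelling curve at $\epsilon>\epsilon_0$.  The opposite-side
clause sometimes quoted for this family (curve for $\epsilon>\epsilon_0$
when $L<0$) contradicts the stability classification and the simulated
phase portraits; `ns_report()` records the comparison in
`paper_statement_agrees` instead of adopting it.  For the canonical
configuration $a=16/11$, $\delta=1/2$ the package computes
$L\approx-0.0177<0$, and simulation confirms the attracting curve at
$\epsilon=0.45<\epsilon_0$ and convergence to E2 at $\epsilon=0.55$.

A verdict of `degenerate` is returned when
$|L| \le 10^{-10}(1+|\zeta_{20}\zeta_{11}|)$ — a scale-aware zero test; no
parameter point exercised by the suite comes near it.  Strong resonances
($\lambda^m=1$, $m\le4$) are *flagged* by `nondegeneracy_check()` at
tolerance $10^{-9}$ on $|\lambda^m-1|$, not unfolded.

## Numerical dynamics: design choices

**Orbits.**  Plain iteration with a divergence guard at $10^{12}$ per
coordinate (the exponential form cannot actually diverge from admissible
states, but the guard turns hypothetical overflow into an informative error
with the step index).  Everything is deterministic; identical inputs give
bit-identical orbits.

**Lyapunov exponents.**  The Benettin tangent-frame method: push an
orthonormal 2-frame through the Jacobian, re-orthonormalize by Gram–Schmidt
every step, accumulate log norms.  Defaults `n = 1e5`, `n_discard = 1000`
resolve the structures studied here at desk runtime.  Two properties anchor
the estimator in tests: the sum of the exponents equals the orbit average of
$\log|\det J|$ (an algebraic identity of the scheme), and on a hyperbolic
fixed point the exponents equal the log eigenvalue moduli.  The latter holds
exactly only in the limit: at finite $n$ the estimate carries an intrinsic
$O(1/n)$ bias, $\log$ of the frame–eigenvector alignment constant, divided
by $n$.  The tests therefore check the raw value coarsely and the two-$n$
Richardson-extrapolated value ($n$ and $2n$) to $10^{-8}$.

**Bifurcation sweeps and onset detection.**  For each $\epsilon$ on a grid
the sweep stores post-transient prey samples (the vertical slices of the
bifurcation diagram) and optionally the maximal exponent.
`ns_onset_estimate()` reports the largest grid $\epsilon$ whose sample
spread exceeds $10^{-3}$.  Near criticality the contraction rate vanishes
linearly in $\epsilon-\epsilon_0$, so the onset test seeds orbits at
$E_2+(0.01,0.01)$ and discards 6000 iterates: with those sizes the residual
transient at $\epsilon_0+0.004$ is already below the spread threshold, and
across the sampled region the detected onset lands within $\pm0.01$ of the
closed-form $\epsilon_0$ (the acceptance tests require $\pm0.02$).

**Underflow extinction.**  For small $\epsilon$ (roughly below $0.36$ in
the canonical configuration) the invariant curve grows so large that the
predator density visits values below the double-precision underflow
threshold; once a coordinate underflows to exactly zero the orbit is
absorbed by the corresponding axis dynamics.  This is a genuine property of
the map in floating-point arithmetic, not a bug; sweep slices in that regime
collapse to the predator-free state.  Jacobian entries are evaluated through
the shares $x/(x+y)$, $y/(x+y)$ rather than $xy/(x+y)^2$ so they stay finite
down to the underflow boundary.

**The chaos question.**  In the literal parameterization $a=1.4$ the sweep
at small $\epsilon$ (grid $0.1912$–$0.2092$, step $0.0015$, $n=3\times10^4$
accumulation steps after $3\times10^3$ discarded) shows a window of positive
maximal Lyapunov exponents around $\epsilon\approx0.192$, just above the
parameter value where orbits are absorbed by extinction.  The measured
exponents are small ($\sim10^{-4}$ at these problem sizes) and shrink as the
accumulation length grows, so the window is reported as a qualitative
feature at the package's default resolution — consistent with an attractor
at the edge between quasiperiodicity, weak phase locking and chaos — rather
than as evidence of robust chaos.  Fixed-size claims about window endpoints
are grid- and transient-dependent and are deliberately not made.

## The two parameterizations

The simulation literature for this model quotes, for $\delta=1/2$, the
predation intensity $a=1.4$ *together with* the coexistence point
$(0.2728, 0.2728)$ and critical value $\epsilon_0=0.5$ — a mutually
inconsistent triple, since $a=1.4$ gives $E_2=(0.3,0.3)$ and
$\epsilon_0=2/7$, while $E_2\approx(0.2728,0.2728)$ and $\epsilon_0=0.5$
both correspond to $a=16/11\approx1.4545$.  The package ships both readings
as scenario files — `fig1_canonical.yaml` ($a=16/11$; used wherever the
critical value $0.5$ or the fixed point $0.2728$ matters) and
`fig1_literal.yaml` ($a=1.4$; used for the small-$\epsilon$ chaos window) —
and documents rather than resolves the inconsistency.

## What the bundled experiments do and do not show

The scenarios and tests exercise the map itself, so "synthetic data" here
means *simulated orbits of the exact model*, not noisy observations.
Passing tests demonstrate internal consistency of theory and simulation
(classification matches eigenvalues; the sweep onset matches $\epsilon_0$;
the curve side matches the sign of $L$), not that any real predator–prey
time series follows this map: no demographic or observation noise, no
immigration, no spatial structure, and one-generation synchrony of both
populations are all baked into the model class.

## Known limitations

* No continuation of the invariant curve, no rotation-number or
  Arnold-tongue analysis; strong resonances are only flagged.
* The normal form is evaluated at criticality only; no parameter-dependent
  normal-form coefficients.
* The Lyapunov estimator's $O(1/n)$ finite-size bias means exponents within
  about $10^{-4}$ of zero cannot be signed reliably at default sizes.
* Center-manifold and normal-form coefficients are exact symbolic
  evaluations at floating-point parameters; no interval arithmetic or
  rigorous validation is attempted.
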