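---
title: "Series solutions of fractional compartmental models by natural transform decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Series solutions of fractional compartmental models by natural transform decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntdm)
library(dplyr)
```

## The problem

Compartmental models of behavioural epidemics — here, smoking — are
increasingly written with a *fractional* time derivative
$D^\mu_\tau$ of order $\mu \in (0, 1]$ in place of $d/d\tau$, because the
memory built into fractional kernels captures hereditary effects that
integer-order models miss. The price is that standard ODE machinery no
longer applies directly, and the choice of fractional kernel (singular
power law vs. nonsingular exponential or Mittag-Leffler kernels) becomes
part of the model.

The **natural transform decomposition method** (NTDM) produces
semi-analytic series solutions for such systems. The natural transform — a
two-parameter generalisation of the Laplace and Sumudu transforms — turns
each fractional derivative into an algebraic factor; Adomian decomposition
expands each state as $x_i = \sum_k x_{i,k}$ and each bilinear
nonlinearity as a convolution of levels; inverting the transform level by
level gives an explicit recursion. The crucial observation exploited by
this package is that the transform never needs to be computed: for each
supported kernel, the combined step "multiply by the kernel factor in the
transform domain and invert" acts *term-wise on monomials*
$c\,\tau^p$, so the whole method closes over finite sums of monomials
$c\,\tau^{a + b\mu}$.

## Exact series algebra

A `frac_series` stores terms keyed by the *exact integer pair* $(a, b)$,
with numeric exponent $a + b\mu$. Exponent arithmetic (addition under
products, $b \mapsto b+1$ or $a \mapsto a+1$ under the operators) is
integer arithmetic; only the coefficients are floating point. Two design
points matter:

* **No floating exponent keys.** At special orders (e.g. $\mu = 0.5$) the
  values $a + b\mu$ of distinct pairs collide; exact pairs keep
  $\tau$-powers and $\tau^\mu$-powers apart, so Caputo-type terms (which
  shift $b$) and Caputo-Fabrizio terms (which shift $a$) coexist without
  spurious merges.
* **Canonical form.** Duplicate keys are merged, coefficients exactly
  equal to zero are dropped, and terms are stored sorted by $(a, b)$;
  canonicalisation is idempotent. Evaluation sums terms in ascending
  numeric exponent (ties broken by $(b, a)$), making every number the
  package prints bit-reproducible. No magnitude-based pruning is applied:
  truncation orders are small (default $K = 2$, supported up to roughly
  10), and term counts grow slowly for bilinear systems, so exactness is
  cheap.

Gamma-function factors produced by fractional integration are evaluated
through `lgamma()` and absorbed into the coefficients; for the exponents
that occur ($p \ge 0$) both gamma arguments are $\ge 1$, so the ratio
$\Gamma(p+1)/\Gamma(p+\mu+1)$ is well conditioned and double precision
carries far more accuracy than the four to six significant figures of any
tabulated solution.

## The three kernel operators

Writing $p = a + b\mu$ for a term $c\,\tau^p$, one NTDM level applies:

| kernel | action on $c\,\tau^p$ |
|---|---|
| Caputo | $c\,\frac{\Gamma(p+1)}{\Gamma(p+\mu+1)}\,\tau^{p+\mu}$ (the order-$\mu$ Riemann-Liouville integral) |
| Caputo-Fabrizio (CF) | $(1-\mu)\,c\,\tau^p + \frac{\mu\,c}{p+1}\,\tau^{p+1}$ |
| Atangana-Baleanu-Caputo (ABC) | $\frac{1}{B(\mu)}\left[(1-\mu)\,c\,\tau^p + c\,\mu\frac{\Gamma(p+1)}{\Gamma(p+\mu+1)}\,\tau^{p+\mu}\right]$ |

At $\mu = 1$ all three reduce to one classical integration, and the three
solutions coincide — a degeneracy the test suite checks to $10^{-10}$.
The ABC normalization $B(\mu)$ is a free function in the kernel's
definition, pinned only by $B(0) = B(1) = 1$; the package defaults to
$B(\mu) \equiv 1$, the choice under which the ABC components carry no
extra prefactor and the package's reference tables are defined. It is
exposed in `kernel_spec()` for users who need a different normalization.

The initial-condition subtraction that the transform introduces is
realised by *seeding* the recursion (level 0 equals the initial state),
not inside the operators; the operators are therefore plain linear maps
on series.

## The recursion and the source-term convention

For a system $D^\mu_\tau x_i = \kappa_i + \sum_j L_{ij} x_j +
\sum c\,x_p x_q$, level $k+1$ is

$$x_{i,k+1} = \mathcal{I}_\mu\Big[\kappa_i + \textstyle\sum_j L_{ij}
x_{j,k} + \sum c\,A_k\Big], \qquad
A_k = \textstyle\sum_{j=0}^{k} x_{p,j}\,x_{q,k-j},$$

with $\mathcal{I}_\mu$ the kernel operator. One genuinely open convention
is where the constant source $\kappa_i$ enters:

* `source_mode = "every_level"` (default): $\kappa_i$ appears in every
  level's right-hand side, exactly as written above. This is the
  convention under which this model family's reference tabulations are
  produced, and the package's table-reproduction functions rely on it.
  Its cost is that the truncated sum is *not* a Taylor polynomial — each
  level past the first re-injects a $\kappa_i$-proportional term (e.g.
  $\alpha\tau^\mu/\Gamma(1+\mu)$), leaving an $O(\tau^\mu)$ residual that
  does not shrink with $K$ at fixed $\tau$.
* `source_mode = "first_level"`: the textbook Adomian convention, source
  only at level 0. At $\mu = 1$ the $K$-truncated sum is then exactly the
  degree-$K$ Maclaurin polynomial of the classical solution, and the
  remainder against a Runge-Kutta reference shrinks like $\tau^{K+1}$
  (the shipped checks verify a log-log slope within $0.3$ of $3$ for
  $K = 2$); at fractional order the remainder against a fractional
  Adams-Bashforth-Moulton reference shrinks like $\tau^{(K+1)\mu}$
  (slope within $0.5$ of $2.4$ at $\mu = 0.8$).

Both conventions agree at levels 0 and 1 and diverge from level 2 on.
The truncation-order tests run under `"first_level"`, where the remainder
theory applies; everything quantitative about the reference tables uses
the default.

Components are always *generated by the recursion*; no closed-form
component is transcribed anywhere in the package. For this model's
defaults the recursion reproduces the tabulated values within the
$2\times10^{-3}$ absolute tolerance the shipped checks apply (covering
4-decimal rounding of the tabulated cells) — except one column of the
classical-order table whose printed values are mutually inconsistent
with the others (see *Limitations*).

## The smoking model

The model compartments are potential smokers $V$, occasional smokers $G$,
smokers $T$, temporary quitters $O$ and permanent quitters $W$:

$$\begin{aligned}
D^\mu_\tau V &= \alpha - \epsilon V T - \vartheta V, &
D^\mu_\tau G &= \epsilon V T - (\varepsilon_1 + \vartheta) G, &
D^\mu_\tau T &= \varepsilon_1 G + \varepsilon_2 T O - (\vartheta + \rho) T,
\\
D^\mu_\tau O &= -\varepsilon_2 T O - \vartheta O + \rho(1-\sigma) T, &
D^\mu_\tau W &= \sigma\rho T - \vartheta W.
\end{aligned}$$

Default rates (per unit time): recruitment $\alpha = 1$, contact
$\epsilon = 0.14$, natural death $\vartheta = 0.05$, cessation
$\rho = 0.8$, permanent-quit fraction $\sigma = 0.1$ (dimensionless),
occasional-to-regular transition $\varepsilon_1 = 0.002$, relapse contact
$\varepsilon_2 = 0.0025$; initial counts $(V, G, T, O, W)(0) =
(40, 10, 20, 10, 5)$. Summing the equations cancels every transfer term,
leaving $D^\mu_\tau N = \alpha - \vartheta N$ for the total $N$: the
solver must (and does, coefficient-wise to $10^{-10}$) reproduce the
scalar solution of that equation as the compartment-sum of its levels,
for every kernel — a strong structural check on the recursion.

```{r}
sol <- ntdm_solve(smoking_system(), kernel_spec("caputo", mu = 1), K = 2)
tidy(sol) |> filter(tau == 0.1)
```

### Reproduction number, stability, sensitivity

The next-generation construction gives the single nonzero eigenvalue

$$\lambda = R_0 = \frac{\varepsilon_1 \epsilon \vartheta V}
{(\varepsilon_1 + \vartheta)(\vartheta + \rho)(\vartheta + \epsilon T)},$$

with $V$ and $T$ left free by the construction; the package evaluates it
at user-supplied values defaulting to the initial counts, where
$\lambda \approx 0.00445 < 1$: the smoking-free state is locally
asymptotically stable. Sensitivity partials of $R_0$ are computed by
direct differentiation of this expression — *not* by transcribing
published sensitivity formulas for this model, two of which are
inconsistent with the calculus (a $\rho$-derivative printed positive yet
annotated non-positive, and a $\vartheta$-derivative annotated
non-negative although the log-derivative
$1/\vartheta - 1/(\varepsilon_1+\vartheta) - 1/(\vartheta+\rho) -
1/(\vartheta+\epsilon T)$ is negative at the default rates). Each partial
is verified against central finite differences to $10^{-6}$ relative. The
robust signs at the defaults: $\partial R_0/\partial\varepsilon_1 > 0$,
$\partial R_0/\partial\epsilon > 0$, $\partial R_0/\partial\rho < 0$.

### Equilibria

A subtlety: the conventional "smoking-free state" quoted for this model,
$(V, 0, T, 0, 0)$ with free $V$ and $T$, is not a stationary point of the
right-hand side unless $T = 0$. `equilibria()` therefore reports the true
smoking-free stationary point $(\alpha/\vartheta, 0, 0, 0, 0)$ (residual
checked $\le 10^{-8}$) while `reproduction_number()` keeps the free
$(V, T)$ arguments of the eigenvalue formula. On the endemic branch the
non-smoker compartments are closed-form functions of $T$, and $T^*$
solves a scalar consistency equation
$\varepsilon_1 G^*(T) + \varepsilon_2 T\,O^*(T) = (\vartheta + \rho)T$,
root-found by bracketed bisection (`uniroot`, tolerance $10^{-12}$) after
a 400-point log-spaced sign scan on $(10^{-12},
10\,\alpha/\vartheta]$. Under the defaults no positive root exists —
consistent with $R_0 < 1$ — and the endemic entry is reported absent with
a diagnostic rather than an error.

```{r}
equilibria()
```

## Verification solvers

Two independent integrators exist *only* to check the series:

* `rk4_classical()`: fixed-step classical Runge-Kutta for $\mu = 1$.
  Richardson self-consistency puts its observed order at $\approx 4$ and
  the $h = 10^{-3} \to 5\times10^{-4}$ change below $10^{-9}$, far below
  every tolerance it underwrites.
* `abm_caputo()`: the product-trapezoidal fractional
  Adams-Bashforth-Moulton predictor-corrector (PECE, one correction per
  step) for Caputo systems. The shipped checks hold it to the closed-form
  linear relaxation $E_\mu(-\tau^\mu)$ within $10^{-4}$ at
  $\mu \in \{0.5, 0.8\}$ ($h = 10^{-4}$; the observed agreement is orders
  of magnitude tighter) and to RK4 within $10^{-5}$ at $\mu = 1$. Its
  cost is quadratic in step count, which is irrelevant at the horizons
  used.

Problem sizes in the shipped tests: RK4 at $h = 10^{-4}$ on $[0, 0.1]$;
ABM at $h = 10^{-4}$ on $[0, 0.5]$ and $h = 10^{-5}$ on $[0, 0.04]$ for
the remainder-order scans — horizons chosen because the three-term series
is a *local* object whose useful range for this model ends near
$\tau \approx 0.5$ anyway (see the truncation diagnostic). All checks run
in seconds.

No CF or ABC reference integrator is provided; those kernels are covered
indirectly through the $\mu = 1$ coincidence, the level-sum conservation
identity (which holds kernel-by-kernel), and hand-expanded low-order
components.

## Truncation diagnostic

`truncation_diagnostic()` reports, per state and grid point, the ratio
|last component| / |partial sum| and the largest $\tau$ at which it stays
below a threshold (default 0.05). This is an empirical convergence-region
estimate, not a proof; for the default model at $K = 2$ it flags the
series as reliable on roughly $\tau \lesssim 0.3$–$0.5$ depending on the
state and kernel. Users who need larger horizons should raise $K$ (cheap)
or switch to `abm_caputo()` (Caputo only).

## Limitations

* The series is local in $\tau$; none of the tabulated grids extend past
  $\tau = 0.5$, and neither should conclusions drawn from $K = 2$ sums.
* Fractional orders are restricted to $\mu \in (0, 1]$; $\mu > 1$ and
  Riemann-Liouville-type derivatives are out of scope.
* Only bilinear nonlinearities are supported; general Adomian polynomials
  for non-polynomial nonlinearities are not implemented.
* Coefficients are numeric for a fixed $\mu$; there is no symbolic-$\mu$
  mode.
* One classical-order reference column for the occasional-smoker
  compartment ($G$ at $\mu = 1$, $\tau > 0$) cannot be reproduced by the
  recursion that generates every other column; the recursion's value at
  $\tau = 0.1$ (19.0756) instead agrees with the value printed for an
  independent decomposition method (19.0721). Similarly, one
  fractional-order block of the temporary-quitter table appears to have
  its kernel columns permuted. The table-reproduction functions compute
  and emit all NTDM columns regardless; the known-inconsistent cells are
  simply not used as checks.
* The two external comparison columns carried by the table layouts
  (q-HATM, LADM) are emitted as placeholders and never computed.
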