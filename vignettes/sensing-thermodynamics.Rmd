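---
title: "Thermodynamic accounting of measurement and erasure in sensory adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic accounting of measurement and erasure in sensory adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensotherm)
```

## The physical picture

A sensory adaptive system (SAS) couples a fast, binary **activity** $a$
and a slow **memory** $m$ to an external signal $\ell$. At constant
signal the system sits in an $\ell$-dependent steady state in which the
memory is correlated with the signal while the average activity is
*adapted* — nearly signal-independent. After an abrupt signal switch the
activity responds within $\tau_a$, then the memory tracks the new signal
within $\tau_m \gg \tau_a$ and the activity returns to its adapted value.

`sensotherm` treats the SAS as a continuous-time Markov chain on a finite
state space $x = (a, m)$ with one generator $W_\ell$ per signal level,
evolving as $\dot p = W_\ell\, p$ (columns index source states; this
convention is asserted by a unit test). The experiment it models is the
**binary switch protocol**: an initial level $\ell_0$ is drawn from a
prior $P(\ell_0)$, the system is prepared in $p_{ss}^{\ell_0}$, and at
$t=0$ the signal switches to $\ell_1 \sim P(\ell_1|\ell_0)$ and is held.
All ledgers average over the four $(\ell_0,\ell_1)$ branches.

### Information ledger

Sensing is measurement plus erasure. Along the relaxation the package
tracks, in nats internally (bits $=$ nats$/\ln 2$ in all reports):

* $I_{meas}(t) = I(x_t;\ell_1)$ — information acquired about the new
  signal, split by the chain rule into a memory part $I(m_t;\ell_1)$ and
  an activity part $I(a_t;\ell_1|m_t)$;
* $I(x_t;\ell_0|\ell_1)$ — remaining *direct* correlation with the old
  signal (conditioning on $\ell_1$ removes the indirect correlation
  routed through the switch kernel). Its decrease is the information
  erased.

### Entropy-production decompositions

With $k_B = T = 1$ and the local-detailed-balance convention
$\ln(W_f/W_b) = -\Delta E + \Delta\mu\,\nu$ (energies in kT, $\nu$ an
integer fuel stoichiometry), the signal-averaged second law reads
$\Sigma_{tot}(t) = \Delta S(x_t|\ell_0,\ell_1) - Q(t) \ge 0$ with $Q$ the
cumulative heat into the system. Two exact decompositions structure it:

* **measurement/erasure**:
  $\Sigma_{era}(t) = I(x_0;\ell_0|\ell_1) - I(x_t;\ell_0|\ell_1)$ is
  purely entropic — erasing old information is energetically free but
  irreversible — while
  $\Sigma_{mea}(t) = \Delta S(x_t) - \Delta I_{meas}(t) - Q(t)$ carries
  all energetics and yields the measurement bound
  $W - \Delta F \ge I_{meas}$ (its minimum margin *is* $\Sigma_{mea}$);
* **nonadiabatic/adiabatic**:
  $\Sigma_{na}(t) = -\Delta\, D(p_t\|p_{ss}^{\ell_1})$ is the transient
  part, $\Sigma_a = \Sigma_{tot} - \Sigma_{na}$ the housekeeping part
  (identically zero under detailed balance). The excess heat $Q_{ex}$,
  defined by $\dot\Sigma_{na} = \dot S - \dot Q_{ex}$, replaces $Q$ for
  sensors whose steady state is itself dissipative, giving the NESS
  refinement $W_{ex} - \Delta F \ge I_{meas}$ with
  $W_{ex} = \Delta E - Q_{ex}$.

Each component is nonnegative and non-decreasing because each is (an
average of) a shrinking relative entropy between distributions evolving
under the same master equation.

## Numerical design

**Exact integrals, not quadrature.** Distributions are advanced with
dense matrix exponentials of the block
$\begin{pmatrix} W & 0 \\ I & 0\end{pmatrix}$, whose lower-left block is
$\int_0^{\Delta t} e^{Ws}\,ds$. Every cumulative heat/work quantity is a
linear functional of $\int p\,dt$ and is therefore exact; the entropic
quantities are state functions evaluated at grid points. As a result the
decomposition identities hold to $\sim 10^{-13}$ on every grid, and the
test suite checks them at $10^{-9}$. The independent oracle for this
machinery is (i) a trapezoid quadrature of the instantaneous flux
expressions on a dense grid and (ii) a Gillespie sampler whose
occupation statistics must match within Monte-Carlo error.

**Grids.** Because $\tau_a \ll \tau_m$, time grids are geometric by
default, from $0.01/(\max$ exit rate$)$ to $30\times$ the slowest
relaxation time $1/|\mathrm{Re}\,\lambda_2|$, with $t=0$ prepended as the
ledger reference. Linear grids are available (`times_grid`).

**Stationary states** come from the SVD null vector, with negatives below
$-10^{-12}$ clipped and renormalized; larger negatives, degenerate null
spaces, residuals above $10^{-10}$, reducible generators, or
irreversible jumps (a rate whose reverse is zero) are errors, not
warnings. Zero-probability states contribute zero to entropies and flux
sums.

**Units.** $k_B = T = 1$; energies in kT; information in nats internally
and bits in user-facing reports (`to_bits` is an exact factor
$1/\ln 2$).

## The bundled sensors

### Equilibrium feedforward sensor (4 states)

Built backwards from its target steady states: memory correlation
$p(m=\ell|\ell) = 1-\varepsilon_m$; adapted activity
$p(a=1|m=\ell,\ell) = \bar a + (2\ell-1)\varepsilon_a$; response branch
$p(a=\ell|m\neq\ell,\ell) = 1-\varepsilon_g$. Boltzmann inversion gives
the energies ($E = -\ln p_{ss}$, referenced so the most probable state
has $E=0$), and the rates are the symmetric local-detailed-balance form
$\omega\, e^{-\Delta E/2}$ with bare rates $\omega_a$ (activity) and
$\omega_m$ (memory). The symmetric split (rather than, say, Metropolis)
is chosen because only detailed balance and the two bare scales are
physically constrained, and the symmetric form is smooth in parameters
and makes $\sqrt{W_f W_b}$ recover the bare rate exactly — which the
tests exploit. With $\bar a = 1/2$ (default) the construction has an
exact mirror symmetry under $(a,m,\ell) \to (1-a,1-m,1-\ell)$.

Defaults: $\varepsilon_a=\varepsilon_m=\varepsilon_g = 0.01$,
$\bar a = 1/2$, $\omega_a = 1$, $\omega_m = 10^{-2}$, uniform independent
switch kernel. These are package choices (config-exposed), selected so
that the protocol is a clean 1-bit operation with small error budget and
two well-separated stages; the qualitative assertions in the tests are
robust to any small-$\varepsilon$ choice. A uniform *independent* kernel
is the default because a deterministic (invertible) kernel makes
$I(x;\ell_0|\ell_1)$ vanish identically and degenerates the erasure
ledger; degenerate protocols are allowed but flagged.

### E. coli chemoreceptor (10 states)

MWC-type free energy per Tar receptor, in kT:
$F(a,m;L) = a\,\varepsilon_r(m_0-m) + a\ln\frac{1+L/K_I}{1+L/K_A}$, with
the first term tagged *internal* (the receptor's own energy) and the
second *environmental* (ligand reservoir). Activity flips are thermal;
methylation steps run CheR-forward ($m\to m+1$) on inactive receptors and
CheB-forward ($m\to m-1$) on active ones, each forward step consuming one
SAM ($\nu = 1$, $\ln(W_f/W_b) = \Delta\mu - \Delta F$, attempt scale
split symmetrically — the split loads transients, not identities).
Around any elementary $(a,m)$ square the cycle affinity is exactly
$2\Delta\mu$, so for $\Delta\mu > 0$ the adapted state is a genuine NESS
whose housekeeping dissipation rate equals $\Delta\mu$ times the
stationary SAM flux; $\Delta\mu = 0$ recovers detailed balance and the
whole equilibrium test suite.

Defaults ($\varepsilon_r = 2$ kT, $m_0 = 1$, $K_I = 18.2\,\mu M$,
$K_A = 3000\,\mu M$, $\Delta\mu = 6$ kT, $\omega_a = 1$,
$\omega_m = 10^{-2}$) follow the consensus Tar parameterization; the
standard step experiment 94 → 720 µM sits inside the adaptive region
$K_I \ll L \ll K_A$ and 5760 µM outside it. These values are flagged as
parameter-sensitive choices, exposed in the config.

**Attractant sign convention.** Increasing attractant *suppresses*
activity (the Tar convention); the generic response cartoon with an
upward activity excursion is its mirror image. All thermodynamic ledgers
are convention-independent.

**Re-adaptation window.** "During the process" integrals need an
endpoint. The package defines the re-adaptation time as the first time,
*after* the extremal excursion, at which the mean activity is back within
5% (relative, `readapt_tol`) of its new stationary value. The naive
"first time within the band" is wrong here because adaptation makes the
old and new adapted activities nearly equal, so the trajectory starts
inside the band before the response has happened.

**Sensing cost.** The cumulative excess work of the up-step branch is
non-monotone: it peaks during the fast response (driven mostly by the
ligand-reservoir interaction) and is then partly consumed as the receptor
uses the stored free energy to adapt, so its net value at re-adaptation
is near zero for any adaptive parameterization. The cost summary
therefore reports as the sensing cost the *gross* supplied work — the
running maximum of cumulative $W_{ex}$ over the window — alongside the
net values. The housekeeping comparator is $T\,\Sigma_a$ accumulated over
the same window, and both are evaluated on the deterministic up-step
branch (the step experiment), while the information quantities come from
the random-switch ensemble, which is the object the measurement/erasure
formalism is defined on.

## What the synthetic fixtures establish — and what they do not

`make_random_model_fixture` generates random connected reversible models
(random energies per signal, random symmetric attempt rates, optionally a
random fuel-driven cycle with $\Delta\mu \in [0,5]$). The identity suite
runs over 100 such fixtures plus both bundled sensors. A green run
establishes that the *accounting* is exact — decompositions, positivity,
monotonicity, bounds — for arbitrary finite reversible models, driven or
not. It does **not** establish anything about real receptors: the
fixtures have no time-scale separation, no adaptation, and no biology;
and the bundled chemoreceptor itself omits receptor cooperativity, the
phosphorylation cascade, the flagellar motor, and ligand-binding shot
noise. Quantities flagged parameter-sensitive (the sensing-vs-
housekeeping ratio above all) depend on the consensus parameter choices
and on the re-adaptation convention, and should be read as order-of-
magnitude statements.

## Known limitations

* Signals switch once at $t=0$; time-dependent protocols, fluctuating
  environments, gradient sensing and frequency response are out of scope.
* Trajectory-level (fluctuating) information and feedback-control
  (Sagawa–Ueda) measures are not computed; the ledgers are ensemble
  quantities.
* Dense matrix exponentials are exact but scale as $O(n^3)$ per step;
  the package is designed for few-state sensors (the bundled models have
  4 and 10 states), not for large reaction networks.
* Memory here is erased because the *signal* changes, not because the
  memory's energy landscape is manipulated; Landauer-style reset
  protocols are a different experiment and are not modelled.
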