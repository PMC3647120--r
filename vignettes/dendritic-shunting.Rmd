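---
title: "Multiplicative dendritic integration: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplicative dendritic integration: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendshunt)
```

## The problem

When an inhibitory synapse lies on the path that an excitatory current must
travel to reach the soma, the inhibitory conductance does not subtract a
fixed amount from the somatic potential — it *divides* the excitatory
signal. This shunting inhibition is invisible to ordinary point-neuron
models, which sum synaptic inputs linearly. Experimentally, the joint
somatic deflection of a simultaneous EPSP and IPSP is well described by an
arithmetic rule

\[ \Delta V \;=\; \mathrm{EPSP} + \mathrm{IPSP} + \kappa\,
   \mathrm{EPSP}\cdot \mathrm{IPSP}, \]

with a shunting strength \(\kappa\) (mV\(^{-1}\)) that depends on where the
two synapses sit on the dendrite. `dendshunt` implements a hierarchy of
models around this rule:

1. a **three-compartment conductance model** (soma, proximal dendritic
   site, distal dendritic site) solved exactly — the ground truth;
2. **reduced single-compartment models** in which the rule above holds by
   construction, with closed-form response functions and \(\kappa\), for
   five synaptic geometries;
3. a **spiking network** of excitatory and inhibitory populations in which
   inhibitory neurons act as peri-somatic *global shunting gates*, and
   which sustains persistent activity at low rates;
4. the **mean-field** fixed-point and linear stability analysis of that
   network.

## The three-compartment model and the reduction

The soma (leak `g_S`, capacitance `C_S`) couples to the proximal site
through asymmetric transfer conductances, and the proximal site couples to
the distal site likewise; each dendritic site has leak `g_D`, capacitance
`C_D`, and one synapse. Excitatory depolarization recruits active channels,
which we absorb into a constant amplification factor `alpha` applied to
transfer conductances leaving an excitatory-side site
(`g_IS = alpha*g_SI`, `g_ES = alpha*g_SE`, `g_EI = alpha*g_IE`).
Steady states are exact solutions of a 3×3 linear system
(`steady_state_three_compartment()`), and `simulate_three_compartment()`
integrates the coupled ODEs with explicit Euler (default `dt = 0.01` ms,
chosen against the fastest membrane time constant of ~1.7 ms; a divergence
guard reports the offending step if `dt` is too coarse). A fixed-step
explicit scheme was chosen over an adaptive one because the same machinery
must handle spike events on a fixed grid in the network module, and because
the linear steady-state solver provides an independent check of the
integrator at every parameter setting.

With the default parameters the compartmental time constants separate by an
order of magnitude:

```{r}
round(time_constants(neuron_params()), 2)
```

Treating the dendritic sites as instantaneously relaxed and neglecting the
antidromic coupling product (`g_IE*g_EI << g_D^2`, valid when the sites are
well separated) collapses the model onto a single somatic equation

\[ \tau_S \frac{dv}{dt} = -(v - E_L) + f_{\mathrm{exc}}(g^E)
   + f_{\mathrm{inh}}(g^I) + \kappa\, f_{\mathrm{exc}} f_{\mathrm{inh}}, \]

with closed-form saturating response functions and a constant \(\kappa\).
For the on-path pair, \(\kappa_{on} = (g_S + g_{IS})/(g_{IS}(E_L - E_I))\):
shunting is strong when the inhibitory reversal is near rest, and grows as
the inhibitory site moves distally (smaller `g_IS`). The multiplicative
separation is an exact algebraic identity for expressions of the form
\((h + \beta g^I)/(\gamma + g^I)\) — see `decompose_multiplicative()`,
which the test suite verifies to machine precision on \(10^4\) random
draws.

The reduction is accurate: over `g_E, g_I` in \([0, 10]\) nS the on-path
reduced steady state deviates from the exact three-compartment solve by at
most ~0.02 mV (the acceptance bound is 1 mV).

### A note on one printed formula

The published grouping of the on-path inhibitory response denominator is
typographically ambiguous; we reconstructed it from the derivation
(substituting the dendritic steady states into the somatic equation), which
gives \(f_p(g^I) = g_{IS} g^I (E_I - E_L) / (D_0 + g^I(g_S + g_{IS}))\)
with \(D_0\) the same constant appearing in the excitatory response.
Expanding the printed grouping term by term gives exactly this expression,
and the full-model oracle confirms it numerically, so there is no conflict.

## Shunting strength in the full model

`extract_shunting_strength()` inverts the arithmetic rule on the full
model: subtract the individual somatic deflections from the joint one and
divide by their product. On-path, the extracted \(\kappa\) is nearly
independent of the input conductances (varies < 1% over `g_I` in
\([0.5, 20]\) nS), validating the constant-\(\kappa\) reduced model.

Two caveats discovered with the exact solver, both consequences of the
antidromic coupling the closed forms neglect:

* **The sign of \(\kappa_{out}\) is not identifiable.** The closed form
  gives \(\kappa_{out} = (g_S + g_{ES})/(g_{ES}(E_L - E_E)) = -0.02\)
  mV\(^{-1}\) — an order of magnitude below \(\kappa_{on}\) — but the
  full-model extraction at the default parameters yields \(+0.012\):
  the neglected coupling terms are of the same size as \(\kappa_{out}\)
  itself. Only the *magnitude* (\(|\kappa_{out}| \ll \kappa_{on}\)) is a
  robust statement, and that is what the tests pin.
* **Which conductance \(\kappa_{out}\) depends on.** The out-of-path model
  is defined by interchanging the labels E and I throughout. In the full
  model, the extracted out-of-path \(\kappa\) is nearly flat in the
  *distal* (inhibitory) conductance (~2% over the scan range) but varies
  strongly (~90%) in the *proximal* (excitatory) one — the proximal
  conductance is the one that shunts. The counterpart of the on-path
  "scan the proximal inhibitory input" experiment is therefore, after the
  label exchange, a scan of the proximal excitatory input, and that is how
  the out-of-path input-dependence test is implemented.

`kappa_distance_scan()` maps \(\kappa\) against the excitatory site
position under the passive-cable distance rule
`g_trf(x) = g_max/(mu*x + 1)` (defaults `g_max = 300` nS, `mu = 3` per
arbitrary distance unit), with the series-resistance constraint
`1/g_SE + 1/g_IE = 1/g_SI` on the out-of-path side. It reproduces the
characteristic spatial profile: \(\kappa\) rises sharply as the excitatory
site approaches the inhibitory one from the out-of-path side, and is
approximately constant on the on-path side *for well-separated sites* —
within ~10 distance units of the inhibitory site the constancy degrades,
which is expected since the reduction assumes separation.

## Multi-branch geometries

Three ways to wire many synapses (per-branch response functions in
`somatic_response_excitatory()`/`somatic_response_inhibitory()`, assembled
by `steady_state_soma()`):

* **single_per_branch** — one synapse per branch; contributions add
  linearly, no shunting term. The published form uses a single
  branch-to-soma transfer conductance `g_TS`; we use the type-appropriate
  value per branch (`g_ES` for excitatory, `g_IS` for inhibitory branches)
  and the summed somatic load `g_S + n_E g_ES + n_I g_IS`, which reduces
  exactly to the published form when all branches share a type.
* **paired_on_path** — an on-path E/I pair on each of `N` branches; each
  branch contributes its own multiplicative term with
  \(\kappa_{N\text{-}on} = (g_S + N g_{IS})/(g_{IS}(E_L - E_I))\), and
  branches add.
* **global_shunting** — excitatory synapses on `N` branches, inhibition
  peri-somatic: the branch responses are summed *before* being multiplied
  by the inhibitory response, with \(\kappa_G = 1/(E_L - E_I)\). Multiple
  inhibitory inputs are summed before the response function.

### The branch-load question (a deliberate design choice)

The published global-shunting inhibitory response divides by
`g_S + g_I + N*g_ES`. With the default table values (`g_ES = 50` nS) and
the network's `N = p*N_E = 200` branches this denominator is ~10^4 nS and
peri-somatic inhibition becomes numerically irrelevant (~0.03 mV at the
operating point); a network built this way has no low-rate attractor and
runs away to ~125 Hz (we verified this by simulation). The same derivation,
however, neglects the transfer-conductance load on the soma when it sets
\(\tau_S \approx C_S/g_S\) — keeping the load there would give
\(\tau_S \approx 0.07\) ms. Applying the neglect consistently to the
somatic balance gives \(f_{Gp}(g^I) = g^I (E_I - E_L)/(g_S + g^I)\).
Supporting this reading, the published mean-field linearization constants
`c = -0.113, d = -0.6218` are consistent with a branch-load-free
\(f_{Gp}\) (they imply an effective load of ~50 nS, not 10^4), while
`a = 0.002, b = 0.175` fit the branch-loaded excitatory response.

Both response functions therefore expose `include_branch_load`; the
reduced module defaults to the published form (`TRUE`), the network module
defaults to `FALSE`. With this choice — and no per-rate tuning — the
simulated network reproduces the reference persistent rates.

## The spiking network

2000 excitatory and 500 inhibitory integrate-and-fire neurons
(`tau_S = C_S/g_S`: 24.7 ms and 12.3 ms respectively; threshold −50 mV,
reset −70 mV, no refractory period since none is specified), each receiving
exactly `p*N_E = 200` excitatory inputs (one branch each) and
`p*N_I = 50` inhibitory inputs, sampled without replacement excluding self
(`fixed_in_degree = TRUE`; Bernoulli sampling is available). Synaptic
conductances follow exponential dynamics with `tau_E = 100` ms (slow,
NMDA-like — this slowness is what lets activity persist across the
inter-spike gaps) and `tau_I = 10` ms, incremented by `w_E = 24` nS and
`w_I = 2` nS per spike, with one integration step (0.1 ms) of propagation
delay. Because all synapses made by one presynaptic neuron carry identical
traces, per-neuron input sums are sparse adjacency-matrix products, which
is why the integrator stays in vectorized R (a 500 ms run of 2500 neurons
takes a few seconds).

Numerical choices:

* **Noise.** The membrane noise term is discretized as
  `sigma*sqrt(dt/tau_S)*N(0,1)` per Euler step (Langevin convention), so
  the stationary voltage s.d. is `sigma/sqrt(2)` independent of `dt`.
  No value of `sigma` is published; we calibrated it once so that the
  spontaneous (pre-stimulus) rate is ≤ 2 Hz and froze `sigma = 2` mV.
  One honest caveat: the noise amplitude is *not* innocuous for the
  attractor — at `sigma = 6` mV the persistent rate rises from ~12.5 to
  ~16 Hz because noise linearizes the threshold. Keeping `sigma` small
  keeps the attractor where the noiseless analysis puts it.
* **Stimulus.** `g_ext` is added to every excitatory branch conductance
  inside the branch response during 50–250 ms, for both populations (the
  published input form is population-generic; a switch restricts it to the
  excitatory population). No value is published; `g_ext = 10` nS switches
  the network reliably (6 nS does not) and was frozen.

A typical run (`simulate_network(network_params(seed = 1))`): silence
before the stimulus, high-rate firing during it, and after stimulus offset
the network settles into self-sustained firing at ~12.5 Hz (excitatory) /
~24.5 Hz (inhibitory) instead of returning to silence. Ablating the
multiplicative term (`kappa_G = 0`) removes the balance: the same network
runs away to >100 Hz. Raising `w_E` raises the persistent rate gradually —
the attractor is adjustable, not saturation-pinned.

## Mean-field analysis

Replacing per-neuron inputs by population averages and the spiking
mechanism by a threshold-linear transfer \(r = \mu [J - \beta]_+\)
(`mu_E = 3.2`, `mu_I = 6.4` Hz/mV, `beta = 17.5` mV — a good fit of the
noiseless integrate-and-fire rate of the two time constants), and
linearizing the response functions at the operating point
(\(f_{Gd} \approx a g + b\), \(f_{Gp} \approx c G + d\)), the
self-consistent input becomes quadratic in the excitatory rate through the
shunting term. `meanfield_fixed_point()` evaluates the coefficients
\(A_1..A_4, B_1..B_3\) and takes the admissible root in the rationalized
form \(r_E = 2B_1/(-B_2 + \sqrt{B_2^2 - 4B_1B_3})\) (verified to be a root
of the quadratic; at \(B_3 = 0\) the linear root \(-B_1/B_2\) is used —
note the rationalized form continues to it only in the \(B_2 < 0\) regime,
which is where the persistent solution lives). Stability follows from the
2×2 Jacobian of the conductance dynamics: one eigenvalue is \(-1\)
*exactly* (a rank structure of the Jacobian, which the implementation
checks against a numerical eigen-decomposition), and the second decreases
with \(\kappa_G\) because only `c < 0`, `d <= 0` multiply it — shunting
stabilizes the persistent state. The randomized monotonicity test uses
this explicit dependence at fixed conductances (the statement the theory
makes); full monotonicity with the fixed point recomputed also holds on
the reference parameter set but can fail for a few percent of strongly
perturbed parameter draws.

The published linearization constants cannot all be re-derived from the
response functions with the table parameters (no choice of `g_ES` and `N`
fits all four; `a`, `b` fit the branch-loaded excitatory response at the
mean-field operating point to 0.2% and ~6%, `c`, `d` fit a load-free
inhibitory response). `meanfield_params()` therefore treats the published
`(a, b, c, d)` as authoritative inputs, and
`linearize_global_responses()` computes the package's own tangents
separately; the two routes are never silently mixed.

```{r}
sol <- meanfield_fixed_point(meanfield_params())
sol
meanfield_stability(meanfield_params())[c("lambda1", "lambda2", "stable")]
```

The mean-field rate (~18 Hz at `w_E = 24`) sits somewhat above the
simulated persistent rate (~12.5 Hz) — the threshold-linear fit
overestimates the curvature of the spiking transfer near threshold — but
both increase monotonically with `w_E` over the sweep band, which is the
property the analysis is meant to explain.

## What the synthetic world does and does not establish

All inputs are self-generated: Poisson spike trains (seeded), sampled
connectivity, Gaussian membrane noise. The generator's defaults are the
stated reference conditions (population sizes, weights, time constants,
stimulus window); `sigma` and `g_ext` are the only free dials and were
frozen after one calibration pass. A green network test therefore
establishes that *this* stated world has a low-rate persistent attractor
with the printed rates — not that the rates are insensitive to the
unpublished noise/stimulus choices (they drift by a few Hz across
reasonable `sigma`), and not that the mean-field caption constants are
derivable from the table. Real cortical tissue — heterogeneous weights,
conduction delays, refractoriness, structured connectivity, voltage-gated
channels beyond a constant `alpha` — is outside the model class.

## Known limitations

* No cable-equation PDE, no morphologies beyond three compartments, no
  active channel dynamics beyond the constant `alpha`.
* No synaptic delays (beyond one step), plasticity, or refractory period.
* The out-of-path reduced model is quantitatively weaker than the on-path
  one (by construction: the amplified antidromic transfer violates its
  own separation assumption), and the sign of its small \(\kappa\) is not
  meaningful.
* The mean-field module neglects input variance and finite-size effects;
  its agreement with simulation is qualitative (monotone trends, stability
  class), not point-wise.
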