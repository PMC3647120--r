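# dendshunt

Dendritic shunting inhibition in neuron and network models.

When an inhibitory synapse sits between an excitatory synapse and the soma,
it divides — rather than subtracts from — the excitatory signal. At steady
state the joint somatic deflection follows a multiplicative arithmetic rule

    ΔV = EPSP + IPSP + κ · EPSP · IPSP,

with a shunting strength κ (mV⁻¹) set by the synaptic geometry. `dendshunt`
is a toolkit for computational neuroscientists studying this non-linearity
across scales:

* **compartmental** — an exact three-compartment conductance neuron
  (soma + two dendritic sites) with steady-state solver, ODE integrator,
  empirical κ extraction, and a passive-cable distance rule
  `g_trf = g_max/(μx + 1)` for position-dependent transfer conductances;
* **reduced** — single-compartment models implementing the multiplicative
  rule with closed-form response functions and κ for five geometries
  (on-path, out-of-path, single-synapse branches, paired on-path branches,
  peri-somatic global shunting), e.g.
  κ_on = (g_S + g_IS)/(g_IS (E_L − E_I));
* **synapses** — spike-driven exponential conductances (exact per-step
  decay, `+w` per spike) and seeded Poisson spike-train generation;
* **network** — a recurrent spiking network (2000 excitatory / 500
  inhibitory integrate-and-fire neurons, fixed in-degree `p·N`) in which
  inhibitory neurons act as global shunting gates; the multiplicative term
  balances recurrent excitation and yields *persistent activity at low
  rates*;
* **meanfield** — the threshold-linear mean-field reduction: fixed-point
  rates r̄_E = 2B₁/(−B₂ + √(B₂² − 4B₁B₃)), conductances g̃ = wτr, and the
  closed-form Jacobian eigenvalues (λ₁ = −1 exactly; λ₂ < 0 means the
  persistent state is stable, and λ₂ decreases with κ_G).

## Worked example

Reduced-vs-full agreement and the shunting strengths:

```r
library(dendshunt)
p <- neuron_params()                     # reference parameter table
round(time_constants(p), 2)
#>  tau_S tau_DI tau_DE
#>  13.45   1.67   2.38

shunting_strength(p, "on_path")          # 0.22  mV^-1
shunting_strength(p, "out_of_path")      # -0.02 mV^-1 (negligible)
shunting_strength(p, "global_shunting")  # 0.1   mV^-1

# multiplicative rule vs the exact three-compartment steady state
steady_state_soma(2, 5, p, "on_path")$v_steady
#> [1] -70.21135
steady_state_three_compartment(p, 2, 5)[["v_S"]]
#> [1] -70.21277
```

Persistent activity in the spiking network (~6 s on one CPU):

```r
sim <- simulate_network(network_params(seed = 1), neuron_params(), duration = 500)
population_rate(sim, "E", c(0, 50))      # spontaneous, pre-stimulus
#> [1] 0
population_rate(sim, "E", c(400, 500))   # persistent, post-stimulus
#> [1] 11.76
population_rate(sim, "I", c(400, 500))
#> [1] 23.54
```

The stimulus (50–250 ms) switches the network from silence into a
self-sustained ~12.5 Hz excitatory / ~24.5 Hz inhibitory state that
outlasts the stimulus; with the shunting term ablated (`kappa_G = 0` in
`network_params()`) the same network runs away to >100 Hz.

Mean-field fixed point and stability:

```r
meanfield_fixed_point(meanfield_params())
#> <meanfield_solution> r_E=17.956 Hz r_I=35.912 Hz  gE=43.095 nS gI=0.7182 nS
meanfield_stability(meanfield_params())[c("lambda1", "lambda2")]
#> $lambda1  [1] -1
#> $lambda2  [1] -3.866702
```

## Command line

```sh
Rscript inst/cli/dendshunt simulate-network --config=inst/extdata/persistent_network.cfg --seed=1 --out=out_dir
Rscript inst/cli/dendshunt meanfield --sweep=20:30:2 --out=out_dir
```

Experiments: `response-curves`, `kappa-scan`, `kappa-distance`,
`simulate-neuron`, `simulate-network`, `meanfield`. Outputs are
tab-separated text with a header row plus a resolved-parameter dump for
provenance. Exit codes: 0 success, 2 configuration error, 3 numerical
failure.

## Notes

The methods vignette (`vignettes/dendritic-shunting.Rmd`) documents the
model assumptions, the calibration of the two unpublished parameters
(noise amplitude, stimulus conductance), the branch-load design choice in
the global inhibitory response, and known limitations.
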