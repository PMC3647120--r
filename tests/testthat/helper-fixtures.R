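# Shared fixtures: reference parameters and small in-code oracles.

table1 <- neuron_params()  # the reference parameter set

# Independent steady-state oracle: the 3x3 linear system written out by
# hand from the membrane equations, solved with the dense solver. Kept
# separate from the package's internal matrix construction on purpose.
oracle_tri_steady <- function(p, g_E, g_I, arrangement = "on_path") {
  if (arrangement == "on_path") {
    A <- matrix(c(
      p$g_S + p$g_IS, -p$g_IS, 0,
      -p$g_SI, p$g_D + p$g_SI + p$g_EI + g_I, -p$g_EI,
      0, -p$g_IE, p$g_D + p$g_IE + g_E), nrow = 3, byrow = TRUE)
    b <- c(p$g_S * p$E_L, p$g_D * p$E_L + g_I * p$E_I,
           p$g_D * p$E_L + g_E * p$E_E)
  } else {
    A <- matrix(c(
      p$g_S + p$g_ES, 0, -p$g_ES,
      0, p$g_D + p$g_EI + g_I, -p$g_EI,
      -p$g_SE, -p$g_IE, p$g_D + p$g_SE + p$g_IE + g_E), nrow = 3, byrow = TRUE)
    b <- c(p$g_S * p$E_L, p$g_D * p$E_L + g_I * p$E_I,
           p$g_D * p$E_L + g_E * p$E_E)
  }
  stats::setNames(solve(A, b), c("v_S", "v_I", "v_E"))
}

# Fig-3A-style geometry: transfer conductances from synapse positions
# under the distance rule (anchor fixes the inhibitory position).
geometry_params <- function(g_SI_anchor, x_E, base = table1,
                            model = distance_model()) {
  x_I <- (model$g_max / g_SI_anchor - 1) / model$mu_spatial
  if (x_E > x_I) {
    g_IE <- transfer_conductance_from_distance(x_E - x_I, model)
    list(arrangement = "on_path",
         params = neuron_params(g_SI = g_SI_anchor, g_IE = g_IE))
  } else {
    g_SE <- transfer_conductance_from_distance(x_E, model)
    g_IE <- 1 / (1 / g_SI_anchor - 1 / g_SE)
    list(arrangement = "out_of_path",
         params = neuron_params(g_SI = g_SI_anchor, g_SE = g_SE, g_IE = g_IE))
  }
}

# Down-scaled network for unit tests (~10x fewer neurons than the
# reference setting; used for structural/determinism properties only).
small_net <- function(..., seed = 42L) {
  network_params(N_E = 200L, N_I = 50L, p = 0.1, seed = seed, ...)
}
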