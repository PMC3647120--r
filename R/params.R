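#' Single-neuron biophysical parameters
#'
#' Container for the constants of the three-compartment neuron: reversal
#' potentials, capacitances, leak and transfer conductances, and the
#' amplification factor `alpha` that links antidromic and orthodromic
#' transfer conductances (`g_IS = alpha * g_SI`, `g_ES = alpha * g_SE`,
#' `g_EI = alpha * g_IE`). Defaults are the reference parameter set used
#' throughout the package.
#'
#' Units follow the usual convention for conductance-based models:
#' potentials in mV, capacitances in pF, conductances in nS, so that
#' pF/nS gives ms and nS*mV gives pA.
#'
#' @param E_L resting (leak reversal) potential, mV.
#' @param E_E excitatory reversal potential, mV.
#' @param E_I inhibitory reversal potential, mV.
#' @param C_S somatic membrane capacitance, pF.
#' @param C_D dendritic membrane capacitance, pF.
#' @param g_S somatic leak conductance, nS.
#' @param g_D dendritic leak conductance, nS.
#' @param g_SI transfer conductance soma -> dendritic site I, nS.
#' @param g_SE transfer conductance soma -> dendritic site E, nS.
#' @param g_IE transfer conductance site I -> site E, nS.
#' @param alpha dimensionless amplification factor (>= 1) applied to
#'   transfer conductances leaving a depolarized (excitatory-side) site.
#' @param g_IS,g_ES,g_EI optional overrides for the derived transfer
#'   conductances; by default computed as `alpha` times their passive
#'   counterparts.
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' p <- neuron_params()
#' p$g_IS  # 25 = alpha * g_SI
#' @export
neuron_params <- function(E_L = -70, E_E = 10, E_I = -80,
                          C_S = 740, C_D = 50,
                          g_S = 30, g_D = 20,
                          g_SI = 5, g_SE = 10, g_IE = 1,
                          alpha = 5,
                          g_IS = alpha * g_SI,
                          g_ES = alpha * g_SE,
                          g_EI = alpha * g_IE) {
  p <- list(E_L = E_L, E_E = E_E, E_I = E_I, C_S = C_S, C_D = C_D,
            g_S = g_S, g_D = g_D, g_SI = g_SI, g_IS = g_IS,
            g_SE = g_SE, g_ES = g_ES, g_IE = g_IE, g_EI = g_EI,
            alpha = alpha)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron_params: '", nm, "' must be a finite numeric scalar")
  }
  if (C_S <= 0 || C_D <= 0) stop("neuron_params: capacitances must be > 0")
  conds <- c("g_S", "g_D", "g_SI", "g_IS", "g_SE", "g_ES", "g_IE", "g_EI")
  if (any(unlist(p[conds]) < 0)) stop("neuron_params: conductances must be >= 0")
  if (alpha < 1) stop("neuron_params: alpha must be >= 1")
  if (!(E_I <= E_L && E_L < E_E))
    stop("neuron_params: require E_I <= E_L < E_E")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  E_L=%g E_E=%g E_I=%g mV | C_S=%g C_D=%g pF\n",
              x$E_L, x$E_E, x$E_I, x$C_S, x$C_D))
  cat(sprintf("  g_S=%g g_D=%g | g_SI=%g g_IS=%g g_SE=%g g_ES=%g g_IE=%g g_EI=%g nS | alpha=%g\n",
              x$g_S, x$g_D, x$g_SI, x$g_IS, x$g_SE, x$g_ES, x$g_IE, x$g_EI, x$alpha))
  invisible(x)
}

#' Compartmental membrane time constants
#'
#' Time constants of the somatic and dendritic compartments,
#' `tau_S = C_S/(g_S + g_IS)`, `tau_DI = C_D/(g_D + g_SI + g_EI)` and
#' `tau_DE = C_D/(g_D + g_IE)`. Their separation (`tau_S` about an order
#' of magnitude slower) is what licenses treating the dendritic sites as
#' instantaneously relaxed in the reduced models.
#'
#' @param params a [neuron_params()] object.
#' @return Named numeric vector `c(tau_S, tau_DI, tau_DE)` in ms.
#' @examples
#' round(time_constants(neuron_params()), 2)  # 13.45 1.67 2.38
#' @export
time_constants <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  c(tau_S  = params$C_S / (params$g_S + params$g_IS),
    tau_DI = params$C_D / (params$g_D + params$g_SI + params$g_EI),
    tau_DE = params$C_D / (params$g_D + params$g_IE))
}

#' Synaptic conductance parameters
#'
#' Time constant and per-spike increment of an exponential synapse: between
#' presynaptic spikes the conductance decays as `exp(-t/tau)` and every
#' spike increments it by `w`.
#'
#' @param tau conductance decay time constant, ms (> 0).
#' @param w conductance increment per presynaptic spike, nS (>= 0).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau, w) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("synapse_params: tau must be a positive scalar (ms)")
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    stop("synapse_params: w must be a non-negative scalar (nS)")
  structure(list(tau = tau, w = w), class = "synapse_params")
}

#' Synaptic geometry of the reduced models
#'
#' Selects which spatial arrangement of synapses the reduced
#' single-compartment model describes, and how many dendritic branches it
#' has. The two-site geometries (`"on_path"`, `"out_of_path"`) force
#' `N = 1`; the multi-branch geometries (`"single_per_branch"`,
#' `"paired_on_path"`, `"global_shunting"`) require `N >= 1`.
#'
#' @param geometry one of `"on_path"`, `"out_of_path"`,
#'   `"single_per_branch"`, `"paired_on_path"`, `"global_shunting"`.
#' @param N number of dendritic branches (integer >= 1).
#' @return An object of class `dendritic_config`.
#' @export
dendritic_config <- function(geometry = c("on_path", "out_of_path",
                                          "single_per_branch",
                                          "paired_on_path",
                                          "global_shunting"),
                             N = 1L) {
  geometry <- match.arg(geometry)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 1 ||
      N != round(N))
    stop("dendritic_config: N must be an integer >= 1")
  N <- as.integer(N)
  if (geometry %in% c("on_path", "out_of_path") && N != 1L)
    stop("dendritic_config: N = 1 is forced for the two-site geometries")
  structure(list(geometry = geometry, N = N), class = "dendritic_config")
}

#' Distance model for transfer conductances
#'
#' Passive-cable distance rule for the effective conductance coupling two
#' sites: resistance grows linearly with distance, so
#' `g_trf(x) = g_max / (mu * x + 1)`. `g_max` is the conductance of two
#' co-localized points (x = 0); `mu` sets the spatial scale (distances are
#' in arbitrary units).
#'
#' @param g_max contact-point conductance, nS (> 0). Default 300.
#' @param mu_spatial spatial scaling factor per distance unit (> 0). Default 3.
#' @return An object of class `distance_model`.
#' @export
distance_model <- function(g_max = 300, mu_spatial = 3) {
  if (!is.numeric(g_max) || length(g_max) != 1L || g_max <= 0)
    stop("distance_model: g_max must be a positive scalar")
  if (!is.numeric(mu_spatial) || length(mu_spatial) != 1L || mu_spatial <= 0)
    stop("distance_model: mu_spatial must be a positive scalar")
  structure(list(g_max = g_max, mu_spatial = mu_spatial),
            class = "distance_model")
}

#' Spiking network parameters
#'
#' Parameters of the recurrent excitatory/inhibitory network with global
#' shunting gates. Defaults reproduce the reference persistent-activity
#' setting: 2000 excitatory and 500 inhibitory neurons, fixed in-degree
#' `p*N` connectivity, slow (NMDA-like, 100 ms) excitatory and fast (10 ms)
#' inhibitory synapses, threshold -50 mV / reset -70 mV, stimulus window
#' 50-250 ms.
#'
#' `sigma` (membrane noise amplitude, mV) and `g_ext` (per-branch external
#' stimulus conductance, nS) are not part of the reference table; the
#' shipped defaults were calibrated once so that the spontaneous rate is
#' below 2 Hz and the stimulus reliably switches the network into the
#' persistent state, then frozen.
#'
#' @param N_E,N_I population sizes.
#' @param p connection probability (in-degree fraction).
#' @param w_E,w_I synaptic weights, nS.
#' @param C_S_E,C_S_I somatic capacitances of the two populations, pF.
#' @param tau_E,tau_I synaptic time constants, ms.
#' @param E_thres spike threshold, mV.
#' @param E_reset reset potential, mV.
#' @param sigma noise amplitude, mV (additive Gaussian voltage noise,
#'   discretized as `sigma*sqrt(dt/tau_S)*N(0,1)` per Euler step).
#' @param g_ext external stimulus conductance added to every excitatory
#'   branch during the stimulus window, nS.
#' @param stim_onset,stim_offset stimulus window, ms.
#' @param dt integration step, ms.
#' @param seed RNG seed (integer).
#' @param fixed_in_degree logical; if `TRUE` (default) every neuron receives
#'   exactly `round(p*N_E)` excitatory and `round(p*N_I)` inhibitory inputs;
#'   if `FALSE` connections are sampled Bernoulli(p).
#' @param stim_population which population receives the stimulus:
#'   `"both"` (default) or `"E"`.
#' @param include_branch_load logical; whether the global inhibitory
#'   response keeps the `N*g_ES` dendritic branch load in its denominator.
#'   The network default is `FALSE`, consistent with the peri-somatic
#'   approximation `tau_S ~ C_S/g_S` (see the package vignette).
#' @param kappa_G optional override of the global shunting strength
#'   (mV^-1); `NULL` (default) derives `1/(E_L - E_I)` from the neuron
#'   parameters. Setting 0 ablates the multiplicative shunting term.
#' @return An object of class `network_params`.
#' @export
network_params <- function(N_E = 2000L, N_I = 500L, p = 0.1,
                           w_E = 24, w_I = 2,
                           C_S_E = 740, C_S_I = 370,
                           tau_E = 100, tau_I = 10,
                           E_thres = -50, E_reset = -70,
                           sigma = 2, g_ext = 10,
                           stim_onset = 50, stim_offset = 250,
                           dt = 0.1, seed = 1L,
                           fixed_in_degree = TRUE,
                           stim_population = c("both", "E"),
                           include_branch_load = FALSE,
                           kappa_G = NULL) {
  stim_population <- match.arg(stim_population)
  if (p <= 0 || p > 1) stop("network_params: require 0 < p <= 1")
  if (E_reset > E_thres) stop("network_params: require E_reset <= E_thres")
  if (dt <= 0) stop("network_params: dt must be > 0")
  if (N_E < 1 || N_I < 1) stop("network_params: population sizes must be >= 1")
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I), p = p,
                 w_E = w_E, w_I = w_I, C_S_E = C_S_E, C_S_I = C_S_I,
                 tau_E = tau_E, tau_I = tau_I,
                 E_thres = E_thres, E_reset = E_reset,
                 sigma = sigma, g_ext = g_ext,
                 stim_onset = stim_onset, stim_offset = stim_offset,
                 dt = dt, seed = as.integer(seed),
                 fixed_in_degree = fixed_in_degree,
                 stim_population = stim_population,
                 include_branch_load = include_branch_load,
                 kappa_G = kappa_G),
            class = "network_params")
}
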