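# Reduced single-compartment ("dendritic integrate-and-fire") models.
#
# Separation of time scales: the dendritic compartments relax to steady
# state instantly relative to the soma, which collapses the
# three-compartment model onto one somatic equation
#   tau_S dv/dt = -(v - E_L) + F(g_E, g_I)
# where the drive F combines an excitatory response, an inhibitory
# response, and a multiplicative shunting term weighted by a constant
# kappa. The response functions and kappa depend on the synaptic geometry.

# Constant part of the on-path denominator; also the full f_d denominator
# factor (Eq-level constant D0 = gS gD + gS gSI + gS gEI + gD gIS + gEI gIS).
.D0_on <- function(p) {
  p$g_S * p$g_D + p$g_S * p$g_SI + p$g_S * p$g_EI +
    p$g_D * p$g_IS + p$g_EI * p$g_IS
}

# Out-of-path analogue under full E/I label exchange.
.D0_out <- function(p) {
  p$g_S * p$g_D + p$g_S * p$g_SE + p$g_S * p$g_IE +
    p$g_D * p$g_ES + p$g_IE * p$g_ES
}

.as_config <- function(config) {
  if (inherits(config, "dendritic_config")) return(config)
  dendritic_config(config)
}

#' Steady state of the somatic point-neuron model
#'
#' The textbook single-compartment steady state with both synapses directly
#' on the soma: `v = E_L + (g_E/gamma)(E_E - E_L) + (g_I/gamma)(E_I - E_L)`
#' with `gamma = g_S + g_E + g_I`. Both conductances are divided by a
#' factor containing the other one, which is the simplest form of the
#' shunting non-linearity.
#'
#' @param g_E,g_I synaptic conductances, nS (vectorized, >= 0).
#' @param params a [neuron_params()]; the leak is `params$g_S`.
#' @return Steady-state membrane potential(s), mV.
#' @export
point_neuron_steady_state <- function(g_E, g_I, params = neuron_params()) {
  if (any(g_E < 0) || any(g_I < 0)) stop("conductances must be >= 0")
  gamma <- params$g_S + g_E + g_I
  params$E_L + (g_E / gamma) * (params$E_E - params$E_L) +
    (g_I / gamma) * (params$E_I - params$E_L)
}

#' Somatic response to excitation alone
#'
#' Voltage change at the soma produced by an excitatory conductance when no
#' inhibition is present, for the selected synaptic geometry. Zero at
#' `g_E = 0`, strictly increasing, and saturating to a finite limit for
#' large conductance (the dendritic site clamps to its local equilibrium).
#'
#' For `"out_of_path"` the excitatory synapse is the proximal one, so this
#' is the proximal-site response; for `"global_shunting"` and the branch
#' geometries it is the per-branch response.
#'
#' @param g_E excitatory conductance(s), nS (vectorized).
#' @param params a [neuron_params()].
#' @param config geometry name or [dendritic_config()].
#' @param N number of branches (taken from `config` if given there).
#' @return Somatic depolarization(s), mV.
#' @export
somatic_response_excitatory <- function(g_E, params = neuron_params(),
                                        config = "on_path", N = NULL) {
  cfg <- .as_config(config)
  if (!is.null(N)) cfg$N <- as.integer(N)
  if (any(g_E < 0)) stop("g_E must be >= 0")
  p <- params
  dVE <- p$E_E - p$E_L
  switch(cfg$geometry,
    on_path = p$g_IS * p$g_EI * g_E * dVE /
      (.D0_on(p) * (p$g_D + g_E + p$g_IE)),
    out_of_path = p$g_ES * g_E * dVE /
      (.D0_out(p) + g_E * (p$g_S + p$g_ES)),
    single_per_branch = p$g_ES * g_E * dVE /
      ((p$g_S + cfg$N * p$g_ES) * (p$g_D + g_E)),
    paired_on_path = p$g_IS * p$g_EI * g_E * dVE /
      (p$g_D * (p$g_D + g_E) * (p$g_S + cfg$N * p$g_IS)),
    global_shunting = p$g_ES * g_E * dVE /
      ((p$g_D + g_E) * (p$g_S + cfg$N * p$g_ES)),
    stop("unknown geometry: ", cfg$geometry))
}

#' Somatic response to inhibition alone
#'
#' Voltage change at the soma produced by an inhibitory conductance when no
#' excitation is present. Zero at `g_I = 0`, strictly decreasing, and
#' saturating to a finite negative limit.
#'
#' For `"global_shunting"` the inhibitory synapse sits peri-somatically and
#' `g_I` is the (summed) inhibitory conductance; `include_branch_load`
#' controls whether the `N * g_ES` dendritic branch load appears in the
#' denominator (see the vignette; the spiking network uses `FALSE`).
#'
#' @param g_I inhibitory conductance(s), nS (vectorized).
#' @inheritParams somatic_response_excitatory
#' @param include_branch_load logical, only used for `"global_shunting"`.
#' @return Somatic deflection(s), mV (non-positive).
#' @export
somatic_response_inhibitory <- function(g_I, params = neuron_params(),
                                        config = "on_path", N = NULL,
                                        include_branch_load = TRUE) {
  cfg <- .as_config(config)
  if (!is.null(N)) cfg$N <- as.integer(N)
  if (any(g_I < 0)) stop("g_I must be >= 0")
  p <- params
  dVI <- p$E_I - p$E_L
  switch(cfg$geometry,
    on_path = p$g_IS * g_I * dVI /
      (.D0_on(p) + g_I * (p$g_S + p$g_IS)),
    out_of_path = p$g_ES * p$g_IE * g_I * dVI /
      (.D0_out(p) * (p$g_D + g_I + p$g_EI)),
    single_per_branch = p$g_IS * g_I * dVI /
      ((p$g_S + cfg$N * p$g_IS) * (p$g_D + g_I)),
    paired_on_path = p$g_IS * g_I * dVI /
      ((p$g_S + cfg$N * p$g_IS) * (p$g_D + g_I + p$g_IE)),
    global_shunting = g_I * dVI /
      (p$g_S + g_I + if (include_branch_load) cfg$N * p$g_ES else 0),
    stop("unknown geometry: ", cfg$geometry))
}

#' Closed-form shunting strength
#'
#' The constant kappa weighting the multiplicative term of the reduced
#' models: `kappa_on = (g_S + g_IS)/(g_IS (E_L - E_I))` for the on-path
#' pair, `kappa_out = (g_S + g_ES)/(g_ES (E_L - E_E))` for the out-of-path
#' pair, `kappa_Non = (g_S + N g_IS)/(g_IS (E_L - E_I))` for N paired
#' on-path branches, and `kappa_G = 1/(E_L - E_I)` for peri-somatic global
#' shunting. Shunting is strong when the inhibitory reversal is close to
#' rest (on-path, global) and negligible when the relevant reversal is far
#' from rest (out-of-path).
#'
#' @inheritParams somatic_response_excitatory
#' @return kappa in mV^-1.
#' @examples
#' shunting_strength(neuron_params(), "on_path")          # 0.22
#' shunting_strength(neuron_params(), "out_of_path")      # -0.02
#' shunting_strength(neuron_params(), "global_shunting")  # 0.1
#' @export
shunting_strength <- function(params = neuron_params(), config = "on_path",
                              N = NULL) {
  cfg <- .as_config(config)
  if (!is.null(N)) cfg$N <- as.integer(N)
  p <- params
  switch(cfg$geometry,
    on_path = {
      if (p$g_IS <= 0) stop("kappa_on undefined: g_IS must be > 0")
      if (p$E_L == p$E_I) stop("kappa_on undefined: E_L equals E_I")
      (p$g_S + p$g_IS) / (p$g_IS * (p$E_L - p$E_I))
    },
    out_of_path = {
      if (p$g_ES <= 0) stop("kappa_out undefined: g_ES must be > 0")
      if (p$E_L == p$E_E) stop("kappa_out undefined: E_L equals E_E")
      (p$g_S + p$g_ES) / (p$g_ES * (p$E_L - p$E_E))
    },
    paired_on_path = {
      if (p$g_IS <= 0) stop("kappa_Non undefined: g_IS must be > 0")
      if (p$E_L == p$E_I) stop("kappa_Non undefined: E_L equals E_I")
      (p$g_S + cfg$N * p$g_IS) / (p$g_IS * (p$E_L - p$E_I))
    },
    global_shunting = {
      if (p$E_L == p$E_I) stop("kappa_G undefined: E_L equals E_I")
      1 / (p$E_L - p$E_I)
    },
    single_per_branch = stop(
      "single_per_branch has no shunting term (responses add linearly)"),
    stop("unknown geometry: ", cfg$geometry))
}

#' Somatic time constant of the reduced model
#'
#' `tau_S = C_S / (g_S + load)` where the load is the summed branch-to-soma
#' transfer conductance of the geometry: `g_IS` (on-path), `g_ES`
#' (out-of-path), `N g_IS` (paired on-path), the per-type sum for
#' single-per-branch, and 0 for global shunting (peri-somatic inhibition,
#' `tau_S ~ C_S/g_S`).
#'
#' @inheritParams somatic_response_excitatory
#' @param n_E,n_I branch counts per synapse type for
#'   `"single_per_branch"` (default: all `N` excitatory).
#' @return tau_S in ms.
#' @export
tau_soma <- function(params = neuron_params(), config = "on_path", N = NULL,
                     n_E = NULL, n_I = NULL) {
  cfg <- .as_config(config)
  if (!is.null(N)) cfg$N <- as.integer(N)
  p <- params
  load <- switch(cfg$geometry,
    on_path = p$g_IS,
    out_of_path = p$g_ES,
    paired_on_path = cfg$N * p$g_IS,
    global_shunting = 0,
    single_per_branch = {
      if (is.null(n_E) && is.null(n_I)) { n_E <- cfg$N; n_I <- 0L }
      (if (is.null(n_E)) 0 else n_E) * p$g_ES +
        (if (is.null(n_I)) 0 else n_I) * p$g_IS
    },
    stop("unknown geometry: ", cfg$geometry))
  p$C_S / (p$g_S + load)
}

#' Steady somatic potential of the reduced model
#'
#' Assembles the geometry's combination of excitatory and inhibitory
#' response functions and shunting strength into the steady somatic
#' potential. For the two-site geometries,
#' `v = E_L + f_exc + f_inh + kappa * f_exc * f_inh`; for paired on-path
#' branches the multiplicative term is summed per branch; for
#' single-per-branch there is no multiplicative term; for global shunting
#' the per-branch excitatory responses are summed before the multiplication
#' and all inhibitory conductances are summed before `f_inh`.
#'
#' @param g_E excitatory conductance(s): a scalar for the two-site
#'   geometries, a length-`N` vector (one per branch) otherwise.
#' @param g_I inhibitory conductance(s): a scalar for two-site and paired
#'   geometries (paired accepts a length-`N` vector); for global shunting a
#'   scalar or a vector that is summed; for single-per-branch a vector of
#'   the inhibitory branches' conductances (may be length 0).
#' @inheritParams somatic_response_inhibitory
#' @return A list of class `response_decomposition` with elements `f_exc`
#'   (summed excitatory response, mV), `f_inh` (summed inhibitory response,
#'   mV), `kappa` (mV^-1, `NA` for single-per-branch), `interaction` (the
#'   multiplicative contribution actually entering the sum, mV) and
#'   `v_steady` (mV).
#' @export
steady_state_soma <- function(g_E, g_I, params = neuron_params(),
                              config = "on_path",
                              include_branch_load = TRUE) {
  cfg <- .as_config(config)
  p <- params
  if (any(g_E < 0) || any(g_I < 0)) stop("conductances must be >= 0")
  geom <- cfg$geometry
  if (geom %in% c("on_path", "out_of_path")) {
    if (length(g_E) != 1L || length(g_I) != 1L)
      stop("two-site geometries take scalar g_E and g_I")
    fe <- somatic_response_excitatory(g_E, p, cfg)
    fi <- somatic_response_inhibitory(g_I, p, cfg)
    k <- shunting_strength(p, cfg)
    inter <- k * fe * fi
  } else if (geom == "paired_on_path") {
    if (length(g_E) == 1L) g_E <- rep(g_E, cfg$N)
    if (length(g_I) == 1L) g_I <- rep(g_I, cfg$N)
    if (length(g_E) != cfg$N || length(g_I) != cfg$N)
      stop("paired_on_path needs per-branch conductance vectors of length N = ",
           cfg$N)
    fd <- somatic_response_excitatory(g_E, p, cfg)
    fp <- somatic_response_inhibitory(g_I, p, cfg)
    k <- shunting_strength(p, cfg)
    fe <- sum(fd); fi <- sum(fp); inter <- k * sum(fd * fp)
  } else if (geom == "global_shunting") {
    if (length(g_E) != cfg$N)
      stop("global_shunting needs a per-branch g_E vector of length N = ",
           cfg$N)
    fd <- somatic_response_excitatory(g_E, p, cfg)
    fi <- somatic_response_inhibitory(sum(g_I), p, cfg,
                                      include_branch_load = include_branch_load)
    k <- shunting_strength(p, cfg)
    fe <- sum(fd); inter <- k * fi * fe
  } else if (geom == "single_per_branch") {
    if (length(g_E) + length(g_I) != cfg$N)
      stop("single_per_branch needs length(g_E) + length(g_I) = N = ", cfg$N)
    # mixed-type branch load: g_S + n_E g_ES + n_I g_IS
    load <- p$g_S + length(g_E) * p$g_ES + length(g_I) * p$g_IS
    fe <- sum(p$g_ES * g_E * (p$E_E - p$E_L) / (load * (p$g_D + g_E)))
    fi <- sum(p$g_IS * g_I * (p$E_I - p$E_L) / (load * (p$g_D + g_I)))
    k <- NA_real_; inter <- 0
  } else stop("unknown geometry: ", geom)
  structure(list(f_exc = fe, f_inh = fi, kappa = k, interaction = inter,
                 v_steady = p$E_L + fe + fi + inter),
            class = "response_decomposition")
}

#' @export
print.response_decomposition <- function(x, ...) {
  cat(sprintf("<response_decomposition> f_exc=%.4g f_inh=%.4g kappa=%.4g interaction=%.4g v_steady=%.4g mV\n",
              x$f_exc, x$f_inh, x$kappa, x$interaction, x$v_steady))
  invisible(x)
}

#' Simulate the reduced neuron
#'
#' First-order relaxation of the somatic potential toward the instantaneous
#' reduced steady state, `tau_S dv/dt = -(v - E_L) + F(g_E(t), g_I(t))`,
#' with optional threshold/reset spiking. The drive functions are evaluated
#' on the instantaneous synaptic conductances each step (the dendritic
#' compartments are assumed instantly relaxed); no extra dendritic
#' filtering is applied.
#'
#' @inheritParams steady_state_soma
#' @param g_E excitatory conductance drive: a numeric vector with one value
#'   per step (two-site geometries) or an `N x nstep` matrix (branch
#'   geometries). Scalars are recycled.
#' @param g_I inhibitory drive: a vector per step (or `N x nstep` matrix
#'   for paired branches); scalars recycled. For global shunting a
#'   multi-row matrix is summed column-wise.
#' @param duration simulation time, ms.
#' @param dt integration step, ms.
#' @param threshold spike threshold, mV, or `NULL` (default) for
#'   sub-threshold dynamics. A typical spiking setting is -50.
#' @param reset reset potential after a spike, mV (default `E_L`).
#' @param v0 initial potential, mV (default `E_L`).
#' @return A list with `trace` (data.frame `time_ms`, `v_mV`) and
#'   `spike_times` (numeric vector, ms).
#' @export
simulate_reduced_neuron <- function(params, config, g_E, g_I,
                                    duration, dt = 0.1,
                                    threshold = NULL, reset = params$E_L,
                                    v0 = params$E_L,
                                    include_branch_load = TRUE) {
  cfg <- .as_config(config)
  if (dt <= 0) stop("dt must be > 0")
  nstep <- as.integer(round(duration / dt))
  drive_mat <- function(g, nr, nm) {
    if (is.matrix(g)) {
      if (ncol(g) != nstep) stop(nm, " matrix must have duration/dt columns")
      g
    } else if (length(g) == 1L) {
      matrix(g, nrow = nr, ncol = nstep)
    } else if (length(g) == nstep) {
      matrix(g, nrow = nr, ncol = nstep, byrow = TRUE)
    } else stop(nm, " must be scalar, per-step vector, or matrix")
  }
  p <- params
  geom <- cfg$geometry
  # drive F(t) = v_steady(t) - E_L, vectorized over steps
  if (geom %in% c("on_path", "out_of_path")) {
    gE <- drive_mat(g_E, 1L, "g_E")[1L, ]; gI <- drive_mat(g_I, 1L, "g_I")[1L, ]
    fe <- somatic_response_excitatory(gE, p, cfg)
    fi <- somatic_response_inhibitory(gI, p, cfg)
    F_t <- fe + fi + shunting_strength(p, cfg) * fe * fi
    tau <- tau_soma(p, cfg)
  } else if (geom == "paired_on_path") {
    gE <- drive_mat(g_E, cfg$N, "g_E"); gI <- drive_mat(g_I, cfg$N, "g_I")
    fd <- somatic_response_excitatory(gE, p, cfg)
    fp <- somatic_response_inhibitory(gI, p, cfg)
    F_t <- colSums(fd) + colSums(fp) +
      shunting_strength(p, cfg) * colSums(fd * fp)
    tau <- tau_soma(p, cfg)
  } else if (geom == "global_shunting") {
    gE <- drive_mat(g_E, cfg$N, "g_E")
    gI <- colSums(drive_mat(g_I, 1L, "g_I"))
    sum_fd <- colSums(somatic_response_excitatory(gE, p, cfg))
    fp <- somatic_response_inhibitory(gI, p, cfg,
                                      include_branch_load = include_branch_load)
    F_t <- sum_fd + fp + shunting_strength(p, cfg) * fp * sum_fd
    tau <- tau_soma(p, cfg)
  } else stop("simulate_reduced_neuron: unsupported geometry ", geom)
  v <- v0
  out <- numeric(nstep + 1L); out[1L] <- v
  spikes <- numeric(0)
  a <- dt / tau
  for (k in seq_len(nstep)) {
    v <- v + a * (-(v - p$E_L) + F_t[k])
    if (!is.null(threshold) && v >= threshold) {
      spikes <- c(spikes, k * dt)
      v <- reset
    }
    out[k + 1L] <- v
  }
  list(trace = data.frame(time_ms = seq(0, by = dt, length.out = nstep + 1L),
                          v_mV = out),
       spike_times = spikes)
}

#' Multiplicative decomposition of a mixed conductance ratio
#'
#' The algebraic identity behind the multiplicative shunting rule: a mixed
#' expression `(h + beta*g_I)/(gamma + g_I)`, in which excitation (through
#' `h`) and inhibition (through `g_I`) are entangled by the shared
#' denominator, separates exactly into
#' `f1(g_I) + f2(h) - (1/beta) f1(g_I) f2(h)` with
#' `f1 = beta*g_I/(gamma + g_I)` and `f2 = h/gamma`.
#'
#' @param h excitatory numerator term (any real; mV*nS scale).
#' @param beta inhibitory driving force, mV (non-zero; in the reduced
#'   models this is `E_I - E_L`).
#' @param gamma denominator constant, nS (> 0, with `gamma + g_I > 0`).
#' @param g_I inhibitory conductance, nS.
#' @return A list with `f1`, `f2`, `reconstruction`
#'   (`f1 + f2 - f1*f2/beta`) and `target` (`(h + beta*g_I)/(gamma + g_I)`);
#'   `reconstruction == target` to machine precision.
#' @export
decompose_multiplicative <- function(h, beta, gamma, g_I) {
  if (any(beta == 0)) stop("decomposition undefined for beta = 0")
  if (any(gamma <= 0) || any(gamma + g_I <= 0))
    stop("require gamma > 0 and gamma + g_I > 0")
  f1 <- beta * g_I / (gamma + g_I)
  f2 <- h / gamma
  list(f1 = f1, f2 = f2,
       reconstruction = f1 + f2 - f1 * f2 / beta,
       target = (h + beta * g_I) / (gamma + g_I))
}
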