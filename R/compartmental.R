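# Three-compartment conductance model: soma coupled to two dendritic sites
# in series (soma -- proximal -- distal). On-path: the inhibitory synapse is
# proximal (between the excitatory site and the soma). Out-of-path: the
# labels E and I are interchanged throughout, so the excitatory synapse is
# proximal and its transfer conductances carry the amplification alpha
# (g_ES = alpha*g_SE, g_EI = alpha*g_IE).

# Coefficient matrix and RHS of the steady-state system, in the voltage
# order (v_S, v_I, v_E). Shared by the solver and the ODE integrator.
.tri_system <- function(params, g_E, g_I, arrangement) {
  p <- params
  if (arrangement == "on_path") {
    A <- rbind(
      c(p$g_S + p$g_IS,            -p$g_IS,                       0),
      c(-p$g_SI, p$g_D + p$g_SI + p$g_EI + g_I,             -p$g_EI),
      c(0,                         -p$g_IE, p$g_D + p$g_IE + g_E))
    b <- c(p$g_S * p$E_L,
           p$g_D * p$E_L + g_I * p$E_I,
           p$g_D * p$E_L + g_E * p$E_E)
  } else {
    A <- rbind(
      c(p$g_S + p$g_ES,            0,                       -p$g_ES),
      c(0, p$g_D + p$g_EI + g_I,                            -p$g_EI),
      c(-p$g_SE, -p$g_IE, p$g_D + p$g_SE + p$g_IE + g_E))
    b <- c(p$g_S * p$E_L,
           p$g_D * p$E_L + g_I * p$E_I,
           p$g_D * p$E_L + g_E * p$E_E)
  }
  list(A = A, b = b)
}

.check_arrangement <- function(config) {
  if (inherits(config, "dendritic_config")) config <- config$geometry
  if (!config %in% c("on_path", "out_of_path"))
    stop("arrangement must be 'on_path' or 'out_of_path'")
  config
}

#' Steady state of the three-compartment model
#'
#' Exact solution of the 3x3 linear system obtained by setting the
#' compartmental membrane equations to steady state under constant synaptic
#' drive. No small-transfer-conductance approximation is made; this is the
#' ground truth against which the reduced single-compartment models are
#' checked.
#'
#' @param params a [neuron_params()] object.
#' @param g_E excitatory synaptic conductance, nS (scalar >= 0).
#' @param g_I inhibitory synaptic conductance, nS (scalar >= 0).
#' @param config `"on_path"` (inhibition proximal, default) or
#'   `"out_of_path"` (labels exchanged), or a [dendritic_config()].
#' @return Named numeric vector `c(v_S, v_I, v_E)` of steady-state
#'   potentials in mV.
#' @examples
#' steady_state_three_compartment(neuron_params(), g_E = 2, g_I = 0)
#' @export
steady_state_three_compartment <- function(params, g_E, g_I,
                                           config = "on_path") {
  stopifnot(inherits(params, "neuron_params"))
  arrangement <- .check_arrangement(config)
  if (!is.numeric(g_E) || length(g_E) != 1L || g_E < 0 ||
      !is.numeric(g_I) || length(g_I) != 1L || g_I < 0)
    stop("g_E and g_I must be non-negative scalars")
  sys <- .tri_system(params, g_E, g_I, arrangement)
  v <- tryCatch(solve(sys$A, sys$b), error = function(e)
    stop("singular steady-state system (degenerate conductances): ",
         conditionMessage(e)))
  names(v) <- c("v_S", "v_I", "v_E")
  v
}

#' Simulate the three-compartment model
#'
#' Forward (explicit Euler) integration of the coupled membrane equations of
#' the soma and the two dendritic sites, under a time-varying synaptic
#' conductance drive. With constant drive the traces converge to
#' [steady_state_three_compartment()].
#'
#' @inheritParams steady_state_three_compartment
#' @param g_E,g_I synaptic conductances, either scalars (constant drive) or
#'   numeric vectors with one value per time step.
#' @param duration simulation time, ms.
#' @param dt integration step, ms (0.01 recommended given the ~1.7 ms
#'   dendritic time constants).
#' @param v0 initial potentials; a single value or a length-3 vector
#'   `(v_S, v_I, v_E)`. Defaults to `E_L`.
#' @return A data.frame with columns `time_ms`, `v_S`, `v_I`, `v_E`.
#' @export
simulate_three_compartment <- function(params, g_E, g_I,
                                       config = "on_path",
                                       duration = 200, dt = 0.01,
                                       v0 = NULL) {
  stopifnot(inherits(params, "neuron_params"))
  arrangement <- .check_arrangement(config)
  if (dt <= 0) stop("dt must be > 0")
  if (duration < dt) stop("duration must be >= dt")
  nstep <- as.integer(round(duration / dt))
  g_E <- .expand_drive(g_E, nstep, "g_E")
  g_I <- .expand_drive(g_I, nstep, "g_I")
  p <- params
  if (is.null(v0)) v0 <- rep(p$E_L, 3)
  if (length(v0) == 1L) v0 <- rep(v0, 3)
  v <- as.numeric(v0)
  caps <- c(p$C_S, p$C_D, p$C_D)
  out <- matrix(NA_real_, nrow = nstep + 1L, ncol = 3L)
  out[1L, ] <- v
  vmax <- abs(p$E_E) + abs(p$E_I) + 100
  for (k in seq_len(nstep)) {
    sys <- .tri_system(p, g_E[k], g_I[k], arrangement)
    # membrane currents: b - A %*% v  (pA); dv = dt * current / C
    v <- v + dt * (sys$b - as.numeric(sys$A %*% v)) / caps
    if (any(!is.finite(v)) || any(abs(v) > vmax))
      stop("integration diverged at step ", k, " (t = ", k * dt,
           " ms); reduce dt")
    out[k + 1L, ] <- v
  }
  data.frame(time_ms = seq(0, by = dt, length.out = nstep + 1L),
             v_S = out[, 1L], v_I = out[, 2L], v_E = out[, 3L])
}

.expand_drive <- function(g, nstep, name) {
  if (!is.numeric(g) || any(g < 0)) stop(name, " must be non-negative")
  if (length(g) == 1L) return(rep(g, nstep))
  if (length(g) != nstep)
    stop(name, " must be scalar or of length duration/dt = ", nstep)
  g
}

#' Empirical shunting strength from the full model
#'
#' Extracts the shunting strength kappa (mV^-1) from the full
#' three-compartment steady state by inverting the arithmetic integration
#' rule `DeltaV = DeltaV_E + DeltaV_I + kappa * DeltaV_E * DeltaV_I`:
#' the individual excitatory and inhibitory somatic deflections are
#' subtracted from the joint deflection and the remainder is divided by
#' their product.
#'
#' @inheritParams steady_state_three_compartment
#' @param g_E,g_I synaptic conductances, nS; both must be > 0 (the rule is
#'   undefined for single inputs).
#' @return kappa in mV^-1.
#' @examples
#' extract_shunting_strength(neuron_params(), g_E = 2, g_I = 2)
#' @export
extract_shunting_strength <- function(params, g_E, g_I, config = "on_path") {
  if (!is.numeric(g_E) || g_E <= 0 || !is.numeric(g_I) || g_I <= 0)
    stop("kappa extraction requires g_E > 0 and g_I > 0 ",
         "(both individual contributions must be nonzero)")
  arrangement <- .check_arrangement(config)
  E_L <- params$E_L
  d_both <- steady_state_three_compartment(params, g_E, g_I, arrangement)[["v_S"]] - E_L
  d_E <- steady_state_three_compartment(params, g_E, 0, arrangement)[["v_S"]] - E_L
  d_I <- steady_state_three_compartment(params, 0, g_I, arrangement)[["v_S"]] - E_L
  (d_both - d_E - d_I) / (d_E * d_I)
}

#' Transfer conductance from cable distance
#'
#' Passive-cable rule `g_trf(x) = g_max / (mu * x + 1)`: the resistance
#' between two dendritic points grows linearly with their distance.
#'
#' @param x distance (arbitrary units, >= 0); vectorized.
#' @param model a [distance_model()].
#' @return Transfer conductance(s) in nS, strictly decreasing in `x`.
#' @export
transfer_conductance_from_distance <- function(x, model = distance_model()) {
  stopifnot(inherits(model, "distance_model"))
  if (!is.numeric(x) || any(x < 0)) stop("distance x must be >= 0")
  model$g_max / (model$mu_spatial * x + 1)
}

# Neuron parameters implied by synapse positions under the distance rule.
# The inhibitory anchor fixes g_SI (equivalently the position x_I); the
# excitatory position x_E selects on-path (x_E > x_I) or out-of-path
# (x_E < x_I). Out-of-path uses the series-resistance constraint
# 1/g_SE + 1/g_IE = 1/g_SI.
.params_at_positions <- function(base, g_SI_anchor, x_E, model) {
  alpha <- base$alpha
  x_I <- (model$g_max / g_SI_anchor - 1) / model$mu_spatial
  if (x_E > x_I) {
    g_IE <- transfer_conductance_from_distance(x_E - x_I, model)
    list(arrangement = "on_path",
         params = neuron_params(E_L = base$E_L, E_E = base$E_E, E_I = base$E_I,
                                C_S = base$C_S, C_D = base$C_D,
                                g_S = base$g_S, g_D = base$g_D,
                                g_SI = g_SI_anchor, g_SE = base$g_SE,
                                g_IE = g_IE, alpha = alpha))
  } else {
    g_SE <- transfer_conductance_from_distance(x_E, model)
    if (g_SE <= g_SI_anchor)
      stop("out-of-path series constraint requires g_SE > g_SI ",
           "(excitatory site must be closer to the soma)")
    g_IE <- 1 / (1 / g_SI_anchor - 1 / g_SE)
    list(arrangement = "out_of_path",
         params = neuron_params(E_L = base$E_L, E_E = base$E_E, E_I = base$E_I,
                                C_S = base$C_S, C_D = base$C_D,
                                g_S = base$g_S, g_D = base$g_D,
                                g_SI = g_SI_anchor, g_SE = g_SE,
                                g_IE = g_IE, alpha = alpha))
  }
}

#' Shunting strength versus synapse distance
#'
#' Scans the full-model shunting strength as the excitatory site is moved
#' along the dendrite while the inhibitory site is held at fixed anchor
#' positions (parameterized by their soma-to-I transfer conductance
#' `g_SI`). Where `x_E` crosses the inhibitory position the configuration
#' switches from out-of-path to on-path. Transfer conductances follow the
#' distance rule of [transfer_conductance_from_distance()]; for
#' out-of-path positions the series-resistance constraint
#' `1/g_SE + 1/g_IE = 1/g_SI` is imposed.
#'
#' @param params a [neuron_params()] object supplying everything except the
#'   position-dependent transfer conductances.
#' @param anchors numeric vector of `g_SI` anchor values, nS (e.g.
#'   `c(2.2, 3, 5)`; a smaller anchor means a more distal inhibitory site).
#' @param x_E numeric vector of excitatory positions (distance from soma,
#'   arbitrary units).
#' @param g_E,g_I synaptic conductances used for the kappa extraction, nS.
#' @param model a [distance_model()].
#' @return A data.frame with columns `x_E`, `g_SI_anchor`, `arrangement`,
#'   `kappa`.
#' @export
kappa_distance_scan <- function(params, anchors, x_E,
                                g_E = 2, g_I = 2,
                                model = distance_model()) {
  stopifnot(inherits(params, "neuron_params"))
  if (length(anchors) == 0L) stop("anchor list must not be empty")
  if (any(anchors <= 0)) stop("anchors must be positive conductances")
  if (any(x_E <= 0)) stop("positions must be positive")
  rows <- list()
  for (anc in anchors) {
    x_I <- (model$g_max / anc - 1) / model$mu_spatial
    for (x in x_E) {
      if (isTRUE(all.equal(x, x_I))) next  # co-localized sites: undefined
      geo <- .params_at_positions(params, anc, x, model)
      k <- extract_shunting_strength(geo$params, g_E, g_I, geo$arrangement)
      rows[[length(rows) + 1L]] <-
        data.frame(x_E = x, g_SI_anchor = anc,
                   arrangement = geo$arrangement, kappa = k)
    }
  }
  do.call(rbind, rows)
}
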