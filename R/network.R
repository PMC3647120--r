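# Recurrent spiking network of excitatory and inhibitory populations in
# which every neuron integrates its inputs through the global-shunting
# reduced model: one dendritic branch per excitatory input (per-branch
# saturating response f_Gd), all inhibitory inputs summed peri-somatically
# (f_Gp), and a multiplicative kappa_G coupling between the two.
#
# Because every synapse made by presynaptic neuron j carries the same
# spike train, weight and time constant, all its conductances share one
# trace; the per-neuron branch sums therefore reduce to sparse
# adjacency-matrix products, which keeps the integration loop in
# vectorized R.

#' Build fixed in-degree connectivity
#'
#' Samples, for every neuron of the network (excitatory neurons first,
#' then inhibitory), exactly `round(p*N_E)` excitatory and `round(p*N_I)`
#' inhibitory presynaptic partners without replacement, excluding
#' self-connections. Each excitatory input has its own dendritic branch.
#' With `fixed_in_degree = FALSE`, partners are instead included
#' independently with probability `p` (in-degrees then vary).
#'
#' @param net a [network_params()]; `net$seed` makes the sample
#'   reproducible.
#' @return An object of class `connectivity`: a list with integer matrices
#'   `pre_E` (`N x k_E`) and `pre_I` (`N x k_I`) of presynaptic ids
#'   (E ids in `1..N_E`, I ids in `1..N_I`), or ragged lists when
#'   `fixed_in_degree = FALSE`.
#' @export
build_connectivity <- function(net) {
  stopifnot(inherits(net, "network_params"))
  kE <- as.integer(round(net$p * net$N_E))
  kI <- as.integer(round(net$p * net$N_I))
  if (kE < 1 || kI < 1)
    stop("p*N_E and p*N_I must both be >= 1 (got ", kE, ", ", kI, ")")
  N <- net$N_E + net$N_I
  set.seed(net$seed)
  if (net$fixed_in_degree) {
    pre_E <- matrix(0L, nrow = N, ncol = kE)
    pre_I <- matrix(0L, nrow = N, ncol = kI)
    for (i in seq_len(N)) {
      poolE <- if (i <= net$N_E) seq_len(net$N_E)[-i] else seq_len(net$N_E)
      pre_E[i, ] <- sample(poolE, kE)
      poolI <- if (i > net$N_E) seq_len(net$N_I)[-(i - net$N_E)]
               else seq_len(net$N_I)
      pre_I[i, ] <- sample(poolI, kI)
    }
  } else {
    pre_E <- lapply(seq_len(N), function(i) {
      poolE <- if (i <= net$N_E) seq_len(net$N_E)[-i] else seq_len(net$N_E)
      poolE[stats::runif(length(poolE)) < net$p]
    })
    pre_I <- lapply(seq_len(N), function(i) {
      poolI <- if (i > net$N_E) seq_len(net$N_I)[-(i - net$N_E)]
               else seq_len(net$N_I)
      poolI[stats::runif(length(poolI)) < net$p]
    })
  }
  structure(list(pre_E = pre_E, pre_I = pre_I,
                 N_E = net$N_E, N_I = net$N_I,
                 fixed_in_degree = net$fixed_in_degree),
            class = "connectivity")
}

.adjacency <- function(pre, N, ncols) {
  if (is.matrix(pre)) {
    Matrix::sparseMatrix(i = rep(seq_len(N), each = ncol(pre)),
                         j = as.integer(t(pre)), x = 1,
                         dims = c(N, ncols))
  } else {
    lens <- lengths(pre)
    Matrix::sparseMatrix(i = rep(seq_len(N), lens),
                         j = unlist(pre), x = 1, dims = c(N, ncols))
  }
}

#' Simulate the global-shunting spiking network
#'
#' Euler-Maruyama integration (step `net$dt`) of
#' `tau_S dv_i/dt = -(v_i - E_L) + J_i + sigma*xi_i` where the synaptic
#' input `J_i` sums the per-branch excitatory responses
#' `f_Gd(g_ij^E + g_ext)` (the external stimulus conductance `g_ext` is
#' added to every branch during the stimulus window), the peri-somatic
#' inhibitory response `f_Gp(sum_j g_ij^I)`, and the multiplicative global
#' shunting term `kappa_G * f_Gp * sum f_Gd`. A neuron crossing `E_thres`
#' emits a spike (delivered to its targets on the next step) and resets to
#' `E_reset`. Synaptic conductances follow the exponential dynamics of
#' [evolve_conductance()] with `(tau_E, w_E)` and `(tau_I, w_I)`.
#'
#' The per-branch response uses `N = round(p*N_E)` branches and the full
#' branch load in its denominator; the peri-somatic inhibitory response
#' omits the branch load by default (`net$include_branch_load = FALSE`),
#' consistent with `tau_S ~ C_S/g_S`; see the vignette for why this
#' choice is required for a low-rate persistent state.
#'
#' @param net a [network_params()].
#' @param neuron a [neuron_params()] (supplies `E_L`, `E_E`, `E_I`, `g_S`,
#'   `g_D`, `g_ES`).
#' @param duration simulation time, ms.
#' @param connectivity optional pre-built [build_connectivity()] result;
#'   rebuilt from `net` when `NULL`.
#' @param record_v optional integer vector of neuron ids whose voltage
#'   traces to record.
#' @return An object of class `network_sim`: list with `raster`
#'   (data.frame `time_ms`, `neuron_id`, `pop` with `"E"`/`"I"`; neuron ids
#'   `1..N_E` are excitatory, `N_E+1..N_E+N_I` inhibitory), `duration`,
#'   `net`, `neuron`, and optionally `v_traces`.
#' @export
simulate_network <- function(net, neuron = neuron_params(), duration = 500,
                             connectivity = NULL, record_v = NULL) {
  stopifnot(inherits(net, "network_params"), inherits(neuron, "neuron_params"))
  if (duration <= 0) stop("duration must be > 0")
  if (is.null(connectivity)) connectivity <- build_connectivity(net)
  N <- net$N_E + net$N_I
  A <- .adjacency(connectivity$pre_E, N, net$N_E)
  B <- .adjacency(connectivity$pre_I, N, net$N_I)
  Nb <- as.integer(round(net$p * net$N_E))  # branches per neuron
  p <- neuron
  k_fd <- p$g_ES * (p$E_E - p$E_L) / (p$g_S + Nb * p$g_ES)
  gI_load <- p$g_S + if (net$include_branch_load) Nb * p$g_ES else 0
  kappa_G <- if (is.null(net$kappa_G)) 1 / (p$E_L - p$E_I) else net$kappa_G
  dt <- net$dt
  nstep <- as.integer(round(duration / dt))
  decE <- exp(-dt / net$tau_E); decI <- exp(-dt / net$tau_I)
  tauS <- c(rep(net$C_S_E / p$g_S, net$N_E), rep(net$C_S_I / p$g_S, net$N_I))
  euler <- dt / tauS
  noise_amp <- net$sigma * sqrt(dt / tauS)
  stim_mask_E <- rep(TRUE, N)
  if (net$stim_population == "E") stim_mask_E[(net$N_E + 1L):N] <- FALSE

  set.seed(net$seed + 1L)  # offset: connectivity consumed net$seed
  v <- rep(p$E_L, N)
  sE <- numeric(net$N_E); sI <- numeric(net$N_I)
  prev_E <- integer(0); prev_I <- integer(0)
  spikes_t <- vector("list", nstep)
  rec <- if (!is.null(record_v))
    matrix(NA_real_, nrow = nstep + 1L, ncol = length(record_v)) else NULL
  if (!is.null(rec)) rec[1L, ] <- v[record_v]

  for (k in seq_len(nstep)) {
    t_ms <- k * dt
    sE <- sE * decE
    sI <- sI * decI
    if (length(prev_E)) sE <- sE + net$w_E * tabulate(prev_E, net$N_E)
    if (length(prev_I)) sI <- sI + net$w_I * tabulate(prev_I, net$N_I)
    stim_on <- t_ms > net$stim_onset && t_ms <= net$stim_offset
    gx <- if (stim_on) net$g_ext else 0
    ge <- sE + gx
    fd <- k_fd * ge / (p$g_D + ge)
    sum_fd <- as.numeric(A %*% fd)
    if (stim_on && !all(stim_mask_E)) {
      # population-restricted stimulus: recompute unstimulated rows
      fd0 <- k_fd * sE / (p$g_D + sE)
      sum_fd0 <- as.numeric(A %*% fd0)
      sum_fd[!stim_mask_E] <- sum_fd0[!stim_mask_E]
    }
    G_I <- as.numeric(B %*% sI)
    f_gp <- G_I * (p$E_I - p$E_L) / (gI_load + G_I)
    J <- sum_fd + f_gp + kappa_G * f_gp * sum_fd
    v <- v + euler * (-(v - p$E_L) + J) + noise_amp * stats::rnorm(N)
    if (any(!is.finite(v)))
      stop("network simulation diverged (non-finite voltage) at step ", k)
    sp <- which(v >= net$E_thres)
    if (length(sp)) v[sp] <- net$E_reset
    spikes_t[[k]] <- sp
    prev_E <- sp[sp <= net$N_E]
    prev_I <- sp[sp > net$N_E] - net$N_E
    if (!is.null(rec)) rec[k + 1L, ] <- v[record_v]
  }
  ns <- lengths(spikes_t)
  raster <- data.frame(
    time_ms = rep(seq_len(nstep) * dt, ns),
    neuron_id = unlist(spikes_t),
    pop = character(sum(ns)))
  raster$pop <- ifelse(raster$neuron_id <= net$N_E, "E", "I")
  out <- list(raster = raster, duration = duration, net = net, neuron = neuron)
  if (!is.null(rec)) {
    vt <- data.frame(seq(0, by = dt, length.out = nstep + 1L), rec)
    names(vt) <- c("time_ms", paste0("v_", record_v))
    out$v_traces <- vt
  }
  structure(out, class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf("<network_sim> %d E + %d I neurons, %g ms, %d spikes\n",
              x$net$N_E, x$net$N_I, x$duration, nrow(x$raster)))
  invisible(x)
}

#' Population firing rate from a raster
#'
#' Mean single-neuron firing rate of a population in a time window: total
#' spikes of the population inside the window divided by population size
#' and window length.
#'
#' @param sim a `network_sim` object from [simulate_network()], or a raster
#'   data.frame with columns `time_ms` and `pop` (then `n_pop` is
#'   required).
#' @param population `"E"` or `"I"`.
#' @param window length-2 numeric `(start, end)` in ms; spikes in
#'   `(start, end]` are counted.
#' @param n_pop population size when `sim` is a bare raster.
#' @return Rate in Hz.
#' @export
population_rate <- function(sim, population = c("E", "I"), window,
                            n_pop = NULL) {
  population <- match.arg(population)
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be (start, end) with end > start")
  if (inherits(sim, "network_sim")) {
    raster <- sim$raster
    n_pop <- if (population == "E") sim$net$N_E else sim$net$N_I
    if (window[2] > sim$duration + 1e-9)
      stop("window extends beyond the simulation")
  } else {
    raster <- sim
    if (is.null(n_pop)) stop("n_pop is required for a bare raster")
  }
  n <- sum(raster$pop == population &
             raster$time_ms > window[1] & raster$time_ms <= window[2])
  n / (n_pop * (window[2] - window[1]) / 1000)
}
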