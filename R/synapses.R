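# Spike-driven exponential synaptic conductances and spike-train fixtures.

#' Spike train constructor
#'
#' A validated container for presynaptic spike times: sorted, non-negative,
#' finite, in ms.
#'
#' @param times numeric vector of spike times, ms.
#' @param source optional source identifier.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times = numeric(0), source = NULL) {
  if (!is.numeric(times)) stop("spike times must be numeric")
  if (any(!is.finite(times)) || any(times < 0))
    stop("spike times must be finite and non-negative")
  if (is.unsorted(times, strictly = FALSE))
    stop("spike times must be sorted increasingly")
  structure(list(times = as.numeric(times), source = source),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes%s\n", length(x$times),
              if (is.null(x$source)) "" else paste0(" from ", x$source)))
  invisible(x)
}

#' Evolve an exponential synaptic conductance
#'
#' Integrates `tau dg/dt = -g + tau * w * sum_m delta(t - t_m)` on a fixed
#' time grid: between spikes the conductance decays by the exact per-step
#' factor `exp(-dt/tau)` (so the spike-free trajectory carries no
#' integrator error), and each presynaptic spike increments it by exactly
#' `w` (the delta pulse integrates to `w`). Spikes are binned to the grid;
#' k spikes in one bin increment by `k*w`.
#'
#' @param g0 initial conductance, nS (>= 0).
#' @param train a [spike_train()] (times within `[0, duration]`).
#' @param params a [synapse_params()].
#' @param duration trace length, ms.
#' @param dt grid step, ms.
#' @return data.frame with columns `time_ms`, `g_nS`; the sample at
#'   `time_ms = t` includes increments from spikes binned at `t`.
#' @examples
#' # pure decay: g(100) = 10/e for tau = 100
#' tr <- evolve_conductance(10, spike_train(), synapse_params(100, 1), 100, 0.1)
#' tail(tr$g_nS, 1)
#' @export
evolve_conductance <- function(g0, train, params, duration, dt = 0.1) {
  stopifnot(inherits(train, "spike_train"), inherits(params, "synapse_params"))
  if (dt <= 0) stop("dt must be > 0")
  if (g0 < 0) stop("g0 must be >= 0")
  if (length(train$times) && max(train$times) > duration)
    stop("spike train extends beyond duration")
  nstep <- as.integer(round(duration / dt))
  # bin index 0..nstep; a spike at time t lands on grid sample round(t/dt)
  inc <- numeric(nstep + 1L)
  if (length(train$times)) {
    idx <- pmin(pmax(as.integer(round(train$times / dt)), 0L), nstep) + 1L
    tab <- tabulate(idx, nbins = nstep + 1L)
    inc <- params$w * tab
  }
  dec <- exp(-dt / params$tau)
  g <- numeric(nstep + 1L)
  g[1L] <- g0 + inc[1L]
  for (k in seq_len(nstep)) g[k + 1L] <- g[k] * dec + inc[k + 1L]
  data.frame(time_ms = seq(0, by = dt, length.out = nstep + 1L), g_nS = g)
}

#' Homogeneous Poisson spike train
#'
#' Seeded fixture generator: a homogeneous Poisson process of the given
#' rate on `[0, duration]`. Used to drive single-neuron simulations and to
#' validate the mean-field substitution `g ~ w * tau * r`.
#'
#' @param rate firing rate, Hz (>= 0).
#' @param duration interval length, ms.
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit, and identical seeds give identical trains.
#' @return A [spike_train()].
#' @export
poisson_spike_train <- function(rate, duration, seed = NULL) {
  if (!is.numeric(rate) || rate < 0) stop("rate must be >= 0")
  if (duration < 0) stop("duration must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  n <- stats::rpois(1L, rate * duration / 1000)
  spike_train(sort(stats::runif(n, 0, duration)))
}
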