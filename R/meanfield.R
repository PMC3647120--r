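# Rate-based mean-field reduction of the global-shunting network.
#
# Population-averaged synaptic conductances obey
#   tau_E dgE/dt = -gE + wE tauE rE,   tau_I dgI/dt = -gI + wI tauI rI,
# rates follow a threshold-linear transfer r = mu [J - beta]_+, and the
# response functions are linearized around the operating point:
# f_Gd ~ a*gE + b, f_Gp ~ c*(N_I p gI) + d. The self-consistent input then
# becomes quadratic in the excitatory rate through the multiplicative
# shunting term, and the persistent-activity rate is the admissible root.

#' Mean-field parameters
#'
#' Threshold-linear gains, response-function linearization constants and
#' network constants of the mean-field reduction. Defaults are the
#' reference persistent-activity setting; the linearization constants
#' `(a, b, c, d)` are taken as authoritative published values and can
#' alternatively be recomputed with [linearize_global_responses()] (the
#' two routes are kept distinct deliberately, see the vignette).
#'
#' Units: rates in Hz; `tau_E`, `tau_I` are accepted in ms and converted
#' to seconds inside the products `w*tau*r`, so conductances stay in nS.
#'
#' @param mu_E,mu_I threshold-linear gains, Hz/mV (`a > 0` requires
#'   admissibility `mu_E > 0`, `mu_I > 0`).
#' @param beta rate threshold, mV.
#' @param a,b slope (mV/nS) and intercept (mV) of the linearized per-branch
#'   excitatory response (`a > 0`, `b >= 0`).
#' @param c_,d slope and intercept of the linearized global inhibitory
#'   response (`c_ < 0`, `d <= 0`).
#' @param kappa_G global shunting strength, mV^-1.
#' @param w_E,w_I synaptic weights, nS.
#' @param tau_E,tau_I synaptic time constants, ms.
#' @param p connection probability.
#' @param N_E,N_I population sizes.
#' @return An object of class `meanfield_params`.
#' @export
meanfield_params <- function(mu_E = 3.2, mu_I = 6.4, beta = 17.5,
                             a = 0.002, b = 0.175, c_ = -0.113, d = -0.6218,
                             kappa_G = 0.1,
                             w_E = 24, w_I = 2, tau_E = 100, tau_I = 10,
                             p = 0.1, N_E = 2000L, N_I = 500L) {
  if (a <= 0 || b < 0 || c_ >= 0 || d > 0)
    stop("admissibility requires a > 0, b >= 0, c_ < 0, d <= 0")
  if (mu_E <= 0 || mu_I <= 0) stop("gains must be positive")
  structure(list(mu_E = mu_E, mu_I = mu_I, beta = beta,
                 a = a, b = b, c_ = c_, d = d, kappa_G = kappa_G,
                 w_E = w_E, w_I = w_I, tau_E = tau_E, tau_I = tau_I,
                 p = p, N_E = as.integer(N_E), N_I = as.integer(N_I)),
            class = "meanfield_params")
}

#' Linearize the global-shunting response functions
#'
#' Tangent-line coefficients of the per-branch excitatory response `f_Gd`
#' at a per-branch conductance `g_E` and of the peri-somatic inhibitory
#' response `f_Gp` at a summed inhibitory conductance `G_I` (closed-form
#' derivatives): returns `(a, b, c, d)` with `f_Gd(g) ~ a*g + b` near
#' `g_E` and `f_Gp(G) ~ c*G + d` near `G_I`. At the origin both intercepts
#' are zero; `a > 0` and `c < 0` always hold for the standard reversal
#' ordering.
#'
#' @param neuron a [neuron_params()].
#' @param N number of dendritic branches.
#' @param operating_point numeric `(g_E, G_I)` in nS, non-negative.
#' @param include_branch_load logical; whether `f_Gp` keeps the `N*g_ES`
#'   load (see [somatic_response_inhibitory()]).
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
linearize_global_responses <- function(neuron, N, operating_point = c(0, 0),
                                       include_branch_load = TRUE) {
  stopifnot(inherits(neuron, "neuron_params"), length(operating_point) == 2L)
  if (any(operating_point < 0)) stop("operating point must be non-negative")
  p <- neuron
  g0 <- operating_point[1]; G0 <- operating_point[2]
  S <- p$g_S + N * p$g_ES
  # f_Gd = g_ES * g * (E_E - E_L) / ((g_D + g) * S): d/dg = k * g_D/(g_D+g)^2
  kd <- p$g_ES * (p$E_E - p$E_L) / S
  a <- kd * p$g_D / (p$g_D + g0)^2
  b <- kd * g0 / (p$g_D + g0) - a * g0
  SI <- p$g_S + if (include_branch_load) N * p$g_ES else 0
  # f_Gp = G * (E_I - E_L) / (SI + G): d/dG = (E_I - E_L) * SI/(SI+G)^2
  cc <- (p$E_I - p$E_L) * SI / (SI + G0)^2
  d <- G0 * (p$E_I - p$E_L) / (SI + G0) - cc * G0
  c(a = a, b = b, c = cc, d = d)
}

#' Mean-field input coefficients
#'
#' The coefficients of the self-consistent synaptic input
#' `J = A1*r_E + A2*r_I + A3*r_E*r_I + A4`:
#' `A1 = a wE tauE p NE (1 + d kG)`,
#' `A2 = c wI tauI p NI (1 + b kG p NE)`,
#' `A3 = kG (a wE tauE p NE)(c wI tauI p NI)`,
#' `A4 = b p NE (1 + d kG) + d`. At `kappa_G = 0` the shunting pathway
#' vanishes (`A3 = 0`) and the network is purely linear.
#'
#' @param mf a [meanfield_params()].
#' @return Named numeric vector `c(A1, A2, A3, A4)`.
#' @export
meanfield_coefficients <- function(mf) {
  stopifnot(inherits(mf, "meanfield_params"))
  tE <- mf$tau_E / 1000; tI <- mf$tau_I / 1000
  kG <- mf$kappa_G
  eE <- mf$a * mf$w_E * tE * mf$p * mf$N_E
  eI <- mf$c_ * mf$w_I * tI * mf$p * mf$N_I
  c(A1 = eE * (1 + mf$d * kG),
    A2 = eI * (1 + mf$b * kG * mf$p * mf$N_E),
    A3 = kG * eE * eI,
    A4 = mf$b * mf$p * mf$N_E * (1 + mf$d * kG) + mf$d)
}

#' Mean-field fixed point
#'
#' Solves the self-consistency condition for the population rates. With
#' `B1 = mu_E(A4 - beta)`, `B2 = mu_E A1 + mu_I A2 - 1`, `B3 = mu_I A3`,
#' the excitatory rate satisfies `B3 r^2 + B2 r + B1 = 0` and the
#' admissible root is taken in the rationalized form
#' `r_E = 2 B1 / (-B2 + sqrt(B2^2 - 4 B1 B3))`; the inhibitory rate is
#' `r_I = (mu_I/mu_E) r_E` and the fixed-point conductances are
#' `gE = r_E wE tauE`, `gI = r_I wI tauI`.
#'
#' @param mf a [meanfield_params()].
#' @return An object of class `meanfield_solution`: list with `A` (A1..A4),
#'   `B` (B1..B3), `r_E_bar`, `r_I_bar` (Hz), `g_E_bar`, `g_I_bar` (nS).
#' @export
meanfield_fixed_point <- function(mf) {
  A <- meanfield_coefficients(mf)
  B <- c(B1 = mf$mu_E * (A[["A4"]] - mf$beta),
         B2 = mf$mu_E * A[["A1"]] + mf$mu_I * A[["A2"]] - 1,
         B3 = mf$mu_I * A[["A3"]])
  B1 <- B[["B1"]]; B2 <- B[["B2"]]; B3 <- B[["B3"]]
  if (abs(B3) < 1e-14) {
    # linear limit (kappa_G = 0): B2 r + B1 = 0
    if (abs(B2) < 1e-14) stop("no steady state: degenerate linear system")
    rE <- -B1 / B2
    if (rE < 0) stop("no admissible rate: linear fixed point is negative")
  } else {
    disc <- B2^2 - 4 * B1 * B3
    if (disc < 0) stop("no steady state: negative discriminant")
    rE <- 2 * B1 / (-B2 + sqrt(disc))
    roots <- c(rE, (-B2 - sqrt(disc)) / (2 * B3))
    ok <- roots[is.finite(roots) & roots >= 0]
    if (!length(ok)) stop("no admissible rate: both roots negative")
    rE <- ok[1]
  }
  rI <- mf$mu_I / mf$mu_E * rE
  structure(list(A = A, B = B,
                 r_E_bar = rE, r_I_bar = rI,
                 g_E_bar = rE * mf$w_E * mf$tau_E / 1000,
                 g_I_bar = rI * mf$w_I * mf$tau_I / 1000),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf("<meanfield_solution> r_E=%.3f Hz r_I=%.3f Hz  gE=%.3f nS gI=%.4f nS\n",
              x$r_E_bar, x$r_I_bar, x$g_E_bar, x$g_I_bar))
  invisible(x)
}

# Jacobian of the conductance dynamics at the fixed point (unscaled by the
# synaptic time constants, as in the closed-form eigenvalues).
.meanfield_jacobian <- function(mf, sol) {
  tE <- mf$tau_E / 1000; tI <- mf$tau_I / 1000
  kG <- mf$kappa_G
  pNE <- mf$p * mf$N_E; pNI <- mf$p * mf$N_I
  gE <- sol$g_E_bar; gI <- sol$g_I_bar
  # dJ/dgE = pNE a (1 + kG d + kG c pNI gI); dJ/dgI = pNI c (1 + kG pNE b + kG pNE a gE)
  dJ_dgE <- pNE * mf$a * (1 + kG * mf$d + kG * mf$c_ * pNI * gI)
  dJ_dgI <- pNI * mf$c_ * (1 + kG * pNE * mf$b + kG * pNE * mf$a * gE)
  rbind(c(-1 + mf$w_E * tE * mf$mu_E * dJ_dgE,
          mf$w_E * tE * mf$mu_E * dJ_dgI),
        c(mf$w_I * tI * mf$mu_I * dJ_dgE,
          -1 + mf$w_I * tI * mf$mu_I * dJ_dgI))
}

#' Mean-field linear stability
#'
#' Eigenvalues of the 2x2 Jacobian of the conductance dynamics at the
#' fixed point. The closed forms are `lambda1 = -1` (always) and
#' `lambda2 = NEp wE tauE muE a (1 + kG d + kG NIp c gI)
#'          + NIp c wI tauI muI (1 + kG NEp b + kG NEp a gE) - 1`;
#' both are verified against a numerical eigen-decomposition of the
#' Jacobian and an internal-consistency error is raised on mismatch.
#' The fixed point is stable iff `lambda2 < 0`; because `c < 0` and
#' `d <= 0`, increasing the shunting strength `kappa_G` lowers `lambda2`
#' (shunting stabilizes the persistent state).
#'
#' @param mf a [meanfield_params()].
#' @param solution a [meanfield_fixed_point()] result (computed from `mf`
#'   when `NULL`).
#' @param tol relative tolerance for the closed-form vs numeric check.
#' @return A list with `lambda1`, `lambda2`, `stable`, and the numeric
#'   eigenvalues `lambda_numeric`.
#' @export
meanfield_stability <- function(mf, solution = NULL, tol = 1e-9) {
  stopifnot(inherits(mf, "meanfield_params"))
  if (is.null(solution)) solution <- meanfield_fixed_point(mf)
  J <- .meanfield_jacobian(mf, solution)
  lam2 <- (J[1, 1] + 1) + (J[2, 2] + 1) - 1  # trace identity, lambda1 = -1
  lam_num <- sort(Re(eigen(J, only.values = TRUE)$values))
  closed <- sort(c(-1, lam2))
  scale <- pmax(abs(closed), 1)
  if (any(abs(lam_num - closed) / scale > tol))
    stop("internal consistency error: closed-form eigenvalues ",
         paste(signif(closed, 10), collapse = ", "),
         " disagree with numeric ",
         paste(signif(lam_num, 10), collapse = ", "))
  list(lambda1 = -1, lambda2 = lam2, stable = lam2 < 0,
       lambda_numeric = lam_num)
}

#' Mean-field rate sweep over the excitatory weight
#'
#' Evaluates the fixed point and its stability for a sequence of
#' excitatory synaptic weights. Points where no admissible fixed point
#' exists are recorded as `NA`.
#'
#' @param mf a [meanfield_params()] providing all parameters except `w_E`.
#' @param w_E_values numeric vector of excitatory weights, nS (non-empty).
#' @return data.frame with columns `w_E`, `r_E_bar`, `r_I_bar`, `lambda2`,
#'   `stable`.
#' @export
rate_sweep <- function(mf, w_E_values) {
  stopifnot(inherits(mf, "meanfield_params"))
  if (!length(w_E_values)) stop("sweep must be non-empty")
  rows <- lapply(w_E_values, function(w) {
    m <- mf; m$w_E <- w
    sol <- tryCatch(meanfield_fixed_point(m), error = function(e) NULL)
    if (is.null(sol))
      return(data.frame(w_E = w, r_E_bar = NA_real_, r_I_bar = NA_real_,
                        lambda2 = NA_real_, stable = NA))
    st <- meanfield_stability(m, sol)
    data.frame(w_E = w, r_E_bar = sol$r_E_bar, r_I_bar = sol$r_I_bar,
               lambda2 = st$lambda2, stable = st$stable)
  })
  do.call(rbind, rows)
}
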