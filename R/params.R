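#' Model parameters of the frontal-cortex activity map
#'
#' Constructs the parameter set of the one-dimensional neural-activity map
#' \deqn{F(x) = K (B \tanh(w_2 x) - A \tanh(w_1 x)),}
#' in which an excitatory (`B`, `w2`) and an inhibitory (`A`, `w1`) neural
#' population compete, and the frontal output is fed back through the sensory
#' cortex with attenuation `K`.  `K < 1` models loss of information along the
#' sensory-to-frontal pathway (lowered attention); positive and negative `x`
#' correspond to active and resting population states.
#'
#' @param A Output synaptic weight of the inhibitory population. Default 13.0,
#'   the headline setting at which chaos-chaos intermittency (CCI) occurs for
#'   intermediate `K`.
#' @param B Output synaptic weight of the excitatory population (default 5.821).
#' @param w1 Input synaptic weight of the inhibitory population (> 0, default
#'   0.2223).
#' @param w2 Input synaptic weight of the excitatory population (> 0, default
#'   1.487).
#' @param K Attenuation coefficient of the sensory feedback loop, in (0, 1]
#'   (default 0.9, inside the CCI band at `A = 13`).
#'
#' @return An object of class `"model_params"`: a named list with fields
#'   `A`, `B`, `w1`, `w2`, `K`.
#' @seealso [control_params()], [sim_config()], [map_F()]
#' @examples
#' mp <- model_params()
#' map_F(0.5, mp)
#' @export
model_params <- function(A = 13.0, B = 5.821, w1 = 0.2223, w2 = 1.487,
                         K = 0.9) {
  for (nm in c("A", "B", "w1", "w2", "K")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (w1 <= 0) stop("'w1' must be > 0", call. = FALSE)
  if (w2 <= 0) stop("'w2' must be > 0", call. = FALSE)
  if (K <= 0 || K > 1) stop("'K' must be in (0, 1]", call. = FALSE)
  structure(list(A = A, B = B, w1 = w1, w2 = w2, K = K),
            class = "model_params")
}

#' Control parameters: RRO feedback, periodic stimulus, measurement noise
#'
#' Parameters of the "reduced region of orbit" (RRO) feedback signal
#' \deqn{u(x) = -(x - x_d)\, e^{-(x - x_d)^2 / (2\sigma^2)},}
#' applied with strength `C`, of the periodic reference stimulus
#' \eqn{S(n) = \alpha \sin(2\pi n / p)}, and of Gaussian measurement noise of
#' strength `D` corrupting the activity estimate inside the feedback term.
#' The feedback lowers the absolute local extrema of the composite map and
#' thereby controls whether the positive- and negative-activity attractors
#' merge (enabling CCI) or separate.
#'
#' @param C RRO feedback strength (>= 0). Default 0.2, the strength at which
#'   synchronization of CCI to the reference stimulus peaks at the headline
#'   model setting.
#' @param x_d Merging point of the two attractors, the centre of the feedback
#'   window. Default 0 (the map is odd about 0).
#' @param sigma Width of the Gaussian feedback window (> 0, default 1.0; the
#'   map's extrema lie within one window width of the origin).
#' @param D Measurement-noise strength (>= 0, default 0: noise-free feedback).
#' @param alpha Stimulus amplitude (>= 0, default 0.15).
#' @param p Stimulus period in map iterations (integer >= 2, default 32).
#'
#' @return An object of class `"control_params"`.
#' @seealso [rro_u()], [stimulus_S()], [iterate()]
#' @export
control_params <- function(C = 0.2, x_d = 0, sigma = 1.0, D = 0,
                           alpha = 0.15, p = 32L) {
  for (nm in c("C", "x_d", "sigma", "D", "alpha", "p")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (C < 0) stop("'C' must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (D < 0) stop("'D' must be >= 0", call. = FALSE)
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (p != round(p) || p < 2) stop("'p' must be an integer >= 2", call. = FALSE)
  structure(list(C = C, x_d = x_d, sigma = sigma, D = D,
                 alpha = alpha, p = as.integer(p)),
            class = "control_params")
}

#' Simulation configuration
#'
#' Run lengths, trial count, RNG seed and the initial-condition policy for
#' trajectory simulations.  Initial states are drawn uniformly on
#' \eqn{[-2, 2]} excluding a band of half-width `1e-3` around the unstable
#' fixed point at 0; each trial uses an RNG substream derived as
#' `seed + trial`, so adding trials never perturbs earlier ones.
#'
#' @param n_transient Iterations discarded before recording (default 1000).
#' @param n_samples Iterations recorded after the transient (default 20000).
#' @param n_trials Number of independent initial conditions (default 10).
#' @param seed Master RNG seed (default 1).
#' @param x0 Optional explicit initial state.  If `NULL` (default), `x(0)` is
#'   sampled per trial from the policy above.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_transient = 1000L, n_samples = 20000L,
                       n_trials = 10L, seed = 1L, x0 = NULL) {
  if (n_transient < 0) stop("'n_transient' must be >= 0", call. = FALSE)
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (!is.null(x0) && (!is.numeric(x0) || !all(is.finite(x0))))
    stop("'x0' must be finite if supplied", call. = FALSE)
  structure(list(n_transient = as.integer(n_transient),
                 n_samples = as.integer(n_samples),
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed), x0 = x0),
            class = "sim_config")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Neural-activity map parameters\n")
  cat(sprintf("  A = %g, B = %g, w1 = %g, w2 = %g, K = %g\n",
              x$A, x$B, x$w1, x$w2, x$K))
  invisible(x)
}

#' @export
print.control_params <- function(x, ...) {
  cat("RRO feedback / stimulus parameters\n")
  cat(sprintf("  C = %g, x_d = %g, sigma = %g, D = %g, alpha = %g, p = %d\n",
              x$C, x$x_d, x$sigma, x$D, x$alpha, x$p))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: transient %d, samples %d, trials %d, seed %d\n",
    x$n_transient, x$n_samples, x$n_trials, x$seed))
  if (!is.null(x$x0)) cat(sprintf("  fixed x0 = %g\n", x$x0[1]))
  invisible(x)
}

# Draw one initial state per trial: uniform on [-2, 2], excluding the
# unstable fixed point at 0 by a 1e-3 band.  Uses the current RNG stream.
draw_x0 <- function(n = 1L) {
  x <- stats::runif(n, -2, 2)
  bad <- abs(x) < 1e-3
  while (any(bad)) {
    x[bad] <- stats::runif(sum(bad), -2, 2)
    bad <- abs(x) < 1e-3
  }
  x
}
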