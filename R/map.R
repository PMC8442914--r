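#' Neural-activity map function
#'
#' Evaluates \eqn{F(x) = K (B \tanh(w_2 x) - A \tanh(w_1 x))}, the discrete
#' map governing frontal-cortex activity under competition between an
#' excitatory and an inhibitory population.  `F` is odd: `F(-x) = -F(x)`.
#'
#' @param x State value(s); finite numeric.
#' @param mp A [model_params()] object.
#' @return `F(x)`, same length as `x`.
#' @examples
#' map_F(c(-1, 0, 1), model_params())
#' @export
map_F <- function(x, mp) {
  stopifnot(inherits(mp, "model_params"))
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  mp$K * (mp$B * tanh(mp$w2 * x) - mp$A * tanh(mp$w1 * x))
}

#' RRO feedback signal
#'
#' Evaluates the "reduced region of orbit" feedback
#' \eqn{u(x) = -(x - x_d) e^{-(x - x_d)^2/(2\sigma^2)}}: a restoring signal
#' confined to a Gaussian window of width `sigma` around the attractor-merging
#' point `x_d`.  `u` is odd about `x_d`, with extrema of magnitude
#' \eqn{\sigma e^{-1/2}} at \eqn{x = x_d \pm \sigma}.
#'
#' @param x State value(s); finite numeric.
#' @param cp A [control_params()] object (fields `x_d`, `sigma` used).
#' @return `u(x)`, same length as `x`.  Note the feedback applied to the map
#'   is `C * u(x)`; the strength `C` is not included here.
#' @examples
#' rro_u(1, control_params())   # -exp(-1/2)
#' @export
rro_u <- function(x, cp) {
  stopifnot(inherits(cp, "control_params"))
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  z <- x - cp$x_d
  -z * exp(-z^2 / (2 * cp$sigma^2))
}

#' RRO feedback computed from a noisy activity measurement
#'
#' Evaluates \eqn{u_e(x) = u(x + D \xi)} where \eqn{\xi} is a standard-normal
#' measurement error: the corrupted estimate `x + D * xi` enters both the
#' linear prefactor and the Gaussian window.  With `D = 0` this reduces
#' exactly to [rro_u()].
#'
#' @param x True state value(s).
#' @param cp A [control_params()] object (fields `x_d`, `sigma`, `D` used).
#' @param xi Standard-normal draw(s), one per state value.
#' @return `u_e(x)`, same length as `x`.
#' @export
rro_u_noisy <- function(x, cp, xi) {
  stopifnot(inherits(cp, "control_params"))
  if (!is.numeric(xi) || !all(is.finite(xi)))
    stop("'xi' must be finite numeric", call. = FALSE)
  rro_u(x + cp$D * xi, cp)
}

#' Periodic reference stimulus
#'
#' \eqn{S(n) = \alpha \sin(2\pi n / p)}: the weak periodic input representing
#' the intended (healthy, low-fluctuation) neural activity that CCI should
#' synchronize to.
#'
#' @param n Integer time index(es), >= 0.
#' @param cp A [control_params()] object (fields `alpha`, `p` used).
#' @return `S(n)`, same length as `n`.
#' @export
stimulus_S <- function(n, cp) {
  stopifnot(inherits(cp, "control_params"))
  if (!is.numeric(n) || any(n != round(n)) || any(n < 0))
    stop("'n' must be integer >= 0", call. = FALSE)
  cp$alpha * sin(2 * pi * (n %% cp$p) / cp$p)
}

#' Composite controlled map
#'
#' Evaluates the autonomous part of the controlled system,
#' \eqn{G(x) = F(x) + C u(x)}.  The attractor-merging analysis and the
#' Lyapunov sweeps operate on this composite map (no stimulus, no noise).
#'
#' @inheritParams map_F
#' @param cp A [control_params()] object.
#' @return `G(x)`, same length as `x`.
#' @export
map_G <- function(x, mp, cp) {
  map_F(x, mp) + cp$C * rro_u(x, cp)
}

#' Derivative of the composite controlled map
#'
#' Closed-form \eqn{G'(x)} used as an independent oracle for the
#' perturbation-method Lyapunov estimator:
#' \eqn{F'(x) = K (B w_2 \mathrm{sech}^2(w_2 x) - A w_1 \mathrm{sech}^2(w_1 x))}
#' and \eqn{u'(x) = -(1 - (x - x_d)^2/\sigma^2)\, e^{-(x-x_d)^2/(2\sigma^2)}}.
#'
#' @inheritParams map_G
#' @return `G'(x)`, same length as `x`.
#' @export
map_G_deriv <- function(x, mp, cp) {
  fp <- mp$K * (mp$B * mp$w2 / cosh(mp$w2 * x)^2 -
                mp$A * mp$w1 / cosh(mp$w1 * x)^2)
  z <- x - cp$x_d
  up <- -(1 - z^2 / cp$sigma^2) * exp(-z^2 / (2 * cp$sigma^2))
  fp + cp$C * up
}

# Vectorized iteration engine.  Columns are independent runs (trials and/or
# parameter-grid cells); model/control fields may be vectors recycled across
# columns.  Returns the post-transient state matrix (n_samples x ncol) plus
# the aligned absolute time indices, and, when noise is active, accumulates
# the applied-feedback series.  This single engine backs iterate() and all
# sweeps so scalar and sweep paths cannot drift apart.
iterate_engine <- function(x0, n_transient, n_samples,
                           A, B, w1, w2, K, C, x_d, sigma, D, alpha, p,
                           record_cu = FALSE, guard = 1e6) {
  np <- length(x0)
  n_tot <- n_transient + n_samples
  A <- rep_len(A, np); B <- rep_len(B, np); w1 <- rep_len(w1, np)
  w2 <- rep_len(w2, np); K <- rep_len(K, np); C <- rep_len(C, np)
  D <- rep_len(D, np)
  xs <- matrix(NA_real_, n_samples, np)
  cus <- if (record_cu) matrix(NA_real_, n_samples, np) else NULL
  x <- x0
  noisy <- any(D > 0)
  for (n in seq_len(n_tot)) {
    s_n <- alpha * sin(2 * pi * ((n - 1) %% p) / p)
    xm <- if (noisy) x + D * stats::rnorm(np) else x
    z <- xm - x_d
    u <- -z * exp(-z^2 / (2 * sigma^2))
    if (n > n_transient) {
      xs[n - n_transient, ] <- x
      if (record_cu) cus[n - n_transient, ] <- C * u
    }
    x <- K * (B * tanh(w2 * x) - A * tanh(w1 * x)) + C * u + s_n
    if (any(abs(x) > guard))
      stop("trajectory diverged (|x| > ", guard, ") at step ", n,
           call. = FALSE)
  }
  list(x = xs, cu = cus, n = seq_len(n_tot)[seq_len(n_samples) + n_transient] - 1L)
}

#' Iterate the controlled neural-activity map
#'
#' Simulates \eqn{x(n+1) = F(x(n)) + C u(x(n)) + S(n)} (with `u` replaced by
#' the noisy-measurement feedback \eqn{u_e} when `D > 0`), discards the
#' transient, and returns the aligned series of state, stimulus, applied
#' feedback, and the binarized activity \eqn{X(n) = \pm 1} (`+1` iff
#' `x(n) >= 0`) on which the CCI synchronization metrics operate.  The noise
#' corrupts only the activity estimate inside the feedback term; the state
#' update itself uses the true `x(n)`.
#'
#' @param mp A [model_params()] object.
#' @param cp A [control_params()] object.
#' @param sc A [sim_config()] object.  `sc$seed` seeds the RNG when `x0` is
#'   sampled or `D > 0`; a single trial is run (use the sweep functions for
#'   multi-trial aggregation).
#' @param x0 Optional initial state; overrides `sc$x0`.  If neither is given,
#'   `x(0)` is drawn uniformly from \eqn{[-2,2]} excluding `|x| < 1e-3`.
#' @param trial Trial index used to derive the RNG substream
#'   (`sc$seed + trial`); default 1.
#'
#' @return An object of class `"rro_trajectory"`: a data frame with columns
#'   `n` (absolute time index, transient included in the count), `x`, `s`
#'   (stimulus), `cu` (applied feedback `C*u`), `X` (binarized state), and
#'   attributes `model`, `control`, `sim` recording the generating
#'   parameters.
#' @examples
#' tr <- iterate(model_params(), control_params(C = 0), sim_config(
#'   n_transient = 100, n_samples = 500), x0 = 0.5)
#' table(tr$X)
#' @export
iterate <- function(mp, cp, sc, x0 = NULL, trial = 1L) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"),
            inherits(sc, "sim_config"))
  set.seed(sc$seed + as.integer(trial))
  if (is.null(x0)) x0 <- if (!is.null(sc$x0)) sc$x0[1] else draw_x0(1L)
  if (!is.finite(x0)) stop("'x0' must be finite", call. = FALSE)
  eng <- iterate_engine(x0, sc$n_transient, sc$n_samples,
                        mp$A, mp$B, mp$w1, mp$w2, mp$K,
                        cp$C, cp$x_d, cp$sigma, cp$D, cp$alpha, cp$p,
                        record_cu = TRUE)
  x <- eng$x[, 1]
  out <- data.frame(n = eng$n,
                    x = x,
                    s = cp$alpha * sin(2 * pi * (eng$n %% cp$p) / cp$p),
                    cu = eng$cu[, 1],
                    X = ifelse(x >= 0, 1L, -1L))
  structure(out, class = c("rro_trajectory", "data.frame"),
            model = mp, control = cp, sim = sc, x0 = x0, trial = trial)
}

#' @export
print.rro_trajectory <- function(x, ...) {
  mp <- attr(x, "model"); cp <- attr(x, "control")
  cat(sprintf("Controlled-map trajectory: %d recorded steps\n", nrow(x)))
  cat(sprintf("  A = %g, K = %g, C = %g, alpha = %g, p = %d, D = %g\n",
              mp$A, mp$K, cp$C, cp$alpha, cp$p, cp$D))
  sw <- sum(diff(x$X) != 0)
  cat(sprintf("  sign switches: %d;  x range [%.3f, %.3f]\n",
              sw, min(x$x), max(x$x)))
  invisible(x)
}
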