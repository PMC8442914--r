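#' Local extrema of the composite controlled map
#'
#' Locates the local maximum of \eqn{G(x) = F(x) + C u(x)} on the positive
#' side of the merging point `x_d` and the local minimum on the negative
#' side.  The extremal *values* `f_max` and `f_min` are the quantities the
#' attractor-merging condition is evaluated at: the once-iterated images
#' `G(f_max)`, `G(f_min)` decide whether the two single-sign attractors merge.
#' A coarse grid on `[x_d, x_d + 3 sigma]` (and its mirror) brackets the
#' extremum, which is then refined by golden-section search to an absolute
#' tolerance below `1e-8` in `G`.
#'
#' @param mp A [model_params()] object.
#' @param cp A [control_params()] object; only the autonomous fields
#'   (`C`, `x_d`, `sigma`) are used.
#' @param n_grid Number of coarse-grid points per side (default 10001; sweeps
#'   may lower this — accuracy is restored by the refinement stage).
#' @return An object of class `"merging_assessment"` with fields `x_max`,
#'   `f_max`, `x_min`, `f_min` (extremal locations and values),
#'   `g_at_fmax`, `g_at_fmin`, `merged` (filled by [merging_condition()];
#'   `NA` here), and `no_extremum` — `TRUE` when `G` is monotone on the
#'   bracket and no interior extremum exists.
#' @examples
#' find_map_extrema(model_params(), control_params(C = 0))
#' @export
find_map_extrema <- function(mp, cp, n_grid = 10001L) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"))
  g <- function(x) map_G(x, mp, cp)
  hi <- cp$x_d + 3 * cp$sigma
  xs <- seq(cp$x_d, hi, length.out = n_grid)
  gx <- g(xs)
  i <- which.max(gx)
  res <- structure(list(x_max = NA_real_, f_max = NA_real_,
                        x_min = NA_real_, f_min = NA_real_,
                        g_at_fmax = NA_real_, g_at_fmin = NA_real_,
                        merged = NA, no_extremum = TRUE,
                        model = mp, control = cp),
                   class = "merging_assessment")
  if (i == 1L || i == n_grid) return(res)  # monotone: no interior maximum
  opt <- stats::optimize(g, lower = xs[i - 1L], upper = xs[i + 1L],
                         maximum = TRUE, tol = 1e-12)
  res$no_extremum <- FALSE
  res$x_max <- opt$maximum
  res$f_max <- opt$objective
  # minimum on the negative side; by construction it is the mirrored search
  lo <- cp$x_d - 3 * cp$sigma
  xs2 <- seq(lo, cp$x_d, length.out = n_grid)
  gx2 <- g(xs2)
  j <- which.min(gx2)
  if (j == 1L || j == n_grid) { res$no_extremum <- TRUE; return(res) }
  opt2 <- stats::optimize(g, lower = xs2[j - 1L], upper = xs2[j + 1L],
                          maximum = FALSE, tol = 1e-12)
  res$x_min <- opt2$minimum
  res$f_min <- opt2$objective
  res
}

#' Attractor-merging bifurcation condition
#'
#' Applies the composite map once more to its own extremal values and tests
#' the sign pattern that decides attractor merging: the positive- and
#' negative-activity chaotic attractors are merged — CCI is possible — iff
#' \eqn{G(f_{max}) < 0} and \eqn{G(f_{min}) > 0}.  Equality marks the
#' attractor-merging bifurcation point; the opposite signs mean the orbit is
#' confined to one side of `x_d` forever.
#'
#' @inheritParams find_map_extrema
#' @return A `"merging_assessment"` with `g_at_fmax`, `g_at_fmin` and the
#'   logical `merged` filled in (all `NA` when no interior extremum exists).
#' @examples
#' merging_condition(model_params(), control_params(C = 0))$merged    # TRUE
#' merging_condition(model_params(), control_params(C = 0.5))$merged  # FALSE
#' @export
merging_condition <- function(mp, cp, n_grid = 10001L) {
  res <- find_map_extrema(mp, cp, n_grid = n_grid)
  if (res$no_extremum) return(res)
  res$g_at_fmax <- map_G(res$f_max, mp, cp)
  res$g_at_fmin <- map_G(res$f_min, mp, cp)
  res$merged <- (res$g_at_fmax < 0) && (res$g_at_fmin > 0)
  res
}

#' @export
print.merging_assessment <- function(x, ...) {
  if (x$no_extremum) {
    cat("Composite map has no interior extremum on the search bracket\n")
    return(invisible(x))
  }
  cat(sprintf("Map extrema: f_max = %.6f at x = %.6f; f_min = %.6f at x = %.6f\n",
              x$f_max, x$x_max, x$f_min, x$x_min))
  if (!is.na(x$merged))
    cat(sprintf("G(f_max) = %+.6f, G(f_min) = %+.6f  ->  attractors %s\n",
                x$g_at_fmax, x$g_at_fmin,
                if (x$merged) "MERGED (CCI possible)" else "separated"))
  invisible(x)
}

# Vectorized Lyapunov engine over parameter columns.  Perturbation method:
# a replica displaced by d0 is evolved tau steps alongside the orbit, the
# log separation growth is accumulated, and the replica is renormalized back
# to distance d0.  With tau = 1 this is per-step renormalization.  Columns
# are independent (A, K, C) cells; x0 one value per column.
lyapunov_engine <- function(x0, n_transient, M, tau, d0,
                            A, B, w1, w2, K, C, x_d, sigma) {
  np <- length(x0)
  A <- rep_len(A, np); B <- rep_len(B, np); w1 <- rep_len(w1, np)
  w2 <- rep_len(w2, np); K <- rep_len(K, np); C <- rep_len(C, np)
  g <- function(x) {
    z <- x - x_d
    K * (B * tanh(w2 * x) - A * tanh(w1 * x)) - C * z * exp(-z^2 / (2 * sigma^2))
  }
  x <- x0
  for (n in seq_len(n_transient)) x <- g(x)
  acc <- numeric(np)
  underflow <- FALSE
  for (k in seq_len(M)) {
    xp <- x + d0
    for (t in seq_len(tau)) { x <- g(x); xp <- g(xp) }
    d1 <- abs(xp - x)
    if (any(d1 == 0)) { underflow <- TRUE; d1[d1 == 0] <- .Machine$double.xmin }
    acc <- acc + log(d1 / d0)
  }
  list(lambda = acc / (M * tau), underflow = underflow)
}

#' Lyapunov exponent of the autonomous controlled map
#'
#' Estimates the Lyapunov exponent by the perturbation method: `M` replicas
#' displaced by `d0` are launched at steps \eqn{n_0 + (k-1)\tau} along a
#' post-transient orbit, each evolved `tau` steps with the full nonlinear
#' map, and \eqn{\lambda = \frac{1}{\tau M}\sum_k \ln(d_k(\tau)/d_0)}
#' (natural log, per iteration).  Windows do not overlap.  `lambda > 0`
#' classifies the orbit as chaotic, `lambda < 0` as periodic.  The estimator
#' applies to the autonomous composite map (`alpha = 0`, `D = 0`); stimulus
#' and noise settings in `cp` are ignored with a warning.
#'
#' @inheritParams find_map_extrema
#' @param sc A [sim_config()] object; `sc$seed` (plus `trial`) seeds the
#'   initial-condition draw, `sc$n_transient` is the discarded transient and
#'   `sc$n_samples` bounds the usable orbit length (`M * tau` must not
#'   exceed it).
#' @param M Number of perturbed replicas (default 10000).
#' @param tau Growth interval in steps per replica (default 1:
#'   per-step renormalization).
#' @param d0 Initial perturbation size (default 1e-8).
#' @param x0 Optional explicit initial state.
#' @param trial Trial index for the RNG substream (default 1).
#' @return An object of class `"lyapunov_estimate"`: list with `lambda`,
#'   `M`, `tau`, `d0`, and logical `chaotic` (`lambda > 0`).
#' @examples
#' lyapunov_exponent(model_params(), control_params(C = 0),
#'                   sim_config(n_samples = 2000), M = 2000)
#' @export
lyapunov_exponent <- function(mp, cp, sc, M = 10000L, tau = 1L, d0 = 1e-8,
                              x0 = NULL, trial = 1L) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"),
            inherits(sc, "sim_config"))
  if (d0 <= 0) stop("'d0' must be > 0", call. = FALSE)
  if (M < 1 || tau < 1) stop("'M' and 'tau' must be >= 1", call. = FALSE)
  if (M * tau > sc$n_samples)
    stop("M * tau (", M * tau, ") exceeds available samples (",
         sc$n_samples, ")", call. = FALSE)
  if (cp$alpha > 0 || cp$D > 0)
    warning("Lyapunov exponent is computed on the autonomous map; ",
            "'alpha' and 'D' are ignored")
  set.seed(sc$seed + as.integer(trial))
  if (is.null(x0)) x0 <- if (!is.null(sc$x0)) sc$x0[1] else draw_x0(1L)
  eng <- lyapunov_engine(x0, sc$n_transient, M, tau, d0,
                         mp$A, mp$B, mp$w1, mp$w2, mp$K,
                         cp$C, cp$x_d, cp$sigma)
  if (eng$underflow)
    stop("perturbation separation underflowed to zero; increase d0",
         call. = FALSE)
  structure(list(lambda = eng$lambda[1], M = as.integer(M),
                 tau = as.integer(tau), d0 = d0,
                 chaotic = eng$lambda[1] > 0),
            class = "lyapunov_estimate")
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf("Lyapunov exponent: lambda = %.5f (%s)  [M = %d, tau = %d, d0 = %g]\n",
              x$lambda, if (x$chaotic) "chaotic" else "periodic",
              x$M, x$tau, x$d0))
  invisible(x)
}

#' Critical RRO feedback strength for attractor separation
#'
#' Finds the feedback strength `C*` at which the attractor-merging condition
#' switches from merged to separated, i.e. the root of
#' \eqn{G(f_{max})(C) = 0}, by bisection over `c_range`.  Below `C*` the
#' composite map supports CCI between the positive and negative activity
#' regions; above it the orbit is confined to one sign.
#'
#' @inheritParams find_map_extrema
#' @param cp_base A [control_params()] object supplying `x_d` and `sigma`;
#'   its `C` is ignored.
#' @param c_range Length-2 interval to search (default `c(0, 0.5)`).  The
#'   condition must be merged at the low end and separated at the high end.
#' @param tol Bisection tolerance on `C` (default 1e-4).
#' @return An object of class `"critical_c"`: list with `C_star`,
#'   `g_at_fmax`, `g_at_fmin` (evaluated at `C_star`), `no_transition`
#'   (`TRUE`, with `C_star = NA`, when the sign of `G(f_max)` does not change
#'   across `c_range`), and the inputs.
#' @examples
#' critical_feedback_strength(model_params(K = 0.9), control_params())
#' @export
critical_feedback_strength <- function(mp, cp_base, c_range = c(0, 0.5),
                                       tol = 1e-4, n_grid = 10001L) {
  stopifnot(inherits(mp, "model_params"), inherits(cp_base, "control_params"),
            length(c_range) == 2L, c_range[1] < c_range[2], tol > 0)
  g_fmax <- function(C) {
    cp <- control_params(C = C, x_d = cp_base$x_d, sigma = cp_base$sigma,
                         alpha = 0, p = cp_base$p)
    ma <- merging_condition(mp, cp, n_grid = n_grid)
    if (ma$no_extremum)
      stop("no interior extremum at C = ", C, call. = FALSE)
    ma$g_at_fmax
  }
  lo <- c_range[1]; hi <- c_range[2]
  g_lo <- g_fmax(lo); g_hi <- g_fmax(hi)
  if (sign(g_lo) == sign(g_hi)) {
    return(structure(list(C_star = NA_real_, g_at_fmax = NA_real_,
                          g_at_fmin = NA_real_, no_transition = TRUE,
                          c_range = c_range, model = mp),
                     class = "critical_c"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(g_fmax(mid)) == sign(g_lo)) lo <- mid else hi <- mid
  }
  C_star <- (lo + hi) / 2
  cp <- control_params(C = C_star, x_d = cp_base$x_d, sigma = cp_base$sigma,
                       alpha = 0, p = cp_base$p)
  ma <- merging_condition(mp, cp, n_grid = n_grid)
  structure(list(C_star = C_star, g_at_fmax = ma$g_at_fmax,
                 g_at_fmin = ma$g_at_fmin, no_transition = FALSE,
                 c_range = c_range, tol = tol, model = mp),
            class = "critical_c")
}

#' @export
print.critical_c <- function(x, ...) {
  if (x$no_transition) {
    cat("No merging-to-separation transition in C range [",
        x$c_range[1], ", ", x$c_range[2], "]\n", sep = "")
  } else {
    cat(sprintf(
      "Critical feedback strength C* = %.4f (K = %g): G(f_max) = %+.2e, G(f_min) = %+.2e\n",
      x$C_star, x$model$K, x$g_at_fmax, x$g_at_fmin))
  }
  invisible(x)
}
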