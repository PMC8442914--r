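# Shared validation for sweep grids.
check_grid <- function(grid, name = "grid") {
  if (length(grid) < 1L || !is.numeric(grid) || !all(is.finite(grid)))
    stop("'", name, "' must be a non-empty finite numeric vector",
         call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("'", name, "' must be strictly increasing", call. = FALSE)
  grid
}

# Substitute one swept parameter into (mp, cp) and return the per-cell
# parameter vectors the vectorized engines consume.
axis_vectors <- function(mp, cp, axis, grid) {
  if (!axis %in% c("A", "K", "C"))
    stop("'axis' must be one of \"A\", \"K\", \"C\"", call. = FALSE)
  v <- list(A = mp$A, K = mp$K, C = cp$C)
  v[[axis]] <- grid
  v
}

# Lyapunov exponent + merging condition along a single parameter axis.
# Work-horse behind sweep_bifurcation() and cci_regions().
sweep_dynamics <- function(mp, cp, sc, axis, grid, M = 10000L,
                           lambda_thresh = 1e-3, n_grid_extrema = 2049L) {
  check_grid(grid, axis)
  v <- axis_vectors(mp, cp, axis, grid)
  ng <- length(grid)
  set.seed(sc$seed + 1L)
  x0 <- if (!is.null(sc$x0)) rep_len(sc$x0, ng) else draw_x0(ng)
  lam <- lyapunov_engine(x0, sc$n_transient, M, 1L, 1e-8,
                         rep_len(v$A, ng), mp$B, mp$w1, mp$w2,
                         rep_len(v$K, ng), rep_len(v$C, ng),
                         cp$x_d, cp$sigma)$lambda
  g_max <- g_min <- rep(NA_real_, ng)
  merged <- rep(NA, ng)
  for (i in seq_len(ng)) {
    mpi <- mp; cpi <- cp
    if (axis == "C") cpi$C <- grid[i] else mpi[[axis]] <- grid[i]
    ma <- merging_condition(mpi, cpi, n_grid = n_grid_extrema)
    if (!ma$no_extremum) {
      g_max[i] <- ma$g_at_fmax; g_min[i] <- ma$g_at_fmin
      merged[i] <- ma$merged
    }
  }
  out <- data.frame(value = grid, lambda = lam, g_at_fmax = g_max,
                    g_at_fmin = g_min, merged = merged,
                    cci = merged & (lam > lambda_thresh))
  names(out)[1] <- axis
  out
}

#' Bifurcation-diagram sweep along one parameter
#'
#' For each value of the swept parameter (`A`, `K`, or `C`) runs two
#' post-transient trials — one from a positive and one from a negative
#' initial state, so both single-sign attractors are visible when they are
#' separated — and records `n_keep` attractor samples, together with the
#' Lyapunov exponent and the attractor-merging condition values for the
#' same parameter.  Autonomous system only (`alpha` and `D` ignored).
#'
#' @param mp,cp,sc [model_params()], [control_params()], [sim_config()].
#' @param axis Name of the swept parameter: `"A"`, `"K"`, or `"C"`.
#' @param grid Strictly increasing numeric grid.
#' @param n_keep Post-transient samples recorded per trial (default 200).
#' @param M Lyapunov replica count (default 10000).
#' @return A list of class `"bifurcation_sweep"`: `$samples` (long data
#'   frame: swept value, `trial` in `"pos"/"neg"`, `step`, `x`) and
#'   `$metrics` (one row per grid value: `lambda`, `g_at_fmax`, `g_at_fmin`,
#'   `merged`, `cci`).
#' @examples
#' bs <- sweep_bifurcation(model_params(), control_params(), sim_config(
#'   n_transient = 500, n_samples = 2000), "C", seq(0, 0.5, by = 0.1),
#'   n_keep = 50, M = 2000)
#' bs$metrics
#' @export
sweep_bifurcation <- function(mp, cp, sc, axis, grid, n_keep = 200L,
                              M = 10000L) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"),
            inherits(sc, "sim_config"))
  check_grid(grid, axis)
  metrics <- sweep_dynamics(mp, cp, sc, axis, grid, M = M)
  v <- axis_vectors(mp, cp, axis, grid)
  ng <- length(grid)
  set.seed(sc$seed + 1L)
  x0_pos <- abs(draw_x0(ng))
  set.seed(sc$seed + 2L)
  x0_neg <- -abs(draw_x0(ng))
  rep2 <- function(z) rep(rep_len(z, ng), 2L)
  eng <- iterate_engine(c(x0_pos, x0_neg), sc$n_transient, as.integer(n_keep),
                        rep2(v$A), mp$B, mp$w1, mp$w2, rep2(v$K), rep2(v$C),
                        cp$x_d, cp$sigma, D = 0, alpha = 0, p = cp$p)
  samples <- data.frame(
    value = rep(rep(grid, 2L), each = n_keep),
    trial = rep(c("pos", "neg"), each = n_keep * ng),
    step = rep(seq_len(n_keep), 2L * ng),
    x = as.vector(eng$x))
  names(samples)[1] <- axis
  structure(list(samples = samples, metrics = metrics),
            class = "bifurcation_sweep",
            params = sweep_params(mp, cp, sc, axis = axis,
                                  grid_n = ng, n_keep = n_keep))
}

#' @export
print.bifurcation_sweep <- function(x, ...) {
  m <- x$metrics
  ax <- names(m)[1]
  cat(sprintf("Bifurcation sweep over %s (%d points, [%g, %g])\n",
              ax, nrow(m), min(m[[ax]]), max(m[[ax]])))
  cat(sprintf("  CCI (merged & lambda > 0) at %d points; %d attractor samples\n",
              sum(m$cci, na.rm = TRUE), nrow(x$samples)))
  invisible(x)
}

#' Lyapunov exponent and merging condition on an A-by-K grid
#'
#' Maps out where chaos-chaos intermittency lives in the plane spanned by
#' the inhibitory output weight `A` and the sensory attenuation `K`:
#' for every grid cell the Lyapunov exponent (autonomous map, one random
#' initial state per cell) and the merging-condition values are computed.
#' CCI territory is `merged & lambda > 0`.
#'
#' @inheritParams sweep_bifurcation
#' @param a_grid,k_grid Strictly increasing grids for `A` and `K`.
#' @return Data frame of class `"sweep_table"`, one row per `(A, K)` cell:
#'   `A`, `K`, `lambda`, `g_at_fmax`, `g_at_fmin`, `merged`, `cci`.
#' @export
sweep_lyapunov_2d <- function(mp, cp, sc, a_grid, k_grid, M = 10000L,
                              lambda_thresh = 1e-3) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"),
            inherits(sc, "sim_config"))
  check_grid(a_grid, "a_grid"); check_grid(k_grid, "k_grid")
  cells <- expand.grid(K = k_grid, A = a_grid)[, c("A", "K")]
  nc <- nrow(cells)
  set.seed(sc$seed + 1L)
  x0 <- draw_x0(nc)
  lam <- lyapunov_engine(x0, sc$n_transient, M, 1L, 1e-8,
                         cells$A, mp$B, mp$w1, mp$w2, cells$K,
                         cp$C, cp$x_d, cp$sigma)$lambda
  g_max <- g_min <- rep(NA_real_, nc)
  merged <- rep(NA, nc)
  for (i in seq_len(nc)) {
    mpi <- mp; mpi$A <- cells$A[i]; mpi$K <- cells$K[i]
    ma <- merging_condition(mpi, cp, n_grid = 1025L)
    if (!ma$no_extremum) {
      g_max[i] <- ma$g_at_fmax; g_min[i] <- ma$g_at_fmin
      merged[i] <- ma$merged
    }
  }
  out <- data.frame(A = cells$A, K = cells$K, lambda = lam,
                    g_at_fmax = g_max, g_at_fmin = g_min, merged = merged,
                    cci = merged & (lam > lambda_thresh))
  structure(out, class = c("sweep_table", "data.frame"),
            params = sweep_params(mp, cp, sc, a_grid_n = length(a_grid),
                                  k_grid_n = length(k_grid)))
}

#' Synchronization and perturbation versus feedback strength
#'
#' The chaotic-resonance sweep: for every feedback strength on `c_grid`
#' (and every stimulus period in `p_list`) runs `sc$n_trials` independent
#' trials of the stimulus-driven system, computes the delay-maximized
#' correlation between binarized activity and stimulus plus the
#' perturbation magnitude, and aggregates mean and SD over trials.
#' Correlation peaks at feedback strengths slightly below the
#' attractor-merging point, where the weak stimulus itself can tip the
#' orbit between the nearly-separated attractors.
#'
#' @inheritParams sweep_bifurcation
#' @param c_grid Strictly increasing grid of feedback strengths.
#' @param alpha Stimulus amplitude (default from `cp`).
#' @param p_list Stimulus periods to evaluate (default `cp$p`).
#' @return Data frame of class `"sweep_table"`, one row per `(p, C)`:
#'   `mean_max_corr`, `sd_max_corr`, `mean_theta`, `sd_theta`, `n_pinned`
#'   (trials whose orbit never switched sign), `n_trials`.  Per-trial values
#'   are kept in attribute `"trials"`.
#' @examples
#' sweep_sync_vs_C(model_params(), control_params(), sim_config(
#'   n_transient = 500, n_samples = 4000, n_trials = 3), c_grid = c(0.05, 0.2))
#' @export
sweep_sync_vs_C <- function(mp, cp, sc, c_grid, alpha = cp$alpha,
                            p_list = cp$p) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"),
            inherits(sc, "sim_config"))
  check_grid(c_grid, "c_grid")
  nC <- length(c_grid)
  rows <- list()
  for (p in p_list) {
    for (trial in seq_len(sc$n_trials)) {
      set.seed(sc$seed + trial)
      x0 <- if (!is.null(sc$x0)) rep_len(sc$x0, nC) else draw_x0(nC)
      eng <- iterate_engine(x0, sc$n_transient, sc$n_samples,
                            mp$A, mp$B, mp$w1, mp$w2, mp$K,
                            c_grid, cp$x_d, cp$sigma, cp$D, alpha, p,
                            record_cu = TRUE)
      m <- sync_from_matrix(eng$x, eng$cu, eng$n[1], alpha, p)
      rows[[length(rows) + 1L]] <- data.frame(
        p = p, C = c_grid, trial = trial, max_corr = m$max_corr,
        argmax_delay = m$argmax_delay, theta = m$theta, pinned = m$pinned)
    }
  }
  trials <- do.call(rbind, rows)
  agg <- aggregate_sync(trials, c("p", "C"))
  structure(agg, class = c("sweep_table", "data.frame"),
            trials = trials,
            params = sweep_params(mp, cp, sc, alpha = alpha,
                                  p_list = paste(p_list, collapse = ","),
                                  c_grid_n = nC))
}

#' Synchronization robustness against measurement noise
#'
#' Holds the feedback strength fixed (typically at the resonance peak) and
#' sweeps the measurement-noise strength `D` corrupting the activity
#' estimate inside the RRO feedback term, aggregating the delay-maximized
#' correlation and the perturbation magnitude over `sc$n_trials` trials per
#' noise level.  Noise is redrawn every iteration from the per-trial RNG
#' substream.
#'
#' @inheritParams sweep_sync_vs_C
#' @param d_grid Strictly increasing grid of noise strengths (may start
#'   at 0).
#' @return Data frame of class `"sweep_table"`, one row per `D`, same
#'   metric columns as [sweep_sync_vs_C()].
#' @export
sweep_noise <- function(mp, cp, sc, d_grid, alpha = cp$alpha, p = cp$p) {
  stopifnot(inherits(mp, "model_params"), inherits(cp, "control_params"),
            inherits(sc, "sim_config"))
  if (length(d_grid) < 1L || any(d_grid < 0))
    stop("'d_grid' must be non-negative", call. = FALSE)
  if (length(d_grid) > 1L && any(diff(d_grid) <= 0))
    stop("'d_grid' must be strictly increasing", call. = FALSE)
  nD <- length(d_grid)
  rows <- list()
  for (trial in seq_len(sc$n_trials)) {
    set.seed(sc$seed + trial)
    x0 <- if (!is.null(sc$x0)) rep_len(sc$x0, nD) else draw_x0(nD)
    eng <- iterate_engine(x0, sc$n_transient, sc$n_samples,
                          mp$A, mp$B, mp$w1, mp$w2, mp$K,
                          cp$C, cp$x_d, cp$sigma, d_grid, alpha, p,
                          record_cu = TRUE)
    m <- sync_from_matrix(eng$x, eng$cu, eng$n[1], alpha, p)
    rows[[length(rows) + 1L]] <- data.frame(
      D = d_grid, trial = trial, max_corr = m$max_corr,
      argmax_delay = m$argmax_delay, theta = m$theta, pinned = m$pinned)
  }
  trials <- do.call(rbind, rows)
  agg <- aggregate_sync(trials, "D")
  structure(agg, class = c("sweep_table", "data.frame"),
            trials = trials,
            params = sweep_params(mp, cp, sc, alpha = alpha, p = p,
                                  d_grid_n = nD))
}

# Mean/SD aggregation of per-trial sync metrics over grouping columns.
aggregate_sync <- function(trials, by) {
  key <- trials[by]
  sp <- split(seq_len(nrow(trials)), key, drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(idx) {
    g <- trials[idx, , drop = FALSE]
    mc <- g$max_corr
    data.frame(g[1, by, drop = FALSE],
               mean_max_corr = mean(mc), sd_max_corr = stats::sd(mc),
               mean_theta = mean(g$theta), sd_theta = stats::sd(g$theta),
               n_pinned = sum(g$pinned), n_trials = nrow(g))
  }))
  out$sd_max_corr[is.na(out$sd_max_corr)] <- 0  # single trial: SD = 0
  out$sd_theta[is.na(out$sd_theta)] <- 0
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chaos-chaos intermittency regions along a parameter axis
#'
#' Sweeps one parameter, classifies every grid point as CCI iff the
#' attractor-merging condition is satisfied *and* the Lyapunov exponent
#' exceeds `lambda_thresh` (a small positive threshold absorbing estimator
#' noise near zero), and extracts the maximal contiguous runs of CCI
#' points.  Each run edge is refined by one bisection level: the midpoint
#' between the edge grid point and its non-CCI neighbour is re-evaluated
#' and replaces the edge when it is itself CCI.
#'
#' @inheritParams sweep_bifurcation
#' @param lambda_thresh Chaos classification threshold on the Lyapunov
#'   exponent (default 1e-3).
#' @param refine Refine region edges by one bisection level (default TRUE).
#' @return Data frame of class `"cci_regions"`: one row per contiguous CCI
#'   run with columns `start`, `end` (parameter values, refined when
#'   requested) and `n_points`.  Zero rows when no CCI is found.  The full
#'   per-point sweep is kept in attribute `"sweep"`.
#' @examples
#' cci_regions(model_params(), control_params(C = 0), sim_config(
#'   n_samples = 2000), "K", seq(0.84, 0.88, by = 0.005), M = 2000)
#' @export
cci_regions <- function(mp, cp, sc, axis, grid, M = 10000L,
                        lambda_thresh = 1e-3, refine = TRUE) {
  dyn <- sweep_dynamics(mp, cp, sc, axis, grid, M = M,
                        lambda_thresh = lambda_thresh)
  cci <- dyn$cci
  cci[is.na(cci)] <- FALSE
  r <- rle(cci)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  runs <- data.frame(start = grid[starts[keep]], end = grid[ends[keep]],
                     n_points = r$lengths[keep])
  is_cci_at <- function(val) {
    mpi <- mp; cpi <- cp
    if (axis == "C") cpi$C <- val else mpi[[axis]] <- val
    ma <- merging_condition(mpi, cpi, n_grid = 2049L)
    if (ma$no_extremum || !ma$merged) return(FALSE)
    le <- lyapunov_exponent(mpi, cpi, sc, M = M)
    le$lambda > lambda_thresh
  }
  if (refine && nrow(runs) > 0L) {
    for (i in seq_len(nrow(runs))) {
      si <- starts[keep[i]]; ei <- ends[keep[i]]
      if (si > 1L) {
        mid <- (grid[si - 1L] + grid[si]) / 2
        if (is_cci_at(mid)) runs$start[i] <- mid
      }
      if (ei < length(grid)) {
        mid <- (grid[ei] + grid[ei + 1L]) / 2
        if (is_cci_at(mid)) runs$end[i] <- mid
      }
    }
  }
  structure(runs, class = c("cci_regions", "data.frame"),
            sweep = dyn, axis = axis,
            params = sweep_params(mp, cp, sc, axis = axis,
                                  grid_n = length(grid)))
}

#' @export
print.cci_regions <- function(x, ...) {
  ax <- attr(x, "axis")
  if (nrow(x) == 0L) {
    cat("No CCI regions found on the", ax, "grid\n")
    return(invisible(x))
  }
  cat(sprintf("CCI regions along %s (merged attractors & lambda > 0):\n", ax))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%g, %g]  (%d grid points)\n",
                x$start[i], x$end[i], x$n_points[i]))
  invisible(x)
}

# Flat named list of all generating parameters, attached to sweep outputs
# and serialized into TSV headers so every table can be recomputed.
sweep_params <- function(mp, cp, sc, ...) {
  c(list(A = mp$A, B = mp$B, w1 = mp$w1, w2 = mp$w2, K = mp$K,
         C = cp$C, x_d = cp$x_d, sigma = cp$sigma, D = cp$D,
         alpha = cp$alpha, p = cp$p,
         n_transient = sc$n_transient, n_samples = sc$n_samples,
         n_trials = sc$n_trials, seed = sc$seed),
    list(...))
}
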