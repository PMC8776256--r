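#' Configuration for rate-network simulations
#'
#' Parameters of the stochastic rate dynamics
#' `tau dz_i/dt = -z_i + sum_j J_ij nu_j + mu_ext_i + xi_i sqrt(tau) sigma_i`,
#' integrated with the Euler-Maruyama scheme.
#'
#' @param tau Membrane/rate time constant (arbitrary time units).
#' @param dt Integration step; must satisfy `dt <= tau / 10`.
#' @param duration Total simulated time.
#' @param burn_in Initial time discarded before estimating statistics.
#' @param sigma_noise Per-neuron white-noise strength (scalar or vector).
#' @param mu_ext Constant external drive (scalar or vector).
#' @param bin Width of the time bins used for the trajectory covariance
#'   estimator; should be much larger than `tau` (default `50 * tau`).
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tau = 1, dt = tau / 20, duration = 500 * tau,
                       burn_in = 50 * tau, sigma_noise = 1, mu_ext = 0,
                       bin = 50 * tau, seed = 1L) {
  if (dt > tau / 10) stop("'dt' must not exceed tau/10", call. = FALSE)
  if (burn_in >= duration) stop("'burn_in' must be below 'duration'",
                                call. = FALSE)
  structure(list(tau = tau, dt = dt, duration = duration, burn_in = burn_in,
                 sigma_noise = sigma_noise, mu_ext = mu_ext, bin = bin,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a linear or threshold-linear rate network
#'
#' Euler-Maruyama integration of the white-noise driven rate dynamics. The
#' output nonlinearity is either the identity (`"linear"`) or the rectified
#' linear unit (`"relu"`, `phi(z) = max(z, 0)`). After the burn-in, mean
#' rates and pairwise integrated covariances are estimated from the retained
#' trajectory; covariances are estimated from time-bin averages with bins
#' much longer than tau, and are reported in units of tau (so that they are
#' directly comparable to [stationary_covariance_lyapunov()]).
#'
#' @param J Connectivity matrix (n x n, dense or sparse).
#' @param phi `"linear"` or `"relu"`.
#' @param cfg A [sim_config()].
#' @param z_max Divergence guard: the integration aborts with an error if
#'   any `|z|` exceeds this bound.
#' @param keep_trajectory If `TRUE`, the binned rate trajectory is returned.
#' @return Object of class `trajectory_summary` with `mean_rates`,
#'   `covariances` (integrated, units of tau), `estimator = "trajectory"`,
#'   `effective_duration`, and optionally `trajectory`.
#' @export
simulate_rate_network <- function(J, phi = c("linear", "relu"), cfg,
                                  z_max = 1e6, keep_trajectory = FALSE) {
  phi <- match.arg(phi)
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(J)
  J <- as.matrix(J)
  f <- if (phi == "linear") identity else function(z) pmax(z, 0)
  dt <- cfg$dt; tau <- cfg$tau
  nsteps <- ceiling(cfg$duration / dt)
  nburn <- ceiling(cfg$burn_in / dt)
  sig <- rep_len(cfg$sigma_noise, n)
  mu <- rep_len(cfg$mu_ext, n)
  steps_per_bin <- max(1L, round(cfg$bin / dt))
  set.seed(cfg$seed)
  z <- rep(0, n)
  noise_scale <- sig * sqrt(dt / tau)
  bins <- list()
  acc <- rep(0, n); acc_n <- 0L
  rate_sum <- rep(0, n); rate_n <- 0L
  z_sum <- z2_sum <- rep(0, n)
  for (step in seq_len(nsteps)) {
    nu <- f(z)
    z <- z + (dt / tau) * (as.numeric(J %*% nu) - z + mu) +
      noise_scale * stats::rnorm(n)
    if (any(abs(z) > z_max))
      stop("rate dynamics diverged: |z| exceeded z_max; network unstable?",
           call. = FALSE)
    if (step > nburn) {
      nu <- f(z)
      rate_sum <- rate_sum + nu; rate_n <- rate_n + 1L
      z_sum <- z_sum + z; z2_sum <- z2_sum + z^2
      acc <- acc + nu; acc_n <- acc_n + 1L
      if (acc_n == steps_per_bin) {
        bins[[length(bins) + 1L]] <- acc / acc_n
        acc <- rep(0, n); acc_n <- 0L
      }
    }
  }
  B <- do.call(rbind, bins)
  if (is.null(B) || nrow(B) < 3)
    stop("too few complete bins after burn-in; increase duration",
         call. = FALSE)
  # cov of bin means ~ C_int / bin; report C_int / tau
  covs <- stats::cov(B) * (steps_per_bin * dt) / tau
  structure(list(mean_rates = rate_sum / rate_n,
                 covariances = (covs + t(covs)) / 2,
                 var_state = z2_sum / rate_n - (z_sum / rate_n)^2,
                 estimator = "trajectory",
                 effective_duration = (nsteps - nburn) * dt,
                 n_bins = nrow(B),
                 trajectory = if (keep_trajectory) B else NULL),
            class = "trajectory_summary")
}

#' Stationary integrated covariance by a deterministic linear solve
#'
#' For the linearized dynamics with effective connectivity W and independent
#' white noise of per-neuron variances `noise`, the time-lag integrated
#' covariance (in units of tau) is `(1-W)^(-1) diag(noise) (1-W)^(-T)`. For
#' `W = 0` this reduces to `diag(noise)`, fixing the normalization
#' convention shared with the theory module and the trajectory estimator.
#'
#' @param W Effective connectivity matrix; spectral bound must be < 1.
#' @param noise Per-neuron noise variances (scalar or vector).
#' @return Symmetric positive-semidefinite covariance matrix.
#' @export
stationary_covariance_lyapunov <- function(W, noise = 1) {
  n <- nrow(W)
  sb <- spectral_bound(W)
  if (sb >= 1)
    stop(sprintf("unstable dynamics: spectral bound %.4f >= 1", sb),
         call. = FALSE)
  noise <- rep_len(noise, n)
  X <- solve(diag(n) - as.matrix(W))
  C <- X %*% (noise * t(X))       # X diag(noise) X^T
  (C + t(C)) / 2
}

#' Distance-resolved statistics of a covariance matrix
#'
#' Groups the off-diagonal entries of a pairwise covariance matrix by
#' minimal-image distance between the neurons' cells and by population pair
#' class (EE/EI/II), and reports per-bin mean, variance and pair count.
#' Empty cells are retained with `count = 0` and `NA` moments.
#'
#' @param covm Covariance matrix (n x n).
#' @param geom A [grid_geometry()] with matching neuron count, or a
#'   precomputed distance matrix.
#' @param labels Optional population labels per neuron (defaults to the
#'   geometry's populations; use `NULL` labels to pool all pairs).
#' @param breaks Optional numeric bin breaks for distance; by default every
#'   distinct distance is its own bin.
#' @param bias_correction If `TRUE`, subtracts from each variance the
#'   estimator-noise contribution `mean[(c_ii c_jj + c_ij^2)]/(l - 1)`
#'   expected when the covariances were estimated from `n_samples` bins.
#' @param n_samples Number of samples behind the covariance estimates
#'   (required when `bias_correction = TRUE`).
#' @return Data frame with columns `distance`, `pair_class`, `mean`,
#'   `variance`, `count`.
#' @export
distance_resolved_statistics <- function(covm, geom, labels, breaks = NULL,
                                         bias_correction = FALSE,
                                         n_samples = NULL) {
  X <- if (inherits(geom, "grid_geometry")) pair_distances(geom) else geom
  stopifnot(nrow(covm) == nrow(X))
  if (missing(labels))
    labels <- if (inherits(geom, "grid_geometry")) geom$population else NULL
  n <- nrow(covm)
  ut <- upper.tri(covm)
  xd <- X[ut]; cv <- covm[ut]
  if (!is.null(breaks)) {
    grp_d <- breaks[findInterval(xd, breaks, all.inside = TRUE)]
  } else grp_d <- round(xd, 9)
  if (!is.null(labels)) {
    li <- matrix(as.character(labels), n, n)
    cls <- paste0(pmin(li, t(li)), pmax(li, t(li)))[ut]
  } else cls <- rep("all", length(xd))
  noise_term <- 0
  if (bias_correction) {
    if (is.null(n_samples))
      stop("'n_samples' needed for the bias correction", call. = FALSE)
    v <- diag(covm)
    vivj <- (outer(v, v) + covm^2)[ut] / (n_samples - 1)
  }
  key <- interaction(grp_d, cls, drop = TRUE)
  agg <- function(f) tapply(cv, key, f)
  out <- data.frame(
    distance = as.numeric(tapply(grp_d, key, `[`, 1)),
    pair_class = as.character(tapply(cls, key, `[`, 1)),
    mean = as.numeric(agg(mean)),
    variance = as.numeric(agg(function(z) if (length(z) > 1) stats::var(z) else 0)),
    count = as.integer(agg(length)))
  if (bias_correction) {
    corr <- as.numeric(tapply(vivj, key, mean))
    out$variance <- out$variance - corr
  }
  out <- out[order(out$pair_class, out$distance), ]
  rownames(out) <- NULL
  out
}
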