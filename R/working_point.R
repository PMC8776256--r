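#' Moments of the rectified-linear transfer of a Gaussian input
#'
#' For input `z ~ Normal(mu, sigma^2)` and `nu = phi(z) = max(z, 0)`,
#' returns the closed-form mean and variance of the output rate and the
#' probability that the unit is active (`z > 0`):
#' `Mean(nu) = sigma/sqrt(2 pi) exp(-mu^2/(2 sigma^2)) +
#'  mu/2 (1 + erf(mu/(sqrt(2) sigma)))` and
#' `fraction_active = Phi(mu/sigma)`. The variance follows from the
#' censored-Gaussian second moment
#' `E[nu^2] = (mu^2 + sigma^2) Phi(mu/sigma) + mu sigma phi(mu/sigma)`.
#'
#' @param mu Mean input (vectorized).
#' @param sigma Input standard deviation (> 0, vectorized).
#' @return Data frame with columns `mean_rate`, `var_rate`,
#'   `fraction_active`.
#' @examples
#' relu_rate_moments(0, 1)  # mean 1/sqrt(2*pi), var (1 - 1/pi)/2
#' @export
relu_rate_moments <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be positive", call. = FALSE)
  r <- mu / sigma
  mean_rate <- sigma / sqrt(2 * pi) * exp(-r^2 / 2) +
    mu / 2 * (1 + erf(r / sqrt(2)))
  second <- (mu^2 + sigma^2) * stats::pnorm(r) + mu * sigma * stats::dnorm(r)
  data.frame(mean_rate = mean_rate,
             var_rate = second - mean_rate^2,
             fraction_active = stats::pnorm(r))
}

## error function
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Synaptic weight realizing a target spectral bound
#'
#' In a sparse inhibitory network with fixed indegree `K = p N` in which, at
#' the operating point, half of the population is active, the effective
#' linear network has half the population size; its disorder bulk has radius
#' `|w| sqrt((N/2) p (1-p))`. Setting this to R gives
#' `w = -R / sqrt((N/2) p (1-p))`.
#'
#' @param R Target spectral bound (>= 0).
#' @param N Number of neurons (even).
#' @param p Connection probability, in (0, 1).
#' @return The (negative) synaptic weight.
#' @examples
#' weight_for_spectral_bound(0.8, 2000, 0.1)  # ~ -0.0843
#' @export
weight_for_spectral_bound <- function(R, N, p) {
  stopifnot(R >= 0, p > 0, p < 1, N > 0)
  -R / sqrt((N / 2) * p * (1 - p))
}

#' External drive that puts half the population above threshold
#'
#' Mean external input mu_ext such that the self-consistent mean total
#' input of the ReLU network is zero, which makes the expected fraction of
#' active neurons exactly one half. The closed form follows from the
#' mean-field equations `mu = mu_ext + K w Mean(nu)` and
#' `sigma^2 = sigma_ext^2 + K w^2 Var(nu)` evaluated at `mu = 0`:
#' `mu_ext = R sigma_ext sqrt(N p / (pi (1-p) - (pi-1) R^2))`.
#'
#' @param R Spectral bound.
#' @param N Network size.
#' @param p Connection probability.
#' @param sigma_ext Standard deviation of the quenched external input.
#' @param route `"closed_form"` (default) or `"fixed_point"`: the latter
#'   solves the self-consistency numerically and exists as an independent
#'   cross-check of the closed form.
#' @return `mu_ext` (> 0 for R > 0).
#' @export
external_drive_for_half_activation <- function(R, N, p, sigma_ext = 1,
                                               route = c("closed_form",
                                                         "fixed_point")) {
  route <- match.arg(route)
  denom <- pi * (1 - p) - (pi - 1) * R^2
  if (denom <= 0)
    stop("no real solution: pi*(1-p) - (pi-1)*R^2 must be positive",
         call. = FALSE)
  if (route == "closed_form")
    return(R * sigma_ext * sqrt(N * p / denom))
  K <- p * N
  w <- weight_for_spectral_bound(R, N, p)
  # sigma^2 = sigma_ext^2 + K w^2 Var(nu)|_{mu=0}, Var(nu)|_{mu=0} known
  fp <- function(s2) sigma_ext^2 + K * w^2 * s2 * (1 - 1 / pi) / 2
  s2 <- sigma_ext^2
  for (i in 1:200) {
    s2_new <- fp(s2)
    if (abs(s2_new - s2) < 1e-14) break
    s2 <- s2_new
  }
  -K * w * sqrt(s2) / sqrt(2 * pi)
}

#' Sparse random network with fixed indegree
#'
#' Every neuron receives exactly `K = round(p N)` synapses of weight `w`
#' from presynaptic partners drawn without replacement (no self-loops).
#'
#' @param N Number of neurons.
#' @param p Connection probability.
#' @param w Synaptic weight.
#' @param seed RNG seed.
#' @return Sparse connectivity matrix (`dgCMatrix`, rows postsynaptic).
#' @export
fixed_indegree_network <- function(N, p, w, seed = 1L) {
  K <- round(p * N)
  set.seed(as.integer(seed))
  pre <- vapply(seq_len(N), function(i) sample.int(N - 1L, K),
                integer(K))
  pre <- pre + (pre >= rep(seq_len(N), each = K))  # skip self
  Matrix::sparseMatrix(i = rep(seq_len(N), each = K),
                       j = as.integer(pre), x = w, dims = c(N, N))
}

#' Paired external inputs with a shared and an independent component
#'
#' Draws mean external inputs for two networks as
#' `mu_i^(a) = mu_shared_i + delta_i^(a)` with
#' `mu_shared_i ~ N(mu_ext, (1-epsilon) sigma_ext^2)` and
#' `delta_i^(a) ~ N(0, epsilon sigma_ext^2)` drawn independently per
#' network, so the expected Pearson correlation between the two input
#' vectors is `1 - epsilon`.
#'
#' @param mu_ext Common mean.
#' @param sigma_ext Total input standard deviation.
#' @param epsilon Independent-component fraction, in [0, 1].
#' @param N Number of neurons.
#' @param seed RNG seed.
#' @return List with vectors `inputs1`, `inputs2`.
#' @export
draw_paired_inputs <- function(mu_ext, sigma_ext, epsilon, N, seed = 1L) {
  if (epsilon < 0 || epsilon > 1)
    stop("'epsilon' must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  shared <- stats::rnorm(N, mu_ext, sqrt(1 - epsilon) * sigma_ext)
  list(inputs1 = shared + stats::rnorm(N, 0, sqrt(epsilon) * sigma_ext),
       inputs2 = shared + stats::rnorm(N, 0, sqrt(epsilon) * sigma_ext))
}

#' Noise-free fixed point of the ReLU rate network
#'
#' Damped fixed-point iteration for `z = J phi(z) + mu`. The damping factor
#' is chosen from the strength of the (strongly negative) population
#' feedback so that the iteration is a stable discretization of the
#' underlying relaxation dynamics.
#'
#' @param J Connectivity matrix.
#' @param mu External input vector.
#' @param eta Damping factor; by default set adaptively.
#' @param tol Convergence tolerance on the update.
#' @param maxit Maximum iterations.
#' @return The fixed-point input vector `z` (rates are `pmax(z, 0)`).
#' @export
relu_fixed_point <- function(J, mu, eta = NULL, tol = 1e-10, maxit = 50000L) {
  n <- length(mu)
  if (is.null(eta)) {
    row1 <- sum(abs(J[1, ]))
    eta <- min(0.1, 1.5 / (1 + row1))
  }
  z <- mu
  for (it in seq_len(maxit)) {
    z_new <- as.numeric(J %*% pmax(z, 0)) + mu
    delta <- max(abs(z_new - z))
    z <- z + eta * (z_new - z)
    if (delta < tol) return(z)
  }
  stop("ReLU fixed point did not converge; dynamics may be unstable",
       call. = FALSE)
}

#' Two-network working-point experiment
#'
#' One sparse random network (fixed structural connectivity) is evaluated
#' under two external input patterns that share a common component and
#' differ by an independent component of fraction `epsilon`. For each input
#' pattern the noise-free ReLU fixed point determines which neurons are
#' active; the effective connectivity `W = J diag(phi'(z))` of the active
#' subnetwork then yields the integrated covariances by a deterministic
#' linear solve (or, optionally, by full stochastic simulation). The
#' experiment quantifies how strongly firing-rate patterns and covariance
#' patterns differ between the two working points:
#' \itemize{
#'   \item `input_corr`: Pearson correlation of the external input vectors
#'     (expected `1 - epsilon`);
#'   \item `rate_corr`: correlation of the mean-rate vectors, excluding
#'     neurons silent (rate below `silent_threshold`) in either network;
#'   \item `cov_corr`: correlation of the integrated covariances over a
#'     random sample of `n_pairs` neuron pairs, silent neurons included.
#' }
#' Reported rates are noise-averaged: `E[phi(z + noise)]` with the
#' closed-form ReLU moments and the per-neuron linearized stationary noise
#' SD, the deterministic analogue of time-averaged rates of the stochastic
#' dynamics (set `smooth_rates = FALSE` for the bare fixed-point rates).
#'
#' @param R Spectral bound of the (active-subnetwork) effective
#'   connectivity.
#' @param N Network size.
#' @param p Connection probability.
#' @param epsilon Independent-input fraction.
#' @param sigma_ext Quenched external input SD.
#' @param sigma_noise Dynamic white-noise strength.
#' @param seed RNG seed (connectivity, inputs and pair sample).
#' @param estimator `"linear_solve"` (deterministic, default) or
#'   `"simulation"` (Euler-Maruyama; also yields split-half
#'   reliabilities).
#' @param n_pairs Number of sampled pairs for the covariance correlation.
#' @param silent_threshold Rate below which a neuron counts as silent.
#' @param smooth_rates Use noise-averaged rates (default `TRUE`).
#' @param sim_duration Duration (units of tau) for the simulation
#'   estimator.
#' @return Object of class `two_net_result`.
#' @export
two_network_experiment <- function(R, N = 2000, p = 0.1, epsilon = 0.1,
                                   sigma_ext = 1, sigma_noise = 0.1,
                                   seed = 1L,
                                   estimator = c("linear_solve", "simulation"),
                                   n_pairs = 5000,
                                   silent_threshold = 1e-3,
                                   smooth_rates = TRUE,
                                   sim_duration = 2000) {
  estimator <- match.arg(estimator)
  if (R <= 0 || R >= 1) stop("'R' must lie in (0, 1)", call. = FALSE)
  w <- weight_for_spectral_bound(R, N, p)
  mu_ext <- external_drive_for_half_activation(R, N, p, sigma_ext)
  J <- fixed_indegree_network(N, p, w, seed = seed)
  inp <- draw_paired_inputs(mu_ext, sigma_ext, epsilon, N,
                            seed = seed + 1000L)
  nets <- lapply(1:2, function(a) {
    mu <- if (a == 1) inp$inputs1 else inp$inputs2
    z <- relu_fixed_point(J, mu)
    act <- as.numeric(z > 0)
    Jd <- as.matrix(J)
    W <- Jd * rep(act, each = N)            # J %*% diag(phi'(z))
    if (estimator == "linear_solve") {
      X <- solve(diag(N) - W)
      Cz <- sigma_noise^2 * tcrossprod(X)
      C <- Cz * outer(act, act)             # covariances of nu
      if (smooth_rates) {
        sloc <- sigma_noise / sqrt(2) * sqrt(rowSums(X^2))
        rates <- relu_rate_moments(z, pmax(sloc, 1e-12))$mean_rate
      } else rates <- pmax(z, 0)
      halves <- NULL
    } else {
      cfg <- sim_config(tau = 1, dt = 0.05, duration = sim_duration,
                        burn_in = 100, sigma_noise = sigma_noise,
                        mu_ext = mu, bin = 20, seed = seed + 10L * a)
      tr <- simulate_rate_network(J, "relu", cfg, keep_trajectory = TRUE)
      rates <- tr$mean_rates
      C <- tr$covariances
      B <- tr$trajectory
      h <- nrow(B) %/% 2
      halves <- list(first = list(rates = colMeans(B[1:h, ]),
                                  C = stats::cov(B[1:h, ]) * cfg$bin),
                     second = list(rates = colMeans(B[(h + 1):(2 * h), ]),
                                   C = stats::cov(B[(h + 1):(2 * h), ]) *
                                     cfg$bin))
    }
    list(rates = rates, C = C, frac_active = mean(act), halves = halves)
  })
  set.seed(seed + 2000L)
  ii <- sample.int(N, n_pairs, replace = TRUE)
  jj <- sample.int(N, n_pairs, replace = TRUE)
  wrap <- ii == jj
  jj[wrap] <- (jj[wrap] %% N) + 1L
  pair_idx <- cbind(ii, jj)
  keep <- nets[[1]]$rates >= silent_threshold &
    nets[[2]]$rates >= silent_threshold
  rate_corr <- stats::cor(nets[[1]]$rates[keep], nets[[2]]$rates[keep])
  cov_corr <- stats::cor(nets[[1]]$C[pair_idx], nets[[2]]$C[pair_idx])
  within <- NULL
  if (!is.null(nets[[1]]$halves)) {
    wh <- function(net) {
      k2 <- net$halves$first$rates >= silent_threshold &
        net$halves$second$rates >= silent_threshold
      c(rate = stats::cor(net$halves$first$rates[k2],
                          net$halves$second$rates[k2]),
        cov = stats::cor(net$halves$first$C[pair_idx],
                         net$halves$second$C[pair_idx]))
    }
    within <- rbind(net1 = wh(nets[[1]]), net2 = wh(nets[[2]]))
  }
  structure(list(R = R, N = N, p = p, epsilon = epsilon,
                 estimator = estimator,
                 input_corr = stats::cor(inp$inputs1, inp$inputs2),
                 rate_corr = rate_corr, cov_corr = cov_corr,
                 fraction_active = c(nets[[1]]$frac_active,
                                     nets[[2]]$frac_active),
                 rates = cbind(net1 = nets[[1]]$rates,
                               net2 = nets[[2]]$rates),
                 cov_sample = cbind(net1 = nets[[1]]$C[pair_idx],
                                    net2 = nets[[2]]$C[pair_idx]),
                 within_half_corrs = within,
                 halves = if (estimator == "simulation")
                   list(net1 = nets[[1]]$halves, net2 = nets[[2]]$halves)
                 else NULL,
                 pair_idx = pair_idx,
                 n_silent_excluded = sum(!keep), seed = seed),
            class = "two_net_result")
}

#' Sweep the spectral bound in the two-network experiment
#'
#' Runs [two_network_experiment()] for a set of spectral bounds and
#' replicate seeds and collects the rate- and covariance-pattern
#' correlations. Near criticality the covariance patterns become far more
#' sensitive to the working point than the rate patterns.
#'
#' @param R_values Spectral bounds (all < 1).
#' @param reps Number of replicate seeds per R.
#' @param seed Base seed.
#' @param ... Passed to [two_network_experiment()].
#' @return Data frame with columns `R`, `rep`, `rate_corr`, `cov_corr`.
#' @export
sweep_spectral_bound <- function(R_values, reps = 1, seed = 1L, ...) {
  grid <- expand.grid(R = R_values, rep = seq_len(reps))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ex <- two_network_experiment(R = grid$R[i],
                                 seed = seed + 37L * (i - 1L), ...)
    data.frame(R = grid$R[i], rep = grid$rep[i],
               rate_corr = ex$rate_corr, cov_corr = ex$cov_corr)
  })
  do.call(rbind, res)
}
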