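# shared fixtures and cached heavy computations (computed once per run)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# five paired-network experiments at the study conditions of the
# working-point figure (R = 0.8, N = 2000, p = 0.1, epsilon = 0.1)
wp_runs <- function() {
  cached("wp_runs", lapply(1:5, function(s)
    two_network_experiment(R = 0.8, N = 2000, p = 0.1, epsilon = 0.1,
                           sigma_ext = 1, sigma_noise = 0.1, seed = s)))
}

# six synthetic resting-state datasets at generator defaults, analyzed
# end-to-end with the spike pipeline
e2e_runs <- function() {
  cached("e2e_runs", lapply(1:6, function(s) {
    ds <- generate_resting_dataset(synthetic_config(seed = s))
    res <- analyze_resting(ds)
    list(ds = ds, res = res,
         rel = (res$fit_shared$d - ds$ground_truth$d_eff) /
           ds$ground_truth$d_eff)
  }))
}

# small task config used to exercise the epoch machinery quickly
small_task_cfg <- function(seed, modulation = 0.3) {
  synthetic_config(n_side = 14, n_units = 60, n_trials_task = 100,
                   modulation = modulation, seed = seed)
}

# decay constant of the exponential part of a long-range curve whose
# algebraic prefactor is known: regress log(y * x^(-p) * sqrt(x)) on x
tail_decay <- function(x, y, power = 1) {
  keep <- y > 0 & x > 0
  x <- x[keep]; y <- y[keep]
  f <- stats::lm(I(log(y) - power * log(x) + 0.5 * log(x)) ~ x)
  -1 / stats::coef(f)[[2]]
}

# four sub-period vectors with exactly prescribed within (S1-S2, P1-P2)
# and between (Sx-Py) correlations, built on an orthonormal basis
exact_corr_session <- function(n = 24, w = 0.8, b = 0.5) {
  m <- scale(matrix(stats::rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
  basis <- qr.Q(qr(m))   # orthonormal, mean-zero: cor == inner product
  e <- lapply(1:4, function(i) basis[, i])
  S1 <- e[[1]]
  S2 <- w * e[[1]] + sqrt(1 - w^2) * e[[2]]
  a1 <- b
  b1 <- (b - w * b) / sqrt(1 - w^2)
  c1 <- sqrt(1 - a1^2 - b1^2)
  P1 <- a1 * e[[1]] + b1 * e[[2]] + c1 * e[[3]]
  g1 <- (w - a1^2 - b1^2) / c1
  d1 <- sqrt(1 - a1^2 - b1^2 - g1^2)
  P2 <- a1 * e[[1]] + b1 * e[[2]] + g1 * e[[3]] + d1 * e[[4]]
  list(S1 = list(rates = S1, covs = S1), S2 = list(rates = S2, covs = S2),
       P1 = list(rates = P1, covs = P1), P2 = list(rates = P2, covs = P2))
}
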