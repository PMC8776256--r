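#' Parameters of the linear-response covariance theory
#'
#' Collects everything the closed-form covariance statistics need: the input
#' noise strength D, the spectral bound R of the effective connectivity, and
#' the spatial moments of the connectivity kernels. Per presynaptic
#' population b, the mean kernel is `m_b(x) = rho_b w_b n q_b(x)` and the
#' variance (heterogeneity) kernel is `s_b(x) = rho_b w_b^2 n q_b(x)(1 -
#' q_b(x))`, with `rho_b` the population density per cell area. The zero
#' modes of the variance kernels are normalized so that their sum -- the
#' spectral bound of the connectivity variance matrix -- equals `R^2`, which
#' fixes the excitatory weight exactly as in
#' [ensemble_connectivity_moments()].
#'
#' Moments are computed from the discrete lattice kernel when a geometry is
#' supplied (so that they match matrix computations on that lattice exactly)
#' and from continuum integrals otherwise.
#'
#' @param profile A [conn_profile()].
#' @param R Spectral bound of the effective connectivity, in [0, 1).
#' @param D Input noise strength (variance of the external white-noise drive
#'   per neuron). The normalization is fixed by the empty-network case: for
#'   `M = S = 0` the covariance matrix equals `D` times the identity.
#' @param g_ratio Inhibitory-to-excitatory weight ratio.
#' @param geom Optional [grid_geometry()]; if given, moments use discrete
#'   minimal-image lattice sums on that geometry.
#' @param pitch Cell pitch for the continuum densities when `geom` is `NULL`.
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(profile, R, D = 1, g_ratio = 8, geom = NULL,
                          pitch = 1) {
  stopifnot(inherits(profile, "conn_profile"))
  if (!(R >= 0 && R < 1))
    stop("'R' must lie in [0, 1); the linear theory diverges at R = 1",
         call. = FALSE)
  if (D <= 0) stop("'D' must be positive", call. = FALSE)
  if (!is.null(geom)) {
    pitch <- geom$pitch
    X <- pair_distances(geom)
    x <- X[1, ]                     # kernel seen from an E reference neuron
    pop <- geom$population
    dpre <- ifelse(pop == "E", profile$d_E, profile$d_I)
    q <- switch(profile$shape,
                exponential = profile$peak_probability * exp(-x / dpre),
                gaussian = profile$peak_probability * exp(-x^2 / (2 * dpre^2)))
    q[1] <- 0                        # no self-loop
    sker <- profile$n_trials * q * (1 - q) * ifelse(pop == "E", 1, g_ratio^2)
    mker <- profile$n_trials * q * ifelse(pop == "E", 1, -g_ratio)
    mom <- function(k, p) {          # zero mode and second moment per pop
      c(sum(k[pop == p]), sum((x^2 * k)[pop == p]) / sum(k[pop == p]))
    }
    sE <- mom(sker, "E"); sI <- mom(sker, "I")
    mE <- mom(mker, "E"); mI <- mom(abs(mker), "I")
    s_zero <- c(E = sE[1], I = sI[1])
    x2_s <- c(E = sE[2], I = sI[2])
    m_zero_rel <- c(E = mE[1], I = -mI[1])
    x2_m <- c(E = mE[2], I = mI[2])
    # exact zero mode from the 2x2 receiver-population matrix (the excluded
    # self-term differs between E and I receivers); rescale the rank-one
    # per-population split to match it
    qI <- q; qI[1] <- connection_prob(profile, 0, "E"); qI[5] <- 0
    skerI <- profile$n_trials * qI * (1 - qI) *
      ifelse(pop == "E", 1, g_ratio^2)
    Z <- rbind(c(sum(sker[pop == "E"]), sum(sker[pop == "I"])),
               c(sum(skerI[pop == "E"]), sum(skerI[pop == "I"])))
    z_exact <- max(Re(eigen(Z, only.values = TRUE)$values))
    s_zero <- s_zero * z_exact / sum(s_zero)
  } else {
    rho <- c(E = 4, I = 1) / pitch^2
    ker <- function(pop) {
      d <- if (pop == "E") profile$d_E else profile$d_I
      function(x) switch(profile$shape,
                         exponential = profile$peak_probability * exp(-x / d),
                         gaussian = profile$peak_probability *
                           exp(-x^2 / (2 * d^2)))
    }
    int2d <- function(f) 2 * pi * stats::integrate(function(x) x * f(x), 0, Inf,
                                                   rel.tol = 1e-10)$value
    s_zero <- x2_s <- m_zero_rel <- x2_m <- c(E = NA_real_, I = NA_real_)
    for (p in c("E", "I")) {
      q <- ker(p)
      sv0 <- int2d(function(x) q(x) * (1 - q(x)))
      sv2 <- int2d(function(x) x^2 * q(x) * (1 - q(x)))
      mv0 <- int2d(q)
      mv2 <- int2d(function(x) x^2 * q(x))
      wfac <- if (p == "E") 1 else g_ratio^2
      s_zero[p] <- rho[[p]] * profile$n_trials * sv0 * wfac
      x2_s[p] <- sv2 / sv0
      m_zero_rel[p] <- rho[[p]] * profile$n_trials * mv0 *
        (if (p == "E") 1 else -g_ratio)
      x2_m[p] <- mv2 / mv0
    }
  }
  # calibrate w_E so that sum of variance zero modes equals R^2
  w_E <- R / sqrt(sum(s_zero))
  s_pops <- w_E^2 * s_zero                # sums to R^2
  m_pops <- w_E * m_zero_rel              # population-resolved mean coupling
  rho <- c(E = 4, I = 1) / pitch^2
  structure(list(profile = profile, R = R, D = D, g_ratio = g_ratio,
                 w_E = w_E, pitch = pitch, rho = rho,
                 s_pops = s_pops, x2_s = x2_s,
                 m_pops = m_pops, x2_m = x2_m,
                 m0 = sum(m_pops), lattice = !is.null(geom)),
            class = "theory_params")
}

#' Closed-form mean and variance matrices of pairwise covariances
#'
#' Evaluates the matrix expressions for the mean and the variance of the
#' distribution of pairwise covariances of a spatially organized random
#' network: `cbar = (1-M)^(-1) D/(1-R^2) (1-M)^(-T)` and
#' `dc2 = (1-S)^(-1) (D/(1-R^2))^2 (1-S)^(-T)`, where M and S are the
#' ensemble mean and variance of the effective connectivity and R is its
#' spectral bound (the square root of the spectral bound of S). Both
#' expressions are evaluated by linear solves and symmetrized.
#'
#' @param x Either a calibrated `network_realization` (its ensemble moments
#'   are constructed from geometry, profile and calibration) or a list with
#'   elements `M`, `S`, `R` as returned by [ensemble_connectivity_moments()].
#' @param D Input noise strength.
#' @return List with `mean` and `variance` matrices, and the `R` used.
#' @export
covariance_moments <- function(x, D = 1) {
  if (inherits(x, "network_realization")) {
    if (is.null(x$W))
      stop("network has no calibrated weights; run assemble_effective_connectivity()",
           call. = FALSE)
    x <- ensemble_connectivity_moments(x$geometry, x$profile,
                                       target_R = x$target_R,
                                       g_ratio = x$g_ratio)
  }
  M <- x$M; S <- x$S
  n <- nrow(S)
  R2 <- if (!is.null(x$geometry))
    zero_mode_2x2(S, x$geometry$population)
  else max(Re(eigen(S, only.values = TRUE, symmetric = FALSE)$values))
  if (R2 >= 1)
    stop(sprintf("unstable network: spectral bound of the variance matrix is %.4f >= 1",
                 R2), call. = FALSE)
  bm <- suppressWarnings(spectral_bound(M))
  if (bm >= 1)
    stop(sprintf("unstable network: eigenvalue %.4f of the mean matrix >= 1",
                 bm), call. = FALSE)
  pref <- D / (1 - R2)
  Am <- solve(diag(n) - M)
  As <- solve(diag(n) - S)
  cbar <- pref * tcrossprod(Am)
  dc2 <- pref^2 * tcrossprod(As)
  list(mean = (cbar + t(cbar)) / 2, variance = (dc2 + t(dc2)) / 2,
       R = sqrt(R2))
}

#' Fourier transform of the connectivity variance kernel
#'
#' The eigenvalues of the spatial variance operator are given by the
#' two-dimensional Fourier transform of the connectivity variance profile.
#' This evaluates the continuum (Hankel) transform
#' `s(K) = sum_b s_b * f_b(K)` with each population kernel normalized to its
#' zero mode, so `s(0)` equals the prescribed zero mode `R^2`.
#'
#' @param params A [theory_params()].
#' @param K Radial wavenumbers (vector).
#' @param kernel `"variance"` (default) or `"mean"`.
#' @return `s(K)` (real for these isotropic kernels), same length as `K`.
#' @export
profile_fourier_kernel <- function(params, K, kernel = c("variance", "mean")) {
  kernel <- match.arg(kernel)
  zp <- if (kernel == "variance") params$s_pops else params$m_pops
  vapply(K, function(k) {
    tot <- 0
    for (p in c("E", "I")) {
      d <- if (p == "E") params$profile$d_E else params$profile$d_I
      p0 <- params$profile$peak_probability
      base <- function(x) switch(params$profile$shape,
                                 exponential = exp(-x / d),
                                 gaussian = exp(-x^2 / (2 * d^2)))
      kf <- if (kernel == "variance") {
        function(x) p0 * base(x) * (1 - p0 * base(x))
      } else {
        function(x) p0 * base(x)
      }
      f0 <- stats::integrate(function(x) x * kf(x), 0, Inf,
                             rel.tol = 1e-10)$value
      fk <- stats::integrate(function(x) x * kf(x) * besselJ(k * x, 0), 0,
                             upper_cut(d, k), rel.tol = 1e-9,
                             subdivisions = 500L)$value
      tot <- tot + zp[[p]] * fk / f0
    }
    tot
  }, numeric(1))
}

## integration cutoff: kernel tail below 1e-12
upper_cut <- function(d, k) 40 * d

## Pade [0/2] summaries of the resummed variance kernel: pooled decay
## constant from the denominator pole of the rational approximation, and
## per-population constants whose squared difference is pinned to the
## anatomical one (independent of R). Verified against the numerically
## measured tail of the full matrix expression on large lattices.
pade_summary <- function(params) {
  s0 <- sum(params$s_pops)
  cs <- sum(params$s_pops * params$x2_s / 4)
  if (s0 >= 1)
    stop("variance zero mode >= 1: network beyond the critical point",
         call. = FALSE)
  delta2 <- params$x2_s / 4 + cs / (1 - s0)       # per-population d_eff^2
  pooled <- sqrt(cs / (s0 * (1 - s0)))            # denominator-pole constant
  list(s0 = s0, r = params$s_pops / (1 - s0), delta = sqrt(delta2),
       pooled = pooled, pooled_pade = pooled, A1 = s0 / (1 - s0))
}

#' Spatial interaction kernel B(x)
#'
#' The resummation of all multi-synaptic propagation paths,
#' `B(x) = (2 pi)^(-2) * integral d^2k s(K)/(1 - s(K)) exp(i K x)`, evaluated
#' either by radial (Hankel) quadrature of the exact continuum kernel or by
#' the rational (Pade) approximation of the kernel around `K = 0`, which
#' yields a modified Bessel function of the second kind:
#' `B(x) ~ K0(x / d_eff)`, hence `B(x) ~ exp(-x/d_eff)/sqrt(x)` at long
#' range.
#'
#' @param params A [theory_params()].
#' @param x Distances (> 0 for the smooth part).
#' @param method `"pade"` or `"quadrature"`.
#' @return `B(x)`, with attribute `"method"`.
#' @export
spatial_interaction_kernel <- function(params, x,
                                       method = c("pade", "quadrature")) {
  method <- match.arg(method)
  ps <- pade_summary(params)
  if (ps$s0 >= 1) stop("zero mode >= 1: B(x) diverges", call. = FALSE)
  out <- if (method == "pade") {
    ps$A1 / (2 * pi * ps$pooled^2) * besselK(x / ps$pooled, 0)
  } else {
    vapply(x, function(xx) {
      f <- function(k) {
        s <- profile_fourier_kernel(params, k)
        k * s / (1 - s) * besselJ(k * xx, 0)
      }
      kmax <- 30 / min(params$profile$d_E, params$profile$d_I)
      # split at zeros of J0 to tame oscillation
      j0z <- c(2.404826, 5.520078, 8.653728, 11.791534, 14.930918)
      brk <- unique(pmin(c(0, j0z / max(xx, 1e-9), kmax), kmax))
      brk <- sort(brk)
      tot <- 0
      for (i in seq_len(length(brk) - 1)) {
        tot <- tot + stats::integrate(Vectorize(f), brk[i], brk[i + 1],
                                      rel.tol = 1e-7,
                                      subdivisions = 400L)$value
      }
      tot / (2 * pi)
    }, numeric(1))
  }
  attr(out, "method") <- method
  out
}

#' Effective decay constant of the variance of covariances
#'
#' The length scale on which the variance of pairwise covariances decays at
#' long range. From the rational approximation of the Fourier kernel the
#' pooled constant is `d_eff = d * sqrt(a / (1 - R^2))` for a single profile
#' scale d, where the constant a depends only on the profile shape (3/2 for
#' an exponential profile, 1/2 for a gaussian, with a small correction from
#' the binomial variance factor `1 - q`). `d_eff` grows monotonically with R
#' and diverges as R approaches one.
#'
#' Either supply `d` and `R` (plus `shape`) for the single-scale closed
#' form, or `params` for the population-resolved constants of a full
#' parameter set.
#'
#' @param d Connectivity length scale.
#' @param R Spectral bound, in [0, 1).
#' @param shape Profile shape for the closed form.
#' @param params Optional [theory_params()]; if given, `d` and `R` are
#'   ignored.
#' @param pop For `params`: `"pooled"`, `"E"` or `"I"`.
#' @return The effective decay constant (same units as d).
#' @examples
#' effective_decay_constant(d = 1, R = 0.8)   # ~ 2.04
#' @export
effective_decay_constant <- function(d = NULL, R = NULL,
                                     shape = c("exponential", "gaussian"),
                                     params = NULL,
                                     pop = c("pooled", "E", "I")) {
  pop <- match.arg(pop)
  if (!is.null(params)) {
    ps <- pade_summary(params)
    return(if (pop == "pooled") ps$pooled else ps$delta[[pop]])
  }
  shape <- match.arg(shape)
  if (!(R >= 0 && R < 1)) stop("'R' must lie in [0, 1)", call. = FALSE)
  if (d <= 0) stop("'d' must be positive", call. = FALSE)
  a <- if (shape == "exponential") 3 / 2 else 1 / 2
  d * sqrt(a / (1 - R^2))
}

#' Population eigenvalue and decay constant of the mean covariance
#'
#' The mean covariance decays on a length scale set by the population
#' eigenvalue m0 (the zero mode of the mean coupling kernel). The decay
#' constant is obtained from the pole of the resummed mean kernel
#' `m(K)/(1 - m(K))` continued to imaginary wavenumber; for
#' inhibition-dominated networks (m0 < 0) this pole sits close to the
#' inverse excitatory profile scale, so the mean decays steeply -- much
#' faster than the variance near criticality.
#'
#' @param params A [theory_params()].
#' @return List with `m0` (population eigenvalue, relative units) and
#'   `dbar` (decay constant of the mean covariance).
#' @export
mean_decay_constant <- function(params) {
  m0 <- params$m0
  if (m0 >= 1)
    stop("population eigenvalue >= 1: mean covariance diverges", call. = FALSE)
  # analytic continuation of the continuum kernel to K = i*kappa
  mk <- function(kap) {
    tot <- 0
    for (p in c("E", "I")) {
      d <- if (p == "E") params$profile$d_E else params$profile$d_I
      f <- switch(params$profile$shape,
                  exponential = (1 - (kap * d)^2)^(-3 / 2),
                  gaussian = exp((kap * d)^2 / 2))
      tot <- tot + params$m_pops[[p]] * f
    }
    tot
  }
  dmax <- max(params$profile$d_E, params$profile$d_I)
  up <- 1 / dmax * (1 - 1e-9)
  g <- function(kap) 1 - mk(kap)
  if (g(up) > 0) {                 # no pole before the branch point:
    dbar <- dmax                   # decay limited by the direct profile
  } else {
    dbar <- 1 / stats::uniroot(g, c(1e-9, up), tol = 1e-12)$root
  }
  list(m0 = m0, dbar = dbar)
}

#' Distance-resolved variance of pairwise covariances (theory curve)
#'
#' The smooth part of the variance of the covariance distribution versus
#' distance, `dc2(x) = (D/(1-R^2))^2 [B-terms + (B**B)-terms]`, built from
#' the per-population Pade kernels: single-kernel terms contribute
#' `K0(x/d_eff)` Bessel decay, the two-fold spatial convolution contributes
#' `x K1(x/d_eff)`, which dominates at long range (`~ x exp(-x/d_eff)`).
#' The delta contribution at x = 0 is excluded so that distance-binned
#' comparisons can omit same-site pairs; its amplitude `(D/(1-R^2))^2` is
#' returned as attribute `"delta"`.
#'
#' @param params A [theory_params()].
#' @param x Distances (> 0).
#' @param pair `"pooled"`, `"EE"`, `"EI"` or `"II"`: which population pair's
#'   covariance variance to return.
#' @return Theory curve values at `x`; attribute `"delta"` holds the x = 0
#'   delta amplitude and `"d_eff"` the pooled decay constant.
#' @export
variance_profile <- function(params, x, pair = c("pooled", "EE", "EI", "II")) {
  pair <- match.arg(pair)
  ps <- pade_summary(params)
  pref <- params$D / (1 - ps$s0)
  rho <- params$rho
  bterm <- function(p) {
    (1 / rho[[p]]) * ps$r[[p]] / (2 * pi * ps$delta[[p]]^2) *
      besselK(x / ps$delta[[p]], 0)
  }
  conv <- 0
  for (p in c("E", "I")) {
    conv <- conv + (1 / rho[[p]]) * ps$r[[p]]^2 /
      (4 * pi * ps$delta[[p]]^3) * x * besselK(x / ps$delta[[p]], 1)
  }
  wE <- 0.8; wI <- 0.2            # population fractions of the 4E+1I cell
  bpart <- switch(pair,
                  EE = 2 * bterm("E"),
                  II = 2 * bterm("I"),
                  EI = bterm("E") + bterm("I"),
                  pooled = 2 * (wE * bterm("E") + wI * bterm("I")))
  out <- pref^2 * (bpart + conv)
  attr(out, "delta") <- pref^2
  attr(out, "d_eff") <- ps$pooled
  out
}

#' Distance-resolved mean of pairwise covariances (theory curve)
#'
#' Smooth part of the mean covariance versus distance, evaluated by radial
#' quadrature of the resummed mean kernel `m(K)/(1-m(K))` (the rational
#' closed form is unreliable for sign-mixed E-I kernels). For
#' inhibition-dominated networks the curve is small and decays on the scale
#' returned by [mean_decay_constant()], much shorter than the variance scale
#' near criticality.
#'
#' @param params A [theory_params()].
#' @param x Distances (> 0).
#' @return List with `profile` (mean covariance at `x`, delta part excluded)
#'   and `dbar` (decay constant).
#' @export
mean_profile <- function(params, x) {
  R2 <- params$R^2
  pref <- params$D / (1 - R2)
  md <- mean_decay_constant(params)
  ds <- c(E = params$profile$d_E, I = params$profile$d_I)
  fK <- function(k, d) switch(params$profile$shape,
                              exponential = (1 + (k * d)^2)^(-3 / 2),
                              gaussian = exp(-(k * d)^2 / 2))
  wpop <- c(E = 0.8, I = 0.2)
  prof <- vapply(x, function(xx) {
    f <- function(k) {
      fE <- fK(k, ds[["E"]]); fI <- fK(k, ds[["I"]])
      m <- params$m_pops[["E"]] * fE + params$m_pops[["I"]] * fI
      bE <- params$m_pops[["E"]] * fE / (1 - m)
      bI <- params$m_pops[["I"]] * fI / (1 - m)
      # pooled (1+Bm)(1+Bm)^T - delta: single-kernel terms plus the
      # per-population spatial convolutions
      ker <- 2 * (wpop[["E"]] * bE / params$rho[["E"]] +
                    wpop[["I"]] * bI / params$rho[["I"]]) +
        bE^2 / params$rho[["E"]] + bI^2 / params$rho[["I"]]
      k * ker * besselJ(k * xx, 0)
    }
    kmax <- 30 / min(ds)
    j0z <- c(2.404826, 5.520078, 8.653728, 11.791534, 14.930918)
    brk <- sort(unique(pmin(c(0, j0z / max(xx, 1e-9), kmax), kmax)))
    tot <- 0
    for (i in seq_len(length(brk) - 1)) {
      tot <- tot + stats::integrate(Vectorize(f), brk[i], brk[i + 1],
                                    rel.tol = 1e-6,
                                    subdivisions = 400L)$value
    }
    pref * tot / (2 * pi)
  }, numeric(1))
  list(profile = prof, dbar = md$dbar, m0 = md$m0)
}

#' Difference of squared effective decay constants between populations
#'
#' For weights depending only on the presynaptic population, the squared
#' effective decay constants of excitatory and inhibitory covariance
#' variances obey `d_eff_E^2 - d_eff_I^2 = a * (d_E^2 - d_I^2)`, where a is
#' the profile-shape constant. The relation does not involve the
#' eigenvalues: near criticality both effective scales diverge while their
#' difference stays pinned to the anatomical one, so their relative
#' difference vanishes.
#'
#' @param d_E,d_I Anatomical profile scales.
#' @param R Spectral bound (enters the individual constants, not the
#'   difference).
#' @param shape Profile shape.
#' @param peak_probability If > 0, includes the binomial `1 - q` correction
#'   to the shape constant.
#' @return List with `difference` (`d_eff_E^2 - d_eff_I^2`), `ratio`
#'   (difference divided by `d_E^2 - d_I^2`) and the individual constants
#'   `d_eff_E`, `d_eff_I`.
#' @export
population_decay_difference <- function(d_E, d_I, R,
                                        shape = c("exponential", "gaussian"),
                                        peak_probability = 0) {
  shape <- match.arg(shape)
  prof <- conn_profile(shape, d_E = d_E, d_I = d_I,
                       peak_probability = max(peak_probability, 1e-9),
                       n_trials = 1)
  par <- theory_params(prof, R = R, D = 1)
  ps <- pade_summary(par)
  diff2 <- ps$delta[["E"]]^2 - ps$delta[["I"]]^2
  list(difference = diff2,
       ratio = if (d_E == d_I) NA_real_ else diff2 / (d_E^2 - d_I^2),
       d_eff_E = ps$delta[["E"]], d_eff_I = ps$delta[["I"]])
}

#' Extract a decay constant from a distance-resolved curve
#'
#' Weighted least-squares fit of a decay law to (x, y) data. Supported
#' forms: a pure exponential `a exp(-x/d)`; the long-range form of the
#' convolution term `a x exp(-x/d)`; and the two-term Bessel family
#' `a [K0(x/d) + A1/(2d) x K1(x/d)]` that the covariance theory predicts,
#' with fixed mixing amplitude `A1 = R^2/(1-R^2)`.
#'
#' @param x,y Distance and curve values (y > 0 for the Bessel forms at
#'   x > 0; the point x = 0 is dropped for forms that diverge there).
#' @param weights Optional fit weights (normalized internally).
#' @param form One of `"exponential"`, `"x_exponential"`, `"bessel_mix"`.
#' @param A1 Mixing amplitude for `"bessel_mix"`.
#' @return Object of class `decay_law` with `amplitude`, `length_constant`,
#'   `form`, `mse`.
#' @export
fit_decay_constant <- function(x, y, weights = NULL,
                               form = c("exponential", "x_exponential",
                                        "bessel_mix"),
                               A1 = NULL) {
  form <- match.arg(form)
  if (form != "exponential") {
    keep <- x > 0
    x <- x[keep]; y <- y[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  weights <- weights / sum(weights)
  if (form == "bessel_mix" && is.null(A1))
    stop("'A1' required for form = 'bessel_mix'", call. = FALSE)
  model <- switch(form,
                  exponential = function(a, d) a * exp(-x / d),
                  x_exponential = function(a, d) a * x * exp(-x / d),
                  bessel_mix = function(a, d)
                    a * (besselK(x / d, 0) + A1 / (2 * d) * x *
                           besselK(x / d, 1)))
  obj <- function(par) {
    pred <- model(exp(par[1]), exp(par[2]))
    sum(weights * (y - pred)^2)
  }
  span <- max(x) - min(x) + diff(range(x)) / length(x)
  best <- NULL
  for (d0 in span * c(0.1, 0.3, 1)) {
    y0 <- max(abs(y[which.min(x)]), 1e-12)
    o <- stats::optim(c(log(y0), log(d0)), obj,
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(amplitude = exp(best$par[1]),
                 length_constant = exp(best$par[2]),
                 form = form, mse = best$value,
                 convergence = best$convergence),
            class = "decay_law")
}

#' Tidy table of theory curves
#'
#' Evaluates the distance-resolved mean and variance theory curves for all
#' population pairs on a distance grid, suitable for CSV export.
#'
#' @param params A [theory_params()].
#' @param x Distance grid (> 0).
#' @param mean_curve If `TRUE`, also evaluate the (slower, quadrature-based)
#'   mean profile.
#' @return A data frame with columns `x`, `population_pair`, `variance`,
#'   optionally `mean`, plus attributes `d_eff` and `dbar`.
#' @export
theory_curve_table <- function(params, x, mean_curve = FALSE) {
  out <- do.call(rbind, lapply(c("pooled", "EE", "EI", "II"), function(p) {
    data.frame(x = x, population_pair = p,
               variance = as.numeric(variance_profile(params, x, p)))
  }))
  attr(out, "d_eff") <- effective_decay_constant(params = params)
  if (mean_curve) {
    mp <- mean_profile(params, x)
    out$mean <- rep(mp$profile, 4)
    attr(out, "dbar") <- mp$dbar
  }
  out
}
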