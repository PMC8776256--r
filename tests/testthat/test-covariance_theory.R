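test_that("matrix expressions reduce to identity for an empty network", {
  n <- 4
  x <- list(M = matrix(0, n, n), S = matrix(0, n, n))
  cm <- covariance_moments(x, D = 1)
  expect_equal(cm$mean, diag(n))
  expect_equal(cm$variance, diag(n))
  expect_equal(cm$R, 0)
})

test_that("matrix expressions match a brute-force Neumann series", {
  M <- rbind(c(0, 0.2), c(0.1, 0))
  S <- rbind(c(0, 0.05), c(0.08, 0))
  # sum W^n to machine precision
  neumann <- function(W) {
    A <- diag(2); P <- diag(2)
    repeat {
      P <- P %*% W
      if (max(abs(P)) < 1e-18) break
      A <- A + P
    }
    A
  }
  R2 <- max(Re(eigen(S, only.values = TRUE)$values))
  pref <- 1 / (1 - R2)
  Am <- neumann(M); As <- neumann(S)
  cm <- covariance_moments(list(M = M, S = S), D = 1)
  expect_equal(cm$mean, pref * Am %*% t(Am), tolerance = 1e-12)
  expect_equal(cm$variance, pref^2 * As %*% t(As), tolerance = 1e-12)
})

test_that("matrix outputs are symmetric and instability raises an error", {
  geom <- grid_geometry(6, pitch = 0.4)
  mom <- ensemble_connectivity_moments(geom, conn_profile(), 0.7)
  cm <- covariance_moments(mom)
  expect_lt(max(abs(cm$variance - t(cm$variance))) /
              max(abs(cm$variance)), 1e-12)
  expect_equal(cm$R, 0.7, tolerance = 1e-10)
  bad <- list(M = matrix(0, 2, 2), S = diag(c(1.2, 0.5)))
  expect_error(covariance_moments(bad), "unstable")
})

test_that("fourier kernel: maximal zero mode, lattice-sum oracle, decay", {
  for (shape in c("exponential", "gaussian")) {
    prof <- conn_profile(shape, d_E = 0.6, d_I = 0.6, peak_probability = 0.2)
    par <- theory_params(prof, R = 0.5, pitch = 0.4)
    s0 <- profile_fourier_kernel(par, 0)
    expect_equal(s0, 0.25, tolerance = 1e-6)   # zero mode = R^2
    K <- c(0.3, 0.6, 1.0)
    sK <- profile_fourier_kernel(par, K)
    expect_true(all(sK < s0))
    # direct lattice sum on a 21 x 21 stencil
    xy <- expand.grid(x = (-10:10) * 0.4, y = (-10:10) * 0.4)
    r <- sqrt(xy$x^2 + xy$y^2)
    lat <- vapply(K, function(k) {
      tot <- 0
      for (p in c("E", "I")) {
        q <- connection_prob(prof, r, p)
        ker <- q * (1 - q)
        tot <- tot + par$s_pops[[p]] * sum(ker * cos(k * xy$x)) / sum(ker)
      }
      tot
    }, numeric(1))
    expect_lt(max(abs(sK - lat) / lat), 0.01)
    # kernel vanishes at large K
    expect_lt(profile_fourier_kernel(par, 12), 0.05 * s0)
  }
})

test_that("B(x): quadrature vs rational form, asymptotic ratio, weak-coupling limit", {
  prof <- conn_profile(d_E = 0.5, d_I = 0.5, peak_probability = 0.2)
  par <- theory_params(prof, R = 0.8)
  xs <- c(1.2, 2, 3)                       # x > 2d
  bq <- spatial_interaction_kernel(par, xs, "quadrature")
  bp <- spatial_interaction_kernel(par, xs, "pade")
  expect_lt(max(abs(bp - bq) / bq), 0.10)

  # long-range law B ~ exp(-x/d_eff)/sqrt(x): check the ratio at 5d vs 10d
  deff <- effective_decay_constant(params = par)
  r_num <- spatial_interaction_kernel(par, 5, "quadrature") /
    spatial_interaction_kernel(par, 2.5, "quadrature")
  r_th <- exp(-2.5 / deff) * sqrt(1 / 2)
  expect_lt(abs(r_num / r_th - 1), 0.15)

  # vanishing zero mode: the resummation truncates to the direct kernel
  par0 <- theory_params(prof, R = 0.05)
  b0 <- spatial_interaction_kernel(par0, 1.0, "quadrature")
  direct <- stats::integrate(function(k)
    k * profile_fourier_kernel(par0, k) * besselJ(k * 1.0, 0),
    0, 60, subdivisions = 1000L)$value / (2 * pi)
  expect_equal(b0, direct, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("effective decay constant: monotone in R, proportional to d, divergent", {
  Rs <- seq(0, 0.99, by = 0.11)
  ds <- vapply(Rs, function(R) effective_decay_constant(d = 1, R = R),
               numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_equal(effective_decay_constant(d = 2, R = 0.7),
               2 * effective_decay_constant(d = 1, R = 0.7))
  expect_gt(effective_decay_constant(d = 1, R = 0.99) /
              effective_decay_constant(d = 1, R = 0.5), 5)
  expect_gt(effective_decay_constant(d = 1, R = 0.95),
            effective_decay_constant(d = 1, R = 0.5))
  expect_error(effective_decay_constant(d = 1, R = 1), "R")
})

test_that("variance profile: amplitude scaling and long-range slope", {
  prof <- conn_profile(d_E = 0.5, d_I = 0.5, peak_probability = 0.2)
  par1 <- theory_params(prof, R = 0.9, D = 1)
  par2 <- theory_params(prof, R = 0.9, D = 2)
  xs <- seq(1.5, 5, by = 0.25)             # [3d, 10d]
  v1 <- as.numeric(variance_profile(par1, xs))
  v2 <- as.numeric(variance_profile(par2, xs))
  expect_equal(v2 / v1, rep(4, length(xs)), tolerance = 1e-10)

  deff <- effective_decay_constant(params = par1)
  dfit <- tail_decay(xs, v1, power = 1)    # x e^{-x/deff} dominates
  expect_lt(abs(dfit - deff) / deff, 0.15)
})

test_that("matrix theory on a 16x16-cell lattice decays at the predicted rate", {
  geom <- grid_geometry(16, pitch = 0.4)
  prof <- conn_profile(d_E = 0.32, d_I = 0.32)
  mom <- ensemble_connectivity_moments(geom, prof, 0.8)
  cm <- covariance_moments(mom, D = 1)
  tbl <- distance_resolved_statistics(cm$variance, geom, labels = NULL)
  sel <- tbl$distance > 2 * prof$d_E & tbl$distance <= 0.35 * geom$box
  dfit <- tail_decay(tbl$distance[sel], tbl$mean[sel], power = 1)
  par <- theory_params(prof, R = 0.8, geom = geom)
  deff <- effective_decay_constant(params = par)
  expect_lt(abs(dfit - deff) / deff, 0.20)
})

test_that("mean covariance decays steeply: dbar below d_eff, matrix oracle", {
  geom <- grid_geometry(16, pitch = 0.4)
  prof <- conn_profile(d_E = 0.4, d_I = 0.28)
  par <- theory_params(prof, R = 0.8, g_ratio = 10, geom = geom)
  md <- mean_decay_constant(par)
  expect_lt(md$m0, 0)                       # inhibition dominated
  deff <- effective_decay_constant(params = par)
  expect_lt(md$dbar, deff)

  mom <- ensemble_connectivity_moments(geom, prof, 0.8, g_ratio = 10)
  cm <- covariance_moments(mom)
  tbl <- distance_resolved_statistics(cm$mean, geom, labels = NULL)
  sel <- tbl$distance > 0.4 & tbl$distance < 2.2
  fit <- fit_decay_constant(tbl$distance[sel], abs(tbl$mean[sel]),
                            form = "exponential")
  expect_lt(abs(fit$length_constant - md$dbar) / md$dbar, 0.25)

  # theory curve tracks the matrix mean pointwise
  mp <- mean_profile(par, tbl$distance[sel])
  expect_gt(stats::cor(mp$profile, tbl$mean[sel]), 0.95)
})

test_that("balanced-zero population coupling truncates the mean resummation", {
  prof <- conn_profile(d_E = 0.5, d_I = 0.5, peak_probability = 0.2)
  par <- theory_params(prof, R = 0.6, g_ratio = 4)   # 4E vs g=4 inhibition
  expect_lt(abs(par$m0), 1e-10)
  # with m(K) = 0 throughout, only the direct (single- and two-hop) terms
  # of the mean kernel survive: the single-hop parts cancel by balance and
  # the two-hop part is the plain convolution of the mean kernels
  xs <- c(0.5, 1, 2)
  mp <- mean_profile(par, xs)
  d <- 0.5
  direct <- vapply(xs, function(xx) {
    f <- function(k) {
      fk <- (1 + (k * d)^2)^(-3 / 2)
      conv <- (par$m_pops[["E"]]^2 / par$rho[["E"]] +
                 par$m_pops[["I"]]^2 / par$rho[["I"]]) * fk^2
      k * conv * besselJ(k * xx, 0)
    }
    (par$D / (1 - par$R^2)) *
      stats::integrate(Vectorize(f), 0, 60, subdivisions = 1000L)$value /
      (2 * pi)
  }, numeric(1))
  expect_equal(mp$profile, direct, tolerance = 0.01)
})

test_that("squared decay-constant difference is pinned to the anatomical one", {
  # equal profiles: no difference at any R
  expect_equal(population_decay_difference(1, 1, 0.5)$difference, 0,
               tolerance = 1e-9)
  # the ratio is independent of the spectral bound
  ratios <- vapply(c(0.5, 0.7, 0.9), function(R)
    population_decay_difference(1, 0.75, R)$ratio, numeric(1))
  expect_lt(max(abs(ratios / ratios[1] - 1)), 0.05)
  # near criticality the relative difference of the (large) constants is small
  pd <- population_decay_difference(1, 0.75, 0.98)
  expect_lt((pd$d_eff_E - pd$d_eff_I) / pd$d_eff_E, 0.05)
  expect_gt(pd$d_eff_E, 4)   # both constants large near criticality
})

test_that("near criticality the EE/EI/II variance curves share one length scale", {
  par <- theory_params(conn_profile(d_E = 0.4, d_I = 0.32), R = 0.95)
  deff <- effective_decay_constant(params = par)
  dcls <- vapply(c("EE", "EI", "II"), function(pc) {
    xs <- seq(4, 8, by = 0.25) * deff
    tail_decay(xs, as.numeric(variance_profile(par, xs, pc)), power = 1)
  }, numeric(1))
  expect_lt((max(dcls) - min(dcls)) / min(dcls), 0.10)
})

test_that("decay-law fitting recovers parameters exactly on noiseless curves", {
  x <- seq(0, 5, by = 0.25)
  y <- 2 * exp(-x / 1.5)
  f <- fit_decay_constant(x, y, form = "exponential")
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
  expect_equal(f$length_constant, 1.5, tolerance = 1e-6)

  y2 <- 0.7 * x * exp(-x / 2)
  f2 <- fit_decay_constant(x, y2, form = "x_exponential")
  expect_equal(f2$length_constant, 2, tolerance = 1e-5)

  y3 <- 3 * (besselK(pmax(x, 0.2) / 1.2, 0) +
               2 / (2 * 1.2) * pmax(x, 0.2) * besselK(pmax(x, 0.2) / 1.2, 1))
  f3 <- fit_decay_constant(pmax(x, 0.2), y3, form = "bessel_mix", A1 = 2)
  expect_equal(f3$length_constant, 1.2, tolerance = 1e-5)
})

test_that("theory curve table covers all pairs and carries the decay constant", {
  par <- theory_params(conn_profile(d_E = 0.5, d_I = 0.4,
                                    peak_probability = 0.2), R = 0.8)
  tb <- theory_curve_table(par, x = c(0.5, 1, 2))
  expect_setequal(unique(tb$population_pair), c("pooled", "EE", "EI", "II"))
  expect_equal(nrow(tb), 12)
  expect_gt(attr(tb, "d_eff"), 0)
})
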