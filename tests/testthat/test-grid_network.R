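test_that("grid geometry has the 4E+1I composition and periodic extents", {
  g <- grid_geometry(10, pitch = 1)
  expect_equal(nrow(g$positions), 500)
  expect_equal(nrow(g$cells), 100)
  expect_equal(as.integer(table(g$population)), c(400, 100))

  g2 <- grid_geometry(2, pitch = 0.5)
  expect_equal(nrow(g2$positions), 20)
  D <- pair_distances(g2)
  expect_equal(max(D), sqrt(0.5^2 + 0.5^2), tolerance = 1e-12)

  expect_error(grid_geometry(1), "integer >= 2")
  expect_error(grid_geometry(4, pitch = 0), "positive")
  expect_error(grid_geometry(4, pitch = -1), "positive")
})

test_that("minimal-image distance wraps, is symmetric, and vanishes iff equal", {
  expect_equal(periodic_distance(c(0, 0), c(9, 0), box = 10), 1)
  expect_equal(periodic_distance(c(0, 0), c(5, 5), box = 10), sqrt(50))
  expect_equal(periodic_distance(c(3, 4), c(3, 4), box = 10), 0)
  a <- c(1.2, 7.7); b <- c(9.1, 0.3)
  expect_equal(periodic_distance(a, b, 10), periodic_distance(b, a, 10))
  expect_gt(periodic_distance(a, b, 10), 0)
})

test_that("synapse counts follow the distance-dependent binomial law", {
  g <- grid_geometry(4, pitch = 1)
  prof <- conn_profile("exponential", d_E = 1, d_I = 1,
                       peak_probability = 0.4, n_trials = 1)
  # determinism
  n1 <- sample_synapse_counts(g, prof, seed = 11)
  n2 <- sample_synapse_counts(g, prof, seed = 11)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(diag(n1$counts) == 0))

  # vanishing peak probability: no synapses
  p0 <- conn_profile("exponential", d_E = 1, d_I = 1,
                     peak_probability = 1e-12, n_trials = 5)
  expect_true(all(sample_synapse_counts(g, p0, seed = 1)$counts == 0))

  # Monte-Carlo mean count vs the closed-form binomial mean, within 3 SE
  D <- pair_distances(g)
  q <- connection_prob(prof, D, "E")
  diag(q) <- 0
  tot <- matrix(0, nrow(D), ncol(D))
  nrep <- 40
  for (s in 1:nrep) tot <- tot + sample_synapse_counts(g, prof, seed = s)$counts
  for (dist in c(0, 1, sqrt(2))) {
    sel <- abs(D - dist) < 1e-9 & upper.tri(D)
    m_emp <- mean(tot[sel]) / nrep
    qd <- q[sel][1]
    se <- sqrt(qd * (1 - qd) / (sum(sel) * nrep))
    expect_lt(abs(m_emp - qd), 3 * se + 1e-12)
  }
})

test_that("statistical isotropy: x- and y-axis mean counts agree within 3 SE", {
  g <- grid_geometry(6, pitch = 1)
  prof <- conn_profile(d_E = 1, d_I = 1, peak_probability = 0.4, n_trials = 1)
  D <- pair_distances(g)
  px <- g$positions
  dx <- abs(critcov:::min_image(outer(px[, 1], px[, 1], "-"), g$box))
  dy <- abs(critcov:::min_image(outer(px[, 2], px[, 2], "-"), g$box))
  selx <- dx == 2 & dy == 0 & upper.tri(D)   # pure x displacement
  sely <- dy == 2 & dx == 0 & upper.tri(D)   # pure y displacement
  totx <- toty <- 0
  nrep <- 30
  for (s in 1:nrep) {
    cc <- sample_synapse_counts(g, prof, seed = 100 + s)$counts
    totx <- totx + mean(cc[selx]); toty <- toty + mean(cc[sely])
  }
  qd <- connection_prob(prof, 2, "E")
  se <- sqrt(qd * (1 - qd) / (sum(selx) * nrep))
  expect_lt(abs(totx - toty) / nrep, 3 * sqrt(2) * se)
})

test_that("spectral calibration hits the target bound and is scale invariant", {
  g <- grid_geometry(8, pitch = 0.4)
  prof <- conn_profile()
  net0 <- sample_synapse_counts(g, prof, seed = 3)
  for (R in c(0.5, 0.8, 0.95)) {
    net <- assemble_effective_connectivity(net0, target_R = R)
    expect_equal(spectral_bound(net$W), R, tolerance = 1e-3)
  }
  # doubling the raw weights (here: counts) leaves the calibrated W unchanged
  net_a <- assemble_effective_connectivity(net0, 0.8)
  net_b <- net0
  net_b$counts <- 2L * net0$counts
  net_b <- assemble_effective_connectivity(net_b, 0.8)
  expect_equal(net_a$W, net_b$W, tolerance = 1e-10)

  # a zero network cannot be calibrated
  net_z <- net0
  net_z$counts[] <- 0L
  expect_error(assemble_effective_connectivity(net_z, 0.8), "zero")
})

test_that("spectrum summary: bound, brute-force oracle, population eigenvalue", {
  expect_equal(spectral_summary(matrix(0, 3, 3))$spectral_bound, 0)
  expect_equal(spectral_summary(diag(c(0.3, -0.5)))$spectral_bound, 0.3)
  expect_error(spectral_summary(matrix(1, 2, 3)), "square")

  # 6x6 oracle: roots of the characteristic polynomial via the
  # Faddeev-LeVerrier coefficients (independent of eigen())
  set.seed(42)
  W <- matrix(rnorm(36, 0, 0.3), 6, 6) * (matrix(runif(36), 6, 6) < 0.5)
  n <- 6
  coefs <- numeric(n + 1); coefs[1] <- 1
  Mk <- diag(n)
  for (k in 1:n) {
    Ak <- W %*% Mk
    coefs[k + 1] <- -sum(diag(Ak)) / k
    Mk <- Ak + coefs[k + 1] * diag(n)
  }
  roots <- polyroot(rev(coefs))
  expect_equal(spectral_summary(W)$spectral_bound, max(Re(roots)),
               tolerance = 1e-8)

  # inhibition-dominated parameterization: negative population eigenvalue
  g <- grid_geometry(8, pitch = 0.4)
  net <- sample_synapse_counts(g, conn_profile(), seed = 2)
  net <- assemble_effective_connectivity(net, 0.8, g_ratio = 8)
  ss <- spectral_summary(net$W, g$population)
  expect_lt(Re(ss$population_eigenvalue), 0)
  expect_lt(Re(ss$population_eigenvalue), ss$spectral_bound)
})

test_that("realized disorder of a calibrated network sits near the target", {
  g <- grid_geometry(12, pitch = 0.4)
  net <- sample_synapse_counts(g, conn_profile(), seed = 5)
  net <- assemble_effective_connectivity(net, 0.8)
  r <- realized_disorder(net)
  expect_gt(r, 0.5)
  expect_lt(r, 0.85)
})
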