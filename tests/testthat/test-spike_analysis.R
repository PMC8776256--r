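# small task-free dataset builder: known spikes on a 3 x 3 patch of the grid
toy_dataset <- function(spike_times, snr = NULL, widths = NULL) {
  n <- length(spike_times)
  units <- data.frame(unit_id = seq_len(n),
                      row = rep(1:3, length.out = n),
                      col = rep(1:3, each = 3, length.out = n))
  if (!is.null(snr)) units$snr <- snr
  if (!is.null(widths)) units$width <- widths
  spikes <- data.frame(unit_id = rep(seq_len(n), lengths(spike_times)),
                       t = unlist(spike_times))
  spike_dataset(spikes, units, segments = data.frame(start = 0, stop = 600))
}

test_that("waveform-width classification applies thresholds and demotion", {
  lab <- classify_units_by_waveform(c(0.30, 0.335, 0.50), c(0.33, 0.34))
  expect_equal(as.character(lab), c("I", "unclassified", "E"))
  # monkey-N thresholds
  labN <- classify_units_by_waveform(c(0.50, 0.405, 0.39), c(0.40, 0.41))
  expect_equal(as.character(labN), c("E", "unclassified", "I"))
  # step 2: low single-waveform agreement demotes to unclassified
  lab2 <- classify_units_by_waveform(c(0.30, 0.50), c(0.33, 0.34),
                                     single_fraction = c(0.4, 0.9),
                                     fraction_threshold = 0.6)
  expect_equal(as.character(lab2), c("unclassified", "E"))
  expect_warning(classify_units_by_waveform(c(NA, 0.5), c(0.33, 0.34)),
                 "missing")
  expect_error(classify_units_by_waveform(0.3, c(0.4, 0.33)), "threshold")
})

test_that("unit filter enforces SNR and rate bounds inclusively", {
  # units: exactly 1 Hz, well above, and below threshold
  sp <- list(seq(0.5, 599.5, by = 1),        # 600 spikes in 600 s = 1 Hz
             seq(0.1, 599.9, by = 0.2),      # 5 Hz
             c(10, 300))                     # ~0.003 Hz
  ds <- toy_dataset(sp, snr = c(3, 2.4, 3))
  out <- filter_units(ds)
  expect_equal(out$units$unit_id, 1L)        # unit 2 fails SNR, 3 fails rate
  rem <- attr(out, "removed")
  expect_setequal(rem$reason[rem$unit_id == 2], "snr")
  expect_setequal(rem$reason[rem$unit_id == 3], "rate")
  ds_bad <- toy_dataset(list(c(1, 2), c(3, 4)), snr = c(1, 1))
  expect_error(filter_units(ds_bad), "no units")
})

test_that("coincidence filter drops hyper-synchronous sampling steps", {
  # three units on distinct electrodes firing in the same sampling step
  t0 <- round(100 * 30000) / 30000
  sp <- list(c(t0, 200), c(t0, 201), c(t0, 202, 203))
  ds <- toy_dataset(sp, snr = c(3, 3, 3))
  out <- filter_units(ds, rate_min = 0, coincidence_k = 3)
  expect_false(any(abs(out$spikes$t - t0) < 1e-9))
  expect_equal(nrow(out$spikes), 4)          # only the synchronous step lost
})

test_that("spike-count covariance equals the (l-1)-normalized estimator", {
  # hand-crafted counts via spike times: 3 bins of 1 s
  sp <- list(c(1.5, 2.2, 2.7),   # counts 0,1,2
             c(0.1, 0.2, 1.3))   # counts 2,1,0
  n <- 2
  units <- data.frame(unit_id = 1:2, row = c(1, 1), col = c(1, 2))
  ds <- spike_dataset(data.frame(unit_id = rep(1:2, each = 3),
                                 t = unlist(sp)), units,
                      segments = data.frame(start = 0, stop = 3))
  bc <- bin_and_covary(ds, bin_width = 1)
  expect_equal(unname(bc$counts), rbind(c(0, 1, 2), c(2, 1, 0)))
  expect_equal(bc$covariance[1, 2], -1)
  expect_equal(bc$covariance[2, 1], -1)
  expect_equal(bc$n_bins, 3L)

  # identical trains: covariance 1, correlation 1
  ds2 <- spike_dataset(data.frame(unit_id = rep(1:2, each = 6),
                                  t = rep(c(0.5, 1.2, 1.7, 2.1, 2.5, 2.9),
                                          2)),
                       units, segments = data.frame(start = 0, stop = 3))
  bc2 <- bin_and_covary(ds2, bin_width = 1)
  expect_equal(bc2$covariance[1, 2], 1)
  expect_equal(bc2$correlation[1, 2], 1)
})

test_that("covariance matrix matches a brute-force two-pass computation", {
  set.seed(12)
  counts <- matrix(rpois(8 * 40, 4), 8, 40)
  units <- data.frame(unit_id = 1:8, row = rep(1:2, 4), col = rep(1:4, 2))
  # brute force: explicit double loop over pairs
  l <- ncol(counts)
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    bi <- counts[i, ] - mean(counts[i, ])
    bj <- counts[j, ] - mean(counts[j, ])
    brute[i, j] <- sum(bi * bj) / (l - 1)
  }
  expect_equal(stats::cov(t(counts)), brute, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(brute, t(brute))
})

test_that("distance-resolved variance table: degenerate and corrected cases", {
  # constant off-diagonal covariance: zero variance at every distance
  n <- 9
  cm <- matrix(0.7, n, n); diag(cm) <- 2
  units <- data.frame(unit_id = 1:n, row = rep(1:3, 3), col = rep(1:3, each = 3))
  tbl <- variance_vs_distance(cm, units, bias_correction = FALSE)
  expect_true(all(abs(tbl$variance) < 1e-12))
  expect_true(all(tbl$mean == 0.7))

  # estimator-noise correction is tiny for long recordings
  set.seed(5)
  nu <- 20; l <- 200000
  A <- matrix(rnorm(nu * nu, 0, 1.2 / sqrt(nu)), nu, nu)
  C <- diag(nu) + tcrossprod(A)             # dispersed covariances
  cnt <- matrix(rnorm(nu * l), nu, l)
  cnt <- t(chol(C)) %*% cnt
  cm2 <- stats::cov(t(cnt))
  u2 <- data.frame(unit_id = 1:nu, row = rep(1:4, 5), col = rep(1:5, each = 4))
  t_raw <- variance_vs_distance(cm2, u2, bias_correction = FALSE)
  t_cor <- variance_vs_distance(cm2, u2, bias_correction = TRUE, n_bins = l)
  rel <- abs(t_cor$variance - t_raw$variance) / t_raw$variance
  expect_lt(max(rel[t_raw$count >= 5]), 1e-3)
})

test_that("bias-corrected variance is closer to the generative ground truth", {
  set.seed(9)
  nu <- 15; l <- 400
  A <- matrix(rnorm(nu * nu, 0, 0.6 / sqrt(nu)), nu, nu)
  C <- diag(nu) + tcrossprod(A)
  u <- data.frame(unit_id = 1:nu, row = rep(1:3, 5), col = rep(1:5, each = 3))
  truth <- variance_vs_distance(C, u, bias_correction = FALSE)
  err_raw <- err_cor <- 0
  for (s in 1:20) {
    cnt <- t(chol(C)) %*% matrix(rnorm(nu * l), nu, l)
    cm <- stats::cov(t(cnt))
    t_raw <- variance_vs_distance(cm, u, bias_correction = FALSE)
    t_cor <- variance_vs_distance(cm, u, bias_correction = TRUE, n_bins = l)
    ok <- truth$count >= 3
    err_raw <- err_raw + mean(abs(t_raw$variance - truth$variance)[ok])
    err_cor <- err_cor + mean(abs(t_cor$variance - truth$variance)[ok])
  }
  expect_lt(err_cor, err_raw)
})

test_that("weighted exponential fits recover noiseless parameters", {
  x <- seq(0, 5, by = 0.5)
  mk <- function(a, d, cl) data.frame(distance = x, pair_class = cl,
                                      mean = 0, variance = a * exp(-x / d),
                                      count = 10L, excluded = FALSE)
  tbl <- mk(2, 1.5, "EE")
  f <- fit_exponential_decay(tbl, "free")
  expect_equal(unname(f$amplitudes[["EE"]]), 2, tolerance = 1e-6)
  expect_equal(unname(f$d[["EE"]]), 1.5, tolerance = 1e-6)

  tbl3 <- rbind(mk(1, 1, "EE"), mk(2, 1, "EI"), mk(3, 1, "II"))
  fs <- fit_exponential_decay(tbl3, "shared_slope")
  expect_equal(unname(fs$d), 1, tolerance = 1e-6)
  expect_equal(unname(fs$amplitudes), c(1, 2, 3), tolerance = 1e-5)

  # nested models: the constrained fit cannot beat the free fit
  set.seed(2)
  tbl_n <- rbind(mk(1, 0.8, "EE"), mk(2, 1.4, "EI"), mk(3, 1.1, "II"))
  tbl_n$variance <- tbl_n$variance * exp(rnorm(nrow(tbl_n), 0, 0.1))
  f_free <- fit_exponential_decay(tbl_n, "free")
  f_sh <- fit_exponential_decay(tbl_n, "shared_slope")
  expect_gte(f_sh$mse, f_free$mse - 1e-12)

  # equal generating slopes: the shared/free mse ratio is closer to one
  # than for data generated with genuinely different slopes
  tbl_e <- rbind(mk(1, 1.2, "EE"), mk(2, 1.2, "EI"), mk(3, 1.2, "II"))
  tbl_e$variance <- tbl_e$variance * exp(rnorm(nrow(tbl_e), 0, 0.05))
  r_equal <- fit_exponential_decay(tbl_e, "shared_slope")$mse /
    fit_exponential_decay(tbl_e, "free")$mse
  r_diff <- f_sh$mse / f_free$mse
  expect_lt(r_equal, r_diff)

  expect_error(fit_exponential_decay(mk(1, 1, "EE")[1:2, ], "free"),
               "3 distance points")
})

test_that("epoch segmentation follows the trial event template", {
  tr <- data.frame(trial = 1:3, TS = c(0, 10, NA),
                   CUE_OFF = c(1.1, NA, 21.1))
  ep <- suppressMessages(segment_epochs(tr))
  s1 <- ep[ep$trial == 1 & ep$epoch == "S1", ]
  expect_equal(c(s1$start, s1$stop), c(0, 0.2))
  s2 <- ep[ep$trial == 1 & ep$epoch == "S2", ]
  expect_equal(c(s2$start, s2$stop), c(0.2, 0.4))
  p1 <- ep[ep$trial == 1 & ep$epoch == "P1", ]
  expect_equal(c(p1$start, p1$stop), c(1.1, 1.3))
  # trial 2 lacks CUE_OFF: S epochs only
  expect_setequal(as.character(ep$epoch[ep$trial == 2]), c("S1", "S2"))
  # trial 3 lacks TS: dropped entirely
  expect_false(3 %in% ep$trial)
  expect_error(segment_epochs(data.frame(trial = c(1, 1), TS = c(0, 1))),
               "duplicated")
  expect_error(segment_epochs(data.frame(trial = 1, TS = 5, CUE_OFF = 4)),
               "ill-ordered")
})

test_that("epoch comparison: degrees of freedom, pooled statistics, KS fallback", {
  set.seed(77)
  s5 <- lapply(1:5, function(i) exact_corr_session())
  cmp5 <- compare_epochs(s5)
  expect_equal(cmp5$rates$df, 28)
  s8 <- lapply(1:8, function(i) exact_corr_session())
  cmp8 <- compare_epochs(s8)
  expect_equal(cmp8$covariances$df, 46)

  # zero-spread groups: m = difference of means, pooled s = 0
  expect_equal(cmp5$rates$m, 0.3, tolerance = 1e-10)
  expect_equal(cmp5$rates$s, 0, tolerance = 1e-10)
  expect_equal(cmp5$rates$ci, c(0.3, 0.3), tolerance = 1e-9)
  # constant groups fail normality, so the KS fallback must have run
  expect_false(is.null(cmp5$rates$ks))
  expect_equal(cmp5$rates$ks$D, 1)
})
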