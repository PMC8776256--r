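#' Construct a spike dataset
#'
#' The common currency of the empirical pipeline: a table of spike times, a
#' table of unit metadata (electrode position, waveform width,
#' signal-to-noise ratio, population label), optional trial events for task
#' recordings, optional analyzable segments for resting-state recordings,
#' and an optional ground-truth block attached by the synthetic generator.
#'
#' @param spikes Data frame with columns `unit_id` and `t` (spike time, s).
#' @param units Data frame with columns `unit_id`, `row`, `col` (electrode
#'   grid indices, 1-based), and optionally `width` (waveform width, ms),
#'   `snr`, `label` (`"E"`, `"I"` or `"unclassified"`),
#'   `single_wf_fraction` (agreement fraction of single waveforms with the
#'   average-waveform class).
#' @param trials Optional data frame of event times per trial with columns
#'   `trial` and event columns such as `TS`, `WS`, `CUE_ON`, `CUE_OFF`,
#'   `GO` (seconds).
#' @param segments Optional data frame with columns `start`, `stop` of
#'   analyzable intervals.
#' @param pitch Electrode pitch in mm (0.4 for a Utah array).
#' @param grid_dim Electrode grid dimensions.
#' @param ground_truth Optional list (generator-known covariances etc.).
#' @return Object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, units, trials = NULL, segments = NULL,
                          pitch = 0.4, grid_dim = c(10, 10),
                          ground_truth = NULL) {
  stopifnot(all(c("unit_id", "t") %in% names(spikes)),
            all(c("unit_id", "row", "col") %in% names(units)))
  if (anyDuplicated(units$unit_id))
    stop("duplicated unit ids in 'units'", call. = FALSE)
  if (!all(spikes$unit_id %in% units$unit_id))
    stop("spike table contains unknown unit ids", call. = FALSE)
  if (any(units$row < 1 | units$row > grid_dim[1] |
          units$col < 1 | units$col > grid_dim[2]))
    stop("electrode coordinates outside the grid", call. = FALSE)
  if (!is.null(units$width) && any(units$width <= 0, na.rm = TRUE))
    stop("waveform widths must be positive", call. = FALSE)
  structure(list(spikes = spikes, units = units, trials = trials,
                 segments = segments, pitch = pitch, grid_dim = grid_dim,
                 ground_truth = ground_truth),
            class = "spike_dataset")
}

#' Classify units into putative excitatory and inhibitory by waveform width
#'
#' Two-step classification. Step 1 applies width thresholds to the average
#' waveform: widths at or below `thresholds[1]` are narrow-spiking
#' (putative inhibitory), widths at or above `thresholds[2]` are
#' broad-spiking (putative excitatory), and widths in the gap stay
#' unclassified. Step 2 demotes units whose single-waveform agreement
#' fraction (the share of single waveforms pre-classified like the average
#' waveform) falls below `fraction_threshold`. Recommended thresholds from
#' monkey-specific width distributions: 0.33/0.34 ms (monkey E) and
#' 0.40/0.41 ms (monkey N).
#'
#' @param widths Average-waveform widths in ms (NA allowed; yields
#'   unclassified with a warning).
#' @param thresholds Length-2 numeric `c(narrow_max, broad_min)` in ms.
#' @param single_fraction Optional per-unit single-waveform agreement
#'   fractions for step 2.
#' @param fraction_threshold Minimum agreement fraction to keep a step-1
#'   label.
#' @return Factor with levels `"E"`, `"I"`, `"unclassified"`.
#' @examples
#' classify_units_by_waveform(c(0.30, 0.335, 0.50), c(0.33, 0.34))
#' @export
classify_units_by_waveform <- function(widths, thresholds = c(0.33, 0.34),
                                       single_fraction = NULL,
                                       fraction_threshold = 0.6) {
  if (thresholds[1] > thresholds[2])
    stop("narrow threshold must not exceed broad threshold", call. = FALSE)
  lab <- rep("unclassified", length(widths))
  if (anyNA(widths))
    warning("missing waveform widths: units left unclassified")
  lab[!is.na(widths) & widths <= thresholds[1]] <- "I"
  lab[!is.na(widths) & widths >= thresholds[2]] <- "E"
  if (!is.null(single_fraction)) {
    demote <- !is.na(single_fraction) & single_fraction < fraction_threshold
    lab[demote] <- "unclassified"
  }
  factor(lab, levels = c("E", "I", "unclassified"))
}

#' Filter units by signal-to-noise ratio and firing rate
#'
#' Keeps units with `snr >= snr_min` and average firing rate
#' `>= rate_min` (rates computed over the analyzable segments if present,
#' otherwise over the full recording span). Optionally applies a simplified
#' coincidence filter first: spikes that occur in the same sampling step as
#' spikes on at least `coincidence_k - 1` other electrodes are removed
#' before rates are computed (a stand-in for hyper-synchronous artifact
#' removal).
#'
#' @param ds A [spike_dataset()].
#' @param snr_min Minimal SNR (inclusive).
#' @param rate_min Minimal average rate in Hz (inclusive).
#' @param coincidence_k If non-`NULL`, remove spikes coincident across at
#'   least this many electrodes within one sampling step.
#' @param sampling_dt Sampling resolution in seconds (1/30000 by default).
#' @return The filtered dataset; removed units are recorded in attribute
#'   `"removed"` with reasons.
#' @export
filter_units <- function(ds, snr_min = 2.5, rate_min = 1,
                         coincidence_k = NULL, sampling_dt = 1 / 30000) {
  stopifnot(inherits(ds, "spike_dataset"))
  spikes <- ds$spikes
  if (!is.null(coincidence_k)) {
    step <- round(spikes$t / sampling_dt)
    elec <- with(ds$units, paste(row, col)[match(spikes$unit_id, unit_id)])
    tab <- tapply(elec, step, function(e) length(unique(e)))
    bad_steps <- as.numeric(names(tab))[tab >= coincidence_k]
    spikes <- spikes[!(step %in% bad_steps), , drop = FALSE]
  }
  span <- if (!is.null(ds$segments)) sum(ds$segments$stop - ds$segments$start)
          else diff(range(spikes$t))
  counts <- table(factor(spikes$unit_id, levels = ds$units$unit_id))
  rates <- as.numeric(counts) / span
  snr <- if (is.null(ds$units$snr)) rep(Inf, nrow(ds$units)) else ds$units$snr
  keep <- snr >= snr_min & rates >= rate_min
  removed <- data.frame(unit_id = ds$units$unit_id[!keep],
                        reason = ifelse(snr[!keep] < snr_min, "snr",
                                        "rate"))
  if (!any(keep))
    stop("no units survive the SNR/rate filter", call. = FALSE)
  ds$units <- ds$units[keep, , drop = FALSE]
  ds$spikes <- spikes[spikes$unit_id %in% ds$units$unit_id, , drop = FALSE]
  attr(ds, "removed") <- removed
  ds
}

#' Bin spike trains and compute spike-count covariances
#'
#' Concatenates the analyzable intervals, bins each unit's spike train, and
#' computes the pairwise spike-count covariance matrix
#' `COV(i, j) = <b_i - mu_i, b_j - mu_j> / (l - 1)` (scalar product over
#' the `l` bins), together with the Pearson correlation matrix obtained by
#' diagonal normalization. Resting-state analyses use 1 s bins; task
#' analyses use one bin per trial sub-period (200 ms).
#'
#' @param ds A [spike_dataset()].
#' @param bin_width Bin width in seconds.
#' @param intervals Optional data frame (`start`, `stop`) overriding the
#'   dataset's segments; each interval is cut into `bin_width` bins
#'   (partial bins at interval ends are dropped).
#' @return List with `counts` (units x bins), `covariance`, `correlation`,
#'   `n_bins`. Units with zero count variance get `NA` correlations (with a
#'   warning) but keep their covariances.
#' @export
bin_and_covary <- function(ds, bin_width = 1, intervals = NULL) {
  stopifnot(inherits(ds, "spike_dataset"))
  if (is.null(intervals)) intervals <- ds$segments
  if (is.null(intervals))
    intervals <- data.frame(start = min(ds$spikes$t),
                            stop = max(ds$spikes$t) + 1e-9)
  ids <- ds$units$unit_id
  counts <- NULL
  for (k in seq_len(nrow(intervals))) {
    nb <- floor((intervals$stop[k] - intervals$start[k]) / bin_width)
    if (nb < 1) next
    edges <- intervals$start[k] + bin_width * (0:nb)
    sel <- ds$spikes$t >= edges[1] & ds$spikes$t < edges[nb + 1]
    sp <- ds$spikes[sel, , drop = FALSE]
    bin_idx <- findInterval(sp$t, edges, rightmost.closed = FALSE)
    m <- table(factor(sp$unit_id, levels = ids),
               factor(bin_idx, levels = seq_len(nb)))
    counts <- cbind(counts, unclass(m))
  }
  l <- ncol(counts)
  if (is.null(l) || l < 2)
    stop("need at least two bins to estimate covariances", call. = FALSE)
  counts <- matrix(as.numeric(counts), nrow = length(ids),
                   dimnames = list(ids, NULL))
  covm <- stats::cov(t(counts))            # the (l-1)-normalized estimator
  v <- diag(covm)
  if (any(v == 0))
    warning("units with zero count variance: correlations undefined")
  corm <- covm / sqrt(outer(v, v))
  corm[v == 0, ] <- NA; corm[, v == 0] <- NA
  list(counts = counts, covariance = covm, correlation = corm, n_bins = l)
}

#' Distance-resolved variance of cross-covariances
#'
#' Groups cross-covariances by inter-electrode distance (open array
#' geometry, no periodic wrapping; units on one electrode are at distance
#' zero) and population pair class, and returns the variance of the
#' covariance distribution at each distance, optionally corrected for the
#' estimator-noise bias due to the finite number of bins: the sample
#' covariance of two weakly dependent count vectors over `l` bins has
#' sampling variance `~ (c_ii c_jj + c_ij^2)/(l - 1)`, which inflates the
#' across-pair variance and is subtracted per distance/class cell.
#'
#' @param covm Covariance matrix (from [bin_and_covary()]).
#' @param units Unit metadata (rows aligned with `covm`), needing `row`,
#'   `col` and optionally `label`.
#' @param pitch Electrode pitch (mm).
#' @param bias_correction Apply the finite-sample correction.
#' @param n_bins Number of bins behind `covm` (needed for the correction).
#' @param min_count Cells with fewer pairs are flagged `excluded` (kept in
#'   the table, dropped by the fitting function).
#' @return Data frame with `distance`, `pair_class`, `mean`, `variance`,
#'   `count`, `excluded`.
#' @export
variance_vs_distance <- function(covm, units, pitch = 0.4,
                                 bias_correction = TRUE, n_bins = NULL,
                                 min_count = 2L) {
  n <- nrow(covm)
  stopifnot(nrow(units) == n)
  if (bias_correction && is.null(n_bins))
    stop("'n_bins' is required for the bias correction", call. = FALSE)
  px <- (units$col - 1) * pitch
  py <- (units$row - 1) * pitch
  X <- sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2)
  lab <- if (!is.null(units$label)) as.character(units$label)
         else rep("all", n)
  li <- matrix(lab, n, n)
  cls <- paste0(pmin(li, t(li)), pmax(li, t(li)))
  cls[li == "unclassified" | t(li) == "unclassified"] <- "pooled"
  ut <- upper.tri(covm)
  xd <- round(X[ut], 6); cv <- covm[ut]; cl <- cls[ut]
  key <- interaction(xd, cl, drop = TRUE)
  out <- data.frame(
    distance = as.numeric(tapply(xd, key, `[`, 1)),
    pair_class = as.character(tapply(cl, key, `[`, 1)),
    mean = as.numeric(tapply(cv, key, mean)),
    variance = as.numeric(tapply(cv, key, function(z)
      if (length(z) > 1) stats::var(z) else 0)),
    count = as.integer(tapply(cv, key, length)))
  if (bias_correction) {
    v <- diag(covm)
    noise <- (outer(v, v) + covm^2)[ut] / (n_bins - 1)
    out$variance <- out$variance - as.numeric(tapply(noise, key, mean))
  }
  out$excluded <- out$count < min_count
  out <- out[order(out$pair_class, out$distance), ]
  rownames(out) <- NULL
  out
}

#' Weighted exponential fits to distance-resolved variances
#'
#' Fits `y = a exp(-x/d)` to the distance-resolved variance of
#' cross-covariances, weighting each distance by its relative pair count.
#' In `"free"` mode each population-pair class gets its own amplitude and
#' decay constant; in `"shared_slope"` mode one decay constant is fitted
#' jointly with per-class amplitudes. The weighted mean squared error is
#' reported on the same weighting, so free and constrained fits are
#' directly comparable (the constrained fit can never have a smaller mse).
#'
#' @param tbl Output of [variance_vs_distance()] (rows with
#'   `excluded = TRUE` or `NA` variance are dropped).
#' @param mode `"free"` or `"shared_slope"`.
#' @param classes Which classes to fit (defaults to all present except
#'   `"pooled"` when class labels exist).
#' @return Object of class `cov_decay_fit`: a list with `mode`,
#'   `amplitudes` (named), `d` (named vector in free mode, scalar in
#'   shared mode), `mse`, `n_points`.
#' @export
fit_exponential_decay <- function(tbl, mode = c("free", "shared_slope"),
                                  classes = NULL) {
  mode <- match.arg(mode)
  tbl <- tbl[!is.na(tbl$variance) & !tbl$excluded, , drop = FALSE]
  if (is.null(classes)) {
    classes <- setdiff(unique(tbl$pair_class), "pooled")
    if (length(classes) == 0) classes <- unique(tbl$pair_class)
  }
  tbl <- tbl[tbl$pair_class %in% classes, , drop = FALSE]
  if (any(table(factor(tbl$pair_class, levels = classes)) < 3))
    stop("need at least 3 distance points per class", call. = FALSE)
  w <- tbl$count / sum(tbl$count)
  cls <- factor(tbl$pair_class, levels = classes)
  nc <- length(classes)
  if (mode == "free") {
    fits <- lapply(classes, function(cl) {
      s <- cls == cl
      fit_one_exp(tbl$distance[s], tbl$variance[s], tbl$count[s])
    })
    amp <- vapply(fits, `[[`, numeric(1), "a")
    dd <- vapply(fits, `[[`, numeric(1), "d")
    names(amp) <- names(dd) <- classes
    pred <- amp[cls] * exp(-tbl$distance / dd[cls])
    mse <- sum(w * (tbl$variance - pred)^2)
    conv <- all(vapply(fits, `[[`, numeric(1), "convergence") == 0)
  } else {
    obj <- function(par) {
      amp <- exp(par[seq_len(nc)]); d <- exp(par[nc + 1])
      pred <- amp[as.integer(cls)] * exp(-tbl$distance / d)
      sum(w * (tbl$variance - pred)^2)
    }
    a0 <- vapply(classes, function(cl)
      log(max(tbl$variance[cls == cl][1], 1e-12)), numeric(1))
    best <- NULL
    for (d0 in c(0.3, 1, 3)) {
      o <- stats::optim(c(a0, log(d0)), obj,
                        control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (best$convergence != 0)
      stop(structure(list(message = "shared-slope fit did not converge",
                          call = sys.call(), last = exp(best$par)),
                     class = c("fit_error", "error", "condition")))
    amp <- exp(best$par[seq_len(nc)]); names(amp) <- classes
    dd <- exp(best$par[nc + 1])
    mse <- best$value
    conv <- TRUE
  }
  structure(list(mode = mode, amplitudes = amp, d = dd, mse = mse,
                 n_points = nrow(tbl), classes = classes,
                 converged = conv, data = tbl),
            class = "cov_decay_fit")
}

## single weighted exponential fit with multi-start
fit_one_exp <- function(x, y, counts) {
  w <- counts / sum(counts)
  obj <- function(par) sum(w * (y - exp(par[1]) * exp(-x / exp(par[2])))^2)
  best <- NULL
  for (d0 in c(0.3, 1, 3)) {
    o <- stats::optim(c(log(max(abs(y[1]), 1e-12)), log(d0)), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(a = exp(best$par[1]), d = exp(best$par[2]), mse = best$value,
       convergence = best$convergence)
}

#' Cut trials into behavioral epochs
#'
#' From per-trial event times, builds the four 200 ms analysis sub-periods:
#' S1 = [TS, TS + 0.2), S2 = [TS + 0.2, TS + 0.4) (starting period) and
#' P1 = [CUE_OFF, CUE_OFF + 0.2), P2 = [CUE_OFF + 0.2, CUE_OFF + 0.4)
#' (preparatory period). Trials missing TS are dropped entirely; trials
#' missing CUE_OFF are excluded from the P epochs only. Trials with
#' duplicated or ill-ordered events are rejected.
#'
#' @param trials Data frame with columns `trial`, `TS` and optionally
#'   `CUE_OFF` (seconds; NA for missing events).
#' @return Data frame with columns `trial`, `epoch` (factor S1/S2/P1/P2),
#'   `start`, `stop`.
#' @export
segment_epochs <- function(trials) {
  stopifnot("trial" %in% names(trials), "TS" %in% names(trials))
  if (anyDuplicated(trials$trial))
    stop("duplicated trial ids", call. = FALSE)
  bad <- !is.na(trials$TS) & !is.na(trials$CUE_OFF) &
    trials$CUE_OFF <= trials$TS
  if (any(bad))
    stop("ill-ordered events (CUE_OFF before TS) in trials: ",
         paste(trials$trial[bad], collapse = ", "), call. = FALSE)
  keepS <- !is.na(trials$TS)
  if (!all(keepS))
    message(sum(!keepS), " trial(s) without TS dropped")
  out <- NULL
  for (i in which(keepS)) {
    ts <- trials$TS[i]
    out <- rbind(out,
                 data.frame(trial = trials$trial[i],
                            epoch = c("S1", "S2"),
                            start = ts + c(0, 0.2), stop = ts + c(0.2, 0.4)))
    co <- if ("CUE_OFF" %in% names(trials)) trials$CUE_OFF[i] else NA
    if (!is.na(co))
      out <- rbind(out,
                   data.frame(trial = trials$trial[i],
                              epoch = c("P1", "P2"),
                              start = co + c(0, 0.2),
                              stop = co + c(0.2, 0.4)))
  }
  out$epoch <- factor(out$epoch, levels = c("S1", "S2", "P1", "P2"))
  out
}

#' Per-sub-period firing rates and covariances of a task dataset
#'
#' For each of the four sub-periods (S1, S2, P1, P2), bins spikes with one
#' bin per trial (200 ms) and computes the per-unit average firing rates
#' and the pairwise spike-count covariance vector (upper triangle).
#'
#' @param ds A [spike_dataset()] with trial events.
#' @return Named list (per epoch) of lists with `rates` (Hz) and `covs`.
#' @export
epoch_rate_cov <- function(ds) {
  stopifnot(inherits(ds, "spike_dataset"), !is.null(ds$trials))
  ep <- segment_epochs(ds$trials)
  out <- list()
  for (e in levels(ep$epoch)) {
    iv <- ep[ep$epoch == e, c("start", "stop")]
    bw <- iv$stop[1] - iv$start[1]
    bc <- bin_and_covary(ds, bin_width = bw, intervals = iv)
    out[[e]] <- list(rates = rowMeans(bc$counts) / bw,
                     covs = bc$covariance[upper.tri(bc$covariance)])
  }
  out
}

#' Compare within- and between-epoch pattern correlations across sessions
#'
#' For each recording session, with rate and covariance vectors from the
#' four sub-periods S1, S2, P1, P2, computes two within-epoch correlations
#' (S1-S2, P1-P2) and four between-epoch correlations (Sx-Py). Within and
#' between groups, pooled over sessions, are compared by a two-sided
#' Student t test with `df = (N_sessions*2 - 1) + (N_sessions*4 - 1)`
#' degrees of freedom, preceded by Shapiro-Wilk normality and F
#' variance-equality diagnostics; when normality fails, a two-sample
#' Kolmogorov-Smirnov test is run as fallback. The confidence interval for
#' the group difference is `m +/- t(df) * s` with
#' `m = m_within - m_between` and s the pooled standard deviation.
#'
#' @param sessions List (one element per session) of named lists with
#'   elements `S1`, `S2`, `P1`, `P2`, each containing `rates` and `covs`
#'   vectors (as from [epoch_rate_cov()]).
#' @param alpha Significance level.
#' @return Object of class `epoch_comparison` with one sub-result per
#'   quantity (`rates`, `covariances`): group values, means, `m`, pooled
#'   `s`, `t`, `df`, `p`, `ci`, diagnostics.
#' @export
compare_epochs <- function(sessions, alpha = 0.05) {
  n_sessions <- length(sessions)
  one <- function(field) {
    within <- between <- c()
    for (s in sessions) {
      g <- function(a, b) stats::cor(s[[a]][[field]], s[[b]][[field]])
      within <- c(within, g("S1", "S2"), g("P1", "P2"))
      between <- c(between, g("S1", "P1"), g("S1", "P2"),
                   g("S2", "P1"), g("S2", "P2"))
    }
    nw <- length(within); nb <- length(between)
    df <- (n_sessions * 2 - 1) + (n_sessions * 4 - 1)
    m <- mean(within) - mean(between)
    s2w <- stats::var(within); s2b <- stats::var(between)
    s_pool <- sqrt(((nw - 1) * s2w + (nb - 1) * s2b) / (nw + nb - 2))
    res <- list(within = within, between = between, m = m, s = s_pool,
                df = df, n_within = nw, n_between = nb)
    if (n_sessions >= 2) {
      tstat <- m / (s_pool * sqrt(1 / nw + 1 / nb))
      res$t <- tstat
      res$p <- 2 * stats::pt(-abs(tstat), df)
      res$ci <- m + c(-1, 1) * stats::qt(1 - alpha / 2, df) * s_pool
      res$shapiro_within <- tryCatch(stats::shapiro.test(within)$p.value,
                                     error = function(e) NA_real_)
      res$shapiro_between <- tryCatch(stats::shapiro.test(between)$p.value,
                                      error = function(e) NA_real_)
      res$f_test_p <- tryCatch(stats::var.test(within, between)$p.value,
                               error = function(e) NA_real_)
      normal_ok <- !anyNA(c(res$shapiro_within, res$shapiro_between)) &&
        res$shapiro_within > alpha && res$shapiro_between > alpha
      if (!normal_ok) {
        ks <- suppressWarnings(stats::ks.test(within, between))
        res$ks <- list(D = unname(ks$statistic), p = ks$p.value)
      }
    }
    res
  }
  structure(list(rates = one("rates"), covariances = one("covs"),
                 n_sessions = n_sessions, alpha = alpha),
            class = "epoch_comparison")
}

#' Run the resting-state covariance pipeline
#'
#' Convenience runner: filters units, bins the resting segments, computes
#' spike-count covariances, the distance-resolved bias-corrected variance
#' table, and both exponential fits. Works identically for recorded
#' datasets loaded with [read_spike_dataset()] and for synthetic ones.
#'
#' @param ds A [spike_dataset()].
#' @param bin_width Bin width in seconds (1 s for resting state).
#' @param snr_min,rate_min Unit filter thresholds.
#' @return List with `dataset` (filtered), `binned`, `distance_table`,
#'   `fit_free`, `fit_shared`.
#' @export
analyze_resting <- function(ds, bin_width = 1, snr_min = 2.5, rate_min = 1) {
  ds <- filter_units(ds, snr_min = snr_min, rate_min = rate_min)
  bc <- bin_and_covary(ds, bin_width = bin_width)
  tbl <- variance_vs_distance(bc$covariance, ds$units, pitch = ds$pitch,
                              bias_correction = TRUE, n_bins = bc$n_bins)
  list(dataset = ds, binned = bc, distance_table = tbl,
       fit_free = fit_exponential_decay(tbl, "free"),
       fit_shared = fit_exponential_decay(tbl, "shared_slope"))
}
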