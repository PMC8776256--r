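#' Configuration of the synthetic Utah-array data generator
#'
#' Describes a synthetic recording emulating a 10 x 10 multielectrode array
#' (0.4 mm pitch) implanted in a spatially organized network. The
#' generating network is a periodic lattice (larger than the array, so that
#' array distances are free of wrap-around) whose effective connectivity is
#' calibrated to a spectral bound `R`; the array reads out the central
#' window. Spikes are emitted as a doubly stochastic (Cox) process: rate
#' fluctuations with the network's stationary covariance, Poisson spiking
#' given rates.
#'
#' @param grid_dim Electrode grid dimensions (array window).
#' @param pitch Electrode pitch in mm.
#' @param n_units Number of recorded units (~1-3 per electrode).
#' @param n_side Lattice cells per side of the generating network (must
#'   exceed `max(grid_dim)`; the margin keeps array distances un-wrapped).
#' @param R Target spectral bound of the generating network.
#' @param d_E,d_I Connectivity profile scales (mm).
#' @param peak_probability,n_trials Binomial connectivity parameters.
#' @param g_ratio Inhibitory-to-excitatory weight ratio (> 4 times the
#'   squared profile-scale ratio keeps the population feedback
#'   inhibition-dominated).
#' @param duration_s Resting-state duration (seconds of analyzable data).
#' @param rate_median,rate_sdlog Log-normal base firing rate distribution
#'   (Hz); the default spans roughly 1-30 Hz with a few units below the
#'   1 Hz filter.
#' @param cov_sd Target standard deviation of pairwise spike-count
#'   covariances (1 s bins), which sets the rate-fluctuation gain.
#' @param width_E,width_I Mean/SD (ms) of the waveform width distributions
#'   of broad- and narrow-spiking units, straddling the 0.33/0.34 ms
#'   thresholds.
#' @param unclassifiable_fraction Fraction of units with widths inside the
#'   threshold gap.
#' @param low_agreement_fraction Fraction of units with a low
#'   single-waveform agreement fraction (demoted in step 2).
#' @param n_trials_task,modulation Task variant: number of trials and
#'   epoch gain-modulation strength in [0, 1] (0 = no S/P difference).
#' @param seed RNG seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_dim = c(10, 10), pitch = 0.4,
                             n_units = 130, n_side = 26, R = 0.9,
                             d_E = 0.4, d_I = 0.4,
                             peak_probability = 0.3, n_trials = 1,
                             g_ratio = 8, duration_s = 600,
                             rate_median = 8, rate_sdlog = 0.7,
                             cov_sd = 1.5,
                             width_E = c(0.44, 0.035),
                             width_I = c(0.26, 0.03),
                             unclassifiable_fraction = 0.08,
                             low_agreement_fraction = 0.05,
                             n_trials_task = 150, modulation = 0.3,
                             seed = 1L) {
  if (n_side <= max(grid_dim))
    stop("'n_side' must exceed the array size to provide a margin",
         call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

## shared machinery: build the calibrated network and unit sample
build_generator_network <- function(cfg) {
  geom <- grid_geometry(cfg$n_side, cfg$pitch)
  prof <- conn_profile("exponential", d_E = cfg$d_E, d_I = cfg$d_I,
                       peak_probability = cfg$peak_probability,
                       n_trials = cfg$n_trials)
  net <- sample_synapse_counts(geom, prof, seed = cfg$seed)
  net <- assemble_effective_connectivity(net, target_R = cfg$R,
                                         g_ratio = cfg$g_ratio)
  # array = central grid_dim window of electrodes (one per lattice cell)
  off <- floor((cfg$n_side - cfg$grid_dim) / 2)
  ex <- (off[1] + seq_len(cfg$grid_dim[1]) - 1) * cfg$pitch
  ey <- (off[2] + seq_len(cfg$grid_dim[2]) - 1) * cfg$pitch
  in_win <- geom$cells$x[geom$cell_id] %in% ex &
    geom$cells$y[geom$cell_id] %in% ey
  cand <- which(in_win)
  set.seed(cfg$seed + 1L)
  units_idx <- sort(sample(cand, cfg$n_units))
  urow <- match(geom$cells$y[geom$cell_id[units_idx]], ey)
  ucol <- match(geom$cells$x[geom$cell_id[units_idx]], ex)
  list(geom = geom, prof = prof, net = net, units_idx = units_idx,
       urow = urow, ucol = ucol)
}

## unit metadata table with synthetic waveform widths, SNR, agreement
make_unit_table <- function(cfg, gen) {
  n <- cfg$n_units
  pop <- gen$geom$population[gen$units_idx]
  set.seed(cfg$seed + 2L)
  width <- ifelse(pop == "E",
                  stats::rnorm(n, cfg$width_E[1], cfg$width_E[2]),
                  stats::rnorm(n, cfg$width_I[1], cfg$width_I[2]))
  gap <- stats::runif(n) < cfg$unclassifiable_fraction
  width[gap] <- stats::runif(sum(gap), 0.331, 0.339)
  width <- pmax(width, 0.1)
  agree <- stats::runif(n, 0.75, 0.98)
  low <- stats::runif(n) < cfg$low_agreement_fraction
  agree[low] <- stats::runif(sum(low), 0.30, 0.55)
  snr <- stats::rlnorm(n, log(3.5), 0.25)
  data.frame(unit_id = seq_len(n), row = gen$urow, col = gen$ucol,
             width = round(width, 4), snr = round(snr, 3),
             single_wf_fraction = round(agree, 3),
             label = classify_units_by_waveform(width,
                                                single_fraction = agree),
             true_label = as.character(pop))
}

## round times to the 30 kHz sampling grid (exact round trips)
snap_times <- function(t, rate = 30000) round(t * rate) / rate

#' Generate a synthetic resting-state recording with known ground truth
#'
#' Simulates the spatial network's stationary rate fluctuations (via the
#' deterministic linear solve of the calibrated realization), maps the
#' central lattice window onto the electrode array, and emits spikes as an
#' inhomogeneous Poisson process given per-bin rates
#' `lambda_i(b) = r_i + kappa * z_i(b)` with `z ~ N(0, C)` drawn
#' independently per 1 s bin. Pairwise spike-count covariances (1 s bins)
#' therefore equal `kappa^2 * C` up to Poisson noise. The dataset carries
#' the generator's ground truth: the true count-covariance matrix, the
#' realized disorder strength of the calibrated network, and the
#' theoretical effective decay constant evaluated at that realized
#' disorder.
#'
#' @param cfg A [synthetic_config()].
#' @return A [spike_dataset()] with a `ground_truth` list (`covariance`,
#'   `d_eff`, `R_target`, `R_eff`, `rates`, `kappa`, `true_label`).
#' @export
generate_resting_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gen <- build_generator_network(cfg)
  units <- make_unit_table(cfg, gen)
  C_full <- stationary_covariance_lyapunov(gen$net$W, noise = 1)
  Cu <- C_full[gen$units_idx, gen$units_idx]
  R_eff <- realized_disorder(gen$net)
  par_eff <- theory_params(gen$prof, R = min(R_eff, 0.999),
                           g_ratio = cfg$g_ratio, geom = gen$geom)
  d_eff <- effective_decay_constant(params = par_eff)
  # rate-fluctuation gain from the target covariance dispersion
  sd0 <- stats::sd(Cu[upper.tri(Cu)])
  kappa <- sqrt(cfg$cov_sd / sd0)
  set.seed(cfg$seed + 3L)
  n <- cfg$n_units
  rates <- stats::rlnorm(n, log(cfg$rate_median), cfg$rate_sdlog)
  # two resting segments separated by a gap
  n_bins <- ceiling(cfg$duration_s)
  half <- n_bins %/% 2
  seg <- data.frame(start = c(0, half + 30), stop = c(half, half + 30 +
                                                        (n_bins - half)))
  L <- chol(Cu + diag(1e-9 * max(diag(Cu)), n))
  sp_unit <- vector("list", n)
  bin_starts <- c(seq_len(half) - 1, half + 30 + seq_len(n_bins - half) - 1)
  Z <- matrix(stats::rnorm(n_bins * n), n_bins, n) %*% L
  lam <- sweep(kappa * Z, 2, rates, "+")
  lam[lam < 0] <- 0
  counts <- matrix(stats::rpois(n_bins * n, lam), n_bins, n)
  for (i in seq_len(n)) {
    tot <- sum(counts[, i])
    if (tot == 0) { sp_unit[[i]] <- numeric(0); next }
    b <- rep(bin_starts, counts[, i])
    sp_unit[[i]] <- snap_times(b + stats::runif(tot))
  }
  spikes <- data.frame(unit_id = rep(seq_len(n), lengths(sp_unit)),
                       t = unlist(sp_unit))
  spikes <- spikes[order(spikes$t, spikes$unit_id), ]
  rownames(spikes) <- NULL
  spike_dataset(spikes, units, segments = seg, pitch = cfg$pitch,
                grid_dim = cfg$grid_dim,
                ground_truth = list(covariance = kappa^2 * Cu,
                                    d_eff = d_eff,
                                    R_target = cfg$R, R_eff = R_eff,
                                    rates = rates, kappa = kappa,
                                    true_label = units$true_label))
}

#' Generate a synthetic reach-to-grasp-like task recording
#'
#' Builds trials with the instructed-delay event template (trial start TS,
#' warning signal 400 ms later, cue onset after another 400 ms lasting
#' 300 ms, and a GO signal 1 s after cue offset) and emits spikes whose
#' statistics differ between the starting period (S, first 400 ms after
#' TS) and the preparatory period (P, 400 ms after cue offset): per-neuron
#' gains are modulated between the epochs, which changes both the firing
#' rates (log-normal gain with between-epoch correlation `1 - modulation`)
#' and the effective connectivity (transmission gates flip for a fraction
#' of neurons), hence the intrinsically generated covariance pattern. At
#' large spectral bounds a sizable fraction of pairs flips covariance sign
#' between the epochs while rates stay highly correlated within an epoch.
#'
#' @param cfg A [synthetic_config()].
#' @return A [spike_dataset()] with trials and a `ground_truth` list
#'   (`C_S`, `C_P` count-covariance matrices, `rates_S`, `rates_P`,
#'   `gates_S`, `gates_P`).
#' @export
generate_task_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gen <- build_generator_network(cfg)
  units <- make_unit_table(cfg, gen)
  N <- nrow(gen$net$W)
  n <- cfg$n_units
  set.seed(cfg$seed + 4L)
  # correlated per-neuron modulation fields for the two epochs
  rho <- 1 - cfg$modulation
  eta_sh <- stats::rnorm(N)
  eta <- lapply(1:2, function(a)
    sqrt(rho) * eta_sh + sqrt(1 - rho) * stats::rnorm(N))
  gates <- lapply(eta, function(e) as.numeric(e > 0))
  # gated effective connectivities; the common scale puts the larger of
  # the two epochs' spectral bounds at R (both epochs stay stable)
  Wg <- lapply(gates, function(a) gen$net$W * rep(a, each = N))
  sc <- cfg$R / max(vapply(Wg, spectral_bound, numeric(1)))
  Cs <- lapply(Wg, function(W) {
    sb <- spectral_bound(W * sc)
    if (sb >= 1) stop("gated network unstable", call. = FALSE)
    stationary_covariance_lyapunov(W * sc, noise = 1)[gen$units_idx,
                                                      gen$units_idx]
  })
  base <- stats::rlnorm(N, log(cfg$rate_median), cfg$rate_sdlog)
  rates <- lapply(eta, function(e) base * exp(0.4 * e))
  ru <- lapply(rates, function(r) r[gen$units_idx])
  sd0 <- stats::sd(Cs[[1]][upper.tri(Cs[[1]])])
  bw <- 0.2
  kappa <- sqrt(cfg$cov_sd / sd0)          # count-cov scale ~ kappa^2 C bw
  # trial event times
  nt <- cfg$n_trials_task
  iti <- 1.5 + stats::runif(nt, 0, 0.5)
  TS <- cumsum(c(1, utils::head(3.1 + iti, -1)))  # trial length: TS..GO+1
  trials <- data.frame(trial = seq_len(nt), TS = snap_times(TS),
                       WS = snap_times(TS + 0.4),
                       CUE_ON = snap_times(TS + 0.8),
                       CUE_OFF = snap_times(TS + 1.1),
                       GO = snap_times(TS + 2.1))
  Ls <- lapply(Cs, function(C) chol(C + diag(1e-9 * max(diag(C)), n)))
  sp <- list()
  for (tr in seq_len(nt)) {
    for (e in 1:2) {                       # 1 = S epoch, 2 = P epoch
      t0 <- if (e == 1) trials$TS[tr] else trials$CUE_OFF[tr]
      for (half in 0:1) {                  # two 200 ms sub-periods
        z <- as.numeric(stats::rnorm(n) %*% Ls[[e]])
        lam <- pmax(ru[[e]] + kappa * z / sqrt(bw), 0)
        cnt <- stats::rpois(n, lam * bw)
        idx <- rep(seq_len(n), cnt)
        if (length(idx))
          sp[[length(sp) + 1L]] <-
            data.frame(unit_id = idx,
                       t = snap_times(t0 + half * bw +
                                        stats::runif(length(idx)) * bw))
      }
    }
    # background spiking between the analysis windows keeps overall rates
    bg_iv <- rbind(c(trials$TS[tr] + 0.4, trials$CUE_OFF[tr]),
                   c(trials$CUE_OFF[tr] + 0.4, trials$GO[tr] + 0.5))
    for (k in 1:2) {
      dur <- bg_iv[k, 2] - bg_iv[k, 1]
      cnt <- stats::rpois(n, base[gen$units_idx] * dur)
      idx <- rep(seq_len(n), cnt)
      if (length(idx))
        sp[[length(sp) + 1L]] <-
          data.frame(unit_id = idx,
                     t = snap_times(bg_iv[k, 1] +
                                      stats::runif(length(idx)) * dur))
    }
  }
  spikes <- do.call(rbind, sp)
  spikes <- spikes[order(spikes$t, spikes$unit_id), ]
  rownames(spikes) <- NULL
  spike_dataset(spikes, units, trials = trials, pitch = cfg$pitch,
                grid_dim = cfg$grid_dim,
                ground_truth = list(C_S = kappa^2 * bw * Cs[[1]],
                                    C_P = kappa^2 * bw * Cs[[2]],
                                    rates_S = ru[[1]], rates_P = ru[[2]],
                                    gates_S = gates[[1]][gen$units_idx],
                                    gates_P = gates[[2]][gen$units_idx]))
}

#' Write a spike dataset to a plain-text directory
#'
#' Versioned schema: `meta.json` plus CSV tables (`spikes.csv` stores
#' integer sample indices at 30 kHz, guaranteeing lossless round trips).
#' Ground-truth blocks, when present, are written alongside and restored
#' on read; real recordings simply have none.
#'
#' @param ds A [spike_dataset()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_spike_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "spike_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = 1L, pitch = ds$pitch,
               grid_dim = ds$grid_dim, sampling_rate = 30000L,
               has_trials = !is.null(ds$trials),
               has_segments = !is.null(ds$segments),
               ground_truth_fields = names(ds$ground_truth))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- data.frame(unit_id = ds$spikes$unit_id,
                   sample = as.integer(round(ds$spikes$t * 30000)))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  utils::write.csv(ds$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  if (!is.null(ds$trials))
    write_num_csv(ds$trials, file.path(path, "trials.csv"))
  if (!is.null(ds$segments))
    write_num_csv(ds$segments, file.path(path, "segments.csv"))
  if (!is.null(ds$ground_truth)) {
    for (nm in names(ds$ground_truth)) {
      v <- ds$ground_truth[[nm]]
      f <- file.path(path, paste0("gt_", nm, ".csv"))
      if (is.matrix(v)) write_num_csv(as.data.frame(v), f)
      else write_num_csv(data.frame(value = v), f)
    }
  }
  invisible(path)
}

## full-precision numeric CSV (doubles survive the round trip exactly)
write_num_csv <- function(df, file) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

#' Read a spike dataset written by [write_spike_dataset()]
#'
#' @param path Dataset directory.
#' @return A [spike_dataset()]; the ground-truth block is restored when
#'   present.
#' @export
read_spike_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf))
    stop("not a spike dataset: missing meta.json", call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L)
    stop("unsupported or corrupt dataset schema (expected version 1)",
         call. = FALSE)
  need <- c("spikes.csv", "units.csv")
  if (isTRUE(meta$has_trials)) need <- c(need, "trials.csv")
  if (isTRUE(meta$has_segments)) need <- c(need, "segments.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("corrupt or truncated dataset: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  spikes <- data.frame(unit_id = sp$unit_id, t = sp$sample / meta$sampling_rate)
  units <- utils::read.csv(file.path(path, "units.csv"))
  trials <- if (isTRUE(meta$has_trials))
    utils::read.csv(file.path(path, "trials.csv")) else NULL
  segments <- if (isTRUE(meta$has_segments))
    utils::read.csv(file.path(path, "segments.csv")) else NULL
  gt <- NULL
  gtf <- meta$ground_truth_fields
  if (length(gtf)) {
    gt <- lapply(gtf, function(nm) {
      v <- utils::read.csv(file.path(path, paste0("gt_", nm, ".csv")))
      if (ncol(v) == 1) v$value else as.matrix(v)
    })
    names(gt) <- gtf
  }
  spike_dataset(spikes, units, trials = trials, segments = segments,
                pitch = meta$pitch, grid_dim = meta$grid_dim,
                ground_truth = gt)
}
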