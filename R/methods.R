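#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("Periodic 2D grid: %d x %d cells (pitch %g), %d neurons (4E+1I per cell)\n",
              x$n_cells_per_side, x$n_cells_per_side, x$pitch,
              length(x$population)))
  invisible(x)
}

#' @export
print.conn_profile <- function(x, ...) {
  cat(sprintf("%s connectivity profile: d_E = %g, d_I = %g, peak p = %g, n_trials = %d\n",
              x$shape, x$d_E, x$d_I, x$peak_probability, x$n_trials))
  invisible(x)
}

#' @export
print.network_realization <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf("Network realization: %d neurons, %d synapses (seed %d)\n",
              n, sum(x$counts), x$seed))
  if (!is.null(x$W))
    cat(sprintf("  calibrated: spectral bound %.3f (g_ratio %g)\n",
                x$target_R, x$g_ratio))
  else cat("  counts only; run assemble_effective_connectivity()\n")
  invisible(x)
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Spectrum: %d eigenvalues, spectral bound R = %.4f\n",
              length(x$eigenvalues), x$spectral_bound))
  if (!is.null(x$population_eigenvalue))
    cat(sprintf("  population eigenvalue: %.4f%+.4fi\n",
                Re(x$population_eigenvalue), Im(x$population_eigenvalue)))
  invisible(x)
}

#' Eigenvalue cloud of an effective connectivity matrix
#'
#' @param x A `spectrum_summary`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spectrum_summary <- function(x, ...) {
  graphics::plot(Re(x$eigenvalues), Im(x$eigenvalues), pch = 16, cex = 0.4,
                 xlab = expression(Re(lambda)), ylab = expression(Im(lambda)),
                 ...)
  graphics::abline(v = x$spectral_bound, lty = 2)
  invisible(x)
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("Covariance theory parameters: R = %g, D = %g, g_ratio = %g (%s kernel, %s moments)\n",
              x$R, x$D, x$g_ratio, x$profile$shape,
              if (x$lattice) "lattice" else "continuum"))
  cat(sprintf("  population eigenvalue m0 = %.3f; variance zero modes E %.3f / I %.3f\n",
              x$m0, x$s_pops[["E"]], x$s_pops[["I"]]))
  invisible(x)
}

#' @export
print.decay_law <- function(x, ...) {
  cat(sprintf("Decay law (%s): amplitude %.4g, length constant %.4g\n",
              x$form, x$amplitude, x$length_constant))
  invisible(x)
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("Rate-network trajectory: %d neurons, %g time units (%d bins), estimator '%s'\n",
              length(x$mean_rates), x$effective_duration, x$n_bins,
              x$estimator))
  invisible(x)
}

#' @export
print.two_net_result <- function(x, ...) {
  cat(sprintf("Two-network experiment: R = %g, N = %d, epsilon = %g (%s)\n",
              x$R, x$N, x$epsilon, x$estimator))
  cat(sprintf("  input corr %.3f | rate corr %.3f | covariance corr %.3f\n",
              x$input_corr, x$rate_corr, x$cov_corr))
  cat(sprintf("  fraction active: %.3f / %.3f; silent excluded: %d\n",
              x$fraction_active[1], x$fraction_active[2],
              x$n_silent_excluded))
  invisible(x)
}

#' Rate and covariance scatter of a two-network experiment
#'
#' @param x A `two_net_result`.
#' @param what `"rates"` or `"covariances"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.two_net_result <- function(x, what = c("rates", "covariances"), ...) {
  what <- match.arg(what)
  if (what == "rates") {
    graphics::plot(x$rates[, 1], x$rates[, 2], pch = 16, cex = 0.3,
                   xlab = "rate, network 1", ylab = "rate, network 2", ...)
  } else {
    graphics::plot(x$cov_sample[, 1], x$cov_sample[, 2], pch = 16,
                   cex = 0.3, xlab = "covariance, network 1",
                   ylab = "covariance, network 2", ...)
  }
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("Spike dataset: %d units on a %d x %d array (pitch %g mm), %d spikes\n",
              nrow(x$units), x$grid_dim[1], x$grid_dim[2], x$pitch,
              nrow(x$spikes)))
  if (!is.null(x$segments))
    cat(sprintf("  %d resting segment(s), %.0f s analyzable\n",
                nrow(x$segments), sum(x$segments$stop - x$segments$start)))
  if (!is.null(x$trials))
    cat(sprintf("  %d trials\n", nrow(x$trials)))
  if (!is.null(x$ground_truth))
    cat("  synthetic: carries generator ground truth\n")
  invisible(x)
}

#' @export
summary.spike_dataset <- function(object, ...) {
  span <- if (!is.null(object$segments))
    sum(object$segments$stop - object$segments$start)
  else diff(range(object$spikes$t))
  counts <- table(factor(object$spikes$unit_id,
                         levels = object$units$unit_id))
  lab <- if (!is.null(object$units$label)) table(object$units$label) else NULL
  out <- list(n_units = nrow(object$units), n_spikes = nrow(object$spikes),
              rate_range = range(as.numeric(counts) / span),
              labels = lab)
  class(out) <- "summary.spike_dataset"
  out
}

#' @export
print.summary.spike_dataset <- function(x, ...) {
  cat(sprintf("%d units, %d spikes; firing rates %.2f-%.2f Hz\n",
              x$n_units, x$n_spikes, x$rate_range[1], x$rate_range[2]))
  if (!is.null(x$labels)) print(x$labels)
  invisible(x)
}

#' @export
print.cov_decay_fit <- function(x, ...) {
  cat(sprintf("Weighted exponential fit (%s), %d points, weighted mse %.4g\n",
              x$mode, x$n_points, x$mse))
  if (x$mode == "shared_slope") {
    cat(sprintf("  common decay constant d = %.4g\n", x$d))
    for (cl in x$classes)
      cat(sprintf("  %s: a = %.4g\n", cl, x$amplitudes[[cl]]))
  } else {
    for (cl in x$classes)
      cat(sprintf("  %s: a = %.4g, d = %.4g\n", cl, x$amplitudes[[cl]],
                  x$d[[cl]]))
  }
  invisible(x)
}

#' @export
coef.cov_decay_fit <- function(object, ...) {
  if (object$mode == "shared_slope")
    c(object$amplitudes, d = unname(object$d))
  else c(stats::setNames(object$amplitudes,
                         paste0("a_", object$classes)),
         stats::setNames(object$d, paste0("d_", object$classes)))
}

#' Distance-resolved variances with fitted exponential curves
#'
#' @param x A `cov_decay_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cov_decay_fit <- function(x, ...) {
  tbl <- x$data
  graphics::plot(tbl$distance, tbl$variance,
                 cex = 0.5 + 2 * tbl$count / max(tbl$count),
                 col = as.integer(factor(tbl$pair_class)),
                 xlab = "distance (mm)", ylab = "variance of covariances",
                 ...)
  xs <- seq(0, max(tbl$distance), length.out = 100)
  for (k in seq_along(x$classes)) {
    d <- if (x$mode == "shared_slope") x$d else x$d[[k]]
    graphics::lines(xs, x$amplitudes[[k]] * exp(-xs / d), col = k)
  }
  graphics::legend("topright", legend = x$classes, col = seq_along(x$classes),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("Epoch comparison over %d session(s), alpha = %g\n",
              x$n_sessions, x$alpha))
  for (nm in c("rates", "covariances")) {
    r <- x[[nm]]
    cat(sprintf("  %s: within %.3f, between %.3f, m = %.3f",
                nm, mean(r$within), mean(r$between), r$m))
    if (!is.null(r$t))
      cat(sprintf(", t(%d) = %.2f, p = %.3g, CI [%.3f, %.3f]",
                  r$df, r$t, r$p, r$ci[1], r$ci[2]))
    cat("\n")
    if (!is.null(r$ks))
      cat(sprintf("    KS fallback: D = %.3f, p = %.3g\n", r$ks$D, r$ks$p))
  }
  invisible(x)
}
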