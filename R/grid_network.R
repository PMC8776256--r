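#' Periodic grid geometry for a spatial E-I network
#'
#' Builds the geometry of a two-dimensional excitatory-inhibitory network in
#' which space is divided into cells arranged on a periodic square lattice.
#' Each cell houses four excitatory neurons and one inhibitory neuron, all
#' located at the cell centre; distances between neurons are defined
#' cell-to-cell, so neurons sharing a cell are at distance zero.
#'
#' @param n_cells_per_side Number of lattice cells per side (integer, >= 2).
#' @param pitch Lattice constant, the distance between neighbouring cell
#'   centres. Model length units; when emulating a Utah array one unit of
#'   0.4 corresponds to the 400 micron inter-electrode pitch in mm.
#' @return An object of class `grid_geometry` with components
#'   `n_cells_per_side`, `pitch`, `box` (side length of the periodic domain),
#'   `cells` (data frame of cell-centre coordinates), `cell_id` (cell index
#'   per neuron), `population` (factor `"E"`/`"I"` per neuron) and
#'   `positions` (n x 2 matrix of neuron coordinates).
#' @examples
#' g <- grid_geometry(4, pitch = 1)
#' nrow(g$positions)  # 80 neurons: 5 per cell
#' @export
grid_geometry <- function(n_cells_per_side, pitch = 1) {
  if (length(n_cells_per_side) != 1L || is.na(n_cells_per_side) ||
      n_cells_per_side != round(n_cells_per_side) || n_cells_per_side < 2)
    stop("'n_cells_per_side' must be a single integer >= 2", call. = FALSE)
  if (length(pitch) != 1L || is.na(pitch) || pitch <= 0)
    stop("'pitch' must be a single positive number", call. = FALSE)
  n_cells_per_side <- as.integer(n_cells_per_side)
  ax <- (seq_len(n_cells_per_side) - 1L) * pitch
  cells <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  cell_id <- rep(seq_len(n_cells), each = 5L)
  population <- factor(rep(c("E", "E", "E", "E", "I"), n_cells),
                       levels = c("E", "I"))
  positions <- cbind(x = cells$x[cell_id], y = cells$y[cell_id])
  structure(
    list(n_cells_per_side = n_cells_per_side, pitch = pitch,
         box = n_cells_per_side * pitch, cells = cells, cell_id = cell_id,
         population = population, positions = positions),
    class = "grid_geometry")
}

#' Minimal-image Euclidean distance under periodic boundaries
#'
#' @param a,b Numeric vectors of length 2, or matrices with 2 columns,
#'   giving positions in `[0, box)`.
#' @param box Side length of the periodic square domain.
#' @return Minimal-image Euclidean distance(s); symmetric in `a`, `b` and
#'   zero iff `a == b` (modulo the box).
#' @examples
#' periodic_distance(c(0, 0), c(9, 0), box = 10)  # 1: wraps around
#' @export
periodic_distance <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  d <- a - b
  d <- d - box * round(d / box)
  unname(sqrt(rowSums(d^2)))
}

## minimal-image signed differences for a vector of coordinates
min_image <- function(d, box) d - box * round(d / box)

#' All pairwise neuron distances of a grid geometry
#'
#' @param geom A [grid_geometry()].
#' @return A symmetric n x n matrix of minimal-image distances between
#'   neuron (cell-centre) positions.
#' @export
pair_distances <- function(geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  dx <- min_image(outer(geom$cells$x, geom$cells$x, "-"), geom$box)
  dy <- min_image(outer(geom$cells$y, geom$cells$y, "-"), geom$box)
  cd <- sqrt(dx^2 + dy^2)
  cd[geom$cell_id, geom$cell_id]
}

#' Distance-dependent connectivity profile
#'
#' Connection probabilities decay with cell distance x as
#' `peak_probability * k(x/d)` where the kernel `k` is `exp(-x/d)`
#' (exponential, the default) or `exp(-x^2/(2 d^2))` (gaussian), with
#' separate length scales for excitatory and inhibitory presynaptic neurons.
#' Synapse counts between an ordered neuron pair are drawn from a binomial
#' distribution with `n_trials` trials at this probability, which allows for
#' multapses when `n_trials > 1`.
#'
#' @param shape Kernel shape, `"exponential"` or `"gaussian"`.
#' @param d_E,d_I Length scales of the excitatory / inhibitory outgoing
#'   profiles (same units as the lattice pitch; both > 0).
#' @param peak_probability Connection probability at distance zero, in (0, 1].
#' @param n_trials Number of binomial trials for the synapse-count draw.
#' @return An object of class `conn_profile`.
#' @export
conn_profile <- function(shape = c("exponential", "gaussian"),
                         d_E = 0.4, d_I = 0.4,
                         peak_probability = 0.3, n_trials = 1L) {
  shape <- match.arg(shape)
  if (!(d_E > 0 && d_I > 0))
    stop("profile length scales must be positive", call. = FALSE)
  if (!(peak_probability > 0 && peak_probability <= 1))
    stop("'peak_probability' must lie in (0, 1]", call. = FALSE)
  if (n_trials < 1 || n_trials != round(n_trials))
    stop("'n_trials' must be a positive integer", call. = FALSE)
  structure(list(shape = shape, d_E = d_E, d_I = d_I,
                 peak_probability = peak_probability,
                 n_trials = as.integer(n_trials)),
            class = "conn_profile")
}

#' Connection probability at distance x
#'
#' @param profile A [conn_profile()].
#' @param x Distances (numeric vector or matrix).
#' @param pop Presynaptic population, `"E"` or `"I"`.
#' @return Probabilities `peak_probability * k(x/d_pop)`.
#' @export
connection_prob <- function(profile, x, pop = c("E", "I")) {
  pop <- match.arg(pop)
  d <- if (pop == "E") profile$d_E else profile$d_I
  k <- switch(profile$shape,
              exponential = exp(-x / d),
              gaussian = exp(-x^2 / (2 * d^2)))
  profile$peak_probability * k
}

## n x n matrix of connection probabilities, presynaptic profile per column
connection_prob_matrix <- function(geom, profile) {
  X <- pair_distances(geom)
  d_pre <- ifelse(geom$population == "E", profile$d_E, profile$d_I)
  q <- switch(profile$shape,
              exponential = profile$peak_probability *
                exp(-sweep(X, 2, d_pre, "/")),
              gaussian = profile$peak_probability *
                exp(-sweep(X^2, 2, 2 * d_pre^2, "/")))
  diag(q) <- 0  # no self-loops
  q
}

#' Sample synapse counts for a spatial network realization
#'
#' Draws, independently for every ordered neuron pair (i, j), the number of
#' synapses j -> i from `Binomial(n_trials, q(x_ij))`, where `q` is the
#' distance-dependent connection probability of the presynaptic neuron's
#' population. The diagonal is zero (no self-loops).
#'
#' @param geom A [grid_geometry()].
#' @param profile A [conn_profile()].
#' @param seed Integer RNG seed; identical seeds give identical realizations.
#' @return An object of class `network_realization` with elements `counts`
#'   (integer matrix, rows = postsynaptic), `geometry`, `profile`, `seed`.
#'   Weights are attached later by [assemble_effective_connectivity()].
#' @export
sample_synapse_counts <- function(geom, profile, seed = 1L) {
  stopifnot(inherits(geom, "grid_geometry"), inherits(profile, "conn_profile"))
  q <- connection_prob_matrix(geom, profile)
  if (any(q > 1 | q < 0))
    stop("connection probability outside [0, 1]; check profile parameters",
         call. = FALSE)
  n <- nrow(q)
  set.seed(as.integer(seed))
  counts <- matrix(stats::rbinom(n * n, profile$n_trials, q), n, n)
  diag(counts) <- 0L
  structure(list(counts = counts, geometry = geom, profile = profile,
                 seed = as.integer(seed), weights = NULL),
            class = "network_realization")
}

#' Assemble and calibrate the effective connectivity matrix
#'
#' Assigns synaptic weights that depend only on the presynaptic population
#' (`w_E` for excitatory columns, `-g_ratio * w_E` for inhibitory columns),
#' multiplies them by the sampled synapse counts, and rescales the whole
#' matrix so that its empirical spectral bound (largest real part of any
#' eigenvalue) equals `target_R`. Because the calibration is a global
#' rescaling, the result is invariant under any uniform scaling of the
#' initial weights.
#'
#' @param net A `network_realization` from [sample_synapse_counts()].
#' @param target_R Target spectral bound, in (0, 1).
#' @param g_ratio Ratio `|w_I| / w_E` of inhibitory to excitatory weight
#'   magnitudes. Values above 4 make the population feedback of the 4E+1I
#'   composition inhibition-dominated.
#' @param tol Tolerance for the post-calibration check of the spectral bound.
#' @return The input object with elements `W` (calibrated effective
#'   connectivity), `w_E`, `g_ratio`, `target_R` filled in.
#' @export
assemble_effective_connectivity <- function(net, target_R, g_ratio = 8,
                                            tol = 1e-3) {
  stopifnot(inherits(net, "network_realization"))
  if (!(target_R > 0 && target_R < 1))
    stop("'target_R' must lie in (0, 1)", call. = FALSE)
  w_sign <- ifelse(net$geometry$population == "E", 1, -g_ratio)
  J <- sweep(net$counts, 2, w_sign, "*")
  if (all(J == 0))
    stop("all synapse counts are zero; cannot calibrate a zero matrix",
         call. = FALSE)
  r0 <- spectral_bound(J)
  if (r0 <= 0)
    stop("raw spectral bound is not positive; cannot rescale to target",
         call. = FALSE)
  scale <- target_R / r0
  W <- J * scale
  r1 <- spectral_bound(W)
  if (abs(r1 - target_R) > tol)
    stop(sprintf("calibration failed: spectral bound %.6f vs target %.6f",
                 r1, target_R), call. = FALSE)
  net$W <- W
  net$w_E <- scale
  net$g_ratio <- g_ratio
  net$target_R <- target_R
  net
}

#' Largest real part of the eigenvalue spectrum
#'
#' For large matrices the computation uses ARPACK (via \pkg{igraph}) on the
#' sparse matrix, asking for the eigenvalues of largest real part; small
#' matrices use a full dense decomposition.
#'
#' @param W Square numeric matrix (dense or `Matrix` sparse).
#' @param nev Number of Ritz values requested from ARPACK.
#' @return The spectral bound, `max(Re(lambda))`.
#' @export
spectral_bound <- function(W, nev = 4L) {
  n <- nrow(W)
  if (n != ncol(W)) stop("matrix must be square", call. = FALSE)
  if (n <= 400) return(max(Re(eigen(as.matrix(W), only.values = TRUE)$values)))
  A <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  res <- tryCatch({
    ar <- igraph::arpack(function(x, extra) as.numeric(A %*% x),
                         options = list(n = n, nev = nev,
                                        ncv = max(4 * nev + 1, 20),
                                        which = "LR", maxiter = 5000),
                         sym = FALSE)
    max(Re(ar$values))
  }, error = function(e) NULL)
  if (is.null(res))
    res <- max(Re(eigen(as.matrix(W), only.values = TRUE)$values))
  res
}

#' Eigenvalue spectrum summary of an effective connectivity matrix
#'
#' Computes the full eigenvalue spectrum, the spectral bound R (largest real
#' part), and the population eigenvalue: the eigenvalue, with largest real
#' part, of the 2 x 2 population-averaged coupling matrix whose (a, b) entry
#' is the mean summed input from population b to a neuron of population a.
#' In inhibition-dominated networks the population eigenvalue is negative
#' while the spectral bound is set by the disorder bulk.
#'
#' @param W Square effective connectivity matrix.
#' @param population Optional factor of population labels (`"E"`/`"I"`) per
#'   neuron; required for the population eigenvalue.
#' @return Object of class `spectrum_summary` with `eigenvalues`,
#'   `spectral_bound`, `population_matrix` and `population_eigenvalue`.
#' @export
spectral_summary <- function(W, population = NULL) {
  if (is.null(dim(W)) || nrow(W) != ncol(W))
    stop("'W' must be a square matrix", call. = FALSE)
  W <- as.matrix(W)
  ev <- eigen(W, only.values = TRUE)$values
  pop_mat <- pop_ev <- NULL
  if (!is.null(population)) {
    population <- factor(population, levels = c("E", "I"))
    pop_mat <- matrix(NA_real_, 2, 2, dimnames = list(c("E", "I"), c("E", "I")))
    for (a in c("E", "I")) for (b in c("E", "I")) {
      rows <- which(population == a)
      pop_mat[a, b] <- mean(rowSums(W[rows, population == b, drop = FALSE]))
    }
    pe <- eigen(pop_mat, only.values = TRUE)$values
    pop_ev <- pe[which.max(Re(pe))]
  }
  structure(list(eigenvalues = ev, spectral_bound = max(Re(ev)),
                 population_matrix = pop_mat, population_eigenvalue = pop_ev),
            class = "spectrum_summary")
}

#' Ensemble mean and variance matrices of the effective connectivity
#'
#' For a given geometry, profile and weight parameterization, the entries of
#' the random connectivity matrix `W_ij = w_j * counts_ij` have mean
#' `w_j * n_trials * q(x_ij)` and variance
#' `w_j^2 * n_trials * q(x_ij) (1 - q(x_ij))`. These two deterministic
#' matrices (`M` and `S`) drive the closed-form covariance statistics. The
#' excitatory weight is calibrated analytically so that the spectral bound of
#' `S` -- its constant row sum, by translation symmetry and positivity --
#' equals `target_R^2`, placing the disorder bulk edge of `W` at `target_R`.
#'
#' @param geom A [grid_geometry()].
#' @param profile A [conn_profile()].
#' @param target_R Desired spectral bound of the effective connectivity.
#' @param g_ratio Inhibitory-to-excitatory weight ratio.
#' @return List with `M`, `S`, `w_E`, `R` and the geometry/profile.
#' @export
ensemble_connectivity_moments <- function(geom, profile, target_R,
                                          g_ratio = 8) {
  q <- connection_prob_matrix(geom, profile)
  w_sign <- ifelse(geom$population == "E", 1, -g_ratio)
  S1 <- sweep(profile$n_trials * q * (1 - q), 2, w_sign^2, "*")
  z <- zero_mode_2x2(S1, geom$population)
  w_E <- target_R / sqrt(z)
  list(M = sweep(profile$n_trials * q, 2, w_E * w_sign, "*"),
       S = w_E^2 * S1, w_E = w_E, R = target_R,
       geometry = geom, profile = profile, g_ratio = g_ratio)
}

## exact spectral bound of a spatial variance matrix: by translation
## symmetry the kernel is maximal at wavevector zero, where it reduces to
## the 2x2 population matrix of row sums split by presynaptic population
## (rows differ between E and I receivers through the excluded self-term)
zero_mode_2x2 <- function(S, population) {
  iE <- match("E", population); iI <- match("I", population)
  isE <- population == "E"
  Z <- rbind(c(sum(S[iE, isE]), sum(S[iE, !isE])),
             c(sum(S[iI, isE]), sum(S[iI, !isE])))
  max(Re(eigen(Z, only.values = TRUE)$values))
}

#' Realized disorder strength of a calibrated network
#'
#' The linear-response theory parameterizes heterogeneity by the zero mode of
#' the connectivity variance; for a single realization calibrated to a given
#' spectral bound, the realized disorder zero mode (mean row sum of squared
#' deviations from the ensemble mean) differs slightly from the nominal
#' target because the extreme eigenvalue fluctuates beyond the bulk edge.
#' Theory comparisons for a specific realization should use this value.
#'
#' @param net A calibrated `network_realization` (with `W`).
#' @return The realized disorder strength `R_eff` (square root of the zero
#'   mode), comparable to the nominal `target_R`.
#' @export
realized_disorder <- function(net) {
  stopifnot(inherits(net, "network_realization"), !is.null(net$W))
  q <- connection_prob_matrix(net$geometry, net$profile)
  w_sign <- ifelse(net$geometry$population == "E", 1, -net$g_ratio)
  M <- sweep(net$profile$n_trials * q, 2, net$w_E * w_sign, "*")
  D2 <- (net$W - M)^2
  pop <- net$geometry$population
  isE <- pop == "E"
  # realized analogue of the ensemble zero mode: population-averaged rows
  Z <- rbind(c(mean(rowSums(D2[isE, isE])), mean(rowSums(D2[isE, !isE]))),
             c(mean(rowSums(D2[!isE, isE])), mean(rowSums(D2[!isE, !isE]))))
  sqrt(max(Re(eigen(Z, only.values = TRUE)$values)))
}
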