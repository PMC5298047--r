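#' Gamma response-function parameters
#'
#' The canonical startle eyeblink response function (SEBRF) is a gamma
#' probability density with shape `k`, scale `theta` (seconds), shifted by an
#' onset latency `x0` (seconds) and scaled by an amplitude `A`:
#' `A / (theta^k Gamma(k)) * (x - x0)^(k-1) * exp(-(x - x0)/theta)` for
#' `x > x0`, zero otherwise. Its mode (peak time) is `x0 + (k - 1) * theta`.
#'
#' @param k shape (> 0, dimensionless).
#' @param theta scale in seconds (> 0).
#' @param x0 onset latency in seconds.
#' @param A amplitude (arbitrary units); with `A = 1` the function integrates
#'   to 1 over its full support.
#' @return list of class `gamma_params`.
#' @export
gamma_params <- function(k, theta, x0, A = 1) {
  if (!is.finite(k) || k <= 0) stop("gamma_params: k must be > 0")
  if (!is.finite(theta) || theta <= 0) stop("gamma_params: theta must be > 0")
  if (!is.finite(x0)) stop("gamma_params: x0 must be finite")
  structure(list(k = k, theta = theta, x0 = x0, A = A),
            class = "gamma_params")
}

#' Gaussian tail parameters (model M3)
#' @param mu centre in seconds.
#' @param sigma width in seconds (> 0).
#' @param amplitude peak value of the (unit-peak) Gaussian component.
#' @return list of class `gaussian_params`.
#' @export
gaussian_params <- function(mu, sigma, amplitude = 1) {
  if (!is.finite(sigma) || sigma <= 0) stop("gaussian_params: sigma must be > 0")
  structure(list(mu = mu, sigma = sigma, amplitude = amplitude),
            class = "gaussian_params")
}

#' Canonical response-function presets
#'
#' Published parameter sets for the canonical SEBRF: `initial` (28-250 Hz
#' band), `optimized_m2st` (60-480 Hz band) and `optimized_m4st` (50-470 Hz
#' band), plus the Gaussian tail of model M3 fitted alongside the initial set.
#' Each preset carries the band it was derived under as attribute `band`.
#'
#' @format a named list with elements `initial`, `optimized_m2st`,
#'   `optimized_m4st` (each `gamma_params`) and `m3_gaussian`
#'   (`gaussian_params`).
#' @export
sebrf_presets <- list(
  initial        = structure(gamma_params(2.5320, 0.0154, 0.0383),
                             band = c(28, 250)),
  optimized_m2st = structure(gamma_params(3.7167, 0.0103, 0.0340),
                             band = c(60, 480)),
  optimized_m4st = structure(gamma_params(3.5114, 0.0108, 0.0345),
                             band = c(50, 470)),
  m3_gaussian    = gaussian_params(0.2119, 0.1854)
)

#' Evaluate the gamma response function on a time grid
#'
#' @param grid sorted numeric vector of times in seconds.
#' @param params a [gamma_params()].
#' @return numeric vector; zero at and before `x0`, nonnegative for `A > 0`.
#' @export
gamma_rf <- function(grid, params) {
  if (is.unsorted(grid)) stop("gamma_rf: grid must be sorted")
  out <- numeric(length(grid))
  pos <- grid > params$x0
  out[pos] <- params$A *
    stats::dgamma(grid[pos] - params$x0, shape = params$k, scale = params$theta)
  out
}

#' Analytic time derivative of the gamma response function
#'
#' Differentiating the gamma expression gives
#' `f'(x) = f(x) * ((k - 1)/(x - x0) - 1/theta)` for `x > x0`; exact on any
#' grid, unlike a finite difference.
#'
#' @inheritParams gamma_rf
#' @return numeric vector, zero at and before `x0`.
#' @export
gamma_rf_deriv <- function(grid, params) {
  if (is.unsorted(grid)) stop("gamma_rf_deriv: grid must be sorted")
  out <- numeric(length(grid))
  pos <- grid > params$x0
  u <- grid[pos] - params$x0
  f <- params$A * stats::dgamma(u, shape = params$k, scale = params$theta)
  out[pos] <- f * ((params$k - 1) / u - 1 / params$theta)
  out
}

#' Evaluate the Gaussian tail component
#'
#' Unit-peak Gaussian `amplitude * exp(-(x - mu)^2 / (2 sigma^2))`; its free
#' scaling in a basis set is absorbed by the regression coefficient.
#'
#' @inheritParams gamma_rf
#' @param params a [gaussian_params()].
#' @return numeric vector.
#' @export
gaussian_tail <- function(grid, params) {
  params$amplitude * exp(-(grid - params$mu)^2 / (2 * params$sigma^2))
}

#' Extract fixed-length epochs around startle onsets
#'
#' Cuts one row per event from the recording over the half-open window
#' `[onset, onset + window)`; row `i` starts at sample
#' `floor(onset_i * rate)`.
#'
#' @param rec an [emg_recording()] (normally preprocessed).
#' @param events validated events data.frame for this recording's subject.
#' @param window epoch length in seconds (default 0.5).
#' @return an `epoch_set`: list with `data` (trials x samples matrix), `meta`
#'   (per-trial data.frame), `sampling_rate`, `window`, and `grid` (times of
#'   the columns relative to onset).
#' @export
extract_epochs <- function(rec, events, window = 0.5) {
  rate <- rec$sampling_rate
  len <- round(window * rate)
  if (len < 1) stop("extract_epochs: window shorter than one sample")
  n <- nrow(events)
  out <- matrix(NA_real_, n, len)
  for (i in seq_len(n)) {
    start <- onset_sample(events$sound_onset[i], rate) + 1L
    stop_ <- start + len - 1L
    if (stop_ > length(rec$samples))
      stop(sprintf("extract_epochs: epoch for trial %d (onset %g s) exceeds recording end",
                   events$trial_index[i], events$sound_onset[i]))
    out[i, ] <- rec$samples[start:stop_]
  }
  structure(list(data = out,
                 meta = data.frame(subject_id = events$subject_id,
                                   trial_index = events$trial_index,
                                   cs_type = events$cs_type,
                                   stringsAsFactors = FALSE),
                 sampling_rate = rate, window = window,
                 grid = (seq_len(len) - 1L) / rate),
            class = "epoch_set")
}

#' Principal components of an epoch set
#'
#' Singular value decomposition of the uncentred trials-by-samples matrix;
#' with rectified EMG the first component then tracks the mean burst shape.
#' The first component is sign-flipped if needed so its maximal absolute
#' deflection is positive.
#'
#' @param epochs an `epoch_set` or a trials-by-samples matrix.
#' @param n number of components requested.
#' @return list with `components` (samples x n matrix, unit norm columns),
#'   `variance_fractions` (length n, non-increasing, summing to at most 1),
#'   and `scores` (trials x n).
#' @export
principal_components <- function(epochs, n = 2) {
  x <- if (inherits(epochs, "epoch_set")) epochs$data else as.matrix(epochs)
  if (nrow(x) < 2L) stop("principal_components: need at least 2 trials")
  sv <- svd(x)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (n > rank)
    stop(sprintf("principal_components: n = %d exceeds matrix rank %d", n, rank))
  comps <- sv$v[, seq_len(n), drop = FALSE]
  scores <- x %*% comps
  varfrac <- sv$d[seq_len(n)]^2 / sum(sv$d^2)
  if (comps[which.max(abs(comps[, 1])), 1] < 0) {
    comps[, 1] <- -comps[, 1]
    scores[, 1] <- -scores[, 1]
  }
  list(components = comps, variance_fractions = varfrac, scores = scores)
}

gamma_rss <- function(par, y, grid) {
  p <- tryCatch(gamma_params(exp(par[1]), exp(par[2]), par[3], par[4]),
                error = function(e) NULL)
  if (is.null(p)) return(Inf)
  r <- y - gamma_rf(grid, p)
  sum(r * r)
}

default_gamma_init <- function(y, grid) {
  pk <- which.max(y)
  peak_t <- grid[pk]
  thresh <- 0.1 * y[pk]
  before <- which(grid < peak_t & y >= thresh)
  x0 <- if (length(before)) grid[min(before)] else max(grid[1], peak_t / 2)
  x0 <- min(x0, peak_t - 2 * (grid[2] - grid[1]))
  k <- 2
  theta <- max((peak_t - x0) / (k - 1), grid[2] - grid[1])
  A <- sum(pmax(y, 0)) * (grid[2] - grid[1])
  gamma_params(k, theta, x0, max(A, .Machine$double.eps))
}

#' Fit a gamma response function by Nelder-Mead least squares
#'
#' Minimises the residual sum of squares between `y` and [gamma_rf()] using
#' the Nelder-Mead simplex (`stats::optim`). The shape and scale are searched
#' on the log scale to enforce positivity. Unless an `init` is supplied, the
#' start is derived from the data (onset at 10% of peak, shape 2, scale from
#' the peak time, amplitude from the area) and the search is restarted from a
#' set of deterministic perturbations of that start, keeping the best fit.
#'
#' @param y sampled response (finite numeric vector).
#' @param grid time grid in seconds, same length as `y`.
#' @param init optional [gamma_params()] starting point.
#' @param n_restarts number of perturbed restarts (>= 1).
#' @param maxit iteration cap per start.
#' @return a `gamma_params` with attributes `rss` (achieved residual sum of
#'   squares) and `converged` (logical; a warning is raised when no start
#'   converged and the best-so-far is returned).
#' @export
fit_gamma <- function(y, grid, init = NULL, n_restarts = 3, maxit = 2000) {
  stopifnot(length(y) == length(grid))
  if (!all(is.finite(y))) stop("fit_gamma: y must be finite")
  base_init <- if (is.null(init)) default_gamma_init(y, grid) else init
  perturb <- list(c(1, 1, 0), c(1.3, 0.75, -0.005), c(0.75, 1.3, 0.005),
                  c(1.6, 0.6, -0.01), c(0.6, 1.6, 0.01))
  best <- NULL
  best_conv <- FALSE
  for (j in seq_len(max(1L, n_restarts))) {
    pj <- perturb[[((j - 1L) %% length(perturb)) + 1L]]
    start <- c(log(base_init$k * pj[1]), log(base_init$theta * pj[2]),
               base_init$x0 + pj[3], base_init$A)
    fit <- stats::optim(start, gamma_rss, y = y, grid = grid,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_conv <- fit$convergence == 0
    }
  }
  init_rss <- gamma_rss(c(log(base_init$k), log(base_init$theta),
                          base_init$x0, base_init$A), y, grid)
  if (best$value > init_rss) {
    # never worse than the starting point
    best$par <- c(log(base_init$k), log(base_init$theta),
                  base_init$x0, base_init$A)
    best$value <- init_rss
  }
  if (!best_conv)
    warning("fit_gamma: Nelder-Mead did not converge; returning best fit found")
  out <- gamma_params(exp(best$par[1]), exp(best$par[2]), best$par[3],
                      best$par[4])
  attr(out, "rss") <- best$value
  attr(out, "converged") <- best_conv
  out
}

#' Gram-Schmidt orthogonalisation of basis components
#'
#' Classical Gram-Schmidt with the unweighted discrete inner product (sum over
#' the grid). The first component is left unchanged; each later component has
#' its projections on all earlier ones removed (no renormalisation). A later
#' component that collapses to (numerically) zero is flagged degenerate.
#'
#' @param components samples-by-components matrix.
#' @return matrix of the same shape with attribute `degenerate` (logical per
#'   column).
#' @export
gram_schmidt <- function(components) {
  m <- as.matrix(components)
  if (ncol(m) < 1L) stop("gram_schmidt: need at least one component")
  if (sum(m[, 1]^2) == 0) stop("gram_schmidt: first component has zero norm")
  degen <- logical(ncol(m))
  for (j in seq_len(ncol(m))[-1]) {
    for (i in seq_len(j - 1L)) {
      ni <- sum(m[, i]^2)
      if (ni > 0) m[, j] <- m[, j] - (sum(m[, i] * m[, j]) / ni) * m[, i]
    }
    if (sqrt(sum(m[, j]^2)) < 1e-10 * sqrt(sum(m[, 1]^2))) degen[j] <- TRUE
  }
  attr(m, "degenerate") <- degen
  m
}

#' Build the basis set for a model
#'
#' M1 and M4 use the canonical SEBRF alone; M2 adds its analytic time
#' derivative; M3 adds a Gaussian tail. For M2 and M3 the later component is
#' Gram-Schmidt-orthogonalised to the canonical SEBRF.
#'
#' @param model_id one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param params a [gamma_params()] (default: the published initial set).
#' @param gaussian a [gaussian_params()] for M3 (default: the published tail).
#' @param rate sampling rate in Hz.
#' @param window epoch window in seconds.
#' @return a `basis_set`: list with `components` (samples x n matrix),
#'   `labels`, `grid`, `params`, `model_id`, `orthogonalized`.
#' @export
build_basis <- function(model_id, params = sebrf_presets$initial,
                        gaussian = sebrf_presets$m3_gaussian,
                        rate = 1000, window = 0.5) {
  grid <- (seq_len(round(window * rate)) - 1L) / rate
  f <- gamma_rf(grid, params)
  ortho <- FALSE
  if (model_id %in% c("M1", "M4")) {
    comps <- matrix(f, ncol = 1)
    labels <- "SEBRF"
  } else if (model_id == "M2") {
    comps <- cbind(f, gamma_rf_deriv(grid, params))
    labels <- c("SEBRF", "SEBRF_deriv")
    comps <- gram_schmidt(comps)
    ortho <- TRUE
  } else if (model_id == "M3") {
    comps <- cbind(f, gaussian_tail(grid, gaussian))
    labels <- c("SEBRF", "Gaussian_tail")
    comps <- gram_schmidt(comps)
    ortho <- TRUE
  } else stop("build_basis: unknown model_id ", shQuote(model_id))
  colnames(comps) <- labels
  structure(list(components = comps, labels = labels, grid = grid,
                 params = params,
                 gaussian = if (model_id == "M3") gaussian else NULL,
                 model_id = model_id, orthogonalized = ortho,
                 sampling_rate = rate, window = window),
            class = "basis_set")
}

#' Write a basis set as delimited text with a JSON parameter sidecar
#' @param basis a `basis_set`.
#' @param path output path for the component table (`<path>.json` gets the
#'   generating parameters).
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  tab <- data.frame(time = basis$grid, basis$components, check.names = FALSE)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  side <- list(model_id = basis$model_id,
               params = unclass(basis$params),
               gaussian = if (!is.null(basis$gaussian)) unclass(basis$gaussian),
               orthogonalized = basis$orthogonalized,
               sampling_rate = basis$sampling_rate, window = basis$window,
               labels = basis$labels)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
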