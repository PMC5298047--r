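#' @title Model inversion: GLM convolution and dictionary matching
#' @description Estimation of startle eyeblink amplitudes (and latencies for
#'   the M4 family) from the preprocessed EMG. Models M1-M3 (and the
#'   single-trial variant M2ST) are inverted as general linear convolution
#'   models via the Moore-Penrose pseudoinverse; M4/M4ST first estimate the
#'   response latency by matching against a dictionary of latency-shifted unit
#'   responses, then enter the matched element into the GLM.
#' @name model_inversion
NULL

# minimum-norm least squares via the Moore-Penrose pseudoinverse.
# For tall designs the right singular vectors are taken from the (small)
# eigendecomposition of X'X, which gives the identical pseudoinverse solution
# beta = V_r D_r^-2 V_r' X'y at a fraction of the cost of a full SVD.
pinv_solve <- function(X, y, tol_factor = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (n > 3L * p) {
    eg <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    tol <- if (is.null(tol_factor)) max(dim(X)) * .Machine$double.eps * d[1]
           else tol_factor
    pos <- d > tol
    if (!any(pos)) stop("pinv_solve: design matrix is (numerically) zero")
    vr <- eg$vectors[, pos, drop = FALSE]
    beta <- vr %*% (crossprod(vr, crossprod(X, y)) / d[pos]^2)
  } else {
    sv <- svd(X)
    d <- sv$d
    tol <- if (is.null(tol_factor)) max(dim(X)) * .Machine$double.eps * d[1]
           else tol_factor
    pos <- d > tol
    if (!any(pos)) stop("pinv_solve: design matrix is (numerically) zero")
    beta <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], y) / d[pos])
  }
  list(beta = drop(beta), rank = sum(pos), rank_deficient = any(!pos))
}

ordered_conditions <- function(cs_type) CS_TYPES[CS_TYPES %in% unique(cs_type)]

# place `component` at each onset (seconds), truncating at n_samples
place_at_onsets <- function(component, onsets, n_samples, rate) {
  col <- numeric(n_samples)
  for (on in onsets) {
    start <- onset_sample(on, rate) + 1L
    if (start > n_samples)
      stop("build_design: onset ", on, " s beyond recording end")
    take <- min(length(component), n_samples - start + 1L)
    idx <- start:(start + take - 1L)
    col[idx] <- col[idx] + component[seq_len(take)]
  }
  col
}

#' Build a convolution design matrix
#'
#' Each column is the convolution of a delta train (impulses at the startle
#' onsets of one condition, or of one trial) with one basis component;
#' responses running past the recording end are truncated.
#'
#' @param events validated events data.frame (single subject).
#' @param basis a `basis_set` (or any list with `components` matrix and
#'   `sampling_rate`).
#' @param n_samples length of the modelled recording.
#' @param rate sampling rate in Hz.
#' @param scope `"condition"` (one delta train per condition) or `"trial"`
#'   (one per trial).
#' @return list with `X` (samples x regressors matrix) and `columns`
#'   (data.frame: condition, trial_index, component for each column).
#' @export
build_design <- function(events, basis, n_samples, rate,
                         scope = c("condition", "trial")) {
  scope <- match.arg(scope)
  if (nrow(events) == 0L) stop("build_design: no events")
  comps <- basis$components
  ncomp <- ncol(comps)
  if (scope == "condition") {
    conds <- ordered_conditions(events$cs_type)
    cols <- vector("list", length(conds) * ncomp)
    meta <- data.frame()
    idx <- 0L
    for (cond in conds) {
      ons <- events$sound_onset[events$cs_type == cond]
      for (j in seq_len(ncomp)) {
        idx <- idx + 1L
        cols[[idx]] <- place_at_onsets(comps[, j], ons, n_samples, rate)
        meta <- rbind(meta, data.frame(condition = cond, trial_index = NA,
                                       component = colnames(comps)[j]))
      }
    }
  } else {
    cols <- vector("list", nrow(events) * ncomp)
    meta <- data.frame()
    idx <- 0L
    for (i in seq_len(nrow(events))) {
      for (j in seq_len(ncomp)) {
        idx <- idx + 1L
        cols[[idx]] <- place_at_onsets(comps[, j], events$sound_onset[i],
                                       n_samples, rate)
        meta <- rbind(meta, data.frame(condition = events$cs_type[i],
                                       trial_index = events$trial_index[i],
                                       component = colnames(comps)[j]))
      }
    }
  }
  list(X = do.call(cbind, cols), columns = meta)
}

#' Fit a convolution GLM by Moore-Penrose pseudoinverse
#'
#' Solves `Y = X beta + e` in the least-squares sense using the singular value
#' decomposition (the minimum-norm solution when `X` is rank deficient, in
#' which case a warning is raised).
#'
#' @param y observed signal: an [emg_recording()] or numeric vector.
#' @param X design matrix (or the list returned by [build_design()]).
#' @return list with `beta`, `fitted`, `residuals`, `rank`, `rank_deficient`.
#' @export
fit_glm <- function(y, X) {
  if (inherits(y, "emg_recording")) y <- y$samples
  cols <- NULL
  if (is.list(X) && !is.null(X$X)) { cols <- X$columns; X <- X$X }
  stopifnot(nrow(X) == length(y))
  if (all(X == 0)) stop("fit_glm: all-zero design matrix")
  sol <- pinv_solve(X, y)
  if (sol$rank_deficient)
    warning("fit_glm: design matrix is rank deficient (rank ", sol$rank,
            " of ", ncol(X), "); minimum-norm estimates returned")
  fitted <- drop(X %*% sol$beta)
  list(beta = sol$beta, fitted = fitted, residuals = y - fitted,
       rank = sol$rank, rank_deficient = sol$rank_deficient, columns = cols)
}

#' Reconstruct the response and quantify its amplitude
#'
#' Reconstructs `r(t) = sum_i beta_i * component_i(t)` over the epoch window
#' and quantifies the amplitude as the signed value of `r` at the point of
#' maximal absolute deviation from zero (`definition = "peak"`), or as the
#' signed integral of `r` over the window (`definition = "area"`).
#'
#' @param beta coefficient vector, one per basis component.
#' @param basis a `basis_set`.
#' @param window evaluation window in seconds (default: the basis window).
#' @param definition `"peak"` or `"area"`.
#' @return list with `amplitude` and `t_peak` (seconds; `NA` for `"area"`).
#' @export
reconstruct_amplitude <- function(beta, basis, window = basis$window,
                                  definition = c("peak", "area")) {
  definition <- match.arg(definition)
  stopifnot(length(beta) == ncol(basis$components))
  keep <- basis$grid < window
  r <- drop(basis$components[keep, , drop = FALSE] %*% beta)
  if (definition == "area")
    return(list(amplitude = sum(r) / basis$sampling_rate, t_peak = NA_real_))
  i <- which.max(abs(r))
  list(amplitude = r[i], t_peak = basis$grid[keep][i])
}

#' Build a dictionary of latency-shifted unit responses
#'
#' One row per latency on a grid with one-sample spacing spanning
#' `latency_window`; each row is the unit-amplitude (`A = 1`) canonical
#' response function with its onset at that latency, evaluated on a segment
#' grid long enough that the latest candidate is fully observed over the
#' epoch window (segment length = epoch window plus the latency span above
#' the canonical onset).
#'
#' @param params a [gamma_params()]; its `x0` is the canonical onset.
#' @param latency_window absolute onset-latency bounds in seconds,
#'   `c(lo, hi)` with `lo <= hi`; the published default is
#'   `x0 + c(-0.02, 0.13)`, see [dictionary_latency_window()].
#' @param rate sampling rate in Hz.
#' @param epoch_window epoch length in seconds.
#' @return a `dictionary`: list with `rows` (latencies x samples matrix),
#'   `latencies` (seconds), `grid`, `params`, `sampling_rate`.
#' @export
build_dictionary <- function(params, latency_window = NULL, rate = 1000,
                             epoch_window = 0.5) {
  if (is.null(latency_window))
    latency_window <- params$x0 + c(-0.02, 0.13)
  if (length(latency_window) != 2L || latency_window[1] > latency_window[2])
    stop("build_dictionary: empty or unordered latency window")
  n_lat <- floor((latency_window[2] - latency_window[1]) * rate + 1e-9) + 1L
  lats <- latency_window[1] + (seq_len(n_lat) - 1L) / rate
  ext <- max(0, max(lats) - params$x0)
  len <- round((epoch_window + ext) * rate)
  grid <- (seq_len(len) - 1L) / rate
  rows <- matrix(0, n_lat, len)
  for (i in seq_len(n_lat))
    rows[i, ] <- gamma_rf(grid, gamma_params(params$k, params$theta,
                                             lats[i], A = 1))
  structure(list(rows = rows, latencies = lats, grid = grid, params = params,
                 sampling_rate = rate, epoch_window = epoch_window),
            class = "dictionary")
}

#' Published dictionary latency window
#'
#' `[x0 - 0.02, x0 + 0.13]` seconds around the canonical onset, expanded on
#' both sides by twice the standard deviation of the measured sound-onset
#' delay when that was only recorded approximately.
#'
#' @param params a [gamma_params()].
#' @param sound_delay_sd standard deviation of the sound-onset delay (s).
#' @return numeric `c(lo, hi)` of absolute latencies in seconds.
#' @export
dictionary_latency_window <- function(params, sound_delay_sd = 0) {
  params$x0 + c(-0.02 - 2 * sound_delay_sd, 0.13 + 2 * sound_delay_sd)
}

#' Match a data segment against a dictionary
#'
#' Returns the dictionary element maximising the signed inner product with the
#' segment (ties broken toward the earliest latency). A segment orthogonal to
#' every element (e.g. all zeros) is flagged degenerate.
#'
#' @param segment numeric vector on the dictionary's segment grid, or a
#'   trials-by-samples matrix whose inner products are summed across rows
#'   (the per-condition variant).
#' @param dictionary a `dictionary`.
#' @return list with `latency` (seconds), `index`, `regressor` (the matched
#'   row), `inner_products`, `degenerate`.
#' @export
dictionary_match <- function(segment, dictionary) {
  if (is.matrix(segment)) {
    stopifnot(ncol(segment) == ncol(dictionary$rows))
    ip <- drop(dictionary$rows %*% colSums(segment))
  } else {
    stopifnot(length(segment) == ncol(dictionary$rows))
    ip <- drop(dictionary$rows %*% segment)
  }
  i <- which.max(ip)  # which.max returns the first (earliest) maximum
  list(latency = dictionary$latencies[i], index = i,
       regressor = dictionary$rows[i, ], inner_products = ip,
       degenerate = all(abs(ip - ip[1]) < .Machine$double.eps * max(1, abs(ip[1]))))
}

extract_segments <- function(rec, onsets, len) {
  out <- matrix(NA_real_, length(onsets), len)
  for (i in seq_along(onsets)) {
    start <- onset_sample(onsets[i], rec$sampling_rate) + 1L
    stop_ <- start + len - 1L
    if (stop_ > length(rec$samples))
      stop("estimate: matching segment at onset ", onsets[i],
           " s exceeds recording end")
    out[i, ] <- rec$samples[start:stop_]
  }
  out
}

amplitude_rows <- function(subject_id, method, scope, condition, trial_index,
                           amplitude, latency = NA_real_) {
  data.frame(subject_id = subject_id, method = method, scope = scope,
             condition = condition, trial_index = trial_index,
             amplitude = amplitude, latency = latency,
             stringsAsFactors = FALSE)
}

#' Per-condition means of a single-trial amplitude table
#'
#' @param table amplitude table with trial-scope rows.
#' @return amplitude table with one `scope = "condition"` row per subject,
#'   method and condition (mean amplitude; mean latency where present).
#' @export
condition_means <- function(table) {
  tr <- table[table$scope == "trial", , drop = FALSE]
  if (!nrow(tr)) return(tr)
  agg <- stats::aggregate(cbind(amplitude, latency) ~ subject_id + method + condition,
                          data = tr, FUN = mean, na.action = stats::na.pass)
  amplitude_rows(agg$subject_id, agg$method, "condition", agg$condition,
                 NA_integer_, agg$amplitude, agg$latency)
}

estimate_glm_family <- function(rec, events, method, basis, config) {
  scope <- if (method == "M2ST") "trial" else "condition"
  des <- build_design(events, basis, length(rec$samples), rec$sampling_rate,
                      scope = scope)
  # a constant column absorbs the baseline of the rectified signal (the mean
  # of rectified noise is positive and would otherwise bias response betas)
  fit <- fit_glm(rec$samples, cbind(des$X, 1))
  ncomp <- ncol(basis$components)
  units <- unique(des$columns[, c("condition", "trial_index")])
  out <- NULL
  for (i in seq_len(nrow(units))) {
    sel <- des$columns$condition == units$condition[i] &
      (is.na(units$trial_index[i]) |
         (!is.na(des$columns$trial_index) &
            des$columns$trial_index == units$trial_index[i]))
    rec_amp <- reconstruct_amplitude(fit$beta[which(sel)], basis,
                                     window = config$epoch_window,
                                     definition = config$amplitude_definition)
    out <- rbind(out, amplitude_rows(rec$subject_id, method, scope,
                                     units$condition[i], units$trial_index[i],
                                     rec_amp$amplitude))
  }
  if (scope == "trial") out <- rbind(out, condition_means(out))
  out
}

estimate_dictionary_family <- function(rec, events, method, params, config) {
  rate <- rec$sampling_rate
  latwin <- params$x0 + config$latency_window +
    c(-2, 2) * config$sound_delay_sd
  dict <- build_dictionary(params, latwin, rate,
                           epoch_window = config$epoch_window)
  len <- ncol(dict$rows)
  per_trial <- method == "M4ST"
  # matched regressor and latency per trial or per condition
  if (per_trial) {
    groups <- split(seq_len(nrow(events)), seq_len(nrow(events)))
  } else {
    groups <- split(seq_len(nrow(events)), events$cs_type)
    groups <- groups[ordered_conditions(events$cs_type)]
  }
  regs <- list(); lats <- numeric(0); meta <- data.frame()
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    seg <- extract_segments(rec, events$sound_onset[idx], len)
    m <- dictionary_match(seg, dict)
    regs[[g]] <- m$regressor
    lats[g] <- m$latency
    meta <- rbind(meta, data.frame(
      condition = if (per_trial) events$cs_type[idx] else names(groups)[g],
      trial_index = if (per_trial) events$trial_index[idx] else NA))
  }
  # one regressor per trial/condition, all entered into a single GLM
  X <- matrix(0, length(rec$samples), length(groups) + 1L)
  for (g in seq_along(groups))
    X[, g] <- place_at_onsets(regs[[g]], events$sound_onset[groups[[g]]],
                              length(rec$samples), rate)
  X[, length(groups) + 1L] <- 1  # baseline of the rectified signal
  fit <- fit_glm(rec$samples, X)
  out <- NULL
  for (g in seq_along(groups)) {
    pseudo_basis <- list(components = matrix(regs[[g]], ncol = 1),
                         grid = dict$grid, sampling_rate = rate,
                         window = config$epoch_window + max(0, lats[g] - params$x0))
    rec_amp <- reconstruct_amplitude(fit$beta[g], pseudo_basis,
                                     window = pseudo_basis$window,
                                     definition = config$amplitude_definition)
    out <- rbind(out, amplitude_rows(rec$subject_id, method,
                                     if (per_trial) "trial" else "condition",
                                     meta$condition[g], meta$trial_index[g],
                                     rec_amp$amplitude, latency = lats[g]))
  }
  if (per_trial) out <- rbind(out, condition_means(out))
  out
}

#' Estimate startle eyeblink amplitudes from one recording
#'
#' Runs the requested model on a (raw or preprocessed) recording and its
#' events. `M1`, `M2`, `M3` yield one amplitude per condition; `M2ST` one per
#' trial (plus condition means); `M4` one per condition with a shared matched
#' latency per condition; `M4ST` per-trial amplitudes and latencies. Peak
#' scoring methods `B1`, `Br`, `G1`, `G2` are dispatched to the corresponding
#' scorers (which always start from the raw signal).
#'
#' @param rec an [emg_recording()] for a single subject.
#' @param events validated events for that subject.
#' @param method one of `"M1"`, `"M2"`, `"M2ST"`, `"M3"`, `"M4"`, `"M4ST"`,
#'   `"B1"`, `"Br"`, `"G1"`, `"G2"`.
#' @param params canonical response-function parameters ([gamma_params()]).
#' @param gaussian Gaussian tail parameters (M3 only).
#' @param config an [analysis_config()].
#' @param preprocessed set `TRUE` when `rec` has already been passed through
#'   [preprocess_model()] (ignored by the peak scorers, which apply their own
#'   published chains to the raw signal).
#' @return an amplitude table (data.frame) with columns `subject_id`,
#'   `method`, `scope`, `condition`, `trial_index`, `amplitude`, `latency`.
#' @export
estimate_startle <- function(rec, events, method,
                             params = sebrf_presets$initial,
                             gaussian = sebrf_presets$m3_gaussian,
                             config = analysis_config(),
                             preprocessed = FALSE) {
  method <- match.arg(method, c("M1", "M2", "M2ST", "M3", "M4", "M4ST",
                                "B1", "Br", "G1", "G2"))
  events <- validate_events(events, duration = duration(rec))
  if (method %in% c("B1", "Br", "G1", "G2")) {
    scorer <- switch(method, B1 = score_b1, Br = score_br,
                     G1 = score_g1, G2 = score_g2)
    return(scorer(rec, events, config = config))
  }
  if (!preprocessed) rec <- preprocess_model(rec, config)
  if (method %in% c("M1", "M2", "M2ST", "M3")) {
    basis_model <- if (method == "M2ST") "M2" else method
    basis <- build_basis(basis_model, params = params, gaussian = gaussian,
                         rate = rec$sampling_rate,
                         window = config$epoch_window)
    estimate_glm_family(rec, events, method, basis, config)
  } else {
    estimate_dictionary_family(rec, events, method, params, config)
  }
}

#' Estimate amplitudes for a multi-subject dataset
#'
#' Maps [estimate_startle()] over a named list of recordings, pairing each
#' with its subject's events, and row-binds the amplitude tables.
#'
#' @param recordings named list of [emg_recording()]s (names = subject ids).
#' @param events events data.frame covering all subjects.
#' @inheritParams estimate_startle
#' @return combined amplitude table.
#' @export
estimate_dataset <- function(recordings, events, method,
                             params = sebrf_presets$initial,
                             gaussian = sebrf_presets$m3_gaussian,
                             config = analysis_config(),
                             preprocessed = FALSE) {
  out <- lapply(names(recordings), function(sid) {
    ev <- events[events$subject_id == sid, , drop = FALSE]
    estimate_startle(recordings[[sid]], ev, method, params = params,
                     gaussian = gaussian, config = config,
                     preprocessed = preprocessed)
  })
  do.call(rbind, out)
}
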