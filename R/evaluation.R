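#' @title Evaluation: normalization, statistics and predictive validity
#' @description Within-subject z-scoring of single-trial estimates, paired
#'   t tests with Cohen's d, the predictive-validity regression (CS type
#'   predicted from the amplitude estimate with subject-specific intercepts),
#'   its AIC, decisive-model comparison across methods, and the empirical
#'   filter-band grid search.
#' @name evaluation
NULL

#' Z-score single-trial estimates within each subject
#'
#' Per subject, trial-scope amplitudes are standardised to mean 0 and
#' standard deviation 1 (n-1 convention) across that subject's CS+ and CS-
#' trials pooled; condition-mean rows are recomputed from the normalized
#' scores.
#'
#' @param table amplitude table with trial-scope rows.
#' @return amplitude table of the same shape with normalized amplitudes.
#' @export
normalize_within_subject <- function(table) {
  tr <- table[table$scope == "trial", , drop = FALSE]
  if (!nrow(tr)) stop("normalize_within_subject: no trial-scope rows")
  for (sid in unique(tr$subject_id)) {
    sel <- tr$subject_id == sid
    if (sum(sel) < 2L)
      stop("normalize_within_subject: subject ", sid, " has fewer than 2 trials")
    s <- stats::sd(tr$amplitude[sel])
    if (!is.finite(s) || s == 0)
      stop("normalize_within_subject: zero within-subject variance for subject ",
           sid)
    tr$amplitude[sel] <- (tr$amplitude[sel] - mean(tr$amplitude[sel])) / s
  }
  rbind(tr, condition_means(tr))
}

#' Paired t test on per-subject condition means
#'
#' @param csp,csm per-subject CS+ and CS- means, paired by position.
#' @return list with `t`, `df` (= n - 1), `p` (two-sided), `n`.
#' @export
paired_t <- function(csp, csm) {
  stopifnot(length(csp) == length(csm))
  n <- length(csp)
  if (n < 2L) stop("paired_t: need at least 2 pairs")
  d <- csp - csm
  if (stats::sd(d) == 0) stop("paired_t: zero-variance differences")
  tt <- stats::t.test(csp, csm, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n)
}

#' Cohen's d from a paired t statistic
#'
#' `d = t / sqrt(n)` where `n` is the number of subjects.
#'
#' @param t paired t statistic(s).
#' @param n sample size(s), recycled against `t`.
#' @return Cohen's d.
#' @export
cohens_d <- function(t, n) {
  if (any(n < 1)) stop("cohens_d: n must be >= 1")
  t / sqrt(n)
}

#' Predictive-validity regression
#'
#' Least-squares regression predicting CS type (CS+ coded 1, CS- coded 0)
#' from the amplitude estimate, with subject-specific intercepts to absorb
#' between-subject variability. With one CS+ and one CS- mean per subject the
#' slope's t statistic is algebraically identical to the paired t test on the
#' CS+/CS- differences. The CS coding does not affect RSS-based AIC
#' differences between methods.
#'
#' @param table amplitude table; condition-scope rows (or trial rows, from
#'   which condition means are computed) for conditions CSP and CSM.
#' @return list with `rss`, `slope`, `t_slope`, `k` (number of regression
#'   coefficients = n_subjects + 1), `n` (number of observations),
#'   `subjects`.
#' @export
predictive_regression <- function(table) {
  cm <- table[table$scope == "condition" & table$condition %in% c("CSP", "CSM"),
              , drop = FALSE]
  if (!nrow(cm)) cm <- condition_means(table)
  cm <- cm[cm$condition %in% c("CSP", "CSM"), , drop = FALSE]
  subjects <- sort(unique(cm$subject_id))
  per <- table(cm$subject_id, cm$condition)
  if (!all(per == 1L))
    stop("predictive_regression: need exactly one CSP and one CSM mean per subject")
  y <- as.numeric(cm$condition == "CSP")
  x <- cm$amplitude
  subj <- factor(cm$subject_id, levels = subjects)
  fit <- stats::lm(y ~ x + subj)
  sm <- summary(fit)
  if (!"x" %in% rownames(sm$coefficients))
    stop("predictive_regression: rank-deficient fit (constant amplitudes?)")
  rss <- sum(stats::residuals(fit)^2)
  list(rss = rss, slope = unname(stats::coef(fit)["x"]),
       t_slope = unname(sm$coefficients["x", "t value"]),
       k = length(stats::coef(fit)), n = length(y), subjects = subjects)
}

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n * log(RSS / n) + 2k` (natural logarithm). A zero RSS yields
#' `-Inf`, flagged by a warning as degenerate.
#'
#' @param n number of observations.
#' @param rss residual sum of squares.
#' @param k number of model parameters.
#' @return the AIC value.
#' @export
aic_from_rss <- function(n, rss, k) {
  if (n <= 0) stop("aic_from_rss: n must be positive")
  if (rss < 0) stop("aic_from_rss: rss must be nonnegative")
  if (rss == 0) {
    warning("aic_from_rss: zero RSS; AIC is -Inf (degenerate perfect fit)")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

#' Compare methods by predictive validity
#'
#' Runs the predictive regression for each method's amplitude table on the
#' same subjects, converts the RSS to AIC, and reports paired t, two-sided p,
#' Cohen's d, pairwise AIC differences and decisive flags (`|dAIC| > 3`,
#' i.e. relative evidence below exp(-3) ~ .05).
#'
#' @param tables named list of amplitude tables, one per method.
#' @return a `comparison_result`: list with `methods` (data.frame of t, df,
#'   p, d, aic, n, k per method), `delta_aic` (matrix, row minus column),
#'   `decisive` (logical matrix), `n`, `k`.
#' @export
compare_methods <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("compare_methods: tables must be a named list")
  stats_df <- NULL
  subj_ref <- NULL
  aics <- numeric(0)
  for (m in names(tables)) {
    pr <- predictive_regression(tables[[m]])
    if (is.null(subj_ref)) subj_ref <- pr$subjects
    else if (!identical(subj_ref, pr$subjects))
      stop("compare_methods: subject mismatch between methods ",
           names(tables)[1], " and ", m)
    cm <- tables[[m]]
    cm <- cm[cm$scope == "condition" & cm$condition %in% c("CSP", "CSM"), ,
             drop = FALSE]
    if (!nrow(cm)) cm <- condition_means(tables[[m]])
    csp <- cm$amplitude[cm$condition == "CSP"][match(subj_ref, cm$subject_id[cm$condition == "CSP"])]
    csm <- cm$amplitude[cm$condition == "CSM"][match(subj_ref, cm$subject_id[cm$condition == "CSM"])]
    tt <- paired_t(csp, csm)
    aic <- aic_from_rss(pr$n, pr$rss, pr$k)
    aics[m] <- aic
    stats_df <- rbind(stats_df, data.frame(
      method = m, t = tt$t, df = tt$df, p = tt$p,
      d = cohens_d(tt$t, tt$n), aic = aic, n = pr$n, k = pr$k,
      stringsAsFactors = FALSE))
  }
  nm <- names(tables)
  delta <- outer(aics, aics, `-`)
  dimnames(delta) <- list(nm, nm)
  decisive <- abs(delta) > 3
  diag(decisive) <- FALSE
  structure(list(methods = stats_df, delta_aic = delta, decisive = decisive,
                 n = stats_df$n[1], k = stats_df$k[1]),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  print(x$methods, row.names = FALSE, digits = 4)
  if (nrow(x$methods) > 1L) {
    cat("pairwise delta AIC (row - column):\n")
    print(round(x$delta_aic, 2))
  }
  invisible(x)
}

#' Serialise a comparison result to JSON
#' @param result a `comparison_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(result, path) {
  out <- list(methods = result$methods,
              delta_aic = result$delta_aic,
              decisive = result$decisive, n = result$n, k = result$k)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Refit the response function on re-preprocessed data
#'
#' Default refit used by [filter_grid_search()]: pools the 0-500 ms epochs of
#' all subjects, takes the first (uncentred) principal component and fits the
#' gamma response function to it.
#'
#' @param recordings named list of preprocessed recordings.
#' @param events events data.frame covering all subjects.
#' @param config an [analysis_config()].
#' @return fitted [gamma_params()].
#' @export
refit_response_function <- function(recordings, events, config) {
  ep <- lapply(names(recordings), function(sid)
    extract_epochs(recordings[[sid]],
                   events[events$subject_id == sid, , drop = FALSE],
                   window = config$epoch_window)$data)
  pooled <- do.call(rbind, ep)
  rate <- recordings[[1]]$sampling_rate
  grid <- (seq_len(ncol(pooled)) - 1L) / rate
  pc1 <- principal_components(pooled, 1)$components[, 1]
  # rectified noise gives the uncentred PC1 a positive floor that scales with
  # the cell's noise bandwidth; remove the pre-onset level so the gamma is
  # fitted to the burst alone
  pc1 <- pc1 - mean(pc1[grid < 0.02])
  fit_gamma(pc1, grid, n_restarts = 1)
}

#' Empirical filter-band optimization by grid search
#'
#' For every combination of high-pass and low-pass cutoff on the grid
#' (published default: high-pass 10-90 Hz, low-pass 200-490 Hz, both in
#' steps of 10 Hz, 270 cells), the raw recordings are re-preprocessed with
#' that band, the response function is re-derived (via `refit_fn`), the
#' amplitudes are re-estimated with the requested model, and the
#' predictive-validity AIC is computed. Cells with cutoffs at or above
#' Nyquist are skipped with a warning. Ties for the best cell are broken
#' toward the lowest high-pass, then the lowest low-pass cutoff.
#'
#' @param recordings named list of raw [emg_recording()]s.
#' @param events events data.frame covering all subjects.
#' @param model_id model used for amplitude estimation (`"M1"`, `"M2"`,
#'   `"M2ST"`, `"M3"`, `"M4"`, `"M4ST"`).
#' @param grid_hp high-pass cutoffs (Hz).
#' @param grid_lp low-pass cutoffs (Hz).
#' @param config base [analysis_config()]; each cell overrides its `band`.
#' @param refit_fn function `(recordings, events, config) -> gamma_params`
#'   re-deriving the response function per cell; `NULL` reuses `params`
#'   unchanged.
#' @param params starting response-function parameters (also used when
#'   `refit_fn` is `NULL`).
#' @return a `filter_search_result`: list with `grid` (data.frame hp, lp,
#'   aic), `best` (row of `grid`), `best_params`, `params_per_cell`.
#' @export
filter_grid_search <- function(recordings, events, model_id = "M4ST",
                               grid_hp = seq(10, 90, by = 10),
                               grid_lp = seq(200, 490, by = 10),
                               config = analysis_config(),
                               refit_fn = refit_response_function,
                               params = sebrf_presets$initial) {
  nyq <- recordings[[1]]$sampling_rate / 2
  cells <- expand.grid(hp = grid_hp, lp = grid_lp)
  cells <- cells[order(cells$hp, cells$lp), ]
  aic <- rep(NA_real_, nrow(cells))
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    hp <- cells$hp[i]; lp <- cells$lp[i]
    if (hp >= lp || lp >= nyq) {
      warning(sprintf("filter_grid_search: skipping infeasible cell (%g, %g)",
                      hp, lp))
      next
    }
    cfg <- config
    cfg$band <- c(hp, lp)
    pp <- lapply(recordings, preprocess_model, config = cfg)
    cell_params <- if (is.null(refit_fn)) params
                   else refit_fn(pp, events, cfg)
    tab <- estimate_dataset(pp, events, model_id, params = cell_params,
                            config = cfg, preprocessed = TRUE)
    pr <- predictive_regression(tab)
    aic[i] <- aic_from_rss(pr$n, pr$rss, pr$k)
    fits[[i]] <- cell_params
  }
  grid <- data.frame(hp = cells$hp, lp = cells$lp, aic = aic)
  ok <- which(is.finite(aic))
  if (!length(ok)) stop("filter_grid_search: no feasible grid cell")
  best_i <- ok[order(aic[ok], cells$hp[ok], cells$lp[ok])][1]
  structure(list(grid = grid, best = grid[best_i, ],
                 best_params = fits[[best_i]], params_per_cell = fits,
                 model_id = model_id),
            class = "filter_search_result")
}

#' Write a filter-search result as a delimited grid plus JSON summary
#' @param result a `filter_search_result`.
#' @param path output path for the grid table (`<path>.json` gets the
#'   summary).
#' @return `path`, invisibly.
#' @export
write_filter_search <- function(result, path) {
  utils::write.table(result$grid, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  side <- list(model_id = result$model_id,
               best = as.list(result$best),
               best_params = unclass(result$best_params))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
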