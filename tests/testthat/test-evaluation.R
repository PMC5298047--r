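make_trial_table <- function(subjects, trials_per_cond, amp_fn,
                             method = "M4ST") {
  rows <- NULL
  for (s in seq_along(subjects)) {
    for (cond in c("CSP", "CSM")) {
      for (i in seq_len(trials_per_cond)) {
        rows <- rbind(rows, data.frame(
          subject_id = subjects[s], method = method, scope = "trial",
          condition = cond,
          trial_index = (if (cond == "CSP") 0 else trials_per_cond) + i - 1L,
          amplitude = amp_fn(s, cond, i), latency = NA_real_,
          stringsAsFactors = FALSE))
      }
    }
  }
  rbind(rows, condition_means(rows))
}

test_that("within-subject z-scoring has the documented properties", {
  tab <- data.frame(subject_id = "a", method = "B1", scope = "trial",
                    condition = c("CSP", "CSM"), trial_index = 0:1,
                    amplitude = c(1, 3), latency = NA_real_)
  z <- normalize_within_subject(tab)
  expect_equal(sort(z$amplitude[z$scope == "trial"]),
               c(-0.707, 0.707), tolerance = 1e-3)  # n-1 SD convention

  set.seed(41)
  tab2 <- make_trial_table(c("a", "b", "c"), 5,
                           function(s, cond, i) rnorm(1, s + (cond == "CSP")))
  z1 <- normalize_within_subject(tab2)
  # per-subject mean 0 and SD 1
  for (sid in c("a", "b", "c")) {
    v <- z1$amplitude[z1$scope == "trial" & z1$subject_id == sid]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # idempotence and location invariance
  expect_equal(normalize_within_subject(z1)$amplitude, z1$amplitude,
               tolerance = 1e-10)
  tab3 <- tab2
  tab3$amplitude <- tab3$amplitude +
    as.integer(factor(tab3$subject_id)) * 100
  tab3 <- rbind(tab3[tab3$scope == "trial", ])
  z3 <- normalize_within_subject(tab3)
  expect_equal(z3$amplitude[z3$scope == "trial"],
               z1$amplitude[z1$scope == "trial"], tolerance = 1e-10)

  const <- tab; const$amplitude <- c(2, 2)
  expect_error(normalize_within_subject(const), "zero within-subject variance")
})

test_that("paired t behaves at the degenerate directions", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_error(paired_t(x, x), "zero-variance")
  r <- paired_t(x, rev(x))
  expect_equal(r$df, 3)

  id <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(id$t, 0, tolerance = 1e-12)
  expect_equal(id$p, 1, tolerance = 1e-12)

  set.seed(1)
  big <- paired_t(c(5, 6, 7, 8) + rnorm(4, 0, 1e-4), c(4, 5, 6, 7))
  expect_gt(big$t, 100)
  expect_lt(big$p, 1e-5)
})

test_that("paired t type-I error is near nominal", {
  set.seed(99)
  n_sims <- 1000
  rejections <- sum(replicate(n_sims, {
    a <- rnorm(12); b <- rnorm(12)
    paired_t(a, b)$p < 0.05
  }))
  # binomial 99.9% band around 5% over 1000 simulations
  expect_gte(rejections, 28)
  expect_lte(rejections, 73)
})

test_that("Cohen's d reproduces the published worked examples", {
  # printed values are rounded to 2 dp, so agree within half a unit in the
  # last place (5.21/sqrt(20) = 1.1650 sits exactly at the boundary)
  expect_lt(abs(cohens_d(5.21, 20) - 1.17), 0.00501)
  expect_lt(abs(cohens_d(3.09, 15) - 0.80), 0.00501)
  expect_equal(cohens_d(0, 10), 0)
})

test_that("predictive regression slope t equals the paired t", {
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(8:25, 1)
    csp <- rnorm(n, 1, 1); csm <- rnorm(n, 0.7, 1)
    tab <- make_trial_table(sprintf("s%02d", 1:n), 1,
                            function(s, cond, i)
                              if (cond == "CSP") csp[s] else csm[s])
    pr <- predictive_regression(tab)
    tt <- paired_t(csp, csm)
    expect_equal(signif(pr$t_slope, 6), signif(tt$t, 6))
    expect_equal(pr$k, n + 1)
    expect_equal(pr$n, 2 * n)
  }
})

test_that("predictive regression handles perfect and null structure", {
  n <- 10
  # perfectly separating amplitudes with subject offsets: near-zero RSS
  tab <- make_trial_table(sprintf("s%02d", 1:n), 1,
                          function(s, cond, i) s * 10 + (cond == "CSP"))
  pr <- predictive_regression(tab)
  expect_lt(pr$rss, 1e-20)

  # null: slope estimates centre on zero across simulations
  set.seed(53)
  slopes <- replicate(200, {
    t0 <- make_trial_table(sprintf("s%02d", 1:8), 1,
                           function(s, cond, i) rnorm(1))
    predictive_regression(t0)$slope
  })
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(200))

  const <- make_trial_table(sprintf("s%02d", 1:5), 1, function(s, cond, i) 1)
  expect_error(predictive_regression(const), "rank-deficient")
})

test_that("AIC formula matches its closed forms and monotonicity", {
  expect_equal(aic_from_rss(100, 100, 2), 4)
  expect_equal(aic_from_rss(40, 10, 21), 40 * log(0.25) + 42)
  expect_equal(aic_from_rss(40, 10, 21), -13.452, tolerance = 1e-3)
  expect_lt(aic_from_rss(50, 5, 3), aic_from_rss(50, 9, 3))
  expect_warning(v <- aic_from_rss(10, 0, 2), "degenerate")
  expect_identical(v, -Inf)
  expect_error(aic_from_rss(0, 1, 2), "positive")
})

test_that("method comparison flags decisive AIC differences correctly", {
  set.seed(61)
  n <- 14
  true_diff <- rnorm(n, 1, 0.3)
  subj <- sprintf("s%02d", 1:n)
  good <- make_trial_table(subj, 1, function(s, cond, i)
    5 * s + (cond == "CSP") * true_diff[s] + rnorm(1, 0, 0.1), method = "good")
  noise <- make_trial_table(subj, 1, function(s, cond, i) rnorm(1),
                            method = "noise")
  res <- compare_methods(list(good = good, noise = noise))
  expect_s3_class(res, "comparison_result")
  expect_lt(res$delta_aic["good", "noise"], -3)
  expect_true(res$decisive["good", "noise"])
  expect_equal(res$methods$d, res$methods$t / sqrt(n), tolerance = 1e-12)

  # affine invariance: dAIC exactly 0 between a table and a rescaled copy
  scaled <- good; scaled$amplitude <- 3.7 * scaled$amplitude + 11
  scaled$method <- "scaled"
  res2 <- compare_methods(list(a = good, b = scaled))
  expect_equal(res2$delta_aic["a", "b"], 0, tolerance = 1e-9)
  expect_false(res2$decisive["a", "b"])

  # single method: no differences
  res1 <- compare_methods(list(only = good))
  expect_equal(dim(res1$delta_aic), c(1L, 1L))
  expect_false(any(res1$decisive))

  other <- make_trial_table(sprintf("x%02d", 1:n), 1,
                            function(s, cond, i) rnorm(1))
  expect_error(compare_methods(list(a = good, b = other)), "subject mismatch")
})

test_that("equal-noise method copies are rarely decisively different", {
  # two scorers applied to the same recordings share the trial noise; model
  # this as a common score plus a small method-specific perturbation
  set.seed(62)
  n_decisive <- sum(replicate(100, {
    subj <- sprintf("s%02d", 1:10)
    diff <- rnorm(10, 0.8, 0.3)
    shared <- matrix(rnorm(20, 0, 0.4), 10, 2)
    f <- function(extra) function(s, cond, i)
      3 * s + (cond == "CSP") * diff[s] + shared[s, 1 + (cond == "CSP")] +
        rnorm(1, 0, extra)
    a <- make_trial_table(subj, 1, f(0.01), method = "a")
    b <- make_trial_table(subj, 1, f(0.01), method = "b")
    compare_methods(list(a = a, b = b))$decisive[1, 2]
  }))
  expect_lt(n_decisive, 10)
})

test_that("comparison results serialise to JSON", {
  tab <- make_trial_table(sprintf("s%02d", 1:6), 2,
                          function(s, cond, i) s + (cond == "CSP") + rnorm(1, 0, .2))
  res <- compare_methods(list(m = tab))
  p <- withr::local_tempfile(fileext = ".json")
  write_comparison(res, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$methods$aic, res$methods$aic, tolerance = 1e-9)
})

test_that("the filter grid search reports a well-formed surface", {
  sim <- small_sim(seed = 71, n_subjects = 3, trials_per_condition = 4)
  gs <- filter_grid_search(sim$recordings, sim$events, model_id = "M1",
                           grid_hp = c(30, 60), grid_lp = c(250),
                           refit_fn = NULL)
  expect_equal(nrow(gs$grid), 2L)
  expect_true(all(is.finite(gs$grid$aic)))
  expect_equal(gs$best$aic, min(gs$grid$aic))

  # a one-cell grid trivially wins; infeasible cells are skipped with warning
  gs1 <- filter_grid_search(sim$recordings, sim$events, model_id = "M1",
                            grid_hp = 30, grid_lp = 250, refit_fn = NULL)
  expect_equal(nrow(gs1$grid), 1L)
  expect_warning(
    filter_grid_search(sim$recordings, sim$events, model_id = "M1",
                       grid_hp = c(30, 400), grid_lp = c(350), refit_fn = NULL),
    "infeasible")
})

test_that("the default grid has the published dimensions", {
  hp <- seq(10, 90, by = 10)
  lp <- seq(200, 490, by = 10)
  expect_equal(length(hp) * length(lp), 270L)
  expect_identical(formals(filter_grid_search)$grid_hp,
                   quote(seq(10, 90, by = 10)))
  expect_identical(formals(filter_grid_search)$grid_lp,
                   quote(seq(200, 490, by = 10)))
})
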