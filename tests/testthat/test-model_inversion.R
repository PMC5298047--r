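canonical <- sebrf_presets$initial

test_that("design matrices place basis functions at onsets", {
  b <- build_basis("M1", rate = 1000, window = 0.5)
  ev <- make_events(1.0, cs_type = "CSP")
  des <- build_design(ev, b, 3000, 1000, scope = "condition")
  expect_equal(ncol(des$X), 1L)
  expect_equal(des$X[1001:1500, 1], b$components[, 1], ignore_attr = TRUE)
  expect_true(all(des$X[c(1:1000, 1501:3000), 1] == 0))

  b2 <- build_basis("M2")
  ev2 <- make_events(c(1, 3, 5, 7), cs_type = c("CSP", "CSM", "CSP", "CSM"))
  des2 <- build_design(ev2, b2, 9000, 1000, scope = "condition")
  expect_equal(ncol(des2$X), 4L)  # 2 conditions x 2 components

  # trial scope with non-overlapping events: disjoint column support
  des3 <- build_design(ev2, b2, 9000, 1000, scope = "trial")
  expect_equal(ncol(des3$X), 8L)
  supp <- apply(des3$X != 0, 2, which)
  for (i in seq(1, 7, by = 2))
    for (j in setdiff(seq(1, 7, by = 2), i))
      expect_length(intersect(supp[[i]], supp[[j]]), 0)

  expect_error(build_design(make_events(99), b, 3000, 1000), "beyond recording")
  expect_error(build_design(ev[0, ], b, 3000, 1000), "no events")
})

test_that("GLM inversion is exact on noiseless data and unbiased under noise", {
  b <- build_basis("M2")
  ev <- make_events(c(1, 3, 5, 7), cs_type = c("CSP", "CSM", "CSP", "CSM"))
  des <- build_design(ev, b, 9000, 1000, scope = "condition")
  beta <- c(2, -1, 0.5, 3)
  y <- drop(des$X %*% beta)
  fit <- fit_glm(y, des)
  expect_equal(fit$beta, beta, tolerance = 1e-10)
  expect_equal(fit$residuals, numeric(9000), tolerance = 1e-9)

  expect_equal(fit_glm(numeric(9000), des)$beta, numeric(4), tolerance = 1e-12)
  expect_error(fit_glm(y, matrix(0, 9000, 2)), "all-zero")

  # Monte-Carlo unbiasedness: mean estimate within 2 SEs of truth
  onsets <- seq(1, by = 1.2, length.out = 40)
  ev40 <- make_events(onsets, cs_type = rep(c("CSP", "CSM"), 20))
  n <- ceiling((max(onsets) + 1) * 1000)
  des40 <- build_design(ev40, build_basis("M1"), n, 1000, "condition")
  beta40 <- c(3, 1)
  signal <- drop(des40$X %*% beta40)
  ests <- sapply(1:100, function(s) {
    set.seed(s)
    fit_glm(signal + rnorm(n, 0, 2), des40)$beta
  })
  se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  expect_true(all(abs(rowMeans(ests) - beta40) < 2 * se + 1e-8))
})

test_that("amplitude reconstruction equals the dense-grid oracle", {
  b <- build_basis("M2")
  beta <- c(1.5, -4)
  r <- reconstruct_amplitude(beta, b)
  # oracle: brute-force evaluation of the summed basis on the grid
  dense <- drop(b$components %*% beta)
  i <- which.max(abs(dense))
  expect_equal(r$amplitude, dense[i])
  expect_equal(r$t_peak, b$grid[i])

  b1 <- build_basis("M1")
  r1 <- reconstruct_amplitude(2.5, b1)
  expect_equal(r1$amplitude, 2.5 * max(b1$components[, 1]))
  expect_equal(reconstruct_amplitude(0, b1)$amplitude, 0)

  # signed-area alternative
  ra <- reconstruct_amplitude(beta, b, definition = "area")
  expect_equal(ra$amplitude, sum(dense) / 1000)
})

test_that("dictionaries enumerate sample-resolution latencies", {
  d <- build_dictionary(canonical, rate = 1000)
  expect_equal(nrow(d$rows), 151L)  # round(0.15 * rate) + 1
  expect_equal(d$latencies[1], canonical$x0 - 0.02)
  expect_equal(d$latencies[151], canonical$x0 + 0.13, tolerance = 1e-9)

  d0 <- build_dictionary(canonical, canonical$x0 + c(0, 0), rate = 1000)
  expect_equal(nrow(d0$rows), 1L)

  # consecutive rows are one-sample shifted copies
  cc <- sapply(2:5, function(i) {
    x <- d$rows[i - 1, ]; y <- d$rows[i, ]
    which.max(sapply(0:3, function(lag)
      sum(x[1:(length(x) - lag)] * y[(lag + 1):length(y)]))) - 1
  })
  expect_equal(cc, rep(1L, 4))

  expect_error(build_dictionary(canonical, c(0.2, 0.1)), "unordered")

  # latency-window expansion by twice the sound-onset-delay SD
  w <- dictionary_latency_window(canonical, sound_delay_sd = 0.004)
  expect_equal(w, canonical$x0 + c(-0.028, 0.138))
})

test_that("dictionary matching finds the generating latency", {
  d <- build_dictionary(canonical, rate = 1000)
  j <- 77L
  m <- dictionary_match(d$rows[j, ], d)
  expect_equal(m$index, j)
  expect_equal(m$latency, d$latencies[j])

  # scaled + noisy segment still matches (inner product is scale-monotone)
  set.seed(5)
  hits <- sapply(1:20, function(s) {
    seg <- 5 * d$rows[j, ] + rnorm(ncol(d$rows), 0, 0.05 * max(d$rows[j, ]))
    dictionary_match(seg, d)$index
  })
  expect_true(all(abs(hits - j) <= 1))

  z <- dictionary_match(numeric(ncol(d$rows)), d)
  expect_equal(z$index, 1L)  # earliest-latency tie break
  expect_true(z$degenerate)
})

test_that("estimators recover known structure end-to-end", {
  # noiseless single trial at a shifted latency: M4ST recovers it exactly
  rate <- 1000
  true_lat <- canonical$x0 + 0.05
  true_amp <- 3
  n <- 4000
  grid <- (seq_len(n) - 1) / rate
  onset <- 1.0
  sig <- true_amp * gamma_rf(grid, gamma_params(canonical$k, canonical$theta,
                                                onset + true_lat, A = 1))
  rec <- emg_recording(sig, rate)
  ev <- make_events(onset, cs_type = "CSP")
  tab <- estimate_startle(rec, ev, "M4ST", preprocessed = TRUE)
  tr <- tab[tab$scope == "trial", ]
  expect_equal(tr$latency, true_lat, tolerance = 1e-9)
  peak <- max(gamma_rf(seq(0, 0.7, 1 / rate),
                       gamma_params(canonical$k, canonical$theta, true_lat, 1)))
  expect_rel_error(tr$amplitude, true_amp * peak, 0.01)

  # M1 on data built as condition-collapsed design x known beta
  ev4 <- make_events(c(1, 3, 5, 7), cs_type = c("CSP", "CSM", "CSP", "CSM"))
  b1 <- build_basis("M1")
  des <- build_design(ev4, b1, 9000, rate, "condition")
  beta <- c(4, 2)
  rec4 <- emg_recording(drop(des$X %*% beta), rate)
  tab4 <- estimate_startle(rec4, ev4, "M1", preprocessed = TRUE)
  got <- tab4$amplitude[match(c("CSP", "CSM"), tab4$condition)]
  expect_equal(got, beta * max(b1$components[, 1]), tolerance = 1e-8)
})

test_that("M4ST latency recovery is exact at zero noise across the window", {
  rate <- 1000
  offsets <- c(-0.018, -0.01, 0, 0.04, 0.09, 0.125)
  for (off in offsets) {
    lat <- canonical$x0 + off
    grid <- (seq_len(3000) - 1) / rate
    sig <- 2 * gamma_rf(grid, gamma_params(canonical$k, canonical$theta,
                                           1 + lat, A = 1))
    tab <- estimate_startle(emg_recording(sig, rate), make_events(1, "CSP"),
                            "M4ST", preprocessed = TRUE)
    expect_equal(tab$latency[tab$scope == "trial"], lat, tolerance = 1e-9)
  }
})

test_that("amplitude estimates are equivariant to signal scaling", {
  sim <- small_sim(seed = 77, n_subjects = 1, trials_per_condition = 3)
  rec <- sim$recordings$s01
  ev <- sim$events
  for (meth in c("M1", "M2ST", "M4ST", "B1", "G2")) {
    t1 <- estimate_startle(rec, ev, meth)
    rec2 <- rec; rec2$samples <- 3 * rec$samples
    t2 <- estimate_startle(rec2, ev, meth)
    expect_equal(t2$amplitude, 3 * t1$amplitude, tolerance = 1e-6)
  }
})

test_that("a width-zero dictionary reproduces the M1 GLM estimate", {
  sim <- small_sim(seed = 78, n_subjects = 1, trials_per_condition = 3)
  rec <- preprocess_model(sim$recordings$s01)
  ev <- sim$events
  cfg <- analysis_config(latency_window = c(0, 0))
  m4 <- estimate_startle(rec, ev, "M4", config = cfg, preprocessed = TRUE)
  m1 <- estimate_startle(rec, ev, "M1", preprocessed = TRUE)
  m4c <- m4[m4$scope == "condition", ]
  m1c <- m1[m1$scope == "condition", ]
  expect_equal(m4c$amplitude[match(c("CSP", "CSM"), m4c$condition)],
               m1c$amplitude[match(c("CSP", "CSM"), m1c$condition)],
               tolerance = 1e-9)
  expect_equal(unique(m4c$latency), canonical$x0)
})
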