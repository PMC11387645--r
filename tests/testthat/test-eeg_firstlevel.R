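test_that("the preliminary-response filter removes exactly the fast trials", {
  set.seed(401)
  ep <- make_epochs(array(rnorm(20 * 2 * 10), c(20, 2, 10)))
  out <- drop_fast_response_trials(ep)
  expect_equal(out$n_removed, 0L)
  expect_equal(dim(out$epochs$data), dim(ep$data))
  ep$metadata$rt2_ms[7] <- 50
  out2 <- drop_fast_response_trials(ep)
  expect_equal(out2$n_removed, 1L)
  expect_false(6L %in% out2$epochs$metadata$trial)   # 0-based trial ids
  out3 <- drop_fast_response_trials(ep, threshold_ms = 0)
  expect_equal(out3$n_removed, 0L)
})

test_that("baseline correction subtracts the pre-feedback mean exactly", {
  # hand 4-sample trace at 500 Hz starting -2 ms: samples at -2 and 0 ms
  # form the baseline window
  x <- array(0, c(1, 1, 4)); x[1, 1, ] <- c(1, 3, 10, 20)
  ep <- make_epochs(x, srate = 500, t0 = -2)
  bc <- baseline_correct(ep, window = c(-2, 0))
  expect_equal(as.vector(bc$data), c(1, 3, 10, 20) - 2)
  # constant signal goes to zero; offsets are invariant
  y <- array(7, c(3, 2, 8))
  expect_true(all(abs(baseline_correct(make_epochs(y))$data) < 1e-10))
  set.seed(402)
  z <- array(rnorm(3 * 2 * 8), c(3, 2, 8))
  b1 <- baseline_correct(make_epochs(z))$data
  b2 <- baseline_correct(make_epochs(z + 5))$data
  expect_equal(b1, b2, tolerance = 1e-10)
  expect_error(baseline_correct(make_epochs(y), c(-500, -400)), "window")
})

test_that("artifact rejection removes a planted gross outlier", {
  set.seed(403)
  x <- array(rnorm(500 * 2 * 20), c(500, 2, 20))
  x[137, , ] <- x[137, , ] + 50
  out <- adaptive_artifact_rejection(make_epochs(x))
  expect_equal(out$removed, 137L)
})

test_that("homogeneous data forces the minimum removal via threshold decay", {
  set.seed(404)
  x <- array(rnorm(200 * 2 * 20), c(200, 2, 20))
  out <- adaptive_artifact_rejection(make_epochs(x))
  expect_gte(length(out$removed), 1L)
  expect_lte(length(out$removed), 10L)
  expect_lt(out$threshold, 4)
})

test_that("heavy contamination is capped at the maximal fraction", {
  set.seed(405)
  x <- array(rnorm(300 * 2 * 20), c(300, 2, 20))
  bad <- sample(300, 30)
  x[bad, , ] <- x[bad, , ] + 30
  out <- adaptive_artifact_rejection(make_epochs(x))
  expect_lte(length(out$removed), 15L)   # 5% of 300
  expect_true(all(out$removed %in% bad)) # only contaminated trials go
  expect_error(adaptive_artifact_rejection(make_epochs(x), min_remove = 20),
               "min_remove")
})

test_that("noiseless planted linear data is recovered exactly", {
  set.seed(406)
  n <- 40
  trans <- rep(c(1, -1), n / 2)
  rpe <- rnorm(n)
  rpe_z <- as.numeric(scale(rpe))
  b_true <- c(2, -0.5, 1.2, 0.4)
  x <- array(0, c(n, 2, 6))
  for (t in 1:6)
    x[, 2, t] <- b_true[1] + b_true[2] * trans + b_true[3] * rpe_z +
      b_true[4] * trans * rpe_z
  md <- data.frame(trial = 1:n - 1L, rt1_ms = 500, rt2_ms = 500,
                   transition = ifelse(trans > 0, "common", "rare"),
                   rpe = rpe)
  ep <- make_epochs(x, channels = c("FCz", "Cz"), metadata = md)
  bm <- robust_regress_trials(ep)
  expect_equal(as.vector(bm$b[, "Cz", 3]), b_true, tolerance = 1e-6)
  expect_equal(as.vector(bm$b[, "FCz", 3]), c(0, 0, 0, 0),
               tolerance = 1e-8)
  expect_equal(bm$regressors,
               c("intercept", "transition", "rpe", "transition:rpe"))
})

test_that("Huber weights beat least squares under gross outliers", {
  set.seed(407)
  reps <- 30
  err_h <- err_o <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    n <- 60
    rpe <- rnorm(n)
    md <- data.frame(trial = 1:n - 1L, rt1_ms = 500, rt2_ms = 500,
                     transition = sample(c("common", "rare"), n, TRUE),
                     rpe = rpe)
    tr <- ifelse(md$transition == "common", 1, -1)
    y <- 1 + 0.8 * tr + 1.5 * as.numeric(scale(rpe)) + rnorm(n)
    out <- sample(n, 3)               # 5% gross outliers
    y[out] <- y[out] + sample(c(-1, 1), 3, TRUE) * 40
    x <- array(y, c(n, 1, 1))
    ep <- make_epochs(x, channels = "FCz", metadata = md)
    bh <- robust_regress_trials(ep)
    bo <- robust_regress_trials(ep, huber_k = Inf)
    err_h[r, ] <- c(bh$b["transition", 1, 1] - 0.8,
                    bh$b["rpe", 1, 1] - 1.5)
    err_o[r, ] <- c(bo$b["transition", 1, 1] - 0.8,
                    bo$b["rpe", 1, 1] - 1.5)
  }
  expect_lt(sqrt(mean(err_h^2)), sqrt(mean(err_o^2)))
})

test_that("the IRLS solution matches MASS::rlm at a single point", {
  set.seed(408)
  n <- 80
  rpe <- rnorm(n)
  md <- data.frame(trial = 1:n - 1L, rt1_ms = 500, rt2_ms = 500,
                   transition = sample(c("common", "rare"), n, TRUE),
                   rpe = rpe)
  tr <- ifelse(md$transition == "common", 1, -1)
  y <- 0.5 - 0.6 * tr + 1.1 * as.numeric(scale(rpe)) + rnorm(n)
  y[1:4] <- y[1:4] + 15
  ep <- make_epochs(array(y, c(n, 1, 1)), channels = "FCz", metadata = md)
  ours <- robust_regress_trials(ep, tol = 1e-10, max_iter = 200)
  rz <- as.numeric(scale(rpe))
  ref <- MASS::rlm(y ~ tr * rz, psi = MASS::psi.huber, k = 1.345,
                   maxit = 200, acc = 1e-10, scale.est = "MAD")
  expect_equal(unname(ours$b[, 1, 1]),
               unname(coef(ref)[c(1, 2, 3, 4)]), tolerance = 0.02)
})

test_that("with an infinite tuning constant the fit equals least squares", {
  set.seed(409)
  n <- 50
  md <- data.frame(trial = 1:n - 1L, rt1_ms = 500, rt2_ms = 500,
                   transition = sample(c("common", "rare"), n, TRUE),
                   rpe = rnorm(n))
  y <- rnorm(n, sd = 3)
  ep <- make_epochs(array(y, c(n, 1, 1)), channels = "FCz", metadata = md)
  b_inf <- robust_regress_trials(ep, huber_k = Inf)$b[, 1, 1]
  tr <- ifelse(md$transition == "common", 1, -1)
  rz <- as.numeric(scale(md$rpe))
  b_ols <- coef(lm(y ~ tr + rz + I(tr * rz)))
  expect_equal(unname(b_inf), unname(b_ols), tolerance = 1e-10)
})

test_that("group maps use BH adjustment consistent with an independent rule", {
  set.seed(410)
  maps <- lapply(1:8, function(i) {
    x <- array(rnorm(30 * 2 * 5), c(30, 2, 5))
    x[, 1, 2] <- x[, 1, 2] + 2        # planted effect at FCz, sample 2
    md <- data.frame(trial = 1:30 - 1L, rt1_ms = 500, rt2_ms = 500,
                     transition = sample(c("common", "rare"), 30, TRUE),
                     rpe = rnorm(30))
    robust_regress_trials(make_epochs(x, channels = c("FCz", "Cz"),
                                      metadata = md))
  })
  tm <- group_tmap(maps, "intercept")
  expect_equal(as.vector(tm$p_adj),
               oracle_bh_adjust(as.vector(tm$p)), tolerance = 1e-12)
  expect_true(tm$mask["FCz", 2])
  # degenerate zero-variance points are flagged
  cmaps <- lapply(maps, function(m) { m$b["intercept", "Cz", 1] <- 3; m })
  expect_warning(tmz <- group_tmap(cmaps, "intercept"), "zero variance")
  expect_equal(unname(tmz$p["Cz", 1]), 0)
  expect_error(group_tmap(maps[1:2], "rpe"), "3 subjects")
})

test_that("component windows are found at the planted peak latencies", {
  times <- seq(-200, 798, by = 2)
  ga <- matrix(0, 2, length(times), dimnames = list(c("FCz", "Cz"), NULL))
  ga["FCz", ] <- -3 * exp(-(times - 294)^2 / (2 * 25^2))
  ga["Cz", ] <- 4 * exp(-(times - 370)^2 / (2 * 50^2))
  w <- find_component_windows(ga, times)
  expect_equal(w$peak_ms, c(294, 370))
  expect_equal(w$win_lo, c(269, 345))
  expect_equal(w$win_hi, c(319, 395))
  # tie rule: two equal troughs pick the earlier latency
  ga2 <- ga
  ga2["FCz", ] <- 0
  ga2["FCz", times %in% c(280, 320)] <- -5
  w2 <- find_component_windows(ga2, times)
  expect_equal(w2$peak_ms[1], 280)
  # boundary peak warns
  ga3 <- ga
  ga3["FCz", ] <- -times   # most negative at the upper search edge
  expect_warning(find_component_windows(ga3, times), "boundary")
})

test_that("window averaging of b values is plain arithmetic", {
  bmap <- list(b = array(0, c(2, 1, 5),
                         dimnames = list(c("intercept", "rpe"), "Cz",
                                         NULL)),
               regressors = c("intercept", "rpe"), channels = "Cz",
               times = c(0, 2, 4, 6, 8), subject_id = "sx", n_trials = 10)
  class(bmap) <- "beta_map"
  bmap$b["rpe", 1, ] <- c(1, 2, 3, 4, 5)
  win <- list(channel = "Cz", win_lo = 0, win_hi = 8)
  expect_equal(mean_b_in_window(bmap, win), 3)
  bmap$b["rpe", 1, ] <- 2
  expect_equal(mean_b_in_window(bmap, win), 2)
  # linear ramp over a symmetric window gives the center value
  bmap$b["rpe", 1, ] <- bmap$times * 0.5
  expect_equal(mean_b_in_window(bmap, win), 0.5 * 4)
  expect_error(mean_b_in_window(bmap, list(channel = "FCz", win_lo = 0,
                                           win_hi = 8)), "channel")
})
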