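test_that("stay design coding matches the +1/-1 convention losslessly", {
  tr <- fixture_trials()        # rewards 3, -2, 5; common, common, rare
  d <- twostepEEG:::stay_rows(as_behavior(tr))
  expect_equal(nrow(d), 2L)     # first trial dropped
  expect_equal(d$reward_prev, c(1, -1))
  expect_equal(d$transition_prev, c(1, 1))
  expect_equal(d$stay, c(0L, 0L))  # choices 0, 1, 0
  # decoding the codes recovers the labels
  expect_equal(ifelse(d$reward_prev > 0, "yes", "no"), c("yes", "no"))
  expect_equal(ifelse(d$transition_prev > 0, "common", "rare"),
               c("common", "common"))
  # zero points count as non-reward
  tr0 <- tr; tr0$reward_points <- c(0L, 1L, 1L)
  d0 <- twostepEEG:::stay_rows(as_behavior(tr0))
  expect_equal(d0$reward_prev[1], -1)
})

test_that("random responders are excluded, learners of either kind kept", {
  cfg <- task_config()
  set.seed(201)
  rand <- simulate_subject(agent_params(0.5, 0.5, 0, 0.5), cfg)
  expect_false(screen_random_responder(rand)$keep)
  mf <- simulate_subject(agent_params(0.6, 0.6, 10, w = 0), cfg, "mf_pure")
  s_mf <- screen_random_responder(mf)
  expect_true(s_mf$keep)
  expect_gt(s_mf$reward_coef, 0)
  mb <- simulate_subject(agent_params(0.6, 0, 10, w = 1), cfg, "mb_pure")
  s_mb <- screen_random_responder(mb)
  expect_true(s_mb$keep)
  expect_gt(s_mb$interaction_coef, 0)
})

test_that("screening keeps nearly all non-random agents", {
  cfg <- task_config()
  set.seed(202)
  kept <- vapply(1:20, function(i) {
    w <- runif(1)
    b <- simulate_subject(agent_params(runif(1, 0.3, 0.8),
                                       runif(1, 0.3, 0.9),
                                       runif(1, 3, 8), w), cfg)
    screen_random_responder(b)$keep
  }, logical(1))
  expect_gte(mean(kept), 0.95)
})

test_that("the stay design standardizes traits and drops first trials", {
  cfg <- task_config(n_trials = 3)
  set.seed(203)
  behs <- simulate_cohort(6, agent_params(0.5, 0.5, 3, 0.5), cfg)
  traits <- data.frame(subject_id = sprintf("s%03d", 1:6),
                       bis_score = c(50, 60, 70, 55, 65, 75),
                       oci_score = c(5, 10, 20, 8, 15, 30))
  des <- build_stay_design(behs, traits)
  expect_equal(nrow(des), 6 * 2)          # one row lost per subject
  expect_equal(mean(unique(des$bis_z)), 0, tolerance = 1e-12)
  expect_equal(sd(unique(des$bis_z)), 1, tolerance = 1e-12)
  expect_match(attr(des, "formula"), "transition_prev \\* reward_prev")
  # missing traits: listwise exclusion with warning
  traits$oci_score[2] <- NA
  expect_warning(des2 <- build_stay_design(behs, traits), "missing trait")
  expect_equal(length(unique(des2$subject_id)), 5L)
})

test_that("the stay GLMM detects planted model-free and model-based control", {
  cfg <- task_config(n_trials = 250)
  set.seed(204)
  behs <- simulate_cohort(12, agent_params(0.6, 0.6, 6, w = 0), cfg,
                          "mf_pure")
  traits <- data.frame(subject_id = sprintf("s%03d", 1:12),
                       bis_score = rnorm(12, 65, 10),
                       oci_score = rnorm(12, 12, 8))
  fit <- fit_stay_glmm(build_stay_design(behs, traits), nAGQ = 0)
  tab <- fit$table
  rew <- tab[tab$term == "reward_prev", ]
  expect_gt(rew$beta, 1)                    # odds ratio above 1
  expect_lt(rew$p, 0.05)
})

test_that("the RT-delta marker recovers the generator's rare slowing", {
  cfg <- task_config(n_trials = 300, rare_slowing_ms = 30, rt_sdlog = 0.2)
  set.seed(205)
  deltas <- vapply(1:25, function(i)
    rt_delta(simulate_subject(agent_params(0.5, 0.5, 3, 0.5), cfg)),
    numeric(1))
  expect_equal(mean(deltas), 30, tolerance = 0.35)  # within ~10 ms
  # trivial cases
  tr <- fixture_trials(); tr$rt2_ms <- c(400, 400, 400)
  expect_equal(rt_delta(as_behavior(tr)), 0)
  tr$rt2_ms <- c(400, 500, 650)   # single rare trial (the third)
  expect_equal(rt_delta(as_behavior(tr)), 650 - 450)
  tr$transition <- rep("common", 3)
  expect_true(is.na(rt_delta(as_behavior(tr))))
})

test_that("the cohort RT regression runs and finds no spurious links", {
  cfg <- task_config(n_trials = 200)
  set.seed(206)
  deltas <- vapply(1:24, function(i)
    rt_delta(simulate_subject(agent_params(0.5, 0.5, 3, 0.5), cfg)),
    numeric(1))
  names(deltas) <- sprintf("s%03d", 1:24)
  traits <- data.frame(subject_id = names(deltas),
                       bis_score = rnorm(24, 65, 10),
                       oci_score = rnorm(24, 12, 8))
  tab <- rt_delta_regression(deltas, traits)
  expect_equal(tab$term, c("(Intercept)", "bis", "oci", "bis:oci"))
  # traits were drawn independently of RT: coefficients near zero
  expect_true(all(abs(tab$beta[-1]) < 2.5 * tab$se[-1] + 1e-9 |
                    tab$p[-1] > 0.01))
})
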