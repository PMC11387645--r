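#' Two-step task configuration
#'
#' Defines the environment of the two-step sequential decision task: 500
#' trials in which a first-stage choice between two spaceships leads, with
#' probability \code{p_common} = 0.8, to that spaceship's preferred planet
#' (common transition) and otherwise to the other planet (rare transition).
#' Each second-stage action pays an integer number of points that drifts
#' over trials as a random walk with reflective bounds at
#' \code{reward_min} = -4 and \code{reward_max} = +5.
#'
#' Synthetic response times are drawn from a log-normal distribution with
#' an additive slowing on rare-transition trials (stage 2), emulating the
#' orienting response used by the RT-delta marker of model-based control.
#'
#' @param n_trials number of trials (default 500, played as 4 blocks of 125;
#'   the block structure is metadata only).
#' @param p_common probability of the common transition, in (0.5, 1].
#' @param reward_min,reward_max reflective bounds of the point walk.
#' @param walk_step integer step size of the point walk.
#' @param walk_step_prob per-trial probability that each of the four
#'   second-stage payoffs moves.
#' @param response_window_ms maximal response time.
#' @param rt_meanlog,rt_sdlog log-normal RT parameters (ms scale).
#' @param rare_slowing_ms additive stage-2 slowing on rare trials, ms.
#' @param p_fast probability that a trial is given an artificially fast
#'   (< 100 ms) response, to exercise the preliminary-response filter.
#' @param p_miss probability that a trial is recorded as missed (no
#'   response; excluded from likelihood and analyses).
#' @return an object of class \code{task_config}.
#' @export
task_config <- function(n_trials = 500L, p_common = 0.8,
                        reward_min = -4L, reward_max = 5L,
                        walk_step = 1L, walk_step_prob = 0.2,
                        response_window_ms = 2000,
                        rt_meanlog = log(450), rt_sdlog = 0.25,
                        rare_slowing_ms = 30,
                        p_fast = 0, p_miss = 0) {
  stopifnot(n_trials > 0, p_common > 0.5, p_common <= 1,
            reward_min < 0, reward_max > 0,
            walk_step > 0, walk_step_prob >= 0, walk_step_prob <= 1,
            p_fast >= 0, p_fast < 1, p_miss >= 0, p_miss < 1)
  structure(list(n_trials = as.integer(n_trials), p_common = p_common,
                 reward_min = as.integer(reward_min),
                 reward_max = as.integer(reward_max),
                 walk_step = as.integer(walk_step),
                 walk_step_prob = walk_step_prob,
                 response_window_ms = response_window_ms,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rare_slowing_ms = rare_slowing_ms,
                 p_fast = p_fast, p_miss = p_miss),
            class = "task_config")
}

# stage-2 states are indexed 1 = "B", 2 = "C"; action 0 prefers B, action 1
# prefers C (the instructed, fixed spaceship-planet mapping)
preferred_stage <- function(a1) ifelse(a1 == 0L, 1L, 2L)

#' Sample the stage-1 to stage-2 transition
#'
#' With probability \code{p_common} the chosen action leads to its preferred
#' planet; otherwise to the other planet. Vectorized over \code{a1}; draws
#' come from the R random number generator (seed with \code{set.seed}).
#'
#' @param a1 stage-1 action(s), 0 or 1.
#' @param cfg a \code{\link{task_config}}.
#' @return a data.frame with columns \code{s2} ("B" or "C") and
#'   \code{transition} ("common" or "rare").
#' @export
sample_transition <- function(a1, cfg = task_config()) {
  if (!all(a1 %in% c(0L, 1L))) stop("a1 must be 0 or 1")
  pref <- preferred_stage(a1)
  common <- stats::runif(length(a1)) < cfg$p_common
  s2i <- ifelse(common, pref, 3L - pref)
  data.frame(s2 = c("B", "C")[s2i],
             transition = ifelse(common, "common", "rare"),
             stringsAsFactors = FALSE)
}

#' Advance the second-stage point walk one trial
#'
#' Each of the four (stage-2 state, action) payoffs independently moves by
#' \code{walk_step} up or down with probability \code{walk_step_prob}, and
#' any excursion past \code{reward_min}/\code{reward_max} is reflected back
#' inside the bounds.
#'
#' @param rewards 2 x 2 integer matrix of payoffs, rows = stages B and C,
#'   columns = actions 0 and 1.
#' @param cfg a \code{\link{task_config}}.
#' @return updated 2 x 2 payoff matrix.
#' @export
step_reward_walk <- function(rewards, cfg = task_config()) {
  if (any(rewards < cfg$reward_min | rewards > cfg$reward_max))
    stop("rewards outside the configured bounds")
  move <- stats::runif(4) < cfg$walk_step_prob
  dir <- sample(c(-1L, 1L), 4, replace = TRUE)
  r <- rewards + move * dir * cfg$walk_step
  # reflect at the bounds
  r[r > cfg$reward_max] <- 2L * cfg$reward_max - r[r > cfg$reward_max]
  r[r < cfg$reward_min] <- 2L * cfg$reward_min - r[r < cfg$reward_min]
  r
}

#' Simulate one subject playing the two-step task
#'
#' A hybrid SARSA(lambda) agent (see \code{\link{agent_params}}) plays
#' \code{cfg$n_trials} trials: stage-1 and stage-2 actions are sampled from
#' \code{\link{choice_probabilities}}, transitions from
#' \code{\link{sample_transition}}, and points from the reflective reward
#' walk. Q-values are updated after every trial with the same equations used
#' for likelihood evaluation, so the recorded generative prediction errors
#' equal those recovered by \code{\link{sequence_loglik}} at the true
#' parameters. Rewards enter the value update on the fitting scale
#' (points / \code{reward_max}).
#'
#' @param params an \code{\link{agent_params}} object.
#' @param cfg a \code{\link{task_config}}.
#' @param variant model variant label (see \code{\link{model_variants}});
#'   parameters that the variant fixes must be at their fixed values.
#' @param subject_id subject label.
#' @return a \code{subject_behavior} object: a data.frame of trials with
#'   columns \code{trial}, \code{a1}, \code{s2}, \code{transition},
#'   \code{a2}, \code{reward_points}, \code{rt1_ms}, \code{rt2_ms},
#'   \code{rpe} (generative delta2, fitting scale), plus attributes
#'   \code{subject_id} and \code{params}.
#' @export
simulate_subject <- function(params, cfg = task_config(),
                             variant = "hybrid_choice",
                             subject_id = "s01") {
  check_variant_params(params, variant)
  n <- cfg$n_trials
  q <- matrix(0, 3, 2)                       # rows sA, sB, sC
  pay <- matrix(sample(cfg$reward_min:cfg$reward_max, 4, replace = TRUE),
                2, 2)
  out <- data.frame(trial = seq_len(n) - 1L, a1 = NA_integer_,
                    s2 = NA_character_, transition = NA_character_,
                    a2 = NA_integer_, reward_points = NA_integer_,
                    rt1_ms = NA_real_, rt2_ms = NA_real_, rpe = NA_real_,
                    stringsAsFactors = FALSE)
  prev_a1 <- NA_integer_
  for (t in seq_len(n)) {
    missed <- cfg$p_miss > 0 && stats::runif(1) < cfg$p_miss
    if (!missed) {
      qmb <- mb_values(q, cfg$p_common)
      qnet <- hybrid_values(qmb, q[1, ], params$w)
      p1 <- choice_probabilities(qnet, params$beta, params$pi, params$rho,
                                 prev_choice = prev_a1, prev_key = prev_a1)
      a1 <- (stats::runif(1) < p1[2]) * 1L
      tr <- sample_transition(a1, cfg)
      s2i <- if (tr$s2 == "B") 2L else 3L
      p2 <- choice_probabilities(q[s2i, ], params$beta)
      a2 <- (stats::runif(1) < p2[2]) * 1L
      pts <- pay[s2i - 1L, a2 + 1L]
      r <- pts / cfg$reward_max
      d1 <- q[s2i, a2 + 1L] - q[1, a1 + 1L]
      d2 <- r - q[s2i, a2 + 1L]
      q[1, a1 + 1L] <- q[1, a1 + 1L] + params$alpha * d1 +
        params$alpha * params$lam * d2
      q[s2i, a2 + 1L] <- q[s2i, a2 + 1L] + params$alpha * d2
      rare <- tr$transition == "rare"
      rt1 <- stats::rlnorm(1, cfg$rt_meanlog, cfg$rt_sdlog)
      rt2 <- stats::rlnorm(1, cfg$rt_meanlog, cfg$rt_sdlog) +
        if (rare) cfg$rare_slowing_ms else 0
      if (cfg$p_fast > 0 && stats::runif(1) < cfg$p_fast)
        rt2 <- stats::runif(1, 10, 99)
      out$a1[t] <- a1; out$s2[t] <- tr$s2; out$transition[t] <- tr$transition
      out$a2[t] <- a2; out$reward_points[t] <- pts
      out$rt1_ms[t] <- rt1; out$rt2_ms[t] <- rt2; out$rpe[t] <- d2
      prev_a1 <- a1
    } else {
      prev_a1 <- NA_integer_                 # missed trial resets stickiness
    }
    pay <- step_reward_walk(pay, cfg)
    stopifnot(all(pay >= cfg$reward_min & pay <= cfg$reward_max))
  }
  structure(out, subject_id = subject_id, params = params,
            class = c("subject_behavior", "data.frame"))
}

#' @method print subject_behavior
#' @export
print.subject_behavior <- function(x, ...) {
  cat("<subject_behavior> ", attr(x, "subject_id"), ": ",
      nrow(x), " trials, ",
      sum(!is.na(x$a1)), " with responses\n", sep = "")
  invisible(x)
}

#' Write / read a behavioral trial table
#'
#' The on-disk format is a plain CSV with one row per trial and columns
#' \code{subject_id, trial, a1, s2, transition, a2, reward_points, rt1_ms,
#' rt2_ms} (transition as literal "common"/"rare"). Multiple subjects are
#' stacked.
#'
#' @param behaviors a \code{subject_behavior} or list of them.
#' @param path file path.
#' @export
write_behavior_csv <- function(behaviors, path) {
  if (inherits(behaviors, "subject_behavior")) behaviors <- list(behaviors)
  rows <- lapply(behaviors, function(b) {
    cbind(subject_id = attr(b, "subject_id"),
          as.data.frame(b)[, c("trial", "a1", "s2", "transition", "a2",
                               "reward_points", "rt1_ms", "rt2_ms")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @return \code{read_behavior_csv}: a named list of
#'   \code{subject_behavior} objects.
#' @export
read_behavior_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "a1", "s2", "transition", "a2",
            "reward_points", "rt1_ms", "rt2_ms")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sp <- split(d, d$subject_id)
  out <- lapply(names(sp), function(id) {
    b <- sp[[id]][order(sp[[id]]$trial), setdiff(need, "subject_id")]
    rownames(b) <- NULL
    structure(b, subject_id = id,
              class = c("subject_behavior", "data.frame"))
  })
  names(out) <- names(sp)
  out
}
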