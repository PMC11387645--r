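#' Free parameters of one reinforcement-learning model variant
#'
#' The hybrid model family has up to six free parameters: learning rate
#' \code{alpha} in [0,1], eligibility-trace decay \code{lam} in [0,1],
#' softmax inverse temperature \code{beta} >= 0, model-based weight
#' \code{w} in [0,1] (0 = pure model-free, 1 = pure model-based), choice
#' stickiness \code{pi} (bonus for repeating the previous stage-1 stimulus)
#' and response stickiness \code{rho} (bonus for repeating the previous
#' response key), both unbounded reals.
#'
#' @param alpha,lam,beta,w,pi,rho numeric scalars, see Description.
#' @return an \code{agent_params} list.
#' @export
agent_params <- function(alpha, lam = 0, beta, w = 0, pi = 0, rho = 0) {
  stopifnot(alpha >= 0, alpha <= 1, lam >= 0, lam <= 1,
            beta >= 0, w >= 0, w <= 1,
            is.finite(pi), is.finite(rho))
  structure(list(alpha = alpha, lam = lam, beta = beta, w = w,
                 pi = pi, rho = rho), class = "agent_params")
}

#' The nine model variants: 3 families x 3 stickiness levels
#'
#' Families fix the model-based weight (\code{mf}: w = 0, \code{mb}: w = 1,
#' \code{hybrid}: w free). Stickiness levels are \code{pure} (pi = rho = 0),
#' \code{choice} (rho = 0) and \code{choice_response} (both free). The
#' eligibility trace lam is free for mf and hybrid; for pure model-based
#' agents stage-1 model-free values never influence choice, so lam is fixed
#' at 0 and not counted as a free parameter.
#'
#' @return character vector of the nine variant labels.
#' @export
model_variants <- function() {
  as.vector(outer(c("mf", "mb", "hybrid"),
                  c("pure", "choice", "choice_response"), paste, sep = "_"))
}

#' @rdname model_variants
#' @param variant a variant label.
#' @return \code{variant_free_params}: names of the variant's free
#'   parameters, in canonical order.
#' @export
variant_free_params <- function(variant) {
  parts <- strsplit(variant, "_", fixed = TRUE)[[1]]
  family <- parts[1]
  stick <- paste(parts[-1], collapse = "_")
  if (!family %in% c("mf", "mb", "hybrid") ||
      !stick %in% c("pure", "choice", "choice_response"))
    stop("unknown model variant: ", variant)
  p <- c("alpha", if (family != "mb") "lam", "beta",
         if (family == "hybrid") "w",
         if (stick != "pure") "pi",
         if (stick == "choice_response") "rho")
  p
}

check_variant_params <- function(params, variant) {
  free <- variant_free_params(variant)
  fixed <- list(w = if (grepl("^mf", variant)) 0 else
                  if (grepl("^mb", variant)) 1 else NULL,
                lam = if (grepl("^mb", variant)) 0 else NULL,
                pi = if (!("pi" %in% free)) 0 else NULL,
                rho = if (!("rho" %in% free)) 0 else NULL)
  for (nm in names(fixed)) {
    if (!is.null(fixed[[nm]]) && params[[nm]] != fixed[[nm]])
      stop("parameter ", nm, " must equal ", fixed[[nm]],
           " for variant ", variant)
  }
  invisible(TRUE)
}

#' SARSA(lambda) model-free value update for one trial
#'
#' Computes the two signed prediction errors with pre-update values and
#' applies the eligibility-weighted updates at the second stage: the
#' stage-1 prediction error delta1 = Q(s2, a2) - Q(s1, a1) (stage-1 reward
#' is always zero), the stage-2 prediction error delta2 = r - Q(s2, a2),
#' and the updates Q(s1, a1) += alpha * delta1 + alpha * lam * delta2 and
#' Q(s2, a2) += alpha * delta2. With lam = 0 only the current stage's value
#' learns from the outcome. Unvisited (state, action) pairs are unchanged.
#'
#' @param q 3 x 2 value matrix, rows = states (sA, sB, sC), columns =
#'   actions (0, 1).
#' @param a1,a2 chosen actions, 0 or 1.
#' @param s2 realized second stage, "B" or "C".
#' @param reward outcome on the fitting scale.
#' @param alpha,lam learning rate and eligibility decay.
#' @return list with \code{q} (updated matrix), \code{delta1},
#'   \code{delta2}.
#' @export
mf_update <- function(q, a1, s2, a2, reward, alpha, lam) {
  s2i <- if (s2 == "B") 2L else if (s2 == "C") 3L else
    stop("s2 must be 'B' or 'C'")
  d1 <- q[s2i, a2 + 1L] - q[1L, a1 + 1L]
  d2 <- reward - q[s2i, a2 + 1L]
  q[1L, a1 + 1L] <- q[1L, a1 + 1L] + alpha * d1 + alpha * lam * d2
  q[s2i, a2 + 1L] <- q[s2i, a2 + 1L] + alpha * d2
  list(q = q, delta1 = d1, delta2 = d2)
}

#' Model-based stage-1 values from the instructed transition structure
#'
#' Q_MB(sA, a) = P(sB | a) max_a' Q(sB, a') + P(sC | a) max_a' Q(sC, a'),
#' using the true transition matrix (action 0 reaches B with probability
#' \code{p_common}, action 1 reaches C with that probability).
#'
#' @param q 3 x 2 value matrix as in \code{\link{mf_update}}.
#' @param p_common common-transition probability in (0.5, 1].
#' @return numeric length-2 vector of model-based values for actions 0, 1.
#' @export
mb_values <- function(q, p_common) {
  stopifnot(p_common > 0.5, p_common <= 1)
  mB <- max(q[2L, ]); mC <- max(q[3L, ])
  c(p_common * mB + (1 - p_common) * mC,
    (1 - p_common) * mB + p_common * mC)
}

#' Hybrid arbitration between model-based and model-free values
#'
#' Qnet = w * Q_MB + (1 - w) * Q_MF, elementwise.
#'
#' @param q_mb,q_mf_stage1 length-2 value vectors.
#' @param w model-based weight in [0, 1].
#' @return length-2 net value vector.
#' @export
hybrid_values <- function(q_mb, q_mf_stage1, w) {
  stopifnot(w >= 0, w <= 1)
  w * q_mb + (1 - w) * q_mf_stage1
}

#' Softmax choice rule with choice and response stickiness
#'
#' P(a) is proportional to exp(beta * (Qnet(a) + pi * rep(a) +
#' rho * resp(a))), where rep(a) = 1 if stage-1 action a was chosen on the
#' previous trial and resp(a) = 1 if action a uses the previous trial's
#' response key. Both indicators are 0 on the first trial (pass \code{NA}).
#' Computed via log-sum-exp, so it is stable for large beta.
#'
#' @param qnet net values of the available actions (length 2).
#' @param beta inverse temperature, >= 0.
#' @param pi,rho stickiness bonuses (stage 1 only; leave 0 at stage 2).
#' @param prev_choice previous stage-1 action (0/1) or NA.
#' @param prev_key previous response key (0/1) or NA.
#' @param key_of_action key assigned to each action this trial; with the
#'   default fixed stimulus positions action a uses key a.
#' @return probability vector over actions, summing to 1.
#' @export
choice_probabilities <- function(qnet, beta, pi = 0, rho = 0,
                                 prev_choice = NA, prev_key = NA,
                                 key_of_action = c(0L, 1L)) {
  if (beta < 0) stop("beta must be non-negative")
  a <- seq_along(qnet) - 1L
  rep_a <- as.numeric(!is.na(prev_choice) & a == prev_choice)
  resp_a <- as.numeric(!is.na(prev_key) & key_of_action == prev_key)
  v <- beta * (qnet + pi * rep_a + rho * resp_a)
  v <- v - max(v)
  exp(v) / sum(exp(v))
}

#' Sequence log-likelihood and trial-wise prediction errors
#'
#' Walks a subject's trial sequence in order, accumulating the log
#' probability of both stage choices under the given parameters and model
#' variant, with Q-values updated after each trial. The returned
#' \code{delta2} series is the signed reward prediction error used
#' downstream as the single-trial EEG regressor. Rewards are scaled by
#' \code{reward_scale} before entering the update (default: 1 /
#' \code{reward_max}, mapping points into [-0.8, 1]).
#'
#' Trials with missing responses contribute no likelihood; they reset the
#' stickiness indicators while Q-values are carried forward.
#'
#' @param params an \code{\link{agent_params}}.
#' @param behavior a \code{subject_behavior} (or compatible data.frame).
#' @param cfg a \code{\link{task_config}}.
#' @param variant model variant label.
#' @param reward_scale multiplier applied to points.
#' @param engine "cpp" (compiled fast path, total log-likelihood only) or
#'   "R" (reference implementation with per-trial detail).
#' @return list with \code{loglik} (total), \code{n_obs} (number of choice
#'   observations) and, for the R engine, \code{trials}: a data.frame with
#'   \code{loglik1}, \code{loglik2}, \code{delta1}, \code{delta2}.
#' @export
sequence_loglik <- function(params, behavior, cfg = task_config(),
                            variant = "hybrid_choice",
                            reward_scale = 1 / cfg$reward_max,
                            engine = c("R", "cpp")) {
  engine <- match.arg(engine)
  check_variant_params(params, variant)
  valid <- !is.na(behavior$a1) & !is.na(behavior$a2)
  if (engine == "cpp") {
    ll <- cpp_sequence_loglik(
      as.double(c(params$alpha, params$lam, params$beta, params$w,
                  params$pi, params$rho)),
      as.integer(behavior$a1), as.integer(behavior$s2 == "C"),
      as.integer(behavior$a2),
      as.double(behavior$reward_points * reward_scale),
      as.integer(valid), cfg$p_common)
    return(list(loglik = ll, n_obs = 2L * sum(valid)))
  }
  q <- matrix(0, 3, 2)
  n <- nrow(behavior)
  ll1 <- ll2 <- d1v <- d2v <- rep(NA_real_, n)
  prev_a1 <- NA_integer_
  for (t in seq_len(n)) {
    if (!valid[t]) { prev_a1 <- NA_integer_; next }
    a1 <- behavior$a1[t]; a2 <- behavior$a2[t]; s2 <- behavior$s2[t]
    qmb <- mb_values(q, cfg$p_common)
    qnet <- hybrid_values(qmb, q[1, ], params$w)
    p1 <- choice_probabilities(qnet, params$beta, params$pi, params$rho,
                               prev_choice = prev_a1, prev_key = prev_a1)
    s2i <- if (s2 == "B") 2L else 3L
    p2 <- choice_probabilities(q[s2i, ], params$beta)
    ll1[t] <- log(p1[a1 + 1L]); ll2[t] <- log(p2[a2 + 1L])
    upd <- mf_update(q, a1, s2, a2, behavior$reward_points[t] * reward_scale,
                     params$alpha, params$lam)
    q <- upd$q; d1v[t] <- upd$delta1; d2v[t] <- upd$delta2
    # at stage 2 the model-based and model-free values coincide by
    # construction (updates are shared); guarded here as an invariant
    prev_a1 <- a1
  }
  total <- sum(ll1, na.rm = TRUE) + sum(ll2, na.rm = TRUE)
  if (!is.finite(total)) stop("non-finite log-likelihood at trial ",
                              which(!is.finite(ll1 + ll2))[1])
  list(loglik = total, n_obs = 2L * sum(valid),
       trials = data.frame(trial = behavior$trial, loglik1 = ll1,
                           loglik2 = ll2, delta1 = d1v, delta2 = d2v))
}

#' Export a subject's signed RPE series
#'
#' Writes the per-trial stage-2 prediction errors (column \code{rpe})
#' aligned to trial index, for joining with EEG epoch metadata.
#'
#' @param behavior a \code{subject_behavior}.
#' @param params parameters at which to evaluate the series.
#' @param path file path.
#' @inheritParams sequence_loglik
#' @export
write_rpe_csv <- function(behavior, params, path, cfg = task_config(),
                          variant = "hybrid_choice") {
  sl <- sequence_loglik(params, behavior, cfg, variant, engine = "R")
  utils::write.csv(data.frame(subject_id = attr(behavior, "subject_id"),
                              trial = behavior$trial,
                              rpe = sl$trials$delta2),
                   path, row.names = FALSE)
  invisible(path)
}
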