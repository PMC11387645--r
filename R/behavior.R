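#' Screen out random responders
#'
#' A subject is retained only if stay probability is positively associated
#' with the previous trial's reward or with the reward-by-transition
#' interaction in a per-subject logistic regression
#' (stay ~ reward_prev + reward_prev:transition_prev), i.e. at least one of
#' the two coefficients is positive with one-sided p < \code{alpha}.
#' Complete separation (a perfectly reward-driven chooser) makes the Wald
#' test uninformative; such subjects are kept when the diverging
#' coefficient is positive, and flagged.
#'
#' @param behavior a \code{subject_behavior}.
#' @param alpha one-sided significance threshold (default 0.05).
#' @return list: \code{keep} (logical), \code{reward_coef},
#'   \code{interaction_coef}, one-sided \code{reward_p},
#'   \code{interaction_p}, \code{separation} flag.
#' @export
screen_random_responder <- function(behavior, alpha = 0.05) {
  d <- stay_rows(behavior)
  if (nrow(d) < 2) stop("need at least 2 trials")
  fit <- suppressWarnings(
    stats::glm(stay ~ reward_prev + reward_prev:transition_prev,
               family = stats::binomial(), data = d,
               control = list(maxit = 100)))
  co <- summary(fit)$coefficients
  get <- function(term) {
    if (!term %in% rownames(co)) return(c(NA_real_, NA_real_))
    c(co[term, "Estimate"], stats::pnorm(-co[term, "z value"]))
  }
  rw <- get("reward_prev")
  ix <- get("reward_prev:transition_prev")
  sep <- any(abs(stats::fitted(fit)) > 1 - 1e-8 |
               stats::fitted(fit) < 1e-8) && any(abs(co[, 1]) > 10)
  keep <- isTRUE(rw[1] > 0 && rw[2] < alpha) ||
    isTRUE(ix[1] > 0 && ix[2] < alpha) ||
    (sep && (isTRUE(rw[1] > 10) || isTRUE(ix[1] > 10)))
  list(keep = keep, reward_coef = rw[1], interaction_coef = ix[1],
       reward_p = rw[2], interaction_p = ix[2], separation = sep)
}

# per-trial stay rows with the +/-1 coding of the previous trial's reward
# (points > 0 -> +1) and transition (common -> +1); first trial dropped.
# Missed trials break the stay chain on both sides.
stay_rows <- function(behavior) {
  b <- as.data.frame(behavior)
  n <- nrow(b)
  if (n < 2) return(data.frame())
  cur <- 2:n; prev <- 1:(n - 1)
  ok <- !is.na(b$a1[cur]) & !is.na(b$a1[prev])
  data.frame(trial = b$trial[cur][ok],
             stay = as.integer(b$a1[cur][ok] == b$a1[prev][ok]),
             reward_prev = ifelse(b$reward_points[prev][ok] > 0, 1, -1),
             transition_prev = ifelse(b$transition[prev][ok] == "common",
                                      1, -1))
}

#' Build the stay-probability design table
#'
#' One row per trial from the second onward, with the previous trial's
#' reward and transition coded +1/-1 (reward yes/common: +1) and BIS-11 and
#' OCI-R sum scores z-standardized across the included subjects. Subjects
#' with missing trait scores are dropped listwise with a warning.
#'
#' @param behaviors list of \code{subject_behavior} objects.
#' @param traits data.frame with columns \code{subject_id},
#'   \code{bis_score}, \code{oci_score} and optionally \code{gender}
#'   (coded to +/-0.5 when present).
#' @return a \code{stay_design} data.frame with attribute \code{formula}
#'   describing the intended mixed model.
#' @export
build_stay_design <- function(behaviors, traits) {
  ids <- vapply(behaviors, function(b) attr(b, "subject_id"), character(1))
  traits <- traits[match(ids, traits$subject_id), , drop = FALSE]
  ok <- !is.na(traits$bis_score) & !is.na(traits$oci_score)
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " subject(s) with missing trait scores")
    behaviors <- behaviors[ok]; traits <- traits[ok, ]; ids <- ids[ok]
  }
  bis_z <- as.numeric(scale(traits$bis_score))
  oci_z <- as.numeric(scale(traits$oci_score))
  gender <- if ("gender" %in% names(traits))
    ifelse(traits$gender == traits$gender[1], 0.5, -0.5) else NULL
  rows <- lapply(seq_along(behaviors), function(i) {
    d <- stay_rows(behaviors[[i]])
    if (!nrow(d)) return(NULL)
    d$subject_id <- ids[i]; d$bis_z <- bis_z[i]; d$oci_z <- oci_z[i]
    if (!is.null(gender)) d$gender_code <- gender[i]
    d
  })
  out <- do.call(rbind, rows)
  f <- "stay ~ transition_prev * reward_prev * bis_z * oci_z + (transition_prev * reward_prev | subject_id)"
  structure(out, formula = f, class = c("stay_design", "data.frame"))
}

#' Fit the stay-probability generalized linear mixed model
#'
#' Delegates to \code{lme4::glmer} with the full four-way fixed-effect
#' design (previous transition x previous reward x BIS x OCI, plus gender
#' when present) and by-subject random slopes for transition, reward and
#' their interaction. Fixed effects are reported exponentiated (odds
#' ratios). On non-convergence the random structure is simplified to a
#' random intercept and the refit is flagged.
#'
#' @param design a \code{stay_design}.
#' @param nAGQ passed to \code{glmer}; 0 uses the faster penalized
#'   least-squares approximation, adequate for the effect signs and odds
#'   ratios examined here.
#' @return list: \code{table} (data.frame with exponentiated \code{beta},
#'   \code{se}, \code{t}, \code{p} per term), \code{simplified} flag,
#'   \code{fit} (the merMod).
#' @export
fit_stay_glmm <- function(design, nAGQ = 1) {
  fixed <- "transition_prev * reward_prev * bis_z * oci_z"
  if ("gender_code" %in% names(design))
    fixed <- paste(fixed, "+ gender_code")
  full <- stats::as.formula(paste(
    "stay ~", fixed, "+ (transition_prev * reward_prev | subject_id)"))
  simple <- stats::as.formula(paste("stay ~", fixed, "+ (1 | subject_id)"))
  try_fit <- function(f) tryCatch(
    lme4::glmer(f, data = design, family = stats::binomial(), nAGQ = nAGQ),
    error = function(e) NULL, warning = function(w) NULL)
  fit <- try_fit(full); simplified <- FALSE
  if (is.null(fit)) { fit <- try_fit(simple); simplified <- TRUE }
  if (is.null(fit)) stop("stay GLMM failed to converge in both structures")
  co <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(co), beta = exp(co[, "Estimate"]),
                    se = co[, "Std. Error"], t = co[, "z value"],
                    p = co[, "Pr(>|z|)"], row.names = NULL)
  list(table = tab, simplified = simplified, fit = fit)
}

#' Reaction-time marker of model-based control
#'
#' Median stage-2 RT on rare-transition trials minus the median on
#' common-transition trials; surprise-driven slowing after rare transitions
#' indexes a mental representation of the transition structure.
#'
#' @param behavior a \code{subject_behavior}.
#' @param stage 2 (default) or 1; which response's RT to use.
#' @return milliseconds, or NA when a transition type has no valid trial.
#' @export
rt_delta <- function(behavior, stage = 2) {
  rt <- if (stage == 2) behavior$rt2_ms else behavior$rt1_ms
  ok <- !is.na(rt) & !is.na(behavior$transition)
  rare <- rt[ok & behavior$transition == "rare"]
  common <- rt[ok & behavior$transition == "common"]
  if (!length(rare) || !length(common)) return(NA_real_)
  stats::median(rare) - stats::median(common)
}

#' Cohort-level robust regression of the RT marker on traits
#'
#' Huber robust regression of per-subject RT deltas on z-scored BIS-11,
#' OCI-R and their interaction; subjects with missing deltas are dropped.
#'
#' @param deltas named numeric vector of per-subject
#'   \code{\link{rt_delta}} values (names = subject ids).
#' @param traits trait data.frame as in \code{\link{build_stay_design}}.
#' @return coefficient table from \code{\link{huber_lm}}.
#' @export
rt_delta_regression <- function(deltas, traits) {
  traits <- traits[match(names(deltas), traits$subject_id), ]
  ok <- !is.na(deltas)
  bis <- as.numeric(scale(traits$bis_score))[ok]
  oci <- as.numeric(scale(traits$oci_score))[ok]
  X <- cbind(`(Intercept)` = 1, bis = bis, oci = oci,
             `bis:oci` = bis * oci)
  huber_lm(X, deltas[ok])
}
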