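#' Parameter bounds and transforms for maximum-likelihood fitting
#'
#' Unit-interval parameters (alpha, lam, w) are optimized on the logit
#' scale, beta on the log scale (upper bound 20), and the stickiness
#' parameters pi and rho on the identity scale. Optimizing in the
#' transformed space honors the bounds without a constrained solver.
#'
#' @return a data.frame with one row per parameter: \code{lower},
#'   \code{upper}, \code{transform}.
#' @export
parameter_bounds <- function() {
  data.frame(param = c("alpha", "lam", "beta", "w", "pi", "rho"),
             lower = c(0, 0, 1e-6, 0, -5, -5),
             upper = c(1, 1, 20, 1, 5, 5),
             transform = c("logit", "logit", "log", "logit",
                           "identity", "identity"),
             stringsAsFactors = FALSE)
}

to_unconstrained <- function(x, transform) {
  switch(transform,
         logit = stats::qlogis(pmin(pmax(x, 1e-9), 1 - 1e-9)),
         log = log(pmax(x, 1e-12)),
         identity = x)
}

to_constrained <- function(z, transform, upper = Inf) {
  switch(transform,
         logit = stats::plogis(z),
         log = pmin(exp(z), upper),
         identity = z)
}

params_from_free <- function(theta, variant) {
  free <- variant_free_params(variant)
  pb <- parameter_bounds()
  full <- c(alpha = NA_real_, lam = 0, beta = NA_real_,
            w = if (grepl("^mf", variant)) 0 else
              if (grepl("^mb", variant)) 1 else NA_real_,
            pi = 0, rho = 0)
  for (i in seq_along(free)) {
    row <- pb[pb$param == free[i], ]
    full[free[i]] <- to_constrained(theta[i], row$transform, row$upper)
  }
  agent_params(full["alpha"], full["lam"], full["beta"], full["w"],
               full["pi"], full["rho"])
}

random_start <- function(variant) {
  free <- variant_free_params(variant)
  pb <- parameter_bounds()
  vapply(free, function(p) {
    row <- pb[pb$param == p, ]
    x <- switch(p,
                alpha = stats::runif(1, 0.1, 0.9),
                lam = stats::runif(1, 0.1, 0.9),
                beta = exp(stats::runif(1, log(0.5), log(10))),
                w = stats::runif(1, 0.1, 0.9),
                pi = stats::rnorm(1, 0, 0.5),
                rho = stats::rnorm(1, 0, 0.5))
    to_unconstrained(x, row$transform)
  }, numeric(1))
}

#' Bayesian Information Criterion
#'
#' BIC = k * ln(n_obs) - 2 * loglik, where n_obs counts every retained
#' choice observation (two per complete trial).
#'
#' @param loglik total log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n_obs number of choice observations.
#' @export
bic <- function(loglik, k, n_obs) {
  if (n_obs < 1) stop("n_obs must be at least 1")
  k * log(n_obs) - 2 * loglik
}

#' Fit one subject's trial sequence by maximum likelihood
#'
#' Maximizes \code{\link{sequence_loglik}} over the variant's free
#' parameters in transformed space (BFGS, numerical gradients) from
#' \code{n_restarts} random starts, keeping the best optimum. The signed
#' RPE series at the optimum is attached for downstream EEG analysis.
#' With the same \code{seed} the fit is fully reproducible.
#'
#' @param behavior a \code{subject_behavior} with at least
#'   \code{min_trials} valid trials.
#' @param variant model variant label (see \code{\link{model_variants}}).
#' @param cfg a \code{\link{task_config}}.
#' @param n_restarts number of random optimizer starts (default 20).
#' @param seed optional integer seed controlling the starts.
#' @param min_trials floor on valid trials (default 50).
#' @param reward_scale reward multiplier, see \code{\link{sequence_loglik}}.
#' @return a \code{fit_result} list: \code{variant}, \code{params},
#'   \code{loglik}, \code{n_obs}, \code{k}, \code{bic},
#'   \code{n_restarts_converged}, \code{rpe_series}, and a
#'   \code{flat_likelihood} diagnostic flag (restart optima spread below
#'   tolerance while beta is pinned near 0).
#' @export
fit_subject <- function(behavior, variant = "hybrid_choice",
                        cfg = task_config(), n_restarts = 20, seed = NULL,
                        min_trials = 50, reward_scale = 1 / cfg$reward_max) {
  valid <- !is.na(behavior$a1) & !is.na(behavior$a2)
  if (sum(valid) < min_trials)
    stop("fewer than ", min_trials, " valid trials")
  free <- variant_free_params(variant)
  a1 <- as.integer(behavior$a1); s2c <- as.integer(behavior$s2 == "C")
  a2 <- as.integer(behavior$a2)
  rew <- as.double(behavior$reward_points * reward_scale)
  vld <- as.integer(valid)
  # fast theta -> (alpha, lam, beta, w, pi, rho) mapping for the optimizer
  pb <- parameter_bounds()
  idx <- match(free, pb$param)
  logit_i <- which(pb$transform[idx] == "logit")
  log_i <- which(pb$transform[idx] == "log")
  upper <- pb$upper[idx]
  base <- c(alpha = NA_real_, lam = 0,  beta = NA_real_,
            w = if (grepl("^mf", variant)) 0 else
              if (grepl("^mb", variant)) 1 else NA_real_,
            pi = 0, rho = 0)
  pos <- match(free, names(base))
  theta_to_par <- function(theta) {
    x <- theta
    x[logit_i] <- stats::plogis(x[logit_i])
    x[log_i] <- pmin(exp(x[log_i]), upper[log_i])
    p <- base; p[pos] <- x
    p
  }
  negll <- function(theta)
    -cpp_sequence_loglik(theta_to_par(theta), a1, s2c, a2, rew, vld,
                         cfg$p_common)
  runner <- function() {
    best <- NULL; conv <- 0L; optima <- numeric(0)
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        stats::optim(random_start(variant), negll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      conv <- conv + as.integer(fit$convergence == 0)
      optima <- c(optima, -fit$value)
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    list(best = best, conv = conv, optima = optima)
  }
  res <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  if (is.null(res$best)) stop("all ", n_restarts, " restarts failed")
  params <- params_from_free(res$best$par, variant)
  sl <- sequence_loglik(params, behavior, cfg, variant,
                        reward_scale = reward_scale, engine = "R")
  flat <- params$beta < 0.05 &&
    (length(res$optima) < 2 || diff(range(res$optima)) < 1e-3)
  structure(list(variant = variant, params = params,
                 loglik = -res$best$value, n_obs = sl$n_obs,
                 k = length(free),
                 bic = bic(-res$best$value, length(free), sl$n_obs),
                 n_restarts_converged = res$conv,
                 rpe_series = sl$trials$delta2,
                 flat_likelihood = flat),
            class = "fit_result")
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$variant, ": loglik ", round(x$loglik, 2),
      ", BIC ", round(x$bic, 2), ", k = ", x$k, "\n", sep = "")
  p <- x$params
  cat(sprintf("  alpha=%.3f lam=%.3f beta=%.3f w=%.3f pi=%.3f rho=%.3f\n",
              p$alpha, p$lam, p$beta, p$w, p$pi, p$rho))
  invisible(x)
}

#' Model comparison across subjects by summed BIC
#'
#' Fits each variant to each subject on identical trial sets and sums BIC
#' per variant; the winner is the variant with the lowest summed BIC, ties
#' broken toward fewer free parameters.
#'
#' @param behaviors list of \code{subject_behavior} objects.
#' @param variants variant labels (default: all nine).
#' @param seed integer seed; per-subject-per-variant fit seeds are derived
#'   from it deterministically.
#' @inheritParams fit_subject
#' @return a \code{model_comparison} list: \code{table} (per subject x
#'   variant BIC), \code{summed} (named vector), \code{winner},
#'   \code{fits} (winner-variant fit per subject).
#' @export
compare_models <- function(behaviors, variants = model_variants(),
                           cfg = task_config(), n_restarts = 20,
                           seed = 1L) {
  stopifnot(length(behaviors) >= 1)
  nv <- vapply(behaviors, function(b) sum(!is.na(b$a1) & !is.na(b$a2)),
               integer(1))
  tab <- matrix(NA_real_, length(behaviors), length(variants),
                dimnames = list(names(behaviors) %||%
                                  seq_along(behaviors), variants))
  fits <- vector("list", length(behaviors))
  for (i in seq_along(behaviors)) {
    fits[[i]] <- list()
    for (v in variants) {
      f <- fit_subject(behaviors[[i]], v, cfg, n_restarts,
                       seed = (seed * 1009L + i * 97L +
                                 match(v, variants)) %% .Machine$integer.max)
      if (f$n_obs != 2L * nv[i]) stop("variant fitted on mismatched trials")
      tab[i, v] <- f$bic
      fits[[i]][[v]] <- f
    }
  }
  summed <- colSums(tab)
  k <- vapply(variants, function(v) length(variant_free_params(v)),
              integer(1))
  ord <- order(summed, k)   # ties toward fewer parameters
  structure(list(table = tab, summed = summed, winner = variants[ord[1]],
                 fits = fits), class = "model_comparison")
}

#' @method print model_comparison
#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> winner:", x$winner, "\n")
  print(round(sort(x$summed), 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
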