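#' Run the full synthetic study: cohort -> behavior -> EEG -> second level
#'
#' Generates a cohort from \code{spec}, simulates each subject's task
#' behavior with their own hybrid parameters, extracts the generative
#' signed RPE series, synthesizes feedback-locked epochs with the planted
#' trait-linked modulations, runs the first-level preprocessing and robust
#' regressions separately within common and rare trials, averages the RPE
#' b values in the FRN and P3 windows found on the grand average, and fits
#' the four second-level models (FRN/P3 x common/rare).
#'
#' By default the second level uses the generator's true w (its recovery
#' by maximum likelihood is certified separately); set \code{fit_w = TRUE}
#' to refit each subject's hybrid+choice model and use the estimated w.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param cfg a \code{\link{task_config}}.
#' @param srate epoch sampling rate (500 Hz for full fidelity; lower rates
#'   thin the time axis proportionally for faster simulation studies).
#' @param channels montage (must include FCz and Cz).
#' @param fit_w refit w by maximum likelihood instead of using the true w.
#' @param n_restarts optimizer restarts when \code{fit_w}.
#' @param artifact_rejection apply \code{\link{adaptive_artifact_rejection}}
#'   (on by default; the generator plants no artifacts, so rejection
#'   removes the forced minimum only).
#' @return list: \code{cohort}, \code{windows}, \code{mean_b} (data.frame
#'   subject x component x transition), \code{second_level} (named list of
#'   the four \code{\link{second_level_regression}} results), \code{tmaps}
#'   (group FDR maps for the full-design regressors), \code{beta_maps}.
#' @export
run_synthetic_study <- function(spec = cohort_spec(), cfg = task_config(),
                                srate = 500,
                                channels = c("FCz", "Cz", "Pz", "F3", "F4"),
                                fit_w = FALSE, n_restarts = 20,
                                artifact_rejection = TRUE) {
  cohort <- generate_cohort(spec)
  n <- nrow(cohort)
  epochs <- vector("list", n)
  behaviors <- vector("list", n)
  w_used <- numeric(n)
  for (i in seq_len(n)) {
    pars <- agent_params(cohort$alpha[i], cohort$lam[i], cohort$beta[i],
                         cohort$w_true[i], cohort$pi[i])
    beh <- simulate_subject(pars, cfg, "hybrid_choice",
                            subject_id = cohort$subject_id[i])
    behaviors[[i]] <- beh
    ep <- generate_eeg_epochs(beh, beh$rpe, cohort[i, ], spec,
                              srate = srate, channels = channels)
    flt <- drop_fast_response_trials(ep)
    ep <- flt$epochs
    if (artifact_rejection)
      ep <- adaptive_artifact_rejection(ep)$epochs
    epochs[[i]] <- baseline_correct(ep)
    w_used[i] <- if (fit_w)
      fit_subject(beh, "hybrid_choice", cfg, n_restarts,
                  seed = i)$params$w
    else cohort$w_true[i]
  }
  ga <- grand_average(epochs)
  wins <- find_component_windows(ga, epoch_times(epochs[[1]]))
  full_maps <- lapply(seq_len(n), function(i)
    robust_regress_trials(epochs[[i]],
                          subject_id = cohort$subject_id[i]))
  tmaps <- lapply(c(transition = "transition", rpe = "rpe",
                    interaction = "transition:rpe"),
                  function(r) group_tmap(full_maps, r))
  cells <- expand.grid(component = c("FRN", "P3"),
                       transition = c("common", "rare"),
                       stringsAsFactors = FALSE)
  mean_b <- data.frame(subject_id = cohort$subject_id)
  sub_maps <- list()
  for (tt in c("common", "rare"))
    sub_maps[[tt]] <- lapply(seq_len(n), function(i)
      robust_regress_trials(epochs[[i]], subset = tt,
                            subject_id = cohort$subject_id[i]))
  second <- list()
  for (j in seq_len(nrow(cells))) {
    comp <- cells$component[j]; tt <- cells$transition[j]
    win <- wins[wins$component == comp, ]
    vals <- vapply(sub_maps[[tt]], mean_b_in_window, numeric(1),
                   window = win, regressor = "rpe")
    mean_b[[paste(comp, tt, sep = "_")]] <- vals
    second[[paste(comp, tt, sep = "_")]] <-
      second_level_regression(vals, cohort$bis_score, cohort$oci_score,
                              w_used, component = comp,
                              transition_type = tt)
  }
  list(cohort = cohort, behaviors = behaviors, windows = wins,
       mean_b = mean_b, second_level = second, tmaps = tmaps,
       beta_maps = full_maps, w_used = w_used)
}
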