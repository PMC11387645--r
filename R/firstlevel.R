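#' Feedback-locked epoch array
#'
#' A light container for one subject's feedback-locked EEG: a trials x
#' channels x time numeric array with sampling rate, epoch start and
#' per-trial metadata (the join keys to the behavioral table).
#'
#' @param data trials x channels x time array, microvolts.
#' @param srate sampling rate, Hz.
#' @param t0_ms epoch start relative to feedback onset, ms.
#' @param channels channel labels (length = dim 2).
#' @param metadata data.frame with one row per trial; must contain
#'   \code{trial} and is expected to carry \code{rt1_ms}, \code{rt2_ms},
#'   \code{transition}, \code{rpe} for the downstream filters/regressors.
#' @return an \code{epoch_array}.
#' @export
epoch_array <- function(data, srate = 500, t0_ms = -200,
                        channels = dimnames(data)[[2]], metadata) {
  stopifnot(length(dim(data)) == 3, length(channels) == dim(data)[2],
            nrow(metadata) == dim(data)[1], "trial" %in% names(metadata))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, srate = srate, t0_ms = t0_ms,
                 channels = channels, metadata = metadata),
            class = "epoch_array")
}

#' @method print epoch_array
#' @export
print.epoch_array <- function(x, ...) {
  cat("<epoch_array> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples @ ", x$srate, " Hz, t0 ",
      x$t0_ms, " ms\n", sep = "")
  invisible(x)
}

#' @rdname epoch_array
#' @param x an \code{epoch_array}.
#' @return \code{epoch_times}: sample times in ms relative to feedback.
#' @export
epoch_times <- function(x) {
  x$t0_ms + (seq_len(dim(x$data)[3]) - 1) * 1000 / x$srate
}

subset_epochs <- function(x, keep) {
  x$data <- x$data[keep, , , drop = FALSE]
  x$metadata <- x$metadata[keep, , drop = FALSE]
  x
}

#' Remove trials with preliminary responses
#'
#' Drops trials whose stage-1 or stage-2 reaction time is below
#' \code{threshold_ms} (default 100 ms).
#'
#' @param epochs an \code{\link{epoch_array}} whose metadata carries
#'   \code{rt1_ms} and \code{rt2_ms}.
#' @param threshold_ms RT threshold.
#' @return list: \code{epochs} (filtered), \code{n_removed}.
#' @export
drop_fast_response_trials <- function(epochs, threshold_ms = 100) {
  md <- epochs$metadata
  if (!all(c("rt1_ms", "rt2_ms") %in% names(md)))
    stop("metadata must carry rt1_ms and rt2_ms")
  fast <- (!is.na(md$rt1_ms) & md$rt1_ms < threshold_ms) |
    (!is.na(md$rt2_ms) & md$rt2_ms < threshold_ms)
  list(epochs = subset_epochs(epochs, !fast), n_removed = sum(fast))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -200 to 0 ms before feedback).
#'
#' @param epochs an \code{\link{epoch_array}}.
#' @param window c(start, end) in ms; must lie inside the epoch.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  tms <- epoch_times(epochs)
  idx <- which(tms >= window[1] & tms <= window[2])
  if (!length(idx)) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time (dim 3)
  epochs
}

#' Adaptive artifact rejection
#'
#' Scores each trial by its maximum absolute z across channel x time
#' (z computed pointwise over trials) and rejects trials above an SD
#' threshold starting at \code{start_sd}. The threshold is adapted in
#' steps of \code{step}: lowered until at least \code{min_remove} trials
#' are rejected, raised until at most \code{max_frac} of trials are.
#'
#' @param epochs an \code{\link{epoch_array}} with >= 20 trials.
#' @param start_sd initial threshold in SDs (default 4).
#' @param step threshold adaptation step (default 0.1).
#' @param min_remove minimum number of rejected trials (default 1).
#' @param max_frac maximum rejected fraction (default 0.05).
#' @return list: \code{epochs} (kept), \code{removed} (original trial
#'   indices), \code{threshold} (final SD threshold).
#' @export
adaptive_artifact_rejection <- function(epochs, start_sd = 4, step = 0.1,
                                        min_remove = 1, max_frac = 0.05) {
  n <- dim(epochs$data)[1]
  if (n < 20) stop("need at least 20 trials")
  if (min_remove > floor(max_frac * n))
    stop("min_remove exceeds the maximum removable fraction")
  x <- epochs$data
  mu <- apply(x, c(2, 3), mean)
  sd_ <- apply(x, c(2, 3), stats::sd)
  sd_[sd_ < 1e-12] <- Inf
  z <- sweep(sweep(x, c(2, 3), mu, "-"), c(2, 3), sd_, "/")
  score <- apply(abs(z), 1, max)
  thr <- start_sd
  count <- function(th) sum(score > th)
  for (i in 1:10000) {
    if (count(thr) < min_remove) thr <- thr - step
    else if (count(thr) > max_frac * n) thr <- thr + step
    else break
  }
  if (count(thr) < min_remove || count(thr) > max_frac * n)
    stop("threshold adaptation could not satisfy the removal constraints")
  rej <- which(score > thr)
  list(epochs = subset_epochs(epochs, setdiff(seq_len(n), rej)),
       removed = rej, threshold = thr)
}

#' Single-trial robust regression over channel x time
#'
#' Fits, at every (channel, time) point, the robust (Huber) regression
#' EEG ~ transition + rpe + transition:rpe across trials, with transition
#' coded common = +1 / rare = -1 and the signed RPE z-scored within
#' subject. With \code{subset} = "common" or "rare" the analysis is
#' restricted to one transition type and the transition columns are
#' dropped (EEG ~ rpe).
#'
#' @param epochs a preprocessed \code{\link{epoch_array}} whose metadata
#'   carries \code{transition} and \code{rpe}.
#' @param subset NULL (full design), "common" or "rare".
#' @param huber_k Huber tuning constant (default 1.345, 95 per cent
#'   Gaussian efficiency); \code{Inf} gives ordinary least squares.
#' @param max_iter,tol IRLS iteration cap and coefficient tolerance.
#' @param subject_id label stored in the result.
#' @return a \code{beta_map}: list with \code{b} (regressor x channel x
#'   time array), \code{regressors}, \code{channels}, \code{times},
#'   \code{subject_id}, \code{n_trials}.
#' @export
robust_regress_trials <- function(epochs, subset = NULL, huber_k = 1.345,
                                  max_iter = 50, tol = 1e-8,
                                  subject_id = "s01") {
  md <- epochs$metadata
  if (!all(c("transition", "rpe") %in% names(md)))
    stop("metadata must carry transition and rpe")
  if (!is.null(subset)) {
    keep <- md$transition == subset
    epochs <- subset_epochs(epochs, keep)
    md <- epochs$metadata
  }
  n <- nrow(md)
  if (n < 10) stop("need at least 10 trials after subsetting")
  rpe_z <- as.numeric(scale(md$rpe))
  if (is.null(subset)) {
    trans <- ifelse(md$transition == "common", 1, -1)
    X <- cbind(intercept = 1, transition = trans, rpe = rpe_z,
               `transition:rpe` = trans * rpe_z)
  } else {
    X <- cbind(intercept = 1, rpe = rpe_z)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "))
  nc <- length(epochs$channels); nt <- dim(epochs$data)[3]
  Y <- matrix(epochs$data, nrow = n)      # trials x (channel*time)
  B <- cpp_huber_irls(X, Y, huber_k, max_iter, tol)
  if (any(!is.finite(B))) stop("non-finite regression weights")
  b <- array(B, c(ncol(X), nc, nt))       # columns of Y are (channel, time)
  dimnames(b) <- list(colnames(X), epochs$channels, NULL)
  structure(list(b = b, regressors = colnames(X),
                 channels = epochs$channels, times = epoch_times(epochs),
                 subject_id = subject_id, n_trials = n),
            class = "beta_map")
}

#' Group t-map with FDR correction
#'
#' At every (channel, time) point, a two-tailed one-sample t-test of the
#' subjects' regression weights against zero; p-values are
#' Benjamini-Hochberg adjusted over the stated family (by default all time
#' points at the two component channels FCz and Cz; \code{family =
#' "scalp"} uses every channel).
#'
#' @param beta_maps list of \code{beta_map}s (same grid).
#' @param regressor regressor name.
#' @param q FDR level (default 0.05).
#' @param family "components" (default; channels in \code{channels}) or
#'   "scalp".
#' @param channels channels forming the "components" family.
#' @return list of channel x time matrices \code{t}, \code{p},
#'   \code{p_adj}, logical \code{mask}, plus \code{times},
#'   \code{channels}, \code{n_subjects}.
#' @export
group_tmap <- function(beta_maps, regressor, q = 0.05,
                       family = c("components", "scalp"),
                       channels = c("FCz", "Cz")) {
  family <- match.arg(family)
  ns <- length(beta_maps)
  if (ns < 3) stop("need at least 3 subjects")
  chs <- if (family == "scalp") beta_maps[[1]]$channels else
    intersect(channels, beta_maps[[1]]$channels)
  nt <- length(beta_maps[[1]]$times)
  stack <- vapply(beta_maps,
                  function(bm) bm$b[regressor, chs, , drop = TRUE],
                  array(0, c(length(chs), nt)))
  stack <- array(stack, c(length(chs), nt, ns))
  m <- apply(stack, c(1, 2), mean)
  s <- apply(stack, c(1, 2), stats::sd)
  tval <- m / (s / sqrt(ns))
  p <- 2 * stats::pt(-abs(tval), df = ns - 1)
  zero_var <- s < 1e-14
  if (any(zero_var)) {
    p[zero_var] <- ifelse(abs(m[zero_var]) > 1e-14, 0, 1)
    warning(sum(zero_var), " points with zero variance across subjects")
  }
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  dimnames(tval) <- dimnames(p) <- dimnames(p_adj) <- list(chs, NULL)
  list(t = tval, p = p, p_adj = p_adj, mask = p_adj < q,
       times = beta_maps[[1]]$times, channels = chs, n_subjects = ns)
}

#' Locate the FRN and P3 component windows on the grand average
#'
#' The FRN is the most negative sample at FCz within 250-350 ms after
#' feedback, the P3 the most positive sample at Cz within 330-430 ms; each
#' component's analysis window is peak latency +/- 25 ms. Ties are broken
#' toward the earlier latency; a peak at the search boundary triggers a
#' truncation warning.
#'
#' @param grand_average channels x time matrix (row names = channels), the
#'   mean over all retained subjects and trials.
#' @param times sample times in ms.
#' @param halfwidth_ms half width of the analysis window (default 25).
#' @return a data.frame with one row per component: \code{component},
#'   \code{channel}, \code{peak_ms}, \code{win_lo}, \code{win_hi}.
#' @export
find_component_windows <- function(grand_average, times,
                                   halfwidth_ms = 25) {
  locate <- function(channel, lo, hi, direction) {
    if (!channel %in% rownames(grand_average))
      stop("channel ", channel, " not present")
    idx <- which(times >= lo & times <= hi)
    y <- grand_average[channel, idx] * direction
    pk <- idx[which.max(y)]            # which.max = earliest on ties
    if (pk == idx[1] || pk == idx[length(idx)])
      warning("peak at the ", lo, "-", hi,
              " ms search boundary; window may be truncated")
    times[pk]
  }
  frn <- locate("FCz", 250, 350, -1)
  p3 <- locate("Cz", 330, 430, +1)
  data.frame(component = c("FRN", "P3"), channel = c("FCz", "Cz"),
             peak_ms = c(frn, p3),
             win_lo = c(frn, p3) - halfwidth_ms,
             win_hi = c(frn, p3) + halfwidth_ms,
             stringsAsFactors = FALSE)
}

#' Average a regressor's weights inside a component window
#'
#' Arithmetic mean of the named regressor's b values over the window's
#' samples at the window's channel.
#'
#' @param beta_map a \code{beta_map}.
#' @param window one row of \code{\link{find_component_windows}} output
#'   (or any list with \code{channel}, \code{win_lo}, \code{win_hi}).
#' @param regressor regressor name (default "rpe").
#' @return scalar mean b.
#' @export
mean_b_in_window <- function(beta_map, window, regressor = "rpe") {
  if (!window$channel %in% beta_map$channels)
    stop("channel ", window$channel, " not present in beta map")
  idx <- which(beta_map$times >= window$win_lo &
                 beta_map$times <= window$win_hi)
  if (!length(idx)) stop("window contains no samples")
  mean(beta_map$b[regressor, window$channel, idx])
}

#' Grand-average ERP over subjects
#'
#' @param epoch_list list of \code{\link{epoch_array}}s on a common grid.
#' @return channels x time matrix of the mean over all trials of all
#'   subjects.
#' @export
grand_average <- function(epoch_list) {
  sums <- NULL; n <- 0
  for (ep in epoch_list) {
    s <- apply(ep$data, c(2, 3), sum)
    sums <- if (is.null(sums)) s else sums + s
    n <- n + dim(ep$data)[1]
  }
  ga <- sums / n
  rownames(ga) <- epoch_list[[1]]$channels
  ga
}

#' Robust (Huber) linear model with sandwich standard errors
#'
#' The M-estimation core shared by the second-level and RT-delta
#' regressions: IRLS with Huber weights (tuning constant \code{k}), scale
#' from the median absolute residual, and standard errors from the
#' M-estimation sandwich. p-values use the t distribution on n - p
#' degrees of freedom.
#'
#' @param X design matrix (with intercept column).
#' @param y response vector.
#' @param k Huber tuning constant; \code{Inf} reduces to OLS.
#' @param max_iter,tol IRLS controls.
#' @return data.frame with \code{term}, \code{beta}, \code{se}, \code{t},
#'   \code{p}.
#' @export
huber_lm <- function(X, y, k = 1.345, max_iter = 100, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("collinear design columns: ",
         paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "))
  b <- qr.coef(qrX, y)
  s <- 1
  for (it in seq_len(max_iter)) {
    r <- y - X %*% b
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-12) break
    wgt <- if (is.finite(k)) pmin(1, k / abs(r / s)) else rep(1, n)
    bn <- qr.coef(qr(X * sqrt(wgt)), y * sqrt(wgt))
    if (max(abs(bn - b)) < tol * (1 + max(abs(bn)))) { b <- bn; break }
    b <- bn
  }
  r <- as.vector(y - X %*% b)
  u <- r / s
  psi <- if (is.finite(k)) pmax(-k, pmin(k, u)) else u
  psi_d <- if (is.finite(k)) as.numeric(abs(u) <= k) else rep(1, n)
  A <- crossprod(X * psi_d, X) / n
  Bm <- crossprod(X * (psi * s), X * (psi * s)) / n
  Ai <- solve(A)
  V <- Ai %*% Bm %*% Ai / n * (n / (n - p))   # small-sample correction
  se <- sqrt(diag(V))
  tv <- as.vector(b) / se
  data.frame(term = colnames(X), beta = as.vector(b), se = se, t = tv,
             p = 2 * stats::pt(-abs(tv), df = n - p), row.names = NULL)
}
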