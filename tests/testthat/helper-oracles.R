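# Independent, deliberately plain oracles used to check the package's
# implementations. These share no code with the package: every formula is
# written out step by step.

# Trace oracle for the trial-sequence likelihood: explicit Q bookkeeping
# with scalar arithmetic, softmax written out directly.
oracle_loglik <- function(alpha, lam, beta, w, pi_, rho, trials,
                          p_common, scale) {
  QA <- c(0, 0); QB <- c(0, 0); QC <- c(0, 0)
  prev <- NA
  ll <- 0
  d2 <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    a1 <- trials$a1[i]; s2 <- trials$s2[i]; a2 <- trials$a2[i]
    r <- trials$reward_points[i] * scale
    maxB <- max(QB); maxC <- max(QC)
    qmb <- c(p_common * maxB + (1 - p_common) * maxC,
             (1 - p_common) * maxB + p_common * maxC)
    qnet <- w * qmb + (1 - w) * QA
    bonus <- c(0, 0)
    if (!is.na(prev)) bonus[prev + 1] <- pi_ + rho
    e1 <- exp(beta * (qnet[1] + bonus[1]))
    e2 <- exp(beta * (qnet[2] + bonus[2]))
    ll <- ll + log(c(e1, e2)[a1 + 1] / (e1 + e2))
    Q2 <- if (s2 == "B") QB else QC
    f1 <- exp(beta * Q2[1]); f2 <- exp(beta * Q2[2])
    ll <- ll + log(c(f1, f2)[a2 + 1] / (f1 + f2))
    delta1 <- Q2[a2 + 1] - QA[a1 + 1]
    delta2 <- r - Q2[a2 + 1]
    QA[a1 + 1] <- QA[a1 + 1] + alpha * delta1 + alpha * lam * delta2
    Q2[a2 + 1] <- Q2[a2 + 1] + alpha * delta2
    if (s2 == "B") QB <- Q2 else QC <- Q2
    d2[i] <- delta2
    prev <- a1
  }
  list(loglik = ll, delta2 = d2)
}

# Independent Benjamini-Hochberg: sort, compare p_(i) to q*i/m, adjust by
# the step-up rule.
oracle_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# A fixed 3-trial sequence used by several equation-oracle tests.
fixture_trials <- function() {
  data.frame(trial = 0:2,
             a1 = c(0L, 1L, 0L), s2 = c("B", "C", "C"),
             transition = c("common", "common", "rare"),
             a2 = c(1L, 0L, 1L), reward_points = c(3L, -2L, 5L),
             rt1_ms = 400, rt2_ms = 450)
}

as_behavior <- function(df, id = "sx") {
  structure(df, subject_id = id,
            class = c("subject_behavior", "data.frame"))
}

# Tiny epoch array with fully controlled content.
make_epochs <- function(data, srate = 500, t0 = -200,
                        channels = paste0("ch", seq_len(dim(data)[2])),
                        metadata = NULL) {
  if (is.null(metadata))
    metadata <- data.frame(trial = seq_len(dim(data)[1]) - 1L,
                           rt1_ms = 500, rt2_ms = 500,
                           transition = "common", rpe = 0)
  epoch_array(data, srate = srate, t0_ms = t0, channels = channels,
              metadata = metadata)
}

# Simulate a small cohort of agents sharing one parameter set.
simulate_cohort <- function(n, params, cfg, variant = "hybrid_choice") {
  lapply(seq_len(n), function(i)
    simulate_subject(params, cfg, variant,
                     subject_id = sprintf("s%03d", i)))
}
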