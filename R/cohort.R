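#' Specification of a synthetic study cohort
#'
#' Defines the joint distribution of trait scores, agent parameters and
#' EEG modulation gains for a simulated cohort. BIS-11 and OCI-R sum
#' scores are drawn from a bivariate normal; the model-based weight w is a
#' logistic function of standardized compulsivity (negative link by
#' default) plus noise; per-subject ERP modulation gains are linear in
#' standardized traits / w per the *_link slopes.
#'
#' The planted links mirror the effect structure under study: the RPE
#' modulation of the FRN grows with w (default slope 0.31 microvolt per
#' z), and the RPE modulation of the P3 on rare-transition trials shrinks
#' with compulsivity (default slope -0.45 microvolt per z).
#'
#' @param n_subjects cohort size.
#' @param bis_mean,bis_sd,oci_mean,oci_sd trait sum-score moments.
#' @param trait_correlation BIS-OCI correlation, |r| < 1.
#' @param w_link slope of logit(w) on standardized OCI (default -0.5).
#' @param w_noise_sd logit-scale noise SD of w.
#' @param frn_gain,p3_gain population mean RPE-modulation gains
#'   (microvolt per z-scored RPE) for the two components.
#' @param frn_w_link,frn_bis_link slopes of the FRN gain on z-scored w and
#'   BIS.
#' @param p3_oci_link slope of the P3 gain on z-scored OCI.
#' @param p3_oci_scope "rare" (default: the OCI link applies on
#'   rare-transition trials only) or "both".
#' @param gain_noise_sd SD of subject-level gain noise, microvolt.
#' @param frn_trans_b,p3_trans_b transition main effects (coefficient of
#'   common = +1 coding; negative = larger amplitude on rare trials).
#' @param frn_base,p3_base component base amplitudes, microvolt.
#' @param frn_valence_mix fraction of the FRN's RPE modulation carried by
#'   a signed-linear term; the remainder is a feedback-valence step.
#' @param p3_abs_gain,p3_signed_frac the P3's RPE response is U-shaped:
#'   |RPE| weight and the relative signed-linear admixture.
#' @param interaction_boost multiplicative strengthening of RPE effects on
#'   common trials (factor 1 + boost on common, 1 - boost on rare).
#' @param noise_sd single-trial EEG noise SD, microvolt.
#' @param noise_smooth_ms Gaussian kernel SD used to band-limit the noise
#'   in time; 0 leaves the noise white.
#' @param rpe_standardization scale on which the planted modulation is
#'   linear in the RPE: "all" (z over all valid trials, the default) or
#'   "within_transition" (z within each transition type, matching the
#'   units of the subset first-level regressions; rare trials carry larger
#'   prediction errors, so the two scales differ by a per-type factor).
#' @return a \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 30,
                        bis_mean = 65, bis_sd = 10,
                        oci_mean = 12, oci_sd = 8,
                        trait_correlation = 0.3,
                        w_link = -0.5, w_noise_sd = 0.8,
                        frn_gain = 1.6, p3_gain = 1.0,
                        frn_w_link = 0.31, frn_bis_link = 0,
                        p3_oci_link = -0.45,
                        p3_oci_scope = c("rare", "both"),
                        gain_noise_sd = 1.0,
                        frn_trans_b = -0.62, p3_trans_b = -1.25,
                        frn_base = -4, p3_base = 6,
                        frn_valence_mix = 0.7,
                        p3_abs_gain = 0.8, p3_signed_frac = 0.55,
                        interaction_boost = 0.3,
                        noise_sd = 12, noise_smooth_ms = 8,
                        rpe_standardization = c("all",
                                                "within_transition")) {
  stopifnot(n_subjects >= 1, abs(trait_correlation) < 1, noise_sd > 0,
            bis_sd > 0, oci_sd > 0, gain_noise_sd >= 0)
  p3_oci_scope <- match.arg(p3_oci_scope)
  rpe_standardization <- match.arg(rpe_standardization)
  spec <- as.list(environment())
  structure(spec[order(match(names(spec), names(formals())))],
            class = "cohort_spec")
}

#' ERP component templates
#'
#' Gaussian-windowed half-waves standing in for measured ERP shapes: the
#' FRN as a negative deflection at FCz peaking at 294 ms (FWHM 60 ms), the
#' P3 as a positive deflection at Cz peaking at 370 ms (FWHM 120 ms).
#' Peak amplitude of the unit template is 1 microvolt.
#'
#' @param component "FRN" or "P3".
#' @param channel,peak_ms,fwhm_ms,polarity template fields; defaults per
#'   component.
#' @return an \code{erp_template} list.
#' @export
erp_template <- function(component = c("FRN", "P3"), channel = NULL,
                         peak_ms = NULL, fwhm_ms = NULL, polarity = NULL) {
  component <- match.arg(component)
  def <- if (component == "FRN")
    list(channel = "FCz", peak_ms = 294, fwhm_ms = 60, polarity = -1)
  else list(channel = "Cz", peak_ms = 370, fwhm_ms = 120, polarity = +1)
  out <- list(component = component,
              channel = channel %||% def$channel,
              peak_ms = peak_ms %||% def$peak_ms,
              fwhm_ms = fwhm_ms %||% def$fwhm_ms,
              polarity = polarity %||% def$polarity)
  if (component == "FRN" && (out$peak_ms < 250 || out$peak_ms > 350))
    stop("FRN peak must lie in 250-350 ms")
  if (component == "P3" && (out$peak_ms < 330 || out$peak_ms > 430))
    stop("P3 peak must lie in 330-430 ms")
  structure(out, class = "erp_template")
}

template_shape <- function(tpl, times) {
  sigma <- tpl$fwhm_ms / (2 * sqrt(2 * log(2)))
  exp(-(times - tpl$peak_ms)^2 / (2 * sigma^2))
}

#' Draw a synthetic cohort: traits, w, agent parameters, gains
#'
#' Traits come from the bivariate normal of the spec; w =
#' plogis(w_link * oci_z + noise); the remaining agent parameters are
#' drawn uniformly within plausible ranges (alpha in 0.2-0.8, lambda in
#' 0.3-0.9, beta in 2-8, pi in 0-0.4). Per-subject ERP gains are linear in
#' z-scored traits / w plus noise. All generative quantities are stored
#' for recovery testing.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data.frame with one row per subject: ids, raw and z-scored
#'   traits, true w and agent parameters, true FRN/P3 gains (for the P3,
#'   the common- and rare-trial gains separately).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_subjects
  r <- spec$trait_correlation
  z1 <- stats::rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  bis <- spec$bis_mean + spec$bis_sd * z1
  oci <- spec$oci_mean + spec$oci_sd * z2
  bis_z <- if (n > 1) as.numeric(scale(bis)) else 0
  oci_z <- if (n > 1) as.numeric(scale(oci)) else 0
  w <- stats::plogis(spec$w_link * oci_z + stats::rnorm(n, 0, spec$w_noise_sd))
  w_z <- if (n > 1) as.numeric(scale(w)) else 0
  frn_gain <- spec$frn_gain + spec$frn_w_link * w_z +
    spec$frn_bis_link * bis_z + stats::rnorm(n, 0, spec$gain_noise_sd)
  p3_noise <- stats::rnorm(n, 0, spec$gain_noise_sd)
  p3_gain_rare <- spec$p3_gain + spec$p3_oci_link * oci_z + p3_noise
  p3_gain_common <- spec$p3_gain + p3_noise +
    if (spec$p3_oci_scope == "both") spec$p3_oci_link * oci_z else 0
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             bis_score = bis, oci_score = oci,
             bis_z = bis_z, oci_z = oci_z,
             w_true = w, w_z = w_z,
             alpha = stats::runif(n, 0.2, 0.8),
             lam = stats::runif(n, 0.3, 0.9),
             beta = stats::runif(n, 2, 8),
             pi = stats::runif(n, 0, 0.4),
             frn_gain = frn_gain,
             p3_gain_common = p3_gain_common,
             p3_gain_rare = p3_gain_rare,
             stringsAsFactors = FALSE)
}

#' Generate feedback-locked EEG epochs with planted effects
#'
#' Builds one subject's trials x channels x time epoch array (500 Hz,
#' -200 to 1000 ms, channels FCz, Cz, Pz, F3, F4) as band-limited Gaussian
#' noise plus two planted components: at FCz an FRN whose amplitude
#' carries a base deflection, a transition main effect, and an RPE
#' modulation (mixture of signed-linear and valence-step terms, scaled by
#' the subject's FRN gain and stronger on common trials); at Cz a P3 with
#' a rarity main effect and a U-shaped RPE modulation (|RPE| plus a signed
#' admixture, scaled by the subject's transition-specific P3 gain).
#'
#' @param behavior a \code{subject_behavior}.
#' @param rpe_series signed RPE per trial, aligned to \code{behavior};
#'   z-scored internally (as in the first-level design).
#' @param subject_row the subject's row of \code{\link{generate_cohort}}
#'   output (gains are read from it).
#' @param spec a \code{\link{cohort_spec}}.
#' @param srate sampling rate, Hz.
#' @param channels channel labels; must include FCz and Cz.
#' @param templates list with elements \code{frn} and \code{p3}
#'   (\code{\link{erp_template}}s).
#' @return an \code{\link{epoch_array}} whose metadata joins trial,
#'   transition, rpe and the RTs.
#' @export
generate_eeg_epochs <- function(behavior, rpe_series, subject_row,
                                spec = cohort_spec(), srate = 500,
                                channels = c("FCz", "Cz", "Pz", "F3", "F4"),
                                templates = list(frn = erp_template("FRN"),
                                                 p3 = erp_template("P3"))) {
  if (length(rpe_series) != nrow(behavior))
    stop("rpe series misaligned with trials")
  ok <- !is.na(behavior$a1) & !is.na(behavior$a2)
  b <- as.data.frame(behavior)[ok, ]
  rpe <- rpe_series[ok]
  n <- nrow(b)
  times <- seq(-200, 1000 - 1000 / srate, by = 1000 / srate)
  nt <- length(times)
  nc <- length(channels)
  trans <- ifelse(b$transition == "common", 1, -1)
  rpe_z <- as.numeric(scale(rpe))
  if (identical(spec$rpe_standardization, "within_transition"))
    for (tt in unique(trans))
      rpe_z[trans == tt] <- as.numeric(scale(rpe[trans == tt]))
  boost <- 1 + spec$interaction_boost * trans
  valence <- ifelse(rpe > 0, 1, -1)
  frn_mod <- spec$frn_valence_mix * rpe_z +
    (1 - spec$frn_valence_mix) * valence
  frn_amp <- spec$frn_base + spec$frn_trans_b * trans +
    subject_row$frn_gain * frn_mod * boost
  p3_gain_i <- ifelse(trans == 1, subject_row$p3_gain_common,
                      subject_row$p3_gain_rare)
  p3_mod <- spec$p3_abs_gain * abs(rpe_z) + spec$p3_signed_frac * rpe_z
  p3_amp <- spec$p3_base + spec$p3_trans_b * trans +
    p3_gain_i * p3_mod * boost
  noise <- array(stats::rnorm(n * nc * nt), c(n, nc, nt))
  if (spec$noise_smooth_ms > 0) {
    sig <- spec$noise_smooth_ms * srate / 1000
    half <- ceiling(3 * sig)
    kern <- stats::dnorm(-half:half, sd = sig)
    kern <- kern / sqrt(sum(kern^2))   # preserves the noise variance
    flat <- matrix(noise, n * nc, nt)
    pad <- cbind(flat[, rev(seq_len(half)), drop = FALSE], flat,
                 flat[, nt + 1 - seq_len(half), drop = FALSE])
    sm <- t(apply(pad, 1, function(x) stats::filter(x, kern, sides = 2)))
    noise <- array(sm[, (half + 1):(half + nt)], c(n, nc, nt))
  }
  data <- noise * spec$noise_sd
  shp_f <- template_shape(templates$frn, times)
  shp_p <- template_shape(templates$p3, times)
  i_f <- match(templates$frn$channel, channels)
  i_p <- match(templates$p3$channel, channels)
  if (is.na(i_f) || is.na(i_p)) stop("template channels must be present")
  # amplitudes are signed (frn_base < 0 yields the negative deflection);
  # the template polarity field is descriptive metadata
  data[, i_f, ] <- data[, i_f, ] + outer(frn_amp, shp_f)
  data[, i_p, ] <- data[, i_p, ] + outer(p3_amp, shp_p)
  md <- data.frame(trial = b$trial, transition = b$transition, rpe = rpe,
                   rt1_ms = b$rt1_ms, rt2_ms = b$rt2_ms,
                   stringsAsFactors = FALSE)
  epoch_array(data, srate = srate, t0_ms = -200, channels = channels,
              metadata = md)
}
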