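#' Second-level robust regression of windowed RPE effects on traits and w
#'
#' Regresses per-subject mean RPE b values (one component window, one
#' transition type) on z-scored BIS-11, OCI-R and w with all their
#' interactions (8 terms): mean_b ~ BIS + OCI + w + BIS:OCI + BIS:w +
#' OCI:w + BIS:OCI:w. Predictors are z-scored before entry; interaction
#' columns are products of the z-scored mains and are not re-standardized.
#' Fitting is by Huber M-estimation with sandwich standard errors
#' (\code{\link{huber_lm}}).
#'
#' @param mean_b numeric vector of per-subject windowed RPE b values.
#' @param bis,oci,w per-subject trait sum scores and weighting parameter
#'   (raw scale; z-scored internally).
#' @param component,transition_type labels stored in the result.
#' @param min_n minimal complete-case count (default 20).
#' @return a \code{second_level_result}: coefficient table plus labels.
#' @export
second_level_regression <- function(mean_b, bis, oci, w,
                                    component = "FRN",
                                    transition_type = "common",
                                    min_n = 20) {
  ok <- stats::complete.cases(mean_b, bis, oci, w)
  if (sum(ok) < min_n) stop("fewer than ", min_n, " complete cases")
  b <- as.numeric(scale(bis[ok])); o <- as.numeric(scale(oci[ok]))
  ww <- as.numeric(scale(w[ok]))
  X <- cbind(`(Intercept)` = 1, BIS = b, OCI = o, w = ww,
             `BIS:OCI` = b * o, `BIS:w` = b * ww, `OCI:w` = o * ww,
             `BIS:OCI:w` = b * o * ww)
  tab <- huber_lm(X, mean_b[ok])
  structure(list(component = component, transition_type = transition_type,
                 n = sum(ok), table = tab),
            class = "second_level_result")
}

#' @method print second_level_result
#' @export
print.second_level_result <- function(x, ...) {
  cat("<second_level_result> ", x$component, ", ", x$transition_type,
      " trials, n = ", x$n, "\n", sep = "")
  print(transform(x$table, beta = round(beta, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 3)))
  invisible(x)
}

#' Median-split follow-up regressions
#'
#' Splits subjects at the median of one moderator (ties go to the low
#' group) and fits, within each group, a robust regression of the
#' windowed b values on the other predictor alone (z-scored within the
#' full sample before splitting).
#'
#' @param mean_b per-subject windowed RPE b values.
#' @param split_values values defining the median split (e.g. BIS scores).
#' @param predictor_values the predictor regressed within each group.
#' @param min_n minimal group size (default 10).
#' @return list with elements \code{low} and \code{high}, each a
#'   \code{\link{huber_lm}} table, plus \code{n_low}, \code{n_high}.
#' @export
median_split_followup <- function(mean_b, split_values, predictor_values,
                                  min_n = 10) {
  ok <- stats::complete.cases(mean_b, split_values, predictor_values)
  mb <- mean_b[ok]; sv <- split_values[ok]
  pv <- as.numeric(scale(predictor_values[ok]))
  low <- sv <= stats::median(sv)
  if (sum(low) < min_n || sum(!low) < min_n)
    stop("median-split group below ", min_n, " subjects")
  fit1 <- function(sel) huber_lm(cbind(`(Intercept)` = 1,
                                       predictor = pv[sel]), mb[sel])
  list(low = fit1(low), high = fit1(!low),
       n_low = sum(low), n_high = sum(!low))
}

#' z-test comparing two regression coefficients
#'
#' z = (b1 - b2) / sqrt(se1^2 + se2^2) with a two-sided standard-normal
#' p-value.
#'
#' @param b1,se1,b2,se2 coefficients and standard errors.
#' @return list with \code{z} and \code{p}.
#' @export
compare_coefficients_z <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
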