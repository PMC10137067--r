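## Survival analysis used throughout: Kaplan-Meier, log-rank, Cox PH.
## All three stand on the survival package; this module fixes the
## conventions (Efron ties, Wald 95% CI) and the tabular interfaces.

.check_survival <- function(data) {
  stopifnot(all(c("time_days", "event") %in% names(data)))
  if (nrow(data) < 1L) stop("no subjects")
  if (any(!is.finite(data$time_days)) || any(data$time_days <= 0))
    stop("survival times must be positive and finite")
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(data)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; duplicate event times
#' are handled as a single drop with multiplicity.
#'
#' @param data data.frame with columns `time_days` and `event` (1 = event,
#'   0 = censored).
#' @return data.frame (time, n_risk, n_event, surv); `surv` is
#'   non-increasing and starts from S(0) = 1.
#' @export
kmEstimate <- function(data) {
  .check_survival(data)
  fit <- survival::survfit(survival::Surv(data$time_days, data$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test between groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance.
#'
#' @param data data.frame with `time_days` and `event`.
#' @param groups group labels aligned to rows of `data` (>= 2 non-empty
#'   groups).
#' @return list (statistic, df, p).
#' @export
logrankTest <- function(data, groups) {
  .check_survival(data)
  g <- factor(groups)
  if (nlevels(g) < 2L || any(table(g) == 0))
    stop("need >= 2 non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(data$time_days, data$event) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie correction (switchable to
#' Breslow); hazard ratios with Wald 95% confidence intervals. Constant
#' covariates and non-converged fits are rejected rather than silently
#' reported.
#'
#' @param data data.frame with `time_days` and `event`.
#' @param covariates numeric vector or patients x p matrix/data.frame of
#'   covariates aligned to rows of `data`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame per covariate: coef, hr, ci_lower, ci_upper, se, p;
#'   attribute `converged`.
#' @export
coxFit <- function(data, covariates, ties = c("efron", "breslow")) {
  .check_survival(data)
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != nrow(data)) stop("covariates misaligned with survival")
  if (nrow(X) <= ncol(X)) stop("need n > p")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant covariate(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  fit <- survival::coxph(survival::Surv(data$time_days, data$event) ~ X,
                         ties = ties, control =
                           survival::coxph.control(iter.max = 100))
  conv <- fit$iter < 100 && all(is.finite(coef(fit))) &&
    all(is.finite(sqrt(diag(fit$var))))
  if (!conv)
    warning("Cox fit did not converge cleanly (monotone likelihood?)")
  cf <- coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(
    covariate = colnames(X),
    coef = unname(cf),
    hr = unname(exp(cf)),
    ci_lower = unname(exp(cf - 1.96 * se)),
    ci_upper = unname(exp(cf + 1.96 * se)),
    se = unname(se),
    p = unname(2 * pnorm(-abs(cf / se))),
    stringsAsFactors = FALSE)
  attr(out, "converged") <- conv
  attr(out, "score_test") <- unname(fit$score)
  out
}
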