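# Native survival machinery: Kaplan-Meier product-limit estimator with
# Greenwood log(-log) confidence bands and Brookmeyer-Crowley median CI,
# the two-group log-rank test, and quantile dichotomization. These are
# implemented directly (not delegated) because the maximally-selected
# cutpoint search and its permutation null are built on top of them and
# verified against exhaustive enumeration.

.surv_vectors <- function(surv) {
  validate_survival(surv)
  list(time = as.numeric(surv$os_months), event = as.integer(surv$os_event),
       id = as.character(surv$sample_id))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator over distinct event times, with Greenwood
#' variance, log(-log)-transformed pointwise 95% confidence bands, the
#' median survival time (smallest time with `S(t) <= 0.5`, undefined when
#' the curve never reaches 0.5) and its Brookmeyer-Crowley 95% CI (the
#' times at which the pointwise bands cross 0.5).
#'
#' @param surv survival table (columns `sample_id`, `os_months`,
#'   `os_event`).
#' @param conf_level confidence level for the bands (default 0.95).
#' @return object of class `km_curve`: list with `time`, `n_risk`,
#'   `n_event`, `surv`, `lower`, `upper`, `median`, `median_ci`, `n`,
#'   `n_events`.
#' @export
km_estimate <- function(surv, conf_level = 0.95) {
  sv <- .surv_vectors(surv)
  n <- length(sv$time)
  if (n < 1) stop("need at least one subject", call. = FALSE)
  et <- sort(unique(sv$time[sv$event == 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (length(et) == 0L) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), lower = numeric(0), upper = numeric(0),
                median = NA_real_, median_ci = c(NA_real_, NA_real_),
                n = n, n_events = 0L)
    class(out) <- "km_curve"
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(sv$time >= t), 0L)
  n_event <- vapply(et, function(t) sum(sv$time == t & sv$event == 1), 0L)
  s <- cumprod(1 - n_event / n_risk)
  # Greenwood variance of log S, then log(-log) bands
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  lower <- upper <- rep(NA_real_, length(s))
  ok <- s > 0 & s < 1
  se_ll <- sqrt(gw[ok]) / abs(log(s[ok]))
  lower[ok] <- s[ok]^exp(z * se_ll)
  upper[ok] <- s[ok]^exp(-z * se_ll)
  lower[s == 0] <- 0
  upper[s == 0] <- 0
  med <- if (any(s <= 0.5 + 1e-12)) et[which(s <= 0.5 + 1e-12)[1L]] else NA_real_
  ci_lo <- if (any(!is.na(lower) & lower <= 0.5 + 1e-12))
    et[which(!is.na(lower) & lower <= 0.5 + 1e-12)[1L]] else NA_real_
  ci_hi <- if (any(!is.na(upper) & upper <= 0.5 + 1e-12))
    et[which(!is.na(upper) & upper <= 0.5 + 1e-12)[1L]] else NA_real_
  out <- list(time = et, n_risk = n_risk, n_event = n_event, surv = s,
              lower = lower, upper = upper, median = med,
              median_ci = c(ci_lo, ci_hi), n = n, n_events = sum(n_event))
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " subjects, ", x$n_events, " events\n",
      sep = "")
  cat("median survival: ",
      if (is.na(x$median)) "not reached" else format(x$median),
      " (95% CI ", format(x$median_ci[1]), "-", format(x$median_ci[2]),
      ")\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Score statistic `U = sum_i (d1i - n1i * di / ni)` (observed minus
#' expected events in group 1, summed over distinct event times) with
#' hypergeometric variance
#' `V = sum_i di * (n1i/ni) * (1 - n1i/ni) * (ni - di) / (ni - 1)`;
#' `chi2 = U^2 / V` referred to a chi-square with 1 df. Group 1 is the
#' first level of `groups`.
#'
#' @param surv survival table.
#' @param groups factor (or coercible) with exactly two levels aligned to
#'   `surv` rows.
#' @return list of class `logrank_result`: `U`, `V`, `chi2`, `z`, `p`,
#'   `n_per_group`.
#' @export
logrank_test <- function(surv, groups) {
  sv <- .surv_vectors(surv)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != length(sv$time))
    stop("groups must align with the survival table rows", call. = FALSE)
  if (nlevels(groups) != 2)
    stop("exactly two nonempty groups required", call. = FALSE)
  g1 <- groups == levels(groups)[1L]
  if (sum(sv$event) < 1) stop("no events observed", call. = FALSE)
  et <- sort(unique(sv$time[sv$event == 1]))
  U <- 0; V <- 0
  for (t in et) {
    at <- sv$time >= t
    ni <- sum(at)
    di <- sum(sv$time == t & sv$event == 1)
    n1i <- sum(at & g1)
    d1i <- sum(sv$time == t & sv$event == 1 & g1)
    U <- U + (d1i - n1i * di / ni)
    if (ni > 1)
      V <- V + di * (n1i / ni) * (1 - n1i / ni) * (ni - di) / (ni - 1)
  }
  if (V <= 0) stop("log-rank variance is zero (no information)",
                   call. = FALSE)
  chi2 <- U^2 / V
  out <- list(U = U, V = V, chi2 = chi2, z = U / sqrt(V),
              p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
              n_per_group = table(groups))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("log-rank test: chi2 = ", format(x$chi2, digits = 4),
      " (1 df), p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Dichotomize a score at an empirical quantile
#'
#' Threshold at the linear-interpolation empirical quantile (R type 7);
#' a sample is `high` iff its score is strictly greater than the
#' threshold, so with `q = 2/3` about one third of samples are labeled
#' high (ties at the threshold fall low).
#'
#' @param score named numeric vector of per-sample scores.
#' @param q quantile in (0, 1); default 2/3 (upper tertile).
#' @return list with `labels` (factor `low`/`high`, named by sample) and
#'   `threshold`.
#' @export
categorize_by_quantile <- function(score, q = 2/3) {
  stopifnot(is.numeric(score), q > 0, q < 1)
  if (length(unique(score)) < 2)
    stop("scores are constant; no quantile split possible", call. = FALSE)
  thr <- unname(stats::quantile(score, probs = q, type = 7))
  labels <- factor(ifelse(score > thr, "high", "low"),
                   levels = c("low", "high"))
  names(labels) <- names(score)
  list(labels = labels, threshold = thr)
}
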