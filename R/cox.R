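# Cox proportional hazards modelling with the univariate-to-multivariable
# entry rule. Estimation delegates to survival::coxph (Efron tie handling);
# this module owns input validation, the screening logic and the tidy
# hazard-ratio tables.

.cox_formula <- function(covariates) {
  stats::as.formula(paste("survival::Surv(os_months, os_event) ~",
                          paste(sprintf("`%s`", covariates), collapse = " + ")))
}

.cox_table <- function(fit, conf_level = 0.95) {
  s <- summary(fit, conf.int = conf_level)
  co <- s$coefficients
  data.frame(term = rownames(co),
             hazard_ratio = unname(co[, "exp(coef)"]),
             ci_lo = unname(s$conf.int[, 3L]),
             ci_hi = unname(s$conf.int[, 4L]),
             p = unname(co[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

.fit_one_cox <- function(surv, covariates) {
  for (v in covariates) {
    col <- surv[[v]]
    if (is.numeric(col) && stats::sd(col) == 0)
      stop("covariate '", v, "' has zero variance", call. = FALSE)
    if (!is.numeric(col) && length(unique(col)) < 2)
      stop("covariate '", v, "' has zero variance", call. = FALSE)
  }
  fit <- survival::coxph(.cox_formula(covariates), data = surv,
                         ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("collinear covariates (coefficients not estimable): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  fit
}

# Likelihood-ratio p for the whole covariate block of a fit (used for the
# screening decision so multi-level factors are judged as one parameter
# block, not per dummy).
.lr_p <- function(fit) {
  lr <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  stats::pchisq(lr, df = sum(!is.na(stats::coef(fit))), lower.tail = FALSE)
}

#' Cox proportional hazards fit
#'
#' `mode = "multivariable"` fits all covariates jointly.
#' `mode = "univariate_screen"` first fits each covariate alone, then
#' refits jointly the covariates whose univariate likelihood-ratio p is
#' below `entry_p` (the classical univariate-to-multivariable entry rule).
#' Ties are handled by the Efron approximation; per-coefficient hazard
#' ratios carry Wald confidence intervals and p-values.
#'
#' @param surv survival table whose extra columns hold the covariates.
#' @param covariates character vector of covariate column names.
#' @param mode `"multivariable"` or `"univariate_screen"`.
#' @param entry_p univariate entry threshold (default 0.05).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `cox_result`: list with `table` (final-model
#'   hazard ratios), `fit` (the `coxph` object), `loglik`; in screening
#'   mode also `univariate` (per-covariate table with `entry` flag) and
#'   `entered` (covariate names kept).
#' @export
cox_fit <- function(surv, covariates,
                    mode = c("multivariable", "univariate_screen"),
                    entry_p = 0.05, conf_level = 0.95) {
  mode <- match.arg(mode)
  validate_survival(surv)
  stopifnot(is.character(covariates), length(covariates) >= 1)
  missing <- setdiff(covariates, names(surv))
  if (length(missing))
    stop("covariate column(s) not in survival table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (sum(surv$os_event) < 1) stop("no events observed", call. = FALSE)
  if (anyDuplicated(covariates))
    stop("duplicated covariate name(s): ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "),
         call. = FALSE)

  if (mode == "multivariable") {
    fit <- .fit_one_cox(surv, covariates)
    out <- list(table = .cox_table(fit, conf_level), fit = fit,
                loglik = fit$loglik[2L], mode = mode)
    class(out) <- "cox_result"
    return(out)
  }

  uni <- lapply(covariates, function(v) {
    fit <- .fit_one_cox(surv, v)
    tab <- .cox_table(fit, conf_level)
    tab$covariate <- v
    tab$p_block <- .lr_p(fit)
    tab
  })
  uni_tab <- do.call(rbind, uni)
  block_p <- vapply(covariates, function(v)
    uni_tab$p_block[uni_tab$covariate == v][1L], 0)
  entered <- covariates[block_p < entry_p]
  uni_tab$entry <- uni_tab$covariate %in% entered
  final <- if (length(entered)) .fit_one_cox(surv, entered) else NULL
  out <- list(univariate = uni_tab, entered = entered, entry_p = entry_p,
              table = if (is.null(final)) NULL
                      else .cox_table(final, conf_level),
              fit = final,
              loglik = if (is.null(final)) NA_real_ else final$loglik[2L],
              mode = mode)
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  if (x$mode == "univariate_screen") {
    cat("univariate screen (entry at p < ", x$entry_p, "): entered ",
        if (length(x$entered)) paste(x$entered, collapse = ", ")
        else "none", "\n", sep = "")
  }
  if (!is.null(x$table)) {
    cat("final Cox model (Efron ties):\n")
    print(format(x$table, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
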