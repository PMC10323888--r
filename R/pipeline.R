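# End-to-end orchestration from a single config (YAML/JSON file or R list):
# simulate or load cohorts -> anchor screen -> intersect -> score ->
# stratify (maxstat + quantile) -> KM/log-rank -> Cox, writing every
# intermediate to disk with a checksummed manifest.

.pipeline_keys <- c("cohorts", "anchor", "r_min", "q_max", "quantile_q",
                    "maxstat", "cox_covariates", "outdir", "seed",
                    "signature_name")
.cohort_keys <- c("path", "survival_path", "simulate")

#' Read and validate a pipeline config
#'
#' @param config path to a YAML or JSON file, or an R list with the same
#'   structure. Keys: `cohorts` (list; each entry either `path` +
#'   `survival_path` or a `simulate` block of [cohort_spec()] arguments),
#'   `anchor`, `r_min` (scalar or per-cohort), `q_max`, `quantile_q`,
#'   `maxstat` (`minprop`, `n_perm`), `cox_covariates`, `outdir`, `seed`,
#'   `signature_name`. Unknown keys are rejected.
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$cohorts) || length(config$cohorts) < 2)
    stop("config must list at least two cohorts", call. = FALSE)
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    unknown <- setdiff(names(co), .cohort_keys)
    if (length(unknown))
      stop("cohort ", i, ": unknown key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (is.null(co$simulate) && (is.null(co$path) || is.null(co$survival_path)))
      stop("cohort ", i, ": needs either a simulate block or path + ",
           "survival_path", call. = FALSE)
  }
  defaults <- list(anchor = "SALL4", r_min = 0.4, q_max = 0.05,
                   quantile_q = 2/3,
                   maxstat = list(minprop = 0.1, n_perm = 1000),
                   cox_covariates = character(0), seed = 1,
                   signature_name = "anchor_signature")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config$cox_covariates <- as.character(unlist(config$cox_covariates))
  if (is.null(config$maxstat$minprop)) config$maxstat$minprop <- 0.1
  if (is.null(config$maxstat$n_perm)) config$maxstat$n_perm <- 1000
  config
}

.stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L +
    match(stage, c("simulate", "maxstat")) * 17L
}

#' Run the full signature pipeline
#'
#' Stages, in dependency order: obtain cohorts (simulate or load), screen
#' every cohort against the anchor gene, select at the per-cohort cutoffs
#' and intersect into the signature, score the signature per sample in
#' every cohort, stratify cohort 1 by the maximally selected log-rank
#' cutpoint and by the quantile cutoff, summarize Kaplan-Meier curves and
#' the log-rank test for both stratifications, and fit Cox models (signature
#' group plus any configured covariates, univariate screen then
#' multivariable). All artifacts are written under `outdir` and listed with
#' MD5 checksums in `manifest.json`. An empty intersection is a clean
#' terminal state (`status = "empty_signature"`), not an error.
#'
#' @param config config file path or list, see [read_pipeline_config()].
#' @param outdir output directory (overrides the config entry).
#' @return the manifest, invisibly: list with `status`, `files`,
#'   `checksums`, `seeds`, and headline `results`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_pipeline_config(config)
  outdir <- outdir %||% cfg$outdir %||% stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name) { files[[name]] <<- file.path(outdir, name); files[[name]] }

  stage <- "load_cohorts"
  result <- tryCatch({
    cohorts <- vector("list", length(cfg$cohorts))
    for (i in seq_along(cfg$cohorts)) {
      co <- cfg$cohorts[[i]]
      if (!is.null(co$simulate)) {
        sim_args <- co$simulate
        sim_args$seed <- sim_args$seed %||%
          (.stage_seed(cfg$seed, "simulate") + i)
        spec <- do.call(cohort_spec, sim_args)
        cohort <- generate_cohort(spec, sample_prefix = sprintf("C%dS", i))
      } else {
        cohort <- list(expr = read_expression(co$path),
                       surv = read_survival(co$survival_path))
      }
      write_expression(cohort$expr, emit(sprintf("cohort%d_expr.tsv", i)))
      write_survival(cohort$surv, emit(sprintf("cohort%d_survival.csv", i)))
      cohorts[[i]] <- cohort
    }

    stage <- "screen"
    screen <- derive_anchor_signature(
      lapply(cohorts, `[[`, "expr"), anchor = cfg$anchor,
      r_min = unlist(cfg$r_min), q_max = cfg$q_max,
      name = cfg$signature_name)
    for (i in seq_along(screen$screens))
      utils::write.table(screen$screens[[i]],
                         emit(sprintf("screen_cohort%d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    if (is.null(screen$signature)) {
      manifest <- .write_manifest(outdir, files, cfg, status = "empty_signature",
                                  results = list())
      return(manifest)
    }
    write_gmt(screen$signature, emit("signature.gmt"))

    stage <- "score"
    scores <- lapply(cohorts, function(co)
      signature_score(co$expr, screen$signature))
    score_df <- data.frame(
      sample_id = unlist(lapply(scores, names), use.names = FALSE),
      cohort = rep(seq_along(scores), lengths(scores)),
      score = unlist(scores, use.names = FALSE))
    utils::write.table(score_df, emit("signature_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "stratify"
    surv1 <- cohorts[[1L]]$surv
    cut <- maxstat_cutpoint(scores[[1L]], surv1,
                            minprop = cfg$maxstat$minprop,
                            n_perm = cfg$maxstat$n_perm,
                            seed = .stage_seed(cfg$seed, "maxstat"))
    tert <- categorize_by_quantile(scores[[1L]], q = cfg$quantile_q)
    jsonlite::write_json(
      list(cutpoint = cut$cutpoint, max_stat = cut$max_stat,
           p_perm = cut$p_perm, n_candidates = cut$n_candidates,
           quantile_threshold = tert$threshold, quantile_q = cfg$quantile_q),
      emit("cutpoint.json"), auto_unbox = TRUE, digits = NA)
    labels_df <- data.frame(sample_id = surv1$sample_id,
                            maxstat_group = as.character(cut$groups),
                            quantile_group =
                              as.character(tert$labels[surv1$sample_id]))
    utils::write.csv(labels_df, emit("group_labels.csv"), row.names = FALSE,
                     quote = FALSE)

    stage <- "km_logrank"
    km_rows <- list(); lr <- list()
    for (split in c("maxstat_group", "quantile_group")) {
      grp <- factor(labels_df[[split]], levels = c("low", "high"))
      lr[[split]] <- logrank_test(surv1, grp)
      for (lev in levels(grp)) {
        km <- km_estimate(surv1[grp == lev, , drop = FALSE])
        km_rows[[paste(split, lev)]] <- data.frame(
          split = split, group = lev, n = km$n, events = km$n_events,
          median_os = km$median, median_lo = km$median_ci[1L],
          median_hi = km$median_ci[2L],
          logrank_chi2 = lr[[split]]$chi2, logrank_p = lr[[split]]$p)
      }
    }
    utils::write.table(do.call(rbind, km_rows), emit("km_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "cox"
    surv_cox <- surv1
    surv_cox$signature_high <-
      as.integer(labels_df$maxstat_group == "high")
    covars <- c("signature_high", cfg$cox_covariates)
    cox <- cox_fit(surv_cox, covars, mode = "univariate_screen",
                   entry_p = 0.05)
    utils::write.table(cox$univariate, emit("cox_univariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cox$table))
      utils::write.table(cox$table, emit("cox_final.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)

    hr_row <- cox$univariate[cox$univariate$covariate == "signature_high", ]
    results <- list(
      signature_size = length(screen$signature$genes),
      cutpoint = cut$cutpoint, max_stat = cut$max_stat,
      p_perm = cut$p_perm,
      logrank_p_maxstat = lr$maxstat_group$p,
      logrank_p_quantile = lr$quantile_group$p,
      signature_high_hr = hr_row$hazard_ratio[1L],
      signature_high_hr_ci = c(hr_row$ci_lo[1L], hr_row$ci_hi[1L]))
    .write_manifest(outdir, files, cfg, status = "ok", results = results)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_manifest <- function(outdir, files, cfg, status, results) {
  checks <- tools::md5sum(unlist(files))
  manifest <- list(status = status,
                   files = as.list(stats::setNames(unlist(files),
                                                   names(files))),
                   checksums = as.list(stats::setNames(unname(checks),
                                                       names(files))),
                   seeds = list(root = cfg$seed,
                                simulate = .stage_seed(cfg$seed, "simulate"),
                                maxstat = .stage_seed(cfg$seed, "maxstat")),
                   results = results)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  manifest
}
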