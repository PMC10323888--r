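# Synthetic multi-cohort generator.
#
# One latent "stromal" factor per sample drives both the anchor gene and a
# correlated gene module, and (through a proportional-hazards model) overall
# survival. This is the minimal structure under which a correlation screen,
# cross-cohort intersection and survival stratification all have a known
# ground truth.

#' Specify a synthetic cohort
#'
#' Per sample j a latent factor f_j ~ N(0, 1) is drawn. The anchor gene row
#' is `anchor_loading * f + noise`, each of the `module_genes` module rows is
#' `module_loading * f + noise`, remaining genes are iid noise; all rows sit
#' on a common baseline log-intensity. Survival time is exponential with
#' hazard `baseline_hazard * exp(beta * f)`, censored by an independent
#' U(0, censor_max) time.
#'
#' Defaults describe the emulated study conditions: cohorts of 250 resected
#' tumors, 5000 measured genes, a 24-gene stromal module with loadings 0.8
#' against unit noise, a log-hazard slope of 0.5 per latent-factor unit,
#' baseline hazard 0.035 per month (median survival near 20 months) and
#' 10 years of follow-up.
#'
#' @param n_samples number of samples (>= 10).
#' @param n_genes total genes including anchor and module.
#' @param anchor_gene anchor gene id.
#' @param module_genes number of correlated module genes.
#' @param anchor_loading,module_loading latent-factor loadings (>= 0).
#' @param noise_sd residual standard deviation (> 0).
#' @param beta log-hazard per unit latent factor.
#' @param baseline_hazard baseline hazard per month.
#' @param censor_max upper bound of the uniform censoring time, months.
#' @param baseline_mean baseline log-intensity added to every gene.
#' @param seed integer seed; all randomness is reproducible from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 250, n_genes = 5000,
                        anchor_gene = "SALL4", module_genes = 24,
                        anchor_loading = 0.8, module_loading = 0.8,
                        noise_sd = 1, beta = 0.5, baseline_hazard = 0.035,
                        censor_max = 120, baseline_mean = 7, seed = 1) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               anchor_gene = harmonize_gene_ids(anchor_gene),
               module_genes = as.integer(module_genes),
               anchor_loading = anchor_loading, module_loading = module_loading,
               noise_sd = noise_sd, beta = beta,
               baseline_hazard = baseline_hazard, censor_max = censor_max,
               baseline_mean = baseline_mean, seed = as.integer(seed))
  if (spec$n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  if (spec$anchor_loading < 0 || spec$module_loading < 0)
    stop("loadings must be non-negative", call. = FALSE)
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (spec$censor_max <= 0) stop("censor_max must be positive", call. = FALSE)
  if (spec$module_genes + 1L > spec$n_genes)
    stop("module_genes + anchor exceed n_genes", call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

# Child seed for a named substream; keeps expression untouched when only
# survival settings change. Kept below 2^31 - 1.
.child_seed <- function(seed, stream) {
  offs <- c(expression = 101L, survival = 211L, panin = 307L)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stream]]
}

#' Generate one synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param module_gene_ids optional character vector naming the module genes
#'   (length `spec$module_genes`); defaults to `MODG001...`.
#' @param sample_prefix prefix for generated sample ids.
#' @return list with elements `expr` (genes x samples matrix), `surv`
#'   (survival table) and `truth` (module gene set, latent factor, beta).
#' @export
generate_cohort <- function(spec, module_gene_ids = NULL,
                            sample_prefix = "S") {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$module_genes
  if (is.null(module_gene_ids))
    module_gene_ids <- sprintf("MODG%03d", seq_len(m))
  module_gene_ids <- harmonize_gene_ids(module_gene_ids)
  if (length(module_gene_ids) != m || anyDuplicated(module_gene_ids))
    stop("module_gene_ids must be ", m, " unique ids", call. = FALSE)
  n <- spec$n_samples
  n_bg <- spec$n_genes - m - 1L
  genes <- c(spec$anchor_gene, module_gene_ids,
             if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)))
  if (anyDuplicated(genes))
    stop("anchor or module ids collide with background gene ids", call. = FALSE)
  samples <- sprintf("%s%04d", sample_prefix, seq_len(n))

  set.seed(.child_seed(spec$seed, "expression"))
  f <- stats::rnorm(n)
  expr <- matrix(stats::rnorm(length(genes) * n, sd = spec$noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))
  expr[1L, ] <- expr[1L, ] + spec$anchor_loading * f
  if (m > 0)
    expr[1L + seq_len(m), ] <-
      expr[1L + seq_len(m), ] + rep(spec$module_loading * f, each = m)
  expr <- expr + spec$baseline_mean

  set.seed(.child_seed(spec$seed, "survival"))
  rate <- spec$baseline_hazard * exp(spec$beta * f)
  t_event <- stats::rexp(n, rate = rate)
  t_cens <- spec$censor_max * stats::runif(n)
  surv <- data.frame(sample_id = samples,
                     os_months = pmin(t_event, t_cens),
                     os_event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  truth <- list(module_gene_ids = gene_set("planted_module", module_gene_ids),
                latent_factor = stats::setNames(f, samples),
                true_beta = spec$beta, anchor_gene = spec$anchor_gene)
  list(expr = expr, surv = surv, truth = truth)
}

#' Generate several cohorts sharing (or not) a planted module
#'
#' @param specs list of [cohort_spec()]s (>= 2) with a common anchor gene.
#' @param shared_module if `TRUE` (default) the same module gene ids are
#'   planted in every cohort; otherwise each cohort gets its own disjoint
#'   module ids.
#' @return list with `cohorts` (per-cohort output of [generate_cohort()],
#'   samples prefixed `C<i>S`) and `truth` (the shared module gene set, or
#'   the per-cohort sets when not shared).
#' @export
generate_multicohort <- function(specs, shared_module = TRUE) {
  stopifnot(is.list(specs), length(specs) >= 2)
  anchors <- vapply(specs, function(s) s$anchor_gene, "")
  if (length(unique(anchors)) != 1L)
    stop("all cohorts must use the same anchor gene; got: ",
         paste(unique(anchors), collapse = ", "), call. = FALSE)
  m <- specs[[1L]]$module_genes
  cohorts <- vector("list", length(specs))
  if (shared_module) {
    ids <- sprintf("MODG%03d", seq_len(m))
    for (i in seq_along(specs))
      cohorts[[i]] <- generate_cohort(specs[[i]], module_gene_ids = ids,
                                      sample_prefix = sprintf("C%dS", i))
    truth <- list(module_gene_ids = gene_set("planted_module", ids))
  } else {
    for (i in seq_along(specs)) {
      ids <- sprintf("C%dMOD%03d", i, seq_len(specs[[i]]$module_genes))
      cohorts[[i]] <- generate_cohort(specs[[i]], module_gene_ids = ids,
                                      sample_prefix = sprintf("C%dS", i))
    }
    truth <- list(module_gene_ids = lapply(cohorts,
                                           function(co) co$truth$module_gene_ids))
  }
  list(cohorts = cohorts, truth = truth)
}

#' Generate a normal / PanIN / carcinoma three-group study
#'
#' Emulates a progression dataset for contrast-based signature filtering:
#' one planted set is over-expressed in carcinoma relative to the
#' premalignant (PanIN) group, another relative to normal tissue, with a
#' controllable shared subset over-expressed relative to both. Genes unique
#' to one planted set are additionally shifted in the other contrast's
#' baseline group so they stay null there.
#'
#' @param n_per_group samples per group (>= 2).
#' @param n_genes total genes.
#' @param n_up_pdac_vs_panin,n_up_pdac_vs_normal planted set sizes.
#' @param n_shared genes belonging to both planted sets (the by-construction
#'   intersection); at most the smaller planted count.
#' @param effect_log2fc planted shift on the log2 scale (> 1 for the shift
#'   to clear a log2FC > 1 filter).
#' @param noise_sd residual standard deviation.
#' @param baseline_mean baseline log2 intensity.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples), `groups` (factor levels
#'   normal, panin, pdac) and `truth` (the two planted gene sets).
#' @export
generate_panin_study <- function(n_per_group = 10, n_genes = 2000,
                                 n_up_pdac_vs_panin = 50,
                                 n_up_pdac_vs_normal = 50, n_shared = 25,
                                 effect_log2fc = 2, noise_sd = 0.5,
                                 baseline_mean = 7, seed = 1) {
  n_planted <- n_up_pdac_vs_panin + n_up_pdac_vs_normal - n_shared
  if (n_shared > min(n_up_pdac_vs_panin, n_up_pdac_vs_normal))
    stop("n_shared exceeds a planted set size", call. = FALSE)
  if (n_planted > n_genes)
    stop("planted counts exceed n_genes", call. = FALSE)
  groups <- factor(rep(c("normal", "panin", "pdac"), each = n_per_group),
                   levels = c("normal", "panin", "pdac"))
  samples <- sprintf("P%03d", seq_along(groups))
  genes <- sprintf("PG%05d", seq_len(n_genes))
  set.seed(.child_seed(seed, "panin"))
  expr <- matrix(stats::rnorm(n_genes * length(groups), mean = baseline_mean,
                              sd = noise_sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  shared <- genes[seq_len(n_shared)]
  only_panin <- genes[n_shared + seq_len(n_up_pdac_vs_panin - n_shared)]
  only_normal <- genes[n_up_pdac_vs_panin +
                         seq_len(n_up_pdac_vs_normal - n_shared)]
  up <- function(g, grp) {
    if (length(g))
      expr[g, groups == grp] <<- expr[g, groups == grp] + effect_log2fc
  }
  up(c(shared, only_panin, only_normal), "pdac")
  up(only_panin, "normal")  # elevated in normal too => null vs normal
  up(only_normal, "panin")  # elevated in PanIN too  => null vs PanIN
  truth <- list(
    up_vs_panin = gene_set("planted_up_vs_panin", c(shared, only_panin)),
    up_vs_normal = gene_set("planted_up_vs_normal", c(shared, only_normal)))
  list(expr = expr, groups = groups, truth = truth)
}
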