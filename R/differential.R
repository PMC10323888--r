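# Two-group differential expression on log2-scale matrices, with either a
# Welch t-test or an empirical-Bayes moderated t (per-gene variances shrunk
# toward a moment-matched scaled inverse chi-square prior), plus the
# threshold filter and the three-way intersection producing the
# invasiveness signature.

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone,
# nearly linear in 1/y); y > 0.
trigamma_inverse <- function(y) {
  stopifnot(is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Moment-matched prior (d0, s0^2) for gene variances s2 on df degrees of
# freedom: matches mean and variance of log(s2) under s2 ~ s0^2 * F(df, d0).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  if (sum(ok) < 2) return(list(d0 = Inf, s0_2 = exp(mean(e))))
  evar <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) return(list(d0 = Inf, s0_2 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Two-group differential expression
#'
#' Compares the second factor level against the first (the reference) on a
#' log2-scale matrix: `log2fc = mean(level 2) - mean(level 1)`.
#' `method = "welch"` is the unequal-variance t-test;
#' `method = "moderated"` shrinks per-gene pooled variances toward a
#' moment-matched prior (posterior variance
#' `(d0 * s0^2 + df * s^2) / (d0 + df)` on `df + d0` degrees of freedom),
#' an empirical-Bayes moderation in the limma tradition. q-values are BH
#' adjusted over all tested genes.
#'
#' @param mat numeric log2-scale matrix, genes in rows.
#' @param groups factor (or coercible) of length `ncol(mat)` with exactly
#'   two levels, each with >= 2 samples.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param prior_df optional fixed prior degrees of freedom for the
#'   moderated method (overrides the moment-matched estimate; `0` disables
#'   shrinkage entirely, recovering the ordinary pooled t).
#' @return data.frame with columns `gene_id`, `log2fc`, `t`, `p`, `q` and
#'   `var_floored` (TRUE where a zero pooled variance was floored at 1e-8).
#' @export
dge <- function(mat, groups, method = c("moderated", "welch"),
                prior_df = NULL) {
  method <- match.arg(method)
  validate_expression(mat)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != ncol(mat))
    stop("groups must have one label per sample", call. = FALSE)
  if (nlevels(groups) != 2)
    stop("exactly two group levels required, got ", nlevels(groups),
         call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  g1 <- groups == levels(groups)[1L]  # reference
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    floored <- se2 <= 0
    se2[floored] <- 1e-8
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / pmax((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1),
                       .Machine$double.xmin)
    df[floored] <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(tstat), df = df)
  } else {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    floored <- s2 <= 0
    s2[floored] <- 1e-8
    prior <- fit_variance_prior(s2, df)
    if (!is.null(prior_df)) prior$d0 <- prior_df
    post <- if (is.finite(prior$d0))
      (prior$d0 * prior$s0_2 + df * s2) / (prior$d0 + df)
    else rep(prior$s0_2, length(s2))
    tstat <- lfc / sqrt(post * (1 / n1 + 1 / n2))
    df_total <- min(df + prior$d0, 1e6)
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
  }
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  data.frame(gene_id = rownames(mat), log2fc = lfc, t = tstat, p = p,
             q = bh_adjust(p), var_floored = floored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter a differential-expression table
#'
#' Strict thresholds, matching the derivation criteria: `q < q_max` and
#' `log2fc > lfc_min` (up), `log2fc < -lfc_min` (down), or
#' `|log2fc| > lfc_min` (both).
#'
#' @param res result of [dge()].
#' @param lfc_min log2 fold-change cutoff (default 1).
#' @param q_max adjusted-p cutoff (default 0.05).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param name name for the returned set.
#' @return a [gene_set()], or `NULL` when nothing passes.
#' @export
filter_dge <- function(res, lfc_min = 1, q_max = 0.05,
                       direction = c("up", "down", "both"),
                       name = "dge_selected") {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "log2fc", "q") %in% names(res)))
  keep <- res$q < q_max & switch(direction,
    up = res$log2fc > lfc_min,
    down = res$log2fc < -lfc_min,
    both = abs(res$log2fc) > lfc_min)
  genes <- res$gene_id[keep]
  if (length(genes) == 0L) return(NULL)
  gene_set(name, genes)
}

#' Derive the invasiveness signature
#'
#' Three-way intersection of (i) genes up in carcinoma versus the
#' premalignant group, (ii) genes up in carcinoma versus normal tissue and
#' (iii) the anchor-correlated signature. Run on the published inputs this
#' recovers the 7-gene invasiveness subset of the 24-gene stromal signature.
#'
#' @param up_vs_premalignant,up_vs_normal [gene_set()]s of up-regulated
#'   genes from the two contrasts (or `NULL`).
#' @param anchor_signature the anchor-correlated [gene_set()] (nonempty).
#' @param name name for the result.
#' @return a [gene_set()] in deterministic sorted order, or `NULL` when the
#'   intersection is empty.
#' @export
derive_invasive_signature <- function(up_vs_premalignant, up_vs_normal,
                                      anchor_signature,
                                      name = "invasive_signature") {
  if (is.null(anchor_signature) || length(anchor_signature$genes) == 0L)
    stop("anchor signature must be nonempty", call. = FALSE)
  intersect_signatures(list(up_vs_premalignant, up_vs_normal,
                            anchor_signature), name = name)
}
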