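# Anchor-gene correlation screen, BH adjustment, threshold selection and
# cross-cohort intersection -- the signature-derivation core.

#' Correlate every gene to an anchor gene
#'
#' Pearson correlation of each non-anchor gene row with the anchor row.
#' Two-sided p-values come from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom; q-values are Benjamini-Hochberg adjusted
#' across all screened genes of the matrix (the within-cohort universe).
#' Genes with zero variance are excluded (count reported via message).
#'
#' @param mat numeric expression matrix, genes in rows.
#' @param anchor anchor gene id (harmonized before lookup).
#' @return data.frame with columns `gene_id`, `r`, `p`, `q`, `n_used`,
#'   one row per screened gene; the anchor itself is absent.
#' @export
correlate_to_anchor <- function(mat, anchor = "SALL4") {
  validate_expression(mat)
  anchor <- harmonize_gene_ids(anchor)
  rn <- harmonize_gene_ids(rownames(mat))
  idx <- match(anchor, rn)
  if (is.na(idx))
    stop("anchor gene '", anchor, "' not found in matrix", call. = FALSE)
  n <- ncol(mat)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  a <- mat[idx, ]
  if (stats::sd(a) == 0)
    stop("anchor gene '", anchor, "' has zero variance", call. = FALSE)
  others <- mat[-idx, , drop = FALSE]
  rv <- rowSums((others - rowMeans(others))^2)
  degenerate <- rv == 0
  if (any(degenerate))
    message("correlate_to_anchor: excluding ", sum(degenerate),
            " zero-variance gene(s)")
  others <- others[!degenerate, , drop = FALSE]
  if (nrow(others) == 0L)
    stop("no gene with positive variance to screen", call. = FALSE)
  r <- as.vector(stats::cor(t(others), a))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] even at |r| = 1
  data.frame(gene_id = harmonize_gene_ids(rownames(others)),
             r = r, p = p, q = bh_adjust(p), n_used = n,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select anchor-correlated genes by threshold
#'
#' Applies the screen's cutoffs with strict inequalities: `q < q_max` and
#' `r > r_min` (one-sided positive, the default) or `|r| > r_min`
#' (`sided = "absolute"`).
#'
#' @param res result of [correlate_to_anchor()].
#' @param r_min correlation cutoff in `[0, 1)`.
#' @param q_max adjusted-p cutoff in `(0, 1]`.
#' @param sided `"positive"` or `"absolute"`.
#' @param name name for the returned set.
#' @return a [gene_set()], or `NULL` when no gene passes (an empty selection
#'   is a valid outcome, not an error).
#' @export
select_correlated <- function(res, r_min = 0.4, q_max = 0.05,
                              sided = c("positive", "absolute"),
                              name = "anchor_correlated") {
  sided <- match.arg(sided)
  stopifnot(all(c("gene_id", "r", "q") %in% names(res)),
            r_min >= 0, r_min < 1, q_max > 0, q_max <= 1)
  keep <- res$q < q_max &
    (if (sided == "positive") res$r > r_min else abs(res$r) > r_min)
  genes <- res$gene_id[keep]
  if (length(genes) == 0L) return(NULL)
  gene_set(name, genes)
}

#' Intersect gene sets across cohorts
#'
#' Exact set intersection after identifier harmonization; the result is
#' sorted for determinism. A `NULL` entry (an empty per-cohort selection)
#' short-circuits to an empty intersection.
#'
#' @param sets list of [gene_set()]s (or `NULL`s), length >= 2.
#' @param name name for the intersection signature.
#' @return a [gene_set()], or `NULL` when the intersection is empty.
#' @export
intersect_signatures <- function(sets, name = "signature") {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (any(vapply(sets, is.null, NA))) return(NULL)
  gene_lists <- lapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    harmonize_gene_ids(s$genes)
  })
  common <- sort(Reduce(intersect, gene_lists))
  if (length(common) == 0L) return(NULL)
  gene_set(name, common)
}

#' Full multi-cohort screen-and-intersect
#'
#' Convenience wrapper: screens each cohort against the anchor, applies the
#' per-cohort correlation cutoffs and the shared q cutoff, and intersects.
#'
#' @param mats list of expression matrices.
#' @param anchor anchor gene id.
#' @param r_min numeric vector of per-cohort correlation cutoffs (recycled).
#' @param q_max adjusted-p cutoff shared by all cohorts.
#' @param sided passed to [select_correlated()].
#' @param name signature name.
#' @return list with `screens` (per-cohort screen tables), `selected`
#'   (per-cohort gene sets) and `signature` (the intersection, or `NULL`).
#' @export
derive_anchor_signature <- function(mats, anchor = "SALL4", r_min = 0.4,
                                    q_max = 0.05,
                                    sided = c("positive", "absolute"),
                                    name = "anchor_signature") {
  sided <- match.arg(sided)
  stopifnot(is.list(mats), length(mats) >= 2)
  r_min <- rep_len(r_min, length(mats))
  screens <- lapply(mats, correlate_to_anchor, anchor = anchor)
  selected <- mapply(function(res, rm, i) {
    select_correlated(res, r_min = rm, q_max = q_max, sided = sided,
                      name = sprintf("cohort%d_selected", i))
  }, screens, r_min, seq_along(screens), SIMPLIFY = FALSE)
  list(screens = screens, selected = selected,
       signature = intersect_signatures(selected, name = name))
}
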