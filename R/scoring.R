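# Per-sample scoring of gene sets: row z-scoring, mean-z signature scores,
# marker-set (MCP-counter-style) population scores, and a generic
# hypergeometric over-representation test.

#' Z-score matrix rows
#'
#' Centers each gene row to mean 0 and scales to sample standard deviation
#' 1 (denominator n - 1). Zero-variance rows are dropped with a warning.
#'
#' @param mat numeric matrix, genes in rows, >= 2 samples.
#' @return the row-standardized matrix.
#' @export
zscore_rows <- function(mat) {
  validate_expression(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples to z-score", call. = FALSE)
  m <- rowMeans(mat)
  s <- sqrt(rowSums((mat - m)^2) / (ncol(mat) - 1))
  degenerate <- s == 0
  if (all(degenerate))
    stop("every row has zero variance; nothing to z-score", call. = FALSE)
  if (any(degenerate))
    warning("zscore_rows: dropping ", sum(degenerate),
            " zero-variance row(s)", call. = FALSE)
  (mat[!degenerate, , drop = FALSE] - m[!degenerate]) / s[!degenerate]
}

# Match a gene set against matrix rows after harmonization; returns row
# indices, reporting how many set members are absent.
.match_set <- function(mat, set, warn_missing = TRUE) {
  rn <- harmonize_gene_ids(rownames(mat))
  idx <- match(set$genes, rn)
  if (warn_missing && any(is.na(idx)))
    message("gene set '", set$name, "': ", sum(is.na(idx)),
            " of ", length(idx), " gene(s) absent from matrix")
  idx[!is.na(idx)]
}

#' Signature score per sample
#'
#' `method = "mean_z"`: the mean over signature genes of row-z-scored
#' expression. A convention, documented as such: gene weights are equal and
#' each gene contributes on the z scale, which makes the score invariant
#' under gene-wise affine rescaling of the input.
#'
#' @param mat numeric expression matrix, genes in rows.
#' @param sig a [gene_set()]; members absent from the matrix are reported
#'   and skipped.
#' @param method scoring method (only `"mean_z"`).
#' @return named numeric vector, one score per sample.
#' @export
signature_score <- function(mat, sig, method = "mean_z") {
  method <- match.arg(method, "mean_z")
  stopifnot(inherits(sig, "gene_set"))
  idx <- .match_set(mat, sig)
  if (length(idx) == 0L)
    stop("no gene of set '", sig$name, "' is present in the matrix",
         call. = FALSE)
  z <- zscore_rows(mat[idx, , drop = FALSE])
  colMeans(z)
}

#' Marker-set population scores
#'
#' MCP-counter-style aggregation: the per-sample arithmetic mean of raw
#' (log-scale, not z-scored) expression over each population's marker genes.
#' Scores are comparable between samples within a population, not across
#' populations.
#'
#' @param mat numeric log-scale matrix, genes in rows.
#' @param marker_sets list of [gene_set()]s, one per cell population.
#' @return numeric matrix, populations in rows, samples in columns;
#'   populations whose markers are entirely absent are skipped with a
#'   warning.
#' @export
marker_population_score <- function(mat, marker_sets) {
  validate_expression(mat)
  if (inherits(marker_sets, "gene_set")) marker_sets <- list(marker_sets)
  rows <- lapply(marker_sets, function(s) {
    idx <- .match_set(mat, s)
    if (length(idx) == 0L) {
      warning("marker set '", s$name, "' entirely absent; skipped",
              call. = FALSE)
      return(NULL)
    }
    colMeans(mat[idx, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, NA)
  if (!any(keep)) stop("no marker set overlaps the matrix", call. = FALSE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- vapply(marker_sets[keep], `[[`, "", "name")
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query and the set, with
#' the supplied universe as the sampling population. Query genes outside
#' the universe are dropped with a warning; annotation sets are intersected
#' with the universe. q-values are BH adjusted across annotation sets.
#'
#' @param query a [gene_set()] of genes of interest.
#' @param annotations list of annotation [gene_set()]s.
#' @param universe a [gene_set()] defining the gene universe (for matrix
#'   based analyses, all genes of the analyzed matrix).
#' @param q_max significance cutoff on the adjusted p (default 0.01).
#' @return data.frame with one row per annotation set: `set_name`,
#'   `overlap`, `set_size`, `query_size`, `universe_size`, `p`, `q`,
#'   `significant`.
#' @export
ora_hypergeometric <- function(query, annotations, universe, q_max = 0.01) {
  stopifnot(inherits(query, "gene_set"), inherits(universe, "gene_set"),
            is.list(annotations))
  uni <- universe$genes
  if (length(uni) == 0L) stop("empty universe", call. = FALSE)
  q_genes <- intersect(query$genes, uni)
  if (length(q_genes) < length(query$genes))
    warning("dropping ", length(query$genes) - length(q_genes),
            " query gene(s) outside the universe", call. = FALSE)
  n_q <- length(q_genes)
  rows <- lapply(annotations, function(s) {
    stopifnot(inherits(s, "gene_set"))
    set_genes <- intersect(s$genes, uni)
    ov <- length(intersect(q_genes, set_genes))
    p <- stats::phyper(ov - 1L, length(set_genes),
                       length(uni) - length(set_genes), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = s$name, overlap = ov, set_size = length(set_genes),
               query_size = n_q, universe_size = length(uni),
               p = min(max(p, 0), 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p <- pmax(out$p, .Machine$double.xmin)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_max
  out[order(out$p), , drop = FALSE]
}
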