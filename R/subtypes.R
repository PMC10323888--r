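# Cross-cohort molecular subtype machinery: nearest-centroid models built
# from one-versus-all differential expression, Pearson-correlation
# assignment, and single-pass hierarchical clustering on correlation
# distance with score-ordered branch labels.

#' Build per-subtype centroids
#'
#' For every subtype, a one-versus-all differential analysis
#' (subtype vs all remaining samples) ranks genes by ascending p-value
#' (ties broken by descending |t|); the top `n_top` genes form the
#' subtype's signature and the centroid is the mean expression profile of
#' the subtype's samples over those genes. Each centroid lives on its own
#' signature gene space.
#'
#' @param mat numeric expression matrix, genes in rows.
#' @param labels per-sample subtype factor (>= 2 levels, each with >= 3
#'   samples).
#' @param n_top signature size per subtype (default 1000; capped at the
#'   number of genes with a warning).
#' @param method DE method passed to [dge()].
#' @return object of class `centroid_model`: named list with one element
#'   per subtype, each holding `genes` and `centroid`.
#' @export
build_centroids <- function(mat, labels, n_top = 1000,
                            method = c("moderated", "welch")) {
  method <- match.arg(method)
  validate_expression(mat)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(mat))
    stop("labels must have one entry per sample", call. = FALSE)
  if (nlevels(labels) < 2)
    stop("need at least two subtypes", call. = FALSE)
  small <- names(which(table(labels) < 3))
  if (length(small))
    stop("subtype(s) with fewer than 3 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  if (n_top > nrow(mat)) {
    warning("n_top exceeds gene count; capped at ", nrow(mat), call. = FALSE)
    n_top <- nrow(mat)
  }
  model <- lapply(levels(labels), function(s) {
    ova <- factor(ifelse(labels == s, s, "rest"), levels = c("rest", s))
    res <- dge(mat, ova, method = method)
    ord <- order(res$p, -abs(res$t))
    genes <- res$gene_id[ord][seq_len(n_top)]
    centroid <- rowMeans(mat[genes, labels == s, drop = FALSE])
    list(genes = genes, centroid = centroid)
  })
  names(model) <- levels(labels)
  structure(model, class = "centroid_model", n_top = n_top)
}

#' Assign samples to subtypes by centroid correlation
#'
#' For each sample and each subtype, the Pearson correlation between the
#' sample's expression restricted to that subtype's signature genes and
#' the subtype centroid; the assigned label is the argmax. Exact ties go
#' to the lexicographically first subtype and are flagged; a sample whose
#' correlations are all undefined (zero variance) is labeled `unassigned`.
#'
#' @param mat numeric expression matrix of the cohort to classify.
#' @param model a [build_centroids()] model; each subtype needs >= 3 of its
#'   signature genes present in `mat`.
#' @return data.frame with `sample_id`, `label`, `tie`, and one correlation
#'   column `r_<subtype>` per subtype.
#' @export
assign_by_centroid <- function(mat, model) {
  stopifnot(inherits(model, "centroid_model"))
  validate_expression(mat)
  rn <- harmonize_gene_ids(rownames(mat))
  cors <- sapply(names(model), function(s) {
    genes <- harmonize_gene_ids(model[[s]]$genes)
    idx <- match(genes, rn)
    ok <- !is.na(idx)
    if (sum(ok) < 3)
      stop("subtype '", s, "': fewer than 3 signature genes present",
           call. = FALSE)
    suppressWarnings(
      as.vector(stats::cor(mat[idx[ok], , drop = FALSE],
                           model[[s]]$centroid[ok])))
  })
  cors <- matrix(cors, nrow = ncol(mat),
                 dimnames = list(colnames(mat), names(model)))
  subtypes <- sort(colnames(cors))   # lexicographic tie order
  labels <- character(nrow(cors)); tie <- logical(nrow(cors))
  for (i in seq_len(nrow(cors))) {
    r <- cors[i, subtypes]
    if (all(is.na(r))) { labels[i] <- "unassigned"; next }
    best <- max(r, na.rm = TRUE)
    hit <- subtypes[!is.na(r) & r == best]
    labels[i] <- hit[1L]
    tie[i] <- length(hit) > 1L
  }
  out <- data.frame(sample_id = rownames(cors), label = labels, tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(cors) <- paste0("r_", colnames(cors))
  cbind(out, as.data.frame(cors, row.names = NULL))
}

#' Cluster samples on correlation distance
#'
#' Single-pass agglomerative clustering (average linkage) of samples on
#' `1 - Pearson r` computed over a gene set, cut into `k` branches.
#' Branches are relabeled deterministically in increasing order of their
#' mean `score_for_labeling` (`C1` = lowest score), a reproducible stand-in
#' for manual branch annotation.
#'
#' @param mat numeric expression matrix.
#' @param genes a [gene_set()] (>= 2 members present in `mat`).
#' @param k number of clusters (<= number of samples).
#' @param score_for_labeling named per-sample numeric score used to order
#'   branch labels.
#' @return factor of cluster labels `C1..Ck`, named by sample, with the
#'   per-branch mean scores as attribute `branch_score`.
#' @export
consensus_cluster <- function(mat, genes, k, score_for_labeling) {
  validate_expression(mat)
  stopifnot(inherits(genes, "gene_set"), is.numeric(score_for_labeling))
  if (k > ncol(mat)) stop("k exceeds the number of samples", call. = FALSE)
  idx <- .match_set(mat, genes)
  if (length(idx) < 2)
    stop("fewer than 2 genes of the set present in the matrix",
         call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(mat[idx, , drop = FALSE]))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = k)
  score <- score_for_labeling[colnames(mat)]
  branch_mean <- tapply(score, raw, mean)
  ord <- order(branch_mean)
  relabel <- stats::setNames(sprintf("C%d", order(ord)), names(branch_mean))
  labels <- factor(relabel[as.character(raw)],
                   levels = sprintf("C%d", seq_len(k)))
  names(labels) <- colnames(mat)
  attr(labels, "branch_score") <-
    stats::setNames(as.vector(branch_mean)[ord], sprintf("C%d", seq_len(k)))
  labels
}
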