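# Readers/writers for the plain-text formats the pipeline touches, plus
# identifier harmonization and probe-to-gene collapsing.
#
# An expression matrix is an ordinary numeric matrix, genes in rows
# (rownames = gene ids, colnames = sample ids), on a log scale.
# A survival table is a data.frame with columns sample_id, os_months,
# os_event; any further columns are covariates.
# A gene set is the list structure produced by gene_set().

#' Harmonize gene identifiers
#'
#' Uppercases and strips surrounding whitespace. Applied internally before
#' every set operation so that cohorts annotated with drifting symbol case
#' still intersect; exported because callers preparing their own sets will
#' want the same convention.
#'
#' @param x character vector of gene identifiers.
#' @return character vector of harmonized identifiers.
#' @export
harmonize_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a gene set
#'
#' @param name set name (nonempty string).
#' @param genes character vector of gene ids; duplicates are removed,
#'   identifiers are harmonized with [harmonize_gene_ids()].
#' @param description free-text description (GMT second field).
#' @return an object of class `gene_set`: a list with elements `name`,
#'   `description` and `genes`.
#' @export
gene_set <- function(name, genes, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(harmonize_gene_ids(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L)
    stop("gene set '", name, "' has no genes", call. = FALSE)
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", length(x$genes), " genes)\n", sep = "")
  cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) ", ...", "\n", sep = "")
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

validate_expression <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop(what, " must carry gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(mat)[duplicated(rownames(mat))]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- colnames(mat)[duplicated(colnames(mat))]
  if (length(dup))
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(mat)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(mat)
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file (TSV or CSV, chosen by extension) with a
#' header row and row identifiers in the first column. Values must be
#' numeric and finite. Duplicate row identifiers are only legal when a
#' probe map is supplied, in which case rows are collapsed to genes with
#' [collapse_probes()].
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`;
#'   the returned matrix always has genes in rows.
#' @param probe_map optional data.frame with columns `probe_id`, `gene_id`.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            probe_map = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("format error: expected a header row and at least one data column in ",
         path, call. = FALSE)
  row_ids <- trimws(as.character(df[[1L]]))
  col_ids <- colnames(df)[-1L]   # before subsetting: [.data.frame dedups names
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop("parse error: non-numeric value at row ", row_ids[bad],
           ", column '", col_ids[j], "' in ", path, call. = FALSE)
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- row_ids
  colnames(mat) <- col_ids
  if (orientation == "samples_in_rows") mat <- t(mat)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(rownames(mat))) {
    if (is.null(probe_map)) {
      dup <- unique(rownames(mat)[duplicated(rownames(mat))])
      stop("duplicate gene ids (supply a probe_map to collapse): ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    return(collapse_probes(mat, probe_map))
  }
  if (!is.null(probe_map)) return(collapse_probes(mat, probe_map))
  validate_expression(mat)
  mat
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: first column `gene_id`, header row of
#' sample ids, delimiter chosen by extension.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene-level rows
#'
#' For genes measured by several probes the gene's expression is the
#' arithmetic mean of its probe rows, per sample. Probes absent from the
#' map are dropped (count reported via message).
#'
#' @param mat numeric matrix keyed by probe ids.
#' @param probe_map data.frame with columns `probe_id` and `gene_id`; every
#'   probe maps to exactly one gene.
#' @return numeric matrix keyed by gene ids.
#' @export
collapse_probes <- function(mat, probe_map) {
  stopifnot(is.matrix(mat), is.data.frame(probe_map),
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id))
    stop("probe map assigns some probe to more than one gene", call. = FALSE)
  if (any(!nzchar(trimws(probe_map$gene_id))))
    stop("probe map contains empty gene ids", call. = FALSE)
  gene_of <- stats::setNames(harmonize_gene_ids(probe_map$gene_id),
                             trimws(probe_map$probe_id))
  probes <- rownames(mat)
  mapped <- probes %in% names(gene_of)
  if (sum(!mapped) > 0L)
    message("collapse_probes: dropping ", sum(!mapped), " unmapped probe(s)")
  if (!any(mapped))
    stop("no probe in the matrix is present in the probe map", call. = FALSE)
  sub <- mat[mapped, , drop = FALSE]
  grp <- gene_of[rownames(sub)]
  sums <- rowsum(sub, group = grp, reorder = TRUE)
  counts <- as.vector(table(grp)[rownames(sums)])
  out <- sums / counts
  validate_expression(out)
  out
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one tab-separated set per line, fields
#' `name`, `description`, `gene1`, ..., `geneN`.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT format error at line ", i, ": expected name, description ",
           "and at least one gene", call. = FALSE)
    sets[[i]] <- gene_set(f[1L], f[-(1:2)], description = f[2L])
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' CSV with required columns `sample_id`, `os_months` (months, >= 0) and
#' `os_event` (1 = death, 0 = censored); any extra columns are carried
#' along verbatim as covariates.
#'
#' @param path CSV path.
#' @return data.frame with the columns above.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_survival(df)
  df
}

#' @rdname read_survival
#' @param surv survival table.
#' @export
write_survival <- function(surv, path) {
  validate_survival(surv)
  utils::write.csv(surv, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_survival <- function(surv) {
  req <- c("sample_id", "os_months", "os_event")
  missing <- setdiff(req, names(surv))
  if (length(missing))
    stop("survival table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(surv$sample_id))
    stop("duplicate sample ids in survival table", call. = FALSE)
  if (any(!is.finite(surv$os_months)) || any(surv$os_months < 0))
    stop("os_months must be finite and non-negative", call. = FALSE)
  if (!all(surv$os_event %in% c(0, 1)))
    stop("os_event must be 0 (censored) or 1 (death)", call. = FALSE)
  invisible(surv)
}
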