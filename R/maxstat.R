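# Maximally selected log-rank statistics (Hothorn-Lausen style cutpoint
# selection) with a permutation p-value.
#
# The search evaluates the standardized two-group log-rank statistic at
# every admissible cutpoint of a continuous score. It is vectorized: for a
# given entry order of samples into the "high" group (samples sorted by
# decreasing score), the group-1 at-risk and event counts at every distinct
# event time are cumulative block sums, so all candidate statistics come
# from one K x C matrix computation. Permutation replicates reuse the same
# machinery with a random entry order, which is exactly a random
# score-survival relabeling.

# Per-dataset constants for the vectorized search.
.ms_prepare <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  K <- length(et)
  if (K == 0L) stop("no events observed", call. = FALSE)
  at_risk <- outer(et, time, "<=")            # K x n logical
  is_ev <- outer(et, time, "==") & rep(event == 1, each = K)
  ni <- rowSums(at_risk)
  di <- rowSums(is_ev)
  w2 <- ifelse(ni > 1, (ni - di) / (ni - 1), 0)
  list(A = at_risk * 1, B = is_ev * 1, ni = ni, di = di, w2 = w2, K = K)
}

# Standardized log-rank z at each candidate position (number of samples in
# the high group), for a given entry order of the n samples.
.ms_stats <- function(prep, ord, positions) {
  A <- prep$A[, ord, drop = FALSE]
  B <- prep$B[, ord, drop = FALSE]
  C <- length(positions)
  n1 <- matrix(0, prep$K, C)
  d1 <- matrix(0, prep$K, C)
  run_a <- numeric(prep$K)
  run_b <- numeric(prep$K)
  prev <- 0L
  for (c in seq_len(C)) {
    idx <- (prev + 1L):positions[c]
    run_a <- run_a + rowSums(A[, idx, drop = FALSE])
    run_b <- run_b + rowSums(B[, idx, drop = FALSE])
    n1[, c] <- run_a
    d1[, c] <- run_b
    prev <- positions[c]
  }
  U <- colSums(d1 - (n1 * prep$di) / prep$ni)
  P <- n1 / prep$ni
  V <- colSums(prep$di * P * (1 - P) * prep$w2)
  z <- ifelse(V > 0, U / sqrt(V), NA_real_)
  z
}

#' Maximally selected log-rank cutpoint
#'
#' Candidate cutpoints are the midpoints between consecutive distinct score
#' values whose split leaves at least `ceil(minprop * n)` samples on each
#' side. Each candidate is scored by the standardized two-group log-rank
#' statistic (|z|, identical to [logrank_test()] on the induced split); the
#' selected cutpoint maximizes |z| (ties resolved toward the smallest
#' cutpoint). Significance is assessed by a permutation test: scores are
#' randomly relabeled against the survival data `n_perm` times and
#' `p_perm = (1 + #{perm max >= observed max}) / (1 + n_perm)`.
#'
#' @param score named numeric vector of per-sample scores (names = sample
#'   ids, matched against `surv$sample_id`).
#' @param surv survival table.
#' @param minprop minimum fraction of samples on each side of a cut
#'   (default 0.1).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return object of class `cutpoint_result`: `cutpoint`, `max_stat`,
#'   `p_perm`, `n_candidates`, `groups` (factor `low`/`high` named by
#'   sample), `candidates` (data.frame of cutpoint, n_high, z).
#' @export
maxstat_cutpoint <- function(score, surv, minprop = 0.1, n_perm = 1000,
                             seed = 1) {
  stopifnot(is.numeric(score), minprop > 0, minprop < 0.5, n_perm >= 0)
  sv <- .surv_vectors(surv)
  if (is.null(names(score)))
    stop("score must be named by sample id", call. = FALSE)
  idx <- match(sv$id, names(score))
  if (any(is.na(idx)))
    stop("samples missing from score vector: ",
         paste(utils::head(sv$id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  score <- score[idx]
  n <- length(score)
  cmin <- ceiling(minprop * n)
  if (2 * cmin > n) stop("too few samples for minprop = ", minprop,
                         call. = FALSE)

  # candidate positions: counts of samples strictly above each admissible
  # boundary between consecutive distinct score values
  ss <- sort(score, decreasing = TRUE)
  bound <- which(ss[-n] != ss[-1L])   # i: boundary between ss[i] and ss[i+1]
  if (length(bound) == 0L)
    stop("scores are constant; no candidate cutpoint", call. = FALSE)
  admissible <- bound >= cmin & (n - bound) >= cmin
  if (!any(admissible))
    stop("no admissible candidate cutpoint under minprop = ", minprop,
         call. = FALSE)
  positions <- bound[admissible]
  cutvals <- unname((ss[positions] + ss[positions + 1L]) / 2)

  prep <- .ms_prepare(sv$time, sv$event)
  ord_obs <- order(score, decreasing = TRUE)
  z_obs <- .ms_stats(prep, ord_obs, positions)
  absz <- abs(z_obs)
  if (all(is.na(absz)))
    stop("log-rank variance is zero at every candidate", call. = FALSE)
  max_stat <- max(absz, na.rm = TRUE)
  # cutvals decrease with position; smallest cutpoint on ties = last argmax
  hit <- which(!is.na(absz) & absz == max_stat)
  best <- hit[length(hit)]
  cutpoint <- cutvals[best]

  p_perm <- NA_real_
  perm_max <- numeric(0)
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    perm_max <- vapply(seq_len(n_perm), function(b) {
      z <- .ms_stats(prep, sample.int(n), positions)
      if (all(is.na(z))) -Inf else max(abs(z), na.rm = TRUE)
    }, 0)
    p_perm <- (1 + sum(perm_max >= max_stat)) / (1 + n_perm)
  }

  groups <- factor(ifelse(score > cutpoint, "high", "low"),
                   levels = c("low", "high"))
  names(groups) <- sv$id
  out <- list(cutpoint = cutpoint, max_stat = max_stat, p_perm = p_perm,
              n_candidates = length(positions), groups = groups,
              candidates = data.frame(cutpoint = cutvals,
                                      n_high = as.integer(positions),
                                      z = z_obs))
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("maximally selected log-rank cutpoint\n")
  cat("  cutpoint: ", format(x$cutpoint, digits = 4),
      "  (", sum(x$groups == "high"), " high / ",
      sum(x$groups == "low"), " low)\n", sep = "")
  cat("  max |z|: ", format(x$max_stat, digits = 4),
      "  over ", x$n_candidates, " candidates\n", sep = "")
  cat("  permutation p: ", format.pval(x$p_perm, digits = 3), "\n", sep = "")
  invisible(x)
}
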