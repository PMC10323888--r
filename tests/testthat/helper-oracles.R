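# Independent oracles used across the suite. Each re-derives the quantity
# from its textbook definition, independently of the package's code paths.

# Benjamini-Hochberg step-up from the definition: on sorted p-values,
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1, mapped back.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, (m / i) * p[o[i]])
    q[o[i]] <- min(running, 1)
  }
  q
}

# Textbook Pearson correlation and its t-test from raw sums.
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Exhaustive maximally-selected search from the definition: every midpoint
# between consecutive distinct score values with >= ceil(minprop n) samples
# per side, each evaluated with logrank_test.
brute_maxstat <- function(score, surv, minprop = 0.1) {
  n <- length(score)
  cmin <- ceiling(minprop * n)
  score <- score[match(surv$sample_id, names(score))]
  vals <- sort(unique(score))
  cuts <- (vals[-1] + vals[-length(vals)]) / 2
  best <- NULL
  for (cut in cuts) {
    grp <- factor(ifelse(score > cut, "high", "low"),
                  levels = c("low", "high"))
    if (sum(grp == "high") < cmin || sum(grp == "low") < cmin) next
    z <- tryCatch(abs(logrank_test(surv, grp)$z), error = function(e) NA)
    if (is.na(z)) next
    if (is.null(best) || z > best$z ||
        (z == best$z && cut < best$cut)) best <- list(cut = cut, z = z)
  }
  best
}

# Random right-censored survival data with unique ids.
random_surv <- function(n, event_rate = 0.05, censor_max = 40) {
  t_ev <- stats::rexp(n, event_rate)
  t_cn <- stats::runif(n, 0, censor_max)
  data.frame(sample_id = sprintf("R%04d", seq_len(n)),
             os_months = pmin(t_ev, t_cn),
             os_event = as.integer(t_ev <= t_cn),
             stringsAsFactors = FALSE)
}

# Hand-evaluated Welch t-test for a single gene.
brute_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

# Exact upper-tail hypergeometric by combinatorial counting (and, for tiny
# universes, by literal enumeration of all query subsets).
brute_hyper <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size,
                                    query_size - ks)) /
    choose(universe_size, query_size)
}
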