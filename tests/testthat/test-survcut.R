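surv_df <- function(time, event, prefix = "S") {
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_along(time)),
             os_months = time, os_event = as.integer(event),
             stringsAsFactors = FALSE)
}

test_that("product-limit estimator matches hand-computed toy tables", {
  # three deaths, no censoring
  km <- km_estimate(surv_df(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(km$median, 2)
  # one censored at 2: 3/4 at t=1, 3/4 * 1/2 at t=3, 0 at t=4
  km2 <- km_estimate(surv_df(c(1, 2, 3, 4), c(1, 0, 1, 1)))
  expect_equal(km2$time, c(1, 3, 4))
  expect_equal(km2$surv, c(3/4, 3/8, 0), tolerance = 1e-12)
  # all censored: S never drops, median undefined
  km3 <- km_estimate(surv_df(c(1, 2, 3), c(0, 0, 0)))
  expect_length(km3$time, 0L)
  expect_true(is.na(km3$median))
  expect_error(km_estimate(surv_df(-1, 1)), "non-negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(20)
  t <- round(rexp(40, 0.1), 2)
  km <- km_estimate(surv_df(t, rep(1, 40)))
  for (i in seq_along(km$time))
    expect_equal(km$surv[i], mean(t > km$time[i]), tolerance = 1e-12)
})

test_that("KM estimates and median CI agree with survfit (log-log)", {
  set.seed(33)
  surv <- random_surv(80)
  km <- km_estimate(surv)
  fit <- survival::survfit(
    survival::Surv(os_months, os_event) ~ 1, data = surv,
    conf.type = "log-log")
  sm <- summary(fit, times = km$time)
  expect_equal(km$surv, sm$surv, tolerance = 1e-10)
  expect_equal(km$lower, sm$lower, tolerance = 1e-8)
  expect_equal(km$upper, sm$upper, tolerance = 1e-8)
  q <- quantile(fit, probs = 0.5)
  expect_equal(km$median, unname(q$quantile), tolerance = 1e-10)
  expect_equal(unname(km$median_ci),
               c(unname(q$lower), unname(q$upper)), tolerance = 1e-10)
})

test_that("log-rank U and V match the hand-computed O-E table", {
  # g1 = (1, 2) events, g2 = (3, 4) events:
  # t=1: U += 1 - 2/4, V += (2/4)(2/4)(3/3); t=2: U += 1 - 1/3,
  # V += (1/3)(2/3); t=3,4: no group-1 subjects at risk contribute 0
  surv <- surv_df(c(1, 2, 3, 4), c(1, 1, 1, 1))
  lr <- logrank_test(surv, factor(c("g1", "g1", "g2", "g2")))
  expect_equal(lr$U, 7/6, tolerance = 1e-12)
  expect_equal(lr$V, 0.25 + 2/9, tolerance = 1e-12)
  expect_equal(lr$chi2, (7/6)^2 / (17/36), tolerance = 1e-12)
  expect_equal(lr$z^2, lr$chi2, tolerance = 1e-12)
})

test_that("identical interleaved groups give U = 0", {
  t <- c(1, 1, 2, 2, 5, 5, 9, 9)
  e <- c(1, 1, 0, 0, 1, 1, 1, 1)
  lr <- logrank_test(surv_df(t, e), factor(rep(c("a", "b"), 4)))
  expect_lt(abs(lr$U), 1e-12)
  expect_lt(lr$chi2, 1e-20)
})

test_that("swapping group labels negates U, keeps chi2 and p", {
  set.seed(44)
  surv <- random_surv(60)
  g <- factor(sample(c("a", "b"), 60, replace = TRUE))
  lr1 <- logrank_test(surv, g)
  lr2 <- logrank_test(surv, factor(g, levels = c("b", "a")))
  expect_equal(lr2$U, -lr1$U, tolerance = 1e-12)
  expect_equal(lr2$chi2, lr1$chi2, tolerance = 1e-12)
  expect_equal(lr2$p, lr1$p, tolerance = 1e-12)
})

test_that("log-rank chi2 matches survdiff on random datasets", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    surv <- random_surv(n)
    g <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (min(table(g)) < 2 || sum(surv$os_event) < 2) next
    lr <- logrank_test(surv, g)
    sd <- survival::survdiff(
      survival::Surv(os_months, os_event) ~ g, data = cbind(surv, g = g))
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
  }
})

test_that("degenerate log-rank inputs raise errors", {
  surv <- surv_df(c(1, 2, 3), c(1, 1, 1))
  expect_error(logrank_test(surv, factor(c("a", "a", "a"))), "two")
  expect_error(logrank_test(surv_df(c(1, 2), c(0, 0)),
                            factor(c("a", "b"))), "events")
})

test_that("quantile dichotomization labels the top third high", {
  sc <- setNames(as.numeric(1:9), sprintf("S%03d", 1:9))
  cat3 <- categorize_by_quantile(sc, q = 2/3)
  expect_equal(sum(cat3$labels == "high"), 3L)
  expect_equal(unname(cat3$threshold),
               unname(quantile(sc, 2/3, type = 7)))
  expect_error(categorize_by_quantile(rep(1, 5)), "constant")
})

test_that("ties at the threshold fall low", {
  sc <- setNames(c(rep(5, 6), 6, 7, 8), sprintf("S%03d", 1:9))
  cat3 <- categorize_by_quantile(sc, q = 2/3)
  # threshold lands inside the tie mass at 5: none of the tied samples high
  expect_true(all(cat3$labels[sc == 5] == "low"))
  expect_lte(mean(cat3$labels == "high"), 1/3 + 1e-12)
  set.seed(66)
  for (i in 1:20) {
    s <- setNames(sample(round(rnorm(8), 1), 30, replace = TRUE),
                  sprintf("S%03d", 1:30))
    if (length(unique(s)) < 2) next
    cc <- categorize_by_quantile(s, q = 2/3)
    tie_mass <- mean(s == cc$threshold)
    expect_lte(mean(cc$labels == "high"), 1/3 + tie_mass + 1e-12)
  }
})

test_that("quantile and maxstat groupings feed KM machinery identically", {
  set.seed(70)
  co <- generate_cohort(cohort_spec(n_samples = 80, n_genes = 60,
                                    module_genes = 5, seed = 70))
  sc <- signature_score(co$expr, co$truth$module_gene_ids)
  tert <- categorize_by_quantile(sc, 2/3)
  cut <- maxstat_cutpoint(sc, co$surv, n_perm = 0)
  for (labels in list(tert$labels, cut$groups)) {
    lr <- logrank_test(co$surv, labels[co$surv$sample_id])
    expect_s3_class(lr, "logrank_result")
    km <- km_estimate(co$surv[labels[co$surv$sample_id] == "high", ])
    expect_s3_class(km, "km_curve")
  }
})

test_that("Cox score test at beta = 0 equals the log-rank chi2", {
  set.seed(88)
  surv <- random_surv(70)
  surv$os_months <- surv$os_months + runif(70, 0, 1e-4)  # break ties
  surv$grp <- rbinom(70, 1, 0.5)
  lr <- logrank_test(surv, factor(surv$grp, levels = c(1, 0)))
  fit <- survival::coxph(survival::Surv(os_months, os_event) ~ grp,
                         data = surv, ties = "breslow")
  expect_equal(unname(fit$score), lr$chi2, tolerance = 1e-6)
})

test_that("cox_fit estimates a known hazard ratio and flags bad input", {
  n <- 500
  make_surv <- function(seed) {
    set.seed(seed)
    grp <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.04 * 2^grp)
    cens <- runif(n, 0, 60)
    data.frame(sample_id = sprintf("S%04d", 1:n),
               os_months = pmin(t_ev, cens),
               os_event = as.integer(t_ev <= cens), grp = grp)
  }
  hrs <- vapply(1:10, function(s) cox_fit(make_surv(s), "grp")$table$hazard_ratio, 0)
  expect_gt(median(hrs), 1.6)
  expect_lt(median(hrs), 2.5)
  surv <- make_surv(99)
  fit <- cox_fit(surv, "grp")
  expect_true(fit$table$ci_lo <= fit$table$hazard_ratio &
                fit$table$hazard_ratio <= fit$table$ci_hi)
  surv$flat <- 1
  expect_error(cox_fit(surv, "flat"), "zero variance")
  surv$dup <- surv$grp
  expect_error(cox_fit(surv, c("grp", "dup")), "collinear")
  expect_error(cox_fit(surv, c("grp", "grp")), "duplicated")
})

test_that("univariate screen enters only covariates below the threshold", {
  set.seed(111)
  n <- 300
  good <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  t_ev <- rexp(n, 0.05 * exp(0.8 * good))
  cens <- runif(n, 0, 50)
  surv <- data.frame(sample_id = sprintf("S%04d", 1:n),
                     os_months = pmin(t_ev, cens),
                     os_event = as.integer(t_ev <= cens),
                     good = good, noise = noise)
  fit <- cox_fit(surv, c("good", "noise"), mode = "univariate_screen")
  expect_true("good" %in% fit$entered)
  expect_false("noise" %in% fit$entered)
  expect_equal(fit$table$term, "good")
})
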