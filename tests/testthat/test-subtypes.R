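# Planted-block cohort: each subtype over-expresses its own gene block by
# `effect` standard deviations.
block_cohort <- function(n_per = 20, n_genes = 200, block = 10, effect = 1.5,
                         k = 3, noise = 1, seed = 1, prefix = "S") {
  set.seed(seed)
  labels <- factor(rep(sprintf("sub%d", seq_len(k)), each = n_per))
  n <- length(labels)
  mat <- matrix(rnorm(n_genes * n, 7, noise), n_genes,
                dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                sprintf("%s%03d", prefix, seq_len(n))))
  for (s in seq_len(k)) {
    rows <- (s - 1) * block + seq_len(block)
    mat[rows, labels == sprintf("sub%d", s)] <-
      mat[rows, labels == sprintf("sub%d", s)] + effect
  }
  list(mat = mat, labels = labels,
       blocks = lapply(seq_len(k), function(s)
         sprintf("G%04d", (s - 1) * block + seq_len(block))))
}

test_that("one-vs-all signatures recover a planted distinguishing block", {
  # two subtypes differing only in one 10-gene block: that block is the
  # entire differential structure, so both signatures equal it exactly
  set.seed(2)
  labels <- factor(rep(c("sub1", "sub2"), each = 15))
  mat <- matrix(rnorm(100 * 30, 7, 0.5), 100,
                dimnames = list(sprintf("G%04d", 1:100),
                                sprintf("S%03d", 1:30)))
  block <- sprintf("G%04d", 1:10)
  mat[block, labels == "sub1"] <- mat[block, labels == "sub1"] + 3
  model <- build_centroids(mat, labels, n_top = 10)
  expect_setequal(model$sub1$genes, block)
  expect_setequal(model$sub2$genes, block)
})

test_that("degenerate label sets are rejected; n_top is capped", {
  d <- block_cohort(n_per = 10, n_genes = 50, seed = 3)
  expect_error(build_centroids(d$mat, factor(rep("x", ncol(d$mat)))),
               "two subtypes")
  small <- d$labels
  small[1:28] <- "sub1"   # leaves sub2 with 2 samples
  expect_error(build_centroids(d$mat, droplevels(small)), "fewer than 3")
  expect_warning(model <- build_centroids(d$mat, d$labels, n_top = 999),
                 "capped")
  expect_length(model$sub1$genes, 50L)
})

test_that("the model is invariant to sample order", {
  d <- block_cohort(seed = 5)
  perm <- sample(ncol(d$mat))
  m1 <- build_centroids(d$mat, d$labels, n_top = 20)
  m2 <- build_centroids(d$mat[, perm], d$labels[perm], n_top = 20)
  for (s in names(m1)) {
    expect_identical(m1[[s]]$genes, m2[[s]]$genes)
    expect_equal(m1[[s]]$centroid, m2[[s]]$centroid, tolerance = 1e-12)
  }
})

test_that("a sample equal to a centroid is assigned with r = 1", {
  d <- block_cohort(n_per = 10, n_genes = 60, block = 10, effect = 2,
                    k = 2, seed = 7)
  model <- build_centroids(d$mat, d$labels, n_top = 10)
  probe <- matrix(0, nrow(d$mat), 1,
                  dimnames = list(rownames(d$mat), "probe"))
  probe[, 1] <- rnorm(nrow(d$mat))
  probe[model$sub1$genes, 1] <- model$sub1$centroid
  out <- assign_by_centroid(cbind(d$mat[, 1, drop = FALSE], probe), model)
  expect_equal(out$label[out$sample_id == "probe"], "sub1")
  expect_equal(out$r_sub1[out$sample_id == "probe"], 1, tolerance = 1e-12)
})

test_that("noiseless block data is classified perfectly", {
  d <- block_cohort(n_per = 10, n_genes = 80, block = 10, effect = 2,
                    k = 2, noise = 1e-6, seed = 8)
  model <- build_centroids(d$mat, d$labels, n_top = 10)
  out <- assign_by_centroid(d$mat, model)
  expect_equal(mean(out$label == as.character(d$labels)), 1.0)
})

test_that("resubstitution accuracy is high on separated subtypes", {
  # signatures sized to span both the subtype's up-block and the other
  # subtypes' blocks: a correlation classifier needs centroids with
  # internal contrast
  d <- block_cohort(n_per = 20, n_genes = 150, block = 12, effect = 1.5,
                    k = 3, seed = 9)
  model <- build_centroids(d$mat, d$labels, n_top = 36)
  out <- assign_by_centroid(d$mat, model)
  expect_gte(mean(out$label == as.character(d$labels)), 0.95)
})

test_that("centroid models transfer across cohorts with independent noise", {
  accs <- sapply(1:5, function(i) {
    train <- block_cohort(n_per = 20, n_genes = 150, block = 12,
                          effect = 1.5, k = 3, seed = 100 + i)
    test <- block_cohort(n_per = 20, n_genes = 150, block = 12,
                         effect = 1.5, k = 3, seed = 200 + i, prefix = "T")
    model <- build_centroids(train$mat, train$labels, n_top = 36)
    out <- assign_by_centroid(test$mat, model)
    mean(out$label == as.character(test$labels))
  })
  expect_gte(median(accs), 0.90)
})

test_that("per-sample affine transforms do not change assignments", {
  d <- block_cohort(n_per = 10, n_genes = 80, block = 10, effect = 2,
                    k = 2, seed = 11)
  model <- build_centroids(d$mat, d$labels, n_top = 10)
  out1 <- assign_by_centroid(d$mat, model)
  shifted <- sweep(sweep(d$mat, 2, runif(ncol(d$mat), 1, 3), "*"),
                   2, rnorm(ncol(d$mat)), "+")
  out2 <- assign_by_centroid(shifted, model)
  expect_equal(out1$label, out2$label)
})

test_that("correlation-distance clustering recovers planted structure", {
  d <- block_cohort(n_per = 15, n_genes = 60, block = 20, effect = 2,
                    k = 2, noise = 1e-6, seed = 13)
  sig <- gene_set("sig", unlist(d$blocks))
  score <- setNames(as.numeric(d$labels == "sub2"), colnames(d$mat))
  cl <- consensus_cluster(d$mat, sig, k = 2, score_for_labeling = score)
  # zero noise: exact block recovery; C1 = branch with the lower score
  expect_true(all(cl[d$labels == "sub1"] == "C1"))
  expect_true(all(cl[d$labels == "sub2"] == "C2"))

  # k = n: every sample its own cluster
  cl_n <- consensus_cluster(d$mat, sig, k = ncol(d$mat),
                            score_for_labeling = score)
  expect_equal(length(unique(cl_n)), ncol(d$mat))
  expect_error(consensus_cluster(d$mat, sig, k = ncol(d$mat) + 1,
                                 score_for_labeling = score), "exceeds")
})

test_that("clustering at moderate separation agrees with the planted labels", {
  agree <- sapply(1:10, function(i) {
    d <- block_cohort(n_per = 15, n_genes = 80, block = 25, effect = 2,
                      k = 2, noise = 1, seed = 300 + i)
    sig <- gene_set("sig", unlist(d$blocks))
    score <- setNames(rnorm(ncol(d$mat)), colnames(d$mat))
    cl <- consensus_cluster(d$mat, sig, k = 2, score_for_labeling = score)
    tab <- table(cl, d$labels)
    (max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])) / sum(tab)
  })
  expect_gte(median(agree), 0.9)
})
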