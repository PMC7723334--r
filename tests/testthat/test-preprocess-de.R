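test_that("quantile normalisation forces the common sorted distribution", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4), 2, 2), conditions = c("a", "a"))
  # columns [1,2] and [3,4]: sorted-row means are (1+3)/2 = 2 and (2+4)/2 = 3
  out <- quantile_normalize(m)
  expect_equal(unname(out$values), matrix(c(2, 3, 2, 3), 2, 2))
  # identical columns are a fixed point
  v <- matrix(rnorm(20), 10, 2)
  v[, 2] <- v[, 1]
  m2 <- toy_matrix(v, conditions = c("a", "a"))
  expect_equal(quantile_normalize(m2)$values, m2$values)
  # a single-row matrix collapses to the row mean
  m3 <- toy_matrix(matrix(c(5, 9), 1, 2), conditions = c("a", "a"))
  expect_equal(unname(quantile_normalize(m3)$values), matrix(c(7, 7), 1, 2))
})

test_that("median centring zeroes row medians and is idempotent", {
  v <- matrix(c(1, 2, 3, 7, 7, 7), 2, 3, byrow = TRUE)
  out <- median_center_rows(v)
  expect_equal(out[1, ], c(-1, 0, 1))
  expect_equal(out[2, ], c(0, 0, 0))
  expect_equal(median_center_rows(out), out)
  r <- matrix(rnorm(60), 6, 10)
  expect_true(all(abs(apply(median_center_rows(r), 1, median)) < 1e-12))
})

test_that("UPGMA clustering merges nearest 1-D points first", {
  v <- matrix(c(0, 1, 10, 11), 4, 1)
  rownames(v) <- paste0("p", 1:4)
  hc <- hierarchical_cluster(v, axis = "features", distance = "euclidean")
  # first two merges join {0,1} and {10,11} at height 1
  expect_equal(sort(abs(hc$merge[1, ])), c(1, 2))
  expect_equal(sort(abs(hc$merge[2, ])), c(3, 4))
  expect_equal(hc$height[1:2], c(1, 1))
  # average linkage: final height is the mean of the 4 cross-pair distances
  expect_equal(hc$height[3], mean(c(10, 11, 9, 10)))
  k2 <- stats::cutree(hc$hclust, k = 2)
  expect_identical(unname(k2), c(1L, 1L, 2L, 2L))
  expect_match(hc$newick, "^\\(")
  # two items: single merge at their distance
  v2 <- matrix(c(0, 3), 2, 1); rownames(v2) <- c("a", "b")
  hc2 <- hierarchical_cluster(v2, axis = "features")
  expect_equal(hc2$height, 3)
  # identical items merge at height 0
  v3 <- matrix(1, 3, 2); rownames(v3) <- paste0("x", 1:3)
  expect_true(all(hierarchical_cluster(v3, axis = "features")$height == 0))
  expect_error(hierarchical_cluster(v3[1, , drop = FALSE], axis = "features"),
               ">= 2 items")
})

test_that("PCA returns centred scores, orthonormal loadings, ordered variance", {
  set.seed(1)
  latent <- rnorm(9)
  v <- outer(rnorm(20), latent)  # rank 1, no noise
  m <- toy_matrix(v)
  pc <- pca_samples(m, 2)
  expect_equal(pc$explained_variance_ratio[1], 1.0, tolerance = 1e-10)
  expect_true(all(abs(colMeans(pc$scores)) < 1e-10))
  noisy <- toy_matrix(v + matrix(rnorm(180, sd = 0.1), 20, 9))
  pc2 <- pca_samples(noisy, 3)
  expect_true(all(diff(pc2$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pc2$explained_variance_ratio), 1 + 1e-12)
  expect_equal(crossprod(pc2$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(pca_samples(m, 100), "n_components")
})

test_that("differential test follows the signed fold-change convention", {
  v <- rbind(c(5, 5, 5, 6, 6, 6),
             c(6, 6, 6, 5, 5, 5),
             c(1, 2, 3, 1, 2, 3))
  rownames(v) <- c("up2", "down2", "same")
  m <- toy_matrix(v, conditions = rep(c("a", "b"), each = 3))
  st <- differential_test(m, "a", "b")
  expect_equal(st$log2fc, c(1, -1, 0))
  expect_equal(st$fold_change, c(2, -2, 1))
  expect_equal(st$p_raw[3], 1)           # identical groups: t = 0, p = 1
  expect_equal(st$p_raw[1], 0)           # zero pooled variance, unequal means
  expect_true(st$degenerate[1])
  expect_false(st$degenerate[3])
  expect_error(differential_test(m, "a", "missing"), "condition")
  # Welch variant agrees with t.test
  set.seed(2)
  v2 <- matrix(rnorm(60), 10, 6)
  m2 <- toy_matrix(v2, conditions = rep(c("a", "b"), each = 3))
  stw <- differential_test(m2, "a", "b", var_equal = FALSE)
  ref <- apply(v2, 1, function(x) t.test(x[4:6], x[1:3])$p.value)
  expect_equal(stw$p_raw, unname(ref), tolerance = 1e-12)
})

test_that("BH and Holm adjustments match their step formulas", {
  expect_equal(adjust_bh(0.05), 0.05)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_holm(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(adjust_holm(0.2), 0.2)
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(adjust_bh(p) - bh_oracle(p))), 1e-12)
    expect_lt(max(abs(adjust_holm(p) - holm_oracle(p))), 1e-12)
    expect_true(all(adjust_bh(p) >= p & adjust_bh(p) <= 1))
    expect_true(all(adjust_holm(p) >= p & adjust_holm(p) <= 1))
  }
  expect_error(adjust_bh(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(adjust_holm(-0.1), "\\[0, 1\\]")
})

test_that("DE calls gate on both fold change and the species p mode", {
  stats <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(log2(2.5), log2(1.9), -log2(3), 0.1),
    fold_change = c(2.5, 1.9, -3, 2^0.1),
    p_raw = c(1e-5, 1e-6, 1e-5, 1e-6),
    stringsAsFactors = FALSE)
  calls <- call_de(stats, threshold_policy(), species = "mRNA")
  expect_identical(calls$direction, c("up", "not_de", "down", "not_de"))
  expect_true(all(calls$p_adj >= calls$p_raw))
  # the laxer miRNA ratio threshold admits FC 1.6
  mir <- data.frame(feature_id = "m", log2fc = log2(1.6), fold_change = 1.6,
                    p_raw = 0.001, stringsAsFactors = FALSE)
  expect_identical(call_de(mir, threshold_policy(), "miRNA")$direction, "up")
  expect_identical(call_de(mir, threshold_policy(), "mRNA")$direction, "not_de")
  # circRNA gates on raw p
  circ <- data.frame(feature_id = paste0("c", 1:20), log2fc = 1.1,
                     fold_change = 2^1.1,
                     p_raw = c(0.04, rep(0.9, 19)), stringsAsFactors = FALSE)
  circ_calls <- call_de(circ, threshold_policy(), "circRNA")
  expect_identical(circ_calls$direction[1], "up")  # despite p_adj = 0.8
  expect_gt(circ_calls$p_adj[1], 0.05)
  expect_error(threshold_policy(alpha = 1.5), "alpha")
  expect_error(threshold_policy(min_fc = c(lncRNA = 0.5, circRNA = 2,
                                           miRNA = 1.5, mRNA = 2)), ">= 1")
})

test_that("merging keeps only direction-consistent intersections", {
  mk <- function(ids, dirs, cmp) data.frame(
    feature_id = ids, species = "lncRNA", comparison = cmp,
    log2fc = ifelse(dirs == "up", 2, -2),
    fold_change = ifelse(dirs == "up", 4, -4),
    p_raw = 0.001, p_adj = 0.01, direction = dirs, stringsAsFactors = FALSE)
  a <- mk(c("x", "y", "z", "w"), c("up", "up", "down", "not_de"), "AvsCtrl")
  b <- mk(c("x", "y", "z", "w"), c("up", "down", "down", "down"), "BvsCtrl")
  m <- merge_comparisons(a, b)
  expect_setequal(m$feature_id, c("x", "z"))
  expect_identical(m$direction[m$feature_id == "x"], "up")
  expect_identical(m$direction[m$feature_id == "z"], "down")
  expect_true(all(m$comparison == "merged"))
  # merged set is contained in both inputs
  de_a <- a$feature_id[a$direction != "not_de"]
  de_b <- b$feature_id[b$direction != "not_de"]
  expect_true(all(m$feature_id %in% de_a) && all(m$feature_id %in% de_b))
  expect_lte(nrow(m), min(length(de_a), length(de_b)))
  b2 <- mk("x", "up", "BvsCtrl"); b2$species <- "mRNA"
  expect_error(merge_comparisons(a, b2), "species")
})

test_that("pure-null data keeps the adjusted-call rate below alpha", {
  frac <- vapply(1:12, function(s) {
    d <- generate_dataset(null_sim_config(seed = 900L + s))
    res <- run_de_analysis(d$bundle$expression, d$bundle$conditions)
    calls <- res$calls$mRNA$AvsCtrl
    mean(calls$p_adj < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})
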