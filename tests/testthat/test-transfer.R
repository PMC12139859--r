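test_that("cluster mean z-score profiles: identities and oracle", {
  set.seed(3)
  expr <- matrix(rnorm(100 * 30), nrow = 100,
                 dimnames = list(sprintf("c%03d", 1:100),
                                 sprintf("g%02d", 1:30)))
  # one cluster containing all cells -> all-zero profile
  one <- cluster_mean_zscore(expr, rep("k1", 100))
  expect_equal(max(abs(one)), 0, tolerance = 1e-12)
  # two equal clusters, a gene expressed only in A: opposite equal values
  expr2 <- matrix(0, 40, 2, dimnames = list(paste0("c", 1:40), c("gA", "gB")))
  expr2[1:20, "gA"] <- 1
  expr2[, "gB"] <- rnorm(40)
  pr <- cluster_mean_zscore(expr2, rep(c("A", "B"), each = 20))
  expect_gt(pr["A", "gA"], 0)
  expect_equal(pr["A", "gA"], -pr["B", "gA"], tolerance = 1e-12)
  # direct two-pass re-computation oracle
  cl <- sample(c("x", "y", "z"), 100, replace = TRUE)
  got <- cluster_mean_zscore(expr, cl)
  z <- scale(expr)
  manual <- do.call(rbind, lapply(sort(unique(cl)), function(k)
    colMeans(z[cl == k, , drop = FALSE])))
  expect_equal(unname(unclass(got)), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant genes are excluded and reported
  expr3 <- cbind(expr, const = 5)
  got3 <- cluster_mean_zscore(expr3, cl)
  expect_false("const" %in% colnames(got3))
  expect_true("const" %in% attr(got3, "excluded_genes"))
})

test_that("correlation assignment: identity, scale invariance, ties", {
  set.seed(6)
  ref <- matrix(rnorm(5 * 40), nrow = 5,
                dimnames = list(paste0("r", 1:5), paste0("g", 1:40)))
  asg <- correlate_and_assign(ref, ref)
  expect_equal(asg$label, rownames(ref))
  expect_equal(asg$correlation, rep(1, 5), tolerance = 1e-12)
  # positive scaling leaves Pearson correlation unchanged
  asg2 <- correlate_and_assign(ref * 3, ref)
  expect_equal(asg2$label, rownames(ref))
  # affine transform with positive scale too
  asg3 <- correlate_and_assign(ref * 2 + 1, ref)
  expect_equal(asg3$label, rownames(ref))
  # an exact tie yields no assignment
  refdup <- rbind(ref, r6 = ref[1, ])
  tie <- correlate_and_assign(ref[1, , drop = FALSE], refdup)
  expect_true(is.na(tie$label))
  expect_error(correlate_and_assign(ref[, 1, drop = FALSE],
                                    ref[, 1, drop = FALSE]), "shared genes")
})

test_that("simulated profiles are recovered through assignment", {
  cfg <- sim_config(seed = 25, n_clusters = 20, n_profile_genes = 200,
                    noise_sd = 0.1, confusion_rate = 0)
  lp <- simulate_label_profiles(cfg)
  asg <- correlate_and_assign(lp$query, lp$reference)
  expect_equal(asg$label, unname(lp$true_map[asg$query_cluster]))
  # with planted confusion, the true (confused) map is still recovered
  cfg2 <- sim_config(seed = 26, n_clusters = 10, n_profile_genes = 300,
                     noise_sd = 0.05, confusion_rate = 0.3)
  lp2 <- simulate_label_profiles(cfg2)
  asg2 <- correlate_and_assign(lp2$query, lp2$reference)
  expect_equal(asg2$label, unname(lp2$true_map[asg2$query_cluster]))
})

test_that("label recovery stays >= 95% at noise_sd 0.2 across seeds", {
  acc <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 500 + s, n_clusters = 20,
                      n_profile_genes = 200, noise_sd = 0.2)
    lp <- simulate_label_profiles(cfg)
    asg <- correlate_and_assign(lp$query, lp$reference)
    mean(asg$label == unname(lp$true_map[asg$query_cluster]))
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("refinement gates on score > 0.85 strictly and strict majority", {
  preds <- data.frame(
    cell_id = sprintf("c%02d", 1:20),
    subcluster_id = "s1",
    predicted_label = rep(c("X", "Y"), c(18, 2)),
    score = c(rep(0.9, 18), 0.9, 0.9))
  out <- refine_subcluster_labels(preds)
  expect_equal(unique(out$assignments$label), "X")
  expect_equal(nrow(out$assignments), 20)  # every cell, low-conf included
  # cells at exactly 0.85 do not vote
  preds2 <- preds
  preds2$score <- c(rep(0.85, 18), 0.95, 0.95)  # only the two Y cells vote
  out2 <- refine_subcluster_labels(preds2)
  expect_equal(unique(out2$assignments$label), "Y")
  # 50/50 split of high-confidence labels -> removed under strict majority
  preds3 <- preds
  preds3$predicted_label <- rep(c("X", "Y"), each = 10)
  preds3$score <- 0.9
  out3 <- refine_subcluster_labels(preds3)
  expect_equal(nrow(out3$assignments), 0)
  expect_equal(out3$dropped$reason, "modal label tie")
  # no high-confidence cells -> dropped
  preds4 <- preds; preds4$score <- 0.5
  out4 <- refine_subcluster_labels(preds4)
  expect_equal(out4$dropped$reason, "no high-confidence cells")
  # cell-order invariance
  out5 <- refine_subcluster_labels(preds[sample(nrow(preds)), ])
  expect_setequal(out5$assignments$cell_id, out$assignments$cell_id)
  expect_equal(unique(out5$assignments$label), "X")
})

test_that("consistency rule is strict at more-than-80%", {
  mk <- function(n_top, n_other) data.frame(
    cell_id = seq_len(n_top + n_other), subcluster_id = "s",
    predicted_label = rep(c("A", "B"), c(n_top, n_other)))
  expect_true(consistency_assign(mk(81, 19))$assigned)
  expect_false(consistency_assign(mk(80, 20))$assigned)   # exactly 80%
  # three-way 40/35/25 split is not assigned
  p3 <- data.frame(cell_id = 1:100, subcluster_id = "s",
                   predicted_label = rep(c("A", "B", "C"), c(40, 35, 25)))
  expect_false(consistency_assign(p3)$assigned)
  expect_true(is.na(consistency_assign(p3)$label))
})
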